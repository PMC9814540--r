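#  Physics-based interaction fields between a rigid protein and atomistic
#  probes evaluated on grid nodes: electrostatics, soft van der Waals,
#  hydrophobic contacts and directional hydrogen-bond terms, plus the
#  tanh scaling, Gaussian binning and correlation-based probe selection used
#  to assemble multi-channel network inputs.

.D_CLAMP <- 0.5   # Angstrom; singular-distance clamp for 1/d style terms
.R0_HBOND <- 1.94 # Angstrom; ideal hydrogen-bond heavy-atom distance

.as_points <- function(x) {
  if (inherits(x, "grid_spec")) grid_coords(x) else matrix(as.numeric(x), ncol = 3L)
}

# distance matrix points x atoms, computed in column chunks over atoms
.dist_pa <- function(pts, axyz) {
  np <- nrow(pts)
  na <- nrow(axyz)
  d <- matrix(0, np, na)
  for (j in seq_len(na)) {
    d[, j] <- sqrt((pts[, 1] - axyz[j, 1])^2 + (pts[, 2] - axyz[j, 2])^2 +
                   (pts[, 3] - axyz[j, 3])^2)
  }
  d
}

.atom_xyz <- function(structure)
  unname(as.matrix(structure$atoms[, c("x", "y", "z")]))

#' Electrostatic field of the protein at a set of points
#'
#' `sum_i Q_i / |R_i - r_k|` in charge/Angstrom units.  Distances below 0.5
#' Angstrom are clamped to avoid the Coulomb singularity at atom centers.
#'
#' @param structure a `hydronet_structure`.
#' @param where a `grid_spec` (evaluates on every node and returns a
#'   `scalar_grid`) or an `m x 3` point matrix (returns a numeric vector).
#' @return `scalar_grid` or numeric vector of raw field values.
#' @export
electrostatic_field <- function(structure, where) {
  pts <- .as_points(where)
  d <- pmax(.dist_pa(pts, .atom_xyz(structure)), .D_CLAMP)
  v <- as.numeric((1 / d) %*% structure$atoms$charge)
  if (inherits(where, "grid_spec")) scalar_grid(where, v) else v
}

#' Soft van der Waals (steric) field
#'
#' `sum_i sqrt(eps_i eps_p) ((sigma_ip/d)^4 - (sigma_ip/d)^2)` with
#' `sigma_ip = sigma_i + sigma_p`; a soft alternative to the 12-6 potential.
#' Zero at `d = sigma_ip`, minimum `-sqrt(eps_i eps_p)/4` at
#' `d = sigma_ip * sqrt(2)`.
#'
#' @inheritParams electrostatic_field
#' @param sigma_p probe vdW radius (Angstrom), default 1.6 (water probe).
#' @param eps_p probe well depth (kcal/mol), default 0.012.
#' @export
steric_field <- function(structure, where, sigma_p = 1.6, eps_p = 0.012) {
  pts <- .as_points(where)
  a <- structure$atoms
  d <- pmax(.dist_pa(pts, .atom_xyz(structure)), .D_CLAMP)
  sip <- matrix(a$sigma + sigma_p, nrow(d), ncol(d), byrow = TRUE)
  x2 <- (sip / d)^2
  contrib <- (x2^2 - x2)
  v <- as.numeric(contrib %*% sqrt(a$epsilon * eps_p))
  if (inherits(where, "grid_spec")) scalar_grid(where, v) else v
}

#' Atom indices forming the apolar set for the hydrophobic field
#'
#' Carbons, sulfurs and hydrogens bonded to either; configurable by
#' overriding this helper's result when calling [hydrophobic_field()].
#' @param structure a `hydronet_structure`.
#' @return integer vector of atom indices.
#' @export
apolar_atoms <- function(structure) {
  a <- structure$atoms
  cs <- which(a$element %in% c("C", "S"))
  hs <- which(a$element == "H")
  h_on_cs <- hs[vapply(hs, function(i) any(structure$bonds[[i]] %in% cs), logical(1))]
  sort(c(cs, h_on_cs))
}

#' Hydrophobic contact field
#'
#' Per apolar atom a smoothstep-like cubic in
#' `s = 2 (d - sigma_ip - 2) / 3`: 1 for `s <= -1`,
#' `0.25 s^3 - 0.75 s + 0.5` for `-1 < s < 1`, 0 for `s >= 1`.
#'
#' @inheritParams steric_field
#' @param atoms indices of apolar atoms; default [apolar_atoms()].
#' @export
hydrophobic_field <- function(structure, where, sigma_p = 1.6,
                              atoms = apolar_atoms(structure)) {
  pts <- .as_points(where)
  v <- numeric(nrow(pts))
  if (length(atoms)) {
    a <- structure$atoms[atoms, , drop = FALSE]
    d <- .dist_pa(pts, as.matrix(a[, c("x", "y", "z")]))
    s <- sweep(d, 2L, a$sigma + sigma_p + 2) * (2 / 3)
    contrib <- 0.25 * s^3 - 0.75 * s + 0.5
    contrib[s <= -1] <- 1
    contrib[s >= 1] <- 0
    v <- rowSums(contrib)
  }
  if (inherits(where, "grid_spec")) scalar_grid(where, v) else v
}

#' Hydrogen-bond acceptor field
#'
#' `sum over acceptor heavy atoms of exp(-(d - R0)^2)` with `R0 = 1.94`
#' Angstrom, peaking at ideal hydrogen-bond distance from protein acceptors
#' (where a water probe could donate).
#'
#' @inheritParams electrostatic_field
#' @export
hbond_acceptor_field <- function(structure, where) {
  pts <- .as_points(where)
  acc <- which(structure$atoms$is_acceptor)
  v <- numeric(nrow(pts))
  if (length(acc)) {
    d <- .dist_pa(pts, .atom_xyz(structure)[acc, , drop = FALSE])
    v <- rowSums(exp(-(d - .R0_HBOND)^2))
  }
  if (inherits(where, "grid_spec")) scalar_grid(where, v) else v
}

#' Hydrogen-bond donor field
#'
#' Per donor hydrogen `-exp(-(d - R0)^2) * cos(alpha)` when
#' `cos(alpha) < 0`, else 0, where `d` is the donor-heavy-atom to point
#' distance and `alpha` is the angle at the hydrogen between the
#' donor-to-hydrogen and hydrogen-to-point directions (linear D-H...k gives
#' `cos(alpha) = -1`, so ideal geometry at `d = R0` scores +1).
#'
#' @inheritParams electrostatic_field
#' @export
hbond_donor_field <- function(structure, where) {
  pts <- .as_points(where)
  v <- numeric(nrow(pts))
  axyz <- .atom_xyz(structure)
  for (i in which(structure$atoms$is_donor)) {
    hs <- structure$donor_h[[i]]
    if (is.null(hs) || length(hs) == 0L) {
      warning("donor atom without hydrogens skipped")
      next
    }
    D <- axyz[i, ]
    dk <- sqrt((pts[, 1] - D[1])^2 + (pts[, 2] - D[2])^2 + (pts[, 3] - D[3])^2)
    radial <- exp(-(dk - .R0_HBOND)^2)
    for (h in hs) {
      H <- axyz[h, ]
      u <- D - H
      u <- u / sqrt(sum(u^2))                 # H -> D direction
      w1 <- pts[, 1] - H[1]; w2 <- pts[, 2] - H[2]; w3 <- pts[, 3] - H[3]
      nw <- sqrt(w1^2 + w2^2 + w3^2)
      nw[nw < 1e-12] <- 1e-12
      cosa <- (w1 * u[1] + w2 * u[2] + w3 * u[3]) / nw  # cos angle at H
      contrib <- -radial * cosa
      contrib[cosa >= 0] <- 0
      v <- v + contrib
    }
  }
  if (inherits(where, "grid_spec")) scalar_grid(where, v) else v
}

#' Scale a raw interaction field with tanh
#'
#' Electrostatics maps to [-1, 1]; the steric field has its attractive
#' (negative) part clipped at zero before squashing; all fields end in
#' [0, 1] except electrostatics.
#'
#' @param x raw field: `scalar_grid` or numeric.
#' @param kind one of "elst", "steric", "hphob", "hbond_acc", "hbond_don".
#' @return same container as `x` with scaled values.
#' @export
scale_field <- function(x, kind = c("elst", "steric", "hphob",
                                    "hbond_acc", "hbond_don")) {
  kind <- match.arg(kind)
  f <- function(v) {
    if (kind == "steric") v <- pmax(v, 0)
    tanh(v)
  }
  if (inherits(x, "scalar_grid")) scalar_grid(x$spec, f(x$values)) else f(x)
}

#' The five scaled interaction fields of the water probe on a lattice
#'
#' Convenience wrapper returning a `multi_channel_grid` with channels
#' `elst`, `steric`, `hphob`, `hbond_acc`, `hbond_don`, each tanh-scaled.
#'
#' @param structure a `hydronet_structure`.
#' @param spec a `grid_spec`.
#' @param sigma_p,eps_p water-probe parameters.
#' @export
water_probe_fields <- function(structure, spec, sigma_p = 1.6, eps_p = 0.012) {
  multi_channel_grid(spec, list(
    elst      = scale_field(electrostatic_field(structure, spec), "elst")$values,
    steric    = scale_field(steric_field(structure, spec, sigma_p, eps_p), "steric")$values,
    hphob     = scale_field(hydrophobic_field(structure, spec, sigma_p), "hphob")$values,
    hbond_acc = scale_field(hbond_acceptor_field(structure, spec), "hbond_acc")$values,
    hbond_don = scale_field(hbond_donor_field(structure, spec), "hbond_don")$values))
}

#' Gaussian soft binning of scalar values
#'
#' Each value is encoded as a vector of Gaussian bin activations
#' `exp(-(v - c_i)^2 / (2 w^2))` with bin centers
#' `c_i = min(range) + i w`, `i = 1..n_bins`, `w = diff(range)/n_bins`.
#' Values outside `range` are clipped.
#'
#' @param values numeric vector.
#' @param n_bins number of bins (default 20).
#' @param range encoding range, default `c(0, 1)` (use `c(-1, 1)` for the
#'   electrostatic channel, giving bin width 2/20).
#' @return `length(values) x n_bins` matrix (a vector input gives 1 row).
#' @export
gaussian_bin <- function(values, n_bins = 20L, range = c(0, 1)) {
  w <- diff(range) / n_bins
  centers <- range[1] + w * seq_len(n_bins)
  v <- pmin(pmax(values, range[1]), range[2])
  exp(-(outer(v, centers, "-"))^2 / (2 * w^2))
}

#' Bundled probe library
#'
#' Twelve probes spanning water-like, charged, hydrogen-bonding, hydrophobic
#' and halogen-like characters.  Each probe is a weighted combination of the
#' five interaction field types with probe-specific vdW parameters and
#' charge.  Probe names follow common MIF naming for reporting only.
#'
#' @return data.frame with columns name, sigma_p, eps_p, charge and the
#'   field weights w_elst, w_steric, w_hphob, w_acc, w_don.
#' @export
default_probe_table <- function() {
  utils::read.delim(
    system.file("extdata", "probe_table.tsv", package = "hydronet",
                mustWork = TRUE),
    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Build the multi-channel probe input grid
#'
#' One channel per probe; each channel is the weighted sum of the raw
#' interaction fields with the probe's parameters, clipped at
#' `+/- clip` kcal/mol and linearly scaled to [-1, 1].
#'
#' @param structure a `hydronet_structure`.
#' @param spec a `grid_spec`.
#' @param probes probe table (see [default_probe_table()]) or a character
#'   vector of probe names selecting rows of the default table.
#' @param clip clip level in kcal/mol (default 20).
#' @return a `multi_channel_grid` with one channel per probe.
#' @export
build_probe_channels <- function(structure, spec, probes = default_probe_table(),
                                 clip = 20) {
  if (is.character(probes)) {
    tab <- default_probe_table()
    miss <- setdiff(probes, tab$name)
    if (length(miss)) stop("unknown probe name(s): ", paste(miss, collapse = ", "))
    probes <- tab[match(probes, tab$name), , drop = FALSE]
  }
  pts <- grid_coords(spec)
  elst <- electrostatic_field(structure, pts)
  acc <- hbond_acceptor_field(structure, pts)
  don <- hbond_donor_field(structure, pts)
  channels <- list()
  for (r in seq_len(nrow(probes))) {
    p <- probes[r, ]
    e <- p$w_elst * p$charge * elst +
      p$w_steric * steric_field(structure, pts, p$sigma_p, p$eps_p) +
      p$w_hphob * hydrophobic_field(structure, pts, p$sigma_p) +
      p$w_acc * acc + p$w_don * don
    e <- pmin(pmax(e, -clip), clip) / clip
    channels[[p$name]] <- array(e, dim = spec$dims)
  }
  multi_channel_grid(spec, channels)
}

#' Correlation distance matrix between channels
#'
#' Distance between two channels is one minus the Pearson correlation of
#' their node values.
#'
#' @param channel_matrix numeric matrix, nodes in rows, channels in columns.
#' @return symmetric distance matrix.
#' @export
probe_distance_matrix <- function(channel_matrix) {
  1 - stats::cor(channel_matrix)
}

#' Select representative probes by correlation clustering
#'
#' Clusters a channel library under the distance one minus Pearson
#' correlation using k-medoids (PAM) and returns one representative (the
#' medoid) per cluster.  Deterministic for a fixed input order.
#'
#' @param channel_matrix numeric matrix, nodes x channels, with channel
#'   names as column names; concatenate nodes from several structures to
#'   stabilize the correlations.
#' @param k number of representatives (default 12).
#' @return list with `probes` (representative channel names) and
#'   `clustering` (cluster index per channel).
#' @export
select_probes <- function(channel_matrix, k = 12L) {
  if (is.null(colnames(channel_matrix)))
    colnames(channel_matrix) <- paste0("ch", seq_len(ncol(channel_matrix)))
  if (k > ncol(channel_matrix))
    stop("k exceeds the number of candidate channels")
  D <- probe_distance_matrix(channel_matrix)
  if (k == ncol(channel_matrix)) {
    return(list(probes = colnames(channel_matrix),
                clustering = seq_len(ncol(channel_matrix))))
  }
  pm <- cluster::pam(stats::as.dist(D), k = k, diss = TRUE)
  list(probes = colnames(channel_matrix)[pm$id.med],
       clustering = unname(pm$clustering))
}
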