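#  Synthetic toy binding pockets with oracle hydration grids.
#
#  The generator builds a spherical shell of parameterized pseudo-atoms
#  around an empty pocket, lines the wall with donor/acceptor/charged
#  atoms, and derives an occupancy grid that is 0 inside atoms, ~bulk
#  density (0.02) in accessible space and enhanced (up to ~0.07-0.08) near
#  favourable polar environments.  A short-range Gaussian smoothing of the
#  enhancement mimics water-water network coupling, so that neighbourhood
#  descriptors carry genuine signal beyond the point fields.  The
#  free-energy grid is a monotone decreasing map of occupancy.  Everything
#  is a deterministic function of (spec, seed).

#' Specification of a toy pocket system
#'
#' @param n_atoms total pseudo-atom count before hydrogens (default 70).
#' @param pocket_radius empty pocket radius (Angstrom, default 4).
#' @param n_donor,n_acceptor,n_charged counts of polar wall atoms (defaults
#'   6, 6, 2); the remainder is apolar carbon.
#' @param noise occupancy noise standard deviation (default 0.0015, small
#'   against the 0.02 bulk level).
#' @param seed RNG seed; generation is fully reproducible.
#' @return list of class `toy_system_spec`.
#' @export
toy_system_spec <- function(n_atoms = 70L, pocket_radius = 4.0,
                            n_donor = 6L, n_acceptor = 6L, n_charged = 2L,
                            noise = 0.0015, seed = 1L) {
  if (n_donor + n_acceptor + n_charged > n_atoms)
    stop("polar atom counts exceed n_atoms")
  structure(list(n_atoms = as.integer(n_atoms), pocket_radius = pocket_radius,
                 n_donor = as.integer(n_donor), n_acceptor = as.integer(n_acceptor),
                 n_charged = as.integer(n_charged), noise = noise,
                 seed = as.integer(seed)),
            class = "toy_system_spec")
}

# quasi-uniform points on a sphere (Fibonacci lattice)
.fib_sphere <- function(n, radius) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  radius * cbind(r * cos(phi), r * sin(phi), z)
}

.random_rotation <- function() {
  repeat {
    q <- stats::rnorm(4)
    n <- sqrt(sum(q^2))
    if (n > 1e-8) break
  }
  q <- q / n
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Generate a toy pocket structure and pseudo-ligand
#'
#' Pseudo-atoms are placed on two concentric shells around an empty
#' spherical pocket (wall at `pocket_radius + 1.7`, backing layer 2.2
#' Angstrom further out), randomly rotated and jittered per seed, with a
#' minimum interatomic separation of 2 Angstrom.  Donor nitrogens carry an
#' explicit hydrogen pointing into the pocket; acceptors are oxygens;
#' charged atoms carry +/-0.8 e.  The pseudo-ligand is a small carbon
#' cluster whose centroid sits at the pocket center (the origin).
#'
#' @param spec a `toy_system_spec`.
#' @return list with `structure` (a `hydronet_structure`), `ligand`
#'   (a `hydronet_ligand`) and `spec`.
#' @export
generate_toy_protein <- function(spec = toy_system_spec()) {
  set.seed(spec$seed)
  n1 <- ceiling(0.6 * spec$n_atoms)
  n2 <- spec$n_atoms - n1
  r1 <- spec$pocket_radius + 1.7
  r2 <- r1 + 2.2
  R <- .random_rotation()
  for (attempt in 1:20) {
    p1 <- .fib_sphere(n1, r1) %*% R
    p2 <- .fib_sphere(n2, r2) %*% .random_rotation()
    pos <- rbind(p1, p2) + matrix(stats::rnorm(3 * spec$n_atoms, sd = 0.15),
                                  ncol = 3L)
    if (min(stats::dist(pos)) >= 2.0) break
    if (attempt == 20L) stop("infeasible packing: cannot satisfy 2 A separation")
  }
  # polar atoms live on the inner wall so they line the pocket
  polar_n <- spec$n_donor + spec$n_acceptor + spec$n_charged
  if (polar_n > n1) stop("infeasible packing: polar atoms exceed wall atoms")
  polar_idx <- sample.int(n1, polar_n)
  don_idx <- polar_idx[seq_len(spec$n_donor)]
  acc_idx <- polar_idx[spec$n_donor + seq_len(spec$n_acceptor)]
  chg_idx <- polar_idx[spec$n_donor + spec$n_acceptor + seq_len(spec$n_charged)]

  n <- spec$n_atoms
  element <- rep("C", n)
  charge <- rep(0, n)
  donor <- rep(FALSE, n)
  acceptor <- rep(FALSE, n)
  element[don_idx] <- "N"; charge[don_idx] <- -0.4; donor[don_idx] <- TRUE
  element[acc_idx] <- "O"; charge[acc_idx] <- -0.55; acceptor[acc_idx] <- TRUE
  if (spec$n_charged > 0) {
    half <- seq_along(chg_idx) %% 2L == 1L
    element[chg_idx[half]] <- "O"; charge[chg_idx[half]] <- -0.8
    acceptor[chg_idx[half]] <- TRUE
    element[chg_idx[!half]] <- "N"; charge[chg_idx[!half]] <- 0.6
    donor[chg_idx[!half]] <- TRUE
  }
  atoms <- data.frame(name = paste0(element, seq_len(n)), resid = "TOY",
                      resno = seq_len(n), chain = "A",
                      x = pos[, 1], y = pos[, 2], z = pos[, 3],
                      element = element, charge = charge,
                      is_donor = donor, is_acceptor = acceptor,
                      stringsAsFactors = FALSE)
  # explicit hydrogens on donors, pointing toward the pocket center
  hrows <- lapply(which(donor), function(i) {
    u <- -pos[i, ] / sqrt(sum(pos[i, ]^2))
    hp <- pos[i, ] + u * 1.0
    data.frame(name = paste0("H", i), resid = "TOY", resno = i, chain = "A",
               x = hp[1], y = hp[2], z = hp[3], element = "H", charge = 0.35,
               is_donor = FALSE, is_acceptor = FALSE, stringsAsFactors = FALSE)
  })
  atoms <- rbind(atoms, do.call(rbind, hrows))
  st <- hydronet_structure(atoms, topology = FALSE)
  lig_xyz <- rbind(c(1.2, 0, 0), c(-1.2, 0, 0), c(0, 1.2, 0), c(0, -1.2, 0))
  list(structure = st, ligand = ligand_from_xyz(lig_xyz), spec = spec)
}

# separable Gaussian smoothing of a 3D array (sigma in node units)
.gauss_smooth3d <- function(arr, sigma_nodes) {
  if (sigma_nodes <= 0) return(arr)
  r <- max(1L, ceiling(3 * sigma_nodes))
  k <- exp(-((-r):r)^2 / (2 * sigma_nodes^2))
  k <- k / sum(k)
  d <- dim(arr)
  conv_axis <- function(a, axis) {
    a <- aperm(a, c(axis, setdiff(1:3, axis)))
    da <- dim(a)
    m <- matrix(a, nrow = da[1])
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (o in (-r):r) {
      src <- pmin(pmax(seq_len(n) + o, 1L), n)   # replicate-pad edges
      out <- out + k[o + r + 1L] * m[src, , drop = FALSE]
    }
    aperm(array(out, da), order(c(axis, setdiff(1:3, axis))))
  }
  for (axis in 1:3) arr <- conv_axis(arr, axis)
  arr
}

#' Oracle hydration grid for a toy system
#'
#' Occupancy is 0 inside atoms (steric exclusion), rises to the bulk level
#' 0.02 in accessible space and is enhanced toward ~0.07 where the
#' hydrogen-bond and electrostatic fields are favourable; the enhancement
#' is smoothed with a short-range Gaussian (water-network coupling) and
#' perturbed by seeded noise.  The free-energy grid is
#' `dG = 2.5 - 3.8 log(occ / 0.02) + noise`, clamped to [-3, 8] kcal/mol
#' (sub-bulk occupancy means water that is favourable to displace).
#'
#' @param structure a `hydronet_structure` (toy or real).
#' @param spec a `grid_spec`.
#' @param seed RNG seed for the noise.
#' @param noise occupancy noise SD (default 0.0015).
#' @param bulk bulk density (default 0.02).
#' @param enhance_max maximum enhancement above bulk (default 0.065).
#' @param smooth_sigma Gaussian smoothing width (Angstrom, default 0.6,
#'   i.e. about 1.4 Angstrom full width at half maximum).
#' @return a `hydration_grid`.
#' @export
oracle_hydration_grid <- function(structure, spec, seed = 1L, noise = 0.0015,
                                  bulk = 0.02, enhance_max = 0.065,
                                  smooth_sigma = 0.6) {
  set.seed(seed)
  pts <- grid_coords(spec)
  a <- structure$atoms
  msd <- rep(Inf, nrow(pts))
  for (i in seq_len(nrow(a))) {
    d <- sqrt((pts[, 1] - a$x[i])^2 + (pts[, 2] - a$y[i])^2 +
              (pts[, 3] - a$z[i])^2)
    msd <- pmin(msd, d - a$sigma[i])
  }
  excl <- pmin(pmax(msd / 0.4, 0), 1)
  acc <- tanh(hbond_acceptor_field(structure, pts))
  don <- tanh(hbond_donor_field(structure, pts))
  els <- abs(tanh(electrostatic_field(structure, pts)))
  affinity <- acc + don + 0.3 * els
  # soft threshold: weakly favourable regions stay at bulk, cores saturate
  enh <- pmin(pmax((affinity - 0.5) / 0.7, 0), 1) * excl
  enh <- .gauss_smooth3d(array(enh, spec$dims), smooth_sigma / spec$spacing)
  occ <- excl * bulk + enhance_max * as.vector(enh) * excl
  occ <- occ + stats::rnorm(length(occ), sd = noise) * (excl > 0)
  occ <- pmin(pmax(occ, 0), 0.085)
  dg <- 2.5 - 3.8 * log(pmax(occ, 0.002) / bulk) +
    stats::rnorm(length(occ), sd = 0.15)
  dg[occ == 0] <- 8
  dg <- pmin(pmax(dg, -3), 8)
  hydration_grid(scalar_grid(spec, occ), scalar_grid(spec, dg))
}

#' K-fold split utilities
#'
#' @param n number of systems.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return list of `k` disjoint integer vectors covering `1:n`.
#' @export
kfold_split <- function(n, k = 5L, seed = 1L) {
  if (n < k) stop("fewer systems than folds")
  set.seed(seed)
  ord <- sample.int(n)
  unname(split(ord, rep(seq_len(k), length.out = n)))
}

#' Generate a corpus of toy systems with oracle hydration data
#'
#' Every system gets its own seeded toy pocket, a cubic grid centered on
#' the pseudo-ligand, the oracle hydration grid, threshold labels and
#' (optionally) the 12-probe input channels and/or the five scaled
#' water-probe fields.
#'
#' @param n_systems number of systems (>= 2).
#' @param spec_template `toy_system_spec` whose seed is re-derived per
#'   system.
#' @param seed master seed.
#' @param extent,spacing grid geometry (defaults 11 Angstrom, 0.5
#'   Angstrom; segmentation-padded dims).
#' @param divisor dims divisor for the segmentation grid (default 8).
#' @param probes compute 12-probe channels per system.
#' @param fields compute the five scaled water-probe fields per system.
#' @param folds number of cross-validation folds (default 5).
#' @return list with `systems` (each: structure, ligand, grid, hydration,
#'   labels, optionally channels/fields) and `folds`.
#' @export
make_dataset <- function(n_systems, spec_template = toy_system_spec(),
                         seed = 1L, extent = 11, spacing = 0.5, divisor = 8L,
                         probes = FALSE, fields = TRUE, folds = 5L) {
  if (n_systems < 2L) stop("need at least 2 systems")
  set.seed(seed)
  sub <- sample.int(1e6, n_systems)
  systems <- lapply(seq_len(n_systems), function(i) {
    sp <- spec_template
    sp$seed <- sub[i]
    sys <- generate_toy_protein(sp)
    g <- binding_site_grid(c(0, 0, 0), extent, spacing, segmentation = TRUE,
                           divisor = divisor)
    hyd <- oracle_hydration_grid(sys$structure, g, seed = sub[i],
                                 noise = sp$noise)
    out <- list(structure = sys$structure, ligand = sys$ligand, grid = g,
                hydration = hyd,
                labels = occupancy_to_labels(hyd$occupancy))
    if (fields) out$fields <- water_probe_fields(sys$structure, g)
    if (probes) out$channels <- build_probe_channels(sys$structure, g)
    out
  })
  list(systems = systems,
       folds = kfold_split(n_systems, min(folds, n_systems), seed))
}

#' Sample point-wise training data from a corpus
#'
#' Draws lattice nodes from each system (interior nodes away from the grid
#' boundary), computes regression descriptors and pairs them with the
#' oracle occupancy and free energy.  Occupied nodes
#' (occupancy above [occupied_threshold()]) are used, mirroring the
#' two-stage classify-then-regress protocol.
#'
#' @param systems list of systems from [make_dataset()] (with `fields`).
#' @param n_per_system nodes sampled per system (default 150).
#' @param l_max spherical-harmonics depth (default 1).
#' @param margin boundary nodes excluded from sampling (default 4).
#' @param seed RNG seed.
#' @return list with `x` (descriptor matrix), `y` (matrix occupancy, free
#'   energy) and `system` (index per row).
#' @export
sample_pointwise_data <- function(systems, n_per_system = 150L, l_max = 1L,
                                  margin = 4L, seed = 1L) {
  set.seed(seed)
  offs <- sh_shell_offsets(systems[[1]]$grid$spacing, l_max)
  xs <- list(); ys <- list(); si <- list()
  for (i in seq_along(systems)) {
    s <- systems[[i]]
    dims <- s$grid$dims
    occ <- s$hydration$occupancy$values
    ok <- which(boundary_mask(dims, margin) & occ > occupied_threshold())
    take <- sample(ok, min(n_per_system, length(ok)))
    nodes <- arrayInd(take, dims)
    xs[[i]] <- regression_descriptor_matrix(s$fields, nodes, l_max, offs)
    ys[[i]] <- cbind(occupancy = occ[take],
                     free_energy = s$hydration$free_energy$values[take])
    si[[i]] <- rep(i, length(take))
  }
  list(x = do.call(rbind, xs), y = do.call(rbind, ys),
       system = unlist(si))
}
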