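#  Per-grid-point input vectors for the point-wise networks.
#
#  Classification descriptors encode surface-corrected distance histograms
#  (all atoms, donors, acceptors) plus a side-chain flexibility block.
#  Regression descriptors concatenate Gaussian-binned direct interaction
#  fields with rotation-invariant spherical-harmonics moments of the fields
#  on seven concentric shells of neighbouring grid points.

.DBIN_N <- 25L
.DBIN_W <- 7 / 25           # Angstrom
.DBIN_CUTOFF <- 6           # Angstrom, on surface-corrected distance
.DBIN_CENTERS <- .DBIN_W * seq_len(.DBIN_N) - 1

.SHELL_EPS <- 0.01
#' Shell intervals for the environment encoding
#'
#' Seven spherical shells `[0,1], [0.5,1.5], ..., [3,4]` Angstrom (each
#' widened by a small epsilon) around a query point; neighbouring lattice
#' nodes falling in a shell are projected on the unit sphere for the
#' spherical-harmonics expansion.
#'
#' @return data.frame with columns `lo`, `hi` (Angstrom).
#' @export
shell_spec <- function() {
  lo <- seq(0, 3, by = 0.5)
  data.frame(lo = lo, hi = lo + 1)
}

# raw (pre-tanh) Gaussian distance-bin accumulations for a set of atoms
.distance_bin_raw <- function(structure, point, atom_idx, weights = NULL) {
  acc <- numeric(.DBIN_N)
  if (length(atom_idx) == 0L) return(acc)
  a <- structure$atoms[atom_idx, , drop = FALSE]
  d <- sqrt((a$x - point[1])^2 + (a$y - point[2])^2 + (a$z - point[3])^2)
  rt <- d - a$sigma
  keep <- rt <= .DBIN_CUTOFF
  if (!any(keep)) return(acc)
  rt <- rt[keep]
  wgt <- if (is.null(weights)) rep(1, length(rt)) else weights[keep]
  g <- exp(-(outer(rt, .DBIN_CENTERS, "-"))^2 / (2 * .DBIN_W^2))
  as.numeric(crossprod(g, wgt))
}

#' Surface-corrected distance-bin vector
#'
#' Distances from the query point to atoms, reduced by each atom's vdW
#' radius, are accumulated into 25 Gaussian bins (bin width 7/25 Angstrom,
#' centers spanning up to 6 Angstrom) and squashed per bin with
#' `tanh(sum/5)`.
#'
#' @param structure a `hydronet_structure`.
#' @param point numeric length-3 (Angstrom).
#' @param atom_filter "all", "donor" or "acceptor".
#' @return numeric vector of length 25 in [0, 1).
#' @export
distance_bin_vector <- function(structure, point,
                                atom_filter = c("all", "donor", "acceptor")) {
  atom_filter <- match.arg(atom_filter)
  idx <- switch(atom_filter,
                all = seq_len(nrow(structure$atoms)),
                donor = which(structure$atoms$is_donor),
                acceptor = which(structure$atoms$is_acceptor))
  tanh(.distance_bin_raw(structure, point, idx) / 5)
}

#' Side-chain flexibility bin vector
#'
#' Side-chain atoms are weighted by `f_i = 2 tanh(t_i / 4)` where `t_i` is
#' the topological bond-count distance to the residue Calpha (backbone atoms
#' are rigid and excluded).  The weighted accumulation `q` is subtracted
#' from the unweighted all-atom accumulation `p` before the per-bin
#' `tanh(./5)` squash, so entries lie in (-1, 1).
#'
#' @inheritParams distance_bin_vector
#' @return numeric vector of length 25.
#' @export
flexibility_bin_vector <- function(structure, point) {
  p <- .distance_bin_raw(structure, point, seq_len(nrow(structure$atoms)))
  t_i <- structure$atoms$topo_dist
  side <- which(!is.na(t_i) & !structure$atoms$is_backbone)
  q <- .distance_bin_raw(structure, point, side, weights = 2 * tanh(t_i[side] / 4))
  tanh((p - q) / 5)
}

#' 100-dimensional classification descriptor
#'
#' Concatenation of the all-atom, donor-atom, acceptor-atom and flexibility
#' distance-bin vectors (4 x 25).
#'
#' @inheritParams distance_bin_vector
#' @return numeric vector of length 100.
#' @export
build_classification_descriptor <- function(structure, point) {
  c(distance_bin_vector(structure, point, "all"),
    distance_bin_vector(structure, point, "donor"),
    distance_bin_vector(structure, point, "acceptor"),
    flexibility_bin_vector(structure, point))
}

#' Real orthonormal spherical harmonics
#'
#' Evaluates the real spherical harmonics `Y_l^m` up to degree `l_max` at
#' directions given by polar angle `theta` and azimuth `phi`.  Columns are
#' ordered `(l, m)` = (0,0), (1,-1), (1,0), (1,1), (2,-2), ...
#'
#' @param theta,phi numeric vectors (radians).
#' @param l_max maximum degree.
#' @return matrix `length(theta) x (l_max+1)^2`.
#' @export
real_spherical_harmonics <- function(theta, phi, l_max) {
  n <- length(theta)
  K <- (l_max + 1L)^2
  Y <- matrix(0, n, K)
  x <- cos(theta)
  col <- 1L
  for (l in 0:l_max) {
    P <- if (l == 0L) matrix(1, 1L, n) else pracma::legendre(l, x)
    if (is.null(dim(P))) P <- matrix(P, nrow = l + 1L)
    for (m in -l:l) {
      am <- abs(m)
      nrm <- sqrt((2 * l + 1) / (4 * pi) *
                    exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      base <- nrm * P[am + 1L, ]
      Y[, col] <- if (m == 0L) base
      else if (m > 0L) sqrt(2) * base * cos(m * phi)
      else sqrt(2) * base * sin(am * phi)
      col <- col + 1L
    }
  }
  Y
}

#' Spherical-harmonics expansion of field samples on a shell
#'
#' Shell samples are projected on the unit sphere and the coefficients are
#' estimated by quadrature `a_l^m = (4 pi / N) sum_j E_j Y_l^m(dir_j)`.
#' Degrees with fewer samples than coefficients, or an empty shell, yield
#' zero coefficients with a warning.
#'
#' @param values field values at the sample points (length N).
#' @param directions `N x 3` matrix of direction vectors from the query
#'   point to the samples (need not be normalized).
#' @param l_max maximum degree (default 1).
#' @return object of class `sh_expansion`: list with `l_max` and
#'   `coefficients` (list over l of numeric vectors of length 2l+1).
#' @export
sh_expand_shell <- function(values, directions, l_max = 1L) {
  N <- length(values)
  coeffs <- lapply(0:l_max, function(l) numeric(2 * l + 1))
  if (N == 0L) {
    warning("empty shell: zero spherical-harmonics expansion")
  } else {
    directions <- matrix(as.numeric(directions), ncol = 3L)
    nr <- sqrt(rowSums(directions^2))
    nr[nr < 1e-12] <- 1e-12
    u <- directions / nr
    theta <- acos(pmin(pmax(u[, 3], -1), 1))
    phi <- atan2(u[, 2], u[, 1])
    Y <- real_spherical_harmonics(theta, phi, l_max)
    a <- (4 * pi / N) * as.numeric(crossprod(Y, values))
    col <- 1L
    for (l in 0:l_max) {
      if (N < (l + 1L)^2) {
        warning("too few shell samples for degree ", l, "; coefficients set to 0")
        col <- col + 2L * l + 1L
        next
      }
      coeffs[[l + 1L]] <- a[col:(col + 2L * l)]
      col <- col + 2L * l + 1L
    }
  }
  structure(list(l_max = as.integer(l_max), coefficients = coeffs),
            class = "sh_expansion")
}

#' Rotation-invariant moment norms of an expansion
#'
#' `a~_l = sqrt(sum_m (a_l^m)^2)`, the L2 norm of the degree-l coefficient
#' vector, one value per degree.  The L2 norm is invariant under rotations
#' of the expanded field (the coefficients transform by an orthogonal
#' Wigner matrix within each degree).
#'
#' @param expansion an `sh_expansion`.
#' @return numeric vector of length `l_max + 1`.
#' @export
sh_moments <- function(expansion) {
  vapply(expansion$coefficients, function(a) sqrt(sum(a^2)), numeric(1))
}

#' Binned moment vector of an expansion
#'
#' Per degree, `tanh(a~_l)` Gaussian-binned into 5 bins over [0, 1].
#'
#' @param expansion an `sh_expansion`.
#' @return numeric vector of length `5 (l_max + 1)`, degree-major.
#' @export
sh_moment_vector <- function(expansion) {
  m <- tanh(sh_moments(expansion))
  as.numeric(t(gaussian_bin(m, n_bins = 5L, range = c(0, 1))))
}

.field_range <- function(name) if (name == "elst") c(-1, 1) else c(0, 1)

#' Direct-interaction block of the regression descriptor
#'
#' The five scaled fields interpolated at the point, each Gaussian-binned
#' into 20 bins (bin width 2/20 for electrostatics over [-1,1], 1/20 for
#' the [0,1] channels).
#'
#' @param fields `multi_channel_grid` with the five scaled water-probe
#'   fields (see [water_probe_fields()]).
#' @param point numeric length-3.
#' @return numeric vector of length 100.
#' @export
direct_interaction_block <- function(fields, point) {
  out <- numeric(0)
  for (nm in names(fields$channels)) {
    v <- trilinear_interpolate(scalar_grid(fields$spec, fields$channels[[nm]]), point)
    out <- c(out, as.numeric(gaussian_bin(v, 20L, .field_range(nm))))
  }
  out
}

#' Full regression descriptor for one point
#'
#' Concatenates the 100-entry direct block with the environment block: for
#' each degree `l = 0..l_max`, for each of the 7 shells and each field, the
#' 5-bin moment vector (so raising `l_max` appends entries after the
#' existing ones).
#'
#' @inheritParams direct_interaction_block
#' @param l_max maximum spherical-harmonics degree (default 1).
#' @return numeric vector of length `100 + 175 (l_max + 1)`.
#' @export
build_regression_descriptor <- function(fields, point, l_max = 1L) {
  spec <- fields$spec
  co <- grid_coords(spec)
  d <- sqrt((co[, 1] - point[1])^2 + (co[, 2] - point[2])^2 +
            (co[, 3] - point[3])^2)
  sh <- shell_spec()
  nms <- names(fields$channels)
  # moments[l+1, shell, field]
  moments <- array(0, dim = c(l_max + 1L, nrow(sh), length(nms)))
  for (s in seq_len(nrow(sh))) {
    inshell <- which(d >= sh$lo[s] - .SHELL_EPS & d <= sh$hi[s] + .SHELL_EPS)
    dirs <- co[inshell, , drop = FALSE] -
      matrix(point, length(inshell), 3L, byrow = TRUE)
    for (f in seq_along(nms)) {
      vals <- fields$channels[[f]][inshell]
      ex <- sh_expand_shell(vals, dirs, l_max)
      moments[, s, f] <- sh_moments(ex)
    }
  }
  env <- numeric(0)
  for (l in 0:l_max)
    for (s in seq_len(nrow(sh)))
      for (f in seq_along(nms))
        env <- c(env, as.numeric(gaussian_bin(tanh(moments[l + 1L, s, f]),
                                              5L, c(0, 1))))
  c(direct_interaction_block(fields, point), env)
}

#' Precompute shell offsets and harmonics for lattice-node descriptors
#'
#' On a regular lattice every node sees the same pattern of neighbouring
#' nodes, so shell memberships, directions and spherical-harmonics values
#' can be computed once per grid spacing and reused for every node.
#'
#' @param spacing lattice spacing (Angstrom).
#' @param l_max maximum degree.
#' @return list of per-shell lists with integer `offsets` (n x 3) and
#'   harmonics matrix `Y` (n x (l_max+1)^2).
#' @export
sh_shell_offsets <- function(spacing, l_max = 1L) {
  sh <- shell_spec()
  rmax <- max(sh$hi) + .SHELL_EPS
  m <- as.integer(ceiling(rmax / spacing))
  g <- expand.grid(i = -m:m, j = -m:m, k = -m:m)
  d <- spacing * sqrt(g$i^2 + g$j^2 + g$k^2)
  lapply(seq_len(nrow(sh)), function(s) {
    sel <- which(d >= sh$lo[s] - .SHELL_EPS & d <= sh$hi[s] + .SHELL_EPS)
    off <- as.matrix(g[sel, , drop = FALSE])
    dd <- d[sel]
    dd[dd < 1e-12] <- 1e-12
    u <- off * spacing / dd
    theta <- acos(pmin(pmax(u[, 3], -1), 1))
    phi <- atan2(u[, 2], u[, 1])
    list(offsets = unname(off),
         Y = real_spherical_harmonics(theta, phi, l_max))
  })
}

#' Regression descriptors for a batch of lattice nodes
#'
#' Fast path of [build_regression_descriptor()] for query points that are
#' lattice nodes: shell memberships are shared offsets, and the expansion
#' for all nodes of a shell reduces to one matrix product per field.
#' Offsets reaching outside the lattice are dropped per node (the
#' quadrature normalization uses the per-node count of valid samples).
#'
#' @param fields `multi_channel_grid` of the five scaled fields.
#' @param nodes integer matrix `P x 3` of 1-based array indices.
#' @param l_max maximum degree (default 1).
#' @param offsets optional precomputed [sh_shell_offsets()].
#' @return numeric matrix `P x (100 + 175 (l_max+1))`.
#' @export
regression_descriptor_matrix <- function(fields, nodes, l_max = 1L,
                                         offsets = NULL) {
  spec <- fields$spec
  if (is.null(offsets)) offsets <- sh_shell_offsets(spec$spacing, l_max)
  nodes <- matrix(as.integer(nodes), ncol = 3L)
  P <- nrow(nodes)
  n <- spec$dims
  nms <- names(fields$channels)
  nf <- length(nms)
  K <- (l_max + 1L)^2
  lin0 <- (nodes[, 1] - 1L) + n[1] * ((nodes[, 2] - 1L) + n[2] * (nodes[, 3] - 1L))

  direct <- matrix(0, P, 20L * nf)
  for (f in seq_len(nf)) {
    v <- fields$channels[[f]][lin0 + 1L]
    direct[, (f - 1L) * 20L + 1:20] <- gaussian_bin(v, 20L, .field_range(nms[f]))
  }

  moments <- array(0, dim = c(P, l_max + 1L, length(offsets), nf))
  for (s in seq_along(offsets)) {
    off <- offsets[[s]]$offsets
    Y <- offsets[[s]]$Y
    no <- nrow(off)
    ii <- outer(nodes[, 1], off[, 1], "+")
    jj <- outer(nodes[, 2], off[, 2], "+")
    kk <- outer(nodes[, 3], off[, 3], "+")
    valid <- ii >= 1L & ii <= n[1] & jj >= 1L & jj <= n[2] & kk >= 1L & kk <= n[3]
    lin <- (ii - 1L) + n[1] * ((jj - 1L) + n[2] * (kk - 1L)) + 1L
    lin[!valid] <- 1L
    nvalid <- rowSums(valid)
    nvalid[nvalid == 0L] <- 1L
    for (f in seq_len(nf)) {
      V <- matrix(fields$channels[[f]][lin], P, no)
      V[!valid] <- 0
      A <- (4 * pi / nvalid) * (V %*% Y)     # P x K coefficient matrix
      col <- 1L
      for (l in 0:l_max) {
        moments[, l + 1L, s, f] <- sqrt(rowSums(A[, col:(col + 2L * l),
                                                  drop = FALSE]^2))
        col <- col + 2L * l + 1L
      }
    }
  }
  env <- matrix(0, P, 5L * (l_max + 1L) * length(offsets) * nf)
  colb <- 0L
  for (l in 0:l_max)
    for (s in seq_along(offsets))
      for (f in seq_len(nf)) {
        env[, colb + 1:5] <- gaussian_bin(tanh(moments[, l + 1L, s, f]),
                                          5L, c(0, 1))
        colb <- colb + 5L
      }
  cbind(direct, env)
}
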