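#' Regular 3D grid specification
#'
#' Defines an isotropic, axis-aligned lattice by its minimum corner
#' (`origin`), node spacing and node counts per axis.  Node coordinates are
#' `origin + (index - 1) * spacing` with 1-based indices; the first array
#' dimension runs along x, the second along y, the third along z.
#'
#' @param origin numeric length-3, minimum-corner coordinates (Angstrom).
#' @param spacing positive scalar node spacing (Angstrom), isotropic.
#' @param dims integer length-3 node counts, each >= 2.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(origin, spacing, dims) {
  origin <- as.numeric(origin)
  dims <- as.integer(dims)
  stopifnot(length(origin) == 3L, length(dims) == 3L)
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("grid spacing must be a positive scalar")
  if (any(dims < 2L)) stop("grid dims must each be >= 2")
  structure(list(origin = origin, spacing = as.numeric(spacing), dims = dims),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d x %d nodes, spacing %.4g A, origin (%.3f, %.3f, %.3f)\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Number of nodes in a grid
#' @param spec a `grid_spec`.
#' @return integer node count.
#' @export
grid_n_nodes <- function(spec) prod(spec$dims)

#' Cartesian coordinates of all grid nodes
#'
#' @param spec a `grid_spec`.
#' @return numeric matrix `n x 3` in the grid's storage order (x fastest).
#' @export
grid_coords <- function(spec) {
  ax <- lapply(1:3, function(a) spec$origin[a] + (seq_len(spec$dims[a]) - 1) * spec$spacing)
  n <- spec$dims
  cbind(rep(ax[[1]], times = n[2] * n[3]),
        rep(rep(ax[[2]], each = n[1]), times = n[3]),
        rep(ax[[3]], each = n[1] * n[2]))
}

#' Scalar field on a grid
#'
#' @param spec a `grid_spec`.
#' @param values numeric array with `dim == spec$dims`, or a scalar that is
#'   recycled, or a vector of length `prod(dims)` in storage order.
#' @return An object of class `scalar_grid` with elements `spec` and `values`.
#' @export
scalar_grid <- function(spec, values = 0) {
  stopifnot(inherits(spec, "grid_spec"))
  if (length(values) == 1L) values <- array(values, dim = spec$dims)
  if (is.null(dim(values))) {
    if (length(values) != grid_n_nodes(spec))
      stop("values length does not match grid dims")
    values <- array(values, dim = spec$dims)
  }
  if (!identical(as.integer(dim(values)), spec$dims))
    stop("values array shape does not match grid dims")
  structure(list(spec = spec, values = values), class = "scalar_grid")
}

#' @export
print.scalar_grid <- function(x, ...) {
  cat("scalar_grid on "); print(x$spec)
  cat(sprintf("  values in [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Multi-channel grid (stack of named scalar fields on one lattice)
#'
#' @param spec a `grid_spec`.
#' @param channels named list of numeric arrays, each with `dim == spec$dims`.
#' @return An object of class `multi_channel_grid`.
#' @export
multi_channel_grid <- function(spec, channels) {
  stopifnot(inherits(spec, "grid_spec"), is.list(channels))
  nm <- names(channels)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    stop("channels must have unique non-empty names")
  for (ch in channels)
    if (!identical(as.integer(dim(ch)), spec$dims))
      stop("all channels must share the grid dims")
  structure(list(spec = spec, channels = channels), class = "multi_channel_grid")
}

#' Occupancy + free-energy grid pair
#'
#' @param occupancy `scalar_grid` of unitless water density (>= 0).
#' @param free_energy `scalar_grid` of desolvation free energy (kcal/mol) on
#'   the same lattice.
#' @return An object of class `hydration_grid`.
#' @export
hydration_grid <- function(occupancy, free_energy) {
  stopifnot(inherits(occupancy, "scalar_grid"), inherits(free_energy, "scalar_grid"))
  if (!isTRUE(all.equal(occupancy$spec, free_energy$spec)))
    stop("occupancy and free_energy must share one grid_spec")
  if (min(occupancy$values) < 0) stop("occupancy must be non-negative")
  structure(list(occupancy = occupancy, free_energy = free_energy),
            class = "hydration_grid")
}

#' Build a cubic binding-site grid around a center
#'
#' The lattice is centered on `center` and covers at least `extent` Angstrom
#' along each axis.  In segmentation mode the node count is rounded up to a
#' multiple of `divisor` so the lattice can pass through the down-sampling
#' stages of a U-Net.
#'
#' @param center numeric length-3 (typically a ligand centroid).
#' @param extent edge length to cover (Angstrom), > 0.
#' @param spacing node spacing (Angstrom), > 0.
#' @param segmentation logical; pad dims for the segmentation model.
#' @param divisor dims divisor used in segmentation mode (default 32 = 2^5,
#'   five down-sampling stages).
#' @return a `grid_spec`.
#' @export
binding_site_grid <- function(center, extent, spacing = 0.5,
                              segmentation = FALSE, divisor = 32L) {
  center <- as.numeric(center)
  stopifnot(length(center) == 3L)
  if (extent <= 0) stop("extent must be positive")
  if (spacing <= 0) stop("spacing must be positive")
  if (segmentation) {
    n <- as.integer(divisor * ceiling(ceiling(extent / spacing) / divisor))
  } else {
    n <- as.integer(ceiling(extent / spacing) + 1L)
  }
  origin <- center - (n - 1) / 2 * spacing
  grid_spec(origin, spacing, rep(n, 3L))
}

#' Trilinear interpolation of a scalar grid
#'
#' Standard trilinear blend of the eight lattice nodes enclosing each query
#' point.  Exact for affine fields; bounded by the corner values.
#'
#' @param grid a `scalar_grid`.
#' @param points numeric length-3 vector or `m x 3` matrix (Angstrom).
#' @return numeric vector of interpolated values.
#' @export
trilinear_interpolate <- function(grid, points) {
  stopifnot(inherits(grid, "scalar_grid"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  sp <- grid$spec
  u <- sweep(points, 2L, sp$origin) / sp$spacing
  eps <- 1e-9
  lo <- -eps
  hi <- sp$dims - 1 + eps
  if (any(u[, 1] < lo | u[, 2] < lo | u[, 3] < lo |
          u[, 1] > hi[1] | u[, 2] > hi[2] | u[, 3] > hi[3]))
    stop("point outside grid bounding box")
  i0 <- pmin(pmax(floor(u), 0), matrix(sp$dims - 2, nrow(u), 3L, byrow = TRUE))
  f <- u - i0
  f <- pmin(pmax(f, 0), 1)
  n <- sp$dims
  base <- i0[, 1] + n[1] * (i0[, 2] + n[2] * i0[, 3]) + 1  # 1-based linear index
  v <- grid$values
  sx <- 1L; sy <- n[1]; sz <- n[1] * n[2]
  c000 <- v[base];                 c100 <- v[base + sx]
  c010 <- v[base + sy];            c110 <- v[base + sx + sy]
  c001 <- v[base + sz];            c101 <- v[base + sx + sz]
  c011 <- v[base + sy + sz];       c111 <- v[base + sx + sy + sz]
  fx <- f[, 1]; fy <- f[, 2]; fz <- f[, 3]
  c00 <- c000 * (1 - fx) + c100 * fx
  c10 <- c010 * (1 - fx) + c110 * fx
  c01 <- c001 * (1 - fx) + c101 * fx
  c11 <- c011 * (1 - fx) + c111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  as.numeric(c0 * (1 - fz) + c1 * fz)
}

#' Mask of grid nodes near a ligand
#'
#' Marks every node within `radius` of any ligand heavy atom.  Used to
#' restrict evaluation metrics to the region around a co-crystallized ligand.
#'
#' @param spec a `grid_spec`.
#' @param ligand a `hydronet_ligand` or an `m x 3` coordinate matrix.
#' @param radius cutoff (Angstrom), default 5.
#' @return logical array of `dim == spec$dims`.
#' @export
ligand_mask <- function(spec, ligand, radius = 5) {
  xyz <- if (inherits(ligand, "hydronet_ligand")) ligand$xyz else as.matrix(ligand)
  co <- grid_coords(spec)
  d2min <- rep(Inf, nrow(co))
  r2 <- radius^2
  for (i in seq_len(nrow(xyz))) {
    d2 <- (co[, 1] - xyz[i, 1])^2 + (co[, 2] - xyz[i, 2])^2 + (co[, 3] - xyz[i, 3])^2
    d2min <- pmin(d2min, d2)
  }
  m <- array(d2min <= r2, dim = spec$dims)
  if (!any(m)) warning("ligand mask is empty: ligand lies outside the grid region")
  m
}

#' Crop a grid to the region around a ligand
#'
#' @inheritParams ligand_mask
#' @param grid a `scalar_grid`.
#' @return list with `mask` (logical array) and `values` (numeric vector of
#'   the masked node values).
#' @export
crop_around_ligand <- function(grid, ligand, radius = 5) {
  stopifnot(inherits(grid, "scalar_grid"))
  m <- ligand_mask(grid$spec, ligand, radius)
  list(mask = m, values = grid$values[m])
}

#' Read a scalar grid from an OpenDX file
#'
#' Supports the regular-positions/regular-connections OpenDX dialect with an
#' isotropic, axis-aligned delta.  Values are stored z-fastest in the file
#' and rearranged to this package's x-fastest order.
#'
#' @param path file path.
#' @return a `scalar_grid`.
#' @export
read_dx <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  gp <- grep("class gridpositions counts", lines, value = TRUE)
  if (length(gp) != 1L) stop("malformed DX header: gridpositions line missing")
  dims <- as.integer(strsplit(trimws(sub(".*counts", "", gp)), "\\s+")[[1]])
  og <- grep("^\\s*origin", lines, value = TRUE)
  if (length(og) != 1L) stop("malformed DX header: origin line missing")
  origin <- as.numeric(strsplit(trimws(sub("origin", "", og)), "\\s+")[[1]])
  dl <- grep("^\\s*delta", lines, value = TRUE)
  if (length(dl) != 3L) stop("malformed DX header: expected 3 delta lines")
  D <- t(vapply(dl, function(s)
    as.numeric(strsplit(trimws(sub("delta", "", s)), "\\s+")[[1]]),
    numeric(3)))
  offdiag <- D; diag(offdiag) <- 0
  if (any(abs(offdiag) > 1e-12)) stop("unsupported DX grid: delta is not axis-aligned")
  h <- diag(D)
  if (max(h) - min(h) > 1e-9 * max(h))
    stop("unsupported DX grid: non-isotropic delta (spacings differ between axes)")
  istart <- grep("data follows", lines)
  if (length(istart) != 1L) stop("malformed DX file: data section missing")
  iend <- grep("attribute|class field", lines)
  iend <- iend[iend > istart]
  iend <- if (length(iend)) min(iend) - 1L else length(lines)
  vals <- as.numeric(unlist(strsplit(trimws(lines[(istart + 1L):iend]), "\\s+")))
  vals <- vals[!is.na(vals)]
  if (length(vals) != prod(dims)) stop("malformed DX file: value count mismatch")
  arr <- aperm(array(vals, dim = rev(dims)), c(3, 2, 1))  # file is z-fastest
  scalar_grid(grid_spec(origin, h[1], dims), arr)
}

#' Write a scalar grid to an OpenDX file
#'
#' @param grid a `scalar_grid`.
#' @param path output file path.
#' @param name data-set name written into the footer.
#' @return `path`, invisibly.
#' @export
write_dx <- function(grid, path, name = "hydronet grid") {
  stopifnot(inherits(grid, "scalar_grid"))
  sp <- grid$spec
  n <- sp$dims
  h <- sp$spacing
  hdr <- c(
    sprintf("object 1 class gridpositions counts %d %d %d", n[1], n[2], n[3]),
    sprintf("origin %.9g %.9g %.9g", sp$origin[1], sp$origin[2], sp$origin[3]),
    sprintf("delta %.9g 0 0", h),
    sprintf("delta 0 %.9g 0", h),
    sprintf("delta 0 0 %.9g", h),
    sprintf("object 2 class gridconnections counts %d %d %d", n[1], n[2], n[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows", prod(n)))
  vals <- as.vector(aperm(grid$values, c(3, 2, 1)))  # z-fastest on disk
  pad <- (-length(vals)) %% 3L
  body <- matrix(c(sprintf("%.9g", vals), rep("", pad)), nrow = 3L)
  body <- apply(body, 2L, paste, collapse = " ")
  ftr <- c("attribute \"dep\" string \"positions\"",
           sprintf("object \"%s\" class field", name),
           "component \"positions\" value 1",
           "component \"connections\" value 2",
           "component \"data\" value 3")
  writeLines(c(hdr, trimws(body), ftr), path)
  invisible(path)
}
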