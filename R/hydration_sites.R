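#  Conversion of occupancy grids into discrete hydration sites (quality
#  threshold clustering with standard-parameter defaults; an
#  occupancy-weighted DBSCAN variant) and comparison against reference
#  (crystallographic) water positions.

.site_summary <- function(coords, occ, members, dg = NULL) {
  w <- occ / sum(occ)
  center <- colSums(coords * w)
  data.frame(x = center[1], y = center[2], z = center[3],
             n_points = length(members),
             occupancy = mean(occ),
             free_energy = if (is.null(dg)) NA_real_ else mean(dg))
}

.collect_sites <- function(occupancy, member_sets, free_energy) {
  spec <- occupancy$spec
  co <- grid_coords(spec)
  ov <- as.vector(occupancy$values)
  dgv <- if (is.null(free_energy)) NULL else as.vector(free_energy$values)
  if (length(member_sets) == 0L) {
    out <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      n_points = integer(0), occupancy = numeric(0),
                      free_energy = numeric(0))
    attr(out, "members") <- list()
    class(out) <- c("hydration_sites", "data.frame")
    return(out)
  }
  rows <- lapply(member_sets, function(m)
    .site_summary(co[m, , drop = FALSE], ov[m], m,
                  if (is.null(dgv)) NULL else dgv[m]))
  out <- do.call(rbind, rows)
  # strongest site first
  ord <- order(-vapply(member_sets, function(m) sum(ov[m]), numeric(1)))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "members") <- member_sets[ord]
  class(out) <- c("hydration_sites", "data.frame")
  out
}

#' Quality-threshold clustering of an occupancy grid
#'
#' Candidate nodes (occupancy above `occ_min`) are clustered by the QT
#' algorithm: the largest cluster whose pairwise diameter stays within
#' `diameter` is extracted repeatedly; clusters smaller than `min_points`
#' are discarded.  Ties are broken by the higher summed occupancy, then
#' the lower node index, making the procedure deterministic and invariant
#' to node enumeration order.  Defaults follow the standard protocol:
#' diameter 1.9 Angstrom, at least 5 grid points.
#'
#' @param occupancy a `scalar_grid`.
#' @param occ_min candidate threshold (default 0.02, approximately bulk).
#' @param diameter maximum cluster diameter (Angstrom).
#' @param min_points minimum cluster size.
#' @param free_energy optional `scalar_grid` for per-site mean free energy.
#' @return `hydration_sites` data.frame (center, size, mean occupancy,
#'   mean free energy) with member node indices as attribute `members`.
#' @export
cluster_qt <- function(occupancy, occ_min = 0.02, diameter = 1.9,
                       min_points = 5L, free_energy = NULL) {
  stopifnot(inherits(occupancy, "scalar_grid"))
  if (occ_min <= 0) stop("occ_min must be positive")
  ov <- as.vector(occupancy$values)
  cand <- which(ov > occ_min)
  if (length(cand) == 0L) return(.collect_sites(occupancy, list(), free_energy))
  co <- grid_coords(occupancy$spec)[cand, , drop = FALSE]
  occ <- ov[cand]
  remaining <- seq_along(cand)
  member_sets <- list()
  while (length(remaining) >= min_points) {
    best <- NULL
    for (s in remaining) {
      d2s <- (co[remaining, 1] - co[s, 1])^2 + (co[remaining, 2] - co[s, 2])^2 +
             (co[remaining, 3] - co[s, 3])^2
      nb <- remaining[d2s <= diameter^2]
      if (length(nb) < 2L) { cl <- s }
      else {
        # greedy growth minimizing the running diameter
        dm <- as.matrix(stats::dist(co[nb, , drop = FALSE]))
        si <- match(s, nb)
        inset <- si
        maxd <- dm[si, ]
        repeat {
          elig <- setdiff(which(maxd <= diameter), inset)
          if (length(elig) == 0L) break
          pick <- elig[order(maxd[elig], elig)][1]
          inset <- c(inset, pick)
          maxd <- pmax(maxd, dm[pick, ])
        }
        cl <- nb[sort(inset)]
      }
      score <- c(length(cl), sum(occ[cl]), -min(cand[cl]))
      if (is.null(best) || score[1] > best$score[1] ||
          (score[1] == best$score[1] && score[2] > best$score[2]) ||
          (score[1] == best$score[1] && score[2] == best$score[2] &&
           score[3] > best$score[3])) {
        best <- list(cl = cl, score = score)
      }
    }
    if (length(best$cl) < min_points) break
    member_sets[[length(member_sets) + 1L]] <- cand[best$cl]
    remaining <- setdiff(remaining, best$cl)
  }
  .collect_sites(occupancy, member_sets, free_energy)
}

#' Occupancy-weighted DBSCAN clustering of an occupancy grid
#'
#' Density-based variant: candidate nodes are clustered with DBSCAN where a
#' node is a core point when the summed occupancy of its eps-neighbourhood
#' (in units of bulk density 0.02) reaches `min_samples`.  Site summaries
#' are computed as in [cluster_qt()].
#'
#' @inheritParams cluster_qt
#' @param eps neighbourhood radius (Angstrom, default 1.0).
#' @param min_samples minimum bulk-equivalent neighbourhood weight.
#' @export
cluster_dbscan <- function(occupancy, occ_min = 0.02, eps = 1.0,
                           min_samples = 5L, free_energy = NULL) {
  stopifnot(inherits(occupancy, "scalar_grid"))
  if (occ_min <= 0) stop("occ_min must be positive")
  ov <- as.vector(occupancy$values)
  cand <- which(ov > occ_min)
  if (length(cand) == 0L) return(.collect_sites(occupancy, list(), free_energy))
  co <- grid_coords(occupancy$spec)[cand, , drop = FALSE]
  w <- ov[cand] / 0.02
  n <- length(cand)
  dm <- as.matrix(stats::dist(co))
  nb <- lapply(seq_len(n), function(i) which(dm[i, ] <= eps))
  core <- vapply(seq_len(n), function(i) sum(w[nb[[i]]]) >= min_samples, logical(1))
  labels <- integer(n)   # 0 = unvisited/noise
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    frontier <- i
    labels[i] <- cl
    while (length(frontier)) {
      nxt <- integer(0)
      for (j in frontier) {
        for (q in nb[[j]]) {
          if (labels[q] == 0L) {
            labels[q] <- cl
            if (core[q]) nxt <- c(nxt, q)
          }
        }
      }
      frontier <- nxt
    }
  }
  member_sets <- lapply(seq_len(cl), function(k) cand[labels == k])
  member_sets <- Filter(function(m) length(m) > 0L, member_sets)
  .collect_sites(occupancy, member_sets, free_energy)
}

#' Match predicted hydration sites against X-ray water positions
#'
#' Retains reference waters lying within 5 Angstrom of any ligand atom and
#' of any protein atom, then bins each retained water by the distance to
#' its nearest predicted site: <= 1.0, <= 1.5, <= 2.0 Angstrom, or
#' "not detected" beyond 2 Angstrom.
#'
#' @param sites `hydration_sites` (or a matrix of site centers).
#' @param waters `m x 3` matrix of water oxygen coordinates.
#' @param ligand a `hydronet_ligand` or coordinate matrix.
#' @param protein a `hydronet_structure` or coordinate matrix.
#' @param retain_radius water retention cutoff (default 5 Angstrom).
#' @return data.frame with water coordinates, nearest-site distance and
#'   bin label ("<=1.0", "<=1.5", "<=2.0", "not detected").
#' @export
match_xray_waters <- function(sites, waters, ligand, protein,
                              retain_radius = 5) {
  waters <- matrix(as.numeric(waters), ncol = 3L)
  lxyz <- if (inherits(ligand, "hydronet_ligand")) ligand$xyz else as.matrix(ligand)
  pxyz <- if (inherits(protein, "hydronet_structure"))
    as.matrix(protein$atoms[, c("x", "y", "z")]) else as.matrix(protein)
  centers <- if (is.data.frame(sites)) as.matrix(sites[, c("x", "y", "z")])
             else matrix(as.numeric(sites), ncol = 3L)
  mind <- function(pts, ref) {
    vapply(seq_len(nrow(pts)), function(i)
      sqrt(min((ref[, 1] - pts[i, 1])^2 + (ref[, 2] - pts[i, 2])^2 +
               (ref[, 3] - pts[i, 3])^2)), numeric(1))
  }
  keep <- mind(waters, lxyz) <= retain_radius & mind(waters, pxyz) <= retain_radius
  waters <- waters[keep, , drop = FALSE]
  if (nrow(waters) == 0L) {
    warning("no reference waters within the retention radius")
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      distance = numeric(0), bin = character(0)))
  }
  d <- if (nrow(centers)) mind(waters, centers) else rep(Inf, nrow(waters))
  bin <- cut(d, breaks = c(-Inf, 1.0, 1.5, 2.0, Inf),
             labels = c("<=1.0", "<=1.5", "<=2.0", "not detected"))
  data.frame(x = waters[, 1], y = waters[, 2], z = waters[, 3],
             distance = d, bin = as.character(bin))
}

#' Write hydration sites as PDB pseudo-waters
#'
#' Sites are written as HETATM oxygen records with the mean occupancy in
#' the occupancy column and the mean free energy in the B-factor column.
#'
#' @param sites a `hydration_sites` data.frame.
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
write_sites_pdb <- function(sites, path) {
  lines <- vapply(seq_len(nrow(sites)), function(i) {
    sprintf("HETATM%5d  O   HOH A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           O",
            i, i, sites$x[i], sites$y[i], sites$z[i],
            min(sites$occupancy[i] * 10, 9.99),
            if (is.na(sites$free_energy[i])) 0 else sites$free_energy[i])
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}
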