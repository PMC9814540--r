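#  Ligand desolvation scoring from a predicted free-energy grid and linear
#  regression against experimental binding free energies.

#' Per-ligand desolvation free energy from a grid
#'
#' For each ligand heavy atom the desolvation free energy is read from the
#' grid by trilinear interpolation over the eight enclosing nodes; the
#' atomic contributions are summed.  Atoms outside the grid contribute 0
#' and are counted (substituents of a congeneric series may poke past the
#' box edge).  Hydrogens are excluded.
#'
#' @param free_energy a `scalar_grid` of desolvation free energies
#'   (kcal/mol).
#' @param ligand a `hydronet_ligand` (or `m x 3` heavy-atom coordinates).
#' @return object of class `desolvation_score`: list with `per_atom`
#'   contributions, `total` and `n_outside`.
#' @export
ligand_desolvation <- function(free_energy, ligand) {
  stopifnot(inherits(free_energy, "scalar_grid"))
  xyz <- if (inherits(ligand, "hydronet_ligand")) ligand$xyz
         else matrix(as.numeric(ligand), ncol = 3L)
  sp <- free_energy$spec
  hi <- sp$origin + (sp$dims - 1) * sp$spacing
  inside <- xyz[, 1] >= sp$origin[1] & xyz[, 1] <= hi[1] &
            xyz[, 2] >= sp$origin[2] & xyz[, 2] <= hi[2] &
            xyz[, 3] >= sp$origin[3] & xyz[, 3] <= hi[3]
  if (!any(inside)) stop("all ligand atoms lie outside the free-energy grid")
  per_atom <- numeric(nrow(xyz))
  per_atom[inside] <- trilinear_interpolate(free_energy,
                                            xyz[inside, , drop = FALSE])
  structure(list(per_atom = per_atom, total = sum(per_atom),
                 n_outside = sum(!inside)),
            class = "desolvation_score")
}

#' @export
print.desolvation_score <- function(x, ...) {
  cat(sprintf("desolvation score: %.3f kcal/mol over %d atoms (%d outside grid)\n",
              x$total, length(x$per_atom), x$n_outside))
  invisible(x)
}

#' Linear regression of binding affinity on desolvation scores
#'
#' Ordinary least squares of experimental binding free energies on
#' per-ligand desolvation totals.
#'
#' @param scores numeric vector of desolvation totals (kcal/mol), or a list
#'   of `desolvation_score` objects.
#' @param experimental_dg numeric vector of experimental binding free
#'   energies (kcal/mol), same length.
#' @return list with `slope`, `intercept`, `r_squared` and the underlying
#'   `lm` fit.
#' @export
regress_affinity <- function(scores, experimental_dg) {
  if (is.list(scores)) scores <- vapply(scores, `[[`, numeric(1), "total")
  if (length(scores) < 3L) stop("need at least 3 ligands for regression")
  if (length(scores) != length(experimental_dg))
    stop("scores and affinities differ in length")
  if (stats::sd(scores) < 1e-12) stop("zero variance in desolvation scores")
  fit <- stats::lm(experimental_dg ~ scores)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared,
       fit = fit)
}

#' Convert inhibition constants to binding free energies
#'
#' `dG = RT ln(Ki)` with Ki in molar units, RT = 0.593 kcal/mol (298 K).
#'
#' @param ki numeric vector of Ki or IC50 values in molar units.
#' @return binding free energies (kcal/mol, negative for binders).
#' @export
ki_to_dg <- function(ki) 0.593 * log(ki)
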