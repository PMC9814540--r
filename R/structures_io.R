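#  Protein / ligand structure input, parameter assignment and topology.
#
#  A structure is a plain list: `atoms` (one data.frame row per atom with
#  coordinates, an Amber-type charge/vdW parameterization, donor/acceptor
#  annotation and the topological distance to the residue Calpha) and
#  `bonds` (adjacency list over atom indices).  PDB parsing is delegated to
#  bio3d; the parameter and donor/acceptor template tables are packaged TSVs.

.covalent_radii <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05,
                     P = 1.07, F = 0.57, CL = 1.02, BR = 1.20, I = 1.39)

.backbone_names <- c("N", "CA", "C", "O", "OXT", "H", "HN", "H1", "H2", "H3",
                     "HA", "HA2", "HA3")

#' Bundled Amber-type atom parameter table
#'
#' Per-(residue, atom-name) partial charges for backbone and polar side-chain
#' atoms (residue `*` = any residue), with element-based van der Waals
#' radius/well-depth and fallback charges for atoms not listed.  The values
#' are an Amber-type approximation packaged with hydronet, not a verbatim
#' force-field export.
#'
#' @return list with data.frames `atoms` (resid, atom, charge) and
#'   `elements` (element, sigma, epsilon, charge).
#' @export
default_parameter_table <- function() {
  read1 <- function(f) utils::read.delim(
    system.file("extdata", f, package = "hydronet", mustWork = TRUE),
    stringsAsFactors = FALSE)
  list(atoms = read1("atom_params.tsv"), elements = read1("element_params.tsv"))
}

#' Bundled donor/acceptor residue template table
#'
#' Fixed per-(residue, atom-name) hydrogen-bond donor/acceptor assignment
#' (residue `*` = any residue; an explicit residue row overrides the
#' wildcard, e.g. proline backbone N is not a donor).
#'
#' @return data.frame with columns resid, atom, donor, acceptor.
#' @export
default_donor_acceptor_table <- function() {
  utils::read.delim(
    system.file("extdata", "donor_acceptor.tsv", package = "hydronet",
                mustWork = TRUE),
    stringsAsFactors = FALSE)
}

.guess_element <- function(name, elesy = NULL) {
  if (!is.null(elesy) && !is.na(elesy) && nzchar(trimws(elesy)))
    return(toupper(trimws(elesy)))
  nm <- gsub("[0-9']", "", toupper(trimws(name)))
  if (nm %in% c("CL", "BR", "SE")) return(nm)
  # PDB hydrogen names may start with a digit handled above; first letter rules
  substr(nm, 1L, 1L)
}

#' Construct a parameterized structure from an atom table
#'
#' Low-level constructor shared by [load_structure()] and the synthetic-data
#' generator.  Infers covalent bonds from interatomic distances, assigns
#' missing parameters from `params`, sets donor/acceptor flags from the
#' template table (a donor is only retained if it has at least one bonded
#' hydrogen) and fills topological distances to the residue Calpha.
#'
#' @param atoms data.frame with at least columns `name`, `resid`, `resno`,
#'   `x`, `y`, `z`; optional `element`, `charge`, `sigma`, `epsilon`,
#'   `chain`, `is_donor`, `is_acceptor`.
#' @param params parameter table as returned by [default_parameter_table()].
#' @param da_table donor/acceptor template table.
#' @param topology logical, compute per-residue topological distances
#'   (requires Calpha atoms; synthetic pseudo-proteins set this FALSE).
#' @return object of class `hydronet_structure`.
#' @export
hydronet_structure <- function(atoms, params = default_parameter_table(),
                               da_table = default_donor_acceptor_table(),
                               topology = TRUE) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  n <- nrow(atoms)
  if (n == 0L) stop("structure has no atoms")
  if (is.null(atoms$chain)) atoms$chain <- "A"
  if (is.null(atoms$element))
    atoms$element <- vapply(atoms$name, .guess_element, character(1))
  atoms$element <- toupper(atoms$element)

  el <- params$elements
  ie <- match(atoms$element, el$element)
  if (anyNA(ie)) {
    bad <- unique(atoms$element[is.na(ie)])
    stop("parameterization error: no parameters for element(s) ",
         paste(bad, collapse = ", "))
  }
  if (is.null(atoms$sigma)) atoms$sigma <- el$sigma[ie]
  if (is.null(atoms$epsilon)) atoms$epsilon <- el$epsilon[ie]
  if (is.null(atoms$charge)) {
    key <- paste(atoms$resid, atoms$name)
    tab <- params$atoms
    q <- tab$charge[match(key, paste(tab$resid, tab$atom))]
    # wildcard rows fill in where no residue-specific row matched
    wtab <- tab[tab$resid == "*", ]
    qw <- wtab$charge[match(atoms$name, wtab$atom)]
    q[is.na(q)] <- qw[is.na(q)]
    q[is.na(q)] <- el$charge[ie][is.na(q)]
    atoms$charge <- q
  }
  if (any(atoms$sigma <= 0) || any(atoms$epsilon < 0))
    stop("parameterization error: invalid sigma/epsilon")

  atoms$is_backbone <- atoms$name %in% .backbone_names
  bonds <- infer_bonds(as.matrix(atoms[, c("x", "y", "z")]), atoms$element)

  if (is.null(atoms$is_donor) || is.null(atoms$is_acceptor)) {
    da <- da_table
    key <- paste(atoms$resid, atoms$name)
    i1 <- match(key, paste(da$resid, da$atom))
    wda <- da[da$resid == "*", ]
    iw <- match(atoms$name, wda$atom)
    don <- ifelse(!is.na(i1), da$donor[i1] == 1,
                  !is.na(iw) & wda$donor[iw] == 1)
    acc <- ifelse(!is.na(i1), da$acceptor[i1] == 1,
                  !is.na(iw) & wda$acceptor[iw] == 1)
    atoms$is_donor <- don
    atoms$is_acceptor <- acc
  }
  atoms$is_donor <- as.logical(atoms$is_donor)
  atoms$is_acceptor <- as.logical(atoms$is_acceptor)

  # donors require at least one bonded hydrogen
  donor_h <- vector("list", n)
  isH <- atoms$element == "H"
  for (i in which(atoms$is_donor)) {
    hs <- bonds[[i]][isH[bonds[[i]]]]
    if (length(hs) == 0L) {
      warning("donor atom ", atoms$name[i], " (", atoms$resid[i], atoms$resno[i],
              ") has no bonded hydrogen; donor flag dropped")
      atoms$is_donor[i] <- FALSE
    } else donor_h[[i]] <- hs
  }

  st <- structure(list(atoms = atoms, bonds = bonds, donor_h = donor_h),
                  class = "hydronet_structure")
  if (topology) st <- topological_distances(st) else st$atoms$topo_dist <- NA_integer_
  st
}

#' @export
print.hydronet_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("hydronet_structure: %d atoms, %d residues, %d donors, %d acceptors\n",
              nrow(a), length(unique(paste(a$chain, a$resno))),
              sum(a$is_donor), sum(a$is_acceptor)))
  invisible(x)
}

#' Infer covalent bonds from interatomic distances
#'
#' Two atoms are bonded when their distance is below the sum of covalent
#' radii plus 0.45 Angstrom tolerance.  PDB CONECT records are unreliable,
#' so bonds are always derived geometrically.
#'
#' @param xyz `n x 3` coordinate matrix (Angstrom).
#' @param elements character vector of element symbols.
#' @return adjacency list: integer vector of neighbours per atom.
#' @export
infer_bonds <- function(xyz, elements) {
  n <- nrow(xyz)
  r <- .covalent_radii[toupper(elements)]
  r[is.na(r)] <- 0.76
  adj <- vector("list", n)
  # chunked O(n^2) distance evaluation
  chunk <- max(1L, floor(4e6 / n))
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(n, s + chunk - 1L)
    d2 <- outer(xyz[idx, 1], xyz[, 1], "-")^2 +
          outer(xyz[idx, 2], xyz[, 2], "-")^2 +
          outer(xyz[idx, 3], xyz[, 3], "-")^2
    cut2 <- outer(r[idx], r, "+") + 0.45
    cut2 <- cut2^2
    hit <- d2 < cut2 & d2 > 1e-6
    for (k in seq_along(idx)) adj[[idx[k]]] <- which(hit[k, ])
  }
  adj
}

#' Topological distance of side-chain atoms to the residue Calpha
#'
#' Breadth-first search over the covalent bond graph, restricted to each
#' residue's atoms.  The Calpha itself has distance 0; backbone atoms are
#' treated as rigid and carry `NA`.
#'
#' @param structure a `hydronet_structure` with bonds built.
#' @return the structure with `atoms$topo_dist` filled.
#' @export
topological_distances <- function(structure) {
  a <- structure$atoms
  t_i <- rep(NA_integer_, nrow(a))
  resk <- paste(a$chain, a$resno)
  for (rk in unique(resk)) {
    idx <- which(resk == rk)
    ca <- idx[a$name[idx] == "CA"]
    if (length(ca) == 0L) next
    ca <- ca[1]
    # BFS within the residue
    dist <- rep(NA_integer_, nrow(a))
    dist[ca] <- 0L
    frontier <- ca
    while (length(frontier)) {
      nxt <- integer(0)
      for (i in frontier) {
        nb <- structure$bonds[[i]]
        nb <- nb[nb %in% idx & is.na(dist[nb])]
        dist[nb] <- dist[i] + 1L
        nxt <- c(nxt, nb)
      }
      frontier <- nxt
    }
    side <- idx[!a$is_backbone[idx] | a$name[idx] == "CA"]
    if (any(is.na(dist[setdiff(side, ca)])))
      stop("topology error: side-chain atom disconnected from Calpha in residue ",
           a$resid[ca], a$resno[ca])
    t_i[side] <- dist[side]
  }
  structure$atoms$topo_dist <- t_i
  structure
}

#' Load and parameterize a protein structure from a PDB file
#'
#' Waters, ions and other heteroatoms are removed; only ATOM records with
#' alternate location "" or "A" are retained.  Hydrogens are assumed to be
#' present in the input (no protonation-state prediction is performed).
#' Every atom receives a partial charge, vdW radius and well depth from the
#' bundled parameter table, and donor/acceptor flags from the residue
#' template table.
#'
#' @param pdb_path path to a PDB file.
#' @param params parameter table, see [default_parameter_table()].
#' @return a `hydronet_structure`.
#' @export
load_structure <- function(pdb_path, params = default_parameter_table()) {
  pdb <- tryCatch(bio3d::read.pdb(pdb_path, verbose = FALSE),
                  error = function(e) stop("format error: cannot parse PDB file '",
                                           pdb_path, "': ", conditionMessage(e)))
  at <- pdb$atom
  keep <- at$type == "ATOM" &
    !(at$resid %in% c("HOH", "WAT", "DOD", "NA", "CL", "K", "MG", "CA2", "ZN",
                      "MN", "FE", "SO4", "PO4")) &
    (is.na(at$alt) | at$alt %in% c("", "A"))
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0L) stop("format error: no protein ATOM records in ", pdb_path)
  atoms <- data.frame(
    name = at$elety, resid = at$resid, resno = at$resno,
    chain = ifelse(is.na(at$chain), "A", at$chain),
    x = at$x, y = at$y, z = at$z,
    element = mapply(.guess_element, at$elety, at$elesy),
    stringsAsFactors = FALSE)
  hydronet_structure(atoms, params = params)
}

#' Write a cleaned, parameterized structure back to PDB
#'
#' @param structure a `hydronet_structure`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  a <- structure$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(a)),
                   resno = a$resno, resid = a$resid, eleno = seq_len(nrow(a)),
                   elety = a$name, chain = a$chain,
                   elesy = a$element)
  invisible(path)
}

#' Load a ligand from MOL2 or SDF
#'
#' @param path ligand file; format chosen by extension (`.mol2` via bio3d,
#'   `.sdf`/`.mol` via ChemmineR).
#' @return object of class `hydronet_ligand`: `xyz` (heavy-atom coordinate
#'   matrix), `elements`, `centroid` (mean heavy-atom position).
#' @export
load_ligand <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "mol2") {
    m <- bio3d::read.mol2(path)
    at <- m$atom
    xyz <- cbind(at$x, at$y, at$z)
    elements <- toupper(sub("\\..*$", "", at$elena))
    elements <- vapply(elements, .guess_element, character(1))
  } else if (ext %in% c("sdf", "mol")) {
    if (!requireNamespace("ChemmineR", quietly = TRUE))
      stop("reading SDF requires the ChemmineR package")
    sdf <- ChemmineR::read.SDFset(path)
    ab <- ChemmineR::atomblock(sdf[[1]])
    xyz <- unname(ab[, 1:3, drop = FALSE])
    elements <- toupper(gsub("_.*$", "", rownames(ab)))
  } else stop("format error: unsupported ligand format '", ext, "'")
  ligand_from_xyz(xyz, elements)
}

#' Build a ligand object from raw coordinates
#'
#' @param xyz `m x 3` coordinate matrix.
#' @param elements element symbols, length `m`.
#' @return a `hydronet_ligand` (heavy atoms only; centroid over heavy atoms).
#' @export
ligand_from_xyz <- function(xyz, elements = rep("C", nrow(xyz))) {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  if (nrow(xyz) == 0L) stop("empty molecule")
  heavy <- toupper(elements) != "H"
  if (!any(heavy)) stop("empty molecule: no heavy atoms")
  xyz <- xyz[heavy, , drop = FALSE]
  structure(list(xyz = xyz, elements = toupper(elements[heavy]),
                 centroid = colMeans(xyz)),
            class = "hydronet_ligand")
}

#' @export
print.hydronet_ligand <- function(x, ...) {
  cat(sprintf("hydronet_ligand: %d heavy atoms, centroid (%.3f, %.3f, %.3f)\n",
              nrow(x$xyz), x$centroid[1], x$centroid[2], x$centroid[3]))
  invisible(x)
}
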