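# Shared fixtures: a small tripeptide PDB written at test time, minimal
# ligand files, single-atom structures for analytic field checks, and a
# memoized synthetic corpus reused by the heavier tests.

# idealized (non-physical but bond-consistent) ALA-SER-LYS tripeptide plus
# one crystallographic water; residue i is translated by (i-1)*3.8 A in x
tripeptide_atoms <- function() {
  res <- function(i, resid, extra) {
    off <- c((i - 1) * 3.8, 0, 0)
    base <- list(
      c("N",  0.00,  0.00, 0), c("H", -0.94, -0.34, 0),
      c("CA", 1.46,  0.00, 0), c("C",  2.20,  1.20, 0),
      c("O",  1.70,  2.30, 0))
    rows <- lapply(c(base, extra), function(a)
      data.frame(name = a[1], resid = resid, resno = i,
                 x = as.numeric(a[2]) + off[1], y = as.numeric(a[3]) + off[2],
                 z = as.numeric(a[4]) + off[3], stringsAsFactors = FALSE))
    do.call(rbind, rows)
  }
  ala <- res(1, "ALA", list(c("CB", 1.46, -1.53, 0)))
  ser <- res(2, "SER", list(c("CB", 1.46, -1.53, 0),
                            c("OG", 1.46, -2.95, 0),
                            c("HG", 2.26, -3.48, 0)))
  lys <- res(3, "LYS", list(c("CB", 1.46, -1.53, 0),
                            c("CG", 1.46, -3.05, 0),
                            c("CD", 1.46, -4.57, 0),
                            c("CE", 1.46, -6.09, 0),
                            c("NZ", 1.46, -7.56, 0),
                            c("HZ1", 2.26, -8.16, 0),
                            c("HZ2", 0.66, -8.16, 0)))
  rbind(ala, ser, lys)
}

write_test_pdb <- function(path = tempfile(fileext = ".pdb"),
                           with_water = TRUE) {
  at <- tripeptide_atoms()
  lines <- vapply(seq_len(nrow(at)), function(i) {
    el <- substr(gsub("[0-9]", "", at$name[i]), 1, 1)
    sprintf("ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, at$name[i], at$resid[i], "A", at$resno[i],
            at$x[i], at$y[i], at$z[i], 1.0, 0.0, el)
  }, character(1))
  if (with_water)
    lines <- c(lines,
               sprintf("HETATM%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                       nrow(at) + 1L, "O", "HOH", "A", 99L, 10, 10, 10, 1.0, 0.0, "O"))
  writeLines(c(lines, "END"), path)
  path
}

write_benzene_mol2 <- function(path = tempfile(fileext = ".mol2")) {
  r <- 1.39
  ang <- (0:5) * pi / 3
  xy <- cbind(2 + r * cos(ang), 1 + r * sin(ang), 0.5)
  atoms <- vapply(1:6, function(i)
    sprintf("%7d C%d %9.4f %9.4f %9.4f C.ar 1 BNZ 0.0000",
            i, i, xy[i, 1], xy[i, 2], xy[i, 3]), character(1))
  bonds <- vapply(1:6, function(i)
    sprintf("%6d %4d %4d ar", i, i, i %% 6 + 1), character(1))
  writeLines(c("@<TRIPOS>MOLECULE", "benzene", "  6 6 0 0 0",
               "SMALL", "NO_CHARGES", "", "@<TRIPOS>ATOM", atoms,
               "@<TRIPOS>BOND", bonds), path)
  path
}

# structure with a single parameterized pseudo-atom
single_atom_structure <- function(element = "O", charge = 0,
                                  donor = FALSE, acceptor = FALSE,
                                  pos = c(0, 0, 0)) {
  hydronet_structure(
    data.frame(name = paste0(element, 1), resid = "TOY", resno = 1,
               x = pos[1], y = pos[2], z = pos[3], element = element,
               charge = charge, is_donor = donor, is_acceptor = acceptor,
               stringsAsFactors = FALSE),
    topology = FALSE)
}

# donor heavy atom at the origin with its hydrogen at (1, 0, 0)
donor_structure <- function() {
  hydronet_structure(
    rbind(data.frame(name = "N1", resid = "TOY", resno = 1, x = 0, y = 0, z = 0,
                     element = "N", charge = 0, is_donor = TRUE,
                     is_acceptor = FALSE, stringsAsFactors = FALSE),
          data.frame(name = "H1", resid = "TOY", resno = 1, x = 1, y = 0, z = 0,
                     element = "H", charge = 0.3, is_donor = FALSE,
                     is_acceptor = FALSE, stringsAsFactors = FALSE)),
    topology = FALSE)
}

# uniform Fibonacci directions on the unit sphere (dense, quasi-uniform)
fib_directions <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(r * cos(phi), r * sin(phi), z)
}

random_rotation_matrix <- function() {
  repeat {
    q <- stats::rnorm(4)
    nq <- sqrt(sum(q^2))
    if (nq > 1e-8) break
  }
  q <- q / nq
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# memoized corpora shared across test files (built once per test run)
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

small_field_corpus <- function() {
  cached("small_field_corpus", function()
    make_dataset(4, seed = 202, probes = FALSE, fields = TRUE, folds = 2L))
}
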