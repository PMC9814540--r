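test_that("electrostatic field is Q/r with superposition and clamping", {
  st <- single_atom_structure("O", charge = 1)
  expect_equal(electrostatic_field(st, matrix(c(2, 0, 0), 1)), 0.5)
  st2 <- hydronet_structure(
    data.frame(name = c("O1", "O2"), resid = "TOY", resno = 1:2,
               x = c(1, 2), y = 0, z = 0, element = "O", charge = 1,
               is_donor = FALSE, is_acceptor = FALSE,
               stringsAsFactors = FALSE), topology = FALSE)
  expect_equal(electrostatic_field(st2, matrix(c(0, 0, 0), 1)), 1.5)
  st0 <- single_atom_structure("C", charge = 0)
  expect_equal(electrostatic_field(st0, matrix(rnorm(9), 3)), rep(0, 3))
  # coincident node clamps the distance at 0.5 A
  expect_equal(electrostatic_field(st, matrix(c(0, 0, 0), 1)), 2)
})

test_that("steric field has the analytic zero, minimum and decay", {
  st <- single_atom_structure("C")
  sip <- st$atoms$sigma + 1.6
  emin <- -sqrt(st$atoms$epsilon * 0.012) / 4
  expect_equal(steric_field(st, matrix(c(sip, 0, 0), 1)), 0, tolerance = 1e-12)
  expect_equal(steric_field(st, matrix(c(sip * sqrt(2), 0, 0), 1)), emin)
  # far-field decay follows the quadratic tail -(sigma_ip/d)^2
  far <- steric_field(st, matrix(c(100 * sip, 0, 0), 1))
  expect_equal(far, sqrt(st$atoms$epsilon * 0.012) * (1e-8 - 1e-4),
               tolerance = 1e-9)
  farther <- steric_field(st, matrix(c(1000 * sip, 0, 0), 1))
  expect_lt(abs(farther), abs(far) / 99)
})

test_that("hydrophobic cubic hits 1, 0.5, 0 and is continuous at the knots", {
  st <- single_atom_structure("C")
  sip <- st$atoms$sigma + 1.6
  d_of_s <- function(s) 1.5 * s + sip + 2
  at <- function(s) hydrophobic_field(st, matrix(c(d_of_s(s), 0, 0), 1))
  expect_equal(at(-1), 1)
  expect_equal(at(0), 0.5)
  expect_equal(at(1), 0)
  # cubic branch itself evaluates to 0 and 1 at the knots (continuity)
  expect_equal(0.25 * 1^3 - 0.75 * 1 + 0.5, 0)
  expect_equal(0.25 * (-1)^3 - 0.75 * (-1) + 0.5, 1)
  expect_equal(at(1 - 1e-7), 0, tolerance = 1e-6)
  expect_equal(at(-1 + 1e-7), 1, tolerance = 1e-6)
  # oxygen is not apolar: no contribution
  expect_equal(hydrophobic_field(single_atom_structure("O"),
                                 matrix(c(3, 0, 0), 1)), 0)
})

test_that("hydrogen-bond acceptor field peaks at 1.94 A", {
  st <- single_atom_structure("O", acceptor = TRUE)
  expect_equal(hbond_acceptor_field(st, matrix(c(1.94, 0, 0), 1)), 1)
  expect_equal(hbond_acceptor_field(st, matrix(c(2.94, 0, 0), 1)), exp(-1))
  none <- single_atom_structure("C")
  expect_equal(hbond_acceptor_field(none, matrix(c(1.94, 0, 0), 1)), 0)
})

test_that("hydrogen-bond donor field rewards linear D-H...point geometry", {
  st <- donor_structure()   # D at origin, H at (1,0,0)
  expect_equal(hbond_donor_field(st, matrix(c(1.94, 0, 0), 1)), 1)
  # point on the donor side: cos(alpha) >= 0 branch gives 0
  expect_equal(hbond_donor_field(st, matrix(c(-1.94, 0, 0), 1)), 0)
  # 90-degree geometry at the hydrogen: cos = 0 boundary
  expect_equal(hbond_donor_field(st, matrix(c(1, 1.6, 0), 1)), 0)
})

test_that("tanh scaling maps fields into declared ranges", {
  expect_equal(scale_field(0, "hphob"), 0)
  expect_equal(scale_field(1e6, "hphob"), 1)
  expect_equal(scale_field(1, "hbond_acc"), tanh(1))
  # attractive steric values are clipped at zero before squashing
  expect_equal(scale_field(-0.4, "steric"), 0)
  expect_equal(scale_field(0.7, "steric"), tanh(0.7))
  # electrostatics keeps its sign
  expect_equal(scale_field(-2, "elst"), tanh(-2))
  set.seed(4)
  v <- rnorm(100, sd = 4)
  expect_true(all(scale_field(v, "elst") >= -1 & scale_field(v, "elst") <= 1))
  expect_true(all(scale_field(v, "steric") >= 0 & scale_field(v, "steric") <= 1))
})

test_that("Gaussian binning peaks at the nearest center", {
  b <- gaussian_bin(0.35, 20, c(0, 1))   # centers 0.05, 0.10, ..., 1.00
  expect_equal(b[1, 7], 1)               # 0.35 is exactly center 7
  # midpoint between two centers activates both equally at exp(-1/8)
  b2 <- gaussian_bin(0.375, 20, c(0, 1))
  expect_equal(b2[1, 7], b2[1, 8])
  expect_equal(b2[1, 7], exp(-1 / 8))
  # unimodal: peak bin is the argmax nearest the value
  b3 <- gaussian_bin(0.62, 20, c(0, 1))
  expect_equal(which.max(b3[1, ]), 12)
  expect_gt(sum(b3), 0)
  # electrostatic channel uses bin width 2/20 over [-1, 1]
  b4 <- gaussian_bin(-0.9, 20, c(-1, 1))
  expect_equal(b4[1, 1], 1)
})

test_that("fields are additive over atoms and match a brute-force loop", {
  set.seed(8)
  n <- 6
  atoms <- data.frame(name = paste0("O", 1:n), resid = "TOY", resno = 1:n,
                      x = runif(n, -3, 3), y = runif(n, -3, 3),
                      z = runif(n, -3, 3), element = "O",
                      charge = runif(n, -1, 1), is_donor = FALSE,
                      is_acceptor = TRUE, stringsAsFactors = FALSE)
  st <- hydronet_structure(atoms, topology = FALSE)
  pts <- matrix(runif(15, -6, 6), 5)
  # brute-force per-atom accumulation
  ref_e <- ref_a <- numeric(5)
  for (k in 1:5) for (i in 1:n) {
    d <- max(sqrt(sum((pts[k, ] - c(atoms$x[i], atoms$y[i], atoms$z[i]))^2)), 0.5)
    ref_e[k] <- ref_e[k] + atoms$charge[i] / d
    d2 <- sqrt(sum((pts[k, ] - c(atoms$x[i], atoms$y[i], atoms$z[i]))^2))
    ref_a[k] <- ref_a[k] + exp(-(d2 - 1.94)^2)
  }
  expect_equal(electrostatic_field(st, pts), ref_e, tolerance = 1e-12)
  expect_equal(hbond_acceptor_field(st, pts), ref_a, tolerance = 1e-12)
})

test_that("fields are equivariant under rigid rotation and translation", {
  sys <- generate_toy_protein(toy_system_spec(n_atoms = 30, seed = 5))
  st <- sys$structure
  set.seed(6)
  R <- random_rotation_matrix()
  tr <- c(1.5, -2, 0.7)
  a2 <- st$atoms
  xyz <- as.matrix(a2[, c("x", "y", "z")]) %*% t(R)
  a2$x <- xyz[, 1] + tr[1]; a2$y <- xyz[, 2] + tr[2]; a2$z <- xyz[, 3] + tr[3]
  st2 <- st
  st2$atoms <- a2
  pts <- matrix(runif(30, -4, 4), 10)
  pts2 <- pts %*% t(R) + matrix(tr, 10, 3, byrow = TRUE)
  for (f in list(electrostatic_field, hbond_acceptor_field,
                 hbond_donor_field,
                 function(s, p) steric_field(s, p),
                 function(s, p) hydrophobic_field(s, p))) {
    expect_equal(f(st, pts), f(st2, pts2), tolerance = 1e-9)
  }
})

test_that("probe channels number 12 and obey the clip-and-scale rule", {
  sys <- generate_toy_protein(toy_system_spec(n_atoms = 25, seed = 2))
  g <- binding_site_grid(c(0, 0, 0), 6, 1)
  ch <- build_probe_channels(sys$structure, g)
  expect_length(ch$channels, 12)
  expect_true(all(vapply(ch$channels, function(v)
    min(v) >= -1 && max(v) <= 1, logical(1))))
  expect_error(build_probe_channels(sys$structure, g, probes = "NOPE"),
               "unknown probe")
  # a raw field beyond the clip level saturates at +/- 1
  big <- single_atom_structure("O", charge = 500)   # huge Coulomb values
  gsm <- grid_spec(c(1, 0, 0), 0.5, c(2, 2, 2))
  chb <- build_probe_channels(big, gsm,
                              probes = default_probe_table()[7, ])  # N+ probe
  expect_equal(max(chb$channels[[1]]), 1)
})

test_that("probe selection clusters by Pearson correlation distance", {
  set.seed(9)
  base <- matrix(rnorm(500 * 4), 500, 4)
  lib <- cbind(base[, 1], 2 * base[, 1] + 5,     # perfectly correlated pair
               base[, 2], -base[, 2],            # anticorrelated pair
               base[, 3], base[, 4])
  colnames(lib) <- paste0("p", 1:6)
  D <- probe_distance_matrix(lib)
  expect_equal(D[1, 2], 0, tolerance = 1e-12)
  expect_equal(D[3, 4], 2, tolerance = 1e-12)
  sel <- select_probes(lib, k = 4)
  expect_length(sel$probes, 4)
  expect_equal(sel$clustering[1], sel$clustering[2])  # duplicates share a cluster
  # orthogonal library with k equal to its size: every channel represents itself
  ortho <- matrix(rnorm(200 * 5), 200, 5)
  colnames(ortho) <- paste0("q", 1:5)
  sel2 <- select_probes(ortho, k = 5)
  expect_setequal(sel2$probes, colnames(ortho))
  expect_error(select_probes(ortho, k = 9), "exceeds")
})
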