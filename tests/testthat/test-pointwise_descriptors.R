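test_that("distance bins accumulate Gaussians then squash with tanh(./5)", {
  # one atom placed so its surface-corrected distance hits bin center 10
  st <- single_atom_structure("C")
  centers <- (7 / 25) * (1:25) - 1
  rt <- centers[10]
  v <- distance_bin_vector(st, c(st$atoms$sigma + rt, 0, 0))
  expect_equal(v[10], tanh(1 / 5))
  # far away: zero vector
  expect_equal(distance_bin_vector(st, c(50, 0, 0)), rep(0, 25))
  # five stacked atoms at one surface distance saturate toward tanh(1)
  at5 <- do.call(rbind, lapply(1:5, function(i)
    data.frame(name = paste0("C", i), resid = "TOY", resno = i,
               x = 0, y = 0, z = 0, element = "C", charge = 0,
               is_donor = FALSE, is_acceptor = FALSE,
               stringsAsFactors = FALSE)))
  st5 <- suppressWarnings(hydronet_structure(at5, topology = FALSE))
  v5 <- distance_bin_vector(st5, c(st$atoms$sigma + rt, 0, 0))
  expect_equal(v5[10], tanh(5 / 5))
})

test_that("flexibility block weights side chains by 2 tanh(t/4)", {
  expect_equal(2 * tanh(4 / 4), 1.523, tolerance = 1e-3)
  st <- load_structure(write_test_pdb())
  # an all-backbone environment leaves the block equal to the all-atom vector
  bb <- st
  keep <- bb$atoms$is_backbone
  bb$atoms <- bb$atoms[keep, ]
  bb$bonds <- lapply(bb$bonds[keep], function(x) integer(0))
  bb$donor_h <- vector("list", sum(keep))
  p0 <- c(1.46, 1, 0)
  expect_equal(flexibility_bin_vector(bb, p0), distance_bin_vector(bb, p0, "all"))
  # single side-chain atom with huge t: weight saturates at 2, so the raw
  # accumulation becomes p - 2p = -p and the block is the negated all-atom
  # vector
  one <- single_atom_structure("C")
  one$atoms$topo_dist <- 100L
  one$atoms$is_backbone <- FALSE
  pq <- c(3, 0, 0)
  expect_equal(flexibility_bin_vector(one, pq),
               -distance_bin_vector(one, pq), tolerance = 1e-10)
})

test_that("classification descriptor is 100-long, order-free and zero in vacuum", {
  st <- load_structure(write_test_pdb())
  d <- build_classification_descriptor(st, c(1.5, -1, 0.3))
  expect_length(d, 100)
  expect_equal(build_classification_descriptor(st, c(500, 500, 500)), rep(0, 100))
  # permuting atom order leaves the descriptor bitwise identical
  perm <- rev(seq_len(nrow(st$atoms)))
  st2 <- st
  st2$atoms <- st$atoms[perm, ]
  remap <- match(seq_len(nrow(st$atoms)), perm)
  st2$bonds <- lapply(st$bonds[perm], function(nb) remap[nb])
  st2$donor_h <- lapply(st$donor_h[perm], function(h) if (is.null(h)) NULL else remap[h])
  expect_equal(build_classification_descriptor(st2, c(1.5, -1, 0.3)), d,
               tolerance = 1e-12)
  # determinism: identical inputs give bitwise-identical output
  expect_identical(build_classification_descriptor(st, c(1.5, -1, 0.3)), d)
})

test_that("spherical-harmonics quadrature recovers constants and pure modes", {
  u <- fib_directions(2000)
  ex <- sh_expand_shell(rep(3.5, 2000), u, l_max = 2)
  a00 <- ex$coefficients[[1]]
  expect_equal(a00, 3.5 * sqrt(4 * pi), tolerance = 1e-3)
  m <- sh_moments(ex)
  expect_lt(m[2], 1e-2 * abs(a00))
  expect_lt(m[3], 1e-2 * abs(a00))
  # a pure l=1 field dominates the other degrees by >= 10x
  y10 <- sqrt(3 / (4 * pi)) * u[, 3]
  m1 <- sh_moments(sh_expand_shell(y10, u, l_max = 2))
  expect_gt(m1[2], 10 * m1[1])
  expect_gt(m1[2], 10 * m1[3])
  # all-zero samples give a zero expansion
  ex0 <- sh_expand_shell(rep(0, 50), fib_directions(50), l_max = 2)
  expect_equal(sh_moments(ex0), rep(0, 3))
  expect_warning(sh_expand_shell(numeric(0), matrix(0, 0, 3), 1), "empty shell")
})

test_that("moment norms are invariant under joint rotations", {
  set.seed(12)
  u <- fib_directions(600)
  f <- 0.3 + 0.5 * u[, 1] - 0.2 * u[, 2] * u[, 3]
  base <- sh_moments(sh_expand_shell(f, u, l_max = 2))
  for (i in 1:10) {
    R <- random_rotation_matrix()
    m2 <- sh_moments(sh_expand_shell(f, u %*% t(R), l_max = 2))
    expect_equal(m2, base, tolerance = 1e-3)
  }
})

test_that("moment vectors bin tanh(moment) over 5 bins", {
  ex0 <- sh_expand_shell(rep(0, 50), fib_directions(50), l_max = 1)
  mv <- sh_moment_vector(ex0)
  expect_length(mv, 10)
  expect_equal(which.max(mv[1:5]), 1)    # tanh(0) = 0 sits below the first center
  # a moment of ~1 squashes to tanh(1) ~ 0.76, nearest bin center 0.8 (bin 4)
  exc <- sh_expand_shell(rep(1 / sqrt(4 * pi), 400), fib_directions(400), 0)
  expect_equal(sh_moments(exc), 1, tolerance = 1e-3)
  expect_equal(which.max(sh_moment_vector(exc)), 4)
})

test_that("regression descriptors have the documented block structure", {
  ds <- small_field_corpus()
  s <- ds$systems[[1]]
  pt <- c(0.25, 0.25, 0.25)
  d1 <- build_regression_descriptor(s$fields, pt, l_max = 1)
  expect_length(d1, 100 + 7 * 5 * 2 * 5)
  d0 <- build_regression_descriptor(s$fields, pt, l_max = 0)
  expect_length(d0, 100 + 175)
  # raising l_max strictly appends: the shared prefix is unchanged
  expect_equal(d1[seq_along(d0)], d0)
  expect_equal(nrow(shell_spec()), 7)
  # direct block of a far-vacuum point equals the binning of all-zero fields
  far <- scalar_grid(s$grid, 0)
  vac_fields <- multi_channel_grid(s$grid, list(
    elst = far$values, steric = far$values, hphob = far$values,
    hbond_acc = far$values, hbond_don = far$values))
  dv <- build_regression_descriptor(vac_fields, pt, l_max = 0)
  expect_equal(dv[1:20], as.numeric(gaussian_bin(0, 20, c(-1, 1))))
  expect_equal(dv[21:40], as.numeric(gaussian_bin(0, 20, c(0, 1))))
})

test_that("batch lattice-node descriptors agree with the general path", {
  ds <- small_field_corpus()
  s <- ds$systems[[1]]
  nodes <- rbind(c(12, 12, 12), c(9, 13, 11), c(14, 10, 12))
  M <- regression_descriptor_matrix(s$fields, nodes, l_max = 1)
  expect_equal(dim(M), c(3L, 450L))
  for (i in 1:3) {
    pt <- s$grid$origin + (nodes[i, ] - 1) * s$grid$spacing
    expect_equal(M[i, ], build_regression_descriptor(s$fields, pt, l_max = 1),
                 tolerance = 1e-12)
  }
  # descriptors are deterministic
  expect_identical(M, regression_descriptor_matrix(s$fields, nodes, l_max = 1))
})
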