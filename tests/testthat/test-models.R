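test_that("occupancy labels follow the threshold ladder and stay monotone", {
  g <- grid_spec(c(0, 0, 0), 1, c(2, 2, 2))
  occ <- array(c(0.05, 0, 1.0, 0.02, 0.021, 0.07, 0.0699, 0.045), c(2, 2, 2))
  lab <- occupancy_to_labels(scalar_grid(g, occ))
  expect_equal(dim(lab), c(2, 2, 2, 6))
  expect_equal(lab[1, 1, 1, ], c(1, 1, 1, 1, 0, 0))   # 0.05
  expect_equal(lab[2, 1, 1, ], rep(0, 6))             # 0 (strict >)
  expect_equal(lab[1, 2, 1, ], rep(1, 6))             # 1.0
  expect_equal(lab[2, 2, 1, ], c(1, 0, 0, 0, 0, 0))   # 0.02 exactly
  # monotone: a label set at a higher threshold implies all lower ones
  for (i in 1:2) for (j in 1:2) for (k in 1:2)
    expect_true(all(diff(lab[i, j, k, ]) <= 0))
  expect_error(occupancy_to_labels(scalar_grid(g, occ), c(0.1, 0.05)),
               "increasing")
})

test_that("GDL algebra: identity gives 0, complement gives 1", {
  set.seed(21)
  r <- matrix(rbinom(4 * 100, 1, 0.2), 4, 100)
  expect_equal(gdl_loss(r, r), 0)
  expect_equal(gdl_loss(r, 1 - r), 1)
  p <- matrix(runif(400), 4, 100)
  v <- gdl_loss(r, p)
  expect_gte(v, 0)
  expect_lte(v, 1)
  expect_warning(gdl_loss(matrix(0, 2, 10), matrix(0.5, 2, 10)), "all-empty")
})

test_that("GDL matches an independent brute-force evaluation", {
  # half-occupied single-label grid scored with a uniform 0.5 prediction
  r <- matrix(c(rep(1, 8), rep(0, 8)), 1, 16)
  p <- matrix(0.5, 1, 16)
  w <- 1 / (sum(r)^2 + 1)
  manual <- 1 - 2 * (w * sum(r * p)) / (w * sum(r + p))
  expect_equal(gdl_loss(r, p), manual)
  # two-label case with explicit per-label sums
  r2 <- rbind(c(1, 1, 0, 0), c(0, 1, 0, 0))
  p2 <- rbind(c(0.9, 0.4, 0.1, 0.0), c(0.2, 0.8, 0.1, 0.1))
  w2 <- 1 / (rowSums(r2)^2 + 1)
  w2 <- w2 / sum(w2)
  manual2 <- 1 - 2 * sum(w2 * rowSums(r2 * p2)) / sum(w2 * rowSums(r2 + p2))
  expect_equal(gdl_loss(r2, p2), manual2)
})

test_that("smoothed Dice behaves at the identity, disjoint and tiny scales", {
  set.seed(22)
  r <- rbinom(4000, 1, 0.4)
  expect_equal(smoothed_dice(r, r), 1, tolerance = 1e-3)
  disj <- 1 - r
  expect_lt(smoothed_dice(r, disj), 1e-3)
  # 2x2x2 hand example
  rr <- array(c(1, 0, 0, 1, 0, 0, 0, 0), c(2, 2, 2))
  pp <- array(c(0.8, 0.1, 0.2, 0.6, 0, 0, 0, 0.3), c(2, 2, 2))
  expect_equal(smoothed_dice(rr, pp),
               (2 * (0.8 + 0.6) + 1) / (2 + sum(pp) + 1))
})

test_that("precision and recall are computed per threshold channel", {
  ref <- array(c(0.05, 0.01, 0.08, 0.0), c(2, 2, 1))
  prd <- array(c(0.06, 0.04, 0.01, 0.0), c(2, 2, 1))
  pr <- precision_recall(ref, prd, thresholds = 0.03)
  expect_equal(pr$tp, 1)   # 0.05/0.06
  expect_equal(pr$fp, 1)   # 0.01/0.04
  expect_equal(pr$fn, 1)   # 0.08/0.01
  expect_equal(pr$precision, 0.5)
  expect_equal(pr$recall, 0.5)
  m <- array(c(TRUE, TRUE, FALSE, TRUE), c(2, 2, 1))
  pr2 <- precision_recall(ref, prd, thresholds = 0.03, mask = m)
  expect_equal(pr2$tp, 1)
  expect_equal(pr2$fn, 0)
})

test_that("channel combination returns the top confident threshold", {
  th <- occupancy_thresholds()
  p <- array(0, c(1, 1, 1, 6))
  p[1, 1, 1, ] <- c(1, 1, 1, 1, 1, 1)
  expect_equal(as.numeric(combine_channels(p)), 0.07)
  p[1, 1, 1, ] <- c(1, 0, 0, 0, 0, 0)
  expect_equal(as.numeric(combine_channels(p)), 0)   # accessible, sub-bulk
  p[1, 1, 1, ] <- rep(0.49, 6)
  expect_equal(as.numeric(combine_channels(p)), 0)
  p[1, 1, 1, ] <- c(1, 1, 0.6, 0.2, 0, 0)
  expect_equal(as.numeric(combine_channels(p)), 0.03)
})

test_that("segmentation models have the documented stage structure", {
  cfg_b <- segmentation_config("baseline")
  expect_length(cfg_b$encoder_filters, 6)
  expect_equal(cfg_b$encoder_filters, c(32L, 64L, 128L, 256L, 512L, 512L))
  cfg_i <- segmentation_config("inception_residual")
  expect_length(cfg_i$encoder_filters, 5)
  m_b <- build_segmentation_model(segmentation_config("baseline",
    encoder_filters = c(4L, 6L, 8L), in_channels = 2L), seed = 1)
  expect_equal(n_encoder_stages(m_b), 3)
  m_i <- build_segmentation_model(segmentation_config("inception_residual",
    encoder_filters = c(4L, 6L), in_channels = 2L), seed = 1)
  expect_equal(n_encoder_stages(m_i), 2)
  # output keeps the spatial shape with 6 channels
  x <- matrix(rnorm(2 * 512), 2, 512)
  attr(x, "dims") <- c(8L, 8L, 8L)
  pr <- predict_segmentation(m_b, x)
  expect_equal(dim(pr), c(8, 8, 8, 6))
  expect_true(all(pr >= 0 & pr <= 1))
  # indivisible dims are rejected
  x9 <- matrix(rnorm(2 * 9^3), 2, 9^3)
  attr(x9, "dims") <- c(9L, 9L, 9L)
  expect_error(predict_segmentation(m_b, x9), "divisible")
})

test_that("network gradients agree with numerical differentiation", {
  for (variant in c("inception_residual", "baseline")) {
    cfg <- segmentation_config(variant, encoder_filters = c(4L, 6L),
                               in_channels = 3L, out_channels = 2L,
                               dropout = 0)
    m <- build_segmentation_model(cfg, seed = 2)
    dims <- c(4L, 4L, 4L)
    set.seed(5)
    x <- matrix(rnorm(3 * 64), 3, 64)
    r <- matrix(rbinom(2 * 64, 1, 0.3), 2, 64)
    fw <- hydronet:::.seg_forward(m, x, dims, FALSE)
    loss0 <- gdl_loss(r, fw$pred)
    g <- hydronet:::.seg_backward(m, fw$cache, hydronet:::.gdl_grad(r, fw$pred))
    flat <- function(t, prefix = "") {
      out <- list()
      if (is.list(t)) {
        keys <- if (!is.null(names(t))) names(t) else seq_along(t)
        for (k in keys) {
          if (is.null(t[[k]])) next
          out <- c(out, flat(t[[k]], paste(prefix, k)))
        }
      } else out[[prefix]] <- t
      out
    }
    fg <- flat(g)
    worst <- 0
    set.seed(9)
    for (nm in sample(names(fg), min(12, length(fg)))) {
      path <- strsplit(trimws(nm), " +")[[1]]
      ii <- sample(length(fg[[nm]]), 1)
      m2 <- m
      expr <- paste0("m2$params",
                     paste(vapply(path, function(z)
                       if (grepl("^[0-9]+$", z)) sprintf("[[%s]]", z)
                       else sprintf("[[\"%s\"]]", z), character(1)),
                       collapse = ""), "[ii]")
      v0 <- eval(parse(text = expr))
      eval(parse(text = paste0(expr, " <- v0 + 1e-6")))
      l2 <- gdl_loss(r, hydronet:::.seg_forward(m2, x, dims, FALSE)$pred)
      worst <- max(worst, abs((l2 - loss0) / 1e-6 - fg[[nm]][ii]))
    }
    expect_lt(worst, 1e-5)
  }
})

test_that("dense-network gradients agree with numerical differentiation", {
  set.seed(4)
  X <- matrix(rnorm(5 * 7), 5, 7)
  Y <- matrix(rnorm(5 * 2), 5, 2)
  params <- hydronet:::.mlp_init(c(7, 6, 4, 2), seed = 9)
  cache <- hydronet:::.mlp_forward(params, X, "linear", 0, FALSE)
  dout <- 2 * (cache$out - Y) / length(Y)
  g <- hydronet:::.mlp_backward(params, cache, dout)
  lossfn <- function(p)
    mean((hydronet:::.mlp_forward(p, X, "linear", 0, FALSE)$out - Y)^2)
  worst <- 0
  for (li in 1:3) for (ii in sample(length(params$W[[li]]), 5)) {
    p2 <- params
    p2$W[[li]][ii] <- p2$W[[li]][ii] + 1e-6
    worst <- max(worst, abs((lossfn(p2) - lossfn(params)) / 1e-6 -
                              g$W[[li]][ii]))
  }
  expect_lt(worst, 1e-4)
})

test_that("rotation augmentation enumerates 24 distinct proper rotations", {
  rots <- hydronet:::.rot24()
  expect_length(rots, 24)
  a <- array(seq_len(27), c(3, 3, 3))
  imgs <- vapply(rots, function(r) paste(rotate_array90(a, r), collapse = ","),
                 character(1))
  expect_equal(length(unique(imgs)), 24)
  # identity is among them and rotations permute, not alter, the values
  expect_true(paste(a, collapse = ",") %in% imgs)
  for (r in rots[1:5]) expect_equal(sort(rotate_array90(a, r)), 1:27)
})

test_that("segmentation training reduces the loss on a small oracle corpus", {
  ds <- small_field_corpus()
  train <- lapply(ds$systems, function(s) {
    x <- do.call(rbind, lapply(s$fields$channels, as.vector))
    list(x = x, r = hydronet:::.to_label_matrix(s$labels), dims = s$grid$dims)
  })
  cfg <- segmentation_config("inception_residual", encoder_filters = c(4L, 8L),
                             in_channels = 5L, dropout = 0)
  m <- build_segmentation_model(cfg, seed = 1)
  m <- train_segmentation(m, train, epochs = 4, batch_size = 2, lr = 3e-3,
                          seed = 1)
  expect_lt(tail(m$history$loss, 1), m$history$initial)
  # deterministic for a fixed seed
  m2 <- build_segmentation_model(cfg, seed = 1)
  m2 <- train_segmentation(m2, train, epochs = 2, batch_size = 2, lr = 3e-3,
                           seed = 1)
  m3 <- build_segmentation_model(cfg, seed = 1)
  m3 <- train_segmentation(m3, train, epochs = 2, batch_size = 2, lr = 3e-3,
                           seed = 1)
  expect_identical(m2$history$loss, m3$history$loss)
  # all-zero labels abort
  z <- lapply(train, function(s) { s$r <- s$r * 0; s })
  expect_error(train_segmentation(build_segmentation_model(cfg, 1), z),
               "degenerate")
  expect_error(train_segmentation(build_segmentation_model(cfg, 1), list()),
               "empty")
})

test_that("identity augmentation leaves the first-batch loss unchanged", {
  ds <- small_field_corpus()
  s <- ds$systems[[1]]
  x <- do.call(rbind, lapply(s$fields$channels, as.vector))
  r <- hydronet:::.to_label_matrix(s$labels)
  cfg <- segmentation_config("inception_residual", encoder_filters = c(4L, 8L),
                             in_channels = 5L, dropout = 0)
  m <- build_segmentation_model(cfg, seed = 1)
  rot_id <- hydronet:::.rot24()[[1]]   # identity permutation, no flips
  expect_equal(rot_id$perm, c(1, 2, 3))
  x_rot <- hydronet:::.rotate_mat(x, s$grid$dims, rot_id)
  expect_equal(x_rot, x)
  fw1 <- hydronet:::.seg_forward(m, x, s$grid$dims, FALSE)
  fw2 <- hydronet:::.seg_forward(m, x_rot, s$grid$dims, FALSE)
  expect_equal(gdl_loss(r, fw1$pred), gdl_loss(r, fw2$pred))
})

test_that("point-wise classifier separates separable classes and is bounded", {
  set.seed(31)
  n <- 600
  X <- matrix(rnorm(n * 10), n, 10)
  y <- as.numeric(X[, 1] + 0.5 * X[, 2] > 0)
  tr <- 1:400; te <- 401:600
  clf <- train_pointwise_classifier(X[tr, ], y[tr], hidden = c(32L, 16L),
                                    epochs = 60, batch_size = 100, lr = 3e-3,
                                    dropout = 0.1, seed = 1)
  p <- predict(clf, X[te, ])
  expect_true(all(p >= 0 & p <= 1))
  expect_gt(mean((p > 0.5) == y[te]), 0.95)
  # shuffled labels give chance-level accuracy
  set.seed(32)
  ysh <- sample(y[tr])
  clf0 <- train_pointwise_classifier(X[tr, ], ysh, hidden = c(32L, 16L),
                                     epochs = 30, batch_size = 100, lr = 3e-3,
                                     dropout = 0.1, seed = 1)
  acc0 <- mean((predict(clf0, X[te, ]) > 0.5) == y[te])
  expect_lt(abs(acc0 - 0.5), 0.12)
  expect_error(train_pointwise_classifier(X, rep(1, n)), "single-class")
  # occupancy values are binarized at the occupied threshold
  occ <- c(rep(0, 5), rep(1e-6, 5), rep(1e-3, 10))
  expect_equal(occupied_threshold(), 1e-5)
  expect_error(train_pointwise_classifier(X[1:10, ], occ[1:10]), "single-class")
})

test_that("point-wise regressor fits and respects constant targets", {
  set.seed(33)
  X <- matrix(rnorm(300 * 8), 300, 8)
  Y <- cbind(X[, 1] * 0.05 + 0.02, 2 - 3 * X[, 2])
  reg <- train_pointwise_regressor(X, Y, hidden = c(32L, 16L), epochs = 100,
                                   batch_size = 100, lr = 3e-3, dropout = 0,
                                   seed = 1)
  pr <- predict(reg, X)
  expect_gt(cor(pr[, 1], Y[, 1]), 0.95)
  expect_gt(cor(pr[, 2], Y[, 2]), 0.95)
  cst <- train_pointwise_regressor(X, cbind(rep(0.5, 300), rep(-1, 300)),
                                   hidden = c(16L), epochs = 100,
                                   batch_size = 100, lr = 1e-2, dropout = 0,
                                   seed = 1)
  pc <- predict(cst, X)
  expect_lt(sd(pc[, 1]), 0.1)
  expect_lt(sd(pc[, 2]), 0.1)
  expect_equal(mean(pc[, 1]), 0.5, tolerance = 0.2)
  expect_equal(mean(pc[, 2]), -1, tolerance = 0.2)
  expect_error(train_pointwise_regressor(X[0, ], Y[0, ]), "empty")
})

test_that("permutation importance reports near-zero drop for constant channels", {
  ds <- small_field_corpus()
  train <- lapply(ds$systems, function(s) {
    x <- rbind(as.vector(s$fields$channels$hbond_acc),
               rep(0.3, prod(s$grid$dims)))      # constant second channel
    rownames(x) <- c("informative", "constant")
    list(x = x, r = hydronet:::.to_label_matrix(s$labels), dims = s$grid$dims)
  })
  cfg <- segmentation_config("inception_residual", encoder_filters = c(4L, 8L),
                             in_channels = 2L, dropout = 0)
  m <- build_segmentation_model(cfg, seed = 2)
  m <- train_segmentation(m, train[1:3], epochs = 4, batch_size = 1, lr = 3e-3,
                          seed = 2, augment = FALSE)
  pi <- permutation_importance(m, train[4], repeats = 2, seed = 1)
  expect_equal(pi$drop[pi$channel == "constant"], 0, tolerance = 1e-12)
})

test_that("boundary mask removes a margin of nodes per face", {
  bm <- boundary_mask(c(8L, 8L, 8L), margin = 2)
  expect_equal(sum(bm), 4^3)
  expect_false(bm[1, 5, 5])
  expect_true(bm[3, 3, 3])
  expect_equal(sum(boundary_mask(c(4L, 4L, 4L), margin = 2)), 0)
})

test_that("model checkpoints round-trip and reject version mismatches", {
  cfg <- segmentation_config("inception_residual", encoder_filters = c(4L, 6L),
                             in_channels = 2L, dropout = 0)
  m <- build_segmentation_model(cfg, seed = 5)
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(m2$params, m$params)
  x <- matrix(rnorm(2 * 64), 2, 64)
  attr(x, "dims") <- c(4L, 4L, 4L)
  expect_identical(predict_segmentation(m, x), predict_segmentation(m2, x))
  # tampered version refuses to load
  ck <- readRDS(path)
  ck$version <- "0.0.0"
  saveRDS(ck, path)
  expect_error(load_model(path), "version mismatch")
  saveRDS(list(a = 1), path)
  expect_error(load_model(path), "not a hydronet checkpoint")
})

test_that("averaging permutation repeats lowers the importance variance", {
  ds <- small_field_corpus()
  train <- lapply(ds$systems, function(s) {
    x <- rbind(as.vector(s$fields$channels$hbond_acc),
               as.vector(s$fields$channels$elst))
    list(x = x, r = hydronet:::.to_label_matrix(s$labels), dims = s$grid$dims)
  })
  cfg <- segmentation_config("inception_residual", encoder_filters = c(4L, 8L),
                             in_channels = 2L, dropout = 0)
  m <- build_segmentation_model(cfg, seed = 2)
  m <- train_segmentation(m, train[1:3], epochs = 3, batch_size = 1,
                          lr = 3e-3, seed = 2, augment = FALSE)
  drops1 <- vapply(1:6, function(sd)
    permutation_importance(m, train[4], repeats = 1, seed = sd)$drop[1],
    numeric(1))
  drops3 <- vapply(1:6, function(sd)
    permutation_importance(m, train[4], repeats = 3, seed = sd)$drop[1],
    numeric(1))
  expect_lt(var(drops3), var(drops1))
})
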