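#  Label construction, generalized Dice loss, evaluation metrics, training
#  drivers for the segmentation and point-wise networks, and permutation
#  importance of input channels.

#' Default occupancy threshold ladder
#'
#' The six occupancy levels used as segmentation classes: 0 marks any water
#' accessibility, 0.02 is approximately bulk water density, higher values
#' mark increasingly dense hydration-site cores (values above 0.07 are
#' rare).
#' @return numeric vector of length 6.
#' @export
occupancy_thresholds <- function() c(0, 0.02, 0.03, 0.045, 0.06, 0.07)

#' Transform an occupancy grid into cumulative threshold labels
#'
#' Label `l` at node `n` is 1 when occupancy strictly exceeds threshold
#' `l`, so labels are monotone non-increasing along the threshold ladder.
#'
#' @param occupancy a `scalar_grid` or numeric array (values >= 0).
#' @param thresholds increasing numeric vector.
#' @return numeric array `dim(occupancy) x length(thresholds)` of 0/1.
#' @export
occupancy_to_labels <- function(occupancy, thresholds = occupancy_thresholds()) {
  if (inherits(occupancy, "scalar_grid")) occupancy <- occupancy$values
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly increasing")
  out <- vapply(thresholds, function(th) (occupancy > th) + 0,
                FUN.VALUE = occupancy + 0)
  array(out, dim = c(dim(occupancy), length(thresholds)))
}

# labels/predictions as (L x N) matrices from dims x L arrays
.to_label_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  d <- dim(x)
  L <- d[length(d)]
  t(matrix(x, ncol = L))
}

#' Generalized Dice loss
#'
#' `GDL = 1 - 2 (sum_l w_l sum_n r_ln p_ln) / (sum_l w_l sum_n (r_ln + p_ln))`
#' with class weights `w_l = 1 / ((sum_n r_ln)^2 + 1)` inversely
#' proportional to the squared class population.  Classes that are entirely
#' absent from the reference are dropped from the sums (their inverse
#' population weight would otherwise dwarf every populated class and erase
#' the learning signal); when every class is empty the epsilon-guarded
#' weights are used and a warning is raised.  For a binary reference
#' compared with itself the loss is exactly 0; against its complement it
#' is 1.
#'
#' @param reference 0/1 labels: array `dims x L` or matrix `L x N`.
#' @param prediction probabilities in [0,1], same shape.
#' @return scalar loss in [0, 1].
#' @export
gdl_loss <- function(reference, prediction) {
  r <- .to_label_matrix(reference)
  p <- .to_label_matrix(prediction)
  if (!all(dim(r) == dim(p))) stop("reference and prediction shapes differ")
  w <- .gdl_weights(r)
  num <- sum(w * rowSums(r * p))
  den <- sum(w * rowSums(r + p))
  if (den == 0) return(1)
  1 - 2 * num / den
}

.gdl_weights <- function(r) {
  pop <- rowSums(r)
  w <- 1 / (pop^2 + 1)
  if (all(pop == 0)) {
    warning("all-empty reference: GDL computed with weight guard")
  } else {
    w[pop == 0] <- 0
  }
  # normalizing the weights leaves the GDL ratio unchanged but keeps the
  # gradient magnitude independent of the class populations
  w / sum(w)
}

# gradient of gdl_loss w.r.t. the prediction matrix (L x N)
.gdl_grad <- function(r, p) {
  w <- suppressWarnings(.gdl_weights(r))
  num <- sum(w * rowSums(r * p))
  den <- sum(w * rowSums(r + p))
  if (den == 0) return(p * 0)
  (-2) * (w * r * den - num * w) / den^2
}

#' Smoothed Dice overlap
#'
#' `(2 sum r p + eps) / (sum r + sum p + eps)` with smoothing constant
#' `eps = 1`; prediction confidences enter directly (no binarization).
#'
#' @param reference,prediction numeric arrays/matrices of matching shape.
#' @param mask optional logical mask applied to both (per node; recycled
#'   over label channels when the inputs carry a trailing label dimension).
#' @param eps smoothing constant.
#' @return scalar in (0, 1].
#' @export
smoothed_dice <- function(reference, prediction, mask = NULL, eps = 1) {
  if (!is.null(mask)) {
    if (length(mask) == length(reference)) {       # per-element mask
      keep <- as.vector(mask)
      r <- as.vector(reference)[keep]
      p <- as.vector(prediction)[keep]
    } else {                                       # per-node mask, L channels
      r <- .to_label_matrix(reference)[, as.vector(mask), drop = FALSE]
      p <- .to_label_matrix(prediction)[, as.vector(mask), drop = FALSE]
    }
  } else {
    r <- reference; p <- prediction
  }
  (2 * sum(r * p) + eps) / (sum(r) + sum(p) + eps)
}

#' Precision and recall per occupancy threshold
#'
#' Binarizes reference and predicted occupancy at each threshold (strict >)
#' and reports precision and recall, optionally restricted to a mask (for
#' example the 5 Angstrom ligand region).
#'
#' @param reference,prediction occupancy grids (`scalar_grid` or array).
#' @param thresholds occupancy levels (default drops the 0 level:
#'   `c(0.02, 0.03, 0.045, 0.06, 0.07)`).
#' @param mask optional logical array.
#' @return data.frame with threshold, tp/fp/fn counts, precision, recall.
#' @export
precision_recall <- function(reference, prediction,
                             thresholds = occupancy_thresholds()[-1],
                             mask = NULL) {
  r <- if (inherits(reference, "scalar_grid")) reference$values else reference
  p <- if (inherits(prediction, "scalar_grid")) prediction$values else prediction
  r <- as.vector(r); p <- as.vector(p)
  if (!is.null(mask)) { keep <- as.vector(mask); r <- r[keep]; p <- p[keep] }
  out <- lapply(thresholds, function(th) {
    rb <- r > th; pb <- p > th
    tp <- sum(rb & pb); fp <- sum(!rb & pb); fn <- sum(rb & !pb)
    data.frame(threshold = th, tp = tp, fp = fp, fn = fn,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
  })
  do.call(rbind, out)
}

#' Combine threshold channels into a hydration-likeliness grid
#'
#' Per node, the hydration score is the largest threshold whose channel
#' probability reaches 0.5 (0 when none does), giving a grid in occupancy
#' units directly comparable to the threshold ladder.
#'
#' @param prediction array `dims x L` of channel probabilities.
#' @param thresholds threshold ladder matching the channels.
#' @param spec optional `grid_spec`; when given, a `scalar_grid` is
#'   returned.
#' @return numeric array (or `scalar_grid`) of hydration scores.
#' @export
combine_channels <- function(prediction, thresholds = occupancy_thresholds(),
                             spec = NULL) {
  p <- .to_label_matrix(prediction)
  L <- nrow(p)
  if (L != length(thresholds)) stop("channel count does not match thresholds")
  hit <- p >= 0.5
  score <- rep(0, ncol(p))
  for (l in seq_len(L)) score[hit[l, ]] <- thresholds[l]
  d <- dim(prediction)
  arr <- array(score, dim = d[-length(d)])
  if (!is.null(spec)) scalar_grid(spec, arr) else arr
}

#' Interior mask dropping grid-boundary nodes
#'
#' The segmentation network lacks spatial context at the box boundary, so
#' predictions within `margin` nodes of any face are typically discarded.
#'
#' @param dims grid dims (or a `grid_spec`).
#' @param margin nodes to drop per face (default 4).
#' @return logical array, TRUE on interior nodes.
#' @export
boundary_mask <- function(dims, margin = 4L) {
  if (inherits(dims, "grid_spec")) dims <- dims$dims
  m <- array(FALSE, dim = dims)
  if (any(dims <= 2 * margin)) return(m)
  idx <- lapply(dims, function(n) (margin + 1L):(n - margin))
  m[idx[[1]], idx[[2]], idx[[3]]] <- TRUE
  m
}

# ---- axis-aligned 90-degree rotations (data augmentation) ----------------

.rot24 <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  psign <- c(1, -1, -1, 1, 1, -1)
  out <- list()
  for (ip in seq_along(perms))
    for (f1 in c(FALSE, TRUE)) for (f2 in c(FALSE, TRUE)) for (f3 in c(FALSE, TRUE)) {
      s <- psign[ip] * (-1)^sum(c(f1, f2, f3))
      if (s == 1) out[[length(out) + 1L]] <- list(perm = perms[[ip]],
                                                  flip = c(f1, f2, f3))
    }
  out
}

#' Apply one of the 24 axis-aligned rotations to a cubic 3D array
#'
#' @param arr cubic numeric array.
#' @param rot element of the internal rotation list (an integer 1..24 is
#'   also accepted).
#' @return rotated array of identical shape.
#' @export
rotate_array90 <- function(arr, rot) {
  if (is.numeric(rot) && length(rot) == 1L) rot <- .rot24()[[rot]]
  a <- aperm(arr, rot$perm)
  d <- dim(a)
  ix <- if (rot$flip[1]) d[1]:1 else 1:d[1]
  iy <- if (rot$flip[2]) d[2]:1 else 1:d[2]
  iz <- if (rot$flip[3]) d[3]:1 else 1:d[3]
  a[ix, iy, iz, drop = FALSE]
}

# rotate a (C x N) feature matrix sample
.rotate_mat <- function(x, dims, rot) {
  t(apply(x, 1L, function(v) as.vector(rotate_array90(array(v, dims), rot))))
}

# ---- segmentation training ----------------------------------------------

.tree_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) return(Map(.tree_add, a, b))
  a + b
}

.tree_scale <- function(a, s) {
  if (is.null(a)) return(NULL)
  if (is.list(a)) return(lapply(a, .tree_scale, s = s))
  a * s
}

.as_seg_sample <- function(sample) {
  if (!is.null(sample$x)) {
    list(x = sample$x, r = sample$r, dims = sample$dims)
  } else {
    ch <- sample$channels
    dims <- ch$spec$dims
    x <- do.call(rbind, lapply(ch$channels, as.vector))
    r <- .to_label_matrix(sample$labels)
    list(x = x, r = r, dims = dims)
  }
}

#' Train a segmentation model with the generalized Dice loss
#'
#' Adam optimization with on-the-fly data augmentation by random
#' axis-aligned 90-degree rotations applied jointly to inputs and labels.
#' Fully deterministic for a fixed seed.
#'
#' @param model a `segmentation_model`.
#' @param dataset list of samples, each either
#'   `list(channels = multi_channel_grid, labels = dims x L array)` or
#'   pre-flattened `list(x = C x N matrix, r = L x N matrix, dims = dims)`.
#' @param epochs,lr,batch_size optimizer settings (defaults 30, 1e-3, 16).
#' @param seed RNG seed.
#' @param augment apply random rotations during training.
#' @param verbose print epoch losses.
#' @return the model with trained parameters and a `history` element:
#'   `initial` (mean GDL before training) and `loss` (per epoch).
#' @export
train_segmentation <- function(model, dataset, epochs = 30L, lr = 1e-3,
                               batch_size = 16L, seed = 1L, augment = TRUE,
                               verbose = FALSE) {
  if (length(dataset) == 0L) stop("empty dataset")
  samples <- lapply(dataset, .as_seg_sample)
  if (all(vapply(samples, function(s) all(s$r == 0), logical(1))))
    stop("degenerate dataset: all label grids are zero")
  set.seed(seed)
  rots <- .rot24()
  state <- .adam_state(model$params)
  if (is.null(model$history)) {
    # start each output channel at its class prior (clipped logit)
    freq <- rowMeans(vapply(samples, function(s) rowMeans(s$r),
                            numeric(nrow(samples[[1]]$r))))
    model$params$final$b <- log(pmin(pmax(freq, 0.01), 0.99) /
                                  (1 - pmin(pmax(freq, 0.01), 0.99)))
  }
  initial <- mean(vapply(samples, function(s)
    gdl_loss(s$r, .seg_forward(model, s$x, s$dims, FALSE)$pred), numeric(1)))
  nhist <- numeric(epochs)
  n <- length(samples)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    tot <- 0
    for (bs in seq(1L, n, by = batch_size)) {
      idx <- ord[bs:min(n, bs + batch_size - 1L)]
      gacc <- NULL
      for (i in idx) {
        s <- samples[[i]]
        if (augment) {
          rot <- rots[[sample.int(24L, 1L)]]
          x <- .rotate_mat(s$x, s$dims, rot)
          r <- .rotate_mat(s$r, s$dims, rot)
        } else { x <- s$x; r <- s$r }
        fw <- .seg_forward(model, x, s$dims, training = TRUE)
        tot <- tot + gdl_loss(r, fw$pred)
        g <- .seg_backward(model, fw$cache, .gdl_grad(r, fw$pred))
        gacc <- .tree_add(gacc, g)
      }
      gacc <- .tree_scale(gacc, 1 / length(idx))
      st <- .adam_step(model$params, gacc, state, lr)
      model$params <- st$params
      state[c("m", "v", "t")] <- st$state
    }
    nhist[ep] <- tot / n
    if (verbose) message(sprintf("epoch %d: GDL %.4f", ep, nhist[ep]))
  }
  model$history <- list(initial = initial, loss = nhist)
  model
}

# ---- point-wise models ---------------------------------------------------

#' Occupancy threshold separating occupied from unoccupied points
#' @return scalar `1e-5`.
#' @export
occupied_threshold <- function() 1e-5

#' Train the point-wise occupancy classifier
#'
#' Binary classifier (occupied vs unoccupied grid point) on 100-dimensional
#' classification descriptors: hidden layers 1024/512 with leaky-ReLU and
#' dropout 0.5, sigmoid output, binary cross-entropy, Adam.
#'
#' @param descriptors matrix, one descriptor per row.
#' @param occupancy numeric vector of reference occupancies (labels are
#'   `occupancy > occupied_threshold()`), or a logical/0-1 label vector.
#' @param hidden hidden-layer widths (default `c(1024, 512)`).
#' @param epochs,batch_size,lr,dropout training settings (defaults 50, 250,
#'   1e-3, 0.5).
#' @param seed RNG seed.
#' @return a `hydronet_mlp` classifier.
#' @export
train_pointwise_classifier <- function(descriptors, occupancy,
                                       hidden = c(1024L, 512L), epochs = 50L,
                                       batch_size = 250L, lr = 1e-3,
                                       dropout = 0.5, seed = 1L) {
  y <- if (is.logical(occupancy) || all(occupancy %in% c(0, 1)))
    as.numeric(occupancy) else as.numeric(occupancy > occupied_threshold())
  if (length(unique(y)) < 2L)
    stop("single-class data: cannot train the classifier")
  mlp_train(descriptors, matrix(y, ncol = 1L), hidden, "sigmoid",
            epochs = epochs, batch_size = batch_size, lr = lr,
            dropout = dropout, seed = seed)
}

#' Train the point-wise occupancy/free-energy regressor
#'
#' Two-output regression (occupancy, desolvation free energy) on the
#' spherical-harmonics regression descriptors for points classified as
#' occupied: hidden layers 2048/1024, leaky-ReLU, dropout 0.5, linear
#' output, mean squared error on per-output standardized targets.
#'
#' @param descriptors matrix, one descriptor per row.
#' @param targets matrix `n x 2` (occupancy, free energy) or `n x k`.
#' @param hidden hidden-layer widths (default `c(2048, 1024)`).
#' @param epochs,batch_size,lr,dropout training settings (defaults 125,
#'   250, 1e-3, 0.5).
#' @param seed RNG seed.
#' @return object of class `pointwise_regressor` wrapping a
#'   `hydronet_mlp` plus the target standardization.
#' @export
train_pointwise_regressor <- function(descriptors, targets,
                                      hidden = c(2048L, 1024L), epochs = 125L,
                                      batch_size = 250L, lr = 1e-3,
                                      dropout = 0.5, seed = 1L) {
  targets <- as.matrix(targets)
  if (nrow(targets) == 0L) stop("empty target set")
  mu <- colMeans(targets)
  sdv <- apply(targets, 2L, stats::sd)
  sdv[sdv < 1e-12] <- 1
  Z <- sweep(sweep(targets, 2L, mu), 2L, sdv, "/")
  net <- mlp_train(descriptors, Z, hidden, "linear", epochs = epochs,
                   batch_size = batch_size, lr = lr, dropout = dropout,
                   seed = seed)
  structure(list(net = net, mu = mu, sd = sdv), class = "pointwise_regressor")
}

#' @export
predict.pointwise_regressor <- function(object, newdata, ...) {
  Z <- predict(object$net, newdata)
  sweep(sweep(Z, 2L, object$sd, "*"), 2L, object$mu, "+")
}

# ---- permutation importance ----------------------------------------------

#' Permutation importance of input channels
#'
#' Mean-decrease-accuracy style importance: each input channel in turn has
#' its node values randomly permuted within every sample, the model is
#' re-evaluated, and the drop of the metric relative to the unperturbed
#' baseline is averaged over repeats.  Larger drop = more important
#' channel.
#'
#' @param model a trained `segmentation_model`.
#' @param dataset list of samples as in [train_segmentation()].
#' @param metric function(pred_matrix L x N, ref_matrix L x N) -> scalar;
#'   default smoothed Dice.
#' @param repeats permutations per channel (default 3).
#' @param seed RNG seed.
#' @param mask optional logical array restricting the metric.
#' @return data.frame with channel, baseline, permuted (mean metric after
#'   shuffling) and drop.
#' @export
permutation_importance <- function(model, dataset,
                                   metric = function(p, r) smoothed_dice(r, p),
                                   repeats = 3L, seed = 1L, mask = NULL) {
  samples <- lapply(dataset, .as_seg_sample)
  set.seed(seed)
  apply_mask <- function(m) {
    if (is.null(mask)) m else m[, as.vector(mask), drop = FALSE]
  }
  base_preds <- lapply(samples, function(s)
    .seg_forward(model, s$x, s$dims, FALSE)$pred)
  baseline <- mean(mapply(function(p, s) metric(apply_mask(p), apply_mask(s$r)),
                          base_preds, samples))
  C <- nrow(samples[[1]]$x)
  chn <- rownames(samples[[1]]$x)
  if (is.null(chn)) chn <- paste0("ch", seq_len(C))
  res <- lapply(seq_len(C), function(ci) {
    vals <- numeric(repeats)
    for (rep_i in seq_len(repeats)) {
      ms <- vapply(samples, function(s) {
        x <- s$x
        x[ci, ] <- x[ci, sample.int(ncol(x))]
        p <- .seg_forward(model, x, s$dims, FALSE)$pred
        metric(apply_mask(p), apply_mask(s$r))
      }, numeric(1))
      vals[rep_i] <- mean(ms)
    }
    data.frame(channel = chn[ci], baseline = baseline,
               permuted = mean(vals), drop = baseline - mean(vals))
  })
  do.call(rbind, res)
}

# ---- model checkpoints ---------------------------------------------------

#' Save a trained model to a single-file checkpoint
#'
#' The archive stores the model (configuration plus weights) together with
#' the package version and the probe/descriptor conventions it was trained
#' under; [load_model()] refuses checkpoints whose version does not match
#' the installed package.
#'
#' @param model a `segmentation_model`, `hydronet_mlp` or
#'   `pointwise_regressor`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  saveRDS(list(format = "hydronet-checkpoint",
               version = as.character(utils::packageVersion("hydronet")),
               probe_names = default_probe_table()$name,
               n_shells = nrow(shell_spec()),
               model = model),
          path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path checkpoint written by [save_model()].
#' @return the stored model object.
#' @export
load_model <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "hydronet-checkpoint"))
    stop("not a hydronet checkpoint: ", path)
  cur <- as.character(utils::packageVersion("hydronet"))
  if (!identical(ck$version, cur))
    stop("checkpoint version mismatch: saved with ", ck$version,
         ", installed package is ", cur)
  ck$model
}
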