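#  3D U-Net segmentation networks (baseline and Inception+Residual
#  variants), built on the Rcpp im2col convolution primitives.  Feature maps
#  are (channels x voxels) matrices with the voxel linear index running x
#  fastest, matching the package's grid arrays.  Every convolution or
#  inception block is followed by per-channel normalization, leaky-ReLU and
#  (optionally) dropout.  Forward passes cache every intermediate needed
#  for the hand-written backward passes; gradients are verified against
#  numerical differentiation in the test suite.

.conv_init <- function(cin, cout, k, stride = 1L, pad = 0L) {
  sd <- sqrt(2 / (cin * k^3))
  list(W = matrix(stats::rnorm(cout * cin * k^3, sd = sd), cout, cin * k^3),
       b = numeric(cout), k = as.integer(k), stride = as.integer(stride),
       pad = as.integer(pad), cin = as.integer(cin), cout = as.integer(cout))
}

.conv_f <- function(layer, x, dims) {
  r <- .conv3d_forward(x, as.integer(dims), layer$W, layer$b,
                       layer$k, layer$stride, layer$pad)
  list(y = r$y, odims = r$odims)
}

.conv_b <- function(layer, x, dims, gy) {
  .conv3d_backward(x, as.integer(dims), layer$W, gy,
                   layer$k, layer$stride, layer$pad)
}

.lrelu_f <- function(x) ifelse(x > 0, x, .lrelu_slope * x)
.lrelu_b <- function(x, gy) gy * ifelse(x > 0, 1, .lrelu_slope)

# per-channel normalization over the voxels of one sample (instance-norm
# style; keeps activations bounded without running statistics)
.norm_init <- function(C) list(gamma = rep(1, C), beta = numeric(C))

.norm_f <- function(layer, x) {
  mu <- rowMeans(x)
  xc <- x - mu
  s <- sqrt(rowMeans(xc^2) + 1e-5)
  xhat <- xc / s
  list(y = layer$gamma * xhat + layer$beta, xhat = xhat, s = s)
}

.norm_b <- function(layer, nf, gy) {
  gxhat <- gy * layer$gamma
  gx <- (gxhat - rowMeans(gxhat) - nf$xhat * rowMeans(gxhat * nf$xhat)) / nf$s
  list(gx = gx,
       grads = list(gamma = rowSums(gy * nf$xhat), beta = rowSums(gy)))
}

.up_map <- function(dims) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  ix <- rep((0:(2 * nx - 1)) %/% 2, times = 4 * ny * nz)
  iy <- rep(rep((0:(2 * ny - 1)) %/% 2, each = 2 * nx), times = 2 * nz)
  iz <- rep((0:(2 * nz - 1)) %/% 2, each = 4 * nx * ny)
  ix + nx * (iy + ny * iz) + 1L
}

.up_f <- function(x, dims) {
  map <- .up_map(dims)
  list(y = x[, map, drop = FALSE], odims = 2L * dims)
}

.up_b <- function(gy, dims) {
  map <- .up_map(dims)
  t(rowsum(t(gy), group = map))   # groups 1..N sorted: original voxel order
}

# Inception block: parallel branches with effective kernel sizes 1, 3 and 5
# ("same" padding), channel-concatenated; filter split ~ 1/4, 1/2, 1/4.
# The kernel-5 branch is factorized into two stacked kernel-3 convolutions
# (same receptive field, far less im2col traffic), with a leaky ReLU in
# between.
.incep_init <- function(cin, f) {
  f1 <- max(1L, f %/% 4L)
  f5 <- max(1L, f %/% 4L)
  f3 <- f - f1 - f5
  list(b1 = .conv_init(cin, f1, 1L, 1L, 0L),
       b3 = .conv_init(cin, f3, 3L, 1L, 1L),
       b5a = .conv_init(cin, f5, 3L, 1L, 1L),
       b5b = .conv_init(f5, f5, 3L, 1L, 1L))
}

.incep_f <- function(blk, x, dims, cache = FALSE) {
  y1 <- .conv_f(blk$b1, x, dims)$y
  y3 <- .conv_f(blk$b3, x, dims)$y
  y5a <- .conv_f(blk$b5a, x, dims)$y
  y5 <- .conv_f(blk$b5b, .lrelu_f(y5a), dims)$y
  y <- rbind(y1, y3, y5)
  if (cache) attr(y, "y5a") <- y5a
  y
}

.incep_b <- function(blk, x, dims, gy, y5a = NULL) {
  if (is.null(y5a)) y5a <- .conv_f(blk$b5a, x, dims)$y
  n1 <- blk$b1$cout; n3 <- blk$b3$cout
  g1 <- .conv_b(blk$b1, x, dims, gy[seq_len(n1), , drop = FALSE])
  g3 <- .conv_b(blk$b3, x, dims, gy[n1 + seq_len(n3), , drop = FALSE])
  g5b <- .conv_b(blk$b5b, .lrelu_f(y5a), dims,
                 gy[(n1 + n3 + 1):nrow(gy), , drop = FALSE])
  g5a <- .conv_b(blk$b5a, x, dims, .lrelu_b(y5a, g5b$gx))
  list(gx = g1$gx + g3$gx + g5a$gx,
       grads = list(b1 = list(W = g1$gW, b = as.numeric(g1$gb)),
                    b3 = list(W = g3$gW, b = as.numeric(g3$gb)),
                    b5a = list(W = g5a$gW, b = as.numeric(g5a$gb)),
                    b5b = list(W = g5b$gW, b = as.numeric(g5b$gb))))
}

.dropout_f <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(y = x, mask = NULL))
  m <- matrix(stats::runif(length(x)) >= rate, nrow(x), ncol(x)) / (1 - rate)
  list(y = x * m, mask = m)
}

# one conv-or-inception block: body -> norm -> leaky ReLU -> dropout
.block_f <- function(blk, nrm, x, dims, incep, dropout, training) {
  if (incep) {
    z <- .incep_f(blk, x, dims, cache = TRUE)
    odims <- dims
  } else {
    r <- .conv_f(blk, x, dims)
    z <- r$y
    odims <- r$odims
  }
  nf <- .norm_f(nrm, z)
  dr <- .dropout_f(.lrelu_f(nf$y), dropout, training)
  list(y = dr$y, odims = odims,
       cache = list(x = x, dims = dims, z = z, nf = nf, mask = dr$mask))
}

.block_b <- function(blk, nrm, cc, gy, incep) {
  if (!is.null(cc$mask)) gy <- gy * cc$mask
  gy <- .lrelu_b(cc$nf$y, gy)
  nb <- .norm_b(nrm, cc$nf, gy)
  if (incep) {
    gb <- .incep_b(blk, cc$x, cc$dims, nb$gx, attr(cc$z, "y5a"))
    list(gx = gb$gx, gblk = gb$grads, gnrm = nb$grads)
  } else {
    gb <- .conv_b(blk, cc$x, cc$dims, nb$gx)
    list(gx = gb$gx, gblk = list(W = gb$gW, b = as.numeric(gb$gb)),
         gnrm = nb$grads)
  }
}

#' Segmentation network configuration
#'
#' @param variant "inception_residual" (default) or "baseline".
#' @param encoder_filters filter counts per encoder stage; the first stage
#'   keeps full resolution, every later stage halves it.  Defaults:
#'   baseline `c(32, 64, 128, 256, 512, 512)` (6 stages), inception_residual
#'   `c(32, 64, 128, 256, 512)` (5 stages).
#' @param decoder_filters filter counts per decoder stage (one fewer than
#'   encoder stages).
#' @param in_channels input probe channels (default 12).
#' @param out_channels output occupancy-threshold channels (default 6).
#' @param dropout dropout rate inside blocks during training.
#' @return list of class `segmentation_config`.
#' @export
segmentation_config <- function(variant = c("inception_residual", "baseline"),
                                encoder_filters = NULL, decoder_filters = NULL,
                                in_channels = 12L, out_channels = 6L,
                                dropout = 0.1) {
  variant <- match.arg(variant)
  if (is.null(encoder_filters))
    encoder_filters <- if (variant == "baseline") c(32L, 64L, 128L, 256L, 512L, 512L)
    else c(32L, 64L, 128L, 256L, 512L)
  L <- length(encoder_filters)
  if (L < 2L) stop("need at least 2 encoder stages")
  if (is.null(decoder_filters))
    decoder_filters <- rev(encoder_filters[-L])
  if (length(decoder_filters) != L - 1L)
    stop("decoder_filters must have one entry fewer than encoder_filters")
  structure(list(variant = variant,
                 encoder_filters = as.integer(encoder_filters),
                 decoder_filters = as.integer(decoder_filters),
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 dropout = dropout),
            class = "segmentation_config")
}

#' Build an untrained segmentation model
#'
#' Both variants are encoder-decoder U-Nets with stride-2 kernel-2
#' down-sampling convolutions, nearest-neighbour up-sampling and skip
#' connections; every convolution or inception block is followed by
#' per-channel normalization, leaky-ReLU activation and dropout.  The
#' inception_residual variant replaces plain convolutions with Inception
#' blocks (parallel effective kernels 1/3/5) and passes each skip through a
#' residual block.  The final layer is a kernel-1 convolution to
#' `out_channels` with sigmoid activation (one independent probability per
#' occupancy threshold, since the labels are cumulative).  Input grids must
#' be divisible by `2^(n_encoder_stages - 1)` per axis.
#'
#' @param config a `segmentation_config`.
#' @param seed RNG seed for weight initialization.
#' @return object of class `segmentation_model`.
#' @export
build_segmentation_model <- function(config = segmentation_config(), seed = 1L) {
  set.seed(seed)
  L <- length(config$encoder_filters)
  ef <- config$encoder_filters
  df <- config$decoder_filters
  incep <- config$variant == "inception_residual"
  p <- list(enc = vector("list", L), nenc = vector("list", L),
            down = vector("list", L), ndown = vector("list", L),
            dec = vector("list", L - 1L), ndec = vector("list", L - 1L),
            res = vector("list", L - 1L), nres = vector("list", L - 1L))
  p$enc[[1]] <- if (incep) .incep_init(config$in_channels, ef[1])
                else .conv_init(config$in_channels, ef[1], 3L, 1L, 1L)
  p$nenc[[1]] <- .norm_init(ef[1])
  for (l in 2:L) {
    p$down[[l]] <- .conv_init(ef[l - 1L], ef[l], 2L, 2L, 0L)
    p$ndown[[l]] <- .norm_init(ef[l])
    if (incep) {
      p$enc[[l]] <- .incep_init(ef[l], ef[l])
      p$nenc[[l]] <- .norm_init(ef[l])
    }
  }
  for (j in seq_len(L - 1L)) {
    l <- L - j                       # decoder j consumes the skip from level l
    cin <- if (j == 1L) ef[L] else df[j - 1L] + ef[l + 1L]
    p$dec[[j]] <- if (incep) .incep_init(cin, df[j])
                  else .conv_init(cin, df[j], 3L, 1L, 1L)
    p$ndec[[j]] <- .norm_init(df[j])
    if (incep) {
      p$res[[j]] <- .conv_init(ef[l], ef[l], 3L, 1L, 1L)
      p$nres[[j]] <- .norm_init(ef[l])
    }
  }
  p$final <- .conv_init(df[L - 1L] + ef[1], config$out_channels, 1L, 1L, 0L)
  structure(list(config = config, params = p, seed = seed),
            class = "segmentation_model")
}

#' Number of encoder stages of a model
#' @param model a `segmentation_model`.
#' @return integer stage count.
#' @export
n_encoder_stages <- function(model) length(model$config$encoder_filters)

.check_seg_dims <- function(model, dims) {
  div <- 2^(n_encoder_stages(model) - 1L)
  if (any(dims %% div != 0))
    stop("input dims must be divisible by ", div,
         " for this network depth (got ", paste(dims, collapse = "x"), ")")
}

# full forward pass; x is (in_channels x N), dims the spatial dims.
.seg_forward <- function(model, x, dims, training = FALSE) {
  cfg <- model$config
  p <- model$params
  L <- length(cfg$encoder_filters)
  .check_seg_dims(model, dims)
  incep <- cfg$variant == "inception_residual"
  cache <- list(enc = vector("list", L), down = vector("list", L),
                dec = vector("list", L - 1L), res = vector("list", L - 1L))
  h <- vector("list", L)
  ddims <- vector("list", L)
  cur <- x; curd <- dims
  for (l in seq_len(L)) {
    if (l > 1L) {
      bf <- .block_f(p$down[[l]], p$ndown[[l]], cur, curd, FALSE,
                     cfg$dropout, training)
      cache$down[[l]] <- bf$cache
      cur <- bf$y; curd <- bf$odims
    }
    if (!is.null(p$enc[[l]])) {
      bf <- .block_f(p$enc[[l]], p$nenc[[l]], cur, curd, incep,
                     cfg$dropout, training)
      cache$enc[[l]] <- bf$cache
      cur <- bf$y
    }
    h[[l]] <- cur
    ddims[[l]] <- curd
  }
  for (j in seq_len(L - 1L)) {
    l <- L - j
    up <- .up_f(cur, curd)
    curd <- up$odims
    bf <- .block_f(p$dec[[j]], p$ndec[[j]], up$y, curd, incep,
                   cfg$dropout, training)
    cache$dec[[j]] <- bf$cache
    skip_in <- h[[l]]
    if (incep) {
      rz <- .conv_f(p$res[[j]], skip_in, ddims[[l]])$y
      rn <- .norm_f(p$nres[[j]], rz)
      pre <- skip_in + rn$y
      skip <- .lrelu_f(pre)
      cache$res[[j]] <- list(x = skip_in, dims = ddims[[l]], rn = rn, pre = pre)
    } else skip <- skip_in
    cache$dec[[j]]$nc_dec <- nrow(bf$y)
    cur <- rbind(bf$y, skip)
  }
  zf <- .conv_f(p$final, cur, curd)$y
  pred <- 1 / (1 + exp(-zf))
  cache$final <- list(x = cur, dims = curd, z = zf)
  list(pred = pred, cache = cache)
}

# backward pass from dLoss/dpred; returns gradient tree matching params.
.seg_backward <- function(model, cache, gpred) {
  cfg <- model$config
  p <- model$params
  L <- length(cfg$encoder_filters)
  incep <- cfg$variant == "inception_residual"
  g <- list(enc = vector("list", L), nenc = vector("list", L),
            down = vector("list", L), ndown = vector("list", L),
            dec = vector("list", L - 1L), ndec = vector("list", L - 1L),
            res = vector("list", L - 1L), nres = vector("list", L - 1L))

  pred <- 1 / (1 + exp(-cache$final$z))
  gz <- gpred * pred * (1 - pred)
  gf <- .conv_b(p$final, cache$final$x, cache$final$dims, gz)
  g$final <- list(W = gf$gW, b = as.numeric(gf$gb))
  gcur <- gf$gx

  gh <- vector("list", L)   # gradients flowing into the encoder outputs
  for (j in (L - 1L):1L) {
    cc <- cache$dec[[j]]
    l <- L - j
    nd <- cc$nc_dec
    gdec_out <- gcur[seq_len(nd), , drop = FALSE]
    gskip <- gcur[(nd + 1L):nrow(gcur), , drop = FALSE]
    if (incep) {
      rc <- cache$res[[j]]
      gpre <- .lrelu_b(rc$pre, gskip)
      nb <- .norm_b(p$nres[[j]], rc$rn, gpre)
      gr <- .conv_b(p$res[[j]], rc$x, rc$dims, nb$gx)
      g$res[[j]] <- list(W = gr$gW, b = as.numeric(gr$gb))
      g$nres[[j]] <- nb$grads
      gskip_in <- gpre + gr$gx
    } else gskip_in <- gskip
    gh[[l]] <- if (is.null(gh[[l]])) gskip_in else gh[[l]] + gskip_in
    bb <- .block_b(p$dec[[j]], p$ndec[[j]], cc, gdec_out, incep)
    g$dec[[j]] <- bb$gblk
    g$ndec[[j]] <- bb$gnrm
    gcur <- .up_b(bb$gx, cc$dims %/% 2L)   # dims before the 2x upsample
  }
  gh[[L]] <- if (is.null(gh[[L]])) gcur else gh[[L]] + gcur

  for (l in L:1L) {
    gcur <- gh[[l]]
    if (!is.null(p$enc[[l]])) {
      bb <- .block_b(p$enc[[l]], p$nenc[[l]], cache$enc[[l]], gcur, incep)
      g$enc[[l]] <- bb$gblk
      g$nenc[[l]] <- bb$gnrm
      gcur <- bb$gx
    }
    if (l > 1L) {
      bb <- .block_b(p$down[[l]], p$ndown[[l]], cache$down[[l]], gcur, FALSE)
      g$down[[l]] <- bb$gblk
      g$ndown[[l]] <- bb$gnrm
      gh[[l - 1L]] <- if (is.null(gh[[l - 1L]])) bb$gx else gh[[l - 1L]] + bb$gx
    }
  }
  g
}

#' Run a segmentation model on a probe-channel grid
#'
#' @param model a trained `segmentation_model`.
#' @param channels a `multi_channel_grid` (or channels x voxels matrix with
#'   a `dims` attribute).
#' @return array `dims x out_channels` of per-threshold probabilities.
#' @export
predict_segmentation <- function(model, channels) {
  if (inherits(channels, "multi_channel_grid")) {
    dims <- channels$spec$dims
    x <- do.call(rbind, lapply(channels$channels, as.vector))
  } else {
    x <- channels
    dims <- attr(channels, "dims")
  }
  fw <- .seg_forward(model, x, dims, training = FALSE)
  array(t(fw$pred), dim = c(dims, model$config$out_channels))
}
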