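#  Minimal fully connected network engine (leaky-ReLU hidden layers,
#  dropout, Adam) used by the point-wise classifier and regressor.  Written
#  in base R matrix algebra; gradients are verified against numerical
#  differentiation in the test suite.

.lrelu_slope <- 0.1

.mlp_init <- function(sizes, seed) {
  set.seed(seed)
  L <- length(sizes) - 1L
  W <- vector("list", L)
  b <- vector("list", L)
  for (i in seq_len(L)) {
    sd <- sqrt(2 / sizes[i])
    W[[i]] <- matrix(stats::rnorm(sizes[i] * sizes[i + 1], sd = sd),
                     sizes[i], sizes[i + 1])
    b[[i]] <- numeric(sizes[i + 1])
  }
  list(W = W, b = b)
}

# forward pass; returns pre-activations and dropout masks for backprop
.mlp_forward <- function(params, X, out_activation, dropout = 0, training = FALSE) {
  L <- length(params$W)
  A <- X
  Zs <- vector("list", L)
  As <- vector("list", L + 1L)
  masks <- vector("list", L)
  As[[1]] <- A
  for (i in seq_len(L)) {
    Z <- A %*% params$W[[i]] + matrix(params$b[[i]], nrow(A), length(params$b[[i]]),
                                      byrow = TRUE)
    Zs[[i]] <- Z
    if (i < L) {
      A <- ifelse(Z > 0, Z, .lrelu_slope * Z)
      if (training && dropout > 0) {
        m <- matrix(stats::runif(length(A)) >= dropout, nrow(A), ncol(A)) / (1 - dropout)
        masks[[i]] <- m
        A <- A * m
      }
    } else {
      A <- switch(out_activation,
                  sigmoid = 1 / (1 + exp(-Z)),
                  linear = Z)
    }
    As[[i + 1L]] <- A
  }
  list(out = A, Zs = Zs, As = As, masks = masks)
}

# gradient of the loss w.r.t. parameters; dout is dLoss/d(pre-activation of
# the output layer) -- both BCE+sigmoid and MSE+linear reduce to (out - Y).
.mlp_backward <- function(params, cache, dout, dropout = 0) {
  L <- length(params$W)
  gW <- vector("list", L)
  gb <- vector("list", L)
  delta <- dout
  for (i in L:1) {
    gW[[i]] <- crossprod(cache$As[[i]], delta)
    gb[[i]] <- colSums(delta)
    if (i > 1L) {
      dA <- tcrossprod(delta, params$W[[i]])
      if (!is.null(cache$masks[[i - 1L]])) dA <- dA * cache$masks[[i - 1L]]
      Z <- cache$Zs[[i - 1L]]
      delta <- dA * ifelse(Z > 0, 1, .lrelu_slope)
    }
  }
  list(W = gW, b = gb)
}

.adam_state <- function(params) {
  zero_like <- function(x) if (is.list(x)) lapply(x, zero_like) else x * 0
  list(m = zero_like(params), v = zero_like(params), t = 0)
}

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  # walk params and grads in parallel; leaves without a gradient (layer
  # hyper-parameters such as kernel size, or unused slots) are untouched.
  upd <- function(p, g, m, v) {
    if (is.null(g)) return(list(p = p, m = m, v = v))
    if (is.list(p)) {
      keys <- if (!is.null(names(p))) names(p) else seq_along(p)
      pm <- m; pv <- v
      for (kk in keys) {
        gk <- if (is.list(g) && ((is.character(kk) && kk %in% names(g)) ||
                                 (!is.character(kk) && kk <= length(g))))
          g[[kk]] else NULL
        o <- upd(p[[kk]], gk, m[[kk]], v[[kk]])
        # list() wrapping keeps NULL placeholders (e.g. the unused first
        # down-sampling slot) instead of deleting them
        p[kk] <- list(o$p); pm[kk] <- list(o$m); pv[kk] <- list(o$v)
      }
      return(list(p = p, m = pm, v = pv))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^state$t)
    vhat <- v / (1 - beta2^state$t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  out <- upd(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = state$t))
}

#' Train a fully connected network
#'
#' Shared backbone of the point-wise classifier and regressor: leaky-ReLU
#' hidden layers with dropout, an output layer with sigmoid (binary
#' cross-entropy loss) or linear (mean squared error) activation, Adam
#' optimization with fixed seed.
#'
#' @param X numeric matrix, samples in rows.
#' @param Y numeric matrix of targets (n x 1 labels in [0,1] for
#'   classification, n x k for regression).
#' @param hidden integer vector of hidden-layer widths.
#' @param out_activation "sigmoid" or "linear".
#' @param epochs,batch_size,lr,dropout training hyper-parameters.
#' @param seed integer RNG seed; fixes initialization, shuffling and
#'   dropout masks.
#' @param verbose print the loss every few epochs.
#' @return object of class `hydronet_mlp` with elements `params`, `config`
#'   and `history` (mean training loss per epoch).
#' @export
mlp_train <- function(X, Y, hidden, out_activation = c("linear", "sigmoid"),
                      epochs = 50L, batch_size = 250L, lr = 1e-3,
                      dropout = 0.5, seed = 1L, verbose = FALSE) {
  out_activation <- match.arg(out_activation)
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) == 0L) stop("empty training set")
  sizes <- c(ncol(X), hidden, ncol(Y))
  params <- .mlp_init(sizes, seed)
  state <- .adam_state(params)
  n <- nrow(X)
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    tot <- 0
    for (s in seq(1L, n, by = batch_size)) {
      idx <- ord[s:min(n, s + batch_size - 1L)]
      xb <- X[idx, , drop = FALSE]
      yb <- Y[idx, , drop = FALSE]
      cache <- .mlp_forward(params, xb, out_activation, dropout, training = TRUE)
      if (out_activation == "sigmoid") {
        p <- pmin(pmax(cache$out, 1e-12), 1 - 1e-12)
        loss <- -mean(yb * log(p) + (1 - yb) * log(1 - p))
      } else {
        loss <- mean((cache$out - yb)^2)
      }
      dout <- (cache$out - yb) / length(yb)   # dLoss/dZ_out for both losses
      if (out_activation == "linear") dout <- 2 * dout
      grads <- .mlp_backward(params, cache, dout, dropout)
      st <- .adam_step(params, grads, state, lr)
      params <- st$params
      state[c("m", "v", "t")] <- st$state
      tot <- tot + loss * length(idx)
    }
    history[ep] <- tot / n
    if (verbose && (ep %% 10L == 0L || ep == 1L))
      message(sprintf("epoch %d: loss %.5f", ep, history[ep]))
  }
  structure(list(params = params,
                 config = list(sizes = sizes, out_activation = out_activation,
                               dropout = dropout, lr = lr, epochs = epochs,
                               batch_size = batch_size, seed = seed),
                 history = history),
            class = "hydronet_mlp")
}

#' Predict with a trained fully connected network
#'
#' @param object a `hydronet_mlp`.
#' @param newdata matrix of descriptors, samples in rows.
#' @param ... unused.
#' @return matrix of network outputs.
#' @export
predict.hydronet_mlp <- function(object, newdata, ...) {
  .mlp_forward(object$params, as.matrix(newdata),
               object$config$out_activation, dropout = 0, training = FALSE)$out
}
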