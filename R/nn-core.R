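## Minimal reverse-mode layer library for the package's classifiers.
## Activations are 4-d arrays laid out (time, electrode, batch, channel):
## temporal windows are then contiguous in memory and every convolution
## reduces to one im2col + BLAS matrix multiply.

## ---- temporal convolution (groups = 1) ------------------------------------
## x: (T, H, N, Cin); W: (k, Cin, Cout); b: Cout
conv_time_fwd <- function(x, W, b, pad = 0) {
  d <- dim(x); T <- d[1]; H <- d[2]; N <- d[3]; C <- d[4]
  k <- dim(W)[1]; Cout <- dim(W)[3]
  if (dim(W)[2] != C) stop("conv_time: input has ", C, " channels, kernel ",
                           dim(W)[2], call. = FALSE)
  HN <- H * N
  xm <- x
  dim(xm) <- c(T, HN * C)
  if (pad > 0) {
    xpm <- matrix(0, T + 2 * pad, HN * C)
    xpm[(pad + 1):(pad + T), ] <- xm
  } else xpm <- xm
  Tout <- nrow(xpm) - k + 1
  Xcol <- matrix(0, Tout * HN, k * C)
  for (c in seq_len(C)) {
    cols <- ((c - 1) * HN + 1):(c * HN)
    for (r in seq_len(k)) {
      Xcol[, (c - 1) * k + r] <- xpm[r:(r + Tout - 1), cols]
    }
  }
  Y <- Xcol %*% matrix(W, k * C, Cout)
  Y <- Y + rep(b, each = nrow(Y))
  list(y = array(Y, c(Tout, H, N, Cout)),
       cache = list(Xcol = Xcol, dims = d, k = k, pad = pad, W = W))
}

conv_time_bwd <- function(dy, cache) {
  d <- cache$dims; T <- d[1]; H <- d[2]; N <- d[3]; C <- d[4]
  k <- cache$k; pad <- cache$pad; W <- cache$W
  Cout <- dim(W)[3]
  Tout <- dim(dy)[1]
  dYm <- matrix(dy, Tout * H * N, Cout)
  dW <- array(crossprod(cache$Xcol, dYm), dim(W))
  db <- colSums(dYm)
  dXcol <- tcrossprod(dYm, matrix(W, k * C, Cout))
  Tp <- T + 2 * pad
  HN <- H * N
  dxpm <- matrix(0, Tp, HN * C)
  for (c in seq_len(C)) {
    cols <- ((c - 1) * HN + 1):(c * HN)
    for (r in seq_len(k)) {
      dxpm[r:(r + Tout - 1), cols] <- dxpm[r:(r + Tout - 1), cols] +
        matrix(dXcol[, (c - 1) * k + r], Tout, HN)
    }
  }
  dxm <- if (pad > 0) dxpm[(pad + 1):(pad + T), , drop = FALSE] else dxpm
  list(dx = array(dxm, d), dW = dW, db = db)
}

## ---- depthwise temporal convolution (groups = Cin) ------------------------
## x: (T, H, N, Cin); W: (k, mult, Cin); b: Cin * mult; valid mode.
## Output channel (c-1)*mult + j comes from input channel c.
conv_depthwise_fwd <- function(x, W, b) {
  d <- dim(x); T <- d[1]; H <- d[2]; N <- d[3]; C <- d[4]
  k <- dim(W)[1]; mult <- dim(W)[2]
  if (dim(W)[3] != C) stop("depthwise: channel mismatch", call. = FALSE)
  Tout <- T - k + 1
  HN <- H * N
  xm <- x
  dim(xm) <- c(T, HN * C)
  ym <- matrix(0, Tout * HN, C * mult)
  Xcols <- vector("list", C)
  for (c in seq_len(C)) {
    cols <- ((c - 1) * HN + 1):(c * HN)
    Xc <- matrix(0, Tout * HN, k)
    for (r in seq_len(k)) Xc[, r] <- xm[r:(r + Tout - 1), cols]
    out_cols <- (c - 1) * mult + seq_len(mult)
    ym[, out_cols] <- Xc %*% W[, , c] +
      rep(b[out_cols], each = Tout * HN)
    Xcols[[c]] <- Xc
  }
  list(y = array(ym, c(Tout, H, N, C * mult)),
       cache = list(Xcols = Xcols, dims = d, W = W))
}

conv_depthwise_bwd <- function(dy, cache) {
  d <- cache$dims; T <- d[1]; H <- d[2]; N <- d[3]; C <- d[4]
  W <- cache$W; k <- dim(W)[1]; mult <- dim(W)[2]
  Tout <- dim(dy)[1]
  HN <- H * N
  dym <- dy
  dim(dym) <- c(Tout * HN, C * mult)
  dxm <- matrix(0, T, HN * C)
  dW <- array(0, dim(W))
  db <- numeric(C * mult)
  for (c in seq_len(C)) {
    out_cols <- (c - 1) * mult + seq_len(mult)
    in_cols <- ((c - 1) * HN + 1):(c * HN)
    dYc <- dym[, out_cols, drop = FALSE]
    dW[, , c] <- crossprod(cache$Xcols[[c]], dYc)
    db[out_cols] <- colSums(dYc)
    dXc <- tcrossprod(dYc, W[, , c])
    for (r in seq_len(k)) {
      dxm[r:(r + Tout - 1), in_cols] <- dxm[r:(r + Tout - 1), in_cols] +
        matrix(dXc[, r], Tout, HN)
    }
  }
  list(dx = array(dxm, d), dW = dW, db = db)
}

## ---- batch normalization ---------------------------------------------------
## Core operates on an m x features matrix; the conv wrapper folds
## (T, H, N) into m so statistics are per channel.

#' Initialize batch-normalization state
#'
#' @param n_features Number of features to normalize.
#' @param eps Variance stability constant.
#' @param momentum Running-statistics update rate.
#' @return List with learnable \code{gamma}/\code{beta} and running
#'   statistics, as consumed by \code{\link{batch_norm}}.
#' @export
bn_init <- function(n_features, eps = 1e-5, momentum = 0.1) {
  list(gamma = rep(1, n_features), beta = rep(0, n_features),
       running_mean = rep(0, n_features), running_var = rep(1, n_features),
       eps = eps, momentum = momentum)
}

bn_fwd_mat <- function(M, p, mode) {
  if (mode == "train") {
    if (nrow(M) < 2) stop("batch norm needs a batch of at least 2 in train",
                          " mode", call. = FALSE)
    mu <- colMeans(M)
    v <- colMeans(M^2) - mu^2
    p$running_mean <- (1 - p$momentum) * p$running_mean + p$momentum * mu
    p$running_var <- (1 - p$momentum) * p$running_var + p$momentum * v
  } else {
    mu <- p$running_mean
    v <- p$running_var
  }
  inv <- 1 / sqrt(v + p$eps)
  m <- nrow(M)
  ## fused: y = M * (inv * gamma) + (beta - mu * inv * gamma)
  k1 <- inv * p$gamma
  xhat <- M * rep(inv, each = m) - rep(mu * inv, each = m)
  y <- M * rep(k1, each = m) + rep(p$beta - mu * k1, each = m)
  list(y = y, params = p,
       cache = list(xhat = xhat, inv = inv, gamma = p$gamma,
                    train = mode == "train"))
}

bn_bwd_mat <- function(dY, cache) {
  m <- nrow(dY)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dxhat <- dY * rep(cache$gamma, each = m)
  if (cache$train) {
    t1 <- dxhat - rep(colMeans(dxhat), each = m)
    t2 <- cache$xhat * rep(colMeans(dxhat * cache$xhat), each = m)
    dX <- (t1 - t2) * rep(cache$inv, each = m)
  } else {
    dX <- dxhat * rep(cache$inv, each = m)
  }
  list(dx = dX, dgamma = dgamma, dbeta = dbeta)
}

bn_fwd_chan <- function(x, p, mode) {
  d <- dim(x)
  dim(x) <- c(prod(d[1:3]), d[4])
  out <- bn_fwd_mat(x, p, mode)
  dim(out$y) <- d
  out$cache$dims <- d
  out
}

bn_bwd_chan <- function(dy, cache) {
  d <- cache$dims
  dim(dy) <- c(prod(d[1:3]), d[4])
  out <- bn_bwd_mat(dy, cache)
  dim(out$dx) <- d
  out
}

#' Batch normalization of a feature matrix
#'
#' Per-feature standardization by batch statistics (train mode) or by
#' running statistics (eval mode), followed by the learned scale and shift
#' \eqn{y = \gamma \hat{x} + \beta}. Train mode updates the running
#' statistics by exponential moving average.
#'
#' @param x Batch x features numeric matrix.
#' @param params State from \code{\link{bn_init}} (fields \code{gamma},
#'   \code{beta}, \code{eps}, \code{momentum}, running statistics).
#' @param mode \code{"train"} or \code{"eval"}.
#' @return List: \code{y} (normalized batch) and \code{params} (with
#'   updated running statistics in train mode).
#' @export
batch_norm <- function(x, params, mode = c("train", "eval")) {
  mode <- match.arg(mode)
  out <- bn_fwd_mat(as.matrix(x), params, mode)
  list(y = out$y, params = out$params)
}

## ---- pointwise nonlinearities, pooling, dropout, dense --------------------
## branch-free ELU: y = max(x,0) + expm1(min(x,0)); dy/dx = min(y + 1, 1)
elu_fwd <- function(x) {
  y <- pmax(x, 0) + expm1(pmin(x, 0))
  dim(y) <- dim(x)
  list(y = y, cache = y)
}

elu_bwd <- function(dy, cache) {
  dy * pmin(cache + 1, 1)
}

avgpool_time_fwd <- function(x, k) {
  d <- dim(x)
  Tk <- d[1] %/% k
  xt <- x[1:(Tk * k), , , , drop = FALSE]
  y <- array(colMeans(matrix(xt, k, Tk * d[2] * d[3] * d[4])),
             c(Tk, d[2], d[3], d[4]))
  list(y = y, cache = list(dims = d, k = k, Tk = Tk))
}

avgpool_time_bwd <- function(dy, cache) {
  d <- cache$dims; k <- cache$k; Tk <- cache$Tk
  up <- matrix(rep(as.vector(dy) / k, each = k), k * Tk)
  dx <- array(0, d)
  dx[1:(k * Tk), , , ] <- array(up, c(k * Tk, d[2], d[3], d[4]))
  dx
}

dropout_fwd <- function(x, p, mode) {
  if (mode != "train" || p <= 0) {
    return(list(y = x, cache = NULL))
  }
  mask <- array(stats::rbinom(length(x), 1, 1 - p) / (1 - p), dim(x))
  list(y = x * mask, cache = mask)
}

dropout_bwd <- function(dy, cache) {
  if (is.null(cache)) dy else dy * cache
}

## flatten (T,H,N,C) -> (N, T*H*C), sample-major
flatten_fwd <- function(x) {
  d <- dim(x)
  list(y = t(matrix(aperm(x, c(1, 2, 4, 3)), d[1] * d[2] * d[4], d[3])),
       cache = d)
}

flatten_bwd <- function(dy, d) {
  aperm(array(t(dy), c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
}

dense_fwd <- function(x, W, b) {
  list(y = x %*% W + rep(b, each = nrow(x)), cache = list(x = x, W = W))
}

dense_bwd <- function(dy, cache) {
  list(dx = tcrossprod(dy, cache$W),
       dW = crossprod(cache$x, dy), db = colSums(dy))
}

## ---- weighted softmax cross-entropy ---------------------------------------
## scores: N x K; y: integer class 1..K; w: per-class weights
softmax_xent <- function(scores, y, w = rep(1, ncol(scores))) {
  N <- nrow(scores)
  s <- scores - apply(scores, 1, max)
  es <- exp(s)
  p <- es / rowSums(es)
  wi <- w[y]
  idx <- cbind(seq_len(N), y)
  loss <- -sum(wi * log(pmax(p[idx], 1e-300))) / sum(wi)
  dp <- p * wi
  dp[idx] <- dp[idx] - wi
  list(loss = loss, dscores = dp / sum(wi), probs = p)
}

## ---- Adam ------------------------------------------------------------------
adam_init <- function(params) {
  list(m = rapply(params, function(p) p * 0, how = "replace"),
       v = rapply(params, function(p) p * 0, how = "replace"),
       t = 0)
}

## params and grads share one nested-list shape; state updated in lockstep
adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- lapply(stats::setNames(names(p), names(p)), function(nm) {
        walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
      })
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^state$t)
    vhat <- v / (1 - beta2^state$t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  out <- walk(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = state$t))
}
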