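#' EEGNet-style network configuration
#'
#' Compact convolutional classifier for epochs of shape channels x samples:
#' temporal convolution (1 -> 16 feature maps, kernel (1, 51), padding
#' (0, 25) so the time length is preserved) -> batch norm -> depthwise
#' temporal convolution (16 -> 32, kernel (1, 10), groups 16, valid mode)
#' -> batch norm -> activation -> average pooling (1, 4) -> pointwise 1x1
#' convolution (32 -> 32) -> batch norm -> activation -> flatten ->
#' dropout -> dense to 2 classes. With 8 x 400 input the time dimension
#' runs 400 -> 400 -> 391 -> 97.
#'
#' @param n_channels Electrode count (input height), default 8.
#' @param n_samples Epoch length in samples, default 400.
#' @param f1 Temporal feature maps (default 16).
#' @param depth_mult Depthwise multiplier (default 2, giving 32 maps).
#' @param kernel1,pad1 Temporal kernel length and padding (51, 25).
#' @param kernel_dw Depthwise kernel length (10).
#' @param pool Average-pooling width (4).
#' @param dropout Dropout rate before the dense head (0.25).
#' @param activation Only \code{"elu"} is implemented.
#' @param bn_eps,bn_momentum Batch-norm constants.
#' @param n_classes Output classes (2: RH, ND).
#' @return List of class \code{eegnet_config}.
#' @export
eegnet_config <- function(n_channels = 8, n_samples = 400, f1 = 16,
                          depth_mult = 2, kernel1 = 51, pad1 = 25,
                          kernel_dw = 10, pool = 4, dropout = 0.25,
                          activation = "elu", bn_eps = 1e-5,
                          bn_momentum = 0.1, n_classes = 2) {
  stopifnot(activation == "elu", f1 >= 1, depth_mult >= 1)
  cfg <- structure(list(n_channels = n_channels, n_samples = n_samples,
                        f1 = f1, depth_mult = depth_mult, kernel1 = kernel1,
                        pad1 = pad1, kernel_dw = kernel_dw, pool = pool,
                        dropout = dropout, activation = activation,
                        bn_eps = bn_eps, bn_momentum = bn_momentum,
                        n_classes = n_classes),
                   class = c("eegnet_config", "model_config"))
  sh <- eegnet_shapes(cfg)
  if (sh$t_dw < 1) stop("epoch too short for the depthwise kernel",
                        call. = FALSE)
  cfg
}

#' Layer-by-layer shape contract, from the configuration alone
#'
#' @param cfg An \code{\link{eegnet_config}}.
#' @return List of time lengths \code{t_in}, \code{t_conv1}, \code{t_dw},
#'   \code{t_pool}, channel counts \code{c_conv1}, \code{c_dw}, and the
#'   flattened feature count \code{n_flat}.
#' @export
eegnet_shapes <- function(cfg) {
  t1 <- cfg$n_samples + 2 * cfg$pad1 - cfg$kernel1 + 1
  t_dw <- t1 - cfg$kernel_dw + 1
  t_pool <- t_dw %/% cfg$pool
  c_dw <- cfg$f1 * cfg$depth_mult
  list(t_in = cfg$n_samples, t_conv1 = t1, t_dw = t_dw, t_pool = t_pool,
       c_conv1 = cfg$f1, c_dw = c_dw,
       n_flat = t_pool * cfg$n_channels * c_dw)
}

#' Initialize EEGNet parameters
#'
#' Glorot-scaled normal weights, zero biases; deterministic under
#' \code{seed}.
#'
#' @param cfg An \code{\link{eegnet_config}}.
#' @param seed Integer RNG seed.
#' @return Nested parameter list (weights plus batch-norm states).
#' @export
eegnet_init <- function(cfg, seed = 1L) {
  set.seed(seed)
  sh <- eegnet_shapes(cfg)
  gn <- function(...) {
    d <- c(...)
    array(stats::rnorm(prod(d), sd = sqrt(2 / sum(d[1] * d[length(d)] + 1))),
          d)
  }
  list(
    conv1 = list(W = gn(cfg$kernel1, 1, cfg$f1), b = numeric(cfg$f1)),
    bn1 = bn_init(cfg$f1, cfg$bn_eps, cfg$bn_momentum),
    dw = list(W = gn(cfg$kernel_dw, cfg$depth_mult, cfg$f1),
              b = numeric(sh$c_dw)),
    bn2 = bn_init(sh$c_dw, cfg$bn_eps, cfg$bn_momentum),
    pw = list(W = gn(1, sh$c_dw, sh$c_dw), b = numeric(sh$c_dw)),
    bn3 = bn_init(sh$c_dw, cfg$bn_eps, cfg$bn_momentum),
    dense = list(W = matrix(stats::rnorm(sh$n_flat * cfg$n_classes,
                                         sd = sqrt(2 / sh$n_flat)),
                            sh$n_flat, cfg$n_classes),
                 b = numeric(cfg$n_classes)))
}

## epochs x channels x samples -> (T, H, N, 1)
epochs_to_input <- function(data) {
  d <- dim(data)
  array(aperm(data, c(3, 2, 1)), c(d[3], d[2], d[1], 1))
}

#' EEGNet forward pass
#'
#' @param x Input batch: epochs x channels x samples array, or the internal
#'   (time, electrode, batch, 1) layout.
#' @param cfg An \code{\link{eegnet_config}}.
#' @param params From \code{\link{eegnet_init}} (or a training step).
#' @param mode \code{"train"} (batch statistics, dropout active) or
#'   \code{"eval"} (running statistics, no dropout).
#' @return List: \code{scores} (batch x 2), \code{params} (running BN stats
#'   updated in train mode), \code{cache} (for the backward pass).
#' @export
eegnet_forward <- function(x, cfg, params, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  if (length(dim(x)) == 3) x <- epochs_to_input(x)
  d <- dim(x)
  if (d[1] != cfg$n_samples || d[2] != cfg$n_channels) {
    stop("input is ", d[2], " channels x ", d[1], " samples; config wants ",
         cfg$n_channels, " x ", cfg$n_samples, call. = FALSE)
  }
  cache <- list()
  c1 <- conv_time_fwd(x, params$conv1$W, params$conv1$b, pad = cfg$pad1)
  cache$c1 <- c1$cache
  b1 <- bn_fwd_chan(c1$y, params$bn1, mode)
  params$bn1 <- b1$params; cache$b1 <- b1$cache
  dw <- conv_depthwise_fwd(b1$y, params$dw$W, params$dw$b)
  cache$dw <- dw$cache
  b2 <- bn_fwd_chan(dw$y, params$bn2, mode)
  params$bn2 <- b2$params; cache$b2 <- b2$cache
  a1 <- elu_fwd(b2$y); cache$a1 <- a1$cache
  pl <- avgpool_time_fwd(a1$y, cfg$pool); cache$pl <- pl$cache
  pw <- conv_time_fwd(pl$y, params$pw$W, params$pw$b, pad = 0)
  cache$pw <- pw$cache
  b3 <- bn_fwd_chan(pw$y, params$bn3, mode)
  params$bn3 <- b3$params; cache$b3 <- b3$cache
  a2 <- elu_fwd(b3$y); cache$a2 <- a2$cache
  fl <- flatten_fwd(a2$y); cache$fl <- fl$cache
  dr <- dropout_fwd(fl$y, cfg$dropout, mode); cache$dr <- dr$cache
  de <- dense_fwd(dr$y, params$dense$W, params$dense$b)
  cache$de <- de$cache
  list(scores = de$y, params = params, cache = cache)
}

## gradient of all parameters given dscores
eegnet_backward <- function(dscores, cache) {
  g <- list()
  de <- dense_bwd(dscores, cache$de)
  g$dense <- list(W = de$dW, b = de$db)
  dd <- dropout_bwd(de$dx, cache$dr)
  dfl <- flatten_bwd(dd, cache$fl)
  da2 <- elu_bwd(dfl, cache$a2)
  b3 <- bn_bwd_chan(da2, cache$b3)
  g$bn3 <- list(gamma = b3$dgamma, beta = b3$dbeta)
  pw <- conv_time_bwd(b3$dx, cache$pw)
  g$pw <- list(W = pw$dW, b = pw$db)
  dpl <- avgpool_time_bwd(pw$dx, cache$pl)
  da1 <- elu_bwd(dpl, cache$a1)
  b2 <- bn_bwd_chan(da1, cache$b2)
  g$bn2 <- list(gamma = b2$dgamma, beta = b2$dbeta)
  dw <- conv_depthwise_bwd(b2$dx, cache$dw)
  g$dw <- list(W = dw$dW, b = dw$db)
  b1 <- bn_bwd_chan(dw$dx, cache$b1)
  g$bn1 <- list(gamma = b1$dgamma, beta = b1$dbeta)
  c1 <- conv_time_bwd(b1$dx, cache$c1)
  g$conv1 <- list(W = c1$dW, b = c1$db)
  g
}
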