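#' Recurrent baseline configuration (RNN / LSTM)
#'
#' Two stacked recurrent layers with input size 1000 and hidden size 128,
#' followed by a dense head on the final hidden state. An 8 x 400 epoch
#' (3200 values) is channel-concatenated and zero-padded to
#' \code{ceiling(3200 / input_size)} = 4 time steps of width 1000.
#'
#' @param cell \code{"rnn"} (tanh) or \code{"lstm"}.
#' @param num_layers Stacked layers (default 2).
#' @param input_size Per-step input width (default 1000).
#' @param hidden_size Hidden state width (default 128).
#' @param n_classes Output classes (default 2).
#' @return List of class \code{recurrent_config}.
#' @export
recurrent_config <- function(cell = c("rnn", "lstm"), num_layers = 2,
                             input_size = 1000, hidden_size = 128,
                             n_classes = 2) {
  cell <- match.arg(cell)
  stopifnot(num_layers >= 1, input_size >= 1, hidden_size >= 1)
  structure(list(cell = cell, num_layers = num_layers,
                 input_size = input_size, hidden_size = hidden_size,
                 n_classes = n_classes),
            class = c("recurrent_config", "model_config"))
}

#' Initialize recurrent network parameters
#'
#' Uniform \code{(-1/sqrt(hidden), 1/sqrt(hidden))} weights, the usual
#' recurrent-network default; deterministic under \code{seed}.
#'
#' @param cfg A \code{\link{recurrent_config}}.
#' @param seed Integer RNG seed.
#' @return Nested parameter list: per-layer input/hidden weights and
#'   biases plus the dense head.
#' @export
recurrent_init <- function(cfg, seed = 1L) {
  set.seed(seed)
  H <- cfg$hidden_size
  gmult <- if (cfg$cell == "lstm") 4L else 1L
  s <- 1 / sqrt(H)
  ru <- function(r, c) matrix(stats::runif(r * c, -s, s), r, c)
  layers <- lapply(seq_len(cfg$num_layers), function(l) {
    inp <- if (l == 1) cfg$input_size else H
    list(W_ih = ru(inp, H * gmult), W_hh = ru(H, H * gmult),
         b = numeric(H * gmult))
  })
  names(layers) <- paste0("layer", seq_len(cfg$num_layers))
  c(layers, list(dense = list(W = ru(H, cfg$n_classes),
                              b = numeric(cfg$n_classes))))
}

## epochs x channels x samples -> list of step matrices (N x input_size)
epochs_to_steps <- function(data, input_size) {
  d <- dim(data)
  len <- d[2] * d[3]
  steps <- ceiling(len / input_size)
  flat <- matrix(0, d[1], steps * input_size)
  ## channel-concatenated: channel 1's samples, then channel 2's, ...
  flat[, 1:len] <- matrix(aperm(data, c(1, 3, 2)), d[1], len)
  lapply(seq_len(steps), function(t) {
    flat[, ((t - 1) * input_size + 1):(t * input_size), drop = FALSE]
  })
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Recurrent forward pass
#'
#' @param x Epochs x channels x samples array, or a list of per-step
#'   batch x input_size matrices.
#' @param cfg A \code{\link{recurrent_config}}.
#' @param params From \code{\link{recurrent_init}}.
#' @return List: \code{scores} (batch x classes), \code{cache}.
#' @export
recurrent_forward <- function(x, cfg, params) {
  steps <- if (is.list(x)) x else epochs_to_steps(x, cfg$input_size)
  if (length(steps) == 0) stop("zero-length sequence", call. = FALSE)
  N <- nrow(steps[[1]])
  H <- cfg$hidden_size
  Tn <- length(steps)
  cache <- list(steps = steps, layers = vector("list", cfg$num_layers))
  inp <- steps
  for (l in seq_len(cfg$num_layers)) {
    P <- params[[paste0("layer", l)]]
    h <- matrix(0, N, H)
    lc <- list(h = vector("list", Tn), inp = inp)
    if (cfg$cell == "lstm") {
      cst <- matrix(0, N, H)
      lc$gates <- vector("list", Tn); lc$c <- vector("list", Tn)
    }
    out <- vector("list", Tn)
    for (t in seq_len(Tn)) {
      z <- inp[[t]] %*% P$W_ih + h %*% P$W_hh +
        rep(P$b, each = N)
      if (cfg$cell == "rnn") {
        h <- tanh(z)
      } else {
        i <- sigmoid(z[, 1:H, drop = FALSE])
        f <- sigmoid(z[, (H + 1):(2 * H), drop = FALSE])
        g <- tanh(z[, (2 * H + 1):(3 * H), drop = FALSE])
        o <- sigmoid(z[, (3 * H + 1):(4 * H), drop = FALSE])
        cst <- f * cst + i * g
        h <- o * tanh(cst)
        lc$gates[[t]] <- list(i = i, f = f, g = g, o = o)
        lc$c[[t]] <- cst
      }
      lc$h[[t]] <- h
      out[[t]] <- h
    }
    cache$layers[[l]] <- lc
    inp <- out
  }
  hT <- inp[[Tn]]
  de <- dense_fwd(hT, params$dense$W, params$dense$b)
  cache$de <- de$cache
  list(scores = de$y, cache = cache)
}

## full BPTT gradient
recurrent_backward <- function(dscores, cfg, params, cache) {
  H <- cfg$hidden_size
  Tn <- length(cache$steps)
  N <- nrow(dscores)
  g <- list()
  de <- dense_bwd(dscores, cache$de)
  g$dense <- list(W = de$dW, b = de$db)
  ## gradient flowing into each layer's output sequence
  dout <- vector("list", Tn)
  for (t in seq_len(Tn)) dout[[t]] <- matrix(0, N, H)
  dout[[Tn]] <- de$dx
  for (l in rev(seq_len(cfg$num_layers))) {
    P <- params[[paste0("layer", l)]]
    lc <- cache$layers[[l]]
    dW_ih <- P$W_ih * 0; dW_hh <- P$W_hh * 0; db <- P$b * 0
    dh_next <- matrix(0, N, H)
    dc_next <- matrix(0, N, H)
    dinp <- vector("list", Tn)
    for (t in rev(seq_len(Tn))) {
      dh <- dout[[t]] + dh_next
      h_prev <- if (t > 1) lc$h[[t - 1]] else matrix(0, N, H)
      if (cfg$cell == "rnn") {
        dz <- dh * (1 - lc$h[[t]]^2)
      } else {
        gt <- lc$gates[[t]]
        c_prev <- if (t > 1) lc$c[[t - 1]] else matrix(0, N, H)
        tc <- tanh(lc$c[[t]])
        do <- dh * tc
        dc <- dh * gt$o * (1 - tc^2) + dc_next
        di <- dc * gt$g
        df <- dc * c_prev
        dg <- dc * gt$i
        dc_next <- dc * gt$f
        dz <- cbind(di * gt$i * (1 - gt$i),
                    df * gt$f * (1 - gt$f),
                    dg * (1 - gt$g^2),
                    do * gt$o * (1 - gt$o))
      }
      dW_ih <- dW_ih + crossprod(lc$inp[[t]], dz)
      dW_hh <- dW_hh + crossprod(h_prev, dz)
      db <- db + colSums(dz)
      dh_next <- tcrossprod(dz, P$W_hh)
      dinp[[t]] <- tcrossprod(dz, P$W_ih)
    }
    g[[paste0("layer", l)]] <- list(W_ih = dW_ih, W_hh = dW_hh, b = db)
    dout <- dinp
  }
  g
}
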