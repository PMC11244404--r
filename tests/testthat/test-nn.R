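num_grad <- function(f, x, eps = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

grad_close <- function(analytic, numeric, tol = 1e-5) {
  scale <- max(abs(analytic), abs(numeric), 1e-4)
  max(abs(analytic - numeric)) / scale < tol
}

test_that("EEGNet shape contract: 400 -> 400 -> 391 -> 97", {
  sh <- eegnet_shapes(eegnet_config())
  expect_equal(sh$t_conv1, 400)
  expect_equal(sh$t_dw, 391)
  expect_equal(sh$t_pool, 97)
  expect_equal(sh$c_conv1, 16)
  expect_equal(sh$c_dw, 32)
  expect_equal(sh$n_flat, 97 * 8 * 32)
})

test_that("EEGNet forward propagates those shapes and rejects mismatches", {
  cfg <- eegnet_config()
  p <- eegnet_init(cfg, seed = 1)
  x <- array(rnorm(3 * 8 * 400), c(3, 8, 400))
  out <- eegnet_forward(x, cfg, p, "eval")
  expect_equal(dim(out$scores), c(3, 2))
  ## depthwise block output really has 32 channels
  expect_equal(out$cache$b2$dims, c(391, 8, 3, 32))
  expect_error(eegnet_forward(array(0, c(2, 4, 400)), cfg, p, "eval"),
               "channels")
})

test_that("all-zero weights yield uniform class scores", {
  cfg <- eegnet_config(n_channels = 4, n_samples = 80, f1 = 4,
                       kernel1 = 9, pad1 = 4, kernel_dw = 5, dropout = 0)
  p <- eegnet_init(cfg, seed = 1)
  p <- rapply(p, function(v) v * 0, how = "replace")
  p$bn1$running_var <- p$bn1$running_var + 1
  p$bn2$running_var <- p$bn2$running_var + 1
  p$bn3$running_var <- p$bn3$running_var + 1
  out <- eegnet_forward(array(rnorm(4 * 4 * 80), c(4, 4, 80)), cfg, p, "eval")
  expect_true(all(out$scores == 0))
  rcfg <- recurrent_config("lstm", input_size = 10, hidden_size = 4)
  rp <- rapply(recurrent_init(rcfg, 1), function(v) v * 0, how = "replace")
  rout <- recurrent_forward(array(0, c(3, 2, 10)), rcfg, rp)
  expect_true(all(rout$scores == 0))
})

test_that("analytic gradients match finite differences (EEGNet)", {
  cfg <- eegnet_config(n_channels = 2, n_samples = 20, f1 = 3,
                       depth_mult = 2, kernel1 = 5, pad1 = 2, kernel_dw = 3,
                       pool = 2, dropout = 0)
  p <- eegnet_init(cfg, seed = 3)
  set.seed(31)
  x <- array(rnorm(4 * 2 * 20), c(4, 2, 20))
  y <- c(1, 2, 1, 2)
  lossfun <- function(params) {
    softmax_xent(eegnet_forward(x, cfg, params, "train")$scores, y)$loss
  }
  fw <- eegnet_forward(x, cfg, p, "train")
  gr <- eegnet_backward(softmax_xent(fw$scores, y)$dscores, fw$cache)
  for (blk in c("conv1", "dw", "pw", "dense")) {
    f <- function(v) { p2 <- p; p2[[blk]]$W <- v; lossfun(p2) }
    expect_true(grad_close(gr[[blk]]$W, num_grad(f, p[[blk]]$W)),
                label = paste(blk, "W gradient"))
  }
  for (blk in c("bn1", "bn2", "bn3")) {
    f <- function(v) { p2 <- p; p2[[blk]]$gamma <- v; lossfun(p2) }
    expect_true(grad_close(gr[[blk]]$gamma, num_grad(f, p[[blk]]$gamma)),
                label = paste(blk, "gamma gradient"))
  }
})

test_that("analytic gradients match finite differences (RNN and LSTM)", {
  set.seed(41)
  xs <- lapply(1:3, function(t) matrix(rnorm(4 * 7), 4, 7))
  y <- c(1, 2, 2, 1)
  for (cell in c("rnn", "lstm")) {
    cfg <- recurrent_config(cell, input_size = 7, hidden_size = 5)
    p <- recurrent_init(cfg, seed = 4)
    lf <- function(params) {
      softmax_xent(recurrent_forward(xs, cfg, params)$scores, y)$loss
    }
    fw <- recurrent_forward(xs, cfg, p)
    gr <- recurrent_backward(softmax_xent(fw$scores, y)$dscores, cfg, p,
                             fw$cache)
    for (blk in c("layer1", "layer2")) for (nm in c("W_ih", "W_hh", "b")) {
      f <- function(v) { p2 <- p; p2[[blk]][[nm]] <- v; lf(p2) }
      expect_true(grad_close(gr[[blk]][[nm]], num_grad(f, p[[blk]][[nm]])),
                  label = paste(cell, blk, nm))
    }
  }
})

test_that("depthwise convolution equals a zero-filled standard convolution", {
  set.seed(51)
  x <- array(rnorm(10 * 3 * 2 * 4), c(10, 3, 2, 4))   # (T,H,N,C=4)
  Wd <- array(rnorm(3 * 2 * 4), c(3, 2, 4))            # k=3, mult=2, C=4
  b <- rnorm(8)
  dw <- conv_depthwise_fwd(x, Wd, b)
  ## standard conv with the same kernels on a block-sparse weight tensor
  Wf <- array(0, c(3, 4, 8))
  for (c in 1:4) for (j in 1:2) Wf[, c, (c - 1) * 2 + j] <- Wd[, j, c]
  full <- conv_time_fwd(x, Wf, b, pad = 0)
  expect_lt(max(abs(dw$y - full$y)), 1e-6)
})

test_that("batch norm standardizes, inverts and degenerates correctly", {
  set.seed(61)
  m <- 2000
  X <- matrix(rnorm(m * 3, mean = c(5, -2, 0), sd = c(2, 1, 3)), m, 3,
              byrow = TRUE)
  p <- bn_init(3)
  out <- batch_norm(X, p, "train")
  expect_lt(max(abs(colMeans(out$y))), 3 / sqrt(m))
  expect_lt(max(abs(apply(out$y, 2, stats::var) - 1)), 5 / sqrt(m))
  ## gamma = sd, beta = mean recovers the input up to the eps effect
  p2 <- bn_init(3)
  mu <- colMeans(X)
  v <- colMeans(X^2) - mu^2
  p2$gamma <- sqrt(v); p2$beta <- mu
  out2 <- batch_norm(X, p2, "train")
  expect_equal(out2$y, X, tolerance = 1e-4)
  ## constant feature collapses to beta
  Xc <- cbind(rep(4, 100), rnorm(100))
  p3 <- bn_init(2); p3$beta <- c(7, 0)
  out3 <- batch_norm(Xc, p3, "train")
  expect_equal(out3$y[, 1], rep(7, 100), tolerance = 1e-6)
  ## batch of one in train mode is an error
  expect_error(batch_norm(X[1, , drop = FALSE], p, "train"), "at least 2")
  ## eval mode uses running statistics
  out4 <- batch_norm(X, out$params, "eval")
  expect_false(identical(out4$y, out$y))
})

test_that("recurrent hidden states have width 128 at both layers", {
  cfg <- recurrent_config("rnn")
  p <- recurrent_init(cfg, seed = 1)
  x <- array(rnorm(2 * 8 * 400), c(2, 8, 400))
  out <- recurrent_forward(x, cfg, p)
  expect_equal(length(out$cache$steps), 4)        # 3200 padded to 4 x 1000
  expect_equal(dim(out$cache$layers[[1]]$h[[1]]), c(2, 128))
  expect_equal(dim(out$cache$layers[[2]]$h[[4]]), c(2, 128))
  expect_error(recurrent_forward(list(), cfg, p), "zero-length")
})

test_that("LSTM with open forget gate and closed input gate holds state", {
  cfg <- recurrent_config("lstm", num_layers = 1, input_size = 6,
                          hidden_size = 3)
  p <- recurrent_init(cfg, seed = 2)
  p$layer1$W_ih[] <- 0; p$layer1$W_hh[] <- 0
  H <- 3
  p$layer1$b[1:H] <- -50          # input gate ~ 0
  p$layer1$b[(H + 1):(2 * H)] <- 50   # forget gate ~ 1
  p$layer1$b[(3 * H + 1):(4 * H)] <- 50  # output gate ~ 1
  xs <- lapply(1:5, function(t) matrix(0, 2, 6))
  out <- recurrent_forward(xs, cfg, p)
  hs <- out$cache$layers[[1]]$h
  for (t in 2:5) expect_equal(hs[[t]], hs[[1]])
})
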