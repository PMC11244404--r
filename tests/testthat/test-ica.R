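test_that("whitening yields identity covariance and honors component count", {
  set.seed(5)
  X <- matrix(rnorm(8 * 5000), 8) * (1:8) + rnorm(8)
  wh <- whiten(X)
  expect_equal(dim(wh$Z), c(8, 5000))
  C <- wh$Z %*% t(wh$Z) / ncol(wh$Z)
  expect_lt(max(abs(C - diag(8))), 1e-8)
  expect_equal(wh$Z, wh$K %*% (X - wh$means), tolerance = 1e-10)
  ## rank deficiency is reported
  expect_error(whiten(rbind(X[1, ], X[1, ], X[2, ])), "rank deficient")
  expect_error(whiten(X, 9), "cannot extract")
})

test_that("already-unmixed sub-Gaussian sources are recovered exactly", {
  set.seed(6)
  S <- matrix(runif(8 * 20000, -sqrt(3), sqrt(3)), 8)
  wh <- whiten(S)
  fit <- fastica_fit(wh$Z, seed = 7)
  expect_true(fit$converged)
  rec <- fit$W %*% wh$Z
  m <- match_sources(rec, S)
  expect_gt(min(m$pairs$abs_cor), 0.999)
})

test_that("the unmixing matrix stays orthonormal after decorrelation", {
  sim <- fix_sim60()
  rec <- rereference(sim$recording)
  model <- ica_fit(rec, 8, seed = 11)
  WWt <- model$W %*% t(model$W)
  expect_lt(max(abs(WWt - diag(8))), 1e-6)
  ## reconstruction identity: A S reproduces the demeaned data
  S <- ica_sources(model, rec)
  expect_lt(max(abs(model$A %*% S - (rec$data - model$means))), 1e-8)
})

test_that("mixed synthetic sources are recovered above 0.95 mean |corr|", {
  sim <- fix_sim60()
  rec <- rereference(sim$recording)
  model <- ica_fit(rec, 8, seed = 11)
  S_est <- ica_sources(model, rec)
  ## references: the 8 sources, after the same mastoid-average reference
  ## (re-referencing only rescales each source's channel projection)
  m <- match_sources(S_est, sim$sources$sources)
  expect_gt(m$mean_abs_cor, 0.95)
})

test_that("identical seeds give identical unmixing matrices", {
  sim <- fix_sim60()
  rec <- rereference(sim$recording)
  a <- ica_fit(rec, 8, seed = 13)
  b <- ica_fit(rec, 8, seed = 13)
  expect_identical(a$W, b$W)
  c <- ica_fit(rec, 8, seed = 14)
  expect_false(identical(c$W, a$W))
})

test_that("artifact scoring ranks the blink component first across seeds", {
  hits <- 0
  n_seeds <- 10
  for (s in seq_len(n_seeds)) {
    sim <- simulate_recording(synth_config(duration = 20, seed = 300 + s))
    rec <- rereference(sim$recording)
    model <- ica_fit(rec, 8, seed = s)
    S <- ica_sources(model, rec)
    sc <- identify_artifact_components(model, S, fs = rec$fs)
    ## which estimated component matches the true blink source?
    j_blink <- which(sim$sources$kinds == "blink-artifact")
    cm <- abs(stats::cor(t(S), t(sim$sources$sources)))
    est_blink <- which.max(cm[, j_blink])
    if (sc$component[1] == est_blink) hits <- hits + 1
  }
  expect_gte(hits, n_seeds - 1)
})

test_that("exactly the ocular and cardiac components are excluded", {
  sim <- fix_sim60()
  rec <- rereference(sim$recording)
  model <- ica_fit(rec, 8, seed = 11)
  S <- ica_sources(model, rec)
  sc <- identify_artifact_components(model, S, fs = rec$fs)
  expect_equal(sum(sc$flagged), 2)
  cm <- abs(stats::cor(t(S), t(sim$sources$sources)))
  truth <- c(which.max(cm[, sim$sources$kinds == "blink-artifact"]),
             which.max(cm[, sim$sources$kinds == "cardiac-artifact"]))
  expect_setequal(sc$component[sc$flagged], truth)
})

test_that("artifact-free recordings produce no flagged components", {
  cfg <- synth_config(duration = 20, artifact_rate = 0,
                      blink_amplitude = 0, cardiac_amplitude = 1e-6,
                      seed = 42)
  sim <- simulate_recording(cfg)
  rec <- rereference(sim$recording)
  model <- ica_fit(rec, 8, seed = 2)
  S <- ica_sources(model, rec)
  sc <- identify_artifact_components(model, S, fs = rec$fs)
  expect_false(any(sc$flagged))
})

test_that("component removal obeys the empty and full exclusion limits", {
  sim <- fix_sim60()
  rec <- rereference(sim$recording)
  model <- ica_fit(rec, 8, seed = 11)
  same <- remove_components(rec, model, integer())
  expect_lt(max(abs(same$data - rec$data)), 1e-9)
  none <- remove_components(rec, model, 1:8)
  resid <- none$data - model$means
  expect_lt(mean(resid^2) / mean((rec$data - model$means)^2), 1e-6)
  expect_error(remove_components(rec, model, 9), "out of range")
})

test_that("removing the blink component cleans Fp delta power, spares alpha", {
  sim <- fix_sim60()
  rec <- rereference(sim$recording)
  model <- ica_fit(rec, 8, seed = 11)
  S <- ica_sources(model, rec)
  sc <- identify_artifact_components(model, S, fs = rec$fs)
  ## the top-scored component is the blink; remove only it
  clean <- remove_components(rec, model, sc$component[1])
  fp <- grep("^Fp", rec$channel_names)
  bandpow <- function(x, lo, hi) {
    n <- length(x)
    f <- (0:(n - 1)) * rec$fs / n
    P <- Mod(stats::fft(x))^2
    sum(P[f >= lo & f < hi])
  }
  before_d <- sum(sapply(fp, function(i) bandpow(rec$data[i, ], 0.5, 4)))
  after_d <- sum(sapply(fp, function(i) bandpow(clean$data[i, ], 0.5, 4)))
  expect_lt(after_d / before_d, 0.10)
  before_a <- sum(sapply(fp, function(i) bandpow(rec$data[i, ], 8, 13)))
  after_a <- sum(sapply(fp, function(i) bandpow(clean$data[i, ], 8, 13)))
  expect_lt(abs(after_a / before_a - 1), 0.10)
})
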