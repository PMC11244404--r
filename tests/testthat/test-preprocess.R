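make_rec <- function(data, names, fs = 500) {
  eeg_recording(data, fs, names)
}

test_that("mastoid re-referencing subtracts the mastoid average", {
  x <- matrix(rnorm(4 * 100), 4, 100)
  ## zero mastoids: scalp channels unchanged
  rec <- make_rec(rbind(x, 0, 0), c("Fp1", "Fpz", "F3", "F4", "M1", "M2"))
  out <- rereference(rec)
  expect_equal(out$data, x)
  expect_equal(out$reference, "mastoid-average")
  expect_equal(out$channel_names, c("Fp1", "Fpz", "F3", "F4"))
  ## constant mastoids c: every sample shifted by -c
  rec2 <- make_rec(rbind(x, 3, 3), c("Fp1", "Fpz", "F3", "F4", "M1", "M2"))
  expect_equal(rereference(rec2)$data, x - 3)
  ## errors: missing reference channel, double re-reference
  expect_error(rereference(make_rec(x, c("a", "b", "c", "M1"))),
               "M2")
  expect_error(rereference(out), "already")
})

test_that("default fixture re-references to exactly the 8 frontal channels", {
  out <- rereference(fix_sim60()$recording)
  expect_equal(out$channel_names,
               c("Fp2", "Fpz", "Fp1", "F4", "Fz", "F3", "FC2", "FC1"))
})

test_that("designed taps are symmetric with the correct DC behavior", {
  for (spec in list(filter_spec("low-pass", 30),
                    filter_spec("high-pass", 0.1),
                    filter_spec("notch", 40))) {
    b <- design_fir(spec, 500)$b
    expect_equal(b, rev(b), tolerance = 1e-12)
    expect_length(b, spec$order + 1)
  }
  expect_equal(sum(design_fir(filter_spec("low-pass", 30), 500)$b), 1,
               tolerance = 1e-12)
  ## high-pass rejects DC to machine precision
  hp <- design_fir(filter_spec("high-pass", 0.1), 500)
  expect_lt(frequency_response(hp, 0, 500), 1e-6)
  ## notch passes DC
  nt <- design_fir(filter_spec("notch", 40), 500)
  expect_equal(frequency_response(nt, 0, 500), 1, tolerance = 1e-6)
})

test_that("low-pass magnitude contract holds at the default order", {
  lp <- design_fir(filter_spec("low-pass", 30), 500)
  expect_gt(frequency_response(lp, 20, 500), 0.9)
  expect_lt(frequency_response(lp, 45, 500), 0.1)
})

test_that("notch minimum sits at the configured center", {
  nt <- design_fir(filter_spec("notch", 40), 500)
  f <- seq(35, 45, by = 0.1)
  H <- frequency_response(nt, f, 500)
  expect_lt(abs(f[which.min(H)] - 40), 1)
})

test_that("cutoffs at or above Nyquist are rejected", {
  expect_error(design_fir(filter_spec("low-pass", 250), 500), "Nyquist")
  expect_error(design_fir(filter_spec("low-pass", 300), 500), "Nyquist")
  expect_error(frequency_response(c(1), 260, 500), "Hz")
  expect_equal(nyquist(500), 250)
})

test_that("frequency response matches a brute-force DFT of padded taps", {
  set.seed(4)
  b <- rnorm(31)
  N <- 512
  fs <- 500
  brute <- Mod(stats::fft(c(b, numeric(N - length(b)))))[1:(N / 4)]
  freqs <- (0:(N / 4 - 1)) * fs / N
  expect_equal(frequency_response(b, freqs, fs), brute, tolerance = 1e-10)
  expect_equal(frequency_response(c(1), c(0, 10, 250), 500), c(1, 1, 1))
})

test_that("windowed-sinc design agrees with the signal package", {
  skip_if_not_installed("signal")
  lp <- design_fir(filter_spec("low-pass", 30, order = 100), 500)
  ref <- as.numeric(signal::fir1(100, 30 / 250, type = "low"))
  f <- seq(0, 250, by = 2.5)
  expect_equal(frequency_response(lp, f, 500),
               frequency_response(ref, f, 500), tolerance = 0.02)
})

test_that("zero-phase filtering preserves pass-band tones, kills stop-band", {
  fs <- 500
  t <- (0:(20 * fs - 1)) / fs
  amp_at <- function(rec, f0) {
    P <- Mod(stats::fft(rec$data[1, ]))^2
    fbin <- round(f0 * length(t) / fs) + 1
    sqrt(max(P[(fbin - 2):(fbin + 2)]))
  }
  lp <- design_fir(filter_spec("low-pass", 30), fs)
  rec10 <- make_rec(matrix(sin(2 * pi * 10 * t), 1), "Fp1", fs)
  rec60 <- make_rec(matrix(sin(2 * pi * 60 * t), 1), "Fp1", fs)
  expect_gt(amp_at(apply_filter(rec10, lp), 10) / amp_at(rec10, 10), 0.95)
  expect_lt(amp_at(apply_filter(rec60, lp), 60) / amp_at(rec60, 60), 0.10)
})

test_that("the identity filter returns the input unchanged", {
  idf <- structure(list(b = 1, spec = filter_spec("low-pass", 1, order = 0)),
                   class = "fir_coefficients")
  rec <- make_rec(matrix(rnorm(300), 2), c("a", "b"), 100)
  expect_equal(apply_filter(rec, idf)$data, rec$data)
})

test_that("filtering is linear and filters commute", {
  fs <- 500
  set.seed(8)
  x <- matrix(rnorm(2 * 4000), 2, 4000)
  y <- matrix(rnorm(2 * 4000), 2, 4000)
  nm <- c("a", "b")
  lp <- design_fir(filter_spec("low-pass", 30, order = 200), fs)
  hp <- design_fir(filter_spec("high-pass", 1, order = 200), fs)
  fx <- apply_filter(make_rec(x, nm, fs), lp)$data
  fy <- apply_filter(make_rec(y, nm, fs), lp)$data
  fxy <- apply_filter(make_rec(x + y, nm, fs), lp)$data
  expect_lt(max(abs(fxy - (fx + fy))), 1e-9)
  ab <- apply_filter(apply_filter(make_rec(x, nm, fs), lp), hp)$data
  ba <- apply_filter(apply_filter(make_rec(x, nm, fs), hp), lp)$data
  expect_lt(max(abs(ab - ba)), 1e-9)
})

test_that("zero-phase application introduces no lag", {
  fs <- 500
  t <- (0:(10 * fs - 1)) / fs
  x <- sin(2 * pi * 8 * t) + 0.5 * sin(2 * pi * 12 * t)
  lp <- design_fir(filter_spec("low-pass", 30), fs)
  y <- apply_filter(make_rec(matrix(x, 1), "a", fs), lp)$data[1, ]
  cc <- stats::ccf(x, y, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("too-short recordings are rejected", {
  lp <- design_fir(filter_spec("low-pass", 30), 500)
  expect_error(apply_filter(make_rec(matrix(rnorm(600), 1), "a", 500), lp),
               "too short")
})
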