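test_that("band table matches the canonical five-band definition", {
  tab <- eeg_bands()
  expect_equal(tab$band, c("delta", "theta", "alpha", "beta", "gamma"))
  expect_equal(tab$lo, c(0.5, 4, 8, 13, 30))
  expect_equal(tab$hi, c(4, 8, 13, 30, 42))
  ## half-open bands partition 0.5-42 Hz with no overlap
  expect_equal(tab$hi[-5], tab$lo[-1])
})

test_that("oscillatory sources keep >= 80% of power in their tagged band", {
  sim <- fix_sim60()
  src <- sim$sources
  fs <- src$fs
  n <- ncol(src$sources)
  f <- (0:(n - 1)) * fs / n
  f <- pmin(f, fs - f)
  for (j in which(src$kinds == "band-oscillation")) {
    P <- Mod(stats::fft(src$sources[j, ]))^2
    edges <- src$bands[[j]]
    frac <- sum(P[f >= edges[1] & f < edges[2]]) / sum(P)
    expect_gt(frac, 0.8)
    ## periodogram peak lies inside the band
    peak_f <- f[which.max(P)]
    expect_true(peak_f >= edges[1] && peak_f < edges[2])
  }
})

test_that("configured band-power contrast is recovered from epochs", {
  ## RH theta/alpha amplitude x1.5 -> band power ratio ~ 1.5^2, within 10%
  ep <- fix_epochs600_clean()
  psd <- compute_psd(ep)
  for (b in c("theta", "alpha")) {
    bp <- rowMeans(band_power(psd, b))
    ratio <- mean(bp[psd$labels == "RH"]) / mean(bp[psd$labels == "ND"])
    expect_gt(ratio, 1.5^2 * 0.9)
    expect_lt(ratio, 1.5^2 * 1.1)
  }
  ## an unmodulated band far from the modulated ones shows no contrast
  ## (Hann taper, so boxcar sidelobe leakage does not confound the check)
  psd_h <- compute_psd(ep, window = "hann")
  bp <- rowMeans(band_power(psd_h, "gamma"))
  ratio <- mean(bp[psd_h$labels == "RH"]) / mean(bp[psd_h$labels == "ND"])
  expect_lt(abs(ratio - 1), 0.1)
})

test_that("identity mixing reproduces sources on channels", {
  cfg <- synth_config(duration = 5, noise_sd = 0,
                      channel_names = c("Fp1", "Fp2", "Fpz", "F3", "F4"),
                      mastoid_names = c("M1", "M2"), seed = 3)
  src <- generate_sources(cfg)
  n_src <- nrow(src$sources)
  A <- diag(n_src)[1:7, ]          # 5 scalp + 2 mastoid rows, 7 sources
  rownames(A) <- c(cfg$channel_names, cfg$mastoid_names)
  mix <- structure(list(A = A, kinds = src$kinds), class = "mixing_spec")
  out <- mix_and_annotate(src, mix, cfg)
  expect_equal(unname(out$recording$data), unname(A %*% src$sources))
  expect_equal(unname(out$recording$data[1, ]), src$sources[1, ])
})

test_that("default montage has the eight frontal channels plus mastoids", {
  sim <- fix_sim60()
  expect_equal(sim$recording$channel_names,
               c("Fp2", "Fpz", "Fp1", "F4", "Fz", "F3", "FC2", "FC1",
                 "M1", "M2"))
  expect_equal(sim$recording$fs, 500)
})

test_that("blink topography is concentrated on the frontal poles", {
  sim <- fix_sim60()
  j <- which(sim$sources$kinds == "blink-artifact")
  col <- abs(sim$mixing$A[, j])
  fp <- grepl("^Fp", rownames(sim$mixing$A))
  expect_true(min(col[fp]) > max(col[!fp]))
  expect_equal(qr(sim$mixing$A)$rank, min(dim(sim$mixing$A)))
})

test_that("channel variance decomposes into mixed source power plus noise", {
  sim <- fix_sim600()
  A <- sim$mixing$A
  S <- sim$sources$sources
  vs <- apply(S, 1, stats::var)
  noise_var <- 0.5^2
  pred <- as.vector(A^2 %*% vs) + noise_var
  obs <- apply(sim$recording$data, 1, stats::var)
  expect_lt(max(abs(obs - pred) / pred), 0.05)
})

test_that("annotations follow the active state with one event per second", {
  sim <- fix_sim600()
  ev <- sim$events
  expect_equal(nrow(ev), 602)
  expect_true(all(diff(ev$onset_s) == 1))
  expect_true(all(ev$label %in% c("RH", "ND")))
  ## 20 s alternating blocks starting RH
  expect_equal(ev$label[1:41],
               rep(c("RH", "ND", "RH"), times = c(20, 20, 1)))
})

test_that("generation is bit-reproducible under a fixed seed", {
  a <- simulate_recording(synth_config(duration = 4, seed = 77))
  b <- simulate_recording(synth_config(duration = 4, seed = 77))
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$sources$sources, b$sources$sources)
  c <- simulate_recording(synth_config(duration = 4, seed = 78))
  expect_false(identical(a$recording$data, c$recording$data))
})

test_that("configuration and timeline validation reject bad input", {
  expect_error(synth_config(class_band_power = list(
    RH = c(sigma = 1.5), ND = c(theta = 1))), "unknown band")
  expect_error(synth_config(class_band_power = list(
    RH = c(theta = -1), ND = c(theta = 1))), "> 0")
  cfg <- synth_config(duration = 4)
  expect_error(generate_sources(cfg, eeg_events(c(1, 2), c("RH", "ND"))),
               "start at t = 0")
  expect_error(generate_sources(cfg, eeg_events(c(0, 9), c("RH", "ND"))),
               "inside")
  bad <- eeg_events(c(0, 1), c("RH", "ND")); bad$onset_s <- c(0, 0)
  expect_error(generate_sources(cfg, bad), "strictly increasing")
})

test_that("a 60 s recording at 500 Hz has exactly 30000 samples per channel", {
  sim <- fix_sim60()
  expect_equal(ncol(sim$recording$data), 30000)
})
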