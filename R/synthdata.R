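#' Configuration for the synthetic EEG generator
#'
#' Defines the simulated montage and the statistical structure of the
#' two-state (RH vs ND) recording: one narrowband oscillatory source per
#' canonical band, stereotyped blink and cardiac artifact sources, broadband
#' sensor noise, and a block-alternating state timeline whose active state
#' scales the amplitude of selected band sources.
#'
#' Oscillatory sources are constant-envelope frequency-modulated oscillators:
#' the instantaneous frequency performs a clamped Ornstein--Uhlenbeck wander
#' inside the band. This keeps essentially all source power inside the
#' tagged band, gives the strongly sub-Gaussian (arcsine) marginal that
#' blind source separation needs, and makes the configured between-state
#' band-power contrast recoverable from sub-second epochs.
#'
#' @param fs Sampling rate, Hz.
#' @param duration Recording length, seconds.
#' @param channel_names Scalp channel names (10--20 system).
#' @param mastoid_names Names of the two synthesized mastoid reference
#'   channels appended after the scalp channels.
#' @param class_band_power Named list \code{RH}/\code{ND}, each a named
#'   vector of per-band amplitude multipliers. The default gives the RH
#'   state a 1.5x theta and alpha amplitude (2.25x power) increase.
#' @param band_amplitude Per-band source RMS amplitude, microvolts.
#' @param artifact_rate Blink events per minute.
#' @param blink_amplitude,cardiac_amplitude Artifact source RMS, microvolts.
#' @param cardiac_hz Cardiac pulse rate, Hz.
#' @param line_hz Optional mains-interference oscillator frequency (Hz);
#'   \code{NULL} disables it.
#' @param noise_sd Broadband per-channel sensor noise SD, microvolts.
#' @param event_spacing Seconds between successive event annotations.
#' @param state_block_s Length of each alternating RH/ND state block, seconds.
#' @param fm_tau Correlation time of the frequency wander, seconds.
#' @param seed Integer RNG seed; fixed seed gives bit-identical output.
#' @return A list of class \code{synth_config}.
#' @export
synth_config <- function(fs = 500,
                         duration = 602,
                         channel_names = c("Fp2", "Fpz", "Fp1", "F4",
                                           "Fz", "F3", "FC2", "FC1"),
                         mastoid_names = c("M1", "M2"),
                         class_band_power = list(
                           RH = c(delta = 1, theta = 1.5, alpha = 1.5,
                                  beta = 1, gamma = 1),
                           ND = c(delta = 1, theta = 1, alpha = 1,
                                  beta = 1, gamma = 1)),
                         band_amplitude = c(delta = 8, theta = 6, alpha = 9,
                                            beta = 4, gamma = 3),
                         artifact_rate = 12,
                         blink_amplitude = 30,
                         cardiac_amplitude = 3,
                         cardiac_hz = 1.2,
                         line_hz = NULL,
                         noise_sd = 0.5,
                         event_spacing = 1,
                         state_block_s = 20,
                         fm_tau = 0.5,
                         seed = 1L) {
  stopifnot(fs > 0, duration > 0, event_spacing > 0, state_block_s > 0,
            noise_sd >= 0, artifact_rate >= 0)
  all_names <- c(channel_names, mastoid_names)
  if (anyDuplicated(all_names)) stop("channel names must be unique",
                                     call. = FALSE)
  valid <- eeg_bands()$band
  for (cls in c("RH", "ND")) {
    mult <- class_band_power[[cls]]
    if (is.null(mult)) stop("class_band_power must define '", cls, "'",
                            call. = FALSE)
    bad <- setdiff(names(mult), valid)
    if (length(bad)) stop("unknown band name(s) in class_band_power: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    if (any(mult <= 0)) stop("band multipliers must be > 0", call. = FALSE)
  }
  if (any(band_amplitude <= 0)) stop("band amplitudes must be > 0",
                                     call. = FALSE)
  structure(list(
    fs = fs, duration = duration, channel_names = channel_names,
    mastoid_names = mastoid_names, class_band_power = class_band_power,
    band_amplitude = band_amplitude, artifact_rate = artifact_rate,
    blink_amplitude = blink_amplitude, cardiac_amplitude = cardiac_amplitude,
    cardiac_hz = cardiac_hz, line_hz = line_hz, noise_sd = noise_sd,
    event_spacing = event_spacing, state_block_s = state_block_s,
    fm_tau = fm_tau, seed = as.integer(seed)), class = "synth_config")
}

#' Block-alternating RH/ND state timeline
#'
#' @param config A \code{\link{synth_config}}.
#' @param start First state, \code{"RH"} or \code{"ND"}.
#' @return An \code{\link{eeg_events}} stream of state-block onsets covering
#'   \code{[0, duration]}; each state holds until the next onset.
#' @export
make_state_timeline <- function(config, start = "RH") {
  stopifnot(start %in% c("RH", "ND"))
  onsets <- seq(0, config$duration - 1e-9, by = config$state_block_s)
  lab <- rep(c(start, setdiff(c("RH", "ND"), start)),
             length.out = length(onsets))
  eeg_events(onsets, lab)
}

## state label at each sample index (1-based), from a block timeline
state_at_samples <- function(timeline, n, fs) {
  t <- (seq_len(n) - 1) / fs
  idx <- findInterval(t, timeline$onset_s)
  idx[idx < 1] <- 1
  timeline$label[idx]
}

## Constant-envelope FM oscillator, unit RMS. The instantaneous frequency
## is a unit-variance Ornstein-Uhlenbeck wander squashed into (lo, hi) by
## a logistic map, so its density is bell-shaped mid-band and vanishes at
## the edges (no spectral pile-up at the band boundaries).
fm_oscillation <- function(n, lo, hi, fs, tau) {
  a <- exp(-1 / (tau * fs))
  innov <- stats::rnorm(n) * sqrt(1 - a^2)
  z <- numeric(n)
  z[1] <- stats::rnorm(1)
  for (t in 2:n) z[t] <- a * z[t - 1] + innov[t]
  f <- lo + (hi - lo) * stats::plogis(1.6 * z)
  phi <- 2 * pi * cumsum(f) / fs + stats::runif(1, 0, 2 * pi)
  sqrt(2) * cos(phi)
}

## stereotyped 300 ms biphasic blink pulses at Poisson times, unit RMS
blink_source <- function(n, fs, rate_per_min) {
  x <- numeric(n)
  tt <- seq(0, 0.3, by = 1 / fs)
  tpl <- sin(2 * pi * tt / 0.3) * exp(-((tt - 0.15) / 0.1)^2)
  k <- stats::rpois(1, rate_per_min * n / fs / 60)
  if (k > 0) {
    onsets <- sort(sample.int(n - length(tpl), k))
    for (o in onsets) {
      span <- o:(o + length(tpl) - 1)
      x[span] <- x[span] + tpl
    }
  }
  s <- stats::sd(x)
  if (s > 0) x <- x / s
  x
}

## sharp QRS-like pulse train at cardiac_hz, unit RMS
cardiac_source <- function(n, fs, hz) {
  x <- numeric(n)
  tt <- seq(0, 0.08, by = 1 / fs)
  tpl <- c(-0.2, diff(exp(-((tt - 0.04) / 0.012)^2))) * 40
  onsets <- round(seq(1, n - length(tpl), by = fs / hz) +
                    stats::runif(1, 0, fs / 4))
  for (o in onsets) {
    span <- o:(o + length(tpl) - 1)
    x[span] <- x[span] + tpl
  }
  x / stats::sd(x)
}

#' Generate latent sources for a synthetic recording
#'
#' Produces one narrowband oscillatory source per canonical band, with its
#' amplitude scaled sample-by-sample by the active state's band multiplier,
#' plus blink and cardiac artifact sources (and an optional mains
#' oscillator). Deterministic under \code{config$seed}.
#'
#' @param config A \code{\link{synth_config}}.
#' @param timeline State timeline from \code{\link{make_state_timeline}}
#'   (or any \code{\link{eeg_events}} stream of state-block onsets starting
#'   at 0 and lying inside the recording).
#' @return A list of class \code{source_set}: \code{sources} (n_sources x
#'   samples, unit-free until scaled by \code{band_amplitude}),
#'   \code{kinds}, \code{bands} (per-source \code{c(lo, hi)} or NA), and
#'   \code{timeline}.
#' @export
generate_sources <- function(config, timeline = make_state_timeline(config)) {
  n <- round(config$duration * config$fs)
  if (nrow(timeline) == 0 || timeline$onset_s[1] > 1e-9) {
    stop("state timeline must start at t = 0", call. = FALSE)
  }
  if (any(timeline$onset_s < 0) ||
      any(timeline$onset_s >= config$duration)) {
    stop("state timeline onsets must lie inside [0, duration)",
         call. = FALSE)
  }
  if (any(diff(timeline$onset_s) <= 0)) {
    stop("state timeline onsets must be strictly increasing", call. = FALSE)
  }
  set.seed(config$seed)
  tab <- eeg_bands()
  state <- state_at_samples(timeline, n, config$fs)
  is_rh <- state == "RH"

  sources <- list(); kinds <- character(); bands <- list()
  for (i in seq_len(nrow(tab))) {
    b <- tab$band[i]
    s <- fm_oscillation(n, tab$lo[i], tab$hi[i], config$fs, config$fm_tau) *
      config$band_amplitude[[b]]
    gain <- rep(mult_for(config, "ND", b), n)
    gain[is_rh] <- mult_for(config, "RH", b)
    sources[[b]] <- s * gain
    kinds <- c(kinds, "band-oscillation")
    bands[[b]] <- c(lo = tab$lo[i], hi = tab$hi[i])
  }
  sources$blink <- blink_source(n, config$fs, config$artifact_rate) *
    config$blink_amplitude
  kinds <- c(kinds, "blink-artifact"); bands$blink <- c(NA, NA)
  sources$cardiac <- cardiac_source(n, config$fs, config$cardiac_hz) *
    config$cardiac_amplitude
  kinds <- c(kinds, "cardiac-artifact"); bands$cardiac <- c(NA, NA)
  if (!is.null(config$line_hz)) {
    sources$line <- fm_oscillation(n, config$line_hz - 1,
                                   config$line_hz + 1, config$fs, tau = 2) *
      config$cardiac_amplitude
    kinds <- c(kinds, "line-noise")
    bands$line <- c(lo = config$line_hz - 1, hi = config$line_hz + 1)
  }
  S <- do.call(rbind, sources)
  structure(list(sources = S, kinds = kinds, bands = bands,
                 timeline = timeline, fs = config$fs),
            class = "source_set")
}

mult_for <- function(config, cls, band) {
  m <- config$class_band_power[[cls]][band]
  if (is.na(m)) 1 else unname(m)
}

#' Mixing specification (source topographies)
#'
#' Builds the channels-by-sources mixing matrix. Band sources project onto
#' all scalp channels with channel-specific signs and magnitudes (distinct
#' cortical generators present different dipole orientations to the
#' montage, which also keeps the mixing well conditioned); the blink
#' column is concentrated on the frontal-pole channels (largest weights on
#' Fp1/Fpz/Fp2); the cardiac (and mains) columns are diffuse. Mastoid
#' channels carry attenuated copies of the diffuse sources. Deterministic
#' under \code{config$seed}.
#'
#' @param config A \code{\link{synth_config}}.
#' @param source_set The \code{\link{generate_sources}} output (fixes the
#'   source count and kinds).
#' @return A list of class \code{mixing_spec} with \code{A} (n_channels x
#'   n_sources, rownames = channel names) and \code{kinds}.
#' @export
mixing_spec <- function(config, source_set) {
  set.seed(config$seed + 1L)
  ch <- c(config$channel_names, config$mastoid_names)
  n_ch <- length(ch)
  n_src <- nrow(source_set$sources)
  n_scalp <- length(config$channel_names)
  is_fp <- grepl("^Fp", config$channel_names)
  A <- matrix(0, n_ch, n_src, dimnames = list(ch, rownames(source_set$sources)))
  for (j in seq_len(n_src)) {
    kind <- source_set$kinds[j]
    if (kind == "blink-artifact") {
      w <- numeric(n_scalp)
      w[is_fp] <- stats::runif(sum(is_fp), 0.9, 1.1)
      w[!is_fp] <- stats::runif(sum(!is_fp), 0.05, 0.35)
      A[seq_len(n_scalp), j] <- w
      A[-seq_len(n_scalp), j] <- 0.05
    } else if (kind == "cardiac-artifact") {
      A[seq_len(n_scalp), j] <- stats::runif(n_scalp, 0.3, 1)
      A[-seq_len(n_scalp), j] <- stats::runif(n_ch - n_scalp, 0.1, 0.25)
    } else {
      sgn <- sample(c(-1, 1), n_scalp, replace = TRUE)
      A[seq_len(n_scalp), j] <- sgn * stats::runif(n_scalp, 0.3, 1)
      A[-seq_len(n_scalp), j] <- sample(c(-1, 1), n_ch - n_scalp, TRUE) *
        stats::runif(n_ch - n_scalp, 0.1, 0.25)
    }
  }
  if (qr(A)$rank < min(dim(A))) stop("mixing matrix is rank deficient",
                                     call. = FALSE)
  structure(list(A = A, kinds = source_set$kinds), class = "mixing_spec")
}

#' Mix sources onto channels and emit event annotations
#'
#' Forms \code{X = A S + noise}, appends the synthesized mastoid reference
#' channels, and lays down one annotation every \code{event_spacing}
#' seconds labeled with the state active at its onset. Only onsets whose
#' 1-second analysis window fits inside the recording are annotated.
#'
#' @param source_set From \code{\link{generate_sources}}.
#' @param mixing From \code{\link{mixing_spec}}.
#' @param config The same \code{\link{synth_config}}.
#' @return List with \code{recording} (\code{\link{eeg_recording}}) and
#'   \code{events} (\code{\link{eeg_events}}).
#' @export
mix_and_annotate <- function(source_set, mixing, config) {
  S <- source_set$sources
  A <- mixing$A
  if (ncol(A) != nrow(S)) {
    stop("mixing matrix has ", ncol(A), " source columns but ", nrow(S),
         " sources were supplied", call. = FALSE)
  }
  n_ch_expected <- length(config$channel_names) + length(config$mastoid_names)
  if (nrow(A) != n_ch_expected) {
    stop("mixing matrix has ", nrow(A), " channel rows but config names ",
         n_ch_expected, " channels", call. = FALSE)
  }
  set.seed(config$seed + 2L)
  X <- A %*% S
  if (config$noise_sd > 0) {
    X <- X + matrix(stats::rnorm(length(X), sd = config$noise_sd), nrow(X))
  }
  rec <- eeg_recording(X, config$fs, rownames(A), reference = "as-recorded",
                       history = sprintf("simulated(seed=%d)", config$seed))
  onsets <- seq(0, config$duration - 1, by = config$event_spacing)
  lab <- source_set$timeline$label[findInterval(onsets,
                                                source_set$timeline$onset_s)]
  list(recording = rec, events = eeg_events(onsets, lab))
}

#' One-call synthetic recording
#'
#' Convenience wrapper: timeline, sources, mixing, mixing + annotation.
#'
#' @param config A \code{\link{synth_config}}.
#' @param timeline Optional custom state timeline.
#' @return List with \code{recording}, \code{events}, \code{sources},
#'   \code{mixing}, \code{timeline}.
#' @export
#' @examples
#' sim <- simulate_recording(synth_config(duration = 10, seed = 7))
#' sim$recording
simulate_recording <- function(config = synth_config(),
                               timeline = make_state_timeline(config)) {
  src <- generate_sources(config, timeline)
  mix <- mixing_spec(config, src)
  out <- mix_and_annotate(src, mix, config)
  list(recording = out$recording, events = out$events, sources = src,
       mixing = mix, timeline = timeline)
}
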