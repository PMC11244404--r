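#' Re-reference to the bilateral mastoid average
#'
#' Subtracts the mean of the two mastoid channels from every scalp channel
#' and drops the mastoids from the output.
#'
#' @param rec An \code{\link{eeg_recording}} with reference
#'   \code{"as-recorded"}.
#' @param ref_names The two mastoid channel names.
#' @return Re-referenced \code{\link{eeg_recording}} (scalp channels only).
#' @export
rereference <- function(rec, ref_names = c("M1", "M2")) {
  if (rec$reference != "as-recorded") {
    stop("recording is already re-referenced (", rec$reference, ")",
         call. = FALSE)
  }
  missing <- setdiff(ref_names, rec$channel_names)
  if (length(missing)) {
    stop("reference channel(s) not present: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ref_idx <- match(ref_names, rec$channel_names)
  ref <- colMeans(rec$data[ref_idx, , drop = FALSE])
  keep <- setdiff(seq_len(nrow(rec$data)), ref_idx)
  out <- eeg_recording(
    sweep(rec$data[keep, , drop = FALSE], 2, ref, "-"),
    rec$fs, rec$channel_names[keep], reference = "as-recorded",
    history = c(rec$history,
                paste0("rereference(", paste(ref_names, collapse = ","), ")")))
  out$reference <- "mastoid-average"
  out
}

#' FIR filter specification
#'
#' @param kind \code{"low-pass"}, \code{"high-pass"} or \code{"notch"}.
#' @param fc Cutoff frequency in Hz (notch: center frequency).
#' @param half_width Half-width of the notch stop band, Hz.
#' @param order Filter order M (taps - 1); must be even so the linear-phase
#'   taps have an integer group delay of M/2 samples. Defaults: 500 for
#'   low-pass/notch (one second at 500 Hz), 3000 for high-pass (long enough
#'   for a ~0.5 Hz transition at a 0.1 Hz cutoff).
#' @return A list of class \code{filter_spec}.
#' @export
filter_spec <- function(kind = c("low-pass", "high-pass", "notch"),
                        fc, half_width = 2,
                        order = if (match.arg(kind) == "high-pass") 3000L
                                else 500L) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(fc), length(fc) == 1, fc > 0,
            order >= 0, half_width > 0)
  if (order %% 2 != 0) stop("filter order must be even (type I linear phase)",
                            call. = FALSE)
  structure(list(kind = kind, fc = fc, half_width = half_width,
                 order = as.integer(order), design = "windowed-sinc/hamming"),
            class = "filter_spec")
}

## Hamming-windowed sinc low-pass prototype, DC gain exactly 1
sinc_lowpass <- function(fc, fs, order) {
  m <- 0:order
  x <- 2 * fc / fs * (m - order / 2)
  h <- 2 * fc / fs * ifelse(x == 0, 1, sin(pi * x) / (pi * x))
  w <- 0.54 - 0.46 * cos(2 * pi * m / order)
  b <- h * w
  b / sum(b)
}

#' Design linear-phase FIR taps
#'
#' Windowed-sinc (Hamming) design. The low-pass prototype is normalized to
#' unit DC gain; the high-pass is its spectral complement (delta minus
#' low-pass), so its DC gain is zero to machine precision; the notch is the
#' complement of a band-pass built from two low-pass prototypes.
#'
#' @param spec A \code{\link{filter_spec}}.
#' @param fs Sampling rate, Hz.
#' @return List of class \code{fir_coefficients}: \code{b} (taps, length
#'   order + 1, symmetric) and \code{spec}.
#' @export
design_fir <- function(spec, fs) {
  stopifnot(inherits(spec, "filter_spec"), fs > 0)
  hi_edge <- if (spec$kind == "notch") spec$fc + spec$half_width else spec$fc
  if (hi_edge >= nyquist(fs)) {
    stop("cutoff ", hi_edge, " Hz violates the Nyquist limit ",
         nyquist(fs), " Hz at fs = ", fs, " Hz", call. = FALSE)
  }
  M <- spec$order
  delta <- numeric(M + 1); delta[M / 2 + 1] <- 1
  b <- switch(spec$kind,
    "low-pass"  = sinc_lowpass(spec$fc, fs, M),
    "high-pass" = delta - sinc_lowpass(spec$fc, fs, M),
    "notch" = {
      lo <- max(spec$fc - spec$half_width, 1e-6)
      bp <- sinc_lowpass(spec$fc + spec$half_width, fs, M) -
        sinc_lowpass(lo, fs, M)
      delta - bp
    })
  structure(list(b = b, spec = spec, fs = fs), class = "fir_coefficients")
}

#' Magnitude frequency response of FIR taps
#'
#' \eqn{|H(f)| = |\sum_r b_r e^{-i 2 \pi f r / f_s}|}.
#'
#' @param coef A \code{\link{design_fir}} result, or a bare numeric tap
#'   vector.
#' @param freqs Frequencies to evaluate, Hz, within \code{[0, fs/2]}.
#' @param fs Sampling rate, Hz.
#' @return Numeric vector of magnitudes, one per frequency.
#' @export
frequency_response <- function(coef, freqs, fs) {
  b <- if (inherits(coef, "fir_coefficients")) coef$b else as.numeric(coef)
  if (any(freqs < 0) || any(freqs > nyquist(fs))) {
    stop("frequencies must lie in [0, ", nyquist(fs), "] Hz", call. = FALSE)
  }
  r <- seq_along(b) - 1
  vapply(freqs, function(f) Mod(sum(b * exp(-2i * pi * f * r / fs))), 0)
}

## full linear convolution via FFT
conv_full <- function(x, b) {
  n <- length(x) + length(b) - 1
  nfft <- stats::nextn(n, 2)
  Re(stats::fft(stats::fft(c(x, numeric(nfft - length(x)))) *
                  stats::fft(c(b, numeric(nfft - length(b)))),
                inverse = TRUE))[1:n] / nfft
}

## one zero-phase pass: reflect-pad by one filter length, convolve,
## compensate the M/2 group delay, trim
zero_phase_pass <- function(x, b) {
  n <- length(x)
  L <- length(b)
  M <- L - 1
  left <- x[pmin(L + 1, n):2]
  right <- x[(n - 1):max(n - L, 1)]
  xp <- c(left, x, right)
  y <- conv_full(xp, b)
  off <- length(left) + M / 2
  y[(off + 1):(off + n)]
}

#' Apply an FIR filter with zero phase
#'
#' Forward--backward application of symmetric linear-phase taps with
#' reflect padding of one filter length at each edge: no phase distortion,
#' output length equals input length, squared magnitude response.
#'
#' @param rec An \code{\link{eeg_recording}}.
#' @param coef A \code{\link{design_fir}} result.
#' @return The filtered \code{\link{eeg_recording}}; history records the
#'   filter specification.
#' @export
apply_filter <- function(rec, coef) {
  stopifnot(inherits(coef, "fir_coefficients"))
  L <- length(coef$b)
  n <- ncol(rec$data)
  if (L > 1 && n < 3 * L) {
    stop("recording too short (", n, " samples) for ", L,
         "-tap zero-phase filtering; need at least ", 3 * L, call. = FALSE)
  }
  out <- rec
  out$data <- t(apply(rec$data, 1, function(x) {
    y <- zero_phase_pass(x, coef$b)
    rev(zero_phase_pass(rev(y), coef$b))
  }))
  dimnames(out$data) <- NULL
  append_history(out, sprintf("%s(fc=%g,order=%d)", coef$spec$kind,
                              coef$spec$fc, coef$spec$order))
}
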