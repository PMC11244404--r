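#' Wavelet specification for the continuous wavelet comparison path
#'
#' The package's primary spectral tool is the periodogram; the continuous
#' wavelet transform (CWT) is provided as an alternative time--frequency
#' view for cross-checking filter and band-power results.
#'
#' @param mother Mother wavelet; only \code{"morlet"} (omega0 = 6) is
#'   implemented.
#' @param scales Positive, strictly increasing scale factors (seconds).
#' @param omega0 Morlet center angular frequency (rad), default 6.
#' @return List of class \code{wavelet_spec}.
#' @export
wavelet_spec <- function(mother = "morlet", scales, omega0 = 6) {
  mother <- match.arg(mother)
  if (length(scales) == 0) stop("scale list must be non-empty", call. = FALSE)
  if (any(scales <= 0) || is.unsorted(scales, strictly = TRUE)) {
    stop("scales must be positive and strictly increasing", call. = FALSE)
  }
  structure(list(mother = mother, scales = as.numeric(scales),
                 omega0 = omega0), class = "wavelet_spec")
}

#' Pseudo-frequency of each scale
#'
#' For the Morlet wavelet, scale \code{a} (in seconds) corresponds to
#' frequency \code{omega0 / (2 pi a)} Hz.
#'
#' @param spec A \code{\link{wavelet_spec}}.
#' @return Numeric vector of Hz, one per scale.
#' @export
wavelet_pseudo_freq <- function(spec) {
  spec$omega0 / (2 * pi * spec$scales)
}

#' Continuous wavelet transform of a single channel
#'
#' Discretized CWT: for each scale \code{a}, the signal is convolved with
#' the conjugated, time-reversed, \code{1/sqrt(a)}-normalized Morlet
#' wavelet sampled at the signal's rate.
#'
#' @param x Numeric vector (single-channel signal, at least 2 samples).
#' @param spec A \code{\link{wavelet_spec}}.
#' @param fs Sampling rate, Hz.
#' @return Complex matrix, scales x time points.
#' @export
wavelet_transform <- function(x, spec, fs) {
  stopifnot(inherits(spec, "wavelet_spec"))
  if (length(x) < 2) stop("need at least 2 samples", call. = FALSE)
  n <- length(x)
  out <- matrix(0i, length(spec$scales), n)
  for (k in seq_along(spec$scales)) {
    a <- spec$scales[k]
    half <- min(ceiling(4 * a * fs), n)
    t <- (-half:half) / fs
    u <- t / a
    psi <- pi^(-0.25) * exp(1i * spec$omega0 * u) * exp(-u^2 / 2)
    kern <- Conj(psi) / sqrt(a) / fs
    m <- length(kern)
    nfft <- stats::nextn(n + m - 1, 2)
    conv <- stats::fft(stats::fft(c(x, numeric(nfft - n))) *
                         stats::fft(c(kern, numeric(nfft - m))),
                       inverse = TRUE)[1:(n + m - 1)] / nfft
    out[k, ] <- conv[(half + 1):(half + n)]
  }
  out
}
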