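#' Canonical EEG frequency bands
#'
#' The five-band table used throughout the package: delta 0.5--4 Hz,
#' theta 4--8 Hz, alpha 8--13 Hz, beta 13--30 Hz, gamma 30--42 Hz.
#' Bands are half-open intervals \code{[lo, hi)} (lower edge inclusive),
#' so shared edges at 4, 8, 13 and 30 Hz are never double-counted and the
#' union covers 0.5--42 Hz exactly.
#'
#' @return A data frame with columns \code{band}, \code{lo}, \code{hi} (Hz).
#' @export
#' @examples
#' eeg_bands()
eeg_bands <- function() {
  data.frame(
    band = c("delta", "theta", "alpha", "beta", "gamma"),
    lo   = c(0.5, 4, 8, 13, 30),
    hi   = c(4, 8, 13, 30, 42),
    stringsAsFactors = FALSE
  )
}

band_edges <- function(band) {
  tab <- eeg_bands()
  i <- match(band, tab$band)
  if (is.na(i)) {
    stop("unknown band '", band, "'; valid bands: ",
         paste(tab$band, collapse = ", "), call. = FALSE)
  }
  c(lo = tab$lo[i], hi = tab$hi[i])
}

#' Nyquist frequency of a sampling rate
#'
#' @param fs Sampling rate in Hz.
#' @return \code{fs / 2}, the highest frequency representable without
#'   aliasing. For the package's default 500 Hz this is 250 Hz.
#' @export
#' @examples
#' nyquist(500)  # 250
nyquist <- function(fs) {
  stopifnot(is.numeric(fs), length(fs) == 1, fs > 0)
  fs / 2
}
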