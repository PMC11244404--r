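#' Extract event-locked epochs
#'
#' Cuts one fixed-length segment per annotation: samples in
#' \code{[onset + window[1], onset + window[2])}, half-open, which at the
#' defaults (0.2 s to 1.0 s after the event) and 500 Hz is exactly 400
#' samples starting 100 samples after the onset. Events whose window does
#' not fit inside the recording are dropped and counted.
#'
#' @param rec An \code{\link{eeg_recording}}.
#' @param events An \code{\link{eeg_events}} stream.
#' @param window Two-element numeric, seconds relative to the onset.
#' @return List of class \code{epoch_set}: \code{data} (epochs x channels
#'   x samples array), \code{labels}, \code{window}, \code{fs},
#'   \code{epoch_len}, \code{channel_names}, \code{n_dropped}.
#' @export
extract_epochs <- function(rec, events, window = c(0.2, 1.0)) {
  stopifnot(length(window) == 2)
  if (window[2] <= window[1]) {
    stop("epoch window is reversed or empty: (", window[1], ", ",
         window[2], ")", call. = FALSE)
  }
  fs <- rec$fs
  n <- ncol(rec$data)
  epoch_len <- round((window[2] - window[1]) * fs)
  start0 <- round(events$onset_s * fs) + round(window[1] * fs)  # 0-based
  keep <- start0 >= 0 & (start0 + epoch_len) <= n
  n_dropped <- sum(!keep)
  if (!any(keep)) {
    stop("no events have a complete window inside the recording",
         call. = FALSE)
  }
  starts <- start0[keep]
  k <- length(starts)
  data <- array(0, dim = c(k, nrow(rec$data), epoch_len))
  for (i in seq_len(k)) {
    data[i, , ] <- rec$data[, (starts[i] + 1):(starts[i] + epoch_len)]
  }
  structure(list(data = data, labels = events$label[keep],
                 window = window, fs = fs, epoch_len = epoch_len,
                 channel_names = rec$channel_names, n_dropped = n_dropped),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples @ %g Hz\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs))
  cat("  labels:", paste(names(table(x$labels)), table(x$labels),
                         sep = "=", collapse = ", "),
      " dropped:", x$n_dropped, "\n")
  invisible(x)
}

## one-sided periodogram of a vector: |DFT|^2 / N, with doubling of the
## non-DC, non-Nyquist bins (even N assumed for the Nyquist bin)
periodogram_1s <- function(x) {
  N <- length(x)
  P <- Mod(stats::fft(x))^2 / N
  half <- floor(N / 2) + 1
  out <- P[1:half]
  dbl <- 2:(half - if (N %% 2 == 0) 1 else 0)
  out[dbl] <- 2 * out[dbl]
  out
}

#' Periodogram / Welch power spectral density of an epoch set
#'
#' Per epoch and channel: the one-sided periodogram
#' \eqn{PSD(f) = |X(f)|^2 / N} (boxcar window, no detrending), with
#' non-DC/non-Nyquist bins doubled so that the one-sided sum obeys
#' Parseval: \eqn{\sum_f PSD(f) = \sum_n x[n]^2}. The Welch variant
#' averages modified periodograms of 50\%-overlapping Hann-windowed
#' segments.
#'
#' @param epochs An \code{\link{extract_epochs}} result.
#' @param method \code{"periodogram"} (default) or \code{"welch"}.
#' @param window Taper for the periodogram: \code{"boxcar"} (default,
#'   matching the plain squared-DFT definition) or \code{"hann"} (use when
#'   sidelobe leakage from strong narrowband components matters). Power is
#'   rescaled by the window's energy so Parseval holds in expectation.
#' @param nperseg Welch segment length (default \code{min(256, epoch_len)}).
#' @return List of class \code{psd_features}: \code{values} (epochs x
#'   channels x frequency bins), \code{freqs} (Hz), \code{band_powers}
#'   (epochs x channels x 5 bands), \code{band_table}, \code{labels},
#'   \code{fs}, \code{channel_names}, \code{method}.
#' @export
compute_psd <- function(epochs, method = c("periodogram", "welch"),
                        window = c("boxcar", "hann"), nperseg = NULL) {
  method <- match.arg(method)
  window <- match.arg(window)
  stopifnot(inherits(epochs, "epoch_set"))
  N <- epochs$epoch_len
  if (N < 8) stop("epochs too short for spectral estimation", call. = FALSE)
  fs <- epochs$fs
  d <- dim(epochs$data)
  if (method == "periodogram") {
    nfreq <- floor(N / 2) + 1
    freqs <- (0:(nfreq - 1)) * fs / N
    if (window == "boxcar") {
      seg_fun <- periodogram_1s
    } else {
      taper <- 0.5 - 0.5 * cos(2 * pi * (0:(N - 1)) / (N - 1))
      tnorm <- mean(taper^2)
      seg_fun <- function(x) periodogram_1s(x * taper) / tnorm
    }
  } else {
    if (is.null(nperseg)) nperseg <- min(256L, N)
    hop <- max(1L, nperseg %/% 2L)
    win <- 0.5 - 0.5 * cos(2 * pi * (0:(nperseg - 1)) / (nperseg - 1))
    wnorm <- sum(win^2) / nperseg
    nfreq <- floor(nperseg / 2) + 1
    freqs <- (0:(nfreq - 1)) * fs / nperseg
    ## the N/nperseg factor keeps Welch on the same epoch-energy scale as
    ## the periodogram (whose one-sided sum equals sum(x^2))
    seg_fun <- function(x) {
      starts <- seq(1, length(x) - nperseg + 1, by = hop)
      rowMeans(vapply(starts, function(s) {
        periodogram_1s(x[s:(s + nperseg - 1)] * win) / wnorm
      }, numeric(nfreq))) * N / nperseg
    }
  }
  values <- array(0, dim = c(d[1], d[2], nfreq))
  for (e in seq_len(d[1])) {
    for (c in seq_len(d[2])) {
      values[e, c, ] <- seg_fun(epochs$data[e, c, ])
    }
  }
  tab <- eeg_bands()
  band_powers <- array(0, dim = c(d[1], d[2], nrow(tab)),
                       dimnames = list(NULL, NULL, tab$band))
  for (i in seq_len(nrow(tab))) {
    sel <- freqs >= tab$lo[i] & freqs < tab$hi[i]
    band_powers[, , i] <- apply(values[, , sel, drop = FALSE], c(1, 2), sum)
  }
  structure(list(values = values, freqs = freqs,
                 band_powers = band_powers, band_table = tab,
                 labels = epochs$labels, fs = fs,
                 channel_names = epochs$channel_names, method = method),
            class = "psd_features")
}

#' Band power per epoch and channel
#'
#' Sum of one-sided PSD bins with \code{lo <= f < hi} (half-open,
#' lower-edge inclusive).
#'
#' @param psd A \code{\link{compute_psd}} result.
#' @param band Band name: delta, theta, alpha, beta or gamma.
#' @return Epochs x channels numeric matrix.
#' @export
band_power <- function(psd, band) {
  stopifnot(inherits(psd, "psd_features"))
  edges <- band_edges(band)
  sel <- psd$freqs >= edges["lo"] & psd$freqs < edges["hi"]
  apply(psd$values[, , sel, drop = FALSE], c(1, 2), sum)
}

#' Average event-locked waveform per channel
#'
#' @param epochs An \code{\link{extract_epochs}} result with at least one
#'   epoch.
#' @return Channels x samples matrix: the arithmetic mean over epochs.
#' @export
channel_means <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (dim(epochs$data)[1] < 1) stop("empty epoch set", call. = FALSE)
  apply(epochs$data, c(2, 3), mean)
}

#' Flatten PSD band powers to a classifier feature matrix
#'
#' @param psd A \code{\link{compute_psd}} result.
#' @param log Take log power (default TRUE; stabilizes the heavy right
#'   tail of power estimates).
#' @return Epochs x (channels * 5 bands) matrix.
#' @export
psd_feature_matrix <- function(psd, log = TRUE) {
  d <- dim(psd$band_powers)
  m <- matrix(psd$band_powers, d[1], d[2] * d[3])
  if (log) m <- base::log(pmax(m, 1e-20))
  m
}
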