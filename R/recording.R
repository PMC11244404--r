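#' Multichannel EEG recording container
#'
#' A light S3 container for a channels-by-samples matrix with its sampling
#' rate, channel names, reference state and an append-only history of
#' applied operations. Amplitudes are in microvolts, time in seconds,
#' sample indices 0-based in all user-facing arithmetic.
#'
#' @param data Numeric matrix, channels x samples (microvolts).
#' @param fs Sampling rate in Hz.
#' @param channel_names Character vector, one name per row of \code{data}.
#' @param reference Reference state, \code{"as-recorded"} or
#'   \code{"mastoid-average"}.
#' @param history Character vector of operations already applied.
#' @return An object of class \code{eeg_recording}.
#' @export
eeg_recording <- function(data, fs, channel_names,
                          reference = c("as-recorded", "mastoid-average"),
                          history = character()) {
  reference <- match.arg(reference)
  data <- as.matrix(data)
  if (!is.numeric(data) || !all(is.finite(data))) {
    stop("recording data must be a finite numeric matrix", call. = FALSE)
  }
  if (length(channel_names) != nrow(data)) {
    stop("channel_names length (", length(channel_names),
         ") != channel count (", nrow(data), ")", call. = FALSE)
  }
  if (anyDuplicated(channel_names)) {
    stop("channel names must be unique", call. = FALSE)
  }
  stopifnot(is.numeric(fs), length(fs) == 1, fs > 0)
  structure(
    list(data = data, fs = fs, channel_names = as.character(channel_names),
         reference = reference, history = as.character(history)),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  cat("  reference:", x$reference, "\n")
  if (length(x$history)) {
    cat("  history:", paste(x$history, collapse = " -> "), "\n")
  }
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

rec_duration <- function(rec) ncol(rec$data) / rec$fs

append_history <- function(rec, entry) {
  rec$history <- c(rec$history, entry)
  rec
}

#' Event annotation stream
#'
#' Onset times (seconds from recording start) with class labels,
#' \code{"RH"} (road hypnosis) or \code{"ND"} (normal driving).
#'
#' @param onset Numeric vector of onsets in seconds, non-decreasing.
#' @param label Character vector of labels, one of \code{"RH"}, \code{"ND"}.
#' @return A data frame of class \code{eeg_events} with columns
#'   \code{onset_s}, \code{label}.
#' @export
eeg_events <- function(onset, label) {
  if (length(onset) != length(label)) {
    stop("onset and label lengths differ", call. = FALSE)
  }
  if (!all(label %in% c("RH", "ND"))) {
    stop("labels must be 'RH' or 'ND'", call. = FALSE)
  }
  if (is.unsorted(onset)) {
    stop("event onsets must be sorted non-decreasing", call. = FALSE)
  }
  structure(data.frame(onset_s = as.numeric(onset),
                       label = as.character(label),
                       stringsAsFactors = FALSE),
            class = c("eeg_events", "data.frame"))
}
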