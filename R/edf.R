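## Minimal European Data Format (EDF) I/O: continuous 16-bit signals, one
## data record holding the whole recording. Covers exactly what the package
## writes; not a general-purpose EDF implementation.

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

#' Write a recording to an EDF file
#'
#' Signals are quantized to 16 bits over each channel's own physical range,
#' so round-trip error is bounded by one quantization step per channel.
#'
#' @param rec An \code{\link{eeg_recording}}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_edf <- function(rec, path) {
  data <- rec$data
  n_sig <- nrow(data)
  n_samp <- ncol(data)
  dig_min <- -32768; dig_max <- 32767
  ## integer physical bounds: exactly representable in the 8-character
  ## header fields, so the scale survives the round trip
  phys_min <- floor(apply(data, 1, min))
  phys_max <- ceiling(apply(data, 1, max))
  flat <- phys_max - phys_min < 1
  phys_max[flat] <- phys_min[flat] + 1
  header_bytes <- 256L + 256L * n_sig

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(pad_field(x, width), con, nchars = width,
                                     eos = NULL)
  wr("0", 8); wr("synthetic EEG", 80); wr("hypnoseeg", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(header_bytes, 8); wr("", 44)
  wr(1, 8)                                   # one data record
  wr(format(n_samp / rec$fs), 8)             # record duration, s
  wr(n_sig, 4)
  for (nm in rec$channel_names) wr(nm, 16)
  for (i in seq_len(n_sig)) wr("", 80)       # transducer
  for (i in seq_len(n_sig)) wr("uV", 8)
  for (i in seq_len(n_sig)) wr(format(phys_min[i], digits = 8), 8)
  for (i in seq_len(n_sig)) wr(format(phys_max[i], digits = 8), 8)
  for (i in seq_len(n_sig)) wr(dig_min, 8)
  for (i in seq_len(n_sig)) wr(dig_max, 8)
  for (i in seq_len(n_sig)) wr("", 80)       # prefiltering
  for (i in seq_len(n_sig)) wr(n_samp, 8)
  for (i in seq_len(n_sig)) wr("", 32)

  for (i in seq_len(n_sig)) {
    scale <- (dig_max - dig_min) / (phys_max[i] - phys_min[i])
    dig <- round((data[i, ] - phys_min[i]) * scale + dig_min)
    writeBin(as.integer(pmin(pmax(dig, dig_min), dig_max)), con,
             size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by \code{\link{write_edf}}
#'
#' @param path EDF file path.
#' @return An \code{\link{eeg_recording}}.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                       # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  n_sig <- as.integer(rd(4))
  labels <- vapply(seq_len(n_sig), function(i) rd(16), "")
  for (i in seq_len(n_sig)) rd(80)
  for (i in seq_len(n_sig)) rd(8)
  phys_min <- vapply(seq_len(n_sig), function(i) as.numeric(rd(8)), 0)
  phys_max <- vapply(seq_len(n_sig), function(i) as.numeric(rd(8)), 0)
  dig_min <- vapply(seq_len(n_sig), function(i) as.numeric(rd(8)), 0)
  dig_max <- vapply(seq_len(n_sig), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(n_sig)) rd(80)
  spr <- vapply(seq_len(n_sig), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(n_sig)) rd(32)

  data <- matrix(0, n_sig, spr[1] * n_rec)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(n_sig)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2, signed = TRUE,
                     endian = "little")
      phys <- (dig - dig_min[i]) * (phys_max[i] - phys_min[i]) /
        (dig_max[i] - dig_min[i]) + phys_min[i]
      data[i, ((r - 1) * spr[i] + 1):(r * spr[i])] <- phys
    }
  }
  eeg_recording(data, spr[1] / rec_dur, labels, reference = "as-recorded",
                history = paste0("read_edf(", basename(path), ")"))
}

#' Write / read event annotations as TSV
#'
#' Two columns: \code{onset_s} (seconds) and \code{label} (RH or ND).
#'
#' @param events An \code{\link{eeg_events}} stream.
#' @param path TSV file path.
#' @return \code{path} (write) or an \code{\link{eeg_events}} (read).
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  eeg_events(d$onset_s, d$label)
}

#' Write a synthetic fixture (EDF + events TSV)
#'
#' @param recording An \code{\link{eeg_recording}}.
#' @param events An \code{\link{eeg_events}} stream.
#' @param dir Output directory (created if missing).
#' @param name File stem; writes \code{<name>.edf} and
#'   \code{<name>_events.tsv}.
#' @return Named character vector with the two paths.
#' @export
write_fixture <- function(recording, events, dir, name = "synthetic_eeg") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  edf <- file.path(dir, paste0(name, ".edf"))
  tsv <- file.path(dir, paste0(name, "_events.tsv"))
  write_edf(recording, edf)
  write_events(events, tsv)
  c(edf = edf, events = tsv)
}
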