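#' Minimal EDF (European Data Format) writer
#'
#' Writes a continuous multichannel recording as a standard EDF file:
#' ASCII header, one-second data records, 16-bit little-endian samples
#' scaled channel-wise between the physical and digital ranges.  Covers
#' the plain continuous-signal subset of the format (no annotations,
#' identical sampling rate across channels); sufficient for ECG/EEG
#' exchange with the usual biosignal toolboxes.
#'
#' @param data samples x channels numeric matrix; column names become
#'   signal labels
#' @param fs sampling rate in Hz (integer); a trailing partial second is
#'   dropped
#' @param path output file path
#' @param labels optional signal labels overriding column names
#' @return invisibly, the number of data records written
#' @export
write_edf <- function(data, fs, path, labels = NULL) {
  if (is.numeric(data) && !is.matrix(data)) data <- matrix(data, ncol = 1)
  stop_if_not(is.matrix(data) && nrow(data) >= fs,
              "need at least one second of data")
  stop_if_not(fs == round(fs) && fs > 0, "fs must be a positive integer")
  ns <- ncol(data)
  if (is.null(labels)) labels <- colnames(data)
  if (is.null(labels)) labels <- paste0("CH", seq_len(ns))
  n_rec <- nrow(data) %/% fs
  data <- data[seq_len(n_rec * fs), , drop = FALSE]

  pmin_ <- apply(data, 2, min)
  pmax_ <- apply(data, 2, max)
  flat <- pmax_ - pmin_ <= 0
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32767; dmax <- 32767

  pad <- function(x, w) {
    x <- substr(as.character(x), 1, w)
    formatC(x, width = -w)            # left-justified, space padded
  }
  num8 <- function(x) pad(formatC(signif(x, 7), format = "g", digits = 7), 8)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(pad("0", 8), pad("synthetic subject", 80),
                pad("hrvnet recording", 80),
                pad("01.01.20", 8), pad("00.00.00", 8),
                pad(256 * (1 + ns), 8), pad("", 44),
                pad(n_rec, 8), pad("1", 8), pad(ns, 4),
                paste(pad(labels, 16), collapse = ""),
                paste(pad(rep("synthetic", ns), 80), collapse = ""),
                paste(pad(rep("uV", ns), 8), collapse = ""),
                paste(vapply(pmin_, num8, character(1)), collapse = ""),
                paste(vapply(pmax_, num8, character(1)), collapse = ""),
                paste(pad(rep(dmin, ns), 8), collapse = ""),
                paste(pad(rep(dmax, ns), 8), collapse = ""),
                paste(pad(rep("", ns), 80), collapse = ""),
                paste(pad(rep(fs, ns), 8), collapse = ""),
                paste(pad(rep("", ns), 32), collapse = ""))
  writeChar(hdr, con, eos = NULL)

  gain <- (dmax - dmin) / (pmax_ - pmin_)
  dig <- round(sweep(sweep(data, 2, pmin_), 2, gain, "*") + dmin)
  dig <- pmin(pmax(dig, dmin), dmax)
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1) * fs + 1):(r * fs)
    writeBin(as.integer(as.vector(dig[rows, , drop = FALSE])), con,
             size = 2, endian = "little")
  }
  invisible(n_rec)
}

#' Minimal EDF reader
#'
#' Reads files of the continuous subset written by \code{\link{write_edf}}
#' (equal per-channel sampling rates, no annotation channels); samples are
#' rescaled to physical units.
#'
#' @param path EDF file path
#' @return list: \code{data} (samples x channels matrix with labels),
#'   \code{fs} (Hz), \code{labels}
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  version <- rd(8)
  stop_if_not(version == "0", "not an EDF file")
  rd(80); rd(80); rd(8); rd(8)
  rd(8)                                   # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)           # transducer
  for (i in seq_len(ns)) rd(8)            # physical dimension
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)           # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)
  stop_if_not(length(unique(spr)) == 1,
              "mixed per-channel sampling rates are not supported")
  out <- matrix(0, n_rec * spr[1], ns)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      raw <- readBin(con, integer(), n = spr[ch], size = 2,
                     endian = "little", signed = TRUE)
      phys <- (raw - dmin[ch]) / (dmax[ch] - dmin[ch]) *
        (pmax_[ch] - pmin_[ch]) + pmin_[ch]
      out[((r - 1) * spr[ch] + 1):(r * spr[ch]), ch] <- phys
    }
  }
  colnames(out) <- labels
  list(data = out, fs = spr[1] / rec_dur, labels = labels)
}
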