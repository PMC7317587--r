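#' Detect R peaks in a single-lead ECG (Pan-Tompkins)
#'
#' Classic Pan-Tompkins stages: band-pass 5-15 Hz (4th-order Butterworth,
#' zero-phase), five-point derivative, squaring, 150 ms moving-window
#' integration, then adaptive dual-threshold peak picking on the integrated
#' signal with a 200 ms refractory period and a search-back pass at half
#' threshold for missed beats.  Each detection is refined to the local
#' maximum of the band-passed signal so peak times are not biased by the
#' integrator delay.
#'
#' @param ecg an \code{ecg_signal} or numeric waveform vector
#' @param fs sampling rate in Hz (>= 250); taken from the object if present
#' @return object of class \code{r_peaks}: \code{peak_times} (s, strictly
#'   increasing), \code{fs}, \code{quality_flags} (TRUE for peaks found by
#'   the primary threshold, FALSE for search-back rescues)
#' @export
detect_r_peaks <- function(ecg, fs = NULL) {
  if (inherits(ecg, "ecg_signal")) {
    if (is.null(fs)) fs <- ecg$fs
    ecg <- ecg$signal
  }
  stop_if_not(!is.null(fs) && fs >= 250, "fs must be at least 250 Hz")
  n <- length(ecg)
  stop_if_not(n >= 10 * fs, "ECG must be at least 10 s long")
  if (max(ecg) - min(ecg) < .Machine$double.eps^0.5)
    stop("no QRS detected: flatline input", call. = FALSE)

  bf <- signal::butter(4, c(5, 15) / (fs / 2), type = "pass")
  bp <- signal::filtfilt(bf, ecg - mean(ecg))
  # five-point derivative, squaring, moving-window integration (150 ms)
  der <- signal::filter(c(1, 2, 0, -2, -1) * fs / 8, 1, bp)
  sq <- as.numeric(der)^2
  wi <- max(1L, round(0.150 * fs))
  mwi <- as.numeric(signal::filter(rep(1 / wi, wi), 1, sq))

  refr <- round(0.2 * fs)
  # candidate local maxima of the integrated signal
  dm <- diff(mwi)
  cand <- which(dm[-length(dm)] > 0 & dm[-1] <= 0) + 1L
  if (length(cand) == 0) stop("no QRS detected", call. = FALSE)

  spki <- max(mwi[seq_len(min(n, 2 * fs))]) / 3
  npki <- mean(mwi[seq_len(min(n, 2 * fs))]) / 2
  thr <- npki + 0.25 * (spki - npki)
  peaks <- integer(0)
  flags <- logical(0)
  last <- -Inf
  rr_recent <- numeric(0)
  for (i in cand) {
    if (i - last < refr) next
    if (mwi[i] > thr) {
      # search-back: if the gap since the last beat exceeds 1.66x the
      # running RR average, rescan it at half threshold
      if (length(rr_recent) >= 2 && is.finite(last)) {
        rr_avg <- mean(rr_recent)
        if (i - last > 1.66 * rr_avg) {
          seg <- cand[cand > last + refr & cand < i - refr]
          seg <- seg[mwi[seg] > thr / 2]
          if (length(seg)) {
            j <- seg[which.max(mwi[seg])]
            rr_recent <- c(tail(rr_recent, 7), j - last)
            peaks <- c(peaks, j)
            flags <- c(flags, FALSE)
            last <- j
          }
        }
      }
      if (is.finite(last)) rr_recent <- c(tail(rr_recent, 7), i - last)
      peaks <- c(peaks, i)
      flags <- c(flags, TRUE)
      last <- i
      spki <- 0.125 * mwi[i] + 0.875 * spki
    } else {
      npki <- 0.125 * mwi[i] + 0.875 * npki
    }
    thr <- npki + 0.25 * (spki - npki)
  }
  if (length(peaks) < 2) stop("no QRS detected", call. = FALSE)

  # refine each detection to the local band-passed maximum; the MWI peak
  # lags the R wave by roughly the integration window
  half <- round(0.10 * fs)
  ref <- vapply(peaks, function(i) {
    lo <- max(1, i - wi - half); hi <- min(n, i + half)
    as.integer(lo + which.max(bp[lo:hi]) - 1)
  }, integer(1))
  keep <- !duplicated(ref)
  ref <- ref[keep]; flags <- flags[keep]
  ord <- order(ref)
  ref <- ref[ord]; flags <- flags[ord]
  # enforce the refractory period after refinement
  ok <- c(TRUE, diff(ref) >= refr)
  while (!all(ok)) {
    ref <- ref[ok]; flags <- flags[ok]
    ok <- c(TRUE, diff(ref) >= refr)
  }
  structure(list(peak_times = (ref - 1) / fs, fs = fs,
                 quality_flags = flags),
            class = "r_peaks")
}
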