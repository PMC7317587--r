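#' Clean an R-R series into normal-to-normal (NN) intervals
#'
#' Two sequential screens, mirroring common HRV practice:
#' \enumerate{
#'   \item a physiological gate removing intervals outside 200-3000 ms
#'     (detector artifacts), and
#'   \item the sequential 20\% ectopic filter: an interval is kept only if
#'     it differs from the \emph{previous retained} interval by at most
#'     20\%; the first gated interval anchors the filter.
#' }
#' The operation is idempotent: running it on its own output removes
#' nothing further.
#'
#' @param rr numeric R-R intervals in ms, an \code{rr_series}, or an
#'   \code{r_peaks} object (intervals taken as successive differences)
#' @param onset_times optional onset time (s) of each interval, i.e. the
#'   time of the beat opening it; derived by cumulation when missing
#' @param tolerance relative-change threshold of the ectopic filter
#' @return object of class \code{nn_series}: \code{intervals} (ms),
#'   \code{onset_times} (s), \code{removed} (indices into the input),
#'   \code{removed_reason}
#' @export
clean_nn <- function(rr, onset_times = NULL, tolerance = 0.20) {
  if (inherits(rr, "r_peaks")) {
    onset_times <- rr$peak_times[-length(rr$peak_times)]
    rr <- diff(rr$peak_times) * 1000
  } else if (inherits(rr, "rr_series")) {
    onset_times <- rr$beat_times[-length(rr$beat_times)]
    rr <- rr$intervals
  }
  stop_if_not(length(rr) >= 4, "need at least 4 intervals")
  if (is.null(onset_times)) onset_times <- c(0, cumsum(rr[-length(rr)]) / 1000)
  stop_if_not(length(onset_times) == length(rr),
              "onset_times must match intervals")

  gate <- rr > 200 & rr < 3000
  reason <- character(length(rr))
  reason[!gate] <- "physiological gate"
  keep <- gate
  last_kept <- NA_real_
  for (i in seq_along(rr)) {
    if (!keep[i]) next
    if (is.na(last_kept)) {
      last_kept <- rr[i]
    } else if (abs(rr[i] - last_kept) / last_kept > tolerance) {
      keep[i] <- FALSE
      reason[i] <- "20% filter"
    } else {
      last_kept <- rr[i]
    }
  }
  if (sum(keep) < 4)
    stop("series too short after cleaning", call. = FALSE)
  structure(list(intervals = rr[keep], onset_times = onset_times[keep],
                 removed = which(!keep),
                 removed_reason = reason[!keep]),
            class = "nn_series")
}

#' Interpolate an NN series to a uniformly sampled tachogram
#'
#' Cubic-spline interpolation of the NN intervals against their onset
#' times, evaluated on a uniform grid (default 4 Hz) spanning the cleaned
#' record.  Deleted ectopic beats are bridged by the spline.
#'
#' @param nn an \code{nn_series}
#' @param fs_interp resampling rate in Hz (default 4)
#' @return object of class \code{tachogram}: \code{values} (ms),
#'   \code{times} (s), \code{fs_interp}
#' @export
interpolate_tachogram <- function(nn, fs_interp = 4) {
  stopifnot(inherits(nn, "nn_series"))
  stop_if_not(length(nn$intervals) >= 4, "need at least 4 NN intervals")
  stop_if_not(fs_interp > 0, "fs_interp must be positive")
  t0 <- nn$onset_times[1]
  t1 <- nn$onset_times[length(nn$onset_times)]
  grid <- seq(t0, t1, by = 1 / fs_interp)
  vals <- spline(nn$onset_times, nn$intervals, xout = grid,
                 method = "fmm")$y
  structure(list(values = vals, times = grid, fs_interp = fs_interp),
            class = "tachogram")
}

#' Time-domain HRV summary
#'
#' Computes the standard clinical time-domain measures from cleaned NN
#' intervals:
#' \describe{
#'   \item{sdnn}{sample SD of all NN intervals (ms)}
#'   \item{sdnni}{mean of per-segment SDs, segments being consecutive
#'     50-second spans of onset time; a trailing partial segment counts
#'     only if it holds at least 10 beats}
#'   \item{rmssd}{root mean square of successive differences (ms)}
#'   \item{pnn50}{percentage of successive differences exceeding 50 ms}
#'   \item{hr}{mean heart rate, 60000 / mean NN interval (bpm)}
#' }
#'
#' @param nn an \code{nn_series} (or numeric NN intervals in ms)
#' @param segment_s SDNNi segment length in seconds (default 50)
#' @param min_segment_beats minimum beats for a trailing partial segment
#' @return named list: \code{sdnn}, \code{sdnni}, \code{rmssd},
#'   \code{pnn50}, \code{hr}
#' @export
time_domain <- function(nn, segment_s = 50, min_segment_beats = 10) {
  if (is.numeric(nn)) {
    nn <- list(intervals = nn,
               onset_times = c(0, cumsum(nn[-length(nn)]) / 1000))
  }
  x <- nn$intervals
  stop_if_not(length(x) >= 2, "need at least 2 intervals")
  d <- diff(x)
  seg <- floor((nn$onset_times - nn$onset_times[1]) / segment_s)
  counts <- table(seg)
  full_span <- (max(nn$onset_times) - nn$onset_times[1]) %/% segment_s
  seg_sd <- vapply(names(counts), function(s) {
    in_seg <- seg == as.integer(s)
    is_partial <- as.integer(s) == full_span &&
      (max(nn$onset_times) - nn$onset_times[1]) %% segment_s > 0
    if (is_partial && sum(in_seg) < min_segment_beats) return(NA_real_)
    if (sum(in_seg) < 2) return(NA_real_)
    sd(x[in_seg])
  }, numeric(1))
  list(sdnn = sd(x),
       sdnni = mean(seg_sd, na.rm = TRUE),
       rmssd = sqrt(mean(d^2)),
       pnn50 = if (length(d)) 100 * mean(abs(d) > 50) else 0,
       hr = 60000 / mean(x))
}
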