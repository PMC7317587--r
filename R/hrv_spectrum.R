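#' Autoregressive (Burg) power spectrum of a tachogram
#'
#' Removes the mean and linear trend, fits an AR model of the given order
#' by Burg's method, and evaluates the one-sided parametric spectrum
#' \deqn{S(f) = 2 \sigma^2 / (f_s |1 - \sum_k a_k e^{-2\pi i f k / f_s}|^2)}
#' on a dense frequency grid.  LF and HF powers are obtained by trapezoidal
#' integration over the standard bands, LF = [0.04, 0.15) Hz and
#' HF = [0.15, 0.4] Hz.  AR peaks of high-order fits are extremely narrow,
#' so the default grid is deliberately fine (32769 points to Nyquist);
#' total integrated power then tracks the detrended variance closely.
#'
#' @param tach a \code{tachogram} (or numeric ms series at \code{fs_interp})
#' @param order AR model order (default 16, the common HRV toolbox setting)
#' @param fs_interp sampling rate when \code{tach} is a bare vector
#' @param n_freq number of grid points from 0 to Nyquist
#' @return object of class \code{hrv_spectrum}: \code{freqs} (Hz),
#'   \code{psd} (ms^2/Hz), \code{lf_power}, \code{hf_power} (ms^2),
#'   \code{ar_order}, \code{total_power}, \code{variance}
#' @export
ar_spectrum <- function(tach, order = 16, fs_interp = NULL, n_freq = 32769) {
  if (inherits(tach, "tachogram")) {
    fs <- tach$fs_interp
    x <- tach$values
  } else {
    stop_if_not(!is.null(fs_interp), "fs_interp needed for a bare vector")
    fs <- fs_interp
    x <- as.numeric(tach)
  }
  stop_if_not(length(x) > 4 * order,
              "tachogram must be longer than 4 x AR order")
  # detrend: mean + linear trend
  tt <- seq_along(x)
  x <- residuals_lin(x, tt)
  v <- var(x)
  if (v < .Machine$double.eps)
    stop("degenerate series: zero variance", call. = FALSE)
  fit <- ar(x, aic = FALSE, order.max = order, method = "burg",
            demean = FALSE)
  if (fit$var.pred < v * 1e-12)
    stop("degenerate series: AR innovation variance is numerically zero",
         call. = FALSE)
  freqs <- seq(0, fs / 2, length.out = n_freq)
  H <- 1 - as.vector(ar_exp_grid(n_freq, order) %*% fit$ar)
  psd <- 2 * fit$var.pred / fs / Mod(H)^2
  lf <- freqs >= 0.04 & freqs < 0.15
  hf <- freqs >= 0.15 & freqs <= 0.40
  structure(list(freqs = freqs, psd = psd, ar_order = order,
                 lf_power = pracma::trapz(freqs[lf], psd[lf]),
                 hf_power = pracma::trapz(freqs[hf], psd[hf]),
                 total_power = pracma::trapz(freqs, psd),
                 variance = v),
            class = "hrv_spectrum")
}

# least-squares detrend against an arbitrary regressor
residuals_lin <- function(y, t) {
  t <- t - mean(t)
  y - mean(y) - sum(t * (y - mean(y))) / sum(t * t) * t
}

# cache for the (n_freq x order) complex exponential grid; depends only on
# the normalised frequency grid, not on fs
.ar_grid_cache <- new.env(parent = emptyenv())
ar_exp_grid <- function(n_freq, order) {
  key <- paste(n_freq, order)
  if (!is.null(.ar_grid_cache[[key]])) return(.ar_grid_cache[[key]])
  fn <- seq(0, 0.5, length.out = n_freq)
  E <- exp(-2i * pi * outer(fn, seq_len(order)))
  .ar_grid_cache[[key]] <- E
  E
}

#' One-row HRV summary for a subject
#'
#' Convenience wrapper running the full HRV chain -- cleaning
#' (\code{\link{clean_nn}}), 4 Hz spline interpolation
#' (\code{\link{interpolate_tachogram}}), Burg spectrum
#' (\code{\link{ar_spectrum}}) and time-domain measures
#' (\code{\link{time_domain}}) -- and returning the conventional report row.
#'
#' @param rr raw R-R intervals (ms vector, \code{rr_series} or
#'   \code{r_peaks})
#' @param ar_order AR order for the spectral step
#' @param fs_interp tachogram resampling rate (Hz)
#' @param segment_s SDNNi segment length (s)
#' @return one-row data.frame with columns HR, LF, HF, SDNN, SDNNi, RMSSD,
#'   pNN50
#' @export
hrv_summary <- function(rr, ar_order = 16, fs_interp = 4, segment_s = 50) {
  nn <- clean_nn(rr)
  td <- time_domain(nn, segment_s = segment_s)
  sp <- ar_spectrum(interpolate_tachogram(nn, fs_interp), order = ar_order)
  data.frame(HR = td$hr, LF = sp$lf_power, HF = sp$hf_power,
             SDNN = td$sdnn, SDNNi = td$sdnni, RMSSD = td$rmssd,
             pNN50 = td$pnn50)
}
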