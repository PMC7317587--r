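#' Specification for a synthetic R-R interval series
#'
#' Describes a tachogram-level cardiac simulator: an instantaneous R-R
#' interval modulated by one low-frequency (Mayer-wave range) and one
#' high-frequency (respiratory range) sinusoid plus Gaussian beat-to-beat
#' jitter.  Beats are laid down by integrating the instantaneous interval,
#' so the modulation frequencies land inside the standard LF (0.04-0.15 Hz)
#' and HF (0.15-0.4 Hz) analysis bands by construction.
#'
#' @param duration_s recording length in seconds (default 300, i.e. the
#'   conventional 5-minute resting epoch)
#' @param mean_rr mean R-R interval in ms
#' @param lf_freq,hf_freq modulation frequencies in Hz; must lie inside the
#'   LF and HF bands respectively
#' @param lf_amp,hf_amp modulation amplitudes in ms
#' @param noise_sd beat-to-beat Gaussian jitter SD in ms
#' @param ectopic_rate fraction of beats replaced by ectopic-like beats
#'   (see \code{\link{inject_ectopics}}); at most 0.2
#' @param seed integer seed; the generator is deterministic given the spec
#' @return an object of class \code{rr_gen_spec}
#' @export
rr_gen_spec <- function(duration_s = 300, mean_rr = 900,
                        lf_freq = 0.1, hf_freq = 0.25,
                        lf_amp = 30, hf_amp = 30,
                        noise_sd = 20, ectopic_rate = 0, seed = NULL) {
  stop_if_not(duration_s > 0, "duration_s must be positive")
  stop_if_not(mean_rr > 0, "mean_rr must be positive")
  stop_if_not(lf_freq >= 0.04 && lf_freq <= 0.15,
              "lf_freq must lie in the LF band [0.04, 0.15] Hz")
  stop_if_not(hf_freq >= 0.15 && hf_freq <= 0.4,
              "hf_freq must lie in the HF band [0.15, 0.4] Hz")
  stop_if_not(ectopic_rate >= 0 && ectopic_rate <= 0.2,
              "ectopic_rate must lie in [0, 0.2]")
  stop_if_not(lf_amp >= 0 && hf_amp >= 0 && noise_sd >= 0,
              "amplitudes and noise_sd must be non-negative")
  structure(list(duration_s = duration_s, mean_rr = mean_rr,
                 lf_freq = lf_freq, hf_freq = hf_freq,
                 lf_amp = lf_amp, hf_amp = hf_amp,
                 noise_sd = noise_sd, ectopic_rate = ectopic_rate,
                 seed = seed),
            class = "rr_gen_spec")
}

#' Generate a synthetic R-R interval series
#'
#' Integrate-and-fire style beat placement: beat k+1 occurs one
#' instantaneous R-R interval after beat k, where the instantaneous interval
#' is \code{mean_rr + lf_amp sin(2 pi lf_freq t) + hf_amp sin(2 pi hf_freq t)}
#' plus Gaussian jitter.  If \code{ectopic_rate > 0}, ectopic-like beats are
#' injected afterwards via \code{\link{inject_ectopics}}.
#'
#' @param spec an \code{\link{rr_gen_spec}}
#' @return an object of class \code{rr_series} with elements
#'   \code{intervals} (ms), \code{beat_times} (s, one more than intervals,
#'   strictly increasing), \code{ectopic} (logical ground-truth flags per
#'   interval) and the generating \code{spec}
#' @export
generate_rr_series <- function(spec) {
  stopifnot(inherits(spec, "rr_gen_spec"))
  with_seed(spec$seed, {
    n_max <- ceiling(spec$duration_s * 1000 / spec$mean_rr * 2) + 8
    jitter <- rnorm(n_max, 0, spec$noise_sd)
    times <- numeric(n_max + 1)
    k <- 1
    repeat {
      t_k <- times[k]
      rr <- spec$mean_rr +
        spec$lf_amp * sin(2 * pi * spec$lf_freq * t_k) +
        spec$hf_amp * sin(2 * pi * spec$hf_freq * t_k) +
        jitter[k]
      rr <- max(rr, 250)            # keep beat times strictly increasing
      t_next <- t_k + rr / 1000
      if (t_next > spec$duration_s || k >= n_max) break
      times[k + 1] <- t_next
      k <- k + 1
    }
    times <- times[seq_len(k)]
    if (length(times) < 5)
      stop("duration too short to contain at least 4 beats", call. = FALSE)
    intervals <- diff(times) * 1000
    ectopic <- rep(FALSE, length(intervals))
    if (spec$ectopic_rate > 0) {
      ej <- inject_ectopics(intervals, spec$ectopic_rate)
      intervals <- ej$intervals
      ectopic <- ej$ectopic
      times <- times[1] + c(0, cumsum(intervals)) / 1000
    }
    structure(list(intervals = intervals, beat_times = times,
                   ectopic = ectopic, spec = spec),
              class = "rr_series")
  })
}

#' Inject ectopic-like beats into an R-R series
#'
#' Selected intervals are shortened to simulate premature beats: interval i
#' becomes \code{rr[i-1] * (1 - u)} with \code{u} drawn uniformly from
#' (0.25, 0.40), so each injected beat deviates from its predecessor by more
#' than the 20\% threshold used by the downstream ectopic filter.  Ground
#' truth flags are returned so filter recall can be measured.
#'
#' @param rr numeric vector of R-R intervals (ms) or an \code{rr_series}
#' @param rate fraction of eligible beats (all but the first) to perturb
#' @param seed optional integer seed
#' @return list with \code{intervals} and logical \code{ectopic} flags
#' @export
inject_ectopics <- function(rr, rate, seed = NULL) {
  if (inherits(rr, "rr_series")) rr <- rr$intervals
  stop_if_not(length(rr) >= 1, "rr must be non-empty")
  stop_if_not(rate >= 0 && rate <= 1, "rate must lie in [0, 1]")
  with_seed(seed, {
    n <- length(rr)
    ectopic <- rep(FALSE, n)
    if (rate > 0 && n >= 2) {
      eligible <- 2:n
      n_pick <- max(if (rate >= 1 / length(eligible)) 1L else 0L,
                    round(rate * length(eligible)))
      n_pick <- min(n_pick, length(eligible))
      picked <- sort(eligible[sample.int(length(eligible), n_pick)])
      u <- runif(n_pick, 0.25, 0.40)
      rr[picked] <- rr[picked - 1] * (1 - u)
      ectopic[picked] <- TRUE
    }
    list(intervals = rr, ectopic = ectopic)
  })
}

#' Render an ECG waveform from an R-R series
#'
#' Places a stylised QRS complex (narrow R wave flanked by small Q and S
#' deflections) at every beat time and adds Gaussian baseline noise.  The
#' waveform is deliberately morphologically minimal -- it exists so that the
#' R-peak detector can be exercised against known beat times -- but the R
#' amplitude is kept at least five times the baseline noise SD.
#'
#' @param rr an \code{rr_series} or numeric vector of intervals (ms)
#' @param fs sampling rate in Hz, at least 250
#' @param noise_sd baseline noise SD relative to unit R amplitude
#' @param seed optional integer seed
#' @return object of class \code{ecg_signal}: \code{signal}, \code{fs},
#'   \code{beat_times} (ground truth, s)
#' @export
generate_ecg <- function(rr, fs = 1000, noise_sd = 0.02, seed = NULL) {
  if (inherits(rr, "rr_series")) {
    beat_times <- rr$beat_times
  } else {
    stop_if_not(length(rr) >= 1, "rr must be non-empty")
    beat_times <- c(0, cumsum(rr) / 1000)
  }
  stop_if_not(fs >= 250, "fs must be at least 250 Hz for QRS morphology")
  stop_if_not(noise_sd <= 0.2, "noise_sd too large: R wave must dominate")
  dur <- max(beat_times) + 0.5
  n <- ceiling(dur * fs)
  tt <- (seq_len(n) - 1) / fs
  # QRS template on a +-60 ms support: R gaussian (sd 10 ms) minus Q/S dips
  tpl_t <- seq(-0.06, 0.06, by = 1 / fs)
  tpl <- exp(-(tpl_t / 0.010)^2) -
    0.15 * exp(-((tpl_t + 0.025) / 0.008)^2) -
    0.20 * exp(-((tpl_t - 0.025) / 0.008)^2)
  with_seed(seed, {
    x <- rnorm(n, 0, noise_sd)
    for (bt in beat_times) {
      i0 <- round((bt + tpl_t[1]) * fs) + 1
      ii <- i0:(i0 + length(tpl) - 1)
      ok <- ii >= 1 & ii <= n
      x[ii[ok]] <- x[ii[ok]] + tpl[ok]
    }
    structure(list(signal = x, fs = fs, beat_times = beat_times),
              class = "ecg_signal")
  })
}
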