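#' Specification for a synthetic multichannel EEG recording
#'
#' Channels are linear mixtures of band-limited common sources plus
#' independent channel noise.  Because magnitude-squared coherence between
#' two channels sharing one source with mixing weights \eqn{a, b} and
#' independent noise is analytically
#' \deqn{C = (a b \sigma_s^2)^2 / ((a^2 \sigma_s^2 + \sigma_n^2)
#'           (b^2 \sigma_s^2 + \sigma_n^2))}
#' within the source band, the generator provides closed-form targets for
#' validating the coherence estimator.
#'
#' @param n_channels number of channels (>= 2); when 19, channels carry the
#'   10-20 montage labels
#' @param fs sampling rate in Hz; must exceed twice the highest band edge
#' @param duration_s recording length in seconds
#' @param band_sources list of sources, each a list with elements
#'   \code{low}, \code{high} (band edges, Hz) and \code{weights} (numeric,
#'   one mixing weight per channel); defaults to one moderate-coherence
#'   source per canonical band (see \code{\link{eeg_bands}})
#' @param channel_noise_sd SD of the independent per-channel noise
#' @param seed integer seed
#' @return object of class \code{eeg_gen_spec}
#' @export
eeg_gen_spec <- function(n_channels = 19, fs = 1000, duration_s = 300,
                         band_sources = NULL, channel_noise_sd = 1,
                         seed = NULL) {
  stop_if_not(n_channels >= 2, "n_channels must be at least 2")
  stop_if_not(duration_s > 0, "duration must be positive")
  if (is.null(band_sources))
    band_sources <- default_band_sources(n_channels)
  for (src in band_sources) {
    stop_if_not(is.numeric(src$low) && is.numeric(src$high) &&
                  src$low > 0 && src$high > src$low,
                "each source needs band edges 0 < low < high")
    stop_if_not(fs > 2 * src$high, "fs must exceed twice the top band edge")
    stop_if_not(length(src$weights) == n_channels &&
                  all(is.finite(src$weights)),
                "each source needs one finite weight per channel")
  }
  stop_if_not(channel_noise_sd >= 0, "channel_noise_sd must be >= 0")
  structure(list(n_channels = n_channels, fs = fs, duration_s = duration_s,
                 band_sources = band_sources,
                 channel_noise_sd = channel_noise_sd, seed = seed),
            class = "eeg_gen_spec")
}

#' Default band-limited sources for the synthetic EEG generator
#'
#' One common source per canonical band with smoothly varying positive
#' mixing weights (anterior-posterior gradient), scaled so that typical
#' pairwise coherence is moderate rather than saturated.
#'
#' @param n_channels number of channels
#' @param scale multiplies all mixing weights (coupling strength dial)
#' @return list of sources as expected by \code{\link{eeg_gen_spec}}
#' @export
default_band_sources <- function(n_channels = 19, scale = 1) {
  bands <- eeg_bands()
  grad <- seq(0.8, 1.2, length.out = n_channels)
  lapply(seq_len(nrow(bands)), function(i) {
    list(low = bands$low[i], high = bands$high[i],
         weights = scale * grad * 0.8,
         band = bands$band[i])
  })
}

#' Generate a synthetic multichannel EEG recording
#'
#' Each source is white Gaussian noise band-passed to its band (4th-order
#' Butterworth, forward-backward filtered so the passband variance target is
#' phase-neutral), normalised to unit variance, then mixed into the channels
#' with the spec's weights; independent Gaussian channel noise is added.
#'
#' @param spec an \code{\link{eeg_gen_spec}}
#' @return object of class \code{eeg_recording}: \code{data} (samples x
#'   channels matrix with channel names), \code{fs}, \code{duration_s}
#' @export
generate_eeg <- function(spec) {
  stopifnot(inherits(spec, "eeg_gen_spec"))
  n <- round(spec$duration_s * spec$fs)
  stop_if_not(n >= 16, "recording too short")
  with_seed(spec$seed, {
    x <- matrix(rnorm(n * spec$n_channels, 0, spec$channel_noise_sd),
                n, spec$n_channels)
    for (src in spec$band_sources) {
      s <- band_limited_noise(n, spec$fs, src$low, src$high)
      x <- x + outer(s, src$weights)
    }
    labels <- if (spec$n_channels == 19) eeg_montage_1020
              else paste0("CH", seq_len(spec$n_channels))
    colnames(x) <- labels
    structure(list(data = x, fs = spec$fs, duration_s = spec$duration_s),
              class = "eeg_recording")
  })
}

# unit-variance Gaussian noise band-passed to [low, high] Hz
band_limited_noise <- function(n, fs, low, high) {
  w <- rnorm(n + 2 * fs)                       # pad to absorb filter edges
  bf <- signal::butter(4, c(low, high) / (fs / 2), type = "pass")
  s <- signal::filtfilt(bf, w)
  s <- s[(fs + 1):(fs + n)]
  s / sd(s)
}

#' Construct an EEG recording object from a numeric matrix
#'
#' @param data samples x channels matrix; column names are channel labels
#'   (modern temporal labels T7/T8/P7/P8 are normalised to T3/T4/T5/T6)
#' @param fs sampling rate in Hz
#' @return object of class \code{eeg_recording}
#' @export
as_eeg_recording <- function(data, fs) {
  stop_if_not(is.matrix(data) && is.numeric(data), "data must be numeric matrix")
  stop_if_not(fs > 80, "fs must exceed 80 Hz (twice the top gamma edge)")
  if (!is.null(colnames(data))) {
    map <- c(T7 = "T3", T8 = "T4", P7 = "T5", P8 = "T6")
    lab <- toupper(colnames(data))
    hit <- lab %in% names(map)
    lab[hit] <- map[lab[hit]]
    colnames(data) <- lab
  }
  structure(list(data = data, fs = fs, duration_s = nrow(data) / fs),
            class = "eeg_recording")
}
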