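#' Canonical EEG frequency bands
#'
#' Band intervals are half-open \code{[low, high)} except gamma, which is
#' closed at 40 Hz, so shared edges (4, 8, 12, 25, 30 Hz) are never counted
#' twice.
#'
#' @return data.frame with columns \code{band}, \code{low}, \code{high} (Hz)
#' @export
eeg_bands <- function() {
  data.frame(band = c("delta", "theta", "alpha", "beta", "high_beta",
                      "gamma"),
             low = c(1, 4, 8, 12, 25, 30),
             high = c(4, 8, 12, 25, 30, 40))
}

#' Mask artifact-contaminated windows by amplitude threshold
#'
#' Splits the recording into consecutive \code{window_s} blocks and marks a
#' block bad when any channel exceeds \code{amp_threshold} in absolute
#' value; spectral estimation later skips windows overlapping a bad block.
#' A stand-in for interactive/visual artifact editing.
#'
#' @param rec an \code{eeg_recording}
#' @param amp_threshold absolute amplitude threshold (> 0)
#' @param window_s rejection block length in seconds
#' @return the recording with a logical per-sample \code{artifact_mask}
#'   element (TRUE = contaminated)
#' @export
reject_artifacts <- function(rec, amp_threshold, window_s = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  stop_if_not(amp_threshold > 0, "amp_threshold must be positive")
  n <- nrow(rec$data)
  blk <- floor(((seq_len(n)) - 1) / (window_s * rec$fs))
  over <- rowSums(abs(rec$data) > amp_threshold) > 0
  bad_blk <- unique(blk[over])
  mask <- blk %in% bad_blk
  wlen <- round(window_s * rec$fs)
  clean_windows <- sum(!mask) %/% wlen
  if (clean_windows < 8)
    stop("insufficient clean data: fewer than 8 artifact-free windows",
         call. = FALSE)
  rec$artifact_mask <- mask
  rec
}

#' Sliding-window Fourier coefficients of a multichannel recording
#'
#' Hann-tapered, mean-removed sliding windows; per window and channel the
#' discrete-Fourier cosine/sine coefficients are evaluated on the grid
#' \code{1/window_s, 2/window_s, ...} up to \code{max_freq}.  Windows
#' overlapping an artifact mask (see \code{\link{reject_artifacts}}) are
#' dropped.  These per-window coefficients are the raw material of the
#' coherence estimator.
#'
#' @param rec an \code{eeg_recording}
#' @param window_s window length in seconds (>= 2 so 1 Hz is resolvable)
#' @param overlap fractional window overlap in [0, 0.95]
#' @param taper window taper; \code{"hann"} or \code{"rect"}
#' @param max_freq highest frequency retained (Hz)
#' @return object of class \code{spectral_coefficients}: complex array
#'   \code{coefs} (frequency x window x channel; real part = cosine, minus
#'   imaginary part = sine coefficient), \code{freqs}, \code{n_windows},
#'   \code{channels}, \code{fs}
#' @export
windowed_spectra <- function(rec, window_s = 2, overlap = 0.75,
                             taper = c("hann", "rect"), max_freq = 45) {
  stopifnot(inherits(rec, "eeg_recording"))
  taper <- match.arg(taper)
  stop_if_not(window_s >= 2, "window_s must be at least 2 s")
  stop_if_not(overlap >= 0 && overlap <= 0.95, "overlap must be in [0, 0.95]")
  fs <- rec$fs
  x <- rec$data
  n <- nrow(x); nch <- ncol(x)
  wlen <- round(window_s * fs)
  stop_if_not(n >= wlen, "record shorter than one window")
  step <- max(1L, round(wlen * (1 - overlap)))
  starts <- seq(1L, n - wlen + 1L, by = step)
  if (!is.null(rec$artifact_mask)) {
    ok <- vapply(starts, function(s) !any(rec$artifact_mask[s:(s + wlen - 1)]),
                 logical(1))
    starts <- starts[ok]
  }
  nw <- length(starts)
  stop_if_not(nw >= 8, "need at least 8 analysis windows")
  freqs <- seq_len(floor(max_freq * window_s)) / window_s
  freqs <- freqs[freqs <= fs / 2]
  nb <- length(freqs)
  win <- if (taper == "hann")
    0.5 - 0.5 * cos(2 * pi * (0:(wlen - 1)) / (wlen - 1)) else rep(1, wlen)
  idx <- as.vector(outer(0:(wlen - 1), starts, "+"))
  segs <- matrix(x[rep(idx, nch) + rep((seq_len(nch) - 1L) * n,
                                       each = wlen * nw)], wlen)
  segs <- (segs - rep(colMeans(segs), each = wlen)) * win
  E <- exp(-2i * pi * outer(freqs / fs, 0:(wlen - 1)))
  coefs <- array(E %*% segs, c(nb, nw, nch))
  channels <- colnames(x)
  if (is.null(channels)) channels <- paste0("CH", seq_len(nch))
  dimnames(coefs) <- list(NULL, NULL, channels)
  structure(list(coefs = coefs, freqs = freqs, n_windows = nw,
                 channels = channels, fs = fs, window_s = window_s),
            class = "spectral_coefficients")
}

#' Magnitude-squared coherence for one channel pair at one frequency
#'
#' With per-window cosine/sine coefficients \eqn{(a_x, b_x)} for channel x
#' and \eqn{(u_y, v_y)} for channel y at frequency f, coherence is
#' \deqn{\frac{(\sum_N a_x u_y + b_x v_y)^2 + (\sum_N a_x v_y - b_x u_y)^2}
#'            {\sum_N (a_x^2 + b_x^2) \; \sum_N (u_y^2 + v_y^2)}}
#' i.e. the squared modulus of the window-summed cross-spectrum over the
#' product of summed auto-spectra.  It is symmetric in the pair, equals 1
#' for identical channels, and is invariant to per-channel rescaling.
#'
#' @param spec a \code{spectral_coefficients} object
#' @param x,y channel names or indices
#' @param f frequency in Hz; must lie on the analysis grid
#' @return coherence value in [0, 1]; zero power in either channel yields 0
#'   with a warning
#' @export
coherence <- function(spec, x, y, f) {
  stopifnot(inherits(spec, "spectral_coefficients"))
  bi <- which(abs(spec$freqs - f) < 1e-9)
  stop_if_not(length(bi) == 1, "f is not on the frequency grid")
  X <- spec$coefs[bi, , x]
  Y <- spec$coefs[bi, , y]
  ax <- Re(X); bx <- -Im(X)
  uy <- Re(Y); vy <- -Im(Y)
  denom <- sum(ax^2 + bx^2) * sum(uy^2 + vy^2)
  if (denom <= 0) {
    warning("zero power at f in one channel; coherence set to 0")
    return(0)
  }
  (sum(ax * uy + bx * vy)^2 + sum(ax * vy - bx * uy)^2) / denom
}

#' Band-averaged coherence adjacency matrices
#'
#' Computes the magnitude-squared coherence of every channel pair at every
#' grid frequency (single pass over the cross-spectral matrix, so matrices
#' are exactly symmetric), then averages the per-bin coherence across the
#' bins of each band.  Diagonals are stored as 1 (self-coherence); graph
#' routines zero them before use.
#'
#' @param spec a \code{spectral_coefficients} object
#' @param bands data.frame with \code{band}, \code{low}, \code{high}
#'   columns; intervals are \code{[low, high)} except the last band, which
#'   is closed at its upper edge
#' @return object of class \code{coherence_set}: named list of symmetric
#'   channel x channel matrices, with the band table as attribute
#'   \code{"bands"}
#' @export
band_adjacency <- function(spec, bands = eeg_bands()) {
  stopifnot(inherits(spec, "spectral_coefficients"))
  nb <- length(spec$freqs)
  nch <- length(spec$channels)
  coh <- array(0, c(nch, nch, nb))
  for (b in seq_len(nb)) {
    A <- t(spec$coefs[b, , ])                 # channels x windows
    S <- A %*% Conj(t(A))
    p <- Re(diag(S))
    denom <- outer(p, p)
    cb <- Mod(S)^2 / denom
    cb[denom <= 0] <- 0
    coh[, , b] <- cb
  }
  out <- vector("list", nrow(bands))
  names(out) <- bands$band
  for (i in seq_len(nrow(bands))) {
    closed <- i == nrow(bands)
    sel <- spec$freqs >= bands$low[i] &
      (if (closed) spec$freqs <= bands$high[i]
       else spec$freqs < bands$high[i])
    if (!any(sel))
      stop("band '", bands$band[i], "' contains no frequency bins",
           call. = FALSE)
    m <- apply(coh[, , sel, drop = FALSE], c(1, 2), mean)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]   # exact symmetry by construction
    diag(m) <- 1
    dimnames(m) <- list(spec$channels, spec$channels)
    out[[i]] <- m
  }
  structure(out, bands = bands, n_windows = spec$n_windows,
            class = "coherence_set")
}
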