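#' Spectrogram configuration
#'
#' Defaults follow the analysis recipe of the original study: a 512-point FFT
#' over 256-sample Hamming-tapered frames with 95% overlap, mapped to a fixed
#' 256 x 112 (frequency x time) image per channel. The stated STFT parameters
#' do not arithmetically produce 112 frames on a 2000-sample window (they give
#' 135), so the raw short-time transform honors the parameters and
#' [conform_shape()] then maps every raw magnitude array onto the fixed image
#' grid: the redundant one-sided bin is dropped on the frequency axis and the
#' time axis is resampled by linear interpolation.
#'
#' @param n_fft FFT length.
#' @param stft_window_len Taper length in samples (<= `n_fft`).
#' @param overlap_fraction Fractional overlap of consecutive frames in `[0, 1)`;
#'   the hop is `max(1, round(stft_window_len * (1 - overlap_fraction)))`.
#' @param window_shape Taper: `"hamming"`, `"hann"` or `"rect"`.
#' @param target_freq_bins,target_time_bins Output image dimensions.
#' @param log_magnitude Convert magnitudes to dB before imaging.
#' @param db_floor Lower clamp for log magnitudes (dB); keeps values finite
#'   for silent inputs.
#' @return Object of class `spectrogram_config`.
#' @export
spectrogram_config <- function(n_fft = 512L, stft_window_len = 256L,
                               overlap_fraction = 0.95,
                               window_shape = c("hamming", "hann", "rect"),
                               target_freq_bins = 256L, target_time_bins = 112L,
                               log_magnitude = TRUE, db_floor = -120) {
  window_shape <- match.arg(window_shape)
  if (stft_window_len > n_fft) stopf("'stft_window_len' must not exceed 'n_fft'")
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    stopf("'overlap_fraction' must lie in [0, 1)")
  }
  if (target_freq_bins < 1 || target_time_bins < 1) {
    stopf("target image dimensions must be positive")
  }
  structure(list(n_fft = as.integer(n_fft),
                 stft_window_len = as.integer(stft_window_len),
                 overlap_fraction = overlap_fraction,
                 window_shape = window_shape,
                 target_freq_bins = as.integer(target_freq_bins),
                 target_time_bins = as.integer(target_time_bins),
                 log_magnitude = isTRUE(log_magnitude),
                 db_floor = db_floor),
            class = "spectrogram_config")
}

#' Reduced spectrogram preset for learning experiments
#'
#' A 16-point FFT over 16-sample Hamming frames with 50% overlap, conformed to
#' an 8 x 8 image: 8 frequency bins of 12.5 Hz covering 0-87.5 Hz at the
#' 200 Hz rate. Amplitude-modulation structure of gesture bursts survives this
#' resolution while shrinking classifier cost by four orders of magnitude
#' relative to the full-size image; used by the end-to-end training
#' experiments and the channel-selection surrogate.
#' @return `spectrogram_config` object.
#' @export
reduced_spectrogram_config <- function() {
  spectrogram_config(n_fft = 16L, stft_window_len = 16L, overlap_fraction = 0.5,
                     target_freq_bins = 8L, target_time_bins = 8L)
}

stft_hop <- function(cfg) max(1L, as.integer(round(cfg$stft_window_len * (1 - cfg$overlap_fraction))))

stft_taper <- function(cfg) {
  L <- cfg$stft_window_len
  switch(cfg$window_shape,
         hamming = as.numeric(signal::hamming(L)),
         hann = as.numeric(signal::hanning(L)),
         rect = rep(1, L))
}

#' One-sided STFT magnitude of a single channel
#'
#' Frames of `stft_window_len` samples are tapered, zero-padded to `n_fft` and
#' transformed; the one-sided magnitude spectrum (`n_fft/2 + 1` bins) is
#' returned. The number of frames is `floor((len - L) / hop) + 1`.
#'
#' @param x Numeric sample vector (length >= `stft_window_len`).
#' @param cfg `spectrogram_config` object.
#' @return Magnitude matrix `[n_fft/2 + 1, n_frames]`.
#' @export
stft_magnitude <- function(x, cfg = spectrogram_config()) {
  L <- cfg$stft_window_len
  if (length(x) < L) {
    stopf("signal of length %d is shorter than the %d-sample taper", length(x), L)
  }
  hop <- stft_hop(cfg)
  starts <- seq(1L, length(x) - L + 1L, by = hop)
  idx <- outer(0:(L - 1L), starts, `+`)
  frames <- matrix(x[idx], nrow = L) * stft_taper(cfg)
  if (cfg$n_fft > L) {
    frames <- rbind(frames, matrix(0, nrow = cfg$n_fft - L, ncol = ncol(frames)))
  }
  sp <- stats::mvfft(frames)
  Mod(sp[seq_len(cfg$n_fft %/% 2 + 1L), , drop = FALSE])
}

#' Convert magnitudes to clamped decibels
#' @param mag Non-negative magnitude array.
#' @param db_floor Lower clamp in dB.
#' @return dB array, finite everywhere.
#' @export
magnitude_to_db <- function(mag, db_floor = -120) {
  pmax(20 * log10(pmax(mag, 10^(db_floor / 20))), db_floor)
}

#' Conform a raw magnitude array to the configured image shape
#'
#' The frequency axis is truncated to `target_freq_bins` (dropping the
#' redundant Nyquist bin of a one-sided spectrum); the time axis is resampled
#' to `target_time_bins` by linear interpolation between frame centers, which
#' preserves constant arrays exactly and is the identity when the raw frame
#' count already matches.
#'
#' @param raw Magnitude array `[freq_bins x n_frames]`.
#' @param cfg `spectrogram_config` object.
#' @return Array `[target_freq_bins x target_time_bins]`.
#' @export
conform_shape <- function(raw, cfg = spectrogram_config()) {
  if (!is.matrix(raw) || nrow(raw) == 0L || ncol(raw) == 0L) {
    stopf("'raw' must be a non-empty magnitude matrix")
  }
  fb <- cfg$target_freq_bins
  if (nrow(raw) < fb) {
    stopf("raw spectrum has %d frequency bins, fewer than the %d required",
          nrow(raw), fb)
  }
  raw <- raw[seq_len(fb), , drop = FALSE]
  tb <- cfg$target_time_bins
  nc <- ncol(raw)
  if (nc == tb) return(raw)
  if (nc == 1L) return(raw[, rep(1L, tb), drop = FALSE])
  xout <- seq(1, nc, length.out = tb)
  lo <- pmin(floor(xout), nc - 1L)
  wt <- xout - lo
  raw[, lo, drop = FALSE] * rep(1 - wt, each = fb) +
    raw[, lo + 1L, drop = FALSE] * rep(wt, each = fb)
}

#' Featurize labeled windows into stacked spectrogram images
#'
#' Every window's selected channels (sEMG and/or IMU; both pass through the
#' identical short-time transform) are converted to conformed magnitude images
#' and stacked along the third axis in the order given, yielding one
#' `target_freq_bins x target_time_bins x n_channels` tensor per window.
#' Values are log-scaled to dB when the configuration asks for it; per-channel
#' standardization is deliberately left to the evaluation layer so that its
#' statistics can be fitted on training folds only.
#'
#' @param ws `window_set` for a single recording.
#' @param recording The `sensor_recording` the windows were cut from.
#' @param channels Character vector of channel names (see [channel_names()]).
#' @param cfg `spectrogram_config` object.
#' @return Object of class `spectrogram_set` with fields `values` (array
#'   `[F, T, C, n_windows]`), `channels`, `windows`, `labels`, `config`.
#'   `length()` gives the window count and `[[i]]` extracts one tensor.
#' @export
featurize <- function(ws, recording, channels, cfg = spectrogram_config()) {
  stopifnot(inherits(ws, "window_set"), inherits(recording, "sensor_recording"))
  if (length(channels) == 0L) stopf("channel subset must be non-empty")
  if (anyDuplicated(channels)) stopf("duplicate channels in subset")
  known <- channel_names(ncol(recording$semg))
  bad <- setdiff(channels, known)
  if (length(bad)) stopf("unknown channel name(s): %s", paste(bad, collapse = ", "))

  n_win <- nrow(ws)
  Fb <- cfg$target_freq_bins; Tb <- cfg$target_time_bins
  out <- array(0, dim = c(Fb, Tb, length(channels), n_win))
  chunk <- max(1L, 512L %/% max(1L, length(channels)))
  for (ci in seq_along(channels)) {
    x <- recording_channel(recording, channels[ci])
    for (i0 in seq(1L, n_win, by = chunk)) {
      ii <- i0:min(n_win, i0 + chunk - 1L)
      mags <- stft_magnitude_multi(x, ws$start_sample[ii], ws$end_sample[ii], cfg)
      for (k in seq_along(ii)) {
        m <- mags[[k]]
        if (cfg$log_magnitude) m <- magnitude_to_db(m, cfg$db_floor)
        out[, , ci, ii[k]] <- conform_shape(m, cfg)
      }
    }
  }
  structure(list(values = out, channels = channels,
                 windows = as.data.frame(ws), labels = ws$label, config = cfg),
            class = "spectrogram_set")
}

# batched STFT over several equal-length windows of one channel: one mvfft
# call per chunk instead of one per window
stft_magnitude_multi <- function(x, start_sample, end_sample, cfg) {
  L <- cfg$stft_window_len
  wlen <- end_sample[1] - start_sample[1] + 1L
  if (wlen < L) stopf("window of %d samples is shorter than the %d-sample taper", wlen, L)
  hop <- stft_hop(cfg)
  fstarts <- seq(1L, wlen - L + 1L, by = hop)
  nf <- length(fstarts)
  # absolute start of every frame of every window
  abs_start <- rep(start_sample, each = nf) + rep(fstarts - 1L, times = length(start_sample))
  idx <- outer(0:(L - 1L), abs_start, `+`)
  frames <- matrix(x[idx], nrow = L) * stft_taper(cfg)
  if (cfg$n_fft > L) {
    frames <- rbind(frames, matrix(0, nrow = cfg$n_fft - L, ncol = ncol(frames)))
  }
  sp <- Mod(stats::mvfft(frames))[seq_len(cfg$n_fft %/% 2 + 1L), , drop = FALSE]
  lapply(seq_along(start_sample), function(k) {
    sp[, ((k - 1L) * nf + 1L):(k * nf), drop = FALSE]
  })
}

#' @export
length.spectrogram_set <- function(x) dim(x$values)[4]

#' @export
`[[.spectrogram_set` <- function(x, i) {
  if (is.character(i)) return(.subset2(x, i))
  v <- x$values[, , , i, drop = FALSE]
  dim(v) <- dim(x$values)[1:3]
  attr(v, "channel_names") <- x$channels
  attr(v, "window_ref") <- list(subject_id = x$windows$subject_id[i],
                                start_s = x$windows$start_s[i])
  v
}

#' @export
print.spectrogram_set <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<spectrogram_set> %d windows of %d x %d x %d (freq x time x channels)\n",
              d[4], d[1], d[2], d[3]))
  invisible(x)
}

#' Fit / apply per-channel standardization
#'
#' Computes mean and standard deviation per channel over all windows, bins and
#' frames of a (training) spectrogram set; applying the standardizer centers
#' and scales each channel. In cross-validated evaluation the fit must only
#' ever see training folds.
#'
#' @param spec `spectrogram_set` object.
#' @return `fit_standardizer()`: object of class `channel_standardizer` with
#'   per-channel `mean` and `sd`.
#' @export
fit_standardizer <- function(spec) {
  stopifnot(inherits(spec, "spectrogram_set"))
  v <- spec$values
  d <- dim(v)
  m <- apply(v, 3, mean)
  s <- apply(v, 3, stats::sd)
  s[s < 1e-8] <- 1
  structure(list(mean = stats::setNames(m, spec$channels),
                 sd = stats::setNames(s, spec$channels)),
            class = "channel_standardizer")
}

#' @rdname fit_standardizer
#' @param st `channel_standardizer` from `fit_standardizer()`.
#' @return `apply_standardizer()`: the spectrogram set with standardized values.
#' @export
apply_standardizer <- function(spec, st) {
  stopifnot(inherits(spec, "spectrogram_set"), inherits(st, "channel_standardizer"))
  i <- match(spec$channels, names(st$mean))
  if (anyNA(i)) stopf("standardizer lacks statistics for some channels")
  d <- dim(spec$values)
  v <- spec$values
  for (c in seq_len(d[3])) {
    v[, , c, ] <- (v[, , c, ] - st$mean[i[c]]) / st$sd[i[c]]
  }
  spec$values <- v
  spec
}
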