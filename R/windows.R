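#' Sliding-window configuration
#'
#' @param window_length_s Window length in seconds (default 10).
#' @param slide_s Slide (hop) between consecutive window starts in seconds
#'   (default 5); must not exceed the window length.
#' @param min_overlap_fraction Fraction of a window that must lie inside
#'   smoking-class activity for the window to be labeled smoking (default 0.5).
#'   Values approaching 0 recover an "any overlap" labeling rule.
#' @return Object of class `windowing_config`.
#' @export
windowing_config <- function(window_length_s = 10, slide_s = 5,
                             min_overlap_fraction = 0.5) {
  check_positive_scalar(window_length_s, "window_length_s")
  check_positive_scalar(slide_s, "slide_s")
  if (slide_s > window_length_s) stopf("'slide_s' must not exceed 'window_length_s'")
  if (!is.numeric(min_overlap_fraction) || min_overlap_fraction <= 0 ||
      min_overlap_fraction > 1) {
    stopf("'min_overlap_fraction' must lie in (0, 1]")
  }
  structure(list(window_length_s = window_length_s, slide_s = slide_s,
                 min_overlap_fraction = min_overlap_fraction),
            class = "windowing_config")
}

#' Segment a recording into overlapping fixed-length windows
#'
#' Window starts form the arithmetic sequence 0, S, 2S, ...; the number of
#' windows is `floor((T - W) / S) + 1` for recording duration T, window length
#' W and slide S. Trailing samples that do not fill a complete window are
#' dropped, and windows never straddle recording boundaries.
#'
#' @param recording `sensor_recording` object.
#' @param cfg `windowing_config` object.
#' @return Object of class `window_set`: a data frame with one row per window
#'   (`subject_id`, `start_s`, `end_s`, `start_sample`, `end_sample`,
#'   `label` all `NA` until [label_windows()] is applied), with the
#'   configuration and sampling rate attached as attributes.
#' @export
segment <- function(recording, cfg = windowing_config()) {
  stopifnot(inherits(recording, "sensor_recording"),
            inherits(cfg, "windowing_config"))
  fs <- recording$sample_rate_hz
  T_s <- recording_duration(recording)
  W <- cfg$window_length_s; S <- cfg$slide_s
  if (T_s < W) {
    stopf("recording of %.2f s is shorter than one %.2f s window", T_s, W)
  }
  n_win <- floor((T_s - W) / S + 1e-9) + 1
  starts <- (seq_len(n_win) - 1) * S
  wlen <- round(W * fs)
  ws <- data.frame(subject_id = recording$subject_id,
                   start_s = starts, end_s = starts + W,
                   start_sample = round(starts * fs) + 1L,
                   label = NA_integer_,
                   stringsAsFactors = FALSE)
  ws$end_sample <- ws$start_sample + wlen - 1L
  structure(ws, class = c("window_set", "data.frame"),
            windowing = cfg, sample_rate_hz = fs, samples_per_window = wlen)
}

# total overlap of [s, e) with the union of the intervals in (starts, ends);
# the union is formed first, so overlapping events are not double counted
interval_overlap <- function(s, e, starts, ends) {
  if (length(starts) == 0L) return(numeric(length(s)))
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  m_start <- starts[1]; m_end <- ends[1]
  us <- numeric(0); ue <- numeric(0)
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= m_end) m_end <- max(m_end, ends[i]) else {
      us <- c(us, m_start); ue <- c(ue, m_end)
      m_start <- starts[i]; m_end <- ends[i]
    }
  }
  us <- c(us, m_start); ue <- c(ue, m_end)
  out <- numeric(length(s))
  for (i in seq_along(us)) {
    out <- out + pmax(0, pmin(e, ue[i]) - pmax(s, us[i]))
  }
  out
}

#' Label windows as smoking / non-smoking from an activity log
#'
#' A window is labeled smoking (1) when the fraction of the window inside the
#' union of smoking-class events is at least `min_overlap_fraction`; all four
#' smoking activity classes count as smoking. Windows outside every logged
#' event are non-smoking (0). The rule is monotone: growing a smoking event
#' never flips a window from 1 to 0.
#'
#' @param ws `window_set` from [segment()].
#' @param log `activity_log` object.
#' @param cfg `windowing_config`; defaults to the configuration stored in `ws`.
#' @return The `window_set` with its `label` column filled in.
#' @export
label_windows <- function(ws, log, cfg = attr(ws, "windowing")) {
  stopifnot(inherits(ws, "window_set"))
  sm <- log[log$activity %in% smoking_classes(), , drop = FALSE]
  ov <- interval_overlap(ws$start_s, ws$end_s, sm$start_s, sm$end_s)
  frac <- ov / cfg$window_length_s
  ws$label <- as.integer(frac >= cfg$min_overlap_fraction - 1e-12)
  ws
}

#' Combine window sets from several recordings
#' @param ... `window_set` objects sharing a configuration.
#' @return A single `window_set`.
#' @export
bind_windows <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) && !inherits(parts[[1]], "window_set")) {
    parts <- parts[[1]]
  }
  out <- do.call(rbind, lapply(parts, as.data.frame))
  structure(out, class = c("window_set", "data.frame"),
            windowing = attr(parts[[1]], "windowing"),
            sample_rate_hz = attr(parts[[1]], "sample_rate_hz"),
            samples_per_window = attr(parts[[1]], "samples_per_window"))
}
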