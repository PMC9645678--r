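#' Activity classes of the scripted study protocol
#'
#' The protocol consists of ten ordered activities of daily living performed
#' while wearing a forearm band: reading aloud, slow and fast treadmill
#' walking, resting, smoking while sitting, talking on the phone, eating,
#' smoking while walking and talking, smoking while talking and sitting, and
#' smoking while walking. Four of the ten are smoking activities.
#'
#' @return Character vector of the ten activity class names, in protocol order.
#' @export
activity_classes <- function() {
  c("reading", "walking_slow", "walking_fast", "resting", "smoking_sitting",
    "phone_talking", "eating", "smoking_walking_talking",
    "smoking_talking_sitting", "smoking_walking")
}

#' @rdname activity_classes
#' @return `smoking_classes()`: the subset of activity classes counted as smoking.
#' @export
smoking_classes <- function() {
  c("smoking_sitting", "smoking_walking_talking", "smoking_talking_sitting",
    "smoking_walking")
}

walking_classes <- function() {
  c("walking_slow", "walking_fast", "smoking_walking_talking", "smoking_walking")
}

# activities whose sEMG/IMU signature is a periodic hand-to-mouth gesture
gesture_classes <- function() c(smoking_classes(), "eating")

#' Channel names of a sensor recording
#'
#' Eight sEMG channels followed by three accelerometer and three gyroscope axes.
#' @param n_semg Number of sEMG channels.
#' @return Character vector of channel identifiers.
#' @export
channel_names <- function(n_semg = 8L) {
  c(paste0("semg", seq_len(n_semg)),
    "accel_x", "accel_y", "accel_z", "gyro_x", "gyro_y", "gyro_z")
}

#' @rdname channel_names
#' @export
semg_channels <- function(n_semg = 8L) paste0("semg", seq_len(n_semg))

#' @rdname channel_names
#' @export
imu_channels <- function() c("accel_x", "accel_y", "accel_z",
                             "gyro_x", "gyro_y", "gyro_z")

#' Default per-activity sEMG channel activation profile
#'
#' Rows are the ten activity classes, columns the eight sEMG channels; entries
#' in \[0, 1\] weight how strongly each channel is recruited during that
#' activity. Smoking gestures recruit mainly channels 4-6 (wrist flexors) with
#' secondary activity on 1 and 7; eating recruits a deliberately different
#' group (2, 3, 8) so that the two hand-to-mouth confounders are separable by
#' sEMG but not by gross kinematics.
#'
#' @param n_semg Number of sEMG channels (profile defined for 8).
#' @return Numeric matrix `[10 x n_semg]` with activity-class row names.
#' @export
default_activation_profile <- function(n_semg = 8L) {
  stopifnot(n_semg == 8L)
  acts <- activity_classes()
  w <- matrix(0, nrow = length(acts), ncol = n_semg,
              dimnames = list(acts, semg_channels(n_semg)))
  smoke <- c(0.55, 0.10, 0.10, 0.85, 0.90, 0.95, 0.60, 0.10)
  for (a in smoking_classes()) w[a, ] <- smoke
  w["eating", ]        <- c(0.15, 0.80, 0.70, 0.35, 0.10, 0.10, 0.15, 0.75)
  w["reading", ]       <- c(0.15, 0.10, 0.00, 0.00, 0.00, 0.00, 0.10, 0.00)
  w["phone_talking", ] <- c(0.00, 0.25, 0.00, 0.10, 0.00, 0.00, 0.25, 0.10)
  w["walking_slow", ]  <- rep(0.05, n_semg)
  w["walking_fast", ]  <- rep(0.08, n_semg)
  w["resting", ]       <- rep(0.00, n_semg)
  w
}

#' Parameters of the synthetic sEMG+IMU generator
#'
#' Houses the emulated hardware constants of the armband (200 Hz sampling,
#' 8-bit sEMG quantization, 8 sEMG channels) together with the effect-size
#' parameters of the gesture model. sEMG is modeled as 20-95 Hz band-passed
#' Gaussian noise whose amplitude is multiplied by `semg_burst_gain` times the
#' activity's channel activation weight during gesture episodes; the IMU sees
#' the gravity vector rotated through a smooth forearm-pitch trajectory during
#' hand-to-mouth gestures plus gait oscillation during walking.
#'
#' @param sample_rate_hz Sampling rate shared by all channels (Hz).
#' @param semg_resolution_bits Integer bit depth of the sEMG quantizer.
#' @param n_semg_channels Number of sEMG channels.
#' @param puff_duration_s Range (lo, hi) of single puff gesture durations (s).
#' @param inter_puff_interval_s Range of gaps between consecutive puffs (s).
#' @param bite_duration_s Range of eating bite gesture durations (s).
#' @param inter_bite_interval_s Range of gaps between bites (s).
#' @param semg_burst_gain Multiplicative sEMG amplitude increase of a fully
#'   activated channel during a gesture, relative to baseline.
#' @param channel_activation_profile Activity-by-channel weight matrix in
#'   \[0, 1\]; see [default_activation_profile()].
#' @param imu_gesture_amplitude Scale of the hand-to-mouth forearm rotation
#'   (1 = a 1.2 rad peak pitch excursion and the implied gyro/accel deflection).
#' @param baseline_noise_sd Resting sEMG noise standard deviation, in
#'   quantizer counts.
#' @param subject_variability Log-normal jitter SD applied per subject to
#'   activation weights and gesture amplitudes.
#' @param seed Integer master seed.
#' @return Object of class `generator_params`.
#' @export
generator_params <- function(sample_rate_hz = 200,
                             semg_resolution_bits = 8L,
                             n_semg_channels = 8L,
                             puff_duration_s = c(2, 4),
                             inter_puff_interval_s = c(20, 40),
                             bite_duration_s = c(1.5, 3),
                             inter_bite_interval_s = c(8, 15),
                             semg_burst_gain = 6,
                             channel_activation_profile = default_activation_profile(n_semg_channels),
                             imu_gesture_amplitude = 1,
                             baseline_noise_sd = 3,
                             subject_variability = 0.15,
                             seed = 1L) {
  check_positive_scalar(sample_rate_hz, "sample_rate_hz")
  check_positive_scalar(semg_burst_gain, "semg_burst_gain")
  check_positive_scalar(imu_gesture_amplitude, "imu_gesture_amplitude")
  check_positive_scalar(baseline_noise_sd, "baseline_noise_sd")
  check_positive_range(puff_duration_s, "puff_duration_s")
  check_positive_range(inter_puff_interval_s, "inter_puff_interval_s")
  check_positive_range(bite_duration_s, "bite_duration_s")
  check_positive_range(inter_bite_interval_s, "inter_bite_interval_s")
  if (!is.numeric(semg_resolution_bits) || semg_resolution_bits < 2) {
    stopf("'semg_resolution_bits' must be an integer >= 2")
  }
  w <- channel_activation_profile
  if (!is.matrix(w) || nrow(w) != length(activity_classes()) ||
      ncol(w) != n_semg_channels || any(w < 0) || any(w > 1)) {
    stopf("'channel_activation_profile' must be a [10 x %d] matrix with weights in [0,1]",
          n_semg_channels)
  }
  if (is.null(rownames(w))) rownames(w) <- activity_classes()
  for (a in c(smoking_classes(), "eating")) {
    if (all(w[a, ] <= 0)) {
      stopf("activation profile row '%s' must have at least one positive weight", a)
    }
  }
  structure(list(
    sample_rate_hz = sample_rate_hz,
    semg_resolution_bits = as.integer(semg_resolution_bits),
    n_semg_channels = as.integer(n_semg_channels),
    puff_duration_s = puff_duration_s,
    inter_puff_interval_s = inter_puff_interval_s,
    bite_duration_s = bite_duration_s,
    inter_bite_interval_s = inter_bite_interval_s,
    semg_burst_gain = semg_burst_gain,
    channel_activation_profile = w,
    imu_gesture_amplitude = imu_gesture_amplitude,
    baseline_noise_sd = baseline_noise_sd,
    subject_variability = subject_variability,
    seed = as.integer(seed)
  ), class = "generator_params")
}

#' "Easy" generator preset for learning-sanity experiments
#'
#' Strong gesture gains, dense puffing, and low baseline noise: each 10-s
#' window inside a smoking session then overlaps at least one puff with high
#' probability, making the classification task cleanly learnable.
#' @param seed Integer master seed.
#' @return `generator_params` object.
#' @export
easy_generator_params <- function(seed = 1L) {
  generator_params(
    puff_duration_s = c(2.5, 4),
    inter_puff_interval_s = c(8, 14),
    bite_duration_s = c(1.5, 3),
    inter_bite_interval_s = c(6, 11),
    semg_burst_gain = 8,
    imu_gesture_amplitude = 1.2,
    baseline_noise_sd = 2.5,
    subject_variability = 0.10,
    seed = seed
  )
}

#' Construct an ordered activity protocol
#'
#' @param activities Character vector of activity classes, in order.
#' @param durations_s Positive durations (s), same length as `activities`.
#'   Non-smoking, non-eating activities are capped at 300 s (the protocol's
#'   5-minute maximum).
#' @return Object of class `activity_protocol`: a data frame with columns
#'   `activity` and `duration_s`.
#' @export
activity_protocol <- function(activities, durations_s) {
  if (length(activities) == 0L) stopf("protocol must contain at least one activity")
  if (length(activities) != length(durations_s)) {
    stopf("'activities' and 'durations_s' must have the same length")
  }
  if (any(!is.finite(durations_s)) || any(durations_s <= 0)) {
    stopf("all durations must be positive and finite")
  }
  capped <- !(activities %in% c(smoking_classes(), "eating"))
  if (any(capped & durations_s > 300)) {
    stopf("non-smoking, non-eating activities are limited to 300 s")
  }
  structure(data.frame(activity = as.character(activities),
                       duration_s = as.numeric(durations_s),
                       stringsAsFactors = FALSE),
            class = c("activity_protocol", "data.frame"))
}

#' Default and reduced study protocols
#'
#' `default_protocol()` emulates the scripted session: the ten ordered
#' activities with four smoking sessions of about 267 s each (the study's
#' 4.75 h over 64 events), 240 s for other activities and 360 s for eating --
#' about 48 min per subject. `easy_protocol()` is the same ordering compressed
#' to 20 min per subject, used by the learning-sanity experiments.
#'
#' @param smoking_session_duration_s Duration of each smoking session (s).
#' @param nonsmoking_duration_s Duration of non-smoking, non-eating activities (s).
#' @param eating_duration_s Duration of the eating activity (s).
#' @return `activity_protocol` object.
#' @export
default_protocol <- function(smoking_session_duration_s = 267,
                             nonsmoking_duration_s = 240,
                             eating_duration_s = 360) {
  acts <- activity_classes()
  dur <- ifelse(acts %in% smoking_classes(), smoking_session_duration_s,
                ifelse(acts == "eating", eating_duration_s, nonsmoking_duration_s))
  activity_protocol(acts, dur)
}

#' @rdname default_protocol
#' @export
easy_protocol <- function() {
  default_protocol(smoking_session_duration_s = 112.5,
                   nonsmoking_duration_s = 120,
                   eating_duration_s = 150)
}

n_smoking_sessions <- function(protocol) sum(protocol$activity %in% smoking_classes())

# draw a train of non-overlapping gesture intervals inside a session:
# alternating gap ~ U(interval range), duration ~ U(duration range), starting
# with a gap; stops when the next gesture would overrun the session end
interval_train <- function(session_start_s, session_end_s, duration_range, gap_range) {
  if (session_end_s <= session_start_s) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  }
  starts <- numeric(0); ends <- numeric(0)
  t <- session_start_s
  repeat {
    g <- stats::runif(1, gap_range[1], gap_range[2])
    d <- stats::runif(1, duration_range[1], duration_range[2])
    s <- t + g
    e <- s + d
    if (e > session_end_s) break
    starts <- c(starts, s); ends <- c(ends, e)
    t <- e
  }
  data.frame(start_s = starts, end_s = ends)
}

#' Draw puff gesture intervals inside a smoking session
#'
#' Puff durations and inter-puff gaps are drawn uniformly from the configured
#' ranges, alternating gap-puff-gap-... from the session start; intervals are
#' non-overlapping and contained in the session. Uses the current RNG stream;
#' seed the stream (or use the higher-level generators) for reproducibility.
#'
#' @param session_start_s,session_end_s Session bounds (s).
#' @param params `generator_params` object.
#' @return Data frame with columns `start_s`, `end_s`, one row per puff;
#'   zero rows if the session is too short for a single puff.
#' @export
puff_train <- function(session_start_s, session_end_s, params) {
  stopifnot(inherits(params, "generator_params"))
  if (session_end_s < session_start_s) stopf("session end precedes session start")
  interval_train(session_start_s, session_end_s,
                 params$puff_duration_s, params$inter_puff_interval_s)
}

# raised-cosine pulse support: adds to envelope `env` a 0->1->0 pulse over
# [s, e] with `ramp` seconds of cosine rise/fall (clipped to half the interval)
add_pulse <- function(env, s, e, fs, ramp = 0.4) {
  n <- length(env)
  i0 <- max(1L, floor(s * fs) + 1L)
  i1 <- min(n, ceiling(e * fs))
  if (i1 < i0) return(env)
  tt <- (seq(i0, i1) - 1) / fs
  r <- min(ramp, (e - s) / 2)
  up <- pmin(1, pmax(0, (tt - s) / r))
  dn <- pmin(1, pmax(0, (e - tt) / r))
  p <- 0.5 * (1 - cospi(up)) * 0.5 * (1 - cospi(dn))
  env[i0:i1] <- pmax(env[i0:i1], p)
  env
}

bandpass_noise <- function(n, fs, lo = 20, hi = 95) {
  ny <- fs / 2
  hi <- min(hi, 0.98 * ny)
  bf <- signal::butter(4, c(lo, hi) / ny, type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n + 400))[201:(n + 200)]
  x / stats::sd(x)
}

#' Generate one subject's synchronized recording and activity log
#'
#' Walks the protocol in order, draws puff trains inside smoking sessions and
#' bite trains inside eating, synthesizes the 8 sEMG channels as
#' amplitude-modulated band-limited noise quantized to the configured bit
#' depth, and synthesizes accelerometer/gyroscope streams from a smooth
#' forearm-pitch trajectory (hand-to-mouth gestures), gait oscillation during
#' walking activities, and measurement noise.
#'
#' @param protocol `activity_protocol` object.
#' @param params `generator_params` object.
#' @param subject_id Subject identifier string.
#' @param seed Seed for this subject; defaults to `params$seed`.
#' @return List with elements `recording` (class `sensor_recording`) and
#'   `log` (class `activity_log`).
#' @export
generate_subject <- function(protocol, params, subject_id = "S01",
                             seed = params$seed) {
  stopifnot(inherits(protocol, "activity_protocol"),
            inherits(params, "generator_params"))
  if (nrow(protocol) == 0L) stopf("empty protocol: nothing to generate")
  fs <- params$sample_rate_hz
  with_seed(seed, {
    # per-subject variability: multiplicative log-normal jitter
    sv <- params$subject_variability
    w <- params$channel_activation_profile *
      matrix(exp(stats::rnorm(length(params$channel_activation_profile), 0, sv)),
             nrow = nrow(params$channel_activation_profile))
    w <- pmin(w, 1)
    amp_jit <- exp(stats::rnorm(1, 0, sv))

    ends <- cumsum(protocol$duration_s)
    starts <- c(0, ends[-length(ends)])
    total_s <- ends[length(ends)]
    n <- round(total_s * fs)
    tt <- (seq_len(n) - 1) / fs

    log <- activity_log(data.frame(activity = protocol$activity,
                                   start_s = starts, end_s = ends,
                                   stringsAsFactors = FALSE))

    # activity index per sample
    act_idx <- findInterval(tt, starts)
    act <- protocol$activity[act_idx]

    # gesture envelope shared by sEMG bursts and the pitch trajectory
    env <- numeric(n)
    for (k in seq_len(nrow(protocol))) {
      a <- protocol$activity[k]
      if (a %in% smoking_classes()) {
        iv <- puff_train(starts[k], ends[k], params)
      } else if (a == "eating") {
        iv <- interval_train(starts[k], ends[k],
                             params$bite_duration_s, params$inter_bite_interval_s)
      } else next
      for (j in seq_len(nrow(iv))) env <- add_pulse(env, iv$start_s[j], iv$end_s[j], fs)
    }

    # sEMG: amplitude-modulated band-passed noise, quantized and clipped
    gesture <- act %in% gesture_classes()
    mod <- ifelse(gesture, env, 1)   # sustained activation for non-gesture classes
    gain <- params$semg_burst_gain
    lim <- 2^(params$semg_resolution_bits - 1)
    semg <- matrix(0L, nrow = n, ncol = params$n_semg_channels,
                   dimnames = list(NULL, semg_channels(params$n_semg_channels)))
    for (c in seq_len(params$n_semg_channels)) {
      a_t <- params$baseline_noise_sd * (1 + (gain - 1) * w[act, c] * mod)
      x <- round(a_t * bandpass_noise(n, fs))
      semg[, c] <- as.integer(pmin(pmax(x, -lim), lim - 1))
    }

    # IMU: forearm pitch excursion during gestures + gait + noise
    theta <- 1.2 * params$imu_gesture_amplitude * amp_jit * env  # rad
    walking <- act %in% walking_classes()
    gait_f <- ifelse(act == "walking_fast", 2.2, 1.8)
    gait <- walking * sin(2 * pi * gait_f * tt)
    accel <- cbind(
      accel_x = sin(theta) + 0.12 * gait + stats::rnorm(n, 0, 0.02),
      accel_y = 0.08 * walking * sin(2 * pi * gait_f * tt + pi / 3) +
        stats::rnorm(n, 0, 0.02),
      accel_z = cos(theta) + 0.10 * gait + stats::rnorm(n, 0, 0.02)
    )
    dtheta <- c(0, diff(theta)) * fs * 180 / pi   # deg/s
    gyro <- cbind(
      gyro_x = 0.3 * dtheta + 25 * walking * sin(2 * pi * gait_f * tt + pi / 2) +
        stats::rnorm(n, 0, 1.5),
      gyro_y = dtheta + stats::rnorm(n, 0, 1.5),
      gyro_z = 15 * walking * sin(2 * pi * gait_f * tt) + stats::rnorm(n, 0, 1.5)
    )

    rec <- sensor_recording(subject_id = subject_id, sample_rate_hz = fs,
                            semg = semg, accel = accel, gyro = gyro,
                            semg_bits = params$semg_resolution_bits)
    list(recording = rec, log = log)
  })
}

#' Generate a synthetic cohort
#'
#' Per-subject sub-seeds are derived deterministically from the master seed, so
#' the whole cohort is a pure function of (protocol, params, seed). Subjects
#' differ through seeded jitter of activation weights and gesture amplitudes,
#' which is what makes leave-one-subject-out evaluation harder than a random
#' split.
#'
#' @param n_subjects Number of subjects (>= 2, as required for LOSO).
#' @param protocol `activity_protocol` object.
#' @param params `generator_params` object.
#' @return List of per-subject lists `(recording, log)`, names = subject ids.
#' @export
generate_cohort <- function(n_subjects, protocol = default_protocol(),
                            params = generator_params()) {
  if (n_subjects < 2) stopf("a cohort needs at least 2 subjects (LOSO requires it)")
  ids <- sprintf("S%02d", seq_len(n_subjects))
  out <- lapply(seq_len(n_subjects), function(i) {
    generate_subject(protocol, params, subject_id = ids[i],
                     seed = derive_seed(params$seed, i))
  })
  names(out) <- ids
  out
}

#' Sensor recording constructor
#'
#' @param subject_id Subject identifier.
#' @param sample_rate_hz Sampling rate (Hz).
#' @param semg Integer matrix `[n x n_semg]` of quantized sEMG counts.
#' @param accel Numeric matrix `[n x 3]`, accelerometer in g.
#' @param gyro Numeric matrix `[n x 3]`, gyroscope in deg/s.
#' @param semg_bits sEMG quantizer bit depth.
#' @param t0 Recording start time offset (s).
#' @return Object of class `sensor_recording`.
#' @export
sensor_recording <- function(subject_id, sample_rate_hz, semg, accel, gyro,
                             semg_bits = 8L, t0 = 0) {
  n <- nrow(semg)
  if (nrow(accel) != n || nrow(gyro) != n) {
    stopf("semg, accel and gyro must share the same number of samples")
  }
  lim <- 2^(semg_bits - 1)
  if (any(semg < -lim | semg > lim - 1)) {
    stopf("sEMG values outside the signed %d-bit range [%d, %d]",
          semg_bits, -lim, lim - 1)
  }
  structure(list(subject_id = subject_id,
                 sample_rate_hz = sample_rate_hz,
                 semg = semg, accel = accel, gyro = gyro,
                 semg_bits = as.integer(semg_bits), t0 = t0),
            class = "sensor_recording")
}

#' @export
print.sensor_recording <- function(x, ...) {
  n <- nrow(x$semg)
  cat(sprintf("<sensor_recording> subject %s: %d samples (%.1f s at %g Hz), %d sEMG + 6 IMU channels\n",
              x$subject_id, n, n / x$sample_rate_hz, x$sample_rate_hz, ncol(x$semg)))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec `sensor_recording` object.
#' @export
recording_duration <- function(rec) nrow(rec$semg) / rec$sample_rate_hz

#' Extract a named channel from a recording
#' @param rec `sensor_recording` object.
#' @param channel Channel name, e.g. `"semg3"` or `"gyro_y"`.
#' @return Numeric vector of samples.
#' @export
recording_channel <- function(rec, channel) {
  sc <- semg_channels(ncol(rec$semg))
  if (channel %in% sc) return(as.numeric(rec$semg[, match(channel, sc)]))
  im <- imu_channels()
  if (channel %in% im) {
    i <- match(channel, im)
    if (i <= 3L) return(rec$accel[, i]) else return(rec$gyro[, i - 3L])
  }
  stopf("unknown channel '%s'", channel)
}

#' Activity log constructor
#'
#' Events are sorted by start time; overlapping events are rejected.
#' @param events Data frame with columns `activity`, `start_s`, `end_s`.
#' @return Object of class `activity_log`.
#' @export
activity_log <- function(events) {
  need <- c("activity", "start_s", "end_s")
  if (!all(need %in% names(events))) {
    stopf("activity log needs columns %s", paste(need, collapse = ", "))
  }
  if (any(events$end_s <= events$start_s)) {
    bad <- which(events$end_s <= events$start_s)[1]
    stopf("activity log event %d ('%s') has end <= start", bad, events$activity[bad])
  }
  events <- events[order(events$start_s), , drop = FALSE]
  rownames(events) <- NULL
  if (nrow(events) > 1L &&
      any(events$start_s[-1] < events$end_s[-nrow(events)] - 1e-9)) {
    stopf("activity log events overlap")
  }
  unknown <- setdiff(unique(events$activity), activity_classes())
  if (length(unknown)) {
    warnf("unknown activity classes (treated as non-smoking): %s",
          paste(unknown, collapse = ", "))
  }
  structure(events, class = c("activity_log", "data.frame"))
}
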