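# Seeded generators emulating SaR-dog field recordings: 100 Hz dual-sensor
# IMU sessions with labelled activity segments, and 2-s audio clips with a
# configurable not-bark:bark imbalance. The signal models are deliberately
# simple: they reproduce the statistical structure the pipeline relies on
# (activity-ordered magnitude variance, harmonic bark bursts vs. low-frequency
# noise), not canine biomechanics.

ACTIVITIES <- c("standing", "walking", "trotting", "running")
ALL_LABELS <- c(ACTIVITIES, "missing")

# run body with a private RNG stream; global .Random.seed is left untouched
with_seed <- function(seed, body) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(seed)
  force(body)
}

#' Describe the activity timeline of a synthetic SaR session
#'
#' @param activities character vector of segment activities, each one of
#'   `"standing"`, `"walking"`, `"trotting"`, `"running"` or `"missing"`.
#' @param durations segment durations in seconds (positive; total >= 2 s).
#' @return a `sardar_schedule` data frame with columns `activity`, `duration`.
#' @examples
#' activity_schedule(c("running", "trotting", "standing"), c(6, 20, 8))
#' @export
activity_schedule <- function(activities, durations) {
  if (length(activities) == 0 || length(activities) != length(durations)) {
    stop("activities and durations must be non-empty and of equal length")
  }
  if (!all(activities %in% ALL_LABELS)) {
    stop("unknown activity: ", paste(setdiff(activities, ALL_LABELS), collapse = ", "))
  }
  if (any(durations <= 0)) stop("durations must be positive")
  if (sum(durations) < 2) stop("total schedule duration must be at least 2 s")
  structure(data.frame(activity = activities, duration = as.numeric(durations),
                       stringsAsFactors = FALSE),
            class = c("sardar_schedule", "data.frame"))
}

#' Parameters of the synthetic signal models
#'
#' Per-activity oscillation amplitudes follow the intensity ordering observed
#' on real recordings (standing < walking < trotting < running, for both the
#' accelerometer and the gyroscope), with gait oscillation at an
#' activity-specific stride frequency plus Gaussian sensor noise and a gravity
#' offset on one accelerometer axis. Bark clips are burst trains of harmonic
#' pulses with a fundamental drawn from `bark_f0_range`; not-bark clips are
#' strongly low-passed noise with footfall transients, so the two classes are
#' separable in the 400-900 Hz band.
#'
#' @param sampling_rate_imu IMU rate in Hz.
#' @param sampling_rate_audio audio rate in Hz.
#' @param amplitudes_acc,amplitudes_gyr named per-activity oscillation
#'   amplitudes (accelerometer: m/s^2; gyroscope: rad/s), ordered
#'   standing < walking < trotting < running.
#' @param stride_hz named per-activity stride frequencies in Hz.
#' @param noise_scale standard deviation of the additive sensor noise.
#' @param gravity constant offset on the accelerometer z axis (m/s^2).
#' @param bark_f0_range bark fundamental frequency range in Hz.
#' @param class_imbalance target not-bark:bark clip ratio (>= 1).
#' @param seed default integer seed for the generators.
#' @return a validated list of class `sardar_synthesis_params`.
#' @export
synthesis_params <- function(sampling_rate_imu = 100,
                             sampling_rate_audio = 44100,
                             amplitudes_acc = c(standing = 0.05, walking = 0.5,
                                                trotting = 1.2, running = 2.5),
                             amplitudes_gyr = c(standing = 0.02, walking = 0.4,
                                                trotting = 1.0, running = 2.2),
                             stride_hz = c(standing = 0, walking = 2,
                                           trotting = 2.8, running = 3.5),
                             noise_scale = 0.05,
                             gravity = 9.81,
                             bark_f0_range = c(400, 900),
                             class_imbalance = 6,
                             seed = 1L) {
  stopifnot(sampling_rate_imu > 0, sampling_rate_audio > 0, noise_scale > 0,
            length(bark_f0_range) == 2, bark_f0_range[1] < bark_f0_range[2],
            class_imbalance >= 1)
  for (amps in list(amplitudes_acc, amplitudes_gyr)) {
    if (!all(ACTIVITIES %in% names(amps))) {
      stop("amplitudes must name all four activities")
    }
    if (!(amps["standing"] < amps["walking"] &&
          amps["walking"] < amps["trotting"] &&
          amps["trotting"] < amps["running"])) {
      stop("amplitudes must be ordered standing < walking < trotting < running")
    }
  }
  structure(list(sampling_rate_imu = sampling_rate_imu,
                 sampling_rate_audio = sampling_rate_audio,
                 amplitudes_acc = amplitudes_acc,
                 amplitudes_gyr = amplitudes_gyr,
                 stride_hz = stride_hz,
                 noise_scale = noise_scale,
                 gravity = gravity,
                 bark_f0_range = bark_f0_range,
                 class_imbalance = class_imbalance,
                 seed = as.integer(seed)),
            class = "sardar_synthesis_params")
}

# oscillation + noise for one segment; per-axis phases and modulation make the
# three axes distinct. A common footfall envelope at the stride period
# modulates all axes together, so the magnitude of the 3-D vector always
# fluctuates with the oscillation amplitude (random per-axis phases alone can
# approximate a constant-magnitude rotation).
synth_segment <- function(n, amp, freq, noise_sd, rate) {
  t <- (seq_len(n) - 1) / rate
  mods <- c(1, 0.8, 0.6)
  phases <- stats::runif(3, 0, 2 * pi)
  env <- if (freq > 0) 0.15 + 0.85 * abs(sin(pi * freq * t)) else 1
  out <- matrix(0, n, 3)
  for (a in 1:3) {
    osc <- if (freq > 0) amp * mods[a] * sin(2 * pi * freq * t + phases[a]) else 0
    # second harmonic gives the gait a non-sinusoidal, footfall-like shape
    osc2 <- if (freq > 0) 0.3 * amp * mods[a] * sin(4 * pi * freq * t + 2 * phases[a]) else 0
    out[, a] <- env * (osc + osc2) + stats::rnorm(n, 0, noise_sd)
  }
  out
}

#' Generate a labelled synthetic IMU session
#'
#' Produces a 100 Hz (by default) dual-sensor recording following `schedule`:
#' each segment carries sinusoidal gait oscillation at its activity's stride
#' frequency and amplitude, additive Gaussian noise, and a constant gravity
#' offset on the accelerometer z axis. "missing" stretches are synthesised
#' with trot-like motion (the dog keeps moving while out of sight) and carry
#' the missing label.
#'
#' @param schedule an [activity_schedule()].
#' @param params a [synthesis_params()].
#' @param session_id identifier attached to the session.
#' @param seed integer seed; defaults to `params$seed`. The output is a pure
#'   function of (arguments, seed).
#' @return a `sardar_imu_session`: list with `session_id`, `data` (data frame
#'   `t, ax, ay, az, gx, gy, gz`) and `segments` (data frame
#'   `start, end, activity`).
#' @export
generate_imu_session <- function(schedule, params = synthesis_params(),
                                 session_id = "S1", seed = params$seed) {
  if (!inherits(schedule, "sardar_schedule")) {
    stop("schedule must be created by activity_schedule()")
  }
  stopifnot(inherits(params, "sardar_synthesis_params"))
  rate <- params$sampling_rate_imu
  with_seed(seed, {
    ns <- round(schedule$duration * rate)
    acc <- matrix(0, 0, 3)
    gyr <- matrix(0, 0, 3)
    for (i in seq_len(nrow(schedule))) {
      act <- schedule$activity[i]
      eff <- if (act == "missing") "trotting" else act
      acc <- rbind(acc, synth_segment(ns[i], params$amplitudes_acc[[eff]],
                                      params$stride_hz[[eff]],
                                      params$noise_scale, rate))
      gyr <- rbind(gyr, synth_segment(ns[i], params$amplitudes_gyr[[eff]],
                                      params$stride_hz[[eff]],
                                      0.6 * params$noise_scale, rate))
    }
    acc[, 3] <- acc[, 3] + params$gravity
    n <- sum(ns)
    ends <- cumsum(ns) / rate
    starts <- c(0, ends[-length(ends)])
    structure(list(
      session_id = session_id,
      data = data.frame(t = (seq_len(n) - 1) / rate,
                        ax = acc[, 1], ay = acc[, 2], az = acc[, 3],
                        gx = gyr[, 1], gy = gyr[, 2], gz = gyr[, 3]),
      segments = data.frame(start = starts, end = ends,
                            activity = schedule$activity,
                            stringsAsFactors = FALSE)),
      class = "sardar_imu_session")
  })
}

#' @export
print.sardar_imu_session <- function(x, ...) {
  cat(sprintf("<sardar_imu_session> %s: %.1f s, %d samples, %d segments (%s)\n",
              x$session_id, max(x$data$t) + diff(x$data$t[1:2]),
              nrow(x$data), nrow(x$segments),
              paste(unique(x$segments$activity), collapse = ", ")))
  invisible(x)
}

# burst of harmonic pulses: fundamental f0 with decaying overtones and a
# sharp-attack/exponential-decay envelope
bark_burst <- function(n, f0, rate, n_harmonics = 5) {
  t <- (seq_len(n) - 1) / rate
  x <- numeric(n)
  for (h in seq_len(n_harmonics)) {
    x <- x + 0.8^(h - 1) * sin(2 * pi * h * f0 * t + stats::runif(1, 0, 2 * pi))
  }
  attack <- pmin(1, t / 0.015)
  decay <- exp(-t / (0.25 * n / rate))
  x * attack * decay
}

# heavily low-passed background noise (AR(1)) keeps the not-bark spectrum well
# below the bark fundamental band
rumble_noise <- function(n, ar = 0.995) {
  as.numeric(stats::filter(stats::rnorm(n), ar, method = "recursive"))
}

#' Generate a labelled 2-s synthetic audio clip
#'
#' Bark clips contain 3-6 bursts of harmonic pulses whose fundamental is drawn
#' from `params$bark_f0_range`; not-bark clips are low-frequency rumble with a
#' few footfall transients. Both are peak-scaled below 1.
#'
#' @param label `"bark"` or `"not_bark"`.
#' @param params a [synthesis_params()].
#' @param seed integer seed; defaults to `params$seed`.
#' @param duration clip duration in seconds.
#' @return a `sardar_audio_clip`: list with `wave`, `rate`, `label`,
#'   `session_id`, `start_time`.
#' @export
generate_audio_clip <- function(label = c("bark", "not_bark"),
                                params = synthesis_params(),
                                seed = params$seed, duration = 2) {
  label <- match.arg(label)
  stopifnot(inherits(params, "sardar_synthesis_params"))
  rate <- params$sampling_rate_audio
  n <- round(duration * rate)
  with_seed(seed, {
    wave <- 0.02 * rumble_noise(n) / 3
    if (label == "bark") {
      n_bursts <- sample(3:6, 1)
      for (b in seq_len(n_bursts)) {
        len <- round(stats::runif(1, 0.15, 0.25) * rate)
        start <- sample.int(n - len, 1)
        f0 <- stats::runif(1, params$bark_f0_range[1], params$bark_f0_range[2])
        burst <- bark_burst(len, f0, rate)
        wave[start:(start + len - 1)] <- wave[start:(start + len - 1)] +
          0.9 * burst / max(abs(burst))
      }
    } else {
      n_steps <- sample(2:5, 1)
      for (b in seq_len(n_steps)) {
        len <- round(0.08 * rate)
        start <- sample.int(n - len, 1)
        t <- (seq_len(len) - 1) / rate
        thump <- sin(2 * pi * stats::runif(1, 60, 120) * t) * exp(-t / 0.02)
        wave[start:(start + len - 1)] <- wave[start:(start + len - 1)] + 0.25 * thump
      }
    }
    peak <- max(abs(wave))
    if (peak > 1) wave <- wave / (peak * 1.05)
    structure(list(wave = wave, rate = rate, label = label,
                   session_id = NA_character_, start_time = NA_real_),
              class = "sardar_audio_clip")
  })
}

#' @export
print.sardar_audio_clip <- function(x, ...) {
  cat(sprintf("<sardar_audio_clip> %s: %.2f s at %d Hz (session %s)\n",
              x$label, length(x$wave) / x$rate, x$rate, x$session_id))
  invisible(x)
}

# random session schedule: release run, then trot/walk/stand blocks, optional
# missing stretch, closing stand (the victim-found posture)
random_schedule <- function() {
  acts <- "running"
  durs <- round(stats::runif(1, 5, 8))
  target <- stats::runif(1, 45, 75)
  while (sum(durs) < target - 10) {
    acts <- c(acts, "trotting", "walking")
    durs <- c(durs, round(stats::runif(1, 6, 10)), round(stats::runif(1, 4, 7)))
    if (stats::runif(1) < 0.4) {
      acts <- c(acts, "missing")
      durs <- c(durs, round(stats::runif(1, 3, 5)))
    }
  }
  acts <- c(acts, "standing")
  durs <- c(durs, round(stats::runif(1, 6, 10)))
  activity_schedule(acts, durs)
}

#' Generate a full synthetic dataset of sessions and audio clips
#'
#' Creates `n_sessions` independent sessions with randomised schedules and a
#' session-tagged pool of audio clips whose overall not-bark:bark ratio equals
#' the configured `params$class_imbalance` (realised within +-10%; bark clips
#' are spread over sessions round-robin, the imbalance is enforced at the
#' clip-sampling level rather than per session).
#'
#' @param n_sessions number of sessions (>= 3, so session-wise train /
#'   validation / test splits exist).
#' @param params a [synthesis_params()].
#' @param seed integer seed; defaults to `params$seed`.
#' @param clips_per_session audio clips generated per session.
#' @return a `sardar_dataset`: list with `sessions` (list of
#'   `sardar_imu_session`) and `clips` (list of `sardar_audio_clip`).
#' @export
generate_dataset <- function(n_sessions, params = synthesis_params(),
                             seed = params$seed, clips_per_session = 12) {
  if (n_sessions < 3) {
    stop("n_sessions must be at least 3 so train/validation/test splits exist")
  }
  ids <- sprintf("S%d", seq_len(n_sessions))
  schedules <- with_seed(seed, lapply(seq_len(n_sessions), function(i) random_schedule()))
  sessions <- lapply(seq_len(n_sessions), function(i) {
    generate_imu_session(schedules[[i]], params, session_id = ids[i],
                         seed = seed + 1000L + i)
  })
  total <- n_sessions * clips_per_session
  n_bark <- max(1L, round(total / (params$class_imbalance + 1)))
  labels <- rep("not_bark", total)
  labels[seq_len(n_bark)] <- "bark"           # round-robin over sessions below
  clip_session <- rep(ids, clips_per_session)  # interleaved: S1, S2, ..., S1, ...
  clips <- lapply(seq_len(total), function(i) {
    clip <- generate_audio_clip(labels[i], params, seed = seed + 5000L + i)
    clip$session_id <- clip_session[i]
    clip
  })
  structure(list(sessions = sessions, clips = clips),
            class = "sardar_dataset")
}

#' @export
print.sardar_dataset <- function(x, ...) {
  labs <- vapply(x$clips, `[[`, "", "label")
  cat(sprintf("<sardar_dataset> %d sessions, %d clips (%d bark / %d not-bark)\n",
              length(x$sessions), length(x$clips),
              sum(labs == "bark"), sum(labs == "not_bark")))
  invisible(x)
}

#' Generate the audio track of a whole synthetic session
#'
#' Returns a waveform time-aligned with an IMU session: low-level background
#' rumble, footfall transients during motion segments, and bark burst trains
#' inside the requested bark intervals (typically while the dog stands at the
#' victim). Used to exercise the stream-replay and alert-fusion stages.
#'
#' @param session a `sardar_imu_session`.
#' @param bark_intervals data frame with `start`, `end` columns in seconds.
#' @param params a [synthesis_params()].
#' @param seed integer seed; defaults to `params$seed`.
#' @return a `sardar_audio_stream`: list with `wave`, `rate`, `session_id`,
#'   `bark_intervals`.
#' @export
generate_session_audio <- function(session, bark_intervals = NULL,
                                   params = synthesis_params(),
                                   seed = params$seed) {
  stopifnot(inherits(session, "sardar_imu_session"))
  rate <- params$sampling_rate_audio
  dur <- nrow(session$data) / params$sampling_rate_imu
  n <- round(dur * rate)
  if (is.null(bark_intervals)) {
    bark_intervals <- data.frame(start = numeric(0), end = numeric(0))
  }
  with_seed(seed, {
    wave <- 0.02 * rumble_noise(n) / 3
    for (i in seq_len(nrow(session$segments))) {
      seg <- session$segments[i, ]
      if (seg$activity %in% c("walking", "trotting", "running", "missing")) {
        steps <- max(1, round((seg$end - seg$start) * 2))
        for (s in seq_len(steps)) {
          len <- round(0.08 * rate)
          start <- round(stats::runif(1, seg$start, max(seg$start, seg$end - 0.1)) * rate) + 1
          if (start + len - 1 > n) next
          t <- (seq_len(len) - 1) / rate
          thump <- sin(2 * pi * stats::runif(1, 60, 120) * t) * exp(-t / 0.02)
          wave[start:(start + len - 1)] <- wave[start:(start + len - 1)] + 0.25 * thump
        }
      }
    }
    for (i in seq_len(nrow(bark_intervals))) {
      iv <- bark_intervals[i, ]
      pos <- iv$start + 0.1
      while (pos < iv$end - 0.3) {
        len <- round(stats::runif(1, 0.15, 0.25) * rate)
        start <- round(pos * rate) + 1
        f0 <- stats::runif(1, params$bark_f0_range[1], params$bark_f0_range[2])
        burst <- bark_burst(len, f0, rate)
        wave[start:(start + len - 1)] <- wave[start:(start + len - 1)] +
          0.9 * burst / max(abs(burst))
        pos <- pos + stats::runif(1, 0.35, 0.6)
      }
    }
    peak <- max(abs(wave))
    if (peak > 1) wave <- wave / (peak * 1.05)
    structure(list(wave = wave, rate = rate, session_id = session$session_id,
                   bark_intervals = bark_intervals),
              class = "sardar_audio_stream")
  })
}
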