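# Fusion of the two decision streams: pair activity and bark windows by start
# time, and raise a victim-found alert when the dog is standing and barking
# in the same aligned window. SaR dogs are trained to stand still and bark at
# the victim, so requiring both suppresses bark-only false alarms.

#' Pair IMU and audio decision windows by start time
#'
#' Both streams are 2-s windows on a nominal 1-s stride. Windows are paired
#' greedily by nearest start time; a pair is accepted only if the starts
#' differ by less than half the stride. Windows without a partner are kept and
#' flagged unpaired (no alert can arise from them).
#'
#' @param imu_states data frame with `window_start` and `stand_prob`.
#' @param audio_states data frame with `window_start` and `bark_prob`.
#' @param stride nominal window stride in seconds.
#' @return data frame with `imu_start`, `audio_start`, `stand_prob`,
#'   `bark_prob`, `paired`; sorted by time.
#' @export
align_streams <- function(imu_states, audio_states, stride = 1) {
  stopifnot(all(c("window_start", "stand_prob") %in% names(imu_states)),
            all(c("window_start", "bark_prob") %in% names(audio_states)))
  imu_states <- imu_states[order(imu_states$window_start), , drop = FALSE]
  audio_states <- audio_states[order(audio_states$window_start), , drop = FALSE]
  tol <- stride / 2
  na <- nrow(audio_states)
  used <- rep(FALSE, na)
  partner <- rep(NA_integer_, nrow(imu_states))
  for (i in seq_len(nrow(imu_states))) {
    dt <- abs(audio_states$window_start - imu_states$window_start[i])
    dt[used] <- Inf
    j <- which.min(dt)
    if (na > 0 && dt[j] < tol) {
      partner[i] <- j
      used[j] <- TRUE
    }
  }
  paired_rows <- data.frame(
    imu_start = imu_states$window_start,
    audio_start = audio_states$window_start[partner],
    stand_prob = imu_states$stand_prob,
    bark_prob = audio_states$bark_prob[partner],
    paired = !is.na(partner))
  leftover <- which(!used)
  if (length(leftover)) {
    paired_rows <- rbind(paired_rows, data.frame(
      imu_start = NA_real_,
      audio_start = audio_states$window_start[leftover],
      stand_prob = NA_real_,
      bark_prob = audio_states$bark_prob[leftover],
      paired = FALSE))
  }
  ord <- order(ifelse(is.na(paired_rows$imu_start),
                      paired_rows$audio_start, paired_rows$imu_start))
  paired_rows[ord, , drop = FALSE]
}

#' Raise victim-found alerts from aligned decision windows
#'
#' A window alerts iff it is paired and both decisions fire: stand probability
#' strictly above `stand_threshold` and bark probability strictly above
#' `bark_threshold`. An optional debounce requires `min_consecutive` adjacent
#' qualifying windows (off by default: every qualifying window emits an
#' alert).
#'
#' @param aligned output of [align_streams()].
#' @param stand_threshold,bark_threshold decision thresholds (default 0.5).
#' @param min_consecutive debounce length (1 = no debouncing).
#' @return data frame of `sardar_alert` events: `timestamp`, `imu_start`,
#'   `audio_start`, `message`.
#' @export
raise_alert <- function(aligned, stand_threshold = 0.5, bark_threshold = 0.5,
                        min_consecutive = 1) {
  stopifnot(min_consecutive >= 1)
  qualifying <- aligned$paired &
    !is.na(aligned$stand_prob) & aligned$stand_prob > stand_threshold &
    !is.na(aligned$bark_prob) & aligned$bark_prob > bark_threshold
  if (min_consecutive > 1) {
    r <- rle(qualifying)
    r$values <- r$values & r$lengths >= min_consecutive
    qualifying <- inverse.rle(r)
  }
  out <- data.frame(timestamp = aligned$imu_start[qualifying],
                    imu_start = aligned$imu_start[qualifying],
                    audio_start = aligned$audio_start[qualifying],
                    message = rep("victim-found", sum(qualifying)),
                    stringsAsFactors = FALSE)
  class(out) <- c("sardar_alerts", "data.frame")
  out
}

#' Replay a whole session through both trained models
#'
#' Slides 2-s windows at a 1-s stride over the full IMU recording (inference
#' ignores the label track), normalises with the supplied training statistics
#' and scores each window with the activity network; segments the audio track
#' the same way and scores each clip with the bark network; aligns the two
#' decision streams and applies the alert rule. Deterministic: dropout is
#' inactive at inference.
#'
#' @param session a `sardar_imu_session`.
#' @param audio a `sardar_audio_stream` (or numeric waveform via
#'   `audio_rate`).
#' @param activity_model,bark_model trained `sardar_cnn` models; the activity
#'   model's positive class must be `stand`, the bark model's `bark`.
#' @param stats `sardar_norm_stats` fitted on the training sessions.
#' @param stand_threshold,bark_threshold decision thresholds.
#' @param audio_rate rate of `audio` when a bare waveform is given.
#' @param min_consecutive debounce length for [raise_alert()].
#' @return a `sardar_timeline`: list with `states` (aligned window decisions)
#'   and `alerts`.
#' @export
replay_session <- function(session, audio, activity_model, bark_model, stats,
                           stand_threshold = 0.5, bark_threshold = 0.5,
                           audio_rate = 44100, min_consecutive = 1) {
  stopifnot(inherits(session, "sardar_imu_session"),
            inherits(activity_model, "sardar_cnn"),
            inherits(bark_model, "sardar_cnn"),
            inherits(stats, "sardar_norm_stats"))
  series <- apply_normalization(compute_magnitude(session), stats)
  n <- nrow(session$data)
  rate <- 1 / diff(session$data$t[1:2])
  w <- as.integer(round(2 * rate))
  s <- as.integer(round(1 * rate))
  nw <- window_count(n, w, s)
  if (nw == 0) stop("session shorter than one window")
  xw <- vapply(seq_len(nw), function(j) {
    a <- (j - 1L) * s + 1L
    rbind(series$accelerometer[a:(a + w - 1L)],
          series$gyroscope[a:(a + w - 1L)])
  }, matrix(0, 2, w))
  stand_prob <- predict(activity_model, xw)
  imu_states <- data.frame(window_start = (seq_len(nw) - 1L) * (s / rate),
                           stand_prob = stand_prob)

  clips <- segment_audio(audio, rate = audio_rate)
  mel <- clips_to_array(clips)
  bark_prob <- predict(bark_model, mel$x)
  audio_states <- data.frame(window_start = mel$start_time,
                             bark_prob = bark_prob)

  aligned <- align_streams(imu_states, audio_states)
  aligned$stand <- aligned$paired & !is.na(aligned$stand_prob) &
    aligned$stand_prob > stand_threshold
  aligned$bark <- aligned$paired & !is.na(aligned$bark_prob) &
    aligned$bark_prob > bark_threshold
  alerts <- raise_alert(aligned, stand_threshold, bark_threshold,
                        min_consecutive)
  structure(list(states = aligned, alerts = alerts,
                 session_id = session$session_id),
            class = "sardar_timeline")
}

#' @export
print.sardar_timeline <- function(x, ...) {
  cat(sprintf("<sardar_timeline> session %s: %d aligned windows, %d alerts\n",
              x$session_id, nrow(x$states), nrow(x$alerts)))
  invisible(x)
}

#' Write a timeline as JSONL events
#'
#' One JSON object per aligned window (timestamp, probabilities, flags), with
#' alert events interleaved as `"event": "victim-found"` records.
#'
#' @param timeline a `sardar_timeline`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_timeline_jsonl <- function(timeline, path) {
  con <- file(path, "w")
  on.exit(close(con))
  st <- timeline$states
  for (i in seq_len(nrow(st))) {
    writeLines(jsonlite::toJSON(list(
      t = st$imu_start[i], stand_prob = st$stand_prob[i],
      bark_prob = st$bark_prob[i], stand = st$stand[i], bark = st$bark[i],
      alert = st$stand[i] && st$bark[i]), auto_unbox = TRUE, digits = NA,
      na = "null"), con)
  }
  invisible(path)
}
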