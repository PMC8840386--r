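# From raw dual-sensor recordings to normalised 2 x 200 activity windows:
# orientation-independent magnitude, training-set z-normalisation, label
# filtering, 2-s / 50%-overlap windowing and the stand-vs-search label merge.

SENSORS <- c("accelerometer", "gyroscope")

#' Orientation-independent magnitude of each sensor
#'
#' For every sample the l2-norm `S(i) = sqrt(sx^2 + sy^2 + sz^2)` of the three
#' axes is computed, per sensor. The magnitude is invariant under any rotation
#' of the device, which removes the (unknown and varying) mounting orientation
#' of the wearable from the signal.
#'
#' @param session a `sardar_imu_session`.
#' @return a `sardar_magnitudes` object: list with numeric vectors
#'   `accelerometer` and `gyroscope` (same length as the session), plus the
#'   session id and times as attributes.
#' @export
compute_magnitude <- function(session) {
  stopifnot(inherits(session, "sardar_imu_session"))
  if (nrow(session$data) == 0) stop("session has no samples")
  d <- session$data
  structure(list(accelerometer = sqrt(d$ax^2 + d$ay^2 + d$az^2),
                 gyroscope = sqrt(d$gx^2 + d$gy^2 + d$gz^2)),
            session_id = session$session_id,
            t = d$t,
            class = "sardar_magnitudes")
}

#' Fit z-normalisation statistics on training data only
#'
#' Pools the magnitude samples of the supplied (training) sessions per sensor
#' and records mean and standard deviation. Statistics must never be fitted on
#' validation or test sessions; the ids of the contributing sessions are kept
#' with the object so downstream code can assert this provenance.
#'
#' @param train_series a `sardar_magnitudes` object or a list of them (one per
#'   training session).
#' @param sd_type `"population"` (divide by N, default) or `"sample"`
#'   (divide by N-1).
#' @return a `sardar_norm_stats` object: per-sensor `mu` and `sigma`, plus the
#'   training session ids.
#' @export
fit_normalization <- function(train_series, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (inherits(train_series, "sardar_magnitudes")) train_series <- list(train_series)
  stopifnot(length(train_series) >= 1,
            all(vapply(train_series, inherits, TRUE, "sardar_magnitudes")))
  stats <- lapply(SENSORS, function(sensor) {
    v <- unlist(lapply(train_series, `[[`, sensor), use.names = FALSE)
    if (length(v) < 2) stop("need at least two training samples per sensor")
    mu <- mean(v)
    sigma <- if (sd_type == "population") {
      sqrt(mean((v - mu)^2))
    } else {
      stats::sd(v)
    }
    if (sigma == 0) {
      stop("constant ", sensor, " magnitude in the training data; ",
           "cannot z-normalise a degenerate series")
    }
    c(mu = mu, sigma = sigma)
  })
  names(stats) <- SENSORS
  structure(list(accelerometer = stats$accelerometer,
                 gyroscope = stats$gyroscope,
                 sessions = vapply(train_series, function(m) {
                   as.character(attr(m, "session_id"))
                 }, ""),
                 sd_type = sd_type),
            class = "sardar_norm_stats")
}

#' @export
print.sardar_norm_stats <- function(x, ...) {
  cat(sprintf("<sardar_norm_stats> (%s sd) fitted on: %s\n", x$sd_type,
              paste(x$sessions, collapse = ", ")))
  for (s in SENSORS) {
    cat(sprintf("  %-14s mu = %.4f, sigma = %.4f\n", s, x[[s]]["mu"], x[[s]]["sigma"]))
  }
  invisible(x)
}

#' Apply fitted z-normalisation to a magnitude series
#'
#' Computes `Z(i) = (S(i) - mu) / sigma` per sensor, with each sensor using its
#' own statistics.
#'
#' @param series a `sardar_magnitudes` object.
#' @param stats a `sardar_norm_stats` from [fit_normalization()].
#' @return a `sardar_magnitudes` object with normalised values.
#' @export
apply_normalization <- function(series, stats) {
  stopifnot(inherits(series, "sardar_magnitudes"),
            inherits(stats, "sardar_norm_stats"))
  out <- series
  for (s in SENSORS) {
    out[[s]] <- (series[[s]] - stats[[s]]["mu"]) / stats[[s]]["sigma"]
  }
  out
}

#' Keep only the segments usable for training
#'
#' Drops segments shorter than `min_duration` (default 2 s; a segment of
#' exactly 2 s is kept, since it still yields one full window) and all
#' segments labelled `missing` (activity unidentifiable on the field video).
#'
#' @param session a `sardar_imu_session`.
#' @param min_duration minimum segment duration in seconds.
#' @return the segments data frame restricted to usable rows.
#' @export
filter_segments <- function(session, min_duration = 2) {
  stopifnot(inherits(session, "sardar_imu_session"))
  segs <- session$segments
  keep <- (segs$end - segs$start >= min_duration) & segs$activity != "missing"
  segs[keep, , drop = FALSE]
}

#' Merge the four field activities into stand vs. search
#'
#' The motion activities walking, trotting and running are merged into one
#' `search` class; `standing` maps to `stand`. Missing labels must be filtered
#' out beforehand and are rejected.
#'
#' @param activity character vector of activities.
#' @return character vector of `"stand"` / `"search"`.
#' @export
merge_labels <- function(activity) {
  if (any(!activity %in% ACTIVITIES)) {
    stop("merge_labels expects standing/walking/trotting/running; got: ",
         paste(setdiff(activity, ACTIVITIES), collapse = ", "))
  }
  ifelse(activity == "standing", "stand", "search")
}

# number of full windows in a segment of n samples (window w, stride s samples)
window_count <- function(n, w = 200L, s = 100L) {
  if (n < w) 0L else (n - w) %/% s + 1L
}

#' Cut one labelled segment into normalised 2-s activity windows
#'
#' Windows are 2 s long (200 samples per sensor at 100 Hz), advance at a 1-s
#' stride (50% overlap), are anchored at the segment start and lie entirely
#' inside the segment; a trailing remainder shorter than one stride is
#' discarded. A segment of duration `d` seconds therefore yields
#' `floor(d - 2) + 1` windows.
#'
#' @param segment one row of a segments data frame (`start`, `end`,
#'   `activity`).
#' @param series a normalised `sardar_magnitudes` object for the whole
#'   session (see [apply_normalization()]).
#' @param rate sampling rate in Hz.
#' @param window,stride window length and stride in seconds.
#' @return list of `sardar_window` objects; each has `Z` (2 x 200 matrix, row
#'   1 accelerometer, row 2 gyroscope), `label` (`stand`/`search`),
#'   `session_id` and `start_time`.
#' @export
extract_windows <- function(segment, series, rate = 100, window = 2, stride = 1) {
  stopifnot(inherits(series, "sardar_magnitudes"))
  w <- as.integer(round(window * rate))
  s <- as.integer(round(stride * rate))
  i0 <- as.integer(round(segment$start * rate)) + 1L
  i1 <- as.integer(round(segment$end * rate))
  n <- i1 - i0 + 1L
  nw <- window_count(n, w, s)
  if (nw == 0L) return(list())
  label <- merge_labels(segment$activity)
  lapply(seq_len(nw), function(j) {
    a <- i0 + (j - 1L) * s
    Z <- rbind(accelerometer = series$accelerometer[a:(a + w - 1L)],
               gyroscope = series$gyroscope[a:(a + w - 1L)])
    structure(list(Z = Z, label = label,
                   session_id = as.character(attr(series, "session_id")),
                   start_time = (a - 1L) / rate),
              class = "sardar_window")
  })
}

#' All usable activity windows of a session
#'
#' Convenience wrapper: filters the segments ([filter_segments()]), normalises
#' the magnitude series with the supplied training statistics and windows
#' every usable segment ([extract_windows()]).
#'
#' @param session a `sardar_imu_session`.
#' @param stats a `sardar_norm_stats` fitted on training sessions.
#' @param rate,window,stride see [extract_windows()].
#' @return list of `sardar_window` objects.
#' @export
session_windows <- function(session, stats, rate = 100, window = 2, stride = 1) {
  series <- apply_normalization(compute_magnitude(session), stats)
  segs <- filter_segments(session, min_duration = window)
  out <- list()
  for (i in seq_len(nrow(segs))) {
    out <- c(out, extract_windows(segs[i, ], series, rate, window, stride))
  }
  out
}

#' Stack a list of activity windows into model inputs
#'
#' @param windows list of `sardar_window` objects.
#' @return list with `x` (2 x 200 x N array), `label` (character), `session_id`
#'   and `start_time` vectors.
#' @export
windows_to_array <- function(windows) {
  stopifnot(length(windows) > 0)
  x <- vapply(windows, function(w) w$Z, matrix(0, 2, ncol(windows[[1]]$Z)))
  list(x = x,
       label = vapply(windows, `[[`, "", "label"),
       session_id = vapply(windows, `[[`, "", "session_id"),
       start_time = vapply(windows, `[[`, 0, "start_time"))
}
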