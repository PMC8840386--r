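# Plain-format plumbing: IMU sessions as CSV + JSONL label tracks, audio as
# 16-bit PCM WAV, dataset manifests as JSON. The WAV codec is written out by
# hand (RIFF/fmt/data chunks) and supports mono/stereo 16- and 24-bit PCM;
# stereo is downmixed by averaging on read.

#' Write / read an IMU session as CSV plus a JSONL label track
#'
#' The CSV has columns `t, ax, ay, az, gx, gy, gz` (seconds and raw sensor
#' units); the label track has one JSON object per line with fields `start`,
#' `end`, `activity`.
#'
#' @param session a `sardar_imu_session`.
#' @param csv_path path of the sample CSV.
#' @param labels_path path of the JSONL segment file; defaults to
#'   `csv_path` with a `.labels.jsonl` extension.
#' @return `write_imu_csv` returns `csv_path` invisibly; `read_imu_csv` the
#'   reconstructed `sardar_imu_session`.
#' @export
write_imu_csv <- function(session, csv_path,
                          labels_path = sub("\\.csv$", ".labels.jsonl", csv_path)) {
  stopifnot(inherits(session, "sardar_imu_session"))
  utils::write.csv(session$data, csv_path, row.names = FALSE)
  con <- file(labels_path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(session$segments))) {
    writeLines(jsonlite::toJSON(as.list(session$segments[i, ]),
                                auto_unbox = TRUE, digits = NA), con)
  }
  invisible(csv_path)
}

#' @rdname write_imu_csv
#' @param session_id identifier for the reconstructed session.
#' @export
read_imu_csv <- function(csv_path,
                         labels_path = sub("\\.csv$", ".labels.jsonl", csv_path),
                         session_id = sub("\\.csv$", "", basename(csv_path))) {
  data <- utils::read.csv(csv_path)
  need <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
  if (!all(need %in% names(data))) {
    stop("IMU CSV must have columns ", paste(need, collapse = ", "))
  }
  segs <- if (file.exists(labels_path)) {
    lines <- readLines(labels_path)
    do.call(rbind, lapply(lines, function(l) {
      as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(start = numeric(0), end = numeric(0), activity = character(0))
  }
  structure(list(session_id = session_id, data = data, segments = segs),
            class = "sardar_imu_session")
}

#' Write / read a waveform as 16-bit PCM WAV
#'
#' Values are clipped to `[-1, 1]` and quantised to 16 bits on write. The
#' reader accepts mono or stereo, 16- or 24-bit PCM; stereo is downmixed by
#' channel averaging.
#'
#' @param wave numeric vector of amplitudes in `[-1, 1]`, or a
#'   `sardar_audio_clip` / `sardar_audio_stream`.
#' @param path file path.
#' @param rate sampling rate in Hz (taken from the object if one is given).
#' @return `write_wav` returns `path` invisibly; `read_wav` a list with
#'   `wave` and `rate`.
#' @export
write_wav <- function(wave, path, rate = 44100) {
  if (inherits(wave, c("sardar_audio_clip", "sardar_audio_stream"))) {
    rate <- wave$rate
    wave <- wave$wave
  }
  stopifnot(is.numeric(wave), length(wave) > 0, rate > 0)
  pcm <- as.integer(round(pmax(-1, pmin(1, wave)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * 2), con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")          # block align
  writeBin(16L, con, size = 2, endian = "little")         # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave_tag <- readChar(con, 4)
  if (!identical(riff, "RIFF") || !identical(wave_tag, "WAVE")) {
    stop("not a RIFF/WAVE file: ", path)
  }
  rate <- NULL; bits <- NULL; channels <- NULL; wave <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (fmt != 1L) stop("only PCM WAV is supported")
      channels <- readBin(con, "integer", 1, size = 2, endian = "little")
      rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
      invisible(readBin(con, "integer", 1, size = 2, endian = "little"))
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (size > 16) invisible(readBin(con, "raw", size - 16))
    } else if (identical(id, "data")) {
      if (is.null(bits)) stop("malformed WAV: data chunk before fmt")
      if (bits == 16) {
        raw <- readBin(con, "integer", size / 2, size = 2, endian = "little")
        wave <- raw / 32767
      } else if (bits == 24) {
        bytes <- readBin(con, "raw", size)
        m <- matrix(as.integer(bytes), nrow = 3)
        val <- m[1, ] + 256L * m[2, ] + 65536L * m[3, ]
        val <- ifelse(val >= 8388608, val - 16777216, val)
        wave <- val / 8388607
      } else {
        stop("only 16- or 24-bit PCM is supported (got ", bits, ")")
      }
      break
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
  }
  if (is.null(wave)) stop("no data chunk found in ", path)
  if (channels > 1) {
    wave <- colMeans(matrix(wave, nrow = channels))
  }
  list(wave = wave, rate = rate)
}

#' Write a dataset to a directory, with a JSON manifest
#'
#' Sessions become `<id>.csv` + `<id>.labels.jsonl`, clips become
#' `clip_<i>.wav`; `manifest.json` records ids, labels, per-clip sessions and
#' the realised class ratio.
#'
#' @param dataset a `sardar_dataset` from [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return the manifest as a list, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sardar_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in dataset$sessions) {
    write_imu_csv(s, file.path(dir, paste0(s$session_id, ".csv")))
  }
  labs <- vapply(dataset$clips, `[[`, "", "label")
  for (i in seq_along(dataset$clips)) {
    write_wav(dataset$clips[[i]], file.path(dir, sprintf("clip_%04d.wav", i)))
  }
  manifest <- list(
    sessions = vapply(dataset$sessions, `[[`, "", "session_id"),
    clips = data.frame(file = sprintf("clip_%04d.wav", seq_along(dataset$clips)),
                       label = labs,
                       session_id = vapply(dataset$clips, `[[`, "", "session_id"),
                       stringsAsFactors = FALSE),
    not_bark_to_bark = sum(labs == "not_bark") / max(1, sum(labs == "bark")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(manifest)
}
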