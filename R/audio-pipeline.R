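# Audio front end: peak normalisation, 2-s / 50%-overlap stream segmentation,
# silence filtering, and log-scaled mel-spectrograms (centered STFT, window
# 1024, hop 512, 128 mel bands; a 2-s clip at 44.1 kHz gives 173 frames).

#' Peak-normalise an audio clip
#'
#' Divides every sample by the maximum absolute value in the clip, so the peak
#' magnitude becomes exactly 1 (dividing by the signed maximum could flip
#' polarity, so the absolute value is used). Idempotent.
#'
#' @param clip a `sardar_audio_clip`, or a numeric waveform.
#' @return same type as the input, normalised.
#' @export
normalize_clip <- function(clip) {
  wave <- if (inherits(clip, "sardar_audio_clip")) clip$wave else clip
  if (length(wave) == 0) stop("empty clip")
  peak <- max(abs(wave))
  if (peak == 0) {
    stop("all-zero clip: peak normalisation is undefined (silent or corrupt input)")
  }
  wave <- wave / peak
  if (inherits(clip, "sardar_audio_clip")) {
    clip$wave <- wave
    clip
  } else {
    wave
  }
}

# mel scale (HTK convention) and its inverse
hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Triangular mel filterbank
#'
#' `n_mels` area-normalised triangular filters spanning 0 Hz to Nyquist, with
#' band edges equally spaced on the (HTK) mel scale. Each filter is scaled by
#' `2 / (f_high - f_low)` so its area is independent of bandwidth.
#'
#' @param n_mels number of mel bands.
#' @param n_fft FFT size (the filterbank covers `n_fft/2 + 1` bins).
#' @param rate sampling rate in Hz.
#' @return `(n_fft/2 + 1) x n_mels` matrix of filter weights.
#' @export
mel_filterbank <- function(n_mels = 128, n_fft = 1024, rate = 44100) {
  n_bins <- n_fft / 2 + 1
  freqs <- (0:(n_bins - 1)) * rate / n_fft
  edges <- mel_to_hz(seq(hz_to_mel(0), hz_to_mel(rate / 2), length.out = n_mels + 2))
  fb <- matrix(0, n_bins, n_mels)
  for (m in seq_len(n_mels)) {
    lo <- edges[m]; ce <- edges[m + 1]; hi <- edges[m + 2]
    up <- (freqs - lo) / (ce - lo)
    down <- (hi - freqs) / (hi - ce)
    fb[, m] <- pmax(0, pmin(up, down)) * 2 / (hi - lo)
  }
  fb
}

#' Log-scaled mel-spectrogram of a 2-s clip
#'
#' Centered (reflection-padded) short-time Fourier transform with a periodic
#' Hann window, power spectrum, projection onto the [mel_filterbank()], and
#' `log(power + 1e-10)` scaling. The frame count is `1 + floor(n / hop)`;
#' at the 44.1 kHz default a 2-s clip yields exactly 173 frames x 128 bands.
#'
#' @param clip a `sardar_audio_clip` (normalise it first) or numeric waveform.
#' @param window STFT window size in samples.
#' @param hop hop length in samples.
#' @param n_mels number of mel bands.
#' @param rate sampling rate (taken from the clip object if given).
#' @param floor_eps additive floor before the log.
#' @return a `sardar_melspec`: frames x mel-bands matrix of log power.
#' @export
compute_logmel <- function(clip, window = 1024, hop = 512, n_mels = 128,
                           rate = 44100, floor_eps = 1e-10) {
  wave <- clip
  if (inherits(clip, "sardar_audio_clip")) {
    rate <- clip$rate
    wave <- clip$wave
  }
  n <- length(wave)
  if (n < hop) stop("clip shorter than one hop length")
  half <- window %/% 2
  # reflection padding centres the first frame on sample 1
  padded <- c(rev(wave[2:(half + 1)]), wave, rev(wave[(n - half):(n - 1)]))
  n_frames <- 1L + n %/% hop
  starts <- (seq_len(n_frames) - 1L) * hop + 1L
  frames <- vapply(starts, function(s) padded[s:(s + window - 1L)],
                   numeric(window))
  hann <- 0.5 - 0.5 * cos(2 * pi * (0:(window - 1)) / window)
  spec <- stats::mvfft(frames * hann)
  power <- Mod(spec[1:(window %/% 2 + 1), , drop = FALSE])^2
  fb <- mel_filterbank(n_mels, window, rate)
  mel <- crossprod(power, fb)            # frames x mel bands
  structure(log(mel + floor_eps),
            rate = rate, window = window, hop = hop,
            class = c("sardar_melspec", "matrix", "array"))
}

#' Cut an audio stream into 2-s clips with 50% overlap
#'
#' Same counting rule as the IMU windows: clips advance at a 1-s stride and a
#' trailing remainder is discarded, so a stream of `d` seconds yields
#' `floor(d - 2) + 1` clips.
#'
#' @param stream a `sardar_audio_stream`, or a numeric waveform.
#' @param rate sampling rate (taken from the object if given).
#' @param window clip length in seconds.
#' @param overlap fractional overlap between consecutive clips, in `[0, 1)`.
#' @return list of `sardar_audio_clip` objects (labels unset), with
#'   `start_time` filled in.
#' @export
segment_audio <- function(stream, rate = 44100, window = 2, overlap = 0.5) {
  session_id <- NA_character_
  wave <- stream
  if (inherits(stream, "sardar_audio_stream")) {
    rate <- stream$rate
    session_id <- stream$session_id
    wave <- stream$wave
  }
  stopifnot(overlap >= 0, overlap < 1)
  w <- as.integer(round(window * rate))
  s <- as.integer(round(window * (1 - overlap) * rate))
  if (length(wave) < w) stop("stream shorter than one window")
  nw <- window_count(length(wave), w, s)
  lapply(seq_len(nw), function(j) {
    a <- (j - 1L) * s + 1L
    structure(list(wave = wave[a:(a + w - 1L)], rate = rate,
                   label = NA_character_, session_id = session_id,
                   start_time = (a - 1L) / rate),
              class = "sardar_audio_clip")
  })
}

#' Drop near-silent clips
#'
#' Clips whose root-mean-square amplitude (measured on the raw,
#' pre-normalisation waveform) falls below `rms_threshold` are removed; they
#' inflate the not-bark class without informing the model.
#'
#' @param clips list of `sardar_audio_clip` objects.
#' @param rms_threshold RMS threshold on raw amplitude (>= 0).
#' @return the surviving clips, with the number removed in attribute
#'   `n_discarded`.
#' @export
discard_silence <- function(clips, rms_threshold = 0.01) {
  stopifnot(rms_threshold >= 0)
  rms <- vapply(clips, function(cl) sqrt(mean(cl$wave^2)), 0)
  keep <- rms >= rms_threshold | (rms_threshold == 0)
  structure(clips[keep], n_discarded = sum(!keep))
}

#' Stack clip spectrograms into model inputs
#'
#' @param clips list of `sardar_audio_clip` objects (normalised internally).
#' @param ... passed to [compute_logmel()].
#' @return list with `x` (frames x bands x N array), `label`, `session_id`,
#'   `start_time`.
#' @export
clips_to_array <- function(clips, ...) {
  stopifnot(length(clips) > 0)
  mels <- lapply(clips, function(cl) compute_logmel(normalize_clip(cl), ...))
  x <- vapply(mels, identity, matrix(0, nrow(mels[[1]]), ncol(mels[[1]])))
  list(x = x,
       label = vapply(clips, `[[`, "", "label"),
       session_id = vapply(clips, `[[`, "", "session_id"),
       start_time = vapply(clips, `[[`, 0, "start_time"))
}
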