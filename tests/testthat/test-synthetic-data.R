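# The synthetic-data generators: seeded determinism, schedule bookkeeping,
# the activity-intensity variance ordering, bark band energy, and dataset
# composition.

test_that("schedules and parameters are validated", {
  expect_error(activity_schedule(character(0), numeric(0)), "non-empty")
  expect_error(activity_schedule("flying", 5), "unknown activity")
  expect_error(activity_schedule("walking", -1), "positive")
  expect_error(activity_schedule("standing", 1.5), "at least 2 s")
  expect_error(synthesis_params(class_imbalance = 0.5), "class_imbalance")
  expect_error(synthesis_params(amplitudes_acc = c(standing = 2, walking = 1,
                                                   trotting = 3, running = 4)),
               "ordered")
})

test_that("IMU sessions are deterministic and consistent with their schedule", {
  sch <- activity_schedule(c("standing", "walking"), c(10, 4))
  p <- synthesis_params()
  s1 <- generate_imu_session(sch, p, seed = 21)
  s2 <- generate_imu_session(sch, p, seed = 21)
  expect_identical(s1, s2)                       # bit-identical repeat
  s3 <- generate_imu_session(sch, p, seed = 22)
  expect_false(identical(s1$data, s3$data))
  expect_identical(nrow(s1$data), 1400L)         # 14 s x 100 Hz
  sole <- generate_imu_session(activity_schedule("standing", 10), p, seed = 1)
  expect_identical(nrow(sole$data), 1000L)       # 10 s x 100 Hz
  # label track partitions the sample range exactly
  expect_equal(s1$segments$start, c(0, 10))
  expect_equal(s1$segments$end, c(10, 14))
  samples_per_segment <- round((s1$segments$end - s1$segments$start) * 100)
  expect_equal(sum(samples_per_segment), nrow(s1$data))
})

test_that("magnitude variance respects the activity-intensity ordering", {
  p <- synthesis_params()
  sch <- activity_schedule(c("standing", "walking", "trotting", "running"),
                           c(4, 4, 4, 4))
  for (seed in 1:50) {
    ses <- generate_imu_session(sch, p, seed = seed)
    mag <- compute_magnitude(ses)
    vars <- vapply(1:4, function(i) {
      idx <- ((i - 1) * 400 + 1):(i * 400)
      c(stats::var(mag$accelerometer[idx]), stats::var(mag$gyroscope[idx]))
    }, numeric(2))
    expect_true(all(diff(vars[1, ]) > 0), info = paste("acc seed", seed))
    expect_true(all(diff(vars[2, ]) > 0), info = paste("gyr seed", seed))
  }
})

test_that("audio clips are deterministic with the stated length", {
  p <- synthesis_params()
  c1 <- generate_audio_clip("bark", p, seed = 5)
  c2 <- generate_audio_clip("bark", p, seed = 5)
  expect_identical(c1$wave, c2$wave)
  expect_identical(length(c1$wave), 88200L)      # 2 s x 44100 Hz
  expect_lte(max(abs(c1$wave)), 1)
})

test_that("bark clips concentrate energy in the fundamental band", {
  p <- synthesis_params()
  band_energy <- function(wave, rate, lo, hi) {
    spec <- abs(stats::fft(wave))^2
    freqs <- (seq_along(wave) - 1) * rate / length(wave)
    sum(spec[freqs >= lo & freqs <= hi])         # direct DFT oracle
  }
  for (seed in c(1, 9, 17)) {
    bark <- generate_audio_clip("bark", p, seed = seed)
    noise <- generate_audio_clip("not_bark", p, seed = seed)
    eb <- band_energy(bark$wave, bark$rate, 400, 900)
    en <- band_energy(noise$wave, noise$rate, 400, 900)
    expect_gt(eb, en)
  }
})

test_that("datasets have distinct session ids and the configured imbalance", {
  p <- synthesis_params()
  ds <- fixture("ds7", function() generate_dataset(7, p, seed = 3,
                                                   clips_per_session = 14))
  ids <- vapply(ds$sessions, `[[`, "", "session_id")
  expect_identical(length(unique(ids)), 7L)
  labs <- vapply(ds$clips, `[[`, "", "label")
  ratio <- sum(labs == "not_bark") / sum(labs == "bark")
  expect_lt(abs(ratio - p$class_imbalance) / p$class_imbalance, 0.10)
  # clips carry session tags covering all sessions
  expect_setequal(unique(vapply(ds$clips, `[[`, "", "session_id")), ids)
  expect_error(generate_dataset(2, p), "at least 3")
})

test_that("session audio places barks only inside the requested intervals", {
  p <- synthesis_params()
  ses <- test_session()
  iv <- data.frame(start = 24, end = 28)
  aud <- generate_session_audio(ses, iv, p, seed = 4)
  expect_identical(length(aud$wave),
                   as.integer(round(nrow(ses$data) / 100 * 44100)))
  band_energy <- function(w) {
    spec <- abs(stats::fft(w))^2
    freqs <- (seq_along(w) - 1) * 44100 / length(w)
    sum(spec[freqs >= 400 & freqs <= 900]) / sum(spec[freqs > 0 & freqs <= 22050])
  }
  inside <- aud$wave[(24 * 44100):(28 * 44100)]
  outside <- aud$wave[(8 * 44100):(12 * 44100)]
  expect_gt(band_energy(inside), 5 * band_energy(outside))
})
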