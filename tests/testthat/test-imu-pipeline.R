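# IMU preprocessing: magnitude, z-normalisation, segment filtering, window
# extraction and the label merge, each against an independent oracle where one
# exists.

make_session <- function(df, segments = NULL, id = "X") {
  if (is.null(segments)) {
    segments <- data.frame(start = 0, end = nrow(df) / 100,
                           activity = "standing")
  }
  structure(list(session_id = id, data = df, segments = segments),
            class = "sardar_imu_session")
}

test_that("magnitude reproduces Pythagorean triples and the zero vector", {
  df <- data.frame(t = c(0, 0.01, 0.02),
                   ax = c(3, 0, 1), ay = c(4, 0, 2), az = c(0, 0, 2),
                   gx = c(1, 2, 0), gy = c(2, 3, 0), gz = c(2, 6, 0))
  m <- compute_magnitude(make_session(df))
  expect_equal(m$accelerometer, c(5, 0, 3))
  expect_equal(m$gyroscope, c(3, 7, 0))
})

test_that("magnitude is invariant under 3-D rotations", {
  set.seed(31)
  for (rep in 1:20) {
    R <- qr.Q(qr(matrix(rnorm(9), 3)))          # random orthogonal matrix
    xyz <- matrix(rnorm(300), ncol = 3)
    rot <- xyz %*% t(R)
    df1 <- data.frame(t = (0:99) / 100, ax = xyz[, 1], ay = xyz[, 2],
                      az = xyz[, 3], gx = rot[, 1], gy = rot[, 2], gz = rot[, 3])
    m <- compute_magnitude(make_session(df1))
    expect_equal(m$accelerometer, m$gyroscope, tolerance = 1e-9)
  }
})

test_that("normalisation statistics behave per the defining algebra", {
  mk <- function(acc, gyr, id = "A") {
    structure(list(accelerometer = acc, gyroscope = gyr),
              session_id = id, class = "sardar_magnitudes")
  }
  st <- fit_normalization(mk(c(1, 3), c(1, 3)))
  expect_equal(unname(st$accelerometer), c(2, 1))   # population convention
  z <- apply_normalization(mk(c(1, 3), c(1, 3)), st)
  expect_equal(z$accelerometer, c(-1, 1))
  # applying fitted stats to their own training series standardises it
  set.seed(32)
  m <- mk(rnorm(500, 5, 2), runif(500))
  st2 <- fit_normalization(m)
  z2 <- apply_normalization(m, st2)
  expect_equal(mean(z2$accelerometer), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(z2$accelerometer^2)), 1, tolerance = 1e-9)
  # constant series S = mu maps to all zeros under external stats
  z3 <- apply_normalization(mk(rep(2, 10), rep(0.5, 10)), st)
  expect_equal(z3$accelerometer, rep(0, 10))
  # identity stats leave the series unchanged
  st_id <- st
  st_id$accelerometer <- c(mu = 0, sigma = 1)
  expect_equal(apply_normalization(m, st_id)$accelerometer, m$accelerometer)
  # round trip recovers S
  back <- z2$accelerometer * st2$accelerometer["sigma"] + st2$accelerometer["mu"]
  expect_equal(unname(back), m$accelerometer, tolerance = 1e-9)
  # degenerate constant training series is rejected
  expect_error(fit_normalization(mk(rep(1, 10), rnorm(10))), "degenerate")
})

test_that("training-fold statistics differ from full-data statistics", {
  s1 <- test_session(seed = 7)
  s2 <- generate_imu_session(activity_schedule(c("running", "standing"), c(6, 6)),
                             synthesis_params(), "T2", seed = 8)
  m1 <- compute_magnitude(s1); m2 <- compute_magnitude(s2)
  st_train <- fit_normalization(list(m1))
  st_full <- fit_normalization(list(m1, m2))
  expect_false(isTRUE(all.equal(st_train$accelerometer, st_full$accelerometer)))
  expect_identical(st_train$sessions, "T1")       # provenance records the fold
})

test_that("segment filtering drops short and missing segments", {
  segs <- data.frame(start = c(0, 2, 10, 13),
                     end = c(1.9, 10, 13, 15),
                     activity = c("standing", "walking", "missing", "walking"))
  ses <- make_session(data.frame(t = (0:1499) / 100, ax = 0, ay = 0, az = 1,
                                 gx = 0, gy = 0, gz = 0), segs)
  kept <- filter_segments(ses)
  expect_equal(nrow(kept), 2)                    # 1.9 s and missing dropped
  expect_equal(kept$activity, c("walking", "walking"))
  expect_equal(kept$end[2] - kept$start[2], 2)   # exactly 2.0 s is kept
})

test_that("label merge maps motion to search and rejects missing", {
  expect_identical(merge_labels(c("trotting", "standing", "running", "walking")),
                   c("search", "stand", "search", "search"))
  expect_error(merge_labels("missing"), "missing")
})

test_that("window counts equal brute-force start enumeration", {
  set.seed(33)
  for (rep in 1:1000) {
    n <- sample(1:2000, 1)
    brute <- 0L
    a <- 1L
    while (a + 200L - 1L <= n) {
      brute <- brute + 1L
      a <- a + 100L
    }
    expect_identical(sardar:::window_count(n), brute)
  }
  # the documented closed forms: 2 s -> 1, 2.5 s -> 1, 6 s -> 5 windows
  expect_identical(sardar:::window_count(200L), 1L)
  expect_identical(sardar:::window_count(250L), 1L)
  expect_identical(sardar:::window_count(600L), 5L)
})

test_that("extracted windows stay inside one segment and match the series", {
  ses <- test_session(seed = 7)
  mags <- compute_magnitude(ses)
  st <- fit_normalization(mags)
  wins <- session_windows(ses, st)
  series <- apply_normalization(mags, st)
  usable <- filter_segments(ses)
  for (w in wins) {
    expect_identical(dim(w$Z), c(2L, 200L))
    expect_identical(rownames(w$Z), c("accelerometer", "gyroscope"))
    inside <- usable$start <= w$start_time + 1e-9 &
      usable$end >= w$start_time + 2 - 1e-9
    expect_true(any(inside))                     # fully within one segment
    seg <- usable[which(inside)[1], ]
    expect_identical(w$label, merge_labels(seg$activity))
    i0 <- round(w$start_time * 100) + 1
    expect_equal(unname(w$Z[1, ]), series$accelerometer[i0:(i0 + 199)])
    expect_equal(unname(w$Z[2, ]), series$gyroscope[i0:(i0 + 199)])
  }
  # per-segment counts follow floor(duration - 2) + 1
  expected <- sum(floor(usable$end - usable$start - 2) + 1)
  expect_identical(length(wins), as.integer(expected))
})
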