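# Shared fixtures, built in code and memoised for the session.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# a short labelled session covering all four activities plus a missing stretch
test_session <- function(seed = 7) {
  fixture(paste0("session", seed), function() {
    sch <- activity_schedule(
      c("running", "trotting", "missing", "walking", "standing"),
      c(5, 8, 3, 6, 7))
    generate_imu_session(sch, synthesis_params(), session_id = "T1", seed = seed)
  })
}

# a tiny architecture exercising every layer kind; cheap to train
tiny_arch <- function() {
  architecture_spec("tiny", c(4L, 24L, 1L), list(
    layer_spec("conv2d", kh = 2, kw = 3, out_ch = 4),
    layer_spec("activation", fun = "relu"),
    layer_spec("maxpool", kh = 1, kw = 2),
    layer_spec("dropout", rate = 0.2),
    layer_spec("conv2d", kh = 2, kw = 3, out_ch = 6),
    layer_spec("activation", fun = "relu"),
    layer_spec("global_maxpool"),
    layer_spec("dense", units = 1),
    layer_spec("activation", fun = "sigmoid")))
}

# linearly separable two-class inputs for the tiny architecture: class 1 has a
# strong positive blob in the upper-left corner, class 0 in the lower-right
tiny_separable <- function(n, seed) {
  set.seed(seed)
  x <- array(stats::rnorm(4 * 24 * n, sd = 0.3), dim = c(4, 24, n))
  y <- rep(c(0, 1), length.out = n)
  for (i in seq_len(n)) {
    if (y[i] == 1) x[1:2, 1:6, i] <- x[1:2, 1:6, i] + 2
    else x[3:4, 19:24, i] <- x[3:4, 19:24, i] + 2
  }
  list(x = x, y = y)
}

# brute-force valid 2-D convolution + bias (single sample), channels-last
oracle_conv2d <- function(x, W, b) {
  # x: (H, W, C) array; W: (kh*kw*C, c_out) matrix in h-fastest patch order
  H <- dim(x)[1]; Wd <- dim(x)[2]; C <- dim(x)[3]
  co <- ncol(W)
  # infer kernel size from an attribute set by the caller
  kh <- attr(W, "kh"); kw <- attr(W, "kw")
  H2 <- H - kh + 1; W2 <- Wd - kw + 1
  out <- array(0, c(H2, W2, co))
  for (c_out in seq_len(co)) {
    for (i in seq_len(H2)) for (j in seq_len(W2)) {
      patch <- x[i:(i + kh - 1), j:(j + kw - 1), , drop = FALSE]
      out[i, j, c_out] <- sum(as.vector(patch) * W[, c_out]) + b[c_out]
    }
  }
  out
}
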