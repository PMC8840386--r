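# The two behaviour-recognition architectures, the training protocol contract, and
# serialisation.

test_that("both architectures realise their reference parameter budgets", {
  bark <- build_bark_cnn()
  expect_identical(count_parameters(bark), 10617L)
  act <- build_activity_cnn()
  expect_identical(count_parameters(act), 21401L)   # quoted as around 21,400
  # per-layer closed form: conv (kh*kw*c_in + 1) * c_out, dense (fan_in + 1)
  expect_identical((3 * 3 * 1 + 1) * 16 + (3 * 3 * 16 + 1) * 24 +
                   (3 * 3 * 24 + 1) * 32 + (32 + 1) * 1, 10617)
  expect_identical((1 * 11 * 1 + 1) * 16 + (1 * 11 * 16 + 1) * 24 +
                   (2 * 11 * 24 + 1) * 32 + (32 + 1) * 1, 21401)
})

test_that("architectures chain to the documented feature-map shapes", {
  act <- build_activity_cnn()
  expect_equal(act$input_shape, c(2L, 200L, 1L))
  # late fusion: kernel height 2 = number of sensor rows at the third conv
  conv3 <- act$layers[[9]]
  expect_equal(c(conv3$kh, conv3$kw, conv3$out_ch), c(2, 11, 32))
  expect_equal(act$in_shapes[[9]][1], 2L)  # both sensor rows still separate
  bark <- build_bark_cnn()
  expect_equal(bark$input_shape, c(173L, 128L, 1L))
  expect_equal(bark$out_shapes[[1]], c(171L, 126L, 16L))
  expect_equal(bark$out_shapes[[3]], c(85L, 63L, 16L))
  expect_equal(tail(bark$out_shapes, 1)[[1]], 1L)   # single sigmoid output
})

test_that("activity layers 1-2 are sensor-local (late fusion)", {
  arch <- build_activity_cnn()
  plans <- sardar:::build_plans(arch)
  set.seed(42)
  w <- sardar:::init_weights(arch)
  base <- matrix(rnorm(400), nrow = 1)
  x1 <- matrix(base, ncol = 1)
  x2 <- x1
  x2[seq(2, 400, by = 2)] <- rnorm(200)  # rewrite the gyroscope row only
  # feature maps after layer 2's pool, before the fusing (2, 11) convolution
  partial <- function(xm) {
    sub <- architecture_spec("head", c(2L, 200L, 1L), arch$layers[1:7])
    sardar:::nn_forward(sub, w[1:7], sardar:::build_plans(sub), xm)$out
  }
  f1 <- partial(x1)
  f2 <- partial(x2)
  # row 1 (accelerometer) positions of each feature map are untouched by row 2
  # (H, W, C) = (2, 18, 24) entering the fusing conv, stored h-fastest
  d1 <- array(as.numeric(f1), c(2, 18, 24))
  d2 <- array(as.numeric(f2), c(2, 18, 24))
  expect_equal(d1[1, , ], d2[1, , ])
  expect_false(isTRUE(all.equal(d1[2, , ], d2[2, , ])))
})

test_that("trainer honours the stopping and checkpoint contract", {
  dat <- tiny_separable(40, seed = 5)
  val <- tiny_separable(20, seed = 6)
  cfg <- training_config(min_epochs = 12, patience = 5, batch_size = 8, seed = 3)
  m <- train_cnn(tiny_arch(), dat$x, dat$y, val$x, val$y, cfg)
  h <- m$history
  expect_gte(m$stopped_epoch, cfg$min_epochs)
  expect_identical(nrow(h), m$stopped_epoch)
  # checkpoint sits at the minimum validation error; among ties, the lowest
  # validation loss, then the earliest epoch
  verr <- 1 - h$val_acc
  expect_equal(verr[m$checkpoint_epoch], min(verr))
  at_min <- which(verr == min(verr))
  expect_equal(h$val_loss[m$checkpoint_epoch], min(h$val_loss[at_min]))
  # optimisation makes progress on separable data
  expect_lt(mean(tail(h$train_loss, 3)), mean(head(h$train_loss, 3)))
  # stopping: the monitor (train accuracy) did not improve in the last
  # `patience` epochs relative to its best before them
  best_before <- max(h$train_acc[1:(m$stopped_epoch - cfg$patience)])
  expect_true(all(h$train_acc[(m$stopped_epoch - cfg$patience + 1):m$stopped_epoch]
                  <= best_before))
})

test_that("trainer rejects degenerate inputs", {
  dat <- tiny_separable(10, seed = 1)
  cfg <- training_config(min_epochs = 2, patience = 2, seed = 1)
  expect_error(train_cnn(tiny_arch(), dat$x, rep(1, 10), dat$x, dat$y, cfg),
               "single class")
  expect_error(train_cnn(tiny_arch(), dat$x, dat$y[1:5], dat$x, dat$y, cfg),
               "label count")
})

test_that("prediction is deterministic and classification follows the tie rule", {
  dat <- tiny_separable(30, seed = 7)
  val <- tiny_separable(10, seed = 8)
  cfg <- training_config(min_epochs = 8, patience = 4, batch_size = 8, seed = 2)
  m <- train_cnn(tiny_arch(), dat$x, dat$y, val$x, val$y, cfg)
  p1 <- predict(m, val$x)
  p2 <- predict(m, val$x)
  expect_identical(p1, p2)          # dropout inactive at inference
  expect_true(all(p1 >= 0 & p1 <= 1))
  # ties go to the negative class; classification is monotone in probability
  expect_identical(classify(c(0.5, 0.5000001), 0.5), c("negative", "positive"))
  probs <- sort(runif(20))
  cls <- classify(probs, 0.5)
  expect_true(all(diff(cls == "positive") >= 0))
})

test_that("serialisation round-trips weights and predictions exactly", {
  dat <- tiny_separable(20, seed = 9)
  val <- tiny_separable(10, seed = 10)
  cfg <- training_config(min_epochs = 5, patience = 3, batch_size = 8, seed = 4)
  m <- train_cnn(tiny_arch(), dat$x, dat$y, val$x, val$y, cfg)
  path <- tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(count_parameters(m2$arch), count_parameters(m$arch))
  expect_equal(predict(m2, val$x), predict(m, val$x), tolerance = 1e-7)
  unlink(path)
})

test_that("training is reproducible for a fixed seed", {
  dat <- tiny_separable(20, seed = 11)
  val <- tiny_separable(10, seed = 12)
  cfg <- training_config(min_epochs = 5, patience = 3, batch_size = 8, seed = 99)
  m1 <- train_cnn(tiny_arch(), dat$x, dat$y, val$x, val$y, cfg)
  m2 <- train_cnn(tiny_arch(), dat$x, dat$y, val$x, val$y, cfg)
  expect_identical(m1$history, m2$history)
  expect_equal(predict(m1, val$x), predict(m2, val$x))
})
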