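# Session-wise folds, confusion accounting and metric arithmetic, each
# checked against brute-force tallies.

test_that("seven sessions give seven rotating folds of 5 + 1 + 1", {
  ids <- sprintf("S%d", 1:7)
  plan <- make_session_folds(ids)
  expect_length(plan, 7)
  for (j in seq_along(plan)) {
    f <- plan[[j]]
    expect_length(f$train, 5)
    expect_length(f$val, 1)
    expect_length(f$test, 1)
    expect_length(intersect(f$train, c(f$val, f$test)), 0)
    expect_setequal(c(f$train, f$val, f$test), ids)
  }
  expect_setequal(vapply(plan, `[[`, "", "test"), ids)  # each tested once
  expect_identical(plan[[7]]$val, "S1")                 # circular rotation
})

test_that("three sessions give minimal 1 + 1 + 1 folds; fewer are rejected", {
  plan <- make_session_folds(c("a", "b", "c"))
  expect_length(plan, 3)
  expect_length(plan[[1]]$train, 1)
  expect_error(make_session_folds(c("a", "b")), "at least 3")
  expect_error(make_session_folds(c("a", "a", "b")), "unique")
})

test_that("confusion counts cross-tabulate correctly", {
  perfect <- compute_confusion(c("a", "b", "a"), c("a", "b", "a"), "a")
  expect_equal(perfect$FP + perfect$FN, 0)
  # the field-validation composition: 57 true barks all found, 2 of 813
  # not-bark windows false-alarmed
  preds <- c(rep("bark", 57), rep("bark", 2), rep("not_bark", 811))
  labs <- c(rep("bark", 57), rep("not_bark", 813))
  cm <- compute_confusion(preds, labs, "bark")
  expect_equal(unlist(cm[c("TP", "FP", "FN", "TN")]),
               c(TP = 57, FP = 2, FN = 0, TN = 811))
  expect_equal(cm$total, 870)
  # swapping the positive class transposes the matrix
  cm2 <- compute_confusion(preds, labs, "not_bark")
  expect_equal(unlist(cm2[c("TP", "FP", "FN", "TN")]),
               c(TP = 811, FP = 0, FN = 2, TN = 57))
  expect_error(compute_confusion("a", c("a", "b"), "a"), "equal length")
})

test_that("confusion totals are conserved on random prediction vectors", {
  set.seed(61)
  for (rep in 1:50) {
    n <- sample(1:500, 1)
    preds <- sample(c("p", "n"), n, replace = TRUE)
    labs <- sample(c("p", "n"), n, replace = TRUE)
    cm <- compute_confusion(preds, labs, "p")
    expect_identical(cm$TP + cm$FP + cm$FN + cm$TN, as.integer(n))
  }
})

test_that("metric arithmetic reproduces the field-validation numbers", {
  cm <- structure(list(TP = 57, FP = 2, FN = 0, TN = 811, positive = "bark",
                       total = 870), class = "sardar_confusion")
  met <- compute_metrics(cm)
  expect_equal(met$accuracy, 99.77, tolerance = 1e-4)
  expect_equal(met$macro_f1, 99.08, tolerance = 1e-4)
  # macro is the convention that matches: the positive-class-only F1 differs
  expect_equal(met$positive_f1, 98.28, tolerance = 1e-4)
  # balanced half-wrong predictions give 50%; a perfect matrix gives 100/100
  half <- structure(list(TP = 5, FP = 5, FN = 5, TN = 5, positive = "p",
                         total = 20), class = "sardar_confusion")
  expect_equal(compute_metrics(half)$accuracy, 50)
  perfect <- structure(list(TP = 7, FP = 0, FN = 0, TN = 3, positive = "p",
                            total = 10), class = "sardar_confusion")
  expect_equal(compute_metrics(perfect)$accuracy, 100)
  expect_equal(compute_metrics(perfect)$macro_f1, 100)
  # zero-support class is flagged and scored 0
  zs <- compute_confusion(rep("n", 5), rep("n", 5), "p")
  expect_true(compute_metrics(zs)$zero_support)
})

test_that("metrics agree with a per-example tally on random vectors", {
  set.seed(62)
  for (rep in 1:1000) {
    n <- sample(2:200, 1)
    labs <- sample(c("p", "n"), n, replace = TRUE)
    preds <- sample(c("p", "n"), n, replace = TRUE)
    met <- compute_metrics(compute_confusion(preds, labs, "p"))
    # oracle: accuracy by direct comparison; F1 per class from first principles
    acc <- 100 * mean(preds == labs)
    f1c <- vapply(c("p", "n"), function(cl) {
      tp <- sum(preds == cl & labs == cl)
      if (2 * tp + sum(preds == cl & labs != cl) + sum(preds != cl & labs == cl) == 0) {
        return(0)
      }
      2 * tp / (2 * tp + sum(preds == cl & labs != cl) + sum(preds != cl & labs == cl))
    }, 0)
    expect_equal(met$accuracy, acc, tolerance = 1e-9)
    expect_equal(met$macro_f1, 100 * mean(f1c), tolerance = 1e-9)
  }
})

test_that("run_experiment aggregates per fold then across folds", {
  plan <- make_session_folds(c("s1", "s2", "s3", "s4"))
  # deterministic stub classifier whose accuracy depends on fold and seed
  fit_predict <- function(fold, seed) {
    n <- 20
    labs <- rep(c("p", "n"), each = n / 2)
    wrong <- (as.integer(sub("s", "", fold$test)) + seed) %% 5
    preds <- labs
    if (wrong > 0) preds[seq_len(wrong)] <- "n"
    list(predictions = preds, labels = labs, positive = "p")
  }
  exp <- run_experiment(fit_predict, plan, n_runs = 3, seeds = c(2, 5, 8))
  expect_identical(nrow(exp$results), 12L)       # n_folds x n_runs rows
  # grand mean equals the mean of per-fold means (equal-weight convention)
  fm <- tapply(exp$results$accuracy, exp$results$fold, mean)
  expect_equal(exp$grand_mean$accuracy, mean(fm))
  expect_equal(sort(exp$fold_means$accuracy), sort(as.numeric(fm)))
  # identical seeds would not be distinct
  expect_error(run_experiment(fit_predict, plan, n_runs = 2, seeds = c(1, 1)),
               "anyDuplicated")
  # the same seed vector reproduces identical rows
  exp2 <- run_experiment(fit_predict, plan, n_runs = 3, seeds = c(2, 5, 8))
  expect_identical(exp$results, exp2$results)
})
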