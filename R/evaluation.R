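# Session-wise (leave-one-session-out) cross-validation with circular
# rotation, confusion matrices, accuracy / macro-F1 metrics, and repeated-run
# averaging.

#' Build a leave-one-session-out fold plan by circular rotation
#'
#' With `n` sessions the plan has `n` folds: fold `j` tests session `j`,
#' validates the next session in circular order, and trains on the remaining
#' `n - 2`. Every session appears exactly once as the test set, and within a
#' fold the three roles are disjoint.
#'
#' @param session_ids character vector of session identifiers (>= 3).
#' @return a `sardar_fold_plan`: list of `list(train, val, test)`.
#' @export
make_session_folds <- function(session_ids) {
  session_ids <- as.character(session_ids)
  n <- length(session_ids)
  if (n < 3) stop("need at least 3 sessions for train/validation/test folds")
  if (anyDuplicated(session_ids)) stop("session ids must be unique")
  folds <- lapply(seq_len(n), function(j) {
    test <- session_ids[j]
    val <- session_ids[j %% n + 1L]
    list(train = setdiff(session_ids, c(test, val)), val = val, test = test)
  })
  structure(folds, session_ids = session_ids, class = "sardar_fold_plan")
}

#' @export
print.sardar_fold_plan <- function(x, ...) {
  cat(sprintf("<sardar_fold_plan> %d folds over sessions: %s\n", length(x),
              paste(attr(x, "session_ids"), collapse = ", ")))
  for (j in seq_along(x)) {
    cat(sprintf("  fold %d: test %s | val %s | train %s\n", j, x[[j]]$test,
                x[[j]]$val, paste(x[[j]]$train, collapse = ", ")))
  }
  invisible(x)
}

#' Binary confusion matrix for a designated positive class
#'
#' @param predictions,labels equal-length vectors (character or factor).
#' @param positive_class the label counted as positive.
#' @return a `sardar_confusion`: list with `TP`, `FP`, `FN`, `TN`,
#'   `positive` and `total`.
#' @export
compute_confusion <- function(predictions, labels, positive_class) {
  predictions <- as.character(predictions)
  labels <- as.character(labels)
  if (length(predictions) != length(labels)) {
    stop("predictions and labels must have equal length")
  }
  pp <- predictions == positive_class
  lp <- labels == positive_class
  structure(list(TP = sum(pp & lp), FP = sum(pp & !lp),
                 FN = sum(!pp & lp), TN = sum(!pp & !lp),
                 positive = positive_class, total = length(labels)),
            class = "sardar_confusion")
}

#' @export
print.sardar_confusion <- function(x, ...) {
  cat(sprintf("<sardar_confusion> positive = %s\n", x$positive))
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2, 2,
              dimnames = list(truth = c(x$positive, "other"),
                              predicted = c(x$positive, "other")))
  print(m)
  invisible(x)
}

#' Accuracy, per-class precision/recall and macro F1 from a confusion matrix
#'
#' Accuracy is `(TP + TN) / total`. The F1 score is reported as the macro
#' average of the per-class F1 scores of the positive and negative class
#' (the unweighted two-class mean); the positive-class-only F1 is also
#' included. A class without support receives F1 = 0 and is flagged.
#'
#' @param cm a `sardar_confusion`.
#' @return a `sardar_metrics` list: `accuracy`, `macro_f1`, `positive_f1`
#'   (all in percent), per-class `precision` / `recall` (fractions), and
#'   `zero_support` flag.
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "sardar_confusion"), cm$total > 0)
  f1_of <- function(tp, fp, fn) {
    if (2 * tp + fp + fn == 0) return(NA_real_)  # no support, no predictions
    2 * tp / (2 * tp + fp + fn)
  }
  f1_pos <- f1_of(cm$TP, cm$FP, cm$FN)
  f1_neg <- f1_of(cm$TN, cm$FN, cm$FP)
  zero_support <- is.na(f1_pos) || is.na(f1_neg)
  f1_pos0 <- if (is.na(f1_pos)) 0 else f1_pos
  f1_neg0 <- if (is.na(f1_neg)) 0 else f1_neg
  prec <- function(tp, fp) if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  structure(list(
    accuracy = 100 * (cm$TP + cm$TN) / cm$total,
    macro_f1 = 100 * (f1_pos0 + f1_neg0) / 2,
    positive_f1 = 100 * f1_pos0,
    precision = c(positive = prec(cm$TP, cm$FP), negative = prec(cm$TN, cm$FN)),
    recall = c(positive = prec(cm$TP, cm$FN), negative = prec(cm$TN, cm$FP)),
    zero_support = zero_support),
    class = "sardar_metrics")
}

#' @export
print.sardar_metrics <- function(x, ...) {
  cat(sprintf("<sardar_metrics> accuracy %.2f%%, macro F1 %.2f%% (positive-class F1 %.2f%%)\n",
              x$accuracy, x$macro_f1, x$positive_f1))
  invisible(x)
}

#' Run a classifier over a fold plan with repeated seeded runs
#'
#' `fit_predict` encapsulates one train-and-evaluate cycle: it is called once
#' per (fold, run) with the fold assignment and a seed, and must return
#' `list(predictions, labels, positive)` for the fold's test session. Results
#' are averaged first within folds across runs, then across folds with equal
#' weight (the grand mean is the mean of the per-fold means).
#'
#' @param fit_predict `function(fold, seed)`, see Details.
#' @param fold_plan a [make_session_folds()] plan.
#' @param n_runs repeated runs per fold (weight-initialisation variance).
#' @param seeds integer vector of length `n_runs` (distinct).
#' @return a `sardar_experiment`: `results` (per fold x run data frame),
#'   `fold_means`, and `grand_mean`.
#' @export
run_experiment <- function(fit_predict, fold_plan, n_runs = 5,
                           seeds = seq_len(n_runs)) {
  stopifnot(inherits(fold_plan, "sardar_fold_plan"),
            length(seeds) == n_runs, !anyDuplicated(seeds))
  rows <- list()
  for (j in seq_along(fold_plan)) {
    for (r in seq_len(n_runs)) {
      res <- fit_predict(fold_plan[[j]], seeds[r])
      if (is.null(res$predictions) || is.null(res$labels)) {
        stop("fit_predict must return predictions and labels")
      }
      met <- compute_metrics(compute_confusion(res$predictions, res$labels,
                                               res$positive))
      rows[[length(rows) + 1L]] <- data.frame(
        fold = j, test_session = fold_plan[[j]]$test, run = r, seed = seeds[r],
        accuracy = met$accuracy, macro_f1 = met$macro_f1,
        positive_f1 = met$positive_f1)
    }
  }
  results <- do.call(rbind, rows)
  fold_means <- stats::aggregate(results[c("accuracy", "macro_f1")],
                                 by = results["fold"], FUN = mean)
  grand_mean <- list(accuracy = mean(fold_means$accuracy),
                     macro_f1 = mean(fold_means$macro_f1))
  structure(list(results = results, fold_means = fold_means,
                 grand_mean = grand_mean),
            class = "sardar_experiment")
}

#' @export
print.sardar_experiment <- function(x, ...) {
  cat(sprintf("<sardar_experiment> %d folds x %d runs: mean accuracy %.2f%%, mean macro F1 %.2f%%\n",
              max(x$results$fold), max(x$results$run),
              x$grand_mean$accuracy, x$grand_mean$macro_f1))
  invisible(x)
}
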