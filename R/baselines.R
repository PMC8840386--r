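# Feature-based comparison classifiers: seven time-domain statistics per
# sensor (14 features) feeding logistic regression, k-NN, a decision tree and
# a random forest. The moment statistics use population (biased) estimators
# and excess kurtosis; a constant input yields 0 for both shape statistics.

FEATURE_NAMES <- as.vector(outer(
  c("mean", "min", "max", "median", "std", "skewness", "kurtosis"),
  c("acc", "gyr"),
  function(f, s) paste(s, f, sep = "_")))

row_features <- function(v) {
  mu <- mean(v)
  s2 <- mean((v - mu)^2)
  s <- sqrt(s2)
  if (s == 0) {
    skew <- 0
    kurt <- 0
  } else {
    skew <- mean((v - mu)^3) / s^3
    kurt <- mean((v - mu)^4) / s2^2 - 3
  }
  c(mean = mu, min = min(v), max = max(v), median = stats::median(v),
    std = s, skewness = skew, kurtosis = kurt)
}

#' Time-domain feature vector of an activity window
#'
#' Seven statistics per sensor row -- mean, minimum, maximum, median, standard
#' deviation (population), skewness and excess kurtosis -- concatenated
#' accelerometer first, 14 features in total. Feature order is fixed and named
#' (`acc_mean`, ..., `gyr_kurtosis`).
#'
#' @param window a `sardar_window`, a 2 x 200 matrix (accelerometer row
#'   first), or a list of either.
#' @return a named numeric vector of length 14, or a matrix (one row per
#'   window) when a list is given.
#' @export
extract_features <- function(window) {
  if (is.list(window) && !inherits(window, "sardar_window")) {
    return(t(vapply(window, extract_features, numeric(14))))
  }
  Z <- if (inherits(window, "sardar_window")) window$Z else window
  stopifnot(is.matrix(Z), nrow(Z) == 2)
  out <- c(row_features(Z[1, ]), row_features(Z[2, ]))
  names(out) <- FEATURE_NAMES
  out
}

#' Train a feature-based baseline classifier
#'
#' Features are standardised with training statistics, then one of the four
#' classic models is fitted: `"LR"` (logistic regression), `"kNN"`
#' (k-nearest neighbours, default k = 5), `"DT"` (CART decision tree) or
#' `"RF"` (random forest, default 100 trees).
#'
#' @param name one of `"LR"`, `"kNN"`, `"DT"`, `"RF"`.
#' @param features numeric matrix (rows = windows, 14 columns) from
#'   [extract_features()].
#' @param labels class labels (character or factor, two levels).
#' @param k neighbours for k-NN.
#' @param ntree trees for the random forest.
#' @param seed integer seed (random forest training is stochastic).
#' @return a `sardar_baseline` model usable with `predict()`.
#' @export
train_baseline <- function(name, features, labels, k = 5, ntree = 100,
                           seed = 1L) {
  if (!name %in% c("LR", "kNN", "DT", "RF")) {
    stop("unknown baseline '", name, "'; expected LR, kNN, DT or RF")
  }
  features <- as.matrix(features)
  y <- factor(labels)
  if (nlevels(y) != 2) stop("baselines expect exactly two classes")
  stopifnot(nrow(features) == length(y))
  center <- colMeans(features)
  scale <- apply(features, 2, stats::sd)
  scale[scale == 0] <- 1
  xs <- scale(features, center = center, scale = scale)
  fit <- with_seed(seed, switch(name,
    LR = {
      df <- data.frame(xs, y = y)
      suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
    },
    kNN = list(train = xs, y = y),  # lazy learner: kept for prediction time
    DT = rpart::rpart(y ~ ., data = data.frame(xs, y = y), method = "class"),
    RF = randomForest::randomForest(xs, y, ntree = ntree)
  ))
  structure(list(name = name, fit = fit, center = center, scale = scale,
                 levels = levels(y), k = k),
            class = "sardar_baseline")
}

#' @export
print.sardar_baseline <- function(x, ...) {
  cat(sprintf("<sardar_baseline> %s (classes: %s)\n", x$name,
              paste(x$levels, collapse = " / ")))
  invisible(x)
}

#' Predict labels from a trained baseline
#'
#' @param object a `sardar_baseline`.
#' @param features feature matrix as in [train_baseline()].
#' @param ... unused.
#' @return factor of predicted labels.
#' @export
predict.sardar_baseline <- function(object, features, ...) {
  xs <- scale(as.matrix(features), center = object$center, scale = object$scale)
  out <- switch(object$name,
    LR = {
      p <- stats::predict(object$fit, newdata = data.frame(xs), type = "response")
      factor(object$levels[(p > 0.5) + 1L], levels = object$levels)
    },
    kNN = class::knn(object$fit$train, xs, object$fit$y, k = object$k),
    DT = stats::predict(object$fit, newdata = data.frame(xs), type = "class"),
    RF = stats::predict(object$fit, xs)
  )
  factor(as.character(out), levels = object$levels)
}
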