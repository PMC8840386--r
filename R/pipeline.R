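# High-level experiment wrappers: session-wise cross-validation of the two
# CNNs and the feature baselines, built from the lower-level modules. Each
# fold refits the normalisation statistics on its training sessions only.

split_windows <- function(sessions, fold, window_s = 2) {
  by_id <- stats::setNames(sessions, vapply(sessions, `[[`, "", "session_id"))
  mags <- lapply(by_id, compute_magnitude)
  stats <- fit_normalization(mags[fold$train])
  role_windows <- function(ids) {
    wins <- unlist(lapply(by_id[ids], session_windows, stats = stats,
                          window = window_s), recursive = FALSE)
    if (length(wins) == 0) stop("no usable windows in sessions ",
                                paste(ids, collapse = ", "))
    windows_to_array(wins)
  }
  list(train = role_windows(fold$train),
       val = role_windows(fold$val),
       test = role_windows(fold$test),
       stats = stats)
}

#' Cross-validate the activity CNN over sessions
#'
#' For every fold of the plan: z-normalisation statistics are fitted on the
#' training sessions only, all three roles are windowed, the late-fusion CNN
#' is trained (stand = positive class) and evaluated on the held-out test
#' session. Repeated runs vary the training seed (weight initialisation,
#' shuffling, dropout).
#'
#' @param sessions list of `sardar_imu_session` objects.
#' @param config a [training_config()]; the full-scale protocol uses
#'   `min_epochs = 500`, `patience = 100`.
#' @param fold_plan optional [make_session_folds()] plan (defaults to all
#'   sessions).
#' @param n_runs,seeds repeated runs, see [run_experiment()].
#' @return a `sardar_experiment`.
#' @export
evaluate_activity_cnn <- function(sessions, config = training_config(),
                                  fold_plan = NULL, n_runs = 1,
                                  seeds = seq_len(n_runs)) {
  if (is.null(fold_plan)) {
    fold_plan <- make_session_folds(vapply(sessions, `[[`, "", "session_id"))
  }
  arch <- build_activity_cnn()
  fit_predict <- function(fold, seed) {
    parts <- split_windows(sessions, fold)
    cfg <- config
    cfg$seed <- as.integer(seed)
    model <- train_cnn(arch, parts$train$x, parts$train$label == "stand",
                       parts$val$x, parts$val$label == "stand",
                       config = cfg, positive = "stand")
    p <- predict(model, parts$test$x)
    list(predictions = classify(p, labels = c("search", "stand")),
         labels = parts$test$label, positive = "stand")
  }
  run_experiment(fit_predict, fold_plan, n_runs = n_runs, seeds = seeds)
}

#' Cross-validate the bark CNN over sessions
#'
#' Clips are max-normalised and turned into log-mel spectrograms once (the
#' audio front end has no statistics fitted on training data); each fold then
#' trains the bark network (bark = positive class) on the training sessions'
#' clips and scores the held-out session.
#'
#' @param clips list of labelled `sardar_audio_clip` objects with session
#'   tags.
#' @param config a [training_config()]; the full-scale protocol uses
#'   `min_epochs = 1000`, `patience = 100`.
#' @param fold_plan optional fold plan over the clip sessions.
#' @param n_runs,seeds repeated runs.
#' @return a `sardar_experiment`.
#' @export
evaluate_bark_cnn <- function(clips, config = training_config(),
                              fold_plan = NULL, n_runs = 1,
                              seeds = seq_len(n_runs)) {
  mel <- clips_to_array(clips)
  if (is.null(fold_plan)) {
    fold_plan <- make_session_folds(unique(mel$session_id))
  }
  arch <- build_bark_cnn()
  fit_predict <- function(fold, seed) {
    tr <- mel$session_id %in% fold$train
    va <- mel$session_id %in% fold$val
    te <- mel$session_id %in% fold$test
    cfg <- config
    cfg$seed <- as.integer(seed)
    model <- train_cnn(arch, mel$x[, , tr, drop = FALSE],
                       mel$label[tr] == "bark",
                       mel$x[, , va, drop = FALSE], mel$label[va] == "bark",
                       config = cfg, positive = "bark")
    p <- predict(model, mel$x[, , te, drop = FALSE])
    list(predictions = classify(p, labels = c("not_bark", "bark")),
         labels = mel$label[te], positive = "bark")
  }
  run_experiment(fit_predict, fold_plan, n_runs = n_runs, seeds = seeds)
}

#' Cross-validate a feature baseline over sessions
#'
#' Same fold structure and preprocessing as the activity CNN (normalised
#' magnitude windows), but with the 14 time-domain features and one of the
#' classic classifiers. The validation session is unused by the baselines
#' (they have no early stopping) but kept out of training for comparability.
#'
#' @param name `"LR"`, `"kNN"`, `"DT"` or `"RF"`.
#' @param sessions list of `sardar_imu_session` objects.
#' @param fold_plan optional fold plan.
#' @param n_runs,seeds repeated runs (only RF training is stochastic).
#' @param ... passed to [train_baseline()].
#' @return a `sardar_experiment`.
#' @export
evaluate_baseline <- function(name, sessions, fold_plan = NULL, n_runs = 1,
                              seeds = seq_len(n_runs), ...) {
  if (is.null(fold_plan)) {
    fold_plan <- make_session_folds(vapply(sessions, `[[`, "", "session_id"))
  }
  fit_predict <- function(fold, seed) {
    parts <- split_windows(sessions, fold)
    ftr <- extract_features(apply(parts$train$x, 3, identity, simplify = FALSE))
    fte <- extract_features(apply(parts$test$x, 3, identity, simplify = FALSE))
    model <- train_baseline(name, ftr, parts$train$label, seed = seed, ...)
    list(predictions = predict(model, fte),
         labels = parts$test$label, positive = "stand")
  }
  run_experiment(fit_predict, fold_plan, n_runs = n_runs, seeds = seeds)
}
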