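# The two behaviour-recognition networks and their training protocol.

#' Late-sensor-fusion CNN for stand-vs-search activity recognition
#'
#' Input is a 2 x 200 matrix of z-normalised magnitude values (accelerometer
#' row first, gyroscope second; 2 s at 100 Hz). The first two convolutional
#' blocks use (1, 11) kernels and therefore process each sensor row
#' independently; the two sensors are fused only by the (2, 11) kernels of the
#' third block (late sensor fusion). A dense layer on the 32 globally
#' max-pooled feature maps emits a single sigmoid probability of the positive
#' class ("stand").
#'
#' Layer stack: conv (1,11) x 16 + ReLU + maxpool (1,4) + dropout 0.5;
#' conv (1,11) x 24 + ReLU + maxpool (1,2) + dropout 0.5;
#' conv (2,11) x 32 + ReLU + global maxpool + dropout 0.5; dense 32 -> 1 +
#' sigmoid. Total 21,401 trainable parameters.
#'
#' @return a `sardar_arch`.
#' @seealso [build_bark_cnn()], [count_parameters()], [train_cnn()]
#' @export
build_activity_cnn <- function() {
  architecture_spec(
    name = "activity_cnn",
    input_shape = c(2L, 200L, 1L),
    layers = list(
      layer_spec("conv2d", kh = 1, kw = 11, out_ch = 16),
      layer_spec("activation", fun = "relu"),
      layer_spec("maxpool", kh = 1, kw = 4),
      layer_spec("dropout", rate = 0.5),
      layer_spec("conv2d", kh = 1, kw = 11, out_ch = 24),
      layer_spec("activation", fun = "relu"),
      layer_spec("maxpool", kh = 1, kw = 2),
      layer_spec("dropout", rate = 0.5),
      layer_spec("conv2d", kh = 2, kw = 11, out_ch = 32),
      layer_spec("activation", fun = "relu"),
      layer_spec("global_maxpool"),
      layer_spec("dropout", rate = 0.5),
      layer_spec("dense", units = 1),
      layer_spec("activation", fun = "sigmoid")
    ))
}

#' Lightweight CNN for bark detection on log-mel spectrograms
#'
#' Input is a 173 x 128 log-scaled mel-spectrogram of a max-normalised 2-s
#' audio clip (frames as rows, mel bands as columns). Three (3, 3)
#' convolutional blocks with 16/24/32 filters, each followed by ReLU, (2, 2)
#' strided max-pooling (global max-pooling for the third) and dropout 0.5,
#' feed a dense 32 -> 1 sigmoid output: the probability of the positive class
#' ("bark"). Total 10,617 trainable parameters.
#'
#' @return a `sardar_arch`.
#' @seealso [build_activity_cnn()], [count_parameters()], [train_cnn()]
#' @export
build_bark_cnn <- function() {
  architecture_spec(
    name = "bark_cnn",
    input_shape = c(173L, 128L, 1L),
    layers = list(
      layer_spec("conv2d", kh = 3, kw = 3, out_ch = 16),
      layer_spec("activation", fun = "relu"),
      layer_spec("maxpool", kh = 2, kw = 2),
      layer_spec("dropout", rate = 0.5),
      layer_spec("conv2d", kh = 3, kw = 3, out_ch = 24),
      layer_spec("activation", fun = "relu"),
      layer_spec("maxpool", kh = 2, kw = 2),
      layer_spec("dropout", rate = 0.5),
      layer_spec("conv2d", kh = 3, kw = 3, out_ch = 32),
      layer_spec("activation", fun = "relu"),
      layer_spec("global_maxpool"),
      layer_spec("dropout", rate = 0.5),
      layer_spec("dense", units = 1),
      layer_spec("activation", fun = "sigmoid")
    ))
}

#' Training configuration for the CNNs
#'
#' Defaults follow the reference training protocol: Adam with learning rate 0.001,
#' beta1 0.9, beta2 0.999, epsilon 1e-8, no decay; binary cross-entropy loss;
#' training runs for at least `min_epochs` and then stops once the stopping
#' monitor (training accuracy) has not improved for `patience` epochs; the
#' returned weights are those of the epoch with the lowest validation error
#' rate. `min_epochs` is 500 for the activity network and 1000 for the bark
#' network in the original protocol; scale both down together with `patience`
#' for quick experiments.
#'
#' @param min_epochs minimum number of training epochs.
#' @param patience epochs without improvement of the stopping monitor before
#'   training halts (applied after `min_epochs`).
#' @param batch_size minibatch size.
#' @param lr,beta1,beta2,epsilon,decay Adam hyperparameters.
#' @param monitor quantity watched by early stopping: `"train_acc"`
#'   (default, as in the original protocol) or `"val_error"`.
#' @param seed integer seed controlling weight initialisation, shuffling and
#'   dropout masks.
#' @return a list of class `sardar_training_config`.
#' @export
training_config <- function(min_epochs = 500, patience = 100, batch_size = 32,
                            lr = 0.001, beta1 = 0.9, beta2 = 0.999,
                            epsilon = 1e-8, decay = 0,
                            monitor = c("train_acc", "val_error"),
                            seed = 1L) {
  stopifnot(patience >= 1, min_epochs >= patience, batch_size >= 1, lr > 0)
  structure(list(min_epochs = as.integer(min_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 lr = lr, beta1 = beta1, beta2 = beta2, epsilon = epsilon,
                 decay = decay, monitor = match.arg(monitor),
                 seed = as.integer(seed)),
            class = "sardar_training_config")
}

# stack a list of H x W matrices (or an (H, W, N) array) into a (H*W, N) matrix
as_input_matrix <- function(x, input_shape) {
  len <- prod(input_shape)
  if (is.list(x)) x <- vapply(x, function(m) as.numeric(m), numeric(len))
  if (is.array(x) && length(dim(x)) == 3) dim(x) <- c(len, dim(x)[3])
  if (is.null(dim(x))) x <- matrix(x, nrow = len)
  if (nrow(x) != len) stop("input shape does not match the architecture")
  x
}

#' Train a CNN with Adam, early stopping and validation checkpointing
#'
#' Implements the training protocol used for both behaviour networks: Adam
#' optimisation of the binary cross-entropy, a floor of `min_epochs` epochs,
#' early stopping once the monitored quantity has not improved for `patience`
#' epochs, and a checkpoint at the epoch with the lowest validation error rate
#' (ties broken by validation loss, then towards the earlier epoch; with small
#' validation sets the error rate alone is too coarse a monitor). Training
#' accuracy is the epoch average over minibatches as seen during optimisation.
#'
#' @param arch a `sardar_arch` from [build_activity_cnn()],
#'   [build_bark_cnn()] or [architecture_spec()].
#' @param x_train,x_val inputs: a list of matrices, an `(H, W, N)` array, or a
#'   pre-flattened `(H*W*C, N)` matrix.
#' @param y_train,y_val binary labels (0/1, logical, or a factor whose second
#'   level is the positive class).
#' @param config a [training_config()].
#' @param positive optional label name of the positive class, stored for
#'   [classify()].
#' @return an object of class `sardar_cnn` with elements `arch`, `weights`
#'   (checkpointed), `history` (per-epoch data frame), `checkpoint_epoch`,
#'   `stopped_epoch`, `config` and `positive`.
#' @export
train_cnn <- function(arch, x_train, y_train, x_val, y_val,
                      config = training_config(), positive = "positive") {
  stopifnot(inherits(arch, "sardar_arch"),
            inherits(config, "sardar_training_config"))
  y_train <- as_binary_labels(y_train)
  y_val <- as_binary_labels(y_val)
  x_train <- as_input_matrix(x_train, arch$input_shape)
  x_val <- as_input_matrix(x_val, arch$input_shape)
  if (ncol(x_train) == 0 || ncol(x_val) == 0) stop("empty training or validation set")
  if (length(y_train) != ncol(x_train) || length(y_val) != ncol(x_val)) {
    stop("label count does not match input count")
  }
  if (length(unique(y_train)) < 2) {
    stop("training set contains a single class; cannot fit a binary classifier")
  }

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  plans <- build_plans(arch)
  weights <- init_weights(arch)
  state <- adam_init(weights)
  bufs <- new_buffer_env()
  n <- ncol(x_train)
  t_step <- 0L
  best_monitor <- -Inf
  since_improve <- 0L
  best_val_err <- Inf
  best_val_loss <- Inf
  best_weights <- weights
  checkpoint_epoch <- NA_integer_
  hist <- list()
  epoch <- 0L
  repeat {
    epoch <- epoch + 1L
    ord <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    loss_sum <- 0; correct <- 0L
    for (s in starts) {
      take <- ord[s:min(s + config$batch_size - 1L, n)]
      xb <- x_train[, take, drop = FALSE]
      yb <- y_train[take]
      fw <- nn_forward(arch, weights, plans, xb, training = TRUE, bufs = bufs)
      p <- as.numeric(fw$out)
      loss_sum <- loss_sum + bce_loss(p, yb) * length(yb)
      correct <- correct + sum((p > 0.5) == (yb == 1))
      dlogit <- matrix((p - yb) / length(yb), nrow = 1)
      grads <- nn_backward(arch, weights, plans, fw$caches, dlogit, bufs = bufs)
      t_step <- t_step + 1L
      up <- adam_step(weights, grads, state, t_step, config$lr, config$beta1,
                      config$beta2, config$epsilon, config$decay)
      weights <- up$weights
      state <- up$state
    }
    train_loss <- loss_sum / n
    train_acc <- correct / n

    vw <- nn_forward(arch, weights, plans, x_val, training = FALSE, bufs = bufs)
    pv <- as.numeric(vw$out)
    val_loss <- bce_loss(pv, y_val)
    val_acc <- mean((pv > 0.5) == (y_val == 1))
    val_err <- 1 - val_acc
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = train_loss,
                                train_acc = train_acc, val_loss = val_loss,
                                val_acc = val_acc)
    # checkpoint on lowest validation error rate; with small validation sets
    # the error rate is coarse and ties at its minimum for long stretches, so
    # ties are broken by validation loss (remaining ties -> earlier epoch)
    if (val_err < best_val_err ||
        (val_err == best_val_err && val_loss < best_val_loss)) {
      best_val_err <- val_err
      best_val_loss <- val_loss
      best_weights <- weights
      checkpoint_epoch <- epoch
    }
    mon <- if (config$monitor == "train_acc") train_acc else -val_err
    if (mon > best_monitor) {
      best_monitor <- mon
      since_improve <- 0L
    } else {
      since_improve <- since_improve + 1L
    }
    if (epoch >= config$min_epochs && since_improve >= config$patience) break
  }
  structure(list(arch = arch, weights = best_weights,
                 history = do.call(rbind, hist),
                 checkpoint_epoch = checkpoint_epoch,
                 stopped_epoch = epoch,
                 config = config, positive = positive),
            class = "sardar_cnn")
}

as_binary_labels <- function(y) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% c(0, 1))) stop("labels must be binary (0/1)")
  as.numeric(y)
}

#' @export
print.sardar_cnn <- function(x, ...) {
  cat(sprintf("<sardar_cnn> %s: %d parameters, trained %d epochs (checkpoint %d, val error %.4f)\n",
              x$arch$name, count_parameters(x$arch), x$stopped_epoch,
              x$checkpoint_epoch,
              1 - x$history$val_acc[x$checkpoint_epoch]))
  invisible(x)
}

#' Predict class probabilities from a trained CNN
#'
#' Dropout is inactive at inference, so predictions are deterministic.
#'
#' @param object a `sardar_cnn`.
#' @param x inputs as in [train_cnn()].
#' @param ... unused.
#' @return numeric vector of positive-class probabilities in `[0, 1]`.
#' @export
predict.sardar_cnn <- function(object, x, ...) {
  xm <- as_input_matrix(x, object$arch$input_shape)
  plans <- build_plans(object$arch)
  bufs <- new_buffer_env()
  chunks <- split(seq_len(ncol(xm)), ceiling(seq_len(ncol(xm)) / 32))
  unlist(lapply(chunks, function(ii) {
    as.numeric(nn_forward(object$arch, object$weights, plans,
                          xm[, ii, drop = FALSE], training = FALSE,
                          bufs = bufs)$out)
  }), use.names = FALSE)
}

#' Turn probabilities into class decisions
#'
#' The positive class is assigned iff the probability strictly exceeds the
#' threshold; a probability exactly at the threshold yields the negative class
#' (the conservative default for alerting).
#'
#' @param probability numeric vector of probabilities.
#' @param threshold decision threshold, default 0.5.
#' @param labels length-2 character vector `c(negative, positive)`.
#' @return character vector of labels.
#' @export
classify <- function(probability, threshold = 0.5,
                     labels = c("negative", "positive")) {
  stopifnot(all(probability >= 0 & probability <= 1), length(labels) == 2)
  labels[(probability > threshold) + 1L]
}

#' Save / load a trained CNN as portable JSON
#'
#' The file embeds the architecture description and the weight tensors at full
#' double precision, so a round-trip reproduces predictions exactly.
#'
#' @param model a `sardar_cnn`.
#' @param path file path.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "sardar_cnn"))
  arch <- model$arch
  payload <- list(
    name = arch$name,
    input_shape = arch$input_shape,
    layers = lapply(arch$layers, function(ly) ly[!vapply(ly, is.null, TRUE)]),
    weights = lapply(model$weights, function(w) {
      if (is.null(w)) NULL else list(W = as.numeric(w$W), dim = dim(w$W), b = w$b)
    }),
    checkpoint_epoch = model$checkpoint_epoch,
    stopped_epoch = model$stopped_epoch,
    positive = model$positive,
    history = model$history
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  layers <- lapply(payload$layers, function(ly) {
    ly <- as.list(ly)   # layers whose fields are all strings simplify to vectors
    layer_spec(ly$kind, kh = ly$kh, kw = ly$kw, out_ch = ly$out_ch,
               rate = ly$rate, units = ly$units, fun = ly$fun)
  })
  arch <- architecture_spec(payload$name, payload$input_shape, layers)
  weights <- lapply(payload$weights, function(w) {
    if (is.null(w) || length(w) == 0) NULL
    else list(W = matrix(w$W, w$dim[1], w$dim[2]), b = as.numeric(w$b))
  })
  structure(list(arch = arch, weights = weights,
                 history = as.data.frame(payload$history),
                 checkpoint_epoch = payload$checkpoint_epoch,
                 stopped_epoch = payload$stopped_epoch,
                 config = NULL, positive = payload$positive),
            class = "sardar_cnn")
}
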