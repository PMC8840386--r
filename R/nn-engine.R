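# Compact CNN engine: valid convolutions via im2col + GEMM, strided max-pooling,
# global max-pooling, inverted dropout, dense layers, sigmoid output, Adam.
# Batches are held as matrices (flattened sample in columns); per-layer index
# plans are precomputed once per architecture, and the conv/pool hot paths run
# in compiled code (src/conv_ops.cpp).

#' Describe a single network layer
#'
#' Layers are declarative: a `layer_spec` carries shapes only, no weights.
#' Supported kinds are `"conv2d"` (valid padding, stride 1), `"maxpool"`
#' (stride equal to the pool size, trailing remainder dropped), `"global_maxpool"`,
#' `"dropout"`, `"dense"` and `"activation"` (`"relu"` or `"sigmoid"`).
#'
#' @param kind layer kind, see Description.
#' @param kh,kw kernel or pool height/width (conv2d, maxpool).
#' @param out_ch number of convolutional filters (conv2d).
#' @param rate dropout probability in `[0, 1)` (dropout).
#' @param units output units (dense).
#' @param fun activation function name (activation).
#' @return an object of class `sardar_layer`.
#' @export
layer_spec <- function(kind, kh = NULL, kw = NULL, out_ch = NULL, rate = NULL,
                       units = NULL, fun = NULL) {
  kind <- match.arg(kind, c("conv2d", "maxpool", "global_maxpool", "dropout",
                            "dense", "activation"))
  if (kind == "conv2d") {
    stopifnot(kh >= 1, kw >= 1, out_ch >= 1)
  } else if (kind == "maxpool") {
    stopifnot(kh >= 1, kw >= 1)
  } else if (kind == "dropout") {
    if (is.null(rate) || rate < 0 || rate >= 1) {
      stop("dropout rate must lie in [0, 1)")
    }
  } else if (kind == "dense") {
    stopifnot(units >= 1)
  } else if (kind == "activation") {
    fun <- match.arg(fun, c("relu", "sigmoid"))
  }
  structure(list(kind = kind, kh = kh, kw = kw, out_ch = out_ch, rate = rate,
                 units = units, fun = fun),
            class = "sardar_layer")
}

#' Assemble a network architecture from layer specifications
#'
#' Propagates shapes through the layer list and fails if any layer cannot be
#' applied to its input (e.g. a kernel larger than the feature map, or a dense
#' layer whose fan-in does not match the flattened input). The realised
#' per-layer input/output shapes are stored alongside the specs.
#'
#' @param name architecture name.
#' @param input_shape integer vector `c(height, width, channels)`.
#' @param layers list of [layer_spec()] objects.
#' @return an object of class `sardar_arch`.
#' @export
architecture_spec <- function(name, input_shape, layers) {
  stopifnot(length(input_shape) == 3, all(input_shape >= 1))
  shape <- as.integer(input_shape)   # c(H, W, C) or NA,NA,len once flattened
  flat <- FALSE
  in_shapes <- out_shapes <- vector("list", length(layers))
  for (k in seq_along(layers)) {
    ly <- layers[[k]]
    if (!inherits(ly, "sardar_layer")) stop("layers must be layer_spec objects")
    in_shapes[[k]] <- shape
    shape <- switch(ly$kind,
      conv2d = {
        if (flat) stop("conv2d after flattening is not supported")
        if (shape[1] < ly$kh || shape[2] < ly$kw) {
          stop(sprintf("layer %d: kernel (%d,%d) larger than input (%d,%d)",
                       k, ly$kh, ly$kw, shape[1], shape[2]))
        }
        c(shape[1] - ly$kh + 1L, shape[2] - ly$kw + 1L, as.integer(ly$out_ch))
      },
      maxpool = {
        if (flat) stop("maxpool after flattening is not supported")
        h2 <- shape[1] %/% ly$kh; w2 <- shape[2] %/% ly$kw
        if (h2 < 1 || w2 < 1) stop(sprintf("layer %d: pool larger than input", k))
        c(as.integer(h2), as.integer(w2), shape[3])
      },
      global_maxpool = {
        if (flat) stop("global_maxpool after flattening is not supported")
        flat <- TRUE
        shape[3]
      },
      dropout = shape,
      dense = {
        flat <- TRUE   # any spatial input is implicitly flattened column-major
        as.integer(ly$units)
      },
      activation = shape
    )
    out_shapes[[k]] <- shape
  }
  structure(list(name = name, input_shape = as.integer(input_shape),
                 layers = layers, in_shapes = in_shapes, out_shapes = out_shapes),
            class = "sardar_arch")
}

#' @export
print.sardar_arch <- function(x, ...) {
  cat(sprintf("<sardar_arch> %s  input %s\n", x$name,
              paste(x$input_shape, collapse = "x")))
  for (k in seq_along(x$layers)) {
    ly <- x$layers[[k]]
    desc <- switch(ly$kind,
      conv2d = sprintf("conv2d (%d,%d) x %d", ly$kh, ly$kw, ly$out_ch),
      maxpool = sprintf("maxpool (%d,%d)", ly$kh, ly$kw),
      global_maxpool = "global_maxpool",
      dropout = sprintf("dropout %.2f", ly$rate),
      dense = sprintf("dense -> %d", ly$units),
      activation = ly$fun)
    cat(sprintf("  [%2d] %-22s -> %s\n", k, desc,
                paste(x$out_shapes[[k]], collapse = "x")))
  }
  cat(sprintf("  trainable parameters: %d\n", count_parameters(x)))
  invisible(x)
}

#' Count trainable parameters of an architecture
#'
#' Convolutions contribute `(kh*kw*c_in + 1) * c_out` (weights plus one bias per
#' filter), dense layers `(fan_in + 1) * units`; pooling, dropout and
#' activations are parameter-free.
#'
#' @param spec a `sardar_arch`.
#' @return integer parameter count.
#' @export
count_parameters <- function(spec) {
  stopifnot(inherits(spec, "sardar_arch"))
  total <- 0L
  for (k in seq_along(spec$layers)) {
    ly <- spec$layers[[k]]
    if (ly$kind == "conv2d") {
      c_in <- spec$in_shapes[[k]][3]
      total <- total + (ly$kh * ly$kw * c_in + 1L) * ly$out_ch
    } else if (ly$kind == "dense") {
      fan_in <- prod(spec$in_shapes[[k]])
      total <- total + (fan_in + 1L) * ly$units
    }
  }
  as.integer(total)
}

# --- index plans ------------------------------------------------------------

# im2col index matrix for a valid stride-1 convolution on an (H, W, C) map
# stored column-major. Rows enumerate the patch (h fastest, then w, then c),
# matching the kernel matrix layout; columns enumerate output positions.
conv_plan <- function(H, W, C, kh, kw) {
  off <- as.vector(outer(outer(0:(kh - 1L), H * (0:(kw - 1L)), "+"),
                         H * W * (0:(C - 1L)), "+"))
  H2 <- H - kh + 1L; W2 <- W - kw + 1L
  orig <- as.vector(outer(1:H2, H * (0:(W2 - 1L)), "+"))
  idx <- outer(as.integer(off), as.integer(orig), "+")
  storage.mode(idx) <- "integer"
  list(idx = idx, kk = kh * kw * C, np = H2 * W2, H2 = H2, W2 = W2,
       len_in = H * W * C)
}

# pooling index matrix: rows enumerate the pool window, columns the outputs
# (h2 fastest, then w2, then channel). Stride equals the pool size.
pool_plan <- function(H, W, C, ph, pw) {
  H2 <- H %/% ph; W2 <- W %/% pw
  off <- as.vector(outer(0:(ph - 1L), H * (0:(pw - 1L)), "+"))
  orig <- as.vector(outer(outer((0:(H2 - 1L)) * ph + 1L,
                                H * pw * (0:(W2 - 1L)), "+"),
                          H * W * (0:(C - 1L)), "+"))
  idx <- outer(as.integer(off), as.integer(orig), "+")
  storage.mode(idx) <- "integer"
  list(idx = idx, pp = ph * pw, np = H2 * W2 * C, len_in = H * W * C)
}

build_plans <- function(arch) {
  plans <- vector("list", length(arch$layers))
  first_conv <- TRUE
  for (k in seq_along(arch$layers)) {
    ly <- arch$layers[[k]]
    s <- arch$in_shapes[[k]]
    if (ly$kind == "conv2d") {
      pl <- conv_plan(s[1], s[2], s[3], ly$kh, ly$kw)
      # a ReLU directly after a convolution is fused into the compiled kernel
      pl$fuse_relu <- k < length(arch$layers) &&
        arch$layers[[k + 1]]$kind == "activation" &&
        identical(arch$layers[[k + 1]]$fun, "relu")
      pl$need_dx <- !first_conv   # input gradient of the first layer is unused
      first_conv <- FALSE
      plans[[k]] <- pl
    } else if (ly$kind == "maxpool") {
      plans[[k]] <- pool_plan(s[1], s[2], s[3], ly$kh, ly$kw)
    } else if (ly$kind == "global_maxpool") {
      plans[[k]] <- pool_plan(s[1], s[2], s[3], s[1], s[2])
    }
  }
  plans
}

# --- initialisation ---------------------------------------------------------

init_weights <- function(arch) {
  weights <- vector("list", length(arch$layers))
  for (k in seq_along(arch$layers)) {
    ly <- arch$layers[[k]]
    if (ly$kind == "conv2d") {
      c_in <- arch$in_shapes[[k]][3]
      fan_in <- ly$kh * ly$kw * c_in
      lim <- 1 / sqrt(fan_in)
      weights[[k]] <- list(
        W = matrix(stats::runif(fan_in * ly$out_ch, -lim, lim), fan_in, ly$out_ch),
        b = numeric(ly$out_ch))
    } else if (ly$kind == "dense") {
      fan_in <- prod(arch$in_shapes[[k]])
      lim <- 1 / sqrt(fan_in)
      weights[[k]] <- list(
        W = matrix(stats::runif(fan_in * ly$units, -lim, lim), fan_in, ly$units),
        b = numeric(ly$units))
    }
  }
  weights
}

# --- forward / backward -----------------------------------------------------

# Reusable activation/gradient buffers, keyed by layer index and batch size.
# The compiled kernels write into these in place; fresh allocation of the
# larger maps every minibatch is measurably slower than the arithmetic.
new_buffer_env <- function() new.env(parent = emptyenv())

get_buf <- function(bufs, key, nr, nc, integer = FALSE) {
  if (!is.null(bufs)) {
    b <- get0(key, envir = bufs, inherits = FALSE)
    if (!is.null(b)) return(b)
  }
  b <- if (integer) matrix(0L, nr, nc) else matrix(0, nr, nc)
  if (!is.null(bufs)) assign(key, b, envir = bufs)
  b
}

# x: (len_in, N) matrix of flattened samples. Returns output (units, N) plus
# per-layer caches when `training` (needed by nn_backward). Buffers handed out
# for one batch size are only valid until the next call with that size.
nn_forward <- function(arch, weights, plans, x, training = FALSE, bufs = NULL) {
  caches <- if (training) vector("list", length(arch$layers))
  n <- ncol(x)
  for (k in seq_along(arch$layers)) {
    ly <- arch$layers[[k]]
    if (ly$kind == "conv2d") {
      pl <- plans[[k]]
      out <- get_buf(bufs, sprintf("f%d_%d", k, n), pl$np * ly$out_ch, n)
      conv_forward_cpp(x, pl$idx, weights[[k]]$W, weights[[k]]$b,
                       pl$fuse_relu, out)
      if (training) caches[[k]] <- list(x = x, out = out)
      x <- out
    } else if (ly$kind %in% c("maxpool", "global_maxpool")) {
      pl <- plans[[k]]
      out <- get_buf(bufs, sprintf("f%d_%d", k, n), pl$np, n)
      src <- get_buf(bufs, sprintf("s%d_%d", k, n), pl$np, n, integer = TRUE)
      pool_forward_cpp(x, pl$idx, out, src)
      if (training) caches[[k]] <- list(src = src)
      x <- out
    } else if (ly$kind == "dropout") {
      if (training) {
        keep <- (stats::runif(length(x)) >= ly$rate) / (1 - ly$rate)
        dim(keep) <- dim(x)
        caches[[k]] <- list(mask = keep)
        x <- x * keep
      }
    } else if (ly$kind == "dense") {
      if (training) caches[[k]] <- list(x = x)
      x <- crossprod(weights[[k]]$W, x) + weights[[k]]$b
    } else if (ly$kind == "activation") {
      if (ly$fun == "relu") {
        if (k > 1 && arch$layers[[k - 1]]$kind == "conv2d" &&
            plans[[k - 1]]$fuse_relu) next  # already applied in the conv kernel
        if (training) caches[[k]] <- list(pos = x > 0)
        x <- x * (x > 0)
      } else {
        x <- 1 / (1 + exp(-x))
      }
    }
  }
  list(out = x, caches = caches)
}

# dout: gradient w.r.t. the network output *logits* for the final dense layer
# (the trailing sigmoid is folded into the loss gradient by the caller).
nn_backward <- function(arch, weights, plans, caches, dout, bufs = NULL) {
  grads <- vector("list", length(arch$layers))
  n <- ncol(dout)
  d <- dout
  for (k in rev(seq_along(arch$layers))) {
    ly <- arch$layers[[k]]
    if (ly$kind == "activation") {
      if (ly$fun == "relu" && !is.null(caches[[k]])) d <- d * caches[[k]]$pos
      # fused ReLUs have no cache here; their derivative is applied in the
      # conv backward kernel. The terminal sigmoid is folded into the loss.
    } else if (ly$kind == "dense") {
      x <- caches[[k]]$x
      grads[[k]] <- list(W = tcrossprod(x, d), b = rowSums(d))
      d <- weights[[k]]$W %*% d
    } else if (ly$kind == "dropout") {
      d <- d * caches[[k]]$mask
    } else if (ly$kind %in% c("maxpool", "global_maxpool")) {
      pl <- plans[[k]]
      dx <- get_buf(bufs, sprintf("b%d_%d", k, n), pl$len_in, n)
      pool_backward_cpp(caches[[k]]$src, d, dx)
      d <- dx
    } else if (ly$kind == "conv2d") {
      pl <- plans[[k]]
      dx <- if (pl$need_dx) {
        get_buf(bufs, sprintf("b%d_%d", k, n), pl$len_in, n)
      } else matrix(0, 0, 0)
      bw <- conv_backward_cpp(caches[[k]]$x, pl$idx, weights[[k]]$W, d,
                              if (pl$fuse_relu) caches[[k]]$out else matrix(0, 0, 0),
                              pl$fuse_relu, pl$need_dx, dx)
      grads[[k]] <- list(W = bw$W, b = as.numeric(bw$b))
      if (!pl$need_dx) break
      d <- dx
    }
  }
  grads
}

# --- optimiser --------------------------------------------------------------

adam_init <- function(weights) {
  lapply(weights, function(w) {
    if (is.null(w)) NULL
    else list(mW = 0 * w$W, vW = 0 * w$W, mb = 0 * w$b, vb = 0 * w$b)
  })
}

adam_step <- function(weights, grads, state, t, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, epsilon = 1e-8, decay = 0) {
  lr_t <- if (decay > 0) lr / (1 + decay * t) else lr
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (k in seq_along(weights)) {
    if (is.null(weights[[k]]) || is.null(grads[[k]])) next
    s <- state[[k]]
    s$mW <- beta1 * s$mW + (1 - beta1) * grads[[k]]$W
    s$vW <- beta2 * s$vW + (1 - beta2) * grads[[k]]$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * grads[[k]]$b
    s$vb <- beta2 * s$vb + (1 - beta2) * grads[[k]]$b^2
    weights[[k]]$W <- weights[[k]]$W -
      lr_t * (s$mW / bc1) / (sqrt(s$vW / bc2) + epsilon)
    weights[[k]]$b <- weights[[k]]$b -
      lr_t * (s$mb / bc1) / (sqrt(s$vb / bc2) + epsilon)
    state[[k]] <- s
  }
  list(weights = weights, state = state)
}

# binary cross-entropy on probabilities, clamped away from 0/1
bce_loss <- function(p, y, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}
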