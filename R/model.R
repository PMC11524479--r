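# Raw-waveform 1-D CNN for species/sex classification of 300-ms epochs.
# Architecture: a frontend of three strided 1-D convolutions (learnable
# temporal downsampling, valid padding), two blocks of 1-D convolution
# ("same" padding) + 1-D max pooling, two fully-connected layers, and a
# softmax output over num_class classes. Forward/backward convolution and
# pooling run in compiled code; the training loop lives in train_eval.R.

#' Model configuration
#'
#' The layer-count structure is fixed (3 frontend convolutions, 2
#' convolution+pool blocks, 2 fully-connected layers, softmax); the
#' per-layer hyperparameters are configurable. The defaults reduce a
#' 2400-sample epoch to 18 temporal positions before the dense head.
#'
#' @param num_class number of output classes (8 for four species x two
#'   sexes).
#' @param input_len epoch length in samples (2400 at 0.3 s x 8000 Hz).
#' @param frontend list of exactly 3 specs `list(filters, kernel, stride)`
#'   applied with valid padding.
#' @param blocks list of exactly 2 specs `list(filters, kernel, pool)`;
#'   convolutions use "same" padding (odd kernels), stride 1.
#' @param fc_sizes integer vector of exactly 2 hidden widths.
#' @param seed integer seed for weight initialization.
#' @return An object of class `wb_model_config`.
#' @export
model_config <- function(num_class = 8L, input_len = 2400L,
                         frontend = list(list(filters = 16L, kernel = 8L, stride = 4L),
                                         list(filters = 16L, kernel = 8L, stride = 4L),
                                         list(filters = 32L, kernel = 4L, stride = 2L)),
                         blocks = list(list(filters = 32L, kernel = 3L, pool = 2L),
                                       list(filters = 64L, kernel = 3L, pool = 2L)),
                         fc_sizes = c(64L, 32L),
                         seed = 1L) {
  stopifnot(num_class >= 2, input_len >= 1)
  if (length(frontend) != 3L) stop("frontend must have exactly 3 conv layers")
  if (length(blocks) != 2L) stop("blocks must have exactly 2 conv+pool blocks")
  if (length(fc_sizes) != 2L) stop("fc_sizes must have exactly 2 fully-connected layers")
  for (b in blocks) if (b$kernel %% 2L != 1L)
    stop("block kernels must be odd for 'same' padding")
  cfg <- structure(list(num_class = as.integer(num_class),
                        input_len = as.integer(input_len),
                        frontend = frontend, blocks = blocks,
                        fc_sizes = as.integer(fc_sizes),
                        activation = "relu", seed = as.integer(seed)),
                   class = "wb_model_config")
  invisible(config_geometry(cfg))  # errors if the temporal axis collapses
  cfg
}

# temporal length after each conv/pool stage; errors if any stage < 1
config_geometry <- function(cfg) {
  L <- cfg$input_len
  out <- integer(0)
  for (f in cfg$frontend) {
    L <- (L - f$kernel) %/% f$stride + 1L
    if (L < 1L) stop("config error: frontend collapses temporal axis to < 1")
    out <- c(out, L)
  }
  for (b in cfg$blocks) {
    L <- L %/% b$pool
    if (L < 1L) stop("config error: pooling collapses temporal axis to < 1")
    out <- c(out, L)
  }
  out
}

#' Build an untrained classifier
#'
#' Initializes all weights with seeded He-scaled normal draws, so the same
#' configuration and seed always produce identical initial parameters.
#'
#' @param cfg a [model_config()].
#' @return An object of class `wb_classifier`.
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "wb_model_config"))
  set.seed(cfg$seed)
  layers <- list()
  c_in <- 1L
  for (f in cfg$frontend) {
    layers[[length(layers) + 1L]] <- list(
      type = "conv",
      W = matrix(rnorm(f$kernel * c_in * f$filters, sd = sqrt(2 / (f$kernel * c_in))),
                 f$kernel * c_in, f$filters),
      b = numeric(f$filters), stride = f$stride, pad = 0L)
    c_in <- f$filters
  }
  for (b in cfg$blocks) {
    layers[[length(layers) + 1L]] <- list(
      type = "conv",
      W = matrix(rnorm(b$kernel * c_in * b$filters, sd = sqrt(2 / (b$kernel * c_in))),
                 b$kernel * c_in, b$filters),
      b = numeric(b$filters), stride = 1L, pad = (b$kernel - 1L) %/% 2L)
    layers[[length(layers) + 1L]] <- list(type = "pool", pool = b$pool)
    c_in <- b$filters
  }
  flat <- rev(config_geometry(cfg))[1] * c_in
  widths <- c(flat, cfg$fc_sizes, cfg$num_class)
  layers[[length(layers) + 1L]] <- list(type = "flatten")
  for (j in seq_len(length(widths) - 1L)) {
    layers[[length(layers) + 1L]] <- list(
      type = "dense",
      W = matrix(rnorm(widths[j] * widths[j + 1L], sd = sqrt(2 / widths[j])),
                 widths[j], widths[j + 1L]),
      b = numeric(widths[j + 1L]),
      act = if (j < length(widths) - 1L) "relu" else "softmax")
  }
  structure(list(config = cfg, layers = layers,
                 training_state = list(trained = FALSE, best_metric = NA_real_,
                                       best_pass = NA_integer_)),
            class = "wb_classifier")
}

#' @export
print.wb_classifier <- function(x, ...) {
  np <- sum(vapply(x$layers, function(l)
    if (!is.null(l$W)) length(l$W) + length(l$b) else 0L, 0))
  cat(sprintf("<wb_classifier> %d classes, input %d samples, %d parameters%s\n",
              x$config$num_class, x$config$input_len, np,
              if (isTRUE(x$training_state$trained))
                sprintf(" (trained; best val %.4f at pass %d)",
                        x$training_state$best_metric, x$training_state$best_pass)
              else " (untrained)"))
  invisible(x)
}

# matrix (N x L) -> cube (L, 1, N)
as_input_cube <- function(X) {
  arr <- array(0, c(ncol(X), 1L, nrow(X)))
  arr[, 1L, ] <- t(X)
  arr
}

# forward pass; returns list(probs, caches) - caches kept for backprop
model_forward <- function(m, X, keep_cache = FALSE) {
  if (ncol(X) != m$config$input_len)
    stop("shape error: epochs have ", ncol(X), " samples, model expects ",
         m$config$input_len)
  caches <- if (keep_cache) vector("list", length(m$layers)) else NULL
  a <- as_input_cube(X)
  for (j in seq_along(m$layers)) {
    l <- m$layers[[j]]
    if (l$type == "conv") {
      z <- conv1d_fwd(a, l$W, l$b, l$stride, l$pad)
      if (keep_cache) caches[[j]] <- list(input = a, pre = z)
      a <- z * (z > 0)                      # ReLU
    } else if (l$type == "pool") {
      r <- maxpool1d_fwd(a, l$pool)
      if (keep_cache) caches[[j]] <- list(idx = r$idx, in_len = dim(a)[1])
      a <- r$out
    } else if (l$type == "flatten") {
      d <- dim(a)
      if (keep_cache) caches[[j]] <- list(dims = d)
      a <- t(matrix(a, d[1] * d[2], d[3]))  # N x (P*C), column-major
    } else {                                # dense
      z <- sweep(a %*% l$W, 2L, l$b, `+`)
      if (keep_cache) caches[[j]] <- list(input = a, pre = z)
      if (l$act == "relu") {
        a <- z * (z > 0)
      } else {                              # softmax, numerically stabilized
        z <- z - apply(z, 1L, max)
        e <- exp(z)
        a <- e / rowSums(e)
      }
    }
  }
  list(probs = a, caches = caches)
}

# backward pass for weighted cross-entropy; returns per-layer grads
model_backward <- function(m, caches, probs, labels, class_weights) {
  n <- nrow(probs)
  wts <- class_weights[labels + 1L]
  delta <- probs
  delta[cbind(seq_len(n), labels + 1L)] <-
    delta[cbind(seq_len(n), labels + 1L)] - 1
  delta <- delta * (wts / n)                # d loss / d logits
  grads <- vector("list", length(m$layers))
  for (j in rev(seq_along(m$layers))) {
    l <- m$layers[[j]]; cache <- caches[[j]]
    if (l$type == "dense") {
      if (l$act == "relu") delta <- delta * (cache$pre > 0)
      grads[[j]] <- list(dW = crossprod(cache$input, delta), db = colSums(delta))
      delta <- tcrossprod(delta, l$W)
    } else if (l$type == "flatten") {
      d <- cache$dims
      delta <- array(t(delta), d)
    } else if (l$type == "pool") {
      delta <- maxpool1d_bwd(cache$idx, delta, cache$in_len)
    } else {                                # conv
      delta <- delta * (cache$pre > 0)
      g <- conv1d_bwd(cache$input, l$W, delta, l$stride, l$pad)
      grads[[j]] <- list(dW = g$dW, db = g$db)
      delta <- g$dX
    }
  }
  grads
}

#' Class probabilities for a batch of epochs
#'
#' Runs the forward pass in inference mode. Each output row is a
#' probability vector over the classes summing to 1.
#'
#' @param m a [build_model()] classifier.
#' @param batch a [wb_epochs()] or numeric matrix with one epoch per row.
#' @param chunk internal batch size for memory control.
#' @return A numeric matrix, `n_epochs x num_class`.
#' @export
predict_proba <- function(m, batch, chunk = 256L) {
  X <- if (inherits(batch, "wb_epochs")) batch$samples else batch
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (nrow(X) == 0L) return(matrix(numeric(0), 0L, m$config$num_class))
  out <- matrix(0, nrow(X), m$config$num_class)
  for (s in seq(1L, nrow(X), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(X))
    out[s:e, ] <- model_forward(m, X[s:e, , drop = FALSE])$probs
  }
  out
}

#' Hard class labels for a batch of epochs
#'
#' Argmax of [predict_proba()]; exact ties resolve to the lowest class
#' index.
#'
#' @inheritParams predict_proba
#' @return Integer labels in `0..num_class-1`.
#' @export
classify <- function(m, batch) {
  p <- predict_proba(m, batch)
  if (nrow(p) == 0L) return(integer(0))
  max.col(p, ties.method = "first") - 1L
}

#' Save a classifier checkpoint
#'
#' Writes a versioned archive holding the configuration and the learned
#' weights. [load_checkpoint()] refuses files whose version or (when an
#' expected configuration is supplied) architecture does not match.
#'
#' @param m a `wb_classifier`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(m, path) {
  saveRDS(list(format = "wingbeatr-checkpoint", version = 1L,
               config = m$config, layers = m$layers,
               training_state = m$training_state), path)
  invisible(path)
}

#' Load a classifier checkpoint
#' @param path checkpoint path written by [save_checkpoint()].
#' @param expect_config optional [model_config()]; loading fails if the
#'   stored configuration differs.
#' @return A `wb_classifier`.
#' @export
load_checkpoint <- function(path, expect_config = NULL) {
  ck <- readRDS(path)
  if (!identical(ck$format, "wingbeatr-checkpoint") || !identical(ck$version, 1L))
    stop("not a recognized checkpoint: ", path)
  if (!is.null(expect_config) && !identical(unclass(ck$config), unclass(expect_config)))
    stop("checkpoint configuration mismatch")
  structure(list(config = ck$config, layers = ck$layers,
                 training_state = ck$training_state),
            class = "wb_classifier")
}
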