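#' Build a ConvNet architecture specification
#'
#' Two families are provided. The `simple` network has two 5x5 convolutional
#' layers (6 and 12 filters by default), each followed by ReLU and a 2x2
#' max-pool with stride 2, and a single fully-connected output layer. The
#' `vgg16` network is the canonical 13-conv/5-pool/3-FC VGG16 stack with 3x3
#' kernels and FC sizes (4096, 4096, 2). Convolutions use same-padding so
#' that only the pools change the spatial size: after each pool the height
#' and width halve exactly, which requires both dimensions to be divisible by
#' 2 at every pooling stage.
#'
#' @param family `"simple"` or `"vgg16"`.
#' @param input_shape Integer triple `(channels, height, width)`; for the
#'   concatenated images this is `(3, n * m, n)`.
#' @param conv_filters Optional override of the per-conv-layer filter counts.
#' @param fc_sizes Optional override of the fully-connected layer sizes
#'   (the final entry is forced to `n_classes`).
#' @param n_classes Number of output classes (default 2).
#' @return An `arch_spec` list with the resolved `layers` (each with its
#'   output shape), `input_shape`, `family` and default learning rate.
#' @export
build_architecture <- function(family = c("simple", "vgg16"),
                               input_shape,
                               conv_filters = NULL, fc_sizes = NULL,
                               n_classes = 2L) {
  family <- match.arg(family)
  if (length(input_shape) != 3L || any(input_shape < 1))
    stop("input_shape must be (channels, height, width)", call. = FALSE)
  input_shape <- as.integer(input_shape)
  if (input_shape[2] < 8L || input_shape[3] < 8L)
    stop("spatial dimensions must each be >= 8", call. = FALSE)

  if (family == "simple") {
    kernel <- 5L
    filters <- if (is.null(conv_filters)) c(6L, 12L) else as.integer(conv_filters)
    blocks <- as.list(filters)            # one conv per pool block
    fc <- if (is.null(fc_sizes)) integer(0) else as.integer(fc_sizes)
    lr <- 0.0023
  } else {
    kernel <- 3L
    filters <- if (is.null(conv_filters))
      c(64L, 64L, 128L, 128L, 256L, 256L, 256L,
        512L, 512L, 512L, 512L, 512L, 512L)
    else as.integer(conv_filters)
    if (length(filters) != 13L)
      stop("vgg16 requires 13 convolutional layers", call. = FALSE)
    split_sizes <- c(2L, 2L, 3L, 3L, 3L)  # convs per pool block
    blocks <- split(filters, rep(seq_along(split_sizes), split_sizes))
    fc <- if (is.null(fc_sizes)) c(4096L, 4096L) else as.integer(fc_sizes)
    lr <- 0.00023
  }

  layers <- list()
  shape <- input_shape                    # (C, H, W)
  for (bl in blocks) {
    for (f in bl) {
      layers[[length(layers) + 1L]] <- list(
        type = "conv", kernel = kernel, in_channels = shape[1],
        filters = as.integer(f), out_shape = c(f, shape[2], shape[3]))
      shape <- c(as.integer(f), shape[2], shape[3])
      layers[[length(layers) + 1L]] <- list(type = "relu", out_shape = shape)
    }
    if (shape[2] %% 2L != 0L || shape[3] %% 2L != 0L)
      stop(sprintf(
        paste("shape error: spatial dims %dx%d are not divisible by 2 at a",
              "pooling stage; choose an image size divisible by 2^(number of pools)"),
        shape[2], shape[3]), call. = FALSE)
    shape <- c(shape[1], shape[2] %/% 2L, shape[3] %/% 2L)
    layers[[length(layers) + 1L]] <- list(type = "pool", window = 2L,
                                          stride = 2L, out_shape = shape)
  }
  flat <- prod(shape)
  layers[[length(layers) + 1L]] <- list(type = "flatten", out_shape = flat)
  sizes <- c(fc, as.integer(n_classes))
  d_in <- flat
  for (i in seq_along(sizes)) {
    layers[[length(layers) + 1L]] <- list(type = "fc", d_in = d_in,
                                          d_out = sizes[i], out_shape = sizes[i])
    if (i < length(sizes))
      layers[[length(layers) + 1L]] <- list(type = "relu", out_shape = sizes[i])
    d_in <- sizes[i]
  }
  structure(list(family = family, input_shape = input_shape, layers = layers,
                 n_classes = as.integer(n_classes), default_lr = lr),
            class = "arch_spec")
}

#' Count learnable parameters of an architecture
#'
#' @param arch An `arch_spec` from [build_architecture()].
#' @param by_layer If `TRUE`, return the per-layer counts instead of the total.
#' @return Total parameter count (weights + biases), or a vector of per-layer
#'   counts.
#' @export
param_count <- function(arch, by_layer = FALSE) {
  counts <- vapply(arch$layers, function(l) {
    switch(l$type,
           conv = l$kernel^2 * l$in_channels * l$filters + l$filters,
           fc = l$d_in * l$d_out + l$d_out,
           0)
  }, numeric(1))
  if (by_layer) counts[counts > 0] else sum(counts)
}

#' @export
print.arch_spec <- function(x, ...) {
  cat(sprintf("<arch_spec> %s, input (%s), %s parameters\n", x$family,
              paste(x$input_shape, collapse = " x "),
              format(param_count(x), big.mark = ",")))
  invisible(x)
}

# He-style initialization, deterministic given seed.
init_params <- function(arch, seed) {
  with_seed(seed, {
    lapply(arch$layers, function(l) {
      if (l$type == "conv") {
        fan_in <- l$kernel^2 * l$in_channels
        list(W = array(rnorm(l$kernel^2 * l$in_channels * l$filters,
                             sd = sqrt(2 / fan_in)),
                       c(l$kernel, l$kernel, l$in_channels, l$filters)),
             b = numeric(l$filters))
      } else if (l$type == "fc") {
        list(W = matrix(rnorm(l$d_in * l$d_out, sd = sqrt(2 / l$d_in)),
                        l$d_out, l$d_in),
             b = numeric(l$d_out))
      } else NULL
    })
  })
}

# Forward pass. X: (H, W, C, N) array. Returns list(scores, caches).
net_forward <- function(arch, params, X, keep_cache = TRUE) {
  caches <- vector("list", length(arch$layers))
  A <- X
  for (i in seq_along(arch$layers)) {
    l <- arch$layers[[i]]
    if (l$type == "conv") {
      if (keep_cache) caches[[i]] <- A
      A <- cpp_conv_forward(A, params[[i]]$W, params[[i]]$b)
    } else if (l$type == "relu") {
      A <- pmax(A, 0)
      if (keep_cache) caches[[i]] <- A          # mask recoverable from output
    } else if (l$type == "pool") {
      pf <- cpp_maxpool_forward(A)
      if (keep_cache) caches[[i]] <- list(argmax = pf$argmax, xdim = dim(A))
      A <- pf$Y
    } else if (l$type == "flatten") {
      if (keep_cache) caches[[i]] <- dim(A)
      N <- dim(A)[4]
      A <- matrix(A, ncol = N)                  # D x N
    } else if (l$type == "fc") {
      if (keep_cache) caches[[i]] <- A
      A <- params[[i]]$W %*% A + params[[i]]$b  # d_out x N
    }
  }
  list(scores = A, caches = caches)
}

# Backward pass from dScores (n_classes x N); returns list of grads per layer.
net_backward <- function(arch, params, caches, dA) {
  grads <- vector("list", length(arch$layers))
  for (i in rev(seq_along(arch$layers))) {
    l <- arch$layers[[i]]
    if (l$type == "fc") {
      A_in <- caches[[i]]
      grads[[i]] <- list(dW = dA %*% t(A_in), db = rowSums(dA))
      dA <- t(params[[i]]$W) %*% dA
    } else if (l$type == "flatten") {
      dA <- array(dA, caches[[i]])
    } else if (l$type == "pool") {
      dA <- cpp_maxpool_backward(dA, caches[[i]]$argmax, caches[[i]]$xdim)
    } else if (l$type == "relu") {
      dA <- dA * (caches[[i]] > 0)
    } else if (l$type == "conv") {
      bw <- cpp_conv_backward(caches[[i]], params[[i]]$W, dA)
      grads[[i]] <- list(dW = bw$dW, db = bw$db)
      dA <- bw$dX
    }
  }
  grads
}

softmax_loss <- function(scores, labels01) {
  # scores: K x N; labels01 in {0, 1} mapped to rows 1, 2
  N <- ncol(scores)
  shifted <- sweep(scores, 2, apply(scores, 2, max))
  Z <- colSums(exp(shifted))
  logp <- sweep(shifted, 2, log(Z))
  idx <- cbind(labels01 + 1L, seq_len(N))
  loss <- -mean(logp[idx])
  P <- exp(logp)
  P[idx] <- P[idx] - 1
  list(loss = loss, dscores = P / N)
}

#' Training configuration
#'
#' @param learning_rate SGD learning rate; defaults to the architecture's
#'   published rate (0.0023 simple, 0.00023 vgg16) when `NULL`.
#' @param max_epochs Maximum number of passes over the training set.
#' @param patience Early-stopping patience: training stops when the
#'   validation loss has not improved for this many consecutive epochs, and
#'   the best-validation weights are restored.
#' @param batch_size Mini-batch size.
#' @param validation_fraction Fraction of the training instances held out for
#'   the early-stopping validation split, in (0, 0.5].
#' @param momentum SGD momentum coefficient.
#' @param seed Integer seed controlling initialization, shuffling and the
#'   validation split.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = NULL, max_epochs = 200L,
                         patience = 10L, batch_size = 16L,
                         validation_fraction = 0.1, momentum = 0.9,
                         seed = 1L) {
  if (patience < 1L) stop("patience must be >= 1", call. = FALSE)
  if (validation_fraction <= 0 || validation_fraction > 0.5)
    stop("validation_fraction must lie in (0, 0.5]", call. = FALSE)
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 validation_fraction = validation_fraction,
                 momentum = momentum, seed = as.integer(seed)),
            class = "train_config")
}

#' Train a ConvNet on a batch of images
#'
#' Minimizes the two-class softmax cross-entropy by mini-batch stochastic
#' gradient descent with momentum. A label-stratified internal validation
#' split drives early stopping: when the validation loss fails to improve
#' for `patience` consecutive epochs, training stops and the weights from
#' the best validation epoch are restored. Given the same seed, data and
#' configuration the result is bit-reproducible.
#'
#' Pixel inputs in `[0, 1]` are centered by subtracting 0.5 before the first
#' convolution (the offset is stored in the model and re-applied at
#' prediction time); zero-mean inputs condition the first-layer gradients
#' much better than all-positive ones.
#'
#' @param arch An `arch_spec`.
#' @param X Image batch, array `(H, W, C, N)` matching `arch$input_shape`
#'   (`C` channels last-but-one), or a list of `H x W x C` arrays.
#' @param labels Integer vector of 0/1 labels, length `N`; both classes must
#'   be present.
#' @param config A [train_config()].
#' @return A `trained_model` with `params`, `arch`, `history` (per-epoch
#'   train/validation losses), `stopped_epoch`, `best_epoch` and `config`.
#' @export
train_convnet <- function(arch, X, labels, config = train_config()) {
  X <- as_image_batch(X)
  input_offset <- 0.5
  X <- X - input_offset
  d <- dim(X)
  expected <- c(arch$input_shape[2], arch$input_shape[3], arch$input_shape[1])
  if (!identical(d[1:3], as.integer(expected)))
    stop(sprintf("images are %s but the architecture expects (H, W, C) = (%s)",
                 paste(d[1:3], collapse = " x "),
                 paste(expected, collapse = ", ")), call. = FALSE)
  N <- d[4]
  labels <- as.integer(labels)
  if (length(labels) != N) stop("one label per image required", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("training data must contain both classes", call. = FALSE)
  lr <- if (is.null(config$learning_rate)) arch$default_lr else config$learning_rate

  with_seed(config$seed, {
    # stratified validation split
    val_idx <- unlist(lapply(split(seq_len(N), labels), function(idx) {
      nv <- max(1L, round(length(idx) * config$validation_fraction))
      idx[sample.int(length(idx), nv)]
    }), use.names = FALSE)
    tr_idx <- setdiff(seq_len(N), val_idx)
    Xtr <- X[, , , tr_idx, drop = FALSE]; ytr <- labels[tr_idx]
    Xval <- X[, , , val_idx, drop = FALSE]; yval <- labels[val_idx]

    params <- init_params(arch, sample.int(.Machine$integer.max, 1))
    velocity <- lapply(params, function(p)
      if (is.null(p)) NULL else list(W = p$W * 0, b = p$b * 0))

    best <- list(loss = Inf, params = params, epoch = 0L)
    history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                          val_loss = numeric(0))
    wait <- 0L
    ntr <- length(tr_idx)
    for (epoch in seq_len(config$max_epochs)) {
      perm <- sample.int(ntr)
      starts <- seq(1L, ntr, by = config$batch_size)
      ep_loss <- 0
      for (s in starts) {
        bi <- perm[s:min(s + config$batch_size - 1L, ntr)]
        fw <- net_forward(arch, params, Xtr[, , , bi, drop = FALSE])
        sl <- softmax_loss(fw$scores, ytr[bi])
        ep_loss <- ep_loss + sl$loss * length(bi)
        grads <- net_backward(arch, params, fw$caches, sl$dscores)
        for (i in seq_along(params)) {
          if (is.null(params[[i]])) next
          velocity[[i]]$W <- config$momentum * velocity[[i]]$W - lr * grads[[i]]$dW
          velocity[[i]]$b <- config$momentum * velocity[[i]]$b - lr * grads[[i]]$db
          params[[i]]$W <- params[[i]]$W + velocity[[i]]$W
          params[[i]]$b <- params[[i]]$b + velocity[[i]]$b
        }
      }
      train_loss <- ep_loss / ntr
      if (!is.finite(train_loss))
        stop(sprintf("divergence: non-finite training loss at epoch %d", epoch),
             call. = FALSE)
      val_loss <- softmax_loss(net_forward(arch, params, Xval,
                                           keep_cache = FALSE)$scores, yval)$loss
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_loss = train_loss,
                                           val_loss = val_loss))
      if (val_loss < best$loss - 1e-12) {
        best <- list(loss = val_loss, params = params, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
    structure(list(arch = arch, params = best$params, history = history,
                   stopped_epoch = nrow(history), best_epoch = best$epoch,
                   config = config, learning_rate = lr,
                   input_offset = input_offset),
              class = "trained_model")
  })
}

# Accept a list of H x W x C arrays or a ready (H, W, C, N) array.
as_image_batch <- function(X) {
  if (is.array(X) && length(dim(X)) == 4L) return(X)
  if (is.list(X)) {
    if (length(X) == 0L) stop("empty image list", call. = FALSE)
    d <- dim(X[[1]])
    out <- array(0, c(d, length(X)))
    for (i in seq_along(X)) {
      if (!identical(dim(X[[i]]), d))
        stop("images in the batch differ in shape", call. = FALSE)
      out[, , , i] <- X[[i]]
    }
    return(out)
  }
  stop("X must be an (H, W, C, N) array or a list of H x W x C arrays",
       call. = FALSE)
}

#' Predict class labels for a batch of images
#'
#' Argmax of the class scores; exact ties are broken toward class 0.
#'
#' @param object A `trained_model`.
#' @param X Image batch as in [train_convnet()]; an empty list yields an
#'   empty label vector.
#' @param ... Unused.
#' @return Integer vector of 0/1 labels.
#' @export
predict.trained_model <- function(object, X, ...) {
  if (is.list(X) && length(X) == 0L) return(integer(0))
  X <- as_image_batch(X)
  d <- dim(X)
  expected <- c(object$arch$input_shape[2], object$arch$input_shape[3],
                object$arch$input_shape[1])
  if (!identical(d[1:3], as.integer(expected)))
    stop("image shape does not match the model's input shape", call. = FALSE)
  off <- if (is.null(object$input_offset)) 0 else object$input_offset
  scores <- net_forward(object$arch, object$params, X - off,
                        keep_cache = FALSE)$scores
  as.integer(scores[2, ] > scores[1, ])
}

#' Classification error rate in percent
#'
#' `(1 - #correct / N) * 100` over a held-out set.
#'
#' @param predicted,actual Equal-length label vectors.
#' @return Percentage in `[0, 100]`.
#' @examples
#' error_rate(c(1, 1, 0, 1), c(1, 1, 1, 1))  # 25
#' @export
error_rate <- function(predicted, actual) {
  if (length(predicted) != length(actual) || length(actual) < 1L)
    stop("predicted and actual must have equal length >= 1", call. = FALSE)
  (1 - mean(predicted == actual)) * 100
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS archive holding the architecture, weights,
#' training history and configuration (including the seed), sufficient to
#' reload and reproduce predictions bit-identically.
#'
#' @param model A `trained_model`.
#' @param path Checkpoint file path.
#' @return `path` (save) or the restored `trained_model` (load).
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "trained_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "trained_model"))
    stop("file is not a model checkpoint", call. = FALSE)
  model
}
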