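#' Model configuration for the image-to-profile network
#'
#' Four 3x3 "same" convolution stages (ReLU, 2x2 max pool) followed by one
#' ReLU dense layer and a linear output of chromatogram length. Trained
#' with mean absolute error under RMSProp. Channel counts and the hidden
#' width default to values that train in minutes on one CPU core; widen
#' them freely on faster hardware.
#'
#' @param layout `"stacked_5d"` (128 x 128 x 5) or `"concat_1d"`
#'   (640 x 128 x 1).
#' @param conv_channels output channels of the four convolution stages.
#' @param dense_width hidden width of the first dense layer.
#' @param n_out output length (chromatogram grid size), default 1501.
#' @param lr RMSProp learning rate.
#' @param rho RMSProp decay.
#' @param epsilon RMSProp stabilizer.
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param train_fraction fraction of pairs used for training in
#'   [split_data()].
#' @param seed integer seed for weight initialization and shuffling.
#' @export
cnn_config <- function(layout = c("stacked_5d", "concat_1d"),
                       conv_channels = c(8L, 16L, 32L, 64L),
                       dense_width = 256L, n_out = 1501L,
                       lr = 1e-3, rho = 0.9, epsilon = 1e-8,
                       batch_size = 16L, epochs = 15L,
                       train_fraction = 0.85, seed = 1L) {
  layout <- match.arg(layout)
  if (length(conv_channels) != 4L) stop_chromcast("exactly 4 convolution stages are required")
  structure(list(layout = layout, conv_channels = as.integer(conv_channels),
                 kernel = 3L, pool = 2L, dense_width = as.integer(dense_width),
                 n_out = as.integer(n_out), lr = lr, rho = rho,
                 epsilon = epsilon, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), train_fraction = train_fraction,
                 seed = as.integer(seed)),
            class = "cnn_config")
}

input_shape_for <- function(config) {
  switch(config$layout,
         stacked_5d = c(128L, 128L, 5L),
         concat_1d = c(640L, 128L, 1L))
}

#' Layer shapes and parameter count implied by a configuration
#'
#' @param config a [cnn_config()].
#' @param input_shape `(H, W, C)`; defaults to the layout's shape.
#' @return list with per-layer `shapes` and the total `n_params`.
#' @export
cnn_shapes <- function(config, input_shape = input_shape_for(config)) {
  H <- input_shape[1L]; W <- input_shape[2L]; C <- input_shape[3L]
  if (H %% 16L || W %% 16L) stop_chromcast("input height/width must be divisible by 16")
  shapes <- list()
  cin <- C
  for (l in 1:4) {
    cout <- config$conv_channels[l]
    shapes[[paste0("conv", l)]] <- c(3L, 3L, cin, cout)
    cin <- cout
    H <- H %/% 2L; W <- W %/% 2L
  }
  flat <- H * W * cin
  shapes$dense1 <- c(config$dense_width, flat)
  shapes$dense2 <- c(config$n_out, config$dense_width)
  n_params <- sum(vapply(1:4, function(l) prod(shapes[[l]]) + shapes[[l]][4L],
                         numeric(1))) +
    prod(shapes$dense1) + config$dense_width +
    prod(shapes$dense2) + config$n_out
  list(shapes = shapes, n_params = n_params, flat = flat)
}

cnn_init <- function(config, input_shape = input_shape_for(config)) {
  sh <- cnn_shapes(config, input_shape)$shapes
  with_seed(config$seed, {
    w <- list()
    for (l in 1:4) {
      d <- sh[[paste0("conv", l)]]
      fan_in <- prod(d[1:3])
      w[[2L * l - 1L]] <- array(rnorm(prod(d), sd = sqrt(2 / fan_in)), dim = d)
      w[[2L * l]] <- rep(0, d[4L])
    }
    d1 <- sh$dense1
    w[[9L]] <- matrix(rnorm(prod(d1), sd = sqrt(2 / d1[2L])), d1[1L], d1[2L])
    w[[10L]] <- rep(0, d1[1L])
    d2 <- sh$dense2
    w[[11L]] <- matrix(rnorm(prod(d2), sd = sqrt(1 / d2[2L])), d2[1L], d2[2L])
    w[[12L]] <- rep(0, d2[1L])
    w
  })
}

zeros_like <- function(w) {
  lapply(w, function(x) {
    z <- x
    z[] <- 0
    z
  })
}

#' Train the convolutional network on a pair dataset
#'
#' @param config a [cnn_config()].
#' @param pairs a [pair_dataset()] (tensors plus per-pair targets).
#' @param pair_idx indices of the pairs to train on (default all).
#' @param val_idx optional indices evaluated after every epoch.
#' @param verbose print per-epoch losses.
#' @return a `trained_model` with `weights`, `config`, the per-epoch
#'   `history`, and the split record.
#' @export
train_cnn <- function(config, pairs, pair_idx = NULL, val_idx = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(config, "cnn_config"), inherits(pairs, "pair_dataset"))
  tdim <- dim(pairs$tensors)
  if (length(tdim) != 4L) stop_chromcast("tensors must be a (H, W, C, T) array")
  n_out <- nrow(pairs$targets)
  if (n_out != config$n_out) {
    stop_chromcast("target length %d does not match config n_out = %d", n_out, config$n_out)
  }
  pair_idx <- pair_idx %||% seq_len(ncol(pairs$targets))
  weights <- cnn_init(config, tdim[1:3])
  cache <- zeros_like(weights)
  history <- data.frame(epoch = integer(0), train_mae = numeric(0),
                        val_mae = numeric(0))
  orders <- with_seed(child_seed(config$seed, "shuffle"),
                      lapply(seq_len(config$epochs), function(e) sample(pair_idx)))
  for (e in seq_len(config$epochs)) {
    res <- cpp_cnn_train_epoch(pairs$tensors, as.integer(tdim[1:3]),
                               as.integer(pairs$pair_tensor),
                               pairs$targets, as.integer(orders[[e]]),
                               weights, cache,
                               config$lr, config$rho, config$epsilon,
                               config$batch_size)
    weights <- res$weights
    cache <- res$cache
    val_mae <- NA_real_
    if (!is.null(val_idx) && length(val_idx)) {
      pv <- predict_pairs(weights, pairs, val_idx)
      val_mae <- mean(abs(pv - pairs$targets[, val_idx, drop = FALSE]))
    }
    history <- rbind(history, data.frame(epoch = e, train_mae = res$loss,
                                         val_mae = val_mae))
    if (verbose) {
      message(sprintf("epoch %d/%d train MAE %.5f%s", e, config$epochs, res$loss,
                      if (is.na(val_mae)) "" else sprintf(" val MAE %.5f", val_mae)))
    }
  }
  structure(list(weights = weights, config = config, history = history,
                 train_idx = pair_idx, input_shape = tdim[1:3]),
            class = "trained_model")
}

predict_pairs <- function(weights, pairs, pair_idx) {
  tdim <- dim(pairs$tensors)
  tidx <- pairs$pair_tensor[pair_idx]
  cpp_cnn_predict(pairs$tensors, as.integer(tdim[1:3]), as.integer(tidx), weights)
}

#' Predict log-concentration profiles for held-out pairs
#'
#' @param object a `trained_model`.
#' @param pairs the [pair_dataset()] the model indexes into (or a bare
#'   tensor array of matching shape).
#' @param pair_idx pair indices to predict; default all.
#' @param ... unused.
#' @return matrix `n_out x length(pair_idx)` of predicted `y*(t)` values.
#' @export
predict.trained_model <- function(object, pairs, pair_idx = NULL, ...) {
  if (is.array(pairs) && length(dim(pairs)) %in% c(3L, 4L)) {
    arr <- if (length(dim(pairs)) == 3L) array(pairs, dim = c(dim(pairs), 1L)) else pairs
    if (!all(dim(arr)[1:3] == object$input_shape)) {
      stop_chromcast("tensor shape (%s) does not match the trained input shape (%s)",
                     paste(dim(arr)[1:3], collapse = "x"),
                     paste(object$input_shape, collapse = "x"))
    }
    return(cpp_cnn_predict(arr, as.integer(dim(arr)[1:3]),
                           seq_len(dim(arr)[4L]), object$weights))
  }
  stopifnot(inherits(pairs, "pair_dataset"))
  if (!all(dim(pairs$tensors)[1:3] == object$input_shape)) {
    stop_chromcast("pair tensors do not match the trained input shape")
  }
  pair_idx <- pair_idx %||% seq_len(ncol(pairs$targets))
  predict_pairs(object$weights, pairs, pair_idx)
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> %s, %d epochs, final train MAE %.5f\n",
              x$config$layout, nrow(x$history),
              tail(x$history$train_mae, 1L)))
  invisible(x)
}

#' Split pairs into training and test sets
#'
#' Seeded, disjoint, exhaustive. With `group_by_plant = TRUE` (the default)
#' all augmented images of one plant land on the same side, preventing the
#' leakage that per-pair splitting of augmented copies would cause.
#'
#' @param pairs a [pair_dataset()], or an integer pair count.
#' @param train_fraction fraction assigned to training.
#' @param seed integer seed.
#' @param group_by_plant keep each plant's pairs on one side.
#' @return list with integer `train` and `test` index vectors.
#' @export
split_data <- function(pairs, train_fraction = 0.85, seed = 1L,
                       group_by_plant = TRUE) {
  n <- if (inherits(pairs, "pair_dataset")) ncol(pairs$targets) else as.integer(pairs)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop_chromcast("train_fraction must lie strictly between 0 and 1")
  }
  min_frac <- min(train_fraction, 1 - train_fraction)
  if (n < 10L || n < ceiling(1 / min_frac)) {
    stop_chromcast("too few pairs (%d) to split at fraction %.2f", n, train_fraction)
  }
  groups <- if (group_by_plant && inherits(pairs, "pair_dataset") &&
                !is.null(pairs$plant)) pairs$plant else seq_len(n)
  sizes <- table(groups)
  ids <- names(sizes)
  ord <- with_seed(seed, sample(length(ids)))
  train_ids <- character(0)
  total <- 0L
  target <- train_fraction * n
  for (g in ids[ord]) {
    if (total >= target) break
    train_ids <- c(train_ids, g)
    total <- total + sizes[[g]]
  }
  # never let the training side swallow every group
  if (length(train_ids) == length(ids)) train_ids <- train_ids[-length(train_ids)]
  train <- which(as.character(groups) %in% train_ids)
  test <- setdiff(seq_len(n), train)
  if (!length(test) || !length(train)) {
    stop_chromcast("split produced an empty side; too few groups")
  }
  list(train = train, test = test)
}
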