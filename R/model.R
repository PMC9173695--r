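#' Model and training configuration
#'
#' Architecture and optimisation settings of the transcript classifier:
#' three convolution blocks (kernel 57, stride 1, each followed by ReLU,
#' max-pooling of 2 and dropout 0.3), two dense layers of 256 units with
#' dropout 0.5, and a 2-way softmax head, trained with plain SGD (momentum
#' 0.9, learning rate 0.01, 120 epochs, batch size 128). The number of
#' filters per convolution is an open architectural knob (default 128).
#'
#' @param n_conv_blocks Number of convolution blocks.
#' @param kernel_size Convolution kernel width (odd).
#' @param stride Convolution stride.
#' @param filters_per_block Filters in each convolution.
#' @param pool_size Max-pooling width (2).
#' @param conv_dropout Dropout rate after each pooling layer.
#' @param dense_units Integer vector of dense-layer widths.
#' @param dense_dropout Dropout rate after each dense layer.
#' @param input_length Fixed input length in nucleotides; shorter sequences
#'   are zero-padded.
#' @param learning_rate,momentum,epochs,batch_size SGD settings.
#' @param seed Integer seed for weight initialisation and batch shuffling.
#' @return An object of class `model_config`.
#' @export
model_config <- function(n_conv_blocks = 3L, kernel_size = 57L, stride = 1L,
                         filters_per_block = 128L, pool_size = 2L,
                         conv_dropout = 0.3, dense_units = c(256L, 256L),
                         dense_dropout = 0.5, input_length = 3000L,
                         learning_rate = 0.01, momentum = 0.9,
                         epochs = 120L, batch_size = 128L, seed = 1L) {
  config <- list(n_conv_blocks = as.integer(n_conv_blocks),
                 kernel_size = as.integer(kernel_size),
                 stride = as.integer(stride),
                 filters_per_block = as.integer(filters_per_block),
                 pool_size = as.integer(pool_size),
                 conv_dropout = conv_dropout,
                 dense_units = as.integer(dense_units),
                 dense_dropout = dense_dropout,
                 n_classes = 2L,
                 input_length = as.integer(input_length),
                 learning_rate = learning_rate, momentum = momentum,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed))
  class(config) <- "model_config"
  validate_config(config)
  config
}

validate_config <- function(config) {
  with(config, {
    if (kernel_size < 1L || kernel_size %% 2L == 0L) {
      stop("kernel_size must be odd and >= 1", call. = FALSE)
    }
    if (pool_size != 2L) stop("only pool_size = 2 is supported",
                              call. = FALSE)
    if (stride < 1L) stop("stride must be >= 1", call. = FALSE)
    if (conv_dropout < 0 || conv_dropout >= 1 ||
        dense_dropout < 0 || dense_dropout >= 1) {
      stop("dropout rates must lie in [0, 1)", call. = FALSE)
    }
    if (input_length < kernel_size) {
      stop("input_length must be >= kernel_size", call. = FALSE)
    }
  })
  if (any(layer_lengths(config) < 1L)) {
    stop("input_length ", config$input_length, " is too small for ",
         config$n_conv_blocks, " pool-by-", config$pool_size, " stages",
         call. = FALSE)
  }
  invisible(config)
}

#' Scaled-down configuration for desk-scale experiments
#'
#' Same architecture family as [model_config()] but sized so training and
#' explanation complete in minutes on one CPU: 16 filters, 600-nt inputs,
#' 30 epochs, mini-batches of 32 (small datasets need smaller batches to get
#' enough gradient steps per epoch) and light dropout (0.1 conv / 0.2
#' dense — the published rates assume corpus-scale data and 120 epochs;
#' at a few hundred sequences they keep the small network under-trained).
#' All arguments of [model_config()] can be overridden.
#'
#' @param ... Overrides passed to [model_config()].
#' @return An object of class `model_config`.
#' @export
scaled_model_config <- function(...) {
  args <- utils::modifyList(list(filters_per_block = 16L,
                                 input_length = 600L, epochs = 30L,
                                 batch_size = 32L, conv_dropout = 0.1,
                                 dense_dropout = 0.2), list(...))
  do.call(model_config, args)
}

#' @export
print.model_config <- function(x, ...) {
  cat("<model_config> ", x$n_conv_blocks, " conv blocks (k=", x$kernel_size,
      ", stride=", x$stride, ", ", x$filters_per_block, " filters) -> dense ",
      paste(x$dense_units, collapse = "/"),
      " -> softmax 2; input ", x$input_length, " nt\n", sep = "")
  cat("  SGD: lr=", x$learning_rate, " momentum=", x$momentum,
      " epochs=", x$epochs, " batch=", x$batch_size,
      " seed=", x$seed, "\n", sep = "")
  invisible(x)
}

#' Build an (untrained) transcript classifier
#'
#' Initialises weights with He-scaled Gaussians (biases at zero, so an
#' all-zero input always scores exactly 0.5/0.5) under the config seed.
#'
#' @param config A [model_config()].
#' @return An object of class `lnc_cnn` carrying the parameter store, the
#'   config, and the class-index map (`mRNA` = 0, `lncRNA` = 1) that is
#'   serialised together with the weights.
#' @export
build_model <- function(config) {
  validate_config(config)
  he <- function(dims, fan_in) array(stats::rnorm(prod(dims), 0,
                                                  sqrt(2 / fan_in)), dims)
  lens <- layer_lengths(config)
  params <- withr::with_seed(config$seed, {
    conv <- vector("list", config$n_conv_blocks)
    cin <- 4L
    for (i in seq_len(config$n_conv_blocks)) {
      conv[[i]] <- list(
        W = he(c(config$kernel_size, cin, config$filters_per_block),
               config$kernel_size * cin),
        b = numeric(config$filters_per_block))
      cin <- config$filters_per_block
    }
    dense <- vector("list", length(config$dense_units))
    fan <- lens[config$n_conv_blocks] * config$filters_per_block
    for (j in seq_along(config$dense_units)) {
      dense[[j]] <- list(W = he(c(fan, config$dense_units[j]), fan),
                         b = numeric(config$dense_units[j]))
      fan <- config$dense_units[j]
    }
    out <- list(W = he(c(fan, 2L), fan), b = numeric(2L))
    list(conv = conv, dense = dense, out = out)
  })
  structure(list(params = params, config = config,
                 class_map = c(mRNA = 0L, lncRNA = 1L),
                 history = NULL, trained = FALSE,
                 schema_version = 1L),
            class = "lnc_cnn")
}

#' Number of trainable parameters
#'
#' @param model An `lnc_cnn`.
#' @return Integer parameter count.
#' @export
n_params <- function(model) {
  sum(rapply(model$params, length, how = "unlist"))
}

#' Train the classifier with SGD
#'
#' Mini-batch stochastic gradient descent with momentum on the two-class
#' cross-entropy. Batches are reshuffled every epoch; dropout is active.
#' The run is deterministic for a given config seed (all randomness flows
#' through R's RNG, restored afterwards).
#'
#' @param model An `lnc_cnn` from [build_model()].
#' @param data An [encode_dataset()] result with labels from both classes and
#'   `max_len` equal to the model input length.
#' @param epochs Optional override of the configured epoch count.
#' @param verbose Print one line per epoch.
#' @return The trained `lnc_cnn`, with a per-epoch `history` tibble
#'   (`epoch`, `loss`, `accuracy`).
#' @export
train_model <- function(model, data, epochs = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "lnc_cnn"), inherits(data, "encoded_dataset"))
  config <- model$config
  check_input_length(data, config)
  if (is.null(data$labels)) stop("training data must be labelled",
                                 call. = FALSE)
  y <- as.integer(data$labels) - 1L   # mRNA=0, lncRNA=1
  if (length(unique(y)) < 2L) {
    stop("training set contains a single class; need both lncRNA and mRNA",
         call. = FALSE)
  }
  if (!is.null(epochs)) config$epochs <- as.integer(epochs)
  params <- model$params
  vel <- rapply(params, function(p) p * 0, how = "replace")
  n <- length(y)
  hist_loss <- hist_acc <- numeric(config$epochs)
  withr::with_seed(config$seed + 1L, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      ep_loss <- ep_correct <- 0
      for (b in batches) {
        Xb <- data$tensor[b, , , drop = FALSE]
        yb <- y[b]
        fw <- nn_forward(params, config, Xb, training = TRUE, keep = TRUE)
        p_true <- fw$probs[cbind(seq_along(b), yb + 1L)]
        ep_loss <- ep_loss - sum(log(pmax(p_true, 1e-12)))
        ep_correct <- ep_correct + sum((fw$probs[, 2L] >= 0.5) == (yb == 1L))
        g <- nn_backward(params, config, fw, Xb, yb)
        upd <- sgd_update(params, vel, g, config$learning_rate,
                          config$momentum)
        params <- upd$params
        vel <- upd$vel
      }
      hist_loss[ep] <- ep_loss / n
      hist_acc[ep] <- ep_correct / n
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  acc %.4f", ep,
                        hist_loss[ep], hist_acc[ep]))
      }
    }
  })
  model$params <- params
  model$config <- config
  model$trained <- TRUE
  model$history <- tibble::tibble(epoch = seq_len(config$epochs),
                                  loss = hist_loss, accuracy = hist_acc)
  model
}

sgd_update <- function(params, vel, g, lr, momentum) {
  for (i in seq_along(params$conv)) {
    for (nm in c("W", "b")) {
      vel$conv[[i]][[nm]] <- momentum * vel$conv[[i]][[nm]] -
        lr * g$conv[[i]][[nm]]
      params$conv[[i]][[nm]] <- params$conv[[i]][[nm]] + vel$conv[[i]][[nm]]
    }
  }
  for (j in seq_along(params$dense)) {
    for (nm in c("W", "b")) {
      vel$dense[[j]][[nm]] <- momentum * vel$dense[[j]][[nm]] -
        lr * g$dense[[j]][[nm]]
      params$dense[[j]][[nm]] <- params$dense[[j]][[nm]] +
        vel$dense[[j]][[nm]]
    }
  }
  for (nm in c("W", "b")) {
    vel$out[[nm]] <- momentum * vel$out[[nm]] - lr * g$out[[nm]]
    params$out[[nm]] <- params$out[[nm]] + vel$out[[nm]]
  }
  list(params = params, vel = vel)
}

check_input_length <- function(data, config) {
  if (data$max_len != config$input_length) {
    stop("input length mismatch: model expects ", config$input_length,
         " nt, received ", data$max_len, call. = FALSE)
  }
  invisible(TRUE)
}

#' Predict class probabilities for transcripts
#'
#' Runs the network in inference mode (dropout off; deterministic). The
#' decision threshold is 0.5 on the lncRNA probability, ties going to
#' lncRNA (the positive class).
#'
#' @param object A trained `lnc_cnn`.
#' @param newdata An [encode_dataset()] result or a records tibble (encoded
#'   on the fly at the model's input length).
#' @param batch_size Internal evaluation chunk size.
#' @param ... Unused.
#' @return A tibble with columns `id`, `p_lncRNA`, `p_mRNA`,
#'   `predicted_label`, in input order.
#' @export
predict.lnc_cnn <- function(object, newdata, batch_size = 256L, ...) {
  if (!inherits(newdata, "encoded_dataset")) {
    newdata <- encode_dataset(newdata, max_len = object$config$input_length,
                              require_labels = FALSE)
  }
  check_input_length(newdata, object$config)
  n <- length(newdata$ids)
  p_lnc <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    fw <- nn_forward(object$params, object$config,
                     newdata$tensor[idx, , , drop = FALSE])
    p_lnc[idx] <- fw$probs[, 2L]
  }
  tibble::tibble(id = newdata$ids, p_lncRNA = p_lnc, p_mRNA = 1 - p_lnc,
                 predicted_label = ifelse(p_lnc >= 0.5, "lncRNA", "mRNA"))
}

#' @export
print.lnc_cnn <- function(x, ...) {
  cat("<lnc_cnn> ", if (x$trained) "trained" else "untrained",
      " transcript classifier, ", format(n_params(x), big.mark = ","),
      " parameters\n", sep = "")
  print(x$config)
  if (!is.null(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  final epoch: loss %.4f, accuracy %.4f\n",
                last$loss, last$accuracy))
  }
  invisible(x)
}

#' Save / load a model artifact
#'
#' The artifact is a single-file container (RDS) holding weights, config,
#' class map and a schema version; a round-trip reproduces predictions
#' bit-for-bit.
#'
#' @param model A `lnc_cnn`.
#' @param path File path for the artifact.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   `lnc_cnn`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "lnc_cnn"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  model <- readRDS(path)
  if (!inherits(model, "lnc_cnn") || is.null(model$schema_version)) {
    stop("not a lnc_cnn model artifact: ", path, call. = FALSE)
  }
  model
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training history of a fitted classifier
#'
#' @param x A trained `lnc_cnn`.
#' @param ... Unused.
#' @return A tibble with one row per epoch: `epoch`, `loss`, `accuracy`.
#' @export
tidy.lnc_cnn <- function(x, ...) {
  if (is.null(x$history)) {
    return(tibble::tibble(epoch = integer(), loss = numeric(),
                          accuracy = numeric()))
  }
  x$history
}

#' One-row summary of a classifier
#'
#' @param x A `lnc_cnn`.
#' @param ... Unused.
#' @return A one-row tibble: `n_params`, `trained`, `epochs`, `final_loss`,
#'   `final_accuracy`.
#' @export
glance.lnc_cnn <- function(x, ...) {
  tibble::tibble(
    n_params = n_params(x), trained = x$trained,
    epochs = if (is.null(x$history)) 0L else nrow(x$history),
    final_loss = if (is.null(x$history)) NA_real_ else
      x$history$loss[nrow(x$history)],
    final_accuracy = if (is.null(x$history)) NA_real_ else
      x$history$accuracy[nrow(x$history)])
}
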