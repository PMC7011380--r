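# Network specification, construction, training and prediction.
#
# The benchmark architecture is: GloVe-initialised embedding (16 x d) ->
# bidirectional LSTM -> five 1-D convolution stages -> dense(20) ->
# dense(2) with a softmax classification head (the regression head ends in
# dense(1) with a sigmoid). Batch normalization and dropout are interposed
# between stages; the ablation variants remove or reorder stages.

OTNET_VARIANTS <- c("full", "no_lstm", "conv_lstm", "no_batchnorm",
                    "no_dropout")

#' Specify a network variant
#'
#' @param variant One of `"full"` (the benchmark: recurrence before
#'   convolutions, with batch normalization and dropout), `"no_lstm"` (no
#'   recurrent stage), `"conv_lstm"` (all five convolution stages before the
#'   recurrent stage), `"no_batchnorm"` (no normalization stages),
#'   `"no_dropout"` (no dropout stages).
#' @param head `"classification"` (softmax over 2 classes) or `"regression"`
#'   (sigmoid cleavage-frequency output).
#' @param embedding_dim Token-vector dimension `d` (default 100).
#' @param recurrent_units LSTM units per direction (default 30).
#' @param recurrent_out Combined biLSTM output width (default
#'   `2 * recurrent_units`).
#' @param conv_filters Five filter counts (default `c(10, 20, 40, 80, 100)`).
#' @param conv_kernels Five kernel sizes (default `c(5, 5, 3, 3, 3)`).
#' @param dense_sizes Fully connected sizes, `c(20, 2)`; the regression head
#'   replaces the final 2 with 1.
#' @param dropout_rate Dropout probability (default 0.3).
#' @return List of class `otnet_spec`.
#' @export
network_spec <- function(variant = OTNET_VARIANTS,
                         head = c("classification", "regression"),
                         embedding_dim = 100L,
                         recurrent_units = 30L,
                         recurrent_out = 2L * recurrent_units,
                         conv_filters = c(10L, 20L, 40L, 80L, 100L),
                         conv_kernels = c(5L, 5L, 3L, 3L, 3L),
                         dense_sizes = c(20L, 2L),
                         dropout_rate = 0.3) {
  variant <- match.arg(variant)
  head <- match.arg(head)
  if (length(conv_filters) != 5L || length(conv_kernels) != 5L) {
    stopf("exactly five convolution stages are required")
  }
  if (length(dense_sizes) != 2L || dense_sizes[1] != 20L ||
      dense_sizes[2] != 2L) {
    stopf("dense sizes are fixed at (20, 2)")
  }
  structure(list(variant = variant, head = head,
                 embedding_dim = as.integer(embedding_dim),
                 recurrent_units = as.integer(recurrent_units),
                 recurrent_out = as.integer(recurrent_out),
                 conv_filters = as.integer(conv_filters),
                 conv_kernels = as.integer(conv_kernels),
                 dense_sizes = as.integer(dense_sizes),
                 dropout_rate = dropout_rate),
            class = "otnet_spec")
}

#' Build an untrained network from a spec
#'
#' Layer parameters are initialised from the current RNG state (seed it for
#' reproducibility); the embedding stage is initialised from the supplied
#' GloVe matrix and fine-tuned during supervised training unless
#' `freeze_embedding`.
#'
#' @param spec An `otnet_spec`.
#' @param embedding_init Numeric `16 x embedding_dim` matrix (e.g. from
#'   [fit_glove()]); `NULL` gives a small random initialisation.
#' @param freeze_embedding If `TRUE` the embedding receives no updates.
#' @return List of class `otnet_arch` with fields `layers`, `spec`,
#'   `freeze_embedding`.
#' @export
build_network <- function(spec, embedding_init = NULL,
                          freeze_embedding = FALSE) {
  stopifnot(inherits(spec, "otnet_spec"))
  d <- spec$embedding_dim
  if (is.null(embedding_init)) {
    embedding_init <- matrix(stats::runif(16L * d, -0.05, 0.05), 16L, d)
  }
  if (!all(dim(embedding_init) == c(16L, d))) {
    stopf("embedding_init must be 16 x %d, got %d x %d", d,
          nrow(embedding_init), ncol(embedding_init))
  }
  if (any(!is.finite(embedding_init))) {
    stopf("embedding_init contains non-finite values")
  }
  use_bn <- spec$variant != "no_batchnorm"
  use_do <- spec$variant != "no_dropout"
  use_lstm <- spec$variant != "no_lstm"
  conv_first <- spec$variant == "conv_lstm"
  layers <- list(layer_embedding(unname(embedding_init)))
  add <- function(ly) layers[[length(layers) + 1L]] <<- ly

  recurrent_block <- function(c_in) {
    add(layer_bilstm(c_in, spec$recurrent_units, spec$recurrent_out))
    if (use_bn) add(layer_batchnorm(spec$recurrent_out))
    if (use_do) add(layer_dropout(spec$dropout_rate))
    spec$recurrent_out
  }
  conv_block <- function(c_in) {
    for (s in 1:5) {
      add(layer_conv1d(c_in, spec$conv_filters[s], spec$conv_kernels[s],
                       activation = "linear"))
      if (use_bn) add(layer_batchnorm(spec$conv_filters[s]))
      add(layer_relu())
      c_in <- spec$conv_filters[s]
    }
    c_in
  }

  width <- d
  if (conv_first) {
    width <- conv_block(width)
    width <- recurrent_block(width)
  } else {
    if (use_lstm) width <- recurrent_block(width)
    width <- conv_block(width)
  }
  add(layer_flatten())
  if (use_do) add(layer_dropout(spec$dropout_rate))
  # normalization between the wide flatten->dense stage and its ReLU keeps
  # the 20 hidden units alive at the high Adam learning rate
  if (use_bn) {
    add(layer_dense(23L * width, spec$dense_sizes[1], activation = "linear"))
    add(layer_batchnorm(spec$dense_sizes[1]))
    add(layer_relu())
  } else {
    add(layer_dense(23L * width, spec$dense_sizes[1], activation = "relu"))
  }
  out_dim <- if (spec$head == "classification") spec$dense_sizes[2] else 1L
  add(layer_dense(spec$dense_sizes[1], out_dim, activation = "linear"))
  structure(list(layers = layers, spec = spec,
                 freeze_embedding = freeze_embedding),
            class = "otnet_arch")
}

#' Structural audit of a built network
#'
#' @param arch An `otnet_arch` (or a trained model).
#' @return List with the ordered `stage_kinds`, counts of normalization /
#'   dropout / recurrent / convolution stages, `n_parameters`, and whether
#'   convolutions precede the recurrent stage.
#' @export
audit_network <- function(arch) {
  if (inherits(arch, "otnet")) arch <- arch$network
  kinds <- vapply(arch$layers, function(ly) ly$kind, character(1))
  conv_pos <- which(kinds == "conv")
  lstm_pos <- which(kinds == "bilstm")
  list(stage_kinds = kinds,
       n_batchnorm = sum(kinds == "batchnorm"),
       n_dropout = sum(kinds == "dropout"),
       n_recurrent = length(lstm_pos),
       n_conv = length(conv_pos),
       n_parameters = n_parameters(arch$layers),
       conv_before_recurrent = length(lstm_pos) > 0L &&
         length(conv_pos) > 0L && min(conv_pos) < min(lstm_pos))
}

batch_loss <- function(arch, tokens, target) {
  logits <- forward_network(arch$layers, tokens, training = TRUE)
  if (arch$spec$head == "classification") {
    loss_softmax_xent(logits, target)
  } else {
    loss_sigmoid_mse(logits, target)
  }
}

eval_loss <- function(arch, tokens, target) {
  logits <- forward_network(arch$layers, tokens, training = FALSE)
  if (arch$spec$head == "classification") {
    loss_softmax_xent(logits, target)$loss
  } else {
    loss_sigmoid_mse(logits, target)$loss
  }
}

clone_params <- function(arch) lapply(arch$layers, function(ly) ly$params)

restore_params <- function(arch, snapshot) {
  for (i in seq_along(arch$layers)) arch$layers[[i]]$params <- snapshot[[i]]
  invisible(arch)
}

#' Train a network on an off-target dataset
#'
#' Runs the imbalance-aware sampler epoch by epoch and optimises the
#' two-class cross-entropy (classification) or the mean squared error on
#' cleavage frequency (regression) with Adam at learning rate 0.01. A fresh
#' batch plan is drawn each epoch (leftover negatives re-enter the next
#' shuffle). Optional early stopping monitors a held-out validation split.
#' Deterministic given `seed` (single-threaded BLAS assumed).
#'
#' @param train An off-target dataset containing both classes.
#' @param spec An `otnet_spec`.
#' @param embedding_init Optional `16 x d` embedding initialisation.
#' @param m Sampler batch-size parameter (default 256).
#' @param composition Sampler batch composition, see [plan_batches()].
#' @param epochs Maximum epochs (default 100).
#' @param learning_rate Adam learning rate (default 0.01).
#' @param seed Integer seed covering initialisation, sampling and dropout.
#' @param validation_fraction Fraction held out for early stopping (default
#'   0.1; 0 disables).
#' @param patience Epochs without validation improvement before stopping
#'   (default 10).
#' @param freeze_embedding Do not update the embedding stage.
#' @param verbose Print per-epoch progress.
#' @return List of class `otnet_model`: `arch` (with fitted parameters),
#'   `spec`, `training_log` (per-batch losses), `epoch_log`, `seed`.
#' @export
train_network <- function(train, spec, embedding_init = NULL, m = 256L,
                          composition = "balanced", epochs = 100L,
                          learning_rate = 0.01, seed = 1L,
                          validation_fraction = 0.1, patience = 10L,
                          freeze_embedding = FALSE, verbose = FALSE) {
  if (spec$head == "classification" && length(unique(train$label)) < 2L) {
    stopf("classification training needs both classes")
  }
  if (spec$head == "regression" && all(train$frequency == 0)) {
    stopf("regression training needs positive frequencies")
  }
  val <- NULL
  if (validation_fraction > 0 && patience > 0 && epochs > 1L) {
    sp <- split_train_test(train, validation_fraction,
                           seed = subseed(seed, 900000L))
    # keep the validation split only if both parts remain trainable
    if (length(unique(sp$train$label)) == 2L &&
        nrow(sp$test) >= 2L) {
      val <- sp$test
      train <- sp$train
    }
  }
  tokens <- encode_dataset(train)
  target_all <- if (spec$head == "classification") train$label else
    train$frequency
  val_tokens <- if (!is.null(val)) encode_dataset(val)
  val_target <- if (!is.null(val)) {
    if (spec$head == "classification") val$label else val$frequency
  }
  local_seed(subseed(seed, 0L), {
    arch <- build_network(spec, embedding_init,
                          freeze_embedding = freeze_embedding)
    training_log <- numeric(0)
    epoch_log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                            val_loss = numeric(0))
    best_val <- Inf; best_snapshot <- NULL; stall <- 0L; step <- 0L
    for (ep in seq_len(epochs)) {
      plan <- plan_batches(train$label, m = m, seed = subseed(seed, ep),
                           composition = composition)
      ep_losses <- numeric(length(plan$negatives))
      for (bi in seq_along(plan$negatives)) {
        idx <- c(plan$negatives[[bi]], plan$positives[[bi]])
        idx <- sample(idx)                      # interleave classes
        res <- batch_loss(arch, tokens[idx, , drop = FALSE],
                          target_all[idx])
        if (!is.finite(res$loss)) {
          if (!is.null(best_snapshot)) restore_params(arch, best_snapshot)
          stopf("non-finite loss at epoch %d batch %d; training aborted at last good checkpoint",
                ep, bi)
        }
        backward_network(arch$layers, res$grad)
        if (arch$freeze_embedding) arch$layers[[1]]$grads <- NULL
        step <- step + 1L
        adam_step(arch$layers, learning_rate, step)
        ep_losses[bi] <- res$loss
      }
      training_log <- c(training_log, ep_losses)
      vl <- if (!is.null(val)) eval_loss(arch, val_tokens, val_target) else NA
      epoch_log <- rbind(epoch_log, data.frame(
        epoch = ep, train_loss = mean(ep_losses), val_loss = vl))
      if (verbose) {
        message(sprintf("epoch %3d  train %.4f  val %s", ep,
                        mean(ep_losses),
                        if (is.na(vl)) "-" else sprintf("%.4f", vl)))
      }
      if (!is.null(val)) {
        if (vl < best_val - 1e-6) {
          best_val <- vl
          best_snapshot <- clone_params(arch)
          stall <- 0L
        } else {
          stall <- stall + 1L
          if (stall >= patience) break
        }
      }
    }
    if (!is.null(best_snapshot)) restore_params(arch, best_snapshot)
    structure(list(arch = arch, spec = spec, training_log = training_log,
                   epoch_log = epoch_log, seed = as.integer(seed)),
              class = "otnet_model")
  })
}

#' Predict scores for a dataset with a trained network
#'
#' Classification returns the class-1 (off-target) probability, regression
#' the predicted cleavage frequency; both lie in `[0, 1]` and follow input
#' order. Inference uses running batch-norm statistics and no dropout.
#'
#' @param model An `otnet_model` (or `otnet` fit).
#' @param data An off-target dataset, or a pre-encoded token matrix.
#' @param batch_size Forward-pass chunk size (memory bound only).
#' @return Numeric score vector.
#' @export
predict_network <- function(model, data, batch_size = 2048L) {
  arch <- if (inherits(model, "otnet")) model$model$arch else model$arch
  tokens <- if (is.matrix(data)) data else encode_dataset(data)
  n <- nrow(tokens)
  out <- numeric(n)
  starts <- seq(1L, n, by = batch_size)
  for (s in starts) {
    e <- min(s + batch_size - 1L, n)
    chunk <- tokens[s:e, , drop = FALSE]
    if (nrow(chunk) == 1L) {  # batch dimension must survive slicing
      chunk <- rbind(chunk, chunk)
      logits <- forward_network(arch$layers, chunk, training = FALSE)
      logits <- logits[1L, , drop = FALSE]
    } else {
      logits <- forward_network(arch$layers, chunk, training = FALSE)
    }
    out[s:e] <- if (arch$spec$head == "classification") {
      softmax_rows(logits)[, 2L]
    } else {
      sigmoid(logits[, 1L])
    }
  }
  out
}
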