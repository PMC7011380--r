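# The user-facing model interface: one fitting function and S3 methods.

#' Fit an off-target propensity network
#'
#' End-to-end fit on an off-target dataset: encodes every sgRNA-DNA pair
#' into its length-23 token vector, builds the 16-token co-occurrence matrix
#' of the training corpus and trains GloVe token vectors on it, then trains
#' the requested network variant with the imbalance-aware batch sampler.
#'
#' @param data An off-target dataset (see [read_offtarget_table()] or
#'   [simulate_offtarget_dataset()]).
#' @param variant Network variant, see [network_spec()].
#' @param head `"classification"` or `"regression"`.
#' @param embedding Either `NULL` (train GloVe on `data`, the default), a
#'   precomputed `16 x embedding_dim` matrix, or a `glove_fit`.
#' @param glove_window,glove_iterations Corpus embedding settings (defaults
#'   5 and 1000).
#' @param epochs,m,learning_rate,validation_fraction,patience,composition
#'   Training settings forwarded to [train_network()].
#' @param seed Integer seed governing embedding training, initialisation,
#'   sampling and dropout.
#' @param ... Further arguments to [network_spec()] (e.g. `conv_filters`,
#'   `recurrent_units`, `dropout_rate`).
#' @return An object of class `otnet` with `print()`, `summary()`,
#'   `predict()`, `plot()`, `coef()` and `residuals()` methods.
#' @export
#' @examples
#' d <- simulate_offtarget_dataset(n_sgrnas = 2, sites_per_sgrna = 150,
#'                                 imbalance_ratio = 10, seed = 3)
#' fit <- otnet(d, epochs = 2, m = 16, embedding_dim = 8,
#'              recurrent_units = 4, conv_filters = c(4, 4, 4, 4, 4),
#'              validation_fraction = 0, seed = 3)
#' head(predict(fit, d))
otnet <- function(data, variant = "full",
                  head = c("classification", "regression"),
                  embedding = NULL, glove_window = 5L,
                  glove_iterations = 1000L, epochs = 100L, m = 256L,
                  learning_rate = 0.01, validation_fraction = 0.1,
                  patience = 10L, composition = "balanced", seed = 1L,
                  ...) {
  head <- match.arg(head)
  cl <- match.call()
  spec <- network_spec(variant = variant, head = head, ...)
  glove <- NULL
  if (is.null(embedding)) {
    corpus <- encode_dataset(data)
    cooc <- build_cooccurrence(corpus, window = glove_window)
    glove <- fit_glove(cooc, d = spec$embedding_dim,
                       iterations = glove_iterations,
                       seed = subseed(seed, 7L))
    emb <- glove$embedding
  } else if (inherits(embedding, "glove_fit")) {
    glove <- embedding
    emb <- embedding$embedding
  } else {
    emb <- embedding
  }
  model <- train_network(data, spec, embedding_init = emb, m = m,
                         composition = composition, epochs = epochs,
                         learning_rate = learning_rate, seed = seed,
                         validation_fraction = validation_fraction,
                         patience = patience)
  structure(list(call = cl, spec = spec, glove = glove, model = model,
                 data_summary = list(n = nrow(data),
                                     n_pos = sum(data$label == 1),
                                     n_sgrnas = length(unique(data$sgrna_id))),
                 seed = as.integer(seed)),
            class = "otnet")
}

#' @export
print.otnet <- function(x, ...) {
  cat(sprintf("Off-target propensity network (variant '%s', %s head)\n",
              x$spec$variant, x$spec$head))
  cat(sprintf("  trained on %d pairs (%d positive, %d sgRNAs)\n",
              x$data_summary$n, x$data_summary$n_pos,
              x$data_summary$n_sgrnas))
  aud <- audit_network(x$model$arch)
  cat(sprintf("  %d parameters; stages: %s\n", aud$n_parameters,
              paste(aud$stage_kinds, collapse = " > ")))
  cat(sprintf("  final training loss %.4f over %d batches\n",
              utils::tail(x$model$training_log, 1),
              length(x$model$training_log)))
  invisible(x)
}

#' @export
summary.otnet <- function(object, ...) {
  aud <- audit_network(object$model$arch)
  el <- object$model$epoch_log
  out <- list(spec = object$spec, audit = aud,
              data_summary = object$data_summary,
              epochs_run = nrow(el),
              final_train_loss = el$train_loss[nrow(el)],
              final_val_loss = el$val_loss[nrow(el)],
              glove_final_cost =
                if (!is.null(object$glove))
                  utils::tail(object$glove$cost_history, 1) else NA_real_)
  class(out) <- "summary.otnet"
  out
}

#' @export
print.summary.otnet <- function(x, ...) {
  cat(sprintf("Variant '%s' (%s head): %d parameters\n", x$spec$variant,
              x$spec$head, x$audit$n_parameters))
  cat(sprintf("  stages: %d recurrent, %d conv, %d batchnorm, %d dropout\n",
              x$audit$n_recurrent, x$audit$n_conv, x$audit$n_batchnorm,
              x$audit$n_dropout))
  cat(sprintf("  data: %d pairs, %d positives, %d sgRNAs\n",
              x$data_summary$n, x$data_summary$n_pos,
              x$data_summary$n_sgrnas))
  cat(sprintf("  epochs run: %d, final train loss %.4f", x$epochs_run,
              x$final_train_loss))
  if (!is.na(x$final_val_loss)) {
    cat(sprintf(", val loss %.4f", x$final_val_loss))
  }
  cat("\n")
  if (!is.na(x$glove_final_cost)) {
    cat(sprintf("  GloVe embedding final cost %.4f\n", x$glove_final_cost))
  }
  invisible(x)
}

#' @export
predict.otnet <- function(object, newdata, ...) {
  predict_network(object$model, newdata)
}

#' @export
coef.otnet <- function(object, ...) {
  params <- lapply(object$model$arch$layers, function(ly) ly$params)
  names(params) <- make.unique(vapply(object$model$arch$layers,
                                      function(ly) ly$kind, character(1)))
  params[lengths(params) > 0]
}

#' Plot the training loss trajectory
#'
#' @param x An `otnet` fit.
#' @param which `"batch"` for per-batch losses or `"epoch"` for epoch means
#'   (with validation loss if recorded).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.otnet <- function(x, which = c("epoch", "batch"), ...) {
  which <- match.arg(which)
  if (which == "batch") {
    graphics::plot(x$model$training_log, type = "l", xlab = "batch",
                   ylab = "loss", ...)
  } else {
    el <- x$model$epoch_log
    graphics::plot(el$epoch, el$train_loss, type = "b", xlab = "epoch",
                   ylab = "loss", ...)
    if (!all(is.na(el$val_loss))) {
      graphics::lines(el$epoch, el$val_loss, type = "b", lty = 2)
      graphics::legend("topright", c("train", "validation"),
                       lty = c(1, 2), bty = "n")
    }
  }
  invisible(x)
}

#' @export
residuals.otnet <- function(object, newdata, ...) {
  if (missing(newdata)) {
    stopf("supply the dataset to compute residuals on (the fit does not retain its training data)")
  }
  p <- predict_network(object$model, newdata)
  if (object$spec$head == "regression") {
    newdata$frequency - p
  } else {
    newdata$label - p
  }
}
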