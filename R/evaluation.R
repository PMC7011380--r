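# Classification and regression metrics, and the two test patterns:
# a random withheld split (see split_train_test) and leave-one-sgRNA-out.

#' Confusion matrix at a score threshold
#'
#' Scores at or above the threshold predict the positive class.
#'
#' @param labels Binary vector (0/1).
#' @param scores Numeric vector of the same length.
#' @param threshold Decision threshold (default 0.5).
#' @return List of class `confusion` with `TP`, `FN`, `FP`, `TN`.
#' @export
confusion_at_threshold <- function(labels, scores, threshold = 0.5) {
  if (length(labels) != length(scores)) {
    stopf("%d labels but %d scores", length(labels), length(scores))
  }
  if (any(!labels %in% c(0, 1))) stopf("labels must be 0 or 1")
  pred <- scores >= threshold
  structure(list(TP = sum(pred & labels == 1),
                 FN = sum(!pred & labels == 1),
                 FP = sum(pred & labels == 0),
                 TN = sum(!pred & labels == 0)),
            class = "confusion")
}

#' @export
print.confusion <- function(x, ...) {
  m <- matrix(c(x$TP, x$FP, x$FN, x$TN), 2, 2,
              dimnames = list(predicted = c("pos", "neg"),
                              actual = c("pos", "neg")))
  print(m)
  invisible(x)
}

#' Recall (sensitivity) from a confusion matrix
#'
#' `Recall = TP / (TP + FN)`: the fraction of actual off-target sites
#' recovered. Undefined without positives.
#'
#' @param M A `confusion` object (or list with `TP` and `FN`).
#' @return Recall in `[0, 1]`.
#' @export
recall <- function(M) {
  if (M$TP + M$FN == 0) {
    stopf("recall undefined: no positive pairs (TP + FN == 0)")
  }
  M$TP / (M$TP + M$FN)
}

#' Areas under the ROC and precision-recall curves
#'
#' auROC by trapezoidal integration of the ROC curve over all score
#' thresholds; auPRC as the area of the precision-recall step curve. Tied
#' scores are grouped into a single threshold step. A constant scorer gives
#' auROC 0.5 and auPRC equal to the prevalence.
#'
#' @inheritParams confusion_at_threshold
#' @return List with `auroc` and `auprc`.
#' @export
ranking_metrics <- function(labels, scores) {
  if (length(labels) != length(scores)) {
    stopf("%d labels but %d scores", length(labels), length(scores))
  }
  P <- sum(labels == 1); N <- sum(labels == 0)
  if (P == 0 || N == 0) {
    stopf("ranking metrics need both classes (got %d positives, %d negatives)",
          P, N)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp_end <- c(which(diff(s) != 0), length(s))  # last index of each tie group
  tp <- cumsum(y == 1)[grp_end]
  fp <- cumsum(y == 0)[grp_end]
  tpr <- c(0, tp / P); fpr <- c(0, fp / N)
  auroc <- sum((fpr[-1] - fpr[-length(fpr)]) *
                 (tpr[-1] + tpr[-length(tpr)]) / 2)
  prec <- tp / (tp + fp)
  rec <- tp / P
  auprc <- sum((rec - c(0, rec[-length(rec)])) * prec)
  list(auroc = auroc, auprc = auprc)
}

#' Pearson and Spearman correlation of predicted and observed frequencies
#'
#' Spearman uses mid-ranks (average ranks on ties).
#'
#' @param true_freq,predicted Numeric vectors, length >= 3, each with
#'   nonzero variance.
#' @return List with `pearson` and `spearman`.
#' @export
correlation_metrics <- function(true_freq, predicted) {
  if (length(true_freq) != length(predicted)) {
    stopf("length mismatch: %d vs %d", length(true_freq), length(predicted))
  }
  if (length(true_freq) < 3L) stopf("need at least 3 observations")
  if (stats::var(true_freq) == 0 || stats::var(predicted) == 0) {
    stopf("correlation undefined: zero variance input")
  }
  list(pearson = stats::cor(true_freq, predicted, method = "pearson"),
       spearman = stats::cor(true_freq, predicted, method = "spearman"))
}

#' Full evaluation report for one set of predictions
#'
#' @inheritParams confusion_at_threshold
#' @param frequencies Optional observed cleavage frequencies for the
#'   correlation metrics (`NA` metrics when absent or degenerate).
#' @param threshold Decision threshold for the recall entry.
#' @return List of class `eval_report` with `recall`, `auroc`, `auprc`,
#'   `pearson`, `spearman`, `n_pos`, `n_neg`.
#' @export
evaluate_predictions <- function(labels, scores, frequencies = NULL,
                                 threshold = 0.5) {
  cm <- confusion_at_threshold(labels, scores, threshold)
  rk <- if (length(unique(labels)) == 2L) {
    ranking_metrics(labels, scores)
  } else {
    list(auroc = NA_real_, auprc = NA_real_)
  }
  cr <- list(pearson = NA_real_, spearman = NA_real_)
  if (!is.null(frequencies)) {
    cr <- tryCatch(correlation_metrics(frequencies, scores),
                   error = function(e) cr)
  }
  structure(list(recall = if (cm$TP + cm$FN > 0) recall(cm) else NA_real_,
                 auroc = rk$auroc, auprc = rk$auprc,
                 pearson = cr$pearson, spearman = cr$spearman,
                 n_pos = cm$TP + cm$FN, n_neg = cm$FP + cm$TN),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "recall %.3f | auROC %.3f | auPRC %.3f | pearson %.3f | spearman %.3f (n+ %d, n- %d)\n",
    x$recall, x$auroc, x$auprc, x$pearson, x$spearman, x$n_pos, x$n_neg))
  invisible(x)
}

#' Leave-one-sgRNA-out cross-validation
#'
#' One fold per distinct `sgrna_id`: all pairs of that guide form the test
#' set and everything else the training set, measuring generalisation to
#' unseen guides. Folds whose test set contains a single class keep their
#' recall but have undefined ranking metrics; those folds are excluded from
#' the mean with a logged notice.
#'
#' @param data An off-target dataset with >= 2 distinct `sgrna_id` values.
#' @param trainer Function `(train_data, seed) -> function(test_data) ->
#'   scores`; see [otnet_trainer()] and [cfd_trainer()].
#' @param seed Integer seed; fold `i` trains with `subseed(seed, i)`.
#' @param threshold Recall threshold.
#' @return List of class `loso_result`: `folds` (named `eval_report`s),
#'   `mean` (metric means over folds where defined), `excluded` (fold names
#'   dropped from ranking means).
#' @export
leave_one_sgrna_out <- function(data, trainer, seed = 1L, threshold = 0.5) {
  ids <- unique(data$sgrna_id)
  if (length(ids) < 2L) stopf("need at least 2 distinct sgRNAs")
  folds <- list(); excluded <- character(0)
  for (i in seq_along(ids)) {
    test <- data[data$sgrna_id == ids[i], , drop = FALSE]
    train <- data[data$sgrna_id != ids[i], , drop = FALSE]
    scorer <- trainer(train, subseed(seed, i))
    scores <- scorer(test)
    rep <- evaluate_predictions(test$label, scores, test$frequency,
                                threshold)
    if (is.na(rep$auroc)) {
      message(sprintf(
        "fold %s: single-class test set; ranking metrics undefined, excluded from means",
        ids[i]))
      excluded <- c(excluded, ids[i])
    }
    folds[[ids[i]]] <- rep
  }
  metric <- function(nm) {
    v <- vapply(folds, function(f) f[[nm]], numeric(1))
    mean(v[!is.na(v)])
  }
  mean_report <- list(recall = metric("recall"), auroc = metric("auroc"),
                      auprc = metric("auprc"), pearson = metric("pearson"),
                      spearman = metric("spearman"))
  structure(list(folds = folds, mean = mean_report, excluded = excluded),
            class = "loso_result")
}

#' @export
print.loso_result <- function(x, ...) {
  cat(sprintf("Leave-one-sgRNA-out over %d folds (%d excluded from ranking means)\n",
              length(x$folds), length(x$excluded)))
  cat(sprintf("  mean recall %.3f | auROC %.3f | auPRC %.3f | pearson %.3f | spearman %.3f\n",
              x$mean$recall, x$mean$auroc, x$mean$auprc, x$mean$pearson,
              x$mean$spearman))
  invisible(x)
}

#' Trainer factories for cross-validation
#'
#' `otnet_trainer()` wraps [otnet()]; `cfd_trainer()` wraps a fixed CFD
#' table (nothing is fitted). Both return a function
#' `(train_data, seed) -> function(test_data) -> scores` suitable for
#' [leave_one_sgrna_out()].
#'
#' @param ... For `otnet_trainer()`, arguments forwarded to [otnet()]
#'   (except `data` and `seed`).
#' @return A trainer function.
#' @export
otnet_trainer <- function(...) {
  args <- list(...)
  function(train_data, seed) {
    fit <- do.call(otnet, c(list(data = train_data, seed = seed), args))
    function(test_data) predict(fit, test_data)
  }
}

#' @rdname otnet_trainer
#' @param table A `cfd_table` for `cfd_trainer()`.
#' @export
cfd_trainer <- function(table) {
  function(train_data, seed) {
    function(test_data) cfd_score_dataset(test_data, table)
  }
}

#' Write per-fold and summary reports
#'
#' @param result A `loso_result`.
#' @param path Output path; `.tsv` writes a per-fold table with a trailing
#'   mean row, `.json` the full structure.
#' @return `path`, invisibly.
#' @export
write_loso_report <- function(result, path) {
  df <- do.call(rbind, lapply(names(result$folds), function(id) {
    f <- result$folds[[id]]
    data.frame(sgrna_id = id, recall = f$recall, auroc = f$auroc,
               auprc = f$auprc, pearson = f$pearson, spearman = f$spearman,
               n_pos = f$n_pos, n_neg = f$n_neg)
  }))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(folds = df, mean = result$mean,
                              excluded = result$excluded),
                         path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    mean_row <- data.frame(sgrna_id = "mean", recall = result$mean$recall,
                           auroc = result$mean$auroc,
                           auprc = result$mean$auprc,
                           pearson = result$mean$pearson,
                           spearman = result$mean$spearman,
                           n_pos = NA, n_neg = NA)
    utils::write.table(rbind(df, mean_row), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
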