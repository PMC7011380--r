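test_that("confusion counts match hand tallies", {
  labels <- c(1, 1, 0, 0, 1, 0, 0, 1, 0, 0)
  scores <- c(0.9, 0.4, 0.6, 0.1, 0.5, 0.5, 0.2, 0.05, 0.8, 0.3)
  cm <- confusion_at_threshold(labels, scores, 0.5)
  # by hand: predicted positive = {1,3,5,6,9}; positives = {1,2,5,8}
  expect_identical(cm$TP, 2L + 0L)  # rows 1 and 5
  expect_identical(cm$FN, 2L)       # rows 2 and 8
  expect_identical(cm$FP, 3L)       # rows 3, 6, 9
  expect_identical(cm$TN, 3L)       # rows 4, 7, 10
  expect_identical(cm$TP + cm$FN + cm$FP + cm$TN, length(labels))
  # perfect predictor and all-zero scorer
  perfect <- confusion_at_threshold(labels, labels, 0.5)
  expect_identical(perfect$FP + perfect$FN, 0L)
  zero <- confusion_at_threshold(labels, rep(0, 10), 0.5)
  expect_identical(zero$TP, 0L)
  expect_identical(zero$FN, 4L)
  expect_error(confusion_at_threshold(labels, scores[-1]), "labels")
  expect_error(confusion_at_threshold(c(0, 2), c(0, 1)), "0 or 1")
})

test_that("recall is TP / (TP + FN)", {
  expect_equal(recall(list(TP = 8, FN = 2)), 0.8)
  expect_equal(recall(list(TP = 0, FN = 5)), 0)
  expect_error(recall(list(TP = 0, FN = 0)), "undefined")
  set.seed(14)
  for (i in 1:100) {
    labels <- sample(0:1, 30, replace = TRUE, prob = c(0.7, 0.3))
    if (sum(labels) == 0) next
    scores <- stats::runif(30)
    cm <- confusion_at_threshold(labels, scores, 0.5)
    # independent direct count over positives
    direct <- sum(scores >= 0.5 & labels == 1) / sum(labels == 1)
    expect_equal(recall(cm), direct)
  }
})

test_that("ranking metrics agree with brute-force oracles", {
  set.seed(15)
  for (i in 1:40) {
    n <- sample(6:30, 1)
    labels <- sample(0:1, n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    # coarse scores force ties
    scores <- sample(seq(0, 1, 0.25), n, replace = TRUE)
    rk <- ranking_metrics(labels, scores)
    expect_equal(rk$auroc, pairwise_auroc(labels, scores),
                 tolerance = 1e-12)
  }
})

test_that("ranking metrics agree with an independent ROC package", {
  skip_if_not_installed("pROC")
  set.seed(16)
  labels <- sample(0:1, 300, replace = TRUE, prob = c(0.9, 0.1))
  scores <- stats::runif(300) + labels * 0.4
  rk <- ranking_metrics(labels, scores)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE)))
  expect_equal(rk$auroc, ref, tolerance = 1e-10)
})

test_that("degenerate scorers hit their closed forms", {
  labels <- c(rep(1, 3), rep(0, 17))
  rk <- ranking_metrics(labels, rep(0.4, 20))
  expect_equal(rk$auroc, 0.5)
  expect_equal(rk$auprc, 3 / 20)  # prevalence
  perfect <- ranking_metrics(labels, labels)
  expect_equal(perfect$auroc, 1.0)
  expect_equal(perfect$auprc, 1.0)
  expect_error(ranking_metrics(rep(1, 5), stats::runif(5)), "both classes")
})

test_that("correlations use mid-ranks under heavy ties", {
  x <- c(1, 0.8, 0.3)
  expect_equal(correlation_metrics(x, x), list(pearson = 1, spearman = 1))
  expect_equal(correlation_metrics(x, 1 - x)$pearson, -1)
  # zero-inflated 250:1-style vector with ties
  set.seed(17)
  truth <- c(rep(0, 250), stats::runif(5))
  pred <- truth + stats::rnorm(255, 0, 0.01)
  got <- correlation_metrics(truth, pred)
  manual <- stats::cor(rank(truth), rank(pred))  # mid-ranks by default
  expect_equal(got$spearman, manual, tolerance = 1e-12)
  expect_error(correlation_metrics(rep(1, 5), stats::runif(5)),
               "zero variance")
  expect_error(correlation_metrics(1:2, 1:2), "at least 3")
})

test_that("evaluation reports are permutation invariant", {
  set.seed(18)
  labels <- sample(0:1, 60, replace = TRUE, prob = c(0.8, 0.2))
  scores <- stats::runif(60)
  freq <- ifelse(labels == 1, stats::runif(60, 0.1, 1), 0)
  r1 <- evaluate_predictions(labels, scores, freq)
  perm <- sample(60)
  r2 <- evaluate_predictions(labels[perm], scores[perm], freq[perm])
  expect_equal(r1, r2)
})

test_that("leave-one-sgRNA-out partitions by guide", {
  d <- simulate_offtarget_dataset(n_sgrnas = 4, sites_per_sgrna = 80,
                                  imbalance_ratio = 15, seed = 23)
  res <- leave_one_sgrna_out(d, cfd_trainer(synthetic_propensity_table(2)),
                             seed = 1)
  expect_length(res$folds, 4L)
  expect_setequal(names(res$folds), unique(d$sgrna_id))
  sizes <- vapply(res$folds, function(f) f$n_pos + f$n_neg, numeric(1))
  expect_identical(sum(sizes), as.numeric(nrow(d)))
  expect_true(all(!is.na(vapply(res$folds, function(f) f$auroc,
                                numeric(1)))))
  expect_error(leave_one_sgrna_out(d[d$sgrna_id == "sgRNA_01", ],
                                   cfd_trainer(cfd_table()), seed = 1),
               "at least 2")
})

test_that("single-class folds lose ranking metrics but keep recall", {
  d <- simulate_offtarget_dataset(n_sgrnas = 3, sites_per_sgrna = 60,
                                  imbalance_ratio = 10, seed = 29)
  # strip the positives from one guide to force a single-class fold
  drop <- d$sgrna_id == "sgRNA_02" & d$label == 1
  d <- as_offtarget_dataset(d[!drop, ])
  expect_message(
    res <- leave_one_sgrna_out(d, cfd_trainer(synthetic_propensity_table(2)),
                               seed = 1),
    "single-class")
  expect_true(is.na(res$folds[["sgRNA_02"]]$auroc))
  expect_identical(res$excluded, "sgRNA_02")
  others <- vapply(res$folds[c("sgRNA_01", "sgRNA_03")],
                   function(f) f$auroc, numeric(1))
  expect_equal(res$mean$auroc, mean(others))
})

test_that("fold reports serialise to TSV and JSON", {
  d <- simulate_offtarget_dataset(n_sgrnas = 3, sites_per_sgrna = 60,
                                  imbalance_ratio = 10, seed = 31)
  res <- leave_one_sgrna_out(d, cfd_trainer(synthetic_propensity_table(2)),
                             seed = 1)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_loso_report(res, tsv)
  tab <- utils::read.delim(tsv)
  expect_identical(nrow(tab), 4L)  # 3 folds + mean row
  js <- withr::local_tempfile(fileext = ".json")
  write_loso_report(res, js)
  expect_equal(jsonlite::read_json(js)$mean$auroc, res$mean$auroc,
               tolerance = 1e-12)
})
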