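# Imbalance-aware batch construction.
#
# With M negatives and batch-size parameter m, an epoch consists of
# N = floor(M / m) batches: the (seeded) shuffled negatives are cut into N
# disjoint subsets of m, and each subset is paired with m positives drawn
# with replacement (random oversampling). Leftover negatives (M mod m) sit
# out the epoch and re-enter the next epoch's shuffle, so batch shapes stay
# fixed while nearly all negative data are traversed each epoch.

#' Plan one epoch of imbalance-aware batches
#'
#' @param data An off-target dataset, or a binary label vector.
#' @param m Batch-size parameter (default 256).
#' @param seed Integer seed; identical `(data, m, seed)` give identical
#'   plans.
#' @param composition `"balanced"` (default): each batch holds `m` negatives
#'   plus `m` oversampled positives (2m total). `"within"`: `floor(m/2)`
#'   negatives plus `ceiling(m/2)` positives (m total), the alternative
#'   reading in which the batch-size parameter bounds the whole batch.
#' @return Object of class `batch_plan`: lists `negatives` and `positives`
#'   of `N` index vectors each, plus bookkeeping (`m`, `seed`,
#'   `composition`, `unused_negatives`).
#' @export
plan_batches <- function(data, m = 256L, seed = 1L,
                         composition = c("balanced", "within")) {
  composition <- match.arg(composition)
  labels <- if (is.data.frame(data)) data$label else data
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  if (length(pos) == 0L) stopf("no positive pairs to oversample")
  neg_per_batch <- if (composition == "balanced") m else m %/% 2L
  pos_per_batch <- if (composition == "balanced") m else m - m %/% 2L
  if (length(neg) < neg_per_batch) {
    stopf("%d negatives is fewer than the %d required per batch",
          length(neg), neg_per_batch)
  }
  n_batches <- length(neg) %/% neg_per_batch
  local_seed(seed, {
    shuffled <- sample(neg)
    used <- shuffled[seq_len(n_batches * neg_per_batch)]
    neg_sets <- split(used, rep(seq_len(n_batches), each = neg_per_batch))
    pos_sets <- lapply(seq_len(n_batches), function(i) {
      sample(pos, pos_per_batch, replace = TRUE)
    })
    structure(list(negatives = unname(neg_sets),
                   positives = unname(pos_sets),
                   m = as.integer(m), seed = as.integer(seed),
                   composition = composition,
                   unused_negatives = shuffled[-seq_along(used)]),
              class = "batch_plan")
  })
}

#' Materialise the batches of a plan
#'
#' Yields the planned batches in order; each batch is internally shuffled
#' (seeded from the plan) so positives and negatives interleave.
#'
#' @param plan A `batch_plan`.
#' @param data The off-target dataset the plan indexes.
#' @return List of batches; each batch is a list with `indices` (into
#'   `data`, oversampled positives repeated), `pairs` (the rows), `labels`
#'   and `frequencies`.
#' @export
iterate_batches <- function(plan, data) {
  n <- nrow(data)
  all_idx <- c(unlist(plan$negatives), unlist(plan$positives))
  if (length(all_idx) && (min(all_idx) < 1L || max(all_idx) > n)) {
    stopf("plan indexes rows outside the dataset (n = %d)", n)
  }
  lapply(seq_along(plan$negatives), function(i) {
    idx <- c(plan$negatives[[i]], plan$positives[[i]])
    idx <- local_seed(subseed(plan$seed, i), sample(idx))
    list(indices = idx,
         pairs = data[idx, , drop = FALSE],
         labels = data$label[idx],
         frequencies = data$frequency[idx])
  })
}

#' Serialise a batch plan to JSON for exact training replay
#'
#' @param plan A `batch_plan`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_batch_plan <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_batch_plan
#' @export
read_batch_plan <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyMatrix = FALSE)
  p$negatives <- lapply(p$negatives, as.integer)
  p$positives <- lapply(p$positives, as.integer)
  structure(p, class = "batch_plan")
}
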