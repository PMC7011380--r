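# GloVe embedding of the 16-token base-pair vocabulary.
#
# Each encoded pair is a 23-token "sentence"; the corpus of all pairs yields
# a 16 x 16 co-occurrence matrix x_{ij}, and token vectors are fit by
# weighted least squares on log co-occurrences:
#   J = sum_{x_ij > 0} f(x_ij) (w_i' c_j + b_i + c_bias_j - log x_ij)^2
# with f(x) = (x / x_max)^alpha for x < x_max, else 1.

#' Build a token co-occurrence matrix from an encoded corpus
#'
#' Counts, for every ordered token pair (i, j), how often j falls inside the
#' context window of i within a sentence; contexts never cross sentence
#' boundaries. With a symmetric window the matrix is symmetric. Inverse
#' distance weighting contributes 1/k for tokens k positions apart (the
#' original GloVe convention); uniform weighting contributes 1.
#'
#' @param corpus Integer matrix of token rows (as from [encode_dataset()])
#'   or a list of equal-length integer token vectors, values in
#'   `[0, vocab - 1]`.
#' @param window Context half-width, an integer >= 1. The default 5 reflects
#'   the original GloVe practice; pass `22` for a full-sentence window on
#'   23-token sentences.
#' @param distance_weighting `"inverse"` (default) or `"uniform"`.
#' @param vocab Vocabulary size, default 16.
#' @return An object of class `glove_cooc`: list with matrix `x`
#'   (`vocab x vocab`), `window` and `distance_weighting`.
#' @export
build_cooccurrence <- function(corpus, window = 5L,
                               distance_weighting = c("inverse", "uniform"),
                               vocab = 16L) {
  distance_weighting <- match.arg(distance_weighting)
  if (is.list(corpus)) {
    len <- unique(lengths(corpus))
    if (length(corpus) == 0L) stopf("corpus is empty")
    if (length(len) != 1L) stopf("all sentences must share one length")
    corpus <- matrix(as.integer(unlist(corpus)), nrow = length(corpus),
                     byrow = TRUE)
  }
  if (!is.matrix(corpus) || nrow(corpus) == 0L) stopf("corpus is empty")
  if (window < 1L) stopf("window must be >= 1")
  storage.mode(corpus) <- "integer"
  if (any(corpus < 0L | corpus >= vocab)) {
    stopf("token values must lie in [0, %d]", vocab - 1L)
  }
  tlen <- ncol(corpus)
  x <- matrix(0, vocab, vocab)
  for (k in seq_len(min(window, tlen - 1L))) {
    a <- corpus[, seq_len(tlen - k), drop = FALSE]
    b <- corpus[, (k + 1L):tlen, drop = FALSE]
    w <- if (distance_weighting == "inverse") 1 / k else 1
    cnt <- tabulate(as.vector(a) * vocab + as.vector(b) + 1L, vocab * vocab)
    m <- matrix(cnt, vocab, vocab, byrow = TRUE)  # row = token of a
    x <- x + w * (m + t(m))                       # symmetric context
  }
  dimnames(x) <- list(0:(vocab - 1L), 0:(vocab - 1L))
  structure(list(x = x, window = as.integer(window),
                 distance_weighting = distance_weighting),
            class = "glove_cooc")
}

cooc_matrix <- function(X) {
  if (inherits(X, "glove_cooc")) X$x else as.matrix(X)
}

#' Row totals, conditional probabilities and probability ratios
#'
#' For co-occurrence counts `x`, computes row totals `X_i = sum_j x_ij`,
#' conditional probabilities `P[i, k] = x_ik / X_i`, and the three-token
#' ratio array `ratio[i, j, k] = P[i, k] / P[j, k]` whose behaviour
#' (near 1, large, or near 0) the embedding is built to reproduce.
#'
#' @param X A `glove_cooc` object or plain nonnegative matrix.
#' @param tokens Row indices (1-based) to include; default all rows. Rows
#'   with zero total are an error, reported by token, never dropped
#'   silently.
#' @return List with `row_totals`, `P` and `ratio`.
#' @export
cooccurrence_stats <- function(X, tokens = NULL) {
  x <- cooc_matrix(X)
  tokens <- tokens %||% seq_len(nrow(x))
  totals <- rowSums(x)[tokens]
  if (any(totals == 0)) {
    stopf("zero row total for token(s) %s: conditional probabilities undefined; pass `tokens` to subset",
          paste(tokens[totals == 0] - 1L, collapse = ", "))
  }
  P <- x[tokens, , drop = FALSE] / totals
  m <- length(tokens)
  v <- ncol(x)
  ratio <- array(NA_real_, c(m, m, v))
  for (j in seq_len(m)) {
    denom <- P[j, ]
    r <- sweep(P, 2L, denom, "/")
    r[, denom == 0] <- NA_real_
    ratio[, j, ] <- r
  }
  list(row_totals = totals, P = P, ratio = ratio)
}

#' Initialise GloVe parameters
#'
#' @param vocab Vocabulary size.
#' @param d Embedding dimension.
#' @param x_max,alpha Weighting-function parameters `f(x) = (x/x_max)^alpha`
#'   for `x < x_max`, else 1.
#' @param seed Integer seed for the uniform initialisation.
#' @return List of class `glove_params` with word vectors `W`, context
#'   vectors `C`, biases `b` and `c_bias`.
#' @export
glove_init <- function(vocab = 16L, d = 100L, x_max = 100, alpha = 0.75,
                       seed = 1L) {
  local_seed(seed, {
    structure(list(
      W = matrix(stats::runif(vocab * d, -0.5, 0.5) / d, vocab, d),
      C = matrix(stats::runif(vocab * d, -0.5, 0.5) / d, vocab, d),
      b = stats::runif(vocab, -0.5, 0.5) / d,
      c_bias = stats::runif(vocab, -0.5, 0.5) / d,
      x_max = x_max, alpha = alpha), class = "glove_params")
  })
}

glove_weights <- function(x, x_max, alpha) {
  f <- ifelse(x < x_max, (x / x_max)^alpha, 1)
  f[x <= 0] <- 0
  f
}

#' GloVe cost function
#'
#' `J = sum f(x_ij) (w_i' c_j + b_i + c_bias_j - log x_ij)^2`, the sum
#' running over nonzero cells only (log 0 is never evaluated).
#'
#' @param params A `glove_params` list.
#' @param X A `glove_cooc` object or plain matrix.
#' @return Nonnegative scalar cost.
#' @export
glove_cost <- function(params, X) {
  x <- cooc_matrix(X)
  if (!all(vapply(params[c("W", "C", "b", "c_bias")],
                  function(p) all(is.finite(p)), logical(1)))) {
    stopf("non-finite parameter values")
  }
  f <- glove_weights(x, params$x_max, params$alpha)
  M <- params$W %*% t(params$C) + outer(params$b, params$c_bias, "+")
  r <- M - suppressWarnings(log(x))
  sum(f[x > 0] * r[x > 0]^2)
}

#' Analytic gradient of the GloVe cost
#'
#' @inheritParams glove_cost
#' @return List with gradients `W`, `C`, `b`, `c_bias`.
#' @export
glove_gradient <- function(params, X) {
  x <- cooc_matrix(X)
  f <- glove_weights(x, params$x_max, params$alpha)
  M <- params$W %*% t(params$C) + outer(params$b, params$c_bias, "+")
  E <- matrix(0, nrow(x), ncol(x))
  nz <- x > 0
  E[nz] <- 2 * f[nz] * (M[nz] - log(x[nz]))
  list(W = E %*% params$C,
       C = t(E) %*% params$W,
       b = rowSums(E),
       c_bias = colSums(E))
}

#' Fit GloVe token vectors on a co-occurrence matrix
#'
#' Full-batch AdaGrad minimisation of [glove_cost()]. The returned embedding
#' is the sum of word and context vectors (standard GloVe composition);
#' `combine = "word"` returns word vectors only.
#'
#' @param X A `glove_cooc` object or nonnegative matrix with at least one
#'   positive entry.
#' @param d Embedding dimension (default 100).
#' @param iterations AdaGrad iterations (default 1000; the 16-token
#'   vocabulary makes this sub-second).
#' @param learning_rate AdaGrad learning rate (default 0.05, the original
#'   GloVe setting).
#' @param seed Seed for the parameter initialisation.
#' @param x_max,alpha Weighting-function parameters.
#' @param combine `"sum"` or `"word"`.
#' @return List of class `glove_fit`: `params`, `embedding`
#'   (`vocab x d`), and `cost_history`.
#' @export
fit_glove <- function(X, d = 100L, iterations = 1000L, learning_rate = 0.05,
                      seed = 1L, x_max = 100, alpha = 0.75,
                      combine = c("sum", "word")) {
  combine <- match.arg(combine)
  x <- cooc_matrix(X)
  if (!any(x > 0)) stopf("co-occurrence matrix has no positive entry")
  if (d < 1L) stopf("embedding dimension must be >= 1")
  vocab <- nrow(x)
  params <- glove_init(vocab, d, x_max = x_max, alpha = alpha, seed = seed)
  hist <- numeric(iterations + 1L)
  hist[1L] <- glove_cost(params, x)
  acc <- list(W = matrix(1e-8, vocab, d), C = matrix(1e-8, vocab, d),
              b = rep(1e-8, vocab), c_bias = rep(1e-8, vocab))
  for (it in seq_len(iterations)) {
    g <- glove_gradient(params, x)
    for (nm in names(acc)) {
      acc[[nm]] <- acc[[nm]] + g[[nm]]^2
      params[[nm]] <- params[[nm]] - learning_rate * g[[nm]] / sqrt(acc[[nm]])
    }
    hist[it + 1L] <- glove_cost(params, x)
    if (!is.finite(hist[it + 1L])) {
      stopf("GloVe training diverged at iteration %d (cost non-finite); reduce learning_rate", it)
    }
  }
  emb <- if (combine == "sum") params$W + params$C else params$W
  rownames(emb) <- rownames(x) %||% as.character(0:(vocab - 1L))
  structure(list(params = params, embedding = emb, cost_history = hist),
            class = "glove_fit")
}

#' Write / read an embedding matrix as whitespace-delimited text
#'
#' One row per token: the token index followed by `d` floats.
#'
#' @param embedding Numeric matrix, tokens in rows.
#' @param path File path.
#' @return `path` (write) or the embedding matrix (read).
#' @export
write_embedding <- function(embedding, path) {
  df <- data.frame(token = 0:(nrow(embedding) - 1L),
                   format(embedding, digits = 17, trim = TRUE))
  utils::write.table(df, path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_embedding
#' @export
read_embedding <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  emb <- m[, -1L, drop = FALSE]
  rownames(emb) <- m[, 1L]
  colnames(emb) <- NULL
  emb
}
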