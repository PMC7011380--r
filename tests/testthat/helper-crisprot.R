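# Shared fixtures and independent oracles. Oracles are deliberately naive
# (loops, exhaustive enumeration) and never share code with the
# implementation they check.

BASES <- c("A", "C", "G", "T")

random_seq23 <- function() paste(sample(BASES, 23, replace = TRUE),
                                 collapse = "")

# A tiny hand-buildable dataset with both classes and two guides.
toy_dataset <- function(n_per_guide = 10, seed = 42) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    rows <- lapply(1:2, function(g) {
      sg <- random_seq23()
      do.call(rbind, lapply(seq_len(n_per_guide), function(i) {
        d <- strsplit(sg, "")[[1]]
        pos <- sample(1:20, sample(1:3, 1))
        for (p in pos) d[p] <- sample(setdiff(BASES, d[p]), 1)
        lab <- as.integer(i <= 2)  # first two sites per guide are positives
        data.frame(sgrna_id = paste0("g", g), sgrna_seq = sg,
                   dna_seq = paste(d, collapse = ""), label = lab,
                   frequency = if (lab == 1) runif(1, 0.1, 0.9) else 0,
                   cell_line = c("A", "B")[g], stringsAsFactors = FALSE)
      }))
    })
    as_offtarget_dataset(do.call(rbind, rows))
  })
}

# Naive triple-loop co-occurrence counter (pair enumeration within the
# window, both directions, optional 1/distance weights).
naive_cooccurrence <- function(corpus, window, weighting = "inverse",
                               vocab = 16) {
  x <- matrix(0, vocab, vocab)
  for (s in seq_len(nrow(corpus))) {
    sent <- corpus[s, ]
    for (i in seq_along(sent)) {
      for (j in seq_along(sent)) {
        k <- abs(i - j)
        if (j != i && k <= window) {
          w <- if (weighting == "inverse") 1 / k else 1
          x[sent[i] + 1, sent[j] + 1] <- x[sent[i] + 1, sent[j] + 1] + w
        }
      }
    }
  }
  x
}

# Concordant-pair auROC with half credit for ties.
pairwise_auroc <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Scalar step-by-step biLSTM oracle: literal gate equations with loops over
# units, no matrix shortcuts.
scalar_bilstm_oracle <- function(inputs, params) {
  u <- ncol(params$W_f)
  run_dir <- function(X) {
    tt <- nrow(X)
    H <- matrix(0, tt, u)
    h <- numeric(u); cc <- numeric(u)
    for (t in seq_len(tt)) {
      z <- c(h, X[t, ])
      f <- i <- g <- o <- numeric(u)
      for (k in seq_len(u)) {
        f[k] <- 1 / (1 + exp(-(sum(z * params$W_f[, k]) + params$b_f[k])))
        i[k] <- 1 / (1 + exp(-(sum(z * params$W_i[, k]) + params$b_i[k])))
        g[k] <- tanh(sum(z * params$W_C[, k]) + params$b_C[k])
        o[k] <- 1 / (1 + exp(-(sum(z * params$W_o[, k]) + params$b_o[k])))
      }
      cc <- f * cc + i * g
      h <- o * tanh(cc)
      H[t, ] <- h
    }
    H
  }
  A <- run_dir(inputs)
  Ab <- run_dir(inputs[nrow(inputs):1, , drop = FALSE])
  Ab <- Ab[nrow(inputs):1, , drop = FALSE]
  out <- matrix(0, nrow(inputs), ncol(params$V))
  for (t in seq_len(nrow(inputs))) {
    out[t, ] <- tanh(as.numeric(A[t, ] %*% params$V) +
                       as.numeric(Ab[t, ] %*% params$V2))
  }
  out
}

random_bilstm_params <- function(u, d, out_dim, scale = 0.5) {
  rnd <- function(nr, nc) matrix(stats::runif(nr * nc, -scale, scale), nr, nc)
  list(W_f = rnd(u + d, u), W_i = rnd(u + d, u), W_C = rnd(u + d, u),
       W_o = rnd(u + d, u),
       b_f = stats::runif(u, -scale, scale),
       b_i = stats::runif(u, -scale, scale),
       b_C = stats::runif(u, -scale, scale),
       b_o = stats::runif(u, -scale, scale),
       V = rnd(u, out_dim), V2 = rnd(u, out_dim))
}

# A linearly separable 40-pair toy: positives carry a fixed mismatch
# signature (G->A at protospacer positions 3 and 7), negatives mismatch
# elsewhere.
separable_dataset <- function(seed = 7) {
  set.seed(seed)
  sg <- paste(c(rep("G", 20), "A", "G", "G"), collapse = "")
  mk <- function(lab, i) {
    d <- strsplit(sg, "")[[1]]
    if (lab == 1) {
      d[3] <- "A"; d[7] <- "A"
    } else {
      for (p in sample(10:20, 2)) d[p] <- sample(c("C", "T"), 1)
    }
    data.frame(sgrna_id = "g1", sgrna_seq = sg,
               dna_seq = paste(d, collapse = ""), label = lab,
               frequency = if (lab == 1) 0.5 else 0, cell_line = "A",
               stringsAsFactors = FALSE)
  }
  rows <- c(lapply(1:20, mk, lab = 1), lapply(1:20, mk, lab = 0))
  as_offtarget_dataset(do.call(rbind, rows))
}

# Small network settings used wherever a test trains a model.
tiny_net_args <- list(embedding_dim = 8L, recurrent_units = 4L,
                      conv_filters = c(4L, 4L, 4L, 4L, 4L),
                      conv_kernels = c(5L, 5L, 3L, 3L, 3L),
                      glove_iterations = 50L)
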