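# Synthetic off-target dataset generator.
#
# Emulates the structure of published Cas9 off-target screens: a set of
# sgRNAs (20-nt protospacer + NGG PAM), candidate loci carrying 1-5
# mismatches each, heavy negative:positive imbalance (default 250:1), and a
# planted multiplicative per-mismatch cleavage propensity so the signal is
# recoverable both by a CFD-style scorer and by the network.

#' Generative configuration for synthetic off-target data
#'
#' @param n_sgrnas Number of guides (default 29, matching published screen
#'   scale).
#' @param sites_per_sgrna Candidate loci per guide.
#' @param mismatch_range Integer range of mismatches per site, default
#'   `c(1, 5)`.
#' @param imbalance_ratio Negatives per positive (default 250).
#' @param ground_truth_table A `cfd_table`-like per-mismatch propensity
#'   table; default [synthetic_propensity_table()] seeded from `seed`.
#' @param noise_sd Standard deviation of the truncated Gaussian perturbation
#'   applied to positive cleavage frequencies (default 0.05).
#' @param seed Integer seed; all generation is bit-reproducible from
#'   `(config, seed)`.
#' @return List of class `otsim_config`.
#' @export
generative_config <- function(n_sgrnas = 29L, sites_per_sgrna = 500L,
                              mismatch_range = c(1L, 5L),
                              imbalance_ratio = 250,
                              ground_truth_table = NULL,
                              noise_sd = 0.05, seed = 1L) {
  if (imbalance_ratio <= 0) stopf("imbalance_ratio must be positive")
  if (mismatch_range[1] < 1L || mismatch_range[2] > 5L ||
      mismatch_range[1] > mismatch_range[2]) {
    stopf("mismatch_range must lie within [1, 5]")
  }
  structure(list(
    n_sgrnas = as.integer(n_sgrnas),
    sites_per_sgrna = as.integer(sites_per_sgrna),
    mismatch_range = as.integer(mismatch_range),
    imbalance_ratio = imbalance_ratio,
    ground_truth_table = ground_truth_table %||%
      synthetic_propensity_table(seed = subseed(seed, 101L)),
    noise_sd = noise_sd,
    seed = as.integer(seed)), class = "otsim_config")
}

#' Synthetic per-mismatch propensity table
#'
#' A complete CFD-style table (all 12 mismatch types at all 20 protospacer
#' positions) with PAM-proximal positions more deleterious than PAM-distal
#' ones, mimicking the position dependence of real mismatch tolerance:
#' `score = exp(-(a_type + b_pos + eps))` with per-type severities drawn as
#' a seeded permutation of an even ladder over `[0.05, 1.5]`, a positional
#' penalty `b_pos` rising linearly from 0.05 (position 1) to 2.4 (position
#' 20), and per-entry jitter `eps ~ N(0, 0.6)`; scores are clamped to
#' `[0.01, 1]`. The spreads are sized so that latent propensities separate
#' clearly from the frequency noise floor of [generative_config()].
#' Synthetic: this is not the published CFD table.
#'
#' @param seed Integer seed.
#' @return A `cfd_table` with 240 entries.
#' @export
synthetic_propensity_table <- function(seed = 1L) {
  local_seed(seed, {
    grid <- expand.grid(rna_base = DNA_BASES, dna_base = DNA_BASES,
                        position = 1:20, stringsAsFactors = FALSE)
    grid <- grid[grid$rna_base != grid$dna_base, ]
    type <- paste(grid$rna_base, grid$dna_base)
    a <- stats::setNames(sample(seq(0.05, 1.5, length.out = 12)),
                         unique(type))
    b <- 0.05 + (grid$position - 1) / 19 * 2.35
    eps <- stats::rnorm(nrow(grid), 0, 0.6)
    grid$score <- pmin(1, pmax(0.01, exp(-(a[type] + b + eps))))
    cfd_table(grid)
  })
}

#' Generate random sgRNA sequences with an NGG PAM
#'
#' Uniform random 20-nt protospacers followed by N-G-G; guaranteed distinct
#' (duplicates are regenerated).
#'
#' @param n Number of guides (>= 1).
#' @param seed Integer seed.
#' @return Character vector of `n` distinct 23-nt sequences.
#' @export
generate_sgrnas <- function(n, seed = 1L) {
  if (n < 1L) stopf("n must be >= 1")
  local_seed(seed, {
    draw <- function(k) {
      vapply(seq_len(k), function(i) {
        paste(c(sample(DNA_BASES, 20, replace = TRUE),
                sample(DNA_BASES, 1), "G", "G"), collapse = "")
      }, character(1))
    }
    out <- draw(n)
    while (anyDuplicated(out)) {
      dup <- which(duplicated(out))
      out[dup] <- draw(length(dup))
    }
    out
  })
}

#' Generate candidate off-target sites for one sgRNA
#'
#' Each site copies the sgRNA and substitutes `k` protospacer positions
#' (`k` uniform over `mismatch_range`, positions uniform without
#' replacement over 1..20, substitute base uniform over the three
#' alternatives). The PAM is preserved.
#'
#' @param sgrna A 23-nt sequence.
#' @param n_sites Number of sites (>= 1).
#' @param config An `otsim_config`.
#' @param seed Integer seed (defaults to `config$seed`).
#' @return Data frame with columns `sgrna_seq` and `dna_seq`.
#' @export
generate_offtarget_sites <- function(sgrna, n_sites, config,
                                     seed = config$seed) {
  if (n_sites < 1L) stopf("n_sites must be >= 1")
  chars <- seq_chars(sgrna, "sgRNA sequence")
  kr <- config$mismatch_range
  local_seed(seed, {
    dna <- vapply(seq_len(n_sites), function(i) {
      k <- sample(seq(kr[1], kr[2]), 1)
      pos <- sample(1:20, k)
      d <- chars
      for (p in pos) d[p] <- sample(setdiff(DNA_BASES, d[p]), 1)
      paste(d, collapse = "")
    }, character(1))
    data.frame(sgrna_seq = sgrna, dna_seq = dna, stringsAsFactors = FALSE)
  })
}

#' Assign planted labels and cleavage frequencies
#'
#' Latent propensity is the multiplicative ground-truth table score of each
#' pair; the top fraction `1 / (1 + imbalance_ratio)` by propensity is
#' labelled positive with frequency equal to the propensity perturbed by
#' Gaussian noise truncated to (0, 1]; the rest are labelled 0 with
#' frequency 0. All-identical propensities are tie-broken by seeded uniform
#' jitter with a message.
#'
#' @param pairs Data frame with `sgrna_seq` and `dna_seq` (extra columns
#'   kept).
#' @param config An `otsim_config`.
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A validated off-target dataset.
#' @export
assign_ground_truth <- function(pairs, config, seed = config$seed) {
  prop <- cfd_score_dataset(pairs, config$ground_truth_table, strict = TRUE)
  n <- length(prop)
  n_pos <- max(1L, round(n / (1 + config$imbalance_ratio)))
  local_seed(seed, {
    if (length(unique(prop)) == 1L) {
      message("all propensities identical; breaking ties by seeded jitter")
    }
    rank_key <- prop + stats::runif(n, 0, 1e-9)  # seeded tie-break
    pos_idx <- order(rank_key, decreasing = TRUE)[seq_len(n_pos)]
    label <- integer(n)
    label[pos_idx] <- 1L
    freq <- numeric(n)
    noise <- stats::rnorm(n_pos, 0, config$noise_sd)
    freq[pos_idx] <- pmin(1, pmax(1e-6, prop[pos_idx] + noise))
    out <- pairs
    if (is.null(out$sgrna_id)) out$sgrna_id <- "sgRNA_1"
    if (is.null(out$cell_line)) out$cell_line <- "synthetic"
    out$label <- label
    out$frequency <- freq
    as_offtarget_dataset(out)
  })
}

#' Simulate a complete synthetic off-target dataset
#'
#' Draws `n_sgrnas` guides, generates `sites_per_sgrna` candidate loci for
#' each, and plants labels/frequencies per guide so positives spread
#' uniformly across guides. Cell lines alternate between two synthetic tags
#' to exercise stratified splitting.
#'
#' @param config An `otsim_config` from [generative_config()]; individual
#'   fields may be overridden via `...` passed to [generative_config()].
#' @param ... Overrides forwarded to [generative_config()] when `config` is
#'   `NULL`.
#' @return A validated off-target dataset.
#' @export
#' @examples
#' d <- simulate_offtarget_dataset(n_sgrnas = 2, sites_per_sgrna = 60,
#'                                 imbalance_ratio = 20, seed = 7)
#' table(d$label)
simulate_offtarget_dataset <- function(config = NULL, ...) {
  config <- config %||% generative_config(...)
  guides <- generate_sgrnas(config$n_sgrnas, seed = subseed(config$seed, 0L))
  parts <- lapply(seq_along(guides), function(i) {
    sites <- generate_offtarget_sites(guides[i], config$sites_per_sgrna,
                                      config, seed = subseed(config$seed, i))
    sites$sgrna_id <- sprintf("sgRNA_%02d", i)
    sites$cell_line <- if (i %% 2L == 1L) "synthA" else "synthB"
    assign_ground_truth(sites, config,
                        seed = subseed(config$seed, 1000L + i))
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
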