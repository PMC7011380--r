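# Tokenisation of sgRNA-DNA base pairs.
#
# A 23-nt sgRNA aligned to a 23-nt genomic site gives one base pair per
# position; with 4 canonical bases on each strand there are 16 ordered pairs,
# so a pair of sequences becomes a length-23 vector of integers in [0, 15].
# The canonical bijection used throughout is lexicographic with A=0, C=1,
# G=2, T=3:  index = 4 * ord(rna) + ord(dna).

DNA_BASES <- c("A", "C", "G", "T")

#' Token index of one sgRNA-DNA base pair
#'
#' Maps an ordered pair of canonical bases to its integer token under the
#' lexicographic convention `4 * ord(rna) + ord(dna)` with
#' A=0, C=1, G=2, T=3. The map is a bijection between the 16 ordered base
#' pairs and `0:15`; matched pairs occupy tokens `c(0, 5, 10, 15)`.
#'
#' @param rna_base Character vector of sgRNA bases (`A`, `C`, `G` or `T`;
#'   the guide is written in DNA alphabet, T standing for U).
#' @param dna_base Character vector of genomic bases, recycled with
#'   `rna_base`.
#' @return Integer vector of tokens in `[0, 15]`.
#' @seealso [encode_pair()], [decode_tokens()], [match_tokens()]
#' @export
#' @examples
#' token_index("A", "A")   # 0
#' token_index("G", "A")   # 8
token_index <- function(rna_base, dna_base) {
  r <- match(rna_base, DNA_BASES)
  d <- match(dna_base, DNA_BASES)
  if (anyNA(r)) {
    stopf("non-canonical sgRNA base(s): %s",
          paste(unique(rna_base[is.na(r)]), collapse = ", "))
  }
  if (anyNA(d)) {
    stopf("non-canonical DNA base(s): %s",
          paste(unique(dna_base[is.na(d)]), collapse = ", "))
  }
  as.integer(4L * (r - 1L) + (d - 1L))
}

#' Tokens representing matched (non-mismatch) base pairs
#'
#' @return Integer vector `token_index(b, b)` for the four bases.
#' @export
match_tokens <- function() token_index(DNA_BASES, DNA_BASES)

seq_chars <- function(seq, what, len = 23L) {
  if (length(seq) != 1L || !is.character(seq)) {
    stopf("%s must be a single character string", what)
  }
  if (nchar(seq) != len) {
    stopf("%s has length %d, expected %d", what, nchar(seq), len)
  }
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  bad <- which(!ch %in% DNA_BASES)
  if (length(bad)) {
    stopf("%s contains non-ACGT character '%s' at position %d",
          what, ch[bad[1]], bad[1])
  }
  ch
}

#' Encode an sgRNA-DNA pair as a length-23 token vector
#'
#' Position `i` of the result is `token_index(sgrna[i], dna[i])`. Positions
#' are 0-based internally; user-facing reports are 1-based with the PAM at
#' positions 21-23.
#'
#' @param sgrna_seq,dna_seq 23-character strings over `ACGT` (lowercase
#'   accepted and upcased).
#' @return Integer vector of length 23 with values in `[0, 15]`.
#' @export
#' @examples
#' s <- strrep("A", 23)
#' encode_pair(s, s)
encode_pair <- function(sgrna_seq, dna_seq) {
  r <- seq_chars(sgrna_seq, "sgRNA sequence")
  d <- seq_chars(dna_seq, "DNA sequence")
  token_index(r, d)
}

#' Decode a token vector back into its sgRNA and DNA sequences
#'
#' Exact inverse of [encode_pair()].
#'
#' @param tokens Integer vector of length 23 with values in `[0, 15]`.
#' @return Named character vector with elements `sgrna_seq` and `dna_seq`.
#' @export
decode_tokens <- function(tokens) {
  if (length(tokens) != 23L) {
    stopf("token vector has length %d, expected 23", length(tokens))
  }
  tokens <- as.integer(tokens)
  bad <- which(is.na(tokens) | tokens < 0L | tokens > 15L)
  if (length(bad)) {
    stopf("token value out of [0,15] at position %d", bad[1])
  }
  c(sgrna_seq = paste(DNA_BASES[tokens %/% 4L + 1L], collapse = ""),
    dna_seq   = paste(DNA_BASES[tokens %% 4L + 1L], collapse = ""))
}

#' Encode every pair of a dataset into a token matrix
#'
#' @param data An off-target dataset (see [read_offtarget_table()]).
#' @return Integer matrix, one row per pair, 23 columns.
#' @export
encode_dataset <- function(data) {
  n <- nrow(data)
  out <- matrix(0L, n, 23L)
  for (i in seq_len(n)) {
    out[i, ] <- tryCatch(
      encode_pair(data$sgrna_seq[i], data$dna_seq[i]),
      error = function(e) stopf("pair %d: %s", i, conditionMessage(e))
    )
  }
  out
}

#' Number of mismatched positions of an sgRNA-DNA pair
#'
#' Counts tokens outside the matched-pair subset; by construction equal to
#' the Hamming distance of the two sequences.
#'
#' @inheritParams encode_pair
#' @param protospacer_only If `TRUE`, count only positions 1-20 (exclude the
#'   PAM).
#' @return Integer mismatch count.
#' @export
mismatch_count <- function(sgrna_seq, dna_seq, protospacer_only = FALSE) {
  tok <- encode_pair(sgrna_seq, dna_seq)
  if (protospacer_only) tok <- tok[1:20]
  sum(!tok %in% match_tokens())
}
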