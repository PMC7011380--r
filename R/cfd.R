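# Multiplicative CFD (Cutting Frequency Determination) scoring.
#
# CFD assigns each mismatch type at each protospacer position (1-20, PAM
# excluded) a score in [0, 1]; the score of a pair is the product over its
# mismatches, and a perfect match scores 1. "rG-dA at position 6" means
# sgRNA base G aligned against DNA base A at protospacer position 6.

cfd_key <- function(rna, dna, pos) paste(rna, dna, pos, sep = ":")

#' Construct a CFD score table
#'
#' @param entries Data frame with columns `rna_base`, `dna_base`, `position`
#'   (1-20) and `score` (in `[0, 1]`). Matched pairs need no entry: they
#'   score 1 implicitly. An empty data frame gives the trivial table under
#'   which every pair scores 1.
#' @return Object of class `cfd_table`.
#' @export
#' @examples
#' cfd_table(data.frame(rna_base = c("G", "C"), dna_base = c("A", "T"),
#'                      position = c(6, 10), score = c(0.67, 0.87)))
cfd_table <- function(entries = data.frame()) {
  if (nrow(entries) == 0L) {
    return(structure(list(scores = numeric(0)), class = "cfd_table"))
  }
  need <- c("rna_base", "dna_base", "position", "score")
  missing <- setdiff(need, names(entries))
  if (length(missing)) {
    stopf("CFD table lacks column(s): %s", paste(missing, collapse = ", "))
  }
  rna <- toupper(as.character(entries$rna_base))
  dna <- toupper(as.character(entries$dna_base))
  pos <- as.integer(entries$position)
  score <- as.numeric(entries$score)
  if (any(!rna %in% DNA_BASES) || any(!dna %in% DNA_BASES)) {
    stopf("CFD table bases must be A, C, G or T")
  }
  if (any(is.na(pos) | pos < 1L | pos > 20L)) {
    stopf("CFD positions must lie in 1..20 (protospacer, PAM excluded)")
  }
  if (any(is.na(score) | score < 0 | score > 1)) {
    stopf("CFD scores must lie in [0, 1]")
  }
  if (any(rna == dna)) {
    stopf("CFD entries must be mismatches (rna_base != dna_base)")
  }
  keys <- cfd_key(rna, dna, pos)
  if (anyDuplicated(keys)) {
    stopf("duplicate CFD entr%s: %s",
          if (sum(duplicated(keys)) > 1) "ies" else "y",
          paste(unique(keys[duplicated(keys)]), collapse = ", "))
  }
  structure(list(scores = stats::setNames(score, keys)), class = "cfd_table")
}

#' @export
print.cfd_table <- function(x, ...) {
  cat(sprintf("CFD score table with %d mismatch entr%s\n",
              length(x$scores), if (length(x$scores) == 1) "y" else "ies"))
  invisible(x)
}

#' Load a CFD score table from TSV
#'
#' Expects a header line and columns `rna_base`, `dna_base`, `position`,
#' `score`.
#'
#' @param path Path to the TSV file.
#' @return A `cfd_table`.
#' @export
load_cfd_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  cfd_table(df)
}

#' CFD score of one sgRNA-DNA pair
#'
#' Multiplies the table entries of every mismatch in the 20-nt protospacer
#' (positions 21-23, the PAM, are excluded); a pair without mismatches
#' scores 1. In strict mode a mismatch missing from the table is an error;
#' otherwise it scores 1 with a warning, so partial tables stay usable.
#'
#' @inheritParams encode_pair
#' @param table A `cfd_table`.
#' @param strict Error on table gaps (default `TRUE`).
#' @param position_origin `"pam_distal"` (default): protospacer position 1
#'   is the 5' end, farthest from the PAM, i.e. string position `i` is CFD
#'   position `i`. `"pam_proximal"`: position 1 abuts the PAM (CFD position
#'   `21 - i`).
#' @return Score in `[0, 1]`.
#' @export
cfd_score <- function(sgrna_seq, dna_seq, table, strict = TRUE,
                      position_origin = c("pam_distal", "pam_proximal")) {
  position_origin <- match.arg(position_origin)
  stopifnot(inherits(table, "cfd_table"))
  r <- seq_chars(sgrna_seq, "sgRNA sequence")
  d <- seq_chars(dna_seq, "DNA sequence")
  mm <- which(r[1:20] != d[1:20])
  if (length(mm) == 0L) return(1)
  pos <- if (position_origin == "pam_distal") mm else 21L - mm
  keys <- cfd_key(r[mm], d[mm], pos)
  sc <- table$scores[keys]
  if (anyNA(sc)) {
    miss <- which(is.na(sc))
    if (strict) {
      stopf("no CFD entry for mismatch r%s-d%s at protospacer position %d",
            r[mm[miss[1]]], d[mm[miss[1]]], pos[miss[1]])
    }
    warnf("scoring %d mismatch(es) absent from the CFD table as 1.0 (%s)",
          length(miss), paste(keys[miss], collapse = ", "))
    sc[miss] <- 1
  }
  prod(sc)
}

#' CFD scores for every pair of a dataset
#'
#' @param data An off-target dataset.
#' @inheritParams cfd_score
#' @return Numeric vector of scores, one per pair.
#' @export
cfd_score_dataset <- function(data, table, strict = TRUE,
                              position_origin = "pam_distal") {
  vapply(seq_len(nrow(data)), function(i) {
    cfd_score(data$sgrna_seq[i], data$dna_seq[i], table, strict = strict,
              position_origin = position_origin)
  }, numeric(1))
}
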