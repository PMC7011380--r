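# Reading, validating and writing off-target tables; dataset splits.
#
# The canonical on-disk form is a 6-column TSV:
#   sgrna_id  sgrna_seq  dna_seq  label  frequency  cell_line
# A dialect (named character vector canonical -> file column) adapts other
# layouts without code changes.

CANONICAL_COLUMNS <- c("sgrna_id", "sgrna_seq", "dna_seq",
                       "label", "frequency", "cell_line")

#' Column dialect for off-target tables
#'
#' @param ... Named overrides mapping canonical column names
#'   (`sgrna_id`, `sgrna_seq`, `dna_seq`, `label`, `frequency`, `cell_line`)
#'   to the column names used in a particular file.
#' @return Named character vector, canonical name -> file column name.
#' @export
#' @examples
#' offtarget_dialect(sgrna_seq = "guide", dna_seq = "site")
offtarget_dialect <- function(...) {
  dialect <- stats::setNames(CANONICAL_COLUMNS, CANONICAL_COLUMNS)
  over <- c(...)
  if (length(over)) {
    unknown <- setdiff(names(over), CANONICAL_COLUMNS)
    if (length(unknown)) {
      stopf("unknown canonical column(s) in dialect: %s",
            paste(unknown, collapse = ", "))
    }
    dialect[names(over)] <- over
  }
  dialect
}

validate_pairs <- function(data, context = "row") {
  problems <- character(0)
  note <- function(i, msg) sprintf("%s %d: %s", context, i, msg)
  for (i in seq_len(nrow(data))) {
    for (col in c("sgrna_seq", "dna_seq")) {
      s <- data[[col]][i]
      if (is.na(s) || nchar(s) != 23L) {
        problems <- c(problems, note(i, sprintf(
          "%s has length %s, expected 23", col,
          if (is.na(s)) "NA" else nchar(s))))
      } else if (grepl("[^ACGT]", s)) {
        problems <- c(problems, note(i, sprintf(
          "%s contains non-ACGT character", col)))
      }
    }
    lab <- data$label[i]
    freq <- data$frequency[i]
    if (is.na(lab) || !lab %in% c(0, 1)) {
      problems <- c(problems, note(i, "label must be 0 or 1"))
    } else if (is.na(freq) || freq < 0 || freq > 1) {
      problems <- c(problems, note(i, "frequency must lie in [0,1]"))
    } else if (lab == 1 && freq <= 0) {
      problems <- c(problems, note(i, "label 1 requires frequency > 0"))
    } else if (lab == 0 && freq != 0) {
      problems <- c(problems, note(i, "label 0 requires frequency == 0"))
    }
    if (length(problems) >= 20L) break
  }
  if (length(problems)) {
    stopf("invalid off-target table:\n%s",
          paste(problems, collapse = "\n"))
  }
  invisible(data)
}

#' Assemble and validate an off-target dataset
#'
#' @param data A data frame with the six canonical columns.
#' @return The validated data frame (sequences upcased), one row per
#'   sgRNA-DNA pair.
#' @export
as_offtarget_dataset <- function(data) {
  missing <- setdiff(CANONICAL_COLUMNS, names(data))
  if (length(missing)) {
    stopf("missing column(s): %s", paste(missing, collapse = ", "))
  }
  data <- as.data.frame(data)[CANONICAL_COLUMNS]
  data$sgrna_id <- as.character(data$sgrna_id)
  data$cell_line <- as.character(data$cell_line)
  data$sgrna_seq <- toupper(as.character(data$sgrna_seq))
  data$dna_seq <- toupper(as.character(data$dna_seq))
  data$label <- as.integer(data$label)
  data$frequency <- as.numeric(data$frequency)
  rownames(data) <- NULL
  validate_pairs(data)
}

#' Read an off-target table
#'
#' Reads a delimited table of sgRNA-DNA pairs into the canonical dataset
#' form. Sequences are upcased; rows violating the 23-nt ACGT constraints
#' are rejected with their row number. Pairs containing ambiguity codes
#' (e.g. `N`) are rejected by default because the 16-token vocabulary has no
#' column for them; `ambiguous = "skip"` drops such rows with a warning.
#'
#' @param path Path to a TSV (or `sep`-delimited) file with a header.
#' @param dialect Column mapping from [offtarget_dialect()].
#' @param ambiguous `"error"` (default) or `"skip"` for rows whose sequences
#'   contain non-ACGT letters.
#' @param sep Field separator, default tab.
#' @return A validated off-target dataset (data frame), row order preserved.
#' @export
read_offtarget_table <- function(path, dialect = offtarget_dialect(),
                                 ambiguous = c("error", "skip"),
                                 sep = "\t") {
  ambiguous <- match.arg(ambiguous)
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- utils::read.delim(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0L) {
    out <- data.frame(sgrna_id = character(0), sgrna_seq = character(0),
                      dna_seq = character(0), label = integer(0),
                      frequency = numeric(0), cell_line = character(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  missing <- setdiff(unname(dialect), names(raw))
  if (length(missing)) {
    stopf("file %s lacks column(s): %s", path, paste(missing, collapse = ", "))
  }
  data <- stats::setNames(raw[unname(dialect)], names(dialect))
  data$sgrna_seq <- toupper(as.character(data$sgrna_seq))
  data$dna_seq <- toupper(as.character(data$dna_seq))
  if (ambiguous == "skip") {
    amb <- grepl("[^ACGT]", data$sgrna_seq) | grepl("[^ACGT]", data$dna_seq)
    if (any(amb)) {
      warnf("skipping %d row(s) with ambiguous bases (rows %s)",
            sum(amb), paste(utils::head(which(amb), 10), collapse = ", "))
      data <- data[!amb, , drop = FALSE]
    }
  }
  as_offtarget_dataset(data)
}

#' Write an off-target dataset as canonical TSV
#'
#' @param data An off-target dataset.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_offtarget_table <- function(data, path) {
  utils::write.table(data[CANONICAL_COLUMNS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write predictions alongside their pairs
#'
#' Appends a `score` column to the canonical columns and writes a TSV that
#' re-reads losslessly (scores kept to full double precision).
#'
#' @param data An off-target dataset.
#' @param scores Numeric vector, one score per pair.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(data, scores, path) {
  if (length(scores) != nrow(data)) {
    stopf("%d scores for %d pairs", length(scores), nrow(data))
  }
  out <- data[CANONICAL_COLUMNS]
  out$score <- format(scores, digits = 17, trim = TRUE, scientific = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Split a dataset into train and test parts
#'
#' Per-stratum test size is `round(test_fraction * stratum size)`; the split
#' is a disjoint, exhaustive partition and is deterministic given `seed`.
#'
#' @param data An off-target dataset.
#' @param test_fraction Fraction in (0, 1) assigned to the test part.
#' @param seed Integer seed.
#' @param stratify_by `"none"` (default) or `"cell_line"`.
#' @return List with elements `train` and `test`.
#' @export
split_train_test <- function(data, test_fraction = 0.2, seed = 1L,
                             stratify_by = c("none", "cell_line")) {
  stratify_by <- match.arg(stratify_by)
  if (nrow(data) == 0L) stopf("dataset is empty")
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1) {
    stopf("test_fraction must lie strictly between 0 and 1")
  }
  strata <- if (stratify_by == "none") {
    list(seq_len(nrow(data)))
  } else {
    split(seq_len(nrow(data)), data$cell_line)
  }
  test_idx <- local_seed(seed, {
    unlist(lapply(strata, function(idx) {
      if (length(idx) < 2L) {
        stopf("stratum of size %d cannot be split", length(idx))
      }
      n_test <- round(test_fraction * length(idx))
      sample(idx, n_test)
    }), use.names = FALSE)
  })
  list(train = data[setdiff(seq_len(nrow(data)), test_idx), , drop = FALSE],
       test = data[sort(test_idx), , drop = FALSE])
}

#' Export the unique sgRNA sequences of a dataset as FASTA
#'
#' @param data An off-target dataset.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
export_sgrna_fasta <- function(data, path) {
  if (!requireNamespace("seqinr", quietly = TRUE)) {
    stopf("export_sgrna_fasta requires the 'seqinr' package")
  }
  u <- !duplicated(data$sgrna_id)
  seqs <- lapply(data$sgrna_seq[u], function(s) strsplit(s, "")[[1]])
  seqinr::write.fasta(seqs, names = data$sgrna_id[u], file.out = path)
  invisible(path)
}
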