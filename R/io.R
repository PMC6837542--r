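#' Read aligned sgRNA-DNA pair tables
#'
#' Tab- or comma-separated files with columns `sgrna`, `dna` and either a
#' numeric `score` (indel frequency, %) or a binary `label`. Column names are
#' matched case-insensitively; files without a header may supply columns in
#' that order via `col_names`.
#'
#' @param path File path.
#' @param col_names Optional character vector naming headerless columns.
#' @return Tibble with canonicalized sequences.
#' @export
read_pairs <- function(path, col_names = NULL) {
  tbl <- .read_table(path, col_names)
  names(tbl) <- tolower(names(tbl))
  if (!all(c("sgrna", "dna") %in% names(tbl))) {
    abort(sprintf("%s: expected columns `sgrna` and `dna`.", path))
  }
  tbl$sgrna <- canonicalize_seq(tbl$sgrna)
  tbl$dna <- canonicalize_seq(tbl$dna)
  if ("score" %in% names(tbl)) .assert_numeric_col(tbl, "score", path)
  as_tibble(tbl)
}

#' Read guide efficiency tables
#'
#' Columns: `seq`, `efficiency`, optional `gene`, `cell_line`, `copy_number`.
#' @inheritParams read_pairs
#' @return Tibble with canonicalized `seq`.
#' @export
read_guides <- function(path, col_names = NULL) {
  tbl <- .read_table(path, col_names)
  names(tbl) <- tolower(names(tbl))
  if (!all(c("seq", "efficiency") %in% names(tbl))) {
    abort(sprintf("%s: expected columns `seq` and `efficiency`.", path))
  }
  tbl$seq <- canonicalize_seq(tbl$seq)
  .assert_numeric_col(tbl, "efficiency", path)
  if (!all(is.finite(tbl$efficiency))) {
    abort(sprintf("%s: `efficiency` must be finite.", path))
  }
  as_tibble(tbl)
}

#' Read a STRING-style gene interaction edge list
#'
#' Three columns (gene, gene, confidence), TSV or CSV, header optional and
#' auto-detected. Raw STRING combined scores on the 0-1000 scale are detected
#' (any confidence > 1) and divided by 1000 unless `rescale = FALSE`.
#' Duplicate / reversed edges collapse to the maximum confidence.
#'
#' @param path File path.
#' @param rescale Auto-rescale 0-1000 confidences to (0,1].
#' @return Tibble with columns `gene_a`, `gene_b`, `confidence`.
#' @export
read_network <- function(path, rescale = TRUE) {
  cn <- if (.headerless(path, value_col = 3)) c("gene_a", "gene_b", "confidence") else NULL
  tbl <- .read_table(path, col_names = cn)
  if (ncol(tbl) < 3) abort(sprintf("%s: expected 3 columns (geneA, geneB, confidence).", path))
  tbl <- tbl[, 1:3]
  names(tbl) <- c("gene_a", "gene_b", "confidence")
  if (!is.numeric(tbl$confidence)) {
    bad <- which(is.na(suppressWarnings(as.numeric(tbl$confidence))))[1]
    abort(sprintf("%s: line %d has a non-numeric confidence value.", path, bad + 1L))
  }
  if (any(tbl$confidence <= 0)) {
    abort(sprintf("%s: line %d has a non-positive confidence.",
                  path, which(tbl$confidence <= 0)[1] + 1L))
  }
  if (rescale && max(tbl$confidence) > 1) {
    tbl$confidence <- tbl$confidence / 1000
  }
  .validate_network(tbl)
}

#' Read a per-cell-line expression table
#'
#' Either long form (`gene`, `value`, optional `cell_line`) or a wide
#' gene-by-cell-line matrix with gene ids in the first column; wide input is
#' pivoted to long. `log2` applies `log2(x + 1)` on ingest.
#'
#' @param path File path.
#' @param log2 Log-transform expression values on read.
#' @return Tibble with columns `gene`, `cell_line` (if applicable), `value`.
#' @export
read_expression <- function(path, log2 = FALSE) {
  cn <- if (.headerless(path, value_col = 2)) c("gene", "value") else NULL
  tbl <- .read_table(path, col_names = cn)
  names(tbl)[1] <- "gene"
  lower <- tolower(names(tbl))
  if ("value" %in% lower) {
    names(tbl) <- lower
  } else if (ncol(tbl) == 2) {
    names(tbl) <- c("gene", "value")
  } else {
    tbl <- tidyr::pivot_longer(tbl, -gene, names_to = "cell_line",
                               values_to = "value")
  }
  .assert_numeric_col(tbl, "value", path)
  if (log2) tbl$value <- base::log2(tbl$value + 1)
  as_tibble(tbl)
}

#' Read bare sequences from FASTA
#'
#' @param path FASTA file.
#' @return Tibble with columns `name`, `seq` (canonicalized).
#' @export
read_fasta_seqs <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readBStringSet(path)
    return(tibble(name = names(ss),
                  seq = unname(canonicalize_seq(as.character(ss)))))
  }
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) abort(sprintf("%s: not a FASTA file.", path))
  id <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], id[!hdr]), paste, "", collapse = "")
  tibble(name = sub("^>\\s*", "", lines[hdr]), seq = canonicalize_seq(unname(seqs)))
}

#' Write a tibble as TSV
#' @param x Data frame. @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_file <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

.headerless <- function(path, value_col) {
  # a numeric value column on line 1 means the file carries no header
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  first <- strsplit(readLines(path, n = 1), delim, fixed = TRUE)[[1]]
  length(first) >= value_col &&
    !is.na(suppressWarnings(as.numeric(first[value_col])))
}

.read_table <- function(path, col_names) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  out <- tryCatch(
    readr::read_delim(path, delim = delim,
                      col_names = col_names %||% TRUE,
                      show_col_types = FALSE, progress = FALSE),
    error = function(e) abort(sprintf("Failed to parse %s: %s", path, conditionMessage(e)))
  )
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    abort(sprintf("%s: malformed row at line %d (%s).",
                  path, probs$row[1], probs$expected[1]))
  }
  out
}

.assert_numeric_col <- function(tbl, col, path) {
  if (!is.numeric(tbl[[col]])) {
    bad <- which(is.na(suppressWarnings(as.numeric(tbl[[col]]))))[1]
    abort(sprintf("%s: column `%s` has a non-numeric value at data line %d.",
                  path, col, bad))
  }
  invisible(tbl)
}
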