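#' Nucleotide token vocabularies
#'
#' Both encoders map onto a 16-symbol vocabulary: the ordered pair of bases
#' observed either at one aligned sgRNA-DNA position (base-pair tokens) or at
#' two contiguous positions of a single sequence (dimer tokens). Token ids are
#' assigned lexicographically over (A, C, G, T) x (A, C, G, T), so
#' (A,A) = 0, (A,C) = 1, ..., (T,T) = 15. The mapping is a fixed constant of
#' the package: models, fixtures and checkpoints all rely on it.
#'
#' @param vocab Which vocabulary to tabulate: `"base_pair"` (first base from
#'   the sgRNA, second from the aligned DNA) or `"dimer"` (bases at positions
#'   k and k+1 of one sequence, 5'->3').
#' @return A 16-row tibble with columns `token`, `first`, `second`, and
#'   `label` (e.g. `"A:C"` for base pairs, `"AC"` for dimers).
#' @examples
#' token_vocab("dimer")
#' @export
token_vocab <- function(vocab = c("base_pair", "dimer")) {
  vocab <- match.arg(vocab)
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(second = bases, first = bases,
                      stringsAsFactors = FALSE)[, c("first", "second")]
  sep <- if (vocab == "base_pair") ":" else ""
  tibble(
    token = 0:15,
    first = grid$first,
    second = grid$second,
    label = paste0(grid$first, sep, grid$second)
  )
}

.BASES <- c(A = 0L, C = 1L, G = 2L, T = 3L)

#' Canonicalize nucleotide sequences
#'
#' Uppercases and maps RNA `U` to DNA `T` so that a single internal alphabet
#' `{A,C,G,T}` is used everywhere. Ambiguity codes (`N`, `R`, ...) and gaps are
#' rejected: model inputs are ungapped, fully resolved sequences.
#'
#' @param x Character vector of sequences.
#' @return Character vector of the same length over `{A,C,G,T}`.
#' @examples
#' canonicalize_seq("augcu")   # "ATGCT"
#' @export
canonicalize_seq <- function(x) {
  if (!is.character(x)) abort("`x` must be a character vector of sequences.")
  out <- chartr("u", "U", toupper(x))
  out <- chartr("U", "T", out)
  bad <- grepl("[^ACGT]", out)
  if (any(bad)) {
    offender <- x[bad][1]
    abort(sprintf(
      "Sequence %d ('%s') contains characters outside {A,C,G,T,U}; ambiguity codes are not supported.",
      which(bad)[1], offender
    ))
  }
  out
}

.seq_to_idx <- function(x) {
  # integer base indices (A=0,C=1,G=2,T=3) for one canonical sequence
  unname(.BASES[strsplit(x, "", fixed = TRUE)[[1]]])
}

#' Encode aligned sgRNA-DNA pairs as base-pair tokens
#'
#' Every aligned position contributes one token: the ordered combination of
#' the sgRNA base and the DNA base at that position (16 possible types).
#' Positions are indexed from 0 and run 5'->3' along the sgRNA, so a Cas9
#' 20-mer alignment yields 20 tokens and a Cas12a 27-mer yields 27.
#'
#' @param pairs A data frame with (at least) character columns `sgrna` and
#'   `dna` holding equal-length aligned sequences. Other columns are preserved
#'   on the per-pair metadata and ignored here.
#' @return A tibble in long form with columns `pair` (row index of the input),
#'   `position` (0-based), `sgrna_base`, `dna_base`, `token`.
#' @seealso [encode_dimers()], [token_matrix()], [decode_base_pairs()]
#' @examples
#' pairs <- tibble::tibble(sgrna = "ACGT", dna = "ACTT")
#' encode_base_pairs(pairs)
#' @export
encode_base_pairs <- function(pairs) {
  stopifnot(is.data.frame(pairs))
  if (!all(c("sgrna", "dna") %in% names(pairs))) {
    abort("`pairs` needs columns `sgrna` and `dna`.")
  }
  if (nrow(pairs) == 0) abort("`pairs` is empty.")
  sg <- canonicalize_seq(pairs$sgrna)
  dn <- canonicalize_seq(pairs$dna)
  if (any(nchar(sg) != nchar(dn))) {
    i <- which(nchar(sg) != nchar(dn))[1]
    abort(sprintf(
      "Alignment error: pair %d has sgRNA length %d but DNA length %d.",
      i, nchar(sg)[i], nchar(dn)[i]
    ))
  }
  lens <- nchar(sg)
  sg_idx <- unlist(lapply(sg, .seq_to_idx), use.names = FALSE)
  dn_idx <- unlist(lapply(dn, .seq_to_idx), use.names = FALSE)
  bases <- names(.BASES)
  tibble(
    pair = rep(seq_along(sg), lens),
    position = unlist(lapply(lens, function(L) 0:(L - 1L)), use.names = FALSE),
    sgrna_base = bases[sg_idx + 1L],
    dna_base = bases[dn_idx + 1L],
    token = as.integer(4L * sg_idx + dn_idx)
  )
}

#' Encode sequences as overlapping dimer tokens
#'
#' A sliding window of length 2 walks each sequence 5'->3'; the k-th token
#' (k from 0) encodes the ordered bases at positions k and k+1, one of 16
#' dimer types. A sequence of length L yields L-1 tokens: 19 for a Cas9
#' 20-mer, 33 for a Cas12a 34-mer.
#'
#' @param guides A data frame with a character column `seq`, or a bare
#'   character vector of sequences.
#' @return A tibble with columns `guide` (input row), `position` (0-based
#'   window start), `dimer` (two-letter label), `token`.
#' @examples
#' encode_dimers("AUGCU")  # AU, UG, GC, CU -> AT, TG, GC, CT internally
#' @export
encode_dimers <- function(guides) {
  if (is.character(guides)) guides <- tibble(seq = guides)
  stopifnot(is.data.frame(guides))
  if (!"seq" %in% names(guides)) abort("`guides` needs a `seq` column.")
  if (nrow(guides) == 0) abort("`guides` is empty.")
  sq <- canonicalize_seq(guides$seq)
  if (any(nchar(sq) < 2)) {
    abort(sprintf("Sequence %d is shorter than 2 bases; no dimer can be extracted.",
                  which(nchar(sq) < 2)[1]))
  }
  lens <- nchar(sq)
  idx <- lapply(sq, .seq_to_idx)
  first <- unlist(lapply(idx, function(v) v[-length(v)]), use.names = FALSE)
  second <- unlist(lapply(idx, function(v) v[-1]), use.names = FALSE)
  bases <- names(.BASES)
  tibble(
    guide = rep(seq_along(sq), lens - 1L),
    position = unlist(lapply(lens, function(L) 0:(L - 2L)), use.names = FALSE),
    dimer = paste0(bases[first + 1L], bases[second + 1L]),
    token = as.integer(4L * first + second)
  )
}

#' Widen a long token tibble into a model-ready matrix
#'
#' @param tokens Output of [encode_base_pairs()] or [encode_dimers()].
#' @return Integer matrix, one row per input pair/guide, one column per
#'   position, values in 0..15.
#' @export
token_matrix <- function(tokens) {
  id_col <- if ("pair" %in% names(tokens)) "pair" else "guide"
  ids <- tokens[[id_col]]
  pos <- tokens$position
  L <- max(pos) + 1L
  n <- max(ids)
  if (!all(tabulate(ids, n) == L)) {
    abort("All sequences must have the same length to form a token matrix.")
  }
  m <- matrix(NA_integer_, n, L)
  m[cbind(ids, pos + 1L)] <- as.integer(tokens$token)
  m
}

#' Decode token sequences back to nucleotide strings
#'
#' Inverse of the encoders; used for round-trip checks and display.
#'
#' @param tokens Long tibble from [encode_base_pairs()].
#' @return For base pairs, a tibble with one row per pair and columns `sgrna`,
#'   `dna`; for dimers, a tibble with `seq`.
#' @export
decode_base_pairs <- function(tokens) {
  bases <- names(.BASES)
  tokens %>%
    arrange(pair, position) %>%
    group_by(pair) %>%
    summarise(
      sgrna = paste(bases[token %/% 4L + 1L], collapse = ""),
      dna = paste(bases[token %% 4L + 1L], collapse = ""),
      .groups = "drop"
    )
}

#' @rdname decode_base_pairs
#' @export
decode_dimers <- function(tokens) {
  bases <- names(.BASES)
  tokens %>%
    arrange(guide, position) %>%
    group_by(guide) %>%
    summarise(
      seq = paste0(
        paste(bases[token[1] %/% 4L + 1L], collapse = ""),
        paste(bases[token %% 4L + 1L], collapse = "")
      ),
      .groups = "drop"
    )
}

#' Validate aligned pairs for a CRISPR system
#'
#' Checks the system-specific expected alignment length (20 for Cas9 spacers,
#' 27 for Cas12a including its 4-base 5' PAM window).
#'
#' @param pairs Data frame with `sgrna`, `dna` columns.
#' @param system `"cas9"` or `"cas12a"`.
#' @param pair_length Override the expected length.
#' @return `pairs` invisibly (canonicalized), or an error.
#' @export
validate_pairs <- function(pairs, system = c("cas9", "cas12a"),
                           pair_length = NULL) {
  system <- match.arg(system)
  expected <- pair_length %||% switch(system, cas9 = 20L, cas12a = 27L)
  pairs$sgrna <- canonicalize_seq(pairs$sgrna)
  pairs$dna <- canonicalize_seq(pairs$dna)
  bad <- nchar(pairs$sgrna) != expected | nchar(pairs$dna) != expected
  if (any(bad)) {
    abort(sprintf("Pair %d does not have the expected %s length %d.",
                  which(bad)[1], system, expected))
  }
  invisible(as_tibble(pairs))
}
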