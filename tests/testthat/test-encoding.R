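test_that("canonicalization uppercases, maps U to T, and rejects ambiguity codes", {
  expect_identical(canonicalize_seq("augcu"), "ATGCT")
  expect_identical(canonicalize_seq("ATGCT"), "ATGCT")  # idempotent
  expect_identical(canonicalize_seq(canonicalize_seq("uuAAcc")), "TTAACC")
  expect_error(canonicalize_seq("ATGNN"), "outside")
  expect_error(canonicalize_seq("ACG-T"), "outside")
})

test_that("both vocabularies contain exactly 16 types and the token map is a bijection", {
  for (v in c("base_pair", "dimer")) {
    tab <- token_vocab(v)
    expect_equal(nrow(tab), 16L)
    expect_setequal(tab$token, 0:15)
    expect_equal(anyDuplicated(tab$label), 0L)
  }
  # exhaustive 4x4 enumeration as length-1 aligned pairs: all ids, no collision
  bases <- c("A", "C", "G", "T")
  combos <- expand.grid(sg = bases, dn = bases, stringsAsFactors = FALSE)
  toks <- encode_base_pairs(tibble::tibble(sgrna = combos$sg, dna = combos$dn))
  expect_setequal(toks$token, 0:15)
  expect_equal(anyDuplicated(toks$token), 0L)
})

test_that("token counts match the stated input lengths for both systems", {
  # base pairs: one per aligned position
  p20 <- tibble::tibble(sgrna = random_seqs(1, 20), dna = random_seqs(1, 20, seed = 2))
  p27 <- tibble::tibble(sgrna = random_seqs(1, 27), dna = random_seqs(1, 27, seed = 2))
  expect_equal(nrow(encode_base_pairs(p20)), 20L)
  expect_equal(nrow(encode_base_pairs(p27)), 27L)
  # dimers: length minus one
  expect_equal(nrow(encode_dimers(random_seqs(1, 20))), 19L)
  expect_equal(nrow(encode_dimers(random_seqs(1, 34))), 33L)
  expect_equal(nrow(encode_dimers("AA")), 1L)
})

test_that("the AUGCU example yields the documented sliding-window dimers", {
  toks <- encode_dimers("AUGCU")
  # AU, UG, GC, CU in RNA letters; T is the internal alphabet for U
  expect_identical(toks$dimer, c("AT", "TG", "GC", "CT"))
  expect_identical(toks$position, 0:3)
  vocab <- token_vocab("dimer")
  expect_identical(toks$token, vocab$token[match(toks$dimer, vocab$label)])
  expect_identical(decode_dimers(toks)$seq, "ATGCT")
})

test_that("a perfectly matched pair uses only the four match-type tokens", {
  s <- random_seqs(1, 20, seed = 3)
  toks <- encode_base_pairs(tibble::tibble(sgrna = s, dna = s))
  match_tokens <- c(0L, 5L, 10L, 15L)  # (A,A),(C,C),(G,G),(T,T)
  expect_true(all(toks$token %in% match_tokens))
})

test_that("encode/decode round-trips and length laws hold over random sequences", {
  for (L in c(2:8, 20, 27, 34, 50)) {
    sg <- random_seqs(3, L, seed = L)
    dn <- random_seqs(3, L, seed = L + 100)
    bp <- encode_base_pairs(tibble::tibble(sgrna = sg, dna = dn))
    expect_equal(nrow(bp), 3L * L)
    dec <- decode_base_pairs(bp)
    expect_identical(dec$sgrna, sg)
    expect_identical(dec$dna, dn)
    dm <- encode_dimers(sg)
    expect_equal(nrow(dm), 3L * (L - 1L))
    expect_identical(decode_dimers(dm)$seq, sg)
  }
})

test_that("reversing a sequence reverses and remaps its dimer tokens", {
  s <- random_seqs(5, 15, seed = 9)
  rev_s <- vapply(strsplit(s, ""), function(x) paste(rev(x), collapse = ""), "")
  fwd <- token_matrix(encode_dimers(s))
  bwd <- token_matrix(encode_dimers(rev_s))
  # oracle, recomputed from scratch: the k-th dimer of the reversed sequence is
  # the (L-1-k)-th dimer of the original with its two bases swapped
  swap <- function(tok) 4L * (tok %% 4L) + tok %/% 4L
  expect_identical(bwd, swap(fwd[, rev(seq_len(ncol(fwd))), drop = FALSE]))
})

test_that("encoders reject malformed input", {
  expect_error(encode_base_pairs(tibble::tibble(sgrna = "ACGT", dna = "ACG")),
               "Alignment error")
  expect_error(encode_dimers("A"), "shorter than 2")
  expect_error(encode_dimers(tibble::tibble(seq = character())), "empty")
  expect_error(token_matrix(encode_dimers(c("ACGT", "ACGTA"))), "same length")
  expect_error(validate_pairs(tibble::tibble(sgrna = "ACGT", dna = "ACGT"), "cas9"),
               "expected cas9 length 20")
})
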