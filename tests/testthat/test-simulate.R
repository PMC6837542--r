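test_that("generators are reproducible seed-for-seed", {
  a <- gen_offtarget(offtarget_sim_config(n_guides = 5, decoys_per_guide = 10, seed = 7))
  b <- gen_offtarget(offtarget_sim_config(n_guides = 5, decoys_per_guide = 10, seed = 7))
  c <- gen_offtarget(offtarget_sim_config(n_guides = 5, decoys_per_guide = 10, seed = 8))
  expect_identical(a, b)
  expect_false(identical(a, c))
  s1 <- gen_ontarget(ontarget_sim_config(n_guides = 20, n_genes = 20, seed = 7))
  s2 <- gen_ontarget(ontarget_sim_config(n_guides = 20, n_genes = 20, seed = 7))
  expect_identical(s1, s2)
})

test_that("off-target decoys carry 0-6 substitutions and penalties follow the weights", {
  w <- rep(0.1, 20)
  w[11] <- 3  # heavy penalty at 0-based position 10
  cfg <- offtarget_sim_config(n_guides = 30, decoys_per_guide = 40,
                              position_weights = w, noise_sd = 0, seed = 5)
  pairs <- gen_offtarget(cfg)
  expect_equal(nrow(pairs), 1200L)
  expect_true(all(nchar(pairs$sgrna) == 20 & nchar(pairs$dna) == 20))
  # reported mismatch counts equal the true Hamming distance, all <= 6
  hamming <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, pairs$sgrna, pairs$dna)
  expect_equal(unname(hamming), pairs$n_mismatch)
  expect_true(all(pairs$n_mismatch %in% 0:6))
  # no mismatch, no noise: maximal activity
  expect_true(all(pairs$score[pairs$n_mismatch == 0] == 100))
  # closed form: activity = 100 * exp(-sum of mismatched weights)
  mm_pos <- mapply(function(a, b) {
    list(which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]))
  }, pairs$sgrna, pairs$dna)
  expected <- 100 * exp(-vapply(mm_pos, function(p) sum(w[p]), numeric(1)))
  expect_equal(pairs$score, unname(expected))
  # a lone mismatch at position 10 is far more damaging than one at position 0
  one_at_10 <- pairs$score[vapply(mm_pos, function(p) identical(p, 11L), TRUE)]
  one_at_0 <- pairs$score[vapply(mm_pos, function(p) identical(p, 1L), TRUE)]
  if (length(one_at_10) > 0 && length(one_at_0) > 0) {
    expect_lt(max(one_at_10), min(one_at_0))
  }
  expect_equal(max(one_at_10, -Inf), 100 * exp(-3), tolerance = 1e-12)
})

test_that("labeling in the generator marks exactly the top fraction", {
  pairs <- gen_offtarget(offtarget_sim_config(n_guides = 50, decoys_per_guide = 80,
                                              seed = 3))
  expect_equal(nrow(pairs), 4000L)
  expect_equal(sum(pairs$label), round(0.2 * 4000))
  cutoff <- min(pairs$score[pairs$label == 1])
  expect_true(all(pairs$score[pairs$label == 0] <= cutoff))
})

test_that("on-target efficiencies follow the planted generative formula exactly", {
  L <- 20
  eff <- matrix(0, L - 1, 16)
  eff[19, ] <- seq(-1.5, 1.5, length.out = 16)  # signal only at dimer_18
  cfg <- ontarget_sim_config(n_guides = 60, seq_length = L, dimer_effects = eff,
                             gene_effect_via_network = 2, n_genes = 30,
                             noise_sd = 0, seed = 9)
  sim <- gen_ontarget(cfg)
  tok <- token_matrix(encode_dimers(sim$guides))
  reconstructed <- eff[cbind(19L, tok[, 19] + 1L)] + 2 * sim$guides$netexpress_z
  expect_equal(sim$guides$efficiency, reconstructed, tolerance = 1e-12)
  expect_identical(sim$dimer_effects, eff)
})

test_that("cell specificity enters only through the network-mediated gene effect", {
  base <- ontarget_sim_config(n_guides = 40, seq_length = 20, n_genes = 25,
                              gene_effect_via_network = 0, noise_sd = 0, seed = 4)
  sim <- gen_ontarget(base)
  by_cl <- split(sim$guides$efficiency, sim$guides$cell_line)
  expect_equal(by_cl[[1]], by_cl[[2]])  # no gene effect: identical across cell lines
  with_eff <- gen_ontarget(ontarget_sim_config(
    n_guides = 40, seq_length = 20, n_genes = 25,
    gene_effect_via_network = 2, noise_sd = 0, seed = 4))
  by_cl2 <- split(with_eff$guides$efficiency, with_eff$guides$cell_line)
  expect_false(isTRUE(all.equal(by_cl2[[1]], by_cl2[[2]])))
})

test_that("without a planted gene effect, NetExpress is uncorrelated with efficiency", {
  sim <- gen_ontarget(ontarget_sim_config(n_guides = 500, seq_length = 20,
                                          gene_effect_via_network = 0, seed = 6))
  g <- dplyr::filter(sim$guides, cell_line == "CL1")
  rho <- cor(g$netexpress, g$efficiency, method = "spearman")
  # permutation null: sd(rho) ~ 1/sqrt(n-1)
  expect_lt(abs(rho), 4 / sqrt(nrow(g) - 1))
})

test_that("toy fixtures match their hand-computed expectations", {
  fx <- gen_toy_fixtures()
  scores <- netexpress(fx$network, fx$expression)
  expect_equal(scores$score[match(fx$expected_netexpress$gene, scores$gene)],
               fx$expected_netexpress$score)
  toks <- encode_dimers(fx$guides[1, ])
  expect_identical(toks$dimer, c("AT", "TG", "GC", "CT"))
  bp <- encode_base_pairs(fx$pairs[1, ])
  expect_true(all(bp$token %in% c(0L, 5L, 10L, 15L)))
})

test_that("generator configs validate their arguments", {
  expect_error(offtarget_sim_config(position_weights = rep(-1, 20)), "nonnegative")
  expect_error(offtarget_sim_config(noise_sd = -1), "nonnegative")
  expect_error(offtarget_sim_config(label_fraction = 1.5), "0,1")
  expect_error(ontarget_sim_config(seq_length = 4), "at least 5")
  expect_error(ontarget_sim_config(dimer_effects = matrix(0, 2, 2)), "16 matrix")
  expect_error(ontarget_sim_config(network_density = 0), "density")
})
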