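test_that("top-fraction labeling picks round(fraction*n) positives with stable ties", {
  withr::with_seed(2, scores <- sample(seq(1, 100)))
  labs <- label_top_fraction(scores, 0.2)
  expect_equal(sum(labs), 20L)
  expect_true(all(scores[labs == 1] > max(scores[labs == 0])))
  # n = 5 -> a single positive, the maximum
  expect_equal(label_top_fraction(c(5, 1, 9, 3, 7), 0.2), c(0L, 0L, 1L, 0L, 0L))
  # all ties: the earliest inputs win the cutoff
  expect_equal(label_top_fraction(rep(1, 10), 0.2),
               c(1L, 1L, rep(0L, 8)))
  expect_error(label_top_fraction(numeric(0)), "empty")
  expect_error(label_top_fraction(1:10, 0), "fraction")
})

test_that("k-fold splits partition the samples with near-equal fold sizes", {
  fs <- kfold_split(10, k = 5, seed = 3)
  expect_setequal(fs$id, 1:10)
  expect_equal(as.integer(table(fs$fold)), rep(2L, 5))
  fs2 <- kfold_split(23, k = 5, seed = 3)
  sizes <- table(fs2$fold)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_equal(sort(fs2$id), 1:23)  # partition: every sample exactly once
  expect_error(kfold_split(3, k = 5), "exceeds")
})

test_that("leave-groups-out keeps held-out groups fully disjoint from training", {
  sgrna <- rep(paste0("sg", 1:10), each = 8)
  ids <- seq_along(sgrna)
  lg <- leave_groups_out(ids, sgrna, held_out = c("sg2", "sg5", "sg9"))
  expect_setequal(sgrna[lg$test], c("sg2", "sg5", "sg9"))
  expect_length(lg$test, 24)
  expect_length(intersect(lg$train, lg$test), 0)
  expect_length(intersect(sgrna[lg$train], sgrna[lg$test]), 0)
  # sampled holdouts: different seeds explore different triples
  triples <- vapply(1:10, function(s) {
    paste(sort(leave_groups_out(ids, sgrna, held_out = 3, seed = s)$held_out_groups),
          collapse = "+")
  }, character(1))
  expect_equal(length(unique(triples)), 10L)
  expect_error(leave_groups_out(ids, sgrna, held_out = "sgX"), "Unknown group")
  expect_error(leave_groups_out(ids, sgrna, held_out = unique(sgrna)), "empty train")
})

test_that("balanced batches oversample positives and visit each negative once", {
  labels <- c(rep(1L, 10), rep(0L, 1000))
  batches <- balanced_batches(labels, batch_size = 32, seed = 4)
  pos_counts <- vapply(batches, function(b) sum(labels[b] == 1L), integer(1))
  frac <- vapply(batches, function(b) mean(labels[b] == 1L), numeric(1))
  full <- lengths(batches) == 32
  expect_true(all(pos_counts[full] >= 12 & pos_counts[full] <= 20))
  expect_true(all(frac >= 0.4 & frac <= 0.6))
  negs <- unlist(lapply(batches, function(b) b[labels[b] == 0L]))
  expect_setequal(negs, which(labels == 0L))
  expect_equal(length(negs), 1000L)  # each negative exactly once per epoch
  # an already balanced set stays balanced
  bal <- balanced_batches(rep(c(0L, 1L), 50), batch_size = 20, seed = 4)
  expect_true(all(vapply(bal, function(b) mean(b %in% which(rep(c(0L, 1L), 50) == 1L)),
                         numeric(1)) %in% c(0.5)))
  expect_error(balanced_batches(rep(0L, 10), 4), "at least one positive")
})

test_that("training is reproducible and reduces the training loss", {
  tok <- random_tokens(60, 12, seed = 8)
  y <- withr::with_seed(8, rnorm(60))
  run <- function() {
    m <- attn_to_crispr(tiny_config(seed = 5))
    train_model(m, tok, y, epochs = 4, batch_size = 16, val_frac = 0.2, seed = 9)
    m$history
  }
  h1 <- run()
  h2 <- run()
  expect_identical(h1, h2)  # bitwise reproducible, single-threaded
  tr <- h1[h1$split == "train", ]
  expect_lt(tr$loss[nrow(tr)], tr$loss[1])
})

test_that("evaluation always uses unresampled held-out data", {
  # with heavy oversampling in training, the fit's prediction table must
  # contain each held-out sample exactly once
  withr::with_seed(10, {
    pairs <- gen_offtarget(offtarget_sim_config(
      n_guides = 6, decoys_per_guide = 20, pair_length = 12, seed = 10))
  })
  fit <- fit_offtarget_model(pairs,
                             config = tiny_config("classify", max_len = 12, seed = 2),
                             epochs = 2, holdout_frac = 0.25, seed = 2)
  expect_equal(anyDuplicated(fit$predictions$row), 0L)
  expect_equal(nrow(fit$predictions), round(0.25 * nrow(pairs)))
  expect_setequal(fit$predictions$truth, c(0L, 1L))
})

test_that("cross-validated fits aggregate per-fold metrics with mean and spread", {
  withr::with_seed(11, {
    pairs <- gen_offtarget(offtarget_sim_config(
      n_guides = 6, decoys_per_guide = 25, pair_length = 12, seed = 11))
  })
  fit <- fit_offtarget_model(pairs, split = "cv", k = 3,
                             config = tiny_config("classify", max_len = 12, seed = 3),
                             epochs = 2, seed = 3)
  td <- tidy(fit)
  expect_equal(sort(unique(td$fold)), 0:2)
  expect_setequal(unique(td$metric), c("auc_roc", "pr_auc"))
  # folds partition the data: every sample predicted exactly once
  expect_setequal(fit$predictions$row, seq_len(nrow(pairs)))
  g <- glance(fit)
  expect_true(all(c("auc_roc", "auc_roc_sd", "n_folds") %in% names(g)))
  expect_equal(g$n_folds, 3L)
})
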