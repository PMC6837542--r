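train_tiny_regressor <- function(n = 40, len = 12, n_extra = 0, seed = 30) {
  tok <- random_tokens(n, len, seed = seed)
  extra <- if (n_extra > 0) {
    withr::with_seed(seed + 1, matrix(rnorm(n * n_extra), n, n_extra))
  }
  y <- withr::with_seed(seed + 2, rnorm(n))
  m <- attn_to_crispr(tiny_config(max_len = len, n_extra = n_extra, seed = seed))
  train_model(m, tok, y, extra = extra, epochs = 2, batch_size = 20,
              val_frac = 0, seed = seed)
  list(model = m, tokens = tok, extra = extra, y = y)
}

test_that("normalized importances sum to one and keep feature order", {
  d <- train_tiny_regressor(n_extra = 2)
  d$model$extra_names <- c("netexpress", "copy_number")
  rep <- perturbation_importance(d$model, d$tokens, d$y, extra = d$extra,
                                 n_repeats = 4, seed = 1)
  expect_s3_class(rep, "importance_report")
  expect_equal(nrow(rep), 12 + 2)
  expect_equal(sum(rep$normalized), 1, tolerance = 1e-9)
  expect_true(all(rep$raw >= 0))
  expect_identical(as.character(rep$feature),
                   c(paste0("dimer_", 0:11), "netexpress", "copy_number"))
  expect_equal(attr(rep, "n_repeats"), 4)
  # same seed, same report
  rep2 <- perturbation_importance(d$model, d$tokens, d$y, extra = d$extra,
                                  n_repeats = 4, seed = 1)
  expect_identical(rep$raw, rep2$raw)
})

test_that("a single-sample dataset gives uniform importances at the baseline loss", {
  d <- train_tiny_regressor()
  rep <- perturbation_importance(d$model, d$tokens[1, , drop = FALSE], d$y[1],
                                 n_repeats = 3, seed = 2)
  expect_true(all(rep$raw == attr(rep, "baseline_loss")))
  expect_equal(rep$normalized, rep(1 / 12, 12))
})

test_that("a feature the model provably ignores scores exactly the baseline loss", {
  d <- train_tiny_regressor(n_extra = 2, seed = 44)
  # cut every first-layer weight from the second extra feature: the model
  # output can no longer depend on it
  n_feat_in <- nrow(d$model$layers$fc1$params$W)
  d$model$layers$fc1$params$W[n_feat_in, ] <- 0
  rep <- perturbation_importance(d$model, d$tokens, d$y, extra = d$extra,
                                 n_repeats = 6, seed = 3)
  base <- attr(rep, "baseline_loss")
  expect_equal(rep$raw[nrow(rep)], base, tolerance = 1e-12)
  expect_gt(max(rep$raw), base)  # other features do perturb the loss
})

test_that("shuffling is column-wise across samples, preserving each column's multiset", {
  # a model whose loss is the mean prediction is unaffected by permutations
  # only if columns are permuted as wholes; verify the permutation mechanics
  # through the exported API: with 2 identical rows, any permutation is a
  # no-op, so every raw score equals the baseline
  d <- train_tiny_regressor(seed = 50)
  tok2 <- d$tokens[c(1, 1), ]
  rep <- perturbation_importance(d$model, tok2, d$y[c(1, 1)], n_repeats = 5, seed = 4)
  expect_true(all(abs(rep$raw - attr(rep, "baseline_loss")) < 1e-12))
})

test_that("exchangeable uninformative features converge to a common importance", {
  d <- train_tiny_regressor(n = 36, len = 8, seed = 55)
  rep <- perturbation_importance(d$model, d$tokens, d$y, n_repeats = 80, seed = 5)
  # all token positions are random noise: importances should be within a few
  # standard errors of their common mean
  spread <- (max(rep$raw) - min(rep$raw)) / mean(rep$raw)
  expect_lt(spread, 0.5)
})

test_that("importance requires a trained, compatible model", {
  m <- attn_to_crispr(tiny_config(seed = 1))
  tok <- random_tokens(5, 12)
  expect_error(perturbation_importance(m, tok, rnorm(5)), "trained")
})

test_that("the importance bar chart renders one bar per feature", {
  d <- train_tiny_regressor(n_extra = 1, seed = 60)
  d$model$extra_names <- "netexpress"
  rep <- perturbation_importance(d$model, d$tokens, d$y, extra = d$extra,
                                 n_repeats = 2, seed = 6)
  p <- autoplot(rep)
  expect_s3_class(p, "ggplot")
  built <- ggplot2::ggplot_build(p)
  expect_equal(nrow(built$data[[1]]), 13)
  expect_identical(levels(rep$feature)[13], "netexpress")
  tmp <- withr::local_tempfile(fileext = ".png")
  expect_identical(plot_importance(rep, tmp), tmp)
  expect_true(file.exists(tmp))
})
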