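num_grad_check <- function(model, tokens, y, extra = NULL, n_checks = 40,
                           eps = 1e-5, tol = 1e-4) {
  model_loss_and_grads(model, tokens, y, extra)
  leaves <- crisprattn:::nn_leaves(model$layers)
  withr::with_seed(99, {
    for (chk in seq_len(n_checks)) {
      l <- leaves[[sample(length(leaves), 1)]]
      if (length(l$params) == 0) next
      pn <- sample(names(l$params), 1)
      k <- sample(length(l$params[[pn]]), 1)
      orig <- l$params[[pn]][k]
      l$params[[pn]][k] <- orig + eps
      lp <- model_loss(model, tokens, y, extra)
      l$params[[pn]][k] <- orig - eps
      lm <- model_loss(model, tokens, y, extra)
      l$params[[pn]][k] <- orig
      num <- (lp - lm) / (2 * eps)
      ana <- l$grads[[pn]][k]
      rel <- abs(num - ana) / max(1e-8, abs(num) + abs(ana))
      expect_true(rel < tol || abs(num - ana) < 1e-7,
                  label = sprintf("gradient of %s$%s[%d] (num %.3g vs ana %.3g)",
                                  class(l)[1], pn, k, num, ana))
    }
  })
  invisible(TRUE)
}

test_that("analytic gradients match central finite differences in every architecture", {
  tok <- random_tokens(8, 12, seed = 3)
  yreg <- withr::with_seed(3, rnorm(8))
  ycls <- withr::with_seed(4, sample(0:1, 8, replace = TRUE))
  ex <- withr::with_seed(5, matrix(rnorm(16), 8, 2))
  num_grad_check(attn_to_mismatch(tiny_config("classify", seed = 5)), tok, ycls)
  num_grad_check(attn_to_crispr(tiny_config(n_extra = 2, seed = 6)), tok, yreg, extra = ex)
  num_grad_check(attn_to_crispr(tiny_config(use_decoder = TRUE, seed = 8)), tok, yreg)
  num_grad_check(seq_crispr(tiny_config(n_extra = 2, seed = 7)), tok, yreg, extra = ex)
})

test_that("the positional table has one vector per position; sinusoidal matches the closed form", {
  tab <- sinusoidal_table(27, 32)
  expect_equal(dim(tab), c(27L, 32L))
  # position 0: all sine components 0, all cosine components 1
  expect_equal(unname(tab[1, seq(1, 32, by = 2)]), rep(0, 16))
  expect_equal(unname(tab[1, seq(2, 32, by = 2)]), rep(1, 16))
  # distinct positions map to distinct vectors
  expect_equal(anyDuplicated(round(tab, 12)), 0L)
  # learned table is trainable: training moves it away from initialization
  m <- attn_to_crispr(tiny_config(seed = 11))
  before <- m$layers$pos$params$P
  tok <- random_tokens(40, 12, seed = 12)
  y <- withr::with_seed(12, rnorm(40))
  train_model(m, tok, y, epochs = 3, batch_size = 20, val_frac = 0, seed = 12)
  expect_gt(max(abs(m$layers$pos$params$P - before)), 0)
  d <- as.matrix(dist(m$layers$pos$params$P))
  expect_gt(min(d[upper.tri(d)]), 0)  # positions stay distinguishable
})

test_that("the attention stack preserves sequence shape and classifier outputs are log-probabilities", {
  cfg <- model_config(task = "classify", max_len = 27, seed = 2)
  m <- attn_to_mismatch(cfg)
  tok <- random_tokens(8, 27, seed = 2)
  lp <- predict(m, tok)  # untrained forward
  expect_equal(dim(lp), c(8L, 2L))
  expect_equal(rowSums(exp(lp)), rep(1, 8), tolerance = 1e-12)
  # shape preservation through the transformer is asserted at runtime inside
  # the attention layer; verify directly too
  emb <- crisprattn:::nn_forward(m$layers$emb, tok)
  emb <- crisprattn:::nn_forward(m$layers$pos, emb)
  out <- crisprattn:::nn_forward(m$layers$block1, emb)
  expect_identical(dim(out), dim(emb))
})

test_that("forward passes are deterministic in eval mode under a fixed seed", {
  m <- attn_to_crispr(tiny_config(seed = 4, dropout = 0.3))
  tok <- random_tokens(10, 12, seed = 6)
  expect_identical(predict(m, tok), predict(m, tok))
  m2 <- attn_to_crispr(tiny_config(seed = 4, dropout = 0.3))
  expect_identical(predict(m, tok), predict(m2, tok))  # same init seed, same weights
})

test_that("each architecture can memorize 64 random samples", {
  tok <- random_tokens(64, 10, seed = 20)
  y_reg <- withr::with_seed(20, rnorm(64))
  y_cls <- withr::with_seed(21, rep(0:1, each = 32))
  mem_cfg <- function(task, seed) model_config(
    task = task, max_len = 10, embed_dim = 16, n_heads = 2,
    n_attention_layers = 1, conv_channels = c(4, 8), ffn_hidden = 16,
    fc_sizes = c(32), dropout = 0, seed = seed)

  m1 <- attn_to_mismatch(mem_cfg("classify", 1))
  train_model(m1, tok, y_cls, epochs = 60, batch_size = 64, lr = 3e-3,
              val_frac = 0, balanced = FALSE, seed = 1)
  acc <- mean(predict(m1, tok, type = "class") == y_cls)
  expect_gt(acc, 0.95)

  m2 <- attn_to_crispr(mem_cfg("regress", 2))
  train_model(m2, tok, y_reg, epochs = 80, batch_size = 64, lr = 3e-3,
              val_frac = 0, seed = 2)
  expect_lt(mean((predict(m2, tok) - y_reg)^2), 0.1 * var(y_reg))

  m3 <- seq_crispr(mem_cfg("regress", 3))
  train_model(m3, tok, y_reg, epochs = 80, batch_size = 64, lr = 3e-3,
              val_frac = 0, seed = 3)
  expect_lt(mean((predict(m3, tok) - y_reg)^2), 0.1 * var(y_reg))
})

test_that("extra biological features are wired into the prediction", {
  m <- attn_to_crispr(tiny_config(n_extra = 2, seed = 9))
  m$extra_center <- c(0, 0)
  m$extra_scale <- c(1, 1)
  tok <- random_tokens(4, 12, seed = 9)
  ex <- matrix(0, 4, 2)
  base <- predict(m, tok, ex)
  ex2 <- ex; ex2[, 1] <- 1
  expect_false(isTRUE(all.equal(predict(m, tok, ex2), base)))
  # feature-length mismatch is a shape error
  expect_error(predict(m, tok, ex[, 1, drop = FALSE]), "extra feature")
})

test_that("degenerate width-1 branches still train (smoke test)", {
  cfg <- model_config(task = "regress", max_len = 8, embed_dim = 8, n_heads = 2,
                      n_attention_layers = 1, conv_channels = c(1, 1),
                      ffn_hidden = 4, recurrent_hidden = 1, fc_sizes = c(4),
                      dropout = 0, seed = 13)
  m <- seq_crispr(cfg)
  tok <- random_tokens(30, 8, seed = 13)
  y <- withr::with_seed(13, rnorm(30))
  expect_no_error(train_model(m, tok, y, epochs = 2, batch_size = 10,
                              val_frac = 0, seed = 13))
  expect_length(predict(m, tok), 30)
})

test_that("invalid configurations are rejected", {
  expect_error(model_config(task = "regress", max_len = 12, embed_dim = 10, n_heads = 4),
               "divisible")
  expect_error(model_config(task = "regress", max_len = 12, dropout = 1), "dropout")
  expect_error(model_config(task = "regress", max_len = 3), "at least 4")
  expect_error(attn_to_mismatch(tiny_config("regress")), "classify")
  expect_error(attn_to_crispr(tiny_config("classify", max_len = 12)), "regress")
  expect_error(seq_crispr(tiny_config("classify", max_len = 12)), "regress")
})
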