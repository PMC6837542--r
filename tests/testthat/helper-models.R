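# Shared tiny configurations and data for fast model tests.

tiny_config <- function(task = "regress", max_len = 12, n_extra = 0,
                        use_decoder = FALSE, seed = 5, dropout = 0) {
  model_config(
    task = task, max_len = max_len, embed_dim = 8, n_heads = 2,
    n_attention_layers = 1, use_decoder = use_decoder,
    conv_channels = c(2, 3), ffn_hidden = 10, recurrent_hidden = 5,
    fc_sizes = c(7), dropout = dropout, n_extra_features = n_extra, seed = seed
  )
}

light_config <- function(task = "regress", max_len = 19, n_extra = 0, seed = 1) {
  model_config(
    task = task, max_len = max_len, embed_dim = 16, n_heads = 4,
    n_attention_layers = 1, conv_channels = c(8, 16), ffn_hidden = 32,
    fc_sizes = c(64, 16), dropout = 0.1, n_extra_features = n_extra, seed = seed
  )
}

random_tokens <- function(n, len, seed = 1) {
  withr::with_seed(seed, matrix(sample(0:15, n * len, replace = TRUE), n, len))
}

random_seqs <- function(n, len, seed = 1) {
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    }, character(1))
  })
}

# full forward/backward pass and analytic gradients for gradient checking
model_loss_and_grads <- function(model, tokens, y, extra = NULL) {
  classify <- model$config$task == "classify"
  crisprattn:::nn_zero_grads(model$layers)
  out <- crisprattn:::model_forward(model, tokens, extra, training = TRUE)
  ls <- if (classify) {
    crisprattn:::nll_from_logits(out, y)
  } else {
    crisprattn:::mse_loss(as.numeric(out), y)
  }
  grad <- if (classify) ls$grad else matrix(ls$grad, ncol = 1)
  crisprattn:::model_backward(model, grad)
  ls$loss
}

model_loss <- function(model, tokens, y, extra = NULL) {
  classify <- model$config$task == "classify"
  out <- crisprattn:::model_forward(model, tokens, extra, training = TRUE)
  if (classify) crisprattn:::nll_from_logits(out, y)$loss
  else crisprattn:::mse_loss(as.numeric(out), y)$loss
}
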