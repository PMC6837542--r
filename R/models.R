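#' Model configuration
#'
#' Collects the hyperparameters shared by the three architectures. Defaults
#' are sized for CPU training on desk-scale data while retaining enough
#' capacity to recover the planted signal in the synthetic benchmarks.
#'
#' @param task `"classify"` (off-target specificity, two log-probabilities)
#'   or `"regress"` (on-target efficiency, one real output).
#' @param max_len Token-sequence length the model consumes: the alignment
#'   length for base-pair models (20 Cas9 / 27 Cas12a), sequence length minus
#'   one for dimer models (19 / 33).
#' @param vocab_size Token vocabulary size; 16 for both encoders.
#' @param embed_dim Embedding width; must be divisible by `n_heads`.
#' @param n_heads Attention heads per block.
#' @param n_attention_layers Encoder blocks stacked after the embedding.
#' @param use_decoder Also stack decoder-style blocks that self-attend the
#'   sequence and cross-attend the encoder output. Off by default: with a
#'   single input stream an encoder-only transformer is the natural reading,
#'   and the flag preserves the two-part alternative.
#' @param conv_channels Two channel counts for the Conv2d-Maxpool pairs.
#' @param conv_kernels,pool_kernels Kernel / pool shapes (lists of length-2
#'   integer vectors). The embedded sequence is treated as a 1-channel
#'   `max_len` x `embed_dim` image.
#' @param ffn_hidden Width of the position-wise feed-forward inside each
#'   attention block.
#' @param recurrent_hidden LSTM hidden size (seqCrispr only).
#' @param fc_sizes Fully connected widths before the output head.
#' @param dropout Dropout probability used in attention blocks and between
#'   fully connected layers.
#' @param n_extra_features Number of per-sample biological covariates
#'   (e.g. NetExpress score, copy number) concatenated after flattening.
#' @param positional `"learned"` (default) or `"sinusoidal"`.
#' @param seed Integer seed for weight initialization.
#' @return A `model_config` list.
#' @export
model_config <- function(task = c("regress", "classify"),
                         max_len,
                         vocab_size = 16L,
                         embed_dim = 32L,
                         n_heads = 4L,
                         n_attention_layers = 2L,
                         use_decoder = FALSE,
                         conv_channels = c(16L, 32L),
                         conv_kernels = list(c(3L, 3L), c(3L, 3L)),
                         pool_kernels = list(c(2L, 2L), c(2L, 2L)),
                         ffn_hidden = 64L,
                         recurrent_hidden = 32L,
                         fc_sizes = c(128L, 32L),
                         dropout = 0.2,
                         n_extra_features = 0L,
                         positional = c("learned", "sinusoidal"),
                         seed = 1L) {
  task <- match.arg(task)
  positional <- match.arg(positional)
  if (embed_dim %% n_heads != 0) {
    abort("`embed_dim` must be divisible by `n_heads`.")
  }
  if (length(conv_channels) != 2 || any(conv_channels < 1)) {
    abort("`conv_channels` must be two positive integers.")
  }
  if (dropout < 0 || dropout >= 1) abort("`dropout` must be in [0, 1).")
  if (max_len < 4) abort("`max_len` must be at least 4 for two 2x2 pooling stages.")
  structure(list(
    task = task, max_len = as.integer(max_len), vocab_size = as.integer(vocab_size),
    embed_dim = as.integer(embed_dim), n_heads = as.integer(n_heads),
    n_attention_layers = as.integer(n_attention_layers), use_decoder = use_decoder,
    conv_channels = as.integer(conv_channels), conv_kernels = conv_kernels,
    pool_kernels = pool_kernels, ffn_hidden = as.integer(ffn_hidden),
    recurrent_hidden = as.integer(recurrent_hidden), fc_sizes = as.integer(fc_sizes),
    dropout = dropout, n_extra_features = as.integer(n_extra_features),
    positional = positional, seed = as.integer(seed)
  ), class = "model_config")
}

.new_model <- function(arch, cfg) {
  m <- new.env(parent = emptyenv())
  m$arch <- arch
  m$config <- cfg
  m$trained <- FALSE
  m$extra_names <- character(cfg$n_extra_features)
  m$extra_center <- NULL
  m$extra_scale <- NULL
  m$history <- NULL
  class(m) <- "crispr_model"
  m
}

.build_fc <- function(n_in, fc_sizes, n_out, dropout) {
  layers <- list()
  cur <- n_in
  for (i in seq_along(fc_sizes)) {
    layers[[paste0("fc", i)]] <- nn_linear(cur, fc_sizes[i])
    layers[[paste0("fc_relu", i)]] <- nn_relu()
    layers[[paste0("fc_drop", i)]] <- nn_dropout(dropout)
    cur <- fc_sizes[i]
  }
  layers$head <- nn_linear(cur, n_out)
  layers
}

.build_attention_model <- function(cfg, arch) {
  m <- .new_model(arch, cfg)
  withr::with_seed(cfg$seed, {
    L <- cfg$max_len
    D <- cfg$embed_dim
    blocks <- lapply(seq_len(cfg$n_attention_layers), function(i) {
      nn_encoder_block(D, cfg$n_heads, L, cfg$ffn_hidden, cfg$dropout)
    })
    dec_blocks <- if (isTRUE(cfg$use_decoder)) {
      lapply(seq_len(cfg$n_attention_layers), function(i) {
        nn_decoder_block(D, cfg$n_heads, L, cfg$ffn_hidden, cfg$dropout)
      })
    } else list()
    n_out <- if (cfg$task == "classify") 2L else 1L
    flat <- conv_stack_out_dim(cfg$conv_channels, L, D)
    m$layers <- c(
      list(
        emb = nn_embedding(cfg$vocab_size, D),
        pos = nn_positional(L, D, cfg$positional)
      ),
      setNames(blocks, paste0("block", seq_along(blocks))),
      setNames(dec_blocks, if (length(dec_blocks)) paste0("dec", seq_along(dec_blocks)) else character()),
      list(conv = nn_conv_stack(cfg$conv_channels, cfg$conv_kernels, cfg$pool_kernels)),
      .build_fc(flat + cfg$n_extra_features, cfg$fc_sizes, n_out, cfg$dropout)
    )
  })
  m
}

#' Build the off-target specificity classifier (attention + CNN)
#'
#' Architecture: base-pair token embedding elementwise-summed with a positional
#' embedding, a stack of multi-head self-attention encoder blocks (shape
#' preserving), two Conv2d + Maxpool stages over the resulting
#' length-by-width matrix, and fully connected layers ending in a log-softmax
#' over two classes (active / inactive off-target pair).
#'
#' @param config A [model_config()] with `task = "classify"` and `max_len`
#'   equal to the alignment length.
#' @return A `crispr_model` (mutable; training updates it in place).
#' @export
attn_to_mismatch <- function(config) {
  if (config$task != "classify") abort("attn_to_mismatch requires task = 'classify'.")
  .build_attention_model(config, "attn_mismatch")
}

#' Build the on-target efficiency regressor (attention + CNN)
#'
#' Same trunk as [attn_to_mismatch()] but consuming dimer tokens (sequence
#' length minus one) and ending in a single linear regression output. Optional
#' per-sample covariates (NetExpress, copy number) are concatenated to the
#' flattened convolutional features before the fully connected layers.
#'
#' @param config A [model_config()] with `task = "regress"`.
#' @return A `crispr_model`.
#' @export
attn_to_crispr <- function(config) {
  if (config$task != "regress") abort("attn_to_crispr requires task = 'regress'.")
  .build_attention_model(config, "attn_crispr")
}

#' Build the CNN/LSTM hybrid regressor (seqCrispr)
#'
#' Dimer embedding feeding a convolutional branch and an LSTM branch in
#' parallel; branch outputs are flattened, concatenated (together with any
#' extra biological features) and passed through fully connected layers to a
#' single linear output.
#'
#' @param config A [model_config()] with `task = "regress"`.
#' @return A `crispr_model`.
#' @export
seq_crispr <- function(config) {
  if (config$task != "regress") abort("seq_crispr requires task = 'regress'.")
  m <- .new_model("seq_crispr", config)
  withr::with_seed(config$seed, {
    L <- config$max_len
    D <- config$embed_dim
    flat <- conv_stack_out_dim(config$conv_channels, L, D) + config$recurrent_hidden
    m$layers <- c(
      list(
        emb = nn_embedding(config$vocab_size, D),
        conv = nn_conv_stack(config$conv_channels, config$conv_kernels,
                             config$pool_kernels),
        lstm = nn_lstm(D, config$recurrent_hidden, L)
      ),
      .build_fc(flat + config$n_extra_features, config$fc_sizes, 1L, config$dropout)
    )
  })
  m
}

## ---- forward / backward ------------------------------------------------------

model_forward <- function(model, tokens, extra = NULL, training = FALSE) {
  cfg <- model$config
  ly <- model$layers
  B <- nrow(tokens)
  if (ncol(tokens) != cfg$max_len) {
    abort(sprintf("Model expects %d tokens per sample, got %d.",
                  cfg$max_len, ncol(tokens)))
  }
  if (cfg$n_extra_features > 0) {
    if (is.null(extra) || ncol(extra) != cfg$n_extra_features) {
      abort(sprintf("Model expects %d extra feature(s) per sample.",
                    cfg$n_extra_features))
    }
  } else {
    extra <- NULL
  }
  x <- nn_forward(ly$emb, tokens, training)
  if (model$arch == "seq_crispr") {
    conv_out <- nn_forward(ly$conv, x, training, geom = c(B, cfg$max_len, cfg$embed_dim))
    lstm_out <- nn_forward(ly$lstm, x, training)
    feat <- cbind(conv_out, lstm_out)
    model$split_at <- ncol(conv_out)
  } else {
    x <- nn_forward(ly$pos, x, training)
    for (nm in grep("^block", names(ly), value = TRUE)) {
      x <- nn_forward(ly[[nm]], x, training)
    }
    for (nm in grep("^dec", names(ly), value = TRUE)) {
      x <- nn_forward(ly[[nm]], x, training)
    }
    feat <- nn_forward(ly$conv, x, training, geom = c(B, cfg$max_len, cfg$embed_dim))
  }
  if (!is.null(extra)) feat <- cbind(feat, extra)
  model$n_feat <- ncol(feat) - cfg$n_extra_features
  h <- feat
  for (i in seq_along(cfg$fc_sizes)) {
    h <- nn_forward(ly[[paste0("fc", i)]], h, training)
    h <- nn_forward(ly[[paste0("fc_relu", i)]], h, training)
    h <- nn_forward(ly[[paste0("fc_drop", i)]], h, training)
  }
  nn_forward(ly$head, h, training)
}

model_backward <- function(model, dout) {
  cfg <- model$config
  ly <- model$layers
  d <- nn_backward(ly$head, dout)
  for (i in rev(seq_along(cfg$fc_sizes))) {
    d <- nn_backward(ly[[paste0("fc_drop", i)]], d)
    d <- nn_backward(ly[[paste0("fc_relu", i)]], d)
    d <- nn_backward(ly[[paste0("fc", i)]], d)
  }
  if (cfg$n_extra_features > 0) {
    d <- d[, seq_len(model$n_feat), drop = FALSE]
  }
  if (model$arch == "seq_crispr") {
    dconv <- d[, seq_len(model$split_at), drop = FALSE]
    dlstm <- d[, (model$split_at + 1):ncol(d), drop = FALSE]
    dx <- nn_backward(ly$conv, dconv) + nn_backward(ly$lstm, dlstm)
  } else {
    dx <- nn_backward(ly$conv, d)
    for (nm in rev(grep("^dec", names(ly), value = TRUE))) {
      dx <- nn_backward(ly[[nm]], dx)
    }
    for (nm in rev(grep("^block", names(ly), value = TRUE))) {
      dx <- nn_backward(ly[[nm]], dx)
    }
    dx <- nn_backward(ly$pos, dx)
  }
  nn_backward(ly$emb, dx)
  invisible(NULL)
}

#' Predict from a crispr_model
#'
#' @param object A `crispr_model`.
#' @param tokens Integer token matrix (rows = samples), e.g. from
#'   [token_matrix()].
#' @param extra Optional numeric matrix of extra features, raw scale; the
#'   standardization learned at fit time is applied automatically when present.
#' @param type For classifiers, `"logprob"` (default, B x 2 matrix),
#'   `"prob"` (positive-class probability) or `"class"`; ignored for
#'   regressors, which return the numeric prediction.
#' @param batch_size Internal forward batch size.
#' @param ... Unused.
#' @return Numeric vector or matrix of predictions.
#' @export
predict.crispr_model <- function(object, tokens, extra = NULL,
                                 type = c("logprob", "prob", "class"),
                                 batch_size = 512L, ...) {
  type <- match.arg(type)
  if (!is.matrix(tokens)) tokens <- token_matrix(tokens)
  if (!is.null(extra)) {
    extra <- as.matrix(extra)
    if (ncol(extra) != object$config$n_extra_features) {
      abort(sprintf("Model expects %d extra feature(s) per sample, got %d.",
                    object$config$n_extra_features, ncol(extra)))
    }
    if (!is.null(object$extra_center)) {
      extra <- scale(extra, center = object$extra_center,
                     scale = object$extra_scale)
    }
  }
  n <- nrow(tokens)
  starts <- seq(1L, n, by = batch_size)
  out <- do.call(rbind, lapply(starts, function(s) {
    idx <- s:min(s + batch_size - 1L, n)
    model_forward(object, tokens[idx, , drop = FALSE],
                  if (is.null(extra)) NULL else extra[idx, , drop = FALSE],
                  training = FALSE)
  }))
  if (object$config$task == "classify") {
    lp <- log_softmax(out)
    switch(type,
           logprob = lp,
           prob = exp(lp[, 2]),
           class = as.integer(lp[, 2] > lp[, 1]))
  } else {
    as.numeric(out)
  }
}

#' @export
print.crispr_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<crispr_model: %s>\n", x$arch))
  cat(sprintf("  task: %s | max_len: %d | embed: %d | heads: %d | blocks: %d\n",
              cfg$task, cfg$max_len, cfg$embed_dim, cfg$n_heads,
              cfg$n_attention_layers))
  cat(sprintf("  conv channels: %s | fc: %s | extra features: %d\n",
              paste(cfg$conv_channels, collapse = ","),
              paste(cfg$fc_sizes, collapse = ","), cfg$n_extra_features))
  cat(sprintf("  parameters: %d | trained: %s\n",
              nn_n_params(x$layers), x$trained))
  invisible(x)
}
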