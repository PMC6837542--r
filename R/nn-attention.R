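# Multi-head scaled-dot-product self-attention and the transformer encoder
# block (post-norm: x -> LN(x + MHA(x)) -> LN(. + FFN(.))). Attention scores
# are computed per sample; sequences here are short (<= ~35 positions), so the
# per-sample loop is cheap while projections stay batched.

nn_mha <- function(dim, n_heads, max_len) {
  stopifnot(dim %% n_heads == 0)
  new_layer("mha",
            params = list(Wq = .glorot(dim, dim), Wk = .glorot(dim, dim),
                          Wv = .glorot(dim, dim), Wo = .glorot(dim, dim)),
            fields = list(dim = dim, n_heads = n_heads, max_len = max_len,
                          dh = dim %/% n_heads))
}

#' @export
nn_forward.nn_mha <- function(layer, x, training = FALSE, ...) {
  L <- layer$max_len
  B <- nrow(x) / L
  D <- layer$dim
  H <- layer$n_heads
  dh <- layer$dh
  Q <- x %*% layer$params$Wq
  K <- x %*% layer$params$Wk
  V <- x %*% layer$params$Wv
  concat <- matrix(0, B * L, D)
  attn <- vector("list", B)
  scale <- 1 / sqrt(dh)
  for (b in seq_len(B)) {
    rows <- ((b - 1) * L + 1):(b * L)
    Ab <- vector("list", H)
    for (h in seq_len(H)) {
      cols <- ((h - 1) * dh + 1):(h * dh)
      Qh <- Q[rows, cols, drop = FALSE]
      Kh <- K[rows, cols, drop = FALSE]
      S <- tcrossprod(Qh, Kh) * scale
      S <- S - S[cbind(seq_len(L), max.col(S, "first"))]
      A <- exp(S)
      A <- A / rowSums(A)
      concat[rows, cols] <- A %*% V[rows, cols, drop = FALSE]
      Ab[[h]] <- A
    }
    attn[[b]] <- Ab
  }
  layer$x <- x
  layer$Q <- Q; layer$K <- K; layer$V <- V
  layer$attn <- attn
  layer$concat <- concat
  out <- concat %*% layer$params$Wo
  stopifnot(identical(dim(out), dim(x)))  # shape-preservation contract
  out
}

#' @export
nn_backward.nn_mha <- function(layer, dout, ...) {
  L <- layer$max_len
  B <- nrow(dout) / L
  D <- layer$dim
  H <- layer$n_heads
  dh <- layer$dh
  scale <- 1 / sqrt(dh)
  layer$grads$Wo <- layer$grads$Wo + crossprod(layer$concat, dout)
  dconcat <- dout %*% t(layer$params$Wo)
  dQ <- matrix(0, B * L, D)
  dK <- matrix(0, B * L, D)
  dV <- matrix(0, B * L, D)
  for (b in seq_len(B)) {
    rows <- ((b - 1) * L + 1):(b * L)
    for (h in seq_len(H)) {
      cols <- ((h - 1) * dh + 1):(h * dh)
      A <- layer$attn[[b]][[h]]
      dOh <- dconcat[rows, cols, drop = FALSE]
      Vh <- layer$V[rows, cols, drop = FALSE]
      dA <- tcrossprod(dOh, Vh)
      dV[rows, cols] <- crossprod(A, dOh)
      dS <- A * (dA - rowSums(dA * A))  # softmax rows
      dQ[rows, cols] <- dS %*% layer$K[rows, cols, drop = FALSE] * scale
      dK[rows, cols] <- crossprod(dS, layer$Q[rows, cols, drop = FALSE]) * scale
    }
  }
  layer$grads$Wq <- layer$grads$Wq + crossprod(layer$x, dQ)
  layer$grads$Wk <- layer$grads$Wk + crossprod(layer$x, dK)
  layer$grads$Wv <- layer$grads$Wv + crossprod(layer$x, dV)
  dQ %*% t(layer$params$Wq) + dK %*% t(layer$params$Wk) +
    dV %*% t(layer$params$Wv)
}

## ---- encoder block ----------------------------------------------------------

nn_encoder_block <- function(dim, n_heads, max_len, ffn_hidden = 2 * dim,
                             dropout = 0) {
  blk <- new_layer("encoder_block",
                   fields = list(dim = dim, max_len = max_len))
  blk$sub <- list(
    mha = nn_mha(dim, n_heads, max_len),
    drop1 = nn_dropout(dropout),
    ln1 = nn_layernorm(dim),
    fc1 = nn_linear(dim, ffn_hidden),
    relu = nn_relu(),
    fc2 = nn_linear(ffn_hidden, dim),
    drop2 = nn_dropout(dropout),
    ln2 = nn_layernorm(dim)
  )
  blk
}

#' @export
nn_forward.nn_encoder_block <- function(layer, x, training = FALSE, ...) {
  s <- layer$sub
  a <- nn_forward(s$drop1, nn_forward(s$mha, x, training), training)
  x1 <- nn_forward(s$ln1, x + a, training)
  f <- nn_forward(s$fc1, x1, training)
  f <- nn_forward(s$relu, f, training)
  f <- nn_forward(s$fc2, f, training)
  f <- nn_forward(s$drop2, f, training)
  nn_forward(s$ln2, x1 + f, training)
}

#' @export
nn_backward.nn_encoder_block <- function(layer, dout, ...) {
  s <- layer$sub
  d2 <- nn_backward(s$ln2, dout)
  df <- nn_backward(s$drop2, d2)
  df <- nn_backward(s$fc2, df)
  df <- nn_backward(s$relu, df)
  df <- nn_backward(s$fc1, df)
  dx1 <- d2 + df
  d1 <- nn_backward(s$ln1, dx1)
  da <- nn_backward(s$drop1, d1)
  da <- nn_backward(s$mha, da)
  d1 + da
}

## ---- decoder-flavoured block (optional fidelity mode) ------------------------
# Self-attends the embedded sequence, then cross-attends the encoder output.
# With no separate target sequence, both attentions consume the same length-L
# stream; this mirrors a decoder stack wired onto a single input.

nn_decoder_block <- function(dim, n_heads, max_len, ffn_hidden = 2 * dim,
                             dropout = 0) {
  blk <- new_layer("decoder_block",
                   fields = list(dim = dim, max_len = max_len))
  blk$sub <- list(
    self = nn_mha(dim, n_heads, max_len),
    ln0 = nn_layernorm(dim),
    cross = nn_cross_attention(dim, n_heads, max_len),
    drop1 = nn_dropout(dropout),
    ln1 = nn_layernorm(dim),
    fc1 = nn_linear(dim, ffn_hidden),
    relu = nn_relu(),
    fc2 = nn_linear(ffn_hidden, dim),
    drop2 = nn_dropout(dropout),
    ln2 = nn_layernorm(dim)
  )
  blk
}

#' @export
nn_forward.nn_decoder_block <- function(layer, x, training = FALSE,
                                        memory = NULL, ...) {
  s <- layer$sub
  a <- nn_forward(s$self, x, training)
  x0 <- nn_forward(s$ln0, x + a, training)
  c_ <- nn_forward(s$cross, x0, training, memory = memory %||% x0)
  c_ <- nn_forward(s$drop1, c_, training)
  x1 <- nn_forward(s$ln1, x0 + c_, training)
  f <- nn_forward(s$fc1, x1, training)
  f <- nn_forward(s$relu, f, training)
  f <- nn_forward(s$fc2, f, training)
  f <- nn_forward(s$drop2, f, training)
  nn_forward(s$ln2, x1 + f, training)
}

#' @export
nn_backward.nn_decoder_block <- function(layer, dout, ...) {
  s <- layer$sub
  d2 <- nn_backward(s$ln2, dout)
  df <- nn_backward(s$drop2, d2)
  df <- nn_backward(s$fc2, df)
  df <- nn_backward(s$relu, df)
  df <- nn_backward(s$fc1, df)
  dx1 <- d2 + df
  d1 <- nn_backward(s$ln1, dx1)
  dc <- nn_backward(s$drop1, d1)
  res <- nn_backward(s$cross, dc)
  # memory is the same stream (x0), so its gradient folds back in before ln0
  dx0 <- d1 + res$dx + res$dmem_same
  d0 <- nn_backward(s$ln0, dx0)
  da <- nn_backward(s$self, d0)
  d0 + da
}

# cross-attention: queries from x, keys/values from `memory`
nn_cross_attention <- function(dim, n_heads, max_len) {
  l <- nn_mha(dim, n_heads, max_len)
  class(l) <- c("nn_cross_attention", class(l))
  l
}

#' @export
nn_forward.nn_cross_attention <- function(layer, x, training = FALSE,
                                          memory = NULL, ...) {
  memory <- memory %||% x
  layer$same <- identical(memory, x)
  L <- layer$max_len
  B <- nrow(x) / L
  D <- layer$dim
  H <- layer$n_heads
  dh <- layer$dh
  Q <- x %*% layer$params$Wq
  K <- memory %*% layer$params$Wk
  V <- memory %*% layer$params$Wv
  concat <- matrix(0, B * L, D)
  attn <- vector("list", B)
  scale <- 1 / sqrt(dh)
  for (b in seq_len(B)) {
    rows <- ((b - 1) * L + 1):(b * L)
    Ab <- vector("list", H)
    for (h in seq_len(H)) {
      cols <- ((h - 1) * dh + 1):(h * dh)
      S <- tcrossprod(Q[rows, cols, drop = FALSE],
                      K[rows, cols, drop = FALSE]) * scale
      S <- S - S[cbind(seq_len(L), max.col(S, "first"))]
      A <- exp(S); A <- A / rowSums(A)
      concat[rows, cols] <- A %*% V[rows, cols, drop = FALSE]
      Ab[[h]] <- A
    }
    attn[[b]] <- Ab
  }
  layer$x <- x; layer$memory <- memory
  layer$Q <- Q; layer$K <- K; layer$V <- V
  layer$attn <- attn; layer$concat <- concat
  concat %*% layer$params$Wo
}

#' @export
nn_backward.nn_cross_attention <- function(layer, dout, ...) {
  L <- layer$max_len
  B <- nrow(dout) / L
  D <- layer$dim; H <- layer$n_heads; dh <- layer$dh
  scale <- 1 / sqrt(dh)
  layer$grads$Wo <- layer$grads$Wo + crossprod(layer$concat, dout)
  dconcat <- dout %*% t(layer$params$Wo)
  dQ <- matrix(0, B * L, D); dK <- dQ; dV <- dQ
  for (b in seq_len(B)) {
    rows <- ((b - 1) * L + 1):(b * L)
    for (h in seq_len(H)) {
      cols <- ((h - 1) * dh + 1):(h * dh)
      A <- layer$attn[[b]][[h]]
      dOh <- dconcat[rows, cols, drop = FALSE]
      dA <- tcrossprod(dOh, layer$V[rows, cols, drop = FALSE])
      dV[rows, cols] <- crossprod(A, dOh)
      dS <- A * (dA - rowSums(dA * A))
      dQ[rows, cols] <- dS %*% layer$K[rows, cols, drop = FALSE] * scale
      dK[rows, cols] <- crossprod(dS, layer$Q[rows, cols, drop = FALSE]) * scale
    }
  }
  layer$grads$Wq <- layer$grads$Wq + crossprod(layer$x, dQ)
  layer$grads$Wk <- layer$grads$Wk + crossprod(layer$memory, dK)
  layer$grads$Wv <- layer$grads$Wv + crossprod(layer$memory, dV)
  dx <- dQ %*% t(layer$params$Wq)
  dmem <- dK %*% t(layer$params$Wk) + dV %*% t(layer$params$Wv)
  list(dx = dx,
       dmem = if (layer$same) NULL else dmem,
       dmem_same = if (layer$same) dmem else 0)
}
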