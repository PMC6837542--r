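# Minimal reverse-mode neural-network engine.
#
# Layers are mutable environments holding `params` (named list of numeric
# matrices/vectors), matching `grads`, and any forward caches needed by the
# backward pass. Sequence activations are stored sample-major: a batch of B
# sequences of length L with embedding width D is a (B*L) x D matrix whose
# rows (b-1)*L + 1 .. b*L belong to sample b. Convolutional activations over
# an H x W grid with C channels are (B*H*W) x C matrices with row index
# ((b-1)*H + h - 1)*W + w. Both layouts keep every heavy operation a single
# BLAS matrix product.

new_layer <- function(type, params = list(), fields = list()) {
  e <- new.env(parent = emptyenv())
  e$params <- params
  e$grads <- lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
  e$sub <- list()
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  class(e) <- c(paste0("nn_", type), "nn_layer")
  e
}

nn_forward <- function(layer, x, training = FALSE, ...) {
  UseMethod("nn_forward")
}
nn_backward <- function(layer, dout, ...) {
  UseMethod("nn_backward")
}

# all leaf layers (those owning parameters) under a layer / list of layers
nn_leaves <- function(x) {
  if (is.list(x) && !is.environment(x)) {
    return(do.call(c, lapply(x, nn_leaves)))
  }
  c(list(x), if (length(x$sub)) do.call(c, lapply(x$sub, nn_leaves)) else list())
}

nn_zero_grads <- function(layers) {
  for (l in nn_leaves(layers)) {
    l$grads <- lapply(l$params, function(p) array(0, dim = dim(p) %||% length(p)))
  }
  invisible(layers)
}

nn_n_params <- function(layers) {
  sum(vapply(nn_leaves(layers), function(l) {
    sum(vapply(l$params, length, 1L))
  }, 1))
}

# Adam with bias correction; optimizer state lives on each layer
nn_adam_step <- function(layers, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8, t = 1) {
  for (l in nn_leaves(layers)) {
    if (length(l$params) == 0) next
    if (is.null(l$opt)) {
      l$opt <- lapply(l$params, function(p) {
        list(m = array(0, dim = dim(p) %||% length(p)),
             v = array(0, dim = dim(p) %||% length(p)))
      })
    }
    for (nm in names(l$params)) {
      g <- l$grads[[nm]]
      st <- l$opt[[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      l$opt[[nm]] <- st
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      l$params[[nm]] <- l$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  invisible(layers)
}

.glorot <- function(nin, nout) {
  matrix(runif(nin * nout, -sqrt(6 / (nin + nout)), sqrt(6 / (nin + nout))),
         nin, nout)
}

## ---- linear ----------------------------------------------------------------

nn_linear <- function(n_in, n_out) {
  new_layer("linear",
            params = list(W = .glorot(n_in, n_out), b = rep(0, n_out)),
            fields = list(n_in = n_in, n_out = n_out))
}

#' @export
nn_forward.nn_linear <- function(layer, x, training = FALSE, ...) {
  layer$x <- x
  out <- x %*% layer$params$W
  out + rep(layer$params$b, each = nrow(out))
}

#' @export
nn_backward.nn_linear <- function(layer, dout, ...) {
  layer$grads$W <- layer$grads$W + crossprod(layer$x, dout)
  layer$grads$b <- layer$grads$b + colSums(dout)
  dout %*% t(layer$params$W)
}

## ---- embedding (token lookup) ----------------------------------------------

nn_embedding <- function(vocab_size, dim) {
  new_layer("embedding",
            params = list(W = matrix(rnorm(vocab_size * dim, sd = 0.1),
                                     vocab_size, dim)),
            fields = list(vocab_size = vocab_size, dim = dim))
}

#' @export
nn_forward.nn_embedding <- function(layer, x, training = FALSE, ...) {
  # x: B x L integer token matrix (0-based ids) -> (B*L) x D, sample-major
  idx <- as.vector(t(x)) + 1L
  if (anyNA(idx) || any(idx < 1L) || any(idx > layer$vocab_size)) {
    abort("Token id outside the embedding vocabulary.")
  }
  layer$idx <- idx
  layer$params$W[idx, , drop = FALSE]
}

#' @export
nn_backward.nn_embedding <- function(layer, dout, ...) {
  rs <- rowsum(dout, group = layer$idx)
  rows <- as.integer(rownames(rs))
  layer$grads$W[rows, ] <- layer$grads$W[rows, ] + rs
  NULL  # no gradient flows past the lookup
}

## ---- positional encoding ---------------------------------------------------

nn_positional <- function(max_len, dim, mode = c("learned", "sinusoidal")) {
  mode <- match.arg(mode)
  P <- if (mode == "learned") {
    matrix(rnorm(max_len * dim, sd = 0.1), max_len, dim)
  } else {
    sinusoidal_table(max_len, dim)
  }
  params <- if (mode == "learned") list(P = P) else list()
  new_layer("positional", params = params,
            fields = list(max_len = max_len, dim = dim, mode = mode,
                          fixed = if (mode == "sinusoidal") P else NULL))
}

#' Fixed sinusoidal positional-encoding table
#'
#' The standard closed form: even columns are sines, odd columns cosines of
#' position / 10000^(2i/d). Offered as an alternative to the default learned
#' positional embedding.
#'
#' @param max_len Number of positions.
#' @param dim Embedding width.
#' @return A `max_len` x `dim` matrix.
#' @export
sinusoidal_table <- function(max_len, dim) {
  pos <- 0:(max_len - 1)
  i <- 0:(dim - 1)
  angle <- outer(pos, 1 / 10000^((i %/% 2) * 2 / dim))
  out <- angle
  out[, i %% 2 == 0] <- sin(angle[, i %% 2 == 0, drop = FALSE])
  out[, i %% 2 == 1] <- cos(angle[, i %% 2 == 1, drop = FALSE])
  out
}

#' @export
nn_forward.nn_positional <- function(layer, x, training = FALSE, ...) {
  L <- layer$max_len
  B <- nrow(x) / L
  pos_idx <- rep(seq_len(L), B)
  layer$pos_idx <- pos_idx
  tab <- layer$params$P %||% layer$fixed
  x + tab[pos_idx, , drop = FALSE]
}

#' @export
nn_backward.nn_positional <- function(layer, dout, ...) {
  if (layer$mode == "learned") {
    rs <- rowsum(dout, group = layer$pos_idx)
    layer$grads$P <- layer$grads$P + rs[order(as.integer(rownames(rs))), ]
  }
  dout
}

## ---- pointwise -------------------------------------------------------------

nn_relu <- function() new_layer("relu")

#' @export
nn_forward.nn_relu <- function(layer, x, training = FALSE, ...) {
  layer$mask <- x > 0
  x * layer$mask
}

#' @export
nn_backward.nn_relu <- function(layer, dout, ...) dout * layer$mask

nn_dropout <- function(p) new_layer("dropout", fields = list(p = p))

#' @export
nn_forward.nn_dropout <- function(layer, x, training = FALSE, ...) {
  if (!training || layer$p <= 0) {
    layer$mask <- NULL
    return(x)
  }
  keep <- 1 - layer$p
  layer$mask <- (matrix(runif(length(x)), nrow(x)) < keep) / keep
  x * layer$mask
}

#' @export
nn_backward.nn_dropout <- function(layer, dout, ...) {
  if (is.null(layer$mask)) dout else dout * layer$mask
}

## ---- layer norm ------------------------------------------------------------

nn_layernorm <- function(dim, eps = 1e-5) {
  new_layer("layernorm",
            params = list(g = rep(1, dim), b = rep(0, dim)),
            fields = list(dim = dim, eps = eps))
}

#' @export
nn_forward.nn_layernorm <- function(layer, x, training = FALSE, ...) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + layer$eps)
  xhat <- xc * inv
  layer$xhat <- xhat
  layer$inv <- inv
  n <- nrow(x)
  xhat * rep(layer$params$g, each = n) + rep(layer$params$b, each = n)
}

#' @export
nn_backward.nn_layernorm <- function(layer, dout, ...) {
  xhat <- layer$xhat
  layer$grads$g <- layer$grads$g + colSums(dout * xhat)
  layer$grads$b <- layer$grads$b + colSums(dout)
  dxhat <- dout * rep(layer$params$g, each = nrow(dout))
  (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * layer$inv
}

## ---- reshape helpers (stateless) -------------------------------------------

# (B*L) x D sample-major -> B x (L*D) row-per-sample
flatten_seq <- function(x, B) {
  matrix(as.vector(t(x)), B, byrow = TRUE)
}

unflatten_seq <- function(x, L, D) {
  matrix(as.vector(t(x)), ncol = D, byrow = TRUE)
}

## ---- losses ----------------------------------------------------------------

# log-softmax over rows, numerically stable
log_softmax <- function(x) {
  m <- apply(x, 1, max)
  xs <- x - m
  xs - log(rowSums(exp(xs)))
}

# mean negative log-likelihood; y in {0,1}; returns loss and gradient wrt logits
nll_from_logits <- function(logits, y) {
  lp <- log_softmax(logits)
  B <- nrow(lp)
  pick <- cbind(seq_len(B), y + 1L)
  loss <- -mean(lp[pick])
  dlp <- matrix(0, B, ncol(lp))
  dlp[pick] <- -1 / B
  # backward through log-softmax: dx = dlp - softmax * rowSums(dlp)
  dlogits <- dlp - exp(lp) * rowSums(dlp)
  list(loss = loss, grad = dlogits, logp = lp)
}

mse_loss <- function(pred, y) {
  d <- pred - y
  list(loss = mean(d * d), grad = 2 * d / length(d))
}
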