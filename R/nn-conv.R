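# 2-D convolution ('same' zero padding, stride 1) and 2x2 max pooling on the
# (B*H*W) x C activation layout. The embedded sequence is treated as a
# one-channel H x W image (H = sequence length, W = embedding width).
# Convolution is im2col + one BLAS product; gather/scatter index tables are
# cached per batch geometry. For a fixed kernel offset the output->input row
# map is injective (padding aside), so the backward scatter is plain indexed
# addition.

nn_conv2d <- function(c_in, c_out, kh = 3, kw = 3) {
  fan_in <- kh * kw * c_in
  new_layer("conv2d",
            params = list(W = .glorot(fan_in, c_out), b = rep(0, c_out)),
            fields = list(c_in = c_in, c_out = c_out, kh = kh, kw = kw,
                          geom = NULL))
}

# index table: for each kernel offset, source row in the zero-padded matrix
.conv_indices <- function(B, H, W, kh, kw) {
  pad_row <- B * H * W + 1L
  hh <- rep(seq_len(H), each = W)
  ww <- rep(seq_len(W), H)
  offs <- expand.grid(dw = seq_len(kw) - (kw %/% 2 + 1L),
                      dh = seq_len(kh) - (kh %/% 2 + 1L))[, c("dh", "dw")]
  idx <- matrix(0L, B * H * W, kh * kw)
  for (k in seq_len(nrow(offs))) {
    h2 <- hh + offs$dh[k]
    w2 <- ww + offs$dw[k]
    inside <- h2 >= 1L & h2 <= H & w2 >= 1L & w2 <= W
    base <- ifelse(inside, (h2 - 1L) * W + w2, NA_integer_)
    full <- rep(base, B) + rep((seq_len(B) - 1L) * (H * W), each = H * W)
    full[is.na(full)] <- pad_row
    idx[, k] <- full
  }
  idx
}

#' @export
nn_forward.nn_conv2d <- function(layer, x, training = FALSE, geom = NULL, ...) {
  # geom: c(B, H, W); required because the layout does not carry shape
  stopifnot(!is.null(geom))
  B <- geom[1]; H <- geom[2]; W <- geom[3]
  key <- paste(geom, collapse = "x")
  if (is.null(layer$geom) || layer$geom_key != key) {
    layer$idx <- .conv_indices(B, H, W, layer$kh, layer$kw)
    layer$geom <- geom
    layer$geom_key <- key
  }
  xa <- rbind(x, 0)
  k2 <- layer$kh * layer$kw
  cols <- vector("list", k2)
  for (k in seq_len(k2)) cols[[k]] <- xa[layer$idx[, k], , drop = FALSE]
  xcol <- do.call(cbind, cols)
  layer$xcol <- xcol
  out <- xcol %*% layer$params$W
  out + rep(layer$params$b, each = nrow(out))
}

#' @export
nn_backward.nn_conv2d <- function(layer, dout, ...) {
  layer$grads$W <- layer$grads$W + crossprod(layer$xcol, dout)
  layer$grads$b <- layer$grads$b + colSums(dout)
  dxcol <- dout %*% t(layer$params$W)
  n <- nrow(dout)
  dxa <- matrix(0, n + 1L, layer$c_in)
  k2 <- layer$kh * layer$kw
  for (k in seq_len(k2)) {
    cols <- ((k - 1L) * layer$c_in + 1L):(k * layer$c_in)
    rows <- layer$idx[, k]
    live <- rows <= n  # drop padding contributions
    dxa[rows[live], ] <- dxa[rows[live], , drop = FALSE] +
      dxcol[live, cols, drop = FALSE]
  }
  dxa[seq_len(n), , drop = FALSE]
}

## ---- max pooling -------------------------------------------------------------

nn_maxpool <- function(ph = 2, pw = 2) {
  new_layer("maxpool", fields = list(ph = ph, pw = pw, geom = NULL))
}

.pool_indices <- function(B, H, W, ph, pw) {
  H2 <- H %/% ph; W2 <- W %/% pw
  hh <- rep(seq_len(H2), each = W2)
  ww <- rep(seq_len(W2), H2)
  offs <- expand.grid(dw = 0:(pw - 1), dh = 0:(ph - 1))[, c("dh", "dw")]
  lapply(seq_len(nrow(offs)), function(k) {
    h2 <- (hh - 1L) * ph + 1L + offs$dh[k]
    w2 <- (ww - 1L) * pw + 1L + offs$dw[k]
    base <- (h2 - 1L) * W + w2
    rep(base, B) + rep((seq_len(B) - 1L) * (H * W), each = H2 * W2)
  })
}

#' @export
nn_forward.nn_maxpool <- function(layer, x, training = FALSE, geom = NULL, ...) {
  stopifnot(!is.null(geom))
  B <- geom[1]; H <- geom[2]; W <- geom[3]
  key <- paste(geom, collapse = "x")
  if (is.null(layer$geom) || layer$geom_key != key) {
    layer$idx <- .pool_indices(B, H, W, layer$ph, layer$pw)
    layer$geom <- geom
    layer$geom_key <- key
  }
  out <- x[layer$idx[[1]], , drop = FALSE]
  arg <- if (training) matrix(1L, nrow(out), ncol(out)) else NULL
  for (k in seq_along(layer$idx)[-1]) {
    cand <- x[layer$idx[[k]], , drop = FALSE]
    better <- cand > out
    out[better] <- cand[better]
    if (training) arg[better] <- k
  }
  layer$arg <- arg
  layer$n_in <- nrow(x)
  out
}

#' @export
nn_backward.nn_maxpool <- function(layer, dout, ...) {
  dx <- matrix(0, layer$n_in, ncol(dout))
  for (k in seq_along(layer$idx)) {
    mask <- layer$arg == k
    if (!any(mask)) next
    contrib <- dout * mask
    rows <- layer$idx[[k]]
    dx[rows, ] <- dx[rows, , drop = FALSE] + contrib
  }
  dx
}

# output spatial size after 'same' conv (unchanged) and pooling
.pool_out <- function(H, W, ph = 2, pw = 2) c(H %/% ph, W %/% pw)

## ---- conv stack: conv-relu-pool twice ---------------------------------------

nn_conv_stack <- function(channels, kernels = list(c(3, 3), c(3, 3)),
                          pools = list(c(2, 2), c(2, 2))) {
  stk <- new_layer("conv_stack", fields = list(channels = channels))
  stk$sub <- list(
    conv1 = nn_conv2d(1, channels[1], kernels[[1]][1], kernels[[1]][2]),
    relu1 = nn_relu(),
    pool1 = nn_maxpool(pools[[1]][1], pools[[1]][2]),
    conv2 = nn_conv2d(channels[1], channels[2], kernels[[2]][1], kernels[[2]][2]),
    relu2 = nn_relu(),
    pool2 = nn_maxpool(pools[[2]][1], pools[[2]][2])
  )
  stk
}

# x: (B*L) x D sequence activations -> flattened B x F conv features
#' @export
nn_forward.nn_conv_stack <- function(layer, x, training = FALSE, geom = NULL, ...) {
  stopifnot(!is.null(geom))
  B <- geom[1]; H <- geom[2]; W <- geom[3]
  s <- layer$sub
  img <- matrix(as.vector(t(x)), ncol = 1)  # H=L, W=D, C=1
  a <- nn_forward(s$conv1, img, training, geom = c(B, H, W))
  a <- nn_forward(s$relu1, a, training)
  a <- nn_forward(s$pool1, a, training, geom = c(B, H, W))
  g1 <- .pool_out(H, W, s$pool1$ph, s$pool1$pw)
  a <- nn_forward(s$conv2, a, training, geom = c(B, g1[1], g1[2]))
  a <- nn_forward(s$relu2, a, training)
  a <- nn_forward(s$pool2, a, training, geom = c(B, g1[1], g1[2]))
  g2 <- .pool_out(g1[1], g1[2], s$pool2$ph, s$pool2$pw)
  layer$g <- list(B = B, H = H, W = W, g1 = g1, g2 = g2)
  # flatten: B x (H2*W2*C2)
  matrix(as.vector(t(a)), B, byrow = TRUE)
}

#' @export
nn_backward.nn_conv_stack <- function(layer, dout, ...) {
  s <- layer$sub
  g <- layer$g
  c2 <- layer$channels[2]
  da <- matrix(as.vector(t(dout)), ncol = c2, byrow = TRUE)
  da <- nn_backward(s$pool2, da)
  da <- nn_backward(s$relu2, da)
  da <- nn_backward(s$conv2, da)
  da <- nn_backward(s$pool1, da)
  da <- nn_backward(s$relu1, da)
  da <- nn_backward(s$conv1, da)
  # back to (B*L) x D sequence layout
  matrix(as.vector(t(da)), ncol = g$W, byrow = TRUE)
}

# number of flattened features produced by the stack for an H x W input
conv_stack_out_dim <- function(channels, H, W) {
  g1 <- .pool_out(H, W)
  g2 <- .pool_out(g1[1], g1[2])
  g2[1] * g2[2] * channels[2]
}
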