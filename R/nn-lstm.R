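# Single-layer LSTM over the sample-major sequence layout; the branch output
# is the final hidden state (B x hidden). Gates are computed with one fused
# matrix product per time step; sequences are short, so the time loop is cheap.

nn_lstm <- function(dim, hidden, max_len) {
  fan <- dim + hidden
  new_layer("lstm",
            params = list(W = .glorot(fan, 4 * hidden), b = rep(0, 4 * hidden)),
            fields = list(dim = dim, hidden = hidden, max_len = max_len))
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

#' @export
nn_forward.nn_lstm <- function(layer, x, training = FALSE, ...) {
  L <- layer$max_len
  B <- nrow(x) / L
  Hn <- layer$hidden
  h <- matrix(0, B, Hn)
  cc <- matrix(0, B, Hn)
  cache <- vector("list", L)
  for (t in seq_len(L)) {
    xt <- x[(seq_len(B) - 1L) * L + t, , drop = FALSE]
    z <- cbind(xt, h) %*% layer$params$W
    z <- z + rep(layer$params$b, each = nrow(z))
    i <- .sigmoid(z[, 1:Hn, drop = FALSE])
    f <- .sigmoid(z[, (Hn + 1):(2 * Hn), drop = FALSE])
    o <- .sigmoid(z[, (2 * Hn + 1):(3 * Hn), drop = FALSE])
    g <- tanh(z[, (3 * Hn + 1):(4 * Hn), drop = FALSE])
    c_prev <- cc
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    cache[[t]] <- list(xt = xt, h_prev = if (t == 1) matrix(0, B, Hn) else cache[[t - 1]]$h,
                       c_prev = c_prev, i = i, f = f, o = o, g = g, c = cc, tc = tc,
                       h = o * tc)
    h <- cache[[t]]$h
  }
  layer$cache <- cache
  layer$B <- B
  h
}

#' @export
nn_backward.nn_lstm <- function(layer, dout, ...) {
  L <- layer$max_len
  B <- layer$B
  Hn <- layer$hidden
  D <- layer$dim
  dh <- dout
  dc <- matrix(0, B, Hn)
  dx <- matrix(0, B * L, D)
  for (t in rev(seq_len(L))) {
    k <- layer$cache[[t]]
    do_ <- dh * k$tc
    dc <- dc + dh * k$o * (1 - k$tc^2)
    di <- dc * k$g
    dg <- dc * k$i
    df <- dc * k$c_prev
    dc_prev <- dc * k$f
    dz <- cbind(di * k$i * (1 - k$i),
                df * k$f * (1 - k$f),
                do_ * k$o * (1 - k$o),
                dg * (1 - k$g^2))
    inp <- cbind(k$xt, k$h_prev)
    layer$grads$W <- layer$grads$W + crossprod(inp, dz)
    layer$grads$b <- layer$grads$b + colSums(dz)
    dinp <- dz %*% t(layer$params$W)
    dx[(seq_len(B) - 1L) * L + t, ] <- dinp[, 1:D, drop = FALSE]
    dh <- dinp[, (D + 1):(D + Hn), drop = FALSE]
    dc <- dc_prev
  }
  dx
}
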