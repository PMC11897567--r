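# Low-level neural network primitives. Layer normalization, GELU and the
# grouped attention kernel live in compiled code (src/mha.cpp); forward
# functions return caches consumed by matching backward functions.

#' Scaled dot-product attention
#'
#' `Attention(Q, K, V) = softmax(Q K' / sqrt(d_k)) V` with the softmax taken
#' row-wise, so each output token is a probability-weighted average of the
#' value rows.
#'
#' @param Q,K,V numeric matrices `tokens x d_k` with matching shapes
#'   (`K` and `V` must have the same number of rows).
#' @param return_attention also return the attention matrix.
#' @return The attended `tokens x d_k` matrix, or (with
#'   `return_attention = TRUE`) a list with `out` and `attention`.
#' @export
scaled_dot_attention <- function(Q, K, V, return_attention = FALSE) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  if (ncol(Q) != ncol(K) || nrow(K) != nrow(V)) {
    stop("shape mismatch: Q is ", nrow(Q), "x", ncol(Q), ", K is ",
         nrow(K), "x", ncol(K), ", V is ", nrow(V), "x", ncol(V))
  }
  S <- Q %*% t(K) / sqrt(ncol(Q))
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  A <- E / rowSums(E)
  out <- A %*% V
  if (return_attention) list(out = out, attention = A) else out
}

#' Sinusoidal position table
#'
#' Entry `(p, 2i-1) = sin(p / 10000^(2(i-1)/D))` and
#' `(p, 2i) = cos(p / 10000^(2(i-1)/D))` for positions `p = 0, ..., n-1`.
#' Used as the initial value of the learnable spatial and temporal position
#' encodings.
#'
#' @param n_positions number of positions (rows).
#' @param D embedding width; must be even.
#' @return numeric matrix `n_positions x D` with entries in `[-1, 1]`.
#' @export
sinusoidal_init <- function(n_positions, D) {
  if (D %% 2 != 0) stop("embedding width D must be even, got ", D)
  p <- seq_len(n_positions) - 1
  i <- seq_len(D / 2) - 1
  ang <- outer(p, 1 / 10000^(2 * i / D))
  out <- matrix(0, n_positions, D)
  out[, seq(1L, D, by = 2L)] <- sin(ang)
  out[, seq(2L, D, by = 2L)] <- cos(ang)
  out
}

# ---- layer normalization over the feature (column) axis, per row ----

ln_forward <- function(X, gamma, beta, eps = 1e-5) {
  ln_forward_cpp(X, gamma, beta, eps)
}

ln_backward <- function(dY, cache, gamma) {
  ln_backward_cpp(dY, cache$xhat, cache$inv, gamma)
}

# ---- exact GELU: x * Phi(x) ----

gelu_forward <- function(X) gelu_forward_cpp(X)

gelu_backward <- function(dY, X, cache) gelu_backward_cpp(dY, X, cache$pn)

# ---- inverted dropout (identity when p == 0 or not training) ----

dropout_forward <- function(X, p, train) {
  if (!train || p <= 0) return(list(out = X, mask = NULL))
  mask <- (matrix(runif(length(X)), nrow(X)) >= p) / (1 - p)
  list(out = X * mask, mask = mask)
}

dropout_backward <- function(dY, mask) {
  if (is.null(mask)) dY else dY * mask
}

# ---- affine layer helpers ----

add_bias <- function(M, b) add_bias_cpp(M, b)

linear_forward <- function(X, W, b) add_bias_cpp(X %*% W, b)

# dW = X' dY, db = colSums(dY), dX = dY W'
linear_backward <- function(dY, X, W) {
  list(dX = dY %*% t(W), dW = crossprod(X, dY), db = colSums(dY))
}
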