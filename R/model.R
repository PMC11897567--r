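# Dual spatial/temporal transformer classifier over DE feature windows.
#
# A window x in R^{T x C x F} is processed as:
#   1. linear projection P (F -> D) plus learnable spatial position
#      encoding E_SPos, giving C channel tokens per frame;
#   2. L pre-norm transformer blocks applied to the C tokens of each frame
#      independently (shared weights across frames) -- the spatial encoder;
#   3. mean pooling over channel tokens -> one token per frame;
#   4. learnable temporal position encoding E_TPos plus L pre-norm blocks
#      over the T frame tokens -- the temporal encoder;
#   5. mean pooling over frames, layer normalization, and a linear head
#      giving K class logits.
# Position encodings are initialized from the sinusoidal table and learned
# thereafter. Blocks use pre-norm residuals, GELU MLPs of width
# mlp_ratio * D, and dropout on the attention and MLP branch outputs.

#' Model configuration
#'
#' @param C number of EEG channels (spatial tokens).
#' @param K number of classes, at least 2.
#' @param T frames per window (default 10).
#' @param F feature bands per channel (default 5).
#' @param D embedding dimension, even and divisible by `H` (default 32).
#' @param L transformer blocks in each of the spatial and temporal encoders
#'   (default 6).
#' @param H attention heads (default 8).
#' @param mlp_ratio MLP hidden width multiplier (default 2).
#' @param dropout dropout probability on attention/MLP branch outputs,
#'   in `[0, 1)` (default 0.1).
#' @return An object of class `stt_config`.
#' @export
stt_config <- function(C, K, T = 10, F = 5, D = 32, L = 6, H = 8,
                       mlp_ratio = 2, dropout = 0.1) {
  if (D %% H != 0) stop("D = ", D, " must be divisible by H = ", H)
  if (D %% 2 != 0) stop("D must be even for the sinusoidal position table")
  if (L < 1) stop("need at least one transformer block")
  if (K < 2) stop("need at least two classes")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  if (mlp_ratio <= 0) stop("mlp_ratio must be positive")
  structure(list(C = as.integer(C), K = as.integer(K), T = as.integer(T),
                 F = as.integer(F), D = as.integer(D), L = as.integer(L),
                 H = as.integer(H), mlp_ratio = mlp_ratio, dropout = dropout),
            class = "stt_config")
}

#' @export
print.stt_config <- function(x, ...) {
  cat(sprintf(
    "<stt_config> C=%d T=%d F=%d -> D=%d, L=%d blocks x2, H=%d heads, K=%d classes\n",
    x$C, x$T, x$F, x$D, x$L, x$H, x$K))
  invisible(x)
}

xavier <- function(n_in, n_out) {
  matrix(rnorm(n_in * n_out, sd = sqrt(2 / (n_in + n_out))), n_in, n_out)
}

init_block_params <- function(D, hidden) {
  list(
    ln1_g = rep(1, D), ln1_b = rep(0, D),
    Wq = xavier(D, D), bq = rep(0, D),
    Wk = xavier(D, D), bk = rep(0, D),
    Wv = xavier(D, D), bv = rep(0, D),
    Wo = xavier(D, D), bo = rep(0, D),
    ln2_g = rep(1, D), ln2_b = rep(0, D),
    W1 = xavier(D, hidden), b1 = rep(0, hidden),
    W2 = xavier(hidden, D), b2 = rep(0, D)
  )
}

#' Initialize model state
#'
#' Weight matrices use Xavier-normal initialization; biases are zero; layer
#' norm gains are one; the spatial and temporal position encodings start
#' from the sinusoidal table ([sinusoidal_init]) and are learnable.
#'
#' @param config an [stt_config].
#' @param seed optional integer seed making the draw reproducible without
#'   disturbing the caller's RNG state.
#' @return An object of class `stt_state`: a nested list of parameter
#'   arrays.
#' @export
init_model_state <- function(config, seed = NULL) {
  draw <- function() {
    hidden <- round(config$mlp_ratio * config$D)
    structure(list(
      P = xavier(config$F, config$D),
      E_SPos = sinusoidal_init(config$C, config$D),
      E_TPos = sinusoidal_init(config$T, config$D),
      spatial = lapply(seq_len(config$L), function(i) init_block_params(config$D, hidden)),
      temporal = lapply(seq_len(config$L), function(i) init_block_params(config$D, hidden)),
      head_g = rep(1, config$D), head_b = rep(0, config$D),
      W_head = xavier(config$D, config$K), b_head = rep(0, config$K)
    ), class = "stt_state")
  }
  if (is.null(seed)) draw() else with_local_seed(seed, draw())
}

#' Number of learnable parameters
#'
#' @param state an `stt_state` (or any nested list of numeric arrays).
#' @return integer parameter count.
#' @export
n_parameters <- function(state) {
  if (is.list(state)) sum(vapply(state, n_parameters, numeric(1))) else length(state)
}

#' Multi-head self-attention over a token matrix
#'
#' Projects tokens to queries, keys and values, attends per head over
#' `D / H`-wide slices, concatenates the heads and applies the output
#' projection.
#'
#' @param x numeric matrix `tokens x D`.
#' @param weights list with `Wq, bq, Wk, bk, Wv, bv, Wo, bo` (e.g. one
#'   block of an `stt_state`).
#' @param config an [stt_config] supplying `H`.
#' @param return_attention also return the `Tk x Tk x H` attention array.
#' @return `tokens x D` matrix, or a list with `out` and `attention`.
#' @export
multi_head_attention <- function(x, weights, config, return_attention = FALSE) {
  x <- as.matrix(x)
  if (ncol(x) != config$D) stop("token width ", ncol(x), " != D = ", config$D)
  QKV <- add_bias(x %*% cbind(weights$Wq, weights$Wk, weights$Wv),
                  c(weights$bq, weights$bk, weights$bv))
  mh <- mha_qkv_forward_cpp(QKV, 1L, nrow(x), config$H)
  out <- linear_forward(mh$out, weights$Wo, weights$bo)
  if (return_attention) list(out = out, attention = mh$attn) else out
}

# ---- pre-norm transformer block over grouped tokens ----
# X: (G*Tk) x D with group tokens in contiguous rows.

block_forward <- function(X, p, G, Tk, H, train = FALSE, drop_p = 0) {
  ln1 <- ln_forward(X, p$ln1_g, p$ln1_b)
  Wqkv <- cbind(p$Wq, p$Wk, p$Wv)
  QKV <- add_bias(ln1$out %*% Wqkv, c(p$bq, p$bk, p$bv))
  mh <- mha_qkv_forward_cpp(QKV, G, Tk, H)
  proj <- linear_forward(mh$out, p$Wo, p$bo)
  do1 <- dropout_forward(proj, drop_p, train)
  X1 <- X + do1$out
  ln2 <- ln_forward(X1, p$ln2_g, p$ln2_b)
  h <- linear_forward(ln2$out, p$W1, p$b1)
  g <- gelu_forward(h)
  m <- linear_forward(g$out, p$W2, p$b2)
  do2 <- dropout_forward(m, drop_p, train)
  list(out = X1 + do2$out,
       cache = list(ln1 = ln1, Wqkv = Wqkv, QKV = QKV, attn = mh$attn,
                    mhout = mh$out, do1mask = do1$mask, X1 = X1,
                    ln2 = ln2, h = h, g = g, do2mask = do2$mask))
}

block_backward <- function(dOut, cache, p, G, Tk, H) {
  D <- ncol(p$Wq)
  dm <- dropout_backward(dOut, cache$do2mask)
  lb2 <- linear_backward(dm, cache$g$out, p$W2)
  dh <- gelu_backward(lb2$dX, cache$h, cache$g)
  lb1 <- linear_backward(dh, cache$ln2$out, p$W1)
  ln2b <- ln_backward(lb1$dX, cache$ln2, p$ln2_g)
  dX1 <- dOut + ln2b$dX
  dproj <- dropout_backward(dX1, cache$do1mask)
  lbo <- linear_backward(dproj, cache$mhout, p$Wo)
  dQKV <- mha_qkv_backward_cpp(lbo$dX, cache$QKV, cache$attn, G, Tk, H)
  dWqkv <- crossprod(cache$ln1$out, dQKV)
  dbqkv <- colSums(dQKV)
  dln1 <- dQKV %*% t(cache$Wqkv)
  ln1b <- ln_backward(dln1, cache$ln1, p$ln1_g)
  iq <- seq_len(D); ik <- D + iq; iv <- 2L * D + iq
  list(dX = dX1 + ln1b$dX,
       grads = list(
         ln1_g = ln1b$dgamma, ln1_b = ln1b$dbeta,
         Wq = dWqkv[, iq, drop = FALSE], bq = dbqkv[iq],
         Wk = dWqkv[, ik, drop = FALSE], bk = dbqkv[ik],
         Wv = dWqkv[, iv, drop = FALSE], bv = dbqkv[iv],
         Wo = lbo$dW, bo = lbo$db,
         ln2_g = ln2b$dgamma, ln2_b = ln2b$dbeta,
         W1 = lb1$dW, b1 = lb1$db, W2 = lb2$dW, b2 = lb2$db))
}

#' Apply one pre-norm transformer block to a token matrix
#'
#' `x + MHA(LN(x))` followed by `(.) + MLP(LN(.))`, the block used by both
#' encoders.
#'
#' @param x numeric matrix `tokens x D`.
#' @param params one block's parameter list (see [init_block_params] fields).
#' @param config an [stt_config].
#' @return `tokens x D` matrix.
#' @export
transformer_block <- function(x, params, config) {
  block_forward(as.matrix(x), params, 1L, nrow(x), config$H)$out
}

# ---- full forward over a window batch ----
# X: [N, T, C, F]. Token rows are ordered channel-fastest, then frame,
# then window for the spatial stage; frame-fastest then window for the
# temporal stage.

stt_forward <- function(state, config, X, train = FALSE,
                        return_attention = FALSE) {
  dims <- dim(X)
  if (length(dims) != 4L || any(dims[2:4] != c(config$T, config$C, config$F))) {
    stop("window batch must be [N x ", config$T, " x ", config$C, " x ",
         config$F, "], got [", paste(dims, collapse = " x "), "]")
  }
  Xs <- matrix(aperm(X, c(3L, 2L, 1L, 4L)), nrow = prod(dims[1:3]))
  stt_forward_tokens(state, config, Xs, dims[1L], train, return_attention)
}

# Fast path over a precomputed token matrix Xs ((C*T*N) x F, rows ordered
# channel-fastest, then frame, then window), used by the training loop to
# avoid re-permuting the feature array for every mini-batch.
stt_forward_tokens <- function(state, config, Xs, N, train = FALSE,
                               return_attention = FALSE) {
  T <- config$T; C <- config$C
  Gs <- N * T
  tok <- Xs %*% state$P + state$E_SPos[rep(seq_len(C), Gs), , drop = FALSE]
  sp_caches <- vector("list", config$L)
  Hcur <- tok
  attn_maps <- if (return_attention) list() else NULL
  for (l in seq_len(config$L)) {
    bf <- block_forward(Hcur, state$spatial[[l]], Gs, C, config$H,
                        train, config$dropout)
    sp_caches[[l]] <- bf$cache
    if (return_attention) attn_maps[[paste0("spatial", l)]] <- bf$cache$attn
    Hcur <- bf$out
  }
  sp_out <- Hcur
  frame_grp <- rep(seq_len(Gs), each = C)
  Ft <- rowsum(sp_out, frame_grp) / C                    # Gs x D, rows (t,n)
  Tt <- Ft + state$E_TPos[rep(seq_len(T), N), , drop = FALSE]
  tp_caches <- vector("list", config$L)
  Hcur <- Tt
  for (l in seq_len(config$L)) {
    bf <- block_forward(Hcur, state$temporal[[l]], N, T, config$H,
                        train, config$dropout)
    tp_caches[[l]] <- bf$cache
    if (return_attention) attn_maps[[paste0("temporal", l)]] <- bf$cache$attn
    Hcur <- bf$out
  }
  tp_out <- Hcur
  win_grp <- rep(seq_len(N), each = T)
  Z <- rowsum(tp_out, win_grp) / T                       # N x D
  hl <- ln_forward(Z, state$head_g, state$head_b)
  logits <- linear_forward(hl$out, state$W_head, state$b_head)
  list(logits = logits,
       cache = list(Xs = Xs, sp_caches = sp_caches, tp_caches = tp_caches,
                    hl = hl, N = N, Gs = Gs),
       attention = attn_maps)
}

stt_backward <- function(dlogits, cache, state, config) {
  N <- cache$N; T <- config$T; C <- config$C; Gs <- cache$Gs
  hb <- linear_backward(dlogits, cache$hl$out, state$W_head)
  hlnb <- ln_backward(hb$dX, cache$hl, state$head_g)
  dTp <- hlnb$dX[rep(seq_len(N), each = T), , drop = FALSE] / T
  tp_grads <- vector("list", config$L)
  for (l in rev(seq_len(config$L))) {
    bb <- block_backward(dTp, cache$tp_caches[[l]], state$temporal[[l]],
                         N, T, config$H)
    tp_grads[[l]] <- bb$grads
    dTp <- bb$dX
  }
  dE_TPos <- rowsum(dTp, rep(seq_len(T), N))
  dSp <- dTp[rep(seq_len(Gs), each = C), , drop = FALSE] / C
  sp_grads <- vector("list", config$L)
  for (l in rev(seq_len(config$L))) {
    bb <- block_backward(dSp, cache$sp_caches[[l]], state$spatial[[l]],
                         Gs, C, config$H)
    sp_grads[[l]] <- bb$grads
    dSp <- bb$dX
  }
  dE_SPos <- rowsum(dSp, rep(seq_len(C), Gs))
  dP <- crossprod(cache$Xs, dSp)
  list(P = dP, E_SPos = dE_SPos, E_TPos = dE_TPos,
       spatial = sp_grads, temporal = tp_grads,
       head_g = hlnb$dgamma, head_b = hlnb$dbeta,
       W_head = hb$dW, b_head = hb$db)
}

#' Spatial encoder applied to one window
#'
#' Projects each frame's `C x F` channel block to `C x D` tokens, adds the
#' spatial position encoding and applies the `L` spatial transformer blocks,
#' identically and independently per frame.
#'
#' @param window numeric array `T x C x F`.
#' @param state an `stt_state`.
#' @param config the matching [stt_config].
#' @return numeric array `T x C x D` of encoded channel tokens.
#' @export
spatial_encode <- function(window, state, config) {
  stopifnot(length(dim(window)) == 3L)
  T <- config$T; C <- config$C
  Xs <- matrix(aperm(window, c(2L, 1L, 3L)), nrow = C * T)  # rows (c,t)
  tok <- Xs %*% state$P + state$E_SPos[rep(seq_len(C), T), , drop = FALSE]
  for (l in seq_len(config$L)) {
    tok <- block_forward(tok, state$spatial[[l]], T, C, config$H)$out
  }
  aperm(array(tok, c(C, T, config$D)), c(2L, 1L, 3L))
}

#' Temporal encoder applied to a frame-token sequence
#'
#' Adds the temporal position encoding and applies the `L` temporal
#' transformer blocks.
#'
#' @param frame_tokens numeric matrix `T x D`.
#' @param state an `stt_state`.
#' @param config the matching [stt_config].
#' @return numeric matrix `T x D`.
#' @export
temporal_encode <- function(frame_tokens, state, config) {
  x <- as.matrix(frame_tokens) + state$E_TPos
  for (l in seq_len(config$L)) {
    x <- block_forward(x, state$temporal[[l]], 1L, config$T, config$H)$out
  }
  x
}

#' Forward pass: window batch to class logits
#'
#' @param state an `stt_state`.
#' @param config the matching [stt_config].
#' @param X numeric array `N x T x C x F` of (normalized) feature windows.
#' @param return_attention also return per-layer attention arrays.
#' @return `N x K` logit matrix, or a list with `logits` and `attention`.
#' @export
stt_logits <- function(state, config, X, return_attention = FALSE) {
  fw <- stt_forward(state, config, X, train = FALSE,
                    return_attention = return_attention)
  if (return_attention) list(logits = fw$logits, attention = fw$attention)
  else fw$logits
}

#' Mean cross-entropy loss
#'
#' `-(1/N) sum_n sum_k y_nk log(softmax(logits)_nk)` with a numerically
#' stable log-sum-exp.
#'
#' @param logits numeric matrix `N x K`.
#' @param labels integer class indices in `1..K` (or a factor).
#' @return non-negative scalar loss (nats).
#' @export
cross_entropy <- function(logits, labels) {
  ce_forward(logits, labels)$loss
}

ce_forward <- function(logits, labels) {
  logits <- as.matrix(logits)
  if (is.factor(labels)) labels <- as.integer(labels)
  N <- nrow(logits); K <- ncol(logits)
  if (length(labels) != N) stop("need one label per logits row")
  if (any(labels < 1L | labels > K)) stop("labels must lie in 1..", K)
  m <- apply(logits, 1L, max)
  ex <- exp(logits - m)
  Zs <- rowSums(ex)
  logp <- logits - m - log(Zs)
  loss <- -mean(logp[cbind(seq_len(N), labels)])
  probs <- ex / Zs
  dlogits <- probs
  dlogits[cbind(seq_len(N), labels)] <- dlogits[cbind(seq_len(N), labels)] - 1
  list(loss = loss, dlogits = dlogits / N, probs = probs)
}
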