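# Shared fixtures and independent oracles, built in code at test time.

# Literal nested-loop evaluation of softmax(QK'/sqrt(dk))V -- the reference
# against which the implementation's attention is checked.
oracle_attention <- function(Q, K, V) {
  n <- nrow(Q); dk <- ncol(Q)
  S <- matrix(0, n, nrow(K))
  for (i in seq_len(n)) {
    for (j in seq_len(nrow(K))) {
      s <- 0
      for (d in seq_len(dk)) s <- s + Q[i, d] * K[j, d]
      S[i, j] <- s / sqrt(dk)
    }
  }
  A <- matrix(0, n, nrow(K))
  for (i in seq_len(n)) {
    e <- exp(S[i, ] - max(S[i, ]))
    A[i, ] <- e / sum(e)
  }
  out <- matrix(0, n, ncol(V))
  for (i in seq_len(n)) {
    for (d in seq_len(ncol(V))) out[i, d] <- sum(A[i, ] * V[, d])
  }
  list(out = out, attention = A)
}

# Literal double-sum cross-entropy of one-hot labels vs softmax(logits).
oracle_cross_entropy <- function(logits, labels) {
  N <- nrow(logits); K <- ncol(logits)
  total <- 0
  for (n in seq_len(N)) {
    p <- exp(logits[n, ]) / sum(exp(logits[n, ]))
    for (k in seq_len(K)) {
      y <- as.numeric(labels[n] == k)
      if (y > 0) total <- total - y * log(p[k])
    }
  }
  total / N
}

# Small synthetic session with the default planted-block profiles.
make_test_session <- function(effect = 1, n_channels = 8, n_classes = 3,
                              trial_duration = 20, trials_per_class = 5,
                              seed = 1) {
  profiles <- make_default_profiles(n_classes, n_channels, effect)
  spec <- synthetic_spec(profiles, n_channels = n_channels,
                         trial_duration = trial_duration,
                         trials_per_class = trials_per_class,
                         rng_seed = seed)
  synthesize_session(spec)
}

# Random windowed feature tensor with balanced labels.
random_windows <- function(n, T = 10, C = 8, F = 5, K = 3, seed = 1,
                           labels = NULL) {
  set.seed(seed)
  vals <- array(rnorm(n * T * C * F), c(n, T, C, F))
  if (is.null(labels)) labels <- paste0("c", rep_len(seq_len(K), n))
  windowed_features(vals, labels, trial_ids = paste0("t", seq_len(n)))
}

# Linearly separable windowed features: per-class mean offsets, small noise.
separable_windows <- function(n_per_class = 20, K = 2, T = 10, C = 4, F = 5,
                              seed = 1, gap = 2) {
  set.seed(seed)
  n <- n_per_class * K
  vals <- array(rnorm(n * T * C * F, sd = 0.3), c(n, T, C, F))
  labels <- rep(paste0("c", seq_len(K)), each = n_per_class)
  for (k in seq_len(K)) {
    rows <- which(labels == paste0("c", k))
    vals[rows, , , k] <- vals[rows, , , k] + gap
  }
  windowed_features(vals, labels, trial_ids = paste0("t", seq_len(n)))
}

small_config <- function(C = 4, K = 2, T = 6, F = 5, D = 8, L = 2, H = 2,
                         dropout = 0) {
  stt_config(C = C, K = K, T = T, F = F, D = D, L = L, H = H,
             mlp_ratio = 2, dropout = dropout)
}

flatten_params <- function(p) unlist(p, use.names = FALSE)
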