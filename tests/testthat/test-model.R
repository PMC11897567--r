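test_that("scaled dot-product attention matches a literal nested-loop oracle", {
  set.seed(10)
  for (i in 1:5) {
    n <- sample(2:5, 1); dk <- sample(2:4, 1)
    Q <- matrix(rnorm(n * dk), n); K <- matrix(rnorm(n * dk), n)
    V <- matrix(rnorm(n * dk), n)
    got <- scaled_dot_attention(Q, K, V, return_attention = TRUE)
    ref <- oracle_attention(Q, K, V)
    expect_lt(max(abs(got$out - ref$out)), 1e-6)
    expect_lt(max(abs(rowSums(got$attention) - 1)), 1e-6)
  }
  # single token: softmax of a scalar is 1, output = V
  v <- matrix(rnorm(3), 1)
  expect_equal(scaled_dot_attention(matrix(1, 1, 3), matrix(2, 1, 3), v), v)
  # identical keys: uniform weights, every row is the column mean of V
  Q <- matrix(rnorm(12), 4); K <- matrix(1, 4, 3); V <- matrix(rnorm(12), 4)
  out <- scaled_dot_attention(Q, K, V)
  expect_equal(out, matrix(colMeans(V), 4, 3, byrow = TRUE), tolerance = 1e-12)
  expect_error(scaled_dot_attention(matrix(0, 2, 3), matrix(0, 2, 2),
                                    matrix(0, 2, 2)), "shape")
})

test_that("multi-head attention equals per-head evaluation plus projection", {
  set.seed(11)
  cfg <- stt_config(C = 4, K = 2, T = 4, F = 5, D = 4, L = 1, H = 2,
                    mlp_ratio = 2, dropout = 0)
  w <- list(Wq = matrix(rnorm(16, sd = 0.5), 4), bq = rnorm(4),
            Wk = matrix(rnorm(16, sd = 0.5), 4), bk = rnorm(4),
            Wv = matrix(rnorm(16, sd = 0.5), 4), bv = rnorm(4),
            Wo = matrix(rnorm(16, sd = 0.5), 4), bo = rnorm(4))
  x <- matrix(rnorm(3 * 4), 3)
  got <- multi_head_attention(x, w, cfg, return_attention = TRUE)
  # manual head-by-head evaluation
  Q <- sweep(x %*% w$Wq, 2, w$bq, "+")
  K <- sweep(x %*% w$Wk, 2, w$bk, "+")
  V <- sweep(x %*% w$Wv, 2, w$bv, "+")
  heads <- lapply(list(1:2, 3:4), function(cols) {
    oracle_attention(Q[, cols, drop = FALSE], K[, cols, drop = FALSE],
                     V[, cols, drop = FALSE])$out
  })
  ref <- sweep(do.call(cbind, heads) %*% w$Wo, 2, w$bo, "+")
  expect_lt(max(abs(got$out - ref)), 1e-6)
  expect_equal(dim(got$out), c(3L, 4L))
  # every head's attention rows are probability distributions
  for (s in seq_len(dim(got$attention)[3])) {
    A <- got$attention[, , s]
    expect_true(all(A >= 0))
    expect_lt(max(abs(rowSums(A) - 1)), 1e-6)
  }

  # H = 1 with identity output projection reduces to plain attention
  cfg1 <- stt_config(C = 4, K = 2, T = 4, F = 5, D = 4, L = 1, H = 1,
                     mlp_ratio = 2, dropout = 0)
  w1 <- w; w1$Wo <- diag(4); w1$bo <- rep(0, 4)
  expect_equal(multi_head_attention(x, w1, cfg1),
               scaled_dot_attention(Q, K, V), tolerance = 1e-10)
})

test_that("sinusoidal table matches the scalar formula and its bounds", {
  tab <- sinusoidal_init(4, 4)
  for (p in 0:3) {
    for (i in 0:1) {
      expect_equal(tab[p + 1, 2 * i + 1], sin(p / 10000^(2 * i / 4)),
                   tolerance = 1e-12)
      expect_equal(tab[p + 1, 2 * i + 2], cos(p / 10000^(2 * i / 4)),
                   tolerance = 1e-12)
    }
  }
  expect_equal(tab[1, ], rep(c(0, 1), 2))
  big <- sinusoidal_init(50, 16)
  expect_true(all(big >= -1 & big <= 1))
  expect_error(sinusoidal_init(4, 5), "even")
})

test_that("a zero-weight transformer block is the identity map", {
  cfg <- small_config()
  st <- init_model_state(cfg, seed = 1)
  p <- st$spatial[[1]]
  for (nm in c("Wq", "Wk", "Wv", "Wo", "W1", "W2")) p[[nm]][] <- 0
  x <- matrix(rnorm(5 * cfg$D), 5)
  expect_equal(transformer_block(x, p, cfg), x, tolerance = 1e-12)
  # shape contract with live weights
  expect_equal(dim(transformer_block(x, st$spatial[[1]], cfg)), dim(x))
})

test_that("backpropagated gradients match finite differences", {
  cfg <- small_config(C = 3, K = 2, T = 4, D = 8, L = 1, H = 2)
  st <- init_model_state(cfg, seed = 3)
  set.seed(4)
  X <- array(rnorm(4 * cfg$T * cfg$C * cfg$F), c(4, cfg$T, cfg$C, cfg$F))
  y <- c(1L, 2L, 1L, 2L)
  loss_at <- function(state) {
    cross_entropy(eegstt:::stt_forward(state, cfg, X)$logits, y)
  }
  fw <- eegstt:::stt_forward(st, cfg, X, train = TRUE)
  ce <- eegstt:::ce_forward(fw$logits, y)
  gr <- eegstt:::stt_backward(ce$dlogits, fw$cache, st, cfg)
  eps <- 1e-5
  probe <- list(c("P", 2, 3), c("E_SPos", 1, 4), c("W_head", 5, 1))
  for (pr in probe) {
    stp <- st; stm <- st
    i <- as.integer(pr[2]); j <- as.integer(pr[3])
    stp[[pr[1]]][i, j] <- stp[[pr[1]]][i, j] + eps
    stm[[pr[1]]][i, j] <- stm[[pr[1]]][i, j] - eps
    fd <- (loss_at(stp) - loss_at(stm)) / (2 * eps)
    expect_equal(unname(gr[[pr[1]]][i, j]), unname(fd), tolerance = 1e-4)
    expect_true(is.finite(fd))
  }
  # a block-internal weight too
  stp <- st; stm <- st
  stp$spatial[[1]]$W1[3, 5] <- stp$spatial[[1]]$W1[3, 5] + eps
  stm$spatial[[1]]$W1[3, 5] <- stm$spatial[[1]]$W1[3, 5] - eps
  fd <- (loss_at(stp) - loss_at(stm)) / (2 * eps)
  expect_equal(gr$spatial[[1]]$W1[3, 5], fd, tolerance = 1e-4)
})

test_that("fused C++ training step reproduces the R reference path exactly", {
  cfg <- stt_config(C = 6, K = 3, T = 8, F = 5, D = 16, L = 3, H = 4,
                    mlp_ratio = 2, dropout = 0)
  st <- init_model_state(cfg, seed = 5)
  set.seed(6)
  X <- array(rnorm(10 * cfg$T * cfg$C * cfg$F), c(10, cfg$T, cfg$C, cfg$F))
  y <- sample.int(3, 10, replace = TRUE)
  fw <- eegstt:::stt_forward(st, cfg, X, train = TRUE)
  ce <- eegstt:::ce_forward(fw$logits, y)
  gr <- eegstt:::stt_backward(ce$dlogits, fw$cache, st, cfg)
  Xs <- matrix(aperm(X, c(3, 2, 1, 4)), nrow = 10 * cfg$T * cfg$C)
  res <- eegstt:::stt_step_cpp(st, Xs, as.integer(y), 10L, cfg$T, cfg$C,
                               cfg$H, cfg$L, 0, TRUE, 99)
  expect_lt(abs(ce$loss - res$loss), 1e-12)
  expect_lt(max(abs(flatten_params(gr) - flatten_params(res$grads))), 1e-12)
})

test_that("spatial encoder is channel-permutation equivariant iff E_SPos is off", {
  cfg <- small_config(C = 5, T = 3, D = 8, L = 2, H = 2)
  st <- init_model_state(cfg, seed = 7)
  set.seed(8)
  win <- array(rnorm(cfg$T * cfg$C * cfg$F), c(cfg$T, cfg$C, cfg$F))
  perm <- c(3, 1, 5, 2, 4)

  st0 <- st; st0$E_SPos[] <- 0
  enc <- spatial_encode(win, st0, cfg)
  enc_perm <- spatial_encode(win[, perm, , drop = FALSE], st0, cfg)
  expect_lt(max(abs(enc[, perm, ] - enc_perm)), 1e-5)

  # with the sinusoidal table, equivariance must break
  enc1 <- spatial_encode(win, st, cfg)
  enc1_perm <- spatial_encode(win[, perm, , drop = FALSE], st, cfg)
  expect_gt(max(abs(enc1[, perm, ] - enc1_perm)), 1e-3)

  # identical frames encode identically (frames processed independently)
  win2 <- win
  win2[2, , ] <- win2[1, , ]
  enc2 <- spatial_encode(win2, st, cfg)
  expect_equal(enc2[1, , ], enc2[2, , ], tolerance = 1e-12)
  expect_equal(dim(enc2), c(cfg$T, cfg$C, cfg$D))
})

test_that("temporal encoder adds its position table and is order sensitive", {
  cfg <- small_config(C = 4, T = 6, D = 8, L = 2, H = 2)
  st <- init_model_state(cfg, seed = 9)
  x <- matrix(rnorm(cfg$T * cfg$D), cfg$T)

  st0 <- st
  for (l in seq_len(cfg$L)) {
    for (nm in c("Wq", "Wk", "Wv", "Wo", "W1", "W2")) {
      st0$temporal[[l]][[nm]][] <- 0
    }
  }
  expect_equal(temporal_encode(x, st0, cfg), x + st0$E_TPos,
               tolerance = 1e-12)

  out_fwd <- temporal_encode(x, st, cfg)
  out_rev <- temporal_encode(x[cfg$T:1, ], st, cfg)
  expect_gt(max(abs(out_fwd - out_rev[cfg$T:1, ])), 1e-6)
  expect_equal(dim(out_fwd), c(cfg$T, cfg$D))
})

test_that("forward pass logits obey shape, softmax and batch independence", {
  cfg <- stt_config(C = 8, K = 3, T = 10, F = 5, D = 32, L = 2, H = 8,
                    mlp_ratio = 2, dropout = 0.1)
  st <- init_model_state(cfg, seed = 10)
  set.seed(11)
  X <- array(rnorm(12 * 10 * 8 * 5), c(12, 10, 8, 5))
  logits <- stt_logits(st, cfg, X)
  expect_equal(dim(logits), c(12L, 3L))
  sm <- exp(logits) / rowSums(exp(logits))
  expect_lt(max(abs(rowSums(sm) - 1)), 1e-6)

  # duplicating a window duplicates its logits row exactly
  X2 <- array(0, c(13, 10, 8, 5))
  X2[1:12, , , ] <- X
  X2[13, , , ] <- X[4, , , ]
  logits2 <- stt_logits(st, cfg, X2)
  expect_equal(logits2[13, ], logits2[4, ], tolerance = 1e-12)
  expect_equal(logits2[1:12, ], logits, tolerance = 1e-12)
})

test_that("cross-entropy matches the literal double sum", {
  expect_equal(cross_entropy(matrix(0, 5, 3), rep(2L, 5)), log(3),
               tolerance = 1e-9)
  # near-certain correct prediction drives the loss to zero
  big <- matrix(c(50, 0, 0), 1)
  expect_lt(cross_entropy(big, 1L), 1e-8)
  set.seed(12)
  logits <- matrix(rnorm(12), 4, 3)
  y <- c(1L, 3L, 2L, 2L)
  expect_equal(cross_entropy(logits, y), oracle_cross_entropy(logits, y),
               tolerance = 1e-8)
  expect_error(cross_entropy(logits, c(1L, 2L, 4L, 1L)), "labels")
})

test_that("parameter count scales linearly in encoder depth", {
  n_at <- function(L) {
    n_parameters(init_model_state(
      stt_config(C = 6, K = 3, T = 8, F = 5, D = 16, L = L, H = 4), seed = 1))
  }
  n1 <- n_at(1); n2 <- n_at(2); n3 <- n_at(3)
  expect_equal(n3 - n2, n2 - n1)
  expect_identical(n_at(2), n_at(2))
})
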