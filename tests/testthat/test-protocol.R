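make_sched <- function(n, labels) {
  trial_schedule(sprintf("t%02d", seq_len(n)), seq_len(n) - 1, seq_len(n),
                 labels)
}

test_that("trial-prefix splits are exact for both session layouts", {
  # 15-trial three-class session, 9/6: trials 1-9 train, 10-15 test
  s15 <- make_sched(15, rep(c("neg", "neu", "pos"), 5))
  sp <- make_split(s15, 9, 6)
  expect_equal(sp$train_ids, sprintf("t%02d", 1:9))
  expect_equal(sp$test_ids, sprintf("t%02d", 10:15))

  # 8-trial two-class session, 6/2
  s8 <- make_sched(8, rep(c("low", "high"), 4))
  sp2 <- make_split(s8, 6, 2)
  expect_equal(sp2$train_ids, sprintf("t%02d", 1:6))
  expect_equal(sp2$test_ids, sprintf("t%02d", 7:8))

  expect_error(make_split(s15, 0, 15), "non-empty")
  expect_error(make_split(s15, 8, 6), "does not match")
  expect_error(make_split(make_sched(6, c("a", "a", "a", "a", "b", "b")),
                          4, 2), "not class-balanced")
})

test_that("metrics match hand-computed accuracy, macro-F1 and confusion", {
  truth <- rep(c("a", "b", "c"), each = 20)
  m <- classification_metrics(truth, truth)
  expect_equal(m$accuracy, 100)
  expect_equal(m$f1_macro, 100)
  expect_equal(unname(diag(m$confusion)), rep(20L, 3))

  # everything predicted as one class on a balanced 3-class set:
  # accuracy 33.33; per-class F1 = (0.5, 0, 0) -> macro 16.67
  m2 <- classification_metrics(truth, rep("a", 60))
  expect_equal(m2$accuracy, 100 / 3, tolerance = 1e-9)
  expect_equal(m2$f1_macro, 100 / 6, tolerance = 1e-9)
  expect_equal(unname(m2$per_class_f1), c(50, 0, 0))

  # confusion rows always sum to the per-class test counts
  set.seed(20)
  pred <- sample(c("a", "b", "c"), 60, replace = TRUE)
  m3 <- classification_metrics(truth, pred)
  expect_equal(unname(rowSums(m3$confusion)), rep(20L, 3))
})

test_that("the learning-rate schedule decays exponentially from 2e-4", {
  cfg <- train_config()
  expect_equal(lr_at_epoch(cfg, 0), 2e-4)
  expect_equal(lr_at_epoch(cfg, 10), 2e-4 * 0.98^10, tolerance = 1e-12)
  expect_equal(lr_at_epoch(cfg, 10), 1.634e-4, tolerance = 1e-3)
})

test_that("training is deterministic and rejects degenerate label sets", {
  w <- separable_windows(n_per_class = 8, K = 2, C = 4)
  cfg <- train_config(epochs = 3, batch_size = 8, rng_seed = 42)
  mcfg <- small_config(C = 4, K = 2, T = 10, D = 8, L = 1, H = 2,
                       dropout = 0.1)
  f1 <- train_model(w, cfg, mcfg)
  f2 <- train_model(w, cfg, mcfg)
  expect_identical(f1$loss_trace, f2$loss_trace)
  expect_identical(flatten_params(f1$state), flatten_params(f2$state))

  single <- w
  single$labels <- rep("c1", length(single$labels))
  expect_error(train_model(single, cfg, NULL), "single class")
})

test_that("training loss decreases on linearly separable features", {
  w <- separable_windows(n_per_class = 16, K = 2, C = 4, gap = 3)
  cfg <- train_config(epochs = 5, batch_size = 32, rng_seed = 1)
  mcfg <- small_config(C = 4, K = 2, T = 10, D = 8, L = 1, H = 2)
  fit <- train_model(apply_normalizer(w, fit_normalizer(w)), cfg, mcfg)
  viol <- sum(diff(fit$loss_trace) > 0)
  expect_lte(viol, 1)
  expect_lt(fit$loss_trace[5], fit$loss_trace[1])
})

test_that("evaluation validates labels and preserves counts", {
  w <- separable_windows(n_per_class = 10, K = 2, C = 4, gap = 3)
  cfg <- train_config(epochs = 4, batch_size = 20, rng_seed = 2)
  mcfg <- small_config(C = 4, K = 2, T = 10, D = 8, L = 1, H = 2)
  norm <- fit_normalizer(w)
  fit <- train_model(apply_normalizer(w, norm), cfg, mcfg)
  m <- evaluate_model(fit, apply_normalizer(w, norm))
  expect_equal(sum(m$confusion), 20)
  expect_equal(unname(rowSums(m$confusion)), c(10L, 10L))

  bad <- w
  bad$labels[1] <- "mystery"
  expect_error(evaluate_model(fit, bad), "outside the training label set")
})

protocol_fixture <- function(n_sessions = 2, effect = 1, seed = 100) {
  lapply(seq_len(n_sessions), function(s) {
    session_to_features(make_test_session(effect = effect,
                                          trial_duration = 12,
                                          seed = seed + s))
  })
}

test_that("the subject-dependent protocol aggregates per-session metrics", {
  sessions <- protocol_fixture(2)
  cfg <- train_config(epochs = 3, rng_seed = 5)
  res <- run_subject_dependent(sessions, 9, 6, train_cfg = cfg,
                               D = 16, L = 1, H = 4)
  expect_length(res$per_session, 2L)
  acc <- vapply(res$per_session, `[[`, numeric(1), "accuracy")
  expect_equal(res$accuracy_mean, mean(acc), tolerance = 1e-9)
  expect_true(res$accuracy_mean >= min(acc) && res$accuracy_mean <= max(acc))

  one <- run_subject_dependent(sessions[1], 9, 6, train_cfg = cfg,
                               D = 16, L = 1, H = 4)
  expect_equal(one$accuracy_mean, one$per_session[[1]]$accuracy)
  expect_equal(one$accuracy_sd, 0)
})

test_that("normalizer and weights are functions of training trials only", {
  sessions <- protocol_fixture(1)
  cfg <- train_config(epochs = 2, rng_seed = 9)
  res1 <- run_subject_dependent(sessions, 9, 6, train_cfg = cfg,
                                D = 16, L = 1, H = 4)

  # corrupt the test trials' features; training artifacts must not change
  corrupted <- sessions
  test_ids <- sprintf("t%02d", 10:15)
  rows <- corrupted[[1]]$features$trial_ids %in% test_ids
  corrupted[[1]]$features$values[rows, , ] <-
    corrupted[[1]]$features$values[rows, , ] * 10 + 3
  res2 <- run_subject_dependent(corrupted, 9, 6, train_cfg = cfg,
                                D = 16, L = 1, H = 4)
  expect_identical(flatten_params(res1$fits[[1]]$state),
                   flatten_params(res2$fits[[1]]$state))
  expect_identical(res1$fits[[1]]$normalizer$mean,
                   res2$fits[[1]]$normalizer$mean)
  expect_identical(res1$fits[[1]]$normalizer$sd,
                   res2$fits[[1]]$normalizer$sd)
})
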