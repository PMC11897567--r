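test_that("differential entropy closed form behaves as the Gaussian entropy", {
  expect_equal(de_from_power(1 / (2 * pi * exp(1))), 0)
  expect_equal(de_from_power(1), 0.5 * log(2 * pi * exp(1)), tolerance = 1e-12)
  # quadrupling the variance adds exactly log 2
  s <- c(0.3, 1, 7)
  expect_equal(de_from_power(4 * s) - de_from_power(s), rep(log(2), 3),
               tolerance = 1e-12)
  expect_error(de_from_power(-1), "non-negative")
  # floor keeps silent channels finite
  expect_true(is.finite(de_from_power(0)))
})

test_that("band power matches time-domain variance for a pure tone", {
  fs <- 128
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  epoch <- rbind(sin(2 * pi * 10 * t), 0.5 * sin(2 * pi * 10 * t))
  bp <- band_power(epoch, fs, band_spec("alpha", 8, 13))
  expect_lt(abs(bp[1] - 0.5) / 0.5, 0.10)
  expect_lt(abs(bp[2] - 0.125) / 0.125, 0.10)
  expect_equal(band_power(matrix(0, 2, fs), fs, band_spec("alpha", 8, 13)),
               c(0, 0))
  expect_error(band_power(epoch, fs, band_spec("hf", 30, 70)), "Nyquist")
})

test_that("band power of white noise follows flat-spectrum proportionality", {
  # fs 200: alpha 8-13 Hz covers 6 of 200 1-Hz bins two-sided -> expected
  # fraction 12/200 of total unit power
  fs <- 200
  set.seed(4)
  est <- mean(replicate(100, {
    band_power(matrix(rnorm(fs), 1), fs, band_spec("alpha", 8, 13))
  }))
  expect_lt(abs(est - 12 / 200) / (12 / 200), 0.20)
})

test_that("extract_de has the right shape, ordering and scaling identity", {
  set.seed(5)
  ep <- epoch_array(array(rnorm(1 * 2 * 128), c(1, 2, 128)), 128,
                    "a", "t1")
  de <- extract_de(ep)
  expect_equal(dim(de$values), c(1L, 2L, 5L))

  # pure alpha-band noise: alpha DE dominates every other band
  spec <- synthetic_spec(list(class_band_profile("x", {
    m <- matrix(0, 2, 5); m[, 3] <- 3; m
  }), class_band_profile("y", matrix(1, 2, 5))), n_channels = 2,
  trial_duration = 8, broadband_noise_sigma = 0)
  x <- synthesize_trial(spec$class_profiles[[1]], spec, 1)
  ep2 <- segment_epochs(raw_recording(x, 128),
                        trial_schedule("t", 0, 8, "a"), 1)
  de2 <- extract_de(ep2)
  mean_by_band <- apply(de2$values, 3L, mean)
  expect_equal(which.max(mean_by_band), 3L)
  expect_true(all(mean_by_band[3] > mean_by_band[-3]))

  # doubling amplitude raises every DE by exactly log 2
  ep_x2 <- epoch_array(ep$data * 2, 128, "a", "t1")
  expect_equal(extract_de(ep_x2)$values - de$values,
               array(log(2), dim(de$values)), tolerance = 1e-9)
})

test_that("windowing counts, boundaries and trial purity are exact", {
  mk_de <- function(frames_per_trial) {
    n <- sum(frames_per_trial)
    ids <- rep(paste0("t", seq_along(frames_per_trial)), frames_per_trial)
    de_features(array(seq_len(n * 2 * 5), c(n, 2, 5)),
                labels = rep("a", n), trial_ids = ids)
  }
  # single 185-frame trial, T = 10, stride 1 -> 176 windows
  expect_equal(dim(window_features(mk_de(185), 10, 1)$values)[1L], 176L)
  # n == T -> exactly one window
  expect_equal(dim(window_features(mk_de(10), 10, 1)$values)[1L], 1L)
  # two 12-frame trials -> 3 + 3 windows, none mixing trials
  w <- window_features(mk_de(c(12, 12)), 10, 1)
  expect_equal(dim(w$values)[1L], 6L)
  expect_equal(w$trial_ids, rep(c("t1", "t2"), each = 3))
  # frames inside one window are consecutive rows of one trial
  de <- mk_de(c(12, 12))
  first_frame_vals <- w$values[4, 1, , ]   # first window of t2 starts at frame 13
  expect_equal(as.vector(first_frame_vals), as.vector(de$values[13, , ]))
  # trials shorter than T contribute nothing
  expect_equal(dim(window_features(mk_de(c(5, 12)), 10, 1)$values)[1L], 3L)
})

test_that("window count conservation holds across random trial layouts", {
  set.seed(6)
  for (rep_i in 1:5) {
    frames <- sample(3:40, 6, replace = TRUE)
    stride <- sample(1:3, 1)
    Tlen <- sample(4:12, 1)
    ids <- rep(paste0("t", 1:6), frames)
    de <- de_features(array(rnorm(sum(frames) * 2 * 5),
                            c(sum(frames), 2, 5)),
                      rep("a", sum(frames)), ids)
    w <- window_features(de, Tlen, stride)
    expected <- sum(pmax(floor((frames - Tlen) / stride) + 1, 0))
    expect_equal(dim(w$values)[1L], expected)
  }
})

test_that("normalization z-scores the training set and ignores test data", {
  w <- random_windows(30, seed = 7)
  norm <- fit_normalizer(w)
  z <- apply_normalizer(w, norm)
  d <- dim(z$values)
  flat <- matrix(z$values, nrow = d[1] * d[2])
  expect_lt(max(abs(colMeans(flat))), 1e-8)
  expect_lt(max(abs(apply(flat, 2, sd) - 1)), 1e-6)

  # constant cell -> floored sd, all-zero output
  wc <- w
  wc$values[, , 1, 1] <- 5
  zc <- apply_normalizer(wc, fit_normalizer(wc))
  expect_equal(max(abs(zc$values[, , 1, 1])), 0)

  # a mean shift in test data survives standardization with train stats
  shift <- w
  shift$values <- shift$values + 2
  zs <- apply_normalizer(shift, norm)
  expect_equal(zs$values - z$values, 2 / array(rep(norm$sd, each = d[1] * d[2]), d),
               tolerance = 1e-10)

  # normalizer depends on the training partition only
  norm2 <- fit_normalizer(w)
  expect_identical(norm$mean, norm2$mean)
  expect_error(fit_normalizer(windowed_features(array(0, c(0, 2, 2, 2)),
                                                character(0), character(0))),
               "empty")
})
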