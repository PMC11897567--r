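sine_recording <- function(freq, fs, dur = 4, channels = 1, amp = 1) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  data <- matrix(rep(amp * sin(2 * pi * freq * t), channels),
                 nrow = channels, byrow = TRUE)
  raw_recording(data, fs)
}

test_that("resampling preserves a pure tone and durations", {
  rec <- sine_recording(10, 512, dur = 4)
  out <- resample_recording(rec, 128)
  expect_equal(out$fs, 128)
  expect_equal(ncol(out$data), ncol(rec$data) / 4)
  t <- seq_len(ncol(out$data)) - 1
  ref <- sin(2 * pi * 10 * t / 128)
  core <- 30:(length(ref) - 30)   # ignore filter edge transients
  expect_gt(cor(out$data[1, core], ref[core]), 0.999)

  expect_identical(resample_recording(rec, 512), rec)
  expect_error(resample_recording(rec, 1024), "upsampling")
})

test_that("re-referencing subtracts the mastoid mean and removes common mode", {
  set.seed(1)
  data <- matrix(rnorm(4 * 100), 4, 100)
  rec <- raw_recording(data, 100, c("F1", "F2", "M1", "M2"))
  out <- rereference(rec, c("M1", "M2"))
  ref <- (data[3, ] + data[4, ]) / 2
  expect_equal(out$data[1, ], data[1, ] - ref)
  expect_equal(out$data[3, ], data[3, ] - ref)

  # constant offset on all channels vanishes
  rec2 <- raw_recording(matrix(5, 3, 10), 10, c("a", "b", "M1"))
  expect_equal(max(abs(rereference(rec2, "M1")$data)), 0)

  # idempotent when re-using retained reference channels
  twice <- rereference(out, c("M1", "M2"))
  expect_equal(twice$data, out$data, tolerance = 1e-12)

  expect_error(rereference(rec, "Mx"), "unknown reference")
})

test_that("zero-phase FIR band-pass passes the band and rejects outside it", {
  rec <- sine_recording(10, 256, dur = 6)
  out <- bandpass_fir(rec, 4, 47)
  core <- 512:(ncol(out$data) - 512)
  amp <- max(abs(out$data[1, core]))
  expect_gt(amp, 10^(-1 / 20))          # within 1 dB of unity
  expect_lt(amp, 10^(1 / 20))

  rec60 <- sine_recording(60, 256, dur = 6)
  out60 <- bandpass_fir(rec60, 4, 47)
  expect_lt(max(abs(out60$data[1, core])), 0.1)

  expect_equal(ncol(out$data), ncol(rec$data))
  expect_error(bandpass_fir(rec, 0, 47), "band edges")
  expect_error(bandpass_fir(rec, 4, 200), "band edges")
})

test_that("band-pass filtering is linear", {
  set.seed(2)
  x <- raw_recording(matrix(rnorm(1024), 1), 128)
  y <- raw_recording(matrix(rnorm(1024), 1), 128)
  z <- raw_recording(2 * x$data + 3 * y$data, 128)
  fx <- bandpass_fir(x, 4, 47)$data
  fy <- bandpass_fir(y, 4, 47)$data
  fz <- bandpass_fir(z, 4, 47)$data
  expect_lt(max(abs(fz - (2 * fx + 3 * fy))) / max(abs(fz)), 1e-9)
})

test_that("epoch segmentation floors durations and never crosses trials", {
  fs <- 100
  # one 10.7 s trial -> 10 epochs
  rec <- raw_recording(matrix(rnorm(2 * 1100), 2), fs)
  sched <- trial_schedule("t1", 0, 10.7, "a")
  ep <- segment_epochs(rec, sched, 1)
  expect_equal(dim(ep$data), c(10L, 2L, 100L))
  expect_equal(unique(ep$labels), "a")

  # trial-unique constants never mix across epochs of different trials
  data <- matrix(0, 1, 500)
  data[1, 1:200] <- 1
  data[1, 201:500] <- 2
  rec2 <- raw_recording(data, fs)
  sched2 <- trial_schedule(c("t1", "t2"), c(0, 2), c(2, 5), c("a", "b"))
  ep2 <- segment_epochs(rec2, sched2, 1)
  expect_equal(dim(ep2$data)[1L], 5L)
  vals <- apply(ep2$data, 1L, function(m) unique(as.vector(m)))
  expect_equal(vals, c(1, 1, 2, 2, 2))
  expect_equal(ep2$trial_ids, c("t1", "t1", "t2", "t2", "t2"))

  # empty schedule -> empty epochs
  ep0 <- segment_epochs(rec, trial_schedule(character(0), numeric(0),
                                            numeric(0), character(0)), 1)
  expect_equal(dim(ep0$data)[1L], 0L)

  expect_error(segment_epochs(rec, trial_schedule("t", 0, 99, "a"), 1),
               "beyond recording")
})

test_that("amplitude rejection drops exactly the offending epochs", {
  set.seed(3)
  data <- array(rnorm(10 * 2 * 50, sd = 10), c(10, 2, 50))
  data[2, 1, 10] <- 150
  data[7, 2, 3] <- -140
  ep <- epoch_array(data, 50, labels = rep("a", 10),
                    trial_ids = rep(c("t1", "t2"), each = 5))
  r <- reject_amplitude(ep, 100)
  expect_equal(r$report$dropped, c(2L, 7L))
  expect_equal(dim(r$epochs$data)[1L], 8L)
  expect_equal(dim(r$epochs$data)[1L] + length(r$report$dropped), 10L)
  expect_equal(as.vector(r$report$per_trial), c(1L, 1L))

  # all quiet -> untouched, empty report
  quiet <- epoch_array(array(rnorm(4 * 2 * 50, sd = 5), c(4, 2, 50)), 50,
                       rep("a", 4), rep("t", 4))
  r2 <- reject_amplitude(quiet, 100)
  expect_equal(r2$epochs$data, quiet$data)
  expect_length(r2$report$dropped, 0L)
})
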