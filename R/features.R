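# Differential-entropy band features.
#
# For a band-limited EEG segment that is approximately Gaussian with
# variance sigma^2, the differential entropy of the band is
#   DE = 1/2 * log(2 * pi * e * sigma^2)   (nats).
# Band variance is estimated per 1-s epoch by a Hann-windowed FFT whose
# squared magnitudes are summed over the band's bins with window-energy
# (Parseval-consistent) normalization, i.e. a one-frame short-time Fourier
# transform at the epoch length.

#' Per-second DE feature array
#'
#' @param values numeric array `frames x channels x bands`, in nats.
#' @param labels class label per frame.
#' @param trial_ids source trial per frame; frame order preserves
#'   within-trial time order.
#' @param band_names,channel_names optional axis labels.
#' @return An object of class `de_features`.
#' @export
de_features <- function(values, labels, trial_ids,
                        band_names = NULL, channel_names = NULL) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  n <- dim(values)[1L]
  if (length(labels) != n || length(trial_ids) != n) {
    stop("labels and trial_ids must have one entry per frame")
  }
  if (any(!is.finite(values))) stop("DE values must be finite")
  structure(list(values = values, labels = as.character(labels),
                 trial_ids = as.character(trial_ids),
                 band_names = band_names, channel_names = channel_names),
            class = "de_features")
}

#' @export
print.de_features <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<de_features> %d frames x %d channels x %d bands (%d trials)\n",
              d[1L], d[2L], d[3L], length(unique(x$trial_ids))))
  invisible(x)
}

#' Windowed DE feature tensor
#'
#' Overlapping sequences of `T` consecutive frames from a single trial;
#' the window label is its trial's label.
#'
#' @param values numeric array `windows x T x channels x bands`.
#' @param labels class label per window.
#' @param trial_ids source trial per window.
#' @return An object of class `windowed_features`.
#' @export
windowed_features <- function(values, labels, trial_ids) {
  stopifnot(is.array(values), length(dim(values)) == 4L)
  n <- dim(values)[1L]
  if (length(labels) != n || length(trial_ids) != n) {
    stop("labels and trial_ids must have one entry per window")
  }
  structure(list(values = values, labels = as.character(labels),
                 trial_ids = as.character(trial_ids)),
            class = "windowed_features")
}

#' @export
print.windowed_features <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<windowed_features> %d windows x T=%d x %d channels x %d bands\n",
              d[1L], d[2L], d[3L], d[4L]))
  invisible(x)
}

#' Band power of one epoch
#'
#' Hann-windowed FFT power summed over the (two-sided) frequency bins whose
#' folded frequency lies in `[low, high]`, normalized by the window energy so
#' that band-limited unit-variance noise yields an expected value of 1.
#'
#' @param epoch numeric matrix `channels x samples`, microvolts.
#' @param fs sampling rate, Hz.
#' @param band a [band_spec] with `high < fs/2`.
#' @return numeric vector, per-channel band power in microvolts squared.
#' @export
band_power <- function(epoch, fs, band) {
  epoch <- as.matrix(epoch)
  if (band$high >= fs / 2) {
    stop("band ", band$name, " upper edge ", band$high,
         " Hz is not below Nyquist ", fs / 2, " Hz")
  }
  S <- ncol(epoch)
  w <- 0.5 * (1 - cos(2 * pi * seq(0L, S - 1L) / (S - 1L)))
  xw <- t(epoch) * w                      # samples x channels
  X <- mvfft(xw)
  P <- (Mod(X)^2) / (S * sum(w^2))   # Parseval: sum over all bins = var
  freqs <- (seq_len(S) - 1L) * fs / S
  folded <- pmin(freqs, fs - freqs)
  sel <- folded >= band$low & folded <= band$high
  colSums(P[sel, , drop = FALSE])
}

#' Differential entropy from band variance
#'
#' Closed form for a Gaussian band: `0.5 * log(2 * pi * e * sigma2)` in
#' nats, with `sigma2` floored at `epsilon` to keep the value finite on
#' silent channels.
#'
#' @param sigma2 band variance(s), microvolts squared; non-negative.
#' @param epsilon variance floor (default 1e-12).
#' @return differential entropy in nats, same shape as `sigma2`.
#' @export
de_from_power <- function(sigma2, epsilon = 1e-12) {
  if (any(sigma2 < 0)) stop("sigma2 must be non-negative")
  0.5 * log(2 * pi * exp(1) * pmax(sigma2, epsilon))
}

#' Extract DE features from labeled epochs
#'
#' @param epochs an [epoch_array] of 1-s (or fixed-length) epochs.
#' @param bands list of [band_spec] (default the five EEG rhythms).
#' @param epsilon variance floor passed to [de_from_power].
#' @return A [de_features] array `frames x channels x bands`.
#' @export
extract_de <- function(epochs, bands = default_bands(), epsilon = 1e-12) {
  stopifnot(inherits(epochs, "epoch_array"))
  d <- dim(epochs$data)
  n <- d[1L]; C <- d[2L]; F <- length(bands)
  vals <- array(0, c(n, C, F))
  for (i in seq_len(n)) {
    ep <- epochs$data[i, , , drop = TRUE]
    if (C == 1L) ep <- matrix(ep, nrow = 1L)
    for (f in seq_len(F)) {
      vals[i, , f] <- de_from_power(band_power(ep, epochs$fs, bands[[f]]),
                                    epsilon)
    }
  }
  de_features(vals, epochs$labels, epochs$trial_ids,
              band_names = band_names(bands),
              channel_names = epochs$channel_names)
}

#' Slide overlapping windows of T frames over each trial
#'
#' Emits, per trial with `n` frames, `floor((n - T) / stride) + 1` windows
#' (none if `n < T`) of consecutive frames. Windows never cross trial
#' boundaries; each window inherits its trial's label.
#'
#' @param de a [de_features] array.
#' @param T window length in frames (default 10).
#' @param stride hop between window starts, frames (default 1).
#' @return A [windowed_features] tensor `windows x T x channels x bands`.
#' @export
window_features <- function(de, T = 10, stride = 1) {
  stopifnot(inherits(de, "de_features"), T >= 1, stride >= 1)
  d <- dim(de$values)
  C <- d[2L]; F <- d[3L]
  trial_order <- unique(de$trial_ids)
  starts_list <- list(); labels <- character(0); ids <- character(0)
  frame_idx <- list()
  for (tid in trial_order) {
    rows <- which(de$trial_ids == tid)
    n <- length(rows)
    if (n < T) next
    starts <- seq(1L, n - T + 1L, by = stride)
    for (s in starts) {
      frame_idx[[length(frame_idx) + 1L]] <- rows[s:(s + T - 1L)]
    }
    labels <- c(labels, rep(de$labels[rows[1L]], length(starts)))
    ids <- c(ids, rep(tid, length(starts)))
  }
  nw <- length(frame_idx)
  vals <- array(0, c(nw, T, C, F))
  for (i in seq_len(nw)) vals[i, , , ] <- de$values[frame_idx[[i]], , , drop = FALSE]
  windowed_features(vals, labels, ids)
}

#' Fit a per-cell z-scoring normalizer on training windows
#'
#' Mean and standard deviation are computed per (channel, band) cell over
#' every frame of every training window. Standard deviations below `floor`
#' are replaced by 1 so constant cells map to zero.
#'
#' @param train a non-empty [windowed_features] training set.
#' @param floor minimum admissible standard deviation.
#' @return An object of class `de_normalizer` with `mean` and `sd`
#'   (`channels x bands` matrices) and a `fitted_on` fingerprint.
#' @export
fit_normalizer <- function(train, floor = 1e-8) {
  stopifnot(inherits(train, "windowed_features"))
  d <- dim(train$values)
  if (d[1L] == 0L) stop("cannot fit a normalizer on an empty training set")
  flat <- matrix(train$values, nrow = d[1L] * d[2L])   # (win*T) x (C*F)
  mu <- colMeans(flat)
  s <- apply(flat, 2L, sd)
  s[!is.finite(s) | s < floor] <- 1
  structure(list(mean = matrix(mu, d[3L], d[4L]),
                 sd = matrix(s, d[3L], d[4L]),
                 fitted_on = sprintf("%d windows x T=%d", d[1L], d[2L])),
            class = "de_normalizer")
}

#' Apply a fitted normalizer
#'
#' @param x a [windowed_features] tensor.
#' @param norm a [de_normalizer] fitted on the training partition.
#' @return A standardized [windowed_features] tensor.
#' @export
apply_normalizer <- function(x, norm) {
  stopifnot(inherits(x, "windowed_features"), inherits(norm, "de_normalizer"))
  d <- dim(x$values)
  if (d[3L] != nrow(norm$mean) || d[4L] != ncol(norm$mean)) {
    stop("normalizer shape ", nrow(norm$mean), " x ", ncol(norm$mean),
         " does not match features ", d[3L], " x ", d[4L])
  }
  flat <- matrix(x$values, nrow = d[1L] * d[2L])
  flat <- sweep(flat, 2L, as.vector(norm$mean), "-")
  flat <- sweep(flat, 2L, as.vector(norm$sd), "/")
  windowed_features(array(flat, d), x$labels, x$trial_ids)
}

#' Full feature path from epochs to normalized windows
#'
#' @param epochs an [epoch_array].
#' @param bands band set.
#' @param T,stride windowing parameters (see [window_features]).
#' @return A [windowed_features] tensor (unnormalized).
#' @export
epochs_to_windows <- function(epochs, bands = default_bands(), T = 10, stride = 1) {
  window_features(extract_de(epochs, bands), T = T, stride = stride)
}
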