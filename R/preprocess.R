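# Preprocessing: resample -> re-reference -> zero-phase FIR band-pass ->
# 1-s epoching -> amplitude-threshold artifact rejection.

#' Resample a recording to a lower rate
#'
#' Zero-phase anti-alias low-pass FIR (forward-backward, cutoff at 90% of
#' the new Nyquist) followed by decimation -- direct subsampling when the
#' rate ratio is an integer, linear interpolation at the new sample times
#' otherwise. Zero-phase filtering keeps trial onsets aligned across rates.
#' Upsampling is not supported.
#'
#' @param rec a [raw_recording].
#' @param target_fs desired sampling rate, Hz; must not exceed `rec$fs`.
#' @return A [raw_recording] at `target_fs`; identity when
#'   `target_fs == rec$fs`.
#' @export
resample_recording <- function(rec, target_fs) {
  stopifnot(inherits(rec, "raw_recording"))
  if (target_fs > rec$fs) {
    stop("upsampling not supported: target_fs ", target_fs, " > fs ", rec$fs)
  }
  if (target_fs == rec$fs) return(rec)
  n <- ncol(rec$data)
  n_taps <- max(16L, min(128L, n %/% 3L * 2L))
  h <- signal::fir1(n_taps, 0.9 * target_fs / rec$fs, type = "low")
  filtered <- t(apply(rec$data, 1L, function(x) signal::filtfilt(h, x)))
  ratio <- rec$fs / target_fs
  n_out <- floor(n * target_fs / rec$fs)
  if (abs(ratio - round(ratio)) < 1e-9) {
    idx <- seq(1L, by = as.integer(round(ratio)), length.out = n_out)
    out <- filtered[, idx, drop = FALSE]
  } else {
    t_new <- (seq_len(n_out) - 1) / target_fs
    t_old <- (seq_len(n) - 1) / rec$fs
    out <- t(apply(filtered, 1L, function(x) {
      stats::approx(t_old, x, xout = t_new)$y
    }))
  }
  raw_recording(out, target_fs, rec$channel_names,
                reference_note = rec$reference_note)
}

#' Re-reference to the mean of selected channels
#'
#' Subtracts, samplewise, the mean of the reference channels (computed before
#' subtraction) from every channel -- e.g. bilateral mastoids M1/M2.
#'
#' @param rec a [raw_recording].
#' @param ref_channels channel names to average as the new reference.
#' @return A [raw_recording] with updated `reference_note`.
#' @export
rereference <- function(rec, ref_channels) {
  stopifnot(inherits(rec, "raw_recording"))
  missing_ch <- setdiff(ref_channels, rec$channel_names)
  if (length(missing_ch)) {
    stop("unknown reference channel(s): ", paste(missing_ch, collapse = ", "))
  }
  ref <- colMeans(rec$data[ref_channels, , drop = FALSE])
  out <- sweep(rec$data, 2L, ref, "-")
  raw_recording(out, rec$fs, rec$channel_names,
                reference_note = paste0("mean(", paste(ref_channels, collapse = ","), ")"))
}

#' Zero-phase FIR band-pass filter
#'
#' Hamming-window FIR design (`signal::fir1`) applied forward-backward
#' (`signal::filtfilt`), giving zero phase distortion and squared magnitude
#' response. Output length equals input length.
#'
#' @param rec a [raw_recording].
#' @param low,high band edges in Hz, `0 < low < high < fs/2`.
#' @param n_taps filter order; default scales with `fs/low` so the
#'   transition band stays narrow relative to the low edge.
#' @return A filtered [raw_recording].
#' @export
bandpass_fir <- function(rec, low, high, n_taps = NULL) {
  stopifnot(inherits(rec, "raw_recording"))
  if (!(low > 0 && low < high && high < rec$fs / 2)) {
    stop("band edges must satisfy 0 < low < high < fs/2 = ", rec$fs / 2)
  }
  if (is.null(n_taps)) {
    n_taps <- min(2L * ceiling(3 * rec$fs / low), ncol(rec$data) %/% 3L * 2L)
    n_taps <- max(n_taps, 16L)
  }
  h <- signal::fir1(n_taps, c(low, high) / (rec$fs / 2), type = "pass")
  out <- t(apply(rec$data, 1L, function(x) signal::filtfilt(h, x)))
  raw_recording(out, rec$fs, rec$channel_names, rec$reference_note)
}

#' Cut a recording into fixed-length labeled epochs
#'
#' Each trial of the schedule is cut into `floor(duration / epoch_len)`
#' non-overlapping epochs inheriting the trial label; trailing partial
#' epochs are discarded and epochs never span trial boundaries.
#'
#' @param rec a [raw_recording].
#' @param schedule a [trial_schedule] lying within the recording.
#' @param epoch_len epoch length in seconds (default 1).
#' @return An [epoch_array].
#' @export
segment_epochs <- function(rec, schedule, epoch_len = 1) {
  stopifnot(inherits(rec, "raw_recording"))
  validate_schedule(schedule)
  if (epoch_len <= 0) stop("epoch_len must be positive")
  spe <- round(rec$fs * epoch_len)
  C <- nrow(rec$data)
  if (nrow(schedule) == 0L) {
    return(epoch_array(array(0, c(0L, C, spe)), rec$fs, character(0),
                       character(0), rec$channel_names))
  }
  if (any(schedule$offset > rec_duration(rec) + 1e-9)) {
    bad <- schedule$trial_id[schedule$offset > rec_duration(rec) + 1e-9]
    stop("schedule extends beyond recording for trial(s): ",
         paste(bad, collapse = ", "))
  }
  pieces <- list(); labels <- character(0); ids <- character(0)
  for (r in seq_len(nrow(schedule))) {
    s0 <- round(schedule$onset[r] * rec$fs)
    s1 <- round(schedule$offset[r] * rec$fs)
    n_ep <- (s1 - s0) %/% spe
    if (n_ep < 1L) next
    for (e in seq_len(n_ep)) {
      idx <- (s0 + (e - 1L) * spe + 1L):(s0 + e * spe)
      pieces[[length(pieces) + 1L]] <- rec$data[, idx, drop = FALSE]
    }
    labels <- c(labels, rep(schedule$label[r], n_ep))
    ids <- c(ids, rep(schedule$trial_id[r], n_ep))
  }
  n <- length(pieces)
  data <- array(0, c(n, C, spe))
  for (i in seq_len(n)) data[i, , ] <- pieces[[i]]
  epoch_array(data, rec$fs, labels, ids, rec$channel_names)
}

#' Reject epochs exceeding an amplitude threshold
#'
#' Drops every epoch in which any channel sample exceeds `threshold`
#' microvolts in absolute value (the +-100 microvolt convention for
#' non-physiological signals), preserving label/trial alignment for the
#' survivors.
#'
#' @param epochs an [epoch_array].
#' @param threshold rejection threshold in microvolts, positive.
#' @return list with `epochs` (surviving [epoch_array]) and `report`
#'   (list with `dropped` epoch indices and `per_trial` drop counts).
#' @export
reject_amplitude <- function(epochs, threshold = 100) {
  stopifnot(inherits(epochs, "epoch_array"), threshold > 0)
  n <- dim(epochs$data)[1L]
  if (n == 0L) return(list(epochs = epochs,
                           report = list(dropped = integer(0),
                                         per_trial = table(character(0)))))
  mx <- apply(abs(epochs$data), 1L, max)
  dropped <- which(mx > threshold)
  keep <- setdiff(seq_len(n), dropped)
  out <- epoch_array(epochs$data[keep, , , drop = FALSE], epochs$fs,
                     epochs$labels[keep], epochs$trial_ids[keep],
                     epochs$channel_names)
  list(epochs = out,
       report = list(dropped = dropped,
                     per_trial = table(epochs$trial_ids[dropped])))
}

#' Standard preprocessing chain
#'
#' Convenience wrapper: resample, optionally re-reference, band-pass filter,
#' epoch, and reject high-amplitude epochs, in that order.
#'
#' @param rec a [raw_recording].
#' @param schedule a [trial_schedule].
#' @param target_fs resampling target, Hz (default 128).
#' @param ref_channels reference channel names or `NULL` to skip.
#' @param band numeric length-2 band-pass edges in Hz or `NULL` to skip
#'   (default `c(4, 47)`).
#' @param reject_uv amplitude rejection threshold in microvolts or `NULL`.
#' @param epoch_len epoch length, seconds.
#' @return list with `epochs` ([epoch_array]) and `rejection` report.
#' @export
preprocess_recording <- function(rec, schedule, target_fs = 128,
                                 ref_channels = NULL, band = c(4, 47),
                                 reject_uv = 100, epoch_len = 1) {
  rec <- resample_recording(rec, target_fs)
  if (!is.null(ref_channels)) rec <- rereference(rec, ref_channels)
  if (!is.null(band)) rec <- bandpass_fir(rec, band[1L], band[2L])
  ep <- segment_epochs(rec, schedule, epoch_len)
  if (is.null(reject_uv)) {
    list(epochs = ep, rejection = NULL)
  } else {
    r <- reject_amplitude(ep, reject_uv)
    list(epochs = r$epochs, rejection = r$report)
  }
}
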