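#' Continuous multichannel EEG recording
#'
#' Container for a continuous recording: a channels x samples matrix in
#' microvolts plus its sampling rate and channel names.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz, positive scalar.
#' @param channel_names unique channel labels, one per row of `data`.
#' @param reference_note free-text description of the current reference.
#' @return An object of class `raw_recording` with elements `data`, `fs`,
#'   `channel_names`, `reference_note`.
#' @export
raw_recording <- function(data, fs, channel_names = NULL,
                          reference_note = "as recorded") {
  data <- as.matrix(data)
  if (!is.numeric(data) || nrow(data) < 1L || ncol(data) < 1L) {
    stop("recording data must be a non-empty numeric channels x samples matrix")
  }
  if (!(is.numeric(fs) && length(fs) == 1L && fs > 0)) {
    stop("fs must be a positive scalar (Hz)")
  }
  if (is.null(channel_names)) {
    channel_names <- sprintf("ch%02d", seq_len(nrow(data)))
  }
  if (length(channel_names) != nrow(data) || anyDuplicated(channel_names)) {
    stop("channel_names must be unique and match the number of rows of data")
  }
  rownames(data) <- channel_names
  structure(
    list(data = data, fs = fs, channel_names = as.character(channel_names),
         reference_note = reference_note),
    class = "raw_recording"
  )
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf(
    "<raw_recording> %d channels x %d samples @ %g Hz (%.1f s), ref: %s\n",
    nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs, x$reference_note
  ))
  invisible(x)
}

n_samples <- function(rec) ncol(rec$data)
rec_duration <- function(rec) ncol(rec$data) / rec$fs

#' Trial schedule
#'
#' Per-trial onset/offset/label records for a recording. Intervals are
#' half-open `[onset, offset)` in seconds from recording start and must not
#' overlap.
#'
#' @param trial_id unique trial identifiers.
#' @param onset,offset trial boundaries in seconds; `onset < offset`.
#' @param label per-trial class label (character or factor).
#' @return A `data.frame` of class `trial_schedule` with columns
#'   `trial_id`, `onset`, `offset`, `label`, ordered by onset.
#' @export
trial_schedule <- function(trial_id, onset, offset, label) {
  df <- data.frame(
    trial_id = as.character(trial_id),
    onset = as.numeric(onset),
    offset = as.numeric(offset),
    label = as.character(label),
    stringsAsFactors = FALSE
  )
  validate_schedule(df)
  df <- df[order(df$onset), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("trial_schedule", "data.frame")
  df
}

validate_schedule <- function(df) {
  if (nrow(df) == 0L) return(invisible(df))
  if (anyDuplicated(df$trial_id)) {
    stop("duplicate trial_id in schedule: ",
         paste(unique(df$trial_id[duplicated(df$trial_id)]), collapse = ", "))
  }
  if (any(!is.finite(df$onset)) || any(!is.finite(df$offset))) {
    stop("non-finite onset/offset in schedule")
  }
  if (any(df$onset < 0)) {
    bad <- df$trial_id[df$onset < 0]
    stop("negative onset for trial(s): ", paste(bad, collapse = ", "))
  }
  if (any(df$onset >= df$offset)) {
    bad <- df$trial_id[df$onset >= df$offset]
    stop("onset >= offset for trial(s): ", paste(bad, collapse = ", "))
  }
  o <- order(df$onset)
  on <- df$onset[o]; off <- df$offset[o]; id <- df$trial_id[o]
  if (nrow(df) > 1L) {
    ov <- which(on[-1L] < off[-nrow(df)])
    if (length(ov)) {
      stop(sprintf("overlapping trials in schedule: %s and %s",
                   id[ov[1L]], id[ov[1L] + 1L]))
    }
  }
  invisible(df)
}

#' Labeled 1-second (or fixed-length) EEG epochs
#'
#' @param data numeric array, epochs x channels x samples-per-epoch (microvolts).
#' @param fs sampling rate, Hz.
#' @param labels class label per epoch.
#' @param trial_ids source trial identifier per epoch.
#' @param channel_names optional channel labels.
#' @return An object of class `epoch_array`.
#' @export
epoch_array <- function(data, fs, labels, trial_ids, channel_names = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  n <- dim(data)[1L]
  if (length(labels) != n || length(trial_ids) != n) {
    stop("labels and trial_ids must have one entry per epoch")
  }
  if (is.null(channel_names)) {
    channel_names <- sprintf("ch%02d", seq_len(dim(data)[2L]))
  }
  structure(
    list(data = data, fs = fs, labels = as.character(labels),
         trial_ids = as.character(trial_ids),
         channel_names = as.character(channel_names)),
    class = "epoch_array"
  )
}

#' @export
print.epoch_array <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_array> %d epochs x %d channels x %d samples @ %g Hz; labels: %s\n",
              d[1L], d[2L], d[3L], x$fs,
              paste(names(table(x$labels)), collapse = "/")))
  invisible(x)
}
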