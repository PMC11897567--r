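# File formats: 16-bit EDF recordings, RDS array containers, schedule CSVs,
# precomputed DE tensors, and YAML run configuration.

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = -width)
}

num_field <- function(x, width) pad_field(format(x, trim = TRUE, digits = 7), width)

#' Write a recording as 16-bit EDF
#'
#' Standard European Data Format: 1-second data records, per-channel
#' physical scaling spanning the channel's observed range, digital range
#' -32768..32767. The sampling rate must be a whole number; trailing
#' samples that do not fill a complete 1-second record are dropped.
#'
#' @param rec a [raw_recording] (microvolts).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  fs <- rec$fs
  if (fs != round(fs)) stop("EDF export requires an integer sampling rate")
  ns <- nrow(rec$data)
  n_rec <- ncol(rec$data) %/% fs
  if (n_rec < 1L) stop("recording shorter than one EDF data record (1 s)")
  data <- rec$data[, seq_len(n_rec * fs), drop = FALSE]
  # round the physical range outward to 2 decimals so the header fields are
  # exact and the scaling used for writing matches what a reader recovers
  pmin_v <- floor(apply(data, 1L, min) * 100) / 100
  pmax_v <- ceiling(apply(data, 1L, max) * 100) / 100
  flat <- pmax_v - pmin_v < 1e-9
  pmin_v[flat] <- pmin_v[flat] - 1; pmax_v[flat] <- pmax_v[flat] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    pad_field("0", 8L), pad_field("X", 80L), pad_field("eegstt", 80L),
    pad_field("01.01.00", 8L), pad_field("00.00.00", 8L),
    num_field(256L * (1L + ns), 8L), pad_field("", 44L),
    num_field(n_rec, 8L), num_field(1L, 8L), num_field(ns, 4L)
  ), con, eos = NULL)
  sig_field <- function(vals, width) {
    writeChar(paste(vapply(vals, num_field, character(1), width = width),
                    collapse = ""), con, eos = NULL)
  }
  writeChar(paste(vapply(rec$channel_names, pad_field, character(1),
                         width = 16L), collapse = ""), con, eos = NULL)
  writeChar(paste(rep(pad_field("", 80L), ns), collapse = ""), con, eos = NULL)
  writeChar(paste(rep(pad_field("uV", 8L), ns), collapse = ""), con, eos = NULL)
  sig_field(pmin_v, 8L)
  sig_field(pmax_v, 8L)
  sig_field(rep(dmin, ns), 8L)
  sig_field(rep(dmax, ns), 8L)
  writeChar(paste(rep(pad_field("", 80L), ns), collapse = ""), con, eos = NULL)
  sig_field(rep(fs, ns), 8L)
  writeChar(paste(rep(pad_field("", 32L), ns), collapse = ""), con, eos = NULL)
  scale <- (dmax - dmin) / (pmax_v - pmin_v)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    dig <- round((data[, idx, drop = FALSE] - pmin_v) * scale) + dmin
    dig <- pmin(pmax(dig, dmin), dmax)
    writeBin(as.integer(t(dig)), con, size = 2L, endian = "little")
  }
  invisible(path)
}

read_edf_header_num <- function(con, width, n = 1L) {
  as.numeric(vapply(seq_len(n), function(i) readChar(con, width), character(1)))
}

#' Read a 16-bit EDF recording
#'
#' Applies the per-channel physical/digital scaling declared in the header
#' and returns data in the header's physical unit (expected microvolts; a
#' different unit elicits a warning and is passed through).
#'
#' @param path EDF file.
#' @return A [raw_recording].
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  version <- trimws(readChar(con, 8L))
  if (version != "0") stop("malformed EDF header: bad version field '", version, "'")
  readChar(con, 80L); readChar(con, 80L)   # patient / recording id
  readChar(con, 8L); readChar(con, 8L)     # date / time
  header_bytes <- read_edf_header_num(con, 8L)
  readChar(con, 44L)
  n_rec <- read_edf_header_num(con, 8L)
  rec_dur <- read_edf_header_num(con, 8L)
  ns <- read_edf_header_num(con, 4L)
  if (!is.finite(ns) || ns < 1) stop("malformed EDF header: bad signal count")
  labels <- trimws(vapply(seq_len(ns), function(i) readChar(con, 16L), character(1)))
  vapply(seq_len(ns), function(i) readChar(con, 80L), character(1))
  units <- trimws(vapply(seq_len(ns), function(i) readChar(con, 8L), character(1)))
  pmin_v <- read_edf_header_num(con, 8L, ns)
  pmax_v <- read_edf_header_num(con, 8L, ns)
  dmin <- read_edf_header_num(con, 8L, ns)
  dmax <- read_edf_header_num(con, 8L, ns)
  vapply(seq_len(ns), function(i) readChar(con, 80L), character(1))
  spr <- read_edf_header_num(con, 8L, ns)
  vapply(seq_len(ns), function(i) readChar(con, 32L), character(1))
  if (length(unique(spr)) != 1L) {
    stop("mixed per-signal sampling rates are not supported")
  }
  if (!all(grepl("^(uV|µV)?$", units))) {
    warning("EDF units are not microvolts (", paste(unique(units), collapse = ","),
            "); values passed through unscaled")
  }
  fs <- spr[1L] / rec_dur
  seek(con, header_bytes)
  data <- matrix(0, ns, n_rec * spr[1L])
  scale <- (pmax_v - pmin_v) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = ns * spr[1L], size = 2L,
                   endian = "little")
    block <- matrix(raw, nrow = spr[1L])            # samples x signals
    idx <- ((r - 1L) * spr[1L] + 1L):(r * spr[1L])
    data[, idx] <- t((block - rep(dmin, each = spr[1L])) *
                       rep(scale, each = spr[1L]) +
                       rep(pmin_v, each = spr[1L]))
  }
  raw_recording(data, fs, labels, reference_note = "as read from EDF")
}

#' Write / read a recording array container
#'
#' A binary container holding the data matrix, sampling rate, channel names
#' and reference note; round-trips bit-exactly.
#'
#' @param rec a [raw_recording].
#' @param path file path (conventionally `.rds`).
#' @return `write_recording_container` returns `path` invisibly;
#'   `read_recording_container` returns a [raw_recording].
#' @export
write_recording_container <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  saveRDS(unclass(rec), path)
  invisible(path)
}

#' @rdname write_recording_container
#' @export
read_recording_container <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- readRDS(path)
  raw_recording(x$data, x$fs, x$channel_names, x$reference_note)
}

#' Read a recording in either supported format
#'
#' @param path file path.
#' @param format `"edf"`, `"rds"`, or `"auto"` (by file extension).
#' @return A [raw_recording].
#' @export
read_recording <- function(path, format = c("auto", "edf", "rds")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "rds"
  }
  if (format == "edf") read_edf(path) else read_recording_container(path)
}

#' Write / read a trial schedule CSV
#'
#' Columns: `trial_id`, `onset_s`, `offset_s`, `label`.
#'
#' @param schedule a [trial_schedule].
#' @param path CSV file path.
#' @return `write_schedule` returns `path` invisibly; `read_schedule`
#'   returns a validated [trial_schedule].
#' @export
write_schedule <- function(schedule, path) {
  df <- data.frame(trial_id = schedule$trial_id, onset_s = schedule$onset,
                   offset_s = schedule$offset, label = schedule$label)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial_id", "onset_s", "offset_s", "label")
  if (!all(need %in% names(df))) {
    stop("schedule CSV must have columns: ", paste(need, collapse = ", "))
  }
  trial_schedule(df$trial_id, df$onset_s, df$offset_s, df$label)
}

#' Write / read a precomputed DE feature tensor
#'
#' Container for per-second DE features with an `[N x C x F]` layout plus
#' per-frame labels and trial ids (the ingestion path for datasets that
#' ship DE features directly).
#'
#' @param de a [de_features] object.
#' @param path file path (`.rds`).
#' @param schedule optional [trial_schedule]; if given, the frame count per
#'   trial must equal the floor of the trial duration in seconds.
#' @return `write_de_tensor` returns `path` invisibly; `read_de_tensor`
#'   returns a validated [de_features].
#' @export
write_de_tensor <- function(de, path) {
  stopifnot(inherits(de, "de_features"))
  saveRDS(unclass(de), path)
  invisible(path)
}

#' @rdname write_de_tensor
#' @export
read_de_tensor <- function(path, schedule = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- readRDS(path)
  de <- de_features(x$values, x$labels, x$trial_ids,
                    band_names = x$band_names, channel_names = x$channel_names)
  if (!is.null(schedule)) {
    for (r in seq_len(nrow(schedule))) {
      expect <- floor(schedule$offset[r] - schedule$onset[r])
      got <- sum(de$trial_ids == schedule$trial_id[r])
      if (got != expect) {
        stop("trial ", schedule$trial_id[r], ": schedule implies ", expect,
             " frames but tensor has ", got)
      }
    }
    extra <- setdiff(unique(de$trial_ids), schedule$trial_id)
    if (length(extra)) {
      stop("tensor contains trials absent from the schedule: ",
           paste(extra, collapse = ", "))
    }
  }
  de
}

# ---- run configuration ----

#' Default run configuration
#'
#' Nested stage parameters with the reference defaults: 128 Hz target rate,
#' 4-47 Hz band-pass, 100 microvolt rejection, T = 10 / stride 1 windows
#' over the five bands, D = 32 / L = 6 / H = 8 architecture, AdamW with
#' lr 2e-4, decay 0.98, weight decay 0.1, batch 128.
#'
#' @return nested named list of defaults.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    synth = list(n_classes = 3L, n_channels = 8L, effect = 1.0,
                 fs = 128, trial_duration = 20, trials_per_class = 5L,
                 broadband_noise_sigma = 0.2),
    preprocess = list(target_fs = 128, band_low = 4, band_high = 47,
                      reject_uv = 100, epoch_len = 1, ref_channels = NULL),
    features = list(T = 10L, stride = 1L),
    model = list(D = 32L, L = 6L, H = 8L, mlp_ratio = 2, dropout = 0.1),
    train = list(initial_lr = 2e-4, lr_decay_per_epoch = 0.98,
                 weight_decay = 0.1, batch_size = 128L, epochs = 50L),
    protocol = list(n_train = 9L, n_test = 6L)
  )
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults)) stop("unknown config key: ", full)
    if (is.list(defaults[[key]]) && !is.null(user[[key]])) {
      if (!is.list(user[[key]])) stop("config key ", full, " must be a section")
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load a YAML run configuration
#'
#' Reads a YAML file and merges it over [default_run_config]; unknown keys
#' are rejected.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return nested named list.
#' @export
load_run_config <- function(path = NULL) {
  defaults <- default_run_config()
  if (is.null(path)) return(defaults)
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(defaults)
  merge_config(defaults, user)
}
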