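# Synthetic band-limited EEG with planted per-class band-power signatures.
#
# Each class is a ClassBandProfile: a channels x bands matrix of standard
# deviations (microvolts) for independent band-limited Gaussian components.
# Classes that scale the variance of a (band, channel) block by (1+effect)^2
# shift the differential entropy of that block by exactly log(1+effect),
# which gives every downstream stage a known ground truth.

#' Per-class band-power profile
#'
#' @param class_label class name.
#' @param band_sigma numeric matrix `channels x bands`: standard deviation in
#'   microvolts of the band-limited Gaussian component per channel and band.
#'   All entries must be non-negative.
#' @param band_names optional column labels.
#' @return An object of class `class_band_profile`.
#' @export
class_band_profile <- function(class_label, band_sigma, band_names = NULL) {
  band_sigma <- as.matrix(band_sigma)
  if (!is.numeric(band_sigma) || any(band_sigma < 0) || any(!is.finite(band_sigma))) {
    stop("band_sigma must be a non-negative finite numeric matrix")
  }
  if (!is.null(band_names)) colnames(band_sigma) <- band_names
  structure(list(class_label = as.character(class_label),
                 band_sigma = band_sigma),
            class = "class_band_profile")
}

#' Synthetic session specification
#'
#' Describes a labeled synthetic EEG session: channel count, sampling rate,
#' trial layout and the per-class band-power profiles. Defaults emulate a
#' compact three-class session with 15 trials (5 per class).
#'
#' @param class_profiles list of [class_band_profile], one per class.
#' @param n_channels number of channels; must match the profiles.
#' @param fs sampling rate, Hz; must exceed twice the highest band edge.
#' @param trial_duration trial length in seconds.
#' @param trials_per_class trials per class.
#' @param broadband_noise_sigma standard deviation (microvolts) of additive
#'   broadband Gaussian noise.
#' @param bands list of [band_spec] defining the band-limited components;
#'   columns of each profile's `band_sigma` correspond to these bands.
#' @param rng_seed integer master seed; fixes all randomness. Per-trial seeds
#'   are derived as `rng_seed + trial index`.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(class_profiles,
                           n_channels = nrow(class_profiles[[1L]]$band_sigma),
                           fs = 128,
                           trial_duration = 20,
                           trials_per_class = 5,
                           broadband_noise_sigma = 0.2,
                           bands = default_bands(),
                           rng_seed = 1L) {
  if (!is.list(class_profiles) || length(class_profiles) == 0L) {
    stop("class_profiles must be a non-empty list of class_band_profile")
  }
  for (p in class_profiles) {
    if (!inherits(p, "class_band_profile")) {
      stop("every element of class_profiles must be a class_band_profile")
    }
    if (nrow(p$band_sigma) != n_channels || ncol(p$band_sigma) != length(bands)) {
      stop("profile band_sigma must be n_channels x n_bands (",
           n_channels, " x ", length(bands), ")")
    }
  }
  if (fs <= 2 * highest_band_edge(bands)) {
    stop("fs = ", fs, " Hz too low for the highest band edge ",
         highest_band_edge(bands), " Hz (need fs > 2 x edge)")
  }
  if (trial_duration <= 0 || trials_per_class < 1) {
    stop("trial_duration and trials_per_class must be positive")
  }
  if (broadband_noise_sigma < 0) stop("broadband_noise_sigma must be >= 0")
  structure(
    list(class_profiles = class_profiles, n_channels = n_channels, fs = fs,
         trial_duration = trial_duration, trials_per_class = trials_per_class,
         broadband_noise_sigma = broadband_noise_sigma, bands = bands,
         rng_seed = as.integer(rng_seed)),
    class = "synthetic_spec"
  )
}

#' Default class profiles with a planted variance effect
#'
#' Builds `n_classes` profiles sharing a 1-microvolt baseline standard
#' deviation in every (channel, band) cell. Class `k` scales its designated
#' block -- band `((k-1) mod n_bands) + 1` over the `k`-th contiguous chunk
#' of channels -- by `1 + effect`. With `effect = 0` all profiles coincide;
#' otherwise each pair of classes differs in at least one cell and the
#' between-class differential-entropy difference in a scaled block is
#' `log(1 + effect)` nats.
#'
#' @param n_classes number of classes, at least 2.
#' @param n_channels number of channels, at least `n_classes`.
#' @param effect non-negative scale factor increment for the planted block.
#' @param bands band set (default the five EEG rhythms).
#' @param baseline_sigma baseline standard deviation in microvolts.
#' @param labels optional class labels (default "class1", ...).
#' @return List of [class_band_profile] of length `n_classes`.
#' @export
make_default_profiles <- function(n_classes, n_channels, effect,
                                  bands = default_bands(),
                                  baseline_sigma = 1,
                                  labels = sprintf("class%d", seq_len(n_classes))) {
  if (!(n_classes >= 2 && n_channels >= n_classes)) {
    stop("need n_classes >= 2 and n_channels >= n_classes")
  }
  if (!(is.numeric(effect) && length(effect) == 1L && effect >= 0)) {
    stop("effect must be a non-negative scalar")
  }
  nb <- length(bands)
  chunk <- sort(rep_len(seq_len(n_classes), n_channels))
  lapply(seq_len(n_classes), function(k) {
    sig <- matrix(baseline_sigma, n_channels, nb,
                  dimnames = list(NULL, band_names(bands)))
    b <- ((k - 1L) %% nb) + 1L
    sig[chunk == k, b] <- baseline_sigma * (1 + effect)
    class_band_profile(labels[k], sig, band_names(bands))
  })
}

#' Planted block of a default profile
#'
#' Returns the (channels, band) block scaled by class `k` under
#' [make_default_profiles], for use when measuring planted effects.
#'
#' @inheritParams make_default_profiles
#' @param k class index.
#' @return list with `channels` (integer vector) and `band` (column index).
#' @export
planted_block <- function(k, n_classes, n_channels, bands = default_bands()) {
  chunk <- sort(rep_len(seq_len(n_classes), n_channels))
  list(channels = which(chunk == k), band = ((k - 1L) %% length(bands)) + 1L)
}

# Run expr with a local RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# FIR band-limit white noise to [low, high] Hz; generous padding absorbs
# filter transients so the retained segment is stationary.
band_limited_noise <- function(n_channels, n_samples, fs, low, high, n_taps = 256L) {
  pad <- 4L * n_taps
  wn <- matrix(rnorm(n_channels * (n_samples + 2L * pad)), nrow = n_channels)
  h <- signal::fir1(n_taps, c(low, high) / (fs / 2), type = "pass")
  out <- t(apply(wn, 1L, function(x) signal::filtfilt(h, x)))
  out[, (pad + 1L):(pad + n_samples), drop = FALSE]
}

#' Synthesize one trial of band-limited Gaussian EEG
#'
#' The trial is a sum over bands of FIR band-limited Gaussian noise, each
#' channel rescaled so its empirical standard deviation equals the profile's
#' `band_sigma[channel, band]` exactly, plus broadband Gaussian noise.
#' Rescaling (rather than trusting filter gain) makes the planted variance --
#' and hence the planted differential entropy -- exact by construction.
#'
#' @param profile a [class_band_profile].
#' @param spec a [synthetic_spec].
#' @param trial_seed integer seed; identical arguments give bit-identical
#'   output.
#' @return numeric matrix `channels x samples` in microvolts.
#' @export
synthesize_trial <- function(profile, spec, trial_seed) {
  stopifnot(inherits(profile, "class_band_profile"),
            inherits(spec, "synthetic_spec"))
  ns <- round(spec$trial_duration * spec$fs)
  C <- spec$n_channels
  with_local_seed(as.integer(trial_seed), {
    x <- matrix(0, C, ns)
    for (b in seq_along(spec$bands)) {
      sig <- profile$band_sigma[, b]
      if (all(sig == 0)) next
      bd <- spec$bands[[b]]
      comp <- band_limited_noise(C, ns, spec$fs, bd$low, bd$high)
      esd <- apply(comp, 1L, sd)
      scale <- ifelse(esd > 0, sig / esd, 0)
      x <- x + comp * scale
    }
    if (spec$broadband_noise_sigma > 0) {
      x <- x + matrix(rnorm(C * ns, sd = spec$broadband_noise_sigma), C, ns)
    }
    x
  })
}

#' Synthesize a labeled session
#'
#' Concatenates trials in class-interleaved order (class 1, 2, ..., K,
#' 1, 2, ...) so that any prefix split of whole rounds is class-balanced,
#' and returns the continuous recording together with its trial schedule.
#'
#' @param spec a [synthetic_spec].
#' @return list with elements `recording` ([raw_recording]) and `schedule`
#'   ([trial_schedule]).
#' @export
synthesize_session <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  K <- length(spec$class_profiles)
  n_trials <- K * spec$trials_per_class
  class_order <- rep(seq_len(K), times = spec$trials_per_class)
  ns <- round(spec$trial_duration * spec$fs)
  data <- matrix(0, spec$n_channels, n_trials * ns)
  onset <- numeric(n_trials); offset <- numeric(n_trials)
  labels <- character(n_trials)
  for (i in seq_len(n_trials)) {
    k <- class_order[i]
    trial <- synthesize_trial(spec$class_profiles[[k]], spec,
                              trial_seed = spec$rng_seed + i)
    data[, ((i - 1L) * ns + 1L):(i * ns)] <- trial
    onset[i] <- (i - 1L) * ns / spec$fs
    offset[i] <- i * ns / spec$fs
    labels[i] <- spec$class_profiles[[k]]$class_label
  }
  rec <- raw_recording(data, spec$fs,
                       channel_names = sprintf("ch%02d", seq_len(spec$n_channels)),
                       reference_note = "synthetic")
  sched <- trial_schedule(sprintf("t%02d", seq_len(n_trials)), onset, offset, labels)
  list(recording = rec, schedule = sched)
}
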