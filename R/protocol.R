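# Subject-dependent evaluation: per-session trial-prefix splits, training,
# and aggregation of accuracy / macro-F1 across sessions.

#' Trial-prefix train/test split
#'
#' The first `n_train` trials (in schedule order) form the training set and
#' the remaining `n_test` the test set -- e.g. 9/6 for a 15-trial
#' three-class session, 6/2 for an 8-trial two-class session.
#'
#' @param schedule a [trial_schedule].
#' @param n_train,n_test trial counts; must sum to the session's trial
#'   count, both positive.
#' @param balance_check error if the training labels are not perfectly
#'   balanced (default `TRUE`).
#' @return list with character vectors `train_ids` and `test_ids`.
#' @export
make_split <- function(schedule, n_train, n_test, balance_check = TRUE) {
  validate_schedule(schedule)
  if (n_train < 1L || n_test < 1L) {
    stop("both partitions must be non-empty (got ", n_train, "/", n_test, ")")
  }
  if (n_train + n_test != nrow(schedule)) {
    stop("split ", n_train, "+", n_test, " does not match the ",
         nrow(schedule), " trials in the schedule")
  }
  ord <- order(schedule$onset)
  ids <- schedule$trial_id[ord]
  labels <- schedule$label[ord]
  train_ids <- ids[seq_len(n_train)]
  if (balance_check) {
    counts <- table(labels[seq_len(n_train)])
    if (length(unique(counts)) != 1L ||
        length(counts) != length(unique(labels))) {
      stop("training prefix is not class-balanced: ",
           paste(names(counts), counts, sep = "=", collapse = ", "))
    }
  }
  list(train_ids = train_ids, test_ids = ids[(n_train + 1L):length(ids)])
}

subset_windows <- function(wf, trial_ids) {
  keep <- wf$trial_ids %in% trial_ids
  windowed_features(wf$values[keep, , , , drop = FALSE],
                    wf$labels[keep], wf$trial_ids[keep])
}

#' Run the subject-dependent protocol over sessions
#'
#' For each session: window the per-second DE features, split trials by
#' recording-order prefix, fit the normalizer on the training windows only,
#' standardize both partitions with it, train a model and evaluate on the
#' held-out trials. Windows are assigned to partitions by their source
#' trial, so no window straddles the split boundary. Per-session seeds are
#' derived as `train_cfg$rng_seed + session index`.
#'
#' @param sessions list of sessions, each a list with elements `features`
#'   (a [de_features]) and `schedule` (a [trial_schedule]).
#' @param n_train,n_test trials per partition (see [make_split]).
#' @param train_cfg a [train_config].
#' @param T,stride windowing parameters.
#' @param D,L,H,mlp_ratio,dropout architecture parameters (see
#'   [stt_config]).
#' @param balance_check passed to [make_split].
#' @return An object of class `protocol_result`: `per_session` list of
#'   [classification_metrics] objects, `accuracy_mean/sd`, `f1_mean/sd`,
#'   and the pooled confusion matrix.
#' @export
run_subject_dependent <- function(sessions, n_train, n_test,
                                  train_cfg = train_config(),
                                  T = 10, stride = 1,
                                  D = 32, L = 6, H = 8,
                                  mlp_ratio = 2, dropout = 0.1,
                                  balance_check = TRUE) {
  if (!length(sessions)) stop("need at least one session")
  per_session <- vector("list", length(sessions))
  fits <- vector("list", length(sessions))
  for (s in seq_along(sessions)) {
    ses <- sessions[[s]]
    stopifnot(inherits(ses$features, "de_features"))
    wf <- window_features(ses$features, T = T, stride = stride)
    split <- make_split(ses$schedule, n_train, n_test,
                        balance_check = balance_check)
    train_wf <- subset_windows(wf, split$train_ids)
    test_wf <- subset_windows(wf, split$test_ids)
    norm <- fit_normalizer(train_wf)
    train_wf <- apply_normalizer(train_wf, norm)
    test_wf <- apply_normalizer(test_wf, norm)
    cfg_s <- train_cfg
    cfg_s$rng_seed <- train_cfg$rng_seed + s
    mcfg <- stt_config(C = dim(train_wf$values)[3L],
                       K = length(unique(train_wf$labels)),
                       T = T, F = dim(train_wf$values)[4L],
                       D = D, L = L, H = H,
                       mlp_ratio = mlp_ratio, dropout = dropout)
    fit <- train_model(train_wf, cfg_s, mcfg)
    fit$normalizer <- norm
    fits[[s]] <- fit
    per_session[[s]] <- evaluate_model(fit, test_wf)
  }
  acc <- vapply(per_session, `[[`, numeric(1), "accuracy")
  f1 <- vapply(per_session, `[[`, numeric(1), "f1_macro")
  pooled <- Reduce(`+`, lapply(per_session, `[[`, "confusion"))
  structure(list(per_session = per_session, fits = fits,
                 accuracy_mean = mean(acc),
                 accuracy_sd = if (length(acc) > 1L) sd(acc) else 0,
                 f1_mean = mean(f1),
                 f1_sd = if (length(f1) > 1L) sd(f1) else 0,
                 confusion_pooled = pooled),
            class = "protocol_result")
}

#' @export
print.protocol_result <- function(x, ...) {
  cat(sprintf(
    "<protocol_result> %d session(s): accuracy %.2f +/- %.2f %%, macro-F1 %.2f +/- %.2f %%\n",
    length(x$per_session), x$accuracy_mean, x$accuracy_sd,
    x$f1_mean, x$f1_sd))
  invisible(x)
}

#' Synthetic session to per-second DE features
#'
#' Convenience path for synthetic data: epoch the recording into 1-s
#' segments and extract DE features, skipping filtering (the generator's
#' band structure is already the signal of interest).
#'
#' @param session list with `recording` and `schedule` as returned by
#'   [synthesize_session].
#' @param bands band set used for feature extraction.
#' @return list with `features` ([de_features]) and `schedule`, the session
#'   format consumed by [run_subject_dependent].
#' @export
session_to_features <- function(session, bands = default_bands()) {
  ep <- segment_epochs(session$recording, session$schedule, epoch_len = 1)
  list(features = extract_de(ep, bands), schedule = session$schedule)
}
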