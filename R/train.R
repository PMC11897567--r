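# AdamW training with exponential learning-rate decay, and evaluation
# metrics (accuracy, macro-F1, confusion matrix).

#' Training configuration
#'
#' Defaults follow the reference recipe: AdamW with initial learning rate
#' 2e-4, exponential decay 0.98 per epoch, weight decay 0.1 and batch size
#' 128.
#'
#' @param initial_lr initial learning rate.
#' @param lr_decay_per_epoch multiplicative decay applied per epoch.
#' @param weight_decay decoupled weight decay coefficient, applied to
#'   weight matrices only (not biases, layer-norm parameters or position
#'   encodings).
#' @param batch_size mini-batch size.
#' @param epochs number of epochs (default 50).
#' @param rng_seed integer master seed fixing initialization, shuffling and
#'   dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(initial_lr = 2e-4, lr_decay_per_epoch = 0.98,
                         weight_decay = 0.1, batch_size = 128,
                         epochs = 50, rng_seed = 1L) {
  stopifnot(initial_lr > 0, lr_decay_per_epoch > 0, lr_decay_per_epoch <= 1,
            weight_decay >= 0, batch_size >= 1, epochs >= 1)
  structure(list(initial_lr = initial_lr,
                 lr_decay_per_epoch = lr_decay_per_epoch,
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 rng_seed = as.integer(rng_seed)),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' `initial_lr * decay^epoch` with `epoch` counted from 0 (the first epoch
#' trains at `initial_lr`).
#'
#' @param cfg a [train_config].
#' @param epoch 0-based epoch index.
#' @return learning rate.
#' @export
lr_at_epoch <- function(cfg, epoch) {
  cfg$initial_lr * cfg$lr_decay_per_epoch^epoch
}

# ---- nested-list parameter tree utilities ----

tree_zeros <- function(p) {
  if (is.list(p)) lapply(p, tree_zeros) else p * 0
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# TRUE where decoupled weight decay applies: 2-D weight matrices other than
# the position encoding tables.
tree_decay_mask <- function(p, name = "") {
  if (is.list(p)) {
    out <- vector("list", length(p))
    nm <- names(p) %||% rep("", length(p))
    for (i in seq_along(p)) out[[i]] <- tree_decay_mask(p[[i]], nm[i])
    names(out) <- names(p)
    out
  } else {
    is.matrix(p) && !(name %in% c("E_SPos", "E_TPos"))
  }
}

adamw_update <- function(p, g, m, v, mask, lr, wd, t,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (is.list(p)) {
    out_p <- p; out_m <- m; out_v <- v
    for (i in seq_along(p)) {
      r <- adamw_update(p[[i]], g[[i]], m[[i]], v[[i]], mask[[i]],
                        lr, wd, t, beta1, beta2, eps)
      out_p[[i]] <- r$p; out_m[[i]] <- r$m; out_v[[i]] <- r$v
    }
    list(p = out_p, m = out_m, v = out_v)
  } else {
    if (is.null(dim(p))) g <- as.vector(g)   # grads may arrive as n x 1
    m2 <- beta1 * m + (1 - beta1) * g
    v2 <- beta2 * v + (1 - beta2) * g * g
    mhat <- m2 / (1 - beta1^t)
    vhat <- v2 / (1 - beta2^t)
    step <- mhat / (sqrt(vhat) + eps)
    if (isTRUE(mask)) step <- step + wd * p
    list(p = p - lr * step, m = m2, v = v2)
  }
}

#' Train the spatial-temporal transformer on feature windows
#'
#' Minimizes the mean cross-entropy over shuffled mini-batches with AdamW
#' and a per-epoch exponential learning-rate schedule. Fully deterministic
#' given `cfg$rng_seed`. The state with the lowest mean training loss across
#' epochs is retained for prediction.
#'
#' @param train a non-empty [windowed_features] training set (normalized).
#' @param cfg a [train_config].
#' @param mcfg an [stt_config]; its `C`, `T`, `F` must match the data and
#'   `K` the number of distinct labels. If `NULL`, a default configuration
#'   is derived from the data.
#' @return An object of class `stt_fit` with elements `state` (best),
#'   `final_state`, `config`, `label_levels`, `loss_trace` (per-epoch mean
#'   training loss) and `train_cfg`.
#' @export
train_model <- function(train, cfg = train_config(), mcfg = NULL) {
  stopifnot(inherits(train, "windowed_features"), inherits(cfg, "train_config"))
  d <- dim(train$values)
  if (d[1L] == 0L) stop("empty training set")
  levels <- sort(unique(train$labels))
  if (length(levels) < 2L) {
    stop("training set has a single class ('", levels, "'); need at least 2")
  }
  y <- match(train$labels, levels)
  if (is.null(mcfg)) {
    mcfg <- stt_config(C = d[3L], K = length(levels), T = d[2L], F = d[4L])
  }
  if (any(c(mcfg$T, mcfg$C, mcfg$F) != d[2:4]) || mcfg$K != length(levels)) {
    stop("model config does not match data: data is T=", d[2L], " C=", d[3L],
         " F=", d[4L], " K=", length(levels))
  }
  N <- d[1L]
  # token matrix for the whole training set, permuted once; each window's
  # C*T token rows are contiguous
  Xs_full <- matrix(aperm(train$values, c(3L, 2L, 1L, 4L)), ncol = d[4L])
  tok_per_win <- d[2L] * d[3L]
  with_local_seed(cfg$rng_seed, {
    state <- init_model_state(mcfg)
    mstate <- tree_zeros(state)
    vstate <- tree_zeros(state)
    mask <- tree_decay_mask(state)
    t_step <- 0L
    loss_trace <- numeric(cfg$epochs)
    best_loss <- Inf
    best_state <- state
    for (e in seq_len(cfg$epochs)) {
      lr <- lr_at_epoch(cfg, e - 1L)
      idx <- sample.int(N)
      batch_starts <- seq(1L, N, by = cfg$batch_size)
      losses <- numeric(length(batch_starts))
      for (bi in seq_along(batch_starts)) {
        rows <- idx[batch_starts[bi]:min(batch_starts[bi] + cfg$batch_size - 1L, N)]
        tok_rows <- as.vector(outer(seq_len(tok_per_win),
                                    (rows - 1L) * tok_per_win, `+`))
        step_seed <- floor(runif(1) * 2^31)
        res <- stt_step_cpp(state, Xs_full[tok_rows, , drop = FALSE],
                            as.integer(y[rows]), length(rows),
                            mcfg$T, mcfg$C, mcfg$H, mcfg$L,
                            mcfg$dropout, TRUE, step_seed)
        losses[bi] <- res$loss
        grads <- res$grads
        t_step <- t_step + 1L
        upd <- adamw_update(state, grads, mstate, vstate, mask,
                            lr, cfg$weight_decay, t_step)
        state <- upd$p; mstate <- upd$m; vstate <- upd$v
        class(state) <- "stt_state"
      }
      loss_trace[e] <- mean(losses)
      if (loss_trace[e] < best_loss) {
        best_loss <- loss_trace[e]
        best_state <- state
      }
    }
    structure(list(state = best_state, final_state = state, config = mcfg,
                   label_levels = levels, loss_trace = loss_trace,
                   train_cfg = cfg),
              class = "stt_fit")
  })
}

#' @export
print.stt_fit <- function(x, ...) {
  cat(sprintf(
    "<stt_fit> %s; %d parameters; %d epochs, final loss %.4f (best %.4f)\n",
    paste(x$label_levels, collapse = "/"), n_parameters(x$state),
    length(x$loss_trace), tail(x$loss_trace, 1L), min(x$loss_trace)))
  invisible(x)
}

#' Predict class labels for feature windows
#'
#' @param object an [stt_fit].
#' @param newdata a [windowed_features] tensor (normalized with the
#'   training-set normalizer).
#' @param ... unused.
#' @return character vector of predicted labels.
#' @export
predict.stt_fit <- function(object, newdata, ...) {
  logits <- stt_logits(object$state, object$config, newdata$values)
  object$label_levels[max.col(logits, ties.method = "first")]
}

#' Evaluate a fitted model on a test set
#'
#' Argmax prediction per window; reports accuracy (%), macro-averaged F1
#' (%), per-class F1 and the K x K confusion matrix with rows = true class.
#'
#' @param fit an [stt_fit].
#' @param test a non-empty [windowed_features] test set (normalized with the
#'   training normalizer).
#' @return An object of class `stt_metrics`.
#' @export
evaluate_model <- function(fit, test) {
  stopifnot(inherits(fit, "stt_fit"), inherits(test, "windowed_features"))
  if (dim(test$values)[1L] == 0L) stop("empty test set")
  unknown <- setdiff(unique(test$labels), fit$label_levels)
  if (length(unknown)) {
    stop("test labels outside the training label set: ",
         paste(unknown, collapse = ", "))
  }
  pred <- predict(fit, test)
  classification_metrics(test$labels, pred, fit$label_levels)
}

#' Classification metrics from true and predicted labels
#'
#' @param truth,pred character vectors of true and predicted labels.
#' @param levels class label set fixing the confusion-matrix order.
#' @return An `stt_metrics` object: `accuracy` and `f1_macro` in percent,
#'   `per_class_f1`, and `confusion` (rows = true class).
#' @export
classification_metrics <- function(truth, pred, levels = sort(unique(truth))) {
  truth <- factor(truth, levels = levels)
  pred <- factor(pred, levels = levels)
  confusion <- table(truth = truth, predicted = pred)
  n <- length(truth)
  acc <- sum(diag(confusion)) / n * 100
  f1 <- vapply(seq_along(levels), function(k) {
    tp <- confusion[k, k]
    fp <- sum(confusion[, k]) - tp
    fn <- sum(confusion[k, ]) - tp
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  }, numeric(1))
  names(f1) <- levels
  structure(list(accuracy = acc, f1_macro = mean(f1) * 100,
                 per_class_f1 = f1 * 100,
                 confusion = unclass(confusion), n = n),
            class = "stt_metrics")
}

#' @export
print.stt_metrics <- function(x, ...) {
  cat(sprintf("<stt_metrics> accuracy %.2f%%, macro-F1 %.2f%% (n = %d)\n",
              x$accuracy, x$f1_macro, x$n))
  print(x$confusion)
  invisible(x)
}
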