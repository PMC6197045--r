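# Training: SGD with momentum and weight decay, step learning-rate decay,
# early stopping at the smoothed log-loss slope sign change, block-wise
# k-fold cross-validation.

#' Training configuration
#'
#' Defaults follow the published regimen: learning rate 0.0003 halved every
#' 100 epochs, momentum 0.9, weight decay 0.0005, batch size 128. The
#' maximum epoch count is not published; it defaults to 300 with early
#' stopping. The optimized loss is categorical cross-entropy on the softmax
#' outputs (the "log loss" whose slope drives early stopping); the 0-1 error
#' is tracked as the reported metric and selects the best epoch.
#'
#' @param base_lr Initial learning rate (default 3e-4).
#' @param lr_halving_period_epochs Epochs between halvings (default 100).
#' @param momentum SGD momentum (default 0.9).
#' @param weight_decay L2 penalty on weights, biases exempt (default 5e-4).
#' @param batch_size Mini-batch size (default 128).
#' @param max_epochs Hard epoch cap (default 300).
#' @param early_stop_smoothing_window Moving-average window for the
#'   validation log-loss slope test (default 5).
#' @param rng_seed Seed governing initialization, batch order and dropout.
#' @return Object of class `har_train_config`.
#' @export
train_config <- function(base_lr = 3e-4, lr_halving_period_epochs = 100L,
                         momentum = 0.9, weight_decay = 5e-4,
                         batch_size = 128L, max_epochs = 300L,
                         early_stop_smoothing_window = 5L, rng_seed = 1L) {
  stopifnot(base_lr > 0, lr_halving_period_epochs >= 1,
            momentum >= 0, momentum < 1, weight_decay >= 0,
            batch_size >= 1, max_epochs >= 1,
            early_stop_smoothing_window >= 1)
  structure(
    list(base_lr = base_lr,
         lr_halving_period_epochs = as.integer(lr_halving_period_epochs),
         momentum = momentum, weight_decay = weight_decay,
         batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs),
         early_stop_smoothing_window = as.integer(early_stop_smoothing_window),
         rng_seed = as.integer(rng_seed)),
    class = "har_train_config"
  )
}

#' Step-decay learning-rate schedule
#'
#' `base_lr * 0.5 ^ floor(epoch / period)` with `epoch` counted from 0.
#'
#' @param epoch Zero-based epoch index (vectorized).
#' @param config A [train_config()].
#' @return Learning rate(s).
#' @export
#' @examples
#' lr_schedule(c(0, 100, 250), train_config())
lr_schedule <- function(epoch, config = train_config()) {
  stopifnot(all(epoch >= 0))
  config$base_lr * 0.5^(epoch %/% config$lr_halving_period_epochs)
}

new_sgd_state <- function(params) {
  zero_like <- function(x) { x[] <- 0; x }
  list(v = list(
    blocks = lapply(params$blocks,
                    function(bl) list(f = zero_like(bl$f), b = zero_like(bl$b))),
    fc1 = lapply(params$fc1, zero_like),
    fc2 = lapply(params$fc2, zero_like)
  ))
}

# one parameter update from precomputed gradients (weight decay on weights
# only, momentum buffer in state)
apply_update <- function(params, grads, lr, config, state) {
  upd <- function(W, dW, v, decay) {
    if (decay) dW <- dW + config$weight_decay * W
    v <- config$momentum * v - lr * dW
    list(W = W + v, v = v)
  }
  for (i in seq_along(params$blocks)) {
    u <- upd(params$blocks[[i]]$f, grads$blocks[[i]]$f,
             state$v$blocks[[i]]$f, TRUE)
    params$blocks[[i]]$f <- u$W; state$v$blocks[[i]]$f <- u$v
    u <- upd(params$blocks[[i]]$b, grads$blocks[[i]]$b,
             state$v$blocks[[i]]$b, FALSE)
    params$blocks[[i]]$b <- u$W; state$v$blocks[[i]]$b <- u$v
  }
  for (nm in c("fc1", "fc2")) {
    u <- upd(params[[nm]]$W, grads[[nm]]$W, state$v[[nm]]$W, TRUE)
    params[[nm]]$W <- u$W; state$v[[nm]]$W <- u$v
    u <- upd(params[[nm]]$b, grads[[nm]]$b, state$v[[nm]]$b, FALSE)
    params[[nm]]$b <- u$W; state$v[[nm]]$b <- u$v
  }
  list(params = params, state = state)
}

label_index <- function(labels, classes) {
  idx <- match(labels, classes)
  if (anyNA(idx)) {
    stop_harcnn("harcnn_bad_class", "label(s) outside the class set: %s",
                paste(unique(labels[is.na(idx)]), collapse = ", "))
  }
  idx
}

#' One SGD step on a mini-batch
#'
#' Gradients of the mean cross-entropy loss (plus L2 weight decay on weights,
#' biases exempt) are combined with the momentum buffer and applied to all
#' parameters. Dropout is active unless the spec's rate is 0.
#'
#' @param params Network parameters.
#' @param batch Non-empty list of labeled windows.
#' @param lr Learning rate for this step.
#' @param config A [train_config()].
#' @param state Momentum state from a previous step, or NULL to start fresh.
#' @param classes Class levels mapping labels to output units (default the
#'   classes recorded in `params`, falling back to [activity_codes()]).
#' @return List with `params`, `state` and the pre-update batch `loss`.
#' @export
sgd_step <- function(params, batch, lr, config = train_config(),
                     state = NULL, classes = NULL) {
  stopifnot(length(batch) >= 1L)
  classes <- classes %||% params$classes %||% activity_codes()
  if (is.null(state)) state <- new_sgd_state(params)
  X <- stack_windows(batch, params$spec)
  y <- label_index(vapply(batch, function(w) w$label, character(1)), classes)
  fwd <- net_forward(X, params, training = params$spec$dropout > 0,
                     cache = TRUE)
  sx <- softmax_xent(fwd$logits, y)
  if (!is.finite(sx$loss)) {
    stop_harcnn("harcnn_divergence", "non-finite training loss; aborting")
  }
  grads <- net_backward(sx$dlogits, params, fwd$cache)
  au <- apply_update(params, grads, lr, config, state)
  list(params = au$params, state = au$state, loss = sx$loss)
}

#' Early-stopping detector on the smoothed validation log-loss
#'
#' Smooths the per-epoch validation log-loss with a trailing moving average
#' of `smoothing_window` epochs and returns the first epoch at which the
#' smoothed curve's first difference becomes strictly positive (the slope
#' sign change from negative to positive); zero slope does not trigger.
#'
#' @param history A `data.frame` with a `val_loss` column (as produced by
#'   [train_network()]) or a bare numeric loss vector.
#' @param smoothing_window Trailing window length (default 5).
#' @return The stopping epoch (1-based index of the last epoch before the
#'   rise), or NULL if the criterion never fires or too few epochs are
#'   recorded.
#' @export
#' @examples
#' detect_early_stop(c(1.0, 0.8, 0.7, 0.75, 0.9), smoothing_window = 1)  # 3
detect_early_stop <- function(history, smoothing_window = 5L) {
  loss <- if (is.data.frame(history)) history$val_loss else as.numeric(history)
  w <- as.integer(smoothing_window)
  n <- length(loss)
  if (n < w + 1L) return(NULL)
  ma <- stats::filter(loss, rep(1 / w, w), sides = 1)  # trailing mean
  ma <- as.numeric(ma)
  for (t in w:(n - 1L)) {
    if (ma[t + 1L] > ma[t]) return(t)
  }
  NULL
}

#' Train the network on all folds but one
#'
#' Trains on the union of the other folds and validates on `held_out_fold`
#' after every epoch, recording training/validation log-loss, validation
#' 0-1 error and the learning rate. Training stops at the early-stopping
#' epoch or `max_epochs`, and the parameters returned are those of the
#' best (minimum validation 0-1 error) epoch — the global minimum of the
#' error function over the epochs run.
#'
#' @param bundle A [dataset_bundle()].
#' @param folds A [make_folds()] assignment for `bundle`.
#' @param held_out_fold Fold index in `1..k` used for validation.
#' @param config A [train_config()].
#' @param spec Network geometry (default [network_spec()]); its `n_classes`
#'   must match the number of distinct labels in the bundle.
#' @param verbose Print per-epoch progress (default FALSE).
#' @return List of class `har_fit`: `params` (best epoch), `history`
#'   (data.frame epoch/lr/train_loss/val_loss/val_error), `best_epoch`,
#'   `stopped_epoch`, `classes`.
#' @export
train_network <- function(bundle, folds, held_out_fold,
                          config = train_config(), spec = network_spec(),
                          verbose = FALSE) {
  stopifnot(inherits(bundle, "har_bundle"), inherits(folds, "har_folds"))
  if (!(held_out_fold %in% seq_len(folds$k))) {
    stop_harcnn("harcnn_bad_value", "held_out_fold %s outside 1..%d",
                format(held_out_fold), folds$k)
  }
  classes <- intersect(activity_codes(), unique(bundle$labels))
  if (length(classes) != spec$n_classes) {
    stop_harcnn("harcnn_bad_class",
                "bundle has %d classes but spec expects %d",
                length(classes), spec$n_classes)
  }
  tr_idx <- which(folds$fold != held_out_fold)
  va_idx <- which(folds$fold == held_out_fold)
  if (length(tr_idx) == 0L) {
    stop_harcnn("harcnn_empty", "training set is empty")
  }
  Xtr <- stack_windows(bundle$windows[tr_idx], spec)
  ytr <- label_index(bundle$labels[tr_idx], classes)
  Xva <- stack_windows(bundle$windows[va_idx], spec)
  yva <- label_index(bundle$labels[va_idx], classes)

  with_seed(config$rng_seed, {
    params <- init_network(spec, seed = config$rng_seed)
    params$classes <- classes
    state <- new_sgd_state(params)
    ntr <- length(tr_idx)
    hist <- data.frame(epoch = integer(0), lr = numeric(0),
                       train_loss = numeric(0), val_loss = numeric(0),
                       val_error = numeric(0))
    best <- list(error = Inf, params = params, epoch = 0L)
    for (epoch in seq_len(config$max_epochs)) {
      lr <- lr_schedule(epoch - 1L, config)
      ord <- sample.int(ntr)
      splits <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      ep_loss <- 0
      for (bidx in splits) {
        Xb <- Xtr[, bidx, , drop = FALSE]
        fwd <- net_forward(Xb, params, training = spec$dropout > 0,
                           cache = TRUE)
        sx <- softmax_xent(fwd$logits, ytr[bidx])
        if (!is.finite(sx$loss)) {
          stop_harcnn("harcnn_divergence", "non-finite training loss")
        }
        grads <- net_backward(sx$dlogits, params, fwd$cache)
        au <- apply_update(params, grads, lr, config, state)
        params <- au$params; state <- au$state
        ep_loss <- ep_loss + sx$loss * length(bidx)
      }
      ev <- evaluate_split(Xva, yva, params)
      hist <- rbind(hist, data.frame(
        epoch = epoch, lr = lr, train_loss = ep_loss / ntr,
        val_loss = ev$loss, val_error = ev$error))
      if (verbose) {
        message(sprintf("epoch %3d lr %.2g train %.4f val %.4f err %.4f",
                        epoch, lr, ep_loss / ntr, ev$loss, ev$error))
      }
      if (ev$error < best$error) {
        best <- list(error = ev$error, params = params, epoch = epoch)
      }
      es <- detect_early_stop(hist, config$early_stop_smoothing_window)
      if (!is.null(es)) break
    }
    structure(
      list(params = best$params, history = hist, best_epoch = best$epoch,
           stopped_epoch = nrow(hist), classes = classes),
      class = "har_fit"
    )
  })
}

# batched validation loss and 0-1 error
evaluate_split <- function(X, y, params, chunk = 256L) {
  n <- dim(X)[2]
  loss <- 0; wrong <- 0L
  for (s in seq.int(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    Z <- net_forward(X[, s:e, , drop = FALSE], params)$logits
    sx <- softmax_xent(Z, y[s:e])
    loss <- loss + sx$loss * (e - s + 1L)
    pred <- max.col(sx$probs, ties.method = "first")
    wrong <- wrong + sum(pred != y[s:e])
  }
  list(loss = loss / n, error = wrong / n)
}

#' Batched prediction for a list of windows
#'
#' @param windows List of windows.
#' @param params Trained parameters (with a `classes` field).
#' @return Character vector of predicted activity codes.
#' @export
predict_windows <- function(windows, params, chunk = 256L) {
  classes <- params$classes %||% activity_codes()
  X <- stack_windows(windows, params$spec)
  n <- dim(X)[2]
  out <- character(n)
  for (s in seq.int(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    Z <- net_forward(X[, s:e, , drop = FALSE], params)$logits
    out[s:e] <- classes[max.col(Z, ties.method = "first")]
  }
  out
}

#' Block-wise k-fold cross-validation
#'
#' Runs `k` trainings, scoring each held-out fold exactly once, and returns
#' the per-fold validation confusion matrices together with their
#' elementwise sum (the pooled matrix) and the mean of per-fold accuracies.
#' Fold `i` uses seed `config$rng_seed + 101 * i` so runs are reproducible
#' yet folds differ.
#'
#' @param bundle A [dataset_bundle()].
#' @param config A [train_config()].
#' @param k Number of folds (default 10).
#' @param spec Network geometry.
#' @param folds Optional precomputed [make_folds()] assignment.
#' @param verbose Passed to [train_network()].
#' @return Object of class `har_cv`: `matrices` (list of k), `pooled`,
#'   `mean_fold_accuracy`, `histories`, `folds`, `classes`.
#' @export
cross_validate <- function(bundle, config = train_config(), k = 10L,
                           spec = network_spec(), folds = NULL,
                           verbose = FALSE) {
  folds <- folds %||% make_folds(bundle, k)
  k <- folds$k
  classes <- intersect(activity_codes(), unique(bundle$labels))
  mats <- vector("list", k)
  hists <- vector("list", k)
  for (i in seq_len(k)) {
    cfg <- config
    cfg$rng_seed <- as.integer(config$rng_seed + 101L * i)
    fit <- train_network(bundle, folds, i, cfg, spec, verbose)
    va <- which(folds$fold == i)
    preds <- predict_windows(bundle$windows[va], fit$params)
    mats[[i]] <- confusion_matrix(bundle$labels[va], preds, classes)
    hists[[i]] <- fit$history
  }
  pooled <- Reduce(`+`, mats)
  structure(
    list(matrices = mats, pooled = pooled,
         mean_fold_accuracy = mean(vapply(mats, overall_accuracy, numeric(1))),
         histories = hists, folds = folds, classes = classes),
    class = "har_cv"
  )
}

#' @export
print.har_cv <- function(x, ...) {
  cat(sprintf("<har_cv> %d folds, pooled accuracy %.3f (mean fold %.3f)\n",
              length(x$matrices), overall_accuracy(x$pooled),
              x$mean_fold_accuracy))
  invisible(x)
}
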