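# Full-network forward and backward passes (batched), plus the public
# single-window forward / predict operations.

# X: (H, B, D) — batch in the middle so convolution output needs no
# transposes. Returns logits (B x K), optionally caches for backward.
# Dropout is inverted (activations scaled by 1/keep at train time), so
# inference needs no rescaling.
net_forward <- function(X, params, training = FALSE, cache = FALSE) {
  spec <- params$spec
  caches <- list()
  A <- X
  for (i in seq_along(params$blocks)) {
    cv <- conv1d_fwd(A, params$blocks[[i]]$f, params$blocks[[i]]$b,
                     cache = cache)
    pl <- pool1d_fwd(cv$Y, spec$pool_h)
    R <- pl$Y
    mask <- R > 0
    R[!mask] <- 0
    if (cache) caches[[i]] <- list(conv = cv, pool = pl, relu_mask = mask)
    A <- R
  }
  B <- dim(A)[2]
  flat <- aperm(A, c(1L, 3L, 2L))       # (H, C, B): height fast, then depth
  dim(flat) <- c(spec$flat_len, B)
  H1 <- crossprod(flat, params$fc1$W)   # B x fc_width
  H1 <- sweep(H1, 2L, params$fc1$b, "+")
  drop_mask <- NULL
  if (training && spec$dropout > 0) {
    keep <- 1 - spec$dropout
    drop_mask <- matrix(stats::rbinom(length(H1), 1L, keep) / keep,
                        nrow(H1), ncol(H1))
    H1 <- H1 * drop_mask
  }
  Z <- sweep(H1 %*% params$fc2$W, 2L, params$fc2$b, "+")
  out <- list(logits = Z)
  if (cache) {
    out$cache <- list(blocks = caches, flat = flat, H1 = H1,
                      drop_mask = drop_mask, B = B)
  }
  out
}

# mean cross-entropy over the batch from logits; y integer class in 1..K.
# Exact log-sum-exp form: no clipping, so the analytic gradient matches the
# finite-difference oracle even for saturated logits.
softmax_xent <- function(logits, y) {
  B <- nrow(logits)
  m <- apply(logits, 1L, max)
  lse <- m + log(rowSums(exp(logits - m)))
  loss <- mean(lse - logits[cbind(seq_len(B), y)])
  P <- exp(logits - lse)
  dZ <- P
  dZ[cbind(seq_len(B), y)] <- dZ[cbind(seq_len(B), y)] - 1
  list(loss = loss, probs = P, dlogits = dZ / B)
}

# gradients of the batch loss w.r.t. every parameter
net_backward <- function(dZ, params, cache) {
  spec <- params$spec
  g <- list(blocks = vector("list", length(params$blocks)))
  dH1 <- tcrossprod(dZ, params$fc2$W)
  g$fc2 <- list(W = crossprod(cache$H1, dZ), b = colSums(dZ))
  if (!is.null(cache$drop_mask)) dH1 <- dH1 * cache$drop_mask
  g$fc1 <- list(W = cache$flat %*% dH1, b = colSums(dH1))
  dflat <- params$fc1$W %*% t(dH1)          # flat_len x B
  nb <- length(params$blocks)
  last <- cache$blocks[[nb]]
  dp <- dim(last$pool$Y)                    # (H, B, C)
  dim(dflat) <- c(dp[1], dp[3], dp[2])
  dA <- aperm(dflat, c(1L, 3L, 2L))
  for (i in rev(seq_along(params$blocks))) {
    bc <- cache$blocks[[i]]
    dA[!bc$relu_mask] <- 0
    dP <- pool1d_bwd(dA, bc$pool, spec$pool_h)
    cb <- conv1d_bwd(dP, params$blocks[[i]]$f, bc$conv)
    g$blocks[[i]] <- list(f = cb$df, b = cb$db)
    dA <- cb$dX
  }
  g
}

# stack a list of windows into the network input array (H, B, D)
stack_windows <- function(windows, spec) {
  B <- length(windows)
  X <- array(0, c(spec$input_len, B, spec$input_channels))
  for (b in seq_len(B)) X[, b, ] <- windows[[b]]$values
  X
}

#' Forward pass on one window
#'
#' Applies the three convolution blocks, flattening, the fully-connected
#' layers and softmax. With `training_mode = TRUE` inverted dropout is
#' applied at the penultimate layer (using R's current RNG stream); at
#' inference the pass is fully deterministic.
#'
#' @param window A [new_window()] (or bare `input_len x 3` matrix).
#' @param params [init_network()] parameters.
#' @param training_mode Apply dropout? (default FALSE).
#' @return Named probability vector over the classes (sums to 1).
#' @export
forward <- function(window, params, training_mode = FALSE) {
  validate_params(params)
  vals <- if (inherits(window, "har_window")) window$values else as.matrix(window)
  spec <- params$spec
  if (!identical(dim(vals), c(spec$input_len, spec$input_channels))) {
    stop_harcnn("harcnn_bad_shape", "window is %d x %d, spec wants %d x %d",
                nrow(vals), ncol(vals), spec$input_len, spec$input_channels)
  }
  X <- array(vals, c(spec$input_len, 1L, spec$input_channels))
  z <- net_forward(X, params, training = training_mode)$logits[1L, ]
  p <- softmax(z)
  names(p) <- if (spec$n_classes == 10L) activity_codes() else NULL
  p
}

#' Predict the activity of one window
#'
#' Argmax of [forward()] probabilities; exact ties break toward the lowest
#' class index in canonical order (WS first).
#'
#' @inheritParams forward
#' @return Activity code (character scalar).
#' @export
predict_activity <- function(window, params) {
  p <- forward(window, params)
  codes <- names(p) %||% as.character(seq_along(p))
  codes[which.max(p)]   # which.max returns the first maximum: documented tie-break
}

#' Zero-one classification error
#'
#' @param predicted,truth Activity codes.
#' @return 0 if equal, else 1 (integer, vectorized).
#' @export
zero_one_loss <- function(predicted, truth) {
  as.integer(predicted != truth)
}
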