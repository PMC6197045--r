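# Conventional-classifier baselines on a 12-feature window summary.
#
# The published comparison lists hyperparameters (Gaussian SVM with kernel
# scale 3; Gini decision tree capped at 5,000 splits; distance-weighted
# Euclidean 10-NN) but not the 12 features themselves, so this package
# defines a documented stand-in feature set and treats the published
# baseline tables as reference context, not exact targets. The classifiers
# are implemented here directly (no tree/SVM library is assumed):
# one-vs-one SMO for the SVM, greedy CART for the tree.

#' Twelve summary features of a window
#'
#' In fixed order: per-axis mean (3), per-axis standard deviation (3),
#' pairwise axis correlations xy, xz, yz (3, zero when undefined), magnitude
#' mean (1), magnitude standard deviation (1), and the dominant frequency of
#' the mean-removed magnitude signal in Hz (1). Deterministic.
#'
#' @param window A [new_window()] or bare numeric matrix with 3 columns.
#' @param sample_rate_hz Sampling rate used to express the dominant
#'   frequency in Hz (default 45.4).
#' @return Named numeric vector of length 12.
#' @export
extract_features <- function(window, sample_rate_hz = 45.4) {
  v <- if (inherits(window, "har_window")) window$values else as.matrix(window)
  mu <- colMeans(v)
  sds <- apply(v, 2L, stats::sd)
  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) 0 else stats::cor(a, b)
  }
  mag <- sqrt(rowSums(v^2))
  out <- c(mu, sds,
           safe_cor(v[, 1], v[, 2]), safe_cor(v[, 1], v[, 3]),
           safe_cor(v[, 2], v[, 3]),
           mean(mag), stats::sd(mag),
           dominant_frequency(mag, sample_rate_hz))
  names(out) <- c("mean_x", "mean_y", "mean_z", "sd_x", "sd_y", "sd_z",
                  "cor_xy", "cor_xz", "cor_yz", "mag_mean", "mag_sd",
                  "dom_freq_hz")
  out
}

#' Dominant frequency of a signal
#'
#' Frequency (Hz) of the largest-magnitude FFT bin of the mean-removed
#' signal, excluding DC; 0 for a constant signal.
#'
#' @param x Numeric vector.
#' @param sample_rate_hz Sampling rate in Hz.
#' @return Frequency in Hz.
#' @export
dominant_frequency <- function(x, sample_rate_hz = 45.4) {
  x <- x - mean(x)
  if (all(abs(x) < 1e-12)) return(0)
  n <- length(x)
  spec <- Mod(stats::fft(x))[2:(n %/% 2 + 1L)]
  which.max(spec) / n * sample_rate_hz
}

#' Feature table for a bundle
#'
#' @param bundle A [dataset_bundle()].
#' @param sample_rate_hz Passed to [extract_features()].
#' @return List with `X` (n x 12 matrix) and `labels`.
#' @export
feature_table <- function(bundle, sample_rate_hz = 45.4) {
  X <- t(vapply(bundle$windows, extract_features, numeric(12),
                sample_rate_hz = sample_rate_hz))
  list(X = X, labels = bundle$labels)
}

#' Read/write feature tables as CSV
#'
#' Twelve feature columns plus a `label` column.
#'
#' @param X Feature matrix; `labels` aligned class codes.
#' @param path File path.
#' @return `write_feature_csv()` returns `path` invisibly;
#'   `read_feature_csv()` a list with `X` and `labels`.
#' @export
write_feature_csv <- function(X, labels, path) {
  df <- as.data.frame(X)
  df$label <- labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  # na.strings empty: the still class is literally labelled "NA"
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = character(0))
  if (!"label" %in% names(df)) {
    stop_harcnn("harcnn_bad_shape", "feature CSV lacks a 'label' column")
  }
  list(X = as.matrix(df[setdiff(names(df), "label")]), labels = df$label)
}

## ---- k-nearest neighbours -------------------------------------------------

fit_knn <- function(X, y, k = 10L) {
  structure(list(X = X, y = y, k = as.integer(k),
                 classes = class_levels(y)), class = "har_knn")
}

predict_knn <- function(fit, Xnew) {
  tr <- fit$X
  k <- min(fit$k, nrow(tr))
  cls <- fit$classes
  # squared Euclidean distances via the expansion trick
  d2 <- outer(rowSums(Xnew^2), rep(1, nrow(tr))) +
    outer(rep(1, nrow(Xnew)), rowSums(tr^2)) - 2 * Xnew %*% t(tr)
  d2[d2 < 0] <- 0
  apply(d2, 1L, function(dr) {
    nb <- order(dr)[seq_len(k)]
    w <- 1 / pmax(sqrt(dr[nb]), 1e-12)   # inverse-distance weights
    votes <- tapply(w, factor(fit$y[nb], levels = cls), sum, default = 0)
    cls[which.max(votes)]
  })
}

## ---- CART decision tree ---------------------------------------------------

# Greedy binary CART with Gini impurity. max_splits caps the total number of
# internal nodes; min_node the smallest node considered for splitting.
fit_tree <- function(X, y, max_splits = 5000L, min_node = 5L) {
  cls <- class_levels(y)
  yi <- match(y, cls)
  K <- length(cls)
  counter <- new.env(parent = emptyenv())
  counter$splits <- 0L

  gini_best <- function(idx) {
    n <- length(idx)
    best <- NULL
    ycnt <- tabulate(yi[idx], K)
    g0 <- 1 - sum((ycnt / n)^2)
    if (g0 <= 0) return(NULL)
    for (j in seq_len(ncol(X))) {
      xv <- X[idx, j]
      ord <- order(xv)
      xs <- xv[ord]; ys <- yi[idx][ord]
      # cumulative class counts along the sorted feature
      cum <- apply(diag(K)[ys, , drop = FALSE], 2L, cumsum)
      if (is.null(dim(cum))) cum <- matrix(cum, nrow = 1L)
      cut_ok <- which(diff(xs) > 0)
      if (!length(cut_ok)) next
      nl <- cut_ok
      nr <- n - nl
      gl <- 1 - rowSums((cum[cut_ok, , drop = FALSE] / nl)^2)
      cr <- matrix(ycnt, length(cut_ok), K, byrow = TRUE) -
        cum[cut_ok, , drop = FALSE]
      gr <- 1 - rowSums((cr / nr)^2)
      gw <- (nl * gl + nr * gr) / n
      b <- which.min(gw)
      if (is.null(best) || gw[b] < best$gw - 1e-12) {
        best <- list(gw = gw[b], j = j,
                     thr = (xs[cut_ok[b]] + xs[cut_ok[b] + 1L]) / 2)
      }
    }
    if (!is.null(best) && best$gw < g0 - 1e-12) best else NULL
  }

  grow <- function(idx) {
    ycnt <- tabulate(yi[idx], K)
    leaf <- list(leaf = TRUE, class = cls[which.max(ycnt)])
    if (length(idx) < min_node || counter$splits >= max_splits) return(leaf)
    sp <- gini_best(idx)
    if (is.null(sp)) return(leaf)
    counter$splits <- counter$splits + 1L
    left <- idx[X[idx, sp$j] <= sp$thr]
    right <- idx[X[idx, sp$j] > sp$thr]
    if (!length(left) || !length(right)) return(leaf)
    list(leaf = FALSE, j = sp$j, thr = sp$thr,
         left = grow(left), right = grow(right))
  }

  structure(list(root = grow(seq_len(nrow(X))), classes = cls,
                 n_splits = counter$splits), class = "har_tree")
}

predict_tree <- function(fit, Xnew) {
  one <- function(x) {
    node <- fit$root
    while (!node$leaf) {
      node <- if (x[node$j] <= node$thr) node$left else node$right
    }
    node$class
  }
  apply(Xnew, 1L, one)
}

## ---- Gaussian-kernel SVM (simplified SMO, one-vs-one) ---------------------

gaussian_kernel <- function(A, B, scale = 3) {
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
  exp(-pmax(d2, 0) / scale^2)
}

# simplified SMO for one binary problem; y in {-1, +1}
smo_binary <- function(K, y, C = 1, tol = 1e-3, max_passes = 5L) {
  n <- length(y)
  alpha <- numeric(n)
  b <- 0
  passes <- 0L
  fcache <- function() as.vector(K %*% (alpha * y)) + b
  while (passes < max_passes) {
    changed <- 0L
    f <- fcache()
    E <- f - y
    for (i in seq_len(n)) {
      if ((y[i] * E[i] < -tol && alpha[i] < C) ||
          (y[i] * E[i] > tol && alpha[i] > 0)) {
        j <- sample.int(n - 1L, 1L)
        if (j >= i) j <- j + 1L
        eta <- 2 * K[i, j] - K[i, i] - K[j, j]
        if (eta >= 0) next
        if (y[i] != y[j]) {
          L <- max(0, alpha[j] - alpha[i]); H <- min(C, C + alpha[j] - alpha[i])
        } else {
          L <- max(0, alpha[i] + alpha[j] - C); H <- min(C, alpha[i] + alpha[j])
        }
        if (L >= H) next
        aj_old <- alpha[j]; ai_old <- alpha[i]
        aj <- aj_old - y[j] * (E[i] - E[j]) / eta
        aj <- min(max(aj, L), H)
        if (abs(aj - aj_old) < 1e-5) next
        ai <- ai_old + y[i] * y[j] * (aj_old - aj)
        alpha[i] <- ai; alpha[j] <- aj
        b1 <- b - E[i] - y[i] * (ai - ai_old) * K[i, i] -
          y[j] * (aj - aj_old) * K[i, j]
        b2 <- b - E[j] - y[i] * (ai - ai_old) * K[i, j] -
          y[j] * (aj - aj_old) * K[j, j]
        b <- if (ai > 0 && ai < C) b1 else if (aj > 0 && aj < C) b2
        else (b1 + b2) / 2
        f <- fcache(); E <- f - y
        changed <- changed + 1L
      }
    }
    passes <- if (changed == 0L) passes + 1L else 0L
  }
  list(alpha = alpha, b = b)
}

fit_svm <- function(X, y, kernel_scale = 3, C = 1, seed = 1L) {
  cls <- class_levels(y)
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  Xs <- scale(X, mu, sdv)
  pairs <- utils::combn(cls, 2L, simplify = FALSE)
  with_seed(seed, {
    models <- lapply(pairs, function(pr) {
      idx <- which(y %in% pr)
      yy <- ifelse(y[idx] == pr[1], 1, -1)
      Xp <- Xs[idx, , drop = FALSE]
      K <- gaussian_kernel(Xp, Xp, kernel_scale)
      fit <- smo_binary(K, yy)
      sv <- which(fit$alpha > 1e-8)
      list(pair = pr, X = Xp[sv, , drop = FALSE],
           coef = (fit$alpha * yy)[sv], b = fit$b)
    })
    structure(list(models = models, classes = cls, mu = mu, sd = sdv,
                   kernel_scale = kernel_scale), class = "har_svm")
  })
}

predict_svm <- function(fit, Xnew) {
  Xs <- scale(Xnew, fit$mu, fit$sd)
  votes <- matrix(0L, nrow(Xs), length(fit$classes),
                  dimnames = list(NULL, fit$classes))
  for (m in fit$models) {
    if (nrow(m$X) == 0L) {
      dec <- rep(m$b, nrow(Xs))
    } else {
      dec <- gaussian_kernel(Xs, m$X, fit$kernel_scale) %*% m$coef + m$b
    }
    win <- ifelse(dec >= 0, m$pair[1], m$pair[2])
    for (cl in m$pair) votes[, cl] <- votes[, cl] + (win == cl)
  }
  fit$classes[max.col(votes, ties.method = "first")]
}

class_levels <- function(y) {
  present <- unique(y)
  if (all(present %in% activity_codes())) {
    intersect(activity_codes(), present)
  } else sort(present)
}

#' Fit a single baseline classifier
#'
#' @param kind One of `"svm"` (Gaussian kernel, scale 3, one-vs-one SMO, on
#'   z-scored features), `"dt"` (Gini CART, at most 5,000 splits) or
#'   `"knn"` (distance-weighted Euclidean voting, 10 neighbours).
#' @param X Feature matrix (rows = windows).
#' @param y Class labels.
#' @param k Neighbours for `"knn"` (default 10).
#' @param max_splits,min_node Tree budget and smallest splittable node.
#' @param kernel_scale,C Gaussian kernel scale and box constraint for
#'   `"svm"`.
#' @param seed Seed for the SVM's SMO working-pair draws.
#' @return Fitted model object with a matching `predict_baseline()` method.
#' @export
fit_baseline <- function(kind, X, y, k = 10L, max_splits = 5000L,
                         min_node = 5L, kernel_scale = 3, C = 1, seed = 1L) {
  switch(kind,
    knn = fit_knn(X, y, k = k),
    dt = fit_tree(X, y, max_splits = max_splits, min_node = min_node),
    svm = fit_svm(X, y, kernel_scale = kernel_scale, C = C, seed = seed),
    stop_harcnn("harcnn_bad_value", "unknown baseline kind '%s'", kind)
  )
}

#' @rdname fit_baseline
#' @param fit A fitted baseline model.
#' @param Xnew New feature matrix.
#' @export
predict_baseline <- function(fit, Xnew) {
  if (inherits(fit, "har_knn")) return(unname(predict_knn(fit, Xnew)))
  if (inherits(fit, "har_tree")) return(unname(predict_tree(fit, Xnew)))
  if (inherits(fit, "har_svm")) return(unname(predict_svm(fit, Xnew)))
  stop_harcnn("harcnn_bad_value", "not a baseline model")
}

#' Cross-validate a baseline classifier on block-wise folds
#'
#' Uses exactly the same fold assignment as the network so accuracies are
#' comparable.
#'
#' @param kind Baseline kind; see [fit_baseline()].
#' @param X Feature matrix aligned with `labels`.
#' @param labels Class labels.
#' @param folds A [make_folds()] assignment aligned with rows of `X`.
#' @inheritParams fit_baseline
#' @return List of class `har_baseline_cv`: `kind`, per-fold `matrices`,
#'   `pooled` matrix.
#' @export
train_baseline <- function(kind, X, labels, folds, k = 10L,
                           max_splits = 5000L, min_node = 5L,
                           kernel_scale = 3, C = 1, seed = 1L) {
  stopifnot(inherits(folds, "har_folds"), nrow(X) == length(labels),
            length(folds$fold) == nrow(X))
  classes <- class_levels(labels)
  mats <- vector("list", folds$k)
  for (i in seq_len(folds$k)) {
    tr <- folds$fold != i
    fit <- fit_baseline(kind, X[tr, , drop = FALSE], labels[tr], k = k,
                        max_splits = max_splits, min_node = min_node,
                        kernel_scale = kernel_scale, C = C, seed = seed)
    preds <- predict_baseline(fit, X[!tr, , drop = FALSE])
    mats[[i]] <- confusion_matrix(labels[!tr], preds, classes)
  }
  structure(list(kind = kind, matrices = mats, pooled = Reduce(`+`, mats)),
            class = "har_baseline_cv")
}
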