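# Shared fixtures and independent oracles. Oracles here are deliberately
# naive (nested loops, finite differences, raw FFT argmax) and never call
# the package's fast paths.

# brute-force valid stride-1 convolution, straight from the definition
oracle_conv <- function(x, f, b = numeric(dim(f)[4])) {
  dx <- dim(x); df <- dim(f)
  H2 <- dx[1] - df[1] + 1L
  W2 <- dx[2] - df[2] + 1L
  y <- array(0, c(H2, W2, df[4]))
  for (i in seq_len(H2)) for (j in seq_len(W2)) for (dd in seq_len(df[4])) {
    acc <- b[dd]
    for (ii in seq_len(df[1])) for (jj in seq_len(df[2]))
      for (d in seq_len(df[3])) {
        acc <- acc + f[ii, jj, d, dd] * x[i + ii - 1L, j + jj - 1L, d]
      }
    y[i, j, dd] <- acc
  }
  y
}

# central-difference gradient of the batch loss w.r.t. one scalar parameter
oracle_num_grad <- function(params, X, y, get, set, eps = 1e-6) {
  lossfn <- function(p) {
    harcnn:::softmax_xent(harcnn:::net_forward(X, p)$logits, y)$loss
  }
  p1 <- set(params, get(params) + eps)
  p2 <- set(params, get(params) - eps)
  (lossfn(p1) - lossfn(p2)) / (2 * eps)
}

# raw FFT-argmax frequency estimate, independent of dominant_frequency()
oracle_peak_freq <- function(v, fs) {
  v <- v - mean(v)
  n <- length(v)
  sp <- Mod(stats::fft(v))[2:(n %/% 2 + 1L)]
  which.max(sp) / n * fs
}

# small well-separated three-class bundle (walking / jumping / still)
toy_bundle <- function(seed = 42L, duration_s = 6, n_subjects = 2L) {
  recs <- list()
  harcnn:::with_seed(seed, {
    for (s in seq_len(n_subjects)) {
      for (act in c("WS", "JR", "NA")) {
        recs[[length(recs) + 1L]] <- simulate_recording(
          sprintf("s%02d", s), act, duration_s)
      }
    }
  })
  recs <- lapply(recs, highpass_filter)
  build_dataset(recs, augmentation_config(rng_seed = seed))
}

# reduced-width network for fast training tests (full 128 x 3 input)
toy_spec <- function(n_classes = 3L) {
  network_spec(blocks = list(c(7L, 12L), c(6L, 16L), c(5L, 16L)),
               fc_width = 32L, n_classes = n_classes)
}

# memoised scaled end-to-end benchmark shared by the acceptance tests:
# default cohort -> filter -> augment -> 2-fold CV CNN (+ baselines on the
# same folds). Runs once per test session per seed.
.benchmark_cache <- new.env(parent = emptyenv())

benchmark_run <- function(seed, with_baselines = FALSE) {
  key <- paste0("s", seed, if (with_baselines) "b" else "")
  hit <- .benchmark_cache[[key]]
  if (!is.null(hit)) return(hit)
  cohort <- simulate_cohort(cohort_config(rng_seed = seed),
                            class_signal_models(separated = TRUE))
  recs <- lapply(cohort$recordings, highpass_filter)
  bundle <- build_dataset(recs, augmentation_config(rng_seed = seed))
  folds <- make_folds(bundle, 2L)
  cfg <- scaled_train_config(seed)
  cv <- cross_validate(bundle, cfg, folds = folds)
  out <- list(bundle = bundle, folds = folds, cv = cv)
  if (with_baselines) {
    ft <- feature_table(bundle)
    out$baselines <- lapply(c(svm = "svm", dt = "dt", knn = "knn"),
                            function(kind) {
                              train_baseline(kind, ft$X, ft$labels, folds,
                                             seed = seed)
                            })
  }
  .benchmark_cache[[key]] <- out
  out
}

# the scaled desk regimen used by the packaged benchmark (mirrors
# default_run_config()$training)
scaled_train_config <- function(seed) {
  tc <- default_run_config(seed)$training
  train_config(base_lr = tc$base_lr,
               lr_halving_period_epochs = tc$lr_halving_period_epochs,
               max_epochs = tc$max_epochs, batch_size = tc$batch_size,
               early_stop_smoothing_window = tc$early_stop_smoothing_window,
               rng_seed = seed)
}
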