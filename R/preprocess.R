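# Preprocessing: zero-phase high-pass filtering, 50 %-overlap window
# segmentation, random rigid-rotation augmentation, and block-wise fold
# assembly.

#' Augmentation configuration
#'
#' Rotation bounds simulate misalignment of the worn sensor: yaw about the
#' vertical axis up to +/-10 deg, pitch up to +/-15 deg, roll up to +/-20 deg
#' (defaults). `copies_per_window` rotated copies are appended adjacent to
#' each base window by [build_dataset()].
#'
#' @param max_yaw_deg,max_pitch_deg,max_roll_deg Non-negative angle bounds in
#'   degrees (defaults 10, 15, 20).
#' @param copies_per_window Non-negative integer number of rotated copies per
#'   base window (default 1).
#' @param rng_seed Integer seed used by [build_dataset()] when drawing angles.
#' @return Object of class `har_augmentation_config`.
#' @export
augmentation_config <- function(max_yaw_deg = 10, max_pitch_deg = 15,
                                max_roll_deg = 20, copies_per_window = 1L,
                                rng_seed = 1L) {
  stopifnot(max_yaw_deg >= 0, max_pitch_deg >= 0, max_roll_deg >= 0,
            copies_per_window >= 0)
  structure(
    list(max_yaw_deg = max_yaw_deg, max_pitch_deg = max_pitch_deg,
         max_roll_deg = max_roll_deg,
         copies_per_window = as.integer(copies_per_window),
         rng_seed = as.integer(rng_seed)),
    class = "har_augmentation_config"
  )
}

#' Zero-phase frequency-domain high-pass filter
#'
#' Removes the gravity/bias component: each axis is Fourier-transformed, all
#' bins strictly below `cutoff_hz` (including DC) are zeroed, and the signal
#' is inverse-transformed. The filter is zero-phase and exactly idempotent.
#'
#' @param recording A [triaxial_recording()].
#' @param cutoff_hz Cutoff in Hz (default 0.5); must be below Nyquist.
#' @return Filtered recording of identical length.
#' @export
highpass_filter <- function(recording, cutoff_hz = 0.5) {
  stopifnot(inherits(recording, "har_recording"))
  n <- nrow(recording$samples)
  if (n < 2L) {
    stop_harcnn("harcnn_bad_shape", "need at least 2 samples to filter")
  }
  fs <- recording$sample_rate_hz
  if (cutoff_hz >= fs / 2) {
    stop_harcnn("harcnn_bad_value",
                "cutoff %g Hz is not below Nyquist (%g Hz)", cutoff_hz, fs / 2)
  }
  freqs <- (seq_len(n) - 1L) / n * fs          # bin frequencies, 0 .. fs
  freqs <- pmin(freqs, fs - freqs)             # two-sided: distance to 0
  keep <- freqs >= cutoff_hz
  filt <- apply(recording$samples, 2L, function(v) {
    Re(stats::fft(stats::fft(v) * keep, inverse = TRUE)) / n
  })
  out <- recording
  out$samples <- filt
  colnames(out$samples) <- c("x", "y", "z")
  out
}

#' Segment a recording into overlapping windows
#'
#' Windows of `window_len` samples are taken at stride
#' `floor(window_len * (1 - overlap_fraction))`; with the defaults adjacent
#' windows share half their data. A trailing remainder shorter than a stride
#' is dropped, so the window count is
#' `floor((N - window_len) / stride) + 1`.
#'
#' @param recording A [triaxial_recording()].
#' @param window_len Samples per window (default 128).
#' @param overlap_fraction Fraction of shared samples in `[0, 1)`
#'   (default 0.5).
#' @return List of [new_window()] objects; empty (with a warning) when the
#'   recording is shorter than one window.
#' @export
segment_windows <- function(recording, window_len = 128L,
                            overlap_fraction = 0.5) {
  stopifnot(inherits(recording, "har_recording"), window_len >= 1L,
            overlap_fraction >= 0, overlap_fraction < 1)
  n <- nrow(recording$samples)
  if (n < window_len) {
    warning(sprintf("recording of %d samples is shorter than one window (%d)",
                    n, window_len))
    return(list())
  }
  stride <- max(1L, as.integer(floor(window_len * (1 - overlap_fraction))))
  starts <- seq.int(1L, n - window_len + 1L, by = stride)
  lapply(starts, function(s) {
    new_window(recording$samples[s:(s + window_len - 1L), , drop = FALSE],
               recording$activity, recording$subject_id,
               origin = list(start_index = s, augmented = FALSE),
               window_len = window_len)
  })
}

#' Rotation matrix from roll, pitch, yaw angles
#'
#' Composition order is fixed and documented: roll about x, then pitch about
#' y, then yaw about z, i.e. `R = Rz(yaw) %*% Ry(pitch) %*% Rx(roll)`.
#'
#' @param roll_deg,pitch_deg,yaw_deg Angles in degrees.
#' @return 3x3 orthogonal matrix.
#' @export
rotation_matrix <- function(roll_deg, pitch_deg, yaw_deg) {
  r <- roll_deg * pi / 180; p <- pitch_deg * pi / 180; y <- yaw_deg * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(r), sin(r), 0, -sin(r), cos(r)), 3, 3)
  Ry <- matrix(c(cos(p), 0, -sin(p), 0, 1, 0, sin(p), 0, cos(p)), 3, 3)
  Rz <- matrix(c(cos(y), sin(y), 0, -sin(y), cos(y), 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Apply one random rigid rotation to a window
#'
#' Draws roll/pitch/yaw uniformly within the configured bounds (from R's
#' current RNG stream; seed with `set.seed()` for reproducibility), builds a
#' single rotation matrix and applies it to all sample vectors. Label and
#' subject are preserved; the drawn angles are recorded in `origin`.
#'
#' @param window A [new_window()].
#' @param config An [augmentation_config()].
#' @return Rotated window.
#' @export
random_rotation <- function(window, config = augmentation_config()) {
  stopifnot(inherits(window, "har_window"),
            inherits(config, "har_augmentation_config"))
  roll  <- stats::runif(1, -config$max_roll_deg,  config$max_roll_deg)
  pitch <- stats::runif(1, -config$max_pitch_deg, config$max_pitch_deg)
  yaw   <- stats::runif(1, -config$max_yaw_deg,   config$max_yaw_deg)
  R <- rotation_matrix(roll, pitch, yaw)
  out <- window
  out$values <- window$values %*% t(R)
  colnames(out$values) <- c("x", "y", "z")
  out$origin <- c(window$origin[setdiff(names(window$origin), "augmented")],
                  list(augmented = TRUE, roll_deg = roll, pitch_deg = pitch,
                       yaw_deg = yaw))
  out
}

#' Build an augmented dataset bundle from labeled recordings
#'
#' Each recording is segmented with [segment_windows()]; for every base
#' window, `copies_per_window` independently rotated copies are appended
#' immediately after it. Windows are kept subject-by-subject in input order
#' within each class (the unshuffled data-block layout), so the per-class
#' count is `base * (1 + copies_per_window)`.
#'
#' Filtering is the caller's responsibility ([highpass_filter()] before
#' segmentation); [cmd_preprocess()] wires the full order filter -> segment ->
#' augment -> bundle.
#'
#' @param recordings List of [triaxial_recording()] objects.
#' @param aug An [augmentation_config()]; its `rng_seed` makes the rotation
#'   draws reproducible.
#' @param window_len,overlap_fraction Passed to [segment_windows()].
#' @return A [dataset_bundle()].
#' @export
build_dataset <- function(recordings, aug = augmentation_config(),
                          window_len = 128L, overlap_fraction = 0.5) {
  if (length(recordings) == 0L) {
    stop_harcnn("harcnn_empty", "no recordings supplied")
  }
  windows <- with_seed(aug$rng_seed, {
    out <- list()
    for (rec in recordings) {
      base <- segment_windows(rec, window_len, overlap_fraction)
      for (w in base) {
        out[[length(out) + 1L]] <- w
        if (aug$copies_per_window > 0L) {
          for (k in seq_len(aug$copies_per_window)) {
            out[[length(out) + 1L]] <- random_rotation(w, aug)
          }
        }
      }
    }
    out
  })
  if (length(windows) == 0L) {
    stop_harcnn("harcnn_empty", "all recordings were shorter than one window")
  }
  dataset_bundle(windows)
}

#' Block-wise fold assignment
#'
#' Splits each class's subject-ordered, unshuffled window list into `k`
#' contiguous blocks whose sizes differ by at most one (the first
#' `n mod k` blocks get the extra window); fold `i` of the dataset is the
#' union of block `i` over classes. This deliberately does not shuffle and is
#' not subject-stratified: contiguity minimises train/validation overlap of
#' the 50 %-overlap windows.
#'
#' @param bundle A [dataset_bundle()].
#' @param k Number of folds (default 10).
#' @return Object of class `har_folds`: list with `fold` (integer vector in
#'   `1..k` aligned with `bundle$windows`) and `k`.
#' @export
make_folds <- function(bundle, k = 10L) {
  stopifnot(inherits(bundle, "har_bundle"), k >= 2L)
  k <- as.integer(k)
  fold <- integer(length(bundle$windows))
  for (cl in unique(bundle$labels)) {
    idx <- class_indices(bundle, cl)
    n <- length(idx)
    if (n < k) {
      stop_harcnn("harcnn_too_few",
                  "class %s has %d windows, fewer than k = %d", cl, n, k)
    }
    sizes <- rep(n %/% k, k)
    extra <- n %% k
    if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    fold[idx] <- rep(seq_len(k), times = sizes)
  }
  structure(list(fold = fold, k = k), class = "har_folds")
}
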