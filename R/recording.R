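# Data model: tri-axial recordings, 128x3 windows, dataset bundles.

#' Construct a tri-axial acceleration recording
#'
#' A recording is one subject performing one activity: an ordered sequence of
#' (x, y, z) accelerations in g units at a fixed sample rate. The sensor
#' clips at +/- 4 g; values outside that envelope are retained unaltered but
#' a warning is raised, since in a simulated or re-read signal they indicate
#' a misconfiguration rather than recoverable data.
#'
#' @param samples Numeric matrix with 3 columns (x, y, z), one row per sample.
#' @param activity One of [activity_codes()].
#' @param subject_id Opaque subject identifier (scalar character).
#' @param sample_rate_hz Sampling frequency in Hz (default 45.4).
#' @return An object of class `har_recording`.
#' @export
#' @examples
#' rec <- triaxial_recording(matrix(c(0, 0, 1), 10, 3, byrow = TRUE),
#'                           "NA", "s01")
#' nrow(rec$samples)
triaxial_recording <- function(samples, activity, subject_id,
                               sample_rate_hz = 45.4) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (ncol(samples) != 3L) {
    stop_harcnn("harcnn_bad_shape", "samples must have 3 columns, got %d",
                ncol(samples))
  }
  if (nrow(samples) < 1L) {
    stop_harcnn("harcnn_bad_shape", "recording must contain at least 1 sample")
  }
  if (!all(is.finite(samples))) {
    stop_harcnn("harcnn_bad_value", "recording contains non-finite samples")
  }
  if (!(is.numeric(sample_rate_hz) && length(sample_rate_hz) == 1L &&
        sample_rate_hz > 0)) {
    stop_harcnn("harcnn_bad_value", "sample_rate_hz must be a positive scalar")
  }
  assert_activity_code(activity)
  n_clip <- sum(abs(samples) > 4)
  if (n_clip > 0L) {
    warning(sprintf(
      "%d sample value(s) outside the +/-4 g sensor range (retained)", n_clip))
  }
  colnames(samples) <- c("x", "y", "z")
  structure(
    list(samples = samples, activity = activity,
         subject_id = as.character(subject_id),
         sample_rate_hz = sample_rate_hz),
    class = "har_recording"
  )
}

#' @export
print.har_recording <- function(x, ...) {
  cat(sprintf("<har_recording> subject %s, activity %s: %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$activity, nrow(x$samples), x$sample_rate_hz,
              nrow(x$samples) / x$sample_rate_hz))
  invisible(x)
}

#' Construct a labeled 128x3 window
#'
#' Windows are the classification instances: `window_len` (default 128)
#' consecutive samples of the three axes, about 2.8 s at 45.4 Hz.
#'
#' @param values Numeric matrix, `window_len` rows x 3 columns, finite.
#' @param label Activity code.
#' @param subject_id Subject identifier.
#' @param origin Optional provenance list (source recording, start index,
#'   augmentation angles); kept verbatim.
#' @param window_len Required number of rows (default 128).
#' @return Object of class `har_window`.
#' @export
new_window <- function(values, label, subject_id, origin = list(),
                       window_len = 128L) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != window_len || ncol(values) != 3L) {
    stop_harcnn("harcnn_bad_shape", "window must be %d x 3, got %d x %d",
                window_len, nrow(values), ncol(values))
  }
  if (!all(is.finite(values))) {
    stop_harcnn("harcnn_bad_value", "window contains non-finite values")
  }
  assert_activity_code(label)
  colnames(values) <- c("x", "y", "z")
  structure(
    list(values = values, label = label,
         subject_id = as.character(subject_id), origin = origin),
    class = "har_window"
  )
}

#' @export
print.har_window <- function(x, ...) {
  cat(sprintf("<har_window> %d x 3, label %s, subject %s\n",
              nrow(x$values), x$label, x$subject_id))
  invisible(x)
}

#' Assemble windows into a dataset bundle
#'
#' A bundle holds the per-class window lists in canonical class order; within
#' a class, each subject's windows are contiguous and subjects appear in
#' input order (the unshuffled "data block" layout that block-wise
#' cross-validation relies on). The manifest records per class and subject
#' how many windows were contributed.
#'
#' @param windows List of [new_window()] objects.
#' @return Object of class `har_bundle` with elements `windows` (reordered
#'   list), `labels`, `subjects` (aligned character vectors) and `manifest`
#'   (data.frame class/subject/n_windows in storage order).
#' @export
dataset_bundle <- function(windows) {
  if (length(windows) == 0L) {
    stop_harcnn("harcnn_empty", "cannot build a bundle from zero windows")
  }
  labels <- vapply(windows, function(w) w$label, character(1))
  subjects <- vapply(windows, function(w) w$subject_id, character(1))
  # stable regrouping: canonical class order, subject first-appearance order
  ord <- order(match(labels, activity_codes()),
               match(subjects, unique(subjects)))
  windows <- windows[ord]
  labels <- labels[ord]
  subjects <- subjects[ord]
  key <- paste(labels, subjects, sep = "\r")
  runs <- rle(key)
  parts <- matrix(unlist(strsplit(runs$values, "\r", fixed = TRUE)),
                  ncol = 2, byrow = TRUE)
  manifest <- data.frame(class = parts[, 1], subject = parts[, 2],
                         n_windows = runs$lengths,
                         stringsAsFactors = FALSE)
  structure(
    list(windows = windows, labels = labels, subjects = subjects,
         manifest = manifest),
    class = "har_bundle"
  )
}

#' @export
print.har_bundle <- function(x, ...) {
  cat(sprintf("<har_bundle> %d windows, %d classes, %d subjects\n",
              length(x$windows), length(unique(x$labels)),
              length(unique(x$subjects))))
  tab <- table(factor(x$labels, levels = activity_codes()))
  print(tab[tab > 0 | TRUE])
  invisible(x)
}

# indices of a bundle's windows belonging to one class, in storage order
class_indices <- function(bundle, code) {
  which(bundle$labels == code)
}
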