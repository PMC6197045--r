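# File I/O: delimited-text recordings and window bundles with a JSON manifest.
#
# Native storage is deliberately plain text: a recording is a three-column
# delimited file (comma or tab) with one header line naming axes and units,
# and a bundle is a directory of per-window files plus a manifest mapping
# class code -> ordered window files. This is a portable stand-in for the
# proprietary cell-array bundles such datasets usually ship in.

#' Read a tri-axial recording from delimited text
#'
#' @param path Path to a comma- or tab-delimited file with three numeric
#'   columns (x, y, z in g) and an optional single header line.
#' @param label Activity code to attach.
#' @param subject_id Subject identifier to attach.
#' @param sample_rate_hz Sampling frequency in Hz (default 45.4).
#' @return A [triaxial_recording()].
#' @export
read_recording <- function(path, label, subject_id, sample_rate_hz = 45.4) {
  if (!file.exists(path)) {
    stop_harcnn("harcnn_missing_file", "recording file not found: %s", path)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop_harcnn("harcnn_empty", "recording file is empty: %s", path)
  }
  sep <- if (grepl("\t", lines[[1L]])) "\t" else ","
  rows <- strsplit(lines, sep, fixed = TRUE)
  widths <- lengths(rows)
  if (any(widths != 3L)) {
    stop_harcnn("harcnn_bad_shape",
                "expected 3 columns, found %d (line %d of %s)",
                widths[which(widths != 3L)[1L]],
                which(widths != 3L)[1L], path)
  }
  vals <- suppressWarnings(
    matrix(as.numeric(trimws(unlist(rows))), ncol = 3L, byrow = TRUE))
  # tolerate one header line of axis names; any other non-numeric row is
  # rejected rather than silently dropped
  start <- 1L
  if (anyNA(vals[1L, ])) start <- 2L
  if (start > nrow(vals)) {
    stop_harcnn("harcnn_empty", "no data rows in %s", path)
  }
  vals <- vals[start:nrow(vals), , drop = FALSE]
  if (anyNA(vals)) {
    bad <- which(rowSums(is.na(vals)) > 0)[1L] + start - 1L
    stop_harcnn("harcnn_bad_value", "non-numeric entry at data line %d of %s",
                bad, path)
  }
  triaxial_recording(vals, label, subject_id, sample_rate_hz)
}

#' Write a tri-axial recording as delimited text
#'
#' Writes a `x_g,y_g,z_g` header followed by one comma-separated row per
#' sample, formatted with `%.12g` so that a read/write round trip preserves
#' samples to well under 1e-9 absolute error and rewriting is byte-stable.
#'
#' @param recording A [triaxial_recording()].
#' @param path Destination file path.
#' @return Invisibly, `path`.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "har_recording"))
  s <- recording$samples
  body <- sprintf("%.12g,%.12g,%.12g", s[, 1], s[, 2], s[, 3])
  ok <- tryCatch({
    suppressWarnings(writeLines(c("x_g,y_g,z_g", body), path))
    TRUE
  }, error = function(e) FALSE)
  if (!ok) {
    stop_harcnn("harcnn_unwritable", "cannot write recording to %s", path)
  }
  invisible(path)
}

#' Write a dataset bundle to a directory
#'
#' Lays out one delimited file per window under `dir/windows/` and a
#' `manifest.json` mapping each class code to its ordered window files,
#' subject labels and counts.
#'
#' @param bundle A [dataset_bundle()].
#' @param dir Destination directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_window_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "har_bundle"))
  wdir <- file.path(dir, "windows")
  dir.create(wdir, recursive = TRUE, showWarnings = FALSE)
  classes <- intersect(activity_codes(), unique(bundle$labels))
  manifest <- list(classes = list())
  for (cl in classes) {
    idx <- class_indices(bundle, cl)
    files <- sprintf("windows/%s_%05d.csv", cl, seq_along(idx))
    for (i in seq_along(idx)) {
      w <- bundle$windows[[idx[i]]]
      v <- w$values
      writeLines(c("x_g,y_g,z_g",
                   sprintf("%.12g,%.12g,%.12g", v[, 1], v[, 2], v[, 3])),
                 file.path(dir, files[i]))
    }
    manifest$classes[[cl]] <- list(
      files = files,
      subjects = bundle$subjects[idx],
      n_windows = length(idx)
    )
  }
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(mpath)
}

#' Read a dataset bundle from a directory and manifest
#'
#' @param dir Bundle directory as written by [write_window_bundle()].
#' @param manifest Path to the manifest (default `dir/manifest.json`).
#' @param window_len Expected rows per window (default 128).
#' @return A [dataset_bundle()].
#' @export
read_window_bundle <- function(dir, manifest = file.path(dir, "manifest.json"),
                               window_len = 128L) {
  if (!file.exists(manifest)) {
    stop_harcnn("harcnn_missing_file", "manifest not found: %s", manifest)
  }
  m <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  windows <- list()
  for (cl in names(m$classes)) {
    assert_activity_code(cl)
    entry <- m$classes[[cl]]
    files <- entry$files
    subjects <- entry$subjects %||% rep("unknown", length(files))
    if (!is.null(entry$n_windows) && entry$n_windows != length(files)) {
      stop_harcnn("harcnn_bad_manifest",
                  "manifest count %d != %d files for class %s",
                  entry$n_windows, length(files), cl)
    }
    for (i in seq_along(files)) {
      rec <- read_recording(file.path(dir, files[i]), cl, subjects[i])
      if (nrow(rec$samples) != window_len) {
        stop_harcnn("harcnn_bad_shape",
                    "window file %s has %d rows, expected %d",
                    files[i], nrow(rec$samples), window_len)
      }
      windows[[length(windows) + 1L]] <- new_window(
        rec$samples, cl, subjects[i],
        origin = list(file = files[i]), window_len = window_len)
    }
  }
  dataset_bundle(windows)
}
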