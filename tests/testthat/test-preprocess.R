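test_that("high-pass filter removes DC and passes in-band tones", {
  fs <- 45.4
  # pure DC vanishes
  rec <- triaxial_recording(matrix(0.5, 256, 3), "NA", "s", fs)
  out <- highpass_filter(rec)
  expect_lt(max(abs(out$samples)), 1e-9)

  # ~5 Hz unit tone is untouched (spectral oracle: in-band bins unchanged).
  # The tone sits on the DFT bin nearest 5 Hz: off-bin tones leak a little
  # energy below the cutoff, which any filter zeroing that band must remove.
  t <- (0:511) / fs
  f5 <- round(5 * 512 / fs) / 512 * fs
  tone <- sin(2 * pi * f5 * t)
  rec <- triaxial_recording(cbind(tone, 0, 0), "WS", "s", fs)
  out <- highpass_filter(rec)
  expect_lt(sqrt(mean((out$samples[, 1] - tone)^2)), 1e-6)

  # linearity: DC + ~2 Hz tone -> the tone alone
  f2 <- round(2 * 512 / fs) / 512 * fs
  tone2 <- sin(2 * pi * f2 * t)
  rec <- triaxial_recording(cbind(1 + tone2, 0, 0), "WS", "s", fs)
  out <- highpass_filter(rec)
  expect_lt(sqrt(mean((out$samples[, 1] - tone2)^2)), 1e-6)

  # idempotence within 1e-6 RMS
  noisy <- simulate_recording("s", "RS", 6, seed = 4)
  once <- highpass_filter(noisy)
  twice <- highpass_filter(once)
  expect_lt(sqrt(mean((twice$samples - once$samples)^2)), 1e-6)

  expect_error(highpass_filter(noisy, cutoff_hz = 23), class = "harcnn_bad_value")
})

test_that("segmentation counts follow the closed-form floor rule", {
  mk <- function(n) triaxial_recording(matrix(seq_len(3 * n) / (3 * n), n, 3),
                                       "WS", "s")
  expect_length(segment_windows(mk(128)), 1L)
  w <- segment_windows(mk(192))
  expect_length(w, 2L)
  expect_identical(vapply(w, function(x) x$origin$start_index, integer(1)),
                   c(1L, 65L))     # starts 0 and 64, one-based
  expect_length(segment_windows(mk(320)), 4L)
  expect_warning(out <- segment_windows(mk(100)), "shorter")
  expect_length(out, 0L)

  # property sweep over lengths
  for (n in seq(128L, 2048L, by = 37L)) {
    stride <- 64L
    expect_length(segment_windows(mk(n)), (n - 128L) %/% stride + 1L)
  }
  # non-default overlap
  expect_length(segment_windows(mk(200), overlap_fraction = 0), 1L)
  expect_length(segment_windows(mk(256), overlap_fraction = 0), 2L)
})

test_that("random rotations are rigid, reproducible and invertible", {
  w <- new_window(matrix(rnorm(128 * 3), 128, 3), "JR", "s")
  # zero bounds: exact identity
  r0 <- random_rotation(w, augmentation_config(0, 0, 0))
  expect_identical(r0$values, w$values)

  set.seed(31)
  for (i in 1:20) {
    r <- random_rotation(w, augmentation_config())
    expect_lt(max(abs(sqrt(rowSums(r$values^2)) -
                        sqrt(rowSums(w$values^2)))), 1e-9)
    # invertible by the transposed matrix
    R <- rotation_matrix(r$origin$roll_deg, r$origin$pitch_deg,
                         r$origin$yaw_deg)
    expect_lt(max(abs(r$values %*% R - w$values)), 1e-9)
    expect_true(abs(r$origin$yaw_deg) <= 10)
    expect_true(abs(r$origin$pitch_deg) <= 15)
    expect_true(abs(r$origin$roll_deg) <= 20)
  }

  # same seed, same draw
  set.seed(5); a <- random_rotation(w, augmentation_config())
  set.seed(5); b <- random_rotation(w, augmentation_config())
  expect_identical(a$values, b$values)
  expect_identical(a$origin, b$origin)
})

test_that("build_dataset appends rotated copies adjacent to their base", {
  rec <- simulate_recording("A", "WS", 192 / 45.4 + 0.01, seed = 2)
  b <- build_dataset(list(rec), augmentation_config(copies_per_window = 1))
  expect_length(b$windows, 4L)   # 2 base + 2 rotated
  expect_identical(vapply(b$windows, function(w) isTRUE(w$origin$augmented),
                          logical(1)), c(FALSE, TRUE, FALSE, TRUE))

  b0 <- build_dataset(list(rec), augmentation_config(copies_per_window = 0))
  expect_length(b0$windows, 2L)
  expect_false(any(vapply(b0$windows, function(w) isTRUE(w$origin$augmented),
                          logical(1))))

  # subject ordering within a class
  recB <- simulate_recording("B", "WS", 5, seed = 3)
  b2 <- build_dataset(list(rec, recB), augmentation_config())
  expect_identical(rle(b2$subjects)$values, c("A", "B"))
  expect_error(build_dataset(list()), class = "harcnn_empty")

  # deterministic given the config seed
  b3 <- build_dataset(list(rec), augmentation_config(copies_per_window = 1))
  expect_identical(b3$windows[[2]]$values, b$windows[[2]]$values)
})

test_that("fold assignment is a balanced contiguous partition", {
  mk_windows <- function(n, cl, subj = "s1") {
    lapply(seq_len(n), function(i)
      new_window(matrix(i, 128, 3), cl, subj))
  }
  b <- dataset_bundle(c(mk_windows(20, "WS"), mk_windows(23, "JR")))
  f <- make_folds(b, 10L)
  ws_sizes <- as.vector(table(f$fold[b$labels == "WS"]))
  jr_sizes <- as.vector(table(f$fold[b$labels == "JR"]))
  expect_identical(ws_sizes, rep(2L, 10))
  expect_identical(sort(jr_sizes, decreasing = TRUE),
                   c(3L, 3L, 3L, rep(2L, 7)))
  # partition: disjoint, exhaustive
  expect_identical(sort(unique(f$fold)), 1:10)
  expect_length(f$fold, length(b$windows))
  # contiguity: fold index is non-decreasing inside each class
  for (cl in c("WS", "JR")) {
    expect_true(!is.unsorted(f$fold[b$labels == cl]))
  }
  # determinism
  expect_identical(make_folds(b, 10L)$fold, f$fold)
  expect_error(make_folds(b, 25L), class = "harcnn_too_few")
})
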