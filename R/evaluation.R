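# Evaluation: confusion matrices, per-class recall/precision/F1, overall
# accuracy, class merging, specificity with the still class as the negative,
# and percentage views.
#
# Orientation: this package stores counts[true, predicted]. Published
# benchmark tables for this problem are laid out transposed (predicted in
# rows, true classes in columns, each column summing to 100 %); `t()` maps
# between the two layouts and the diagonal is unaffected.

#' Confusion matrix from paired labels
#'
#' @param truths,preds Equal-length character vectors of class codes.
#' @param classes Class levels fixing row/column order (default: canonical
#'   activity order restricted to the codes present, or [activity_codes()]
#'   when all labels are standard).
#' @return Square integer matrix, rows = true class, columns = predicted.
#' @export
confusion_matrix <- function(truths, preds, classes = NULL) {
  if (length(truths) != length(preds)) {
    stop_harcnn("harcnn_bad_shape", "truths (%d) and preds (%d) differ in length",
                length(truths), length(preds))
  }
  if (is.null(classes)) {
    present <- unique(c(truths, preds))
    classes <- if (all(present %in% activity_codes())) {
      intersect(activity_codes(), if (length(present)) present else activity_codes())
    } else sort(present)
    if (length(classes) == 0L) classes <- activity_codes()
  }
  m <- table(factor(truths, levels = classes),
             factor(preds, levels = classes))
  m <- matrix(as.integer(m), length(classes), length(classes),
              dimnames = list(true = classes, predicted = classes))
  m
}

#' Overall accuracy of a confusion matrix
#'
#' @param matrix Square count matrix (true x predicted).
#' @return Trace divided by grand total.
#' @export
overall_accuracy <- function(matrix) {
  total <- sum(matrix)
  if (total == 0) {
    stop_harcnn("harcnn_empty", "confusion matrix has no observations")
  }
  sum(diag(matrix)) / total
}

#' Per-class recall, precision and F1
#'
#' Recall is the diagonal over the true-class total, precision the diagonal
#' over the predicted-class total, F1 their harmonic mean. A zero
#' denominator yields `NA` (an explicit undefined marker, never an error);
#' undefined values are excluded from any averaging done downstream.
#'
#' @param matrix Square count matrix (true x predicted).
#' @return `data.frame` with columns class, support, recall, precision, f1,
#'   and the overall accuracy in attribute `overall_accuracy`.
#' @export
per_class_metrics <- function(matrix) {
  di <- diag(matrix)
  true_tot <- rowSums(matrix)
  pred_tot <- colSums(matrix)
  recall <- ifelse(true_tot > 0, di / true_tot, NA_real_)
  precision <- ifelse(pred_tot > 0, di / pred_tot, NA_real_)
  f1 <- ifelse(!is.na(recall) & !is.na(precision) & (recall + precision) > 0,
               2 * recall * precision / (recall + precision), NA_real_)
  out <- data.frame(class = rownames(matrix) %||% as.character(seq_len(nrow(matrix))),
                    support = as.integer(true_tot),
                    recall = unname(recall), precision = unname(precision),
                    f1 = unname(f1), stringsAsFactors = FALSE)
  attr(out, "overall_accuracy") <- overall_accuracy(matrix)
  out
}

#' Merge confusion-matrix classes
#'
#' Sums rows and columns over the preimages of each merged group; the grand
#' total is conserved and the overall accuracy can only increase (confusions
#' inside a merged group move onto the diagonal).
#'
#' @param matrix Square count matrix with class dimnames.
#' @param mapping Named character vector original -> merged (default
#'   [merge_map()] over the matrix's classes).
#' @return Merged count matrix; groups ordered canonically
#'   ([merged_codes()]) when applicable, else by first appearance.
#' @export
merge_classes <- function(matrix, mapping = NULL) {
  classes <- rownames(matrix)
  if (is.null(classes)) {
    stop_harcnn("harcnn_bad_shape", "matrix must carry class dimnames")
  }
  mapping <- mapping %||% merge_map(classes)
  if (!all(classes %in% names(mapping))) {
    stop_harcnn("harcnn_bad_class", "mapping is missing class(es): %s",
                paste(setdiff(classes, names(mapping)), collapse = ", "))
  }
  to <- unname(mapping[classes])
  groups <- unique(to)
  if (all(groups %in% merged_codes())) {
    groups <- intersect(merged_codes(), groups)
  }
  g <- factor(to, levels = groups)
  m <- rowsum(matrix, g)
  m <- t(rowsum(t(m), g))
  m <- matrix(as.integer(m), length(groups), length(groups),
              dimnames = list(true = groups, predicted = groups))
  m
}

#' Specificity with one class as the designated negative
#'
#' With the still class (`NA`) as the negative and every movement class
#' pooled as positive, the specificity of the classifier equals the
#' negative class's recall: the fraction of true negative-class windows
#' predicted as the negative class.
#'
#' @param matrix Square count matrix with class dimnames.
#' @param negative Negative class code (default `"NA"`, the still class).
#' @return Specificity in `[0, 1]`.
#' @export
specificity_vs_negative <- function(matrix, negative = "NA") {
  if (!(negative %in% rownames(matrix))) {
    stop_harcnn("harcnn_bad_class", "negative class %s absent from matrix",
                negative)
  }
  matrix[negative, negative] / sum(matrix[negative, ])
}

#' Column-percentage view of a confusion matrix
#'
#' Scales every column to percentages summing to 100. Published tables for
#' this problem put true classes in columns, so
#' `column_percent_matrix(t(m))` reproduces them from this package's
#' (true x predicted) orientation with recall on the diagonal.
#'
#' @param matrix Square count matrix; every column total must be positive.
#' @return Real matrix of percentages.
#' @export
column_percent_matrix <- function(matrix) {
  cs <- colSums(matrix)
  if (any(cs == 0)) {
    stop_harcnn("harcnn_empty", "column(s) with zero total: %s",
                paste(colnames(matrix)[cs == 0], collapse = ", "))
  }
  sweep(matrix, 2L, cs, "/") * 100
}

#' Bundled reference confusion matrix
#'
#' The published 10-fold cross-validated confusion matrix for the ten child
#' activities (18,363 validation windows, waist-worn sensor benchmark) in
#' this package's (true x predicted) orientation. It is the worked example
#' the evaluation module is checked against: overall accuracy 81.2 %,
#' merged accuracy 91.1 %, specificity 99.2 % with NA as the negative.
#'
#' @param merged Return the seven-class merged matrix instead (computed via
#'   [merge_classes()]).
#' @return Integer count matrix.
#' @export
reference_confusion <- function(merged = FALSE) {
  codes <- activity_codes()
  # predicted-in-rows layout as published; transposed below to (true, pred)
  printed <- matrix(c(
    1368,  428,   29,    5,  116,   19,    4,    0,    0,    2,
     357, 1060,   52,   16,   43,    7,   10,    0,    0,    0,
       2,   47,  886,  366,   42,   44,   59,    0,    0,    0,
       1,    5,  536, 1321,   23,   40,   43,    0,    0,    0,
     136,   66,    8,    6,  906,   64,   32,    2,    1,    0,
      33,   21,   51,   36,   65,  796,   70,    2,    2,    0,
      10,   14,   38,   23,  193,   67, 1621,    0,    0,    0,
       4,    1,    0,    0,    6,    1,    0, 2425,   66,    6,
       1,    1,    1,    0,    1,    3,    0,   73, 2468,    8,
       3,    1,    0,    0,   21,    0,    0,   13,   13, 2053),
    nrow = 10, byrow = TRUE, dimnames = list(codes, codes))
  m <- t(printed)
  dimnames(m) <- list(true = codes, predicted = codes)
  storage.mode(m) <- "integer"
  if (merged) merge_classes(m) else m
}

#' Structured metrics report
#'
#' Computes the full evaluation block for a pooled confusion matrix: counts,
#' per-class metrics, overall accuracy and specificity, plus the same block
#' after class merging. Cross-validation results additionally carry per-fold
#' matrices and the mean-over-folds accuracy (pooled values are the ones
#' that match published tables; both are reported).
#'
#' @param pooled Square count matrix (true x predicted).
#' @param per_fold Optional list of per-fold matrices summing to `pooled`.
#' @return Nested list ready for JSON serialization.
#' @export
metrics_report <- function(pooled, per_fold = NULL) {
  block <- function(m) {
    pm <- per_class_metrics(m)
    list(classes = rownames(m),
         confusion = unname(apply(m, 1L, as.integer, simplify = FALSE)),
         per_class = pm,
         overall_accuracy = overall_accuracy(m),
         specificity_vs_na = if ("NA" %in% rownames(m))
           specificity_vs_negative(m) else NULL)
  }
  rep10 <- block(pooled)
  repm <- block(merge_classes(pooled))
  out <- list(unmerged = rep10, merged = repm)
  if (!is.null(per_fold)) {
    out$per_fold_accuracy <- vapply(per_fold, overall_accuracy, numeric(1))
    out$mean_fold_accuracy <- mean(out$per_fold_accuracy)
  }
  out
}

#' Write a confusion matrix as labeled CSV
#'
#' @param matrix Count matrix with dimnames.
#' @param path Destination path.
#' @return Invisibly, `path`.
#' @export
write_confusion_csv <- function(matrix, path) {
  utils::write.csv(as.data.frame(matrix), path)
  invisible(path)
}
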