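#' Confusion matrix of predicted versus pathology labels
#'
#' Exact cross-tabulation of per-pixel truth (rows) against prediction
#' (columns), classes ordered cancer, glands, stroma.
#'
#' @param truth,predicted Vectors of labels over [TISSUE_CLASSES] (equal
#'   length), or factors/`pixel_prediction` classes.
#' @return An object of class `confusion_matrix` (an integer matrix with
#'   attribute `n_pixels`).
#' @export
confusion_matrix <- function(truth, predicted) {
  if (inherits(predicted, "pixel_prediction")) predicted <- predicted$class
  truth <- as_class_factor(truth)
  predicted <- as_class_factor(predicted)
  if (length(truth) != length(predicted))
    stop("validation error: truth and prediction lengths differ")
  as_confusion_matrix(table(truth = truth, predicted = predicted))
}

#' @noRd
as_confusion_matrix <- function(counts) {
  counts <- as.matrix(unclass(counts))
  storage.mode(counts) <- "integer"
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(counts, n_pixels = sum(counts),
            class = c("confusion_matrix", "matrix"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> %d pixels\n", attr(x, "n_pixels")))
  print(unclass(x))
  invisible(x)
}

#' Agreement report with binomial standard errors
#'
#' Per-class agreement is the percentage of pixels of a pathology class
#' that the classifier assigns to that class, `100 * diag_k / rowsum_k`;
#' its standard error is the binomial `100 * sqrt(p(1-p) / rowsum_k)`.
#' Overall agreement is `100 * trace / n` with the analogous SE. Values are
#' kept at full precision; the conventional display rounds agreement to
#' 0.1 and SE to 0.01 (`agreement_display()`). Rows with zero pixels are
#' skipped with a warning.
#'
#' @param cm A [confusion_matrix()].
#' @return An object of class `agreement_report`: list with `per_class`
#'   (data frame: class, n, agreement, se) and `overall` (n, agreement,
#'   se).
#' @export
agreement_report <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- attr(cm, "n_pixels")
  if (n == 0) stop("validation error: empty confusion matrix")
  rs <- rowSums(cm)
  if (any(rs == 0)) {
    warning("classes with zero pixels skipped: ",
            paste(rownames(cm)[rs == 0], collapse = ", "))
  }
  keep <- rs > 0
  p <- diag(as.matrix(cm))[keep] / rs[keep]
  per_class <- data.frame(
    class = rownames(cm)[keep], n = as.integer(rs[keep]),
    agreement = 100 * p,
    se = 100 * sqrt(p * (1 - p) / rs[keep]),
    row.names = NULL)
  pov <- sum(diag(as.matrix(cm))) / n
  structure(list(per_class = per_class,
                 overall = list(n = n, agreement = 100 * pov,
                                se = 100 * sqrt(pov * (1 - pov) / n))),
            class = "agreement_report")
}

#' @param report An `agreement_report`.
#' @rdname agreement_report
#' @return `agreement_display()` returns the report as a data frame with
#'   agreement rounded to 0.1 and SE to 0.01. Following the convention of
#'   the published tables, the displayed SE is recomputed from the rounded
#'   agreement percentage (the full-precision SE stays in the report);
#'   this is what reproduces every printed SE cell.
#' @export
agreement_display <- function(report) {
  stopifnot(inherits(report, "agreement_report"))
  pc <- report$per_class
  agree <- round(c(pc$agreement, report$overall$agreement), 1)
  n <- c(pc$n, report$overall$n)
  p <- agree / 100
  out <- data.frame(
    class = c(pc$class, "overall"),
    n = n,
    agreement = agree,
    se = round(100 * sqrt(p * (1 - p) / n), 2))
  out
}

#' @export
print.agreement_report <- function(x, ...) {
  print(agreement_display(x), row.names = FALSE)
  invisible(x)
}

#' Merge confusion-matrix classes
#'
#' Sums cells under a class mapping, e.g. combining normal glands and
#' normal stroma into a single `normal` class for a two-class
#' cancer-versus-normal reading. The pixel total is preserved.
#'
#' @param cm A [confusion_matrix()].
#' @param mapping Named character vector mapping every source class to its
#'   merged class, e.g. `c(cancer = "cancer", glands = "normal", stroma =
#'   "normal")` (the default).
#' @return A merged [confusion_matrix()].
#' @export
merge_classes <- function(cm, mapping = c(cancer = "cancer",
                                          glands = "normal",
                                          stroma = "normal")) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (!all(rownames(cm) %in% names(mapping)))
    stop("mapping must cover every source class")
  to <- unique(mapping[rownames(cm)])
  out <- matrix(0L, length(to), length(to), dimnames = list(to, to))
  for (i in rownames(cm)) for (j in colnames(cm))
    out[mapping[i], mapping[j]] <- out[mapping[i], mapping[j]] + cm[i, j]
  as_confusion_matrix(out)
}

#' Majority-rule sample verdict
#'
#' A whole sample is called `cancer` when strictly more than half of its
#' predicted pixels are predicted cancerous; exactly half is `normal`.
#' Background pixels are not part of the prediction and never enter the
#' fraction.
#'
#' @param prediction A `pixel_prediction` (or factor of predicted classes).
#' @param sample_id Identifier carried into the verdict.
#' @return An object of class `sample_verdict`: list with `sample_id`,
#'   `fraction_cancer`, `verdict`.
#' @export
majority_rule_verdict <- function(prediction, sample_id = "S1") {
  cls <- if (inherits(prediction, "pixel_prediction")) prediction$class
         else as_class_factor(prediction)
  if (!length(cls)) stop("validation error: no predicted pixels")
  frac <- mean(cls == "cancer")
  structure(list(sample_id = as.character(sample_id),
                 fraction_cancer = frac,
                 verdict = if (frac > 0.5) "cancer" else "normal"),
            class = "sample_verdict")
}

#' @export
print.sample_verdict <- function(x, ...) {
  cat(sprintf("<sample_verdict> %s: %.1f%% cancer pixels -> %s\n",
              x$sample_id, 100 * x$fraction_cancer, x$verdict))
  invisible(x)
}

#' Percent-composition agreement for mixed-histology regions
#'
#' Compares, per annotated region, the percentage of pixels predicted
#' cancerous against the pathologist's visual percent tumor-cell
#' composition; a region passes when the absolute difference is within
#' `tolerance_pct` points.
#'
#' @param prediction A `pixel_prediction` for one sample grid, in
#'   row-major pixel order.
#' @param mask An [annotation_mask()] carrying a region table and map.
#' @param tolerance_pct Pass tolerance in percentage points (default 10).
#' @return Data frame of class `composition_comparison`: `region_id`,
#'   `pathology_pct_cancer`, `predicted_pct_cancer`, `abs_difference`,
#'   `pass`.
#' @export
composition_agreement <- function(prediction, mask, tolerance_pct = 10) {
  stopifnot(inherits(mask, "msi_mask"))
  if (is.null(mask$regions) || is.null(mask$region_map))
    stop("mask carries no region table/map")
  cls <- prediction$class
  map <- as.vector(t(mask$region_map)) # row-major, aligned to prediction
  if (length(map) != length(cls))
    stop("alignment error: prediction does not match the region map")
  out <- do.call(rbind, lapply(seq_len(nrow(mask$regions)), function(i) {
    r <- mask$regions[i, ]
    idx <- which(map == r$region_id)
    pred_pct <- 100 * mean(cls[idx] == "cancer")
    truth_pct <- 100 * r$f_cancer
    data.frame(region_id = r$region_id,
               pathology_pct_cancer = truth_pct,
               predicted_pct_cancer = pred_pct,
               abs_difference = abs(pred_pct - truth_pct),
               pass = abs(pred_pct - truth_pct) <= tolerance_pct)
  }))
  class(out) <- c("composition_comparison", "data.frame")
  out
}

#' Surgical-margin report
#'
#' Flags each margin sample positive when its percentage of
#' cancer-predicted pixels exceeds `threshold_pct`; the case is positive if
#' any margin is flagged. The default threshold of 1% sits below the
#' roughly 2% pixel-level error floor observed for large normal margins, so
#' single-figure-percentage cancer calls are surfaced for review rather
#' than silently absorbed.
#'
#' @param fractions Named numeric vector: per-margin fraction (0-1) of
#'   pixels predicted cancer (names are margin/sample ids). A list of
#'   `sample_verdict`s is also accepted.
#' @param threshold_pct Positivity threshold in percent of pixels.
#' @return An object of class `margin_report`: data frame (`margin_id`,
#'   `pct_cancer`, `flagged`) with attribute `case_positive`.
#' @export
margin_report <- function(fractions, threshold_pct = 1) {
  if (is.list(fractions) && all(vapply(fractions, inherits, TRUE,
                                       "sample_verdict")))
    fractions <- stats::setNames(
      vapply(fractions, `[[`, numeric(1), "fraction_cancer"),
      vapply(fractions, `[[`, character(1), "sample_id"))
  if (!length(fractions)) stop("need predictions for at least one margin")
  ids <- if (is.null(names(fractions)))
    paste0("margin", seq_along(fractions)) else names(fractions)
  out <- data.frame(margin_id = ids, pct_cancer = 100 * as.numeric(fractions),
                    flagged = 100 * as.numeric(fractions) > threshold_pct)
  attr(out, "case_positive") <- any(out$flagged)
  class(out) <- c("margin_report", "data.frame")
  out
}
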