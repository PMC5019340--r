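#' Load the packaged reference feature-weight table
#'
#' The package ships a digitized copy of the published three-class lasso
#' weight table for pancreatic DESI-MSI (one row per m/z feature selected
#' for at least one of cancer / normal glands / normal stroma, weights on
#' the standardized feature scale, printed to three decimals). Cells absent
#' from the published table mean the feature was not selected for that
#' class and are returned as weight 0; the `selected_*` columns preserve
#' which cells were printed, because one printed weight rounds to 0.000 and
#' would otherwise be indistinguishable from "not selected".
#'
#' @param path Path to a weight-table CSV (columns `mz, cancer, glands,
#'   stroma`, empty cells for unselected features). Defaults to the
#'   packaged reference table.
#' @return A data frame of class `weight_table` with columns `mz`,
#'   `cancer`, `glands`, `stroma` (numeric weights, 0 when unselected) and
#'   logical `selected_cancer`, `selected_glands`, `selected_stroma`.
#' @examples
#' wt <- load_reference_weight_table()
#' nrow(wt)                      # 112 distinct m/z features
#' colSums(wt[, paste0("selected_", TISSUE_CLASSES)])
#' @export
load_reference_weight_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "reference_weight_table.csv",
                        package = "desilasso", mustWork = TRUE)
  x <- read.csv(path)
  need <- c("mz", TISSUE_CLASSES)
  if (!all(need %in% names(x)))
    stop("weight table needs columns ", paste(need, collapse = ", "))
  if (anyDuplicated(x$mz))
    stop("validation error: duplicate m/z rows in weight table")
  for (cl in TISSUE_CLASSES) {
    x[[paste0("selected_", cl)]] <- !is.na(x[[cl]])
    x[[cl]][is.na(x[[cl]])] <- 0
  }
  sel <- x[, paste0("selected_", TISSUE_CLASSES)]
  if (any(rowSums(sel) == 0))
    stop("validation error: weight-table row with no selected class")
  x <- x[order(x$mz), ]
  rownames(x) <- NULL
  class(x) <- c("weight_table", "data.frame")
  x
}

#' Count selected features per class in a weight table
#'
#' @param wt A `weight_table` from [load_reference_weight_table()] or
#'   [extract_weight_table()].
#' @return Named integer vector (cancer, glands, stroma).
#' @export
weight_table_counts <- function(wt) {
  sel_cols <- paste0("selected_", TISSUE_CLASSES)
  if (all(sel_cols %in% names(wt))) {
    stats::setNames(as.integer(colSums(wt[, sel_cols])), TISSUE_CLASSES)
  } else {
    stats::setNames(as.integer(colSums(wt[, TISSUE_CLASSES] != 0)),
                    TISSUE_CLASSES)
  }
}

#' Load a packaged reference confusion matrix
#'
#' Digitized pixel-count cross-tabulations (pathology truth by predicted
#' class) for the published training cohort (45,273 pixels over 25
#' patients) and the independent validation cohort (31,235 pixels).
#'
#' @param set `"training"` or `"validation"`.
#' @param path Optional path to a confusion CSV (columns
#'   `truth, cancer, glands, stroma`).
#' @return A [confusion_matrix()] object.
#' @export
load_reference_confusion <- function(set = c("training", "validation"),
                                     path = NULL) {
  set <- match.arg(set)
  if (is.null(path))
    path <- system.file("extdata",
                        paste0("reference_confusion_", set, ".csv"),
                        package = "desilasso", mustWork = TRUE)
  x <- read.csv(path)
  counts <- as.matrix(x[, -1])
  rownames(counts) <- x$truth
  as_confusion_matrix(counts)
}
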