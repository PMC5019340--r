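#' Pixel-resolved MSI sample
#'
#' An `msi_sample` holds one rectangular grid of pixels, each carrying a full
#' mass spectrum over a common [mass_axis()], together with the sample and
#' patient identity. Spectra are stored as a dense matrix with one row per
#' pixel in row-major order (row index varies slowest); pixels without a
#' recorded spectrum (glass slide imaged outside the tissue) are flagged as
#' background and hold all-zero intensities.
#'
#' @param intensities Numeric matrix, `prod(grid)` rows (row-major pixel
#'   order) by `length(axis)` columns; all values must be finite and >= 0.
#' @param grid Integer vector `c(rows, cols)`.
#' @param axis A [mass_axis()] (or numeric vector of channel centers).
#' @param sample_id,patient_id Identifiers; `patient_id` groups samples for
#'   leave-one-patient-out cross-validation.
#' @param pixel_spacing Pixel pitch in micrometers (default 200, the usual
#'   DESI-MSI spatial resolution).
#' @param background Logical vector over pixels marking glass-slide pixels;
#'   default all `FALSE`.
#' @return An object of class `msi_sample`.
#' @export
msi_sample <- function(intensities, grid, axis, sample_id = "S1",
                       patient_id = "P1", pixel_spacing = 200,
                       background = NULL) {
  grid <- as.integer(grid)
  if (length(grid) != 2L || any(grid < 1L)) stop("grid must be c(rows, cols)")
  if (!inherits(axis, "mass_axis")) axis <- mass_axis(axis)
  intensities <- as.matrix(intensities)
  if (nrow(intensities) != prod(grid))
    stop(sprintf("intensity matrix has %d rows but the grid has %d pixels",
                 nrow(intensities), prod(grid)))
  if (ncol(intensities) != length(axis))
    stop(sprintf("spectra have %d channels but the mass axis has %d",
                 ncol(intensities), length(axis)))
  if (any(!is.finite(intensities)) || any(intensities < 0))
    stop("intensities must be finite and non-negative")
  if (is.null(background)) background <- rep(FALSE, prod(grid))
  structure(
    list(sample_id = as.character(sample_id),
         patient_id = as.character(patient_id),
         grid = grid, pixel_spacing = pixel_spacing,
         mz = axis, intensities = intensities,
         background = as.logical(background)),
    class = "msi_sample")
}

#' @export
print.msi_sample <- function(x, ...) {
  cat(sprintf(
    "<msi_sample> %s (patient %s): %dx%d pixels @ %g um, %d channels, %d background\n",
    x$sample_id, x$patient_id, x$grid[1], x$grid[2], x$pixel_spacing,
    length(x$mz), sum(x$background)))
  invisible(x)
}

#' Row-major linear pixel index for 0-based (row, col) coordinates
#' @noRd
pixel_index <- function(row, col, grid) row * grid[2] + col + 1L

#' Per-pixel annotation mask
#'
#' Ground-truth labels for every pixel of a sample grid, as assigned by
#' histopathologic evaluation: one of `cancer`, `glands`, `stroma`,
#' `excluded` (histology outside the three-class problem) or `background`.
#' Optionally carries a region table for mixed-histology tissue, mapping a
#' region id to a percent cell composition (fractions of cancer / glands /
#' stroma summing to 1) plus a region id map aligning regions to pixels.
#'
#' @param labels Character matrix (rows x cols) of labels in
#'   [MASK_LABELS].
#' @param regions Optional data frame with columns `region_id`, `f_cancer`,
#'   `f_glands`, `f_stroma` (fractions in `[0, 1]` summing to 1 per row).
#' @param region_map Optional integer matrix matching `dim(labels)` giving
#'   each pixel's `region_id` (NA outside all regions).
#' @return An object of class `msi_mask`.
#' @export
annotation_mask <- function(labels, regions = NULL, region_map = NULL) {
  labels <- as.matrix(labels)
  bad <- setdiff(unique(as.vector(labels)), MASK_LABELS)
  if (length(bad))
    stop("unknown mask labels: ", paste(bad, collapse = ", "))
  if (!is.null(regions)) {
    need <- c("region_id", "f_cancer", "f_glands", "f_stroma")
    if (!all(need %in% names(regions)))
      stop("region table needs columns ", paste(need, collapse = ", "))
    comp <- as.matrix(regions[, c("f_cancer", "f_glands", "f_stroma")])
    if (any(comp < 0) || any(comp > 1) ||
        any(abs(rowSums(comp) - 1) > 1e-9))
      stop("region compositions must lie in [0,1] and sum to 1")
  }
  if (!is.null(region_map) && !all(dim(region_map) == dim(labels)))
    stop("region_map shape must equal the label grid")
  structure(list(labels = labels, regions = regions, region_map = region_map),
            class = "msi_mask")
}

#' @export
print.msi_mask <- function(x, ...) {
  tab <- table(factor(as.vector(x$labels), levels = MASK_LABELS))
  cat(sprintf("<msi_mask> %dx%d: %s\n", nrow(x$labels), ncol(x$labels),
              paste(sprintf("%s=%d", names(tab), tab), collapse = " ")))
  invisible(x)
}

#' Pixel labels of a mask in row-major order
#' @param mask An [annotation_mask()].
#' @return Character vector of length `prod(dim(labels))`.
#' @export
mask_labels_rowmajor <- function(mask) {
  as.vector(t(mask$labels))
}
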