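#' Binned feature matrix
#'
#' The classifier's input: one row per pixel, one column per spectral
#' feature obtained by averaging the mass axis in non-overlapping bins
#' (default six channels per bin, turning the 13,320-channel axis into
#' 2,220 features about 0.5 m/z wide). Feature labels are the mean m/z of
#' the channels in each bin.
#'
#' @param x Numeric matrix of binned intensities (pixels x features).
#' @param mz Numeric vector of bin-center m/z labels, strictly increasing.
#' @param pixels Data frame with one row per pixel: `sample_id`,
#'   `patient_id`, `row`, `col` (0-based grid coordinates).
#' @return An object of class `msi_features`.
#' @export
msi_features <- function(x, mz, pixels) {
  x <- as.matrix(x)
  if (ncol(x) != length(mz)) stop("feature count does not match mz labels")
  if (any(diff(mz) <= 0)) stop("feature labels must be strictly increasing")
  if (nrow(x) != nrow(pixels)) stop("pixel index does not match matrix rows")
  structure(list(x = x, mz = as.numeric(mz), pixels = pixels),
            class = "msi_features")
}

#' @export
print.msi_features <- function(x, ...) {
  cat(sprintf("<msi_features> %d pixels x %d features (m/z %.1f-%.1f)\n",
              nrow(x$x), ncol(x$x), x$mz[1], x$mz[length(x$mz)]))
  invisible(x)
}

#' @export
dim.msi_features <- function(x) dim(x$x)

#' Average spectra in non-overlapping m/z bins
#'
#' Feature `j` is the arithmetic mean of channels
#' `[(j-1)*bin_size + 1, j*bin_size]`; a trailing partial bin is averaged
#' over its actual members. Labels are the mean m/z of each bin's channels,
#' reported (by `print` and in weight tables) to one decimal, matching the
#' half-unit spacing of the default axis. Binning both reduces
#' dimensionality and absorbs small registration differences between
#' spectra, so no further smoothing or peak alignment is applied.
#'
#' @param sample An [msi_sample()].
#' @param bin_size Channels per bin (default 6).
#' @return An [msi_features()] with `ceiling(channels / bin_size)` columns
#'   (2,220 for the default axis).
#' @examples
#' ax <- mass_axis(mz_min = 100, mz_max = 101.1, n_channels = 12)
#' s <- msi_sample(matrix(1, 1, 12), c(1, 1), ax)
#' fm <- bin_features(s, bin_size = 6)
#' ncol(fm$x) # 2
#' @export
bin_features <- function(sample, bin_size = 6L) {
  stopifnot(inherits(sample, "msi_sample"))
  bin_size <- as.integer(bin_size)
  nch <- length(sample$mz)
  if (bin_size < 1L) stop("bin_size must be >= 1")
  if (bin_size > nch)
    stop("validation error: bin_size exceeds the channel count")
  grp <- rep(seq_len(ceiling(nch / bin_size)), each = bin_size,
             length.out = nch)
  sizes <- tabulate(grp)
  xb <- t(rowsum(t(sample$intensities), grp, reorder = TRUE)) /
    rep(sizes, each = nrow(sample$intensities))
  mzb <- as.vector(rowsum(as.numeric(sample$mz), grp)) / sizes
  grid <- sample$grid
  pixels <- data.frame(
    sample_id = sample$sample_id, patient_id = sample$patient_id,
    row = rep(seq_len(grid[1]) - 1L, each = grid[2]),
    col = rep(seq_len(grid[2]) - 1L, times = grid[1]))
  msi_features(xb, mzb, pixels)
}

#' Total-ion-current normalization (optional, off by default elsewhere)
#'
#' Divides each pixel's features by that pixel's feature sum. Pixels whose
#' sum is zero are left unchanged and flagged in the returned object's
#' `zero_tic` element. The default pipeline feeds raw binned intensities to
#' the solver (which standardizes per feature internally); TIC scaling is
#' provided for users who want intensity-drift robustness at the price of
#' discarding total-abundance contrast, which is itself discriminative for
#' stroma.
#'
#' @param fm An [msi_features()].
#' @return The normalized [msi_features()], with elements `normalized =
#'   TRUE` and logical `zero_tic`.
#' @export
normalize_tic <- function(fm) {
  stopifnot(inherits(fm, "msi_features"))
  tic <- rowSums(fm$x)
  zero <- tic == 0
  scl <- ifelse(zero, 1, tic)
  fm$x <- fm$x / scl
  fm$normalized <- TRUE
  fm$zero_tic <- zero
  fm
}

#' Select annotated tissue pixels for training or testing
#'
#' Keeps only pixels whose mask label is one of the three tissue classes;
#' `excluded` and `background` pixels are dropped. With no mask, a
#' fallback marks pixels as background when their TIC falls below
#' `background_tic_fraction` of the sample's median TIC and returns the
#' rest unlabeled (`NA`), mirroring how glass-slide pixels are imaged but
#' not analyzed.
#'
#' @param fm An [msi_features()] for one sample grid.
#' @param mask An [annotation_mask()] aligned to the same grid, or `NULL`.
#' @param background_tic_fraction Fallback TIC threshold (default 0.05).
#' @return A list with elements `features` (the subset [msi_features()])
#'   and `labels` (factor over [TISSUE_CLASSES], `NA` when unlabeled).
#' @export
select_pixels <- function(fm, mask = NULL, background_tic_fraction = 0.05) {
  stopifnot(inherits(fm, "msi_features"))
  if (is.null(mask)) {
    tic <- rowSums(fm$x)
    keep <- tic >= background_tic_fraction * stats::median(tic)
    labels <- factor(rep(NA_character_, sum(keep)), levels = TISSUE_CLASSES)
  } else {
    lab <- mask_labels_rowmajor(mask)
    if (length(lab) != nrow(fm$x))
      stop(sprintf("alignment error: mask has %d pixels, features have %d",
                   length(lab), nrow(fm$x)))
    keep <- lab %in% TISSUE_CLASSES
    labels <- factor(lab[keep], levels = TISSUE_CLASSES)
  }
  out <- fm
  out$x <- fm$x[keep, , drop = FALSE]
  out$pixels <- fm$pixels[keep, , drop = FALSE]
  rownames(out$pixels) <- NULL
  list(features = out, labels = labels)
}

#' Stack feature matrices from several samples
#'
#' @param fms List of [msi_features()] sharing the same feature labels.
#' @return A single [msi_features()].
#' @export
rbind_features <- function(fms) {
  stopifnot(length(fms) >= 1)
  mz <- fms[[1]]$mz
  for (f in fms)
    if (!isTRUE(all.equal(f$mz, mz)))
      stop("feature matrices have different feature labels")
  msi_features(do.call(rbind, lapply(fms, `[[`, "x")), mz,
               do.call(rbind, lapply(fms, `[[`, "pixels")))
}
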