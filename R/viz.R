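#' Render a three-color prediction map
#'
#' The conventional false-color reading of per-pixel classifications:
#' cancer red, normal glands green, normal stroma blue, background (or
#' unpredicted pixels) white.
#'
#' @param prediction A `pixel_prediction` whose pixels cover a grid in
#'   row-major order (NA class = background).
#' @param grid Integer `c(rows, cols)`.
#' @param file Optional PNG path; written with [png::writePNG()].
#' @return An `rows x cols x 3` RGB array in `[0, 1]` (class
#'   `prediction_image`), invisibly when `file` is given.
#' @export
render_prediction_map <- function(prediction, grid, file = NULL) {
  cls <- if (inherits(prediction, "pixel_prediction")) prediction$class
         else prediction
  grid <- as.integer(grid)
  if (length(cls) != prod(grid))
    stop(sprintf("prediction covers %d pixels but the grid has %d",
                 length(cls), prod(grid)))
  colors <- rbind(cancer = c(1, 0, 0), glands = c(0, 1, 0),
                  stroma = c(0, 0, 1))
  img <- array(1, dim = c(grid[1], grid[2], 3))
  idx <- match(as.character(cls), rownames(colors))
  for (ch in 1:3) {
    plane <- rep(1, prod(grid))
    ok <- !is.na(idx)
    plane[ok] <- colors[idx[ok], ch]
    img[, , ch] <- matrix(plane, grid[1], grid[2], byrow = TRUE)
  }
  class(img) <- c("prediction_image", class(img))
  if (!is.null(file)) {
    png::writePNG(unclass(img), file)
    return(invisible(img))
  }
  img
}

#' Render an ion image
#'
#' Per-pixel summed intensity over a narrow m/z window
#' `[mz_center - window_halfwidth, mz_center + window_halfwidth]` — the
#' standard way to display the spatial distribution of a single lipid ion.
#' A window covering the whole axis yields the TIC image.
#'
#' @param sample An [msi_sample()].
#' @param mz_center Window center, m/z.
#' @param window_halfwidth Half-width, m/z (default 0.25, half a feature
#'   bin).
#' @param file Optional grayscale PNG path (intensities scaled to max 1).
#' @return A `rows x cols` intensity matrix (class `ion_image`, attribute
#'   `window`), invisibly when `file` is given.
#' @export
render_ion_image <- function(sample, mz_center, window_halfwidth = 0.25,
                             file = NULL) {
  stopifnot(inherits(sample, "msi_sample"))
  mz <- as.numeric(sample$mz)
  lo <- mz_center - window_halfwidth
  hi <- mz_center + window_halfwidth
  idx <- which(mz >= lo & mz <= hi)
  if (!length(idx))
    stop(sprintf("validation error: window [%.4g, %.4g] misses the axis",
                 lo, hi))
  vals <- rowSums(sample$intensities[, idx, drop = FALSE])
  img <- matrix(vals, sample$grid[1], sample$grid[2], byrow = TRUE)
  attr(img, "window") <- c(lo, hi)
  class(img) <- c("ion_image", class(img))
  if (!is.null(file)) {
    mx <- max(img)
    png::writePNG(unclass(img) / (if (mx > 0) mx else 1), file)
    return(invisible(img))
  }
  img
}
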