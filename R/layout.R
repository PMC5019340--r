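#' Tissue layout for synthetic samples
#'
#' A layout places rectangular regions on a pixel grid; each region carries
#' a composition vector (fractions of cancer / glands / stroma summing to
#' 1). Regions must not overlap; pixels outside every region are glass
#' background. Row/col bounds are 0-based and inclusive.
#'
#' @param grid Integer `c(rows, cols)`.
#' @param regions Data frame with columns `region_id`, `row0`, `row1`,
#'   `col0`, `col1`, `f_cancer`, `f_glands`, `f_stroma`.
#' @return An object of class `tissue_layout`.
#' @export
tissue_layout <- function(grid, regions) {
  grid <- as.integer(grid)
  need <- c("region_id", "row0", "row1", "col0", "col1",
            "f_cancer", "f_glands", "f_stroma")
  stopifnot(all(need %in% names(regions)))
  comp <- as.matrix(regions[, c("f_cancer", "f_glands", "f_stroma")])
  if (any(comp < 0) || any(abs(rowSums(comp) - 1) > 1e-9))
    stop("region compositions must be non-negative and sum to 1")
  if (any(regions$row1 < regions$row0) || any(regions$col1 < regions$col0))
    stop("validation error: zero-area region")
  if (any(regions$row0 < 0) || any(regions$col0 < 0) ||
      any(regions$row1 >= grid[1]) || any(regions$col1 >= grid[2]))
    stop("region outside the grid")
  # overlap check on the materialized map
  map <- matrix(NA_integer_, grid[1], grid[2])
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    blk <- map[(r$row0:r$row1) + 1L, (r$col0:r$col1) + 1L]
    if (any(!is.na(blk))) stop("regions overlap")
    map[(r$row0:r$row1) + 1L, (r$col0:r$col1) + 1L] <- r$region_id
  }
  structure(list(grid = grid, regions = regions, region_map = map),
            class = "tissue_layout")
}

#' Ready-made layouts
#'
#' * `layout_pure(class)`: a single pure region filling the grid interior
#'   (a `border`-pixel frame of glass background around it).
#' * `layout_three_class()`: the default training-sample geometry — a large
#'   normal-glands block, a smaller cancer block and a narrow stroma strip,
#'   echoing the strong class imbalance of real cohorts (glands >> cancer
#'   >> stroma). Regions are clear-diagnosis rather than chemically pure:
#'   the dominant class is >= 90% with a small admixture of the others —
#'   in particular the stroma strip carries interleaved glands cells, the
#'   partial-volume situation that makes stroma genuinely hard to call.
#' * `layout_mixed(f_cancer, host)`: one region of tumor cells infiltrating
#'   a normal host tissue, e.g. `layout_mixed(0.15, "glands")` for 15%
#'   tumor in 85% glands or `layout_mixed(0.20, "stroma")` for 20% tumor in
#'   80% stroma.
#'
#' @param grid Integer `c(rows, cols)` (default 45 x 45, about 2,000
#'   pixels).
#' @param class,host A tissue class in [TISSUE_CLASSES].
#' @param f_cancer Tumor-cell fraction of the mixed region.
#' @param border Background frame width in pixels.
#' @return A [tissue_layout()].
#' @export
layout_pure <- function(class, grid = c(45, 45), border = 2L) {
  comp <- stats::setNames(as.numeric(TISSUE_CLASSES == class),
                          paste0("f_", TISSUE_CLASSES))
  tissue_layout(grid, data.frame(
    region_id = 1L, row0 = border, row1 = grid[1] - 1L - border,
    col0 = border, col1 = grid[2] - 1L - border,
    f_cancer = comp[["f_cancer"]], f_glands = comp[["f_glands"]],
    f_stroma = comp[["f_stroma"]]))
}

#' @rdname layout_pure
#' @export
layout_three_class <- function(grid = c(45, 45), border = 2L) {
  r0 <- border; r1 <- grid[1] - 1L - border
  c0 <- border; c1 <- grid[2] - 1L - border
  w <- c1 - c0 + 1L
  if (w < 3L) stop("grid too small for a three-region layout")
  # columns split ~ 62% glands / 26% cancer / 12% stroma, each >= 1 column
  wc <- max(1L, as.integer(round(0.26 * w)))
  ws <- max(1L, as.integer(round(0.12 * w)))
  wg <- w - wc - ws
  cg <- c0 + wg - 1L
  cc <- cg + wc
  tissue_layout(grid, data.frame(
    region_id = 1:3,
    row0 = r0, row1 = r1,
    col0 = c(c0, cg + 1L, cc + 1L),
    col1 = c(cg, cc, c1),
    f_cancer = c(0.00, 0.92, 0.00),
    f_glands = c(0.97, 0.05, 0.25),
    f_stroma = c(0.03, 0.03, 0.75)))
}

#' @rdname layout_pure
#' @export
layout_mixed <- function(f_cancer, host = c("stroma", "glands"),
                         grid = c(45, 45), border = 2L) {
  host <- match.arg(host)
  stopifnot(f_cancer >= 0, f_cancer <= 1)
  tissue_layout(grid, data.frame(
    region_id = 1L, row0 = border, row1 = grid[1] - 1L - border,
    col0 = border, col1 = grid[2] - 1L - border,
    f_cancer = f_cancer,
    f_glands = if (host == "glands") 1 - f_cancer else 0,
    f_stroma = if (host == "stroma") 1 - f_cancer else 0))
}
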