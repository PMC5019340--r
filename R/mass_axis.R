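#' Construct a mass axis
#'
#' A mass axis is the ordered vector of m/z channel centers shared by every
#' pixel spectrum of a sample. The default axis reproduces the acquisition
#' grid of a negative ion mode DESI-MSI experiment: 13,320 equally spaced
#' channels spanning m/z 90 to m/z 1,200 (about 0.0833 m/z per channel), so
#' that averaging channels in non-overlapping groups of six yields 2,220
#' features about 0.5 m/z wide.
#'
#' @param mz Numeric vector of strictly increasing channel centers. If
#'   omitted, an equally spaced axis is built from `mz_min`, `mz_max` and
#'   `n_channels` (endpoints included).
#' @param mz_min,mz_max Axis range in m/z units.
#' @param n_channels Number of channels.
#' @return An object of class `mass_axis`: a numeric vector of channel
#'   centers with attribute `channel_count`.
#' @examples
#' ax <- default_mass_axis()
#' length(ax) # 13320
#' @export
mass_axis <- function(mz = NULL, mz_min = 90, mz_max = 1200,
                      n_channels = 13320L) {
  if (is.null(mz)) {
    n_channels <- as.integer(n_channels)
    if (n_channels < 2L) stop("a mass axis needs at least 2 channels")
    mz <- seq(mz_min, mz_max, length.out = n_channels)
  }
  mz <- as.numeric(mz)
  if (any(diff(mz) <= 0)) stop("mass axis must be strictly increasing")
  structure(mz, channel_count = length(mz), class = "mass_axis")
}

#' @rdname mass_axis
#' @export
default_mass_axis <- function() mass_axis()

#' @export
print.mass_axis <- function(x, ...) {
  cat(sprintf("<mass_axis> %d channels, m/z %.4g-%.4g (spacing %.4g)\n",
              length(x), x[1], x[length(x)], x[2] - x[1]))
  invisible(x)
}

channel_count <- function(axis) length(axis)
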