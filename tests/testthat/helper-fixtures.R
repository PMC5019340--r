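# Small-scale fixtures built in code: a short mass axis with three
# well-separated synthetic lipid profiles, so unit tests run in seconds
# while exercising the same code paths as the full 13,320-channel axis.

tiny_axis <- function() mass_axis(mz_min = 100, mz_max = 130,
                                  n_channels = 121) # 0.25 m/z spacing

tiny_profiles <- function() {
  pk <- function(mz, rel) data.frame(mz = mz, rel = rel, width = 0.5)
  list(
    cancer = class_profile("cancer",
                           pk(c(105, 112, 126), c(1, 0.7, 0.5)), 80),
    glands = class_profile("glands",
                           pk(c(103, 110, 118), c(0.9, 1, 0.6)), 100),
    stroma = class_profile("stroma",
                           pk(c(103, 121, 127), c(1, 0.6, 0.5)), 25))
}

tiny_config <- function(n_patients = 4, grid = c(14, 14), seed = 7,
                        layouts = NULL, ...) {
  cohort_config(
    n_patients = n_patients,
    layouts = if (is.null(layouts)) layout_three_class(grid) else layouts,
    profiles = tiny_profiles(), axis = tiny_axis(), seed = seed, ...)
}

# Labeled feature matrix from a tiny cohort (bin size 2 keeps a few
# channels per feature).
tiny_training <- function(n_patients = 4, grid = c(14, 14), seed = 7, ...) {
  cf <- cohort_features(generate_cohort(tiny_config(n_patients, grid,
                                                    seed, ...)),
                        bin_size = 2)
  cf
}

# A small random multinomial problem for solver tests.
random_problem <- function(n = 50, p = 4, seed = 1, sep = 1.2) {
  set.seed(seed)
  y <- factor(TISSUE_CLASSES[sample.int(3, n, replace = TRUE)],
              levels = TISSUE_CLASSES)
  x <- matrix(rnorm(n * p), n, p)
  for (k in seq_len(min(p, 3)))
    x[, k] <- x[, k] + sep * (as.integer(y) == k)
  list(x = x, y = y)
}
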