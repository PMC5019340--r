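#' Configuration for a synthetic MSI cohort
#'
#' Bundles everything [generate_cohort()] needs: number of patients,
#' samples per patient, the tissue layout given to each sample (a single
#' layout recycled, or a list cycled over samples), class profiles, noise
#' model, mass axis and seed. The defaults are the study conditions used
#' throughout the package's tests: 25 patients, one 45 x 45 sample each
#' with the three-class training geometry, default lipid profiles and
#' noise, full 13,320-channel axis.
#'
#' @param n_patients Number of patients (>= 1).
#' @param samples_per_patient Samples per patient.
#' @param layouts A [tissue_layout()] or list of layouts cycled over
#'   samples.
#' @param profiles List of three [class_profile()]s.
#' @param noise A [noise_model()].
#' @param axis A [mass_axis()].
#' @param seed Integer seed recorded in the cohort metadata.
#' @param patient_prefix Prefix for patient ids.
#' @param blend Partial-volume weight `beta` in `[0, 1]`: each pixel's
#'   expected spectrum is `(1 - beta)` times its sampled label's template
#'   plus `beta` times the region's composition-mixed template, emulating
#'   signal bleed between adjacent cell populations at 200 um resolution.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 25L, samples_per_patient = 1L,
                          layouts = layout_three_class(),
                          profiles = default_class_profiles(),
                          noise = noise_model(), axis = default_mass_axis(),
                          seed = 20130227L, patient_prefix = "P",
                          blend = 0.3) {
  stopifnot(n_patients >= 1, samples_per_patient >= 1,
            blend >= 0, blend <= 1)
  if (inherits(layouts, "tissue_layout")) layouts <- list(layouts)
  structure(list(n_patients = as.integer(n_patients),
                 samples_per_patient = as.integer(samples_per_patient),
                 layouts = layouts, profiles = profiles, noise = noise,
                 axis = axis, seed = as.integer(seed),
                 patient_prefix = patient_prefix, blend = blend),
            class = "cohort_config")
}

#' Generate one synthetic sample on a layout
#'
#' Per-pixel truth labels are sampled from the region's composition
#' (cell-level mixing at the pixel scale); the pixel's expected spectrum is
#' its label's template blended with the region mixture at weight `blend`,
#' then passed through the noise model. Background pixels receive baseline
#' shot noise only.
#'
#' @param layout A [tissue_layout()].
#' @param profiles,noise,axis,blend As in [cohort_config()].
#' @param patient_effect Per-peak multipliers from
#'   [patient_peak_multipliers()].
#' @param sample_id,patient_id Identifiers.
#' @return List with elements `sample` ([msi_sample()]) and `mask`
#'   ([annotation_mask()], carrying the layout's region table and map).
#' @export
generate_sample <- function(layout, profiles = default_class_profiles(),
                            noise = noise_model(),
                            axis = default_mass_axis(),
                            patient_effect = NULL, blend = 0.3,
                            sample_id = "S1", patient_id = "P1") {
  grid <- layout$grid
  n_pix <- prod(grid)
  nch <- length(axis)
  templates <- class_templates(profiles, axis, patient_effect)

  labels <- matrix("background", grid[1], grid[2])
  mu <- matrix(0, n_pix, nch) # expected counts before pixel-level noise
  for (i in seq_len(nrow(layout$regions))) {
    r <- layout$regions[i, ]
    comp <- c(r$f_cancer, r$f_glands, r$f_stroma)
    rows <- r$row0:r$row1; cols <- r$col0:r$col1
    if (!length(rows) || !length(cols))
      stop("validation error: zero-area region")
    mix_t <- as.vector(comp %*% templates)
    cells <- expand.grid(row = rows, col = cols)
    lab <- sample(TISSUE_CLASSES, nrow(cells), replace = TRUE, prob = comp)
    labels[cbind(cells$row + 1L, cells$col + 1L)] <- lab
    idx <- pixel_index(cells$row, cells$col, grid)
    lab_i <- match(lab, TISSUE_CLASSES)
    mu[idx, ] <- (1 - blend) * templates[lab_i, , drop = FALSE] +
      matrix(blend * mix_t, length(idx), nch, byrow = TRUE)
  }
  # per-pixel multiplicative factor and baseline, then shot noise
  if (noise$multiplicative_cv > 0) {
    sdlog <- sqrt(log(1 + noise$multiplicative_cv^2))
    mu <- mu * exp(stats::rnorm(n_pix, -sdlog^2 / 2, sdlog))
  }
  mu <- mu + noise$baseline_level
  x <- if (noise$shot_noise)
    matrix(as.numeric(stats::rpois(length(mu), mu)), n_pix, nch) else mu
  bg <- as.vector(t(labels)) == "background" # row-major
  regions <- layout$regions[, c("region_id", "f_cancer", "f_glands",
                                "f_stroma")]
  list(sample = msi_sample(x, grid, axis, sample_id = sample_id,
                           patient_id = patient_id, background = bg),
       mask = annotation_mask(labels, regions = regions,
                              region_map = layout$region_map))
}

#' Generate a multi-patient synthetic cohort
#'
#' Draws per-patient peak multipliers once per patient, then generates each
#' sample on its layout. Fully reproducible: the seed is set at entry and
#' recorded in the result's metadata.
#'
#' @param config A [cohort_config()].
#' @return List of `list(sample, mask)` entries (one per sample) with
#'   attributes `seed` and `manifest` (data frame: sample_id, patient_id,
#'   layout index).
#' @export
generate_cohort <- function(config) {
  cohort_walk(config, function(entry) entry)
}

#' Walk the cohort generator, applying `f` to each sample as it is drawn
#' (lets callers bin and discard raw spectra without ever holding the whole
#' raw cohort). The RNG stream depends only on the config.
#' @noRd
cohort_walk <- function(config, f) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  out <- list()
  manifest <- NULL
  li <- 0L
  for (p in seq_len(config$n_patients)) {
    pid <- sprintf("%s%02d", config$patient_prefix, p)
    pe <- patient_peak_multipliers(config$profiles,
                                   config$noise$patient_effect_sd)
    for (s in seq_len(config$samples_per_patient)) {
      li <- li + 1L
      layout <- config$layouts[[(li - 1L) %% length(config$layouts) + 1L]]
      sid <- sprintf("%s_S%d", pid, s)
      out[[length(out) + 1L]] <- f(generate_sample(
        layout, config$profiles, config$noise, config$axis,
        patient_effect = pe, blend = config$blend,
        sample_id = sid, patient_id = pid))
      manifest <- rbind(manifest, data.frame(
        sample_id = sid, patient_id = pid,
        layout = (li - 1L) %% length(config$layouts) + 1L))
    }
  }
  attr(out, "seed") <- config$seed
  attr(out, "manifest") <- manifest
  out
}

#' Generate, bin and select a cohort in one streaming pass
#'
#' Equivalent to `cohort_features(generate_cohort(config))` — same seed,
#' same cohort — but each raw sample is binned and discarded before the
#' next is drawn, so memory stays bounded by one raw sample plus the
#' accumulated feature rows. This is the intended entry point for
#' full-axis cohorts, whose raw spectra are ~200 MB per sample.
#'
#' @param config A [cohort_config()].
#' @param bin_size Channels per bin.
#' @return As [cohort_features()].
#' @export
generate_cohort_features <- function(config, bin_size = 6L) {
  parts <- cohort_walk(config, function(entry) {
    sel <- select_pixels(bin_features(entry$sample, bin_size = bin_size),
                         entry$mask)
    rm(entry)
    sel
  })
  features <- rbind_features(lapply(parts, `[[`, "features"))
  labels <- factor(unlist(lapply(parts, function(p) as.character(p$labels))),
                   levels = TISSUE_CLASSES)
  list(features = features, labels = labels,
       patient = features$pixels$patient_id)
}

#' Bin, select and stack a cohort into one labeled feature matrix
#'
#' Convenience wrapper running [bin_features()] and [select_pixels()] on
#' each cohort entry and stacking the results, keeping memory bounded by
#' discarding each raw sample after binning.
#'
#' @param cohort Result of [generate_cohort()] (or any list of
#'   `list(sample, mask)`).
#' @param bin_size Channels per bin.
#' @return List: `features` ([msi_features()]), `labels` (factor),
#'   `patient` (character vector aligned to rows).
#' @export
cohort_features <- function(cohort, bin_size = 6L) {
  parts <- lapply(cohort, function(entry) {
    fm <- bin_features(entry$sample, bin_size = bin_size)
    select_pixels(fm, entry$mask)
  })
  features <- rbind_features(lapply(parts, `[[`, "features"))
  labels <- factor(unlist(lapply(parts, function(p) as.character(p$labels))),
                   levels = TISSUE_CLASSES)
  list(features = features, labels = labels,
       patient = features$pixels$patient_id)
}
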