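#' Class-specific spectral profiles for the synthetic generator
#'
#' A class profile lists the Gaussian peaks (center m/z, relative intensity
#' in (0, 1], width as the Gaussian standard deviation in m/z units) and a
#' total-abundance scale that multiplies the whole template. The default
#' profiles emulate the lipid patterns seen in negative ion mode pancreatic
#' DESI-MSI spectra: normal glands dominated by free fatty acids — oleic
#' (m/z 281.2), palmitic (m/z 255.3) and arachidonic (m/z 303.3) acid —
#' with their dimers near m/z 537.0 and 563.0; cancer enriched in
#' polyunsaturated fatty acids (arachidonic m/z 303.3, adrenic m/z 331.2)
#' and glycerophospholipids (PC chloride adducts m/z 792.4 and 794.4,
#' PG(36:2) m/z 773.6, PI(38:4) m/z 885.6); stroma showing oleic and
#' palmitic acid, PS(36:1) m/z 788.8, PS(38:1) m/z 816.5 and PI(38:4)
#' m/z 885.6 at a markedly lower total ion count than either glands or
#' cancer.
#'
#' @param class Class label (one of [TISSUE_CLASSES]).
#' @param peaks Data frame with columns `mz`, `rel` (relative intensity in
#'   (0, 1]) and `width` (Gaussian sd, m/z units).
#' @param total_abundance_scale Positive scale for the whole template, in
#'   ion counts.
#' @return `class_profile()` returns an object of class `class_profile`;
#'   `default_class_profiles()` a named list of three.
#' @export
class_profile <- function(class, peaks, total_abundance_scale) {
  stopifnot(class %in% TISSUE_CLASSES, nrow(peaks) >= 1,
            all(c("mz", "rel", "width") %in% names(peaks)),
            all(peaks$rel > 0), all(peaks$rel <= 1),
            all(peaks$width > 0), total_abundance_scale > 0)
  structure(list(class = class, peaks = peaks,
                 total_abundance_scale = total_abundance_scale),
            class = "class_profile")
}

#' @param peak_width Default Gaussian sd (m/z units) used for every default
#'   peak; 0.15 spans roughly two channels of the default 0.0833-m/z axis,
#'   keeping each lipid inside a predictable half-unit feature bin.
#' @rdname class_profile
#' @export
default_class_profiles <- function(peak_width = 0.15) {
  pk <- function(mz, rel) data.frame(mz = mz, rel = rel, width = peak_width)
  list(
    cancer = class_profile("cancer", pk(
      mz  = c(255.3, 281.2, 303.3, 331.2, 773.6, 792.4, 794.4, 885.6),
      rel = c(0.45, 0.55, 1.00, 0.70, 0.40, 0.45, 0.50, 0.60)),
      total_abundance_scale = 80),
    glands = class_profile("glands", pk(
      mz  = c(255.3, 281.2, 303.3, 537.0, 563.0, 750.5, 771.5, 833.5,
              861.5, 885.6),
      rel = c(0.90, 1.00, 0.60, 0.45, 0.40, 0.06, 0.06, 0.08, 0.10, 0.12)),
      total_abundance_scale = 100),
    stroma = class_profile("stroma", pk(
      mz  = c(255.3, 281.2, 788.8, 816.5, 885.6),
      rel = c(0.90, 1.00, 0.15, 0.12, 0.20)),
      total_abundance_scale = 10))
}

#' Noise model for synthetic spectra
#'
#' Emulates unmodeled instrument and biological variation: Poisson shot
#' noise on ion counts, a per-pixel log-normal multiplicative factor with
#' coefficient of variation `multiplicative_cv`, a flat additive baseline
#' (counts), and a per-patient log-scale shift drawn once per patient and
#' peak with standard deviation `patient_effect_sd`.
#'
#' @param shot_noise Apply Poisson noise to counts?
#' @param multiplicative_cv Per-pixel log-normal CV (>= 0).
#' @param baseline_level Additive baseline, counts (>= 0).
#' @param patient_effect_sd Log-scale sd of per-patient peak multipliers.
#' @return An object of class `noise_model`. `noise_off()` disables every
#'   component (used by linearity tests).
#' @export
noise_model <- function(shot_noise = TRUE, multiplicative_cv = 0.8,
                        baseline_level = 3, patient_effect_sd = 0.25) {
  stopifnot(multiplicative_cv >= 0, baseline_level >= 0,
            patient_effect_sd >= 0)
  structure(list(shot_noise = isTRUE(shot_noise),
                 multiplicative_cv = multiplicative_cv,
                 baseline_level = baseline_level,
                 patient_effect_sd = patient_effect_sd),
            class = "noise_model")
}

#' @rdname noise_model
#' @export
noise_off <- function() noise_model(FALSE, 0, 0, 0)

#' Noise-free template spectrum of a class profile
#'
#' Sum of Gaussian peaks over the mass axis, times the profile's
#' total-abundance scale and optional per-peak multipliers (the patient
#' effect).
#'
#' @param profile A [class_profile()].
#' @param axis A [mass_axis()].
#' @param peak_multipliers Optional positive vector, one per peak.
#' @return Numeric vector over the axis (expected ion counts).
#' @export
template_spectrum <- function(profile, axis, peak_multipliers = NULL) {
  mz <- as.numeric(axis)
  out <- numeric(length(mz))
  mult <- if (is.null(peak_multipliers)) rep(1, nrow(profile$peaks))
          else peak_multipliers
  stopifnot(length(mult) == nrow(profile$peaks))
  for (i in seq_len(nrow(profile$peaks))) {
    p <- profile$peaks[i, ]
    # only channels within 6 sd matter
    lo <- p$mz - 6 * p$width; hi <- p$mz + 6 * p$width
    idx <- which(mz >= lo & mz <= hi)
    if (!length(idx)) next
    out[idx] <- out[idx] + profile$total_abundance_scale * p$rel * mult[i] *
      exp(-((mz[idx] - p$mz)^2) / (2 * p$width^2))
  }
  out
}

#' Draw one noisy pixel spectrum for a tissue composition
#'
#' The expected spectrum is the convex combination of the class templates
#' weighted by `composition` (fractions cancer / glands / stroma summing to
#' 1, emulating cell-level mixing within a 200 um pixel), scaled by the
#' per-pixel multiplicative factor, plus the baseline; shot noise then
#' draws Poisson counts around it. With [noise_off()] the template mixture
#' is returned exactly.
#'
#' @param composition Numeric 3-vector (cancer, glands, stroma) summing
#'   to 1 within 1e-9.
#' @param profiles List of three [class_profile()]s (or a list of
#'   precomputed templates via `templates`).
#' @param axis A [mass_axis()].
#' @param noise A [noise_model()].
#' @param patient_effect Optional list of per-peak multiplier vectors named
#'   by class (see [patient_peak_multipliers()]).
#' @param templates Optional precomputed 3-row matrix of class templates
#'   (rows in [TISSUE_CLASSES] order) to avoid recomputation.
#' @return Non-negative numeric vector over the axis. Uses R's RNG; seed
#'   with `set.seed()` for reproducibility.
#' @export
generate_pixel_spectrum <- function(composition, profiles, axis,
                                    noise = noise_model(),
                                    patient_effect = NULL,
                                    templates = NULL) {
  if (length(composition) != 3 || abs(sum(composition) - 1) > 1e-9)
    stop("validation error: composition must be a 3-vector summing to 1")
  if (is.null(templates))
    templates <- class_templates(profiles, axis, patient_effect)
  mu <- as.vector(composition %*% templates)
  scale_pixel(mu, noise)
}

#' @noRd
scale_pixel <- function(mu, noise) {
  if (noise$multiplicative_cv > 0) {
    sdlog <- sqrt(log(1 + noise$multiplicative_cv^2))
    mu <- mu * exp(stats::rnorm(1, -sdlog^2 / 2, sdlog))
  }
  mu <- mu + noise$baseline_level
  if (noise$shot_noise) as.numeric(stats::rpois(length(mu), mu)) else mu
}

#' Template matrix (classes x channels) for a profile set
#' @noRd
class_templates <- function(profiles, axis, patient_effect = NULL) {
  t(vapply(TISSUE_CLASSES, function(cl)
    template_spectrum(profiles[[cl]], axis,
                      peak_multipliers = patient_effect[[cl]]),
    numeric(length(axis))))
}

#' Per-patient peak multipliers
#'
#' One log-normal multiplier per profile peak, sd `patient_effect_sd` on
#' the log scale; this is the only thing distinguishing patients when all
#' else is fixed, which is what makes patient-grouped cross-validation
#' meaningfully different from pixel-random splitting.
#'
#' @param profiles List of [class_profile()]s.
#' @param sd Log-scale standard deviation.
#' @return Named list of numeric vectors.
#' @export
patient_peak_multipliers <- function(profiles, sd) {
  lapply(profiles, function(p) exp(stats::rnorm(nrow(p$peaks), 0, sd)))
}
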