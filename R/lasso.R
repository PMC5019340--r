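#' @noRd
as_class_factor <- function(labels) {
  y <- factor(as.character(labels), levels = TISSUE_CLASSES)
  if (anyNA(y)) stop("labels must be in {",
                     paste(TISSUE_CLASSES, collapse = ", "), "}")
  y
}

#' @noRd
feature_matrix_of <- function(x) {
  if (inherits(x, "msi_features")) x$x else as.matrix(x)
}

#' @noRd
feature_mz_of <- function(x) {
  if (inherits(x, "msi_features")) x$mz else seq_len(ncol(as.matrix(x)))
}

#' Per-feature standardization (population sd, zero-variance guarded)
#' @noRd
standardization <- function(x) {
  m <- colMeans(x)
  s <- sqrt(colMeans(x^2) - m^2)
  s[s <= 0 | !is.finite(s)] <- 1
  list(center = m, scale = s)
}

#' Smallest penalty at which every weight is zero
#'
#' Computed from the gradient of the multinomial log-likelihood at the
#' intercept-only fit (class-frequency probabilities) on standardized
#' features.
#'
#' @param x Feature matrix or [msi_features()].
#' @param labels Tissue-class labels.
#' @return `lambda_max` (scalar).
#' @export
lambda_max <- function(x, labels) {
  xm <- feature_matrix_of(x)
  y <- as_class_factor(labels)
  std <- standardization(xm)
  g <- cpp_null_gradient(xm, as.integer(y) - 1L, length(TISSUE_CLASSES),
                         std$center, std$scale)
  max(abs(g))
}

#' Fit the L1-penalized multinomial logistic model
#'
#' Minimizes `(1/n) * multinomial negative log-likelihood +
#' lambda * sum(|w|)` over per-feature standardized inputs by cyclic
#' coordinate descent (per-class iteratively reweighted least squares with
#' active sets and full-gradient KKT screening), warm-started along an
#' internal path from `lambda_max` down to the requested penalty. Weights
#' are reported on the standardized scale — dimensionless and comparable
#' across m/z — with the standardization stored so users can map back to
#' raw intensities. A positive weight marks an ion whose abundance
#' characterizes the class; a negative weight marks an ion whose low
#' abundance or absence does.
#'
#' @param x Feature matrix (pixels x features) or [msi_features()]; values
#'   must be finite.
#' @param labels Pixel labels over [TISSUE_CLASSES]; at least two classes
#'   must be present.
#' @param lambda Penalty (>= 0). At `lambda >= lambda_max` all weights are
#'   zero and predictions fall back to class frequencies.
#' @param tol Relative objective-change tolerance (default 1e-7).
#' @param kkt_tol Stationarity tolerance for the KKT conditions.
#' @param maxit Outer IRLS iteration cap.
#' @param warm_steps Length of the internal warm-start path.
#' @return An object of class `mnlasso`: list with `classes`, `intercepts`,
#'   `weights` (features x classes), `lambda`, `center`, `scale`, `mz`,
#'   `objective`.
#' @export
fit_multinomial_lasso <- function(x, labels, lambda, tol = 1e-7,
                                  kkt_tol = 1e-6, maxit = 100L,
                                  warm_steps = 12L) {
  xm <- feature_matrix_of(x)
  if (any(!is.finite(xm))) stop("validation error: non-finite features")
  y <- as_class_factor(labels)
  if (length(unique(y)) < 2L)
    stop("degenerate fit: a single class is present")
  if (lambda < 0) stop("lambda must be >= 0")
  lmax <- lambda_max(xm, y)
  grid <- if (lambda >= lmax) lambda
          else unique(c(exp(seq(log(lmax), log(max(lambda, 1e-12)),
                                length.out = warm_steps))[-warm_steps],
                        lambda))
  fit <- mnlasso_path_fit(xm, y, grid, tol, kkt_tol, maxit)
  model <- path_model(fit, xm, y, length(grid))
  model$mz <- feature_mz_of(x)
  model
}

#' @noRd
mnlasso_path_fit <- function(xm, y, grid, tol = 1e-7, kkt_tol = 1e-6,
                             maxit = 100L) {
  std <- standardization(xm)
  # bound the solver's standardized-column cache at ~200 MB
  cache_cap <- max(64L, min(ncol(xm), as.integer(2.5e7 / nrow(xm))))
  res <- cpp_mnlasso_path(xm, as.integer(y) - 1L, length(TISSUE_CLASSES),
                          std$center, std$scale, as.numeric(grid),
                          tol, kkt_tol, as.integer(maxit), 100L, cache_cap)
  res$center <- std$center
  res$scale <- std$scale
  res$lambda <- as.numeric(grid)
  res
}

#' @noRd
path_model <- function(fit, xm, y, l) {
  structure(list(
    classes = TISSUE_CLASSES,
    intercepts = stats::setNames(fit$intercepts[, l], TISSUE_CLASSES),
    weights = {
      w <- fit$weights[, , l, drop = TRUE]
      dim(w) <- c(ncol(xm), length(TISSUE_CLASSES))
      colnames(w) <- TISSUE_CLASSES
      w
    },
    lambda = fit$lambda[l], center = fit$center, scale = fit$scale,
    objective = fit$objective[l], iterations = fit$iterations[l],
    class_freq = as.numeric(table(y)) / length(y)),
    class = "mnlasso")
}

#' @export
print.mnlasso <- function(x, ...) {
  cat(sprintf("<mnlasso> lambda=%.4g, %d/%d features active, objective %.6g\n",
              x$lambda, sum(rowSums(x$weights != 0) > 0), nrow(x$weights),
              x$objective))
  invisible(x)
}

#' Fit the full regularization path
#'
#' A log-spaced grid of `n_lambdas` penalties from `lambda_max` down to
#' `lambda_max * lambda_min_ratio`, fitted with warm starts; the first
#' model on the path has all-zero weights by construction.
#'
#' @inheritParams fit_multinomial_lasso
#' @param n_lambdas Grid length (default 100).
#' @param lambda_min_ratio Ratio of the smallest to largest penalty
#'   (default 1e-4).
#' @return An object of class `mnlasso_path`: list of `mnlasso` models
#'   (attribute `lambda` holds the grid).
#' @export
fit_path <- function(x, labels, n_lambdas = 100L, lambda_min_ratio = 1e-4,
                     tol = 1e-7, kkt_tol = 1e-6, maxit = 100L) {
  if (n_lambdas < 2L) stop("n_lambdas must be >= 2")
  xm <- feature_matrix_of(x)
  if (any(!is.finite(xm))) stop("validation error: non-finite features")
  y <- as_class_factor(labels)
  if (length(unique(y)) < 2L)
    stop("degenerate fit: a single class is present")
  lmax <- lambda_max(xm, y)
  grid <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                  length.out = n_lambdas))
  fit <- mnlasso_path_fit(xm, y, grid, tol, kkt_tol, maxit)
  models <- lapply(seq_along(grid), function(l) {
    m <- path_model(fit, xm, y, l)
    m$mz <- feature_mz_of(x)
    m
  })
  structure(models, lambda = grid, class = "mnlasso_path")
}

#' Linear predictor on the standardized scale, exploiting weight sparsity
#' (only columns with a nonzero weight touch the data matrix)
#' @noRd
mnlasso_eta <- function(model, xm) {
  nz <- which(rowSums(model$weights != 0) > 0)
  ws <- model$weights[nz, , drop = FALSE] / model$scale[nz]
  eta <- if (length(nz)) xm[, nz, drop = FALSE] %*% ws
         else matrix(0, nrow(xm), ncol(model$weights))
  shift <- model$intercepts -
    (if (length(nz)) as.numeric(model$center[nz] %*% ws) else 0)
  sweep(eta, 2, shift, "+")
}

#' Per-pixel class probabilities and predictions
#'
#' Applies the stored standardization, computes softmax probabilities and
#' assigns each pixel the highest-probability class; exact probability ties
#' are broken by class order (cancer < glands < stroma). An all-zero-weight
#' model returns the training class frequencies for every pixel.
#'
#' @param model An `mnlasso` model.
#' @param x Feature matrix or [msi_features()] with the model's feature
#'   count.
#' @return An object of class `pixel_prediction`: list with `prob` (pixels
#'   x 3, rows summing to 1), `class` (factor), and the pixel index when
#'   `x` is an [msi_features()].
#' @export
predict_pixels <- function(model, x) {
  stopifnot(inherits(model, "mnlasso"))
  xm <- feature_matrix_of(x)
  if (ncol(xm) != nrow(model$weights))
    stop(sprintf("dimension mismatch: %d features, model has %d",
                 ncol(xm), nrow(model$weights)))
  eta <- mnlasso_eta(model, xm)
  eta <- eta - apply(eta, 1, max)
  p <- exp(eta)
  p <- p / rowSums(p)
  cls <- factor(TISSUE_CLASSES[max.col(p, ties.method = "first")],
                levels = TISSUE_CLASSES)
  structure(list(prob = p, class = cls,
                 pixels = if (inherits(x, "msi_features")) x$pixels),
            class = "pixel_prediction")
}

#' @export
print.pixel_prediction <- function(x, ...) {
  tab <- table(x$class)
  cat(sprintf("<pixel_prediction> %d pixels: %s\n", nrow(x$prob),
              paste(sprintf("%s=%d", names(tab), tab), collapse = " ")))
  invisible(x)
}

#' Signed feature-weight table of a fitted model
#'
#' One row per feature carrying at least one nonzero class weight, labeled
#' by its bin-center m/z (reported to one decimal), sorted by m/z — the
#' fitted analogue of the packaged reference table.
#'
#' @param model An `mnlasso` model.
#' @return A data frame of class `weight_table` (columns `mz`, `cancer`,
#'   `glands`, `stroma`, `selected_*`).
#' @export
extract_weight_table <- function(model) {
  stopifnot(inherits(model, "mnlasso"))
  keep <- rowSums(model$weights != 0) > 0
  out <- data.frame(mz = round(model$mz[keep], 1))
  for (cl in TISSUE_CLASSES) {
    out[[cl]] <- model$weights[keep, cl]
    out[[paste0("selected_", cl)]] <- model$weights[keep, cl] != 0
  }
  out <- out[order(out$mz), ]
  rownames(out) <- NULL
  class(out) <- c("weight_table", "data.frame")
  out
}

#' Objective value of the penalized multinomial fit
#'
#' `(1/n) * negative log-likelihood + lambda * sum(|weights|)` evaluated on
#' standardized features; exposed so tests can compare solutions against
#' independent optimizers.
#'
#' @param model An `mnlasso` model.
#' @param x,labels The fitting data.
#' @return Scalar objective value.
#' @export
mnlasso_objective <- function(model, x, labels) {
  xm <- feature_matrix_of(x)
  y <- as_class_factor(labels)
  eta <- mnlasso_eta(model, xm)
  m <- apply(eta, 1, max)
  lse <- m + log(rowSums(exp(eta - m)))
  nll <- mean(lse - eta[cbind(seq_along(y), as.integer(y))])
  nll + model$lambda * sum(abs(model$weights))
}

#' Patient-grouped cross-validation for the penalty
#'
#' Leave-one-patient-out folds: for each patient, the path is refitted on
#' every other patient's pixels (warm starts along a shared grid anchored
#' at the full-data `lambda_max`) and the held-out pixels are scored. The
#' chosen penalty minimizes the total number of misclassified held-out
#' pixels; ties go to the larger (sparser) penalty. Grouping by patient —
#' rather than splitting pixels at random — is what keeps the error
#' estimate honest in the presence of patient-level batch effects, and it
#' is also how the error reported for the chosen model should be read.
#'
#' @inheritParams fit_multinomial_lasso
#' @param patient Character/factor vector of patient ids, one per pixel.
#' @param n_lambdas,lambda_min_ratio Shared penalty grid (defaults 30 and
#'   1e-3: a coarser grid than [fit_path()]'s since CV only needs to locate
#'   the error minimum).
#' @param weighting `"pixel"` (default: total misclassified pixels) or
#'   `"patient"` (mean of per-patient error rates), since either reading of
#'   "fewest CV errors" is defensible.
#' @param all_patients Optional full roster of cohort patients; members
#'   contributing zero selected pixels are reported with a warning and
#'   excluded from the folds.
#' @param fold_tol,fold_kkt_tol Convergence tolerances for the per-fold
#'   path fits (defaults 1e-5 / 1e-4). Penalty selection only compares
#'   misclassification counts across lambdas, which is insensitive to the
#'   last digits of the fold solutions, so fold fits run looser than the
#'   final refit (which uses `tol` / `kkt_tol`).
#' @param refit Refit on all pixels at the chosen penalty (default TRUE).
#' @return An object of class `mnlasso_cv`: list with `lambda` (grid),
#'   `errors` (per-lambda totals), `error_se` (between-fold standard error
#'   of the per-fold error rate), `chosen_lambda`, `folds` (patient ->
#'   fold), `model` (refit at `chosen_lambda` when `refit`).
#' @export
cv_select_lambda <- function(x, labels, patient, n_lambdas = 30L,
                             lambda_min_ratio = 1e-3, tol = 1e-7,
                             kkt_tol = 1e-6, maxit = 100L,
                             weighting = c("pixel", "patient"),
                             refit = TRUE, all_patients = NULL,
                             fold_tol = 1e-5, fold_kkt_tol = 1e-4) {
  weighting <- match.arg(weighting)
  xm <- feature_matrix_of(x)
  y <- as_class_factor(labels)
  patient <- as.character(patient)
  stopifnot(length(patient) == length(y), nrow(xm) == length(y))
  pats <- unique(patient)
  if (!is.null(all_patients)) {
    empty <- setdiff(as.character(all_patients), pats)
    if (length(empty))
      warning("patients with zero selected pixels excluded from CV: ",
              paste(empty, collapse = ", "))
  }
  if (length(pats) < 2L) stop("patient-grouped CV needs >= 2 patients")

  lmax <- lambda_max(xm, y)
  grid <- if (n_lambdas == 1L) lmax else
    exp(seq(log(lmax), log(lmax * lambda_min_ratio),
            length.out = n_lambdas))

  err <- matrix(0, length(pats), length(grid)) # misclassified per fold
  rate <- matrix(0, length(pats), length(grid))
  nheld <- integer(length(pats))
  for (f in seq_along(pats)) {
    hold <- patient == pats[f]
    fit <- mnlasso_path_fit(xm[!hold, , drop = FALSE], y[!hold], grid,
                            fold_tol, fold_kkt_tol, maxit)
    for (l in seq_along(grid)) {
      m <- path_model(fit, xm[!hold, , drop = FALSE], y[!hold], l)
      pr <- predict_pixels(m, xm[hold, , drop = FALSE])
      err[f, l] <- sum(pr$class != y[hold])
      rate[f, l] <- mean(pr$class != y[hold])
    }
    nheld[f] <- sum(hold)
    rm(fit)
    gc(FALSE)
  }
  total <- if (weighting == "pixel") colSums(err) else colMeans(rate)
  best <- which(total == min(total))[1] # grid descends: first = largest
  chosen <- grid[best]
  se <- apply(rate, 2, function(r) stats::sd(r) / sqrt(length(r)))

  model <- NULL
  if (refit) {
    fit <- mnlasso_path_fit(xm, y, grid[seq_len(best)], tol, kkt_tol, maxit)
    model <- path_model(fit, xm, y, best)
    model$mz <- feature_mz_of(x)
  }
  structure(list(lambda = grid, errors = colSums(err), error_rate = rate,
                 error_se = se, cv_measure = total,
                 weighting = weighting, chosen_lambda = chosen,
                 chosen_index = best,
                 folds = stats::setNames(seq_along(pats), pats),
                 n_held = stats::setNames(nheld, pats), model = model),
            class = "mnlasso_cv")
}

#' @export
print.mnlasso_cv <- function(x, ...) {
  cat(sprintf(
    "<mnlasso_cv> %d folds (one patient each), %d lambdas; chosen %.4g (%d CV errors)\n",
    length(x$folds), length(x$lambda), x$chosen_lambda,
    x$errors[x$chosen_index]))
  invisible(x)
}
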