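test_that("the penalty saturates at lambda_max", {
  pr <- random_problem(n = 60, p = 5, seed = 2)
  lmax <- lambda_max(pr$x, pr$y)
  m <- fit_multinomial_lasso(pr$x, pr$y, lambda = lmax * 1.01)
  expect_true(all(m$weights == 0))
  pred <- predict_pixels(m, pr$x)
  freq <- as.numeric(table(pr$y)) / length(pr$y)
  expect_equal(pred$prob[1, ], freq, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(pred$prob[37, ], freq, tolerance = 1e-8, ignore_attr = TRUE)
  # just below lambda_max something must enter
  m2 <- fit_multinomial_lasso(pr$x, pr$y, lambda = lmax * 0.95)
  expect_gt(sum(m2$weights != 0), 0)
})

test_that("a separable two-class toy reaches 100% training accuracy", {
  x <- rbind(c(0, 0), c(0, 1), c(3, 3), c(3, 4))
  y <- factor(c("glands", "glands", "cancer", "cancer"),
              levels = TISSUE_CLASSES)
  m <- fit_multinomial_lasso(x, y, lambda = 1e-3)
  pred <- predict_pixels(m, x)
  expect_equal(as.character(pred$class), as.character(y))
  # and the objective matches the generic convex-optimizer oracle
  or <- oracle_fit(x, y, 1e-3)
  expect_lt(abs(m$objective - or$objective),
            1e-6 * (1 + abs(or$objective)))
})

test_that("solver matches the convex oracle and satisfies KKT on random problems", {
  set.seed(77)
  worst_gap <- 0; worst_kkt <- 0
  for (case in 1:8) {
    n <- sample(30:60, 1); p <- sample(2:6, 1)
    pr <- random_problem(n = n, p = p, seed = 1000 + case,
                         sep = runif(1, 0.5, 2))
    lmax <- lambda_max(pr$x, pr$y)
    for (lam in lmax * c(0.5, 0.1, 0.02)) {
      m <- fit_multinomial_lasso(pr$x, pr$y, lambda = lam)
      or <- oracle_fit(pr$x, pr$y, lam)
      gap <- abs(m$objective - or$objective) / (1 + abs(or$objective))
      worst_gap <- max(worst_gap, gap)
      worst_kkt <- max(worst_kkt, kkt_residual(m, pr$x, pr$y))
      # our solution never lands above the oracle beyond tolerance
      expect_lt(m$objective, or$objective + 1e-6 * (1 + abs(or$objective)))
    }
  }
  expect_lt(worst_gap, 1e-6)
  expect_lt(worst_kkt, 1e-5)
})

test_that("the objective at convergence beats the null model", {
  pr <- random_problem(n = 50, p = 4, seed = 9)
  lmax <- lambda_max(pr$x, pr$y)
  null_obj <- fit_multinomial_lasso(pr$x, pr$y, lambda = lmax)$objective
  m <- fit_multinomial_lasso(pr$x, pr$y, lambda = lmax * 0.05)
  expect_lte(m$objective, null_obj)
})

test_that("the path starts empty, grows mostly monotonically, and is stable without warm starts", {
  pr <- random_problem(n = 60, p = 6, seed = 4)
  path <- fit_path(pr$x, pr$y, n_lambdas = 25, lambda_min_ratio = 1e-3)
  nz <- vapply(path, function(m) sum(m$weights != 0), integer(1))
  expect_equal(nz[1], 0L) # definition of lambda_max
  # sparsity monotone up to tolerance-level violations
  expect_true(all(diff(nz) >= -1))
  # cold refits at selected grid points reproduce the warm-started
  # objective
  for (l in c(5, 15, 25)) {
    cold <- fit_multinomial_lasso(pr$x, pr$y, lambda = path[[l]]$lambda)
    expect_lt(abs(cold$objective - path[[l]]$objective),
              1e-6 * (1 + path[[l]]$objective))
  }
})

test_that("permuting feature order permutes weights identically", {
  pr <- random_problem(n = 50, p = 6, seed = 12)
  lam <- lambda_max(pr$x, pr$y) * 0.1
  m1 <- fit_multinomial_lasso(pr$x, pr$y, lambda = lam)
  perm <- c(4, 1, 6, 3, 2, 5)
  m2 <- fit_multinomial_lasso(pr$x[, perm], pr$y, lambda = lam)
  expect_equal(m2$weights, m1$weights[perm, ], tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("softmax predictions are proper probabilities with ordered tie-break", {
  pr <- random_problem(n = 40, p = 3, seed = 6)
  m <- fit_multinomial_lasso(pr$x, pr$y, lambda = 0.05)
  pred <- predict_pixels(m, pr$x)
  expect_true(all(abs(rowSums(pred$prob) - 1) < 1e-12))
  expect_true(all(pred$prob >= 0))
  # exact tie -> first class in canonical order
  tie <- structure(list(classes = TISSUE_CLASSES,
                        intercepts = setNames(rep(0, 3), TISSUE_CLASSES),
                        weights = matrix(0, 3, 3,
                                         dimnames = list(NULL, TISSUE_CLASSES)),
                        lambda = 1, center = rep(0, 3), scale = rep(1, 3),
                        mz = 1:3, objective = NA_real_),
                   class = "mnlasso")
  pt <- predict_pixels(tie, matrix(rnorm(6), 2, 3))
  expect_true(all(pt$class == "cancer"))
  expect_error(predict_pixels(m, pr$x[, 1:2]), "dimension mismatch")
})

test_that("degenerate and invalid inputs are rejected", {
  pr <- random_problem(n = 30, p = 3, seed = 8)
  y1 <- factor(rep("cancer", 30), levels = TISSUE_CLASSES)
  expect_error(fit_multinomial_lasso(pr$x, y1, 0.1), "single class")
  xb <- pr$x; xb[3, 2] <- NA
  expect_error(fit_multinomial_lasso(xb, pr$y, 0.1), "non-finite")
  expect_error(fit_multinomial_lasso(pr$x, pr$y, -0.1), "lambda")
  expect_error(fit_path(pr$x, pr$y, n_lambdas = 1), "n_lambdas")
})

test_that("weight tables list exactly the active features with signs", {
  cf <- tiny_training(n_patients = 3, seed = 21)
  lam <- lambda_max(cf$features, cf$labels) * 0.05
  m <- fit_multinomial_lasso(cf$features, cf$labels, lambda = lam)
  wt <- extract_weight_table(m)
  expect_equal(nrow(wt), sum(rowSums(m$weights != 0) > 0))
  expect_true(all(diff(wt$mz) >= 0))
  # planted peaks: the cancer-only peak at m/z 112 must appear with a
  # positive cancer weight (bin centers are within 1 m/z of the peak)
  cancer_rows <- wt[wt$selected_cancer & wt$cancer > 0, ]
  expect_true(any(abs(cancer_rows$mz - 112) < 1))
  # all-zero model -> empty table
  m0 <- fit_multinomial_lasso(cf$features, cf$labels,
                              lambda = lambda_max(cf$features, cf$labels))
  expect_equal(nrow(extract_weight_table(m0)), 0)
})

test_that("patient-grouped CV uses one fold per patient and breaks ties upward", {
  cf <- tiny_training(n_patients = 5, seed = 33)
  cv <- cv_select_lambda(cf$features, cf$labels, cf$patient,
                         n_lambdas = 12, lambda_min_ratio = 1e-2)
  expect_length(cv$folds, 5)
  expect_setequal(names(cv$folds), unique(cf$patient))
  expect_equal(sum(cv$n_held), length(cf$labels))
  # chosen lambda minimizes the pixel-count criterion; among minima the
  # largest lambda wins (grid is descending)
  expect_equal(cv$errors[cv$chosen_index], min(cv$errors))
  first_min <- which(cv$errors == min(cv$errors))[1]
  expect_equal(cv$chosen_index, first_min)
  expect_equal(cv$chosen_lambda, cv$lambda[first_min])
  # single-lambda grid: that lambda is chosen
  cv1 <- cv_select_lambda(cf$features, cf$labels, cf$patient,
                          n_lambdas = 1, refit = FALSE)
  expect_equal(cv1$chosen_lambda, cv1$lambda[1])
  # roster with an absent patient warns
  expect_warning(
    cv_select_lambda(cf$features, cf$labels, cf$patient, n_lambdas = 2,
                     refit = FALSE,
                     all_patients = c(unique(cf$patient), "GHOST")),
    "GHOST")
})

test_that("patient-grouped CV is the honest error estimate under batch effects", {
  # strong patient effects: grouped CV error should not undercut the
  # optimistic pixel-random split at small lambda
  cf <- tiny_training(n_patients = 6, seed = 55,
                      noise = noise_model(patient_effect_sd = 0.6))
  x <- cf$features$x; y <- cf$labels
  lmax <- lambda_max(x, y)
  grid <- lmax * c(0.05, 0.02)
  grouped <- 0; random <- 0
  for (lam in grid) {
    for (p in unique(cf$patient)) {
      hold <- cf$patient == p
      m <- fit_multinomial_lasso(x[!hold, ], y[!hold], lam,
                                 tol = 1e-5, kkt_tol = 1e-4)
      grouped <- grouped + sum(predict_pixels(m, x[hold, ])$class != y[hold])
    }
    set.seed(101)
    fold <- sample(rep(seq_along(unique(cf$patient)), length.out = length(y)))
    for (f in unique(fold)) {
      hold <- fold == f
      m <- fit_multinomial_lasso(x[!hold, ], y[!hold], lam,
                                 tol = 1e-5, kkt_tol = 1e-4)
      random <- random + sum(predict_pixels(m, x[hold, ])$class != y[hold])
    }
  }
  expect_gte(grouped, random)
})

test_that("the solver agrees with glmnet as an independent reference", {
  skip_if_not_installed("glmnet")
  cf <- tiny_training(n_patients = 3, seed = 91)
  x <- cf$features$x; y <- cf$labels
  std <- list(center = colMeans(x),
              scale = sqrt(colMeans(x^2) - colMeans(x)^2))
  std$scale[std$scale <= 0] <- 1
  xs <- scale(x, std$center, std$scale)
  for (ratio in c(0.2, 0.05)) {
    lam <- lambda_max(x, y) * ratio
    ours <- fit_multinomial_lasso(x, y, lambda = lam)
    g <- glmnet::glmnet(xs, y, family = "multinomial", alpha = 1,
                        lambda = lam, standardize = FALSE, thresh = 1e-12)
    W <- sapply(coef(g), function(b) as.numeric(b)[-1])
    b0 <- sapply(coef(g), function(b) as.numeric(b)[1])
    eta <- xs %*% W + matrix(b0, nrow(x), 3, byrow = TRUE)
    mx <- apply(eta, 1, max)
    nll <- mean(mx + log(rowSums(exp(eta - mx))) -
                  eta[cbind(seq_len(nrow(x)), as.integer(y))])
    obj_glmnet <- nll + lam * sum(abs(W))
    expect_lt(abs(ours$objective - obj_glmnet), 1e-5 * (1 + obj_glmnet))
    # same support up to boundary-level weights
    expect_equal(unname(ours$weights[abs(ours$weights) > 1e-4] > 0),
                 unname(W[abs(ours$weights) > 1e-4] > 0))
  }
})
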