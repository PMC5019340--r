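#' Configuration for customized training
#'
#' @param n_clusters Number of joint clusters `G` (default 3, one per
#'   tissue class).
#' @param min_train_per_class Minimum training pixels of every class a
#'   cluster must contain to get its own model (default 30); clusters
#'   below it fall back to the global model.
#' @param seed Clustering seed.
#' @param restarts k-means restarts (k-means++ seeding, best total
#'   within-cluster sum of squares kept).
#' @param n_lambdas,lambda_min_ratio Path/CV settings reused from
#'   [cv_select_lambda()].
#' @return An object of class `customized_config`.
#' @export
customized_config <- function(n_clusters = 3L, min_train_per_class = 30L,
                              seed = 1L, restarts = 10L, n_lambdas = 30L,
                              lambda_min_ratio = 1e-3) {
  stopifnot(n_clusters >= 1, min_train_per_class >= 0, restarts >= 1)
  structure(list(n_clusters = as.integer(n_clusters),
                 min_train_per_class = as.integer(min_train_per_class),
                 seed = as.integer(seed), restarts = as.integer(restarts),
                 n_lambdas = as.integer(n_lambdas),
                 lambda_min_ratio = lambda_min_ratio),
            class = "customized_config")
}

#' k-means++ seeding
#' @noRd
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- numeric(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((x - matrix(x[centers[1], ], n, ncol(x), byrow = TRUE))^2)
  for (i in seq_len(k - 1L)) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[i + 1L] <- sample.int(n, 1, prob = probs)
    d2 <- pmin(d2, rowSums((x - matrix(x[centers[i + 1L], ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  x[centers, , drop = FALSE]
}

#' Cluster training and test pixels jointly
#'
#' k-means with `G` centroids on the feature-wise standardized union of
#' training and test pixels, finding the training points closest to each
#' test point. Deterministic given the seed: k-means++ seeding, `restarts`
#' restarts, the solution with the lowest total within-cluster sum of
#' squares kept.
#'
#' @param train,test Feature matrices or [msi_features()] on the same
#'   feature space.
#' @param G Number of clusters (>= 1, at most the number of test pixels).
#' @param seed Integer seed.
#' @param restarts Number of restarts (default 10).
#' @return List with integer vectors `train` and `test` (cluster ids in
#'   `1..G`) and the `centers` matrix.
#' @export
cluster_joint <- function(train, test, G, seed = 1L, restarts = 10L) {
  xtr <- feature_matrix_of(train)
  xte <- feature_matrix_of(test)
  if (ncol(xtr) != ncol(xte)) stop("train and test feature spaces differ")
  G <- as.integer(G)
  if (G < 1L) stop("G must be >= 1")
  if (G > nrow(xte)) stop("validation error: G exceeds the test pixel count")
  xx <- rbind(xtr, xte)
  std <- standardization(xx)
  xx <- sweep(sweep(xx, 2, std$center), 2, std$scale, "/")
  if (G == 1L) {
    assign <- rep(1L, nrow(xx))
    centers <- matrix(colMeans(xx), 1)
  } else {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    set.seed(seed)
    best <- NULL
    for (r in seq_len(restarts)) {
      km <- stats::kmeans(xx, centers = kmeanspp_centers(xx, G),
                          iter.max = 50L)
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    assign <- best$cluster
    centers <- best$centers
  }
  list(train = assign[seq_len(nrow(xtr))],
       test = assign[nrow(xtr) + seq_len(nrow(xte))],
       centers = centers)
}

#' Customized training: cluster-local lasso models for one test sample
#'
#' For a test sample whose features are available at prediction time, the
#' training and test pixels are clustered jointly; every cluster holding
#' test pixels gets its own lasso model, fitted (with its own
#' patient-grouped CV penalty over the training patients present in the
#' cluster) on just that cluster's training pixels, and applied to the
#' cluster's test pixels. Each cluster thus yields its own list of
#' significant m/z features. Clusters whose training pixels do not cover
#' every class with at least `min_train_per_class` pixels — or hold fewer
#' than two training patients — fall back to the global model; with no
#' usable cluster at all, the global model predicts everything (with a
#' warning). With `G = 1` the procedure reduces exactly to the global
#' model.
#'
#' @param train Training features ([msi_features()] or matrix).
#' @param labels Training labels.
#' @param patient Training patient ids.
#' @param test Test-sample features on the same feature space.
#' @param config A [customized_config()].
#' @param global_model Optional pre-fitted global `mnlasso`; when `NULL`
#'   it is CV-fitted here with the config's path settings.
#' @return An object of class `customized_result`: list with `assignment`
#'   (test-pixel cluster ids), `cluster_models`, `cluster_weight_tables`,
#'   `fallback` (logical per cluster), `prediction` (merged
#'   `pixel_prediction` covering every test pixel exactly once) and
#'   `global_model`.
#' @export
customized_fit_predict <- function(train, labels, patient, test,
                                   config = customized_config(),
                                   global_model = NULL) {
  y <- as_class_factor(labels)
  if (length(unique(y)) < length(TISSUE_CLASSES))
    stop("training data must cover all three classes")
  xtr <- feature_matrix_of(train)
  xte <- feature_matrix_of(test)
  patient <- as.character(patient)

  if (is.null(global_model)) {
    cv <- cv_select_lambda(xtr, y, patient, n_lambdas = config$n_lambdas,
                           lambda_min_ratio = config$lambda_min_ratio)
    global_model <- cv$model
    global_model$mz <- feature_mz_of(train)
  }

  cl <- cluster_joint(xtr, xte, config$n_clusters, seed = config$seed,
                      restarts = config$restarts)
  G <- config$n_clusters
  prob <- matrix(NA_real_, nrow(xte), length(TISSUE_CLASSES),
                 dimnames = list(NULL, TISSUE_CLASSES))
  cls <- rep(NA_character_, nrow(xte))
  models <- vector("list", G)
  tables <- vector("list", G)
  fallback <- rep(NA, G)

  any_local <- FALSE
  for (g in seq_len(G)) {
    te_idx <- which(cl$test == g)
    if (!length(te_idx)) next
    tr_idx <- which(cl$train == g)
    counts <- table(factor(y[tr_idx], levels = TISSUE_CLASSES))
    npat <- length(unique(patient[tr_idx]))
    use_local <- all(counts >= config$min_train_per_class) && npat >= 2L
    if (use_local && G == 1L) {
      # the customized training set is the full training set: the global
      # model IS the cluster model (exact reduction)
      models[[g]] <- global_model
      fallback[g] <- FALSE
      tables[[g]] <- extract_weight_table(global_model)
      pr <- predict_pixels(global_model, xte[te_idx, , drop = FALSE])
      prob[te_idx, ] <- pr$prob
      cls[te_idx] <- as.character(pr$class)
      any_local <- TRUE
      next
    }
    if (use_local) {
      cvg <- cv_select_lambda(xtr[tr_idx, , drop = FALSE], y[tr_idx],
                              patient[tr_idx],
                              n_lambdas = config$n_lambdas,
                              lambda_min_ratio = config$lambda_min_ratio)
      models[[g]] <- cvg$model
      models[[g]]$mz <- feature_mz_of(train)
      any_local <- TRUE
    } else {
      models[[g]] <- global_model
    }
    fallback[g] <- !use_local
    tables[[g]] <- extract_weight_table(models[[g]])
    pr <- predict_pixels(models[[g]], xte[te_idx, , drop = FALSE])
    prob[te_idx, ] <- pr$prob
    cls[te_idx] <- as.character(pr$class)
  }
  if (!any_local && G > 1L)
    warning("no cluster had a usable customized training set; ",
            "global model used throughout")

  structure(list(
    assignment = cl$test,
    cluster_models = models, cluster_weight_tables = tables,
    fallback = fallback,
    prediction = structure(
      list(prob = prob,
           class = factor(cls, levels = TISSUE_CLASSES),
           pixels = if (inherits(test, "msi_features")) test$pixels),
      class = "pixel_prediction"),
    global_model = global_model),
    class = "customized_result")
}

#' @export
print.customized_result <- function(x, ...) {
  used <- which(!is.na(x$fallback))
  cat(sprintf(
    "<customized_result> %d test pixels in %d cluster(s); local models: %s\n",
    length(x$assignment), length(used),
    paste(ifelse(x$fallback[used], "fallback", "local"), collapse = ", ")))
  invisible(x)
}
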