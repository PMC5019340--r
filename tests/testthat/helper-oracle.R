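# Independent oracle for the penalized multinomial objective: a generic
# convex optimizer (L-BFGS-B) on the smooth reformulation w = w+ - w-,
# w+, w- >= 0, which turns the L1 penalty into a linear term under box
# constraints. Shares no code with the package's coordinate-descent path.

# Standardize columns to zero mean / unit population sd (the model's
# documented feature scaling), restated here independently.
oracle_standardize <- function(x) {
  m <- colMeans(x)
  s <- sqrt(colMeans(x^2) - m^2)
  s[s <= 0 | !is.finite(s)] <- 1
  scale(x, center = m, scale = s)
}

# Objective (1/n) NLL + lambda * sum|W| at explicit (b, W) on
# standardized features.
oracle_objective <- function(xs, y, b, W, lambda) {
  n <- nrow(xs)
  eta <- xs %*% W + matrix(b, n, length(b), byrow = TRUE)
  mx <- apply(eta, 1, max)
  lse <- mx + log(rowSums(exp(eta - mx)))
  mean(lse - eta[cbind(seq_len(n), as.integer(y))]) + lambda * sum(abs(W))
}

# Minimize with stats::optim (L-BFGS-B); returns the achieved objective
# and parameters.
oracle_fit <- function(x, y, lambda, maxit = 5000) {
  xs <- oracle_standardize(x)
  n <- nrow(xs); p <- ncol(xs); K <- nlevels(y)
  Y <- sapply(levels(y), function(cl) as.numeric(y == cl))
  unpack <- function(th) {
    b <- th[seq_len(K)]
    wp <- matrix(th[K + seq_len(p * K)], p, K)
    wm <- matrix(th[K + p * K + seq_len(p * K)], p, K)
    list(b = b, W = wp - wm, wp = wp, wm = wm)
  }
  fn <- function(th) {
    pa <- unpack(th)
    eta <- xs %*% pa$W + matrix(pa$b, n, K, byrow = TRUE)
    mx <- apply(eta, 1, max)
    lse <- mx + log(rowSums(exp(eta - mx)))
    mean(lse - eta[cbind(seq_len(n), as.integer(y))]) +
      lambda * sum(pa$wp + pa$wm)
  }
  gr <- function(th) {
    pa <- unpack(th)
    eta <- xs %*% pa$W + matrix(pa$b, n, K, byrow = TRUE)
    mx <- apply(eta, 1, max)
    P <- exp(eta - mx); P <- P / rowSums(P)
    ge <- (P - Y) / n
    gb <- colSums(ge)
    gw <- crossprod(xs, ge)
    c(gb, as.numeric(gw) + lambda, as.numeric(-gw) + lambda)
  }
  th0 <- rep(0, K + 2 * p * K)
  fit <- stats::optim(th0, fn, gr, method = "L-BFGS-B",
                      lower = c(rep(-Inf, K), rep(0, 2 * p * K)),
                      control = list(maxit = maxit, factr = 10))
  pa <- unpack(fit$par)
  list(objective = oracle_objective(xs, y, pa$b, pa$W, lambda),
       b = pa$b, W = pa$W, convergence = fit$convergence)
}

# KKT residual of a fitted mnlasso model, with the gradient recomputed
# here (not by the solver): max over coordinates of the stationarity
# violation.
kkt_residual <- function(model, x, y) {
  xs <- oracle_standardize(x)
  n <- nrow(xs)
  Y <- sapply(TISSUE_CLASSES, function(cl) as.numeric(y == cl))
  eta <- xs %*% model$weights +
    matrix(model$intercepts, n, 3, byrow = TRUE)
  mx <- apply(eta, 1, max)
  P <- exp(eta - mx); P <- P / rowSums(P)
  G <- crossprod(xs, P - Y) / n
  res <- ifelse(model$weights != 0,
                abs(G + model$lambda * sign(model$weights)),
                pmax(0, abs(G) - model$lambda))
  max(res)
}
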