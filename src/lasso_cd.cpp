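// Coordinate-descent path solver for the L1-penalized multinomial logistic
// model. Features are standardized implicitly through (center, scale) so the
// raw matrix is never copied; the reported weights live on the standardized
// scale. Per class, the softmax negative log-likelihood is majorized by a
// weighted least-squares problem (IRLS weights p(1-p), floored) which is
// solved by cyclic coordinate descent over an active feature set; a
// full-gradient KKT screen (one BLAS gemm) grows the active set until no
// coordinate violates the stationarity conditions.
#include <RcppArmadillo.h>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft_threshold(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// Cache of standardized columns; bounded so n * cache_cap stays modest.
struct ColCache {
  const mat &X;
  const vec &center, &scale;
  std::vector<int> slot;
  mat store;
  int used;
  int cap;
  vec scratch;
  ColCache(const mat &X_, const vec &c_, const vec &s_, int cap_)
    : X(X_), center(c_), scale(s_), slot(X_.n_cols, -1),
      store(X_.n_rows, std::min<int>(cap_, 64)), used(0), cap(cap_),
      scratch(X_.n_rows) {}
  const double *get(int j) {
    if (slot[j] >= 0) return store.colptr(slot[j]);
    if (used < cap) {
      if ((int)store.n_cols == used)
        store.resize(store.n_rows, std::min<int>(cap, used * 2 + 1));
      store.col(used) = (X.col(j) - center(j)) / scale(j);
      slot[j] = used;
      return store.colptr(used++);
    }
    scratch = (X.col(j) - center(j)) / scale(j);
    return scratch.memptr();
  }
};

static void softmax_rows(const mat &eta, mat &P) {
  const uword n = eta.n_rows, K = eta.n_cols;
  for (uword i = 0; i < n; ++i) {
    double m = eta(i, 0);
    for (uword k = 1; k < K; ++k) m = std::max(m, eta(i, k));
    double s = 0.0;
    for (uword k = 0; k < K; ++k) { P(i, k) = std::exp(eta(i, k) - m); s += P(i, k); }
    for (uword k = 0; k < K; ++k) P(i, k) /= s;
  }
}

static double neg_loglik(const mat &eta, const ivec &y) {
  const uword n = eta.n_rows, K = eta.n_cols;
  double nll = 0.0;
  for (uword i = 0; i < n; ++i) {
    double m = eta(i, 0);
    for (uword k = 1; k < K; ++k) m = std::max(m, eta(i, k));
    double s = 0.0;
    for (uword k = 0; k < K; ++k) s += std::exp(eta(i, k) - m);
    nll += m + std::log(s) - eta(i, y(i));
  }
  return nll / (double)n;
}

// Full smooth-part gradient on the standardized scale: (1/n) Xs^T (P - Y),
// computed from the raw X with the centering correction so no standardized
// copy of X is ever formed.
static mat full_gradient(const mat &X, const mat &R, const vec &center,
                         const vec &scale) {
  const double n = (double)X.n_rows;
  mat G = X.t() * R;            // p x K gemm
  rowvec cs = sum(R, 0);        // column sums of residual
  for (uword j = 0; j < G.n_rows; ++j)
    for (uword k = 0; k < G.n_cols; ++k)
      G(j, k) = (G(j, k) - center(j) * cs(k)) / (scale(j) * n);
  return G;
}

// [[Rcpp::export]]
Rcpp::List cpp_mnlasso_path(const arma::mat &X, const arma::ivec &y, int K,
                            const arma::vec &center, const arma::vec &scale,
                            const arma::vec &lambda, double tol,
                            double kkt_tol, int maxit_outer, int maxit_cd,
                            int cache_cap) {
  const uword n = X.n_rows, p = X.n_cols;
  const uword nl = lambda.n_elem;
  const double dn = (double)n;

  mat Y(n, (uword)K, fill::zeros);
  vec cls_count((uword)K, fill::zeros);
  for (uword i = 0; i < n; ++i) { Y(i, y(i)) = 1.0; cls_count(y(i)) += 1.0; }

  mat W(p, (uword)K, fill::zeros);
  vec b((uword)K);
  for (int k = 0; k < K; ++k) b(k) = std::log(cls_count(k) / dn);

  mat eta(n, (uword)K);
  for (int k = 0; k < K; ++k) eta.col(k).fill(b(k));
  mat P(n, (uword)K);

  ColCache cache(X, center, scale, cache_cap);
  std::vector<char> is_active(p, 0);
  std::vector<int> act;
  act.reserve(256);

  const double vfloor = 1e-5;
  // The quadratic subproblem need not be solved beyond the accuracy the
  // outer IRLS step can use; the outer loop's KKT criterion (true gradient)
  // controls final quality.
  const double cd_tol = kkt_tol * 0.1;

  cube Wout(p, (uword)K, nl, fill::zeros);
  mat bout((uword)K, nl);
  vec objs(nl), iters(nl);

  vec vvec(n), rz(n);
  mat G_prev; // full gradient at the previous lambda's solution

  for (uword l = 0; l < nl; ++l) {
    const double lam = lambda(l);
    // sequential strong rule: pre-activate features likely to violate KKT
    // at this lambda, so the post-convergence screen rarely finds any
    if (l > 0 && G_prev.n_rows == p) {
      const double thr = 2.0 * lam - lambda(l - 1);
      for (uword j = 0; j < p; ++j) {
        if (is_active[j]) continue;
        for (int k = 0; k < K; ++k) {
          if (std::fabs(G_prev(j, k)) > thr) {
            is_active[j] = 1;
            act.push_back((int)j);
            break;
          }
        }
      }
    }
    bool done = false;
    int outer_used = 0;
    double obj_prev = datum::inf;

    while (!done) {
      // --- inner IRLS/CD cycles on the current active set ---
      for (int outer = 0; outer < maxit_outer; ++outer, ++outer_used) {
        softmax_rows(eta, P);
        for (int k = 0; k < K; ++k) {
          for (uword i = 0; i < n; ++i) {
            double v = P(i, k) * (1.0 - P(i, k));
            vvec(i) = (v < vfloor) ? vfloor : v;
            rz(i) = (Y(i, k) - P(i, k)) / vvec(i);
          }
          // z - eta_k = rz at entry; maintain rz as working residual.
          // aj = (1/n) sum_i v_i xs_ij^2 is fixed for the whole class
          // solve (v does not change inside it) — compute once.
          const double sv = accu(vvec);
          std::vector<double> ajv(act.size());
          for (size_t a = 0; a < act.size(); ++a) {
            const double *xs = cache.get(act[a]);
            double aj = 0.0;
            for (uword i = 0; i < n; ++i) aj += vvec(i) * xs[i] * xs[i];
            ajv[a] = aj / dn;
          }
          // one coordinate visit; returns |change|
          auto visit = [&](size_t a) -> double {
            const int j = act[a];
            const double *xs = cache.get(j);
            double u = 0.0;
            for (uword i = 0; i < n; ++i) u += vvec(i) * xs[i] * rz(i);
            u = u / dn + ajv[a] * W(j, k);
            const double wnew = soft_threshold(u, lam) / ajv[a];
            const double d = wnew - W(j, k);
            if (d != 0.0) {
              for (uword i = 0; i < n; ++i) rz(i) -= d * xs[i];
              W(j, k) = wnew;
            }
            return std::fabs(d);
          };
          auto visit_intercept = [&]() -> double {
            double sr = 0.0;
            for (uword i = 0; i < n; ++i) sr += vvec(i) * rz(i);
            const double db = sr / sv;
            if (db != 0.0) { b(k) += db; rz -= db; }
            return std::fabs(db);
          };
          // working-set iteration: converge on the nonzero coordinates,
          // then one sweep over the whole active set to admit newcomers
          int budget = maxit_cd;
          while (budget > 0) {
            std::vector<size_t> work;
            for (size_t a = 0; a < act.size(); ++a)
              if (W(act[a], k) != 0.0) work.push_back(a);
            while (budget-- > 0) {
              double dmax = visit_intercept();
              for (size_t w = 0; w < work.size(); ++w)
                dmax = std::max(dmax, visit(work[w]));
              if (dmax < cd_tol) break;
            }
            double dmax = visit_intercept();
            bool grew = false;
            for (size_t a = 0; a < act.size(); ++a) {
              const bool was_zero = W(act[a], k) == 0.0;
              dmax = std::max(dmax, visit(a));
              if (was_zero && W(act[a], k) != 0.0) grew = true;
            }
            --budget;
            if (dmax < cd_tol || !grew) break;
          }
          // eta_k = z - rz, and z = eta_k(entry) + (Y - P)/v
          for (uword i = 0; i < n; ++i)
            eta(i, k) += (Y(i, k) - P(i, k)) / vvec(i) - rz(i);
          softmax_rows(eta, P);
        }
        double obj = neg_loglik(eta, y) + lam * accu(abs(W));
        // KKT residual on active coordinates (cheap, active cols only)
        double kkt_res = 0.0;
        {
          mat R = P - Y;
          for (size_t a = 0; a < act.size(); ++a) {
            const int j = act[a];
            const double *xs = cache.get(j);
            for (int k = 0; k < K; ++k) {
              double g = 0.0;
              const double *rc = R.colptr(k);
              for (uword i = 0; i < n; ++i) g += xs[i] * rc[i];
              g /= dn;
              double r;
              if (W(j, k) != 0.0)
                r = std::fabs(g + lam * ((W(j, k) > 0) ? 1.0 : -1.0));
              else
                r = std::max(0.0, std::fabs(g) - lam);
              if (r > kkt_res) kkt_res = r;
            }
          }
        }
        bool obj_ok = std::fabs(obj_prev - obj) < tol * (std::fabs(obj) + 1e-10);
        obj_prev = obj;
        if (obj_ok && kkt_res < kkt_tol) break;
      }
      // --- full-gradient KKT screen; grow the active set ---
      softmax_rows(eta, P);
      mat R = P - Y;
      mat G = full_gradient(X, R, center, scale);
      bool viol = false;
      for (uword j = 0; j < p; ++j) {
        if (is_active[j]) continue;
        for (int k = 0; k < K; ++k) {
          if (std::fabs(G(j, k)) > lam + kkt_tol) {
            is_active[j] = 1;
            act.push_back((int)j);
            viol = true;
            break;
          }
        }
      }
      if (!viol) { done = true; G_prev = G; }
    }
    Wout.slice(l) = W;
    bout.col(l) = b;
    objs(l) = neg_loglik(eta, y) + lam * accu(abs(W));
    iters(l) = outer_used;
    Rcpp::checkUserInterrupt();
  }

  return Rcpp::List::create(
      Rcpp::Named("weights") = Wout, Rcpp::Named("intercepts") = bout,
      Rcpp::Named("objective") = objs, Rcpp::Named("iterations") = iters);
}

// Gradient of the smooth part at the intercept-only fit; its largest absolute
// entry is lambda_max, the smallest penalty with an all-zero weight matrix.
// [[Rcpp::export]]
arma::mat cpp_null_gradient(const arma::mat &X, const arma::ivec &y, int K,
                            const arma::vec &center, const arma::vec &scale) {
  const uword n = X.n_rows;
  mat Y(n, (uword)K, fill::zeros);
  vec cls((uword)K, fill::zeros);
  for (uword i = 0; i < n; ++i) { Y(i, y(i)) = 1.0; cls(y(i)) += 1.0; }
  mat P(n, (uword)K);
  for (int k = 0; k < K; ++k) P.col(k).fill(cls(k) / (double)n);
  mat R = P - Y;
  return full_gradient(X, R, center, scale);
}
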