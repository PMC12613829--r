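// Fast estimation kernel for the bootstrap loop: OLS by normal equations
// and logistic regression by Newton/IRLS, with fixed-size fused
// accumulation passes (score and observed information in one sweep over
// the rows).  The user-facing fits go through stats::lm / stats::glm; this
// kernel exists because percentile-bootstrap inference re-estimates four
// path models per resample, and coverage experiments run hundreds of
// thousands of refits.  Equality with lm/glm is asserted in the test suite.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// ---- fixed-size helpers -------------------------------------------------

template <int P>
static bool solve_small(const double H[P][P], const double g[P],
                        double out[P]) {
  // H holds the upper triangle; symmetrize into a dense matrix
  arma::mat A(P, P);
  arma::vec b(P);
  for (int a = 0; a < P; ++a) {
    b(a) = g[a];
    for (int c = a; c < P; ++c) {
      A(a, c) = H[a][c];
      A(c, a) = H[a][c];
    }
  }
  arma::vec x;
  if (!arma::solve(x, A, b, arma::solve_opts::no_approx)) return false;
  for (int a = 0; a < P; ++a) out[a] = x(a);
  return true;
}

template <int P>
static double loglik_small(const double* const* X, const double* y,
                           const int n, const double beta[P]) {
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    double eta = 0.0;
    for (int a = 0; a < P; ++a) eta += X[a][i] * beta[a];
    double lse = (eta > 0) ? eta + std::log1p(std::exp(-eta))
                           : std::log1p(std::exp(eta));
    ll += y[i] * eta - lse;
  }
  return ll;
}

// Newton iterations with coefficient-change stopping; a step-halving
// line search on the log-likelihood guards the (rare) large steps.
// Returns false on singular information, non-convergence, or any
// |beta| exceeding sep_limit (the bounded-odds separation heuristic).
template <int P>
static bool logistic_small(const double* const* X, const double* y,
                           const int n, double beta[P], int maxit,
                           double tol, double sep_limit, int& iters) {
  double g[P], H[P][P], delta[P];
  for (iters = 1; iters <= maxit; ++iters) {
    for (int a = 0; a < P; ++a) {
      g[a] = 0.0;
      for (int c = 0; c < P; ++c) H[a][c] = 0.0;
    }
    for (int i = 0; i < n; ++i) {
      double xi[P];
      for (int a = 0; a < P; ++a) xi[a] = X[a][i];
      double eta = 0.0;
      for (int a = 0; a < P; ++a) eta += xi[a] * beta[a];
      const double mu = 1.0 / (1.0 + std::exp(-eta));
      const double w = mu * (1.0 - mu);
      const double r = y[i] - mu;
      for (int a = 0; a < P; ++a) {
        g[a] += xi[a] * r;
        const double wxa = w * xi[a];
        for (int c = a; c < P; ++c) H[a][c] += wxa * xi[c];
      }
    }
    if (!solve_small<P>(H, g, delta)) return false;
    double step = 0.0;
    for (int a = 0; a < P; ++a) step = std::max(step, std::fabs(delta[a]));
    if (step > 2.0) {
      // guarded step: halve until the log-likelihood does not decrease
      double ll0 = loglik_small<P>(X, y, n, beta);
      double cand[P];
      int halvings = 0;
      while (halvings < 30) {
        for (int a = 0; a < P; ++a) cand[a] = beta[a] + delta[a];
        if (loglik_small<P>(X, y, n, cand) >= ll0) break;
        for (int a = 0; a < P; ++a) delta[a] *= 0.5;
        ++halvings;
      }
      for (int a = 0; a < P; ++a) beta[a] = beta[a] + delta[a];
    } else {
      for (int a = 0; a < P; ++a) beta[a] += delta[a];
    }
    double bmax = 0.0;
    for (int a = 0; a < P; ++a) bmax = std::max(bmax, std::fabs(beta[a]));
    if (bmax > sep_limit) return false;
    if (step < tol) return true;
  }
  return false;
}

// ---- path-system fit ----------------------------------------------------

struct PathFit {
  double a1, a2, a3, b1, b2, c, c_prime;
  bool ok;
};

// Z columns, in order: intercept, pain, ds_z, pa_z, age_z, sex, dep_base.
// y is the outcome.  Both mediator OLS fits (and, for a continuous
// outcome, both outcome OLS fits) are submatrix solves of the single 7x7
// Gram matrix Z'Z, so the whole linear part costs one BLAS syrk pass.
static PathFit fit_paths_mat(const arma::mat& Z, const arma::vec& y,
                             int family, const double* start_c,
                             const double* start_full, int maxit,
                             double tol, double sep_limit) {
  PathFit r;
  r.ok = false;
  static const arma::uvec cc = {0, 1, 4, 5, 6};
  static const arma::uvec cm = {0, 1, 2, 4, 5, 6};
  static const arma::uvec i_ds = {2}, i_pa = {3};
  arma::mat G = Z.t() * Z;
  arma::vec beta;
  if (!arma::solve(beta, G(cc, cc), G(cc, i_ds),
                   arma::solve_opts::no_approx))
    return r;
  r.a1 = beta(1);
  if (!arma::solve(beta, G(cm, cm), G(cm, i_pa),
                   arma::solve_opts::no_approx))
    return r;
  r.a2 = beta(1);
  r.a3 = beta(2);

  const double* cols[7];
  for (int a = 0; a < 7; ++a) cols[a] = Z.colptr(a);
  const double* Xc[5] = {cols[0], cols[1], cols[4], cols[5], cols[6]};
  const int n = Z.n_rows;
  if (family == 0) {
    int iters;
    double b5[5], b7[7];
    for (int a = 0; a < 5; ++a) b5[a] = start_c[a];
    if (!logistic_small<5>(Xc, y.memptr(), n, b5, maxit, tol, sep_limit,
                           iters))
      return r;
    r.c = b5[1];
    for (int a = 0; a < 7; ++a) b7[a] = start_full[a];
    if (!logistic_small<7>(cols, y.memptr(), n, b7, maxit, tol, sep_limit,
                           iters))
      return r;
    r.c_prime = b7[1];
    r.b1 = b7[2];
    r.b2 = b7[3];
  } else {
    arma::vec Zy = Z.t() * y;
    if (!arma::solve(beta, G(cc, cc), Zy(cc), arma::solve_opts::no_approx))
      return r;
    r.c = beta(1);
    if (!arma::solve(beta, G, Zy, arma::solve_opts::no_approx)) return r;
    r.c_prime = beta(1);
    r.b1 = beta(2);
    r.b2 = beta(3);
  }
  r.ok = true;
  return r;
}

// ---- exported single fits (used directly and as the tested route) ------

// [[Rcpp::export]]
List ols_fit_cpp(const arma::mat& X, const arma::vec& y) {
  arma::vec beta;
  arma::mat XtX = X.t() * X;
  arma::vec Xty = X.t() * y;
  bool ok = arma::solve(beta, XtX, Xty, arma::solve_opts::no_approx);
  return List::create(_["beta"] = beta, _["ok"] = ok);
}

// Bernoulli log-likelihood, numerically stable form of
// sum(y * eta - log(1 + exp(eta))).
static double loglik_arma(const arma::mat& X, const arma::vec& y,
                          const arma::vec& beta) {
  arma::vec eta = X * beta;
  double ll = 0.0;
  for (arma::uword i = 0; i < eta.n_elem; ++i) {
    double e = eta(i);
    double lse = (e > 0) ? e + std::log1p(std::exp(-e))
                         : std::log1p(std::exp(e));
    ll += y(i) * e - lse;
  }
  return ll;
}

// Generic-width Newton fit (same algorithm as the fixed-size path, without
// the compile-time width), for direct testing against stats::glm.
// [[Rcpp::export]]
List logistic_fit_cpp(const arma::mat& X, const arma::vec& y,
                      const arma::vec& start, int maxit = 100,
                      double tol = 1e-10, double sep_limit = 15.0) {
  const arma::uword p = X.n_cols;
  arma::vec beta = start, g(p), delta;
  arma::mat H(p, p);
  int iters = 0;
  bool ok = false;
  for (iters = 1; iters <= maxit; ++iters) {
    arma::vec eta = X * beta;
    arma::vec mu = 1.0 / (1.0 + arma::exp(-eta));
    arma::vec w = mu % (1.0 - mu);
    g = X.t() * (y - mu);
    H = X.t() * (X.each_col() % w);
    if (!arma::solve(delta, H, g, arma::solve_opts::no_approx)) break;
    double step = arma::abs(delta).max();
    if (step > 2.0) {
      // guarded step: halve until the log-likelihood does not decrease
      double ll0 = loglik_arma(X, y, beta);
      int halvings = 0;
      while (loglik_arma(X, y, beta + delta) < ll0 && halvings < 30) {
        delta *= 0.5;
        ++halvings;
      }
    }
    beta += delta;
    if (arma::abs(beta).max() > sep_limit) break;
    if (step < tol) { ok = true; break; }
  }
  return List::create(_["beta"] = beta, _["ok"] = ok,
                      _["iterations"] = iters,
                      _["loglik"] = loglik_arma(X, y, beta));
}

// Full-sample path fit through the same fixed-size code the bootstrap
// uses, so the bootstrap inner loop itself is testable against the
// lm/glm route.
// [[Rcpp::export]]
List fit_paths_cpp(const arma::mat& Z, const arma::vec& y, int family,
                   const arma::vec& start_c, const arma::vec& start_full,
                   int maxit = 100, double tol = 1e-10,
                   double sep_limit = 15.0) {
  PathFit r = fit_paths_mat(Z, y, family, start_c.memptr(),
                            start_full.memptr(), maxit, tol, sep_limit);
  NumericVector est = NumericVector::create(
      _["a1"] = r.a1, _["a2"] = r.a2, _["a3"] = r.a3, _["b1"] = r.b1,
      _["b2"] = r.b2, _["c"] = r.c, _["c_prime"] = r.c_prime);
  return List::create(_["paths"] = est, _["ok"] = r.ok);
}

// ---- bootstrap loop -----------------------------------------------------

// Row-resampling bootstrap of the full path system.  Uses R's RNG so the
// draw sequence is reproducible under set.seed().  Resamples that fail
// estimation (single-class outcome, separation, singular system) are
// redrawn and counted, up to max_draws total draws.
// [[Rcpp::export]]
List boot_paths_cpp(const arma::mat& Z, const arma::vec& y, int B,
                    int family, int max_draws, const arma::vec& start_c,
                    const arma::vec& start_full, bool restandardize = false,
                    int maxit = 100, double tol = 1e-8,
                    double sep_limit = 15.0) {
  const int n = Z.n_rows;
  arma::mat draws(B, 11);
  int failed = 0, total_draws = 0, b = 0;
  std::vector<int> idx(n);
  arma::mat Zb(n, 7);
  arma::vec yb(n);
  while (b < B) {
    if (total_draws >= max_draws)
      return List::create(_["draws"] = draws, _["n_failed"] = failed,
                          _["completed"] = b, _["ok"] = false);
    ++total_draws;
    for (int i = 0; i < n; ++i) {
      int k = (int)(unif_rand() * n);
      if (k >= n) k = n - 1;
      idx[i] = k;
    }
    double ysum = 0.0;
    for (int i = 0; i < n; ++i) {
      yb(i) = y(idx[i]);
      ysum += yb(i);
    }
    if (family == 0 && (ysum < 1.0 || ysum > n - 1.0)) {
      ++failed;
      continue;
    }
    for (int a = 0; a < 7; ++a) {
      double* dst = Zb.colptr(a);
      const double* src = Z.colptr(a);
      for (int i = 0; i < n; ++i) dst[i] = src[idx[i]];
    }
    if (restandardize) {
      for (int a = 2; a <= 4; ++a) { // ds_z, pa_z, age_z
        arma::vec col = Zb.col(a);
        double m = arma::mean(col), s = arma::stddev(col);
        if (s > 0) Zb.col(a) = (col - m) / s;
      }
    }
    PathFit r = fit_paths_mat(Zb, yb, family, start_c.memptr(),
                              start_full.memptr(), maxit, tol, sep_limit);
    if (!r.ok) { ++failed; continue; }
    double ind_ds = r.a1 * r.b1;
    double ind_pa = r.a2 * r.b2;
    double ind_serial = r.a1 * r.a3 * r.b2;
    draws(b, 0) = r.a1;
    draws(b, 1) = r.a2;
    draws(b, 2) = r.a3;
    draws(b, 3) = r.b1;
    draws(b, 4) = r.b2;
    draws(b, 5) = r.c;
    draws(b, 6) = r.c_prime;
    draws(b, 7) = ind_ds;
    draws(b, 8) = ind_pa;
    draws(b, 9) = ind_serial;
    draws(b, 10) = ind_ds + ind_pa + ind_serial;
    ++b;
  }
  return List::create(_["draws"] = draws, _["n_failed"] = failed,
                      _["completed"] = b, _["ok"] = true);
}
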