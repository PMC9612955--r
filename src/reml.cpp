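// Profiled REML for a grouped linear mixed model with a common random-effect
// design within groups and (optionally) two residual-variance classes.
//
// Model: y = X beta + Z_j u_j + e,  u_j ~ N(0, sigma^2 * Lambda Lambda'),
//        e_i ~ N(0, sigma^2 * m_i),  m_i = 1 (class 0) or delta (class 1).
// Lambda is lower-triangular (log-Cholesky parameterisation: log diagonal
// first, then off-diagonal entries column-major); the optional last element
// of theta is log(delta).  sigma^2 and beta are profiled out analytically.
//
// The objective works from per-group sufficient statistics (Z'Z, Z'[X y],
// [X y]'[X y], split by residual class), so one evaluation is a few small
// matrix operations per group and participant-level bootstrap resamples
// reuse the original groups' statistics without touching rows.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double BIG = 1e10;

static mat build_lambda(const vec& theta, int q) {
  mat L(q, q, fill::zeros);
  for (int j = 0; j < q; ++j) L(j, j) = std::exp(theta(j));
  int k = q;
  for (int j = 0; j < q; ++j)
    for (int i = j + 1; i < q; ++i)
      L(i, j) = theta(k++);
  return L;
}

// [[Rcpp::export]]
Rcpp::List reml_group_stats(const arma::mat& XY, const arma::mat& Z,
                            const arma::ivec& gstart, const arma::ivec& gend,
                            const arma::ivec& wclass) {
  const uword q = Z.n_cols, pc = XY.n_cols, J = gstart.n_elem;
  cube Szz0(q, q, J, fill::zeros), Szz1(q, q, J, fill::zeros);
  cube Szx0(q, pc, J, fill::zeros), Szx1(q, pc, J, fill::zeros);
  cube Sxx0(pc, pc, J, fill::zeros), Sxx1(pc, pc, J, fill::zeros);
  ivec n0(J, fill::zeros), n1(J, fill::zeros);
  for (uword g = 0; g < J; ++g) {
    for (uword i = gstart(g); i <= (uword)gend(g); ++i) {
      const rowvec zr = Z.row(i), xr = XY.row(i);
      if (wclass(i) == 1) {
        Szz1.slice(g) += zr.t() * zr;
        Szx1.slice(g) += zr.t() * xr;
        Sxx1.slice(g) += xr.t() * xr;
        n1(g) += 1;
      } else {
        Szz0.slice(g) += zr.t() * zr;
        Szx0.slice(g) += zr.t() * xr;
        Sxx0.slice(g) += xr.t() * xr;
        n0(g) += 1;
      }
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("Szz0") = Szz0, Rcpp::Named("Szz1") = Szz1,
      Rcpp::Named("Szx0") = Szx0, Rcpp::Named("Szx1") = Szx1,
      Rcpp::Named("Sxx0") = Sxx0, Rcpp::Named("Sxx1") = Sxx1,
      Rcpp::Named("n0") = n0, Rcpp::Named("n1") = n1);
}


// zero-copy views onto the stats list's arrays
static cube view3(const Rcpp::NumericVector& v) {
  Rcpp::IntegerVector d = v.attr("dim");
  return cube(const_cast<double*>(v.begin()), d[0], d[1], d[2], false, true);
}

struct StatsView {
  cube Szz0, Szz1, Szx0, Szx1, Sxx0, Sxx1;
  Rcpp::IntegerVector n0, n1;
  explicit StatsView(const Rcpp::List& s)
      : Szz0(view3(s["Szz0"])), Szz1(view3(s["Szz1"])),
        Szx0(view3(s["Szx0"])), Szx1(view3(s["Szx1"])),
        Sxx0(view3(s["Sxx0"])), Sxx1(view3(s["Sxx1"])),
        n0(s["n0"]), n1(s["n1"]) {}
};

// Shared accumulation: C = [X y]' V*^-1 [X y] and log|V*| over the groups
// listed in `take` (1-based, possibly with repeats).
static bool accumulate(const vec& theta, const StatsView& S,
                       const ivec& take, bool has_delta,
                       mat& C, double& logdetV, double& n_tot) {
  const uword q = S.Szz0.n_rows, pc = S.Szx0.n_cols;
  const double delta = has_delta ? std::exp(theta(theta.n_elem - 1)) : 1.0;
  const double log_delta = std::log(delta);
  mat L = build_lambda(theta, q);
  C.zeros(pc, pc);
  logdetV = 0.0;
  n_tot = 0.0;
  const mat Iq = eye(q, q);
  for (uword t = 0; t < take.n_elem; ++t) {
    const uword g = take(t) - 1;
    mat Szz = S.Szz0.slice(g) + S.Szz1.slice(g) / delta;
    mat Szx = S.Szx0.slice(g) + S.Szx1.slice(g) / delta;
    mat Sxx = S.Sxx0.slice(g) + S.Sxx1.slice(g) / delta;
    n_tot += S.n0[g] + S.n1[g];
    logdetV += S.n1[g] * log_delta;
    mat K = symmatu(Iq + L.t() * Szz * L);
    mat Kc;
    if (!chol(Kc, K, "lower")) return false;
    for (uword i = 0; i < q; ++i) logdetV += 2.0 * std::log(Kc(i, i));
    mat G = solve(trimatl(Kc), L.t() * Szx);
    C += Sxx - G.t() * G;
  }
  return true;
}

// [[Rcpp::export]]
double reml_objective(const arma::vec& theta, const Rcpp::List& stats,
                      const arma::ivec& take, bool has_delta) {
  StatsView S(stats);
  const uword pc = S.Szx0.n_cols, p = pc - 1;
  mat C;
  double logdetV, n;
  if (!accumulate(theta, S, take, has_delta, C, logdetV, n))
    return BIG;
  mat A = C.submat(0, 0, p - 1, p - 1);
  vec c = C.submat(0, p, p - 1, p);
  vec beta;
  if (!solve(beta, A, c, solve_opts::no_approx)) return BIG;
  double rss = C(p, p) - dot(c, beta);
  if (!(rss > 0.0)) return BIG;
  double ldA, sgn;
  log_det(ldA, sgn, A);
  if (sgn <= 0.0) return BIG;
  double obj = (n - p) * std::log(rss / (n - p)) + logdetV + ldA;
  return std::isfinite(obj) ? obj : BIG;
}

// Estimates at theta from sufficient statistics (no BLUPs/fitted values).
// [[Rcpp::export]]
Rcpp::List reml_estimates(const arma::vec& theta, const Rcpp::List& stats,
                          const arma::ivec& take, bool has_delta) {
  StatsView S(stats);
  const uword q = S.Szz0.n_rows, pc = S.Szx0.n_cols, p = pc - 1;
  mat C;
  double logdetV, n;
  if (!accumulate(theta, S, take, has_delta, C, logdetV, n))
    Rcpp::stop("random-effect capacitance matrix not positive definite");
  mat A = C.submat(0, 0, p - 1, p - 1);
  vec c = C.submat(0, p, p - 1, p);
  vec beta = solve(A, c, solve_opts::no_approx);
  double rss = C(p, p) - dot(c, beta);
  double sig2 = rss / (n - p);
  double ldA, sgn;
  log_det(ldA, sgn, A);
  mat L = build_lambda(theta, q);
  double delta = has_delta ? std::exp(theta(theta.n_elem - 1)) : 1.0;
  double loglik = -0.5 * ((n - p) * (std::log(2.0 * M_PI * sig2) + 1.0) +
                          logdetV + ldA);
  return Rcpp::List::create(
      Rcpp::Named("beta") = beta,
      Rcpp::Named("vcov") = sig2 * inv_sympd(symmatu(A)),
      Rcpp::Named("sigma2") = sig2, Rcpp::Named("delta") = delta,
      Rcpp::Named("Psi") = sig2 * (L * L.t()),
      Rcpp::Named("loglik") = loglik);
}

// Row-level pass for conditional modes and fitted values (final fits only).
// [[Rcpp::export]]
Rcpp::List reml_blups(const arma::vec& theta, const arma::vec& beta,
                      const arma::mat& XY, const arma::mat& Z,
                      const arma::ivec& gstart, const arma::ivec& gend,
                      const arma::ivec& wclass, bool has_delta) {
  const uword q = Z.n_cols, p = XY.n_cols - 1;
  const double delta = has_delta ? std::exp(theta(theta.n_elem - 1)) : 1.0;
  mat L = build_lambda(theta, q);
  vec y = XY.col(p);
  vec eta = XY.cols(0, p - 1) * beta;
  vec etac = eta;
  mat U(gstart.n_elem, q, fill::zeros);
  for (uword g = 0; g < gstart.n_elem; ++g) {
    const uword r0 = gstart(g), r1 = gend(g);
    const uword nj = r1 - r0 + 1;
    mat Zg = Z.rows(r0, r1);
    vec winv(nj);
    for (uword i = 0; i < nj; ++i)
      winv(i) = (wclass(r0 + i) == 1) ? 1.0 / delta : 1.0;
    mat Zw = Zg.each_col() % winv;
    mat K = symmatu(eye(q, q) + L.t() * (Zg.t() * Zw) * L);
    vec rj = y.subvec(r0, r1) - eta.subvec(r0, r1);
    vec u = L * solve(K, L.t() * (Zw.t() * rj));
    U.row(g) = u.t();
    etac.subvec(r0, r1) += Zg * u;
  }
  return Rcpp::List::create(Rcpp::Named("ranef") = U,
                            Rcpp::Named("fitted_marginal") = eta,
                            Rcpp::Named("fitted_conditional") = etac);
}
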