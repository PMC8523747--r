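// Compound-symmetry (twin random intercept) REML profiled over the
// variance ratio theta = sigma2_pair / sigma2_resid.
//
// The caller orthogonally transforms the data so that the covariance is
// diagonal: pair-difference rows (variance sigma2), singleton rows
// (variance sigma2 * (1 + theta)) and pair-sum rows
// (variance sigma2 * (1 + 2 theta)).  The profile REML criterion is then
// a cheap 1-D function of theta, minimized by golden-section search on
// log(theta).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Profile -2 REML log-likelihood (up to an additive constant) at theta.
// On success fills beta and chol factor R of A = X' W X.
static double cs_criterion(double th,
                           const mat& G0, const mat& G1, const mat& G2,
                           const vec& b0, const vec& b1, const vec& b2,
                           double s0, double s1, double s2,
                           int n, int n1, int n2, int p,
                           vec& beta, mat& R, double& rss, bool& ok) {
  const double w1 = 1.0 / (1.0 + th);
  const double w2 = 1.0 / (1.0 + 2.0 * th);
  mat A = G0 + w1 * G1 + w2 * G2;
  vec b = b0 + w1 * b1 + w2 * b2;
  ok = chol(R, A);
  if (!ok) return datum::inf;
  beta = solve(trimatu(R), solve(trimatl(R.t()), b));
  double yWy = s0 + w1 * s1 + w2 * s2;
  rss = yWy - dot(b, beta);
  if (rss < 1e-300) rss = 1e-300;
  double logdetA = 2.0 * accu(log(R.diag()));
  double logdetD = n1 * std::log(1.0 + th) + n2 * std::log(1.0 + 2.0 * th);
  return (n - p) * std::log(rss) + logdetD + logdetA;
}

// pieces of the unprofiled -2 REML log-likelihood at theta:
// logdet terms and the weighted RSS, for the Satterthwaite machinery
static bool cs_pieces(double th,
                      const mat& G0, const mat& G1, const mat& G2,
                      const vec& b0, const vec& b1, const vec& b2,
                      double s0, double s1, double s2,
                      int n1, int n2, int p,
                      double& rss, double& logdets, double& g_e, int e) {
  const double w1 = 1.0 / (1.0 + th);
  const double w2 = 1.0 / (1.0 + 2.0 * th);
  mat A = G0 + w1 * G1 + w2 * G2;
  vec b = b0 + w1 * b1 + w2 * b2;
  mat R;
  if (!chol(R, A)) return false;
  vec beta = solve(trimatu(R), solve(trimatl(R.t()), b));
  rss = s0 + w1 * s1 + w2 * s2 - dot(b, beta);
  if (rss < 1e-300) rss = 1e-300;
  logdets = 2.0 * accu(log(R.diag())) +
            n1 * std::log(1.0 + th) + n2 * std::log(1.0 + 2.0 * th);
  vec ei(p, fill::zeros); ei(e) = 1.0;
  vec Ainv_e = solve(trimatu(R), solve(trimatl(R.t()), ei));
  g_e = Ainv_e(e);
  return true;
}

// Satterthwaite df for the exposure coefficient: df = 2 f^2 / (grad' V grad)
// with f = Var(beta_e) = sigma2 * g(theta), V the inverse observed REML
// information of (log sigma2, log theta) by central finite differences.
static double satterthwaite_df(double u_hat, double t_hat,
                               const mat& G0, const mat& G1, const mat& G2,
                               const vec& b0, const vec& b1, const vec& b2,
                               double s0, double s1, double s2,
                               int n, int n1, int n2, int p, int e,
                               double df_resid) {
  const double h = 1e-3;
  double rss, lds, g;
  // -2 REML loglik at (u = log sigma2, t = log theta)
  auto F = [&](double u, double t) -> double {
    double rs, ld, gg;
    if (!cs_pieces(std::exp(t), G0, G1, G2, b0, b1, b2, s0, s1, s2,
                   n1, n2, p, rs, ld, gg, e))
      return datum::nan;
    return (n - p) * u + ld + rs * std::exp(-u);
  };
  // g(t) and dg/dt for the delta gradient
  if (!cs_pieces(std::exp(t_hat), G0, G1, G2, b0, b1, b2, s0, s1, s2,
                 n1, n2, p, rss, lds, g, e))
    return df_resid;
  double gp, gm, dum1, dum2;
  if (!cs_pieces(std::exp(t_hat + h), G0, G1, G2, b0, b1, b2, s0, s1, s2,
                 n1, n2, p, dum1, dum2, gp, e) ||
      !cs_pieces(std::exp(t_hat - h), G0, G1, G2, b0, b1, b2, s0, s1, s2,
                 n1, n2, p, dum1, dum2, gm, e))
    return df_resid;
  const double dg_dt = (gp - gm) / (2.0 * h);

  const double f00 = F(u_hat, t_hat);
  const double fpu = F(u_hat + h, t_hat), fmu = F(u_hat - h, t_hat);
  const double fpt = F(u_hat, t_hat + h), fmt = F(u_hat, t_hat - h);
  const double fpp = F(u_hat + h, t_hat + h), fmm = F(u_hat - h, t_hat - h);
  const double fpm = F(u_hat + h, t_hat - h), fmp = F(u_hat - h, t_hat + h);
  mat H(2, 2);
  H(0, 0) = (fpu - 2.0 * f00 + fmu) / (h * h);
  H(1, 1) = (fpt - 2.0 * f00 + fmt) / (h * h);
  H(0, 1) = H(1, 0) = (fpp - fpm - fmp + fmm) / (4.0 * h * h);
  if (!H.is_finite()) return df_resid;
  mat V;
  if (!inv_sympd(V, 0.5 * H)) return df_resid;  // V = 2 H^{-1}
  const double sig2 = std::exp(u_hat);
  vec grad = {sig2 * g, sig2 * dg_dt};
  const double denom = as_scalar(grad.t() * V * grad);
  if (!(denom > 0.0)) return df_resid;
  const double f_var = sig2 * g;
  double df = 2.0 * f_var * f_var / denom;
  if (!std::isfinite(df)) return df_resid;
  if (df < 1.0) df = 1.0;
  if (df > df_resid) df = df_resid;
  return df;
}

// Kenward-Roger adjusted variance of the exposure coefficient.
// The covariance is linear in gamma = (sigma2_e, sigma2_p):
// V = gamma1 I + gamma2 diag(c) with c = 0 (pair-difference rows),
// 1 (singletons), 2 (pair-sum rows).  With everything diagonal by
// group, the KR correction reduces to algebra over the three group
// Gram matrices.  Returns Phi_A[e,e], or a negative value on failure.
static double kr_adjusted_var(double gamma1, double gamma2,
                              const mat& G0, const mat& G1, const mat& G2,
                              int n1, int n2, int e) {
  const int p = G0.n_rows;
  // groups: 0 = pair-diff, 1 = singleton, 2 = pair-sum
  vec v = {gamma1, gamma1 + gamma2, gamma1 + 2.0 * gamma2};
  vec c = {0.0, 1.0, 2.0};
  vec m = {(double)n2, (double)n1, (double)n2};
  if (any(v <= 0.0)) return -1.0;
  const mat* G[3] = {&G0, &G1, &G2};

  auto gsum = [&](const vec& f) {
    mat out(p, p, fill::zeros);
    for (int g = 0; g < 3; ++g) out += f(g) * (*G[g]);
    return out;
  };
  mat A = gsum(1.0 / v);
  mat Phi;
  if (!inv_sympd(Phi, A)) return -1.0;

  // N_i = X' V^-1 A_i V^-1 X, M_ij = X' V^-1 A_i V^-1 A_j V^-1 X
  mat N1 = gsum(1.0 / square(v));
  mat N2 = gsum(c / square(v));
  mat M11 = gsum(1.0 / pow(v, 3));
  mat M12 = gsum(c / pow(v, 3));
  mat M22 = gsum(square(c) / pow(v, 3));
  double S11 = accu(m / square(v));
  double S12 = accu(m % c / square(v));
  double S22 = accu(m % square(c) / square(v));

  // REML information I_ij = (S_ij - 2 tr(Phi M_ij) + tr(Phi N_i Phi N_j))/2
  mat PN1 = Phi * N1, PN2 = Phi * N2;
  mat I(2, 2);
  I(0, 0) = 0.5 * (S11 - 2.0 * trace(Phi * M11) + trace(PN1 * PN1));
  I(0, 1) = I(1, 0) =
      0.5 * (S12 - 2.0 * trace(Phi * M12) + trace(PN1 * PN2));
  I(1, 1) = 0.5 * (S22 - 2.0 * trace(Phi * M22) + trace(PN2 * PN2));
  mat W;
  if (!inv_sympd(W, I)) return -1.0;

  mat D = W(0, 0) * (M11 - N1 * Phi * N1) +
          W(0, 1) * (M12 - N1 * Phi * N2) +
          W(1, 0) * (M12 - N2 * Phi * N1) +
          W(1, 1) * (M22 - N2 * Phi * N2);
  mat PhiA = Phi + 2.0 * Phi * D * Phi;
  return PhiA(e, e);
}

// [[Rcpp::export]]
Rcpp::List reml_cs_batch(const arma::mat& G0, const arma::mat& G1,
                         const arma::mat& G2, const arma::mat& B0,
                         const arma::mat& B1, const arma::mat& B2,
                         const arma::vec& S0, const arma::vec& S1,
                         const arma::vec& S2, int n, int n1, int n2,
                         int expo, double lower, double upper, double tol) {
  const int p = G0.n_rows;
  const int m = B0.n_cols;
  const int e = expo - 1;  // 1-based from R
  const double gr = (std::sqrt(5.0) - 1.0) / 2.0;

  vec est(m, fill::value(datum::nan)), se(m, fill::value(datum::nan));
  vec theta(m, fill::value(datum::nan)), sigma2(m, fill::value(datum::nan));
  vec df_sat(m, fill::value(datum::nan));
  uvec boundary(m, fill::zeros), failed(m, fill::zeros);

  vec beta(p);
  mat R(p, p);
  double rss = 0.0;
  bool ok = false;

  for (int j = 0; j < m; ++j) {
    const vec b0 = B0.col(j), b1 = B1.col(j), b2 = B2.col(j);
    const double s0 = S0(j), s1 = S1(j), s2 = S2(j);

    // golden-section search on t = log(theta)
    double a = lower, b = upper;
    double x1 = b - gr * (b - a), x2 = a + gr * (b - a);
    bool ok1, ok2;
    vec bb(p); mat RR(p, p); double rr;
    double f1 = cs_criterion(std::exp(x1), G0, G1, G2, b0, b1, b2,
                             s0, s1, s2, n, n1, n2, p, bb, RR, rr, ok1);
    double f2 = cs_criterion(std::exp(x2), G0, G1, G2, b0, b1, b2,
                             s0, s1, s2, n, n1, n2, p, bb, RR, rr, ok2);
    while (b - a > tol) {
      if (f1 < f2) {
        b = x2; x2 = x1; f2 = f1;
        x1 = b - gr * (b - a);
        f1 = cs_criterion(std::exp(x1), G0, G1, G2, b0, b1, b2,
                          s0, s1, s2, n, n1, n2, p, bb, RR, rr, ok1);
      } else {
        a = x1; x1 = x2; f1 = f2;
        x2 = a + gr * (b - a);
        f2 = cs_criterion(std::exp(x2), G0, G1, G2, b0, b1, b2,
                          s0, s1, s2, n, n1, n2, p, bb, RR, rr, ok2);
      }
    }
    double t_hat = 0.5 * (a + b);
    // compare interior optimum against the theta -> 0 boundary
    double f_hat = cs_criterion(std::exp(t_hat), G0, G1, G2, b0, b1, b2,
                                s0, s1, s2, n, n1, n2, p, bb, RR, rr, ok);
    double f_lo = cs_criterion(std::exp(lower), G0, G1, G2, b0, b1, b2,
                               s0, s1, s2, n, n1, n2, p, bb, RR, rr, ok1);
    if (ok1 && f_lo <= f_hat) t_hat = lower;

    // upper boundary: theta -> infinity degenerates (within-pair
    // residuals carry no information); collapse to the limit model, a
    // weighted regression on pair means and singletons with df
    // n_pairs + n_singletons - p
    if (t_hat >= upper - 100.0 * tol && n2 > 0 && n1 + n2 > p) {
      mat A = G1 + 0.5 * G2;
      vec b = b1 + 0.5 * b2;
      mat Rb;
      if (chol(Rb, A)) {
        vec bb2 = solve(trimatu(Rb), solve(trimatl(Rb.t()), b));
        double rss2 = s1 + 0.5 * s2 - dot(b, bb2);
        if (rss2 < 1e-300) rss2 = 1e-300;
        int dfb = n1 + n2 - p;
        vec ei(p, fill::zeros); ei(e) = 1.0;
        vec Ainv_e2 = solve(trimatu(Rb), solve(trimatl(Rb.t()), ei));
        est(j) = bb2(e);
        se(j) = std::sqrt(rss2 / dfb * Ainv_e2(e));
        theta(j) = std::exp(upper);
        sigma2(j) = rss2 / dfb;
        boundary(j) = 2;
        df_sat(j) = dfb;
        continue;
      }
    }

    double th_hat = std::exp(t_hat);
    double crit = cs_criterion(th_hat, G0, G1, G2, b0, b1, b2,
                               s0, s1, s2, n, n1, n2, p, beta, R, rss, ok);
    (void)crit;
    if (!ok || !std::isfinite(rss)) { failed(j) = 1; continue; }

    // Var(beta) = sigma2 * A^{-1}; only the exposure entry is needed
    vec ei(p, fill::zeros); ei(e) = 1.0;
    vec Ainv_e = solve(trimatu(R), solve(trimatl(R.t()), ei));
    double s2_hat = rss / (n - p);
    est(j) = beta(e);
    theta(j) = th_hat;
    sigma2(j) = s2_hat;
    boundary(j) = (t_hat <= lower + 1e-12) ? 1 : 0;
    double var_e = s2_hat * Ainv_e(e);
    if (boundary(j) == 0) {
      // small-sample (Kenward-Roger) variance adjustment; fall back to
      // the plug-in variance if the information matrix is singular
      double va = kr_adjusted_var(s2_hat, s2_hat * th_hat,
                                  G0, G1, G2, n1, n2, e);
      if (va > 0.0) var_e = va;
    }
    se(j) = std::sqrt(var_e);
    // at the theta = 0 boundary the model collapses to OLS, where the
    // residual df is exact; otherwise use Satterthwaite
    df_sat(j) = (boundary(j) == 1)
        ? (double)(n - p)
        : satterthwaite_df(std::log(s2_hat), t_hat, G0, G1, G2,
                           B0.col(j), B1.col(j), B2.col(j),
                           S0(j), S1(j), S2(j), n, n1, n2, p, e,
                           (double)(n - p));
  }

  return Rcpp::List::create(
      Rcpp::Named("estimate") = est, Rcpp::Named("se") = se,
      Rcpp::Named("theta") = theta, Rcpp::Named("sigma2") = sigma2,
      Rcpp::Named("boundary") = boundary, Rcpp::Named("failed") = failed,
      Rcpp::Named("df") = df_sat);
}
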