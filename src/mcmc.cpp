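// Block Metropolis-Hastings sampler for the geo-additive multinomial-logit
// model.  Each non-reference category k = 1..7 owns a fixed-effect block,
// optional P-spline blocks, a structured (ICAR) and an unstructured region
// block; proposals are Gaussian IWLS approximations of the full
// conditional, variances update by the conjugate inverse-gamma step.
// All randomness flows through R's RNG so set.seed() governs the chains.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double ETA_CLAMP = 50.0;   // keeps exp() finite; never binding
static const double W_MIN = 1e-10;      // IWLS weight floor

static vec rnorm_vec(unsigned int m) {
  vec z(m);
  for (unsigned int i = 0; i < m; ++i) z(i) = R::norm_rand();
  return z;
}

// log proposal density up to a constant: N(m, Phi^{-1}) evaluated at x,
// with U the upper Cholesky factor of Phi
static double logq(const mat& U, const mat& Phi, const vec& x, const vec& m) {
  vec d = x - m;
  return accu(log(U.diag())) - 0.5 * as_scalar(d.t() * Phi * d);
}

// One IWLS-MH update of a dense coefficient block for category c.
// P/tau2 is the prior precision.  Updates state in place on acceptance.
static bool update_dense(const mat& X, const mat& P, double tau2,
                         vec& coef, const vec& yk,
                         mat& eta, mat& E, vec& denom, unsigned int c) {
  vec etac = eta.col(c);
  vec pi = E.col(c) / denom;
  vec w = clamp(pi % (1.0 - pi), W_MIN, datum::inf);
  vec o = etac - X * coef;
  vec yt = etac + (yk - pi) / w;
  mat Pt = P / tau2;

  mat Xw = X.each_col() % w;
  mat Phi = X.t() * Xw + Pt;
  mat U = chol(Phi);
  vec m = solve(Phi, X.t() * (w % (yt - o)), solve_opts::likely_sympd);
  vec prop = m + solve(trimatu(U), rnorm_vec(coef.n_elem));
  double lq_fwd = logq(U, Phi, prop, m);

  vec etanew = clamp(o + X * prop, -ETA_CLAMP, ETA_CLAMP);
  vec Enew = exp(etanew);
  vec denomNew = denom - E.col(c) + Enew;
  double dll = dot(yk, etanew - etac) - accu(log(denomNew) - log(denom));
  double dlp = -0.5 / tau2 *
    (as_scalar(prop.t() * P * prop) - as_scalar(coef.t() * P * coef));

  vec pi2 = Enew / denomNew;
  vec w2 = clamp(pi2 % (1.0 - pi2), W_MIN, datum::inf);
  vec yt2 = etanew + (yk - pi2) / w2;
  mat Xw2 = X.each_col() % w2;
  mat Phi2 = X.t() * Xw2 + Pt;
  mat U2 = chol(Phi2);
  vec m2 = solve(Phi2, X.t() * (w2 % (yt2 - o)), solve_opts::likely_sympd);
  double lq_rev = logq(U2, Phi2, coef, m2);

  double la = dll + dlp + lq_rev - lq_fwd;
  if (std::log(R::unif_rand()) < la) {
    coef = prop;
    eta.col(c) = etanew;
    E.col(c) = Enew;
    denom = denomNew;
    return true;
  }
  return false;
}

// Same update for a region-indexed block (design = incidence matrix); the
// cross-products collapse to per-region sums, so no n x nr matrix is formed.
static bool update_region(const uvec& reg, unsigned int nr, const mat& P,
                          double tau2, vec& coef, const vec& yk,
                          mat& eta, mat& E, vec& denom, unsigned int c) {
  unsigned int n = reg.n_elem;
  vec etac = eta.col(c);
  vec pi = E.col(c) / denom;
  vec w = clamp(pi % (1.0 - pi), W_MIN, datum::inf);
  vec o = etac - coef.elem(reg);
  vec yt = etac + (yk - pi) / w;
  mat Pt = P / tau2;

  vec wr(nr, fill::zeros), br(nr, fill::zeros);
  vec res = w % (yt - o);
  for (unsigned int i = 0; i < n; ++i) { wr(reg(i)) += w(i); br(reg(i)) += res(i); }
  mat Phi = Pt; Phi.diag() += wr;
  mat U = chol(Phi);
  vec m = solve(Phi, br, solve_opts::likely_sympd);
  vec prop = m + solve(trimatu(U), rnorm_vec(nr));
  double lq_fwd = logq(U, Phi, prop, m);

  vec etanew = clamp(o + prop.elem(reg), -ETA_CLAMP, ETA_CLAMP);
  vec Enew = exp(etanew);
  vec denomNew = denom - E.col(c) + Enew;
  double dll = dot(yk, etanew - etac) - accu(log(denomNew) - log(denom));
  double dlp = -0.5 / tau2 *
    (as_scalar(prop.t() * P * prop) - as_scalar(coef.t() * P * coef));

  vec pi2 = Enew / denomNew;
  vec w2 = clamp(pi2 % (1.0 - pi2), W_MIN, datum::inf);
  vec yt2 = etanew + (yk - pi2) / w2;
  vec wr2(nr, fill::zeros), br2(nr, fill::zeros);
  vec res2 = w2 % (yt2 - o);
  for (unsigned int i = 0; i < n; ++i) { wr2(reg(i)) += w2(i); br2(reg(i)) += res2(i); }
  mat Phi2 = Pt; Phi2.diag() += wr2;
  mat U2 = chol(Phi2);
  vec m2 = solve(Phi2, br2, solve_opts::likely_sympd);
  double lq_rev = logq(U2, Phi2, coef, m2);

  double la = dll + dlp + lq_rev - lq_fwd;
  if (std::log(R::unif_rand()) < la) {
    coef = prop;
    eta.col(c) = etanew;
    E.col(c) = Enew;
    denom = denomNew;
    return true;
  }
  return false;
}

// conjugate inverse-gamma draw: IG(a + rank/2, b + quad/2)
static double draw_variance(double a, double b, double rank_, double quad) {
  double shape = a + 0.5 * rank_;
  double rate = b + 0.5 * quad;
  double g = R::rgamma(shape, 1.0 / rate);
  if (g <= 0) g = 1e-300;
  return 1.0 / g;
}

// [[Rcpp::export]]
Rcpp::List mcmc_multinom_cpp(const arma::ivec& y,            // 0..7 per child
                             const arma::mat& Z,             // n x p fixed design
                             const arma::mat& beta_init,     // p x 7
                             const arma::ivec& region0,      // 0-based, or empty
                             const arma::mat& Q,             // nr x nr (may be 0x0)
                             double rankQ,
                             const Rcpp::List& smoothX,      // list of n x m_s bases
                             const Rcpp::List& smoothP,      // list of penalties
                             const arma::vec& smoothRank,
                             double eps, double a, double b,
                             int n_iter, int burn, int thin,
                             double var_init) {
  const unsigned int n = y.n_elem, p = Z.n_cols, K = 7;
  const bool spatial = region0.n_elem > 0;
  const unsigned int nr = spatial ? Q.n_rows : 0;
  const unsigned int ns = smoothX.size();

  uvec reg;
  if (spatial) reg = conv_to<uvec>::from(region0);

  std::vector<mat> SX(ns);
  std::vector<mat> SP(ns);
  for (unsigned int s = 0; s < ns; ++s) {
    SX[s] = Rcpp::as<mat>(smoothX[s]);
    SP[s] = Rcpp::as<mat>(smoothP[s]);
  }

  mat Beta = beta_init;                       // p x 7
  mat Theta(nr > 0 ? nr : 1, K, fill::zeros);
  mat Phi_(nr > 0 ? nr : 1, K, fill::zeros);
  std::vector<mat> Gamma(ns);
  for (unsigned int s = 0; s < ns; ++s) Gamma[s] = mat(SX[s].n_cols, K, fill::zeros);
  rowvec tau2_theta(K, fill::value(var_init));
  rowvec tau2_phi(K, fill::value(var_init));
  mat tau2_smooth(ns > 0 ? ns : 1, K, fill::value(var_init));

  // linear predictor state
  mat eta = Z * Beta;                          // n x 7
  mat E = exp(eta);
  vec denom = 1.0 + sum(E, 1);

  // indicator columns yk
  mat Yind(n, K, fill::zeros);
  for (unsigned int i = 0; i < n; ++i)
    if (y(i) >= 1) Yind(i, y(i) - 1) = 1.0;

  mat Peps = eps * eye<mat>(p, p);
  mat Inr;
  if (spatial) Inr = eye<mat>(nr, nr);

  const int S = (n_iter - burn + thin - 1) / thin;
  cube BetaS(S, p, K);
  cube ThetaS(spatial ? S : 0, spatial ? nr : 0, spatial ? K : 0);
  cube PhiS = ThetaS;
  mat Tau2tS(spatial ? S : 0, spatial ? K : 0);
  mat Tau2pS = Tau2tS;
  std::vector<cube> GammaS(ns);
  std::vector<mat> Tau2sS(ns);
  for (unsigned int s = 0; s < ns; ++s) {
    GammaS[s] = cube(S, SX[s].n_cols, K);
    Tau2sS[s] = mat(S, K);
  }
  mat acc(2 + ns, K, fill::zeros);   // rows: beta, theta/phi (avg), smooths
  mat accPhi(1, K, fill::zeros);

  int stored = 0;
  for (int it = 0; it < n_iter; ++it) {
    for (unsigned int c = 0; c < K; ++c) {
      vec yk = Yind.col(c);

      vec bcoef = Beta.col(c);
      if (update_dense(Z, Peps, 1.0, bcoef, yk, eta, E, denom, c)) {
        Beta.col(c) = bcoef; acc(0, c) += 1.0;
      }

      for (unsigned int s = 0; s < ns; ++s) {
        vec gcoef = Gamma[s].col(c);
        if (update_dense(SX[s], SP[s], tau2_smooth(s, c), gcoef, yk,
                         eta, E, denom, c)) {
          // centre the fitted smooth; rows of B sum to 1 so a constant
          // coefficient shift moves exactly that constant into the intercept
          double mu = mean(SX[s] * gcoef);
          gcoef -= mu;
          Beta(0, c) += mu;
          Gamma[s].col(c) = gcoef;
          acc(2 + s, c) += 1.0;
        }
        double quad = as_scalar(Gamma[s].col(c).t() * SP[s] * Gamma[s].col(c));
        tau2_smooth(s, c) = draw_variance(a, b, smoothRank(s), quad);
      }

      if (spatial) {
        vec tcoef = Theta.col(c);
        if (update_region(reg, nr, Q, tau2_theta(c), tcoef, yk,
                          eta, E, denom, c)) {
          acc(1, c) += 1.0;
        }
        // sum-to-zero each sweep, intercept absorbs the shift (eta invariant)
        double mu = mean(tcoef);
        tcoef -= mu;
        Beta(0, c) += mu;
        Theta.col(c) = tcoef;
        double quadT = as_scalar(tcoef.t() * Q * tcoef);
        tau2_theta(c) = draw_variance(a, b, rankQ, quadT);

        vec pcoef = Phi_.col(c);
        if (update_region(reg, nr, Inr, tau2_phi(c), pcoef, yk,
                          eta, E, denom, c)) {
          Phi_.col(c) = pcoef; accPhi(0, c) += 1.0;
        }
        double quadP = dot(Phi_.col(c), Phi_.col(c));
        tau2_phi(c) = draw_variance(a, b, (double) nr, quadP);
      }
    }

    if (it >= burn && (it - burn) % thin == 0) {
      for (unsigned int c = 0; c < K; ++c) {
        BetaS.slice(c).row(stored) = Beta.col(c).t();
        if (spatial) {
          ThetaS.slice(c).row(stored) = Theta.col(c).t();
          PhiS.slice(c).row(stored) = Phi_.col(c).t();
          Tau2tS(stored, c) = tau2_theta(c);
          Tau2pS(stored, c) = tau2_phi(c);
        }
        for (unsigned int s = 0; s < ns; ++s) {
          GammaS[s].slice(c).row(stored) = Gamma[s].col(c).t();
          Tau2sS[s](stored, c) = tau2_smooth(s, c);
        }
      }
      ++stored;
    }
    if (it % 500 == 0) Rcpp::checkUserInterrupt();
  }

  Rcpp::List smoothOut(ns), smoothVarOut(ns);
  for (unsigned int s = 0; s < ns; ++s) {
    smoothOut[s] = GammaS[s];
    smoothVarOut[s] = Tau2sS[s];
  }
  return Rcpp::List::create(
    Rcpp::Named("beta") = BetaS,
    Rcpp::Named("theta") = ThetaS,
    Rcpp::Named("phi") = PhiS,
    Rcpp::Named("tau2_theta") = Tau2tS,
    Rcpp::Named("tau2_phi") = Tau2pS,
    Rcpp::Named("smooth") = smoothOut,
    Rcpp::Named("tau2_smooth") = smoothVarOut,
    Rcpp::Named("acc_beta") = acc.row(0).t() / n_iter,
    Rcpp::Named("acc_theta") = spatial ? vec(acc.row(1).t() / n_iter) : vec(),
    Rcpp::Named("acc_phi") = spatial ? vec(accPhi.row(0).t() / n_iter) : vec(),
    Rcpp::Named("acc_smooth") = ns > 0 ?
      mat(acc.rows(2, 1 + ns) / n_iter) : mat(),
    Rcpp::Named("n_stored") = stored);
}
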