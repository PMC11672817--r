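#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Truncated-normal draws (numerically stable in the far tail).
// ---------------------------------------------------------------------------

// Z ~ N(0,1) truncated to (a, Inf). Naive rejection near the bulk,
// Robert (1995) translated-exponential rejection in the tail.
static double rtnorm_std_lower(double a) {
  if (a < 0.45) {
    double z;
    do { z = norm_rand(); } while (z <= a);
    return z;
  }
  const double lambda = 0.5 * (a + std::sqrt(a * a + 4.0));
  for (;;) {
    double z = a + exp_rand() / lambda;
    double diff = z - lambda;
    if (std::log(unif_rand()) <= -0.5 * diff * diff) return z;
  }
}

// X ~ N(mean, sd^2) restricted by sign: status 1 -> X > 0, status 0 -> X <= 0.
static double rtnorm_sign(int status, double mean, double sd) {
  if (status == 1) {
    return mean + sd * rtnorm_std_lower(-mean / sd);
  }
  return mean - sd * rtnorm_std_lower(mean / sd);
}

// [[Rcpp::export]]
NumericVector rtnorm_sign_cpp(IntegerVector status, NumericVector mean,
                              NumericVector sd) {
  const int n = status.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rtnorm_sign(status[i], mean[i], sd[i]);
  return out;
}

// X ~ N(mean, sd^2) truncated to (lower, Inf).
static double rtnorm_lower(double mean, double sd, double lower) {
  return mean + sd * rtnorm_std_lower((lower - mean) / sd);
}

// ---------------------------------------------------------------------------
// Shared helpers for the samplers. All sparse matrices arrive as CSC triplets
// (i = 0-based row indices, p = column pointers, x = values).
// ---------------------------------------------------------------------------

// fitted values per record: W theta, using t(W) stored CSC (columns = records)
static void fitted_records(const int *Wti, const int *Wtp,
                           const double *Wtx, const double *theta,
                           int nrec, double *fit) {
  for (int r = 0; r < nrec; ++r) {
    double s = 0.0;
    for (int k = Wtp[r]; k < Wtp[r + 1]; ++k) s += Wtx[k] * theta[Wti[k]];
    fit[r] = s;
  }
}

// rhs = W'y through t(W) CSC
static void crossprod_Wy(const int *Wti, const int *Wtp,
                         const double *Wtx, const double *y, int nrec,
                         int ptot, double *rhs) {
  std::fill(rhs, rhs + ptot, 0.0);
  for (int r = 0; r < nrec; ++r)
    for (int k = Wtp[r]; k < Wtp[r + 1]; ++k) rhs[Wti[k]] += Wtx[k] * y[r];
}

// quadratic form u' Ainv u
static double quad_Ainv(const int *ai, const int *ap,
                        const double *ax, const double *u, int nu) {
  double q = 0.0;
  for (int j = 0; j < nu; ++j)
    for (int k = ap[j]; k < ap[j + 1]; ++k) q += u[ai[k]] * ax[k] * u[j];
  return q;
}

// bilinear form u' Ainv v
static double bilin_Ainv(const int *ai, const int *ap,
                         const double *ax, const double *u,
                         const double *v, int nu) {
  double q = 0.0;
  for (int j = 0; j < nu; ++j)
    for (int k = ap[j]; k < ap[j + 1]; ++k) q += u[ai[k]] * ax[k] * v[j];
  return q;
}

static double rscaled_inv_chisq(double q, double df) {
  if (df <= 0.0) stop("degrees of freedom for a variance update must be > 0");
  return q / R::rchisq(df);
}

// Sample a 2x2 inverse-Wishart IW(df, S): G = W^-1 with W ~ Wishart(df, S^-1),
// Bartlett decomposition. Requires df > 1 and S positive definite.
static void rinvwishart2(double df, const double S[3], double G[3]) {
  // S, G stored as (11, 12, 22)
  double det = S[0] * S[2] - S[1] * S[1];
  if (det <= 0.0 || S[0] <= 0.0)
    stop("scale matrix for the inverse-Wishart update is not positive definite");
  // Sinv = (1/det) * [S22, -S12; -S12, S11]; chol(Sinv) = L lower
  double v11 = S[2] / det, v12 = -S[1] / det, v22 = S[0] / det;
  double l11 = std::sqrt(v11);
  double l21 = v12 / l11;
  double l22 = std::sqrt(v22 - l21 * l21);
  // Bartlett factor A lower-triangular
  double a11 = std::sqrt(R::rchisq(df));
  double a21 = norm_rand();
  double a22 = std::sqrt(R::rchisq(df - 1.0));
  // W = (L A)(L A)'
  double c11 = l11 * a11;
  double c21 = l21 * a11 + l22 * a21;
  double c22 = l22 * a22;
  double w11 = c11 * c11;
  double w12 = c11 * c21;
  double w22 = c21 * c21 + c22 * c22;
  double dw = w11 * w22 - w12 * w12;
  G[0] = w22 / dw;
  G[1] = -w12 / dw;
  G[2] = w11 / dw;
}

static void check_finite(double x, const char *what) {
  if (!R_finite(x))
    stop("Gibbs sampler diverged: non-finite %s; check the model or priors", what);
}

// ---------------------------------------------------------------------------
// Univariate Gibbs sampler for the repeatability animal model
//   y = X b + Z u + W pe + e,  u ~ N(0, A su2), pe ~ N(0, I spe2),
//   e ~ N(0, I se2)
// Effects are stacked theta = (fixed [nf], u [nu], pe [npe]); M = W'W with W
// the full incidence matrix in that column order. Single-site updates.
// Variances sampled from scaled inverse chi-square full conditionals with
// prior (nu, S) each: q = quadratic + nu*S, df = n + nu.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List gibbs_univariate_cpp(IntegerVector Mi, IntegerVector Mp, NumericVector Mx,
                          IntegerVector Wti, IntegerVector Wtp, NumericVector Wtx,
                          IntegerVector Ai, IntegerVector Ap, NumericVector Ax,
                          NumericVector y, int nf, int nu, int npe,
                          NumericVector init_vc, NumericVector prior_nu,
                          NumericVector prior_s, int n_iter, int burn_in,
                          int thin, bool fix_variances, bool store_effects) {
  const int ptot = nf + nu + npe;
  const int nrec = y.size();
  const int n_store = (n_iter - burn_in) / thin;
  const int *mi = Mi.begin(), *mp = Mp.begin();
  const double *mx = Mx.begin();
  const int *wti = Wti.begin(), *wtp = Wtp.begin();
  const double *wtx = Wtx.begin();
  const int *ai = Ai.begin(), *ap = Ap.begin();
  const double *ax = Ax.begin();
  const double *yv = REAL(y);

  std::vector<double> theta(ptot, 0.0), rhs(ptot), fit(nrec);
  std::vector<double> Mdiag(ptot, 0.0), Adiag(nu, 0.0);
  for (int j = 0; j < ptot; ++j)
    for (int k = mp[j]; k < mp[j + 1]; ++k)
      if (mi[k] == j) Mdiag[j] = mx[k];
  for (int j = 0; j < nu; ++j)
    for (int k = ap[j]; k < ap[j + 1]; ++k)
      if (ai[k] == j) Adiag[j] = ax[k];

  crossprod_Wy(wti, wtp, wtx, yv, nrec, ptot, rhs.data());

  double su2 = init_vc[0], spe2 = init_vc[1], se2 = init_vc[2];

  NumericMatrix draws(n_store, 4);
  NumericMatrix theta_draws(store_effects ? n_store : 0,
                            store_effects ? ptot : 0);
  std::vector<double> esum(ptot, 0.0), esum2(ptot, 0.0);
  int stored = 0;

  for (int iter = 1; iter <= n_iter; ++iter) {
    const double lu = se2 / su2, lpe = se2 / spe2;
    for (int j = 0; j < ptot; ++j) {
      double s = 0.0;
      for (int k = mp[j]; k < mp[j + 1]; ++k) s += mx[k] * theta[mi[k]];
      double cjj = Mdiag[j];
      s -= cjj * theta[j];
      if (j >= nf && j < nf + nu) {
        const int jj = j - nf;
        for (int k = ap[jj]; k < ap[jj + 1]; ++k) {
          const int r = ai[k];
          if (r != jj) s += lu * ax[k] * theta[nf + r];
        }
        cjj += lu * Adiag[jj];
      } else if (j >= nf + nu) {
        cjj += lpe;
      }
      const double mean = (rhs[j] - s) / cjj;
      theta[j] = mean + norm_rand() * std::sqrt(se2 / cjj);
    }

    if (!fix_variances) {
      fitted_records(wti, wtp, wtx, theta.data(), nrec, fit.data());
      double sse = 0.0;
      for (int r = 0; r < nrec; ++r) {
        const double e = yv[r] - fit[r];
        sse += e * e;
      }
      se2 = rscaled_inv_chisq(sse + prior_nu[2] * prior_s[2], nrec + prior_nu[2]);
      const double qu = quad_Ainv(ai, ap, ax, theta.data() + nf, nu);
      su2 = rscaled_inv_chisq(qu + prior_nu[0] * prior_s[0], nu + prior_nu[0]);
      double qpe = 0.0;
      for (int j = nf + nu; j < ptot; ++j) qpe += theta[j] * theta[j];
      spe2 = rscaled_inv_chisq(qpe + prior_nu[1] * prior_s[1], npe + prior_nu[1]);
      check_finite(se2, "residual variance");
      check_finite(su2, "additive variance");
      check_finite(spe2, "permanent-environment variance");
      // numerical floor so variance ratios stay finite
      if (su2 < 1e-10 * se2) su2 = 1e-10 * se2;
      if (spe2 < 1e-10 * se2) spe2 = 1e-10 * se2;
    }

    if (iter > burn_in && (iter - burn_in) % thin == 0) {
      draws(stored, 0) = su2;
      draws(stored, 1) = spe2;
      draws(stored, 2) = se2;
      draws(stored, 3) = su2 / (su2 + spe2 + se2);
      for (int j = 0; j < ptot; ++j) {
        esum[j] += theta[j];
        esum2[j] += theta[j] * theta[j];
        if (store_effects) theta_draws(stored, j) = theta[j];
      }
      ++stored;
    }
    if (iter % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector emean(ptot), esd(ptot);
  for (int j = 0; j < ptot; ++j) {
    emean[j] = esum[j] / n_store;
    const double v = esum2[j] / n_store - emean[j] * emean[j];
    esd[j] = v > 0 ? std::sqrt(v * n_store / std::max(1, n_store - 1)) : 0.0;
  }

  return List::create(_["draws"] = draws, _["effect_mean"] = emean,
                      _["effect_sd"] = esd, _["effect_draws"] = theta_draws);
}

// ---------------------------------------------------------------------------
// Bivariate threshold-linear Gibbs sampler (penalized threshold model).
// Trait 0: days open (observed or penalty-imputed), trait 1: censorship
// liability with threshold 0 (status 1 = censored -> liability > 0).
// Same incidence structure for both traits, so the stacked coefficient
// matrix is Rinv (x) M plus Ginv (x) Ainv and Pinv (x) I prior blocks.
// Residual covariance parameterized as e_DO = b e_l + eps, var(eps) = psi,
// var(e_l) = 1 fixed (identifiability), so R = [psi + b^2, b; b, 1].
// G and P sampled from 2x2 inverse-Wishart full conditionals.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List gibbs_threshold_cpp(IntegerVector Mi, IntegerVector Mp, NumericVector Mx,
                         IntegerVector Wti, IntegerVector Wtp, NumericVector Wtx,
                         IntegerVector Ai, IntegerVector Ap, NumericVector Ax,
                         NumericVector y_do, IntegerVector status,
                         NumericVector lower_bound, bool resample_censored,
                         int nf, int nu, int npe, NumericVector init_G,
                         NumericVector init_P, double init_psi,
                         NumericVector prior_nu, NumericVector prior_s,
                         int n_iter, int burn_in, int thin, bool store_effects,
                         bool store_liabilities) {
  const int ptot = nf + nu + npe;
  const int nrec = y_do.size();
  const int n_store = (n_iter - burn_in) / thin;
  const int *mi = Mi.begin(), *mp = Mp.begin();
  const double *mx = Mx.begin();
  const int *wti = Wti.begin(), *wtp = Wtp.begin();
  const double *wtx = Wtx.begin();
  const int *ai = Ai.begin(), *ap = Ap.begin();
  const double *ax = Ax.begin();

  // theta: column-major [trait0 block | trait1 block], each of length ptot
  std::vector<double> theta(2 * ptot, 0.0);
  std::vector<double> y0(nrec), y1(nrec);
  std::vector<double> rhs0(ptot), rhs1(ptot);
  std::vector<double> fit0(nrec), fit1(nrec);
  std::vector<double> Mdiag(ptot, 0.0), Adiag(nu, 0.0);
  for (int j = 0; j < ptot; ++j)
    for (int k = mp[j]; k < mp[j + 1]; ++k)
      if (mi[k] == j) Mdiag[j] = mx[k];
  for (int j = 0; j < nu; ++j)
    for (int k = ap[j]; k < ap[j + 1]; ++k)
      if (ai[k] == j) Adiag[j] = ax[k];

  for (int r = 0; r < nrec; ++r) {
    y0[r] = y_do[r];
    y1[r] = rtnorm_sign(status[r], 0.0, 1.0); // initial liabilities
  }
  crossprod_Wy(wti, wtp, wtx, y0.data(), nrec, ptot, rhs0.data());

  double G[3] = {init_G[0], init_G[1], init_G[2]};
  double P[3] = {init_P[0], init_P[1], init_P[2]};
  double psi = init_psi, b = (init_G.size() > 3) ? init_G[3] : 0.0;

  const int ncol_draws = 11;
  NumericMatrix draws(n_store, ncol_draws);
  NumericMatrix theta_draws(store_effects ? n_store : 0,
                            store_effects ? 2 * ptot : 0);
  NumericMatrix liab_draws(store_liabilities ? n_store : 0,
                           store_liabilities ? nrec : 0);
  std::vector<double> esum(2 * ptot, 0.0), esum2(2 * ptot, 0.0);
  int stored = 0;

  for (int iter = 1; iter <= n_iter; ++iter) {
    // residual covariance R and its inverse from (b, psi)
    const double r00 = psi + b * b; // var(e_DO)
    const double r01 = b;           // cov(e_DO, e_l); var(e_l) = 1
    const double detR = r00 - r01 * r01; // = psi
    const double Rinv00 = 1.0 / detR;
    const double Rinv01 = -r01 / detR;
    const double Rinv11 = r00 / detR;

    // precisions of the random-effect priors
    double detG = G[0] * G[2] - G[1] * G[1];
    const double Gi00 = G[2] / detG, Gi01 = -G[1] / detG, Gi11 = G[0] / detG;
    double detP = P[0] * P[2] - P[1] * P[1];
    const double Pi00 = P[2] / detP, Pi01 = -P[1] / detP, Pi11 = P[0] / detP;

    crossprod_Wy(wti, wtp, wtx, y1.data(), nrec, ptot, rhs1.data());

    // single-site location updates over (effect j, trait t)
    for (int j = 0; j < ptot; ++j) {
      const bool in_u = (j >= nf && j < nf + nu);
      const bool in_pe = (j >= nf + nu);
      const int jj = in_u ? j - nf : 0;
      for (int t = 0; t < 2; ++t) {
        const double Rt0 = (t == 0) ? Rinv00 : Rinv01;
        const double Rt1 = (t == 0) ? Rinv01 : Rinv11;
        double s = 0.0;
        for (int k = mp[j]; k < mp[j + 1]; ++k) {
          const int r = mi[k];
          s += mx[k] * (Rt0 * theta[r] + Rt1 * theta[ptot + r]);
        }
        double cjj = (t == 0 ? Rinv00 : Rinv11) * Mdiag[j];
        s -= cjj * theta[t * ptot + j];
        if (in_u) {
          const double Gt0 = (t == 0) ? Gi00 : Gi01;
          const double Gt1 = (t == 0) ? Gi01 : Gi11;
          const double gdiag = (t == 0) ? Gi00 : Gi11;
          for (int k = ap[jj]; k < ap[jj + 1]; ++k) {
            const int r = ai[k];
            s += ax[k] * (Gt0 * theta[nf + r] + Gt1 * theta[ptot + nf + r]);
          }
          s -= gdiag * Adiag[jj] * theta[t * ptot + j];
          cjj += gdiag * Adiag[jj];
        } else if (in_pe) {
          const double Pt_other = (t == 0) ? Pi01 : Pi01;
          const double pdiag = (t == 0) ? Pi00 : Pi11;
          s += Pt_other * theta[(1 - t) * ptot + j];
          cjj += pdiag;
        }
        const double rhs_tj = Rt0 * rhs0[j] + Rt1 * rhs1[j];
        const double mean = (rhs_tj - s) / cjj;
        theta[t * ptot + j] = mean + norm_rand() / std::sqrt(cjj);
      }
    }

    fitted_records(wti, wtp, wtx, theta.data(), nrec, fit0.data());
    fitted_records(wti, wtp, wtx, theta.data() + ptot, nrec, fit1.data());

    // liability update: e_l | e_DO ~ N(b e_DO / r00, 1 - b^2 / r00)
    const double slope = b / r00;
    const double csd = std::sqrt(std::max(1.0 - b * b / r00, 1e-12));
    for (int r = 0; r < nrec; ++r) {
      const double e0 = y0[r] - fit0[r];
      const double cmean = fit1[r] + slope * e0;
      y1[r] = rtnorm_sign(status[r], cmean, csd);
    }

    // optional data augmentation of censored DO above its recorded bound
    if (resample_censored) {
      const double psd = std::sqrt(psi);
      for (int r = 0; r < nrec; ++r) {
        if (status[r] == 1) {
          const double e1 = y1[r] - fit1[r];
          y0[r] = rtnorm_lower(fit0[r] + b * e1, psd, lower_bound[r]);
        }
      }
      crossprod_Wy(wti, wtp, wtx, y0.data(), nrec, ptot, rhs0.data());
    }

    // residual parameters: regression of e_DO on e_l
    double s11 = 0.0, s01 = 0.0;
    for (int r = 0; r < nrec; ++r) {
      const double e1 = y1[r] - fit1[r];
      const double e0 = y0[r] - fit0[r];
      s11 += e1 * e1;
      s01 += e0 * e1;
    }
    const double bhat = s01 / s11;
    b = bhat + norm_rand() * std::sqrt(psi / s11);
    double sse = 0.0;
    for (int r = 0; r < nrec; ++r) {
      const double e1 = y1[r] - fit1[r];
      const double eps = (y0[r] - fit0[r]) - b * e1;
      sse += eps * eps;
    }
    psi = rscaled_inv_chisq(sse + prior_nu[2] * prior_s[2], nrec + prior_nu[2]);
    check_finite(psi, "residual variance");

    // genetic covariance matrix
    double Su[3];
    Su[0] = quad_Ainv(ai, ap, ax, theta.data() + nf, nu);
    Su[2] = quad_Ainv(ai, ap, ax, theta.data() + ptot + nf, nu);
    Su[1] = bilin_Ainv(ai, ap, ax, theta.data() + nf, theta.data() + ptot + nf, nu);
    rinvwishart2(nu + prior_nu[0], Su, G);
    check_finite(G[0], "genetic variance");

    // permanent-environment covariance matrix
    double Sp[3] = {0.0, 0.0, 0.0};
    for (int j = nf + nu; j < ptot; ++j) {
      Sp[0] += theta[j] * theta[j];
      Sp[2] += theta[ptot + j] * theta[ptot + j];
      Sp[1] += theta[j] * theta[ptot + j];
    }
    rinvwishart2(npe + prior_nu[1], Sp, P);
    check_finite(P[0], "permanent-environment variance");

    if (iter > burn_in && (iter - burn_in) % thin == 0) {
      const double rdo = psi + b * b;
      draws(stored, 0) = G[0];
      draws(stored, 1) = G[1];
      draws(stored, 2) = G[2];
      draws(stored, 3) = P[0];
      draws(stored, 4) = P[1];
      draws(stored, 5) = P[2];
      draws(stored, 6) = rdo;
      draws(stored, 7) = b;
      draws(stored, 8) = G[0] / (G[0] + P[0] + rdo);
      draws(stored, 9) = G[2] / (G[2] + P[2] + 1.0);
      draws(stored, 10) = G[1] / std::sqrt(G[0] * G[2]);
      for (int j = 0; j < 2 * ptot; ++j) {
        esum[j] += theta[j];
        esum2[j] += theta[j] * theta[j];
        if (store_effects) theta_draws(stored, j) = theta[j];
      }
      if (store_liabilities)
        for (int r = 0; r < nrec; ++r) liab_draws(stored, r) = y1[r];
      ++stored;
    }
    if (iter % 500 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector emean(2 * ptot), esd(2 * ptot);
  for (int j = 0; j < 2 * ptot; ++j) {
    emean[j] = esum[j] / n_store;
    const double v = esum2[j] / n_store - emean[j] * emean[j];
    esd[j] = v > 0 ? std::sqrt(v * n_store / std::max(1, n_store - 1)) : 0.0;
  }

  return List::create(_["draws"] = draws, _["effect_mean"] = emean,
                      _["effect_sd"] = esd, _["effect_draws"] = theta_draws,
                      _["liability_draws"] = liab_draws);
}
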