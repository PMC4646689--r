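// Gibbs samplers for pedigree liability-threshold (animal) models.
//
// The additive-genetic effect is conditioned on the sparse inverse of the
// numerator relationship matrix (Henderson's rules), updated single-site so a
// dense A is never formed. Binary probit responses use Albert-Chib
// truncated-normal augmentation (residual variance fixed at 1); binary logit
// responses use Polya-Gamma augmentation (Devroye sampler, b = 1); the
// three-category models use multinomial-probit utilities against a zero
// baseline with identity residual covariance. Variance components use either
// an inverse-gamma/inverse-Wishart prior or the parameter-expanded
// formulation (working scale alpha ~ N(0,1)), which for the univariate case
// with sigma_u^2 ~ IG(1/2, 1/2) is a half-Cauchy(1) prior on sqrt(V_A).
//
// All randomness flows through R's RNG so seeds set from R reproduce draws.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// ---- truncated standard-deviation-1 normal draws (one-sided) --------------

// N(mu, 1) truncated to (a, Inf); Robert (1995) exponential rejection in the
// tail, plain rejection otherwise.
static double rtnorm_lower(double mu, double a) {
  double astd = a - mu;
  if (astd < 0.45) {
    while (true) {
      double z = R::norm_rand();
      if (z > astd) return mu + z;
    }
  }
  double alpha = 0.5 * (astd + std::sqrt(astd * astd + 4.0));
  while (true) {
    double z = astd + R::exp_rand() / alpha;
    double d = z - alpha;
    if (R::unif_rand() < std::exp(-0.5 * d * d)) return mu + z;
  }
}

static double rtnorm_upper(double mu, double b) {
  return -rtnorm_lower(-mu, -b);
}

// ---- Polya-Gamma PG(1, z) draw (Polson, Scott & Windle 2013) --------------

static const double PG_T = 0.64;

static double pg_coef(int n, double x) {
  double k = (n + 0.5) * M_PI;
  if (x > PG_T) {
    return k * std::exp(-0.5 * k * k * x);
  } else if (x > 0) {
    double e = -1.5 * (std::log(0.5 * M_PI) + std::log(x)) + std::log(k) -
               2.0 * (n + 0.5) * (n + 0.5) / x;
    return std::exp(e);
  }
  return 0.0;
}

// inverse-Gaussian(1/z, 1) truncated to (0, PG_T)
static double pg_rtigauss(double z) {
  double x = PG_T + 1.0;
  if (PG_T < 1.0 / z || z <= 0.0) {
    double alpha = 0.0;
    while (R::unif_rand() > alpha) {
      double e1, e2;
      do {
        e1 = R::exp_rand();
        e2 = R::exp_rand();
      } while (e1 * e1 > 2.0 * e2 / PG_T);
      x = PG_T / ((1.0 + PG_T * e1) * (1.0 + PG_T * e1));
      alpha = std::exp(-0.5 * z * z * x);
    }
  } else {
    double mu = 1.0 / z;
    while (true) {
      double y = R::norm_rand();
      y = y * y;
      double muy = mu * y;
      x = mu + 0.5 * mu * muy - 0.5 * mu * std::sqrt(4.0 * muy + muy * muy);
      if (R::unif_rand() > mu / (mu + x)) x = mu * mu / x;
      if (x <= PG_T) break;
    }
  }
  return x;
}

static double pg_mass_texpon(double z) {
  double fz = 0.125 * M_PI * M_PI + 0.5 * z * z;
  double b = std::sqrt(1.0 / PG_T) * (PG_T * z - 1.0);
  double a = -std::sqrt(1.0 / PG_T) * (PG_T * z + 1.0);
  double x0 = std::log(fz) + fz * PG_T;
  double xb = x0 - z + R::pnorm(b, 0.0, 1.0, 1, 1);
  double xa = x0 + z + R::pnorm(a, 0.0, 1.0, 1, 1);
  double qdivp = 4.0 / M_PI * (std::exp(xb) + std::exp(xa));
  return 1.0 / (1.0 + qdivp);
}

static double pg_draw1(double zin) {
  double z = 0.5 * std::fabs(zin);
  double fz = 0.125 * M_PI * M_PI + 0.5 * z * z;
  while (true) {
    double x;
    if (R::unif_rand() < pg_mass_texpon(z)) {
      x = PG_T + R::exp_rand() / fz;
    } else {
      x = pg_rtigauss(z);
    }
    double s = pg_coef(0, x);
    double y = R::unif_rand() * s;
    int n = 0;
    while (true) {
      ++n;
      if (n % 2 == 1) {
        s -= pg_coef(n, x);
        if (y <= s) return 0.25 * x;
      } else {
        s += pg_coef(n, x);
        if (y > s) break;
      }
    }
  }
}

// [[Rcpp::export]]
Rcpp::NumericVector rpolyagamma1(Rcpp::NumericVector z) {
  int n = z.size();
  Rcpp::NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = pg_draw1(z[i]);
  return out;
}

// ---- small helpers --------------------------------------------------------

static double rinvgamma(double shape, double rate) {
  return 1.0 / R::rgamma(shape, 1.0 / rate);
}

// quadratic form u' Ainv u over a CSC symmetric matrix (full pattern)
static double quad_form_csc(const arma::vec& u, const arma::ivec& Ap,
                            const arma::ivec& Ai, const arma::vec& Ax) {
  double q = 0.0;
  int n = Ap.n_elem - 1;
  for (int j = 0; j < n; ++j)
    for (int k = Ap[j]; k < Ap[j + 1]; ++k) q += Ax[k] * u[Ai[k]] * u[j];
  return q;
}

// Sa = U' Ainv U (2x2) over CSC
static arma::mat quad_form_csc2(const arma::mat& U, const arma::ivec& Ap,
                                const arma::ivec& Ai, const arma::vec& Ax) {
  double s11 = 0.0, s12 = 0.0, s21 = 0.0, s22 = 0.0;
  int n = Ap.n_elem - 1;
  for (int j = 0; j < n; ++j) {
    double a0 = 0.0, a1 = 0.0;
    for (int k = Ap[j]; k < Ap[j + 1]; ++k) {
      a0 += Ax[k] * U(Ai[k], 0);
      a1 += Ax[k] * U(Ai[k], 1);
    }
    s11 += U(j, 0) * a0;
    s12 += U(j, 0) * a1;
    s21 += U(j, 1) * a0;
    s22 += U(j, 1) * a1;
  }
  arma::mat S = {{s11, 0.5 * (s12 + s21)}, {0.5 * (s12 + s21), s22}};
  return S;
}

// draw from N(mean, Prec^{-1}) given precision matrix (small, dense)
static arma::vec rmvnorm_prec(const arma::vec& b, const arma::mat& prec) {
  arma::mat L = arma::chol(prec, "lower");
  arma::vec mean = arma::solve(arma::trimatu(L.t()), arma::solve(arma::trimatl(L), b));
  arma::vec z(b.n_elem);
  for (arma::uword i = 0; i < b.n_elem; ++i) z[i] = R::norm_rand();
  return mean + arma::solve(arma::trimatu(L.t()), z);
}

// inverse-Wishart(df, S) draw for 2x2 S via Bartlett on Wishart(df, S^{-1})
static arma::mat riwish2(double df, const arma::mat& S) {
  arma::mat V = arma::inv_sympd(0.5 * (S + S.t()));
  arma::mat L = arma::chol(V, "lower");
  arma::mat A(2, 2, arma::fill::zeros);
  A(0, 0) = std::sqrt(R::rchisq(df));
  A(1, 1) = std::sqrt(R::rchisq(df - 1.0));
  A(1, 0) = R::norm_rand();
  arma::mat W = L * A * A.t() * L.t();
  return arma::inv_sympd(0.5 * (W + W.t()));
}

// ---- univariate binary animal model ---------------------------------------

// [[Rcpp::export]]
arma::mat gibbs_liability_uni(const arma::ivec& y, const arma::mat& X,
                              const arma::ivec& pid, const arma::ivec& fid,
                              int n_ped, int n_fam, const arma::ivec& Ap,
                              const arma::ivec& Ai, const arma::vec& Ax,
                              int n_iter, int n_burnin, int thin, bool use_c,
                              bool logit, bool px, double ig_shape,
                              double ig_rate, double beta_prior_var) {
  int m = y.n_elem;
  int p = X.n_cols;
  arma::vec beta(p, arma::fill::zeros);
  arma::vec u(n_ped, arma::fill::zeros);
  arma::vec w(std::max(n_fam, 1), arma::fill::zeros);
  double alpha_a = px ? 1.0 : 1.0;
  double alpha_c = 1.0;
  double sig2u = 0.1, sig2w = 0.1;
  arma::vec z(m, arma::fill::zeros);   // working response
  arma::vec wgt(m, arma::fill::ones);  // working precision weights

  // map pedigree index -> observation row (-1 if unphenotyped)
  arma::ivec obs_of_ped(n_ped);
  obs_of_ped.fill(-1);
  for (int j = 0; j < m; ++j) obs_of_ped[pid[j]] = j;

  int n_keep = (n_iter - n_burnin) / thin;
  arma::mat out(n_keep, p + 2);
  int kept = 0;

  arma::vec xb = X * beta;
  arma::mat eyep = arma::eye(p, p) / beta_prior_var;

  for (int it = 0; it < n_iter; ++it) {
    // 1. augmentation
    for (int j = 0; j < m; ++j) {
      double eta = xb[j] + alpha_a * u[pid[j]] +
                   (use_c && fid[j] >= 0 ? alpha_c * w[fid[j]] : 0.0);
      if (logit) {
        double om = pg_draw1(eta);
        wgt[j] = om;
        z[j] = (y[j] - 0.5) / om;
      } else {
        z[j] = y[j] == 1 ? rtnorm_lower(eta, 0.0) : rtnorm_upper(eta, 0.0);
      }
    }

    // 2. fixed effects
    if (p > 0) {
      arma::vec r(m);
      for (int j = 0; j < m; ++j)
        r[j] = z[j] - alpha_a * u[pid[j]] -
               (use_c && fid[j] >= 0 ? alpha_c * w[fid[j]] : 0.0);
      arma::mat Xw = X.each_col() % wgt;
      arma::mat prec = X.t() * Xw + eyep;
      arma::vec b = Xw.t() * r;
      beta = rmvnorm_prec(b, prec);
      xb = X * beta;
    }

    // 3. breeding values, single site over the sparse A-inverse
    for (int i = 0; i < n_ped; ++i) {
      double aii = 0.0, s = 0.0;
      for (int k = Ap[i]; k < Ap[i + 1]; ++k) {
        int row = Ai[k];
        if (row == i)
          aii = Ax[k];
        else
          s += Ax[k] * u[row];
      }
      double prec = aii / sig2u;
      double lin = -s / sig2u;
      int j = obs_of_ped[i];
      if (j >= 0) {
        double r = z[j] - xb[j] -
                   (use_c && fid[j] >= 0 ? alpha_c * w[fid[j]] : 0.0);
        prec += alpha_a * alpha_a * wgt[j];
        lin += alpha_a * wgt[j] * r;
      }
      double v = 1.0 / prec;
      u[i] = v * lin + std::sqrt(v) * R::norm_rand();
    }

    // 4. working-scale parameter (parameter expansion)
    if (px) {
      double prec = 1.0, lin = 0.0;
      for (int j = 0; j < m; ++j) {
        double ui = u[pid[j]];
        double r = z[j] - xb[j] -
                   (use_c && fid[j] >= 0 ? alpha_c * w[fid[j]] : 0.0);
        prec += wgt[j] * ui * ui;
        lin += wgt[j] * ui * r;
      }
      double v = 1.0 / prec;
      alpha_a = v * lin + std::sqrt(v) * R::norm_rand();
    }

    // 5. family-group effects
    if (use_c && n_fam > 0) {
      arma::vec fprec(n_fam, arma::fill::zeros), flin(n_fam, arma::fill::zeros);
      for (int j = 0; j < m; ++j) {
        if (fid[j] < 0) continue;
        double r = z[j] - xb[j] - alpha_a * u[pid[j]];
        fprec[fid[j]] += alpha_c * alpha_c * wgt[j];
        flin[fid[j]] += alpha_c * wgt[j] * r;
      }
      for (int f = 0; f < n_fam; ++f) {
        double v = 1.0 / (fprec[f] + 1.0 / sig2w);
        w[f] = v * flin[f] + std::sqrt(v) * R::norm_rand();
      }
      if (px) {
        double prec = 1.0, lin = 0.0;
        for (int j = 0; j < m; ++j) {
          if (fid[j] < 0) continue;
          double wf = w[fid[j]];
          double r = z[j] - xb[j] - alpha_a * u[pid[j]];
          prec += wgt[j] * wf * wf;
          lin += wgt[j] * wf * r;
        }
        double v = 1.0 / prec;
        alpha_c = v * lin + std::sqrt(v) * R::norm_rand();
      }
    }

    // 6. variances
    double q = quad_form_csc(u, Ap, Ai, Ax);
    sig2u = rinvgamma(ig_shape + 0.5 * n_ped, ig_rate + 0.5 * q);
    if (use_c && n_fam > 0) {
      sig2w = rinvgamma(ig_shape + 0.5 * n_fam,
                        ig_rate + 0.5 * arma::dot(w, w));
    }

    if (it >= n_burnin && (it - n_burnin) % thin == 0) {
      for (int k = 0; k < p; ++k) out(kept, k) = beta[k];
      out(kept, p) = alpha_a * alpha_a * sig2u;
      out(kept, p + 1) = use_c ? alpha_c * alpha_c * sig2w : 0.0;
      ++kept;
    }
  }
  return out.rows(0, kept - 1);
}

// ---- bivariate / categorical animal model (probit) ------------------------

// mode 0: bivariate with one observed trait per record (`trait`, y binary)
// mode 1: three-category latent-utility model (y in {0,1,2}, two utilities)
// [[Rcpp::export]]
arma::mat gibbs_liability_biv(const arma::ivec& y, const arma::ivec& trait,
                              const arma::mat& X, const arma::ivec& pid,
                              const arma::ivec& fid, int n_ped, int n_fam,
                              const arma::ivec& Ap, const arma::ivec& Ai,
                              const arma::vec& Ax, int mode, int n_iter,
                              int n_burnin, int thin, bool use_c, bool px,
                              double nu0, double s0, double beta_prior_var) {
  int m = y.n_elem;
  int p = X.n_cols;
  arma::mat Beta(p, 2, arma::fill::zeros);
  arma::mat U(n_ped, 2, arma::fill::zeros);
  arma::mat W(std::max(n_fam, 1), 2, arma::fill::zeros);
  arma::vec alpha = {1.0, 1.0};
  arma::vec alpha_c = {1.0, 1.0};
  arma::mat Gu = 0.1 * arma::eye(2, 2);
  arma::mat Cw = 0.1 * arma::eye(2, 2);
  arma::mat S0 = s0 * arma::eye(2, 2);
  arma::mat L(m, 2, arma::fill::zeros);         // latent utilities
  arma::imat obs(m, 2, arma::fill::zeros);      // which cells carry likelihood
  for (int j = 0; j < m; ++j) {
    if (mode == 0)
      obs(j, trait[j]) = 1;
    else
      obs(j, 0) = obs(j, 1) = 1;
  }
  arma::ivec obs_of_ped(n_ped);
  obs_of_ped.fill(-1);
  for (int j = 0; j < m; ++j) obs_of_ped[pid[j]] = j;

  int n_keep = (n_iter - n_burnin) / thin;
  arma::mat out(n_keep, 2 * p + 6);
  int kept = 0;
  arma::mat eyep = arma::eye(p, p) / beta_prior_var;
  arma::mat xb = X * Beta;
  std::vector<arma::mat> XtX(2);
  for (int t = 0; t < 2; ++t) {
    arma::mat M = eyep;
    for (int j = 0; j < m; ++j)
      if (obs(j, t)) M += X.row(j).t() * X.row(j);
    XtX[t] = M;
  }

  for (int it = 0; it < n_iter; ++it) {
    arma::mat Gu_inv = arma::inv_sympd(Gu);
    arma::mat Cw_inv = arma::inv_sympd(Cw);
    double gi11 = Gu_inv(0, 0), gi12 = Gu_inv(0, 1), gi22 = Gu_inv(1, 1);
    double ci11 = Cw_inv(0, 0), ci12 = Cw_inv(0, 1), ci22 = Cw_inv(1, 1);

    // 1. latent utilities
    for (int j = 0; j < m; ++j) {
      double e0 = xb(j, 0) + alpha[0] * U(pid[j], 0) +
                  (use_c && fid[j] >= 0 ? alpha_c[0] * W(fid[j], 0) : 0.0);
      double e1 = xb(j, 1) + alpha[1] * U(pid[j], 1) +
                  (use_c && fid[j] >= 0 ? alpha_c[1] * W(fid[j], 1) : 0.0);
      if (mode == 0) {
        int t = trait[j];
        double e = t == 0 ? e0 : e1;
        L(j, t) = y[j] == 1 ? rtnorm_lower(e, 0.0) : rtnorm_upper(e, 0.0);
      } else {
        if (y[j] == 0) {
          L(j, 0) = rtnorm_upper(e0, 0.0);
          L(j, 1) = rtnorm_upper(e1, 0.0);
        } else if (y[j] == 1) {
          L(j, 0) = rtnorm_lower(e0, std::max(0.0, L(j, 1)));
          L(j, 1) = rtnorm_upper(e1, L(j, 0));
        } else {
          L(j, 1) = rtnorm_lower(e1, std::max(0.0, L(j, 0)));
          L(j, 0) = rtnorm_upper(e0, L(j, 1));
        }
      }
    }

    // 2. fixed effects per trait (X'X over the fixed observation pattern is
    // precomputed)
    for (int t = 0; t < 2; ++t) {
      arma::vec r(m, arma::fill::zeros);
      for (int j = 0; j < m; ++j) {
        if (!obs(j, t)) continue;
        r[j] = L(j, t) - alpha[t] * U(pid[j], t) -
               (use_c && fid[j] >= 0 ? alpha_c[t] * W(fid[j], t) : 0.0);
      }
      arma::vec b = X.t() * r;
      Beta.col(t) = rmvnorm_prec(b, XtX[t]);
    }
    xb = X * Beta;

    // 3. breeding-value pairs, single site (scalar 2x2 algebra)
    for (int i = 0; i < n_ped; ++i) {
      double aii = 0.0, s0v = 0.0, s1v = 0.0;
      for (int k = Ap[i]; k < Ap[i + 1]; ++k) {
        int row = Ai[k];
        if (row == i) {
          aii = Ax[k];
        } else {
          s0v += Ax[k] * U(row, 0);
          s1v += Ax[k] * U(row, 1);
        }
      }
      double p11 = aii * gi11, p12 = aii * gi12, p22 = aii * gi22;
      double b0 = -(gi11 * s0v + gi12 * s1v);
      double b1 = -(gi12 * s0v + gi22 * s1v);
      int j = obs_of_ped[i];
      if (j >= 0) {
        if (obs(j, 0)) {
          double r = L(j, 0) - xb(j, 0) -
                     (use_c && fid[j] >= 0 ? alpha_c[0] * W(fid[j], 0) : 0.0);
          p11 += alpha[0] * alpha[0];
          b0 += alpha[0] * r;
        }
        if (obs(j, 1)) {
          double r = L(j, 1) - xb(j, 1) -
                     (use_c && fid[j] >= 0 ? alpha_c[1] * W(fid[j], 1) : 0.0);
          p22 += alpha[1] * alpha[1];
          b1 += alpha[1] * r;
        }
      }
      double det = p11 * p22 - p12 * p12;
      double v11 = p22 / det, v12 = -p12 / det, v22 = p11 / det;
      double mu0 = v11 * b0 + v12 * b1;
      double mu1 = v12 * b0 + v22 * b1;
      double l11 = std::sqrt(v11);
      double l21 = v12 / l11;
      double l22 = std::sqrt(std::max(v22 - l21 * l21, 1e-12));
      double z1 = R::norm_rand(), z2 = R::norm_rand();
      U(i, 0) = mu0 + l11 * z1;
      U(i, 1) = mu1 + l21 * z1 + l22 * z2;
    }

    // 4. working scales
    if (px) {
      for (int t = 0; t < 2; ++t) {
        double prec = 1.0, lin = 0.0;
        for (int j = 0; j < m; ++j) {
          if (!obs(j, t)) continue;
          double ui = U(pid[j], t);
          double r = L(j, t) - xb(j, t) -
                     (use_c && fid[j] >= 0 ? alpha_c[t] * W(fid[j], t) : 0.0);
          prec += ui * ui;
          lin += ui * r;
        }
        double v = 1.0 / prec;
        alpha[t] = v * lin + std::sqrt(v) * R::norm_rand();
      }
    }

    // 5. family effects
    if (use_c && n_fam > 0) {
      arma::mat fprec(n_fam, 2, arma::fill::zeros), flin(n_fam, 2, arma::fill::zeros);
      for (int j = 0; j < m; ++j) {
        if (fid[j] < 0) continue;
        for (int t = 0; t < 2; ++t) {
          if (!obs(j, t)) continue;
          double r = L(j, t) - xb(j, t) - alpha[t] * U(pid[j], t);
          fprec(fid[j], t) += alpha_c[t] * alpha_c[t];
          flin(fid[j], t) += alpha_c[t] * r;
        }
      }
      for (int f = 0; f < n_fam; ++f) {
        double p11 = ci11 + fprec(f, 0), p12 = ci12, p22 = ci22 + fprec(f, 1);
        double b0 = flin(f, 0), b1 = flin(f, 1);
        double det = p11 * p22 - p12 * p12;
        double v11 = p22 / det, v12 = -p12 / det, v22 = p11 / det;
        double mu0 = v11 * b0 + v12 * b1;
        double mu1 = v12 * b0 + v22 * b1;
        double l11 = std::sqrt(v11);
        double l21 = v12 / l11;
        double l22 = std::sqrt(std::max(v22 - l21 * l21, 1e-12));
        double z1 = R::norm_rand(), z2 = R::norm_rand();
        W(f, 0) = mu0 + l11 * z1;
        W(f, 1) = mu1 + l21 * z1 + l22 * z2;
      }
      if (px) {
        for (int t = 0; t < 2; ++t) {
          double prec = 1.0, lin = 0.0;
          for (int j = 0; j < m; ++j) {
            if (fid[j] < 0 || !obs(j, t)) continue;
            double wf = W(fid[j], t);
            double r = L(j, t) - xb(j, t) - alpha[t] * U(pid[j], t);
            prec += wf * wf;
            lin += wf * r;
          }
          double v = 1.0 / prec;
          alpha_c[t] = v * lin + std::sqrt(v) * R::norm_rand();
        }
      }
    }

    // 6. covariance components
    arma::mat Sa = quad_form_csc2(U, Ap, Ai, Ax);
    Gu = riwish2(nu0 + n_ped, S0 + Sa);
    if (use_c && n_fam > 0) {
      arma::mat Sw = W.rows(0, n_fam - 1).t() * W.rows(0, n_fam - 1);
      Cw = riwish2(nu0 + n_fam, S0 + Sw);
    }

    if (it >= n_burnin && (it - n_burnin) % thin == 0) {
      for (int t = 0; t < 2; ++t)
        for (int k = 0; k < p; ++k) out(kept, t * p + k) = Beta(k, t);
      arma::mat Da = arma::diagmat(alpha);
      arma::mat G = Da * Gu * Da;
      arma::mat Dc = arma::diagmat(alpha_c);
      arma::mat C = use_c ? arma::mat(Dc * Cw * Dc) : arma::mat(2, 2, arma::fill::zeros);
      out(kept, 2 * p + 0) = G(0, 0);
      out(kept, 2 * p + 1) = G(1, 0);
      out(kept, 2 * p + 2) = G(1, 1);
      out(kept, 2 * p + 3) = C(0, 0);
      out(kept, 2 * p + 4) = C(1, 0);
      out(kept, 2 * p + 5) = C(1, 1);
      ++kept;
    }
  }
  return out.rows(0, kept - 1);
}
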