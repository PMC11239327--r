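// Gibbs sampler engine for the hierarchical HMM biclustering model.
//
// Conventions: samples in rows, features in columns; z holds 0-based
// cluster labels, rho 0-based feature states (0 = over, 1 = under,
// 2 = irrelevant). All randomness comes from R's RNG so that set.seed()
// at the R level makes runs bit-reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double LOG2PI = 1.837877066409345483560659472811;

static inline double rinvgamma1(double shape, double scale) {
  return 1.0 / R::rgamma(shape, 1.0 / scale); // R::rgamma is shape/scale
}

static arma::vec rdirichlet1(const arma::vec &a) {
  const int K = a.n_elem;
  arma::vec g(K);
  for (int k = 0; k < K; ++k) g[k] = R::rgamma(a[k], 1.0);
  double s = arma::accu(g);
  if (!(s > 0)) { g.fill(1.0 / K); return g; }
  return g / s;
}

// Normal(m, s) truncated to (a, Inf): inverse CDF on the upper tail for
// moderate truncation, Robert's exponential rejection for extreme tails.
static double rtnorm_lower1(double a, double m, double s) {
  double alpha = (a - m) / s;
  if (alpha < 6.0) {
    double pa = R::pnorm(alpha, 0.0, 1.0, 0, 0); // P(Z > alpha)
    double u = R::unif_rand();
    return m + s * R::qnorm(u * pa, 0.0, 1.0, 0, 0);
  }
  double lam = 0.5 * (alpha + std::sqrt(alpha * alpha + 4.0));
  for (;;) {
    double x = alpha + R::exp_rand() / lam;
    double d = x - lam;
    if (R::unif_rand() <= std::exp(-0.5 * d * d)) return m + s * x;
  }
}

// categorical draw from unnormalized log-probabilities lp[0..m-1]
static int sample_cat_log(const double *lp, int m) {
  double mx = lp[0];
  for (int i = 1; i < m; ++i) if (lp[i] > mx) mx = lp[i];
  if (!std::isfinite(mx))
    stop("all states have zero conditional probability");
  double tot = 0.0;
  double prbuf[64];
  std::vector<double> prv;
  double *pr = prbuf;
  if (m > 64) { prv.resize(m); pr = prv.data(); }
  for (int i = 0; i < m; ++i) { pr[i] = std::exp(lp[i] - mx); tot += pr[i]; }
  double u = R::unif_rand() * tot, acc = 0.0;
  for (int i = 0; i < m; ++i) { acc += pr[i]; if (u <= acc) return i; }
  return m - 1;
}

static double dirichlet_logpdf(const arma::vec &x, const arma::vec &a) {
  double out = R::lgammafn(arma::accu(a));
  for (arma::uword i = 0; i < a.n_elem; ++i) {
    out -= R::lgammafn(a[i]);
    out += (a[i] - 1.0) * std::log(std::max(x[i], 1e-300));
  }
  return out;
}

static inline double ig_logpdf(double x, double a, double b) {
  return a * std::log(b) - R::lgammafn(a) - (a + 1.0) * std::log(x) - b / x;
}

// [[Rcpp::export]]
List gibbs_engine_cpp(const arma::mat &Y, int K,
                      const arma::vec &alpha, const arma::vec &delta,
                      double t, double mu0, double s2mu0,
                      double a0, double b0, const arma::vec &v,
                      bool hmm, bool constraint,
                      int iters, int burn_in, int thin,
                      const arma::ivec &z0, const arma::imat &rho0,
                      List params0,
                      bool update_params, bool keep_feature_params,
                      bool verbose) {
  const int n = Y.n_rows, p = Y.n_cols;
  if (iters <= burn_in || burn_in < 0 || thin < 1)
    stop("need iters > burn_in >= 0 and thin >= 1");
  const arma::mat Y2 = Y % Y;

  // ---- state ----
  arma::ivec z = z0 - 1;
  arma::imat rho = rho0 - 1;
  arma::vec omega = as<arma::vec>(params0["omega"]);
  arma::mat xi = as<arma::mat>(params0["xi"]);
  arma::mat muC = as<arma::mat>(params0["mu_cluster"]);
  arma::mat s2C = as<arma::mat>(params0["sigma2_cluster"]);
  arma::cube muF = as<arma::cube>(params0["mu_feature"]);
  arma::cube s2F = as<arma::cube>(params0["sigma2_feature"]);
  arma::vec s2I = as<arma::vec>(params0["sigma2_irrelevant"]);

  // ---- storage ----
  const int S = (iters - burn_in + thin - 1) / thin;
  IntegerMatrix z_draws(n, S);
  IntegerVector rho_draws(static_cast<R_xlen_t>(p) * K * S);
  rho_draws.attr("dim") = IntegerVector::create(p, K, S);
  NumericMatrix omega_draws(K, S);
  NumericVector xi_draws(static_cast<R_xlen_t>(9) * S);
  xi_draws.attr("dim") = IntegerVector::create(3, 3, S);
  NumericVector muC_draws(static_cast<R_xlen_t>(K) * 2 * S);
  muC_draws.attr("dim") = IntegerVector::create(K, 2, S);
  NumericVector s2C_draws(static_cast<R_xlen_t>(K) * 2 * S);
  s2C_draws.attr("dim") = IntegerVector::create(K, 2, S);
  NumericVector cloglik(S), obsloglik(S), logprior(S);
  NumericVector muF_draws(0), s2F_draws(0), s2I_draws(0);
  if (keep_feature_params) {
    muF_draws = NumericVector(static_cast<R_xlen_t>(p) * K * 2 * S);
    muF_draws.attr("dim") = IntegerVector::create(p, K, 2, S);
    s2F_draws = NumericVector(static_cast<R_xlen_t>(p) * K * 2 * S);
    s2F_draws.attr("dim") = IntegerVector::create(p, K, 2, S);
    s2I_draws = NumericVector(static_cast<R_xlen_t>(p) * S);
    s2I_draws.attr("dim") = IntegerVector::create(p, S);
  }

  // online MAP tracking (posterior score and likelihood-only score)
  double best_post = R_NegInf, best_lik = R_NegInf;
  int best_post_idx = -1, best_lik_idx = -1;
  arma::ivec zP, zL; arma::imat rhoP, rhoL;
  arma::vec omP, omL, s2IP, s2IL;
  arma::mat xiP, xiL, muCP, muCL, s2CP, s2CL;
  arma::cube muFP, muFL, s2FP, s2FL;

  int n_empty = 0;
  arma::ivec nk(K);
  arma::mat Csum(p, K), Csum2(p, K);

  auto recount = [&]() {
    nk.zeros(); Csum.zeros(); Csum2.zeros();
    for (int i = 0; i < n; ++i) nk[z[i]]++;
    for (int j = 0; j < p; ++j) {
      const double *yj = Y.colptr(j);
      const double *yj2 = Y2.colptr(j);
      for (int i = 0; i < n; ++i) {
        int k = z[i];
        Csum(j, k) += yj[i];
        Csum2(j, k) += yj2[i];
      }
    }
  };

  const double sdmu0 = std::sqrt(s2mu0);
  // log normalizing constant of the magnitude prior TN(t, mu0, s2mu0)
  const double ltail = R::pnorm((t - mu0) / sdmu0, 0.0, 1.0, 0, 1);

  for (int it = 0; it < iters; ++it) {
    if (it % 200 == 0) Rcpp::checkUserInterrupt();
    recount();

    if (update_params) {
      // (1) cluster probabilities
      {
        arma::vec a(K);
        for (int k = 0; k < K; ++k) a[k] = alpha[k] + nk[k];
        omega = rdirichlet1(a);
      }
      // (2) feature means, then cluster means
      for (int l = 0; l < 2; ++l)
        for (int k = 0; k < K; ++k) {
          const double mc = muC(k, l), vc = s2C(k, l);
          for (int j = 0; j < p; ++j) {
            double vf = s2F(j, k, l), Np = 0.0, Mp = 0.0;
            if (rho(j, k) == l) { Np = nk[k]; Mp = Csum(j, k); }
            double mean = (mc * vf / vc + Mp) / (vf / vc + Np);
            double var = 1.0 / (1.0 / vc + Np / vf);
            muF(j, k, l) = R::rnorm(mean, std::sqrt(var));
          }
        }
      for (int k = 0; k < K; ++k)
        for (int l = 0; l < 2; ++l) {
          double M = 0.0; int N = 0;
          for (int j = 0; j < p; ++j)
            if (rho(j, k) == l) { M += muF(j, k, l); N++; }
          const double vkl = s2C(k, l);
          const double sgn = (l == 0) ? 1.0 : -1.0;
          const double var = 1.0 / (1.0 / s2mu0 + N / vkl);
          if (constraint) {
            double mean = (mu0 * vkl / s2mu0 + sgn * M) / (vkl / s2mu0 + N);
            muC(k, l) = sgn * rtnorm_lower1(t, mean, std::sqrt(var));
          } else {
            double mean = (mu0 * vkl / s2mu0 + M) / (vkl / s2mu0 + N);
            muC(k, l) = R::rnorm(mean, std::sqrt(var));
          }
        }
      // (3) variances
      for (int k = 0; k < K; ++k)
        for (int l = 0; l < 2; ++l) {
          double S2 = 0.0; int N = 0;
          for (int j = 0; j < p; ++j)
            if (rho(j, k) == l) {
              double d = muF(j, k, l) - muC(k, l);
              S2 += d * d; N++;
            }
          s2C(k, l) = rinvgamma1(a0 + 0.5 * N, b0 + 0.5 * S2);
        }
      for (int l = 0; l < 2; ++l)
        for (int k = 0; k < K; ++k)
          for (int j = 0; j < p; ++j) {
            double N = 0.0, SS = 0.0;
            if (rho(j, k) == l) {
              N = nk[k];
              double m = muF(j, k, l);
              SS = Csum2(j, k) - 2.0 * m * Csum(j, k) + nk[k] * m * m;
              if (SS < 0) SS = 0;
            }
            s2F(j, k, l) = rinvgamma1(a0 + 0.5 * N, b0 + 0.5 * SS);
          }
      for (int j = 0; j < p; ++j) {
        double N = 0.0, SS = 0.0;
        for (int k = 0; k < K; ++k)
          if (rho(j, k) == 2) { N += nk[k]; SS += Csum2(j, k); }
        s2I[j] = rinvgamma1(a0 + 0.5 * N, b0 + 0.5 * SS);
      }
      // (4) transition matrix (HMM) or shared state frequencies (non-HMM:
      // i.i.d. categorical states with a Dirichlet-updated distribution,
      // stored as three identical rows of xi)
      if (hmm) {
        arma::mat cnt(3, 3, arma::fill::zeros);
        for (int k = 0; k < K; ++k)
          for (int j = 1; j < p; ++j)
            cnt(rho(j - 1, k), rho(j, k)) += 1.0;
        for (int r = 0; r < 3; ++r) {
          arma::vec a(3);
          for (int l = 0; l < 3; ++l) a[l] = delta[l] + cnt(r, l);
          xi.row(r) = rdirichlet1(a).t();
        }
      } else {
        arma::vec a(delta);
        for (int k = 0; k < K; ++k)
          for (int j = 0; j < p; ++j) a[rho(j, k)] += 1.0;
        arma::rowvec pi = rdirichlet1(a).t();
        for (int r = 0; r < 3; ++r) xi.row(r) = pi;
      }
    }

    // (5) cluster labels: log p(z_i = k) = log omega_k + quadratic in y_i
    {
      arma::mat W(p, K), V(p, K);
      arma::rowvec u(K, arma::fill::zeros);
      for (int k = 0; k < K; ++k)
        for (int j = 0; j < p; ++j) {
          int l = rho(j, k);
          double m = (l == 2) ? 0.0 : muF(j, k, l);
          double var = (l == 2) ? s2I[j] : s2F(j, k, l);
          W(j, k) = -0.5 / var;
          V(j, k) = m / var;
          u[k] += -0.5 * (LOG2PI + std::log(var)) - 0.5 * m * m / var;
        }
      arma::mat L = Y2 * W + Y * V;
      L.each_row() += u;
      for (int k = 0; k < K; ++k) {
        double lo = (omega[k] < 1e-300) ? R_NegInf : std::log(omega[k]);
        L.col(k) += lo;
      }
      std::vector<double> lpv(K);
      for (int i = 0; i < n; ++i) {
        for (int k = 0; k < K; ++k) lpv[k] = L(i, k);
        z[i] = sample_cat_log(lpv.data(), K);
      }
    }

    // (6) feature-state chains: single-site systematic scan per cluster
    recount();
    arma::cube CL(p, K, 3);
    for (int k = 0; k < K; ++k) {
      const double nkd = nk[k];
      for (int j = 0; j < p; ++j) {
        for (int l = 0; l < 2; ++l) {
          double m = muF(j, k, l), var = s2F(j, k, l);
          CL(j, k, l) = -0.5 * nkd * (LOG2PI + std::log(var)) -
            0.5 * (Csum2(j, k) - 2.0 * m * Csum(j, k) + nkd * m * m) / var;
        }
        CL(j, k, 2) = -0.5 * nkd * (LOG2PI + std::log(s2I[j])) -
          0.5 * Csum2(j, k) / s2I[j];
      }
    }
    {
      arma::mat lxi(3, 3);
      for (int r = 0; r < 3; ++r)
        for (int l = 0; l < 3; ++l)
          lxi(r, l) = (xi(r, l) < 1e-300) ? R_NegInf : std::log(xi(r, l));
      double lp[3];
      for (int k = 0; k < K; ++k)
        for (int j = 0; j < p; ++j) {
          for (int l = 0; l < 3; ++l) {
            lp[l] = CL(j, k, l);
            if (hmm) {
              if (j > 0) lp[l] += lxi(rho(j - 1, k), l);
              if (j < p - 1) lp[l] += lxi(l, rho(j + 1, k));
            } else {
              lp[l] += lxi(0, l);  // shared state frequencies
            }
          }
          rho(j, k) = sample_cat_log(lp, 3);
        }
    }

    // ---- per-iteration scores ----
    recount();
    double obsll = 0.0;
    for (int k = 0; k < K; ++k) {
      const double nkd = nk[k];
      for (int j = 0; j < p; ++j) {
        int l = rho(j, k);
        if (l == 2)
          obsll += -0.5 * nkd * (LOG2PI + std::log(s2I[j])) -
            0.5 * Csum2(j, k) / s2I[j];
        else {
          double m = muF(j, k, l), var = s2F(j, k, l);
          obsll += -0.5 * nkd * (LOG2PI + std::log(var)) -
            0.5 * (Csum2(j, k) - 2.0 * m * Csum(j, k) + nkd * m * m) / var;
        }
      }
    }
    double chain = 0.0;
    if (hmm) {
      for (int k = 0; k < K; ++k) {
        chain += std::log(std::max(v[rho(0, k)], 1e-300));
        for (int j = 1; j < p; ++j) {
          double x = xi(rho(j - 1, k), rho(j, k));
          chain += (x < 1e-300) ? R_NegInf : std::log(x);
        }
      }
    } else {
      for (int k = 0; k < K; ++k)
        for (int j = 0; j < p; ++j)
          chain += std::log(std::max(xi(0, rho(j, k)), 1e-300));
    }
    double zpr = 0.0;
    for (int i = 0; i < n; ++i)
      zpr += std::log(std::max(omega[z[i]], 1e-300));
    double cll = obsll + chain + zpr;

    double lpr = 0.0;
    for (int k = 0; k < K; ++k)
      for (int l = 0; l < 2; ++l) {
        if (constraint)
          lpr += R::dnorm(std::fabs(muC(k, l)), mu0, sdmu0, 1) - ltail;
        else
          lpr += R::dnorm(muC(k, l), mu0, sdmu0, 1);
        lpr += ig_logpdf(s2C(k, l), a0, b0);
        double sdc = std::sqrt(s2C(k, l));
        for (int j = 0; j < p; ++j) {
          lpr += R::dnorm(muF(j, k, l), muC(k, l), sdc, 1);
          lpr += ig_logpdf(s2F(j, k, l), a0, b0);
        }
      }
    for (int j = 0; j < p; ++j) lpr += ig_logpdf(s2I[j], a0, b0);
    lpr += dirichlet_logpdf(omega, alpha);
    if (hmm)
      for (int r = 0; r < 3; ++r)
        lpr += dirichlet_logpdf(xi.row(r).t(), delta);
    else
      lpr += dirichlet_logpdf(xi.row(0).t(), delta);

    // ---- retain ----
    if (it >= burn_in && (it - burn_in) % thin == 0) {
      const int s = (it - burn_in) / thin;
      for (int i = 0; i < n; ++i) z_draws(i, s) = z[i] + 1;
      {
        int *rp = INTEGER(rho_draws) + static_cast<R_xlen_t>(s) * p * K;
        for (int k = 0; k < K; ++k)
          for (int j = 0; j < p; ++j) rp[k * p + j] = rho(j, k) + 1;
      }
      for (int k = 0; k < K; ++k) omega_draws(k, s) = omega[k];
      {
        double *xp = REAL(xi_draws) + static_cast<R_xlen_t>(s) * 9;
        for (int l = 0; l < 3; ++l)
          for (int r = 0; r < 3; ++r) xp[l * 3 + r] = xi(r, l);
        double *mp = REAL(muC_draws) + static_cast<R_xlen_t>(s) * K * 2;
        double *sp = REAL(s2C_draws) + static_cast<R_xlen_t>(s) * K * 2;
        for (int l = 0; l < 2; ++l)
          for (int k = 0; k < K; ++k) {
            mp[l * K + k] = muC(k, l);
            sp[l * K + k] = s2C(k, l);
          }
      }
      if (keep_feature_params) {
        double *mf = REAL(muF_draws) + static_cast<R_xlen_t>(s) * p * K * 2;
        double *sf = REAL(s2F_draws) + static_cast<R_xlen_t>(s) * p * K * 2;
        double *si = REAL(s2I_draws) + static_cast<R_xlen_t>(s) * p;
        for (int l = 0; l < 2; ++l)
          for (int k = 0; k < K; ++k)
            for (int j = 0; j < p; ++j) {
              mf[(l * K + k) * p + j] = muF(j, k, l);
              sf[(l * K + k) * p + j] = s2F(j, k, l);
            }
        for (int j = 0; j < p; ++j) si[j] = s2I[j];
      }
      cloglik[s] = cll;
      obsloglik[s] = obsll;
      logprior[s] = lpr;
      if (nk.min() == 0) n_empty++;
      if (cll + lpr > best_post) {
        best_post = cll + lpr; best_post_idx = s;
        zP = z; rhoP = rho; omP = omega; xiP = xi;
        muCP = muC; s2CP = s2C; muFP = muF; s2FP = s2F; s2IP = s2I;
      }
      if (cll > best_lik) {
        best_lik = cll; best_lik_idx = s;
        zL = z; rhoL = rho; omL = omega; xiL = xi;
        muCL = muC; s2CL = s2C; muFL = muF; s2FL = s2F; s2IL = s2I;
      }
    }
    if (verbose && (it + 1) % 500 == 0)
      Rcout << "iteration " << it + 1 << "/" << iters
            << "  complete-data loglik " << cll << "\n";
  }

  auto pack_map = [&](int idx, double score, const arma::ivec &zz,
                      const arma::imat &rr, const arma::vec &om,
                      const arma::mat &xx, const arma::mat &mc,
                      const arma::mat &sc, const arma::cube &mf,
                      const arma::cube &sf, const arma::vec &si) {
    return List::create(
      _["index"] = idx + 1, _["score"] = score,
      _["z"] = IntegerVector(zz.begin(), zz.end()) + 1,
      _["rho"] = wrap(arma::conv_to<arma::imat>::from(rr + 1)),
      _["omega"] = om, _["xi"] = xx, _["mu_cluster"] = mc,
      _["sigma2_cluster"] = sc, _["mu_feature"] = mf,
      _["sigma2_feature"] = sf, _["sigma2_irrelevant"] = si);
  };

  List out = List::create(
    _["z"] = z_draws, _["rho"] = rho_draws,
    _["omega"] = omega_draws, _["xi"] = xi_draws,
    _["mu_cluster"] = muC_draws, _["sigma2_cluster"] = s2C_draws,
    _["cloglik"] = cloglik, _["obsloglik"] = obsloglik,
    _["logprior"] = logprior,
    _["map"] = pack_map(best_post_idx, best_post, zP, rhoP, omP, xiP,
                        muCP, s2CP, muFP, s2FP, s2IP),
    _["map_lik"] = pack_map(best_lik_idx, best_lik, zL, rhoL, omL, xiL,
                            muCL, s2CL, muFL, s2FL, s2IL),
    _["n_empty_cluster_draws"] = n_empty);
  if (keep_feature_params) {
    out["mu_feature"] = muF_draws;
    out["sigma2_feature"] = s2F_draws;
    out["sigma2_irrelevant"] = s2I_draws;
  }
  return out;
}
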