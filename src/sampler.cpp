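// Metropolis-within-Gibbs sampler and likelihood kernels for the
// zero-inflated negative binomial batch mixture model.
//
// Conventions (all matrices column-major as passed from R):
//   Y, X, Z : G x N      (genes x cells)
//   beta    : G x K      (column 1 == baseline type, all zero)
//   nu, phi : G x B      (nu column 1 == reference batch, all zero)
//   pi      : B x K
//   batch   : length N, 0-based in C++
// All randomness flows through R's RNG so set.seed() on the R side makes
// every run bit-reproducible.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double TAIL_EPS = 1e-14;   // certified NB upper-tail truncation
static const int    XCAP     = 200000;  // hard cap on the dropout series

// log f_NB(x; mu, phi), the mean/overdispersion parameterization:
// C(phi+x-1, x) (mu/(mu+phi))^x (phi/(mu+phi))^phi
static inline double nb_lpmf(double x, double mu, double phi) {
  return R::lgammafn(x + phi) - R::lgammafn(phi) - R::lgammafn(x + 1.0)
    + x * (std::log(mu) - std::log(mu + phi))
    + phi * (std::log(phi) - std::log(mu + phi));
}

// log(1 + exp(t)) without overflow
static inline double softplus(double t) {
  if (t > 30.0) return t + std::log1p(std::exp(-t));
  return std::log1p(std::exp(t));
}

// Dropout-inclusive zero-observation kernel.
// Computes, scaled by f_NB(0), the series S = sum_{x>=1} logistic(g0+g1 x) f_NB(x)
// truncated at the smallest x with NB upper-tail mass < TAIL_EPS.
// Returns log( f_NB(0) + S ).  If s_out is non-null, stores S / f_NB(0);
// the caller can then inverse-CDF sample from the series by a second pass.
static double zero_obs_core(double mu, double phi, double g0, double g1,
                            double *s_out) {
  const double lf0 = phi * (std::log(phi) - std::log(mu + phi));
  const double rr  = mu / (mu + phi);
  // cumulative target in the scaled (divided by f0) metric
  const double target = (1.0 - TAIL_EPS) * std::exp(-lf0);
  double t = 1.0, cum = 1.0, S = 0.0;
  double q = std::exp(-g0 - g1);          // exp(-(g0+g1*x)) at x=1
  const double eg = std::exp(-g1);        // g1 < 0 so eg > 1
  for (int x = 1; x <= XCAP; ++x) {
    t *= (phi + x - 1.0) / x * rr;
    S += t / (1.0 + q);
    cum += t;
    if (cum >= target) break;
    q *= eg;
    if (q > 1e300) { // logistic underflow: remaining terms contribute ~ t*exp(-q)
      break;
    }
  }
  if (s_out) *s_out = S;
  return lf0 + std::log1p(S);
}

// Inverse-CDF draw from the truncated dropout series (support x >= 1),
// given u in (0, S) on the scaled metric.  Mirrors zero_obs_core's recurrence.
static int zero_obs_sample(double mu, double phi, double g0, double g1,
                           double u) {
  const double rr = mu / (mu + phi);
  double t = 1.0, acc = 0.0;
  double q = std::exp(-g0 - g1);
  const double eg = std::exp(-g1);
  for (int x = 1; x <= XCAP; ++x) {
    t *= (phi + x - 1.0) / x * rr;
    acc += t / (1.0 + q);
    if (acc >= u) return x;
    q *= eg;
    if (q > 1e300) return x;
  }
  return XCAP;
}

// [[Rcpp::export]]
double cpp_zero_obs_logprob(double mu, double phi, double g0, double g1) {
  return zero_obs_core(mu, phi, g0, g1, (double *)0);
}

// Observed-data log likelihood, Eq.-style mixture over cell types with the
// zero branch = biological zero + dropout series ("full") or plain NB ("nzf").
// [[Rcpp::export]]
double cpp_observed_loglik(const IntegerMatrix &Y, const IntegerVector &batch,
                           const NumericVector &alpha, const NumericMatrix &beta,
                           const NumericMatrix &nu, const NumericVector &delta,
                           const NumericMatrix &phi, const NumericVector &gamma0,
                           const NumericVector &gamma1, const NumericMatrix &pi,
                           const bool nzf) {
  const int G = Y.nrow(), N = Y.ncol(), K = beta.ncol();
  std::vector<double> lk(K);
  double total = 0.0;
  for (int i = 0; i < N; ++i) {
    const int b = batch[i];
    for (int k = 0; k < K; ++k) {
      double s = std::log(pi(b, k));
      for (int g = 0; g < G; ++g) {
        const double mu = std::exp(alpha[g] + beta(g, k) + nu(g, b) + delta[i]);
        const double ph = phi(g, b);
        const int y = Y(g, i);
        if (nzf) {
          s += nb_lpmf(y, mu, ph);
        } else if (y == 0) {
          s += zero_obs_core(mu, ph, gamma0[b], gamma1[b], (double *)0);
        } else {
          s += nb_lpmf(y, mu, ph) - softplus(gamma0[b] + gamma1[b] * y);
        }
      }
      lk[k] = s;
    }
    double m = lk[0];
    for (int k = 1; k < K; ++k) if (lk[k] > m) m = lk[k];
    double sum = 0.0;
    for (int k = 0; k < K; ++k) sum += std::exp(lk[k] - m);
    total += m + std::log(sum);
  }
  return total;
}

// ---------------------------------------------------------------------------
// Full conditional evaluators (likelihood + prior) used by the acceptance-
// ratio oracle tests.  They evaluate the same mathematical quantities the
// sweep uses, by direct summation.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
double cpp_block_logcond(const std::string &block, const int idx1, const int idx2,
                         const NumericVector &value,
                         const IntegerMatrix &X, const IntegerMatrix &Z,
                         const IntegerVector &batch, const IntegerVector &W,
                         const NumericVector &alpha, const NumericMatrix &beta,
                         const NumericMatrix &nu, const NumericVector &delta,
                         const NumericMatrix &phi, const NumericVector &gamma0,
                         const NumericVector &gamma1, const IntegerMatrix &L,
                         const double p, const double tau0sq, const List &hyper) {
  const int G = X.nrow(), N = X.ncol();
  const double tau1sq = as<double>(hyper["tau_beta1_sq"]);
  double out = 0.0;
  if (block == "alpha") {
    const int g = idx1 - 1; const double a = value[0];
    for (int i = 0; i < N; ++i) {
      const int b = batch[i];
      const double mu = std::exp(a + beta(g, W[i]) + nu(g, b) + delta[i]);
      out += nb_lpmf(X(g, i), mu, phi(g, b));
    }
    const double m = as<double>(hyper["m_a"]), v = as<double>(hyper["sigma_a_sq"]);
    out += -0.5 * (a - m) * (a - m) / v;
  } else if (block == "beta") {
    const int g = idx1 - 1, k = idx2 - 1; const double bb = value[0];
    for (int i = 0; i < N; ++i) {
      if (W[i] != k) continue;
      const int b = batch[i];
      const double mu = std::exp(alpha[g] + bb + nu(g, b) + delta[i]);
      out += nb_lpmf(X(g, i), mu, phi(g, b));
    }
    const double v = L(g, k) == 1 ? tau1sq : tau0sq;
    out += -0.5 * bb * bb / v - 0.5 * std::log(v);
  } else if (block == "nu") {
    const int b = idx1 - 1, g = idx2 - 1; const double nn = value[0];
    for (int i = 0; i < N; ++i) {
      if (batch[i] != b) continue;
      const double mu = std::exp(alpha[g] + beta(g, W[i]) + nn + delta[i]);
      out += nb_lpmf(X(g, i), mu, phi(g, b));
    }
    const double m = as<double>(hyper["m_c"]), v = as<double>(hyper["sigma_c_sq"]);
    out += -0.5 * (nn - m) * (nn - m) / v;
  } else if (block == "delta") {
    const int i = idx1 - 1; const double d = value[0];
    const int b = batch[i];
    for (int g = 0; g < G; ++g) {
      const double mu = std::exp(alpha[g] + beta(g, W[i]) + nu(g, b) + d);
      out += nb_lpmf(X(g, i), mu, phi(g, b));
    }
    const double m = as<double>(hyper["m_d"]), v = as<double>(hyper["sigma_d_sq"]);
    out += -0.5 * (d - m) * (d - m) / v;
  } else if (block == "phi") {
    const int b = idx1 - 1, g = idx2 - 1; const double ph = value[0];
    for (int i = 0; i < N; ++i) {
      if (batch[i] != b) continue;
      const double mu = std::exp(alpha[g] + beta(g, W[i]) + nu(g, b) + delta[i]);
      out += nb_lpmf(X(g, i), mu, ph);
    }
    const double ka = as<double>(hyper["kappa_phi"]), ta = as<double>(hyper["tau_phi"]);
    out += (ka - 1.0) * std::log(ph) - ta * ph;
  } else if (block == "gamma") {
    const int b = idx1 - 1;
    const double g0 = value[0], g1 = value[1];
    if (g1 >= 0) return R_NegInf;
    for (int i = 0; i < N; ++i) {
      if (batch[i] != b) continue;
      for (int g = 0; g < G; ++g) {
        const int x = X(g, i);
        if (x <= 0) continue;
        const double t = g0 + g1 * x;
        out += (Z(g, i) == 1 ? t : 0.0) - softplus(t);
      }
    }
    const double v0 = as<double>(hyper["sigma_z0_sq"]);
    const double ag = as<double>(hyper["a_gamma"]), bg = as<double>(hyper["b_gamma"]);
    out += -0.5 * g0 * g0 / v0 + (ag - 1.0) * std::log(-g1) - bg * (-g1);
  } else {
    stop("unknown block");
  }
  return out;
}

// Log acceptance ratio of the joint (L_gk, beta_gk) flip move:
// propose L' = 1 - L with a fresh beta' ~ N(0, tau_{L'}^2); the component
// prior cancels with the proposal density, leaving lik ratio x Bern(p) ratio.
// [[Rcpp::export]]
double cpp_flip_logaccept(const int gR, const int kR, const double betaNew,
                          const IntegerMatrix &X, const IntegerVector &batch,
                          const IntegerVector &W,
                          const NumericVector &alpha, const NumericMatrix &beta,
                          const NumericMatrix &nu, const NumericVector &delta,
                          const NumericMatrix &phi, const IntegerMatrix &L,
                          const double p) {
  const int g = gR - 1, k = kR - 1, N = X.ncol();
  const double bcur = beta(g, k);
  double dll = 0.0;
  for (int i = 0; i < N; ++i) {
    if (W[i] != k) continue;
    const int b = batch[i];
    const double base = alpha[g] + nu(g, b) + delta[i];
    dll += nb_lpmf(X(g, i), std::exp(base + betaNew), phi(g, b))
         - nb_lpmf(X(g, i), std::exp(base + bcur), phi(g, b));
  }
  const double lodds = std::log(p) - std::log1p(-p);
  return dll + (L(g, k) == 0 ? lodds : -lodds);
}

// ---------------------------------------------------------------------------
// The sampler
// ---------------------------------------------------------------------------

struct Adapt {
  std::vector<double> ls;  // log proposal sd
  void init(int n, double s0) { ls.assign(n, std::log(s0)); }
  inline double sd(int j) const { return std::exp(ls[j]); }
  inline void tune(int j, double aprob, double eta) {
    ls[j] += eta * (aprob - 0.30);
    if (ls[j] < -8.0) ls[j] = -8.0;
    if (ls[j] > 3.0)  ls[j] = 3.0;
  }
};

// [[Rcpp::export]]
List cpp_run_chain(const IntegerMatrix &Y, const IntegerVector &batch,
                   const int K, const List &hyper, const List &init,
                   const int nIter, const int burnin, const int thin,
                   const bool nzf, const int wFreeze) {
  const int G = Y.nrow(), N = Y.ncol();
  int B = 0;
  for (int i = 0; i < N; ++i) if (batch[i] + 1 > B) B = batch[i] + 1;

  // hyperparameters
  const double xi = as<double>(hyper["xi"]);
  const double sigma_z0_sq = as<double>(hyper["sigma_z0_sq"]);
  const double a_gamma = as<double>(hyper["a_gamma"]);
  const double b_gamma = as<double>(hyper["b_gamma"]);
  const double m_a = as<double>(hyper["m_a"]), sigma_a_sq = as<double>(hyper["sigma_a_sq"]);
  const double m_c = as<double>(hyper["m_c"]), sigma_c_sq = as<double>(hyper["sigma_c_sq"]);
  const double m_d = as<double>(hyper["m_d"]), sigma_d_sq = as<double>(hyper["sigma_d_sq"]);
  const double kappa_phi = as<double>(hyper["kappa_phi"]);
  const double tau_phi = as<double>(hyper["tau_phi"]);
  const double a_p = as<double>(hyper["a_p"]), b_p = as<double>(hyper["b_p"]);
  const double a_tau = as<double>(hyper["a_tau"]), b_tau = as<double>(hyper["b_tau"]);
  const double tau1sq = as<double>(hyper["tau_beta1_sq"]);

  // state (copies of the initial values)
  std::vector<double> alpha = as<std::vector<double> >(init["alpha"]);
  NumericMatrix beta0 = init["beta"];
  NumericMatrix nu0 = init["nu"];
  NumericMatrix phi0 = init["phi"];
  std::vector<double> beta(beta0.begin(), beta0.end());    // G x K
  std::vector<double> nu(nu0.begin(), nu0.end());          // G x B
  std::vector<double> phiv(phi0.begin(), phi0.end());      // G x B
  std::vector<double> delta = as<std::vector<double> >(init["delta"]);
  std::vector<double> g0v = as<std::vector<double> >(init["gamma0"]);
  std::vector<double> g1v = as<std::vector<double> >(init["gamma1"]);
  NumericMatrix piInit = init["pi"];
  std::vector<double> piv(piInit.begin(), piInit.end());   // B x K
  IntegerVector Winit = init["W"];
  std::vector<int> W(Winit.begin(), Winit.end());          // 0-based
  IntegerMatrix Xinit = init["X"];
  std::vector<int> X(Xinit.begin(), Xinit.end());
  IntegerMatrix Zinit = init["Z"];
  std::vector<int> Z(Zinit.begin(), Zinit.end());
  IntegerMatrix Linit = init["L"];
  std::vector<int> L(Linit.begin(), Linit.end());          // G x K
  double p = as<double>(init["p"]);
  double tau0sq = as<double>(init["tau0sq"]);

  // structural bookkeeping
  std::vector<std::vector<int> > cells_b(B);
  std::vector<int> firstcell(B, -1);
  for (int i = 0; i < N; ++i) {
    const int b = batch[i];
    if (firstcell[b] < 0) firstcell[b] = i;
    cells_b[b].push_back(i);
  }
  std::vector<std::vector<int> > cells_k(K);

  // caches
  std::vector<double> bmu(G * (size_t)N);      // exp(alpha + nu + delta)
  std::vector<double> mu(G * (size_t)N);       // bmu * exp(beta[, W])
  std::vector<double> lognorm(G * (size_t)N);  // log(mu + phi)
  std::vector<double> eb(G * (size_t)K);       // exp(beta)
  std::vector<double> buf(std::max(G, N));     // proposed lognorm scratch
  std::vector<double> lk(K);

  // adaptation state
  Adapt sA; sA.init(G, 0.15);
  Adapt sB; sB.init(G * K, 0.30);
  Adapt sNu; sNu.init(G * B, 0.15);
  Adapt sD; sD.init(N, 0.08);
  Adapt sPh; sPh.init(G * B, 0.40);
  Adapt sG; sG.init(B, 0.10);
  Adapt sRb; sRb.init(B, 0.05);   // per-batch (delta, nu) recentering
  Adapt sRg; sRg.init(1, 0.05);   // global (delta, alpha) recentering

  // acceptance bookkeeping (post burn-in)
  long accA = 0, tryA = 0, accB = 0, tryB = 0, accNu = 0, tryNu = 0;
  long accD = 0, tryD = 0, accPh = 0, tryPh = 0, accG = 0, tryG = 0;
  long accF = 0, tryF = 0;

  // retained draws
  const int T = (nIter - burnin) / thin;
  NumericVector dAlpha(G * (size_t)T), dBeta(G * (size_t)K * T),
      dNu(G * (size_t)B * T), dDelta(N * (size_t)T), dPhi(G * (size_t)B * T),
      dG0(B * (size_t)T), dG1(B * (size_t)T), dPi(B * (size_t)K * T),
      dP(T), dTau(T);
  IntegerVector dW(N * (size_t)T), dL(G * (size_t)K * T);
  NumericMatrix sumXZ1(G, N);
  IntegerMatrix cntZ1(G, N);

  // gamma sufficient-statistic histogram, rebuilt each sweep
  const int HMAX = 8192;
  std::vector<std::vector<double> > hist(B, std::vector<double>(HMAX + 1, 0.0));
  std::vector<std::vector<int> > extras(B);
  std::vector<int> hmax(B, 0);
  std::vector<double> M1(B), S1(B);

  int stored = 0;
  for (int t = 1; t <= nIter; ++t) {
    const bool adapting = (t <= burnin);
    const double eta = 2.0 * std::pow((double)t, -0.6);

    // refresh caches (numerical hygiene: exact recompute once per sweep)
    for (int k = 0; k < K; ++k)
      for (int g = 0; g < G; ++g) eb[g + G * (size_t)k] = std::exp(beta[g + G * (size_t)k]);
    for (int i = 0; i < N; ++i) {
      const int b = batch[i];
      const size_t off = G * (size_t)i, offb = G * (size_t)b, offw = G * (size_t)W[i];
      for (int g = 0; g < G; ++g) {
        const double bm = std::exp(alpha[g] + nu[g + offb] + delta[i]);
        bmu[g + off] = bm;
        const double m = bm * eb[g + offw];
        mu[g + off] = m;
        lognorm[g + off] = std::log(m + phiv[g + offb]);
      }
    }

    // --- (1)+(2) joint (Z, X) draw at observed-zero entries -------------
    if (!nzf) {
      for (int i = 0; i < N; ++i) {
        const int b = batch[i];
        const size_t off = G * (size_t)i, offb = G * (size_t)b;
        const double g0 = g0v[b], g1 = g1v[b];
        for (int g = 0; g < G; ++g) {
          if (Y(g, i) != 0) continue;
          double S;
          zero_obs_core(mu[g + off], phiv[g + offb], g0, g1, &S);
          const double pz1 = S / (1.0 + S);
          if (R::unif_rand() < pz1) {
            const double u = R::unif_rand() * S;
            X[g + off] = zero_obs_sample(mu[g + off], phiv[g + offb], g0, g1, u);
            Z[g + off] = 1;
          } else {
            X[g + off] = 0;
            Z[g + off] = 0;
          }
        }
      }
    }

    // --- (3) W per cell: categorical full conditional -------------------
    // (held fixed during the warm-start phase so the crude initial
    //  parameters first adapt to the k-means partition)
    if (t > wFreeze) for (int i = 0; i < N; ++i) {
      const int b = batch[i];
      const size_t off = G * (size_t)i, offb = G * (size_t)b;
      for (int k = 0; k < K; ++k) {
        const size_t offk = G * (size_t)k;
        double s = std::log(piv[b + B * (size_t)k]);
        for (int g = 0; g < G; ++g) {
          const double ph = phiv[g + offb];
          const double mk = bmu[g + off] * eb[g + offk];
          const double x = (double)X[g + off];
          s += x * beta[g + offk] - (x + ph) * std::log(mk + ph);
        }
        lk[k] = s;
      }
      double m = lk[0];
      for (int k = 1; k < K; ++k) if (lk[k] > m) m = lk[k];
      double tot = 0.0;
      for (int k = 0; k < K; ++k) { lk[k] = std::exp(lk[k] - m); tot += lk[k]; }
      double u = R::unif_rand() * tot;
      int knew = K - 1;
      for (int k = 0; k < K; ++k) { u -= lk[k]; if (u <= 0) { knew = k; break; } }
      if (knew != W[i]) {
        const size_t offk = G * (size_t)knew;
        W[i] = knew;
        for (int g = 0; g < G; ++g) {
          const double m2 = bmu[g + off] * eb[g + offk];
          mu[g + off] = m2;
          lognorm[g + off] = std::log(m2 + phiv[g + offb]);
        }
      }
    }
    for (int k = 0; k < K; ++k) cells_k[k].clear();
    for (int i = 0; i < N; ++i) cells_k[W[i]].push_back(i);

    // --- (4) pi per batch: conjugate Dirichlet ---------------------------
    for (int b = 0; b < B; ++b) {
      std::vector<double> cnt(K, 0.0);
      for (size_t j = 0; j < cells_b[b].size(); ++j) cnt[W[cells_b[b][j]]] += 1.0;
      double tot = 0.0;
      for (int k = 0; k < K; ++k) { cnt[k] = R::rgamma(xi + cnt[k], 1.0); tot += cnt[k]; }
      for (int k = 0; k < K; ++k) piv[b + B * (size_t)k] = cnt[k] / tot;
    }

    // --- (5) gamma per batch: Metropolis on the logistic likelihood ------
    if (!nzf) {
      for (int b = 0; b < B; ++b) {
        std::fill(hist[b].begin(), hist[b].end(), 0.0);
        extras[b].clear();
        hmax[b] = 0; M1[b] = 0.0; S1[b] = 0.0;
      }
      for (int i = 0; i < N; ++i) {
        const int b = batch[i];
        const size_t off = G * (size_t)i;
        for (int g = 0; g < G; ++g) {
          const int x = X[g + off];
          if (x <= 0) continue;
          if (x <= HMAX) { hist[b][x] += 1.0; if (x > hmax[b]) hmax[b] = x; }
          else extras[b].push_back(x);
          if (Z[g + off] == 1) { M1[b] += 1.0; S1[b] += x; }
        }
      }
      for (int b = 0; b < B; ++b) {
        tryG += !adapting;
        const double s = sG.sd(b);
        const double g0n = g0v[b] + s * R::norm_rand();
        const double g1n = g1v[b] + 0.5 * s * R::norm_rand();
        double aprob = 0.0;
        if (g1n < 0) {
          double llo = g0v[b] * M1[b] + g1v[b] * S1[b];
          double lln = g0n * M1[b] + g1n * S1[b];
          for (int x = 1; x <= hmax[b]; ++x) {
            const double c = hist[b][x];
            if (c == 0.0) continue;
            llo -= c * softplus(g0v[b] + g1v[b] * x);
            lln -= c * softplus(g0n + g1n * x);
          }
          for (size_t j = 0; j < extras[b].size(); ++j) {
            const int x = extras[b][j];
            llo -= softplus(g0v[b] + g1v[b] * x);
            lln -= softplus(g0n + g1n * x);
          }
          double lr = lln - llo;
          lr += -0.5 * (g0n * g0n - g0v[b] * g0v[b]) / sigma_z0_sq;
          lr += (a_gamma - 1.0) * (std::log(-g1n) - std::log(-g1v[b]))
              - b_gamma * ((-g1n) - (-g1v[b]));
          aprob = lr >= 0 ? 1.0 : std::exp(lr);
          if (R::unif_rand() < aprob) {
            g0v[b] = g0n; g1v[b] = g1n;
            accG += !adapting;
          }
        }
        if (adapting) sG.tune(b, aprob, eta);
      }
    }

    // --- (6a) alpha_g ----------------------------------------------------
    for (int g = 0; g < G; ++g) {
      tryA += !adapting;
      const double s = sA.sd(g);
      const double dlt = s * R::norm_rand();
      const double eD = std::exp(dlt);
      double dll = 0.0;
      for (int i = 0; i < N; ++i) {
        const size_t idx = g + G * (size_t)i;
        const double ph = phiv[g + G * (size_t)batch[i]];
        const double lp = std::log(mu[idx] * eD + ph);
        buf[i] = lp;
        const double x = (double)X[idx];
        dll += x * dlt + (x + ph) * (lognorm[idx] - lp);
      }
      const double an = alpha[g] + dlt;
      double lr = dll - 0.5 * ((an - m_a) * (an - m_a)
                             - (alpha[g] - m_a) * (alpha[g] - m_a)) / sigma_a_sq;
      const double aprob = lr >= 0 ? 1.0 : std::exp(lr);
      if (R::unif_rand() < aprob) {
        alpha[g] = an;
        for (int i = 0; i < N; ++i) {
          const size_t idx = g + G * (size_t)i;
          bmu[idx] *= eD; mu[idx] *= eD; lognorm[idx] = buf[i];
        }
        accA += !adapting;
      }
      if (adapting) sA.tune(g, aprob, eta);
    }

    // --- (6b) beta_gk, k >= 2 --------------------------------------------
    for (int k = 1; k < K; ++k) {
      const size_t offk = G * (size_t)k;
      const std::vector<int> &ck = cells_k[k];
      for (int g = 0; g < G; ++g) {
        tryB += !adapting;
        const double s = sB.sd(g + offk);
        const double dlt = s * R::norm_rand();
        const double eD = std::exp(dlt);
        double dll = 0.0;
        for (size_t j = 0; j < ck.size(); ++j) {
          const int i = ck[j];
          const size_t idx = g + G * (size_t)i;
          const double ph = phiv[g + G * (size_t)batch[i]];
          const double lp = std::log(mu[idx] * eD + ph);
          buf[j] = lp;
          const double x = (double)X[idx];
          dll += x * dlt + (x + ph) * (lognorm[idx] - lp);
        }
        const double vB = L[g + offk] == 1 ? tau1sq : tau0sq;
        const double bo = beta[g + offk], bn = bo + dlt;
        double lr = dll - 0.5 * (bn * bn - bo * bo) / vB;
        const double aprob = lr >= 0 ? 1.0 : std::exp(lr);
        if (R::unif_rand() < aprob) {
          beta[g + offk] = bn;
          eb[g + offk] *= eD;
          for (size_t j = 0; j < ck.size(); ++j) {
            const size_t idx = g + G * (size_t)ck[j];
            mu[idx] *= eD; lognorm[idx] = buf[j];
          }
          accB += !adapting;
        }
        if (adapting) sB.tune(g + offk, aprob, eta);
      }
    }

    // --- (6c) nu_bg, b >= 2 ----------------------------------------------
    for (int b = 1; b < B; ++b) {
      const size_t offb = G * (size_t)b;
      const std::vector<int> &cb = cells_b[b];
      for (int g = 0; g < G; ++g) {
        tryNu += !adapting;
        const double s = sNu.sd(g + offb);
        const double dlt = s * R::norm_rand();
        const double eD = std::exp(dlt);
        const double ph = phiv[g + offb];
        double dll = 0.0;
        for (size_t j = 0; j < cb.size(); ++j) {
          const size_t idx = g + G * (size_t)cb[j];
          const double lp = std::log(mu[idx] * eD + ph);
          buf[j] = lp;
          const double x = (double)X[idx];
          dll += x * dlt + (x + ph) * (lognorm[idx] - lp);
        }
        const double no = nu[g + offb], nn = no + dlt;
        double lr = dll - 0.5 * ((nn - m_c) * (nn - m_c) - (no - m_c) * (no - m_c)) / sigma_c_sq;
        const double aprob = lr >= 0 ? 1.0 : std::exp(lr);
        if (R::unif_rand() < aprob) {
          nu[g + offb] = nn;
          for (size_t j = 0; j < cb.size(); ++j) {
            const size_t idx = g + G * (size_t)cb[j];
            bmu[idx] *= eD; mu[idx] *= eD; lognorm[idx] = buf[j];
          }
          accNu += !adapting;
        }
        if (adapting) sNu.tune(g + offb, aprob, eta);
      }
    }

    // --- (6d) delta_bi, i != first cell of its batch ----------------------
    for (int i = 0; i < N; ++i) {
      if (i == firstcell[batch[i]]) continue;
      tryD += !adapting;
      const size_t off = G * (size_t)i, offb = G * (size_t)batch[i];
      const double s = sD.sd(i);
      const double dlt = s * R::norm_rand();
      const double eD = std::exp(dlt);
      double dll = 0.0;
      for (int g = 0; g < G; ++g) {
        const double ph = phiv[g + offb];
        const double lp = std::log(mu[g + off] * eD + ph);
        buf[g] = lp;
        const double x = (double)X[g + off];
        dll += x * dlt + (x + ph) * (lognorm[g + off] - lp);
      }
      const double dn = delta[i] + dlt, dold = delta[i];
      double lr = dll - 0.5 * ((dn - m_d) * (dn - m_d) - (dold - m_d) * (dold - m_d)) / sigma_d_sq;
      const double aprob = lr >= 0 ? 1.0 : std::exp(lr);
      if (R::unif_rand() < aprob) {
        delta[i] = dn;
        for (int g = 0; g < G; ++g) {
          bmu[g + off] *= eD; mu[g + off] *= eD; lognorm[g + off] = buf[g];
        }
        accD += !adapting;
      }
      if (adapting) sD.tune(i, aprob, eta);
    }

    // --- (6d') recentering moves on the anchored size factors --------------
    // The model identifies the per-batch location of delta only through the
    // anchor cell (delta = 0 at each batch's first cell): shifting every
    // other delta in a batch by c while shifting that batch's nu by -c
    // changes no likelihood term except the anchor cell's. Sampling that
    // direction scalar-wise mixes extremely slowly, so two dedicated
    // symmetric Metropolis moves target it directly: a per-batch
    // (delta + c, nu - c) shift for b >= 2, and a global
    // (alpha + c, delta - c) shift whose residual falls on all B anchors.
    for (int b = 1; b < B; ++b) {
      const double c = sRb.sd(b) * R::norm_rand();
      const int i0 = firstcell[b];
      const size_t off0 = G * (size_t)i0, offb = G * (size_t)b;
      const double eC = std::exp(-c);
      double lr = 0.0;
      for (int g = 0; g < G; ++g) {
        const double ph = phiv[g + offb];
        const double lp = std::log(mu[g + off0] * eC + ph);
        buf[g] = lp;
        const double x = (double)X[g + off0];
        lr += -x * c + (x + ph) * (lognorm[g + off0] - lp);
      }
      for (size_t j = 0; j < cells_b[b].size(); ++j) {
        const int i = cells_b[b][j];
        if (i == i0) continue;
        const double dn = delta[i] + c;
        lr += -0.5 * ((dn - m_d) * (dn - m_d)
                      - (delta[i] - m_d) * (delta[i] - m_d)) / sigma_d_sq;
      }
      for (int g = 0; g < G; ++g) {
        const double nn = nu[g + offb] - c;
        lr += -0.5 * ((nn - m_c) * (nn - m_c)
                      - (nu[g + offb] - m_c) * (nu[g + offb] - m_c)) / sigma_c_sq;
      }
      const double aprob = lr >= 0 ? 1.0 : std::exp(lr);
      if (R::unif_rand() < aprob) {
        for (size_t j = 0; j < cells_b[b].size(); ++j) {
          const int i = cells_b[b][j];
          if (i != i0) delta[i] += c;
        }
        for (int g = 0; g < G; ++g) {
          nu[g + offb] -= c;
          bmu[g + off0] *= eC;
          mu[g + off0] *= eC;
          lognorm[g + off0] = buf[g];
        }
      }
      if (adapting) sRb.tune(b, aprob, eta);
    }
    {
      const double c = sRg.sd(0) * R::norm_rand();
      const double eC = std::exp(c);
      double lr = 0.0;
      std::vector<double> bufA(G * (size_t)B);
      for (int b = 0; b < B; ++b) {
        const int i0 = firstcell[b];
        const size_t off0 = G * (size_t)i0, offb = G * (size_t)b;
        for (int g = 0; g < G; ++g) {
          const double ph = phiv[g + offb];
          const double lp = std::log(mu[g + off0] * eC + ph);
          bufA[g + offb] = lp;
          const double x = (double)X[g + off0];
          lr += x * c + (x + ph) * (lognorm[g + off0] - lp);
        }
      }
      for (int g = 0; g < G; ++g) {
        const double an = alpha[g] + c;
        lr += -0.5 * ((an - m_a) * (an - m_a)
                      - (alpha[g] - m_a) * (alpha[g] - m_a)) / sigma_a_sq;
      }
      for (int i = 0; i < N; ++i) {
        if (i == firstcell[batch[i]]) continue;
        const double dn = delta[i] - c;
        lr += -0.5 * ((dn - m_d) * (dn - m_d)
                      - (delta[i] - m_d) * (delta[i] - m_d)) / sigma_d_sq;
      }
      const double aprob = lr >= 0 ? 1.0 : std::exp(lr);
      if (R::unif_rand() < aprob) {
        for (int g = 0; g < G; ++g) alpha[g] += c;
        for (int i = 0; i < N; ++i)
          if (i != firstcell[batch[i]]) delta[i] -= c;
        for (int b = 0; b < B; ++b) {
          const int i0 = firstcell[b];
          const size_t off0 = G * (size_t)i0, offb = G * (size_t)b;
          for (int g = 0; g < G; ++g) {
            bmu[g + off0] *= eC;
            mu[g + off0] *= eC;
            lognorm[g + off0] = bufA[g + offb];
          }
        }
      }
      if (adapting) sRg.tune(0, aprob, eta);
    }

    // --- (6e) phi_bg: log-scale random walk --------------------------------
    for (int b = 0; b < B; ++b) {
      const size_t offb = G * (size_t)b;
      const std::vector<int> &cb = cells_b[b];
      for (int g = 0; g < G; ++g) {
        tryPh += !adapting;
        const double s = sPh.sd(g + offb);
        const double po = phiv[g + offb];
        const double lpo = std::log(po);
        const double lpn = lpo + s * R::norm_rand();
        const double pn = std::exp(lpn);
        const double lgo = R::lgammafn(po), lgn = R::lgammafn(pn);
        double dll = 0.0;
        for (size_t j = 0; j < cb.size(); ++j) {
          const size_t idx = g + G * (size_t)cb[j];
          const double lq = std::log(mu[idx] + pn);
          buf[j] = lq;
          const double x = (double)X[idx];
          if (x > 0.0)
            dll += R::lgammafn(x + pn) - R::lgammafn(x + po) - (lgn - lgo);
          dll += -x * (lq - lognorm[idx])
               + pn * (lpn - lq) - po * (lpo - lognorm[idx]);
        }
        double lr = dll + (kappa_phi - 1.0) * (lpn - lpo) - tau_phi * (pn - po)
                  + (lpn - lpo);  // Jacobian of the log-scale proposal
        const double aprob = lr >= 0 ? 1.0 : std::exp(lr);
        if (R::unif_rand() < aprob) {
          phiv[g + offb] = pn;
          for (size_t j = 0; j < cb.size(); ++j)
            lognorm[g + G * (size_t)cb[j]] = buf[j];
          accPh += !adapting;
        }
        if (adapting) sPh.tune(g + offb, aprob, eta);
      }
    }

    // --- (7) joint (L_gk, beta_gk) flip ------------------------------------
    {
      const double lodds = std::log(p) - std::log1p(-p);
      for (int k = 1; k < K; ++k) {
        const size_t offk = G * (size_t)k;
        const std::vector<int> &ck = cells_k[k];
        for (int g = 0; g < G; ++g) {
          tryF += !adapting;
          const int Ln = 1 - L[g + offk];
          const double vN = Ln == 1 ? tau1sq : tau0sq;
          const double bn = std::sqrt(vN) * R::norm_rand();
          const double bo = beta[g + offk];
          const double eD = std::exp(bn - bo);
          double dll = 0.0;
          for (size_t j = 0; j < ck.size(); ++j) {
            const int i = ck[j];
            const size_t idx = g + G * (size_t)i;
            const double ph = phiv[g + G * (size_t)batch[i]];
            const double lp = std::log(mu[idx] * eD + ph);
            buf[j] = lp;
            const double x = (double)X[idx];
            dll += x * (bn - bo) + (x + ph) * (lognorm[idx] - lp);
          }
          const double lr = dll + (Ln == 1 ? lodds : -lodds);
          if (lr >= 0 || R::unif_rand() < std::exp(lr)) {
            L[g + offk] = Ln;
            beta[g + offk] = bn;
            eb[g + offk] *= eD;
            for (size_t j = 0; j < ck.size(); ++j) {
              const size_t idx = g + G * (size_t)ck[j];
              mu[idx] *= eD; lognorm[idx] = buf[j];
            }
            accF += !adapting;
          }
        }
      }
    }

    // --- (8) p: conjugate Beta ---------------------------------------------
    {
      double sumL = 0.0;
      for (int k = 1; k < K; ++k)
        for (int g = 0; g < G; ++g) sumL += L[g + G * (size_t)k];
      const double nTot = (double)G * (K - 1);
      p = R::rbeta(a_p + sumL, b_p + nTot - sumL);
      if (p < 1e-12) p = 1e-12;
      if (p > 1.0 - 1e-12) p = 1.0 - 1e-12;
    }

    // --- (9) tau_beta0^2: conjugate inverse gamma --------------------------
    {
      double n0 = 0.0, ssq = 0.0;
      for (int k = 1; k < K; ++k)
        for (int g = 0; g < G; ++g)
          if (L[g + G * (size_t)k] == 0) {
            n0 += 1.0;
            ssq += beta[g + G * (size_t)k] * beta[g + G * (size_t)k];
          }
      tau0sq = 1.0 / R::rgamma(a_tau + 0.5 * n0, 1.0 / (b_tau + 0.5 * ssq));
      if (tau0sq < 1e-8) tau0sq = 1e-8;
    }

    // --- storage ------------------------------------------------------------
    if (t > burnin && (t - burnin) % thin == 0 && stored < T) {
      const size_t s = stored;
      std::copy(alpha.begin(), alpha.end(), dAlpha.begin() + s * G);
      std::copy(beta.begin(), beta.end(), dBeta.begin() + s * G * K);
      std::copy(nu.begin(), nu.end(), dNu.begin() + s * G * B);
      std::copy(delta.begin(), delta.end(), dDelta.begin() + s * N);
      std::copy(phiv.begin(), phiv.end(), dPhi.begin() + s * G * B);
      std::copy(g0v.begin(), g0v.end(), dG0.begin() + s * B);
      std::copy(g1v.begin(), g1v.end(), dG1.begin() + s * B);
      std::copy(piv.begin(), piv.end(), dPi.begin() + s * B * K);
      std::copy(W.begin(), W.end(), dW.begin() + s * N);
      std::copy(L.begin(), L.end(), dL.begin() + s * G * K);
      dP[stored] = p;
      dTau[stored] = tau0sq;
      for (int i = 0; i < N; ++i) {
        const size_t off = G * (size_t)i;
        for (int g = 0; g < G; ++g)
          if (Z[g + off] == 1) {
            sumXZ1(g, i) += X[g + off];
            cntZ1(g, i) += 1;
          }
      }
      ++stored;
    }
  }

  IntegerMatrix Xout(G, N), Zout(G, N);
  std::copy(X.begin(), X.end(), Xout.begin());
  std::copy(Z.begin(), Z.end(), Zout.begin());

  auto rate = [](long a, long t2) { return t2 > 0 ? (double)a / (double)t2 : NA_REAL; };
  List acc = List::create(
      _["alpha"] = rate(accA, tryA), _["beta"] = rate(accB, tryB),
      _["nu"] = rate(accNu, tryNu), _["delta"] = rate(accD, tryD),
      _["phi"] = rate(accPh, tryPh), _["gamma"] = rate(accG, tryG),
      _["flip"] = rate(accF, tryF));

  dAlpha.attr("dim") = IntegerVector::create(G, T);
  dBeta.attr("dim") = IntegerVector::create(G, K, T);
  dNu.attr("dim") = IntegerVector::create(G, B, T);
  dDelta.attr("dim") = IntegerVector::create(N, T);
  dPhi.attr("dim") = IntegerVector::create(G, B, T);
  dG0.attr("dim") = IntegerVector::create(B, T);
  dG1.attr("dim") = IntegerVector::create(B, T);
  dPi.attr("dim") = IntegerVector::create(B, K, T);
  dW.attr("dim") = IntegerVector::create(N, T);
  dL.attr("dim") = IntegerVector::create(G, K, T);

  return List::create(
      _["alpha"] = dAlpha, _["beta"] = dBeta, _["nu"] = dNu,
      _["delta"] = dDelta, _["phi"] = dPhi, _["gamma0"] = dG0,
      _["gamma1"] = dG1, _["pi"] = dPi, _["W"] = dW, _["L"] = dL,
      _["p"] = dP, _["tau0sq"] = dTau,
      _["sumXZ1"] = sumXZ1, _["cntZ1"] = cntZ1,
      _["finalX"] = Xout, _["finalZ"] = Zout,
      _["acceptance"] = acc, _["nStored"] = stored);
}
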