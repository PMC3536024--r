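// Per-gene Metropolis-within-Gibbs sampler for the truncated-normal
// spike-and-slab isoform expression model:
//   y_il | I_l, beta_l, tau_l ~ N((X beta*_l)_i, 1/tau_l), truncated below at 0
//   beta_kl ~ N(mu0_k, 1/tau0_k) truncated below at 0  (Kuo-Mallick: drawn from
//             the prior while I_kl = 0, so the indicator conditional is exact)
//   I_kl ~ Bernoulli(p); tau_l ~ Gamma(a1, a2); tau0_k ~ Gamma(a10, a20)
// Updates: exact Bernoulli conditional for I; slice sampling on [0, inf) for
// beta; independence Metropolis with the untruncated conjugate Gamma proposal
// for tau and tau0, accepted/rejected on the truncation-normalizer ratio.
#include <Rcpp.h>
using namespace Rcpp;

// log Phi(x), computed on the log scale for tail stability
static inline double lphi(double x) { return R::pnorm(x, 0.0, 1.0, 1, 1); }

// log density of y under N(mu, 1/tau) truncated below at zero
static inline double ll_exon(double y, double mu, double tau) {
  double sd = 1.0 / std::sqrt(tau);
  return R::dnorm(y, mu, sd, 1) - lphi(mu * std::sqrt(tau));
}

// draw from N(mu, sd^2) truncated to [0, inf)
static double rtnorm0(double mu, double sd) {
  double alpha = -mu / sd; // standardized lower bound
  if (!R_finite(alpha)) Rcpp::stop("non-finite state in truncated-normal draw");
  if (alpha < 5.0) {
    double plo = R::pnorm(alpha, 0.0, 1.0, 1, 0);
    double u = R::runif(plo, 1.0);
    if (u >= 1.0) u = 1.0 - 1e-16;
    return mu + sd * R::qnorm(u, 0.0, 1.0, 1, 0);
  }
  // deep-tail case: Robert (1995) translated-exponential rejection
  double a = 0.5 * (alpha + std::sqrt(alpha * alpha + 4.0));
  for (;;) {
    double z = alpha + R::rexp(1.0) / a;
    double rho = std::exp(-0.5 * (z - a) * (z - a));
    if (R::unif_rand() <= rho) return mu + sd * z;
  }
}

struct GeneModelState {
  const NumericMatrix& y;      // m x L
  const IntegerMatrix& X;      // m x s
  NumericMatrix mu;            // m x L running fitted means X beta*
  NumericMatrix beta;          // s x L
  IntegerMatrix I;             // s x L
  NumericVector tau;           // L
  NumericVector tau0;          // s
  const NumericVector& mu0;    // s
  bool lik_on;

  GeneModelState(const NumericMatrix& y_, const IntegerMatrix& X_,
                 const NumericVector& mu0_, bool lik_on_)
    : y(y_), X(X_), mu(y_.nrow(), y_.ncol()), beta(X_.ncol(), y_.ncol()),
      I(X_.ncol(), y_.ncol()), tau(y_.ncol()), tau0(X_.ncol()),
      mu0(mu0_), lik_on(lik_on_) {}

  void refresh_mu() {
    int m = y.nrow(), L = y.ncol(), s = X.ncol();
    for (int l = 0; l < L; ++l)
      for (int i = 0; i < m; ++i) {
        double v = 0.0;
        for (int k = 0; k < s; ++k)
          if (X(i, k)) v += beta(k, l) * I(k, l);
        mu(i, l) = v;
      }
  }

  // log-likelihood of sample l restricted to exons containing isoform k,
  // with isoform k's contribution replaced by `contrib`
  double ll_k(int k, int l, double contrib) {
    if (!lik_on) return 0.0;
    double s_ = 0.0, cur = beta(k, l) * I(k, l);
    int m = y.nrow();
    for (int i = 0; i < m; ++i)
      if (X(i, k))
        s_ += ll_exon(y(i, l), mu(i, l) - cur + contrib, tau[l]);
    return s_;
  }
};

// slice sampler (Neal 2003, stepping out + shrinkage) for beta_kl on [0, inf)
static double slice_beta(GeneModelState& st, int k, int l, double w) {
  double x0 = st.beta(k, l);
  double t0k = st.tau0[k], m0k = st.mu0[k];
  auto logpost = [&](double b) {
    return -0.5 * t0k * (b - m0k) * (b - m0k) + st.ll_k(k, l, b * st.I(k, l));
  };
  double ly = logpost(x0) - R::exp_rand();
  double u = R::unif_rand();
  double lo = x0 - w * u, hi = lo + w;
  if (lo < 0.0) lo = 0.0;
  int cap = 64;
  while (cap-- > 0 && lo > 0.0 && logpost(lo) > ly) { lo -= w; if (lo < 0.0) { lo = 0.0; break; } }
  cap = 64;
  while (cap-- > 0 && logpost(hi) > ly) hi += w;
  for (int it = 0; it < 200; ++it) {
    double x1 = R::runif(lo, hi);
    if (logpost(x1) > ly) return x1;
    if (x1 < x0) lo = x1; else hi = x1;
  }
  return x0; // shrinkage failed to move (numerically degenerate slice)
}

// [[Rcpp::export(name = ".gene_gibbs")]]
List gene_gibbs(NumericMatrix y, IntegerMatrix X,
                double a1, double a2, double a10, double a20,
                NumericVector mu0, double p,
                int n_keep, int burn_in, int thin,
                double tau_fixed, double tau0_fixed, bool likelihood_on,
                NumericMatrix beta_init, IntegerMatrix I_init,
                NumericVector tau_init, NumericVector tau0_init) {
  int m = y.nrow(), L = y.ncol(), s = X.ncol();
  bool tau_free = !(tau_fixed > 0.0), tau0_free = !(tau0_fixed > 0.0);
  GeneModelState st(y, X, mu0, likelihood_on);
  st.beta = clone(beta_init);
  st.I = clone(I_init);
  st.tau = clone(tau_init);
  st.tau0 = clone(tau0_init);
  st.refresh_mu();

  int n_iter = burn_in + n_keep * thin;
  NumericMatrix beta_draws(n_keep, s * L);
  IntegerMatrix I_draws(n_keep, s * L);
  NumericMatrix tau_draws(n_keep, L), tau0_draws(n_keep, s);
  double lodds0 = std::log(p) - std::log1p(-p);
  int acc_tau = 0, try_tau = 0, acc_tau0 = 0, try_tau0 = 0;
  int row = 0;

  for (int it = 0; it < n_iter; ++it) {
    for (int l = 0; l < L; ++l) {
      // --- indicators: exact Bernoulli full conditional ---
      for (int k = 0; k < s; ++k) {
        double lo_ = st.ll_k(k, l, 0.0);
        double l1_ = st.ll_k(k, l, st.beta(k, l));
        double logit = lodds0 + l1_ - lo_;
        double pr = 1.0 / (1.0 + std::exp(-logit));
        int Inew = (R::unif_rand() < pr) ? 1 : 0;
        if (Inew != st.I(k, l)) {
          double d = st.beta(k, l) * (Inew - st.I(k, l));
          for (int i = 0; i < m; ++i) if (X(i, k)) st.mu(i, l) += d;
          st.I(k, l) = Inew;
        }
      }
      // --- isoform expressions ---
      for (int k = 0; k < s; ++k) {
        double bnew;
        if (st.I(k, l) == 0 || !likelihood_on) {
          // prior draw (Kuo-Mallick when the slab is off)
          bnew = rtnorm0(mu0[k], 1.0 / std::sqrt(st.tau0[k]));
        } else {
          int nk = 0;
          for (int i = 0; i < m; ++i) nk += X(i, k);
          double w = 2.0 / std::sqrt(st.tau0[k] + nk * st.tau[l]);
          bnew = slice_beta(st, k, l, w);
        }
        if (st.I(k, l)) {
          double d = bnew - st.beta(k, l);
          for (int i = 0; i < m; ++i) if (X(i, k)) st.mu(i, l) += d;
        }
        st.beta(k, l) = bnew;
      }
      // --- exon-noise precision ---
      if (tau_free) {
        if (!likelihood_on) {
          st.tau[l] = R::rgamma(a1, 1.0 / a2);
        } else {
          double ssr = 0.0;
          for (int i = 0; i < m; ++i) {
            double r = y(i, l) - st.mu(i, l);
            ssr += r * r;
          }
          double a = a1 + 0.5 * m, b = a2 + 0.5 * ssr;
          double prop = R::rgamma(a, 1.0 / b);
          double la = 0.0;
          for (int i = 0; i < m; ++i)
            la += lphi(st.mu(i, l) * std::sqrt(st.tau[l])) -
                  lphi(st.mu(i, l) * std::sqrt(prop));
          ++try_tau;
          if (std::log(R::unif_rand()) < la) { st.tau[l] = prop; ++acc_tau; }
        }
      }
    }
    // --- isoform-level (across-sample) precisions ---
    if (tau0_free) {
      for (int k = 0; k < s; ++k) {
        double ssb = 0.0;
        for (int l = 0; l < L; ++l) {
          double r = st.beta(k, l) - mu0[k];
          ssb += r * r;
        }
        double a = a10 + 0.5 * L, b = a20 + 0.5 * ssb;
        double prop = R::rgamma(a, 1.0 / b);
        double la = L * (lphi(mu0[k] * std::sqrt(st.tau0[k])) -
                         lphi(mu0[k] * std::sqrt(prop)));
        ++try_tau0;
        if (std::log(R::unif_rand()) < la) { st.tau0[k] = prop; ++acc_tau0; }
      }
    }
    if (it >= burn_in && (it - burn_in) % thin == 0) {
      for (int l = 0; l < L; ++l)
        for (int k = 0; k < s; ++k) {
          beta_draws(row, l * s + k) = st.beta(k, l);
          I_draws(row, l * s + k) = st.I(k, l);
        }
      for (int l = 0; l < L; ++l) tau_draws(row, l) = st.tau[l];
      for (int k = 0; k < s; ++k) tau0_draws(row, k) = st.tau0[k];
      ++row;
    }
  }
  return List::create(
    _["beta"] = beta_draws, _["I"] = I_draws,
    _["tau"] = tau_draws, _["tau0"] = tau0_draws,
    _["accept_tau"] = try_tau ? (double)acc_tau / try_tau : NA_REAL,
    _["accept_tau0"] = try_tau0 ? (double)acc_tau0 / try_tau0 : NA_REAL);
}
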