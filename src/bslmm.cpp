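#include <Rcpp.h>
using namespace Rcpp;

// Bayesian sparse linear mixed model sampler.
//
// Model (original coordinates): y = 1 mu + X beta + u + eps,
//   u ~ N(0, sigma_b^2 K), eps ~ N(0, sigma_e^2 I),
//   beta_j = 0 with prob 1 - pi, else N(0, sigma_a^2).
// Hyperpriors: h ~ U(0,1), rho ~ U(0,1), log pi ~ U(log 1/p, 0),
//   p(sigma_e^2) propto 1/sigma_e^2.
// Variance mapping (loci standardized to unit variance, kappa = mean diag K):
//   Vg = h/(1-h) sigma_e^2; sigma_a^2 = rho Vg / (pi p);
//   sigma_b^2 = (1-rho) Vg / kappa.
//
// The polygenic random effect is integrated out analytically: in the
// eigenbasis of K = U D U' (inputs ytil = U'y, Xtil = U'X, onetil = U'1,
// d = diag(D)) the marginal law is
//   ytil ~ N(onetil mu + Xtil beta, W),  W = diag(sigma_b^2 d_k + sigma_e^2),
// so spike-slab inclusion odds are evaluated against the whitened residual
// (no conditioning on a sampled u, which would otherwise absorb locus
// signals and trap the chain in a polygenic mode). One MCMC step =
// geno_updates spike-slab locus updates (beta_j integrated for the odds,
// Rao-Blackwellized draw when included), a Gibbs update of mu, and one
// random-walk Metropolis update of each of log sigma_e^2, h, rho, log pi
// (step sizes adapted towards ~30% acceptance during burn-in, frozen
// afterwards; a step size of 0 holds that hyperparameter fixed). u is drawn
// from its exact conditional only when a thinned sample is recorded, to
// report PVE = var(X beta + u) / (var(X beta + u) + sigma_e^2).
// Uses R's RNG, so results are bit-reproducible under set.seed().

static inline double reflect(double x, double lo, double hi) {
  double w = hi - lo;
  if (w <= 0) return lo;
  double t = x - lo;
  t -= std::floor(t / (2.0 * w)) * (2.0 * w);
  return lo + (t <= w ? t : 2.0 * w - t);
}

struct Hyper {
  double se2, h, rho, logpi;
  double sa2, sb2, pi;
};

static void derive(Hyper &hp, int p, double kappa) {
  hp.pi = std::exp(hp.logpi);
  double vg = hp.h / (1.0 - hp.h) * hp.se2;
  hp.sa2 = std::max(hp.rho * vg / (hp.pi * p), 1e-12);
  hp.sb2 = std::max((1.0 - hp.rho) * vg / kappa, 1e-14);
}

// log posterior terms involving the hyperparameters for fixed (beta, gamma,
// residual r); includes the Jacobian for the log-scale sigma_e^2 proposal.
static double hyper_logpost(const Hyper &hp, const std::vector<double> &r,
                            const NumericVector &d, double ssb, int kact,
                            int n, int p) {
  if (hp.h <= 0 || hp.h >= 1 || hp.rho < 0 || hp.rho > 1) return R_NegInf;
  if (hp.logpi < std::log(1.0 / p) - 1e-12 || hp.logpi > 1e-12) return R_NegInf;
  double lp = 0.0;
  for (int k = 0; k < n; ++k) {
    double w = hp.sb2 * d[k] + hp.se2;
    lp += -0.5 * std::log(w) - r[k] * r[k] / (2.0 * w);
  }
  lp += -0.5 * kact * std::log(hp.sa2) - ssb / (2.0 * hp.sa2);
  if (hp.pi < 1.0 - 1e-12) {
    lp += kact * hp.logpi + (p - kact) * std::log1p(-hp.pi);
  }  // pi at 1: point mass, inclusion forced by infinite prior odds
  lp += -std::log(hp.se2);  // Jeffreys prior on sigma_e^2
  lp += std::log(hp.se2);   // Jacobian of the log-scale proposal
  return lp;
}

// [[Rcpp::export]]
List bslmm_mcmc_cpp(NumericVector ytil, NumericMatrix Xtil,
                    NumericVector onetil, NumericVector d, double kappa,
                    int burnin, int steps, int thin, int geno_updates,
                    double step_se, double step_h, double step_rho,
                    double step_logpi, double init_h, double init_rho,
                    double init_logpi) {
  const int n = ytil.size();
  const int p = Xtil.ncol();

  // state
  std::vector<double> beta(p, 0.0);
  std::vector<int> gamma(p, 0);
  double ssy = 0, so2 = 0, soy = 0;
  for (int k = 0; k < n; ++k) {
    ssy += ytil[k] * ytil[k];
    so2 += onetil[k] * onetil[k];
    soy += onetil[k] * ytil[k];
  }
  double mu = soy / so2;
  Hyper hp;
  hp.se2 = std::max((ssy - soy * soy / so2) / std::max(n - 1, 1), 1e-8);
  hp.h = init_h;
  hp.rho = init_rho;
  hp.logpi = init_logpi;
  derive(hp, p, kappa);

  std::vector<double> r(n), w(n);
  for (int k = 0; k < n; ++k) r[k] = ytil[k] - onetil[k] * mu;
  int kact = 0;
  double ssb = 0.0;

  const int total = burnin + steps;
  const int nsamp = steps / thin;
  NumericMatrix samples(nsamp, 7);
  colnames(samples) = CharacterVector::create("h", "rho", "pi", "sigma_e2",
                                              "mu", "n_gamma", "pve");
  NumericVector pip(p, 0.0), beta_bar(p, 0.0);
  IntegerVector acc(4, 0), prop(4, 0);
  int isamp = 0;
  double stepv[4] = {step_se, step_h, step_rho, step_logpi};
  int acc_win[4] = {0, 0, 0, 0}, prop_win[4] = {0, 0, 0, 0};

  for (int s = 0; s < total; ++s) {
    for (int k = 0; k < n; ++k) w[k] = hp.sb2 * d[k] + hp.se2;

    // --- sparse effect updates against the whitened residual ---
    for (int t = 0; t < geno_updates; ++t) {
      int j = (int)std::floor(unif_rand() * p);
      if (j >= p) j = p - 1;
      double bj = beta[j];
      double z = 0, xtw = 0;
      if (gamma[j]) {
        for (int k = 0; k < n; ++k) {
          double x = Xtil(k, j);
          z += x * (r[k] + x * bj) / w[k];
          xtw += x * x / w[k];
        }
      } else {
        for (int k = 0; k < n; ++k) {
          double x = Xtil(k, j);
          z += x * r[k] / w[k];
          xtw += x * x / w[k];
        }
      }
      double prec = xtw + 1.0 / hp.sa2;
      double m = z / prec;
      double logbf = 0.5 * m * m * prec - 0.5 * std::log(hp.sa2 * prec);
      double logodds = logbf + hp.logpi - std::log1p(-hp.pi);
      double pincl = 1.0 / (1.0 + std::exp(-logodds));
      int newg = (unif_rand() < pincl) ? 1 : 0;
      double newb = 0.0;
      if (newg) newb = m + norm_rand() / std::sqrt(prec);
      if (newg != gamma[j] || newb != bj) {
        for (int k = 0; k < n; ++k) r[k] += Xtil(k, j) * (bj - newb);
        ssb += newb * newb - bj * bj;
        kact += newg - gamma[j];
        beta[j] = newg ? newb : 0.0;
        gamma[j] = newg;
      }
    }

    // --- intercept (weighted Gibbs) ---
    {
      double zo = 0, po = 0;
      for (int k = 0; k < n; ++k) {
        zo += onetil[k] * (r[k] + onetil[k] * mu) / w[k];
        po += onetil[k] * onetil[k] / w[k];
      }
      double nmu = zo / po + norm_rand() / std::sqrt(po);
      for (int k = 0; k < n; ++k) r[k] += onetil[k] * (mu - nmu);
      mu = nmu;
    }

    // --- hyperparameter MH (log se2, h, rho, log pi) ---
    double lp0 = hyper_logpost(hp, r, d, ssb, kact, n, p);
    for (int which = 0; which < 4; ++which) {
      double stepw = stepv[which];
      if (stepw <= 0) continue;  // hyperparameter held fixed
      Hyper hq = hp;
      if (which == 0) {
        hq.se2 = std::exp(std::log(hp.se2) + stepw * norm_rand());
        if (hq.se2 < 1e-12) hq.se2 = 1e-12;
      } else if (which == 1) {
        hq.h = reflect(hp.h + stepw * norm_rand(), 1e-6, 1.0 - 1e-6);
      } else if (which == 2) {
        hq.rho = reflect(hp.rho + stepw * norm_rand(), 0.0, 1.0);
      } else {
        hq.logpi = reflect(hp.logpi + stepw * norm_rand(),
                           std::log(1.0 / p), 0.0);
      }
      derive(hq, p, kappa);
      double lp1 = hyper_logpost(hq, r, d, ssb, kact, n, p);
      bool ok = std::log(unif_rand()) < lp1 - lp0;
      if (ok) { hp = hq; lp0 = lp1; }
      if (s < burnin) {
        ++prop_win[which];
        if (ok) ++acc_win[which];
        if (prop_win[which] == 50) {
          double r50 = acc_win[which] / 50.0;
          stepv[which] *= std::exp(0.6 * (r50 - 0.3));
          if (stepv[which] < 1e-5) stepv[which] = 1e-5;
          if (stepv[which] > 3.0) stepv[which] = 3.0;
          prop_win[which] = acc_win[which] = 0;
        }
      } else {
        ++prop[which];
        if (ok) ++acc[which];
      }
    }

    // --- record ---
    if (s >= burnin && ((s - burnin) % thin) == (thin - 1) && isamp < nsamp) {
      // draw u | rest exactly, then g = Xtil beta + u
      double sg = 0, ssg = 0;
      for (int k = 0; k < n; ++k) {
        double wk = hp.sb2 * d[k] + hp.se2;
        double um = hp.sb2 * d[k] * r[k] / wk;
        double uv = hp.sb2 * d[k] * hp.se2 / wk;
        double u = um + std::sqrt(uv) * norm_rand();
        double g = (ytil[k] - onetil[k] * mu - r[k]) + u;
        sg += onetil[k] * g;  // n * sample mean of g in original coords
        ssg += g * g;
      }
      double mg = sg / n;
      double varg = (ssg - n * mg * mg) / std::max(n - 1, 1);
      if (varg < 0) varg = 0;
      double pve = varg / (varg + hp.se2);
      samples(isamp, 0) = hp.h;
      samples(isamp, 1) = hp.rho;
      samples(isamp, 2) = hp.pi;
      samples(isamp, 3) = hp.se2;
      samples(isamp, 4) = mu;
      samples(isamp, 5) = kact;
      samples(isamp, 6) = pve;
      for (int j = 0; j < p; ++j) {
        pip[j] += gamma[j];
        beta_bar[j] += beta[j];
      }
      ++isamp;
    }

    // periodic residual re-sync against floating-point drift
    if ((s + 1) % 4096 == 0) {
      for (int k = 0; k < n; ++k) {
        double xb = 0;
        for (int j = 0; j < p; ++j)
          if (gamma[j]) xb += Xtil(k, j) * beta[j];
        r[k] = ytil[k] - onetil[k] * mu - xb;
      }
      ssb = 0;
      for (int j = 0; j < p; ++j) ssb += beta[j] * beta[j];
    }
  }

  if (isamp > 0) {
    for (int j = 0; j < p; ++j) {
      pip[j] /= isamp;
      beta_bar[j] /= isamp;
    }
  }
  return List::create(_["samples"] = samples, _["pip"] = pip,
                      _["beta_bar"] = beta_bar, _["accept"] = acc,
                      _["proposed"] = prop);
}
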