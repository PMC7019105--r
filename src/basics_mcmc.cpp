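// Metropolis-within-Gibbs sampler for the hierarchical Poisson-Gamma
// normalization model:
//   spike-in rows:   X_ij ~ Poisson(nu_j * mu_i)
//   biological rows: X_ij ~ NB(size 1/delta_i, mean phi_j * nu_j * mu_i)
//                    (gene-level Gamma(1/delta, 1/delta) random effects
//                     marginalized analytically)
//   nu_j | s_j, theta ~ Gamma(1/theta, rate 1/(s_j * theta))
//   s_j ~ Gamma(s_shape, s_rate)
// Priors: log-normal(0, 2^2) on mu_i and delta_i, Gamma(1,1) on theta;
// phi_j flat on the log scale and rescaled every sweep so that
// sum(phi) = n (identifiability).
//
// The capture-efficiency constants s_j are marginalized out of the chain by
// 1-D quadrature (Simpson on the log-s scale around the analytic mode of
// the integrand), so nu and theta are updated against the exact marginal
// prior of nu; recorded s values are the conditional means E[s_j | nu_j,
// theta]. All positive parameters are updated by adaptive random-walk
// Metropolis on the log scale (target acceptance 0.44, adaptation frozen
// after burn-in). Uses R's RNG, so results reproduce under set.seed().

#include <Rcpp.h>
using namespace Rcpp;

// NB log-likelihood terms that depend on the mean (lgamma terms involving
// only x and the size r cancel in Metropolis ratios for mean updates).
static inline double nb_mean_term(double x, double r, double m) {
  return r * std::log(r / (r + m)) + x * std::log(m / (r + m));
}

static inline double nb_full_term(double x, double r, double m) {
  return R::lgammafn(x + r) - R::lgammafn(r) + r * std::log(r / (r + m)) +
         x * std::log(m / (r + m));
}

// log integrand of the s-marginalization, as a function of t = log(s):
//   h(t) = C + (s_shape - a) t - a*nu*exp(-t) - s_rate*exp(t)
// with a = 1/theta and
//   C = a log a + (a-1) log nu - lgamma(a) + s_shape log s_rate
//       - lgamma(s_shape).
// Returns log integral (want_mean = false) or the conditional mean
// E[s | nu, theta] (want_mean = true), via Simpson quadrature over
// t in [t* - 8 sd, t* + 8 sd].
static double s_marginal(double nu, double a, double s_shape, double s_rate,
                         bool want_mean) {
  const double d = s_shape - a;
  const double u_star = (d + std::sqrt(d * d + 4.0 * s_rate * a * nu)) /
                        (2.0 * s_rate);
  const double t_star = std::log(u_star);
  const double curv = a * nu * std::exp(-t_star) +
                      s_rate * std::exp(t_star);      // -h''(t*)
  const double sd = 1.0 / std::sqrt(curv);
  const int n_pts = 81;                               // even interval count
  const double lo = t_star - 8.0 * sd, hi = t_star + 8.0 * sd;
  const double dt = (hi - lo) / (n_pts - 1);
  const double C = a * std::log(a) + (a - 1.0) * std::log(nu) -
                   R::lgammafn(a) + s_shape * std::log(s_rate) -
                   R::lgammafn(s_shape);
  double h_max = C + d * t_star - a * nu / u_star - s_rate * u_star;
  double sum0 = 0.0, sum1 = 0.0;
  for (int i = 0; i < n_pts; ++i) {
    double t = lo + i * dt;
    double h = C + d * t - a * nu * std::exp(-t) - s_rate * std::exp(t);
    double w = (i == 0 || i == n_pts - 1) ? 1.0 : (i % 2 == 1 ? 4.0 : 2.0);
    double e = w * std::exp(h - h_max);
    sum0 += e;
    if (want_mean) sum1 += e * std::exp(t);
  }
  if (want_mean) return sum1 / sum0;
  return h_max + std::log(sum0 * dt / 3.0);
}

struct Adapt {
  std::vector<double> lsd;
  std::vector<int> acc;
  Adapt(int k, double init) : lsd(k, std::log(init)), acc(k, 0) {}
  void tune(int batch) {
    double step = std::min(0.1, 3.0 / std::sqrt((double)batch + 1.0));
    for (size_t i = 0; i < lsd.size(); ++i) {
      double rate = acc[i] / 50.0;
      lsd[i] += (rate > 0.44 ? step : -step);
      lsd[i] = std::max(-8.0, std::min(3.0, lsd[i]));
      acc[i] = 0;
    }
  }
};

// [[Rcpp::export]]
List basics_gibbs(NumericMatrix bio, NumericMatrix spike,
                  NumericVector mu_b0, NumericVector mu_s0,
                  NumericVector delta0, NumericVector phi0,
                  NumericVector nu0, double theta0,
                  double s_shape, double s_rate,
                  double mu_b_center, double mu_s_center,
                  int n_iter, int burn_in, int thin) {
  const int B = bio.nrow(), S = spike.nrow(), n = bio.ncol();
  const double prior_sd2 = 4.0;  // variance of log-normal prior on mu, delta

  std::vector<double> lmu_b(B), lmu_s(S), ldelta(B), lphi(n), lnu(n);
  for (int i = 0; i < B; ++i) lmu_b[i] = std::log(mu_b0[i]);
  for (int i = 0; i < S; ++i) lmu_s[i] = std::log(mu_s0[i]);
  for (int i = 0; i < B; ++i) ldelta[i] = std::log(delta0[i]);
  for (int j = 0; j < n; ++j) {
    lphi[j] = std::log(phi0[j]);
    lnu[j] = std::log(nu0[j]);
  }
  double ltheta = std::log(theta0);

  // sufficient statistics for the O(1) spike updates
  std::vector<double> spike_rowsum(S, 0.0), spike_colsum(n, 0.0);
  for (int i = 0; i < S; ++i)
    for (int j = 0; j < n; ++j) {
      spike_rowsum[i] += spike(i, j);
      spike_colsum[j] += spike(i, j);
    }

  // cached marginal log-prior of each nu_j at the current theta
  std::vector<double> lmarg(n);
  double a_cur = 1.0 / theta0;
  for (int j = 0; j < n; ++j)
    lmarg[j] = s_marginal(std::exp(lnu[j]), a_cur, s_shape, s_rate, false);

  Adapt ad_mu_b(B, 0.3), ad_mu_s(S, 0.3), ad_delta(B, 0.4),
        ad_phi(n, 0.2), ad_nu(n, 0.2), ad_theta(1, 0.4);

  const int n_keep = (n_iter > burn_in) ? (n_iter - burn_in + thin - 1) / thin
                                        : 0;
  NumericMatrix ch_mu_b(n_keep, B), ch_mu_s(n_keep, S), ch_delta(n_keep, B),
                ch_phi(n_keep, n), ch_s(n_keep, n), ch_nu(n_keep, n);
  NumericVector ch_theta(n_keep);
  int keep = 0;

  std::vector<double> r_i(B), mu_b_i(B), f_j(n);

  RNGScope scope;
  for (int it = 0; it < n_iter; ++it) {
    bool adapting = it < burn_in;
    double sum_nu = 0.0;
    for (int j = 0; j < n; ++j) {
      f_j[j] = std::exp(lphi[j] + lnu[j]);
      sum_nu += std::exp(lnu[j]);
    }
    for (int i = 0; i < B; ++i) {
      r_i[i] = std::exp(-ldelta[i]);
      mu_b_i[i] = std::exp(lmu_b[i]);
    }

    // --- spike-in mu_i: Poisson likelihood collapses to sufficient stats
    for (int i = 0; i < S; ++i) {
      double prop = lmu_s[i] + R::norm_rand() * std::exp(ad_mu_s.lsd[i]);
      double mu_cur = std::exp(lmu_s[i]), mu_new = std::exp(prop);
      double dll = spike_rowsum[i] * (prop - lmu_s[i]) -
                   (mu_new - mu_cur) * sum_nu;
      double e_new = prop - mu_s_center, e_cur = lmu_s[i] - mu_s_center;
      dll += -(e_new * e_new - e_cur * e_cur) / (2.0 * prior_sd2);
      if (std::log(R::unif_rand()) < dll) { lmu_s[i] = prop; ad_mu_s.acc[i]++; }
    }

    // --- biological mu_i
    for (int i = 0; i < B; ++i) {
      double prop = lmu_b[i] + R::norm_rand() * std::exp(ad_mu_b.lsd[i]);
      double mu_cur = mu_b_i[i], mu_new = std::exp(prop);
      double r = r_i[i];
      double dll = 0.0;
      for (int j = 0; j < n; ++j) {
        dll += nb_mean_term(bio(i, j), r, f_j[j] * mu_new) -
               nb_mean_term(bio(i, j), r, f_j[j] * mu_cur);
      }
      double e_new = prop - mu_b_center, e_cur = lmu_b[i] - mu_b_center;
      dll += -(e_new * e_new - e_cur * e_cur) / (2.0 * prior_sd2);
      if (std::log(R::unif_rand()) < dll) {
        lmu_b[i] = prop; mu_b_i[i] = mu_new; ad_mu_b.acc[i]++;
      }
    }

    // --- delta_i (biological over-dispersion)
    for (int i = 0; i < B; ++i) {
      double prop = ldelta[i] + R::norm_rand() * std::exp(ad_delta.lsd[i]);
      double r_cur = r_i[i];
      double r_new = std::exp(-prop);
      double mu_i = mu_b_i[i];
      double dll = 0.0;
      for (int j = 0; j < n; ++j) {
        double m = f_j[j] * mu_i;
        dll += nb_full_term(bio(i, j), r_new, m) -
               nb_full_term(bio(i, j), r_cur, m);
      }
      dll += -(prop * prop - ldelta[i] * ldelta[i]) / (2.0 * prior_sd2);
      if (std::log(R::unif_rand()) < dll) {
        ldelta[i] = prop; r_i[i] = r_new; ad_delta.acc[i]++;
      }
    }

    double theta = std::exp(ltheta);
    a_cur = 1.0 / theta;

    // --- nu_j (latent capture effect; prior marginalized over s_j)
    double sum_mu_s = 0.0;
    for (int i = 0; i < S; ++i) sum_mu_s += std::exp(lmu_s[i]);
    for (int j = 0; j < n; ++j) {
      double prop = lnu[j] + R::norm_rand() * std::exp(ad_nu.lsd[j]);
      double nu_cur = std::exp(lnu[j]), nu_new = std::exp(prop);
      double dll = spike_colsum[j] * (prop - lnu[j]) -
                   (nu_new - nu_cur) * sum_mu_s;
      double phi_j = std::exp(lphi[j]);
      for (int i = 0; i < B; ++i) {
        dll += nb_mean_term(bio(i, j), r_i[i], phi_j * nu_new * mu_b_i[i]) -
               nb_mean_term(bio(i, j), r_i[i], phi_j * nu_cur * mu_b_i[i]);
      }
      double lmarg_new = s_marginal(nu_new, a_cur, s_shape, s_rate, false);
      dll += lmarg_new - lmarg[j] + (prop - lnu[j]);  // marginal + Jacobian
      if (std::log(R::unif_rand()) < dll) {
        lnu[j] = prop; lmarg[j] = lmarg_new;
        f_j[j] = std::exp(lphi[j] + prop);
        ad_nu.acc[j]++;
      }
    }

    // --- phi_j (cell size factor, biological genes only)
    for (int j = 0; j < n; ++j) {
      double prop = lphi[j] + R::norm_rand() * std::exp(ad_phi.lsd[j]);
      double f_cur = f_j[j];
      double f_new = std::exp(prop + lnu[j]);
      double dll = 0.0;
      for (int i = 0; i < B; ++i) {
        dll += nb_mean_term(bio(i, j), r_i[i], f_new * mu_b_i[i]) -
               nb_mean_term(bio(i, j), r_i[i], f_cur * mu_b_i[i]);
      }
      if (std::log(R::unif_rand()) < dll) {
        lphi[j] = prop; f_j[j] = f_new; ad_phi.acc[j]++;
      }
    }
    // identifiability: rescale so that sum(phi) = n
    double sum_phi = 0.0;
    for (int j = 0; j < n; ++j) sum_phi += std::exp(lphi[j]);
    double adj = std::log((double)n / sum_phi);
    for (int j = 0; j < n; ++j) {
      lphi[j] += adj;
      f_j[j] = std::exp(lphi[j] + lnu[j]);
    }

    // --- theta (technical noise; s_j marginalized)
    {
      double prop = ltheta + R::norm_rand() * std::exp(ad_theta.lsd[0]);
      if (prop > -6.0 && prop < 3.0) {
        double a_new = std::exp(-prop);
        double dll = 0.0;
        std::vector<double> lmarg_new(n);
        for (int j = 0; j < n; ++j) {
          lmarg_new[j] = s_marginal(std::exp(lnu[j]), a_new, s_shape, s_rate,
                                    false);
          dll += lmarg_new[j] - lmarg[j];
        }
        double th_new = std::exp(prop);
        dll += -(th_new - theta) + (prop - ltheta);  // Gamma(1,1) + Jacobian
        if (std::log(R::unif_rand()) < dll) {
          ltheta = prop;
          lmarg = lmarg_new;
          ad_theta.acc[0]++;
        }
      }
    }

    if (adapting && (it + 1) % 50 == 0) {
      int batch = (it + 1) / 50;
      ad_mu_b.tune(batch); ad_mu_s.tune(batch); ad_delta.tune(batch);
      ad_phi.tune(batch); ad_nu.tune(batch); ad_theta.tune(batch);
    }

    if (it >= burn_in && (it - burn_in) % thin == 0 && keep < n_keep) {
      double a_rec = std::exp(-ltheta);
      for (int i = 0; i < B; ++i) {
        ch_mu_b(keep, i) = std::exp(lmu_b[i]);
        ch_delta(keep, i) = std::exp(ldelta[i]);
      }
      for (int i = 0; i < S; ++i) ch_mu_s(keep, i) = std::exp(lmu_s[i]);
      for (int j = 0; j < n; ++j) {
        ch_phi(keep, j) = std::exp(lphi[j]);
        ch_nu(keep, j) = std::exp(lnu[j]);
        ch_s(keep, j) = s_marginal(std::exp(lnu[j]), a_rec, s_shape, s_rate,
                                   true);
      }
      ch_theta[keep] = std::exp(ltheta);
      ++keep;
    }
  }

  double acc_theta_total = 0.0;  // report final adapted step as diagnostic
  acc_theta_total = std::exp(ad_theta.lsd[0]);

  return List::create(
    _["mu_bio"] = ch_mu_b, _["mu_spike"] = ch_mu_s, _["delta"] = ch_delta,
    _["phi"] = ch_phi, _["s"] = ch_s, _["nu"] = ch_nu, _["theta"] = ch_theta,
    _["n_kept"] = keep, _["theta_step"] = acc_theta_total);
}
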