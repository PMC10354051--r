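// Blocked adaptive random-walk Metropolis-within-Gibbs sampler for the
// hierarchical trigger-failure race model. One call runs one chain; R
// drives chains and seeds (R's RNG is used throughout, so set.seed on the
// R side makes chains exactly reproducible).
//
// Move set per iteration:
//   1. per-subject 8-parameter block update (multivariate normal proposal,
//      Cholesky of the running residual covariance, global step adapted to
//      23.4% acceptance during burn-in);
//   2. per-subject stop-subspace block update (mu_stop, sigma_stop,
//      tau_stop, z_tf), which trade off against each other and mix
//      slowly inside the full block;
//   3. conditional-prior independence refreshes of z_tf and z_gf
//      (acceptance is a pure likelihood ratio; crosses the flat region
//      of the failure-probability likelihoods);
//   4. per-parameter population (location, scale) block update;
//   5. translation moves: shift a location together with all subject
//      values (mixes along the hierarchical ridge of weakly identified
//      parameters);
//   6. scale-expansion moves: rescale a group scale together with the
//      subject deviations around the location (mixes through the
//      hierarchical funnel); Jacobian c^(n+1).

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

double subject_loglik_cpp(List data, NumericVector theta, double floor_val,
                          int n_nodes);

struct SubjData {
  List raw;
};

static double subj_ll(List &dat_j, const double *th, double floor_val,
                      int n_nodes) {
  NumericVector theta(8);
  for (int k = 0; k < 6; ++k) theta[k] = th[k];
  theta[6] = R::pnorm(th[6], 0.0, 1.0, 1, 0);
  theta[7] = R::pnorm(th[7], 0.0, 1.0, 1, 0);
  return subject_loglik_cpp(dat_j, theta, floor_val, n_nodes);
}

// log truncated-normal density (numerator + normalisation)
static double ld_tnorm(double x, double m, double s, double lo, double hi) {
  if (x < lo || x > hi) return R_NegInf;
  double z = R::pnorm(hi, m, s, 1, 0) - R::pnorm(lo, m, s, 1, 0);
  return R::dnorm(x, m, s, 1) - std::log(z);
}

static double log_trunc_z(double m, double s, double lo, double hi) {
  return std::log(R::pnorm(hi, m, s, 1, 0) - R::pnorm(lo, m, s, 1, 0));
}

// in-place Cholesky (upper) of an n x n row-major matrix; false if not PD
static bool cholN(const double *a, double *r, int n) {
  for (int i = 0; i < n * n; ++i) r[i] = 0.0;
  for (int i = 0; i < n; ++i) {
    double d = a[i * n + i];
    for (int k = 0; k < i; ++k) d -= r[k * n + i] * r[k * n + i];
    if (d <= 0) return false;
    r[i * n + i] = std::sqrt(d);
    for (int j = i + 1; j < n; ++j) {
      double v = a[i * n + j];
      for (int k = 0; k < i; ++k) v -= r[k * n + i] * r[k * n + j];
      r[i * n + j] = v / r[i * n + i];
    }
  }
  return true;
}

// [[Rcpp::export]]
List run_chain_cpp(List dat, NumericMatrix init_theta,
                   NumericVector lower, NumericVector upper,
                   double scale_lower, double scale_upper,
                   NumericVector init_loc, NumericVector init_sc,
                   int iter, int burn, int thin, int n_keep,
                   IntegerVector shift_idx, IntegerVector expand_idx,
                   bool single_subject, double floor_val = -700.0,
                   int n_nodes = 128) {
  int n_subj = dat.size();
  std::vector<List> d;
  d.reserve(n_subj);
  for (int j = 0; j < n_subj; ++j) d.push_back(dat[j]);

  std::vector<std::array<double, 8>> theta(n_subj);
  for (int j = 0; j < n_subj; ++j)
    for (int k = 0; k < 8; ++k) theta[j][k] = init_theta(j, k);
  std::array<double, 8> loc, sc;
  for (int k = 0; k < 8; ++k) { loc[k] = init_loc[k]; sc[k] = init_sc[k]; }

  std::vector<double> ll(n_subj);
  for (int j = 0; j < n_subj; ++j)
    ll[j] = subj_ll(d[j], theta[j].data(), floor_val, n_nodes);

  // adaptation state
  std::vector<std::array<std::array<double, 8>, 8>> run_m2(n_subj);
  std::vector<std::array<double, 8>> run_mean(n_subj);
  for (int j = 0; j < n_subj; ++j) {
    for (int k = 0; k < 8; ++k) {
      run_mean[j][k] = theta[j][k] - loc[k];
      for (int l = 0; l < 8; ++l) run_m2[j][k][l] = 0.0;
    }
  }
  double pop_mean[8][2], pop_m2[8][2][2];
  for (int k = 0; k < 8; ++k) {
    pop_mean[k][0] = loc[k]; pop_mean[k][1] = sc[k];
    for (int a = 0; a < 2; ++a)
      for (int b = 0; b < 2; ++b) pop_m2[k][a][b] = 0.0;
  }
  int run_n = 0;

  const double base_sd[8] = {0.012, 0.008, 0.012, 0.030,
                             0.020, 0.025, 0.40, 0.40};
  std::vector<std::array<std::array<double, 8>, 8>> subj_chol(n_subj);
  for (int j = 0; j < n_subj; ++j)
    for (int k = 0; k < 8; ++k)
      for (int l = 0; l < 8; ++l)
        subj_chol[j][k][l] = (k == l) ? base_sd[k] : 0.0;
  std::vector<double> subj_logstep(n_subj, 0.0);
  // dedicated stop-subspace blocks (mu_stop, sigma_stop, tau_stop, z_tf):
  // these four trade off against each other and mix slowly inside the
  // full 8-dim update, so they get their own adapted proposal
  const int stop_dims[4] = {3, 4, 5, 6};
  std::vector<std::array<double, 16>> stop_chol(n_subj);
  for (int j = 0; j < n_subj; ++j) {
    for (int i = 0; i < 16; ++i) stop_chol[j][i] = 0.0;
    for (int i = 0; i < 4; ++i)
      stop_chol[j][i * 4 + i] = base_sd[stop_dims[i]];
  }
  std::vector<double> stop_logstep(n_subj, 0.0);
  double pop_chol[8][2][2];
  for (int k = 0; k < 8; ++k) {
    pop_chol[k][0][0] = std::max(sc[k] / std::sqrt((double)n_subj), 0.01);
    pop_chol[k][1][1] = std::max(sc[k] / std::sqrt(2.0 * n_subj), 0.008);
    pop_chol[k][0][1] = pop_chol[k][1][0] = 0.0;
  }
  std::vector<double> pop_logstep(8, 0.0);
  const double shift_base[8] = {0.02, 0.02, 0.02, 0.02, 0.02, 0.02, 0.3, 0.3};
  std::vector<double> shift_logstep(8, 0.0), expand_logstep(8, 0.0);

  std::vector<double> acc_subj(n_subj, 0.0);
  std::vector<double> acc_pop(8, 0.0);
  int n_post = 0, keep_i = 0;

  NumericMatrix draws(n_keep, 16 + 8 * n_subj);
  std::vector<double> prop(8), ll_new(n_subj);

  auto group_lp = [&](const double *th) {
    double s = 0.0;
    for (int k = 0; k < 8; ++k)
      s += ld_tnorm(th[k], loc[k], sc[k], lower[k], upper[k]);
    return s;
  };

  for (int it = 1; it <= iter; ++it) {
    bool adapting = it <= burn;
    double gam = adapting ? std::min(0.25, 5.0 / std::sqrt((double)it)) : 0.0;

    // ---- subject blocks ----
    for (int j = 0; j < n_subj; ++j) {
      double step = std::exp(subj_logstep[j]);
      double z[8];
      for (int k = 0; k < 8; ++k) z[k] = R::norm_rand();
      bool ok = true;
      for (int k = 0; k < 8; ++k) {
        double dx = 0.0;
        for (int l = 0; l <= k; ++l) dx += z[l] * subj_chol[j][l][k];
        prop[k] = theta[j][k] + step * dx;
        if (prop[k] < lower[k] || prop[k] > upper[k]) ok = false;
      }
      double a = 0.0;
      if (ok) {
        double llp = subj_ll(d[j], prop.data(), floor_val, n_nodes);
        double lr = llp + group_lp(prop.data()) -
                    (ll[j] + group_lp(theta[j].data()));
        if (std::isfinite(lr) && std::log(R::unif_rand()) < lr) {
          for (int k = 0; k < 8; ++k) theta[j][k] = prop[k];
          ll[j] = llp;
          if (!adapting) acc_subj[j] += 1.0;
          a = 1.0;
        }
      }
      if (adapting) subj_logstep[j] += gam * (a - 0.234);
    }

    // ---- stop-subspace subject blocks ----
    for (int j = 0; j < n_subj; ++j) {
      double step = std::exp(stop_logstep[j]);
      double z[4];
      for (int k = 0; k < 4; ++k) z[k] = R::norm_rand();
      bool ok = true;
      for (int l = 0; l < 8; ++l) prop[l] = theta[j][l];
      for (int k = 0; k < 4; ++k) {
        double dx = 0.0;
        for (int l = 0; l <= k; ++l) dx += z[l] * stop_chol[j][l * 4 + k];
        int kk = stop_dims[k];
        prop[kk] = theta[j][kk] + step * dx;
        if (prop[kk] < lower[kk] || prop[kk] > upper[kk]) ok = false;
      }
      double a = 0.0;
      if (ok) {
        double llp = subj_ll(d[j], prop.data(), floor_val, n_nodes);
        double lr = llp + group_lp(prop.data()) -
                    (ll[j] + group_lp(theta[j].data()));
        if (std::isfinite(lr) && std::log(R::unif_rand()) < lr) {
          for (int k = 0; k < 8; ++k) theta[j][k] = prop[k];
          ll[j] = llp;
          a = 1.0;
        }
      }
      if (adapting) stop_logstep[j] += gam * (a - 0.234);
    }

    // ---- conditional-prior independence refresh of z_tf and z_gf ----
    // Where a probit failure parameter's likelihood is nearly flat the random
    // walk crawls; proposing each subject's value from its group prior
    // leaves a pure likelihood ratio and teleports through the flat
    // region.
    for (int k = 6; k <= 7; ++k) {
      for (int j = 0; j < n_subj; ++j) {
        double plo = R::pnorm(lower[k], loc[k], sc[k], 1, 0);
        double phi = R::pnorm(upper[k], loc[k], sc[k], 1, 0);
        double u = plo + R::unif_rand() * (phi - plo);
        double z_p = R::qnorm(u, loc[k], sc[k], 1, 0);
        double th_p[8];
        for (int l = 0; l < 8; ++l) th_p[l] = theta[j][l];
        th_p[k] = z_p;
        double llp = subj_ll(d[j], th_p, floor_val, n_nodes);
        if (std::isfinite(llp) && std::log(R::unif_rand()) < llp - ll[j]) {
          theta[j][k] = z_p;
          ll[j] = llp;
        }
      }
    }

    // ---- population (location, scale) blocks ----
    if (!single_subject) {
      for (int k = 0; k < 8; ++k) {
        double step = std::exp(pop_logstep[k]);
        double z0 = R::norm_rand(), z1 = R::norm_rand();
        double m_p = loc[k] + step * (z0 * pop_chol[k][0][0]);
        double s_p = sc[k] + step * (z0 * pop_chol[k][0][1] +
                                     z1 * pop_chol[k][1][1]);
        double a = 0.0;
        if (m_p >= lower[k] && m_p <= upper[k] && s_p >= scale_lower &&
            s_p <= scale_upper) {
          double cur = 0.0, nw = 0.0;
          for (int j = 0; j < n_subj; ++j) {
            cur += ld_tnorm(theta[j][k], loc[k], sc[k], lower[k], upper[k]);
            nw += ld_tnorm(theta[j][k], m_p, s_p, lower[k], upper[k]);
          }
          if (std::isfinite(nw) && std::log(R::unif_rand()) < nw - cur) {
            loc[k] = m_p; sc[k] = s_p;
            if (!adapting) acc_pop[k] += 1.0;
            a = 1.0;
          }
        }
        if (adapting) pop_logstep[k] += gam * (a - 0.234);
      }

      // ---- translation moves ----
      for (int ii = 0; ii < shift_idx.size(); ++ii) {
        int k = shift_idx[ii] - 1;
        double delta =
            R::norm_rand() * shift_base[k] * std::exp(shift_logstep[k]);
        double loc_p = loc[k] + delta;
        bool ok = loc_p >= lower[k] && loc_p <= upper[k];
        for (int j = 0; ok && j < n_subj; ++j) {
          double t = theta[j][k] + delta;
          if (t < lower[k] || t > upper[k]) ok = false;
        }
        double a = 0.0;
        if (ok) {
          double lr = n_subj * (log_trunc_z(loc[k], sc[k], lower[k], upper[k]) -
                                log_trunc_z(loc_p, sc[k], lower[k], upper[k]));
          for (int j = 0; j < n_subj; ++j) {
            double th_p[8];
            for (int l = 0; l < 8; ++l) th_p[l] = theta[j][l];
            th_p[k] += delta;
            ll_new[j] = subj_ll(d[j], th_p, floor_val, n_nodes);
            lr += ll_new[j] - ll[j];
          }
          if (std::isfinite(lr) && std::log(R::unif_rand()) < lr) {
            for (int j = 0; j < n_subj; ++j) {
              theta[j][k] += delta;
              ll[j] = ll_new[j];
            }
            loc[k] = loc_p;
            a = 1.0;
          }
        }
        if (adapting) shift_logstep[k] += gam * (a - 0.234);
      }

      // ---- scale-expansion moves ----
      for (int ii = 0; ii < expand_idx.size(); ++ii) {
        int k = expand_idx[ii] - 1;
        double eps = R::norm_rand() * 0.2 * std::exp(expand_logstep[k]);
        double c = std::exp(eps);
        double sc_p = c * sc[k];
        bool ok = sc_p >= scale_lower && sc_p <= scale_upper;
        std::vector<double> th_pk(n_subj);
        for (int j = 0; ok && j < n_subj; ++j) {
          th_pk[j] = loc[k] + c * (theta[j][k] - loc[k]);
          if (th_pk[j] < lower[k] || th_pk[j] > upper[k]) ok = false;
        }
        double a = 0.0;
        if (ok) {
          // prior numerators cancel up to c^-n; Jacobian c^(n+1)
          double lr = eps +
              n_subj * (log_trunc_z(loc[k], sc[k], lower[k], upper[k]) -
                        log_trunc_z(loc[k], sc_p, lower[k], upper[k]));
          for (int j = 0; j < n_subj; ++j) {
            double th_p[8];
            for (int l = 0; l < 8; ++l) th_p[l] = theta[j][l];
            th_p[k] = th_pk[j];
            ll_new[j] = subj_ll(d[j], th_p, floor_val, n_nodes);
            lr += ll_new[j] - ll[j];
          }
          if (std::isfinite(lr) && std::log(R::unif_rand()) < lr) {
            for (int j = 0; j < n_subj; ++j) {
              theta[j][k] = th_pk[j];
              ll[j] = ll_new[j];
            }
            sc[k] = sc_p;
            a = 1.0;
          }
        }
        if (adapting) expand_logstep[k] += gam * (a - 0.234);
      }
    }

    // ---- adaptation of proposal covariances ----
    if (adapting && it > 100) {
      run_n += 1;
      for (int j = 0; j < n_subj; ++j) {
        double dvec[8], d2[8];
        for (int k = 0; k < 8; ++k) {
          double resid = theta[j][k] - loc[k];
          dvec[k] = resid - run_mean[j][k];
          run_mean[j][k] += dvec[k] / run_n;
          d2[k] = resid - run_mean[j][k];
        }
        for (int k = 0; k < 8; ++k)
          for (int l = 0; l < 8; ++l)
            run_m2[j][k][l] += dvec[k] * d2[l];
      }
      for (int k = 0; k < 8; ++k) {
        double v[2] = {loc[k], sc[k]}, dv[2], dv2[2];
        for (int a2 = 0; a2 < 2; ++a2) {
          dv[a2] = v[a2] - pop_mean[k][a2];
          pop_mean[k][a2] += dv[a2] / run_n;
          dv2[a2] = v[a2] - pop_mean[k][a2];
        }
        for (int a2 = 0; a2 < 2; ++a2)
          for (int b = 0; b < 2; ++b) pop_m2[k][a2][b] += dv[a2] * dv2[b];
      }
      if (run_n > 150 && it % 50 == 0) {
        const double fac = 2.38 * 2.38 / 8.0;
        for (int j = 0; j < n_subj; ++j) {
          double cv[8][8], r[8][8];
          for (int k = 0; k < 8; ++k)
            for (int l = 0; l < 8; ++l) {
              cv[k][l] = run_m2[j][k][l] / (run_n - 1) * fac;
              if (k == l) cv[k][l] += (k >= 6 ? 1e-4 : 1e-6);
            }
          if (cholN(&cv[0][0], &r[0][0], 8))
            for (int k = 0; k < 8; ++k)
              for (int l = 0; l < 8; ++l) subj_chol[j][k][l] = r[k][l];
          double cv4[16], r4[16];
          const double fac4 = 2.38 * 2.38 / 4.0;
          for (int k = 0; k < 4; ++k)
            for (int l = 0; l < 4; ++l) {
              cv4[k * 4 + l] = run_m2[j][stop_dims[k]][stop_dims[l]] /
                               (run_n - 1) * fac4;
              if (k == l) cv4[k * 4 + l] += (stop_dims[k] >= 6 ? 1e-4 : 1e-6);
            }
          if (cholN(cv4, r4, 4))
            for (int i = 0; i < 16; ++i) stop_chol[j][i] = r4[i];
        }
        const double fac2 = 2.38 * 2.38 / 2.0;
        for (int k = 0; k < 8; ++k) {
          double a2 = pop_m2[k][0][0] / (run_n - 1) * fac2 + 1e-6;
          double b2 = pop_m2[k][1][1] / (run_n - 1) * fac2 + 1e-6;
          double ab = pop_m2[k][0][1] / (run_n - 1) * fac2;
          double l00 = std::sqrt(a2);
          double l01 = ab / l00;
          double rest = b2 - l01 * l01;
          if (rest > 0) {
            pop_chol[k][0][0] = l00;
            pop_chol[k][0][1] = l01;
            pop_chol[k][1][1] = std::sqrt(rest);
          }
        }
      }
    }

    if (!adapting) {
      n_post += 1;
      if ((it - burn) % thin == 0 && keep_i < n_keep) {
        for (int k = 0; k < 8; ++k) {
          draws(keep_i, k) = loc[k];
          draws(keep_i, 8 + k) = sc[k];
        }
        for (int k = 0; k < 8; ++k)
          for (int j = 0; j < n_subj; ++j)
            draws(keep_i, 16 + k * n_subj + j) = theta[j][k];
        keep_i += 1;
      }
    }
  }

  NumericVector acc(n_subj + 8);
  for (int j = 0; j < n_subj; ++j) acc[j] = acc_subj[j] / std::max(n_post, 1);
  for (int k = 0; k < 8; ++k)
    acc[n_subj + k] = acc_pop[k] / std::max(n_post, 1);
  return List::create(_["draws"] = draws, _["acc"] = acc);
}
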