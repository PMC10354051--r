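// Numerical core for the ex-Gaussian horse-race likelihood.
//
// The ex-Gaussian density and CDF are evaluated in log space so they stay
// finite when tau << sigma. The race probability P(respond | SSD) has no
// closed form; it is integrated with a fixed-node Gauss-Legendre rule over
// the effective support of the go density (the integrand is smooth there;
// the truncated tail mass is below 1e-8 at the node counts used). The
// adaptive quadrature route lives on the R side and the two are
// cross-checked in the test suite.

#include <Rcpp.h>
#include <map>
#include <vector>
#include <cmath>

using namespace Rcpp;

static double exg_logpdf1(double t, double mu, double sigma, double tau) {
  // log f(t) = -log(tau) + (mu - t)/tau + sigma^2/(2 tau^2)
  //            + log Phi((t - mu)/sigma - sigma/tau)
  double z = (t - mu) / sigma - sigma / tau;
  double lphi = R::pnorm(z, 0.0, 1.0, 1, 1);
  return -std::log(tau) + (mu - t) / tau +
         (sigma * sigma) / (2.0 * tau * tau) + lphi;
}

static double exg_cdf1(double t, double mu, double sigma, double tau) {
  double u = (t - mu) / sigma;
  double lphi2 = R::pnorm(u - sigma / tau, 0.0, 1.0, 1, 1);
  double expo = (sigma * sigma) / (2.0 * tau * tau) - (t - mu) / tau + lphi2;
  double val = R::pnorm(u, 0.0, 1.0, 1, 0) -
               (expo < -745.0 ? 0.0 : std::exp(expo));
  if (val < 0.0) val = 0.0;
  if (val > 1.0) val = 1.0;
  return val;
}

// Gauss-Legendre nodes/weights on [-1, 1], cached by n.
static const std::pair<std::vector<double>, std::vector<double>> &
gauleg(int n) {
  static std::map<int, std::pair<std::vector<double>, std::vector<double>>> cache;
  auto it = cache.find(n);
  if (it != cache.end()) return it->second;
  std::vector<double> x(n), w(n);
  int m = (n + 1) / 2;
  for (int i = 0; i < m; ++i) {
    double z = std::cos(M_PI * (i + 0.75) / (n + 0.5));
    double pp = 0.0, z1;
    do {
      double p1 = 1.0, p2 = 0.0;
      for (int j = 0; j < n; ++j) {
        double p3 = p2;
        p2 = p1;
        p1 = ((2.0 * j + 1.0) * z * p2 - j * p3) / (j + 1.0);
      }
      pp = n * (z * p1 - p2) / (z * z - 1.0);
      z1 = z;
      z = z1 - p1 / pp;
    } while (std::fabs(z - z1) > 1e-14);
    x[i] = -z;
    x[n - 1 - i] = z;
    w[i] = 2.0 / ((1.0 - z * z) * pp * pp);
    w[n - 1 - i] = w[i];
  }
  return cache.emplace(n, std::make_pair(std::move(x), std::move(w)))
      .first->second;
}

// P(T_go < ssd + T_stop) for independent ex-Gaussian runners: the integral
// of f_go(t) * S_stop(t - ssd) over the go support.
// The winning probability is integrated over the *stop* finishing-time
// density — P(T_go < ssd + T_stop) = 1 - int f_stop(s) (1 - F_go(ssd+s)) ds
// — because the stop density is the narrower factor: on its support both
// factors vary on the stop runner's own scale, so a fixed Gauss-Legendre
// rule (two panels: Gaussian body, exponential tail; 3:2 node split)
// resolves the integrand regardless of how small sigma_stop gets.
static double race_win_prob(double ssd, double mu_go, double sig_go,
                            double tau_go, double mu_st, double sig_st,
                            double tau_st, int n_nodes) {
  int n1 = (3 * n_nodes) / 5, n2 = n_nodes - n1;
  double a = mu_st - 8.0 * sig_st;
  double b = mu_st + 7.0 * sig_st;
  double c = b + 22.0 * tau_st;
  double edges[3] = {a, b, c};
  int counts[2] = {n1, n2};
  double J = 0.0;
  for (int p = 0; p < 2; ++p) {
    const auto &gl = gauleg(counts[p]);
    double lo = edges[p], hi = edges[p + 1];
    double c1 = 0.5 * (hi - lo), c2 = 0.5 * (hi + lo);
    double acc = 0.0;
    for (int i = 0; i < counts[p]; ++i) {
      double s = c1 * gl.first[i] + c2;
      double fs = std::exp(exg_logpdf1(s, mu_st, sig_st, tau_st));
      double sg = 1.0 - exg_cdf1(ssd + s, mu_go, sig_go, tau_go);
      acc += gl.second[i] * fs * sg;
    }
    J += c1 * acc;
  }
  double val = 1.0 - J;
  if (val < 0.0) val = 0.0;
  if (val > 1.0) val = 1.0;
  return val;
}

// [[Rcpp::export]]
NumericVector exg_logpdf_cpp(NumericVector t, double mu, double sigma,
                             double tau) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = exg_logpdf1(t[i], mu, sigma, tau);
  return out;
}

// [[Rcpp::export]]
NumericVector exg_cdf_cpp(NumericVector t, double mu, double sigma,
                          double tau) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = exg_cdf1(t[i], mu, sigma, tau);
  return out;
}

// [[Rcpp::export]]
NumericVector p_respond_cpp(NumericVector ssd, NumericVector go,
                            NumericVector stop, double p_tf, double p_gf,
                            int n_nodes = 128) {
  int n = ssd.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double I = race_win_prob(ssd[i], go[0], go[1], go[2], stop[0], stop[1],
                             stop[2], n_nodes);
    out[i] = (1.0 - p_gf) * (p_tf + (1.0 - p_tf) * I);
  }
  return out;
}

// Log-likelihood of one subject's reduced data in one condition.
// data: list(go_rt, n_go_omit, sr_rt, sr_ssd, inhib_ssd, inhib_n)
// theta: (mu_go, sigma_go, tau_go, mu_stop, sigma_stop, tau_stop, p_tf, p_gf)
// Each trial's log contribution is floored at `floor_val` so proposals into
// impossible regions are rejected smoothly rather than producing -Inf.
// [[Rcpp::export]]
double subject_loglik_cpp(List data, NumericVector theta,
                          double floor_val = -700.0, int n_nodes = 128) {
  NumericVector go_rt = data["go_rt"];
  int n_go_omit = as<int>(data["n_go_omit"]);
  NumericVector sr_rt = data["sr_rt"];
  NumericVector sr_ssd = data["sr_ssd"];
  NumericVector inhib_ssd = data["inhib_ssd"];
  IntegerVector inhib_n = data["inhib_n"];

  double mu_go = theta[0], sig_go = theta[1], tau_go = theta[2];
  double mu_st = theta[3], sig_st = theta[4], tau_st = theta[5];
  double p_tf = theta[6], p_gf = theta[7];

  if (sig_go <= 0 || tau_go <= 0 || sig_st <= 0 || tau_st <= 0 ||
      p_tf < 0 || p_tf > 1 || p_gf < 0 || p_gf > 1)
    return R_NegInf;

  double ll = 0.0;
  double log1m_gf = std::log1p(-p_gf);

  // go trials with a response: (1 - p_gf) f_go(rt)
  for (int i = 0; i < go_rt.size(); ++i) {
    double l = log1m_gf + exg_logpdf1(go_rt[i], mu_go, sig_go, tau_go);
    ll += std::max(l, floor_val);
  }
  // go omissions: p_gf
  if (n_go_omit > 0) {
    double l = p_gf > 0 ? std::log(p_gf) : R_NegInf;
    ll += n_go_omit * std::max(l, floor_val);
  }
  // signal-respond trials:
  // (1 - p_gf) f_go(rt) [p_tf + (1 - p_tf) S_stop(rt - ssd)]
  for (int i = 0; i < sr_rt.size(); ++i) {
    double mix =
        p_tf + (1.0 - p_tf) *
                   (1.0 - exg_cdf1(sr_rt[i] - sr_ssd[i], mu_st, sig_st, tau_st));
    double l = log1m_gf + exg_logpdf1(sr_rt[i], mu_go, sig_go, tau_go) +
               (mix > 0 ? std::log(mix) : R_NegInf);
    ll += std::max(l, floor_val);
  }
  // successful inhibitions, grouped by unique SSD:
  // 1 - (1 - p_gf)[p_tf + (1 - p_tf) P(go wins | ssd)]
  for (int i = 0; i < inhib_ssd.size(); ++i) {
    double I = race_win_prob(inhib_ssd[i], mu_go, sig_go, tau_go, mu_st,
                             sig_st, tau_st, n_nodes);
    double p_resp = (1.0 - p_gf) * (p_tf + (1.0 - p_tf) * I);
    double p_inh = 1.0 - p_resp;
    double l = p_inh > 0 ? std::log(p_inh) : R_NegInf;
    ll += inhib_n[i] * std::max(l, floor_val);
  }
  return ll;
}
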