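#include <Rcpp.h>
using namespace Rcpp;

// First-passage-time density for a Wiener process with drift v, boundary
// separation a, relative start point w = z/a (measured from the lower
// boundary) and unit diffusion coefficient, evaluated at decision time t
// for absorption at the LOWER boundary. Small-time and large-time series
// expansions; the number of terms is chosen per evaluation so that the
// truncation error of the normalised density stays below `err`.
static double wfpt_lower_raw(double t, double v, double a, double w,
                             double err) {
  if (t <= 0.0 || a <= 0.0) return 0.0;
  const double tt = t / (a * a); // time in normalised units

  // terms needed by the large-time expansion
  double kl;
  if (M_PI * tt * err < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * tt * err) / (M_PI * M_PI * tt));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(tt)));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(tt));
  }
  // terms needed by the small-time expansion
  double ks;
  if (2.0 * std::sqrt(2.0 * M_PI * tt) * err < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * tt *
                         std::log(2.0 * std::sqrt(2.0 * M_PI * tt) * err));
    ks = std::max(ks, std::sqrt(tt) + 1.0);
  } else {
    ks = 2.0;
  }

  double p = 0.0;
  if (ks < kl) { // small-time series is cheaper
    const int K = (int)std::ceil(ks);
    const int lo = -(int)std::floor((K - 1) / 2.0);
    const int hi = (int)std::ceil((K - 1) / 2.0);
    for (int k = lo; k <= hi; ++k) {
      const double wk = w + 2.0 * k;
      p += wk * std::exp(-wk * wk / (2.0 * tt));
    }
    p /= std::sqrt(2.0 * M_PI * tt * tt * tt);
  } else { // large-time series
    const int K = (int)std::ceil(kl);
    for (int k = 1; k <= K; ++k) {
      p += k * std::exp(-k * k * M_PI * M_PI * tt / 2.0) *
           std::sin(k * M_PI * w);
    }
    p *= M_PI;
  }
  if (p < 0.0) p = 0.0; // truncation can leave a negligible negative residue

  // undo the normalisation and reinstate the drift factor
  return p * std::exp(-v * a * w - v * v * t / 2.0) / (a * a);
}

// Defective FPT density in the task parametrisation: boundaries at +/-
// threshold, start X0 = start_bias * threshold, drift mu, unit noise.
// Upper boundary (left choice) via reflection of the lower-boundary form.
static double fpt_density_one(double t, double drift, double threshold,
                              double start_bias, double nondecision,
                              bool upper, double tol) {
  const double td = t - nondecision;
  if (td <= 0.0) return 0.0;
  const double a = 2.0 * threshold;
  if (upper) {
    return wfpt_lower_raw(td, -drift, a, (1.0 - start_bias) / 2.0, tol);
  }
  return wfpt_lower_raw(td, drift, a, (1.0 + start_bias) / 2.0, tol);
}

// [[Rcpp::export]]
NumericVector wfpt_density_cpp(NumericVector t, double drift, double threshold,
                               double start_bias, double nondecision,
                               bool upper, double tol) {
  const int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    out[i] = fpt_density_one(t[i], drift, threshold, start_bias, nondecision,
                             upper, tol);
  }
  return out;
}

static inline double logistic_scalar(double x) {
  return 1.0 / (1.0 + std::exp(-x));
}

// Negative log-likelihood of first-free-choice (choice, RT) pairs under the
// linked DDM. par = (drift_base, drift_reward, drift_info, bias_base,
// bias_reward, bias_info, threshold, nondecision). Per-observation
// log-density floored at log_floor so that rt <= T0 (and numerical
// underflow) yields a large finite penalty rather than -Inf.
// [[Rcpp::export]]
double ddm_nll_cpp(NumericVector rt, IntegerVector choice_sign,
                   NumericVector delta_r, NumericVector delta_i,
                   NumericVector par, double tol, double log_floor) {
  const int n = rt.size();
  const double threshold = par[6];
  const double t0 = par[7];
  if (threshold <= 0.0) return -log_floor * (double)n; // out of domain
  double nll = 0.0;
  for (int i = 0; i < n; ++i) {
    const double mu = par[0] + par[1] * delta_r[i] + par[2] * delta_i[i];
    double bias =
        2.0 * logistic_scalar(par[3] + par[4] * delta_r[i] +
                              par[5] * delta_i[i]) -
        1.0;
    if (bias > 1.0 - 1e-9) bias = 1.0 - 1e-9;
    if (bias < -1.0 + 1e-9) bias = -1.0 + 1e-9;
    const bool upper = choice_sign[i] > 0;
    const double d =
        fpt_density_one(rt[i], mu, threshold, bias, t0, upper, tol);
    double ll = (d > 0.0) ? std::log(d) : log_floor;
    if (ll < log_floor) ll = log_floor;
    nll -= ll;
  }
  return nll;
}

// Normalised density p(tt, w) together with its partial derivatives wrt the
// normalised time tt and the relative start w, using the same series and
// truncation criterion as wfpt_lower_raw. Needed for analytic likelihood
// gradients.
static void wfpt_p_derivs(double tt, double w, double err, double &p,
                          double &p_tt, double &p_w) {
  p = 0.0;
  p_tt = 0.0;
  p_w = 0.0;
  if (tt <= 0.0) return;
  double kl;
  if (M_PI * tt * err < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * tt * err) / (M_PI * M_PI * tt));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(tt)));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(tt));
  }
  double ks;
  if (2.0 * std::sqrt(2.0 * M_PI * tt) * err < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * tt *
                         std::log(2.0 * std::sqrt(2.0 * M_PI * tt) * err));
    ks = std::max(ks, std::sqrt(tt) + 1.0);
  } else {
    ks = 2.0;
  }
  if (ks < kl) {
    const int K = (int)std::ceil(ks) + 1; // one extra term for derivatives
    const int lo = -(int)std::floor((K - 1) / 2.0);
    const int hi = (int)std::ceil((K - 1) / 2.0);
    const double c = 1.0 / std::sqrt(2.0 * M_PI * tt * tt * tt);
    for (int k = lo; k <= hi; ++k) {
      const double s = w + 2.0 * k;
      const double e = std::exp(-s * s / (2.0 * tt));
      p += s * e;
      p_w += e * (1.0 - s * s / tt);
      p_tt += s * e * (-1.5 / tt + s * s / (2.0 * tt * tt));
    }
    p *= c;
    p_w *= c;
    p_tt *= c;
  } else {
    const int K = (int)std::ceil(kl) + 1;
    for (int k = 1; k <= K; ++k) {
      const double E = std::exp(-k * k * M_PI * M_PI * tt / 2.0);
      const double sn = std::sin(k * M_PI * w);
      const double cs = std::cos(k * M_PI * w);
      p += k * E * sn;
      p_w += k * k * E * cs;
      p_tt += k * E * (-k * k * M_PI * M_PI / 2.0) * sn;
    }
    p *= M_PI;
    p_w *= M_PI * M_PI;
    p_tt *= M_PI;
  }
}

// Analytic gradient of the negative log-likelihood wrt the 8 linking
// coefficients. Observations sitting on the log-density floor (rt <= T0 or
// underflow) contribute a zero (sub)gradient, matching the flat penalty in
// ddm_nll_cpp.
// [[Rcpp::export]]
NumericVector ddm_nll_grad_cpp(NumericVector rt, IntegerVector choice_sign,
                               NumericVector delta_r, NumericVector delta_i,
                               NumericVector par, double tol,
                               double log_floor) {
  const int n = rt.size();
  NumericVector grad(8);
  const double threshold = par[6];
  const double t0 = par[7];
  if (threshold <= 0.0) return grad;
  const double a = 2.0 * threshold;
  for (int i = 0; i < n; ++i) {
    const double t = rt[i] - t0;
    if (t <= 0.0) continue; // floored observation
    const double mu = par[0] + par[1] * delta_r[i] + par[2] * delta_i[i];
    const double eta = par[3] + par[4] * delta_r[i] + par[5] * delta_i[i];
    double lw = logistic_scalar(eta); // start measured from lower boundary
    if (lw > 1.0 - 5e-10) lw = 1.0 - 5e-10;
    if (lw < 5e-10) lw = 5e-10;
    const bool upper = choice_sign[i] > 0;
    const double v = upper ? -mu : mu;
    const double w = upper ? 1.0 - lw : lw;
    const double tt = t / (a * a);
    double p, p_tt, p_w;
    wfpt_p_derivs(tt, w, tol, p, p_tt, p_w);
    if (!(p > 0.0)) continue;
    const double logf =
        std::log(p) - v * a * w - v * v * t / 2.0 - 2.0 * std::log(a);
    if (logf <= log_floor) continue;
    const double dlf_dv = -a * w - v * t;
    const double dlf_dw = p_w / p - v * a;
    const double dlf_da = (p_tt / p) * (-2.0 * t / (a * a * a)) - v * w -
                          2.0 / a;
    const double dlf_dt = (p_tt / p) / (a * a) - v * v / 2.0;
    // chain rule back to the task-linked parametrisation
    const double dlf_dmu = upper ? -dlf_dv : dlf_dv;
    const double dwdeta = lw * (1.0 - lw) * (upper ? -1.0 : 1.0);
    const double dlf_deta = dlf_dw * dwdeta;
    // nll = -sum(logf): accumulate negated contributions
    grad[0] -= dlf_dmu;
    grad[1] -= dlf_dmu * delta_r[i];
    grad[2] -= dlf_dmu * delta_i[i];
    grad[3] -= dlf_deta;
    grad[4] -= dlf_deta * delta_r[i];
    grad[5] -= dlf_deta * delta_i[i];
    grad[6] -= dlf_da * 2.0;
    grad[7] -= -dlf_dt;
  }
  return grad;
}

// One Euler-Maruyama step with intra-step boundary-crossing detection.
// Because drift and diffusion are constant the grid-point distribution is
// exact; the only discretisation error is a crossing-and-return between grid
// points, handled by the Brownian-bridge crossing probability
// exp(-2 (b - x0)(b - x1) / dt). Returns +1 / -1 on a crossing, 0 otherwise,
// updating x in place.
static inline int wiener_step(double &x, double drift, double threshold,
                              double dt, double sdt) {
  const double x_old = x;
  x += drift * dt + sdt * norm_rand();
  if (x >= threshold) return 1;
  if (x <= -threshold) return -1;
  const double pu = std::exp(-2.0 * (threshold - x_old) * (threshold - x) / dt);
  if (unif_rand() < pu) return 1;
  const double pl = std::exp(-2.0 * (threshold + x_old) * (threshold + x) / dt);
  if (unif_rand() < pl) return -1;
  return 0;
}

// Euler-Maruyama simulation of the two-boundary Wiener process with common
// parameters for all n paths. Returned time includes the non-decision time.
// Paths still inside the boundaries after max_t seconds are flagged censored.
// Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
DataFrame wiener_sim_cpp(int n, double drift, double threshold,
                         double start_bias, double nondecision, double dt,
                         double max_t) {
  NumericVector time(n);
  IntegerVector boundary(n); // +1 upper, -1 lower, NA censored
  LogicalVector censored(n);
  const double sdt = std::sqrt(dt);
  const int max_steps = (int)std::ceil(max_t / dt);
  for (int i = 0; i < n; ++i) {
    double x = start_bias * threshold;
    int step = 0;
    int b = NA_INTEGER;
    while (step < max_steps) {
      const int hit = wiener_step(x, drift, threshold, dt, sdt);
      ++step;
      if (hit != 0) {
        b = hit;
        break;
      }
    }
    boundary[i] = b;
    censored[i] = (b == NA_INTEGER);
    time[i] = censored[i] ? NA_REAL : nondecision + step * dt;
  }
  return DataFrame::create(_["time"] = time, _["boundary"] = boundary,
                           _["censored"] = censored);
}

// One simulated first passage per row, with per-row drift and start bias and
// shared threshold / non-decision time (one participant-horizon block).
// [[Rcpp::export]]
DataFrame wiener_sim_obs_cpp(NumericVector drift, NumericVector start_bias,
                             double threshold, double nondecision, double dt,
                             double max_t) {
  const int n = drift.size();
  NumericVector time(n);
  IntegerVector boundary(n);
  LogicalVector censored(n);
  const double sdt = std::sqrt(dt);
  const int max_steps = (int)std::ceil(max_t / dt);
  for (int i = 0; i < n; ++i) {
    double x = start_bias[i] * threshold;
    int step = 0;
    int b = NA_INTEGER;
    while (step < max_steps) {
      const int hit = wiener_step(x, drift[i], threshold, dt, sdt);
      ++step;
      if (hit != 0) {
        b = hit;
        break;
      }
    }
    boundary[i] = b;
    censored[i] = (b == NA_INTEGER);
    time[i] = censored[i] ? NA_REAL : nondecision + step * dt;
  }
  return DataFrame::create(_["time"] = time, _["boundary"] = boundary,
                           _["censored"] = censored);
}
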