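#include <Rcpp.h>
using namespace Rcpp;

// Expected counts per TCSPC bin under the steady-state periodic
// bi-exponential model. Each exponential component integrates analytically
// over a bin: integral_{t_j}^{t_j+dt} e^{-t/tau} dt =
// tau (1 - e^{-dt/tau}) e^{-t_j/tau}; the pulse-train superposition
// multiplies the component by 1 / (1 - e^{-T/tau}). offset_c is counts/bin.

// [[Rcpp::export]]
NumericVector cpp_bin_means(double amplitude, double alpha1, double alpha2,
                            double tau1, double tau2, double offset_c,
                            double period_t, int n_bins) {
  NumericVector out(n_bins);
  const double dt = period_t / n_bins;
  const double w1 = 1.0 / (1.0 - std::exp(-period_t / tau1));
  const double w2 = 1.0 / (1.0 - std::exp(-period_t / tau2));
  const double c1 = amplitude * alpha1 * w1 * tau1 * (1.0 - std::exp(-dt / tau1));
  const double c2 = amplitude * alpha2 * w2 * tau2 * (1.0 - std::exp(-dt / tau2));
  const double d1 = std::exp(-dt / tau1);
  const double d2 = std::exp(-dt / tau2);
  double e1 = 1.0, e2 = 1.0;  // e^{-t_j/tau} accumulated multiplicatively
  for (int j = 0; j < n_bins; ++j) {
    out[j] = c1 * e1 + c2 * e2 + offset_c;
    e1 *= d1;
    e2 *= d2;
  }
  return out;
}

// Poisson negative log-likelihood of a decay histogram under the periodic
// bi-exponential model, reported as half the deviance against the
// saturated model: sum_j [mu_j - n_j + n_j log(n_j / mu_j)]. This differs
// from sum(mu - n log mu) by a parameter-free constant but is O(1) near
// the optimum instead of O(total photons), so optimisers can resolve the
// shallow multi-exponential valley without double-precision cancellation.
// Means floored at 1e-12 for numerical safety.

// [[Rcpp::export]]
double cpp_pois_nll(NumericVector counts, double amplitude, double alpha1,
                    double alpha2, double tau1, double tau2, double offset_c,
                    double period_t) {
  const int n_bins = counts.size();
  NumericVector mu = cpp_bin_means(amplitude, alpha1, alpha2, tau1, tau2,
                                   offset_c, period_t, n_bins);
  double nll = 0.0;
  for (int j = 0; j < n_bins; ++j) {
    double m = mu[j] > 1e-12 ? mu[j] : 1e-12;
    double n = counts[j];
    nll += m - n;
    if (n > 0) nll += n * std::log(n / m);
  }
  return nll;
}

// Gradient of the Poisson NLL with respect to the raw parameters
// (A, alpha2, tau1, tau2, C), with alpha1 = 1 - alpha2. Returns length 5.
// d mu_j / d tau uses the analytic derivative of the bin integral
// g_j(tau) = tau (1 - e^{-dt/tau}) e^{-t_j/tau} / (1 - e^{-T/tau}).

// [[Rcpp::export]]
NumericVector cpp_pois_nll_grad(NumericVector counts, double amplitude,
                                double alpha2, double tau1, double tau2,
                                double offset_c, double period_t) {
  const int n_bins = counts.size();
  const double dt = period_t / n_bins;
  const double alpha1 = 1.0 - alpha2;

  const double E1 = std::exp(-dt / tau1), E2 = std::exp(-dt / tau2);
  const double W1 = std::exp(-period_t / tau1), W2 = std::exp(-period_t / tau2);
  const double D1 = 1.0 - E1, D2 = 1.0 - E2;
  const double S1 = 1.0 - W1, S2 = 1.0 - W2;

  double gA = 0, ga2 = 0, gt1 = 0, gt2 = 0, gC = 0;
  double q1 = 1.0, q2 = 1.0;  // e^{-t_j/tau}
  for (int j = 0; j < n_bins; ++j) {
    const double tj = j * dt;
    const double g1 = tau1 * D1 * q1 / S1;
    const double g2 = tau2 * D2 * q2 / S2;
    double mu = amplitude * (alpha1 * g1 + alpha2 * g2) + offset_c;
    if (mu < 1e-12) mu = 1e-12;
    const double r = 1.0 - counts[j] / mu;  // d nll / d mu
    // dg/dtau * tau-free form: dg1/dtau1
    const double dg1 = (q1 / S1) * (D1 - E1 * dt / tau1 + D1 * tj / tau1 +
                                    D1 * W1 * period_t / (S1 * tau1));
    const double dg2 = (q2 / S2) * (D2 - E2 * dt / tau2 + D2 * tj / tau2 +
                                    D2 * W2 * period_t / (S2 * tau2));
    gA += r * (alpha1 * g1 + alpha2 * g2);
    ga2 += r * amplitude * (g2 - g1);
    gt1 += r * amplitude * alpha1 * dg1;
    gt2 += r * amplitude * alpha2 * dg2;
    gC += r;
    q1 *= E1;
    q2 *= E2;
  }
  return NumericVector::create(gA, ga2, gt1, gt2, gC);
}

// ---------------------------------------------------------------------------
// Batched per-pixel Levenberg-Marquardt fitting of the periodic model.
// Minimises the Poisson deviance over transformed parameters
// p = (log A, logit alpha2, log tau1, log tau2 [, C]) with box constraints,
// using the Fisher (expected-information) normal matrix. Mono-exponential
// fits use p = (log A, log tau [, C]).
// ---------------------------------------------------------------------------

namespace {

struct Model {
  double period_t;
  int n_bins;
};

// deviance, gradient and Fisher matrix at transformed params p
// two = bi-exponential; free_c = offset fitted; c_fix used otherwise.
void eval_all(const double* counts, const Model& md, const double* p,
              bool two, bool free_c, double c_fix, double* f_out,
              double* g_out, double* F_out, int npar) {
  const double dt = md.period_t / md.n_bins;
  double A = std::exp(p[0]);
  double a2, t1, t2, C;
  if (two) {
    a2 = 1.0 / (1.0 + std::exp(-p[1]));
    t1 = std::exp(p[2]);
    t2 = std::exp(p[3]);
    C = free_c ? p[4] : c_fix;
  } else {
    a2 = 1.0;
    t1 = t2 = std::exp(p[1]);
    C = free_c ? p[2] : c_fix;
  }
  const double a1 = 1.0 - a2;
  const double E1 = std::exp(-dt / t1), E2 = std::exp(-dt / t2);
  const double W1 = std::exp(-md.period_t / t1), W2 = std::exp(-md.period_t / t2);
  const double D1 = 1.0 - E1, D2 = 1.0 - E2;
  const double S1 = 1.0 - W1, S2 = 1.0 - W2;
  double f = 0.0;
  for (int a = 0; a < npar; ++a) g_out[a] = 0.0;
  for (int a = 0; a < npar * npar; ++a) F_out[a] = 0.0;
  double q1 = 1.0, q2 = 1.0;
  double d[5];
  for (int j = 0; j < md.n_bins; ++j) {
    const double tj = j * dt;
    const double g1 = t1 * D1 * q1 / S1;
    const double g2 = t2 * D2 * q2 / S2;
    double mu = A * (a1 * g1 + a2 * g2) + C;
    if (mu < 1e-12) mu = 1e-12;
    const double n = counts[j];
    f += mu - n;
    if (n > 0) f += n * std::log(n / mu);
    const double r = 1.0 - n / mu;
    const double dg1 = (q1 / S1) * (D1 - E1 * dt / t1 + D1 * tj / t1 +
                                    D1 * W1 * md.period_t / (S1 * t1));
    const double dg2 = (q2 / S2) * (D2 - E2 * dt / t2 + D2 * tj / t2 +
                                    D2 * W2 * md.period_t / (S2 * t2));
    if (two) {
      d[0] = mu - C;                          // d mu / d logA
      d[1] = A * a2 * a1 * (g2 - g1);         // d mu / d eta
      d[2] = A * a1 * t1 * dg1;               // d mu / d log tau1
      d[3] = A * a2 * t2 * dg2;               // d mu / d log tau2
      if (free_c) d[4] = 1.0;
    } else {
      d[0] = mu - C;
      d[1] = A * t2 * dg2;                    // single lifetime
      if (free_c) d[2] = 1.0;
    }
    for (int a = 0; a < npar; ++a) {
      g_out[a] += r * d[a];
      for (int b = a; b < npar; ++b) F_out[a * npar + b] += d[a] * d[b] / mu;
    }
    q1 *= E1;
    q2 *= E2;
  }
  for (int a = 0; a < npar; ++a)
    for (int b = 0; b < a; ++b) F_out[a * npar + b] = F_out[b * npar + a];
  *f_out = f;
}

double eval_f(const double* counts, const Model& md, const double* p,
              bool two, bool free_c, double c_fix) {
  const double dt = md.period_t / md.n_bins;
  double A = std::exp(p[0]);
  double a2, t1, t2, C;
  if (two) {
    a2 = 1.0 / (1.0 + std::exp(-p[1]));
    t1 = std::exp(p[2]);
    t2 = std::exp(p[3]);
    C = free_c ? p[4] : c_fix;
  } else {
    a2 = 1.0;
    t1 = t2 = std::exp(p[1]);
    C = free_c ? p[2] : c_fix;
  }
  const double a1 = 1.0 - a2;
  const double E1 = std::exp(-dt / t1), E2 = std::exp(-dt / t2);
  const double W1 = std::exp(-md.period_t / t1), W2 = std::exp(-md.period_t / t2);
  const double c1 = a1 * t1 * (1.0 - E1) / (1.0 - W1);
  const double c2 = a2 * t2 * (1.0 - E2) / (1.0 - W2);
  double f = 0.0, q1 = 1.0, q2 = 1.0;
  for (int j = 0; j < md.n_bins; ++j) {
    double mu = A * (c1 * q1 + c2 * q2) + C;
    if (mu < 1e-12) mu = 1e-12;
    const double n = counts[j];
    f += mu - n;
    if (n > 0) f += n * std::log(n / mu);
    q1 *= E1;
    q2 *= E2;
  }
  return f;
}

// solve (M) x = b for small npar via Gaussian elimination w/ partial pivot
bool solve_small(double* M, double* b, int n) {
  for (int c = 0; c < n; ++c) {
    int piv = c;
    for (int r2 = c + 1; r2 < n; ++r2)
      if (std::fabs(M[r2 * n + c]) > std::fabs(M[piv * n + c])) piv = r2;
    if (std::fabs(M[piv * n + c]) < 1e-300) return false;
    if (piv != c) {
      for (int k = 0; k < n; ++k) std::swap(M[c * n + k], M[piv * n + k]);
      std::swap(b[c], b[piv]);
    }
    for (int r2 = c + 1; r2 < n; ++r2) {
      const double fac = M[r2 * n + c] / M[c * n + c];
      for (int k = c; k < n; ++k) M[r2 * n + k] -= fac * M[c * n + k];
      b[r2] -= fac * b[c];
    }
  }
  for (int r2 = n - 1; r2 >= 0; --r2) {
    double s = b[r2];
    for (int k = r2 + 1; k < n; ++k) s -= M[r2 * n + k] * b[k];
    b[r2] = s / M[r2 * n + r2];
  }
  return true;
}

// box-constrained LM; p is modified in place; returns final deviance
double lm_fit(const double* counts, const Model& md, double* p, bool two,
              bool free_c, double c_fix, const double* lo, const double* hi,
              int npar, int max_iter, bool* conv) {
  double f, g[5], F[25], M[25], b[5], ptry[5];
  eval_all(counts, md, p, two, free_c, c_fix, &f, g, F, npar);
  double lambda = 1e-3;
  *conv = false;
  for (int it = 0; it < max_iter; ++it) {
    bool stepped = false;
    for (int inner = 0; inner < 12; ++inner) {
      for (int a = 0; a < npar * npar; ++a) M[a] = F[a];
      for (int a = 0; a < npar; ++a) {
        double da = F[a * npar + a];
        M[a * npar + a] = da + lambda * (da > 1e-12 ? da : 1e-12);
        b[a] = -g[a];
      }
      if (!solve_small(M, b, npar)) { lambda *= 10.0; continue; }
      for (int a = 0; a < npar; ++a) {
        ptry[a] = p[a] + b[a];
        if (ptry[a] < lo[a]) ptry[a] = lo[a];
        if (ptry[a] > hi[a]) ptry[a] = hi[a];
      }
      const double ftry = eval_f(counts, md, ptry, two, free_c, c_fix);
      if (ftry <= f) {
        const double gain = f - ftry;
        for (int a = 0; a < npar; ++a) p[a] = ptry[a];
        f = ftry;
        lambda = std::max(lambda / 3.0, 1e-12);
        stepped = true;
        if (gain < 1e-10 * (std::fabs(f) + 1.0)) { *conv = true; return f; }
        break;
      }
      lambda *= 4.0;
      if (lambda > 1e12) { *conv = true; return f; }  // pinned at boundary
    }
    if (!stepped) { *conv = true; return f; }
    eval_all(counts, md, p, two, free_c, c_fix, &f, g, F, npar);
  }
  return f;
}

// log-linear tail/head initialisation (mirrors the R-side initialiser)
void init_guess(const double* h, const Model& md, double tau_min,
                double tau1_max, double tau2_max, bool free_c, double c_fix,
                double* tau1_0, double* tau2_0, double* f2_0, double* c0_out) {
  const int nb = md.n_bins;
  const double dt = md.period_t / nb;
  double hmin = h[0];
  for (int j = 1; j < nb; ++j) hmin = std::min(hmin, h[j]);
  const double c0 = free_c ? 0.5 * hmin : c_fix;
  // tail fit
  int j0 = (int)std::floor(0.6 * nb);
  if (j0 < 0) j0 = 0;
  double sx = 0, sy = 0, sxx = 0, sxy = 0;
  int m = 0;
  for (int j = j0; j < nb; ++j) {
    const double x = (j + 0.5) * dt;
    const double y = std::log(std::max(h[j] - c0, 0.5));
    sx += x; sy += y; sxx += x * x; sxy += x * y;
    ++m;
  }
  double slope = 0, icept = 0;
  const double den = m * sxx - sx * sx;
  if (den > 1e-12) {
    slope = (m * sxy - sx * sy) / den;
    icept = (sy - slope * sx) / m;
  }
  double t2 = (slope < -1e-9) ? -1.0 / slope : 10.0 * md.period_t;
  t2 = std::min(std::max(t2, 2.0), tau2_max);
  // head fit on residual after subtracting extrapolated tail
  int jh = std::max(3, (int)std::floor(0.3 * nb));
  sx = sy = sxx = sxy = 0;
  m = 0;
  int npos = 0;
  double slow_sum = 0, tot = 0;
  for (int j = 0; j < nb; ++j) {
    const double x = (j + 0.5) * dt;
    const double sp = std::exp(icept + slope * x);
    const double hc = std::max(h[j] - c0, 0.0);
    slow_sum += std::min(sp, hc);
    tot += hc;
    if (j < jh) {
      const double resid = hc - sp;
      if (resid > 0) ++npos;
      const double y = std::log(std::max(resid, 0.5));
      sx += x; sy += y; sxx += x * x; sxy += x * y;
      ++m;
    }
  }
  double t1 = 3.0;
  const double den2 = m * sxx - sx * sx;
  if (npos >= 3 && den2 > 1e-12) {
    const double sh = (m * sxy - sx * sy) / den2;
    if (sh < -1e-9) t1 = -1.0 / sh;
  }
  t1 = std::min(std::max(t1, tau_min), tau1_max);
  double f2 = slow_sum / std::max(tot, 1.0);
  f2 = std::min(std::max(f2, 0.02), 0.98);
  *tau1_0 = t1;
  *tau2_0 = t2;
  *f2_0 = f2;
  *c0_out = c0;
}

double unit_total_cpp(const Model& md, double a2, double t1, double t2) {
  const double dt = md.period_t / md.n_bins;
  const double E1 = std::exp(-dt / t1), E2 = std::exp(-dt / t2);
  const double W1 = std::exp(-md.period_t / t1), W2 = std::exp(-md.period_t / t2);
  const double c1 = (1.0 - a2) * t1 * (1.0 - E1) / (1.0 - W1);
  const double c2 = a2 * t2 * (1.0 - E2) / (1.0 - W2);
  double s = 0, q1 = 1.0, q2 = 1.0;
  for (int j = 0; j < md.n_bins; ++j) {
    s += c1 * q1 + c2 * q2;
    q1 *= E1;
    q2 *= E2;
  }
  return s;
}

}  // namespace

// Fit every row of `counts` (pixels x bins). Returns a matrix with columns
// alpha1, alpha2, tau1, tau2, offset, amplitude, deviance, converged,
// collapsed. opts = (c_fix or NA, tau_min, tau1_max, tau2_max, min_alpha,
// collapse_z, restart_chisq, min_photons).

// [[Rcpp::export]]
NumericMatrix cpp_fit_stack(NumericMatrix counts, double period_t,
                            NumericVector opts) {
  const int npx = counts.nrow();
  const int nb = counts.ncol();
  Model md{period_t, nb};
  const bool free_c = !R_finite(opts[0]);
  const double c_fix = free_c ? 0.0 : opts[0];
  const double tau_min = opts[1], tau1_max = opts[2], tau2_max = opts[3];
  const double min_alpha = opts[4], collapse_z = opts[5];
  const double restart_chisq = opts[6], min_photons = opts[7];
  const bool two_comp = opts[8] > 1.5;
  NumericMatrix out(npx, 9);
  std::fill(out.begin(), out.end(), NA_REAL);
  std::vector<double> row(nb);

  const int npar2 = free_c ? 5 : 4;
  const int npar1 = free_c ? 3 : 2;
  double lo2[5] = {-30, -12, std::log(tau_min), std::log(tau_min), 0};
  double hi2[5] = {40, 12, std::log(tau1_max), std::log(tau2_max), 1e12};
  double lo1[3] = {-30, std::log(tau_min), 0};
  double hi1[3] = {40, std::log(tau2_max), 1e12};
  const double t2_mul[3] = {1.0, 0.25, 4.0};
  const double f2_mul[3] = {1.0, 0.5, 1.5};

  for (int i = 0; i < npx; ++i) {
    double N = 0;
    for (int j = 0; j < nb; ++j) {
      row[j] = counts(i, j);
      N += row[j];
    }
    out(i, 8) = 0;  // collapsed flag default
    if (N < min_photons) continue;
    double t1_0, t2_0, f2_0, c0;
    init_guess(row.data(), md, tau_min, tau1_max, tau2_max, free_c, c_fix,
               &t1_0, &t2_0, &f2_0, &c0);
    if (!two_comp) {
      // mono-exponential mode: single lifetime in [tau_min, tau2_max]
      const double Nd = std::max(N - c0 * nb, nb * 0.1);
      double tm = std::min(std::max(t2_0 * f2_0 + t1_0 * (1 - f2_0),
                                    tau_min), tau2_max);
      double A0 = Nd / std::max(unit_total_cpp(md, 1.0, tm, tm), 1e-9);
      double p1[3] = {std::log(A0), std::log(tm), c0};
      bool conv1;
      const double f1 = lm_fit(row.data(), md, p1, false, free_c, c_fix,
                               lo1, hi1, npar1, 150, &conv1);
      out(i, 0) = 0.0;
      out(i, 1) = 1.0;
      out(i, 2) = out(i, 3) = std::exp(p1[1]);
      out(i, 4) = free_c ? p1[2] : c_fix;
      out(i, 5) = std::exp(p1[0]);
      out(i, 6) = f1;
      out(i, 7) = conv1 ? 1.0 : 0.0;
      out(i, 8) = 0.0;
      continue;
    }
    double best_p[5], best_f = R_PosInf;
    bool best_conv = false;
    for (int s = 0; s < 3; ++s) {
      double t2s = std::min(std::max(t2_0 * t2_mul[s], tau_min * 2), tau2_max);
      double f2s = std::min(std::max(f2_0 * f2_mul[s], 0.01), 0.99);
      double a2s = (f2s / t2s) / (f2s / t2s + (1 - f2s) / t1_0);
      a2s = std::min(std::max(a2s, 0.01), 0.99);
      const double Nd = std::max(N - c0 * nb, nb * 0.1);
      double A0 = Nd / std::max(unit_total_cpp(md, a2s, t1_0, t2s), 1e-9);
      double p[5] = {std::log(A0), std::log(a2s / (1 - a2s)),
                     std::log(t1_0), std::log(t2s), c0};
      bool conv;
      const double f = lm_fit(row.data(), md, p, true, free_c, c_fix, lo2,
                              hi2, npar2, 150, &conv);
      if (f < best_f) {
        best_f = f;
        best_conv = conv;
        for (int a = 0; a < npar2; ++a) best_p[a] = p[a];
      }
      if (s == 0 && R_finite(restart_chisq) &&
          best_f / std::max(nb - npar2, 1) <= restart_chisq) break;
    }
    if (!R_finite(best_f)) continue;
    double A = std::exp(best_p[0]);
    double a2 = 1.0 / (1.0 + std::exp(-best_p[1]));
    double t1 = std::exp(best_p[2]);
    double t2 = std::exp(best_p[3]);
    double C = free_c ? best_p[4] : c_fix;
    if (t2 < t1) {
      std::swap(t1, t2);
      a2 = 1.0 - a2;
    }
    double a1 = 1.0 - a2;
    const double min_share = std::min(A * a1 * t1, A * a2 * t2);
    bool collapsed = false;
    if (std::min(a1, a2) < min_alpha ||
        (collapse_z > 0 && min_share < collapse_z * std::sqrt(std::max(N, 1.0)))) {
      // mono-exponential refit
      const double tau_w = a1 * t1 + a2 * t2;
      double tm = std::min(std::max(tau_w, tau_min), tau2_max);
      const double Nd = std::max(N - c0 * nb, nb * 0.1);
      double A0 = Nd / std::max(unit_total_cpp(md, 1.0, tm, tm), 1e-9);
      double p1[3] = {std::log(A0), std::log(tm), c0};
      bool conv1;
      const double f1 = lm_fit(row.data(), md, p1, false, free_c, c_fix, lo1,
                               hi1, npar1, 150, &conv1);
      A = std::exp(p1[0]);
      t1 = t2 = std::exp(p1[1]);
      a1 = 0.0;
      a2 = 1.0;
      C = free_c ? p1[2] : c_fix;
      best_f = f1;
      best_conv = conv1;
      collapsed = true;
    }
    out(i, 0) = a1;
    out(i, 1) = a2;
    out(i, 2) = t1;
    out(i, 3) = t2;
    out(i, 4) = C;
    out(i, 5) = A;
    out(i, 6) = best_f;
    out(i, 7) = best_conv ? 1.0 : 0.0;
    out(i, 8) = collapsed ? 1.0 : 0.0;
  }
  return out;
}
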