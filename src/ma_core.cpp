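#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Exact piecewise-exponential update of the multiplicative-adaptation system
// over a binary song raster. Within each raster bin the inputs are constant,
// so the adaptation variables relax exponentially toward the input and the
// activity ODE has a closed-form solution against the resulting
// constant-plus-exponential drive:
//
//   a_m(s) = I_m + (a_m0 - I_m) e^{-s/tau_a}
//   tau_int dr/ds = -r + u(s),  u(s) = A e^{-s/tau_a}
//   with A = x_s (1 - a_s0) I_s + x_p (1 - a_p0) I_p  (modes exclusive)
//   r(dt) = r0 e^{-dt/tau_int} + A tau_a/(tau_a - tau_int)
//                                  (e^{-dt/tau_a} - e^{-dt/tau_int})
//
// tau_a == tau_int uses the degenerate limit A (dt/tau_int) e^{-dt/tau_int};
// tau_a == Inf freezes the adaptation state and the drive is constant over
// the bin: r(dt) = u + (r0 - u) e^{-dt/tau_int}.
//
// Returns the activity (times polarity) at the END of each bin: row b is the
// state at time t0 + b*dt, which depends on inputs in bins 1..b only.

// [[Rcpp::export]]
NumericMatrix ma_core(NumericVector tau_int, NumericVector tau_a,
                      NumericVector x_s, NumericVector x_p,
                      NumericVector polarity,
                      IntegerVector Is, IntegerVector Ip, double dt,
                      NumericVector r0, NumericVector as0, NumericVector ap0) {
  const int T = Is.size();
  const int N = tau_int.size();
  NumericMatrix out(T, N);

  std::vector<double> r(N), as(N), ap(N), Ei(N), Ea(N), ca(N), dti(N);
  std::vector<bool> inf_a(N), degen(N);
  for (int j = 0; j < N; ++j) {
    r[j] = r0[j]; as[j] = as0[j]; ap[j] = ap0[j];
    double ti = tau_int[j], ta = tau_a[j];
    if (ti <= 0) stop("tau_int must be positive");
    Ei[j] = std::exp(-dt / ti);
    dti[j] = dt / ti;
    inf_a[j] = !R_FINITE(ta);
    if (!inf_a[j]) {
      if (ta <= 0) stop("tau_a must be positive (or Inf)");
      Ea[j] = std::exp(-dt / ta);
      degen[j] = std::fabs(ta - ti) < 1e-12 * ti;
      ca[j] = degen[j] ? 0.0 : ta / (ta - ti);
    } else {
      Ea[j] = 1.0; degen[j] = false; ca[j] = 0.0;
    }
  }

  for (int t = 0; t < T; ++t) {
    const double is = (double)Is[t];
    const double ip = (double)Ip[t];
    for (int j = 0; j < N; ++j) {
      const double A = x_s[j] * (1.0 - as[j]) * is + x_p[j] * (1.0 - ap[j]) * ip;
      if (inf_a[j]) {
        // adaptation frozen: constant drive over the bin
        r[j] = A + (r[j] - A) * Ei[j];
      } else {
        if (degen[j]) {
          r[j] = r[j] * Ei[j] + A * dti[j] * Ei[j];
        } else {
          r[j] = r[j] * Ei[j] + A * ca[j] * (Ea[j] - Ei[j]);
        }
        as[j] = is + (as[j] - is) * Ea[j];
        ap[j] = ip + (ap[j] - ip) * Ea[j];
      }
      out(t, j) = polarity[j] * r[j];
    }
  }
  return out;
}
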