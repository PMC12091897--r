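#include <Rcpp.h>
using namespace Rcpp;

// Parameter vector layout (see pr_params() on the R side):
// 0 p, 1 Cm, 2 gc, 3 gL, 4 gNa, 5 gKDR, 6 gCa, 7 gKAHP, 8 gKC,
// 9 VNa, 10 VCa, 11 VK, 12 VL, 13 Is, 14 Id
// State layout: 0 Vs, 1 Vd, 2 h, 3 n, 4 s, 5 c, 6 q, 7 Ca

// x/(exp(x/k)-1) with the removable singularity at x = 0 filled by its
// limit k; guard width 1e-7 mV matches the R reference implementation.
static inline double expm1_ratio(double x, double k) {
  if (std::fabs(x) < 1e-7) return k;
  return x / std::expm1(x / k);
}

static void pr_deriv_raw(const double* y, const double* par, double Ve,
                         double* dy) {
  const double Vs = y[0], Vd = y[1], h = y[2], n = y[3], s = y[4],
               c = y[5], q = y[6], Ca = y[7];
  const double p = par[0], Cm = par[1], gc = par[2], gL = par[3],
               gNa = par[4], gKDR = par[5], gCa = par[6], gKAHP = par[7],
               gKC = par[8], VNa = par[9], VCa = par[10], VK = par[11],
               VL = par[12], Is = par[13], Id = par[14];

  // The DC field enters as a constant membrane depolarization added to the
  // voltage inside every ionic driving force. Gating kinetics (including the
  // instantaneous sodium activation m) are evaluated at the unshifted state
  // voltages: shifting them as well would make the field a pure change of
  // variables with no effect on firing.
  const double vs = Vs + Ve, vd = Vd + Ve;

  const double am = 0.32 * expm1_ratio(13.1 - Vs, 4.0);
  const double bm = 0.28 * expm1_ratio(Vs - 40.1, 5.0);
  const double minf = am / (am + bm);

  const double ah = 0.128 * std::exp((17.0 - Vs) / 18.0);
  const double bh = 4.0 / (1.0 + std::exp((40.0 - Vs) / 5.0));
  const double an = 0.016 * expm1_ratio(35.1 - Vs, 5.0);
  const double bn = 0.25 * std::exp(0.5 - 0.025 * Vs);
  const double as = 1.6 / (1.0 + std::exp(-0.072 * (Vd - 65.0)));
  const double bs = 0.02 * expm1_ratio(Vd - 51.1, 5.0);

  double ac, bc;
  if (Vd <= 50.0) {
    ac = std::exp((Vd - 10.0) / 11.0 - (Vd - 6.5) / 27.0) / 18.975;
    bc = 2.0 * std::exp((6.5 - Vd) / 27.0) - ac;
  } else {
    ac = 2.0 * std::exp((6.5 - Vd) / 27.0);
    bc = 0.0;
  }
  const double aq = std::min(0.00002 * Ca, 0.01);
  const double bq = 0.001;

  const double chi = std::min(Ca / 250.0, 1.0);

  const double IsLeak = gL * (vs - VL);
  const double INa    = gNa * minf * minf * h * (vs - VNa);
  const double IKDR   = gKDR * n * (vs - VK);
  const double IdLeak = gL * (vd - VL);
  const double ICa    = gCa * s * s * (vd - VCa);
  const double IKC    = gKC * c * chi * (vd - VK);
  const double IKAHP  = gKAHP * q * (vd - VK);

  dy[0] = (-IsLeak - INa - IKDR + gc * (Vd - Vs) / p + Is / p) / Cm;
  dy[1] = (-IdLeak - ICa - IKAHP - IKC + gc * (Vs - Vd) / (1.0 - p) +
           Id / (1.0 - p)) / Cm;
  dy[2] = ah * (1.0 - h) - bh * h;
  dy[3] = an * (1.0 - n) - bn * n;
  dy[4] = as * (1.0 - s) - bs * s;
  dy[5] = ac * (1.0 - c) - bc * c;
  dy[6] = aq * (1.0 - q) - bq * q;
  dy[7] = -0.13 * ICa - 0.075 * Ca;
}

// [[Rcpp::export]]
NumericVector pr_deriv_cpp(NumericVector y, NumericVector par, double Ve) {
  NumericVector dy(8);
  pr_deriv_raw(y.begin(), par.begin(), Ve, dy.begin());
  return dy;
}

// Classical RK4 with fixed step. Records the initial state and then every
// `stride`-th step. Integration stops at the first non-finite state; the
// caller decides whether that is an error.
// [[Rcpp::export]]
List pr_integrate_cpp(NumericVector y0, NumericVector par, double Ve,
                      double dt, int nsteps, int stride) {
  const int nrec_max = nsteps / stride + 1;
  NumericMatrix out(nrec_max, 8);
  double y[8], yt[8], k1[8], k2[8], k3[8], k4[8];
  for (int j = 0; j < 8; ++j) { y[j] = y0[j]; out(0, j) = y[j]; }

  int nrec = 1;
  int fail_step = -1;
  const double* pp = par.begin();

  for (int i = 1; i <= nsteps; ++i) {
    pr_deriv_raw(y, pp, Ve, k1);
    for (int j = 0; j < 8; ++j) yt[j] = y[j] + 0.5 * dt * k1[j];
    pr_deriv_raw(yt, pp, Ve, k2);
    for (int j = 0; j < 8; ++j) yt[j] = y[j] + 0.5 * dt * k2[j];
    pr_deriv_raw(yt, pp, Ve, k3);
    for (int j = 0; j < 8; ++j) yt[j] = y[j] + dt * k3[j];
    pr_deriv_raw(yt, pp, Ve, k4);
    bool ok = true;
    for (int j = 0; j < 8; ++j) {
      y[j] += dt * (k1[j] / 6.0 + k2[j] / 3.0 + k3[j] / 3.0 + k4[j] / 6.0);
      if (!std::isfinite(y[j])) ok = false;
    }
    if (!ok) { fail_step = i; break; }
    if (i % stride == 0) {
      for (int j = 0; j < 8; ++j) out(nrec, j) = y[j];
      ++nrec;
    }
  }

  return List::create(_["states"] = out, _["n_recorded"] = nrec,
                      _["diverged"] = fail_step > 0,
                      _["fail_step"] = fail_step);
}
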