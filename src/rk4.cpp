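// Fixed-step classic Runge-Kutta integration of the relaxation-free Bloch
// equation in the rotating frame. The RF field is sampled at the RK4
// sub-stage times, as required for fourth-order accuracy with
// time-dependent driving. Composite pulses are described by a segment
// table; every sub-stage of a step is evaluated on the segment containing
// the step start, so junctions coinciding with grid points do not break
// the order of accuracy within segments.

#include <Rcpp.h>
#include <cmath>

// Segment table columns: type (0 = sech/tanh, 1 = linear sweep, 2 = square),
// omega1m, A, beta, Tp, tc, phic, t_start, t_end.
struct Seg {
  int type;
  double w1m, A, beta, Tp, tc, phic, t0, t1;
};

static void field_at(const Seg& s, double t, double& wx, double& wy) {
  double am, ph;
  switch (s.type) {
    case 0: {
      double x = (2.0 * s.beta / s.Tp) * (t - s.tc);
      am = s.w1m / std::cosh(x);
      // phi = phic + (A Tp / 2 beta) * log(cosh x)
      double lc = (std::fabs(x) > 20.0)
                      ? std::fabs(x) - std::log(2.0)  // overflow-safe tail
                      : std::log(std::cosh(x));
      ph = s.phic + (s.A * s.Tp / (2.0 * s.beta)) * lc;
      break;
    }
    case 1: {
      am = s.w1m;
      double dt = t - s.tc;
      ph = s.phic + (s.A / s.Tp) * dt * dt;
      break;
    }
    default: {
      am = s.w1m;
      ph = s.phic;
      break;
    }
  }
  wx = am * std::cos(ph);
  wy = am * std::sin(ph);
}

static inline void deriv(double Omega, double wx, double wy,
                         const double* M, double* dM) {
  dM[0] = Omega * M[1] - wy * M[2];
  dM[1] = -Omega * M[0] + wx * M[2];
  dM[2] = wy * M[0] - wx * M[1];
}

static int find_seg(const std::vector<Seg>& segs, double t) {
  int n = (int)segs.size();
  for (int i = 0; i < n; ++i) {
    if (t < segs[i].t1 || i == n - 1) {
      if (t >= segs[i].t0 - 1e-12 * (segs[n - 1].t1 - segs[0].t0 + 1e-300))
        return i;
    }
  }
  return n - 1;
}

// [[Rcpp::export]]
Rcpp::List cpp_rk4(Rcpp::NumericMatrix spec, Rcpp::NumericVector M0,
                   double Omega, double t0, double t1, int nsteps,
                   Rcpp::NumericVector eval_times) {
  int nseg = spec.nrow();
  std::vector<Seg> segs(nseg);
  for (int i = 0; i < nseg; ++i) {
    segs[i].type = (int)spec(i, 0);
    segs[i].w1m = spec(i, 1);
    segs[i].A = spec(i, 2);
    segs[i].beta = spec(i, 3);
    segs[i].Tp = spec(i, 4);
    segs[i].tc = spec(i, 5);
    segs[i].phic = spec(i, 6);
    segs[i].t0 = spec(i, 7);
    segs[i].t1 = spec(i, 8);
  }
  double h = (t1 - t0) / nsteps;
  // map requested times to nearest grid indices
  int m = eval_times.size();
  std::vector<long> want(m);
  for (int j = 0; j < m; ++j) {
    long idx = (long)std::floor((eval_times[j] - t0) / h + 0.5);
    if (idx < 0) idx = 0;
    if (idx > nsteps) idx = nsteps;
    want[j] = idx;
  }
  Rcpp::NumericMatrix out(m, 3);
  Rcpp::NumericVector out_t(m);
  double M[3] = {M0[0], M0[1], M0[2]};
  double k1[3], k2[3], k3[3], k4[3], tmp[3];
  // record any requests at index 0
  for (int j = 0; j < m; ++j) {
    if (want[j] == 0) {
      out(j, 0) = M[0]; out(j, 1) = M[1]; out(j, 2) = M[2];
      out_t[j] = t0;
    }
  }
  for (long i = 0; i < nsteps; ++i) {
    double t = t0 + i * h;
    int si = find_seg(segs, t + 0.5 * h);
    const Seg& s = segs[si];
    double wx, wy;
    field_at(s, t, wx, wy);
    deriv(Omega, wx, wy, M, k1);
    field_at(s, t + 0.5 * h, wx, wy);
    for (int q = 0; q < 3; ++q) tmp[q] = M[q] + 0.5 * h * k1[q];
    deriv(Omega, wx, wy, tmp, k2);
    for (int q = 0; q < 3; ++q) tmp[q] = M[q] + 0.5 * h * k2[q];
    deriv(Omega, wx, wy, tmp, k3);
    field_at(s, t + h, wx, wy);
    for (int q = 0; q < 3; ++q) tmp[q] = M[q] + h * k3[q];
    deriv(Omega, wx, wy, tmp, k4);
    for (int q = 0; q < 3; ++q)
      M[q] += h / 6.0 * (k1[q] + 2.0 * k2[q] + 2.0 * k3[q] + k4[q]);
    for (int j = 0; j < m; ++j) {
      if (want[j] == i + 1) {
        out(j, 0) = M[0]; out(j, 1) = M[1]; out(j, 2) = M[2];
        out_t[j] = t0 + (i + 1) * h;
      }
    }
  }
  Rcpp::NumericVector Mf = Rcpp::NumericVector::create(M[0], M[1], M[2]);
  return Rcpp::List::create(Rcpp::Named("times") = out_t,
                            Rcpp::Named("M") = out,
                            Rcpp::Named("Mfinal") = Mf);
}
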