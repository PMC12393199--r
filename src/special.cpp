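// Special-function kernels for the analytic Bloch-Riccati propagators.
//
// The fundamental systems of the hypergeometric ODEs are evaluated in
// extended precision (std::complex<long double>, ~18-19 significant digits
// on x86-64). Maclaurin series are used only where they are well
// conditioned; elsewhere the defining linear ODE is continued analytically
// with adaptive-order Taylor steps. Along the physical evaluation paths
// (real p in (0,1) for the sech/tanh driving function, the rotated real
// line for the linear-sweep driving function) the fundamental matrix has no
// exponential dichotomy, so the continuation is numerically stable.

#include <Rcpp.h>
#include <complex>
#include <vector>
#include <cmath>

typedef std::complex<long double> cplx;
typedef std::complex<double> cpd;

static const long double PIL = 3.141592653589793238462643383279503L;

static inline cpd to_d(const cplx& z) {
  return cpd((double)z.real(), (double)z.imag());
}
static inline cplx to_l(const cpd& z) {
  return cplx((long double)z.real(), (long double)z.imag());
}
static inline cplx to_l(const Rcomplex& z) {
  return cplx((long double)z.r, (long double)z.i);
}

// ---------------------------------------------------------------------------
// Complex log-gamma (Lanczos, g = 607/128, 15 terms) with reflection.
// Imaginary part may be off by multiples of 2*pi; all uses are exponentiated.
static cplx clgamma(cplx z) {
  static const long double g = 607.0L / 128.0L;
  static const long double coef[15] = {
    0.99999999999999709182L,
    57.156235665862923517L,
    -59.597960355475491248L,
    14.136097974741747174L,
    -0.49191381609762019978L,
    0.33994649984811888699e-4L,
    0.46523628927048575665e-4L,
    -0.98374475304879564677e-4L,
    0.15808870322491248884e-3L,
    -0.21026444172410488319e-3L,
    0.21743961811521264320e-3L,
    -0.16431810653676389022e-3L,
    0.84418223983852743293e-4L,
    -0.26190838401581408670e-4L,
    0.36899182659531622704e-5L
  };
  if (z.real() < 0.5L) {
    // reflection: lgamma(z) = log(pi/sin(pi z)) - lgamma(1 - z)
    cplx s = std::sin(cplx(PIL) * z);
    return std::log(cplx(PIL) / s) - clgamma(cplx(1.0L) - z);
  }
  cplx x = z - cplx(1.0L);
  cplx ser(coef[0]);
  for (int k = 1; k < 15; ++k) ser += cplx(coef[k]) / (x + cplx((long double)k));
  cplx t = x + cplx(g + 0.5L);
  return (x + cplx(0.5L)) * std::log(t) - t +
         cplx(0.5L * std::log(2.0L * PIL)) + std::log(ser);
}

// 1/Gamma(z), zero at the poles.
static cplx recip_gamma(cplx z) {
  long double zr = z.real(), zi = z.imag();
  if (std::abs(zi) < 1e-14L && zr <= 0.5L &&
      std::abs(zr - std::floor(zr + 0.5L)) < 1e-14L) {
    return cplx(0.0L);
  }
  return std::exp(-clgamma(z));
}

// ---------------------------------------------------------------------------
// Maclaurin series of the Gauss hypergeometric function 2F1(a,b;c;z).
static cplx hyp2f1_ser(cplx a, cplx b, cplx c, cplx z) {
  cplx term(1.0L), sum(1.0L);
  for (int n = 0; n < 4000; ++n) {
    cplx nn((long double)n);
    term *= (a + nn) * (b + nn) / ((c + nn) * (nn + cplx(1.0L))) * z;
    sum += term;
    if (std::abs(term) < 1e-24L * std::abs(sum) && n > 4) break;
  }
  return sum;
}

// Maclaurin series of Kummer's M(a, b, z) = 1F1(a; b; z).
static cplx hyp1f1_ser(cplx a, cplx b, cplx z) {
  cplx term(1.0L), sum(1.0L);
  for (int n = 0; n < 8000; ++n) {
    cplx nn((long double)n);
    term *= (a + nn) / ((b + nn) * (nn + cplx(1.0L))) * z;
    sum += term;
    if (std::abs(term) < 1e-24L * std::abs(sum) && n > 4) break;
  }
  return sum;
}

// ---------------------------------------------------------------------------
// Taylor-step analytic continuation of the Gauss hypergeometric ODE
//   z(1-z) w'' + [c - (a+b+1) z] w' - a b w = 0
// from z0 (with value/derivative f, f1) to z0+h. Both z real in (0,1).
static void gauss_taylor_step(cplx a, cplx b, cplx c,
                              long double z0, long double h,
                              cplx& f, cplx& f1) {
  const int NMAX = 400;
  std::vector<cplx> co(NMAX + 2);
  co[0] = f;
  co[1] = f1;
  cplx P0(z0 * (1.0L - z0)), P1(1.0L - 2.0L * z0), P2(-1.0L);
  cplx Q0 = c - (a + b + cplx(1.0L)) * cplx(z0);
  cplx Q1 = -(a + b + cplx(1.0L));
  cplx R = -a * b;
  cplx val = co[0] + co[1] * cplx(h);
  cplx der = co[1];
  long double hp = h;  // h^n for term n
  int stall = 0;
  for (int n = 0; n <= NMAX - 2; ++n) {
    cplx nn((long double)n);
    cplx c2 = -((P1 * nn + Q0) * (nn + cplx(1.0L)) * co[n + 1] +
                (P2 * nn * (nn - cplx(1.0L)) + Q1 * nn + R) * co[n]) /
              (P0 * (nn + cplx(2.0L)) * (nn + cplx(1.0L)));
    co[n + 2] = c2;
    hp *= h;  // h^{n+2}
    cplx tv = c2 * cplx(hp);
    cplx td = cplx((long double)(n + 2)) * c2 * cplx(hp / h);
    val += tv;
    der += td;
    long double sc = std::abs(val) + 1e-300L;
    if (std::abs(tv) < 1e-22L * sc) {
      if (++stall >= 3) break;
    } else {
      stall = 0;
    }
  }
  f = val;
  f1 = der;
}

// Continuation of the linear-sweep (Hermite-type) ODE
//   q'' + 2 p q' + lambda q = 0
// from complex p0 to p0+h.
static void chirp_taylor_step(cplx lambda, cplx p0, cplx h,
                              cplx& f, cplx& f1) {
  const int NMAX = 200;
  std::vector<cplx> co(NMAX + 2);
  co[0] = f;
  co[1] = f1;
  cplx val = co[0] + co[1] * h;
  cplx der = co[1];
  cplx hp = h;
  int stall = 0;
  for (int n = 0; n <= NMAX - 2; ++n) {
    cplx nn((long double)n);
    cplx c2 = -(cplx(2.0L) * p0 * (nn + cplx(1.0L)) * co[n + 1] +
                (cplx(2.0L) * nn + lambda) * co[n]) /
              ((nn + cplx(2.0L)) * (nn + cplx(1.0L)));
    co[n + 2] = c2;
    hp *= h;
    cplx tv = c2 * hp;
    val += tv;
    der += cplx((long double)(n + 2)) * c2 * hp / h;
    long double sc = std::abs(val) + 1e-300L;
    if (std::abs(tv) < 1e-22L * sc) {
      if (++stall >= 3) break;
    } else {
      stall = 0;
    }
  }
  f = val;
  f1 = der;
}

// ---------------------------------------------------------------------------
// Exported: Gauss hypergeometric with derivative, by direct series
// (well-conditioned arguments only; used as an independent cross-check).

// [[Rcpp::export]]
Rcpp::List cpp_hyp2f1_series(Rcomplex a_, Rcomplex b_, Rcomplex c_,
                             Rcomplex z_) {
  cplx a = to_l(a_), b = to_l(b_), c = to_l(c_), z = to_l(z_);
  cplx F = hyp2f1_ser(a, b, c, z);
  cplx dF = a * b / c * hyp2f1_ser(a + cplx(1.0L), b + cplx(1.0L),
                                   c + cplx(1.0L), z);
  return Rcpp::List::create(Rcpp::Named("F") = to_d(F),
                            Rcpp::Named("dF") = to_d(dF));
}

// [[Rcpp::export]]
Rcpp::List cpp_kummer_series(Rcomplex a_, Rcomplex b_, Rcomplex z_) {
  cplx a = to_l(a_), b = to_l(b_), z = to_l(z_);
  cplx F = hyp1f1_ser(a, b, z);
  cplx dF = a / b * hyp1f1_ser(a + cplx(1.0L), b + cplx(1.0L), z);
  return Rcpp::List::create(Rcpp::Named("F") = to_d(F),
                            Rcpp::Named("dF") = to_d(dF));
}

// Hermite function of complex order via its Kummer representation
// (moderate |z| only; series conditioning degrades as exp(|z|^2)).
static void hermite_pair(cplx a, cplx z, cplx& H, cplx& dH) {
  cplx z2 = z * z;
  cplx pref = std::exp(a * std::log(cplx(2.0L)) +
                       cplx(0.5L * std::log(PIL)));
  cplx g1 = recip_gamma((cplx(1.0L) - a) / cplx(2.0L));
  cplx g2 = recip_gamma(-a / cplx(2.0L));
  cplx even = hyp1f1_ser(-a / cplx(2.0L), cplx(0.5L), z2);
  cplx odd = hyp1f1_ser((cplx(1.0L) - a) / cplx(2.0L), cplx(1.5L), z2);
  H = pref * (g1 * even - cplx(2.0L) * z * g2 * odd);
  // H_a'(z) = 2 a H_{a-1}(z)
  cplx am = a - cplx(1.0L);
  cplx prefm = std::exp(am * std::log(cplx(2.0L)) +
                        cplx(0.5L * std::log(PIL)));
  cplx g1m = recip_gamma((cplx(1.0L) - am) / cplx(2.0L));
  cplx g2m = recip_gamma(-am / cplx(2.0L));
  cplx evenm = hyp1f1_ser(-am / cplx(2.0L), cplx(0.5L), z2);
  cplx oddm = hyp1f1_ser((cplx(1.0L) - am) / cplx(2.0L), cplx(1.5L), z2);
  cplx Hm = prefm * (g1m * evenm - cplx(2.0L) * z * g2m * oddm);
  dH = cplx(2.0L) * a * Hm;
}

// [[Rcpp::export]]
Rcpp::List cpp_hermite(Rcomplex a_, Rcomplex z_) {
  cplx H, dH;
  hermite_pair(to_l(a_), to_l(z_), H, dH);
  return Rcpp::List::create(Rcpp::Named("H") = to_d(H),
                            Rcpp::Named("dH") = to_d(dH));
}

// [[Rcpp::export]]
Rcomplex cpp_clgamma(Rcomplex z_) {
  cplx r = clgamma(to_l(z_));
  Rcomplex out;
  out.r = (double)r.real();
  out.i = (double)r.imag();
  return out;
}

// ---------------------------------------------------------------------------
// Fundamental system for the sech/tanh driving function on a sorted grid of
// p values in (0,1). Returns an n x 4 complex matrix with columns
// FA, FB, FA', FB' where FA = 2F1(a,b;c;p) and
// FB = p^(1-c) 2F1(a-c+1, b-c+1; 2-c; p).

// pm = 1 - p computed stably by the caller (full relative precision near
// the p -> 1 endpoint); targets above 1/2 are reconstructed from it in
// long double.

// [[Rcpp::export]]
Rcpp::ComplexMatrix cpp_hs1_basis(Rcpp::NumericVector p,
                                  Rcpp::NumericVector pm, Rcomplex a_,
                                  Rcomplex b_, Rcomplex c_) {
  int n = p.size();
  cplx a = to_l(a_), b = to_l(b_), c = to_l(c_);
  Rcpp::ComplexMatrix out(n, 4);
  if (n == 0) return out;
  if (pm.size() != n) Rcpp::stop("p and pm must have equal length");
  for (int i = 0; i < n; ++i) {
    if (!(p[i] > 0.0 && p[i] < 1.0))
      Rcpp::stop("p values must lie strictly inside (0, 1)");
    if (i > 0 && p[i] < p[i - 1]) Rcpp::stop("p values must be sorted");
  }
  // starting point where the Maclaurin series is well conditioned
  long double mu = std::max(std::max(std::abs(a), std::abs(b)),
                            std::max(std::abs(c), (long double)2.0L));
  long double p_init = std::min((long double)p[0],
                                std::min(0.02L, 0.25L / (mu * mu)));
  // FA branch
  cplx FA = hyp2f1_ser(a, b, c, cplx(p_init));
  cplx FA1 = a * b / c *
             hyp2f1_ser(a + cplx(1.0L), b + cplx(1.0L), c + cplx(1.0L),
                        cplx(p_init));
  // FB branch: p^(1-c) * G with G = 2F1(a-c+1, b-c+1; 2-c; p)
  cplx ac = a - c + cplx(1.0L), bc = b - c + cplx(1.0L),
       cc = cplx(2.0L) - c;
  cplx G = hyp2f1_ser(ac, bc, cc, cplx(p_init));
  cplx G1 = ac * bc / cc *
            hyp2f1_ser(ac + cplx(1.0L), bc + cplx(1.0L), cc + cplx(1.0L),
                       cplx(p_init));
  cplx lp = std::log(cplx(p_init));
  cplx pw = std::exp((cplx(1.0L) - c) * lp);
  cplx FB = pw * G;
  cplx FB1 = pw * ((cplx(1.0L) - c) / cplx(p_init) * G + G1);
  long double z0 = p_init;
  for (int i = 0; i < n; ++i) {
    long double target = (p[i] <= 0.5)
                             ? (long double)p[i]
                             : 1.0L - (long double)pm[i];
    while (z0 < target) {
      long double rad = std::min(z0, 1.0L - z0);
      long double h = std::min(target - z0, 0.45L * rad);
      gauss_taylor_step(a, b, c, z0, h, FA, FA1);
      gauss_taylor_step(a, b, c, z0, h, FB, FB1);
      z0 += h;
    }
    out(i, 0) = Rcomplex{(double)FA.real(), (double)FA.imag()};
    out(i, 1) = Rcomplex{(double)FB.real(), (double)FB.imag()};
    out(i, 2) = Rcomplex{(double)FA1.real(), (double)FA1.imag()};
    out(i, 3) = Rcomplex{(double)FB1.real(), (double)FB1.imag()};
  }
  return out;
}

// ---------------------------------------------------------------------------
// Fundamental system for the linear-sweep driving function at complex p
// values ordered along a polyline from the origin outward (the R wrapper
// splits the two rays). Returns n x 4: qA, qB, qA', qB' where
// qA = M((a+1)/2, 1/2, -p^2) and qB = exp(-p^2) H_a(p); both solve
// q'' + 2 p q' + 2(a+1) q = 0.

// [[Rcpp::export]]
Rcpp::ComplexMatrix cpp_chirp_basis(Rcpp::ComplexVector p, Rcomplex a_) {
  int n = p.size();
  cplx a = to_l(a_);
  cplx lambda = cplx(2.0L) * (a + cplx(1.0L));
  Rcpp::ComplexMatrix out(n, 4);
  if (n == 0) return out;
  // initial values at p = 0
  cplx H0, dH0;
  hermite_pair(a, cplx(0.0L), H0, dH0);
  cplx qA(1.0L), qA1(0.0L);
  cplx qB = H0, qB1 = dH0;
  cplx p0(0.0L);
  for (int i = 0; i < n; ++i) {
    cplx target = to_l(p[i]);
    for (;;) {
      cplx d = target - p0;
      long double dist = std::abs(d);
      if (dist < 1e-30L) break;
      long double hmax = 3.0L / (1.0L + std::abs(p0));
      cplx h = (dist <= hmax) ? d : d * cplx(hmax / dist);
      chirp_taylor_step(lambda, p0, h, qA, qA1);
      chirp_taylor_step(lambda, p0, h, qB, qB1);
      p0 += h;
    }
    out(i, 0) = Rcomplex{(double)qA.real(), (double)qA.imag()};
    out(i, 1) = Rcomplex{(double)qB.real(), (double)qB.imag()};
    out(i, 2) = Rcomplex{(double)qA1.real(), (double)qA1.imag()};
    out(i, 3) = Rcomplex{(double)qB1.real(), (double)qB1.imag()};
  }
  return out;
}
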