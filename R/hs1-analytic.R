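#' @include pulse-models.R projection.R
NULL

#' Solver context for the sech/tanh driving function
#'
#' Bundles a pulse, a resonance offset, and the complex parameters of the
#' Gauss hypergeometric fundamental system that solves the transformed
#' Bloch-Riccati equation.
#'
#' @slot pulse an [HS1Pulse-class].
#' @slot Omega resonance offset (rad/s).
#' @slot a,b,c complex hypergeometric parameters; `Re(c) = 1/2` always.
#' @export
setClass("HS1Context", representation(
  pulse = "HS1Pulse", Omega = "numeric",
  a = "complex", b = "complex", c = "complex"))

#' Hypergeometric parameters of the sech/tanh solver
#'
#' With the pulse phase defined as the integral of the FM function
#' (`dphi1/dt = +fm`), the transformed Riccati equation is the Gauss
#' hypergeometric ODE with
#' `a = (Tp / 4 beta) (-i A + sqrt(omega1m^2 - A^2))`,
#' `b = (Tp / 4 beta) (-i A - sqrt(omega1m^2 - A^2))`,
#' `c = 1/2 + i (Tp / 4 beta) (Omega - A)` (principal square root). For
#' `A = 0` these reduce to `a = Tp omega1m / (4 beta) = -b`,
#' `c = 1/2 + i Tp Omega / (4 beta)`. The identities
#' `a + b = -i A Tp / (2 beta)` and
#' `a b = -(Tp / 4 beta)^2 omega1m^2` hold for every branch; when
#' `A > omega1m` both `a` and `b` are purely imaginary.
#'
#' @param pulse an [HS1Pulse-class] object.
#' @param Omega resonance offset (rad/s).
#' @return Named list with complex entries `a`, `b`, `c`.
#' @export
hs1ABC <- function(pulse, Omega) {
  Tp <- pulse@Tp; beta <- pulse@beta; A <- pulse@A
  s <- sqrt(as.complex(pulse@omega1m^2 - A^2))
  k <- Tp / (4 * beta)
  list(a = k * (-1i * A + s), b = k * (-1i * A - s),
       c = 0.5 + 1i * k * (Omega - A))
}

#' @rdname hs1ABC
#' @return `hs1Context()` returns an [HS1Context-class] object.
#' @export
hs1Context <- function(pulse, Omega) {
  abc <- hs1ABC(pulse, Omega)
  new("HS1Context", pulse = pulse, Omega = Omega, a = abc$a, b = abc$b,
      c = abc$c)
}

#' Reparameterized time variable of the sech/tanh solver
#'
#' `p(t) = (1 + tanh((2 beta / Tp) (t - tc))) / 2`, the logistic map of
#' time onto (0, 1); strictly monotone (increasing for `beta > 0`).
#'
#' @param t numeric vector of times (s); any finite time is allowed.
#' @param pulse an [HS1Pulse-class] object.
#' @return Numeric vector of `p` values in (0, 1).
#' @export
hs1P <- function(t, pulse) {
  x <- (2 * pulse@beta / pulse@Tp) * (t - pulse@tc)
  1 / (1 + exp(-2 * x))
}

# p and its stable complement 1 - p
.hs1Pq <- function(t, pulse) {
  x <- (2 * pulse@beta / pulse@Tp) * (t - pulse@tc)
  list(p = 1 / (1 + exp(-2 * x)), pm = 1 / (1 + exp(2 * x)))
}

#' Fundamental solutions of the sech/tanh hypergeometric equation
#'
#' Evaluates the two fundamental solutions about `p = 0`,
#' `FA = 2F1(a, b; c; p)` (the Gauss series, analytic at 0) and
#' `FB = p^(1-c) 2F1(a-c+1, b-c+1; 2-c; p)`, together with their
#' p-derivatives. Values are produced in extended precision by Maclaurin
#' series at well-conditioned arguments and Taylor-series analytic
#' continuation of the hypergeometric ODE elsewhere.
#'
#' @param p numeric vector in (0, 1).
#' @param a,b,c complex parameters (see [hs1ABC()]; `Re(c) = 1/2` in this
#'   package's contexts, so `c` is never a nonpositive integer).
#' @return Data frame with complex columns `FA`, `FB`, `FA1`, `FB1`.
#' @export
hs1Basis <- function(p, a, b, c) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("p must lie strictly inside (0, 1)", call. = FALSE)
  .hs1BasisStable(p, 1 - p, a, b, c)
}

.hs1BasisStable <- function(p, pm, a, b, c) {
  ord <- order(p)
  m <- cpp_hs1_basis(p[ord], pm[ord], as.complex(a), as.complex(b),
                     as.complex(c))
  inv <- order(ord)
  data.frame(FA = m[inv, 1], FB = m[inv, 2], FA1 = m[inv, 3],
             FB1 = m[inv, 4])
}

# coupling factor K(t): f = -K q'/q with K = i (2 beta / Tp) omega1 / omega1m^2
.hs1K <- function(pulse, t) {
  1i * (2 * pulse@beta / pulse@Tp) * evalRF(pulse, t) / pulse@omega1m^2
}

.asF <- function(fKnown) {
  if (is(fKnown, "RiemannPoint")) {
    if (fKnown@atInfinity) complex(real = Inf, imaginary = Inf)
    else fKnown@value
  } else {
    as.complex(fKnown)
  }
}

.projConstant <- function(f0, Fa, Fb, Fa1, Fb1, K) {
  if (is.finite(Re(f0)) && is.finite(Im(f0))) {
    CA <- f0 * Fb + K * Fb1
    CB <- -(f0 * Fa + K * Fa1)
  } else {
    CA <- Fb
    CB <- -Fa
  }
  s <- max(Mod(CA), Mod(CB))
  if (!is.finite(s) || s == 0)
    stop("degenerate particular constant: (CA, CB) vanished numerically",
         call. = FALSE)
  new("ParticularConstant", CA = CA / s, CB = CB / s)
}

#' Particular-solution constant of the sech/tanh solver
#'
#' Determines the projective pair `(CA : CB)` (with `C = CB / CA`) such
#' that the general Riccati solution reproduces a known stereographic
#' coordinate at a known time. Any single known magnetization at any time
#' fixes the trajectory exactly; anchors at the point at infinity and at
#' poles of the solution ratio are handled by the projective representation.
#'
#' @param fKnown known coordinate: a [RiemannPoint-class] or a complex
#'   scalar (non-finite values mean the point at infinity).
#' @param tKnown time at which `fKnown` holds (s).
#' @param ctx an [HS1Context-class] from [hs1Context()].
#' @return A [ParticularConstant-class] object.
#' @export
hs1Particular <- function(fKnown, tKnown, ctx) {
  pq <- .hs1Pq(tKnown, ctx@pulse)
  bs <- .hs1BasisStable(pq$p, pq$pm, ctx@a, ctx@b, ctx@c)
  K <- .hs1K(ctx@pulse, tKnown)
  .projConstant(.asF(fKnown), bs$FA, bs$FB, bs$FA1, bs$FB1, K)
}

#' Evaluate the sech/tanh Riccati solution
#'
#' `f(t) = -i (2 beta / Tp) (omega1(t) / omega1m^2) *
#' (CA FA' + CB FB') / (CA FA + CB FB)`, evaluated as a projective ratio.
#'
#' @param ctx an [HS1Context-class].
#' @param const a [ParticularConstant-class] from [hs1Particular()].
#' @param t numeric vector of evaluation times (s).
#' @return Complex vector of stereographic coordinates; non-finite entries
#'   denote the point at infinity (magnetization at the south pole).
#' @export
hs1Evaluate <- function(ctx, const, t) {
  pq <- .hs1Pq(t, ctx@pulse)
  bs <- .hs1BasisStable(pq$p, pq$pm, ctx@a, ctx@b, ctx@c)
  K <- .hs1K(ctx@pulse, t)
  num <- const@CA * bs$FA1 + const@CB * bs$FB1
  den <- const@CA * bs$FA + const@CB * bs$FB
  -K * num / den
}

setMethod(".riccatiPropagate", "HS1Pulse",
  function(pulse, Omega, f0, tInit, times) {
    if (pulse@omega1m <= 0)
      stop("analytic propagation requires omega1m > 0", call. = FALSE)
    ctx <- hs1Context(pulse, Omega)
    const <- hs1Particular(f0, tInit, ctx)
    hs1Evaluate(ctx, const, times)
  })

# ---------------------------------------------------------------------------
# self-induced transparency closed form (A = 0, on-resonance, from +z)

#' Closed-form polar-angle solution of the non-frequency-modulated sech pulse
#'
#' For `A = 0`, on resonance, starting from equilibrium, the magnetization
#' stays in the y-z plane and its polar angle is
#' `theta(t) = (omega1m Tp / beta) atan(exp((2 beta / Tp) (t - tc)))`,
#' reported here relative to the initial angle at the pulse start. The
#' returned magnetization is `|M| (0, sin theta, cos theta)`.
#'
#' @param t numeric vector of times (s).
#' @param pulse an [HS1Pulse-class] with `A = 0`.
#' @param norm magnetization norm (units of M0).
#' @return List with `theta` (rad, relative to `tStart`) and `M`
#'   (`length(t) x 3` matrix).
#' @seealso [sitAmplitude()] for the 2-pi amplitude, [sitFinalAngle()].
#' @export
sitClosedForm <- function(t, pulse, norm = 1) {
  if (pulse@A != 0)
    stop("the closed form requires a pulse without frequency modulation ",
         "(A = 0)", call. = FALSE)
  th <- function(tt)
    (pulse@omega1m * pulse@Tp / pulse@beta) *
      atan(exp((2 * pulse@beta / pulse@Tp) * (tt - pulse@tc)))
  theta <- th(t) - th(pulse@tStart)
  M <- cbind(0, norm * sin(theta), norm * cos(theta))
  list(theta = theta, M = M)
}

#' Final polar angle of a non-frequency-modulated sech pulse
#'
#' `theta_f = (omega1m Tp / beta) atan(exp((2 beta / Tp) (tEnd - tc)))`,
#' the absolute final angle in the convention where the angle vanishes as
#' `t -> -infinity`. With `omega1m = sitAmplitude(beta, Tp)` and symmetric
#' truncation this equals `2 pi` exactly.
#'
#' @param pulse an [HS1Pulse-class] with `A = 0`.
#' @return Final angle (rad).
#' @export
sitFinalAngle <- function(pulse) {
  if (pulse@A != 0)
    stop("the closed form requires A = 0", call. = FALSE)
  (pulse@omega1m * pulse@Tp / pulse@beta) *
    atan(exp((2 * pulse@beta / pulse@Tp) * (pulse@tEnd - pulse@tc)))
}
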