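#' @include hs1-analytic.R
NULL

#' Solver context for the linear-sweep (chirp) driving function
#'
#' The transformed Riccati equation for a constant-amplitude pulse with a
#' linear frequency sweep is a confluent hypergeometric (Hermite-type)
#' equation `q'' + 2 p q' + 2 (a + 1) q = 0` in the complex time variable
#' `p`, with basis order `a = -1 - i Tp omega1m^2 / (8 A)` (so
#' `Re(a) = -1` exactly).
#'
#' @slot pulse a [ChirpPulse-class].
#' @slot Omega resonance offset (rad/s).
#' @slot a complex basis order.
#' @slot k complex time scale `sqrt(i A / Tp)` (principal branch).
#' @export
setClass("ChirpContext", representation(
  pulse = "ChirpPulse", Omega = "numeric", a = "complex", k = "complex"))

#' @rdname ChirpContext-class
#' @param pulse a [ChirpPulse-class] with `A != 0`.
#' @param Omega resonance offset (rad/s).
#' @return A `ChirpContext` object.
#' @export
chirpContext <- function(pulse, Omega) {
  if (pulse@A == 0)
    stop("the linear-sweep solver requires A != 0; use the square-pulse ",
         "solver instead", call. = FALSE)
  a <- -1 - 1i * pulse@Tp * pulse@omega1m^2 / (8 * pulse@A)
  k <- sqrt(as.complex(1i * pulse@A / pulse@Tp))
  new("ChirpContext", pulse = pulse, Omega = Omega, a = a, k = k)
}

#' Complex reparameterized time of the linear-sweep solver
#'
#' `p(t) = sqrt(i A / Tp) (t - tc + Tp Omega / (2 A))`: an affine map of
#' time onto a rotated line through the origin of the complex plane
#' (direction `exp(i pi / 4)` for `A > 0`), whose shifted origin absorbs
#' the resonance offset.
#'
#' @param t numeric vector of times (s).
#' @param pulse a [ChirpPulse-class] with `A != 0`.
#' @param Omega resonance offset (rad/s).
#' @return Complex vector.
#' @export
chirpP <- function(t, pulse, Omega) {
  if (pulse@A == 0) stop("chirpP requires A != 0", call. = FALSE)
  k <- sqrt(as.complex(1i * pulse@A / pulse@Tp))
  k * (t - pulse@tc + pulse@Tp * Omega / (2 * pulse@A))
}

#' Fundamental solutions of the linear-sweep equation
#'
#' Returns `FA = M((a+1)/2, 1/2, -p^2)` (Kummer confluent hypergeometric)
#' and `FB = H_a(p)` (Hermite function of complex order `a`), with their
#' p-derivatives; `FA` and `FB exp(-p^2)` are the two fundamental solutions
#' of `q'' + 2 p q' + 2 (a + 1) q = 0`. Evaluation is by Taylor-series
#' analytic continuation of that equation from the origin, where both
#' branches have elementary initial data.
#'
#' @param p complex vector of evaluation points.
#' @param a complex basis order.
#' @return Data frame with complex columns `FA`, `FB`, `FA1`, `FB1`.
#' @export
chirpBasis <- function(p, a) {
  q <- .chirpQBasis(p, a)
  ep <- exp(p^2)
  data.frame(FA = q$qA, FB = q$qB * ep, FA1 = q$qA1,
             FB1 = (q$qB1 + 2 * p * q$qB) * ep)
}

# raw q-basis (qA, qB = e^{-p^2} H_a, and derivatives), continued outward
# along each ray from the origin
.chirpQBasis <- function(p, a) {
  n <- length(p)
  out <- matrix(complex(real = NA_real_), n, 4)
  i0 <- which.max(Mod(p))
  d <- if (Mod(p[i0]) > 0) p[i0] / Mod(p[i0]) else complex(real = 1)
  s <- Re(p * Conj(d))  # signed coordinate along the dominant ray
  for (side in c(-1, 1)) {
    sel <- which(if (side < 0) s < 0 else s >= 0)
    if (!length(sel)) next
    ord <- sel[order(abs(s[sel]))]
    m <- cpp_chirp_basis(p[ord], as.complex(a))
    out[ord, ] <- m
  }
  data.frame(qA = out[, 1], qB = out[, 2], qA1 = out[, 3], qB1 = out[, 4])
}

# coupling factor: f = G q'/q with G = -2 i k exp(i phi1) / omega1m
.chirpG <- function(ctx, t) {
  ph <- evalWaveform(ctx@pulse, t)$phase
  -2i * ctx@k * exp(1i * ph) / ctx@pulse@omega1m
}

#' Particular-solution constant of the linear-sweep solver
#'
#' As [hs1Particular()], for the chirp driving function: returns the
#' projective pair `(CA : CB)` reproducing a known stereographic coordinate
#' at a known time, in the basis of [chirpBasis()] (so `C = CB / CA` is the
#' constant multiplying `FB exp(-p^2)`).
#'
#' @param fKnown a [RiemannPoint-class] or complex scalar (non-finite =
#'   point at infinity).
#' @param tKnown anchor time (s).
#' @param ctx a [ChirpContext-class].
#' @return A [ParticularConstant-class].
#' @export
chirpParticular <- function(fKnown, tKnown, ctx) {
  p0 <- chirpP(tKnown, ctx@pulse, ctx@Omega)
  q <- .chirpQBasis(p0, ctx@a)
  G <- .chirpG(ctx, tKnown)
  f0 <- .asF(fKnown)
  if (is.finite(Re(f0)) && is.finite(Im(f0))) {
    CA <- f0 * q$qB - G * q$qB1
    CB <- G * q$qA1 - f0 * q$qA
  } else {
    CA <- q$qB
    CB <- -q$qA
  }
  s <- max(Mod(CA), Mod(CB))
  if (!is.finite(s) || s == 0)
    stop("degenerate particular constant: (CA, CB) vanished numerically",
         call. = FALSE)
  new("ParticularConstant", CA = CA / s, CB = CB / s)
}

#' Evaluate the linear-sweep Riccati solution
#'
#' @param ctx a [ChirpContext-class].
#' @param const a [ParticularConstant-class] from [chirpParticular()].
#' @param t numeric vector of evaluation times (s).
#' @return Complex stereographic coordinates; non-finite entries denote the
#'   point at infinity.
#' @export
chirpEvaluate <- function(ctx, const, t) {
  p <- chirpP(t, ctx@pulse, ctx@Omega)
  q <- .chirpQBasis(p, ctx@a)
  G <- .chirpG(ctx, t)
  num <- const@CA * q$qA1 + const@CB * q$qB1
  den <- const@CA * q$qA + const@CB * q$qB
  G * num / den
}

setMethod(".riccatiPropagate", "ChirpPulse",
  function(pulse, Omega, f0, tInit, times) {
    if (pulse@A == 0) {
      # zero sweep: constant-amplitude pulse; dispatch to the square solver
      sq <- squarePulse(omega1m = pulse@omega1m, phic = pulse@phic,
                        tStart = pulse@tStart, tEnd = pulse@tEnd)
      return(.riccatiPropagate(sq, Omega, f0, tInit, times))
    }
    if (pulse@omega1m <= 0)
      stop("analytic propagation requires omega1m > 0", call. = FALSE)
    ctx <- chirpContext(pulse, Omega)
    const <- chirpParticular(f0, tInit, ctx)
    chirpEvaluate(ctx, const, times)
  })

# ---------------------------------------------------------------------------
# square pulse: elementary solution on the extended complex plane

#' Particular-solution constant of the square-pulse solver
#'
#' For constant amplitude and phase the Riccati solution is
#' `f(t) = (exp(i phic) / omega1m) (-Omega + weff tanh(C + (i/2) t weff))`
#' with `weff = sqrt(Omega^2 + omega1m^2)`; the constant anchored at a
#' known coordinate `fc` at time `tc` is
#' `C = artanh((omega1m exp(-i phic) fc + Omega) / weff) - (i/2) tc weff`
#' (principal branch). Anchors whose artanh argument falls within `1e-10`
#' of a branch point (+1 or -1) are rejected.
#'
#' @param fKnown a [RiemannPoint-class] or complex scalar (non-finite =
#'   point at infinity).
#' @param tKnown anchor time (s).
#' @param pulse a [SquarePulse-class] with `omega1m > 0`.
#' @param Omega resonance offset (rad/s).
#' @return Complex constant `C`.
#' @export
squareParticular <- function(fKnown, tKnown, pulse, Omega) {
  if (pulse@omega1m <= 0)
    stop("squareParticular requires omega1m > 0", call. = FALSE)
  weff <- sqrt(Omega^2 + pulse@omega1m^2)
  f0 <- .asF(fKnown)
  if (is.finite(Re(f0)) && is.finite(Im(f0))) {
    arg <- (pulse@omega1m * exp(-1i * pulse@phic) * f0 + Omega) / weff
    if (min(Mod(arg - 1), Mod(arg + 1)) < 1e-10)
      stop("degenerate anchor: artanh argument at a branch point",
           call. = FALSE)
    C0 <- atanh(arg)
  } else {
    C0 <- complex(imaginary = pi / 2)  # tanh(i pi / 2) is the pole
  }
  C0 - 0.5i * tKnown * weff
}

setMethod(".riccatiPropagate", "SquarePulse",
  function(pulse, Omega, f0, tInit, times) {
    if (pulse@omega1m == 0) {
      # free precession: f' = -i Omega f
      return(.asF(f0) * exp(-1i * Omega * (times - tInit)))
    }
    weff <- sqrt(Omega^2 + pulse@omega1m^2)
    C0 <- squareParticular(f0, tInit, pulse, Omega)
    (exp(1i * pulse@phic) / pulse@omega1m) *
      (-Omega + weff * tanh(C0 + 0.5i * times * weff))
  })
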