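#' @include AllGenerics.R
NULL

.check_support <- function(pulse, t) {
  tol <- .tol_support * (pulse@tEnd - pulse@tStart)
  if (any(t < pulse@tStart - tol | t > pulse@tEnd + tol))
    stop("time outside the pulse support [", pulse@tStart, ", ",
         pulse@tEnd, "] s", call. = FALSE)
  pmin(pmax(t, pulse@tStart), pulse@tEnd)
}

#' Construct an HS1 (hyperbolic-secant) pulse
#'
#' @param omega1m peak Rabi angular frequency (rad/s), nonnegative.
#' @param A frequency-sweep magnitude parameter (rad/s).
#' @param beta signed dimensionless truncation factor; `sech(beta)` is the
#'   fractional amplitude at `tc +/- Tp/2` and the sign sets the sweep
#'   direction.
#' @param Tp characteristic duration (s): twice the interval from `tc` at
#'   which the amplitude falls to `sech(beta)` of its peak.
#' @param tc time of peak amplitude (s); defaults to `Tp / 2`.
#' @param phic RF phase at `tc` (rad).
#' @param tStart,tEnd support interval (s); defaults to the symmetric
#'   truncation `[tc - Tp/2, tc + Tp/2]`. Choosing them independently of
#'   `tc` expresses asymmetric truncation (e.g. half pulses).
#' @return An [HS1Pulse-class] object.
#' @examples
#' hs1Pulse(omega1m = 2 * pi * 2000, A = 2 * pi * 1000, beta = 3, Tp = 5e-3)
#' @export
hs1Pulse <- function(omega1m, A, beta, Tp, tc = Tp / 2, phic = 0,
                     tStart = tc - Tp / 2, tEnd = tc + Tp / 2) {
  new("HS1Pulse", omega1m = omega1m, A = A, beta = beta, Tp = Tp, tc = tc,
      phic = phic, tStart = tStart, tEnd = tEnd)
}

#' Construct an HS1 pulse from time-bandwidth specifications
#'
#' Maps the practitioner-facing parameters (time-bandwidth factor R and
#' fractional truncation) to the waveform parameters: `beta =
#' asech(truncation)` and `A = pi * R / (Tp * tanh(beta))`, inverting the
#' corrected time-bandwidth relation `R = A * Tp * tanh(beta) / pi`.
#'
#' @inheritParams hs1Pulse
#' @param R dimensionless corrected time-bandwidth factor, nonnegative.
#' @param truncation fractional truncation amplitude in (0, 1).
#' @return An [HS1Pulse-class] object satisfying
#'   `timeBandwidth(pulse) == R` to machine precision.
#' @examples
#' p <- hs1FromSpec(omega1m = 2 * pi * 2000, Tp = 5e-3, R = 10,
#'                  truncation = 0.1)
#' timeBandwidth(p)
#' @export
hs1FromSpec <- function(omega1m, Tp, R, truncation, tc = Tp / 2, phic = 0,
                        tStart = tc - Tp / 2, tEnd = tc + Tp / 2) {
  if (!is.finite(truncation) || truncation <= 0 || truncation >= 1)
    stop("truncation must lie strictly inside (0, 1)", call. = FALSE)
  if (R < 0) stop("R must be nonnegative", call. = FALSE)
  beta <- acosh(1 / truncation)  # asech
  A <- pi * R / (Tp * tanh(beta))
  hs1Pulse(omega1m = omega1m, A = A, beta = beta, Tp = Tp, tc = tc,
           phic = phic, tStart = tStart, tEnd = tEnd)
}

#' Construct a chirp pulse
#'
#' @inheritParams hs1Pulse
#' @param A half-sweep magnitude (rad/s); the sweep width over `Tp` is `2 A`.
#' @param Tp duration over which the sweep width is `2 A` (s).
#' @param tc sweep-center time (s); defaults to `Tp / 2`.
#' @return A [ChirpPulse-class] object.
#' @export
chirpPulse <- function(omega1m, A, Tp, tc = Tp / 2, phic = 0,
                       tStart = tc - Tp / 2, tEnd = tc + Tp / 2) {
  new("ChirpPulse", omega1m = omega1m, A = A, Tp = Tp, tc = tc,
      phic = phic, tStart = tStart, tEnd = tEnd)
}

#' Construct a square pulse
#'
#' @inheritParams hs1Pulse
#' @return A [SquarePulse-class] object.
#' @export
squarePulse <- function(omega1m, phic = 0, tStart = 0, tEnd) {
  new("SquarePulse", omega1m = omega1m, phic = phic, tStart = tStart,
      tEnd = tEnd)
}

#' Construct a composite pulse from segments
#'
#' @param segments list of [RFPulse-class] segments on contiguous intervals.
#' @param phaseOffsets additive phase already applied to each segment's
#'   `phic` (rad); recorded for reporting. Defaults to zeros.
#' @return A [CompositePulse-class] object.
#' @export
compositePulse <- function(segments, phaseOffsets = numeric(length(segments))) {
  starts <- vapply(segments, function(s) s@tStart, numeric(1))
  ends <- vapply(segments, function(s) s@tEnd, numeric(1))
  new("CompositePulse", segments = segments, phaseOffsets = phaseOffsets,
      tStart = min(starts), tEnd = max(ends))
}

# ---------------------------------------------------------------------------
# waveform evaluation

#' @describeIn evalWaveform sech amplitude / tanh frequency modulation.
setMethod("evalWaveform", "HS1Pulse", function(pulse, t) {
  t <- .check_support(pulse, t)
  x <- (2 * pulse@beta / pulse@Tp) * (t - pulse@tc)
  am <- pulse@omega1m / cosh(x)
  fm <- pulse@A * tanh(x)
  # log(omega1m / am) = log(cosh x), computed overflow-safely
  lc <- ifelse(abs(x) > 20, abs(x) - log(2), log(cosh(x)))
  phase <- pulse@phic + (pulse@A * pulse@Tp / (2 * pulse@beta)) * lc
  data.frame(t = t, am = am, fm = fm, phase = phase)
})

#' @describeIn evalWaveform constant amplitude, linear frequency sweep.
setMethod("evalWaveform", "ChirpPulse", function(pulse, t) {
  t <- .check_support(pulse, t)
  dt <- t - pulse@tc
  data.frame(t = t, am = rep(pulse@omega1m, length(t)),
             fm = 2 * pulse@A * dt / pulse@Tp,
             phase = pulse@phic + (pulse@A / pulse@Tp) * dt^2)
})

#' @describeIn evalWaveform constant amplitude and phase, zero FM.
setMethod("evalWaveform", "SquarePulse", function(pulse, t) {
  t <- .check_support(pulse, t)
  data.frame(t = t, am = rep(pulse@omega1m, length(t)),
             fm = rep(0, length(t)), phase = rep(pulse@phic, length(t)))
})

#' @describeIn evalWaveform dispatches to the segment containing each time
#'   (later segment at junctions).
setMethod("evalWaveform", "CompositePulse", function(pulse, t) {
  t <- .check_support(pulse, t)
  starts <- vapply(pulse@segments, function(s) s@tStart, numeric(1))
  idx <- pmax(findInterval(t, starts), 1L)
  out <- do.call(rbind, lapply(seq_along(pulse@segments), function(k) {
    sel <- idx == k
    if (!any(sel)) return(NULL)
    evalWaveform(pulse@segments[[k]], t[sel])
  }))
  out[order(out$t), , drop = FALSE]
})

#' @export
#' @describeIn evalRF complex RF amplitude for any pulse type.
setMethod("evalRF", "RFPulse", function(pulse, t) {
  w <- evalWaveform(pulse, t)
  w$am * exp(1i * w$phase)
})

setMethod("pulseSupport", "RFPulse", function(pulse)
  c(pulse@tStart, pulse@tEnd))

setMethod("pulseDuration", "RFPulse", function(pulse)
  pulse@tEnd - pulse@tStart)

#' @describeIn timeBandwidth `A * Tp * tanh(beta) / pi` (truncation-corrected).
setMethod("timeBandwidth", "HS1Pulse", function(pulse)
  pulse@A * pulse@Tp * tanh(pulse@beta) / pi)

#' @describeIn timeBandwidth `A * Tp / pi`.
setMethod("timeBandwidth", "ChirpPulse", function(pulse)
  pulse@A * pulse@Tp / pi)

# ---------------------------------------------------------------------------
# self-induced transparency amplitude

#' Rabi amplitude of the 2-pi self-induced-transparency sech pulse
#'
#' For a non-frequency-modulated sech pulse (A = 0) on resonance, the final
#' polar angle is `(omega1m * Tp / beta) * atan(exp(beta))`; solving for a
#' 2-pi rotation gives `omega1m = 2 * pi * beta / (Tp * atan(exp(beta)))`.
#' In the low-truncation limit (`atan(exp(beta)) -> pi/2`) this approaches
#' `4 * beta / Tp`.
#'
#' @param beta positive truncation factor.
#' @param Tp characteristic duration (s).
#' @return Peak Rabi angular frequency (rad/s).
#' @examples
#' sitAmplitude(beta = 5.3, Tp = 5e-3)
#' @export
sitAmplitude <- function(beta, Tp) {
  if (any(beta <= 0) || any(Tp <= 0))
    stop("beta and Tp must be positive", call. = FALSE)
  2 * pi * beta / (Tp * atan(exp(beta)))
}

# ---------------------------------------------------------------------------
# BIR-4 builder

#' Build a BIR-4 composite pulse from a half-HS1 template
#'
#' The B1-insensitive rotation pulse BIR-4 is assembled from four
#' asymmetrically truncated half-HS1 segments of equal duration `Tp/2`
#' (total duration `2 * Tp`): amplitude descends from its peak to the
#' truncation level, ascends back to a peak at the composite midpoint, and
#' repeats. The frequency sweep follows the template's tanh branch within
#' each half, with sign reversals at the outer junctions. Inter-segment
#' phase shifts of `pi + theta / 2`, applied to segments 2 and 3 and removed
#' for segment 4, set the net flip angle `theta`.
#'
#' @param theta target flip angle (rad).
#' @param component symmetric [HS1Pulse-class] template supplying `omega1m`,
#'   `A`, `beta`, `Tp`, and the base phase of each half-pulse.
#' @param tStart start time of the composite (s).
#' @return A [CompositePulse-class] of total duration `2 * component Tp`.
#' @examples
#' tmpl <- hs1FromSpec(omega1m = 2 * pi * 2000, Tp = 5e-3, R = 32,
#'                     truncation = 0.1)
#' bir4 <- makeBir4(pi / 2, tmpl)
#' pulseDuration(bir4)  # 10 ms
#' @export
makeBir4 <- function(theta, component, tStart = 0) {
  stopifnot(is(component, "HS1Pulse"))
  w1m <- component@omega1m
  A <- component@A
  beta <- abs(component@beta)
  Tp <- component@Tp
  phi0 <- component@phic
  dphi <- pi + theta / 2
  t0 <- tStart
  half <- Tp / 2
  seg <- function(tc, phic, a, b) {
    hs1Pulse(omega1m = w1m, A = A, beta = beta, Tp = Tp, tc = tc,
             phic = phic, tStart = a, tEnd = b)
  }
  segs <- list(
    seg(t0,            phi0,        t0,            t0 + half),
    seg(t0 + 2 * half, phi0 + dphi, t0 + half,     t0 + 2 * half),
    seg(t0 + 2 * half, phi0 + dphi, t0 + 2 * half, t0 + 3 * half),
    seg(t0 + 4 * half, phi0,        t0 + 3 * half, t0 + 4 * half))
  compositePulse(segs, phaseOffsets = c(0, dphi, dphi, 0))
}

# ---------------------------------------------------------------------------
# show methods

setMethod("show", "HS1Pulse", function(object) {
  cat(sprintf(
    "HS1Pulse: omega1m/2pi = %.6g Hz, A/2pi = %.6g Hz, beta = %.6g\n",
    object@omega1m / (2 * pi), object@A / (2 * pi), object@beta))
  cat(sprintf("  Tp = %.6g s, tc = %.6g s, phic = %.6g rad\n",
              object@Tp, object@tc, object@phic))
  cat(sprintf("  support [%.6g, %.6g] s, R = %.6g, truncation = %.4g\n",
              object@tStart, object@tEnd, timeBandwidth(object),
              1 / cosh(object@beta)))
  invisible(object)
})

setMethod("show", "ChirpPulse", function(object) {
  cat(sprintf("ChirpPulse: omega1m/2pi = %.6g Hz, A/2pi = %.6g Hz\n",
              object@omega1m / (2 * pi), object@A / (2 * pi)))
  cat(sprintf("  Tp = %.6g s, tc = %.6g s, phic = %.6g rad, support [%.6g, %.6g] s\n",
              object@Tp, object@tc, object@phic, object@tStart, object@tEnd))
  invisible(object)
})

setMethod("show", "SquarePulse", function(object) {
  cat(sprintf(
    "SquarePulse: omega1m/2pi = %.6g Hz, phic = %.6g rad, support [%.6g, %.6g] s\n",
    object@omega1m / (2 * pi), object@phic, object@tStart, object@tEnd))
  invisible(object)
})

setMethod("show", "CompositePulse", function(object) {
  cat(sprintf("CompositePulse: %d segments, support [%.6g, %.6g] s\n",
              length(object@segments), object@tStart, object@tEnd))
  for (k in seq_along(object@segments)) {
    s <- object@segments[[k]]
    cat(sprintf("  [%d] %s on [%.6g, %.6g] s, phase offset %.4g rad\n", k,
                class(s), s@tStart, s@tEnd, object@phaseOffsets[k]))
  }
  invisible(object)
})

setMethod("show", "Trajectory", function(object) {
  n <- length(object@times)
  cat(sprintf("Trajectory (%s): %d samples on [%.6g, %.6g] s, |M| = %.6g\n",
              object@provenance, n, object@times[1], object@times[n],
              object@norm))
  invisible(object)
})

setMethod("show", "Isochromat", function(object) {
  cat(sprintf("Isochromat: offset/2pi = %.6g Hz, M = (%.4g, %.4g, %.4g)\n",
              object@offset / (2 * pi), object@M[1], object@M[2],
              object@M[3]))
  invisible(object)
})

setMethod("show", "RiemannPoint", function(object) {
  if (object@atInfinity) {
    cat(sprintf("RiemannPoint: at infinity (south pole), |M| = %.6g\n",
                object@norm))
  } else {
    cat(sprintf("RiemannPoint: f = %.6g%+.6gi, |M| = %.6g\n",
                Re(object@value), Im(object@value), object@norm))
  }
  invisible(object)
})
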