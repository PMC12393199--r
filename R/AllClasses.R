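#' @include BlochRiccati-package.R
NULL

.tol_support <- 1e-9

#' Virtual parent class for RF pulse waveforms
#'
#' All pulse classes carry a closed support interval `[tStart, tEnd]` (s) on
#' which the waveform may be evaluated. Truncated pulses have finite
#' amplitude at the boundaries, so evaluation exactly at the endpoints is
#' allowed.
#'
#' @slot tStart numeric; start of the support interval (s).
#' @slot tEnd numeric; end of the support interval (s).
#' @export
setClass("RFPulse", representation("VIRTUAL",
  tStart = "numeric", tEnd = "numeric"))

setValidity("RFPulse", function(object) {
  if (length(object@tStart) != 1 || length(object@tEnd) != 1)
    return("tStart and tEnd must be scalars")
  if (!is.finite(object@tStart) || !is.finite(object@tEnd))
    return("tStart and tEnd must be finite")
  if (object@tStart >= object@tEnd)
    return("tStart must be strictly less than tEnd")
  TRUE
})

#' Hyperbolic-secant (HS1) pulse
#'
#' Amplitude modulation `omega1m * sech((2 beta / Tp) (t - tc))`, frequency
#' modulation `A * tanh((2 beta / Tp) (t - tc))`, and phase
#' `phic + (A Tp / 2 beta) * log(omega1m / am(t))`. `beta` is the signed
#' dimensionless truncation factor: `sech(beta)` is the fractional amplitude
#' at the symmetric boundaries `tc +/- Tp/2`, and its sign sets the sweep
#' direction. Asymmetric truncation is expressed through a support interval
#' `[tStart, tEnd]` chosen independently of `tc`.
#'
#' @slot omega1m numeric; peak Rabi angular frequency (rad/s), `>= 0`.
#' @slot A numeric; frequency-sweep magnitude parameter (rad/s).
#' @slot beta numeric; signed dimensionless truncation factor, nonzero.
#' @slot Tp numeric; characteristic duration (s), `> 0`.
#' @slot tc numeric; time of peak amplitude (s).
#' @slot phic numeric; RF phase at `tc` (rad).
#' @export
setClass("HS1Pulse", contains = "RFPulse", representation(
  omega1m = "numeric", A = "numeric", beta = "numeric",
  Tp = "numeric", tc = "numeric", phic = "numeric"))

setValidity("HS1Pulse", function(object) {
  if (object@omega1m < 0) return("omega1m must be nonnegative")
  if (object@Tp <= 0) return("Tp must be positive")
  if (object@beta == 0) return("beta must be nonzero")
  TRUE
})

#' Chirp pulse
#'
#' Constant amplitude `omega1m` with a linear frequency sweep
#' `2 A (t - tc) / Tp` and quadratic phase `phic + (A / Tp) (t - tc)^2`.
#' `Tp` is the duration over which the sweep width is `2 A`.
#'
#' @slot omega1m numeric; Rabi angular frequency (rad/s), `>= 0`.
#' @slot A numeric; half-sweep magnitude (rad/s).
#' @slot Tp numeric; sweep-reference duration (s), `> 0`.
#' @slot tc numeric; sweep-center time (s).
#' @slot phic numeric; phase at `tc` (rad).
#' @export
setClass("ChirpPulse", contains = "RFPulse", representation(
  omega1m = "numeric", A = "numeric", Tp = "numeric",
  tc = "numeric", phic = "numeric"))

setValidity("ChirpPulse", function(object) {
  if (object@omega1m < 0) return("omega1m must be nonnegative")
  if (object@Tp <= 0) return("Tp must be positive")
  TRUE
})

#' Square pulse
#'
#' Constant amplitude and phase, zero frequency modulation.
#'
#' @slot omega1m numeric; Rabi angular frequency (rad/s), `>= 0`.
#' @slot phic numeric; phase (rad).
#' @export
setClass("SquarePulse", contains = "RFPulse", representation(
  omega1m = "numeric", phic = "numeric"))

setValidity("SquarePulse", function(object) {
  if (object@omega1m < 0) return("omega1m must be nonnegative")
  TRUE
})

#' Composite pulse
#'
#' An ordered list of pulse segments on contiguous, non-overlapping time
#' intervals. Per-segment additive phase offsets (already folded into each
#' segment's `phic`) are retained in `phaseOffsets` for reporting.
#'
#' @slot segments list of `RFPulse` objects in temporal order.
#' @slot phaseOffsets numeric; additive phase applied to each segment (rad).
#' @export
setClass("CompositePulse", contains = "RFPulse", representation(
  segments = "list", phaseOffsets = "numeric"))

setValidity("CompositePulse", function(object) {
  segs <- object@segments
  if (length(segs) < 1) return("at least one segment is required")
  if (!all(vapply(segs, is, logical(1), class2 = "RFPulse")))
    return("all segments must be RFPulse objects")
  if (length(object@phaseOffsets) != length(segs))
    return("phaseOffsets must have one entry per segment")
  starts <- vapply(segs, function(s) s@tStart, numeric(1))
  ends <- vapply(segs, function(s) s@tEnd, numeric(1))
  dur <- object@tEnd - object@tStart
  if (length(segs) > 1) {
    gap <- abs(starts[-1] - ends[-length(ends)])
    if (any(gap > .tol_support * dur))
      return("segment intervals must be contiguous and non-overlapping")
  }
  if (abs(starts[1] - object@tStart) > .tol_support * dur ||
      abs(ends[length(ends)] - object@tEnd) > .tol_support * dur)
    return("segment intervals must span the composite support")
  if (abs(sum(ends - starts) - dur) > .tol_support * dur)
    return("total duration must equal the sum of segment durations")
  TRUE
})

#' Isochromat: one resonance offset with its magnetization state
#'
#' The magnetization is a 3-vector in units of the equilibrium magnetization
#' M0, with conserved norm `|M|` in `(0, 1]`.
#'
#' @slot offset numeric; resonance offset Omega = omega0 - omegac (rad/s).
#' @slot M numeric(3); magnetization components (units of M0).
#' @export
setClass("Isochromat", representation(offset = "numeric", M = "numeric"))

setValidity("Isochromat", function(object) {
  if (length(object@offset) != 1 || !is.finite(object@offset))
    return("offset must be a finite scalar")
  if (length(object@M) != 3 || any(!is.finite(object@M)))
    return("M must be a finite 3-vector")
  nrm <- sqrt(sum(object@M^2))
  if (nrm <= 0) return("magnetization norm must be positive")
  if (nrm > 1 + 1e-9) return("magnetization norm must not exceed 1 (in M0)")
  TRUE
})

#' Point on the extended complex plane (Riemann sphere)
#'
#' Stereographic image `f = (Mx + i My) / (|M| + Mz)` of a magnetization
#' vector; the south pole maps to the point at infinity. The norm `|M|` is
#' carried so that inversion is well defined.
#'
#' @slot value complex scalar; the finite coordinate (ignored at infinity).
#' @slot atInfinity logical; `TRUE` for the point at infinity.
#' @slot norm numeric; the magnetization norm `|M|` (units of M0).
#' @export
setClass("RiemannPoint", representation(
  value = "complex", atInfinity = "logical", norm = "numeric"))

setValidity("RiemannPoint", function(object) {
  if (length(object@atInfinity) != 1) return("atInfinity must be a scalar")
  if (!object@atInfinity &&
      (length(object@value) != 1 || !is.finite(Re(object@value)) ||
       !is.finite(Im(object@value))))
    return("finite points need a finite complex value")
  if (length(object@norm) != 1 || !is.finite(object@norm) ||
      object@norm <= 0)
    return("norm must be a positive scalar")
  TRUE
})

#' Projective pair encoding the particular-solution constant
#'
#' The integration constant of a particular Riccati solution is
#' `C = CB / CA` on the extended complex plane; the pair `(CA : CB)` is
#' stored projectively so anchors at poles and zeros of the solution ratio
#' remain representable.
#'
#' @slot CA complex scalar.
#' @slot CB complex scalar.
#' @export
setClass("ParticularConstant", representation(CA = "complex", CB = "complex"))

setValidity("ParticularConstant", function(object) {
  if (length(object@CA) != 1 || length(object@CB) != 1)
    return("CA and CB must be scalars")
  if (!is.finite(Mod(object@CA)) || !is.finite(Mod(object@CB)))
    return("CA and CB must be finite")
  if (Mod(object@CA) == 0 && Mod(object@CB) == 0)
    return("(CA, CB) must not both vanish")
  TRUE
})

#' Magnetization trajectory
#'
#' Ordered `(time, magnetization)` samples produced by a propagator, with a
#' provenance tag recording which solver generated them.
#'
#' @slot times numeric; strictly increasing sample times (s).
#' @slot M matrix; `length(times) x 3` magnetization samples (units of M0).
#' @slot norm numeric; common magnetization norm of all samples.
#' @slot provenance character; one of `"analytic-hs1"`, `"analytic-chirp"`,
#'   `"analytic-square"`, `"analytic-composite"`, `"rk4"`,
#'   `"sit-closed-form"`.
#' @export
setClass("Trajectory", representation(
  times = "numeric", M = "matrix", norm = "numeric",
  provenance = "character"))

setValidity("Trajectory", function(object) {
  n <- length(object@times)
  if (n < 1) return("at least one sample is required")
  if (n > 1 && any(diff(object@times) <= 0))
    return("sample times must be strictly increasing")
  if (!is.numeric(object@M) || nrow(object@M) != n || ncol(object@M) != 3)
    return("M must be a numeric length(times) x 3 matrix")
  if (length(object@norm) != 1 || object@norm <= 0)
    return("norm must be a positive scalar")
  TRUE
})
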