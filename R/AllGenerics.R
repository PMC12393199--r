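#' @include AllClasses.R
NULL

#' Evaluate the AM, FM, and phase functions of a pulse
#'
#' @param pulse an [RFPulse-class] object.
#' @param t numeric vector of times within the pulse support (s).
#' @return A data frame with columns `t` (s), `am` (rad/s), `fm` (rad/s),
#'   and `phase` (rad).
#' @examples
#' p <- hs1Pulse(omega1m = 2 * pi * 2000, A = 2 * pi * 1000, beta = 3,
#'               Tp = 5e-3)
#' evalWaveform(p, c(0, 2.5e-3, 5e-3))
#' @export
setGeneric("evalWaveform", function(pulse, t) standardGeneric("evalWaveform"))

#' Evaluate the complex RF amplitude of a pulse
#'
#' Returns `am(t) * exp(1i * phase(t))`, the rotating-frame RF field in
#' angular units.
#'
#' @inheritParams evalWaveform
#' @return Complex vector (rad/s).
#' @export
setGeneric("evalRF", function(pulse, t) standardGeneric("evalRF"))

#' Support interval of a pulse
#'
#' @param pulse an [RFPulse-class] object.
#' @return Numeric length-2 vector `c(tStart, tEnd)` (s).
#' @export
setGeneric("pulseSupport", function(pulse) standardGeneric("pulseSupport"))

#' Pulse duration
#'
#' @param pulse an [RFPulse-class] object.
#' @return Support length in seconds.
#' @export
setGeneric("pulseDuration", function(pulse) standardGeneric("pulseDuration"))

#' Corrected time-bandwidth factor
#'
#' For the sech/tanh pulse this is `A * Tp * tanh(beta) / pi`: the truncated
#' sweep width (Hz) times the duration. For the chirp pulse the convention
#' `A * Tp / pi` is used, the limit of the former at negligible truncation.
#'
#' @param pulse an [HS1Pulse-class] or [ChirpPulse-class] object.
#' @return Dimensionless time-bandwidth factor R.
#' @export
setGeneric("timeBandwidth", function(pulse) standardGeneric("timeBandwidth"))

#' Propagate an isochromat analytically through a pulse
#'
#' Projects the initial magnetization onto the extended complex plane,
#' determines the particular-solution constant from the state at `tInit`,
#' evaluates the closed-form Riccati solution at the requested times, and
#' projects back. The magnetization norm is conserved identically.
#'
#' @param pulse an [RFPulse-class] object.
#' @param iso an [Isochromat-class]; its magnetization is the known state at
#'   `tInit`.
#' @param evalTimes numeric vector of strictly increasing evaluation times
#'   within the pulse support (s).
#' @param tInit anchoring time at which `iso`'s magnetization holds; defaults
#'   to the start of the pulse support. For composite pulses the anchor is
#'   always the composite start.
#' @return A [Trajectory-class] object.
#' @examples
#' p <- hs1FromSpec(omega1m = 2 * pi * 2000, Tp = 5e-3, R = 10,
#'                  truncation = 0.1)
#' iso <- isochromat(offset = 0)
#' tr <- propagate(p, iso, seq(0, 5e-3, length.out = 11))
#' trajM(tr)[11, ]  # adiabatic inversion: Mz close to -1
#' @export
setGeneric("propagate",
  function(pulse, iso, evalTimes, tInit = NULL)
    standardGeneric("propagate"))

#' Propagate an isochromat numerically with fixed-step RK4
#'
#' Classic fourth-order Runge-Kutta integration of the rotating-frame Bloch
#' equation with the RF field sampled at the sub-stage times. Requested
#' evaluation times are snapped to the nearest grid point.
#'
#' @inheritParams propagate
#' @param nSteps number of uniform steps over `[tInit, tFinal]`.
#' @param tInit,tFinal integration window; defaults to the pulse support.
#' @return A [Trajectory-class] object with provenance `"rk4"`.
#' @export
setGeneric("propagateRK4",
  function(pulse, iso, nSteps, evalTimes = NULL, tInit = NULL,
           tFinal = NULL)
    standardGeneric("propagateRK4"))

# internal: closed-form Riccati propagation of a stereographic coordinate.
# f0 is complex (may be Inf for the point at infinity); returns complex
# values (non-finite = point at infinity) at `times`.
setGeneric(".riccatiPropagate",
  function(pulse, Omega, f0, tInit, times)
    standardGeneric(".riccatiPropagate"))

# internal: segment table consumed by the C++ RK4 kernel.
setGeneric(".segmentTable", function(pulse) standardGeneric(".segmentTable"))
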