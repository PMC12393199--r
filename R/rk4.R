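#' @include chirp-square-analytic.R
NULL

setMethod(".segmentTable", "HS1Pulse", function(pulse)
  matrix(c(0, pulse@omega1m, pulse@A, pulse@beta, pulse@Tp, pulse@tc,
           pulse@phic, pulse@tStart, pulse@tEnd), nrow = 1))

setMethod(".segmentTable", "ChirpPulse", function(pulse)
  matrix(c(1, pulse@omega1m, pulse@A, 1, pulse@Tp, pulse@tc, pulse@phic,
           pulse@tStart, pulse@tEnd), nrow = 1))

setMethod(".segmentTable", "SquarePulse", function(pulse)
  matrix(c(2, pulse@omega1m, 0, 1, 1, 0, pulse@phic, pulse@tStart,
           pulse@tEnd), nrow = 1))

setMethod(".segmentTable", "CompositePulse", function(pulse)
  do.call(rbind, lapply(pulse@segments, .segmentTable)))

#' Rotating-frame Bloch derivative
#'
#' Right-hand side of the relaxation-free Bloch equation
#' `dM/dt = (Omega My - w1y Mz, -Omega Mx + w1x Mz, w1y Mx - w1x My)` with
#' `w1x = am cos(phase)`, `w1y = am sin(phase)` taken from the pulse
#' waveform at time `t`. The matrix is skew-symmetric, so
#' `M . dM/dt = 0` and the norm is conserved by the continuous dynamics.
#'
#' @param M numeric magnetization 3-vector.
#' @param t time within the pulse support (s).
#' @param pulse an [RFPulse-class] object.
#' @param Omega resonance offset (rad/s).
#' @return Numeric 3-vector `dM/dt` (units of M0 per second).
#' @export
blochDerivative <- function(M, t, pulse, Omega) {
  w <- evalWaveform(pulse, t)
  wx <- w$am * cos(w$phase)
  wy <- w$am * sin(w$phase)
  c(Omega * M[2] - wy * M[3],
    -Omega * M[1] + wx * M[3],
    wy * M[1] - wx * M[2])
}

#' @describeIn propagateRK4 fixed-step RK4 for any pulse type (composite
#'   segments are honoured per step).
setMethod("propagateRK4", "RFPulse",
  function(pulse, iso, nSteps, evalTimes = NULL, tInit = NULL,
           tFinal = NULL) {
    sup <- pulseSupport(pulse)
    if (is.null(tInit)) tInit <- sup[1]
    if (is.null(tFinal)) tFinal <- sup[2]
    if (nSteps < 1) stop("nSteps must be at least 1", call. = FALSE)
    if (tFinal <= tInit) stop("tFinal must exceed tInit", call. = FALSE)
    if (is.null(evalTimes)) evalTimes <- tFinal
    .check_support(pulse, c(tInit, tFinal, evalTimes))
    res <- cpp_rk4(.segmentTable(pulse), iso@M, iso@offset, tInit, tFinal,
                   as.integer(nSteps), evalTimes)
    tt <- res$times
    if (any(duplicated(tt)))
      stop("evalTimes snap to duplicate RK4 grid points; increase nSteps ",
           "or thin evalTimes", call. = FALSE)
    new("Trajectory", times = tt, M = res$M,
        norm = sqrt(sum(iso@M^2)), provenance = "rk4")
  })
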