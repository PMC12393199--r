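#' @include rk4.R
NULL

.analyticTrajectory <- function(pulse, iso, evalTimes, tInit, provenance) {
  if (length(evalTimes) > 1 && any(diff(evalTimes) <= 0))
    stop("evalTimes must be strictly increasing", call. = FALSE)
  sup <- pulseSupport(pulse)
  if (is.null(tInit)) tInit <- sup[1]
  .check_support(pulse, c(tInit, evalTimes))
  norm <- sqrt(sum(iso@M^2))
  f0 <- .projectC(iso@M, norm)
  f <- .riccatiPropagate(pulse, iso@offset, f0, tInit, evalTimes)
  new("Trajectory", times = evalTimes, M = .unprojectC(f, norm),
      norm = norm, provenance = provenance)
}

#' @describeIn propagate Gauss-hypergeometric solution for the sech/tanh
#'   pulse.
setMethod("propagate", "HS1Pulse",
  function(pulse, iso, evalTimes, tInit = NULL)
    .analyticTrajectory(pulse, iso, evalTimes, tInit, "analytic-hs1"))

#' @describeIn propagate confluent-hypergeometric solution for the
#'   linear-sweep pulse (falls back to the square solver when `A = 0`).
setMethod("propagate", "ChirpPulse",
  function(pulse, iso, evalTimes, tInit = NULL)
    .analyticTrajectory(pulse, iso, evalTimes, tInit, "analytic-chirp"))

#' @describeIn propagate elementary solution for the square pulse.
setMethod("propagate", "SquarePulse",
  function(pulse, iso, evalTimes, tInit = NULL)
    .analyticTrajectory(pulse, iso, evalTimes, tInit, "analytic-square"))

setMethod(".riccatiPropagate", "CompositePulse",
  function(pulse, Omega, f0, tInit, times) {
    segs <- pulse@segments
    nseg <- length(segs)
    if (abs(tInit - pulse@tStart) >
          .tol_support * (pulse@tEnd - pulse@tStart))
      stop("composite propagation anchors at the composite start; supply ",
           "the magnetization there", call. = FALSE)
    starts <- vapply(segs, function(s) s@tStart, numeric(1))
    idx <- pmax(findInterval(times, starts), 1L)
    f <- f0
    out <- complex(length(times))
    for (k in seq_len(nseg)) {
      sel <- which(idx == k)
      tq <- times[sel]
      # evaluate requested times plus the junction for the hand-off;
      # the hand-off uses the analytic coordinate, not a re-projection
      tk <- c(tq, if (k < nseg) segs[[k]]@tEnd)
      if (length(tk)) {
        vals <- .riccatiPropagate(segs[[k]], Omega, f, segs[[k]]@tStart, tk)
        if (length(tq)) out[sel] <- vals[seq_along(tq)]
        if (k < nseg) f <- vals[length(tk)]
      }
    }
    out
  })

#' @describeIn propagate chains the analytic segment solutions of a
#'   composite pulse: each segment's particular constant is anchored at the
#'   segment start with the coordinate inherited from the previous segment
#'   end, so the trajectory is continuous at junctions.
setMethod("propagate", "CompositePulse",
  function(pulse, iso, evalTimes, tInit = NULL)
    .analyticTrajectory(pulse, iso, evalTimes, tInit, "analytic-composite"))

# ---------------------------------------------------------------------------

#' Accessors for trajectories
#'
#' @param traj a [Trajectory-class] object.
#' @return `trajTimes()`: numeric sample times (s); `trajM()`: the
#'   `n x 3` magnetization matrix; `trajProvenance()`: the solver tag.
#' @export
trajTimes <- function(traj) traj@times

#' @rdname trajTimes
#' @export
trajM <- function(traj) traj@M

#' @rdname trajTimes
#' @export
trajProvenance <- function(traj) traj@provenance

#' @export
#' @method as.data.frame Trajectory
as.data.frame.Trajectory <- function(x, ...) {
  data.frame(t_s = x@times, Mx = x@M[, 1], My = x@M[, 2], Mz = x@M[, 3],
             Mxy_abs = sqrt(x@M[, 1]^2 + x@M[, 2]^2))
}

#' Compare two trajectories sample by sample
#'
#' Matches the two time grids (to a relative tolerance of 1e-12 of the time
#' scale) and reports the frame-independent angular error at each shared
#' sample, together with its mean, maximum, and final value. Symmetric in
#' its arguments and invariant under a common rotation of both inputs.
#'
#' @param traj1,traj2 [Trajectory-class] objects on identical grids or
#'   grids with a common subset.
#' @return List with `perSample` (data frame `t`, `error`), `mean`, `max`,
#'   and `final` (radians).
#' @export
compareTrajectories <- function(traj1, traj2) {
  scale <- max(abs(c(traj1@times, traj2@times)), 1e-300)
  key <- function(tt) round(tt / scale, 12)
  m <- match(key(traj1@times), key(traj2@times))
  sel <- which(!is.na(m))
  if (!length(sel))
    stop("trajectories share no common sample times", call. = FALSE)
  errs <- vapply(seq_along(sel), function(i)
    angularError(traj1@M[sel[i], ], traj2@M[m[sel[i]], ]), numeric(1))
  list(perSample = data.frame(t = traj1@times[sel], error = errs),
       mean = mean(errs), max = max(errs), final = errs[length(errs)])
}

#' Convergence of the RK4 oracle toward an analytic solution
#'
#' Propagates the isochromat analytically to the end of the pulse and
#' reports the final angular error of fixed-step RK4 runs with increasing
#' step counts. For a smooth driving function the error decreases with the
#' fourth power of the step count until it reaches the precision floor of
#' the analytic evaluation.
#'
#' @param pulse an [RFPulse-class] object.
#' @param iso an [Isochromat-class] anchored at the pulse start.
#' @param stepCounts increasing integer vector of RK4 step counts.
#' @return Data frame with columns `nSteps` and `finalError` (rad).
#' @seealso [fitLogLogSlope()]
#' @export
convergenceReport <- function(pulse, iso, stepCounts) {
  if (any(diff(stepCounts) <= 0))
    stop("stepCounts must be increasing", call. = FALSE)
  sup <- pulseSupport(pulse)
  Ma <- trajM(propagate(pulse, iso, sup[2]))[1, ]
  errs <- vapply(stepCounts, function(n) {
    Mr <- trajM(propagateRK4(pulse, iso, nSteps = n))[1, ]
    angularError(Ma, Mr)
  }, numeric(1))
  data.frame(nSteps = stepCounts, finalError = errs)
}

#' Log-log convergence slope of an error-versus-steps table
#'
#' Fits `log10(error) ~ log10(nSteps)` over the rows whose error lies
#' between `floorErr` (the precision plateau) and `capErr` (saturation of
#' the angular metric), returning the fitted slope. A classic fourth-order
#' integrator gives a slope near -4 in this window.
#'
#' @param report data frame from [convergenceReport()].
#' @param floorErr,capErr error window bounds (rad).
#' @return Fitted slope (dimensionless); `NA` if fewer than two rows fall
#'   inside the window.
#' @export
fitLogLogSlope <- function(report, floorErr = 1e-11, capErr = 0.3) {
  sel <- report$finalError > floorErr & report$finalError < capErr
  if (sum(sel) < 2) return(NA_real_)
  fit <- lm(log10(finalError) ~ log10(nSteps), data = report[sel, ])
  unname(coef(fit)[2])
}
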