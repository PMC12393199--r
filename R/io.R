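#' @include composite.R
NULL

# ---------------------------------------------------------------------------
# pulse (de)serialization

#' Convert a pulse to and from a plain parameter list
#'
#' The list representation (type tag plus named numeric parameters, all in
#' SI units with angular frequencies in rad/s) round-trips through JSON.
#'
#' @param pulse an [RFPulse-class] object.
#' @return `asPulseList()`: a named list; `pulseFromList()`: a pulse.
#' @export
asPulseList <- function(pulse) {
  if (is(pulse, "HS1Pulse"))
    list(type = "hs1", omega1m = pulse@omega1m, A = pulse@A,
         beta = pulse@beta, Tp = pulse@Tp, tc = pulse@tc,
         phic = pulse@phic, tStart = pulse@tStart, tEnd = pulse@tEnd)
  else if (is(pulse, "ChirpPulse"))
    list(type = "chirp", omega1m = pulse@omega1m, A = pulse@A,
         Tp = pulse@Tp, tc = pulse@tc, phic = pulse@phic,
         tStart = pulse@tStart, tEnd = pulse@tEnd)
  else if (is(pulse, "SquarePulse"))
    list(type = "square", omega1m = pulse@omega1m, phic = pulse@phic,
         tStart = pulse@tStart, tEnd = pulse@tEnd)
  else if (is(pulse, "CompositePulse"))
    list(type = "composite",
         phaseOffsets = pulse@phaseOffsets,
         segments = lapply(pulse@segments, asPulseList))
  else stop("unsupported pulse class: ", class(pulse), call. = FALSE)
}

#' @rdname asPulseList
#' @param x a list produced by `asPulseList()` (or parsed from JSON).
#' @export
pulseFromList <- function(x) {
  switch(x$type,
    hs1 = hs1Pulse(x$omega1m, x$A, x$beta, x$Tp, x$tc, x$phic, x$tStart,
                   x$tEnd),
    chirp = chirpPulse(x$omega1m, x$A, x$Tp, x$tc, x$phic, x$tStart,
                       x$tEnd),
    square = squarePulse(x$omega1m, x$phic, x$tStart, x$tEnd),
    composite = {
      segs <- x$segments
      if (is.data.frame(segs))
        segs <- lapply(seq_len(nrow(segs)), function(i) as.list(segs[i, ]))
      compositePulse(lapply(segs, pulseFromList),
                     as.numeric(x$phaseOffsets))
    },
    stop("unknown pulse type: ", x$type, call. = FALSE))
}

#' Write and read pulses as JSON
#'
#' @param pulse an [RFPulse-class] object.
#' @param path file path.
#' @return `readPulseJSON()` returns the reconstructed pulse;
#'   `writePulseJSON()` returns `path` invisibly.
#' @export
writePulseJSON <- function(pulse, path) {
  jsonlite::write_json(asPulseList(pulse), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writePulseJSON
#' @export
readPulseJSON <- function(path) {
  pulseFromList(jsonlite::read_json(path, simplifyVector = TRUE))
}

# ---------------------------------------------------------------------------
# pulse shape export

# nominal peak amplitude used to normalize shape files
.peakAmplitude <- function(pulse) {
  if (is(pulse, "CompositePulse"))
    max(vapply(pulse@segments, .peakAmplitude, numeric(1)))
  else pulse@omega1m
}

#' Export a pulse as a two-column amplitude/phase shape file
#'
#' Writes `nSamples` uniform time samples across the pulse support as
#' normalized amplitude (in [0, 1]) and phase (degrees), preceded by a
#' header line recording the peak amplitude in Hz, the support duration in
#' seconds, and the sample count.
#'
#' @param pulse an [RFPulse-class] object.
#' @param path output file path.
#' @param nSamples number of uniform samples (>= 2).
#' @return The sampled data frame, invisibly.
#' @export
exportPulseShape <- function(pulse, path, nSamples = 256) {
  if (nSamples < 2) stop("nSamples must be at least 2", call. = FALSE)
  sup <- pulseSupport(pulse)
  tt <- seq(sup[1], sup[2], length.out = nSamples)
  w <- evalWaveform(pulse, tt)
  peak <- .peakAmplitude(pulse)
  amp <- if (peak > 0) w$am / peak else w$am
  deg <- w$phase * 180 / pi
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# omega1m_hz=%.10g duration_s=%.10g n=%d",
                     peak / (2 * pi), sup[2] - sup[1], nSamples), con)
  writeLines(sprintf("%.10f %.6f", amp, deg), con)
  invisible(data.frame(t = tt, amplitude = amp, phase_deg = deg))
}

# ---------------------------------------------------------------------------
# trajectory files

#' Write a trajectory as CSV (with optional JSON parameter sidecar)
#'
#' Columns are fixed as `t_s, Mx, My, Mz, Mxy_abs`. When `params` is
#' given, a JSON sidecar `<path without extension>.json` records it
#' together with the norm and provenance.
#'
#' @param traj a [Trajectory-class] object.
#' @param path output CSV path.
#' @param params optional named list of pulse/isochromat/solver settings.
#' @return `path`, invisibly.
#' @export
writeTrajectory <- function(traj, path, params = NULL) {
  write.csv(as.data.frame(traj), path, row.names = FALSE)
  if (!is.null(params)) {
    side <- paste0(sub("\\.[^.]*$", "", path), ".json")
    jsonlite::write_json(
      c(params, list(norm = traj@norm, provenance = traj@provenance)),
      side, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname writeTrajectory
#' @param provenance tag to attach when reading (defaults to the sidecar's
#'   value if present, else `"file"`).
#' @export
readTrajectory <- function(path, provenance = NULL) {
  d <- read.csv(path)
  if (is.null(provenance)) {
    side <- paste0(sub("\\.[^.]*$", "", path), ".json")
    provenance <- if (file.exists(side))
      jsonlite::read_json(side)$provenance else "file"
    if (is.null(provenance)) provenance <- "file"
  }
  M <- as.matrix(d[, c("Mx", "My", "Mz")])
  dimnames(M) <- NULL
  new("Trajectory", times = d$t_s, M = M,
      norm = sqrt(sum(M[1, ]^2)), provenance = provenance)
}

# ---------------------------------------------------------------------------
# configuration-driven runs

.cfgNum <- function(x) if (is.null(x)) NULL else as.numeric(x)

.buildPulseFromConfig <- function(cfg) {
  pc <- cfg$pulse
  bad <- character(0)
  need <- function(key, ok) if (!ok) bad <<- c(bad, key)
  need("pulse.type", !is.null(pc$type) &&
         pc$type %in% c("hs1", "chirp", "square", "bir4"))
  if (length(bad)) stop("invalid config: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  w1m <- 2 * pi * .cfgNum(pc$omega1m_hz)
  Tp <- .cfgNum(pc$tp_s)
  phic <- if (is.null(pc$phic_rad)) 0 else as.numeric(pc$phic_rad)
  need("pulse.omega1m_hz", length(w1m) == 1 && is.finite(w1m))
  need("pulse.tp_s", length(Tp) == 1 && is.finite(Tp) && Tp > 0)
  if (length(bad)) stop("invalid config: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  tc <- if (is.null(pc$tc_s)) Tp / 2 else as.numeric(pc$tc_s)
  if (pc$type %in% c("hs1", "bir4")) {
    beta <- if (!is.null(pc$beta)) as.numeric(pc$beta)
            else if (!is.null(pc$truncation)) acosh(1 / as.numeric(pc$truncation))
            else { bad <- c(bad, "pulse.beta|pulse.truncation"); NA }
    A <- if (!is.null(pc$A_hz)) 2 * pi * as.numeric(pc$A_hz)
         else if (!is.null(pc$R)) pi * as.numeric(pc$R) / (Tp * tanh(beta))
         else { bad <- c(bad, "pulse.R|pulse.A_hz"); NA }
    if (length(bad)) stop("invalid config: ", paste(bad, collapse = ", "),
                          call. = FALSE)
    comp <- hs1Pulse(w1m, A, beta, Tp, tc = tc, phic = phic)
    if (pc$type == "hs1") return(comp)
    theta <- .cfgNum(cfg$bir4$theta_rad)
    if (is.null(theta)) stop("invalid config: bir4.theta_rad",
                             call. = FALSE)
    return(makeBir4(theta, comp))
  }
  if (pc$type == "chirp") {
    A <- if (!is.null(pc$A_hz)) 2 * pi * as.numeric(pc$A_hz)
         else if (!is.null(pc$R)) pi * as.numeric(pc$R) / Tp
         else stop("invalid config: pulse.R|pulse.A_hz", call. = FALSE)
    return(chirpPulse(w1m, A, Tp, tc = tc, phic = phic))
  }
  squarePulse(w1m, phic = phic, tStart = 0, tEnd = Tp)
}

#' Run a simulation described by a configuration file
#'
#' Reads a YAML or JSON configuration with blocks `pulse` (type and
#' parameters, frequencies in Hz under `*_hz` keys), `isochromat`
#' (`offset_hz`, optional `M`), `solver` (`method` of `analytic`, `rk4`, or
#' `both`; `n_steps`; `n_samples`), and `output` (`prefix`). Writes the
#' trajectory CSV(s) with a JSON parameter sidecar and, when both solvers
#' run, a JSON comparison summary. Runs are deterministic given the
#' configuration.
#'
#' @param path configuration file (`.yaml`/`.yml` or `.json`).
#' @param outDir output directory; defaults to the configuration's
#'   directory.
#' @param quiet suppress informational messages.
#' @return Named list of written file paths, invisibly.
#' @export
runConfig <- function(path, outDir = dirname(path), quiet = FALSE) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  bad <- character(0)
  if (is.null(cfg$pulse)) bad <- c(bad, "pulse")
  sv <- cfg$solver
  method <- if (is.null(sv$method)) "both" else sv$method
  if (!method %in% c("analytic", "rk4", "both"))
    bad <- c(bad, "solver.method")
  if (length(bad))
    stop("invalid config: ", paste(bad, collapse = ", "), call. = FALSE)
  pulse <- .buildPulseFromConfig(cfg)
  off <- if (is.null(cfg$isochromat$offset_hz)) 0
         else 2 * pi * as.numeric(cfg$isochromat$offset_hz)
  M0 <- if (is.null(cfg$isochromat$M)) c(0, 0, 1)
        else as.numeric(cfg$isochromat$M)
  iso <- isochromat(off, M0)
  nSteps <- if (is.null(sv$n_steps)) 10000L else as.integer(sv$n_steps)
  nSamp <- if (is.null(sv$n_samples)) 501L else as.integer(sv$n_samples)
  prefix <- if (is.null(cfg$output$prefix)) "bloch" else cfg$output$prefix
  sup <- pulseSupport(pulse)
  tt <- seq(sup[1], sup[2], length.out = nSamp)
  info <- function(...) if (!quiet) message(sprintf(...))
  info("pulse: %s on [%g, %g] s; offset/2pi = %g Hz; solver: %s",
       class(pulse), sup[1], sup[2], off / (2 * pi), method)
  out <- list()
  params <- list(config = cfg, solver = list(
    method = method, n_steps = nSteps, n_samples = nSamp,
    precision = "double output, extended-precision basis evaluation"))
  base <- file.path(outDir, prefix)
  trA <- trR <- NULL
  if (method %in% c("analytic", "both")) {
    trA <- propagate(pulse, iso, tt)
    out$analytic <- writeTrajectory(trA, paste0(base, "_analytic.csv"),
                                    params)
  }
  if (method %in% c("rk4", "both")) {
    trR <- propagateRK4(pulse, iso, nSteps, evalTimes = tt)
    out$rk4 <- writeTrajectory(trR, paste0(base, "_rk4.csv"), params)
  }
  if (method == "both") {
    cmp <- compareTrajectories(trA, trR)
    out$compare <- paste0(base, "_compare.json")
    jsonlite::write_json(list(mean = cmp$mean, max = cmp$max,
                              final = cmp$final),
                         out$compare, auto_unbox = TRUE, digits = NA)
    info("analytic vs rk4 angular error: mean %.3g, max %.3g, final %.3g rad",
         cmp$mean, cmp$max, cmp$final)
  }
  invisible(out)
}
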