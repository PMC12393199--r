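#' @include AllGenerics.R
NULL

# ---------------------------------------------------------------------------
# internal complex-chart helpers (vectorized; Inf/NaN = point at infinity)

.projectC <- function(M, norm = sqrt(sum(M^2))) {
  if (M[3] >= 0)  # |M| + Mz is cancellation-free here
    return(complex(real = M[1], imaginary = M[2]) / (norm + M[3]))
  # southern hemisphere: |M| + Mz = (Mx^2 + My^2) / (|M| - Mz), which
  # avoids the catastrophic cancellation near the south pole
  t2 <- M[1]^2 + M[2]^2
  if (t2 / (norm - M[3]) < 1e-12 * norm)
    return(complex(real = Inf, imaginary = Inf))
  (norm - M[3]) / complex(real = M[1], imaginary = -M[2])
}

.unprojectC <- function(f, norm = 1) {
  n <- length(f)
  out <- matrix(0, n, 3)
  finite <- is.finite(Re(f)) & is.finite(Im(f))
  big <- !finite | Mod(f) > 1
  if (any(!big)) {
    fn <- f[!big]
    a2 <- Mod(fn)^2
    out[!big, 1] <- 2 * Re(fn) / (1 + a2)
    out[!big, 2] <- 2 * Im(fn) / (1 + a2)
    out[!big, 3] <- (1 - a2) / (1 + a2)
  }
  if (any(big)) {
    g <- ifelse(finite[big], 1 / f[big], 0 + 0i)
    g[!is.finite(Re(g)) | !is.finite(Im(g))] <- 0 + 0i
    b2 <- Mod(g)^2
    out[big, 1] <- 2 * Re(g) / (1 + b2)
    out[big, 2] <- -2 * Im(g) / (1 + b2)
    out[big, 3] <- (b2 - 1) / (1 + b2)
  }
  out * norm
}

# ---------------------------------------------------------------------------

#' Construct an isochromat
#'
#' @param offset resonance offset Omega = omega0 - omegac (rad/s).
#' @param M magnetization 3-vector in units of M0; defaults to equilibrium
#'   `(0, 0, 1)`. Its norm must lie in (0, 1].
#' @return An [Isochromat-class] object.
#' @export
isochromat <- function(offset = 0, M = c(0, 0, 1)) {
  new("Isochromat", offset = offset, M = as.numeric(M))
}

#' @rdname isochromat
#' @param iso an [Isochromat-class] object.
#' @export
resonanceOffset <- function(iso) iso@offset

#' @rdname isochromat
#' @export
magnetization <- function(iso) iso@M

#' Stereographic projection of a magnetization vector
#'
#' Maps a magnetization vector to the extended complex plane via
#' `f = (Mx + i My) / (|M| + Mz)`: the north pole (+z) maps to 0, the
#' equator to the unit circle, and the south pole (-z) to the point at
#' infinity (declared when `|M| + Mz < 1e-12 |M|`).
#'
#' @param M numeric 3-vector with positive norm.
#' @return A [RiemannPoint-class] object carrying the norm `|M|`.
#' @examples
#' riemannProject(c(0, 0, 1))   # f = 0
#' riemannProject(c(1, 0, 0))   # f = 1
#' riemannProject(c(0, 0, -1))  # point at infinity
#' @export
riemannProject <- function(M) {
  M <- as.numeric(M)
  if (length(M) != 3 || any(!is.finite(M)))
    stop("M must be a finite 3-vector", call. = FALSE)
  norm <- sqrt(sum(M^2))
  if (norm <= 0)
    stop("magnetization norm must be positive", call. = FALSE)
  f <- .projectC(M, norm)
  if (!is.finite(Re(f)) || !is.finite(Im(f)))
    new("RiemannPoint", value = complex(1), atInfinity = TRUE, norm = norm)
  else
    new("RiemannPoint", value = f, atInfinity = FALSE, norm = norm)
}

#' Inverse stereographic projection
#'
#' Exact inverse of [riemannProject()]:
#' `Mx + i My = |M| 2 f / (1 + |f|^2)`, `Mz = |M| (1 - |f|^2) / (1 + |f|^2)`.
#' The output norm equals the carried `|M|` identically. Large `|f|` is
#' evaluated on the inverted chart `g = 1/f` to avoid precision loss near
#' the south pole.
#'
#' @param p a [RiemannPoint-class] object.
#' @return Numeric magnetization 3-vector.
#' @export
riemannUnproject <- function(p) {
  stopifnot(is(p, "RiemannPoint"))
  f <- if (p@atInfinity) complex(real = Inf, imaginary = Inf) else p@value
  drop(.unprojectC(f, p@norm))
}

#' Frame-independent angular error between two magnetization vectors
#'
#' The angle between the two vectors, computed as
#' `atan2(|M1 x M2|, M1 . M2)`, which agrees with the arccosine of the
#' clamped normalized dot product but remains fully accurate for small
#' angles. Symmetric in its arguments, lies in `[0, pi]`, and is invariant
#' under any common rotation.
#'
#' @param M1,M2 numeric 3-vectors with positive norm.
#' @return Angle in radians.
#' @examples
#' angularError(c(1, 0, 0), c(0, 1, 0))  # pi/2
#' @export
angularError <- function(M1, M2) {
  M1 <- as.numeric(M1); M2 <- as.numeric(M2)
  n1 <- sqrt(sum(M1^2)); n2 <- sqrt(sum(M2^2))
  if (n1 <= 0 || n2 <= 0)
    stop("zero-norm magnetization has no direction", call. = FALSE)
  cr <- c(M1[2] * M2[3] - M1[3] * M2[2],
          M1[3] * M2[1] - M1[1] * M2[3],
          M1[1] * M2[2] - M1[2] * M2[1])
  atan2(sqrt(sum(cr^2)), sum(M1 * M2))
}

# run code under a temporary RNG state
.withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Seeded isochromat ensemble generator
#'
#' Draws `n` isochromats with orientations uniform on the sphere (normalized
#' triples of independent standard normals) and offsets uniform over
#' `offsetRange`. Reproducible for a fixed seed.
#'
#' @param n number of isochromats (>= 1).
#' @param seed optional integer seed; the caller's RNG state is preserved.
#' @param norm magnetization norm in (0, 1].
#' @param offsetRange length-2 numeric range of offsets (rad/s).
#' @return List of [Isochromat-class] objects.
#' @examples
#' isos <- randomIsochromats(3, seed = 1, offsetRange = 2 * pi * c(-100, 100))
#' @export
randomIsochromats <- function(n, seed = NULL, norm = 1,
                              offsetRange = c(0, 0)) {
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  if (!is.finite(norm) || norm <= 0 || norm > 1)
    stop("norm must lie in (0, 1]", call. = FALSE)
  .withSeed(seed, {
    g <- matrix(rnorm(3 * n), n, 3)
    len <- sqrt(rowSums(g^2))
    g <- g / len * norm
    offs <- runif(n, offsetRange[1], offsetRange[2])
    lapply(seq_len(n), function(i) isochromat(offs[i], g[i, ]))
  })
}
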