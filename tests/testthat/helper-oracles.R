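# Shared fixtures and independent oracles for the solver tests.

# inversion-pulse family used throughout the validation figures
fig2Pulse <- function(truncation, R = 10, omega1m = 2 * pi * 2000,
                      Tp = 5e-3, phic = 0) {
  hs1FromSpec(omega1m = omega1m, Tp = Tp, R = R, truncation = truncation,
              phic = phic)
}

# Rodrigues rotation of v about unit axis by angle (radians)
rodrigues <- function(v, axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  v * cos(angle) + c(a[2] * v[3] - a[3] * v[2],
                     a[3] * v[1] - a[1] * v[3],
                     a[1] * v[2] - a[2] * v[1]) * sin(angle) +
    a * sum(a * v) * (1 - cos(angle))
}

# closed-form magnetization under a constant field: rotation about the
# effective field (w1x, w1y, Omega) at rate -|weff| (independent of the
# Riccati machinery)
squareOracleM <- function(pulse, Omega, M0, t0, t) {
  wx <- pulse@omega1m * cos(pulse@phic)
  wy <- pulse@omega1m * sin(pulse@phic)
  B <- c(wx, wy, Omega)
  nb <- sqrt(sum(B^2))
  if (nb == 0) return(matrix(rep(M0, length(t)), ncol = 3, byrow = TRUE))
  t(vapply(t, function(tt) rodrigues(M0, -B / nb, nb * (tt - t0)),
           numeric(3)))
}

# uniformly random rotation matrix (uses the caller's RNG state)
randomRotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# plain-R backward RK4 over the Bloch equation (for time-reversal checks)
rk4Backward <- function(pulse, Omega, M, t1, t0, nSteps) {
  h <- (t0 - t1) / nSteps
  tt <- t1
  for (i in seq_len(nSteps)) {
    k1 <- blochDerivative(M, tt, pulse, Omega)
    k2 <- blochDerivative(M + h / 2 * k1, tt + h / 2, pulse, Omega)
    k3 <- blochDerivative(M + h / 2 * k2, tt + h / 2, pulse, Omega)
    k4 <- blochDerivative(M + h * k3, tt + h, pulse, Omega)
    M <- M + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    tt <- tt + h
  }
  M
}

# particular constant C = CB / CA of a solver at anchor states taken from a
# trajectory
constantsAlong <- function(kind, pulse, Omega, traj) {
  vapply(seq_along(trajTimes(traj)), function(i) {
    f <- BlochRiccati:::.projectC(trajM(traj)[i, ])
    if (kind == "hs1") {
      ct <- hs1Particular(f, trajTimes(traj)[i], hs1Context(pulse, Omega))
      ct@CB / ct@CA
    } else if (kind == "chirp") {
      ct <- chirpParticular(f, trajTimes(traj)[i],
                            chirpContext(pulse, Omega))
      ct@CB / ct@CA
    } else {
      squareParticular(f, trajTimes(traj)[i], pulse, Omega)
    }
  }, complex(1))
}

# relative spread of a set of complex constants (square-pulse constants are
# reduced modulo the i*pi branch period of artanh first)
constantSpread <- function(C, modIPi = FALSE) {
  if (modIPi)
    C <- C - 1i * pi * round(Im(C - C[1]) / pi)
  mu <- mean(C)
  max(Mod(C - mu)) / mean(Mod(C))
}
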