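test_that("the complex chirp time variable is affine with the stated origin", {
  p <- chirpPulse(2 * pi * 1500, 2 * pi * 2000, 5e-3)
  Om <- 2 * pi * 300
  t0 <- p@tc - p@Tp * Om / (2 * p@A)
  expect_equal(chirpP(t0, p, Om), 0 + 0i, tolerance = 1e-12)
  # affinity: p(t1) + p(t3) = 2 p(t2) for equally spaced times
  tt <- c(1e-3, 2e-3, 3e-3)
  pv <- chirpP(tt, p, Om)
  expect_equal(pv[1] + pv[3], 2 * pv[2], tolerance = 1e-12)
  # direction exp(i pi / 4) for A > 0 and dimensionless scale sqrt(A / Tp)
  expect_equal(Arg(chirpP(p@tc + 1e-3, p, 0)), pi / 4, tolerance = 1e-12)
  expect_error(chirpP(1e-3, chirpPulse(1, 0, 5e-3), 0), "A != 0")
})

test_that("chirp fundamental solutions reduce to Hermite polynomials at integer order", {
  z <- c(0.3, -0.7, 1.2)
  for (n in 0:2) {
    bs <- chirpBasis(z, as.complex(n))
    Href <- switch(n + 1, rep(1, 3), 2 * z, 4 * z^2 - 2)
    expect_equal(bs$FB, as.complex(Href), tolerance = 1e-12)
  }
})

test_that("chirp fundamental solutions match oracles, the Abel identity, and the ODE", {
  a <- -1 - 2.3i
  # frozen values: mpmath Hermite function of complex order and Kummer M
  bs <- chirpBasis(c(0.4 + 0.4i, 1.5 + 1.5i), a)
  expect_equal(bs$FB, c(-1.249420011843024 - 1.187850425982451i,
                        -0.43536337247717594 + 0.99791680657885255i),
               tolerance = 1e-12)
  expect_equal(bs$FA[2], -0.5405618405267139 - 0.11342689434373426i,
               tolerance = 1e-12)
  # dual route at small argument: Kummer series for FA
  p0 <- 0.35 + 0.2i
  direct <- BlochRiccati:::cpp_kummer_series((a + 1) / 2, 0.5 + 0i, -p0^2)
  bs0 <- chirpBasis(p0, a)
  expect_equal(bs0$FA, direct$F, tolerance = 1e-13)
  # Abel identity: Wronskian of (qA, qB e^{-p^2}) is proportional to e^{-p^2}
  pp <- complex(real = c(0.1, 0.5, 1, 2), imaginary = c(0.1, 0.5, 1, 2))
  q <- BlochRiccati:::.chirpQBasis(pp, a)
  W0 <- (q$qA * q$qB1 - q$qB * q$qA1) * exp(pp^2)
  expect_equal(W0, rep(W0[1], 4), tolerance = 1e-12)
  # residual substitution into q'' + 2 p q' + 2 (a + 1) q = 0
  h <- 1e-4
  for (pc in c(0.4 + 0.4i, 2 + 2i)) {
    qm <- BlochRiccati:::.chirpQBasis(c(pc - h, pc, pc + h), a)
    for (col in c("qA", "qB")) {
      v <- qm[[col]]
      res <- (v[1] + v[3] - 2 * v[2]) / h^2 +
        2 * pc * (v[3] - v[1]) / (2 * h) + 2 * (a + 1) * v[2]
      expect_lt(Mod(res) / max(Mod(v)), 1e-6)
    }
  }
  # derivatives against central differences
  qd <- BlochRiccati:::.chirpQBasis(c(0.8 - h, 0.8, 0.8 + h) + 0.3i, a)
  expect_equal((qd$qA[3] - qd$qA[1]) / (2 * h), qd$qA1[2],
               tolerance = 1e-7)
  expect_equal((qd$qB[3] - qd$qB[1]) / (2 * h), qd$qB1[2],
               tolerance = 1e-7)
})

test_that("the chirp particular constant anchors exactly and is conserved", {
  p <- chirpPulse(2 * pi * 1500, pi * 10 / 5e-3, 5e-3)
  Om <- 2 * pi * 200
  ctx <- chirpContext(p, Om)
  f0 <- riemannProject(c(0.3, -0.4, sqrt(0.75)))
  ct <- chirpParticular(f0, 1.7e-3, ctx)
  expect_equal(chirpEvaluate(ctx, ct, 1.7e-3), f0@value,
               tolerance = 1e-12)
  iso <- isochromat(Om, c(0.3, -0.4, sqrt(0.75)))
  tr <- propagateRK4(p, iso, 1e5,
                     evalTimes = seq(0.5e-3, 4.5e-3, length.out = 5))
  C <- constantsAlong("chirp", p, Om, tr)
  expect_lt(constantSpread(C), 1e-6)
})

test_that("chirp propagation matches the oracle across sweeps and offsets", {
  iso <- isochromat(0)
  tt <- seq(0, 5e-3, length.out = 101)
  for (R in c(10, 50, 100)) {
    p <- chirpPulse(2 * pi * 1500, pi * R / 5e-3, 5e-3)
    ta <- propagate(p, iso, tt)
    expect_equal(trajProvenance(ta), "analytic-chirp")
    tr <- propagateRK4(p, iso, 1e4, evalTimes = tt)
    expect_lt(compareTrajectories(ta, tr)$mean, 1e-5)
  }
  # offset sweep at high time-bandwidth
  p <- chirpPulse(2 * pi * 2000, pi * 100 / 5e-3, 5e-3)
  for (offHz in c(50, 500, 5000)) {
    isoO <- isochromat(2 * pi * offHz)
    ta <- propagate(p, isoO, tt)
    tr <- propagateRK4(p, isoO, 1e4, evalTimes = tt)
    expect_lt(compareTrajectories(ta, tr)$mean, 1e-5)
  }
  # identity at the anchor
  t0 <- propagate(p, isochromat(0, c(0, 0.6, 0.8)), 0)
  expect_equal(trajM(t0)[1, ], c(0, 0.6, 0.8), tolerance = 1e-12)
})

test_that("a zero-sweep chirp dispatches to the square-pulse solution", {
  p0 <- chirpPulse(2 * pi * 300, 0, 5e-3, phic = 0.7)
  sq <- squarePulse(2 * pi * 300, phic = 0.7, tStart = p0@tStart,
                    tEnd = p0@tEnd)
  iso <- isochromat(2 * pi * 120, c(0.3, -0.4, sqrt(0.75)))
  tt <- seq(p0@tStart, p0@tEnd, length.out = 21)
  expect_equal(trajM(propagate(p0, iso, tt)),
               trajM(propagate(sq, iso, tt)), tolerance = 1e-13)
})

test_that("the square-pulse constant has its closed form and rejects branch points", {
  w1m <- 2 * pi * 200
  sq <- squarePulse(w1m, phic = 0, tStart = 0, tEnd = 5e-3)
  C <- squareParticular(0 + 0i, 1e-3, sq, 0)
  expect_equal(C, -0.5i * 1e-3 * w1m, tolerance = 1e-14)
  # self-consistency of the anchored solution
  f0 <- riemannProject(c(0.3, -0.4, sqrt(0.75)))
  tr <- propagate(squarePulse(w1m, phic = 0.4, tStart = 0, tEnd = 5e-3),
                  isochromat(2 * pi * 80, c(0.3, -0.4, sqrt(0.75))),
                  c(0, 2e-3))
  expect_equal(trajM(tr)[1, ], c(0.3, -0.4, sqrt(0.75)),
               tolerance = 1e-12)
  # on-resonance +x anchor puts the artanh argument at the branch point
  expect_error(squareParticular(1 + 0i, 0, sq, 0), "branch point")
})

test_that("square propagation is the rotation about the effective field", {
  # pi pulse inverts, quarter cycle excites along the phase-set axis
  w1m <- 2 * pi * 200
  piPulse <- squarePulse(w1m, phic = 0, tStart = 0, tEnd = pi / w1m)
  expect_equal(trajM(propagate(piPulse, isochromat(0), pi / w1m))[1, ],
               c(0, 0, -1), tolerance = 1e-12)
  qPulse <- squarePulse(w1m, phic = pi / 2, tStart = 0,
                        tEnd = pi / (2 * w1m))
  Mq <- trajM(propagate(qPulse, isochromat(0), pi / (2 * w1m)))[1, ]
  # field along +y (phic = pi/2) tips +z toward -x
  expect_equal(Mq, c(-1, 0, 0), tolerance = 1e-12)
  # off-resonance trajectories against the axis-angle closed form
  tt <- seq(0, 5e-3, length.out = 41)
  for (offHz in c(0, 100, 200)) {
    sq <- squarePulse(w1m, phic = pi / 2, tStart = 0, tEnd = 5e-3)
    iso <- isochromat(2 * pi * offHz)
    ta <- propagate(sq, iso, tt)
    Mo <- squareOracleM(sq, resonanceOffset(iso), magnetization(iso), 0,
                        tt)
    devs <- vapply(seq_along(tt), function(i)
      angularError(trajM(ta)[i, ], Mo[i, ]), numeric(1))
    expect_lt(max(devs), 1e-10)
  }
})

test_that("square-pulse trajectories are periodic with period 2 pi / weff", {
  w1m <- 2 * pi * 350
  Om <- 2 * pi * 150
  weff <- sqrt(w1m^2 + Om^2)
  sq <- squarePulse(w1m, phic = 0.3, tStart = 0, tEnd = 3e-2)
  iso <- isochromat(Om, c(0.2, 0.5, sqrt(1 - 0.29)))
  T <- 2 * pi / weff
  tt <- c(1e-3, 1e-3 + T, 1e-3 + 2 * T)
  M <- trajM(propagate(sq, iso, tt))
  expect_lt(angularError(M[1, ], M[2, ]), 1e-10)
  expect_lt(angularError(M[1, ], M[3, ]), 1e-10)
  expect_lt(max(abs(M[1, ] - M[2, ])), 1e-10)
})

test_that("a zero-amplitude square pulse reduces to free precession", {
  Om <- 2 * pi * 100
  sq <- squarePulse(0, tStart = 0, tEnd = 1e-2)
  iso <- isochromat(Om, c(1, 0, 0))
  tq <- pi / (2 * Om)  # quarter turn about +z at rate -Omega
  M <- trajM(propagate(sq, iso, tq))[1, ]
  expect_equal(M, c(0, -1, 0), tolerance = 1e-12)
})
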