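test_that("the logistic time variable p has its stated landmarks and identity", {
  p <- hs1Pulse(2 * pi * 2000, 2 * pi * 800, 2.5, 5e-3)
  expect_equal(hs1P(p@tc, p), 0.5)
  expect_equal(hs1P(p@tc + p@Tp / 2, p), (1 + tanh(2.5)) / 2,
               tolerance = 1e-15)
  expect_equal(hs1P(1e3, p), 1)   # tanh limits
  expect_equal(hs1P(-1e3, p), 0)
  tt <- seq(0, 5e-3, length.out = 41)
  pv <- hs1P(tt, p)
  expect_true(all(diff(pv) > 0))  # strictly monotone for beta > 0
  # sech^2 = 4 p (1 - p) ties p to the AM function
  expect_equal((evalWaveform(p, tt)$am / p@omega1m)^2, 4 * pv * (1 - pv),
               tolerance = 1e-13)
})

test_that("hypergeometric parameters obey their branch identities", {
  Tp <- 5e-3
  p <- hs1FromSpec(2 * pi * 2000, Tp, R = 10, truncation = 0.1)
  Om <- 2 * pi * 100
  abc <- hs1ABC(p, Om)
  k <- Tp / (4 * p@beta)
  expect_equal(abc$a + abc$b, -1i * p@A * Tp / (2 * p@beta),
               tolerance = 1e-14)
  expect_equal(abc$a * abc$b, as.complex(-k^2 * p@omega1m^2),
               tolerance = 1e-14)
  expect_equal(Re(abc$c), 0.5)
  # no-FM reduction: a = Tp w1m / (4 beta) = -b, c = 1/2 + i Tp Omega/(4 beta)
  p0 <- hs1Pulse(2 * pi * 2000, 0, 2.5, Tp)
  abc0 <- hs1ABC(p0, Om)
  expect_equal(abc0$a, as.complex(Tp * p0@omega1m / (4 * p0@beta)))
  expect_equal(abc0$b, -abc0$a)
  expect_equal(abc0$c, 0.5 + 1i * Tp * Om / (4 * p0@beta))
  expect_equal(hs1ABC(p0, 0)$c, 0.5 + 0i)
  # A > omega1m: principal square root makes both a and b purely imaginary
  ph <- hs1FromSpec(2 * pi * 100, 1e-2, R = 50, truncation = 0.5)
  expect_gt(ph@A, ph@omega1m)
  abch <- hs1ABC(ph, 0)
  expect_equal(Re(abch$a), 0, tolerance = 1e-14)
  expect_equal(Re(abch$b), 0, tolerance = 1e-14)
  expect_equal(abch$a + abch$b, -1i * ph@A * 1e-2 / (2 * ph@beta),
               tolerance = 1e-12)
})

test_that("fundamental solutions match an independent arbitrary-precision oracle", {
  # frozen values: mpmath at 30 digits, parameters of the 10%-truncation
  # R = 10 inversion pulse with a 100 Hz offset
  p <- hs1FromSpec(2 * pi * 2000, 5e-3, R = 10, truncation = 0.1)
  abc <- hs1ABC(p, 2 * pi * 100)
  expect_equal(abc$a, 4.5371076972510297 - 2.6371402826591974i,
               tolerance = 1e-14)
  expect_equal(abc$c, 0.5 - 2.3747481375458272i, tolerance = 1e-14)
  bs <- hs1Basis(c(0.3, 0.97), abc$a, abc$b, abc$c)
  ref <- rbind(
    c(-0.7543573705207241 - 0.10262759078988926i,
      0.15106906931517926 - 0.25900545469145568i,
      -0.61946604783628122 + 7.3993292143913148i,
      3.5828868678953088 + 1.8486193234858727i),
    c(-0.28498924005944921 + 0.011970763880171474i,
      0.29440588648449407 - 0.33132597053999986i,
      5.2241492590157217 + 29.018872491755705i,
      3.3711402965798158 + 2.2587531072227071i))
  for (j in 1:4)
    expect_equal(as.complex(bs[[j]]), ref[, j], tolerance = 1e-13)
})

test_that("fundamental solutions satisfy the series limit, Wronskian, and derivatives", {
  p <- hs1FromSpec(2 * pi * 2000, 5e-3, R = 10, truncation = 0.1)
  abc <- hs1ABC(p, 2 * pi * 100)
  # Gauss series is 1 at the origin
  expect_equal(hs1Basis(1e-10, abc$a, abc$b, abc$c)$FA, 1 + 0i,
               tolerance = 1e-8)
  # closed-form Wronskian (1 - c) p^-c (1 - p)^(c - a - b - 1)
  pv <- c(0.15, 0.5, 0.85)
  bs <- hs1Basis(pv, abc$a, abc$b, abc$c)
  W <- bs$FA * bs$FB1 - bs$FB * bs$FA1
  Wref <- (1 - abc$c) * pv^(-abc$c) *
    (1 - pv)^(abc$c - abc$a - abc$b - 1)
  expect_equal(W, Wref, tolerance = 1e-12)
  # dual-route check: Taylor continuation against the direct Gauss series
  s <- BlochRiccati:::cpp_hyp2f1_series(abc$a, abc$b, abc$c, 0.3 + 0i)
  b3 <- hs1Basis(0.3, abc$a, abc$b, abc$c)
  expect_equal(b3$FA, s$F, tolerance = 1e-13)
  expect_equal(b3$FA1, s$dF, tolerance = 1e-13)
  # derivatives agree with central differences
  h <- 1e-6
  bfd <- hs1Basis(c(0.4 - h, 0.4, 0.4 + h), abc$a, abc$b, abc$c)
  expect_equal((bfd$FA[3] - bfd$FA[1]) / (2 * h), bfd$FA1[2],
               tolerance = 1e-8)
  expect_equal((bfd$FB[3] - bfd$FB[1]) / (2 * h), bfd$FB1[2],
               tolerance = 1e-8)
  expect_error(hs1Basis(c(0.2, 1.2), abc$a, abc$b, abc$c), "inside")
})

test_that("the particular constant reproduces its anchor and is a constant of motion", {
  p <- fig2Pulse(0.1)
  Om <- 2 * pi * 100
  ctx <- hs1Context(p, Om)
  iso <- isochromat(Om, c(0.3, -0.4, sqrt(0.75)))
  f0 <- riemannProject(magnetization(iso))
  ct <- hs1Particular(f0, 1.2e-3, ctx)
  expect_equal(hs1Evaluate(ctx, ct, 1.2e-3), f0@value, tolerance = 1e-12)
  # equilibrium anchor at low truncation gives C close to 0
  pl <- fig2Pulse(0.001)
  ctl <- hs1Particular(riemannProject(c(0, 0, 1)), pl@tStart,
                       hs1Context(pl, 0))
  expect_lt(Mod(ctl@CB / ctl@CA), 5e-3)
  # anchors along one finely resolved oracle trajectory agree
  tr <- propagateRK4(p, iso, 1e5,
                     evalTimes = seq(0.5e-3, 4.5e-3, length.out = 5))
  C <- constantsAlong("hs1", p, Om, tr)
  expect_lt(constantSpread(C), 1e-6)
  # an at-infinity anchor is representable projectively
  ctInf <- hs1Particular(riemannProject(c(0, 0, -1)), 1e-3, ctx)
  fInf <- hs1Evaluate(ctx, ctInf, 1e-3)
  expect_true(!is.finite(Mod(fInf)) || Mod(fInf) > 1e10)
})

test_that("the no-FM on-resonance solution reduces to the transparency closed form", {
  b <- acosh(1 / 0.01)
  Tp <- 5e-3
  w <- sitAmplitude(b, Tp)
  ps <- hs1Pulse(w, 0, b, Tp)
  ctx <- hs1Context(ps, 0)
  cst <- new("ParticularConstant", CA = 1 + 0i, CB = 0 + 0i)
  tt <- seq(0.5e-3, 4.5e-3, length.out = 9)
  f <- hs1Evaluate(ctx, cst, tt)
  a0 <- Tp * w / (4 * b)
  fRef <- 1i * tan(2 * a0 * asin(sqrt(hs1P(tt, ps))))
  expect_equal(f, fRef, tolerance = 1e-10)
  # without FM on resonance the dynamics is exactly a planar rotation by
  # the accumulated pulse area: the relative-angle pendulum form matches
  # the propagated solution at the precision floor
  sc <- sitClosedForm(tt, ps)
  tr <- propagate(ps, isochromat(0), tt)
  devs <- vapply(seq_along(tt), function(i)
    angularError(sc$M[i, ], trajM(tr)[i, ]), numeric(1))
  expect_lt(max(devs), 1e-10)
  expect_error(sitClosedForm(1e-3, fig2Pulse(0.1)), "A = 0")
})

test_that("analytic propagation reproduces the oracle for inversion pulses", {
  p <- fig2Pulse(0.1)
  iso <- isochromat(0)
  tt <- seq(0, 5e-3, length.out = 251)
  ta <- propagate(p, iso, tt)
  expect_equal(trajProvenance(ta), "analytic-hs1")
  tr <- propagateRK4(p, iso, 1e4, evalTimes = tt)
  cmp <- compareTrajectories(ta, tr)
  expect_lt(cmp$mean, 1e-5)
  # adiabatic inversion (imperfect at this truncation-reduced sweep)
  expect_equal(trajM(ta)[251, 3], -1, tolerance = 0.1)
  # identity at the anchor
  t0 <- propagate(p, isochromat(2 * pi * 40, c(0.6, 0, 0.8)), 0)
  expect_equal(trajM(t0)[1, ], c(0.6, 0, 0.8), tolerance = 1e-12)
})

test_that("anchoring mid-pulse with an oracle state gives the same trajectory", {
  p <- fig2Pulse(0.25)
  iso <- isochromat(2 * pi * 100, c(0.3, -0.4, sqrt(0.75)))
  tt <- seq(0, 5e-3, length.out = 51)
  tr <- propagateRK4(p, iso, 1e5, evalTimes = tt)
  # anchor at the midpoint using the RK4 state there
  isoMid <- isochromat(resonanceOffset(iso), trajM(tr)[26, ])
  taMid <- propagate(p, isoMid, tt, tInit = tt[26])
  taStart <- propagate(p, iso, tt)
  cmp <- compareTrajectories(taMid, taStart)
  expect_lt(cmp$max, 1e-8)  # differences bounded by the oracle error
})

test_that("propagation conserves an arbitrary magnetization norm identically", {
  p <- fig2Pulse(0.1)
  iso <- isochromat(2 * pi * 250, 0.7 * c(0.2, 0.5, sqrt(1 - 0.29)))
  ta <- propagate(p, iso, seq(0, 5e-3, length.out = 31))
  norms <- sqrt(rowSums(trajM(ta)^2))
  expect_equal(norms, rep(0.7, 31), tolerance = 1e-13)
})
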