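test_that("HS1 waveform matches its closed forms at landmark times", {
  w1m <- 2 * pi * 2000
  p <- hs1Pulse(omega1m = w1m, A = 2 * pi * 800, beta = 3, Tp = 5e-3,
                phic = 0.4)
  w <- evalWaveform(p, p@tc)
  expect_equal(w$am, w1m)
  expect_equal(w$fm, 0)
  expect_equal(w$phase, 0.4)
  # boundary amplitude is the sech(beta) truncation fraction
  wb <- evalWaveform(p, p@tc + p@Tp / 2)
  expect_equal(wb$am / w1m, 1 / cosh(3), tolerance = 1e-14)
  expect_equal(evalWaveform(p, p@tc - p@Tp / 2)$am / w1m, 1 / cosh(3),
               tolerance = 1e-14)
  # complex RF amplitude at the peak
  expect_equal(evalRF(p, p@tc), w1m * exp(0.4i))
  p2 <- hs1Pulse(w1m, 0, 3, 5e-3, phic = pi / 2)
  expect_equal(evalRF(p2, p2@tc), complex(imaginary = w1m))
  expect_error(evalWaveform(p, 6e-3), "support")
})

test_that("HS1 AM is even and FM odd about tc; negating beta flips the sweep", {
  p <- hs1Pulse(2 * pi * 1500, 2 * pi * 600, 2.2, 4e-3)
  pneg <- hs1Pulse(2 * pi * 1500, 2 * pi * 600, -2.2, 4e-3)
  set.seed(7)
  for (d in runif(20, 0, p@Tp / 2)) {
    wp <- evalWaveform(p, p@tc + d)
    wm <- evalWaveform(p, p@tc - d)
    expect_equal(wp$am, wm$am, tolerance = 1e-14)
    expect_equal(wp$fm, -wm$fm, tolerance = 1e-14)
    wn <- evalWaveform(pneg, p@tc + d)
    expect_equal(wn$fm, -wp$fm, tolerance = 1e-14)
    expect_equal(wn$am, wp$am, tolerance = 1e-14)
  }
})

test_that("pulse phase is the integral of the FM function (dphi/dt = fm)", {
  h <- 1e-9
  hs <- hs1Pulse(2 * pi * 2000, 2 * pi * 900, 2.7, 5e-3)
  ch <- chirpPulse(2 * pi * 1500, 2 * pi * 3000, 5e-3)
  for (p in list(hs, ch)) {
    for (t0 in c(1.1e-3, 2.5e-3, 4.2e-3)) {
      num <- (evalWaveform(p, t0 + h)$phase -
                evalWaveform(p, t0 - h)$phase) / (2 * h)
      expect_equal(num, evalWaveform(p, t0)$fm, tolerance = 1e-5)
    }
  }
})

test_that("chirp waveform is a linear sweep with quadratic phase", {
  A <- 2 * pi * 2500
  p <- chirpPulse(2 * pi * 1500, A, 5e-3, phic = 0.1)
  we <- evalWaveform(p, p@tc + p@Tp / 2)
  expect_equal(we$fm, A)
  expect_equal(we$am, p@omega1m)
  expect_equal(evalWaveform(p, p@tc - p@Tp / 2)$fm, -A)
  # complex RF at the sweep end: phase phic + A Tp / 4
  p0 <- chirpPulse(2 * pi * 1500, A, 5e-3, phic = 0)
  expect_equal(evalRF(p0, p0@tc + p0@Tp / 2),
               p0@omega1m * exp(1i * A * p0@Tp / 4), tolerance = 1e-12)
})

test_that("time-bandwidth factor is A Tp tanh(beta) / pi and inverts exactly", {
  expect_equal(timeBandwidth(hs1Pulse(1, 0, 2, 5e-3)), 0)
  # tanh(beta) -> 1: R approaches A Tp / pi
  p <- hs1Pulse(1, A = 10 * pi / 5e-3, beta = 30, Tp = 5e-3)
  expect_equal(timeBandwidth(p), 10, tolerance = 1e-12)
  # round trip through the spec-style constructor
  p2 <- hs1FromSpec(2 * pi * 2000, 5e-3, R = 10, truncation = 0.01)
  expect_equal(timeBandwidth(p2), 10, tolerance = 1e-12)
  # sech(beta) = 0.01, R = 10, Tp = 5 ms corresponds to A/2pi of ~1 kHz
  expect_equal(p2@A / (2 * pi), 1000, tolerance = 2e-4)
  # 10% truncation corresponds to beta = asech(0.1) = 2.993
  p3 <- hs1FromSpec(1, 5e-3, R = 5, truncation = 0.1)
  expect_equal(p3@beta, 2.993, tolerance = 1e-4)
  expect_error(hs1FromSpec(1, 5e-3, R = 5, truncation = 1.2), "truncation")
  expect_error(hs1FromSpec(1, 5e-3, R = 5, truncation = 0), "truncation")
  # chirp convention
  expect_equal(timeBandwidth(chirpPulse(1, A = 10 * pi / 5e-3, Tp = 5e-3)),
               10, tolerance = 1e-12)
})

test_that("2-pi self-induced-transparency amplitude follows the final-angle formula", {
  # large-beta limit: 4 beta / Tp
  expect_equal(sitAmplitude(40, 5e-3), 4 * 40 / 5e-3, tolerance = 1e-12)
  # frozen regression value (independent arbitrary-precision evaluation)
  expect_equal(sitAmplitude(5.298, 5e-3), 4251.9385238124917,
               tolerance = 1e-13)
  # final angle of the closed form is exactly 2 pi by construction
  for (b in c(0.7, 2.5, 5.298)) {
    pulse <- hs1Pulse(sitAmplitude(b, 5e-3), 0, b, 5e-3)
    expect_equal(sitFinalAngle(pulse), 2 * pi, tolerance = 1e-12)
  }
  expect_error(sitAmplitude(-1, 5e-3), "positive")
})

test_that("invalid pulse parameters are rejected by class validity", {
  expect_error(hs1Pulse(-1, 0, 2, 5e-3), "omega1m")
  expect_error(hs1Pulse(1, 0, 0, 5e-3), "beta")
  expect_error(hs1Pulse(1, 0, 2, -5e-3, tStart = 0, tEnd = 1), "Tp")
  expect_error(squarePulse(1, tStart = 1, tEnd = 0.5), "tStart")
})

test_that("BIR-4 is four contiguous half pulses with the flip-angle phase shifts", {
  tmpl <- hs1FromSpec(2 * pi * 2000, 5e-3, R = 32, truncation = 0.1)
  theta <- pi
  b4 <- makeBir4(theta, tmpl)
  expect_s4_class(b4, "CompositePulse")
  expect_equal(pulseDuration(b4), 2 * tmpl@Tp)
  expect_length(b4@segments, 4)
  expect_equal(b4@phaseOffsets, c(0, pi + theta / 2, pi + theta / 2, 0))
  # AM continuous at the outer junctions, peaks at start/middle/end
  w <- evalWaveform(b4, c(0, 2.5e-3 - 1e-12, 2.5e-3 + 1e-12, 5e-3,
                          7.5e-3 - 1e-12, 7.5e-3 + 1e-12, 10e-3))
  expect_equal(w$am[2], w$am[3], tolerance = 1e-9)
  expect_equal(w$am[5], w$am[6], tolerance = 1e-9)
  expect_equal(w$am[c(1, 4, 7)], rep(tmpl@omega1m, 3), tolerance = 1e-9)
  # truncation-level amplitude at the outer junctions
  expect_equal(w$am[2] / tmpl@omega1m, 1 / cosh(tmpl@beta),
               tolerance = 1e-6)
  # contiguity invariant is enforced
  segs <- b4@segments
  segs[[2]]@tStart <- segs[[2]]@tStart + 1e-3
  expect_error(compositePulse(segs), "contiguous")
})
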