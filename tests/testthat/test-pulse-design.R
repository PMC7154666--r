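test_that("hard and Gaussian pulses hit their flip angle by construction", {
  expect_error(gaussianPulse(2.5, 0), "positive")
  expect_error(hardPulse(0.1, -3), "positive")
  g <- gaussianPulse(2.5, 15, nSamples = 250, truncationSigma = 3)
  expect_equal(flipAngleOf(g), 15, tolerance = 1e-12)
  # hard pulse peak amplitude: theta / (gamma tau)
  h <- hardPulse(0.1, 15)
  peak <- (15 * pi / 180) / (2 * pi * 42.577e-3 * 0.1)
  expect_equal(max(pulseSamples(h)), peak, tolerance = 1e-12)
  expect_equal(peak, 9.786, tolerance = 1e-3)
})

test_that("flip angle is linear, excludes side bands, and matches the
           analytic Gaussian area", {
  g <- gaussianPulse(2.5, 10)
  g2 <- g
  g2@samples <- g@samples * 2
  expect_equal(flipAngleOf(g2), 20, tolerance = 1e-12)
  # sampled (midpoint-rule) integral vs the analytic truncated-Gaussian
  # area A sigma sqrt(2 pi) erf(3 / sqrt(2)); agreement is limited by the
  # 250-sample discretization
  n <- nrow(pulseSamples(g))
  t <- ((seq_len(n) - 0.5) / n - 0.5) * 2.5
  sigma <- 2.5 / 6
  amp <- pulseSamples(g)[1, 1] / exp(-t[1]^2 / (2 * sigma^2))
  analytic <- amp * sigma * sqrt(2 * pi) *
    (2 * stats::pnorm(3) - 1)
  discrete <- sum(pulseSamples(g)) * 2.5 / n
  expect_equal(discrete, analytic, tolerance = 1e-3)
  # zero pulse and missing on-resonance band
  z <- new("RFPulse", samples = matrix(0, 10, 1), dwell = 10,
           bandOffsets = 0, label = "zero")
  expect_equal(flipAngleOf(z), 0)
  off <- new("RFPulse", samples = matrix(1, 10, 1), dwell = 10,
             bandOffsets = 6000, label = "offres")
  expect_warning(fa <- flipAngleOf(off), "no on-resonance")
  expect_equal(fa, 0)
})

test_that("RMS B1 over TR follows the power integral", {
  z <- new("RFPulse", samples = matrix(0, 10, 1), dwell = 10,
           bandOffsets = 0, label = "zero")
  expect_equal(b1rmsOverTr(z, 7), 0)
  # hard pulse: B * sqrt(tau / TR)
  h <- hardPulse(0.2, 15)
  B <- max(pulseSamples(h))
  expect_equal(b1rmsOverTr(h, 7), B * sqrt(0.2 / 7), tolerance = 1e-12)
  expect_error(b1rmsOverTr(h, 0.1), "at least the pulse duration")
  # multiband power additivity: total squared power = sum of band powers
  p <- designCsmtPulse(15, csmtDesign(), 7)
  perBand <- vapply(1:3, function(b) {
    single <- new("RFPulse",
                  samples = pulseSamples(p)[, b, drop = FALSE],
                  dwell = p@dwell, bandOffsets = bandOffsets(p)[b],
                  label = "band")
    b1rmsOverTr(single, 7)^2
  }, numeric(1))
  expect_equal(sum(perBand), b1rmsOverTr(p, 7)^2, tolerance = 1e-12)
})

test_that("RMS B1 is invariant to sample-count refinement", {
  for (ns in c(250L, 500L)) {
    d <- new("CsmtDesign", targetB1rms = 1.6, bandOffset = 6000,
             baseDuration = 2.5, baseShape = "gaussian",
             nSamples = ns, truncationSigma = 3)
    p <- designCsmtPulse(25, d, 7)
    expect_equal(b1rmsOverTr(p, 7), 1.6, tolerance = 1e-9)
  }
  g1 <- gaussianPulse(2.5, 15, nSamples = 250)
  g2 <- gaussianPulse(2.5, 15, nSamples = 500)
  expect_lt(abs(b1rmsOverTr(g1, 7) - b1rmsOverTr(g2, 7)) /
              b1rmsOverTr(g1, 7), 1e-4)
})

test_that("constant-power design meets both constraints for every
           protocol flip angle", {
  fas <- c(3, 7, 11, 15, 5, 25, 45)
  rms <- vapply(fas, function(fa) {
    p <- designCsmtPulse(fa, csmtDesign(), 7)
    expect_equal(flipAngleOf(p), fa, tolerance = 1e-9)
    b1rmsOverTr(p, 7)
  }, numeric(1))
  expect_equal(rms, rep(1.6, length(fas)), tolerance = 1e-6)
  expect_lt(diff(range(rms)), 1e-6)
})

test_that("design degenerates and fails gracefully at the power budget", {
  # target set exactly to the on-resonance band's own RMS: zero side bands
  base <- gaussianPulse(2.5, 15)
  own <- b1rmsOverTr(base, 7)
  d <- csmtDesign(targetB1rms = own)
  p <- designCsmtPulse(15, d, 7)
  expect_equal(max(abs(pulseSamples(p)[, c(1, 3)])), 0)
  # infeasible: flip angle too large for the budget
  dSmall <- csmtDesign(targetB1rms = 0.3)
  err <- expect_error(designCsmtPulse(45, dSmall, 7), "infeasible")
  expect_match(conditionMessage(err), "uT")
})
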