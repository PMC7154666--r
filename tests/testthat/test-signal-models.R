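test_that("SPGR closed form: limits and the Ernst angle", {
  tis <- singlePoolTissue(1000, 80)
  expect_equal(spgrSignal(tis, 0, 7), 0)
  # full-recovery limit tr >> t1
  expect_equal(spgrSignal(singlePoolTissue(10, 5), 30 * pi / 180, 1e5),
               sin(30 * pi / 180), tolerance = 1e-10)
  # grid-search argmax equals the closed-form Ernst angle
  fa <- seq(0.001, 0.6, length.out = 20000)
  expect_equal(fa[which.max(spgrSignal(tis, fa, 7))],
               acos(exp(-7 / 1000)), tolerance = 1e-3)
  expect_error(spgrSignal(tis, 0.1, -7), "positive")
})

test_that("bSSFP closed form agrees with iterative Bloch propagation", {
  # frozen spot check
  tis <- singlePoolTissue(1000, 45, 1, 0)
  acq <- bssfpAcq(45, tr = 7, phaseIncrement = 180)
  cf <- bssfpSignal(tis, acq)
  or <- blochPropagateOracle(tis, acq, nReps = 20000)
  expect_lt(abs(cf - or) / abs(or), 1e-8)
  expect_true(attr(or, "converged"))
  expect_lt(abs(bssfpSignal(singlePoolTissue(1000, 45), acq,
                            b1Scale = 1e-9)), 1e-8)
  # property: random draws within physiological ranges (vectorised oracle)
  set.seed(7)
  n <- 200
  t1 <- runif(n, 300, 3000)
  t2 <- runif(n, 20, pmin(t1, 300))
  m0 <- runif(n, 0.3, 1.5)
  df <- runif(n, -71, 71)
  for (inc in c(180, 0)) {
    a <- bssfpAcq(runif(1, 10, 50), tr = 7, phaseIncrement = inc)
    cf <- csmtqmri:::.bssfpSignal(m0, t1, t2, a@faNominal * pi / 180, df,
                                  7, 3.5, inc * pi / 180)
    or <- blochPropagateOracle(list(t1 = t1, t2 = t2, m0 = m0, deltaF = df),
                               a, nReps = 20000)
    expect_lt(max(abs(cf - or) / abs(or)), 1e-8)
  }
})

test_that("bSSFP banding: periodicity and phase-cycle equivalence", {
  acq180 <- bssfpAcq(45, tr = 7, phaseIncrement = 180)
  acq0 <- bssfpAcq(45, tr = 7, phaseIncrement = 0)
  period <- 1000 / 7
  s1 <- bssfpSignal(singlePoolTissue(1000, 45, 1, 20), acq180)
  s2 <- bssfpSignal(singlePoolTissue(1000, 45, 1, 20 + period), acq180)
  expect_equal(abs(s1), abs(s2), tolerance = 1e-10)
  # 180 vs 0 increment with off-resonance shifted by half a period
  s3 <- bssfpSignal(singlePoolTissue(1000, 45, 1, 20 + period / 2), acq0)
  expect_equal(abs(s1), abs(s3), tolerance = 1e-10)
  # on-resonance mid-passband, null at the band edge
  sMid <- abs(bssfpSignal(singlePoolTissue(1000, 45, 1, 0), acq180))
  sEdge <- abs(bssfpSignal(singlePoolTissue(1000, 45, 1, period / 2),
                           acq180))
  expect_gt(sMid, 5 * sEdge)
})

test_that("single-pulse excitation from equilibrium gives the expected FID",
{
  tis <- singlePoolTissue(1000, 45)
  acq <- bssfpAcq(90, tr = 7, phaseIncrement = 0)
  s <- blochPropagateOracle(tis, acq, nReps = 1)
  expect_equal(as.numeric(abs(s)), exp(-3.5 / 45), tolerance = 1e-12)
})

test_that("oracle steady state is a fixed point under rep doubling", {
  tis <- singlePoolTissue(800, 60, 1, 11)
  acq <- bssfpAcq(30, tr = 7, phaseIncrement = 180)
  s1 <- blochPropagateOracle(tis, acq, nReps = 20000)
  s2 <- blochPropagateOracle(tis, acq, nReps = 40000)
  expect_lt(abs(s1 - s2) / abs(s1), 1e-10)
})

test_that("RF spoiling converges to the ideally spoiled signal", {
  acq <- spgrAcq(15, rfIncrement = 50)
  # no transverse coherence survives when t2 -> 0
  tis0 <- singlePoolTissue(1100, 1e-3)
  s <- spgrRfSpoiled(tis0, acq)
  expect_lt(abs(s - spgrSignal(tis0, 15 * pi / 180, 7)) /
              spgrSignal(tis0, 15 * pi / 180, 7), 1e-3)
  expect_error(spgrRfSpoiled(tis0, acq, nIsochromats = 32), "64")
  # ensemble refinement: doubling isochromats barely moves the signal
  tis <- singlePoolTissue(1100, 45)
  s256 <- spgrRfSpoiled(tis, acq, nIsochromats = 256)
  s512 <- spgrRfSpoiled(tis, acq, nIsochromats = 512)
  expect_lt(abs(s512 - s256) / s256, 1e-3)
  expect_true(all(attr(s256, "converged")))
  # absent RF spoiling deviates more than the 50-degree schedule
  ideal <- spgrSignal(tis, 15 * pi / 180, 7)
  s0 <- spgrRfSpoiled(tis, spgrAcq(15, rfIncrement = 0))
  expect_gt(abs(s0 - ideal), abs(s256 - ideal))
})

test_that("saturation rate: power law, additivity and the Lorentzian closed
           form", {
  expect_equal(mtSaturationRate(0, 6000, 12), 0)
  w1 <- mtSaturationRate(1.2, 6000, 12)
  expect_equal(mtSaturationRate(2.4, 6000, 12), 4 * w1, tolerance = 1e-12)
  gam <- 2 * pi * 42.577
  t2bS <- 12e-6
  wL <- pi * (gam * 1.6)^2 * (t2bS / pi) / (1 + (2 * pi * 6000 * t2bS)^2)
  expect_equal(mtSaturationRate(1.6, 6000, 12, "lorentzian"), wL,
               tolerance = 1e-12)
  expect_error(mtSaturationRate(-1, 6000, 12), "non-negative")
  # additivity over pulse bands
  p <- designCsmtPulse(15, csmtDesign(), 7)
  tot <- csmtqmri:::.saturationExponentPerTr(p, 12)
  perBand <- vapply(1:3, function(b) {
    single <- new("RFPulse", samples = pulseSamples(p)[, b, drop = FALSE],
                  dwell = p@dwell, bandOffsets = bandOffsets(p)[b],
                  label = "band")
    csmtqmri:::.saturationExponentPerTr(single, 12)
  }, numeric(1))
  expect_equal(sum(perBand), tot, tolerance = 1e-12)
})

test_that("two-pool models reduce exactly to single pool at zero bound
           fraction", {
  tp <- twoPoolTissue(1100, 45, m0f = 0.77, boundFraction = 0, kf = 0,
                      deltaF = 17)
  sp <- singlePoolTissue(1100, 45, 0.77, 17)
  acqS <- spgrAcq(15, pulse = hardPulse(0.1, 15))
  expect_equal(mtSpgrSignal(tp, acqS),
               spgrSignal(sp, 15 * pi / 180, 7), tolerance = 1e-12)
  acqB <- bssfpAcq(45, phaseIncrement = 180, pulse = hardPulse(0.1, 45))
  expect_lt(abs(mtBssfpSignal(tp, acqB) - bssfpSignal(sp, acqB)) /
              abs(bssfpSignal(sp, acqB)), 1e-10)
})

test_that("fully saturated bound pool matches brute-force propagation with
           a clamped bound term", {
  tp <- wmTwoPool()
  acq <- spgrAcq(15, pulse = hardPulse(0.1, 15))
  # model evaluated at an enormous saturation exponent
  tis <- csmtqmri:::.twoPoolAsList(tp)
  sBig <- csmtqmri:::.mtSpgrSignal(tis, 15 * pi / 180, 1e6 * 7 / 1000, 7)
  # brute force: iterate the pre-pulse recursion clamping Mzb to 0 at pulses
  prop <- csmtqmri:::.exchangePropagator(tis, 7)
  L <- c(tis$m0f, tis$m0f * tis$boundFraction)
  ca <- cos(15 * pi / 180)
  for (k in 1:20000) {
    Lp <- c(L[1] * ca, 0)
    L <- c(prop$p11 * Lp[1] + prop$p12 * Lp[2] + prop$r1,
           prop$p21 * Lp[1] + prop$p22 * Lp[2] + prop$r2)
  }
  expect_equal(sBig, sin(15 * pi / 180) * L[1], tolerance = 1e-10)
})

test_that("all signals scale linearly in equilibrium magnetization", {
  tp <- wmTwoPool(deltaF = 9)
  tp2 <- tp; tp2@m0f <- tp@m0f * 3
  acqS <- spgrAcq(11, pulse = designCsmtPulse(11))
  acqB <- bssfpAcq(25, pulse = designCsmtPulse(25))
  expect_equal(mtSpgrSignal(tp2, acqS), 3 * mtSpgrSignal(tp, acqS),
               tolerance = 1e-12)
  expect_equal(mtBssfpSignal(tp2, acqB), 3 * mtBssfpSignal(tp, acqB),
               tolerance = 1e-12)
  sp <- wmSingle(); sp3 <- singlePoolTissue(1000, 45, 3)
  expect_equal(spgrSignal(sp3, 0.2, 7), 3 * spgrSignal(sp, 0.2, 7),
               tolerance = 1e-14)
})

test_that("two-pool bSSFP: periodic in off-resonance; constant-power pulse
           depresses the signal relative to a weak native pulse", {
  tp <- wmTwoPool(deltaF = 23)
  acq <- bssfpAcq(45, phaseIncrement = 180, pulse = hardPulse(0.1, 45))
  tpShift <- tp; tpShift@deltaF <- 23 + 1000 / 7
  expect_equal(abs(mtBssfpSignal(tp, acq)),
               abs(mtBssfpSignal(tpShift, acq)), tolerance = 1e-10)
  # the 3-band constant-power pulse deposits more saturation than a weak
  # on-resonance pulse at low flip angle -> lower free-pool signal
  tp0 <- wmTwoPool()
  acqNative5 <- bssfpAcq(5, phaseIncrement = 180, pulse = hardPulse(0.1, 5))
  acqCsmt5 <- bssfpAcq(5, phaseIncrement = 180, pulse = designCsmtPulse(5))
  expect_lt(abs(mtBssfpSignal(tp0, acqCsmt5)),
            abs(mtBssfpSignal(tp0, acqNative5)))
})

test_that("cross-protocol T1 bias appears under native pulses and is
           rescued by constant-power excitation", {
  tp <- wmTwoPool(deltaF = 10)
  subs <- defaultSubsets()
  fitT1 <- function(d, subset) {
    rows <- subsetRows(d$meta, subset)
    jsrFitVoxel(d$sig[rows], d$meta[rows, ], 1)@t1
  }
  dNative <- twoPoolVoxelData(tp, "native", vendorDur = 0.1)
  dCsmt <- twoPoolVoxelData(tp, "csmt")
  t1NativeLoHi <- fitT1(dNative, subs$S2)   # SPGR 3/15
  t1NativeMid <- fitT1(dNative, subs$S3)    # SPGR 7/11
  t1CsmtLoHi <- fitT1(dCsmt, subs$S2)
  t1CsmtMid <- fitT1(dCsmt, subs$S3)
  expect_gt(abs(variability(t1NativeLoHi, t1NativeMid)), 2)
  expect_lt(abs(variability(t1CsmtLoHi, t1CsmtMid)), 0.5)
})
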