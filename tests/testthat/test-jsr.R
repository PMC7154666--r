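test_that("linearized SPGR initialization is exact on noiseless data and
           sensitive to the transmit field", {
  tis <- singlePoolTissue(1000, 80, m0 = 2)
  fas <- c(3, 15)
  s <- vapply(fas, function(f) spgrSignal(tis, f * pi / 180, 7), numeric(1))
  est <- despot1Init(s, fas, 1, 7)
  expect_equal(est$t1, 1000, tolerance = 1e-4)
  expect_equal(est$m0, 2, tolerance = 1e-4)
  # ignoring a 0.9 transmit scale biases T1
  sB1 <- vapply(fas, function(f) spgrSignal(tis, 0.9 * f * pi / 180, 7),
                numeric(1))
  estB1 <- despot1Init(sB1, fas, 1, 7)
  expect_gt(abs(estB1$t1 - 1000) / 1000, 0.05)
  expect_error(despot1Init(s, c(10, 10), 1, 7), "distinct")
})

test_that("residual vector: zero at truth, one entry per volume, periodic
           in off-resonance", {
  tis <- wmSingle(deltaF = 12)
  d <- singlePoolVoxelData(tis)
  p <- c(m0 = 1, t1 = 1000, t2 = 45, deltaF = 12)
  r <- jsrResidual(p, d$sig, d$meta)
  expect_length(r, nrow(d$meta))
  expect_equal(max(abs(r)), 0, tolerance = 1e-12)
  # shifting deltaF by one full period leaves bSSFP residuals unchanged
  p2 <- p; p2[["deltaF"]] <- 12 + 1000 / 7
  r2 <- jsrResidual(p2, d$sig, d$meta)
  iB <- which(d$meta$sequence == "bssfp")
  expect_equal(r2[iB], r[iB], tolerance = 1e-10)
  badMeta <- d$meta; badMeta$sequence[1] <- "epi"
  expect_error(jsrResidual(p, d$sig, badMeta), "unknown sequence")
})

test_that("voxel fit recovers noiseless single-pool parameters", {
  for (df in c(-40, 0, 33)) {
    tis <- singlePoolTissue(1000, 45, 0.8, df)
    d <- singlePoolVoxelData(tis, b1 = 0.93)
    est <- jsrFitVoxel(d$sig, d$meta, 0.93)
    expect_true(est@converged)
    expect_lt(abs(est@t1 - 1000) / 1000, 1e-3)
    expect_lt(abs(est@t2 - 45) / 45, 1e-3)
    # off-resonance sign is not identifiable from magnitudes
    expect_lt(abs(abs(est@deltaF) - abs(df)), 0.5)
    expect_true(est@t2LeT1)
  }
})

test_that("voxel at the band edge is recovered wrap-equivalently", {
  edge <- 1000 / 14            # +1/(2 TR) in Hz
  tis <- singlePoolTissue(1000, 45, 1, edge)
  d <- singlePoolVoxelData(tis)
  est <- jsrFitVoxel(d$sig, d$meta, 1)
  wrapDist <- min(abs(abs(est@deltaF) - edge),
                  abs(abs(est@deltaF) - edge + 1000 / 7))
  expect_lt(wrapDist, 0.5)
})

test_that("missing bSSFP volumes make T2 unidentifiable and error out", {
  tis <- wmSingle()
  d <- singlePoolVoxelData(tis)
  iS <- which(d$meta$sequence == "spgr")
  expect_error(jsrFitVoxel(d$sig[iS], d$meta[iS, ], 1), "identifiable")
  one <- c(iS, which(d$meta$sequence == "bssfp")[1])
  expect_error(jsrFitVoxel(d$sig[one], d$meta[one, ], 1), "identifiable")
})

test_that("batched volume engine agrees with the per-voxel reference fit", {
  set.seed(11)
  n <- 40
  meta <- protocolMeta()
  t1 <- runif(n, 700, 1600); t2 <- runif(n, 35, 90)
  m0 <- runif(n, 0.6, 1); df <- runif(n, -60, 60)
  b1 <- runif(n, 0.85, 1.15)
  data <- matrix(0, n, nrow(meta))
  for (j in seq_len(nrow(meta))) {
    a <- b1 * meta$fa[j] * pi / 180
    data[, j] <- if (meta$sequence[j] == "spgr")
      csmtqmri:::.spgrSignal(m0, t1, a, 7)
    else abs(csmtqmri:::.bssfpSignal(m0, t1, t2, a, df, 7, 3.5,
                                     meta$phaseIncrement[j] * pi / 180))
  }
  data <- data + matrix(rnorm(n * nrow(meta), sd = median(data[, 4]) / 100),
                        n, nrow(meta))
  cfg <- fitConfig()
  fit <- csmtqmri:::.jsrEngine(data, meta, b1, 7, 3.5, cfg)
  for (i in seq_len(10)) {
    ref <- jsrFitVoxel(data[i, ], meta, b1[i], cfg)
    expect_lt(abs(fit$p$t1[i] - ref@t1) / ref@t1, 1e-4)
    expect_lt(abs(fit$p$t2[i] - ref@t2) / ref@t2, 1e-4)
  }
})

test_that("volume fit recovers the noiseless phantom and respects the mask",
{
  ph <- makeDigitalPhantom(c(32, 32, 32), seed = 1)
  ph <- csmtqmri:::.singlePoolReduction(ph)
  fl <- makeFieldMaps(c(32, 32, 32), seed = 1)
  acq <- simulateAcquisition(ph, fl, vendorProfiles()$B, protocolSpec(),
                             noiseSd = 0)
  wm <- ph@labels == 1L
  maps <- jsrFitVolume(acq, defaultSubsets()$S1, mask = wm)
  t1err <- abs(maps@t1[wm] - 1100) / 1100
  t2err <- abs(maps@t2[wm] - 45) / 45
  expect_lt(max(t1err), 1e-3)
  expect_lt(max(t2err), 1e-3)
  expect_true(all(is.na(maps@t1[!wm])))
  # two different valid subsets agree on noiseless single-pool data
  maps2 <- jsrFitVolume(acq, defaultSubsets()$S3, mask = wm)
  expect_lt(abs(variability(roiMedian(maps@t1, wm),
                            roiMedian(maps2@t1, wm))), 0.1)
  # determinism
  maps3 <- jsrFitVolume(acq, defaultSubsets()$S1, mask = wm)
  expect_identical(maps@t1, maps3@t1)
})
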