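test_that("digital phantom is deterministic, labelled and WM-rich", {
  ph1 <- makeDigitalPhantom(c(32, 32, 32), seed = 3)
  ph2 <- makeDigitalPhantom(c(32, 32, 32), seed = 3)
  expect_identical(ph1@labels, ph2@labels)
  expect_false(identical(ph1@labels,
                         makeDigitalPhantom(c(32, 32, 32), seed = 4)@labels))
  expect_setequal(unique(as.vector(ph1@labels)), 0:3)
  head <- sum(ph1@labels > 0)
  expect_gte(sum(ph1@labels == 1L) / head, 0.20)
  expect_error(makeDigitalPhantom(c(16, 32, 32)), "at least 32")
})

test_that("white-matter voxel count at the default grid is stable", {
  # golden value established at first build of the 64^3 default geometry
  ph <- makeDigitalPhantom(c(64, 64, 64), seed = 1)
  expect_identical(sum(ph@labels == 1L), 22216L)
})

test_that("field maps span their ranges, are smooth and deterministic", {
  fl <- makeFieldMaps(c(64, 64, 64), seed = 5)
  expect_equal(range(fieldB1(fl)), c(0.85, 1.15), tolerance = 1e-12)
  expect_equal(range(fieldB0(fl)), c(-60, 60), tolerance = 1e-12)
  fl2 <- makeFieldMaps(c(64, 64, 64), seed = 5)
  expect_identical(fieldB1(fl), fieldB1(fl2))
  # degenerate range: uniform map
  flu <- makeFieldMaps(c(32, 32, 32), b1Range = c(1, 1), seed = 1)
  expect_true(all(fieldB1(flu) == 1))
  # smoothness of the quadratic field: voxel-to-voxel steps are a small
  # fraction of the full range (bounded by the generator's degree design)
  for (seed in 1:3) {
    b1 <- fieldB1(makeFieldMaps(c(64, 64, 64), seed = seed))
    n <- 64
    step <- max(abs(b1[-1, , ] - b1[-n, , ]),
                abs(b1[, -1, ] - b1[, -n, ]),
                abs(b1[, , -1] - b1[, , -n]))
    expect_lt(step / diff(range(b1)), 0.025)
  }
})

test_that("Rician noise has the expected zero-signal and high-SNR behavior",
{
  v <- array(100, dim = c(10, 10, 10))
  expect_identical(addRicianNoise(v, 0, 1), v)
  expect_identical(addRicianNoise(v, 2, 7), addRicianNoise(v, 2, 7))
  # zero-signal voxels: Rayleigh mean sd sqrt(pi/2)
  z <- array(0, dim = c(22, 22, 22))
  zn <- addRicianNoise(z, 3, 11)
  expect_equal(mean(zn), 3 * sqrt(pi / 2), tolerance = 0.02)
  # high-SNR voxels: empirical sd approaches the channel sd
  n <- array(1000, dim = c(22, 22, 22))
  nn <- addRicianNoise(n, 3, 13)
  expect_equal(stats::sd(nn), 3, tolerance = 0.05)
})

test_that("simulated acquisition reduces to closed forms for single-pool
           truth and is deterministic", {
  ph <- makeDigitalPhantom(c(32, 32, 32), seed = 1)
  ph@tissueParams <- lapply(ph@tissueParams, function(tp) {
    tp@boundFraction <- 0; tp@kf <- 0; tp
  })
  fl <- makeFieldMaps(c(32, 32, 32), seed = 1)
  vp <- vendorProfiles()
  acq <- simulateAcquisition(ph, fl, vp$B, protocolSpec(), noiseSd = 0)
  expect_length(acqVolumes(acq), 8)
  expect_equal(sum(acqMeta(acq)$sequence == "spgr"), 4)
  expect_equal(sum(acqMeta(acq)$phaseIncrement == 180, na.rm = TRUE), 3)
  expect_equal(sum(acqMeta(acq)$phaseIncrement == 0, na.rm = TRUE), 1)
  # voxel-wise agreement with the closed-form single-pool models
  i <- which(ph@labels == 1L)[c(1, 50, 200)]
  tis <- ph@tissueParams[["1"]]
  for (j in c(2, 6)) {
    m <- acqMeta(acq)[j, ]
    for (v in i) {
      b1v <- fieldB1(fl)[v]
      ref <- if (m$sequence == "spgr") {
        spgrSignal(singlePoolTissue(tis@t1f, tis@t2f, tis@m0f),
                   b1v * m$fa * pi / 180, 7)
      } else {
        abs(bssfpSignal(
          singlePoolTissue(tis@t1f, tis@t2f, tis@m0f, fieldB0(fl)[v]),
          bssfpAcq(m$fa, phaseIncrement = m$phaseIncrement), b1v))
      }
      expect_equal(acqVolumes(acq)[[j]][v], ref, tolerance = 1e-10)
    }
  }
  # same seed, same bytes
  acq2 <- simulateAcquisition(ph, fl, vp$B, protocolSpec(), noiseSd = 0)
  expect_identical(acqVolumes(acq), acqVolumes(acq2))
  acqN <- simulateAcquisition(ph, fl, vp$B, protocolSpec(), seed = 9)
  acqN2 <- simulateAcquisition(ph, fl, vp$B, protocolSpec(), seed = 9)
  expect_identical(acqVolumes(acqN), acqVolumes(acqN2))
})

test_that("replicates share truth and differ only in noise", {
  ph <- makeDigitalPhantom(c(32, 32, 32), seed = 2)
  fl <- makeFieldMaps(c(32, 32, 32), seed = 2)
  vp <- vendorProfiles()
  reps <- replicateAcquisition(ph, fl, vp$A, protocolSpec(), nReplicates = 2,
                               baseSeed = 5)
  expect_length(reps, 2)
  m1 <- acqMeta(reps[[1]]); m2 <- acqMeta(reps[[2]])
  expect_false(any(m1$noiseSeed == m2$noiseSeed))
  expect_identical(reps[[1]]@truth@labels, reps[[2]]@truth@labels)
  # noiseless replicates would be identical: voxelwise variability is zero
  reps0 <- replicateAcquisition(ph, fl, vp$A, protocolSpec(),
                                nReplicates = 2, baseSeed = 5, snr = Inf)
  expect_identical(acqVolumes(reps0[[1]]), acqVolumes(reps0[[2]]))
  v <- voxelwiseVariability(acqVolumes(reps0[[1]])[[1]],
                            acqVolumes(reps0[[2]])[[1]],
                            ph@labels == 1L)
  expect_true(all(v$values == 0))
})
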