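test_that("spherical erosion matches brute-force set computation on digital
           balls", {
  d <- c(25, 25, 25)
  ctr <- 13
  ball <- function(r) {
    g <- expand.grid(x = 1:d[1], y = 1:d[2], z = 1:d[3])
    array((g$x - ctr)^2 + (g$y - ctr)^2 + (g$z - ctr)^2 <= r^2 + 1e-9,
          dim = d)
  }
  b5 <- ball(5)
  expect_identical(erodeMask(b5, 0), b5)
  # brute force: a voxel survives iff every offset within 2 mm stays inside
  er <- erodeMask(b5, 2, 1)
  offs <- expand.grid(dx = -2:2, dy = -2:2, dz = -2:2)
  offs <- offs[offs$dx^2 + offs$dy^2 + offs$dz^2 <= 4 + 1e-9, ]
  inside <- function(x, y, z) {
    all(vapply(seq_len(nrow(offs)), function(i) {
      xx <- x + offs$dx[i]; yy <- y + offs$dy[i]; zz <- z + offs$dz[i]
      xx >= 1 && yy >= 1 && zz >= 1 && xx <= d[1] && yy <= d[2] &&
        zz <= d[3] && b5[xx, yy, zz]
    }, logical(1)))
  }
  idx <- which(b5, arr.ind = TRUE)
  ref <- array(FALSE, dim = d)
  for (i in seq_len(nrow(idx)))
    ref[idx[i, 1], idx[i, 2], idx[i, 3]] <-
      inside(idx[i, 1], idx[i, 2], idx[i, 3])
  expect_identical(er, ref)
  # the eroded ball is the radius-3 digital ball
  expect_identical(er, ball(3))
  expect_error(erodeMask(ball(1), 5), "empty")
})

test_that("erosion output is always a subset of the input", {
  set.seed(21)
  for (k in 1:5) {
    m <- array(runif(20^3) > 0.4, dim = c(20, 20, 20))
    er <- erodeMask(m, 1, 1)
    expect_true(all(!er | m))
  }
})

test_that("ROI median: constants, skew robustness, sort oracle", {
  m <- array(7, dim = c(4, 4, 4))
  mask <- array(TRUE, dim = c(4, 4, 4))
  expect_equal(roiMedian(m, mask), 7)
  sk <- array(NA_real_, dim = c(3, 1, 1))
  sk[] <- c(1, 2, 100)
  expect_equal(roiMedian(sk, array(TRUE, dim = c(3, 1, 1))), 2)
  set.seed(3)
  r <- array(rnorm(125), dim = c(5, 5, 5))
  msk <- array(runif(125) > 0.3, dim = c(5, 5, 5))
  v <- sort(r[msk])
  n <- length(v)
  ref <- if (n %% 2 == 1) v[(n + 1) / 2] else mean(v[n / 2 + 0:1])
  expect_equal(roiMedian(r, msk), ref)
  expect_error(roiMedian(array(NA_real_, dim = c(2, 2, 2)),
                         array(TRUE, dim = c(2, 2, 2))), "no finite")
})

test_that("variability and deviation follow their printed definitions", {
  expect_equal(variability(100, 100), 0)
  expect_equal(variability(110, 90), 20)
  expect_equal(variability(3, 5), -variability(5, 3))
  expect_error(variability(1, -1), "zero")
  expect_equal(deviation(c(90, 100, 110)), c(-10, 0, 10),
               tolerance = 1e-12)
  expect_equal(deviation(c(5, 5, 5)), c(0, 0, 0))
  set.seed(9)
  x <- runif(12, 50, 150)
  expect_equal(sum(deviation(x)), 0, tolerance = 1e-10)
  expect_error(deviation(5), "at least two")
})

test_that("worst-case variability is attained at the extremes", {
  expect_equal(worstCaseVariability(c(4, 4)), 0)
  expect_equal(worstCaseVariability(c(90, 100, 110)), 20)
  # adding an interior value never increases the worst case
  set.seed(5)
  for (k in 1:10) {
    m <- runif(4, 80, 120)
    inner <- runif(1, min(m), max(m))
    expect_lte(worstCaseVariability(c(m, inner)), worstCaseVariability(m))
  }
})

test_that("voxelwise variability: identity, constant ratio, median
           consistency", {
  set.seed(2)
  a <- array(runif(1000, 500, 1500), dim = c(10, 10, 10))
  mask <- array(runif(1000) > 0.2, dim = c(10, 10, 10))
  v0 <- voxelwiseVariability(a, a, mask)
  expect_true(all(v0$values == 0))
  expect_equal(v0$median, 0)
  v1 <- voxelwiseVariability(1.1 * a, a, mask)
  expect_equal(unique(round(v1$values, 10)), 100 * 0.1 / 1.05,
               tolerance = 1e-9)
  # distribution median equals the ROI median of the variability image
  b <- a * array(runif(1000, 0.9, 1.1), dim = dim(a))
  v2 <- voxelwiseVariability(a, b, mask)
  img <- array(NA_real_, dim = dim(a))
  img[mask] <- 100 * (a[mask] - b[mask]) / (0.5 * (a[mask] + b[mask]))
  expect_equal(v2$median, roiMedian(img, mask))
  expect_error(voxelwiseVariability(a, array(1, dim = c(5, 5, 5)), mask),
               "different grids")
})
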