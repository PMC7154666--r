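# Study statistics: mask erosion, distribution medians, pairwise
# variability, deviation from the grand mean, worst-case variability and
# voxelwise variability distributions.

#' Morphological erosion with a spherical structuring element
#'
#' Erodes a binary mask by a ball of the given physical radius (the
#' structuring element is the set of integer offsets within the radius).
#' Used to pull the white-matter region away from tissue boundaries where
#' partial-volume effects would contaminate the statistics.
#'
#' @param mask logical 3-D array
#' @param radiusMm erosion radius (mm), non-negative
#' @param voxelMm isotropic voxel size (mm)
#' @return eroded logical array (a subset of the input)
#' @export
erodeMask <- function(mask, radiusMm, voxelMm = 1) {
  stopifnot(radiusMm >= 0)
  if (radiusMm == 0) return(mask)
  r <- floor(radiusMm / voxelMm + 1e-9)
  offs <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  offs <- offs[with(offs, dx^2 + dy^2 + dz^2) * voxelMm^2 <=
                 radiusMm^2 + 1e-9, ]
  d <- dim(mask)
  out <- mask
  for (i in seq_len(nrow(offs))) {
    sh <- .shiftMask(mask, c(offs$dx[i], offs$dy[i], offs$dz[i]))
    out <- out & sh
  }
  if (!any(out))
    stop(sprintf("erosion by %.1f mm leaves an empty mask", radiusMm))
  out
}

# shift a logical array by integer offsets, padding with FALSE
.shiftMask <- function(mask, off) {
  d <- dim(mask)
  out <- array(FALSE, dim = d)
  src <- dst <- vector("list", 3)
  for (k in 1:3) {
    o <- off[k]
    if (o >= 0) { src[[k]] <- seq_len(d[k] - o); dst[[k]] <- src[[k]] + o }
    else { src[[k]] <- seq(1 - o, d[k]); dst[[k]] <- src[[k]] + o }
    if (d[k] - abs(o) <= 0) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
  out
}

#' Median of a map over a mask
#'
#' The median is used rather than the mean because the white-matter
#' distributions can be skewed; non-finite voxels are excluded.
#'
#' @param map numeric array
#' @param mask logical array of the same shape
#' @return scalar median
#' @export
roiMedian <- function(map, mask) {
  v <- map[mask]
  v <- v[is.finite(v)]
  if (!length(v)) stop("no finite voxels in mask")
  stats::median(v)
}

#' Pairwise variability (percent)
#'
#' Percentage difference normalized by the pair mean:
#' \code{100 (m_i - m_j) / (0.5 (m_i + m_j))}. Signed and antisymmetric.
#'
#' @param mi,mj the two measures (vectorised)
#' @return signed percent difference
#' @examples
#' variability(110, 90)   # 20
#' @export
variability <- function(mi, mj) {
  s <- mi + mj
  if (any(s == 0)) stop("pair mean is zero")
  100 * (mi - mj) / (0.5 * s)
}

#' Deviation from the grand mean (percent)
#'
#' \code{100 (m_i - mean(m)) / mean(m)} for each measure; deviations sum to
#' zero by construction.
#'
#' @param values at least two measures
#' @return vector of signed percent deviations
#' @examples
#' deviation(c(90, 100, 110))
#' @export
deviation <- function(values) {
  if (length(values) < 2) stop("at least two values are required")
  m <- mean(values)
  if (m == 0) stop("mean is zero")
  100 * (values - m) / m
}

#' Worst-case variability (percent)
#'
#' The biggest observed absolute pairwise variability among a set of
#' medians; attained at the extremes of the set.
#'
#' @param medians at least two medians
#' @return maximum absolute pairwise variability
#' @examples
#' worstCaseVariability(c(90, 100, 110))   # variability(110, 90) = 20
#' @export
worstCaseVariability <- function(medians) {
  if (length(medians) < 2) stop("at least two medians are required")
  cmb <- utils::combn(length(medians), 2)
  max(abs(variability(medians[cmb[1, ]], medians[cmb[2, ]])))
}

#' Voxelwise variability distribution
#'
#' Per-voxel pairwise variability of two maps over a mask, summarised as a
#' histogram plus its median (the distribution "center").
#'
#' @param mapA,mapB numeric arrays on the same grid
#' @param mask logical array
#' @param binWidth histogram bin width (percent)
#' @return list: \code{values} (per-voxel percent), \code{median},
#'   \code{breaks}, \code{counts}
#' @export
voxelwiseVariability <- function(mapA, mapB, mask, binWidth = 0.5) {
  if (!identical(dim(mapA), dim(mapB)))
    stop("maps are on different grids")
  a <- mapA[mask]; b <- mapB[mask]
  ok <- is.finite(a) & is.finite(b) & (a + b != 0)
  v <- 100 * (a[ok] - b[ok]) / (0.5 * (a[ok] + b[ok]))
  lim <- max(abs(v), binWidth)
  breaks <- seq(-(ceiling(lim / binWidth) + 0.5) * binWidth,
                (ceiling(lim / binWidth) + 0.5) * binWidth, by = binWidth)
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  list(values = v, median = stats::median(v), breaks = h$breaks,
       counts = h$counts)
}
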