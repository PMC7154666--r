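# Joint system relaxometry: simultaneous single-pool fit of M0, T1, T2 and
# off-resonance from all SPGR and bSSFP magnitudes of a flip-angle subset,
# given the transmit-field map. The fitting model assumes ideal SPGR
# spoiling even when data were simulated with imperfect RF spoiling: that
# mismatch is part of what the harmonized-vs-native comparison studies.

#' Linearized SPGR initialization (DESPOT1)
#'
#' Classic linearization of the Ernst equation: regressing
#' \code{S/sin(a)} on \code{S/tan(a)} over the SPGR points gives slope
#' \code{E1 = exp(-TR/T1)} and intercept \code{m0 (1 - E1)}. The slope is
#' clipped to (0, 1) before the log.
#'
#' @param spgrSignals matrix (voxels x SPGR volumes) or vector of SPGR
#'   magnitudes
#' @param fasNominal nominal flip angles (degrees), one per SPGR volume; at
#'   least two distinct values are required
#' @param b1Scale transmit efficiency per voxel
#' @param tr repetition time (ms)
#' @return list with vectors \code{t1} (ms) and \code{m0}
#' @examples
#' s <- sapply(c(3, 15) * pi / 180, function(a)
#'   spgrSignal(singlePoolTissue(1000, 80), a, 7))
#' despot1Init(s, c(3, 15), 1, 7)
#' @export
despot1Init <- function(spgrSignals, fasNominal, b1Scale = 1, tr = 7) {
  if (is.vector(spgrSignals)) spgrSignals <- matrix(spgrSignals, nrow = 1)
  k <- length(fasNominal)
  if (ncol(spgrSignals) != k)
    stop("one flip angle per SPGR column is required")
  if (length(unique(fasNominal)) < 2)
    stop("at least two distinct SPGR flip angles are required")
  n <- nrow(spgrSignals)
  b1 <- rep_len(b1Scale, n)
  sx <- sy <- sxx <- sxy <- numeric(n)
  for (j in seq_len(k)) {
    a <- b1 * fasNominal[j] * pi / 180
    yj <- spgrSignals[, j] / sin(a)
    xj <- spgrSignals[, j] / tan(a)
    sx <- sx + xj; sy <- sy + yj
    sxx <- sxx + xj * xj; sxy <- sxy + xj * yj
  }
  denom <- k * sxx - sx * sx
  if (any(!is.finite(denom) | abs(denom) < .Machine$double.eps))
    stop("degenerate SPGR design (non-finite linearization)")
  slope <- (k * sxy - sx * sy) / denom
  slope <- .clip(slope, 1e-8, 1 - 1e-8)
  icpt <- (sy - slope * sx) / k
  t1 <- -tr / log(slope)
  list(t1 = t1, m0 = icpt / (1 - slope))
}

# model magnitudes for a parameter state; meta: data.frame with columns
# sequence, fa, phaseIncrement. Returns N x M matrix. `cols` restricts
# evaluation to given columns (others left NA) for cheap partial Jacobians.
.jsrModel <- function(m0, t1, t2, df, b1, meta, tr, te,
                      cols = seq_len(nrow(meta))) {
  n <- length(m0)
  out <- matrix(NA_real_, n, nrow(meta))
  for (j in cols) {
    a <- b1 * meta$fa[j] * pi / 180
    out[, j] <- if (meta$sequence[j] == "spgr") {
      .spgrSignal(m0, t1, a, tr)
    } else {
      abs(.bssfpSignal(m0, t1, t2, a, df, tr, te,
                       meta$phaseIncrement[j] * pi / 180))
    }
  }
  out
}

#' Joint-fit residual vector
#'
#' Concatenated (model - data) over the volumes of a subset: the ideally
#' spoiled SPGR model for SPGR entries (independent of off-resonance) and
#' the magnitude of the bSSFP steady state for bSSFP entries, sharing one
#' \code{m0} across all entries.
#'
#' @param params named numeric vector \code{c(m0, t1, t2, deltaF)}
#' @param measurements magnitudes, one per volume
#' @param meta data.frame with columns \code{sequence} ("spgr"/"bssfp"),
#'   \code{fa} (degrees), \code{phaseIncrement} (degrees, bSSFP)
#' @param b1Scale transmit efficiency
#' @param tr,te protocol timing (ms)
#' @return residual vector, one entry per volume
#' @export
jsrResidual <- function(params, measurements, meta, b1Scale = 1, tr = 7,
                        te = 3.5) {
  if (!all(meta$sequence %in% c("spgr", "bssfp")))
    stop("unknown sequence type in metadata")
  mod <- .jsrModel(params[["m0"]], params[["t1"]], params[["t2"]],
                   params[["deltaF"]], b1Scale, meta, tr, te)
  as.vector(mod) - measurements
}

# off-resonance multistart grid: k equally spaced points spanning the
# principal period, fixed order (deterministic)
.dfStarts <- function(k, tr) {
  period <- 1000 / tr
  ((seq_len(k) - (k + 1) / 2) / k) * period
}

.checkIdentifiable <- function(meta) {
  nS <- sum(meta$sequence == "spgr")
  nB <- sum(meta$sequence == "bssfp")
  nB180 <- sum(meta$sequence == "bssfp" & meta$phaseIncrement == 180)
  if (nS < 1 || nB < 2 || nB180 < 1)
    stop(paste("subset not identifiable: need at least 1 SPGR and 2 bSSFP",
               "volumes including one at 180-degree increment"))
  invisible(TRUE)
}

#' Fit one voxel by joint system relaxometry
#'
#' Bounded nonlinear least squares on (m0, t1, t2, deltaF) via
#' \code{minpack.lm::nls.lm}: T1 and M0 initialized from
#' \code{\link{despot1Init}}, T2 at 80 ms, off-resonance multistarted over
#' its principal period. Best final cost wins; ties are broken by smallest
#' absolute off-resonance.
#'
#' @param measurements magnitudes, one per volume (at least 4, spanning both
#'   sequence families)
#' @param meta volume metadata as in \code{\link{jsrResidual}}
#' @param b1Scale transmit efficiency at the voxel
#' @param config a \linkS4class{FitConfig}
#' @param tr,te protocol timing (ms)
#' @return a \linkS4class{JsrEstimate}
#' @export
jsrFitVoxel <- function(measurements, meta, b1Scale = 1,
                        config = fitConfig(), tr = 7, te = 3.5) {
  .checkIdentifiable(meta)
  if (length(measurements) != nrow(meta))
    stop("one measurement per metadata row is required")
  iS <- which(meta$sequence == "spgr")
  init <- if (length(iS) >= 2 &&
              length(unique(meta$fa[iS])) >= 2) {
    despot1Init(matrix(measurements[iS], nrow = 1), meta$fa[iS], b1Scale, tr)
  } else {
    list(t1 = 1000, m0 = max(measurements) * 10)
  }
  lb <- c(config@m0Bounds[1], config@t1Bounds[1], config@t2Bounds[1],
          config@deltaFBounds[1])
  ub <- c(min(config@m0Bounds[2], .Machine$double.xmax),
          config@t1Bounds[2], config@t2Bounds[2], config@deltaFBounds[2])
  t1i <- .clip(init$t1, config@t1Bounds[1], config@t1Bounds[2])
  m0i <- max(init$m0, 10 * .Machine$double.eps)
  starts <- .dfStarts(config@nMultistartDeltaF, tr)
  best <- NULL
  for (d in starts) {
    p0 <- c(m0 = m0i, t1 = t1i, t2 = 80, deltaF = .clip(d, lb[4], ub[4]))
    fit <- try(minpack.lm::nls.lm(
      par = p0, lower = lb, upper = ub,
      fn = function(p) jsrResidual(c(m0 = p[[1]], t1 = p[[2]], t2 = p[[3]],
                                     deltaF = p[[4]]),
                                   measurements, meta, b1Scale, tr, te),
      control = minpack.lm::nls.lm.control(
        maxiter = min(config@maxIterations * 5L, 1000L), ftol = 1e-14,
        ptol = 1e-12)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    cost <- sum(fit$fvec^2)
    if (is.null(best) || cost < best$cost - 1e-15 ||
        (abs(cost - best$cost) <= 1e-15 &&
         abs(fit$par[[4]]) < abs(best$par[[4]])))
      best <- list(par = fit$par, cost = cost,
                   converged = fit$info %in% 1:4)
  }
  if (is.null(best))
    return(new("JsrEstimate", t1 = NA_real_, t2 = NA_real_, m0 = NA_real_,
               deltaF = NA_real_, residualNorm = NA_real_, converged = FALSE,
               nRestartsUsed = length(starts), t2LeT1 = NA))
  p <- best$par
  new("JsrEstimate", t1 = p[[2]], t2 = p[[3]], m0 = p[[1]], deltaF = p[[4]],
      residualNorm = sqrt(best$cost), converged = best$converged,
      nRestartsUsed = length(starts), t2LeT1 = p[[3]] <= p[[2]])
}

# ---- batched Levenberg-Marquardt over voxels --------------------------------

# One multistart leg: damped least squares on all voxels simultaneously with
# an active set (converged voxels drop out). data: N x M; b1: N. Returns
# final parameter vectors, cost and convergence flags.
.lmLeg <- function(data, meta, b1, tr, te, p, lb, ub, tol, maxit) {
  n <- nrow(data)
  iB <- which(meta$sequence == "bssfp")
  lam <- rep(1e-3, n)
  active <- seq_len(n)
  conv <- rep(FALSE, n)
  modelAt <- function(q, idx, cols) {
    .jsrModel(q$m0[idx], q$t1[idx], q$t2[idx], q$df[idx], b1[idx],
              meta, tr, te, cols)
  }
  mod <- modelAt(p, active, seq_len(ncol(data)))
  res <- mod - data
  cost <- rowSums(res^2)
  for (it in seq_len(maxit)) {
    idx <- active
    nn <- length(idx)
    if (!nn) break
    resA <- res[idx, , drop = FALSE]
    modA <- mod[idx, , drop = FALSE]
    # Jacobian: dS/dm0 analytic (all signals linear in m0); forward
    # differences for t1, t2, deltaF. t2 and deltaF touch only bSSFP columns.
    j1 <- modA / p$m0[idx]
    h1 <- pmax(abs(p$t1[idx]) * 1e-4, 1e-3)
    q <- list(m0 = p$m0, t1 = p$t1 + replace(numeric(n), idx, h1),
              t2 = p$t2, df = p$df)
    j2 <- (modelAt(q, idx, seq_len(ncol(data))) - modA) / h1
    h2 <- pmax(abs(p$t2[idx]) * 1e-4, 1e-4)
    q <- list(m0 = p$m0, t1 = p$t1, t2 = p$t2 + replace(numeric(n), idx, h2),
              df = p$df)
    j3 <- matrix(0, nn, ncol(data))
    j3[, iB] <- (modelAt(q, idx, iB)[, iB, drop = FALSE] -
                   modA[, iB, drop = FALSE]) / h2
    h4 <- rep(0.01, nn)
    q <- list(m0 = p$m0, t1 = p$t1, t2 = p$t2,
              df = p$df + replace(numeric(n), idx, h4))
    j4 <- matrix(0, nn, ncol(data))
    j4[, iB] <- (modelAt(q, idx, iB)[, iB, drop = FALSE] -
                   modA[, iB, drop = FALSE]) / h4
    h11 <- rowSums(j1 * j1); h12 <- rowSums(j1 * j2)
    h13 <- rowSums(j1 * j3); h14 <- rowSums(j1 * j4)
    h22 <- rowSums(j2 * j2); h23 <- rowSums(j2 * j3)
    h24 <- rowSums(j2 * j4); h33 <- rowSums(j3 * j3)
    h34 <- rowSums(j3 * j4); h44 <- rowSums(j4 * j4)
    g1 <- rowSums(j1 * resA); g2 <- rowSums(j2 * resA)
    g3 <- rowSums(j3 * resA); g4 <- rowSums(j4 * resA)
    l <- lam[idx]
    floorH <- 1e-12
    step <- .batCholSolve4(h11 * (1 + l) + floorH, h12, h13, h14,
                           h22 * (1 + l) + floorH, h23, h24,
                           h33 * (1 + l) + floorH, h34,
                           h44 * (1 + l) + floorH, g1, g2, g3, g4)
    cand <- list(
      m0 = .clip(p$m0[idx] - step[[1]], lb[1], ub[1]),
      t1 = .clip(p$t1[idx] - step[[2]], lb[2], ub[2]),
      t2 = .clip(p$t2[idx] - step[[3]], lb[3], ub[3]),
      df = .clip(p$df[idx] - step[[4]], lb[4], ub[4]))
    modNew <- .jsrModel(cand$m0, cand$t1, cand$t2, cand$df, b1[idx],
                        meta, tr, te)
    resNew <- modNew - data[idx, , drop = FALSE]
    costNew <- rowSums(resNew^2)
    acc <- costNew < cost[idx]
    ia <- idx[acc]
    if (length(ia)) {
      p$m0[ia] <- cand$m0[acc]; p$t1[ia] <- cand$t1[acc]
      p$t2[ia] <- cand$t2[acc]; p$df[ia] <- cand$df[acc]
      mod[ia, ] <- modNew[acc, , drop = FALSE]
      res[ia, ] <- resNew[acc, , drop = FALSE]
    }
    rel <- ifelse(acc, (cost[idx] - costNew) /
                    pmax(cost[idx], .Machine$double.xmin), Inf)
    cost[ia] <- costNew[acc]
    lam[idx] <- ifelse(acc, pmax(l / 3, 1e-9), pmin(l * 4, 1e10))
    # drop voxels whose accepted relative improvement fell below tolerance,
    # or that can no longer improve (damping saturated)
    done <- (acc & rel < tol) | (!acc & lam[idx] >= 1e10)
    conv[idx[done & acc]] <- TRUE
    conv[idx[done & !acc]] <- TRUE
    active <- idx[!done]
  }
  conv[active] <- FALSE   # stopped by iteration cap
  list(p = p, cost = cost, converged = conv)
}

# Full batched fit: despot1 init + off-resonance multistart, best cost wins,
# ties broken toward smallest |deltaF|.
.jsrEngine <- function(data, meta, b1, tr, te, config) {
  .checkIdentifiable(meta)
  n <- nrow(data)
  iS <- which(meta$sequence == "spgr")
  init <- if (length(iS) >= 2 && length(unique(meta$fa[iS])) >= 2) {
    despot1Init(data[, iS, drop = FALSE], meta$fa[iS], b1, tr)
  } else {
    list(t1 = rep(1000, n), m0 = apply(data, 1, max) * 10)
  }
  lb <- c(max(config@m0Bounds[1], 1e-9), config@t1Bounds[1],
          config@t2Bounds[1], config@deltaFBounds[1])
  ub <- c(min(config@m0Bounds[2], .Machine$double.xmax),
          config@t1Bounds[2], config@t2Bounds[2], config@deltaFBounds[2])
  t1i <- .clip(init$t1, lb[2], ub[2])
  m0i <- pmax(init$m0, lb[1])
  best <- NULL
  for (d in .dfStarts(config@nMultistartDeltaF, tr)) {
    p0 <- list(m0 = m0i, t1 = t1i, t2 = rep(80, n),
               df = rep(.clip(d, lb[4], ub[4]), n))
    leg <- .lmLeg(data, meta, b1, tr, te, p0, lb, ub,
                  config@tolerance, config@maxIterations)
    if (is.null(best)) {
      best <- leg
    } else {
      better <- leg$cost < best$cost * (1 - 1e-12) |
        (abs(leg$cost - best$cost) <= 1e-12 * pmax(best$cost, 1e-300) &
           abs(leg$p$df) < abs(best$p$df))
      for (f in c("m0", "t1", "t2", "df"))
        best$p[[f]][better] <- leg$p[[f]][better]
      best$cost[better] <- leg$cost[better]
      best$converged[better] <- leg$converged[better]
    }
  }
  best
}

#' Select the volumes of a flip-angle subset
#'
#' @param acq an \linkS4class{AcquisitionSet}
#' @param subset a \linkS4class{SubsetSpec}
#' @return integer volume indices into the acquisition set
#' @export
selectVolumes <- function(acq, subset) {
  meta <- acq@meta
  pick <- function(fa, seqType, inc) {
    i <- which(meta$sequence == seqType & meta$fa == fa &
                 (is.na(inc) | meta$phaseIncrement == inc))
    if (!length(i))
      stop(sprintf("subset '%s' requests a %s volume at %g degrees %s",
                   subset@name, seqType, fa,
                   if (!is.na(inc)) sprintf("(increment %g)", inc) else ""))
    i[1]
  }
  idx <- c(vapply(subset@spgrFas, pick, integer(1), seqType = "spgr",
                  inc = NA),
           vapply(subset@bssfpFas180, pick, integer(1), seqType = "bssfp",
                  inc = 180))
  if (subset@includeBssfp0) {
    i0 <- which(meta$sequence == "bssfp" & meta$phaseIncrement == 0)
    if (!length(i0))
      stop(sprintf("subset '%s' requires the 0-increment bSSFP volume",
                   subset@name))
    idx <- c(idx, i0[1])
  }
  idx
}

#' Fit parameter maps over a mask
#'
#' Voxel-wise joint fit of all masked voxels for one flip-angle subset,
#' computed by a vectorised batched Levenberg-Marquardt sharing the exact
#' per-voxel model of \code{\link{jsrFitVoxel}} (the two agree to tight
#' tolerance; see package tests). Deterministic given the configuration.
#'
#' @param acq an \linkS4class{AcquisitionSet}
#' @param subset a \linkS4class{SubsetSpec}
#' @param b1Map transmit-efficiency array; defaults to the acquisition's
#'   field maps
#' @param mask logical array of voxels to fit; defaults to all nonzero
#'   truth labels
#' @param config a \linkS4class{FitConfig}
#' @return a \linkS4class{JsrMaps}
#' @export
jsrFitVolume <- function(acq, subset, b1Map = NULL, mask = NULL,
                         config = fitConfig(tr = acq@tr)) {
  idx <- selectVolumes(acq, subset)
  meta <- acq@meta[idx, c("sequence", "fa", "phaseIncrement")]
  if (is.null(b1Map)) b1Map <- acq@fields@b1
  if (is.null(mask)) mask <- acq@truth@labels > 0L
  vox <- which(mask)
  if (!length(vox)) stop("empty mask")
  data <- vapply(idx, function(j) acq@volumes[[j]][vox],
                 numeric(length(vox)))
  fit <- .jsrEngine(data, meta, b1Map[vox], acq@tr, acq@te, config)
  shape <- dim(acq@volumes[[1]])
  blank <- array(NA_real_, dim = shape)
  mk <- function(v) { a <- blank; a[vox] <- v; a }
  convA <- array(FALSE, dim = shape); convA[vox] <- fit$converged
  new("JsrMaps",
      t1 = mk(fit$p$t1), t2 = mk(fit$p$t2), m0 = mk(fit$p$m0),
      deltaF = mk(fit$p$df), residual = mk(sqrt(fit$cost)),
      converged = convA, mask = mask,
      provenance = list(
        subset = subset@name,
        volumes = idx,
        vendor = acq@meta$vendor[1],
        csmt = acq@meta$csmt[1],
        replicate = acq@meta$replicate[1],
        nMultistartDeltaF = config@nMultistartDeltaF,
        seed = config@seed))
}
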