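# Synthetic-data generation: digital brain-like phantom, smooth field maps,
# and full acquisition simulation with Rician noise and replicates.

#' Default tissue parameter table
#'
#' Representative two-pool parameters (configuration, not measured facts):
#' white matter t1f 1100 ms, t2f 45 ms, bound fraction 0.15, kf 4/s, t2b
#' 12 us; gray matter 1600/70/0.08/2.5/12; CSF single-pool 4000/1800 ms.
#'
#' @return named list ("1" WM, "2" GM, "3" CSF) of
#'   \linkS4class{TwoPoolTissue}
#' @export
defaultTissueParams <- function() {
  list(
    "1" = twoPoolTissue(1100, 45, m0f = 0.77, boundFraction = 0.15,
                        kf = 4, t2b = 12),
    "2" = twoPoolTissue(1600, 70, m0f = 0.86, boundFraction = 0.08,
                        kf = 2.5, t2b = 12),
    "3" = twoPoolTissue(4000, 1800, m0f = 1.00, boundFraction = 0,
                        kf = 0, t2b = 12)
  )
}

#' Build a digital brain-like phantom
#'
#' Nested ellipsoids standing in for anatomy: a CSF core, a white-matter
#' bulk, and a gray-matter shell inside an ellipsoidal head. Deterministic
#' given the seed (the seed jitters the ellipsoid axes slightly).
#'
#' @param shape integer vector of 3 dimensions, each at least 32
#' @param seed integer seed
#' @param tissueParams per-label tissue table
#' @param voxelSize isotropic voxel size (mm)
#' @return a \linkS4class{PhantomVolume}
#' @examples
#' ph <- makeDigitalPhantom(c(32, 32, 32), seed = 1)
#' table(ph@labels)
#' @export
makeDigitalPhantom <- function(shape = c(64, 64, 64), seed = 1,
                               tissueParams = defaultTissueParams(),
                               voxelSize = 1) {
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 32))
    stop("shape must be 3 dimensions, each at least 32")
  jitter <- .withSeed(.deriveSeed(seed, 11L), stats::runif(3, 0.98, 1.02))
  semi <- c(0.88, 0.80, 0.74) * shape / 2 * jitter
  ctr <- (shape + 1) / 2
  x <- (seq_len(shape[1]) - ctr[1]) / semi[1]
  y <- (seq_len(shape[2]) - ctr[2]) / semi[2]
  z <- (seq_len(shape[3]) - ctr[3]) / semi[3]
  rho2 <- outer(outer(x^2, y^2, `+`), z^2, `+`)
  rho <- sqrt(rho2)
  labels <- array(0L, dim = shape)
  labels[rho <= 1] <- 2L          # gray-matter shell
  labels[rho <= 0.72] <- 1L       # white-matter bulk
  labels[rho <= 0.40] <- 3L       # CSF core
  new("PhantomVolume", labels = labels, tissueParams = tissueParams,
      voxelSize = voxelSize)
}

#' Generate smooth transmit and off-resonance field maps
#'
#' Random low-order (quadratic) polynomial fields in normalized coordinates,
#' affinely rescaled to span the requested ranges exactly across the volume.
#' Deterministic per seed.
#'
#' @param shape 3 dimensions
#' @param b1Range transmit efficiency range, subset of (0, 2)
#' @param b0RangeHz off-resonance range (Hz)
#' @param seed integer seed
#' @return a \linkS4class{FieldMaps}
#' @export
makeFieldMaps <- function(shape = c(64, 64, 64), b1Range = c(0.85, 1.15),
                          b0RangeHz = c(-60, 60), seed = 1) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, length(b1Range) == 2, length(b0RangeHz) == 2)
  if (any(b1Range <= 0) || any(b1Range >= 2))
    stop("b1Range must lie inside (0, 2)")
  b1 <- .polyField(shape, b1Range, .deriveSeed(seed, 21L))
  b0 <- .polyField(shape, b0RangeHz, .deriveSeed(seed, 22L))
  new("FieldMaps", b1 = b1, b0 = b0)
}

# random quadratic polynomial over normalized [-1, 1]^3, rescaled to range
.polyField <- function(shape, range, seed) {
  if (diff(range) == 0) return(array(range[1], dim = shape))
  co <- .withSeed(seed, c(stats::rnorm(3, sd = 1), stats::rnorm(6, sd = 0.5)))
  x <- seq(-1, 1, length.out = shape[1])
  y <- seq(-1, 1, length.out = shape[2])
  z <- seq(-1, 1, length.out = shape[3])
  X <- array(rep(x, times = shape[2] * shape[3]), dim = shape)
  Y <- array(rep(rep(y, each = shape[1]), times = shape[3]), dim = shape)
  Z <- array(rep(z, each = shape[1] * shape[2]), dim = shape)
  f <- co[1] * X + co[2] * Y + co[3] * Z +
    co[4] * X^2 + co[5] * Y^2 + co[6] * Z^2 +
    co[7] * X * Y + co[8] * X * Z + co[9] * Y * Z
  lo <- min(f); hi <- max(f)
  range[1] + (f - lo) / (hi - lo) * diff(range)
}

#' Add Rician magnitude noise
#'
#' Returns the magnitude of (signal + complex Gaussian noise of standard
#' deviation \code{sd} in each channel), the noise model of magnitude MR
#' images. Deterministic per seed.
#'
#' @param volume numeric array of noiseless signal magnitudes
#' @param sd per-channel Gaussian standard deviation
#' @param seed integer seed
#' @return array of the same shape
#' @export
addRicianNoise <- function(volume, sd, seed = 1) {
  stopifnot(sd >= 0)
  if (sd == 0) return(volume)
  n <- length(volume)
  noise <- .withSeed(seed, stats::rnorm(2 * n, sd = sd))
  out <- sqrt((as.vector(volume) + noise[seq_len(n)])^2 +
                noise[n + seq_len(n)]^2)
  array(out, dim = dim(volume))
}

# ---- acquisition simulation -------------------------------------------------

# Build the per-volume plan of a protocol for one vendor: sequence type,
# nominal FA, phase/rf increments and the excitation pulse object.
.protocolPlan <- function(vendor, protocol, design = csmtDesign()) {
  mkPulse <- function(fa) {
    if (protocol@csmt) designCsmtPulse(fa, design, protocol@tr)
    else nativePulse(vendor, fa)
  }
  rfInc <- if (protocol@rfSpoilingMode == "native")
    vendor@nativeRfIncrement else vendor@harmonizedRfIncrement
  rows <- list()
  for (fa in protocol@spgrFas)
    rows[[length(rows) + 1]] <- list(sequence = "spgr", fa = fa,
                                     phaseIncrement = NA_real_,
                                     rfIncrement = rfInc, pulse = mkPulse(fa))
  for (fa in protocol@bssfpFas180)
    rows[[length(rows) + 1]] <- list(sequence = "bssfp", fa = fa,
                                     phaseIncrement = 180,
                                     rfIncrement = NA_real_,
                                     pulse = mkPulse(fa))
  for (fa in protocol@bssfpFas0)
    rows[[length(rows) + 1]] <- list(sequence = "bssfp", fa = fa,
                                     phaseIncrement = 0,
                                     rfIncrement = NA_real_,
                                     pulse = mkPulse(fa))
  rows
}

# Noiseless signal volume for one plan entry under the ideal-spoiling /
# closed-steady-state models, evaluated per tissue label over the head.
.simulateVolume <- function(entry, phantom, fields, tr, te, lineshape) {
  labels <- phantom@labels
  out <- array(0, dim = dim(labels))
  b1 <- fields@b1; b0 <- fields@b0
  for (lab in names(phantom@tissueParams)) {
    idx <- which(labels == as.integer(lab))
    if (!length(idx)) next
    tis <- .twoPoolAsList(phantom@tissueParams[[lab]])
    s <- b1[idx]
    satNom <- .saturationExponentPerTr(entry$pulse, tis$t2b, lineshape)
    faNom <- entry$fa * pi / 180
    if (entry$sequence == "spgr") {
      out[idx] <- .mtSpgrSignal(tis, s * faNom, satNom * s^2, tr)
    } else {
      sig <- .mtBssfpSignal(tis, s * faNom, satNom * s^2, b0[idx], tr, te,
                            entry$phaseIncrement * pi / 180)
      out[idx] <- abs(sig)
    }
  }
  out
}

# SPGR volumes under RF-spoiling ensemble simulation. The spoiled signal of
# a voxel depends on the voxel only through its B1 scale (off-resonance is
# immaterial under uniform gradient dephasing), so each (volume, tissue)
# pair is simulated on a dense grid of the B1-scale coordinate -- all grids
# batched into a single ensemble run -- and spline-interpolated to voxels.
.simulateSpgrIsochromat <- function(entries, phantom, fields, tr, lineshape,
                                    nIsochromats, nReps, nB1Nodes = 25L) {
  labels <- phantom@labels
  b1 <- fields@b1
  phi0 <- unique(vapply(entries, `[[`, numeric(1), "rfIncrement"))
  stopifnot(length(phi0) == 1)
  labNames <- names(phantom@tissueParams)
  labIdx <- lapply(labNames, function(lab) which(labels == as.integer(lab)))
  names(labIdx) <- labNames
  # assemble the node table
  faEff <- satExp <- numeric(0)
  tis <- list(t1f = numeric(0), t2f = numeric(0), m0f = numeric(0),
              boundFraction = numeric(0), kf = numeric(0), t1b = numeric(0))
  segs <- list()
  for (j in seq_along(entries)) {
    e <- entries[[j]]
    faNom <- e$fa * pi / 180
    for (lab in labNames) {
      idx <- labIdx[[lab]]
      if (!length(idx)) next
      tp <- .twoPoolAsList(phantom@tissueParams[[lab]])
      satNom <- .saturationExponentPerTr(e$pulse, tp$t2b, lineshape)
      rng <- range(b1[idx])
      nodes <- if (diff(rng) < 1e-9) rng[1] else
        seq(rng[1], rng[2], length.out = nB1Nodes)
      segs[[length(segs) + 1]] <- list(j = j, lab = lab, nodes = nodes,
                                       at = length(faEff) + seq_along(nodes))
      faEff <- c(faEff, nodes * faNom)
      satExp <- c(satExp, satNom * nodes^2)
      for (f in names(tis)) tis[[f]] <- c(tis[[f]], rep(tp[[f]],
                                                        length(nodes)))
    }
  }
  sig <- .spoiledEnsemble(faEff, satExp, phi0, tis, tr, nIsochromats, nReps)
  vols <- lapply(entries, function(e) array(0, dim = dim(labels)))
  for (sg in segs) {
    idx <- labIdx[[sg$lab]]
    vals <- sig[sg$at]
    vols[[sg$j]][idx] <- if (length(sg$nodes) == 1) vals[1] else
      stats::splinefun(sg$nodes, vals, method = "natural")(b1[idx])
  }
  vols
}

#' Simulate a full acquisition set
#'
#' Evaluates the two-pool signal model voxel-wise for every volume of the
#' protocol at the effective flip angle \code{b1 * faNominal} and the local
#' off-resonance, then adds Rician noise. SPGR volumes use either the
#' ideal-spoiling steady state (\code{spoiling = "ideal"}) or the
#' isochromat RF-spoiling ensemble with the protocol's quadratic increment
#' (\code{spoiling = "isochromat"}).
#'
#' @param phantom a \linkS4class{PhantomVolume}
#' @param fields a \linkS4class{FieldMaps} on the same grid
#' @param vendor a \linkS4class{VendorProfile}
#' @param protocol a \linkS4class{ProtocolSpec}
#' @param noiseSd per-channel noise standard deviation; \code{"auto"} sets
#'   it from the white-matter median of the noiseless highest-FA SPGR volume
#'   divided by \code{snr}; 0 disables noise
#' @param seed integer seed for all noise draws
#' @param snr target white-matter SNR used when \code{noiseSd = "auto"}
#' @param spoiling SPGR spoiling model, \code{"ideal"} or
#'   \code{"isochromat"}
#' @param lineshape bound-pool absorption lineshape
#' @param design constant-power pulse design used when the protocol has
#'   \code{csmt = TRUE}
#' @param nIsochromats,nReps ensemble parameters for isochromat spoiling
#' @param replicate replicate id recorded in metadata
#' @return an \linkS4class{AcquisitionSet}
#' @export
simulateAcquisition <- function(phantom, fields, vendor, protocol,
                                noiseSd = "auto", seed = 1, snr = 100,
                                spoiling = c("ideal", "isochromat"),
                                lineshape = "super-lorentzian",
                                design = csmtDesign(),
                                nIsochromats = 256L, nReps = 2000L,
                                replicate = 1L) {
  spoiling <- match.arg(spoiling)
  stopifnot(identical(dim(phantom@labels), dim(fields@b1)),
            identical(dim(phantom@labels), dim(fields@b0)))
  plan <- .protocolPlan(vendor, protocol, design)
  vols <- lapply(plan, .simulateVolume, phantom = phantom, fields = fields,
                 tr = protocol@tr, te = protocol@te, lineshape = lineshape)
  if (spoiling == "isochromat") {
    iS <- which(vapply(plan, `[[`, character(1), "sequence") == "spgr")
    if (length(iS))
      vols[iS] <- .simulateSpgrIsochromat(plan[iS], phantom, fields,
                                          protocol@tr, lineshape,
                                          nIsochromats, nReps)
  }
  sdVal <- if (identical(noiseSd, "auto")) {
    iRef <- which.max(vapply(plan, function(e)
      ifelse(e$sequence == "spgr", e$fa, -1), numeric(1)))
    wm <- phantom@labels == 1L
    stats::median(vols[[iRef]][wm]) / snr
  } else as.numeric(noiseSd)
  meta <- data.frame(
    volume = seq_along(plan),
    sequence = vapply(plan, `[[`, character(1), "sequence"),
    fa = vapply(plan, `[[`, numeric(1), "fa"),
    phaseIncrement = vapply(plan, `[[`, numeric(1), "phaseIncrement"),
    rfIncrement = vapply(plan, `[[`, numeric(1), "rfIncrement"),
    pulseLabel = vapply(plan, function(e) e$pulse@label, character(1)),
    vendor = vendor@name,
    csmt = protocol@csmt,
    spoilingModel = spoiling,
    replicate = as.integer(replicate),
    noiseSd = sdVal,
    noiseSeed = vapply(seq_along(plan), function(j)
      .deriveSeed(seed, as.integer(replicate), j), integer(1)),
    stringsAsFactors = FALSE)
  if (sdVal > 0)
    vols <- lapply(seq_along(vols), function(j)
      addRicianNoise(vols[[j]], sdVal, meta$noiseSeed[j]))
  new("AcquisitionSet", volumes = vols, meta = meta, fields = fields,
      truth = phantom, tr = protocol@tr, te = protocol@te)
}

# Add noise to a noiseless set (used to build replicates without
# re-simulating the deterministic signal volumes).
.addNoiseToSet <- function(acq, sd, seed, replicate) {
  meta <- acq@meta
  meta$replicate <- as.integer(replicate)
  meta$noiseSd <- sd
  meta$noiseSeed <- vapply(seq_len(nrow(meta)), function(j)
    .deriveSeed(seed, as.integer(replicate), j), integer(1))
  vols <- lapply(seq_along(acq@volumes), function(j)
    addRicianNoise(acq@volumes[[j]], sd, meta$noiseSeed[j]))
  new("AcquisitionSet", volumes = vols, meta = meta, fields = acq@fields,
      truth = acq@truth, tr = acq@tr, te = acq@te)
}

#' Simulate test/retest replicates
#'
#' Simulates the noiseless acquisition once and produces \code{nReplicates}
#' noisy copies sharing truth and fields, with independent noise seeds.
#'
#' @inheritParams simulateAcquisition
#' @param nReplicates number of replicates (at least 2 for test/retest)
#' @param baseSeed seed from which per-replicate noise seeds are derived
#' @param ... further arguments passed to \code{\link{simulateAcquisition}}
#' @return list of \linkS4class{AcquisitionSet}, one per replicate
#' @export
replicateAcquisition <- function(phantom, fields, vendor, protocol,
                                 nReplicates = 2L, baseSeed = 1, snr = 100,
                                 ...) {
  noiseless <- simulateAcquisition(phantom, fields, vendor, protocol,
                                   noiseSd = 0, seed = baseSeed, snr = snr,
                                   ...)
  iRef <- with(noiseless@meta, which(sequence == "spgr"))
  iRef <- iRef[which.max(noiseless@meta$fa[iRef])]
  wm <- phantom@labels == 1L
  sd <- stats::median(noiseless@volumes[[iRef]][wm]) / snr
  lapply(seq_len(nReplicates), function(r)
    .addNoiseToSet(noiseless, sd, baseSeed, r))
}
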