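#' @import methods
NULL

# ---- tissue models ----------------------------------------------------------

#' Single-pool tissue parameters
#'
#' Relaxation parameters of the single-compartment model that joint system
#' relaxometry fits: one source of magnetization per voxel with longitudinal
#' time \code{t1}, transverse time \code{t2} (both ms), equilibrium
#' magnetization \code{m0} (arbitrary units) and off-resonance \code{deltaF}
#' (Hz).
#'
#' @slot t1 longitudinal relaxation time (ms), positive
#' @slot t2 transverse relaxation time (ms), positive, \code{t2 <= t1}
#' @slot m0 equilibrium magnetization (arbitrary units), non-negative
#' @slot deltaF static off-resonance (Hz)
#' @export
setClass("SinglePoolTissue",
  representation(t1 = "numeric", t2 = "numeric", m0 = "numeric",
                 deltaF = "numeric"),
  prototype(t1 = 1000, t2 = 80, m0 = 1, deltaF = 0))

setValidity("SinglePoolTissue", function(object) {
  msg <- character()
  if (object@t1 <= 0) msg <- c(msg, "t1 must be positive")
  if (object@t2 <= 0) msg <- c(msg, "t2 must be positive")
  if (object@t2 > object@t1) msg <- c(msg, "t2 must not exceed t1")
  if (object@m0 < 0) msg <- c(msg, "m0 must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a SinglePoolTissue
#'
#' @param t1,t2 relaxation times (ms)
#' @param m0 equilibrium magnetization (arbitrary units)
#' @param deltaF off-resonance (Hz)
#' @return a \linkS4class{SinglePoolTissue}
#' @examples
#' wm <- singlePoolTissue(t1 = 1000, t2 = 45)
#' @export
singlePoolTissue <- function(t1, t2, m0 = 1, deltaF = 0) {
  new("SinglePoolTissue", t1 = t1, t2 = t2, m0 = m0, deltaF = deltaF)
}

#' Two-pool magnetization-transfer tissue parameters
#'
#' The generative model: a free (liquid) proton pool exchanging with a
#' semisolid bound pool whose transverse relaxation is so short (microseconds)
#' that it carries no observable signal but absorbs RF power according to an
#' absorption lineshape. Detailed balance fixes the reverse exchange rate at
#' \code{kb = kf / boundFraction}.
#'
#' @slot t1f,t2f free-pool relaxation times (ms)
#' @slot m0f free-pool equilibrium magnetization (arbitrary units)
#' @slot boundFraction ratio of bound to free equilibrium magnetization
#' @slot kf forward exchange rate free to bound (1/s)
#' @slot t2b bound-pool transverse time (microseconds)
#' @slot t1b bound-pool longitudinal time (ms), conventionally fixed
#' @slot deltaF static off-resonance (Hz)
#' @export
setClass("TwoPoolTissue",
  representation(t1f = "numeric", t2f = "numeric", m0f = "numeric",
                 boundFraction = "numeric", kf = "numeric", t2b = "numeric",
                 t1b = "numeric", deltaF = "numeric"),
  prototype(t1f = 1100, t2f = 45, m0f = 1, boundFraction = 0.15, kf = 4,
            t2b = 12, t1b = 1000, deltaF = 0))

setValidity("TwoPoolTissue", function(object) {
  msg <- character()
  if (object@t1f <= 0 || object@t2f <= 0 || object@t2b <= 0 ||
      object@t1b <= 0) msg <- c(msg, "all relaxation times must be positive")
  if (object@boundFraction < 0) msg <- c(msg, "boundFraction must be >= 0")
  if (object@kf < 0) msg <- c(msg, "kf must be >= 0")
  if (object@boundFraction == 0 && object@kf > 0)
    msg <- c(msg, "kf must be 0 when boundFraction is 0 (empty bound pool)")
  if (length(msg)) msg else TRUE
})

#' Construct a TwoPoolTissue
#'
#' @param t1f,t2f free-pool relaxation times (ms)
#' @param m0f free-pool equilibrium magnetization
#' @param boundFraction bound/free equilibrium magnetization ratio
#' @param kf forward exchange rate (1/s)
#' @param t2b bound-pool T2 (microseconds)
#' @param t1b bound-pool T1 (ms); 1000 ms by convention
#' @param deltaF off-resonance (Hz)
#' @return a \linkS4class{TwoPoolTissue}
#' @examples
#' wm <- twoPoolTissue(1100, 45, boundFraction = 0.15, kf = 4, t2b = 12)
#' @export
twoPoolTissue <- function(t1f, t2f, m0f = 1, boundFraction = 0.15, kf = 4,
                          t2b = 12, t1b = 1000, deltaF = 0) {
  new("TwoPoolTissue", t1f = t1f, t2f = t2f, m0f = m0f,
      boundFraction = boundFraction, kf = kf, t2b = t2b, t1b = t1b,
      deltaF = deltaF)
}

# ---- RF pulses --------------------------------------------------------------

#' Sampled multiband RF pulse
#'
#' A pulse is a set of simultaneously played frequency bands; each band is a
#' sampled real amplitude envelope (uT) at a carrier offset (Hz). The
#' on-resonance band (offset 0) sets the flip angle; off-resonance bands
#' deposit saturation power without exciting the free pool.
#'
#' @slot samples numeric matrix, nSamples x nBands, amplitudes in uT
#' @slot dwell time per sample (microseconds)
#' @slot bandOffsets carrier offset per band (Hz)
#' @slot label free-text description
#' @export
setClass("RFPulse",
  representation(samples = "matrix", dwell = "numeric",
                 bandOffsets = "numeric", label = "character"),
  prototype(samples = matrix(0, 1, 1), dwell = 100, bandOffsets = 0,
            label = ""))

setValidity("RFPulse", function(object) {
  msg <- character()
  if (ncol(object@samples) != length(object@bandOffsets))
    msg <- c(msg, "one offset per band is required")
  if (object@dwell <= 0) msg <- c(msg, "dwell must be positive")
  if (!all(is.finite(object@samples)))
    msg <- c(msg, "amplitudes must be finite")
  if (length(msg)) msg else TRUE
})

#' @describeIn RFPulse-class pulse duration in ms
#' @param pulse an \linkS4class{RFPulse}
#' @export
pulseDuration <- function(pulse) {
  nrow(pulse@samples) * pulse@dwell / 1000
}

#' @describeIn RFPulse-class band carrier offsets in Hz
#' @export
bandOffsets <- function(pulse) pulse@bandOffsets

#' @describeIn RFPulse-class sampled band amplitudes (uT), nSamples x nBands
#' @export
pulseSamples <- function(pulse) pulse@samples

setMethod("show", "RFPulse", function(object) {
  cat(sprintf("RFPulse '%s': %d band(s), %.3f ms, offsets [%s] Hz\n",
              object@label, ncol(object@samples), pulseDuration(object),
              paste(format(object@bandOffsets), collapse = ", ")))
})

#' Constant-power multiband pulse design target
#'
#' Design parameters of the controlled-saturation pulse family: every
#' excitation in the protocol is built to the same RMS B1 over the repetition
#' period, regardless of flip angle, by adding symmetric off-resonance
#' saturation bands.
#'
#' @slot targetB1rms design RMS B1 over TR (uT)
#' @slot bandOffset side-band offset magnitude (Hz), placed at +/- offset
#' @slot baseDuration duration of the base envelope (ms)
#' @slot baseShape \code{"gaussian"} or \code{"hard"}
#' @slot nSamples samples per band envelope
#' @slot truncationSigma Gaussian truncation (multiples of sigma)
#' @export
setClass("CsmtDesign",
  representation(targetB1rms = "numeric", bandOffset = "numeric",
                 baseDuration = "numeric", baseShape = "character",
                 nSamples = "integer", truncationSigma = "numeric"),
  prototype(targetB1rms = 1.6, bandOffset = 6000, baseDuration = 2.5,
            baseShape = "gaussian", nSamples = 250L, truncationSigma = 3))

setValidity("CsmtDesign", function(object) {
  msg <- character()
  if (object@targetB1rms <= 0) msg <- c(msg, "targetB1rms must be positive")
  if (object@bandOffset <= 0) msg <- c(msg, "bandOffset must be positive")
  if (!object@baseShape %in% c("gaussian", "hard"))
    msg <- c(msg, "baseShape must be 'gaussian' or 'hard'")
  if (length(msg)) msg else TRUE
})

#' Default controlled-saturation pulse design
#'
#' 2.5-ms Gaussian base envelope, +/- 6 kHz saturation bands, target RMS B1
#' of 1.6 uT over the repetition period.
#'
#' @param targetB1rms RMS B1 target over TR (uT)
#' @param bandOffset side-band offset (Hz)
#' @param baseDuration base envelope duration (ms)
#' @param baseShape base envelope shape
#' @return a \linkS4class{CsmtDesign}
#' @export
csmtDesign <- function(targetB1rms = 1.6, bandOffset = 6000,
                       baseDuration = 2.5, baseShape = "gaussian") {
  new("CsmtDesign", targetB1rms = targetB1rms, bandOffset = bandOffset,
      baseDuration = baseDuration, baseShape = baseShape)
}

# ---- acquisitions -----------------------------------------------------------

#' Spoiled gradient-echo acquisition parameters
#'
#' @slot tr repetition time (ms)
#' @slot te echo time (ms)
#' @slot faNominal nominal flip angle (degrees)
#' @slot rfIncrement quadratic RF-spoiling phase increment seed (degrees)
#' @slot pulse the excitation \linkS4class{RFPulse}
#' @export
setClass("SpgrAcq",
  representation(tr = "numeric", te = "numeric", faNominal = "numeric",
                 rfIncrement = "numeric", pulse = "RFPulse"),
  prototype(tr = 7, te = 3.5, faNominal = 15, rfIncrement = 50))

setValidity("SpgrAcq", function(object) {
  msg <- character()
  if (!(object@te > 0 && object@te < object@tr))
    msg <- c(msg, "need 0 < te < tr")
  if (object@faNominal <= 0) msg <- c(msg, "faNominal must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct an SpgrAcq
#' @param tr,te repetition/echo time (ms)
#' @param faNominal nominal flip angle (degrees)
#' @param rfIncrement quadratic RF-spoiling increment (degrees)
#' @param pulse excitation pulse
#' @return an \linkS4class{SpgrAcq}
#' @export
spgrAcq <- function(faNominal, tr = 7, te = 3.5, rfIncrement = 50,
                    pulse = hardPulse(0.1, faNominal)) {
  new("SpgrAcq", tr = tr, te = te, faNominal = faNominal,
      rfIncrement = rfIncrement, pulse = pulse)
}

#' Balanced SSFP acquisition parameters
#'
#' @slot tr repetition time (ms)
#' @slot te echo time (ms); by convention tr/2
#' @slot faNominal nominal flip angle (degrees)
#' @slot phaseIncrement constant per-TR RF phase step (degrees, 0 or 180)
#' @slot pulse the excitation \linkS4class{RFPulse}
#' @export
setClass("BssfpAcq",
  representation(tr = "numeric", te = "numeric", faNominal = "numeric",
                 phaseIncrement = "numeric", pulse = "RFPulse"),
  prototype(tr = 7, te = 3.5, faNominal = 45, phaseIncrement = 180))

setValidity("BssfpAcq", function(object) {
  msg <- character()
  if (!(object@te > 0 && object@te < object@tr))
    msg <- c(msg, "need 0 < te < tr")
  if (object@phaseIncrement < 0 || object@phaseIncrement >= 360)
    msg <- c(msg, "phaseIncrement must be in [0, 360)")
  if (length(msg)) msg else TRUE
})

#' Construct a BssfpAcq
#' @param faNominal nominal flip angle (degrees)
#' @param tr repetition time (ms); te is fixed at tr/2
#' @param phaseIncrement per-TR RF phase step (degrees)
#' @param pulse excitation pulse
#' @return a \linkS4class{BssfpAcq}
#' @export
bssfpAcq <- function(faNominal, tr = 7, phaseIncrement = 180,
                     pulse = hardPulse(0.1, faNominal)) {
  new("BssfpAcq", tr = tr, te = tr / 2, faNominal = faNominal,
      phaseIncrement = phaseIncrement, pulse = pulse)
}

# ---- phantom / fields / protocol -------------------------------------------

#' Digital brain-like phantom
#'
#' Integer label volume (0 background, 1 white matter, 2 gray matter,
#' 3 cerebrospinal fluid) plus the two-pool tissue parameters attached to
#' each nonzero label.
#'
#' @slot labels integer 3-D array of tissue labels
#' @slot tissueParams named list mapping label ("1","2","3") to a
#'   \linkS4class{TwoPoolTissue}
#' @slot voxelSize isotropic voxel size (mm)
#' @export
setClass("PhantomVolume",
  representation(labels = "array", tissueParams = "list",
                 voxelSize = "numeric"),
  prototype(voxelSize = 1))

setValidity("PhantomVolume", function(object) {
  msg <- character()
  labs <- unique(as.vector(object@labels))
  if (!all(labs %in% 0:3)) msg <- c(msg, "labels must be in 0..3")
  need <- as.character(setdiff(labs, 0))
  if (!all(need %in% names(object@tissueParams)))
    msg <- c(msg, "every nonzero label needs a tissueParams entry")
  if (length(msg)) msg else TRUE
})

#' @describeIn PhantomVolume-class per-label tissue parameter list
#' @param phantom a \linkS4class{PhantomVolume}
#' @export
tissueParams <- function(phantom) phantom@tissueParams

setMethod("show", "PhantomVolume", function(object) {
  tab <- table(factor(object@labels, levels = 0:3,
                      labels = c("background", "WM", "GM", "CSF")))
  cat(sprintf("PhantomVolume %s at %.1f mm\n",
              paste(dim(object@labels), collapse = "x"), object@voxelSize))
  print(tab)
})

#' Transmit and static field maps
#'
#' @slot b1 multiplicative transmit efficiency (actual/nominal flip angle)
#' @slot b0 static off-resonance (Hz)
#' @export
setClass("FieldMaps",
  representation(b1 = "array", b0 = "array"))

#' @describeIn FieldMaps-class the B1 transmit efficiency array
#' @param fields a \linkS4class{FieldMaps}
#' @export
fieldB1 <- function(fields) fields@b1

#' @describeIn FieldMaps-class the B0 off-resonance array (Hz)
#' @export
fieldB0 <- function(fields) fields@b0

#' Vendor RF profile
#'
#' Emulates a scanner's native excitation hardware: the excitation pulse
#' family (a fixed-duration envelope scaled in amplitude with flip angle) and
#' the native quadratic RF-spoiling phase increment.
#'
#' @slot name vendor letter ("A", "B", "C")
#' @slot pulseShape \code{"hard"} or \code{"gaussian"}
#' @slot pulseDuration excitation pulse duration (ms)
#' @slot nativeRfIncrement native quadratic spoiling increment (degrees)
#' @slot harmonizedRfIncrement harmonized increment (degrees), 50 by default
#' @export
setClass("VendorProfile",
  representation(name = "character", pulseShape = "character",
                 pulseDuration = "numeric", nativeRfIncrement = "numeric",
                 harmonizedRfIncrement = "numeric"),
  prototype(harmonizedRfIncrement = 50))

setValidity("VendorProfile", function(object) {
  msg <- character()
  if (object@nativeRfIncrement < 0 || object@nativeRfIncrement >= 360)
    msg <- c(msg, "nativeRfIncrement must be in [0, 360)")
  if (!object@pulseShape %in% c("hard", "gaussian"))
    msg <- c(msg, "pulseShape must be 'hard' or 'gaussian'")
  if (length(msg)) msg else TRUE
})

#' The three emulated vendor profiles
#'
#' Vendor A: 0.3-ms hard pulse, native increment 150 degrees. Vendor B:
#' 0.1-ms hard pulse, 50 degrees. Vendor C: 1.6-ms shaped (Gaussian envelope)
#' pulse, 115 degrees. The letter-to-increment assignment follows the listed
#' order of the native increments and is configurable by constructing
#' \linkS4class{VendorProfile} objects directly.
#'
#' @return named list of \linkS4class{VendorProfile} objects
#' @export
vendorProfiles <- function() {
  list(
    A = new("VendorProfile", name = "A", pulseShape = "hard",
            pulseDuration = 0.3, nativeRfIncrement = 150),
    B = new("VendorProfile", name = "B", pulseShape = "hard",
            pulseDuration = 0.1, nativeRfIncrement = 50),
    C = new("VendorProfile", name = "C", pulseShape = "gaussian",
            pulseDuration = 1.6, nativeRfIncrement = 115)
  )
}

#' Acquisition protocol
#'
#' The fixed variable-flip-angle protocol: TR/TE = 7.0/3.5 ms; SPGR at 3, 7,
#' 11, 15 degrees; bSSFP at 5, 25, 45 degrees with 180-degree phase increment
#' plus one 45-degree acquisition at 0-degree increment (which shifts the
#' banding profile and makes off-resonance identifiable).
#'
#' @slot tr,te repetition / echo time (ms)
#' @slot spgrFas SPGR flip angles (degrees)
#' @slot bssfpFas180 bSSFP flip angles at 180-degree increment
#' @slot bssfpFas0 bSSFP flip angles at 0-degree increment
#' @slot csmt use constant-power multiband pulses for all volumes
#' @slot rfSpoilingMode \code{"native"} or \code{"harmonized"}
#' @export
setClass("ProtocolSpec",
  representation(tr = "numeric", te = "numeric", spgrFas = "numeric",
                 bssfpFas180 = "numeric", bssfpFas0 = "numeric",
                 csmt = "logical", rfSpoilingMode = "character"),
  prototype(tr = 7, te = 3.5, spgrFas = c(3, 7, 11, 15),
            bssfpFas180 = c(5, 25, 45), bssfpFas0 = 45, csmt = FALSE,
            rfSpoilingMode = "harmonized"))

setValidity("ProtocolSpec", function(object) {
  msg <- character()
  if (any(c(object@spgrFas, object@bssfpFas180, object@bssfpFas0) <= 0))
    msg <- c(msg, "all flip angles must be positive")
  if (!(object@te > 0 && object@te < object@tr))
    msg <- c(msg, "need 0 < te < tr")
  if (!object@rfSpoilingMode %in% c("native", "harmonized"))
    msg <- c(msg, "rfSpoilingMode must be 'native' or 'harmonized'")
  if (length(msg)) msg else TRUE
})

#' Construct the default protocol
#' @param csmt logical; use constant-power multiband pulses
#' @param rfSpoilingMode \code{"native"} or \code{"harmonized"}
#' @return a \linkS4class{ProtocolSpec}
#' @export
protocolSpec <- function(csmt = FALSE, rfSpoilingMode = "harmonized") {
  new("ProtocolSpec", csmt = csmt, rfSpoilingMode = rfSpoilingMode)
}

#' Simulated acquisition set
#'
#' All image volumes of one protocol run on one vendor, with per-volume
#' metadata, the field maps used, and the ground-truth phantom.
#'
#' @slot volumes list of 3-D arrays (signal magnitude)
#' @slot meta data.frame with one row per volume: sequence, fa,
#'   phaseIncrement, rfIncrement, pulseLabel, vendor, csmt, replicate,
#'   noiseSd, noiseSeed
#' @slot fields the \linkS4class{FieldMaps} used
#' @slot truth the \linkS4class{PhantomVolume} used
#' @slot tr,te protocol timing (ms)
#' @export
setClass("AcquisitionSet",
  representation(volumes = "list", meta = "data.frame", fields = "FieldMaps",
                 truth = "PhantomVolume", tr = "numeric", te = "numeric"))

setValidity("AcquisitionSet", function(object) {
  msg <- character()
  if (length(object@volumes) != nrow(object@meta))
    msg <- c(msg, "one metadata row per volume is required")
  dims <- unique(lapply(object@volumes, dim))
  if (length(dims) > 1) msg <- c(msg, "all volumes must share one grid")
  if (length(msg)) msg else TRUE
})

#' @describeIn AcquisitionSet-class per-volume metadata table
#' @param acq an \linkS4class{AcquisitionSet}
#' @export
acqMeta <- function(acq) acq@meta

#' @describeIn AcquisitionSet-class list of image arrays
#' @export
acqVolumes <- function(acq) acq@volumes

setMethod("show", "AcquisitionSet", function(object) {
  cat(sprintf(
    "AcquisitionSet: %d volumes (%s), vendor %s, %s pulses, %s spoiling\n",
    length(object@volumes),
    paste(dim(object@volumes[[1]]), collapse = "x"),
    object@meta$vendor[1],
    if (isTRUE(object@meta$csmt[1])) "CSMT" else "native",
    object@meta$spoilingModel[1]))
})

# ---- fitting ----------------------------------------------------------------

#' Joint-fit configuration
#'
#' Bounds, tolerances and multistart layout for the joint single-pool fit.
#' Off-resonance is multistarted at \code{nMultistartDeltaF} equally spaced
#' points of its principal period 1/TR; the best final cost wins, ties broken
#' by smallest absolute off-resonance.
#'
#' @slot t1Bounds,t2Bounds,m0Bounds,deltaFBounds parameter bounds
#' @slot tolerance relative cost-decrease stopping tolerance
#' @slot maxIterations iteration cap per start
#' @slot nMultistartDeltaF number of off-resonance starts
#' @slot seed fit seed (recorded in provenance; the fit itself is
#'   deterministic)
#' @export
setClass("FitConfig",
  representation(t1Bounds = "numeric", t2Bounds = "numeric",
                 m0Bounds = "numeric", deltaFBounds = "numeric",
                 tolerance = "numeric", maxIterations = "integer",
                 nMultistartDeltaF = "integer", seed = "integer"),
  prototype(t1Bounds = c(100, 6000), t2Bounds = c(5, 3000),
            m0Bounds = c(1e-9, Inf), deltaFBounds = numeric(0),
            tolerance = 1e-10, maxIterations = 60L,
            nMultistartDeltaF = 4L, seed = 1L))

#' Construct a FitConfig
#' @param tr repetition time (ms), used to set the off-resonance bounds to
#'   the principal band period
#' @param nMultistartDeltaF number of off-resonance starts
#' @param maxIterations iteration cap
#' @param tolerance relative cost-decrease stop
#' @param seed recorded seed
#' @return a \linkS4class{FitConfig}
#' @export
fitConfig <- function(tr = 7, nMultistartDeltaF = 4L, maxIterations = 60L,
                      tolerance = 1e-10, seed = 1L) {
  half <- 1000 / (2 * tr)   # Hz
  new("FitConfig", deltaFBounds = c(-half, half),
      nMultistartDeltaF = as.integer(nMultistartDeltaF),
      maxIterations = as.integer(maxIterations), tolerance = tolerance,
      seed = as.integer(seed))
}

#' Per-voxel joint fit estimate
#'
#' @slot t1,t2 fitted relaxation times (ms)
#' @slot m0 fitted equilibrium magnetization
#' @slot deltaF fitted off-resonance (Hz), principal value in
#'   \code{[-1/(2 TR), +1/(2 TR))}
#' @slot residualNorm Euclidean norm of the final residual
#' @slot converged logical convergence flag
#' @slot nRestartsUsed number of off-resonance starts evaluated
#' @slot t2LeT1 soft plausibility flag (\code{t2 <= t1})
#' @export
setClass("JsrEstimate",
  representation(t1 = "numeric", t2 = "numeric", m0 = "numeric",
                 deltaF = "numeric", residualNorm = "numeric",
                 converged = "logical", nRestartsUsed = "integer",
                 t2LeT1 = "logical"))

setMethod("show", "JsrEstimate", function(object) {
  cat(sprintf(
    "JsrEstimate: T1 %.1f ms, T2 %.2f ms, M0 %.4g, dF %+.2f Hz (%s)\n",
    object@t1, object@t2, object@m0, object@deltaF,
    if (object@converged) "converged" else "NOT converged"))
})

#' Fitted parameter maps
#'
#' Voxelwise joint-fit results over a mask, with provenance.
#'
#' @slot t1,t2,m0,deltaF,residual 3-D parameter arrays (NA outside mask)
#' @slot converged logical 3-D array
#' @slot mask logical 3-D array of fitted voxels
#' @slot provenance list: subset, config summary, seeds
#' @export
setClass("JsrMaps",
  representation(t1 = "array", t2 = "array", m0 = "array", deltaF = "array",
                 residual = "array", converged = "array", mask = "array",
                 provenance = "list"))

setMethod("show", "JsrMaps", function(object) {
  n <- sum(object@mask)
  cat(sprintf(
    "JsrMaps %s: %d fitted voxels, subset '%s', %.1f%% converged\n",
    paste(dim(object@t1), collapse = "x"), n,
    object@provenance$subset %||% "?",
    100 * mean(object@converged[object@mask])))
})

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- analysis ---------------------------------------------------------------

#' Flip-angle subset specification
#'
#' A named selection of protocol volumes used for one estimation. A valid
#' subset contains at least one SPGR and two bSSFP volumes, among which at
#' least one uses the 180-degree phase increment.
#'
#' @slot name subset name
#' @slot spgrFas SPGR flip angles included (degrees)
#' @slot bssfpFas180 bSSFP flip angles at 180-degree increment included
#' @slot includeBssfp0 include the 45-degree, 0-increment volume
#' @export
setClass("SubsetSpec",
  representation(name = "character", spgrFas = "numeric",
                 bssfpFas180 = "numeric", includeBssfp0 = "logical"),
  prototype(includeBssfp0 = TRUE))

setValidity("SubsetSpec", function(object) {
  msg <- character()
  if (length(object@spgrFas) < 1)
    msg <- c(msg, "at least one SPGR flip angle is required")
  nb <- length(object@bssfpFas180) + as.integer(object@includeBssfp0)
  if (nb < 2) msg <- c(msg, "at least two bSSFP volumes are required")
  if (length(object@bssfpFas180) < 1)
    msg <- c(msg, "at least one 180-degree bSSFP volume is required")
  if (length(msg)) msg else TRUE
})

#' Construct a SubsetSpec
#' @param name subset name
#' @param spgrFas SPGR flip angles (degrees)
#' @param bssfpFas180 bSSFP flip angles at 180-degree increment
#' @param includeBssfp0 include the 0-increment 45-degree volume
#' @return a \linkS4class{SubsetSpec}
#' @export
subsetSpec <- function(name, spgrFas, bssfpFas180, includeBssfp0 = TRUE) {
  new("SubsetSpec", name = name, spgrFas = spgrFas,
      bssfpFas180 = bssfpFas180, includeBssfp0 = includeBssfp0)
}

#' Default flip-angle subsets
#'
#' Six configured subsets of the all-measures superset (package defaults;
#' each satisfies the identifiability rule). S1 is the all-measures set.
#'
#' @return named list of \linkS4class{SubsetSpec} objects
#' @export
defaultSubsets <- function() {
  list(
    S1 = subsetSpec("S1", c(3, 7, 11, 15), c(5, 25, 45)),
    S2 = subsetSpec("S2", c(3, 15), c(5, 45)),
    S3 = subsetSpec("S3", c(7, 11), c(25, 45)),
    S4 = subsetSpec("S4", c(3, 7, 11, 15), c(5, 45)),
    S5 = subsetSpec("S5", c(3, 11), c(5, 25)),
    S6 = subsetSpec("S6", c(7, 15), c(25, 45))
  )
}

#' Variability analysis report
#'
#' Tidy tables of the study statistics: per-dataset medians, worst-case
#' variability by grouping, deviations from the grand mean, and voxelwise
#' variability distribution summaries.
#'
#' @slot medians data.frame: vendor, condition, subset, replicate, parameter,
#'   median
#' @slot worstCase data.frame: condition, parameter, grouping, group,
#'   worstCase (percent)
#' @slot deviations data.frame: condition, parameter, vendor, subset,
#'   deviation (percent)
#' @slot voxelwise data.frame: condition, parameter, comparison, vendorA,
#'   vendorB, subset, median (percent)
#' @slot config the study configuration used
#' @export
setClass("VariabilityReport",
  representation(medians = "data.frame", worstCase = "data.frame",
                 deviations = "data.frame", voxelwise = "data.frame",
                 config = "list"))

#' @describeIn VariabilityReport-class table of WM-median estimates
#' @param report a \linkS4class{VariabilityReport}
#' @export
reportMedians <- function(report) report@medians

#' @describeIn VariabilityReport-class worst-case variability table
#' @export
reportWorstCase <- function(report) report@worstCase

#' @describeIn VariabilityReport-class deviations-from-grand-mean table
#' @export
reportDeviations <- function(report) report@deviations

#' @describeIn VariabilityReport-class voxelwise distribution summaries
#' @export
reportVoxelwise <- function(report) report@voxelwise

setMethod("show", "VariabilityReport", function(object) {
  cat(sprintf(
    "VariabilityReport: %d medians (%s vendors x %s subsets), %d worst-case rows\n",
    nrow(object@medians),
    length(unique(object@medians$vendor)),
    length(unique(object@medians$subset)),
    nrow(object@worstCase)))
})
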