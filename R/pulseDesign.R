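# RF pulse construction: vendor hard/shaped pulses and the constant-power
# three-band pulse whose RMS B1 over the repetition period is identical for
# every flip angle in the protocol.

# time-integral (uT*ms) and power integral (uT^2*ms) of one band
.bandIntegral <- function(pulse, band) {
  sum(pulse@samples[, band]) * pulse@dwell / 1000
}
.bandPower <- function(pulse, band) {
  sum(pulse@samples[, band]^2) * pulse@dwell / 1000
}

#' Gaussian-envelope RF pulse
#'
#' Single on-resonance band with a truncated Gaussian envelope, scaled so the
#' on-resonance flip angle equals \code{fa}.
#'
#' @param duration pulse duration (ms)
#' @param fa flip angle (degrees), must be positive
#' @param nSamples number of envelope samples
#' @param truncationSigma truncation point in multiples of sigma
#' @param label pulse label
#' @return an \linkS4class{RFPulse}
#' @examples
#' p <- gaussianPulse(2.5, 15)
#' flipAngleOf(p)
#' @export
gaussianPulse <- function(duration, fa, nSamples = 250L,
                          truncationSigma = 3, label = "gaussian") {
  stopifnot(duration > 0)
  if (fa <= 0) stop("flip angle must be positive")
  dwell <- duration * 1000 / nSamples            # us
  # sample-centre time grid, centred on the pulse midpoint
  t <- (seq_len(nSamples) - 0.5) * duration / nSamples - duration / 2
  sigma <- duration / (2 * truncationSigma)
  env <- exp(-t^2 / (2 * sigma^2))
  # scale so gamma * integral B1 dt = fa
  area <- sum(env) * duration / nSamples          # ms (unit amplitude)
  amp <- (fa * pi / 180) / (.GAMMA_RAD_PER_UT_MS * area)
  new("RFPulse", samples = matrix(env * amp, ncol = 1), dwell = dwell,
      bandOffsets = 0, label = label)
}

#' Hard (rectangular) RF pulse
#'
#' @param duration pulse duration (ms)
#' @param fa flip angle (degrees)
#' @param nSamples number of samples (the envelope is constant)
#' @param label pulse label
#' @return an \linkS4class{RFPulse}
#' @examples
#' # 15 degrees in 0.1 ms requires a peak near 9.79 uT
#' max(pulseSamples(hardPulse(0.1, 15)))
#' @export
hardPulse <- function(duration, fa, nSamples = 16L, label = "hard") {
  stopifnot(duration > 0)
  if (fa <= 0) stop("flip angle must be positive")
  amp <- (fa * pi / 180) / (.GAMMA_RAD_PER_UT_MS * duration)
  new("RFPulse", samples = matrix(rep(amp, nSamples), ncol = 1),
      dwell = duration * 1000 / nSamples, bandOffsets = 0, label = label)
}

#' On-resonance flip angle of a pulse
#'
#' The flip angle is the gyromagnetic ratio times the time-integral of the
#' on-resonance (0 Hz) band amplitude; off-resonance bands are excluded as
#' they do not rotate the free pool.
#'
#' @param pulse an \linkS4class{RFPulse}
#' @return flip angle in degrees (0 with a warning if there is no 0 Hz band)
#' @export
flipAngleOf <- function(pulse) {
  on <- which(pulse@bandOffsets == 0)
  if (length(on) == 0) {
    warning("pulse has no on-resonance band; flip angle is 0")
    return(0)
  }
  area <- sum(vapply(on, function(b) .bandIntegral(pulse, b), numeric(1)))
  .GAMMA_RAD_PER_UT_MS * area * 180 / pi
}

#' RMS B1 over the repetition period
#'
#' \code{sqrt((1/TR) * sum over bands of integral |B1|^2 dt)}, with zero
#' amplitude outside the pulse. This is the saturation-relevant power metric
#' the constant-power design equalizes.
#'
#' @param pulse an \linkS4class{RFPulse}
#' @param tr repetition time (ms); must be at least the pulse duration
#' @return RMS B1 in uT
#' @export
b1rmsOverTr <- function(pulse, tr) {
  if (tr < pulseDuration(pulse))
    stop("tr must be at least the pulse duration")
  p <- sum(vapply(seq_along(pulse@bandOffsets),
                  function(b) .bandPower(pulse, b), numeric(1)))
  sqrt(p / tr)
}

#' Design a constant-power three-band pulse
#'
#' Builds the multiband excitation: an on-resonance base envelope scaled to
#' the requested flip angle, plus two symmetric saturation bands at
#' \code{+/- bandOffset} carrying equal amplitude, scaled so that the RMS B1
#' over the repetition period equals the design target exactly. Because every
#' protocol flip angle is built to the same RMS B1, bound-pool saturation is
#' constant across all measurements.
#'
#' @param fa on-resonance flip angle (degrees)
#' @param design a \linkS4class{CsmtDesign}
#' @param tr repetition time (ms)
#' @return an \linkS4class{RFPulse} with three bands
#' @examples
#' p <- designCsmtPulse(15, csmtDesign(), tr = 7)
#' b1rmsOverTr(p, 7)   # 1.6 uT by construction
#' @export
designCsmtPulse <- function(fa, design = csmtDesign(), tr = 7) {
  base <- switch(design@baseShape,
    gaussian = gaussianPulse(design@baseDuration, fa,
                             nSamples = design@nSamples,
                             truncationSigma = design@truncationSigma),
    hard = hardPulse(design@baseDuration, fa, nSamples = design@nSamples))
  if (tr < design@baseDuration)
    stop("tr must be at least the base pulse duration")
  env <- base@samples[, 1]
  pOn <- sum(env^2) * base@dwell / 1000           # uT^2 * ms
  budget <- design@targetB1rms^2 * tr             # uT^2 * ms
  if (pOn > budget * (1 + 1e-12)) {
    stop(sprintf(paste0(
      "infeasible design: flip angle %.1f deg alone requires RMS B1 of ",
      "%.4f uT over TR %.1f ms, above the %.4f uT target"),
      fa, sqrt(pOn / tr), tr, design@targetB1rms))
  }
  pSide <- max(budget - pOn, 0) / 2               # per side band
  envPower <- sum(env^2) * base@dwell / 1000
  sideScale <- if (pSide > 0) sqrt(pSide / envPower) else 0
  side <- env * sideScale
  new("RFPulse",
      samples = cbind(side, env, side, deparse.level = 0),
      dwell = base@dwell,
      bandOffsets = c(-design@bandOffset, 0, design@bandOffset),
      label = sprintf("csmt3b_fa%g", fa))
}

#' Vendor-native excitation pulse
#'
#' The vendor's fixed-duration envelope scaled in amplitude to the requested
#' flip angle (hard envelope for vendors A and B, Gaussian envelope standing
#' in for the shaped pulse of vendor C).
#'
#' @param vendor a \linkS4class{VendorProfile}
#' @param fa flip angle (degrees)
#' @return an \linkS4class{RFPulse}
#' @export
nativePulse <- function(vendor, fa) {
  if (vendor@pulseShape == "hard")
    hardPulse(vendor@pulseDuration, fa,
              label = sprintf("%s_hard%.1fms_fa%g", vendor@name,
                              vendor@pulseDuration, fa))
  else
    gaussianPulse(vendor@pulseDuration, fa,
                  label = sprintf("%s_shaped%.1fms_fa%g", vendor@name,
                                  vendor@pulseDuration, fa))
}

#' Serialize a pulse definition to JSON
#'
#' @param pulse an \linkS4class{RFPulse}
#' @return a JSON string (samples, dwell, offsets, label)
#' @export
pulseToJson <- function(pulse) {
  jsonlite::toJSON(list(
    label = pulse@label,
    dwell_us = pulse@dwell,
    band_offsets_hz = pulse@bandOffsets,
    samples_ut = apply(pulse@samples, 2, identity, simplify = FALSE)
  ), auto_unbox = TRUE, digits = NA)
}
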