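# Shared fixtures: representative tissues, protocol metadata and a
# single-voxel dataset builder used across the fit tests.

wmSingle <- function(deltaF = 0) singlePoolTissue(1000, 45, 1, deltaF)
wmTwoPool <- function(deltaF = 0)
  twoPoolTissue(1100, 45, m0f = 0.77, boundFraction = 0.15, kf = 4,
                t2b = 12, deltaF = deltaF)

protocolMeta <- function() {
  data.frame(
    sequence = c(rep("spgr", 4), rep("bssfp", 4)),
    fa = c(3, 7, 11, 15, 5, 25, 45, 45),
    phaseIncrement = c(rep(NA, 4), 180, 180, 180, 0))
}

# noiseless magnitudes of the 8-volume protocol for one voxel, using the
# closed-form single-pool models (the fitting model itself)
singlePoolVoxelData <- function(tissue, b1 = 1, tr = 7, te = 3.5) {
  meta <- protocolMeta()
  sig <- vapply(seq_len(nrow(meta)), function(j) {
    a <- b1 * meta$fa[j] * pi / 180
    if (meta$sequence[j] == "spgr") spgrSignal(tissue, a, tr)
    else abs(bssfpSignal(tissue, bssfpAcq(meta$fa[j], tr = tr,
                                          phaseIncrement =
                                            meta$phaseIncrement[j]),
                         b1))
  }, numeric(1))
  list(meta = meta, sig = sig)
}

# noiseless two-pool protocol data for one voxel under ideal spoiling, with
# either vendor-native or constant-power pulses
twoPoolVoxelData <- function(tissue, pulses = c("native", "csmt"),
                             vendorDur = 0.1, b1 = 1, tr = 7, te = 3.5) {
  pulses <- match.arg(pulses)
  meta <- protocolMeta()
  mk <- function(fa) {
    if (pulses == "csmt") designCsmtPulse(fa, csmtDesign(), tr)
    else hardPulse(vendorDur, fa)
  }
  sig <- vapply(seq_len(nrow(meta)), function(j) {
    fa <- meta$fa[j]
    if (meta$sequence[j] == "spgr")
      mtSpgrSignal(tissue, spgrAcq(fa, tr = tr, pulse = mk(fa)), b1)
    else
      abs(mtBssfpSignal(tissue,
                        bssfpAcq(fa, tr = tr,
                                 phaseIncrement = meta$phaseIncrement[j],
                                 pulse = mk(fa)), b1))
  }, numeric(1))
  list(meta = meta, sig = sig)
}

subsetRows <- function(meta, subset) {
  c(which(meta$sequence == "spgr" & meta$fa %in% subset@spgrFas),
    which(meta$sequence == "bssfp" & meta$phaseIncrement == 180 &
            meta$fa %in% subset@bssfpFas180),
    if (subset@includeBssfp0) which(meta$sequence == "bssfp" &
                                      meta$phaseIncrement == 0))
}
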