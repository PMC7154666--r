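# Lazily computed, cached study objects shared across the acceptance tests
# (each is expensive; computing once keeps the suite within a sane runtime).

.studyCache <- new.env(parent = emptyenv())

cachedStudy <- function(name, builder) {
  if (is.null(.studyCache[[name]])) .studyCache[[name]] <- builder()
  .studyCache[[name]]
}

# full three-condition grid: 3 vendors x {native, harmonized, csmt} x 6
# subsets, SNR 100, identical noise seeds across conditions
accFullStudy <- function() cachedStudy("full", function() {
  runStudy(studyConfig(seed = 1L), verbose = FALSE)
})

# test/retest: one vendor (hard 0.1 ms), native and constant-power
# conditions, two noise replicates, all-measures subset
accTrtStudy <- function() cachedStudy("trt", function() {
  runStudy(studyConfig(vendors = "B", conditions = c("native", "csmt"),
                       subsets = defaultSubsets()["S1"], nReplicates = 2L,
                       seed = 1L), verbose = FALSE)
})

# noiseless single-pool phantom under the matching (ideal-spoiling) model
accSinglePoolNoiseless <- function() cachedStudy("sp0", function() {
  runStudy(studyConfig(vendors = "B", conditions = "harmonized",
                       spoiling = "ideal", singlePool = TRUE, snr = Inf,
                       seed = 1L), verbose = FALSE)
})

# the same single-pool phantom at SNR 100
accSinglePoolNoisy <- function() cachedStudy("sp100", function() {
  runStudy(studyConfig(vendors = "B", conditions = "harmonized",
                       spoiling = "ideal", singlePool = TRUE, snr = 100,
                       seed = 1L), verbose = FALSE)
})
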