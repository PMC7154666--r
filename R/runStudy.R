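# End-to-end study orchestration: phantom -> simulate (vendor x condition x
# replicate) -> joint fit per subset -> variability statistics, mirroring
# the three-condition comparison (native, harmonized spoiling, CSMT).

#' Study configuration
#'
#' Conditions: \code{"native"} (vendor pulses, vendor spoiling increments),
#' \code{"harmonized"} (vendor pulses, 50-degree spoiling everywhere) and
#' \code{"csmt"} (constant-power pulses and 50-degree spoiling). Noise seeds
#' are derived from the study seed, vendor and replicate only, so the same
#' noise realizations are reused across conditions (paired comparisons).
#'
#' @slot shape phantom grid dimensions
#' @slot vendors vendor letters simulated
#' @slot conditions subset of \code{c("native", "harmonized", "csmt")}
#' @slot subsets named list of \linkS4class{SubsetSpec}
#' @slot nReplicates noise replicates per vendor-condition
#' @slot snr white-matter SNR of the highest-FA SPGR volume
#' @slot seed master seed
#' @slot spoiling SPGR spoiling simulation model
#' @slot nIsochromats,nReps ensemble simulation parameters
#' @slot b1Range,b0RangeHz field map ranges
#' @slot erosionMm white-matter mask erosion radius (mm)
#' @slot lineshape bound-pool absorption lineshape
#' @slot singlePool replace all tissues by their single-pool reduction
#'   (bound fraction zero); used for model-validation studies
#' @export
setClass("StudyConfig",
  representation(shape = "integer", vendors = "character",
                 conditions = "character", subsets = "list",
                 nReplicates = "integer", snr = "numeric", seed = "integer",
                 spoiling = "character", nIsochromats = "integer",
                 nReps = "integer", b1Range = "numeric",
                 b0RangeHz = "numeric", erosionMm = "numeric",
                 lineshape = "character", singlePool = "logical"))

#' Construct a study configuration
#'
#' @param shape phantom dimensions (default 64 cubed)
#' @param vendors vendor letters
#' @param conditions study conditions
#' @param subsets named list of subsets (default the six configured ones)
#' @param nReplicates replicates per vendor-condition
#' @param snr white-matter SNR (0 or Inf disables noise)
#' @param seed master seed
#' @param spoiling \code{"isochromat"} (default: conditions genuinely
#'   differ in RF spoiling) or \code{"ideal"}
#' @param nIsochromats,nReps ensemble parameters
#' @param b1Range,b0RangeHz field ranges
#' @param erosionMm erosion radius (mm)
#' @param lineshape absorption lineshape
#' @param singlePool run the single-pool reduction of the phantom
#' @return a \linkS4class{StudyConfig}
#' @export
studyConfig <- function(shape = c(64, 64, 64), vendors = c("A", "B", "C"),
                        conditions = c("native", "harmonized", "csmt"),
                        subsets = defaultSubsets(), nReplicates = 1L,
                        snr = 100, seed = 1L,
                        spoiling = c("isochromat", "ideal"),
                        nIsochromats = 256L, nReps = 2000L,
                        b1Range = c(0.85, 1.15), b0RangeHz = c(-60, 60),
                        erosionMm = 2, lineshape = "super-lorentzian",
                        singlePool = FALSE) {
  spoiling <- match.arg(spoiling)
  stopifnot(all(conditions %in% c("native", "harmonized", "csmt")),
            all(vendors %in% c("A", "B", "C")))
  new("StudyConfig", shape = as.integer(shape), vendors = vendors,
      conditions = conditions, subsets = subsets,
      nReplicates = as.integer(nReplicates), snr = snr,
      seed = as.integer(seed), spoiling = spoiling,
      nIsochromats = as.integer(nIsochromats), nReps = as.integer(nReps),
      b1Range = b1Range, b0RangeHz = b0RangeHz, erosionMm = erosionMm,
      lineshape = lineshape, singlePool = singlePool)
}

setMethod("show", "StudyConfig", function(object) {
  cat(sprintf(
    "StudyConfig: %s grid, vendors %s, conditions %s, %d subsets, %d rep(s)\n",
    paste(object@shape, collapse = "x"),
    paste(object@vendors, collapse = "/"),
    paste(object@conditions, collapse = "/"),
    length(object@subsets), object@nReplicates))
})

.protocolForCondition <- function(condition) {
  switch(condition,
    native = protocolSpec(csmt = FALSE, rfSpoilingMode = "native"),
    harmonized = protocolSpec(csmt = FALSE, rfSpoilingMode = "harmonized"),
    csmt = protocolSpec(csmt = TRUE, rfSpoilingMode = "harmonized"),
    stop("unknown condition: ", condition))
}

.singlePoolReduction <- function(phantom) {
  phantom@tissueParams <- lapply(phantom@tissueParams, function(tp) {
    tp@boundFraction <- 0
    tp@kf <- 0
    tp
  })
  phantom
}

#' Run the full reproducibility study
#'
#' Simulates every vendor under every condition, fits every configured
#' flip-angle subset per replicate, extracts eroded-white-matter medians,
#' and assembles the variability report: per-dataset medians, worst-case
#' variability grouped across protocols (within vendor), across vendors
#' (within subset) and combined, deviations from the grand mean over the
#' vendor-by-subset grid, and voxelwise variability distribution summaries
#' (vendor pairs on the same subset, plus test/retest when replicates are
#' available).
#'
#' @param config a \linkS4class{StudyConfig}
#' @param verbose print progress messages
#' @return a \linkS4class{VariabilityReport}
#' @export
runStudy <- function(config = studyConfig(), verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  phantom <- makeDigitalPhantom(config@shape, seed = config@seed)
  if (config@singlePool) phantom <- .singlePoolReduction(phantom)
  fields <- makeFieldMaps(config@shape, config@b1Range, config@b0RangeHz,
                          seed = config@seed)
  wm <- phantom@labels == 1L
  wmEroded <- erodeMask(wm, config@erosionMm, phantom@voxelSize)
  say("eroded WM mask: %d of %d WM voxels", sum(wmEroded), sum(wm))
  profiles <- vendorProfiles()
  noiseless <- config@snr <= 0 || !is.finite(config@snr)
  medians <- list()
  wmValues <- list()   # [[key]] -> list(t1 = vector, t2 = vector) in mask
  fitCfg <- fitConfig(tr = 7)
  for (vendor in config@vendors) {
    for (condition in config@conditions) {
      protocol <- .protocolForCondition(condition)
      say("simulating vendor %s, condition %s ...", vendor, condition)
      baseSeed <- .deriveSeed(config@seed, match(vendor, c("A", "B", "C")))
      reps <- if (noiseless) {
        list(simulateAcquisition(phantom, fields, profiles[[vendor]],
                                 protocol, noiseSd = 0, seed = baseSeed,
                                 spoiling = config@spoiling,
                                 lineshape = config@lineshape,
                                 nIsochromats = config@nIsochromats,
                                 nReps = config@nReps))
      } else {
        replicateAcquisition(phantom, fields, profiles[[vendor]], protocol,
                             nReplicates = config@nReplicates,
                             baseSeed = baseSeed, snr = config@snr,
                             spoiling = config@spoiling,
                             lineshape = config@lineshape,
                             nIsochromats = config@nIsochromats,
                             nReps = config@nReps)
      }
      for (r in seq_along(reps)) {
        for (sName in names(config@subsets)) {
          maps <- jsrFitVolume(reps[[r]], config@subsets[[sName]],
                               mask = wmEroded, config = fitCfg)
          key <- paste(vendor, condition, sName, r, sep = "|")
          wmValues[[key]] <- list(t1 = maps@t1[wmEroded],
                                  t2 = maps@t2[wmEroded])
          for (param in c("t1", "t2")) {
            medians[[length(medians) + 1]] <- data.frame(
              vendor = vendor, condition = condition, subset = sName,
              replicate = r, parameter = param,
              median = stats::median(wmValues[[key]][[param]],
                                     na.rm = TRUE))
          }
        }
        say("  fitted replicate %d (%d subsets)", r,
            length(config@subsets))
      }
    }
  }
  medians <- do.call(rbind, medians)
  report <- .assembleReport(medians, wmValues, config)
  report
}

# Build the worst-case, deviation and voxelwise tables from the medians and
# the masked parameter values.
.assembleReport <- function(medians, wmValues, config) {
  subsetsN <- names(config@subsets)
  wc <- list(); dev <- list(); vox <- list()
  med1 <- medians[medians$replicate == 1, ]
  for (condition in unique(med1$condition)) {
    for (param in c("t1", "t2")) {
      d <- med1[med1$condition == condition & med1$parameter == param, ]
      # cross-protocol: across subsets within each vendor
      for (v in unique(d$vendor)) {
        m <- d$median[d$vendor == v]
        if (length(m) >= 2)
          wc[[length(wc) + 1]] <- data.frame(
            condition = condition, parameter = param,
            grouping = "crossProtocol", group = v,
            worstCase = worstCaseVariability(m))
      }
      # cross-vendor: across vendors within each subset
      for (s in unique(d$subset)) {
        m <- d$median[d$subset == s]
        if (length(m) >= 2)
          wc[[length(wc) + 1]] <- data.frame(
            condition = condition, parameter = param,
            grouping = "crossVendor", group = s,
            worstCase = worstCaseVariability(m))
      }
      # combined grid
      if (nrow(d) >= 2) {
        wc[[length(wc) + 1]] <- data.frame(
          condition = condition, parameter = param, grouping = "combined",
          group = "all", worstCase = worstCaseVariability(d$median))
        dv <- deviation(d$median)
        dev[[length(dev) + 1]] <- data.frame(
          condition = condition, parameter = param, vendor = d$vendor,
          subset = d$subset, deviation = dv)
      }
    }
  }
  # voxelwise distributions
  key <- function(v, c, s, r) paste(v, c, s, r, sep = "|")
  vendors <- unique(med1$vendor)
  for (condition in unique(med1$condition)) {
    for (param in c("t1", "t2")) {
      # vendor pairs, same subset, replicate 1
      if (length(vendors) >= 2) {
        prs <- utils::combn(vendors, 2)
        for (s in subsetsN) {
          for (k in seq_len(ncol(prs))) {
            a <- wmValues[[key(prs[1, k], condition, s, 1)]]
            b <- wmValues[[key(prs[2, k], condition, s, 1)]]
            if (is.null(a) || is.null(b)) next
            va <- a[[param]]; vb <- b[[param]]
            ok <- is.finite(va) & is.finite(vb)
            v <- 100 * (va[ok] - vb[ok]) / (0.5 * (va[ok] + vb[ok]))
            vox[[length(vox) + 1]] <- data.frame(
              condition = condition, parameter = param,
              comparison = "crossVendor", vendorA = prs[1, k],
              vendorB = prs[2, k], subset = s,
              median = stats::median(v))
          }
        }
      }
      # test/retest within vendor
      if (config@nReplicates >= 2) {
        for (v in vendors) {
          for (s in subsetsN) {
            a <- wmValues[[key(v, condition, s, 1)]]
            b <- wmValues[[key(v, condition, s, 2)]]
            if (is.null(a) || is.null(b)) next
            va <- a[[param]]; vb <- b[[param]]
            ok <- is.finite(va) & is.finite(vb)
            vv <- 100 * (va[ok] - vb[ok]) / (0.5 * (va[ok] + vb[ok]))
            vox[[length(vox) + 1]] <- data.frame(
              condition = condition, parameter = param,
              comparison = "testRetest", vendorA = v, vendorB = v,
              subset = s, median = stats::median(vv))
          }
        }
      }
    }
  }
  emptyOr <- function(lst, proto) if (length(lst)) do.call(rbind, lst)
                                  else proto
  new("VariabilityReport",
      medians = medians,
      worstCase = emptyOr(wc, data.frame(
        condition = character(), parameter = character(),
        grouping = character(), group = character(),
        worstCase = numeric())),
      deviations = emptyOr(dev, data.frame(
        condition = character(), parameter = character(),
        vendor = character(), subset = character(),
        deviation = numeric())),
      voxelwise = if (length(vox)) do.call(rbind, vox) else
        data.frame(condition = character(), parameter = character(),
                   comparison = character(), vendorA = character(),
                   vendorB = character(), subset = character(),
                   median = numeric()),
      config = list(shape = config@shape, vendors = config@vendors,
                    conditions = config@conditions,
                    subsets = names(config@subsets),
                    nReplicates = config@nReplicates, snr = config@snr,
                    seed = config@seed, spoiling = config@spoiling,
                    erosionMm = config@erosionMm,
                    singlePool = config@singlePool))
}
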