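# NIfTI exchange and study configuration I/O. Volumes are written as
# NIfTI-1 with a 1-mm isotropic RAS affine (uncompressed, so byte content
# is a pure function of the data); per-volume metadata travels in JSON
# sidecars and a run manifest records configuration, seeds and file hashes.

.niftiAffine <- function(voxelSize) {
  diag(c(rep(voxelSize, 3), 1))
}

.writeVolumeNifti <- function(vol, path, voxelSize = 1) {
  img <- RNifti::asNifti(vol, reference = NULL)
  RNifti::pixdim(img) <- rep(voxelSize, 3)
  RNifti::writeNifti(img, path)
  path
}

.readVolumeNifti <- function(path) {
  out <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("failed to read NIfTI file '",
                                           path, "': ", conditionMessage(e),
                                           call. = FALSE))
  array(as.numeric(out), dim = dim(out))
}

#' Read and validate a study configuration file
#'
#' YAML (or JSON) configuration with fields \code{shape}, \code{vendors},
#' \code{conditions}, \code{seed} (required) and \code{nReplicates},
#' \code{snr}, \code{spoiling}, \code{erosionMm}, \code{subsets} (optional).
#' Every random operation derives its seed from the mandatory \code{seed}.
#'
#' @param path configuration file path
#' @return a \linkS4class{StudyConfig}
#' @export
readStudyConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  for (f in c("shape", "vendors", "conditions", "seed"))
    if (is.null(raw[[f]]))
      stop(sprintf("config validation error: missing required field '%s'",
                   f))
  subsets <- if (is.null(raw$subsets)) defaultSubsets() else {
    out <- lapply(names(raw$subsets), function(nm) {
      s <- raw$subsets[[nm]]
      subsetSpec(nm, as.numeric(s$spgrFas), as.numeric(s$bssfpFas180),
                 isTRUE(s$includeBssfp0 %||% TRUE))
    })
    names(out) <- names(raw$subsets)
    out
  }
  studyConfig(
    shape = as.integer(raw$shape), vendors = as.character(raw$vendors),
    conditions = as.character(raw$conditions), subsets = subsets,
    nReplicates = as.integer(raw$nReplicates %||% 1L),
    snr = as.numeric(raw$snr %||% 100), seed = as.integer(raw$seed),
    spoiling = as.character(raw$spoiling %||% "isochromat"),
    erosionMm = as.numeric(raw$erosionMm %||% 2))
}

#' Write an acquisition set to disk
#'
#' One directory per dataset: \code{volNNN.nii} image volumes with
#' \code{volNNN.json} sidecars (sequence, flip angle, increments, pulse,
#' vendor, seeds), \code{b1.nii}/\code{b0.nii} field maps and
#' \code{labels.nii} truth labels.
#'
#' @param acq an \linkS4class{AcquisitionSet}
#' @param dir output directory (created)
#' @return invisibly, the written file paths
#' @export
writeAcquisitionSet <- function(acq, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vs <- acq@truth@voxelSize
  files <- character()
  for (j in seq_along(acq@volumes)) {
    base <- file.path(dir, sprintf("vol%03d", j))
    .writeVolumeNifti(acq@volumes[[j]], paste0(base, ".nii"), vs)
    row <- as.list(acq@meta[j, ])
    row$tr <- acq@tr; row$te <- acq@te; row$voxelSizeMm <- vs
    jsonlite::write_json(row, paste0(base, ".json"), auto_unbox = TRUE,
                         digits = NA, na = "null")
    files <- c(files, paste0(base, ".nii"), paste0(base, ".json"))
  }
  files <- c(files,
             .writeVolumeNifti(acq@fields@b1, file.path(dir, "b1.nii"), vs),
             .writeVolumeNifti(acq@fields@b0, file.path(dir, "b0.nii"), vs),
             .writeVolumeNifti(acq@truth@labels + 0,
                               file.path(dir, "labels.nii"), vs))
  invisible(files)
}

#' Read an acquisition set from disk
#'
#' @param dir directory written by \code{\link{writeAcquisitionSet}}
#' @return an \linkS4class{AcquisitionSet}
#' @export
readAcquisitionSet <- function(dir) {
  sidecars <- sort(list.files(dir, pattern = "^vol[0-9]+\\.json$",
                              full.names = TRUE))
  if (!length(sidecars)) stop("no volumes found in ", dir)
  meta <- do.call(rbind, lapply(sidecars, function(f) {
    as.data.frame(lapply(jsonlite::read_json(f, simplifyVector = TRUE),
                         function(x) if (is.null(x)) NA else x))
  }))
  for (col in c("fa", "phaseIncrement", "rfIncrement", "replicate",
                "noiseSd", "noiseSeed", "tr", "te", "voxelSizeMm"))
    if (col %in% names(meta)) meta[[col]] <- as.numeric(meta[[col]])
  vols <- lapply(sub("\\.json$", ".nii", sidecars), .readVolumeNifti)
  b1 <- .readVolumeNifti(file.path(dir, "b1.nii"))
  b0 <- .readVolumeNifti(file.path(dir, "b0.nii"))
  labels <- .readVolumeNifti(file.path(dir, "labels.nii"))
  truth <- new("PhantomVolume",
               labels = array(as.integer(round(labels)), dim = dim(labels)),
               tissueParams = defaultTissueParams(),
               voxelSize = meta$voxelSizeMm[1] %||% 1)
  new("AcquisitionSet", volumes = vols,
      meta = meta[, setdiff(names(meta), c("tr", "te", "voxelSizeMm"))],
      fields = new("FieldMaps", b1 = b1, b0 = b0), truth = truth,
      tr = meta$tr[1], te = meta$te[1])
}

#' Write fitted parameter maps
#'
#' @param maps a \linkS4class{JsrMaps}
#' @param dir output directory
#' @param voxelSize voxel size (mm)
#' @return invisibly, the directory
#' @export
writeJsrMaps <- function(maps, dir, voxelSize = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in c("t1", "t2", "m0", "deltaF", "residual"))
    .writeVolumeNifti(slot(maps, p), file.path(dir, paste0(p, ".nii")),
                      voxelSize)
  .writeVolumeNifti(maps@mask + 0, file.path(dir, "mask.nii"), voxelSize)
  .writeVolumeNifti(maps@converged + 0, file.path(dir, "converged.nii"),
                    voxelSize)
  jsonlite::write_json(maps@provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read fitted parameter maps
#'
#' @param dir directory written by \code{\link{writeJsrMaps}}
#' @return a \linkS4class{JsrMaps}
#' @export
readJsrMaps <- function(dir) {
  rd <- function(p) .readVolumeNifti(file.path(dir, paste0(p, ".nii")))
  prov <- jsonlite::read_json(file.path(dir, "provenance.json"),
                              simplifyVector = TRUE)
  new("JsrMaps", t1 = rd("t1"), t2 = rd("t2"), m0 = rd("m0"),
      deltaF = rd("deltaF"), residual = rd("residual"),
      converged = array(rd("converged") > 0.5, dim = dim(rd("converged"))),
      mask = array(rd("mask") > 0.5, dim = dim(rd("mask"))),
      provenance = as.list(prov))
}
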