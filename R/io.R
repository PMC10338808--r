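# Phantom dataset IO: NIfTI signal volumes with bval/bvec sidecars and a
# TSV voxel-label table.

#' Write / read a phantom dataset as NIfTI + sidecars
#'
#' \code{writeDWIDataset} stores the voxels-x-volumes signal array as a
#' 4D NIfTI image (voxels along the first axis), the scheme as FSL-style
#' \code{.bval}/\code{.bvec} sidecars, and the per-voxel region labels and
#' any ground truth as \code{<prefix>_voxels.tsv}.
#' \code{readDWIDataset} reconstructs the \linkS4class{DWIDataset}.
#' The outlier mask, when present, is written as
#' \code{<prefix>_outliers.tsv} (voxel, volume index pairs).
#'
#' @param object a \linkS4class{DWIDataset}.
#' @param prefix output path prefix.
#' @param name scheme label used on re-read.
#' @return \code{writeDWIDataset}: the prefix, invisibly;
#'   \code{readDWIDataset}: a \linkS4class{DWIDataset}.
#' @export
writeDWIDataset <- function(object, prefix) {
  stopifnot(is(object, "DWIDataset"))
  sig <- dwiSignals(object)
  arr <- array(sig, dim = c(nrow(sig), 1L, 1L, ncol(sig)))
  RNifti::writeNifti(RNifti::asNifti(arr), paste0(prefix, ".nii.gz"))
  writeScheme(dwiScheme(object), prefix)
  rd <- SummarizedExperiment::rowData(object)
  vox <- data.frame(voxel = seq_len(nrow(sig)), region = rd$region)
  for (cn in grep("^truth_", colnames(rd), value = TRUE)) {
    vox[[cn]] <- rd[[cn]]
  }
  utils::write.table(vox, paste0(prefix, "_voxels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  mask <- outlierMask(object)
  if (!is.null(mask)) {
    idx <- which(mask, arr.ind = TRUE)
    utils::write.table(data.frame(voxel = idx[, 1L], volume = idx[, 2L]),
                       paste0(prefix, "_outliers.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(prefix)
}

#' @rdname writeDWIDataset
#' @export
readDWIDataset <- function(prefix, name = "custom") {
  arr <- RNifti::readNifti(paste0(prefix, ".nii.gz"))
  d <- dim(arr)
  sig <- matrix(as.numeric(arr), d[1L], d[4L])
  scheme <- readScheme(paste0(prefix, ".bval"), paste0(prefix, ".bvec"),
                       name = name)
  vox <- utils::read.table(paste0(prefix, "_voxels.tsv"), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  truthCols <- grep("^truth_", names(vox), value = TRUE)
  truth <- NULL
  if (length(truthCols) > 0L) {
    truth <- vox[, truthCols, drop = FALSE]
    names(truth) <- sub("^truth_", "", names(truth))
  }
  mask <- NULL
  maskPath <- paste0(prefix, "_outliers.tsv")
  if (file.exists(maskPath)) {
    om <- utils::read.table(maskPath, header = TRUE, sep = "\t")
    mask <- matrix(FALSE, nrow(sig), ncol(sig))
    mask[cbind(om$voxel, om$volume)] <- TRUE
  }
  DWIDataset(sig, scheme, region = vox$region, truth = truth,
             outlierMask = mask)
}

#' Write a region-effect report as TSV
#'
#' Writes the \code{effects} and \code{quartiles} tables of a
#' [regionReport()] result to \code{<prefix>_effects.tsv} and
#' \code{<prefix>_quartiles.tsv}.
#'
#' @param report a list as returned by [regionReport()].
#' @param prefix output path prefix.
#' @return the prefix, invisibly.
#' @export
writeRegionReport <- function(report, prefix) {
  utils::write.table(report$effects, paste0(prefix, "_effects.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$quartiles, paste0(prefix, "_quartiles.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
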