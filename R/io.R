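# NIfTI input/output and study export.

#' Write a volume (or mask) to NIfTI
#'
#' @param x a \linkS4class{VolumeImage} or \linkS4class{VoxelMask}.
#' @param path output path (".nii" or ".nii.gz").
#' @return the path, invisibly.
#' @export
writeVolumeNifti <- function(x, path) {
  arr <- voxelData(x)
  if (is.logical(arr)) arr <- arr * 1L
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- voxelSpacing(x)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume from NIfTI
#'
#' @param path NIfTI file.
#' @param mask read as a \linkS4class{VoxelMask} (values > 0.5) instead of
#'   a \linkS4class{VolumeImage}.
#' @return a VolumeImage or VoxelMask with spacing from the header.
#' @export
readVolumeNifti <- function(path, mask = FALSE) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  arr <- array(as.numeric(img), dim(img)[1:3])
  if (mask) VoxelMask(arr > 0.5, sp) else VolumeImage(arr, sp)
}

#' Export a generated study to NIfTI volumes plus a sessions manifest
#'
#' Writes one image and one VOI mask per session (two-layer subjects
#' additionally get inner/outer layer masks) and a CSV manifest with the
#' session metadata and file paths.
#'
#' @param study result of \code{\link{generateStudy}}.
#' @param dir output directory (created if needed).
#' @param gz write ".nii.gz" (default TRUE).
#' @return the manifest data.frame, invisibly; also written as
#'   \code{sessions.csv}.
#' @export
writeStudyNifti <- function(study, dir, gz = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (gz) ".nii.gz" else ".nii"
  manifest <- study$manifest
  manifest$image_path <- NA_character_
  manifest$mask_path <- NA_character_
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$session_id[i]
    sess <- study$sessions[[id]]
    ip <- file.path(dir, paste0(id, "_img", ext))
    mp <- file.path(dir, paste0(id, "_voi", ext))
    writeVolumeNifti(sess$image, ip)
    writeVolumeNifti(sess$masks$voi, mp)
    for (nm in setdiff(names(sess$masks), "voi"))
      writeVolumeNifti(sess$masks[[nm]], file.path(dir, paste0(id, "_", nm, ext)))
    manifest$image_path[i] <- ip
    manifest$mask_path[i] <- mp
  }
  utils::write.csv(manifest, file.path(dir, "sessions.csv"), row.names = FALSE)
  invisible(manifest)
}
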