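#' Write a synthetic patient to NIfTI-1 files
#'
#' Writes the 4-D DWI stack (one volume per b-value) and one file per
#' segmentation mask, with the voxel geometry recorded in the headers, plus
#' a small JSON sidecar with the b-values.
#'
#' @param patient A [simulate_patient()] result.
#' @param dir Output directory (created if missing).
#' @param patient_id Basename prefix for the files.
#' @return Character vector of the written paths, invisibly.
#' @export
write_patient_nifti <- function(patient, dir, patient_id = "patient") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vox <- patient$dwi$voxel_size_mm
  paths <- c(
    dwi = file.path(dir, paste0(patient_id, "_dwi.nii.gz")),
    prostate = file.path(dir, paste0(patient_id, "_prostate.nii.gz")),
    peripheral_zone = file.path(dir, paste0(patient_id, "_pz.nii.gz")),
    central_gland = file.path(dir, paste0(patient_id, "_cg.nii.gz")),
    bvals = file.path(dir, paste0(patient_id, "_bvals.json"))
  )
  RNifti::writeNifti(RNifti::asNifti(patient$dwi$signal, pixdim = vox),
                     paths[["dwi"]])
  for (m in c("prostate", "peripheral_zone", "central_gland")) {
    vol <- patient$segmentation[[m]] * 1L
    RNifti::writeNifti(RNifti::asNifti(vol, pixdim = vox), paths[[m]])
  }
  jsonlite::write_json(list(b_values = patient$dwi$b_values,
                            voxel_size_mm = vox),
                       paths[["bvals"]], auto_unbox = FALSE, digits = NA)
  invisible(paths)
}

#' Read a DWI series written by [write_patient_nifti()]
#'
#' @param dwi_path Path to the 4-D NIfTI signal file.
#' @param bvals_path Path to the JSON sidecar with b-values and voxel size.
#' @return A [dwi_series()].
#' @export
read_dwi_nifti <- function(dwi_path, bvals_path) {
  img <- RNifti::readNifti(dwi_path)
  meta <- jsonlite::read_json(bvals_path, simplifyVector = TRUE)
  dwi_series(array(as.numeric(img), dim = dim(img)),
             meta$b_values, meta$voxel_size_mm)
}

#' Write a scalar map (restriction score, ADC, compartment) to NIfTI-1
#'
#' @param map An object with a `value` 3-D array and `voxel_size_mm` (e.g.
#'   from [compute_rsirs()] or [fit_adc()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_map_nifti <- function(map, path) {
  RNifti::writeNifti(RNifti::asNifti(map$value, pixdim = map$voxel_size_mm),
                     path)
  invisible(path)
}

#' Read a segmentation mask from NIfTI-1
#'
#' @param path Path to a mask volume (nonzero = inside).
#' @return Logical 3-D array.
#' @export
read_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img) != 0, dim = dim(img))
}
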