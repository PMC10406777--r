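# YAML manifests listing per-patient image/mask/mesh files, the on-disk
# interface between the phantom generator, model building and augmentation.

#' Read a training-sample manifest
#'
#' The manifest is a YAML list under key `samples`, each entry with
#' `patient_id`, `image`, `mask` and `mesh` paths (relative paths resolve
#' against the manifest's directory).
#'
#' @param path manifest YAML file.
#' @return list of [training_sample()].
#' @export
read_sample_manifest <- function(path) {
  man <- yaml::read_yaml(path)
  if (is.null(man$samples)) stop("manifest has no 'samples' list")
  base <- dirname(path)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  lapply(man$samples, function(e) {
    img <- read_volume(resolve(e$image))
    msk_img <- read_volume(resolve(e$mask))
    msk <- binary_mask(array(as.integer(msk_img$data > 0.5),
                             dim(msk_img$data)),
                       msk_img$spacing, msk_img$origin)
    training_sample(img, msk, read_mesh(resolve(e$mesh)), e$patient_id)
  })
}

#' Write a training population to disk with a manifest
#'
#' Each sample is written as `<id>_image.nii.gz`, `<id>_mask.nii.gz` and
#' `<id>_mesh.vtk` plus a `manifest.yaml` consumable by
#' [read_sample_manifest()].
#'
#' @param samples list of [training_sample()].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_sample_manifest <- function(samples, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(samples, function(s) {
    id <- s$patient_id
    write_volume(s$image, file.path(dir, paste0(id, "_image.nii.gz")))
    write_volume(volume_image(s$mask$data * 1, s$mask$spacing, s$mask$origin),
                 file.path(dir, paste0(id, "_mask.nii.gz")))
    write_mesh(s$mesh, file.path(dir, paste0(id, "_mesh.vtk")))
    list(patient_id = id,
         image = paste0(id, "_image.nii.gz"),
         mask = paste0(id, "_mask.nii.gz"),
         mesh = paste0(id, "_mesh.vtk"))
  })
  mp <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(samples = entries), mp)
  invisible(mp)
}
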