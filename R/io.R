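# NIfTI-1 I/O for atlases and subject volumes. All volumes written by the
# package share the atlas affine so that round-tripped images pass the
# alignment check in region_means().

# `datatype` is applied at write time: asNifti() with an explicit datatype
# returns an internal image whose pixdim can no longer be modified.
as_nifti_image <- function(arr, affine, voxel_size) {
  img <- RNifti::asNifti(as.array(arr))
  RNifti::pixdim(img) <- voxel_size
  aff <- matrix(as.numeric(affine), 4, 4)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  img
}

#' Write and read a region atlas
#'
#' The atlas is stored as two plain files: a NIfTI-1 label volume and a CSV
#' region table (`pair_name,region,hemisphere,label_id,baseline_mean`).
#'
#' @param atlas A `pet_atlas`.
#' @param nii_path Path of the label volume (`.nii` or `.nii.gz`).
#' @param regions_path Path of the region table CSV.
#' @return `write_atlas()` returns the paths invisibly; `read_atlas()`
#'   returns a `pet_atlas`.
#' @export
write_atlas <- function(atlas, nii_path, regions_path) {
  atlas <- as_pet_atlas(atlas)
  img <- as_nifti_image(atlas$labels, atlas$affine, atlas$voxel_size)
  RNifti::writeNifti(img, nii_path, datatype = "int16")
  write.csv(atlas$regions, regions_path, row.names = FALSE, quote = FALSE)
  invisible(c(labels = nii_path, regions = regions_path))
}

#' @rdname write_atlas
#' @export
read_atlas <- function(nii_path, regions_path) {
  img <- RNifti::readNifti(nii_path)
  regions <- as_tibble(read.csv(regions_path))
  needed <- c("pair_name", "hemisphere", "label_id")
  if (!all(needed %in% names(regions))) {
    abort("Region table must contain pair_name, hemisphere and label_id.")
  }
  lab <- array(as.integer(img), dim = dim(img))
  present <- setdiff(unique(as.vector(lab)), 0L)
  if (!all(present %in% regions$label_id)) {
    abort("Label volume contains labels absent from the region table.")
  }
  structure(
    list(
      labels = lab,
      affine = matrix(as.numeric(RNifti::xform(img)), 4, 4),
      voxel_size = unname(RNifti::pixdim(img)[seq_len(3)]),
      regions = regions
    ),
    class = "pet_atlas"
  )
}

#' Write a subject volume as NIfTI-1
#'
#' @param volume 3D array (with an `affine` attribute) or `pet_subject`.
#' @param path Destination (`.nii` or `.nii.gz`).
#' @param atlas Optional `pet_atlas` supplying affine/voxel size when the
#'   volume does not carry one.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, atlas = NULL) {
  if (inherits(volume, "pet_subject")) volume <- volume$volume
  affine <- image_affine(volume) %||% as_pet_atlas(atlas)$affine
  voxel_size <- abs(diag(affine)[seq_len(3)])
  img <- as_nifti_image(volume, affine, voxel_size)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a synthetic cohort to a directory
#'
#' Materializes a [generate_cohort()] result as plain files: the atlas
#' (`atlas.nii.gz` + `regions.csv`), one NIfTI volume per subject under
#' `subjects/`, the cohort manifest (`manifest.csv`: subject ids, labels,
#' applied scales, per-subject seeds), and the generator configuration
#' (`config.yaml`).
#'
#' @param cohort A `pet_cohort`.
#' @param atlas The `pet_atlas` the cohort was generated from.
#' @param dir Output directory (created if missing).
#' @param config The [cohort_config()] used (stored for provenance).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, atlas, dir, config = NULL) {
  dir.create(file.path(dir, "subjects"), recursive = TRUE,
             showWarnings = FALSE)
  write_atlas(atlas, file.path(dir, "atlas.nii.gz"),
              file.path(dir, "regions.csv"))
  purrr::walk(cohort$subjects, function(s) {
    write_volume(s, file.path(dir, "subjects",
                              paste0(s$subject_id, ".nii.gz")))
  })
  write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
            row.names = FALSE, quote = FALSE)
  if (!is.null(config)) {
    yaml::write_yaml(unclass(config), file.path(dir, "config.yaml"))
  }
  invisible(dir)
}
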