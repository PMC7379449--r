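#' Regional asymmetry index
#'
#' The asymmetry index compares mean uptake of homologous left/right regions:
#' \deqn{AI = 200 (L - R) / (L + R)}
#' It is dimensionless, lies strictly inside (-200, 200) for positive means,
#' is antisymmetric in its arguments, and is invariant to any common positive
#' scaling of both means — so no count normalization of the PET volume is
#' needed. Under this sign convention, hypometabolism of the left hemisphere
#' (as in left TLE) produces negative AI values.
#'
#' @param left_mean,right_mean Positive regional mean uptake values
#'   (arbitrary counts). Vectorized.
#' @return Numeric AI value(s) in (-200, 200).
#' @examples
#' asymmetry_index(104, 96) # 8
#' asymmetry_index(96, 104) # -8
#' @export
asymmetry_index <- function(left_mean, right_mean) {
  if (!is.numeric(left_mean) || !is.numeric(right_mean)) {
    abort("Regional means must be numeric.")
  }
  if (any(!is.finite(left_mean)) || any(!is.finite(right_mean)) ||
      any(left_mean <= 0) || any(right_mean <= 0)) {
    abort("Regional means must be finite and strictly positive (PET counts).")
  }
  200 * (left_mean - right_mean) / (left_mean + right_mean)
}

#' Regional mean uptake from an atlas-labeled volume
#'
#' Averages voxel values of `volume` within each labeled region of `atlas`.
#' Background (label 0) is excluded. The volume must already be aligned to
#' the atlas grid: same array dimensions and, when both carry affines, the
#' same affine to within an absolute elementwise tolerance of 1e-4
#' (resampling/registration is out of scope; inputs are assumed spatially
#' normalized).
#'
#' @param volume 3D numeric array (or `RNifti` image) of uptake counts.
#' @param atlas A `pet_atlas` object (see [generate_atlas()]) or a list with
#'   elements `labels` (integer array) and `regions` (region table).
#' @return A tibble with one row per atlas region: `pair_name`,
#'   `hemisphere`, `label_id`, `n_voxels`, `mean`.
#' @export
region_means <- function(volume, atlas) {
  atlas <- as_pet_atlas(atlas)
  vol_affine <- image_affine(volume)
  vol <- as.array(volume)
  lab <- as.array(atlas$labels)
  if (!identical(dim(vol), dim(lab))) {
    abort(sprintf(
      "Volume grid (%s) does not match atlas grid (%s).",
      paste(dim(vol), collapse = "x"), paste(dim(lab), collapse = "x")
    ))
  }
  if (!is.null(vol_affine) && !is.null(atlas$affine) &&
      max(abs(vol_affine - matrix(as.numeric(atlas$affine), 4, 4))) > 1e-4) {
    abort("Volume and atlas affines differ by more than 1e-4; inputs must be aligned.")
  }
  regions <- atlas$regions
  idx <- match(lab, regions$label_id) # NA for background / unknown labels
  known <- !is.na(idx)
  n_vox <- tabulate(idx[known], nbins = nrow(regions))
  if (any(n_vox == 0)) {
    abort(paste0("Atlas label(s) with no voxels: ",
                 paste(regions$label_id[n_vox == 0], collapse = ", ")))
  }
  sums <- vapply(split(vol[known], idx[known]), sum, numeric(1))
  means <- numeric(nrow(regions))
  means[as.integer(names(sums))] <- sums
  means <- means / n_vox
  if (any(!is.finite(means))) abort("Non-finite regional mean encountered.")
  tibble::tibble(
    pair_name = regions$pair_name,
    hemisphere = regions$hemisphere,
    label_id = regions$label_id,
    n_voxels = n_vox,
    mean = means
  )
}

# Affine of an in-memory volume: NIfTI images carry an xform, plain arrays
# may carry an "affine" attribute, anything else has none.
image_affine <- function(x) {
  if (inherits(x, "niftiImage")) {
    return(matrix(as.numeric(RNifti::xform(x)), 4, 4))
  }
  a <- attr(x, "affine", exact = TRUE)
  if (is.null(a)) NULL else matrix(as.numeric(a), 4, 4)
}

#' Asymmetry-index feature row from regional means
#'
#' Pairs each region's left and right hemisphere means and applies
#' [asymmetry_index()], yielding one AI value per region pair. The AI is
#' always computed from the two regional means (never voxelwise and then
#' averaged). Columns follow the canonical region order.
#'
#' @param means A tibble as returned by [region_means()].
#' @param subject_id Optional subject identifier stored in the output row.
#' @return A one-row tibble: `subject_id` (if given) and one AI column per
#'   region pair present.
#' @export
compute_features <- function(means, subject_id = NULL) {
  required <- c("pair_name", "hemisphere", "mean")
  if (!is.data.frame(means) || !all(required %in% names(means))) {
    abort("`means` must contain pair_name, hemisphere and mean columns.")
  }
  wide <- tidyr::pivot_wider(
    dplyr::select(means, "pair_name", "hemisphere", "mean"),
    names_from = "hemisphere", values_from = "mean"
  )
  if (!all(c("left", "right") %in% names(wide)) ||
      anyNA(wide$left) || anyNA(wide$right)) {
    abort("Both hemispheres of every region pair are required.")
  }
  wide <- wide[order(match(wide$pair_name, pair_names())), ]
  ai <- asymmetry_index(wide$left, wide$right)
  row <- as_tibble(setNames(as.list(ai), wide$pair_name))
  if (!is.null(subject_id)) {
    row <- dplyr::bind_cols(tibble::tibble(subject_id = subject_id), row)
  }
  row
}

#' Extract the asymmetry feature table from a set of subject volumes
#'
#' Convenience wrapper running [region_means()] and [compute_features()] for
#' each subject of a cohort, producing the classifier-ready feature table.
#'
#' @param subjects A list of subject volumes (3D arrays or `RNifti` images),
#'   optionally named by subject id, or a `pet_cohort` object from
#'   [generate_cohort()].
#' @param atlas The `pet_atlas` the volumes are aligned to.
#' @param labels Optional character vector of Left/Right labels (recycled
#'   from a cohort object when available).
#' @return A tibble with `subject_id`, optional `label`, and the thirteen AI
#'   columns.
#' @export
extract_features <- function(subjects, atlas, labels = NULL) {
  if (inherits(subjects, "pet_cohort")) {
    labels <- labels %||% subjects$manifest$label
    subjects <- subjects$volumes
  }
  ids <- names(subjects) %||% sprintf("S%03d", seq_along(subjects))
  if (is.null(names(subjects))) names(subjects) <- ids
  rows <- purrr::imap(subjects, function(vol, id) {
    compute_features(region_means(vol, atlas), subject_id = id)
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(labels)) {
    if (length(labels) != nrow(out)) {
      abort("`labels` length must match the number of subjects.")
    }
    out <- dplyr::bind_cols(
      out[, "subject_id"],
      tibble::tibble(label = as.character(labels)),
      out[, setdiff(names(out), "subject_id")]
    )
  }
  out
}

#' Write / read an asymmetry feature table as CSV
#'
#' The on-disk format is a plain CSV with header
#' `subject_id,label,<13 pair names>` (the label column is optional).
#'
#' @param data Feature table tibble.
#' @param path File path.
#' @return `write_features()` returns `path` invisibly; `read_features()`
#'   returns the tibble.
#' @export
write_features <- function(data, path) {
  check_feature_table(data)
  write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  out <- as_tibble(read.csv(path, check.names = FALSE))
  check_feature_table(out)
  out
}
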