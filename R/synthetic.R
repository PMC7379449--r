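#' Default planted effect sizes per region pair
#'
#' Fractional ipsilateral uptake reductions (delta) used by the synthetic
#' cohort generator. Values are chosen so that expected asymmetry-index
#' magnitudes 200*delta/(2 - delta) land in roughly 1-6 on the +/-200 AI
#' scale, strongest in mesial temporal structures (hippocampus, amygdala,
#' parahippocampal gyrus) and tapering off in contiguous neocortical and
#' subcortical regions — the gradient described for interictal
#' hypometabolism in mesial TLE.
#'
#' @return Named numeric vector over the thirteen pair names.
#' @export
default_effect_map <- function() {
  c(
    Frontal_Inf_Oper  = 0.015,
    Rolandic_Oper     = 0.015,
    Insula            = 0.020,
    Hippocampus       = 0.060,
    ParaHippocampal   = 0.050,
    Amygdala          = 0.050,
    SupraMarginal     = 0.010,
    Thalamus          = 0.020,
    Temporal_Sup      = 0.025,
    Temporal_Pole_Sup = 0.030,
    Temporal_Mid      = 0.030,
    Temporal_Pole_Mid = 0.040,
    Temporal_Inf      = 0.035
  )
}

#' Expected asymmetry index for a planted effect
#'
#' Closed form for the AI produced by an ipsilateral fractional uptake
#' reduction `delta` and contralateral fractional gain `gain`, on the side
#' convention that the magnitude is reported for a Right-TLE subject
#' (positive AI); a Left-TLE subject has the negated value.
#'
#' @param delta Fractional ipsilateral reduction in \[0, 0.5).
#' @param gain Fractional contralateral increase (default 0).
#' @return Expected AI magnitude `200 * ((1+gain) - (1-delta)) /
#'   ((1-delta) + (1+gain))`.
#' @examples
#' expected_ai(0.06) # 6.185567; a Left subject's hippocampal AI is -6.185567
#' @export
expected_ai <- function(delta, gain = 0) {
  200 * ((1 + gain) - (1 - delta)) / ((1 - delta) + (1 + gain))
}

#' Synthetic cohort configuration
#'
#' Bundles and validates the parameters of the synthetic PET cohort
#' generator. Defaults emulate the cohort structure the analysis assumes:
#' 49 subjects with a 27:22 Left:Right class ratio, per-region ipsilateral
#' hypometabolism of a few percent (see [default_effect_map()]), additive
#' Gaussian voxel noise, and one multiplicative global scale factor per
#' subject (the nuisance the asymmetry index must cancel).
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param left_fraction Fraction of Left-TLE subjects, in (0, 1).
#' @param effect_map Named vector of fractional ipsilateral uptake
#'   reductions per pair name, each in \[0, 0.5).
#' @param contralateral_gain Fractional uptake increase on the
#'   non-epileptogenic side (mild compensatory hypermetabolism; default 0).
#' @param voxel_noise_sd SD of additive Gaussian voxel noise, in counts
#'   (volume generator).
#' @param ai_noise_sd SD of additive Gaussian noise on each AI value
#'   (direct feature-table generator, which bypasses the volume layer).
#' @param global_scale_range Interval of positive per-subject global
#'   multipliers.
#' @param background_mean Mean uptake of unlabeled (background) voxels.
#' @param baseline_range Interval from which per-pair baseline uptake means
#'   are drawn when generating an atlas.
#' @param seed Integer seed controlling all cohort randomness.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 49,
                          left_fraction = 27 / 49,
                          effect_map = default_effect_map(),
                          contralateral_gain = 0,
                          voxel_noise_sd = 5,
                          ai_noise_sd = 2,
                          global_scale_range = c(0.8, 1.2),
                          background_mean = 40,
                          baseline_range = c(80, 120),
                          seed = 1L) {
  if (!is.numeric(n_subjects) || n_subjects < 2) {
    abort("`n_subjects` must be at least 2.")
  }
  if (left_fraction <= 0 || left_fraction >= 1) {
    abort("`left_fraction` must lie strictly inside (0, 1).")
  }
  if (is.null(names(effect_map)) ||
      !all(names(effect_map) %in% pair_names())) {
    abort("`effect_map` must be named by region pair names.")
  }
  if (any(effect_map < 0) || any(effect_map >= 0.5)) {
    abort("Effect sizes must lie in [0, 0.5).")
  }
  if (contralateral_gain < 0 || contralateral_gain >= 1) {
    abort("`contralateral_gain` must lie in [0, 1).")
  }
  if (voxel_noise_sd < 0 || ai_noise_sd < 0) {
    abort("Noise SDs must be nonnegative.")
  }
  if (length(global_scale_range) != 2 || any(global_scale_range <= 0) ||
      diff(global_scale_range) < 0) {
    abort("`global_scale_range` must be a positive increasing interval.")
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects), left_fraction = left_fraction,
      effect_map = effect_map, contralateral_gain = contralateral_gain,
      voxel_noise_sd = voxel_noise_sd, ai_noise_sd = ai_noise_sd,
      global_scale_range = global_scale_range,
      background_mean = background_mean, baseline_range = baseline_range,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Generate a synthetic bilateral region atlas
#'
#' Builds an integer-labeled 3D volume containing the thirteen region pairs
#' as axis-aligned blocks placed mirror-symmetrically about the midsagittal
#' plane (first array axis). Block geometry is deliberately simple: the
#' asymmetry index depends only on regional means, so anatomical shape is
#' irrelevant to the downstream statistics. Hemisphere membership is
#' recorded in the region table, never inferred from voxel coordinates.
#'
#' @param grid_shape Integer vector of 3 array dimensions (default
#'   64 x 64 x 48).
#' @param voxel_size Voxel edge lengths in mm (default 2 mm isotropic).
#' @param seed Seed for the per-pair baseline uptake draws.
#' @param block_size Edge length of each cubic region block, in voxels.
#' @param baseline_range Interval for per-pair baseline uptake means
#'   (identical within a pair).
#' @return A `pet_atlas`: list with `labels` (integer array), `affine`
#'   (4x4), `voxel_size`, and `regions` (tibble: pair_name, region,
#'   hemisphere, label_id, baseline_mean).
#' @export
generate_atlas <- function(grid_shape = c(64L, 64L, 48L),
                           voxel_size = c(2, 2, 2),
                           seed = 1L,
                           block_size = 5L,
                           baseline_range = c(80, 120)) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape < 1)) {
    abort("`grid_shape` must be three positive integers.")
  }
  b <- as.integer(block_size)
  pairs <- region_pairs()
  n_pairs <- nrow(pairs)
  # lay blocks on a y-z lattice inside the left half, with a 2-voxel gap
  margin <- 2L
  step <- b + 2L
  n_col <- 4L
  n_row <- as.integer(ceiling(n_pairs / n_col))
  need_x <- margin + b          # per hemisphere
  need_y <- margin + n_col * step
  need_z <- margin + n_row * step
  if (grid_shape[1] < 2 * need_x || grid_shape[2] < need_y ||
      grid_shape[3] < need_z) {
    abort(sprintf(
      "Grid %s too small to place %d mirror-symmetric region blocks (needs at least %d x %d x %d).",
      paste(grid_shape, collapse = "x"), 2 * n_pairs,
      2 * need_x, need_y, need_z
    ))
  }
  labels <- array(0L, dim = grid_shape)
  nx <- grid_shape[1]
  for (i in seq_len(n_pairs)) {
    row <- (i - 1L) %/% n_col
    col <- (i - 1L) %% n_col
    xs <- (margin + 1L):(margin + b)             # left-hemisphere block
    ys <- (margin + col * step + 1L):(margin + col * step + b)
    zs <- (margin + row * step + 1L):(margin + row * step + b)
    labels[xs, ys, zs] <- 2L * i - 1L
    labels[nx + 1L - xs, ys, zs] <- 2L * i      # mirrored right block
  }
  set.seed(seed)
  baseline <- runif(n_pairs, baseline_range[1], baseline_range[2])
  regions <- tibble::tibble(
    pair_name = rep(pairs$pair_name, each = 2),
    region = rep(pairs$region, each = 2),
    hemisphere = rep(c("left", "right"), times = n_pairs),
    label_id = as.integer(seq_len(2 * n_pairs)),
    baseline_mean = rep(baseline, each = 2)
  )
  affine <- diag(c(voxel_size, 1))
  affine[seq_len(3), 4] <- -voxel_size * grid_shape / 2
  structure(
    list(labels = labels, affine = affine, voxel_size = voxel_size,
         regions = regions),
    class = "pet_atlas"
  )
}

as_pet_atlas <- function(x) {
  if (inherits(x, "pet_atlas")) return(x)
  if (is.list(x) && all(c("labels", "regions") %in% names(x))) {
    x$affine <- x$affine %||% NULL
    class(x) <- "pet_atlas"
    return(x)
  }
  abort("`atlas` must be a pet_atlas or a list with labels and regions.")
}

#' @export
print.pet_atlas <- function(x, ...) {
  cat(sprintf(
    "<pet_atlas> %s voxels, %d regions (%d pairs)\n",
    paste(dim(x$labels), collapse = " x "), nrow(x$regions),
    nrow(x$regions) / 2
  ))
  invisible(x)
}

#' Swap hemisphere bookkeeping of an atlas
#'
#' Returns the atlas with the left/right assignment of every region pair
#' exchanged in the region table. Applying this to the atlas while leaving
#' subject volumes untouched is the mirror operation: every asymmetry index
#' changes sign exactly.
#'
#' @param atlas A `pet_atlas`.
#' @return The hemisphere-swapped `pet_atlas`.
#' @export
swap_hemispheres <- function(atlas) {
  atlas <- as_pet_atlas(atlas)
  atlas$regions$hemisphere <-
    c(left = "right", right = "left")[atlas$regions$hemisphere]
  atlas
}

#' Generate one synthetic PET-like subject volume
#'
#' Voxels of each atlas region are drawn as Gaussian noise around the
#' region's baseline mean, reduced by the planted fractional effect on the
#' side ipsilateral to the epileptogenic focus and increased by
#' `contralateral_gain` on the other side; background voxels sit at
#' `background_mean`. The whole volume is finally multiplied by one
#' subject-level global scale factor — exactly the nuisance the asymmetry
#' index is designed to cancel.
#'
#' @param atlas A `pet_atlas`.
#' @param true_side `"Left"` or `"Right"` — the epileptogenic hemisphere.
#' @param config A [cohort_config()].
#' @param seed Integer seed for this subject's draws.
#' @param subject_id Identifier stored on the result.
#' @return A `pet_subject`: list with `subject_id`, `true_side`, `volume`
#'   (3D array with the atlas affine attached), `applied_scale`.
#' @export
generate_subject <- function(atlas, true_side, config = cohort_config(),
                             seed = 1L, subject_id = "S001") {
  atlas <- as_pet_atlas(atlas)
  if (!is.character(true_side) || length(true_side) != 1 ||
      !true_side %in% tle_classes()) {
    abort("`true_side` must be \"Left\" or \"Right\".")
  }
  regions <- atlas$regions
  delta <- config$effect_map[regions$pair_name]
  delta[is.na(delta)] <- 0
  ipsi <- regions$hemisphere == tolower(true_side)
  factor <- ifelse(ipsi, 1 - delta, 1 + config$contralateral_gain)
  mu <- regions$baseline_mean * factor
  if (any(mu <= 0) || config$background_mean < 0) {
    abort("Configured effects produce nonpositive regional means.")
  }
  set.seed(seed)
  scale <- runif(1, config$global_scale_range[1], config$global_scale_range[2])
  lab <- atlas$labels
  vol <- array(
    rnorm(length(lab), mean = config$background_mean,
          sd = config$voxel_noise_sd),
    dim = dim(lab)
  )
  idx <- match(lab, regions$label_id)
  inside <- !is.na(idx)
  vol[inside] <- mu[idx[inside]] +
    rnorm(sum(inside), mean = 0, sd = config$voxel_noise_sd)
  vol <- vol * scale
  vol[vol < 0] <- 0
  attr(vol, "affine") <- atlas$affine
  structure(
    list(subject_id = subject_id, true_side = true_side, volume = vol,
         applied_scale = scale),
    class = "pet_subject"
  )
}

# Label sequence shared by both cohort generators: round(n * left_fraction)
# Left subjects, order shuffled under the cohort seed; per-subject seeds
# drawn from the same stream so a subject can be regenerated in isolation.
cohort_plan <- function(config) {
  n <- config$n_subjects
  n_left <- round(n * config$left_fraction)
  if (n_left < 1 || n_left > n - 1) {
    abort("`left_fraction` leaves one class empty at this cohort size.")
  }
  set.seed(config$seed)
  labels <- sample(rep(tle_classes(), times = c(n_left, n - n_left)))
  tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(n)),
    label = labels,
    subject_seed = sample.int(.Machine$integer.max, n)
  )
}

#' Generate a synthetic PET cohort of subject volumes
#'
#' Draws a cohort of [generate_subject()] volumes under one configuration:
#' `round(n_subjects * left_fraction)` Left-TLE subjects, order shuffled by
#' the config seed, each subject generated from its own seed drawn from the
#' cohort stream.
#'
#' @param atlas A `pet_atlas`.
#' @param config A [cohort_config()].
#' @return A `pet_cohort`: list with `subjects` (list of `pet_subject`),
#'   `manifest` (tibble: subject_id, label, applied_scale, subject_seed),
#'   and `volumes` (named list of arrays, convenience view).
#' @export
generate_cohort <- function(atlas, config = cohort_config()) {
  atlas <- as_pet_atlas(atlas)
  plan <- cohort_plan(config)
  subjects <- purrr::pmap(
    plan,
    function(subject_id, label, subject_seed) {
      generate_subject(atlas, label, config,
                       seed = subject_seed, subject_id = subject_id)
    }
  )
  names(subjects) <- plan$subject_id
  manifest <- dplyr::mutate(
    plan,
    applied_scale = purrr::map_dbl(subjects, "applied_scale")
  )
  structure(
    list(
      subjects = subjects,
      manifest = manifest,
      volumes = purrr::map(subjects, "volume")
    ),
    class = "pet_cohort"
  )
}

#' Generate an asymmetry feature table directly
#'
#' Shortcut generator that skips the volume layer: each subject's AI per
#' region is drawn as Gaussian noise (`ai_noise_sd`) around the closed-form
#' expectation [expected_ai()] with the sign set by the subject's side
#' (negative for Left TLE). Class balance, shuffling and seeding follow
#' [generate_cohort()] exactly.
#'
#' @param config A [cohort_config()].
#' @return A feature-table tibble: `subject_id`, `label`, thirteen AI
#'   columns.
#' @export
generate_feature_table <- function(config = cohort_config()) {
  plan <- cohort_plan(config)
  delta <- setNames(rep(0, length(pair_names())), pair_names())
  delta[names(config$effect_map)] <- config$effect_map
  mag <- expected_ai(delta, config$contralateral_gain)
  rows <- purrr::pmap(plan, function(subject_id, label, subject_seed) {
    set.seed(subject_seed)
    sign <- if (label == "Left") -1 else 1
    ai <- sign * mag + rnorm(length(mag), sd = config$ai_noise_sd)
    dplyr::bind_cols(
      tibble::tibble(subject_id = subject_id, label = label),
      as_tibble(as.list(setNames(ai, pair_names())))
    )
  })
  dplyr::bind_rows(rows)
}
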