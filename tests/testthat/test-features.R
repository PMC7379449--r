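test_that("asymmetry_index implements 200*(L-R)/(L+R) with its invariants", {
  expect_equal(asymmetry_index(7, 7), 0)
  expect_equal(asymmetry_index(104, 96), 8)
  set.seed(1)
  a <- runif(50, 1, 200)
  b <- runif(50, 1, 200)
  expect_equal(asymmetry_index(a, b), -asymmetry_index(b, a))
  expect_equal(asymmetry_index(3.7 * a, 3.7 * b), asymmetry_index(a, b))
  expect_true(all(abs(asymmetry_index(a, b)) < 200))
  expect_error(asymmetry_index(-1, 5), "positive")
  expect_error(asymmetry_index(0, 5), "positive")
  expect_error(asymmetry_index(NA_real_, 5), "positive|finite")
})

test_that("region_means averages labeled voxels and excludes background", {
  atlas <- tiny_atlas()
  vol <- array(7, dim = dim(atlas$labels))
  m <- region_means(vol, atlas)
  expect_equal(nrow(m), 26)
  expect_true(all(m$mean == 7))
  expect_true(all(m$n_voxels == 8)) # 2x2x2 blocks

  # hand-built single-region check: voxels {2, 4, 6} -> mean 4
  lab <- array(0L, dim = c(3, 1, 1))
  lab[] <- 1L
  mini <- list(
    labels = lab, affine = NULL, voxel_size = c(1, 1, 1),
    regions = tibble::tibble(pair_name = "Hippocampus", hemisphere = "left",
                             label_id = 1L, baseline_mean = 1)
  )
  v <- array(c(2, 4, 6), dim = c(3, 1, 1))
  expect_equal(region_means(v, mini)$mean, 4)
})

test_that("region_means rejects misaligned inputs and empty labels", {
  atlas <- tiny_atlas()
  expect_error(region_means(array(1, dim = c(2, 2, 2)), atlas),
               "does not match")
  # affine mismatch beyond tolerance
  vol <- array(1, dim = dim(atlas$labels))
  aff <- atlas$affine
  aff[1, 4] <- aff[1, 4] + 1
  attr(vol, "affine") <- aff
  expect_error(region_means(vol, atlas), "affine")
  # a region table label with no voxels
  bad <- atlas
  bad$regions <- dplyr::bind_rows(
    bad$regions,
    tibble::tibble(pair_name = "Hippocampus", region = "Hippocampus",
                   hemisphere = "left", label_id = 99L, baseline_mean = 100)
  )
  expect_error(region_means(vol2 <- array(1, dim = dim(atlas$labels)), bad),
               "no voxels")
})

test_that("region_means agrees with a naive triple-loop accumulation", {
  atlas <- tiny_atlas()
  set.seed(4)
  vol <- array(runif(length(atlas$labels), 10, 200),
               dim = dim(atlas$labels))
  fast <- region_means(vol, atlas)
  d <- dim(vol)
  for (row in sample(nrow(fast), 6)) {
    id <- fast$label_id[row]
    total <- 0
    count <- 0
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      if (atlas$labels[i, j, k] == id) {
        total <- total + vol[i, j, k]
        count <- count + 1
      }
    }
    expect_equal(fast$mean[row], total / count, tolerance = 1e-12)
    expect_equal(fast$n_voxels[row], count)
  }
})

test_that("compute_features pairs hemispheres and keeps canonical column order", {
  atlas <- tiny_atlas()
  s <- generate_subject(atlas, "Left", clean_config(), seed = 1)
  feat <- compute_features(region_means(s$volume, atlas), subject_id = "A")
  expect_identical(names(feat), c("subject_id", pair_names()))
  # a missing hemisphere is a pairing error
  m <- region_means(s$volume, atlas)
  expect_error(compute_features(m[m$hemisphere == "left", ]),
               "Both hemispheres")
})

test_that("feature tables round-trip through CSV", {
  tab <- generate_feature_table(cohort_config(n_subjects = 8, seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_features(tab, path)
  back <- read_features(path)
  expect_equal(as.data.frame(back), as.data.frame(tab), tolerance = 1e-12)
  expect_identical(readLines(path, n = 1),
                   paste(c("subject_id", "label", pair_names()),
                         collapse = ","))
})

test_that("atlas and volumes round-trip through NIfTI-1", {
  atlas <- tiny_atlas()
  dir <- withr::local_tempdir()
  write_atlas(atlas, file.path(dir, "atlas.nii.gz"),
              file.path(dir, "regions.csv"))
  back <- read_atlas(file.path(dir, "atlas.nii.gz"),
                     file.path(dir, "regions.csv"))
  expect_equal(as.array(back$labels), unclass(atlas$labels))
  s <- generate_subject(atlas, "Left", clean_config(), seed = 2)
  write_volume(s, file.path(dir, "s.nii.gz"))
  vol <- RNifti::readNifti(file.path(dir, "s.nii.gz"))
  f_disk <- compute_features(region_means(vol, back))
  f_mem <- compute_features(region_means(s$volume, atlas))
  expect_equal(unlist(f_disk), unlist(f_mem), tolerance = 1e-4)
})
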