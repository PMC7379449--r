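test_that("generated atlas places 13 mirror-symmetric pairs with table-held hemispheres", {
  atlas <- generate_atlas(grid_shape = c(64, 64, 48), seed = 1)
  expect_s3_class(atlas, "pet_atlas")
  expect_equal(nrow(atlas$regions), 26)
  expect_setequal(setdiff(unique(as.vector(atlas$labels)), 0L),
                  atlas$regions$label_id)
  counts <- table(atlas$labels[atlas$labels > 0])
  for (pn in pair_names()) {
    ids <- atlas$regions$label_id[atlas$regions$pair_name == pn]
    expect_length(ids, 2)
    expect_equal(unname(counts[as.character(ids[1])]),
                 unname(counts[as.character(ids[2])]))
    # mirror symmetry: flipping the first axis swaps the pair's voxel sets
    flipped <- atlas$labels[dim(atlas$labels)[1]:1, , ]
    expect_equal(which(flipped == ids[1]), which(atlas$labels == ids[2]))
  }
  # baseline identical within pair
  base <- tapply(atlas$regions$baseline_mean, atlas$regions$pair_name,
                 function(x) diff(range(x)))
  expect_true(all(base == 0))
})

test_that("atlas generation is deterministic and rejects undersized grids", {
  a1 <- generate_atlas(seed = 7)
  a2 <- generate_atlas(seed = 7)
  expect_identical(a1$labels, a2$labels)
  expect_identical(a1$regions, a2$regions)
  expect_error(generate_atlas(grid_shape = c(4, 4, 4)), "too small")
})

test_that("noise-free subjects reproduce the closed-form asymmetry index", {
  atlas <- tiny_atlas()
  cfg <- clean_config(effect_map = c(Hippocampus = 0.06))
  s <- generate_subject(atlas, "Left", cfg, seed = 3)
  feat <- compute_features(region_means(s$volume, atlas))
  expect_equal(feat$Hippocampus, 200 * (0.94 - 1) / (0.94 + 1),
               tolerance = 1e-12)
  expect_equal(feat$Hippocampus, -expected_ai(0.06), tolerance = 1e-12)
  # all other regions symmetric
  others <- unlist(feat[setdiff(names(feat), "Hippocampus")])
  expect_true(all(others == 0))
  # right-sided focus gives the mirrored value
  s_r <- generate_subject(atlas, "Right", cfg, seed = 3)
  feat_r <- compute_features(region_means(s_r$volume, atlas))
  expect_equal(feat_r$Hippocampus, expected_ai(0.06), tolerance = 1e-12)
})

test_that("subject generation is deterministic and respects the global scale", {
  atlas <- tiny_atlas()
  cfg <- cohort_config()
  s1 <- generate_subject(atlas, "Left", cfg, seed = 11)
  s2 <- generate_subject(atlas, "Left", cfg, seed = 11)
  expect_identical(s1$volume, s2$volume)
  expect_gte(s1$applied_scale, cfg$global_scale_range[1])
  expect_lte(s1$applied_scale, cfg$global_scale_range[2])
  expect_true(all(s1$volume >= 0))
})

test_that("cohort composition honors the class ratio and seed", {
  atlas <- tiny_atlas()
  cfg <- cohort_config(n_subjects = 49, left_fraction = 27 / 49, seed = 5)
  cohort <- generate_cohort(atlas, cfg)
  expect_equal(sum(cohort$manifest$label == "Left"), 27)
  expect_equal(sum(cohort$manifest$label == "Right"), 22)
  # small even cohort
  tab10 <- generate_feature_table(cohort_config(n_subjects = 10,
                                                left_fraction = 0.5))
  expect_equal(unname(table(tab10$label)["Left"]), 5L)
  # different seeds: same counts, different ordering
  c2 <- generate_cohort(atlas, cohort_config(n_subjects = 49,
                                             left_fraction = 27 / 49,
                                             seed = 6))
  expect_equal(table(c2$manifest$label), table(cohort$manifest$label))
  expect_false(identical(c2$manifest$label, cohort$manifest$label))
  # bit-identical regeneration under the same seed
  c3 <- generate_cohort(atlas, cfg)
  expect_identical(c3$volumes, cohort$volumes)
  expect_error(cohort_config(n_subjects = 1), "at least 2")
})

test_that("direct feature-table generator matches the closed form in the mean", {
  cfg <- cohort_config(n_subjects = 600, left_fraction = 0.5,
                       effect_map = c(Hippocampus = 0.06),
                       ai_noise_sd = 2, seed = 42)
  tab <- generate_feature_table(cfg)
  left_ai <- tab$Hippocampus[tab$label == "Left"]
  se <- 2 / sqrt(length(left_ai))
  expect_lt(abs(mean(left_ai) - (-expected_ai(0.06))), 3 * se)
  # null effects: class-conditional means near zero
  tab0 <- generate_feature_table(cohort_config(n_subjects = 600,
                                               effect_map = c(Hippocampus = 0),
                                               ai_noise_sd = 2, seed = 9))
  expect_lt(abs(mean(tab0$Hippocampus[tab0$label == "Left"])), 3 * se)
  # flipping true side flips every expected AI sign
  means_l <- colMeans(tab[tab$label == "Left", pair_names()])
  means_r <- colMeans(tab[tab$label == "Right", pair_names()])
  expect_lt(abs(means_l["Hippocampus"] + means_r["Hippocampus"]), 3 * se * sqrt(2))
})

test_that("hemisphere swap negates every feature exactly (mirror property)", {
  atlas <- tiny_atlas()
  cfg <- cohort_config(seed = 2)
  s <- generate_subject(atlas, "Left", cfg, seed = 13)
  f <- compute_features(region_means(s$volume, atlas))
  f_sw <- compute_features(region_means(s$volume, swap_hemispheres(atlas)))
  expect_equal(unlist(f_sw), -unlist(f), tolerance = 1e-12)
})

test_that("asymmetry features are invariant to global rescaling of the volume", {
  atlas <- tiny_atlas()
  s <- generate_subject(atlas, "Right", cohort_config(), seed = 17)
  f1 <- compute_features(region_means(s$volume, atlas))
  for (c in c(0.25, 3.7)) {
    v <- s$volume * c
    attr(v, "affine") <- attr(s$volume, "affine")
    f2 <- compute_features(region_means(v, atlas))
    expect_equal(unlist(f2), unlist(f1), tolerance = 1e-10)
  }
})
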