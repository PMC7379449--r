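test_that("a planted one-feature gap yields a depth-1 tree with threshold in the gap", {
  tab <- gap_table()
  fit <- train_c45(tab)
  g <- glance(fit)
  expect_equal(g$depth, 1L)
  expect_equal(g$n_leaves, 2L)
  root <- tidy(fit)[1, ]
  expect_identical(root$feature, "Hippocampus")
  expect_gt(root$threshold, -4)
  expect_lt(root$threshold, 4)
  expect_equal(root$threshold, 0) # midpoint of the (-4, 4) gap
  expect_equal(predict(fit, tab), tab$label)
  # brute force confirms the gap split maximizes gain ratio
  oracle <- oracle_best_split(tab, "Hippocampus")
  expect_equal(split_gain_ratio(tab, "Hippocampus", root$threshold),
               oracle$gain_ratio, tolerance = 1e-12)
})

test_that("gain-ratio split selection matches exhaustive search on small tables", {
  for (seed in 1:8) {
    tab <- random_feature_table(n = 10 + (seed * 5) %% 41, p = 3, seed = seed)
    fit <- train_c45(tab, prune = FALSE)
    oracle <- oracle_best_split(tab, pair_names()[1:3])
    root <- tidy(fit)[1, ]
    if (!is.finite(oracle$gain_ratio)) {
      expect_true(is.na(root$feature)) # no admissible split -> leaf
    } else {
      expect_false(is.na(root$feature))
      expect_equal(split_gain_ratio(tab, root$feature, root$threshold),
                   oracle$gain_ratio, tolerance = 1e-9)
    }
  }
})

test_that("training is invariant to duplicating the data", {
  tab <- gap_table(left = c(-7, -5, -4, -2), right = c(1, 3, 5, 6))
  fit1 <- train_c45(tab)
  fit2 <- train_c45(dplyr::bind_rows(tab, tab))
  expect_equal(tidy(fit1)[c("feature", "threshold", "leaf_class")],
               tidy(fit2)[c("feature", "threshold", "leaf_class")])
})

test_that("degenerate training inputs are handled explicitly", {
  all_left <- tibble::tibble(label = rep("Left", 5),
                             Hippocampus = rnorm(5))
  expect_warning(fit <- train_c45(all_left), "single class")
  expect_equal(glance(fit)$n_leaves, 1L)
  expect_equal(unique(predict(fit, all_left)), "Left")
  expect_error(train_c45(tibble::tibble(label = character(0),
                                        Hippocampus = numeric(0))),
               "at least one row")
  with_na <- gap_table()
  with_na$Hippocampus[1] <- NA
  expect_error(train_c45(with_na), "missing")
})

test_that("shifting a feature by a constant shifts the learned threshold by it", {
  tab <- gap_table(left = c(-6.2, -5.1, -4.4), right = c(3.9, 5.2, 6.6))
  t0 <- tidy(train_c45(tab))$threshold[1]
  for (shift in c(-12.5, 7.25)) {
    shifted <- dplyr::mutate(tab, Hippocampus = Hippocampus + shift)
    expect_equal(tidy(train_c45(shifted))$threshold[1], t0 + shift,
                 tolerance = 1e-12)
  }
})

test_that("mirroring features and labels negates thresholds and swaps leaves", {
  set.seed(21)
  tab <- generate_feature_table(cohort_config(n_subjects = 30, seed = 21))
  fit <- train_c45(tab)
  mirrored <- tab
  mirrored[pair_names()] <- -mirrored[pair_names()]
  mirrored$label <- ifelse(tab$label == "Left", "Right", "Left")
  fit_m <- train_c45(mirrored)
  td <- tidy(fit)
  td_m <- tidy(fit_m)
  expect_equal(nrow(td), nrow(td_m))
  root <- td[1, ]
  root_m <- td_m[1, ]
  expect_identical(root$feature, root_m$feature)
  expect_equal(root_m$threshold, -root$threshold, tolerance = 1e-12)
  # predictions are swapped classes
  pred <- predict(fit, tab)
  pred_m <- predict(fit_m, mirrored)
  expect_identical(pred_m, ifelse(pred == "Left", "Right", "Left"))
})

test_that("noise-free threshold recovery lands inside the planted class gap", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 20
    gap <- sort(runif(2, -3, 3))
    left <- runif(n, gap[1] - 6, gap[1])
    right <- runif(n, gap[2], gap[2] + 6)
    fit <- train_c45(gap_table(left = left, right = right))
    thr <- tidy(fit)$threshold[1]
    expect_gte(thr, max(left))
    expect_lte(thr, min(right))
  }
})

test_that("tree prediction follows the <= convention and validates features", {
  stump <- tree_stump("Hippocampus", 3.18)
  expect_identical(predict(stump, tibble::tibble(Hippocampus = 3.18)), "Left")
  expect_identical(predict(stump, tibble::tibble(Hippocampus = 3.1800001)),
                   "Right")
  expect_error(predict(stump, tibble::tibble(Amygdala = 1)), "Missing feature")
  expect_error(tree_stump("NotARegion", 0), "Unknown region")
})
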