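test_that("stratified 60:40 split reproduces the 31/18 partition", {
  labels <- rep(c("Left", "Right"), c(27, 22))
  plan <- make_split(labels, 31 / 49, seed = 1)
  expect_equal(sum(plan$set == "train"), 31)
  expect_equal(sum(plan$set == "test"), 18)
  counts <- table(plan$label, plan$set)
  expect_equal(unname(counts["Left", "train"]), 17)
  expect_equal(unname(counts["Right", "train"]), 14)
  expect_identical(plan, make_split(labels, 31 / 49, seed = 1))
  expect_false(identical(plan$set, make_split(labels, 31 / 49, seed = 2)$set))
  expect_error(make_split(labels, 1.0), "strictly inside")
  expect_error(make_split(labels, 0), "strictly inside")
})

test_that("stratified folds partition the cohort with near-equal sizes and ratios", {
  labels <- rep(c("Left", "Right"), c(27, 22))
  folds <- make_folds(labels, k = 5, seed = 3)
  sizes <- sort(as.vector(table(folds$fold)), decreasing = TRUE)
  expect_equal(sizes, c(10, 10, 10, 10, 9))
  # nonoverlapping cover by construction: every subject gets one fold
  expect_setequal(folds$fold, 1:5)
  expect_equal(nrow(folds), 49)
  # per-fold class counts as even as integers allow
  by_class <- table(folds$label, folds$fold)
  expect_lte(diff(range(by_class["Left", ])), 1)
  expect_lte(diff(range(by_class["Right", ])), 1)
  # leave-one-out limit
  loo <- make_folds(rep(c("Left", "Right"), 5), k = 10, seed = 1)
  expect_equal(sort(loo$fold), 1:10)
  expect_error(make_folds(labels, k = 1), "at least 2")
  expect_error(make_folds(labels, k = 50), "cannot exceed")
})

test_that("correct_ratio scores exact agreement and penalizes non-calls", {
  tab <- published_test_table()
  expect_equal(correct_ratio(tab$j48, tab$definitive)$correct, 16)
  expect_equal(correct_ratio(tab$j48, tab$definitive)$percent, 89)
  expect_equal(correct_ratio(tab$lmt, tab$definitive)$correct, 17)
  expect_equal(correct_ratio(tab$lmt, tab$definitive)$percent, 94)
  # the voxelwise column contains two "No lateralization" non-calls
  expect_equal(correct_ratio(tab$spm, tab$definitive)$correct, 16)
  expect_equal(correct_ratio(tab$definitive, tab$definitive)$ratio, 1)
  expect_error(correct_ratio(c("Left"), c("Left", "Right")), "equal length")
})

test_that("cohens_kappa matches its definition and an independent implementation", {
  tab <- published_test_table()
  k1 <- cohens_kappa(tab$j48, tab$definitive)
  # independent cross-check of the kappa point estimate
  ct <- table(tab$j48, tab$definitive)
  k_e1071 <- e1071::classAgreement(ct)$kappa
  expect_equal(k1$kappa, k_e1071, tolerance = 1e-12)
  # invariants
  k_sym <- cohens_kappa(tab$definitive, tab$j48)
  expect_equal(k_sym$kappa, k1$kappa)
  expect_equal(k_sym$z, k1$z)
  perfect <- cohens_kappa(tab$definitive, tab$definitive)
  expect_equal(perfect$kappa, 1)
  expect_error(cohens_kappa(rep("Left", 4), rep("Left", 4)), "Degenerate")
  expect_error(cohens_kappa(tab$spm, tab$definitive), "binary")
})

test_that("kappa of independent random predictions centers on zero", {
  set.seed(12)
  kappas <- replicate(200, {
    truth <- sample(c("Left", "Right"), 40, replace = TRUE, prob = c(.55, .45))
    pred <- sample(c("Left", "Right"), 40, replace = TRUE)
    cohens_kappa(pred, truth)$kappa
  })
  expect_lt(abs(mean(kappas)), 0.05)
})

test_that("cross-validation is exact on separable data and null on permuted labels", {
  tab <- generate_feature_table(clean_config(n_subjects = 30, seed = 5))
  for (algo in c("c45", "lmt")) {
    cv <- cross_validate(tab, k = 5, algo = algo, seed = 2)
    expect_equal(cv$mean_ratio, 1.0)
    expect_equal(sum(cv$folds$n), nrow(tab))
    # every subject predicted exactly once
    expect_setequal(cv$predictions$subject_id, tab$subject_id)
  }
  # permuted labels: no signal left
  set.seed(77)
  null_tab <- generate_feature_table(cohort_config(n_subjects = 49, seed = 6))
  null_tab$label <- sample(null_tab$label)
  cv0 <- cross_validate(null_tab, k = 5, algo = "lmt", seed = 3)
  expect_lt(abs(cv0$mean_ratio - 0.5), 0.25)
})

test_that("cv summaries expose per-run rules and pooled agreement", {
  tab <- generate_feature_table(cohort_config(n_subjects = 30, seed = 10))
  cv <- cross_validate(tab, k = 5, algo = "c45", seed = 4)
  td <- tidy(cv)
  expect_identical(names(td), c("fold", "n", "correct", "ratio", "rule"))
  expect_true(all(grepl("AI\\[", td$rule)))
  g <- glance(cv)
  expect_equal(g$mean_ratio, sum(td$correct) / sum(td$n))
  expect_true(g$kappa <= 1 && g$kappa >= -1)
})

test_that("evaluate_predictions combines counts and kappa", {
  tab <- published_test_table()
  m <- evaluate_predictions(tab$lmt, tab$definitive)
  expect_equal(m$correct, 17)
  expect_equal(round(m$kappa, 3), 0.889)
  m2 <- evaluate_predictions(tab$spm, tab$definitive,
                             kappa_binary_only = TRUE)
  expect_equal(m2$correct, 16)
  expect_equal(m2$total, 18)
  expect_true(is.finite(m2$kappa))
})
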