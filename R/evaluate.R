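# Train/test splitting, stratified k-fold cross-validation,
# correct-lateralization ratios and Cohen's kappa with its null-hypothesis
# z statistic.

split_labels <- function(data) {
  if (is.data.frame(data)) {
    check_feature_table(data, require_label = TRUE)
    list(
      subject_id = data$subject_id %||% sprintf("S%03d", seq_len(nrow(data))),
      label = as.character(data$label)
    )
  } else {
    lab <- as.character(data)
    if (!all(lab %in% tle_classes())) {
      abort("Labels must all be \"Left\" or \"Right\".")
    }
    list(subject_id = sprintf("S%03d", seq_along(lab)), label = lab)
  }
}

#' Stratified train/test split
#'
#' Randomized assignment of subjects to a training and a test set,
#' stratified by class, honoring the requested training fraction within
#' rounding (the overall training size is `round(n * train_fraction)`,
#' apportioned across classes by largest remainder).
#'
#' @param data Feature table with a `label` column, or a character vector
#'   of Left/Right labels.
#' @param train_fraction Fraction of subjects assigned to training,
#'   strictly inside (0, 1).
#' @param seed Integer seed making the assignment reproducible.
#' @return Tibble with `subject_id`, `label`, `set` (`"train"`/`"test"`).
#' @examples
#' plan <- make_split(rep(c("Left", "Right"), c(27, 22)), 31 / 49, seed = 1)
#' table(plan$set) # 31 train, 18 test
#' @export
make_split <- function(data, train_fraction, seed = 1L) {
  if (!is.numeric(train_fraction) || train_fraction <= 0 ||
      train_fraction >= 1) {
    abort("`train_fraction` must lie strictly inside (0, 1).")
  }
  info <- split_labels(data)
  lab <- info$label
  n <- length(lab)
  classes <- unique(lab)
  if (length(classes) < 2) abort("At least one subject per class is required.")
  n_train <- round(n * train_fraction)
  ideal <- vapply(classes, function(c) sum(lab == c) * train_fraction,
                  numeric(1))
  take <- floor(ideal)
  rem <- n_train - sum(take)
  if (rem > 0) {
    ord <- order(ideal - take, decreasing = TRUE)
    take[ord[seq_len(rem)]] <- take[ord[seq_len(rem)]] + 1
  }
  set.seed(seed)
  assignment <- rep("test", n)
  for (c in classes) {
    idx <- which(lab == c)
    assignment[sample(idx, take[[c]])] <- "train"
  }
  tibble::tibble(subject_id = info$subject_id, label = lab, set = assignment)
}

#' Stratified k-fold assignment
#'
#' Partitions subjects into `k` nonoverlapping folds covering the whole
#' cohort. With `balance = TRUE` (default) the assignment is stratified:
#' each class is shuffled and dealt round-robin, with the dealing position
#' carried over between classes so that fold sizes differ by at most one
#' and per-fold class ratios are as equal as integer arithmetic allows
#' (49 subjects at 27:22 yield four folds of 10 and one of 9).
#'
#' @param data Feature table with a `label` column, or a label vector.
#' @param k Number of folds, `2 <= k <= n`.
#' @param seed Integer seed.
#' @param balance Stratify by class (default `TRUE`).
#' @return Tibble with `subject_id`, `label`, `fold`.
#' @export
make_folds <- function(data, k = 5L, seed = 1L, balance = TRUE) {
  info <- split_labels(data)
  lab <- info$label
  n <- length(lab)
  k <- as.integer(k)
  if (k < 2) abort("`k` must be at least 2.")
  if (k > n) abort("`k` cannot exceed the number of subjects.")
  set.seed(seed)
  fold <- integer(n)
  if (balance) {
    offset <- 0L
    for (c in intersect(c(tle_classes(), unique(lab)), unique(lab))) {
      idx <- which(lab == c)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
      offset <- (offset + length(idx)) %% k
    }
  } else {
    fold[sample.int(n)] <- ((seq_len(n) - 1L) %% k) + 1L
  }
  tibble::tibble(subject_id = info$subject_id, label = lab, fold = fold)
}

#' Correct-lateralization ratio
#'
#' Exact agreement counts between predicted and true lateralization.
#' Any prediction token other than the true label — including
#' `"No lateralization"` — counts as incorrect.
#'
#' @param predicted,truth Equal-length label vectors.
#' @return One-row tibble: `correct`, `total`, `ratio`, `percent`
#'   (percentage rounded to integer, the conventional reporting style).
#' @examples
#' tab <- published_test_table()
#' correct_ratio(tab$j48, tab$definitive) # 16/18, 89%
#' @export
correct_ratio <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    abort("`predicted` and `truth` must have equal length.")
  }
  if (length(truth) == 0) abort("Empty label vectors.")
  correct <- sum(as.character(predicted) == as.character(truth))
  total <- length(truth)
  tibble::tibble(
    correct = correct, total = total, ratio = correct / total,
    percent = round(100 * correct / total)
  )
}

#' Cohen's kappa with null-hypothesis significance statistic
#'
#' Chance-corrected agreement between two binary (Left/Right) label
#' vectors: observed agreement `po` from the 2x2 table, expected agreement
#' `pe` from the marginal products, `kappa = (po - pe) / (1 - pe)`, the
#' standard error of kappa under the null hypothesis of independence,
#' \deqn{SE_0 = \sqrt{p_e + p_e^2 - \sum_i p_{i+} p_{+i} (p_{i+} + p_{+i})}
#'   / ((1 - p_e)\sqrt{n}),}
#' the z statistic `kappa / SE0` (reported as "T" in some clinical
#' literature) and its two-sided normal p-value.
#'
#' @param predicted,truth Equal-length vectors of `"Left"`/`"Right"`.
#' @return An `ai_kappa` object with fields `table`, `po`, `pe`, `kappa`,
#'   `se0`, `z`, `p_value`, `n`.
#' @examples
#' tab <- published_test_table()
#' cohens_kappa(tab$lmt, tab$definitive) # kappa 0.889, z 3.795
#' @export
cohens_kappa <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    abort("`predicted` and `truth` must have equal length.")
  }
  pr <- as.character(predicted)
  tr <- as.character(truth)
  if (!all(c(pr, tr) %in% tle_classes())) {
    abort("Kappa is defined here for binary Left/Right vectors only.")
  }
  n <- length(tr)
  tab <- table(
    factor(pr, levels = tle_classes()),
    factor(tr, levels = tle_classes())
  )
  p <- tab / n
  po <- sum(diag(p))
  row_m <- rowSums(p)
  col_m <- colSums(p)
  pe <- sum(row_m * col_m)
  if (1 - pe < 1e-12) {
    abort("Degenerate marginals (expected agreement 1): kappa undefined.")
  }
  kappa <- (po - pe) / (1 - pe)
  se0 <- sqrt(pe + pe^2 - sum(row_m * col_m * (row_m + col_m))) /
    ((1 - pe) * sqrt(n))
  z <- kappa / se0
  structure(
    list(table = tab, po = po, pe = pe, kappa = kappa, se0 = se0, z = z,
         p_value = 2 * pnorm(-abs(z)), n = n),
    class = "ai_kappa"
  )
}

#' @export
print.ai_kappa <- function(x, ...) {
  cat(sprintf(
    "Cohen's kappa: %.3f (z = %.3f, p = %.4g, n = %d)\n",
    x$kappa, x$z, x$p_value, x$n
  ))
  invisible(x)
}

#' @method tidy ai_kappa
#' @export
tidy.ai_kappa <- function(x, ...) {
  tibble::tibble(
    kappa = x$kappa, po = x$po, pe = x$pe, se0 = x$se0,
    statistic = x$z, p.value = x$p_value, n = x$n
  )
}

#' @method glance ai_kappa
#' @export
glance.ai_kappa <- function(x, ...) tidy(x)

#' k-fold cross-validated lateralization
#'
#' Runs the full cross-validation protocol on a feature table: stratified
#' fold assignment via [make_folds()], then for each fold a model is
#' trained on the remaining folds with [train_c45()] or [train_lmt()] and
#' used to lateralize the held-out fold. Per-run models (with their
#' rendered rules) and correct/total counts are recorded; the mean correct
#' lateralization ratio equals total correct over total subjects.
#'
#' @param data Feature table with `label` and AI columns.
#' @param k Number of folds (default 5).
#' @param algo `"c45"` or `"lmt"`.
#' @param params Named list of extra arguments passed to the trainer.
#' @param seed Seed controlling fold assignment (and the LMT internal CV).
#' @return An `ai_cv` object: `folds` tibble (fold, n, correct, ratio,
#'   rule, model list-column), `predictions` tibble (subject_id, fold,
#'   truth, prediction), `mean_ratio`, `algo`, `k`, `seed`.
#' @export
cross_validate <- function(data, k = 5L, algo = c("c45", "lmt"),
                           params = list(), seed = 1L) {
  algo <- match.arg(algo)
  check_feature_table(data, require_label = TRUE)
  plan <- make_folds(data, k = k, seed = seed)
  stopifnot(all(sort(unique(plan$fold)) == seq_len(k)))
  trainer <- switch(algo, c45 = train_c45, lmt = train_lmt)
  fold_rows <- vector("list", k)
  pred_rows <- vector("list", k)
  for (f in seq_len(k)) {
    in_test <- plan$fold == f
    train_tab <- data[!in_test, , drop = FALSE]
    test_tab <- data[in_test, , drop = FALSE]
    args <- c(list(train_tab), params)
    if (algo == "lmt" && is.null(params$seed)) args$seed <- seed + f
    model <- do.call(trainer, args)
    pred <- predict(model, test_tab)
    truth <- as.character(test_tab$label)
    cr <- correct_ratio(pred, truth)
    fold_rows[[f]] <- tibble::tibble(
      fold = f, n = cr$total, correct = cr$correct, ratio = cr$ratio,
      rule = format(model), model = list(model)
    )
    pred_rows[[f]] <- tibble::tibble(
      subject_id = plan$subject_id[in_test], fold = f,
      truth = truth, prediction = pred
    )
  }
  folds <- dplyr::bind_rows(fold_rows)
  structure(
    list(
      folds = folds,
      predictions = dplyr::bind_rows(pred_rows),
      mean_ratio = sum(folds$correct) / sum(folds$n),
      algo = algo, k = k, seed = seed
    ),
    class = "ai_cv"
  )
}

#' @export
print.ai_cv <- function(x, ...) {
  cat(sprintf(
    "<ai_cv> %s, %d-fold: mean correct lateralization %d/%d (%d%%)\n",
    x$algo, x$k, sum(x$folds$correct), sum(x$folds$n),
    round(100 * x$mean_ratio)
  ))
  invisible(x)
}

#' @method tidy ai_cv
#' @export
tidy.ai_cv <- function(x, ...) {
  dplyr::select(x$folds, "fold", "n", "correct", "ratio", "rule")
}

#' @method glance ai_cv
#' @export
glance.ai_cv <- function(x, ...) {
  kap <- cohens_kappa(x$predictions$prediction, x$predictions$truth)
  tibble::tibble(
    algo = x$algo, k = x$k,
    correct = sum(x$folds$correct), total = sum(x$folds$n),
    mean_ratio = x$mean_ratio,
    kappa = kap$kappa, statistic = kap$z, p.value = kap$p_value
  )
}

#' Agreement metrics between predictions and truth
#'
#' Convenience wrapper combining [correct_ratio()] and [cohens_kappa()].
#'
#' @param predicted,truth Label vectors; `predicted` may contain
#'   `"No lateralization"`, which is scored incorrect and excluded from
#'   the (binary) kappa computation only if `kappa_binary_only = TRUE`.
#' @param kappa_binary_only Drop non-binary prediction tokens before
#'   computing kappa (default `FALSE`: such tokens raise an error).
#' @return One-row tibble: correct, total, ratio, percent, kappa, se0,
#'   statistic, p.value.
#' @export
evaluate_predictions <- function(predicted, truth,
                                 kappa_binary_only = FALSE) {
  cr <- correct_ratio(predicted, truth)
  pr <- as.character(predicted)
  keep <- rep(TRUE, length(pr))
  if (kappa_binary_only) keep <- pr %in% tle_classes()
  kap <- cohens_kappa(pr[keep], as.character(truth)[keep])
  dplyr::bind_cols(
    cr,
    tibble::tibble(kappa = kap$kappa, se0 = kap$se0, statistic = kap$z,
                   p.value = kap$p_value)
  )
}
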