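# Logistic model tree (LMT) learner. At the cohort sizes this pipeline
# targets, LMT's pruning collapses the tree to its root, so the model is a
# single additive logistic score fitted by LogitBoost with simple
# (one-variable) weighted linear regression base learners; the boosting
# iteration count is chosen by internal cross-validation. The fitted model
# is reported as symmetric per-class linear scores (Left = -Right), the
# form in which all published LMT lateralization rules are printed.

Z_MAX <- 3        # working-response clamp (standard LogitBoost safeguard)
W_MIN <- 1e-24    # weight floor

# One LogitBoost run on a numeric matrix; records per-iteration simple
# regressions so held-out error can be evaluated at every iteration count.
logitboost_fit <- function(X, y01, max_iter) {
  n <- nrow(X)
  p <- ncol(X)
  F <- numeric(n)
  steps <- vector("list", max_iter)
  m_done <- 0L
  for (m in seq_len(max_iter)) {
    prob <- 1 / (1 + exp(-2 * F))
    z <- ifelse(y01 == 1, pmin(1 / pmax(prob, 1e-12), Z_MAX),
                pmax(-1 / pmax(1 - prob, 1e-12), -Z_MAX))
    w <- pmax(prob * (1 - prob), W_MIN)
    sw <- sum(w)
    xw <- colSums(w * X) / sw
    zw <- sum(w * z) / sw
    WX <- w * X
    sxz <- colSums(WX * z) - sw * xw * zw
    sxx <- colSums(WX * X) - sw * xw^2
    ok <- sxx > 1e-12
    if (!any(ok)) break
    score <- ifelse(ok, sxz^2 / sxx, -Inf)   # SSE reduction of each learner
    j <- unname(which.max(score))
    b <- unname(sxz[j] / sxx[j])
    a <- unname(zw - b * xw[j])
    F <- F + 0.5 * (a + b * X[, j])
    steps[[m]] <- c(feature = j, intercept = 0.5 * a, slope = 0.5 * b)
    m_done <- m
  }
  list(steps = steps[seq_len(m_done)], n_iter = m_done)
}

# Cumulative held-out score after each iteration of a fitted boosting run.
logitboost_score_path <- function(fit, X_new) {
  n <- nrow(X_new)
  out <- matrix(0, nrow = n, ncol = max(fit$n_iter, 1))
  F <- numeric(n)
  for (m in seq_len(fit$n_iter)) {
    s <- fit$steps[[m]]
    F <- F + s["intercept"] + s["slope"] * X_new[, s["feature"]]
    out[, m] <- F
  }
  out
}

# Internal CV folds, stratified within class in order of first appearance so
# the assignment is invariant under a global label swap.
internal_folds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  offset <- 0L
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
    offset <- (offset + length(idx)) %% k
  }
  fold
}

#' Train a logistic-model-tree (root logistic) lateralizer
#'
#' Fits an additive logistic score over the asymmetry-index columns by
#' LogitBoost with simple one-variable weighted least-squares base
#' learners. The boosting iteration count is selected by internal
#' stratified cross-validation (minimum held-out misclassification, ties to
#' the smaller count), then the model is refitted on all data for that many
#' iterations. Node splitting below the root is governed by `min_split`;
#' its default is high enough that cohorts of this scale always yield the
#' root-only model, matching the published LMT rules, and the learner
#' accordingly always returns a single linear score model.
#'
#' @param data Feature table with a `label` column (Left/Right) and AI
#'   columns.
#' @param max_iter Maximum LogitBoost iterations (default 200).
#' @param cv_folds Internal CV folds for iteration selection (default 5).
#' @param min_split Minimum node size that would permit splitting
#'   (default 15; retained for interface compatibility).
#' @param seed Seed for the internal CV fold assignment — the only source
#'   of randomness in training.
#' @param features Optional restriction of candidate feature columns.
#' @return An `ai_linear` model: per-class symmetric linear scores with
#'   `intercept` and `coefficients` stored for class `"Left"`.
#' @examples
#' tab <- generate_feature_table(cohort_config(n_subjects = 30, seed = 3))
#' fit <- train_lmt(tab, seed = 1)
#' tidy(fit)
#' @export
train_lmt <- function(data, max_iter = 200L, cv_folds = 5L, min_split = 15L,
                      seed = 1L, features = NULL) {
  features <- check_feature_table(data, require_label = TRUE,
                                  features = features)
  labels <- as.character(data$label)
  if (length(unique(labels)) == 1) {
    warn("Training data contains a single class; model reduces to a constant score.")
  }
  y01 <- as.integer(labels == "Left")
  X <- as.matrix(data[features])
  n <- nrow(X)
  k <- min(cv_folds, n)
  fold <- internal_folds(labels, k, seed)
  cv_err <- matrix(NA_real_, nrow = k, ncol = max_iter)
  for (f in seq_len(k)) {
    tr <- fold != f
    if (sum(tr) < 2 || sum(!tr) < 1) next
    fit_f <- logitboost_fit(X[tr, , drop = FALSE], y01[tr], max_iter)
    if (fit_f$n_iter == 0) next
    path <- logitboost_score_path(fit_f, X[!tr, , drop = FALSE])
    errs <- colMeans((path > 0) != (y01[!tr] == 1))
    cv_err[f, ] <- c(errs, rep(errs[length(errs)],
                               max_iter - fit_f$n_iter))
  }
  total_err <- colSums(cv_err, na.rm = TRUE)
  best_m <- if (all(!is.finite(total_err)) || length(total_err) == 0) {
    max_iter
  } else {
    which.min(total_err)   # ties resolve to the smallest iteration count
  }
  fit <- logitboost_fit(X, y01, best_m)
  intercept <- 0
  coefs <- setNames(numeric(length(features)), features)
  for (s in fit$steps) {
    intercept <- intercept + s["intercept"]
    coefs[s["feature"]] <- coefs[s["feature"]] + s["slope"]
  }
  coefs <- coefs[coefs != 0]
  new_linear_model(
    intercept = unname(intercept), coefficients = coefs,
    n = n, class_counts = table(factor(labels, tle_classes())),
    iterations = fit$n_iter,
    params = list(max_iter = max_iter, cv_folds = cv_folds,
                  min_split = min_split, seed = seed)
  )
}

new_linear_model <- function(intercept, coefficients, n = 0L,
                             class_counts = NULL, iterations = NA_integer_,
                             params = list()) {
  structure(
    list(
      intercept = intercept, coefficients = coefficients,
      classes = tle_classes(), n = n,
      class_counts = class_counts, iterations = iterations, params = params
    ),
    class = "ai_linear"
  )
}

#' Build a fixed linear-score model
#'
#' Constructs an `ai_linear` model from an explicit intercept and
#' coefficient map for class `"Left"`; the class `"Right"` score is its
#' exact negation, as in every published LMT lateralization rule.
#'
#' @param intercept Intercept of the Left-class score.
#' @param coefficients Named numeric vector of AI-column weights
#'   (Left-class score).
#' @return An `ai_linear`.
#' @export
linear_model <- function(intercept, coefficients) {
  unknown <- setdiff(names(coefficients), pair_names())
  if (length(unknown) > 0) {
    abort(paste0("Unknown region pair(s): ", paste(unknown, collapse = ", ")))
  }
  new_linear_model(intercept, coefficients)
}

#' Per-class linear scores of a linear model
#'
#' @param model An `ai_linear`.
#' @param newdata Feature table containing the model's feature columns.
#' @return Tibble with `score_Left`, `score_Right` (exact negatives) and
#'   `prediction`.
#' @export
linear_scores <- function(model, newdata) {
  missing <- setdiff(names(model$coefficients), names(newdata))
  if (length(missing) > 0) {
    abort(paste0("Missing feature column(s): ", paste(missing, collapse = ", ")))
  }
  score <- rep(model$intercept, nrow(newdata))
  for (f in names(model$coefficients)) {
    score <- score + model$coefficients[[f]] * newdata[[f]]
  }
  if (any(!is.finite(score))) abort("Non-finite linear score.")
  tibble::tibble(
    score_Left = score,
    score_Right = -score,
    prediction = ifelse(score > 0, "Left", "Right")  # ties go to Right
  )
}

#' Predict lateralization with a linear-score model
#'
#' Returns the class with the strictly larger linear score; exact ties are
#' broken to `"Right"` for determinism.
#'
#' @param object An `ai_linear`.
#' @param newdata Feature table.
#' @param ... Unused.
#' @return Character vector of `"Left"`/`"Right"` predictions.
#' @export
predict.ai_linear <- function(object, newdata, ...) {
  linear_scores(object, newdata)$prediction
}

#' @export
format.ai_linear <- function(x, ...) {
  lookup <- setNames(region_pairs()$region, region_pairs()$pair_name)
  term <- function(coef, sign) {
    if (length(coef) == 0) return("")
    paste0(" + AI[", lookup[names(coef)], "] * ",
           format(sign * unname(coef), digits = 4), collapse = "")
  }
  paste0(
    "Class Left : ", format(x$intercept, digits = 4),
    term(x$coefficients, 1), "\n",
    "Class Right: ", format(-x$intercept, digits = 4),
    term(x$coefficients, -1)
  )
}

#' @export
print.ai_linear <- function(x, ...) {
  cat("<ai_linear> logistic-score lateralization model\n")
  cat(format(x), "\n")
  invisible(x)
}

#' @method tidy ai_linear
#' @export
tidy.ai_linear <- function(x, ...) {
  tibble::tibble(
    class = "Left",
    term = c("(Intercept)", names(x$coefficients)),
    estimate = c(x$intercept, unname(x$coefficients))
  )
}

#' @method glance ai_linear
#' @export
glance.ai_linear <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    iterations = x$iterations,
    n_features = length(x$coefficients)
  )
}
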