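# Entropy-based decision tree (C4.5 style): binary numeric splits chosen by
# gain ratio, candidate thresholds at midpoints between consecutive distinct
# sorted values, and pessimistic (confidence-bound) subtree pruning. This is
# the J48-type learner of the lateralization pipeline.

entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

# Best gain-ratio split for one feature. Returns NULL or
# list(threshold, gain, gain_ratio).
best_split_one <- function(x, y_int, n_classes, min_leaf, threshold_style) {
  ord <- order(x)
  xs <- x[ord]
  ys <- y_int[ord]
  n <- length(xs)
  counts <- tabulate(ys, nbins = n_classes)
  h_parent <- entropy(counts)
  # cumulative class counts after each position
  cum <- matrix(
    vapply(seq_len(n_classes), function(k) cumsum(ys == k), numeric(n)),
    nrow = n
  )
  boundary <- which(diff(xs) > 0)             # split after position i
  boundary <- boundary[boundary >= min_leaf & (n - boundary) >= min_leaf]
  if (length(boundary) == 0) return(NULL)
  best <- NULL
  for (i in boundary) {
    left_counts <- cum[i, ]
    right_counts <- counts - left_counts
    h_split <- (i / n) * entropy(left_counts) +
      ((n - i) / n) * entropy(right_counts)
    gain <- h_parent - h_split
    if (gain <= 1e-12) next
    split_info <- entropy(c(i, n - i))
    gr <- gain / split_info
    if (is.null(best) || gr > best$gain_ratio + 1e-12) {
      thr <- if (threshold_style == "midpoint") {
        (xs[i] + xs[i + 1]) / 2
      } else {
        xs[i]                                  # C4.5 reports the lower value
      }
      best <- list(threshold = thr, gain = gain, gain_ratio = gr)
    }
  }
  best
}

make_leaf <- function(counts, classes) {
  maj <- which(counts == max(counts))
  cls <- if (length(maj) == 1) classes[maj] else "Right"  # deterministic tie
  list(leaf = TRUE, class = cls, n = sum(counts), counts = counts,
       errors = sum(counts) - max(counts))
}

grow_tree <- function(X, y_int, classes, features, min_leaf, threshold_style) {
  counts <- tabulate(y_int, nbins = length(classes))
  if (sum(counts > 0) <= 1 || sum(counts) < 2 * min_leaf) {
    return(make_leaf(counts, classes))
  }
  best <- NULL
  for (f in features) {
    cand <- best_split_one(X[[f]], y_int, length(classes), min_leaf,
                           threshold_style)
    if (!is.null(cand) &&
        (is.null(best) || cand$gain_ratio > best$gain_ratio + 1e-12)) {
      best <- c(cand, feature = f)
    }
  }
  if (is.null(best)) return(make_leaf(counts, classes))
  go_left <- X[[best$feature]] <= best$threshold
  list(
    leaf = FALSE, feature = best$feature, threshold = best$threshold,
    n = sum(counts), counts = counts,
    left = grow_tree(X[go_left, , drop = FALSE], y_int[go_left], classes,
                     features, min_leaf, threshold_style),
    right = grow_tree(X[!go_left, , drop = FALSE], y_int[!go_left], classes,
                      features, min_leaf, threshold_style)
  )
}

# Pessimistic upper confidence limit on the error rate of a leaf observing
# E errors in N cases: the p with P(X <= E | N, p) = cf (exact binomial
# inversion, the quantity C4.5 approximates).
pessimistic_error <- function(E, N, cf) {
  if (N == 0) return(0)
  qbeta(1 - cf, E + 1, N - E)
}

prune_tree <- function(node, cf) {
  if (node$leaf) return(node)
  node$left <- prune_tree(node$left, cf)
  node$right <- prune_tree(node$right, cf)
  subtree_err <- predicted_errors(node, cf)
  leaf <- make_leaf(node$counts, tle_classes())
  leaf_err <- node$n * pessimistic_error(leaf$errors, node$n, cf)
  if (leaf_err <= subtree_err + 0.1) leaf else node   # C4.5's bias to prune
}

predicted_errors <- function(node, cf) {
  if (node$leaf) {
    return(node$n * pessimistic_error(node$errors, node$n, cf))
  }
  predicted_errors(node$left, cf) + predicted_errors(node$right, cf)
}

#' Train an entropy-based (C4.5-style) decision tree
#'
#' Greedy top-down induction over the asymmetry-index columns: binary
#' numeric splits scored by gain ratio (information gain divided by split
#' information), candidate thresholds at midpoints between consecutive
#' distinct sorted feature values, recursion stopping at pure nodes or
#' below the minimum node size, followed by pessimistic error-based
#' pruning. The split convention is `value <= threshold` follows the first
#' (Left-listed) branch, matching the published rule style.
#'
#' @param data Feature table: tibble with a `label` column (Left/Right) and
#'   asymmetry-index columns.
#' @param min_leaf Minimum number of training instances per leaf
#'   (default 2, the conventional C4.5 value).
#' @param cf Pruning confidence (default 0.25; smaller prunes harder).
#' @param prune Apply error-based pruning (default `TRUE`).
#' @param threshold_style `"midpoint"` (default) places thresholds midway
#'   between neighboring observed values; `"observed"` reports the lower
#'   observed value, as classic C4.5 prints.
#' @param features Optional character vector restricting the candidate
#'   feature columns.
#' @return An `ai_tree` model object.
#' @examples
#' tab <- generate_feature_table(cohort_config(n_subjects = 20, seed = 7))
#' fit <- train_c45(tab)
#' format(fit)
#' @export
train_c45 <- function(data, min_leaf = 2L, cf = 0.25, prune = TRUE,
                      threshold_style = c("midpoint", "observed"),
                      features = NULL) {
  threshold_style <- match.arg(threshold_style)
  features <- check_feature_table(data, require_label = TRUE,
                                  features = features)
  classes <- tle_classes()
  y_int <- match(as.character(data$label), classes)
  if (length(unique(y_int)) == 1) {
    warn("Training data contains a single class; returning a one-leaf tree.")
  }
  X <- data[features]
  node <- grow_tree(X, y_int, classes, features, as.integer(min_leaf),
                    threshold_style)
  if (prune) node <- prune_tree(node, cf)
  structure(
    list(
      node = node, classes = classes, features = features,
      params = list(min_leaf = as.integer(min_leaf), cf = cf,
                    prune = prune, threshold_style = threshold_style),
      n = nrow(data),
      class_counts = setNames(tabulate(y_int, 2), classes)
    ),
    class = "ai_tree"
  )
}

#' Build a fixed single-split tree model
#'
#' Constructs a depth-1 `ai_tree` from an explicit rule of the form
#' "`AI[feature] <= threshold`: `left_class`, else the other class" —
#' the shape of every published J48 lateralization rule.
#'
#' @param feature Pair name the rule tests.
#' @param threshold AI threshold.
#' @param left_class Class predicted when `value <= threshold`.
#' @return An `ai_tree`.
#' @export
tree_stump <- function(feature, threshold, left_class = "Left") {
  if (!feature %in% pair_names()) {
    abort(paste0("Unknown region pair `", feature, "`."))
  }
  classes <- tle_classes()
  other <- setdiff(classes, left_class)
  node <- list(
    leaf = FALSE, feature = feature, threshold = threshold,
    n = 0L, counts = c(0L, 0L),
    left = list(leaf = TRUE, class = left_class, n = 0L,
                counts = c(0L, 0L), errors = 0L),
    right = list(leaf = TRUE, class = other, n = 0L,
                 counts = c(0L, 0L), errors = 0L)
  )
  structure(
    list(node = node, classes = classes, features = feature,
         params = list(fixed = TRUE), n = 0L,
         class_counts = setNames(c(0L, 0L), classes)),
    class = "ai_tree"
  )
}

tree_predict_one <- function(node, row) {
  while (!node$leaf) {
    v <- row[[node$feature]]
    if (is.null(v) || is.na(v)) {
      abort(paste0("Feature `", node$feature, "` required by the model is missing."))
    }
    node <- if (v <= node$threshold) node$left else node$right
  }
  node$class
}

#' Predict lateralization with a tree model
#'
#' @param object An `ai_tree`.
#' @param newdata Feature table containing every feature the model tests.
#' @param ... Unused.
#' @return Character vector of `"Left"`/`"Right"` predictions.
#' @export
predict.ai_tree <- function(object, newdata, ...) {
  missing <- setdiff(tree_features(object$node), names(newdata))
  if (length(missing) > 0) {
    abort(paste0("Missing feature column(s): ", paste(missing, collapse = ", ")))
  }
  vapply(seq_len(nrow(newdata)), function(i) {
    tree_predict_one(object$node, newdata[i, ])
  }, character(1))
}

tree_features <- function(node) {
  if (node$leaf) return(character(0))
  unique(c(node$feature, tree_features(node$left), tree_features(node$right)))
}

tree_depth <- function(node) {
  if (node$leaf) return(0L)
  1L + max(tree_depth(node$left), tree_depth(node$right))
}

tree_n_leaves <- function(node) {
  if (node$leaf) return(1L)
  tree_n_leaves(node$left) + tree_n_leaves(node$right)
}

render_node <- function(node, region_lookup, indent = 0) {
  pad <- strrep("  ", indent)
  if (node$leaf) return(paste0(pad, ": ", node$class))
  name <- region_lookup[node$feature]
  thr <- format(node$threshold, digits = 6)
  c(
    paste0(pad, "AI[", name, "] <= ", thr, render_tip(node$left)),
    if (!node$left$leaf) render_node(node$left, region_lookup, indent + 1),
    paste0(pad, "AI[", name, "] > ", thr, render_tip(node$right)),
    if (!node$right$leaf) render_node(node$right, region_lookup, indent + 1)
  )
}

render_tip <- function(node) if (node$leaf) paste0(": ", node$class) else ""

#' @export
format.ai_tree <- function(x, ...) {
  lookup <- setNames(region_pairs()$region, region_pairs()$pair_name)
  paste(render_node(x$node, lookup), collapse = "\n")
}

#' @export
print.ai_tree <- function(x, ...) {
  cat("<ai_tree> C4.5-style lateralization tree\n")
  cat(format(x), "\n")
  invisible(x)
}

#' @method tidy ai_tree
#' @export
tidy.ai_tree <- function(x, ...) {
  walk <- function(node, depth, path) {
    if (node$leaf) {
      return(tibble::tibble(
        depth = depth, path = path, feature = NA_character_,
        threshold = NA_real_, leaf_class = node$class,
        n = node$n
      ))
    }
    dplyr::bind_rows(
      tibble::tibble(depth = depth, path = path, feature = node$feature,
                     threshold = node$threshold, leaf_class = NA_character_,
                     n = node$n),
      walk(node$left, depth + 1L, paste0(path, "L")),
      walk(node$right, depth + 1L, paste0(path, "R"))
    )
  }
  walk(x$node, 0L, "")
}

#' @method glance ai_tree
#' @export
glance.ai_tree <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    depth = tree_depth(x$node),
    n_leaves = tree_n_leaves(x$node),
    features_used = length(tree_features(x$node))
  )
}
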