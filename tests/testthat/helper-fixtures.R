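# Shared fixtures, built in code.

# Smallest atlas the block-placement scheme accepts; fast to fill.
tiny_atlas <- function(seed = 1L) {
  generate_atlas(grid_shape = c(10L, 20L, 20L), voxel_size = c(4, 4, 4),
                 seed = seed, block_size = 2L)
}

# Noise-free, perfectly scaled generator settings.
clean_config <- function(...) {
  cohort_config(voxel_noise_sd = 0, ai_noise_sd = 0,
                global_scale_range = c(1, 1), ...)
}

# One-feature table with a planted class gap (Left low, Right high).
gap_table <- function(left = c(-6, -5, -4), right = c(4, 5, 6)) {
  tibble::tibble(
    label = rep(c("Left", "Right"), c(length(left), length(right))),
    Hippocampus = c(left, right)
  )
}

# Independent exhaustive gain-ratio search used as the split oracle: plain
# loops, no sharing with the package's split code.
oracle_best_split <- function(data, features, min_leaf = 2) {
  ent <- function(y) {
    p <- table(y) / length(y)
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  y <- data$label
  best <- list(gain_ratio = -Inf)
  for (f in features) {
    x <- data[[f]]
    for (v in sort(unique(x))) {
      left <- x <= v
      if (sum(left) < min_leaf || sum(!left) < min_leaf) next
      gain <- ent(y) - (sum(left) / length(y)) * ent(y[left]) -
        (sum(!left) / length(y)) * ent(y[!left])
      if (gain <= 1e-12) next
      si <- ent(left)
      gr <- gain / si
      if (gr > best$gain_ratio + 1e-12) {
        best <- list(feature = f, value = v, gain = gain, gain_ratio = gr)
      }
    }
  }
  best
}

# Gain ratio achieved by a given (feature, threshold) split — for checking
# that the learner's root split attains the oracle's maximum.
split_gain_ratio <- function(data, feature, threshold) {
  ent <- function(y) {
    p <- table(y) / length(y)
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  y <- data$label
  left <- data[[feature]] <= threshold
  gain <- ent(y) - (sum(left) / length(y)) * ent(y[left]) -
    (sum(!left) / length(y)) * ent(y[!left])
  gain / ent(left)
}

random_feature_table <- function(n, p = 3, seed = 1) {
  set.seed(seed)
  feats <- pair_names()[seq_len(p)]
  tab <- tibble::as_tibble(
    stats::setNames(as.data.frame(matrix(rnorm(n * p), n, p)), feats)
  )
  tab$label <- sample(c("Left", "Right"), n, replace = TRUE)
  # guarantee both classes
  tab$label[1] <- "Left"
  tab$label[2] <- "Right"
  tab
}
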