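#' The thirteen mesial-temporal-associated region pairs
#'
#' The analysis quantifies metabolic asymmetry over thirteen left/right
#' homologous regions that are contiguous or functionally associated with
#' mesial temporal lobe structures: the opercular part of the inferior
#' frontal gyrus, rolandic operculum, insula, hippocampus, parahippocampal
#' gyrus, amygdala, supramarginal gyrus, thalamus, superior temporal gyrus,
#' temporal pole of the superior temporal gyrus, middle temporal gyrus,
#' temporal pole of the middle temporal gyrus, and inferior temporal gyrus.
#' Machine-readable pair names follow the AAL atlas naming convention; the
#' fixed ordering below is the canonical feature-column order.
#'
#' @return A tibble with one row per region pair: `pair_name` (AAL-style
#'   identifier used as feature column name) and `region` (full anatomical
#'   name used when rendering rules).
#' @examples
#' region_pairs()
#' @export
region_pairs <- function() {
  tibble::tibble(
    pair_name = c(
      "Frontal_Inf_Oper", "Rolandic_Oper", "Insula", "Hippocampus",
      "ParaHippocampal", "Amygdala", "SupraMarginal", "Thalamus",
      "Temporal_Sup", "Temporal_Pole_Sup", "Temporal_Mid",
      "Temporal_Pole_Mid", "Temporal_Inf"
    ),
    region = c(
      "Opercular part of inferior frontal gyrus", "Rolandic operculum",
      "Insula", "Hippocampus", "Parahippocampal gyrus", "Amygdala",
      "Supramarginal gyrus", "Thalamus", "Superior temporal gyrus",
      "Temporal pole of superior temporal gyrus", "Middle temporal gyrus",
      "Temporal pole of middle temporal gyrus", "Inferior temporal gyrus"
    )
  )
}

#' Canonical feature column names
#'
#' @return Character vector of the thirteen pair names in canonical order.
#' @keywords internal
#' @export
pair_names <- function() region_pairs()$pair_name

# The two class labels, in the fixed order used throughout the package.
tle_classes <- function() c("Left", "Right")

# Validate a feature table: tibble with the AI columns (all pairs unless a
# declared subset is allowed), finite values, optional binary label column.
check_feature_table <- function(data, require_label = FALSE,
                                features = NULL) {
  if (!is.data.frame(data) || nrow(data) == 0) {
    abort("`data` must be a data frame with at least one row.")
  }
  features <- features %||% intersect(pair_names(), names(data))
  if (length(features) == 0) {
    abort("`data` contains none of the thirteen asymmetry-index columns.")
  }
  for (f in features) {
    v <- data[[f]]
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v))) {
      abort(paste0("Feature column `", f, "` must be numeric with no ",
                   "missing or non-finite values."))
    }
  }
  if (require_label) {
    if (!"label" %in% names(data)) {
      abort("`data` must contain a `label` column with Left/Right classes.")
    }
    lab <- as.character(data$label)
    if (anyNA(lab) || !all(lab %in% tle_classes())) {
      abort("`label` values must all be \"Left\" or \"Right\".")
    }
  }
  features
}
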