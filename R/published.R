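#' Published lateralization rules
#'
#' Returns, as ready-to-use model objects, the fixed classification rules
#' printed with the original cohort analysis: the 60:40 train/test pair of
#' models (a single-split hippocampal tree with threshold 3.18 and a
#' two-region logistic score over the hippocampus and the temporal pole of
#' the middle temporal gyrus), plus the five tree and five linear models
#' produced by the five cross-validation runs.
#'
#' @return A list with elements:
#'   \describe{
#'     \item{j48_test_model}{`ai_tree`: `AI[Hippocampus] <= 3.18 -> Left`,
#'       else Right.}
#'     \item{lmt_test_model}{`ai_linear`: Left score
#'       `0.06 - 0.08 * AI[Hippocampus] - 0.03 * AI[Temporal_Pole_Mid]`.}
#'     \item{cv_run_models}{Tibble with columns `run`, `j48` (list of
#'       `ai_tree`), `lmt` (list of `ai_linear`).}
#'   }
#' @examples
#' rules <- published_rules()
#' predict(rules$j48_test_model,
#'         tibble::tibble(Hippocampus = c(3.18, 5.71)))
#' @export
published_rules <- function() {
  cv_j48 <- list(
    tree_stump("Temporal_Inf", -3.99),
    tree_stump("Temporal_Inf", -3.99),
    tree_stump("ParaHippocampal", -5.46),
    tree_stump("Rolandic_Oper", 2.06),
    tree_stump("ParaHippocampal", -0.24)
  )
  cv_lmt <- list(
    linear_model(0.13, c(Hippocampus = -0.07, Temporal_Pole_Mid = -0.02)),
    linear_model(0.14, c(Hippocampus = -0.07)),
    linear_model(0.16, c(Hippocampus = -0.07, Temporal_Pole_Mid = -0.02)),
    linear_model(0.09, c(Hippocampus = -0.07, Temporal_Pole_Mid = -0.03)),
    linear_model(0.23, c(Hippocampus = -0.07, Temporal_Pole_Mid = -0.02))
  )
  list(
    j48_test_model = tree_stump("Hippocampus", 3.18),
    lmt_test_model = linear_model(
      0.06, c(Hippocampus = -0.08, Temporal_Pole_Mid = -0.03)
    ),
    cv_run_models = tibble::tibble(
      run = seq_len(5), j48 = cv_j48, lmt = cv_lmt
    )
  )
}

#' Published test-set lateralization table
#'
#' The per-patient lateralization calls of the 18-patient test set as
#' printed with the original analysis: the definitive (postsurgical
#' Engel I) lateralization and the calls of two readers, their consensus,
#' the voxel-wise SPM analysis, and the two data-mining models.
#' `"No lateralization"` marks cases where the voxel-wise analysis produced
#' no call; it is always scored as incorrect.
#'
#' @return An 18-row tibble with columns `patient`, `definitive`,
#'   `reader1`, `reader2`, `consensus`, `spm`, `j48`, `lmt`.
#' @export
published_test_table <- function() {
  L <- "Left"; R <- "Right"; NL <- "No lateralization"
  tibble::tibble(
    patient = 1:18,
    definitive = c(L, L, L, L, L, L, L, L, R, R, L, L, R, R, R, R, R, R),
    reader1   = c(L, L, L, L, L, L, L, L, R, R, L, L, R, R, R, R, R, R),
    reader2   = c(L, L, L, L, L, L, L, L, R, R, L, L, L, R, R, R, R, R),
    consensus = c(L, L, L, L, L, L, L, L, R, R, L, L, R, R, R, R, R, R),
    spm       = c(L, L, L, L, L, L, L, L, R, R, L, NL, R, NL, R, R, R, R),
    j48       = c(L, L, L, L, L, L, L, L, R, R, L, R, R, R, R, R, R, L),
    lmt       = c(L, L, L, L, L, L, L, L, R, R, L, R, R, R, R, R, R, R)
  )
}

#' Worked-example asymmetry indices
#'
#' The single published per-patient feature example: the test-set patient
#' (number 12) whose hippocampal AI was 5.71 and whose AI in the temporal
#' pole of the middle temporal gyrus was 7.94 — a left-TLE patient that
#' both published models lateralize (falsely) as Right.
#'
#' @return A one-row feature tibble.
#' @export
worked_example_features <- function() {
  tibble::tibble(
    subject_id = "patient12", label = "Left",
    Hippocampus = 5.71, Temporal_Pole_Mid = 7.94
  )
}
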