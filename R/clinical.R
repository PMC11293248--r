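#' Immunohistochemistry product score
#'
#' Staining intensity (0-3) times positive-cell score (1-4), dichotomized:
#' products of 7 or above are "high", products below 6 are "low". The rule
#' leaves the attainable product 6 unassigned; it is labelled "low" here
#' (so "high" is exactly >= 7) and flagged with a message when hit.
#'
#' @param intensity integer(s) in 0..3.
#' @param positive_cells integer(s) in 1..4.
#' @return data.frame with `intensity`, `positive_cells`, `score`, `label`.
#' @export
ihc_score <- function(intensity, positive_cells) {
  if (any(!intensity %in% 0:3)) stop("intensity must be in 0..3")
  if (any(!positive_cells %in% 1:4)) stop("positive-cell score must be in 1..4")
  score <- intensity * positive_cells
  if (any(score == 6))
    message("IHC product 6 falls in the rule's gap; labelled 'low'")
  data.frame(intensity = intensity, positive_cells = positive_cells,
             score = score, label = ifelse(score >= 7, "high", "low"),
             stringsAsFactors = FALSE)
}

#' Relative expression by the 2^-ddCt method
#'
#' ddCt = (Ct_target,case - Ct_ref,case) - (Ct_target,ctrl - Ct_ref,ctrl);
#' the returned fold change is 2^-ddCt.
#'
#' @param ct_target_case,ct_ref_case,ct_target_ctrl,ct_ref_ctrl finite
#'   threshold-cycle values (vectors recycle as usual).
#' @return numeric fold change(s).
#' @export
fold_change_ddct <- function(ct_target_case, ct_ref_case,
                             ct_target_ctrl, ct_ref_ctrl) {
  stopifnot(all(is.finite(c(ct_target_case, ct_ref_case,
                            ct_target_ctrl, ct_ref_ctrl))))
  ddct <- (ct_target_case - ct_ref_case) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}

#' Rank-based ROC area under the curve
#'
#' Tie-corrected Mann-Whitney pair counting:
#' AUC = (#\{case > control\} + 0.5 #\{ties\}) / (n_case * n_control).
#' Equivalent to the probability that a random case scores above a random
#' control; invariant under monotone transformations of the scores.
#'
#' @param scores_cases,scores_controls non-empty numeric score vectors.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores_cases, scores_controls) {
  if (!length(scores_cases) || !length(scores_controls))
    stop("both groups must be non-empty")
  n1 <- length(scores_cases); n0 <- length(scores_controls)
  r <- rank(c(scores_cases, scores_controls), ties.method = "average")
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u / (n1 * n0)
}
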