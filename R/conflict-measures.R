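#' Between-system value conflict
#'
#' The continuous disagreement between the two systems about the first-stage
#' value difference: `|dq_mb - dq_mf|`, where each `dq` is the system's value
#' of choice 1 minus choice 2.
#'
#' @param dq_mb,dq_mf first-stage value differences of the model-based and
#'   model-free systems.
#' @return Non-negative numeric (vectorized).
#' @export
value_conflict <- function(dq_mb, dq_mf) abs(dq_mb - dq_mf)

#' Between-system action conflict
#'
#' Binary indicator that the systems disagree on the identity of the best
#' action: 1 when the product of the two value differences is strictly
#' negative, 0 otherwise (ties, including either difference being exactly 0,
#' count as no conflict).
#'
#' @inheritParams value_conflict
#' @return 0/1 numeric (vectorized).
#' @export
action_conflict <- function(dq_mb, dq_mf) as.numeric(dq_mb * dq_mf < 0)

#' All conflict covariates for a set of trials
#'
#' Computes the full set of conflict regressors used by the decision layer:
#' between-system value conflict and its square, the binary action-conflict
#' state, within-system conflict (each system's own absolute value
#' difference) and its squares, alongside the perseveration covariate.
#'
#' @param dq_mb,dq_mf first-stage value differences (vectorized).
#' @param rep perseveration covariate in \{-1, 0, 1\}.
#' @return A `data.frame` with columns `dq_mf`, `dq_mb`, `conflict_value`,
#'   `conflict_action`, `within_mf`, `within_mb`, `conflict_value_sq`,
#'   `within_mf_sq`, `within_mb_sq`, `rep`.
#' @examples
#' conflict_features(0.08, -0.12, 1)
#' @export
conflict_features <- function(dq_mb, dq_mf, rep = 0) {
  data.frame(dq_mf = dq_mf, dq_mb = dq_mb,
             conflict_value = value_conflict(dq_mb, dq_mf),
             conflict_action = action_conflict(dq_mb, dq_mf),
             within_mf = abs(dq_mf), within_mb = abs(dq_mb),
             conflict_value_sq = (dq_mb - dq_mf)^2,
             within_mf_sq = dq_mf^2, within_mb_sq = dq_mb^2,
             rep = rep)
}
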