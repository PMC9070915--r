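#' Conflict descriptives
#'
#' Per-subject means of between-system value conflict on trials without and
#' with action conflict, and the per-subject proportion of action-conflict
#' trials, averaged (with SD) across subjects.  A subject with no
#' action-conflict trials contributes a missing with-conflict mean rather
#' than zero.
#'
#' @param conflict data.frame with `subject_id`, `conflict_value`,
#'   `conflict_action` (e.g. [conflict_features()] columns bound to a
#'   Q-trajectory table).
#' @return A list with `per_subject` (one row per subject) and `overall`
#'   (across-subject mean and SD of each descriptive).
#' @export
conflict_descriptives <- function(conflict) {
  ids <- unique(conflict$subject_id)
  per <- do.call(rbind, lapply(ids, function(id) {
    x <- conflict[conflict$subject_id == id, , drop = FALSE]
    ca <- x$conflict_action == 1
    data.frame(subject_id = id,
               mean_value_conflict_no_action = if (any(!ca))
                 mean(x$conflict_value[!ca]) else NA_real_,
               mean_value_conflict_action = if (any(ca))
                 mean(x$conflict_value[ca]) else NA_real_,
               prop_action_conflict = mean(ca),
               stringsAsFactors = FALSE)
  }))
  overall <- data.frame(
    measure = c("value_conflict_no_action", "value_conflict_action",
                "prop_action_conflict"),
    mean = c(mean(per$mean_value_conflict_no_action, na.rm = TRUE),
             mean(per$mean_value_conflict_action, na.rm = TRUE),
             mean(per$prop_action_conflict)),
    sd = c(sd(per$mean_value_conflict_no_action, na.rm = TRUE),
           sd(per$mean_value_conflict_action, na.rm = TRUE),
           sd(per$prop_action_conflict)),
    stringsAsFactors = FALSE)
  list(per_subject = per, overall = overall)
}

#' Between- versus within-system conflict correlations
#'
#' Correlation of between-system value conflict with each system's
#' within-system conflict, pooled across all participants and trials (not a
#' mean of per-subject correlations).  Pearson's coefficient is reported with
#' Spearman's alongside, since the estimator behind published values of this
#' kind is usually unstated.
#'
#' @param conflict data.frame with `conflict_value`, `within_mf`,
#'   `within_mb`.
#' @return A data.frame with one row per pairing (`with_mf`, `with_mb`) and
#'   columns `pearson`, `spearman`; `NA` when a variable has no variance.
#' @export
conflict_correlations <- function(conflict) {
  if (nrow(conflict) < 2) stop("need at least two pooled trials")
  safe_cor <- function(x, y, method) {
    if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
    cor(x, y, method = method)
  }
  data.frame(
    within = c("with_mf", "with_mb"),
    pearson = c(safe_cor(conflict$conflict_value, conflict$within_mf, "pearson"),
                safe_cor(conflict$conflict_value, conflict$within_mb, "pearson")),
    spearman = c(safe_cor(conflict$conflict_value, conflict$within_mf, "spearman"),
                 safe_cor(conflict$conflict_value, conflict$within_mb, "spearman")),
    stringsAsFactors = FALSE)
}

#' Conflict-effect comparison table
#'
#' Collects the headline conflict effects from one or more fitted models into
#' a single table: the value-conflict effect without action conflict, the
#' value-conflict effect under action conflict (the per-draw sum of the
#' base and interaction coefficients), and the action-conflict main effect,
#' for each system's drift strength and for boundary separation, together
#' with the model-based minus model-free differences and significance flags.
#'
#' @param summaries a summary data.frame from [summarize_posterior()], or a
#'   named list of them (one per dataset/model).
#' @return A data.frame with `dataset`, `effect`, `median`, `ci_low`,
#'   `ci_high`, `significant`.
#' @export
effect_report <- function(summaries) {
  if (is.data.frame(summaries)) summaries <- list(fit = summaries)
  wanted <- c(
    v_mb_value_conflict = "mu.v_mb_cv",
    v_mb_value_conflict_with_action = "derived.v_mb_cv_plus_int",
    v_mb_action_conflict = "mu.v_mb_ca",
    v_mf_value_conflict = "mu.v_mf_cv",
    v_mf_value_conflict_with_action = "derived.v_mf_cv_plus_int",
    v_mf_action_conflict = "mu.v_mf_ca",
    diff_value_conflict = "derived.diff_cv",
    diff_value_conflict_with_action = "derived.diff_cv_plus_int",
    diff_action_conflict = "derived.diff_ca",
    a1_value_conflict = "mu.a_cv",
    a1_value_conflict_with_action = "derived.a_cv_plus_int",
    a1_action_conflict = "mu.a_ca")
  out <- lapply(names(summaries), function(nm) {
    s <- summaries[[nm]]
    hit <- wanted[wanted %in% s$parameter]
    if (!length(hit)) return(NULL)
    idx <- match(hit, s$parameter)
    data.frame(dataset = nm, effect = names(hit),
               median = s$median[idx], ci_low = s$ci_low[idx],
               ci_high = s$ci_high[idx], significant = s$significant[idx],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}
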