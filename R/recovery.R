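#' Parameter-recovery harness
#'
#' Repeats the full analysis pipeline on data simulated from known
#' parameters: simulate a study, apply the participant exclusion filter, run
#' the two-step fit (choice-only learning fit, per-subject point estimates,
#' Q-trajectories, decision-layer fit), and tabulate truth against the
#' recovered group-level posteriors.
#'
#' @param truth a [group_truth()].
#' @param study a [study_config()]; replicate `r` uses seed
#'   `study$seed + 1000 * r`.
#' @param n_replicates number of simulated studies.
#' @param mcmc an [mcmc_config()] used for both fitting stages.
#' @param model decision-layer model, `"between"` or `"within"`.
#' @return A list of class `recovery_report`: `table` (one row per replicate
#'   and group-mean parameter: truth, posterior median, central CI, coverage
#'   and significance flags, max split R-hat of the fit), and `errors`
#'   (per-replicate error messages, if any).
#' @export
run_parameter_recovery <- function(truth, study, n_replicates = 20,
                                   mcmc = mcmc_config(preset = "desk"),
                                   model = "between") {
  rows <- list(); errors <- list()
  for (r in seq_len(n_replicates)) {
    st <- study
    st$seed <- study$seed + 1000L * r
    res <- tryCatch({
      sim <- simulate_study(truth, st)
      excl <- apply_exclusions(sim$trials, st$config)
      trials <- excl$retained
      if (length(unique(trials$subject_id)) < 2)
        stop("fewer than two subjects retained")
      m1 <- mcmc; m1$seed <- st$seed + 1L
      fit1 <- fit_stage1_rl(trials, st$config, m1)
      pts <- extract_subject_point_estimates(fit1)
      qt <- compute_q_trajectories(trials, pts$alpha, pts$lam, st$config)
      m2 <- mcmc; m2$seed <- st$seed + 2L
      fit2 <- fit_stage2_ddm(trials, qt, st$config, m2, model = model)
      sum1 <- summarize_posterior(fit1, derived = FALSE)
      sum2 <- summarize_posterior(fit2, derived = FALSE)
      both <- rbind(cbind(sum1, stage = 1L), cbind(sum2, stage = 2L))
      mus <- both[grepl("^mu\\.", both$parameter), , drop = FALSE]
      mus$name <- sub("^mu\\.", "", mus$parameter)
      mus$truth <- unname(truth$mu[mus$name])
      # softmax weights have no generative truth when choices come from the
      # diffusion layer
      mus$truth[mus$stage == 1L & grepl("^beta", mus$name)] <- NA_real_
      data.frame(replicate = r, parameter = mus$name, stage = mus$stage,
                 truth = mus$truth, median = mus$median,
                 ci_low = mus$ci_low, ci_high = mus$ci_high,
                 covered = mus$ci_low <= mus$truth & mus$truth <= mus$ci_high,
                 significant = mus$significant,
                 rhat_max = ifelse(mus$stage == 1L, max(fit1$rhat, na.rm = TRUE),
                                   max(fit2$rhat, na.rm = TRUE)),
                 stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[length(errors) + 1L]] <- list(replicate = r,
                                            message = conditionMessage(res))
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  structure(list(table = do.call(rbind, rows), errors = errors,
                 truth = truth, study = study),
            class = "recovery_report")
}

#' Summary statistics of a recovery batch
#'
#' Aggregates a [run_parameter_recovery()] table into the calibration
#' quantities of interest: group-mean CI coverage across the decision-layer
#' parameters, the per-replicate mean signed error of the conflict drift
#' coefficients with a one-sample t-test against zero, and the rate at which
#' conflict effects are flagged significant.
#'
#' @param report a `recovery_report`.
#' @return A list with `coverage`, `signed_error` (vector per replicate),
#'   `signed_error_p` (t-test p-value), `false_significance_rate`, and the
#'   underlying `table`.
#' @export
recovery_summary <- function(report) {
  tab <- report$table
  ddm <- tab[tab$stage == 2L & !is.na(tab$truth), , drop = FALSE]
  conflict <- grepl("_(cv|ca|int|within|cvsq|wsq)$", ddm$parameter)
  drift <- conflict & grepl("^v_", ddm$parameter)
  coverage <- mean(ddm$covered, na.rm = TRUE)
  err_tab <- ddm[drift, , drop = FALSE]
  signed <- tapply(err_tab$median - err_tab$truth, err_tab$replicate, mean)
  pval <- if (length(signed) >= 2 && sd(signed) > 0)
    t.test(signed)$p.value else NA_real_
  fsr <- mean(ddm$significant[conflict], na.rm = TRUE)
  list(coverage = coverage, signed_error = as.numeric(signed),
       signed_error_p = pval, false_significance_rate = fsr, table = tab)
}
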