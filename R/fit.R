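# prior/initialization rows for the hierarchical parameter tables
prow <- function(name, mu_mean = 0, mu_sd = 20, sd_sd = 20, mu_lower = -Inf,
                 theta_lower = -Inf, init_mu = 0, init_sigma = 1,
                 step0 = 0.3) {
  data.frame(name = name, mu_prior_mean = mu_mean, mu_prior_sd = mu_sd,
             sd_prior_sd = sd_sd, mu_lower = mu_lower,
             theta_lower = theta_lower, init_mu = init_mu,
             init_sigma = init_sigma, step0 = step0,
             stringsAsFactors = FALSE)
}

#' Hierarchical prior specification
#'
#' Builds the group-level prior table for one of the package's hierarchical
#' models.  Defaults follow the fitting scheme: N(0, 20) priors on group
#' means and (zero-truncated) group SDs, N(0, 200) on conflict-related drift
#' coefficients (they multiply products of small value differences), N(0.5, 1)
#' on the mean non-decision time with a N(0, 1) SD prior, and N(1, 20) priors
#' biased positive on the base boundary separations.  Boundary, non-decision
#' time and all SDs are constrained non-negative; `alpha` and `lam` are
#' sampled on an unconstrained scale and pass through a logistic transform
#' inside the likelihood.
#'
#' @param model one of `"stage1"`, `"between"`, `"within"`,
#'   `"reduced_between"`, `"reduced_within"`.
#' @param config a [task_config()]; the newer variant drops the second-stage
#'   decision parameters (`beta2`, `v2_base`, `a2`).
#' @return A `data.frame`, one row per free parameter, with prior and
#'   initialization columns.
#' @export
hierarchical_spec <- function(model = c("stage1", "between", "within",
                                        "reduced_between", "reduced_within"),
                              config) {
  model <- match.arg(model)
  orig <- config$variant == "original"
  learn <- rbind(
    prow("alpha", init_mu = 0, init_sigma = 0.5),
    prow("lam", init_mu = 0, init_sigma = 0.5))
  softmax <- rbind(
    prow("beta_mb", init_mu = 0.5, step0 = 0.5),
    prow("beta_mf", init_mu = 0.5, step0 = 0.5),
    prow("beta_rep", init_mu = 0, step0 = 0.3),
    if (orig) prow("beta2", init_mu = 0.5, step0 = 0.5))
  drift_base <- function(n) prow(n, init_mu = 1, step0 = 0.5)
  drift_conf <- function(n) prow(n, mu_sd = 200, sd_sd = 200,
                                 init_sigma = 2, step0 = 5)
  bound_conf <- function(n) prow(n, step0 = 0.3)
  a_base <- function(n, init) prow(n, mu_mean = 1, mu_lower = 0,
                                   theta_lower = 0, init_mu = init,
                                   init_sigma = 0.2, step0 = 0.15)
  tau_row <- prow("tau", mu_mean = 0.5, mu_sd = 1, sd_sd = 1, mu_lower = 0,
                  theta_lower = 0, init_mu = 0.25, init_sigma = 0.05,
                  step0 = 0.05)
  stage2_rows <- if (orig) rbind(drift_base("v2_base"), a_base("a2", 1.3))
  ddm_between <- rbind(
    drift_base("v_mb_base"), drift_conf("v_mb_cv"), drift_conf("v_mb_ca"),
    drift_conf("v_mb_int"), drift_base("v_mf_base"), drift_conf("v_mf_cv"),
    drift_conf("v_mf_ca"), drift_conf("v_mf_int"), prow("v_rep"),
    a_base("a1_base", 1.5), bound_conf("a_cv"), bound_conf("a_ca"),
    bound_conf("a_int"), prow("s_rep"), stage2_rows, tau_row)
  ddm_within <- rbind(
    drift_base("v_mb_base"), drift_conf("v_mb_within"),
    drift_base("v_mf_base"), drift_conf("v_mf_within"), prow("v_rep"),
    a_base("a1_base", 1.5), bound_conf("a_mb_within"),
    bound_conf("a_mf_within"), prow("s_rep"), stage2_rows, tau_row)
  ddm_red_between <- rbind(
    drift_base("v_mb_base"), drift_conf("v_mb_cvsq"),
    drift_base("v_mf_base"), drift_conf("v_mf_cvsq"), prow("v_rep"),
    a_base("a1_base", 1.5), bound_conf("a_cvsq"), prow("s_rep"),
    stage2_rows, tau_row)
  ddm_red_within <- rbind(
    drift_base("v_mb_base"), drift_conf("v_mb_wsq"),
    drift_base("v_mf_base"), drift_conf("v_mf_wsq"), prow("v_rep"),
    a_base("a1_base", 1.5), bound_conf("a_mb_wsq"),
    bound_conf("a_mf_wsq"), prow("s_rep"), stage2_rows, tau_row)
  tab <- switch(model,
    stage1 = rbind(learn, softmax),
    between = ddm_between,
    within = ddm_within,
    reduced_between = rbind(learn, ddm_red_between),
    reduced_within = rbind(learn, ddm_red_within))
  rownames(tab) <- NULL
  tab
}

# slot index of each named parameter in the 17-slot decision-layer vector the
# likelihood consumes (see src/likelihood.cpp)
DDM_SLOTS <- c(
  v_mb_base = 1, v_mb_cv = 2, v_mb_ca = 3, v_mb_int = 4,
  v_mf_base = 5, v_mf_cv = 6, v_mf_ca = 7, v_mf_int = 8,
  v_rep = 9, a1_base = 10, a_cv = 11, a_ca = 12, a_int = 13, s_rep = 14,
  v2_base = 15, a2 = 16, tau = 17,
  v_mb_within = 2, v_mf_within = 6, a_mb_within = 11, a_mf_within = 12,
  v_mb_cvsq = 2, v_mf_cvsq = 6, a_cvsq = 11,
  v_mb_wsq = 2, v_mf_wsq = 6, a_mb_wsq = 11, a_mf_wsq = 12)

assemble_ddm_theta <- function(theta, extra_offset = 0) {
  nm <- setdiff(rownames(theta), c("alpha", "lam"))
  full <- matrix(0, 17 + extra_offset, ncol(theta))
  if (extra_offset == 2) {
    full[1, ] <- theta["alpha", ]
    full[2, ] <- theta["lam", ]
  }
  full[16 + extra_offset, ] <- 1   # dummy a2 for the newer variant
  for (n in nm)
    full[DDM_SLOTS[[n]] + extra_offset, ] <- theta[n, ]
  full
}

min_valid_rt <- function(d, variant, rt_floor = 0.2) {
  rts <- c(d$rt1[d$m1 == 0 & d$c1 > 0], if (variant == 0L)
    d$rt2[d$m2 == 0 & d$c2 > 0])
  rts <- rts[is.finite(rts) & rts >= rt_floor]
  if (!length(rts)) 0.5 else min(rts)
}

#' Stage 1: hierarchical fit of the learning model to choices
#'
#' Fits `alpha`, `lam` and the softmax weights (`beta_mb`, `beta_mf`,
#' `beta_rep`, and `beta2` for the original variant) to choice data only.
#' Q-values are recomputed inside the likelihood from each proposed `alpha`,
#' `lam` by the hybrid learner's forward sweep.  Group means and SDs follow
#' [hierarchical_spec()]; sampling is Metropolis-within-Gibbs with split
#' R-hat convergence checks.
#'
#' @param trials trial `data.frame` (raw rewards, exclusions already
#'   applied; see [apply_exclusions()]).
#' @param config a [task_config()].
#' @param mcmc an [mcmc_config()].
#' @param spec prior table; defaults to `hierarchical_spec("stage1", config)`.
#' @param rt_floor trials faster than this (seconds) are left out of the
#'   likelihood.
#' @return An `rlddm_fit`.
#' @export
fit_stage1_rl <- function(trials, config, mcmc = mcmc_config(preset = "desk"),
                          spec = hierarchical_spec("stage1", config),
                          rt_floor = 0.2) {
  subjects <- split_subjects(trials, config)
  variant <- variant_code(config)
  loglik <- function(theta) {
    full <- matrix(0, 6, ncol(theta))
    full[1, ] <- theta["alpha", ]; full[2, ] <- theta["lam", ]
    full[3, ] <- theta["beta_mb", ]; full[4, ] <- theta["beta_mf", ]
    full[5, ] <- theta["beta_rep", ]
    if ("beta2" %in% rownames(theta)) full[6, ] <- theta["beta2", ]
    .ll_stage1_all_cpp(subjects, full, variant, config$q_initial, rt_floor)
  }
  fit <- hier_mcmc(subjects, spec, loglik, mcmc)
  fit$model <- "stage1"
  fit$config <- config
  fit
}

#' Stage 2: hierarchical fit of the conflict-modulated decision layer
#'
#' Fits the drift-diffusion layer to choices and response times, with the
#' trial-level conflict covariates fixed at the Q-trajectories computed from
#' the stage-1 point estimates.  `model = "between"` uses the between-system
#' regressors (value conflict, action conflict, their interaction on both
#' drift strengths and on boundary separation); `model = "within"` replaces
#' them with each system's within-system conflict terms (no action-conflict
#' distinction).  Trials with an RT below `rt_floor` or a missing choice at
#' either stage are left out of the likelihood; proposals driving the trial
#' boundary separation non-positive, or the non-decision time past an
#' observed RT, are rejected through a zero likelihood.
#'
#' @inheritParams fit_stage1_rl
#' @param q_traj Q-trajectories from [compute_q_trajectories()] at the
#'   stage-1 point estimates.
#' @param model `"between"` or `"within"`.
#' @return An `rlddm_fit`.
#' @export
fit_stage2_ddm <- function(trials, q_traj, config,
                           mcmc = mcmc_config(preset = "desk"),
                           model = c("between", "within"),
                           spec = hierarchical_spec(match.arg(model), config),
                           rt_floor = 0.2) {
  model <- match.arg(model)
  subjects <- split_subjects(trials, config)
  variant <- variant_code(config)
  for (id in names(subjects)) {
    qs <- q_traj[q_traj$subject_id == id, , drop = FALSE]
    if (nrow(qs) != length(subjects[[id]]$s1))
      stop("q_traj does not cover subject ", id)
    subjects[[id]]$dq_mf <- qs$dq_mf
    subjects[[id]]$dq_mb <- qs$dq_mb
    subjects[[id]]$rep <- qs$rep
    subjects[[id]]$dq2 <- qs$dq2
  }
  code <- if (model == "between") 0L else 1L
  loglik <- function(theta)
    .ll_ddm_all_cpp(subjects, assemble_ddm_theta(theta), code, variant,
                    rt_floor)
  init_theta <- matrix(spec$init_mu, nrow(spec), length(subjects),
                       dimnames = list(spec$name, names(subjects)))
  init_theta["tau", ] <- vapply(subjects, function(d)
    min(0.5 * min_valid_rt(d, variant, rt_floor), 0.4), numeric(1))
  fit <- hier_mcmc(subjects, spec, loglik, mcmc, init_theta = init_theta)
  fit$model <- paste0("stage2_", model)
  fit$config <- config
  fit
}

#' Reduced single-pass hierarchical fit
#'
#' The differentiably-parameterized variant of the analysis that fits
#' learning and decision parameters jointly in one hierarchical model:
#' `alpha` and `lam` receive full posteriors, Q-values are recomputed inside
#' the likelihood on every evaluation, and conflict enters drift and boundary
#' through squared value differences with no action-conflict distinction
#' (`"reduced_between"`: squared between-system conflict;
#' `"reduced_within"`: squared within-system terms).
#'
#' @inheritParams fit_stage1_rl
#' @param model `"between"` or `"within"`.
#' @return An `rlddm_fit`.
#' @export
fit_reduced_single_step <- function(trials, config,
                                    mcmc = mcmc_config(preset = "desk"),
                                    model = c("between", "within"),
                                    spec = NULL, rt_floor = 0.2) {
  model <- match.arg(model)
  if (is.null(spec))
    spec <- hierarchical_spec(paste0("reduced_", model), config)
  subjects <- split_subjects(trials, config)
  variant <- variant_code(config)
  code <- if (model == "between") 2L else 3L
  loglik <- function(theta)
    .ll_reduced_all_cpp(subjects, assemble_ddm_theta(theta, extra_offset = 2),
                        code, variant, config$q_initial, rt_floor)
  init_theta <- matrix(spec$init_mu, nrow(spec), length(subjects),
                       dimnames = list(spec$name, names(subjects)))
  init_theta["tau", ] <- vapply(subjects, function(d)
    min(0.5 * min_valid_rt(d, variant, rt_floor), 0.4), numeric(1))
  fit <- hier_mcmc(subjects, spec, loglik, mcmc, init_theta = init_theta)
  fit$model <- paste0("reduced_", model)
  fit$config <- config
  fit
}
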