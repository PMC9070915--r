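#' Decision-layer parameters
#'
#' The 17 free parameters of the conflict-modulated drift-diffusion layer:
#' base strengths and conflict regressors of the two systems' drift
#' contributions, the perseveration drift and start-point weights, the
#' boundary regression, the second-stage drift gain and boundary (original
#' variant), and the shared non-decision time.
#'
#' @param v_mb_base,v_mb_cv,v_mb_ca,v_mb_int model-based strength: intercept,
#'   value-conflict, action-conflict and interaction coefficients.
#' @param v_mf_base,v_mf_cv,v_mf_ca,v_mf_int model-free analogues.
#' @param v_rep perseveration drift bias.
#' @param a1_base,a_cv,a_ca,a_int first-stage boundary-separation regression
#'   (`a1_base >= 0`).
#' @param s_rep start-point perseveration weight (log-odds scale).
#' @param v2_base second-stage drift gain (original variant).
#' @param a2 second-stage boundary separation (`>= 0`).
#' @param tau non-decision time in seconds (`>= 0`), shared between stages.
#' @return A list of class `ddm_params`.
#' @export
ddm_params <- function(v_mb_base = 0, v_mb_cv = 0, v_mb_ca = 0, v_mb_int = 0,
                       v_mf_base = 0, v_mf_cv = 0, v_mf_ca = 0, v_mf_int = 0,
                       v_rep = 0, a1_base = 1.5, a_cv = 0, a_ca = 0,
                       a_int = 0, s_rep = 0, v2_base = 0, a2 = 1.5,
                       tau = 0.3) {
  stopifnot(a1_base >= 0, a2 >= 0, tau >= 0)
  structure(list(v_mb_base = v_mb_base, v_mb_cv = v_mb_cv, v_mb_ca = v_mb_ca,
                 v_mb_int = v_mb_int, v_mf_base = v_mf_base,
                 v_mf_cv = v_mf_cv, v_mf_ca = v_mf_ca, v_mf_int = v_mf_int,
                 v_rep = v_rep, a1_base = a1_base, a_cv = a_cv, a_ca = a_ca,
                 a_int = a_int, s_rep = s_rep, v2_base = v2_base, a2 = a2,
                 tau = tau), class = "ddm_params")
}

#' Conflict-modulated strength of one decision system
#'
#' The regression mapping conflict onto the strength of a system's drift
#' contribution: `base + cv_coef * conflict_value + ca_coef * conflict_action
#' + int_coef * conflict_value * conflict_action`.
#'
#' @param base intercept.
#' @param cv_coef,ca_coef,int_coef conflict regressor coefficients.
#' @param conflict one row of [conflict_features()] (or a list with
#'   `conflict_value` and `conflict_action`).
#' @return Numeric strength (vectorized over the conflict rows).
#' @export
system_strength <- function(base, cv_coef, ca_coef, int_coef, conflict) {
  base + cv_coef * conflict$conflict_value +
    ca_coef * conflict$conflict_action +
    int_coef * conflict$conflict_value * conflict$conflict_action
}

#' Trial-level drift-diffusion specification
#'
#' Assembles the first-stage diffusion of one trial from the decision-layer
#' parameters and the trial's conflict covariates: drift `v1 = v_mf * dq_mf +
#' v_mb * dq_mb + v_rep * rep` with conflict-modulated system strengths,
#' boundary separation from the conflict regression, and start fraction
#' `w1 = logistic(s_rep * rep)`.  The upper boundary codes choice 1.  A
#' non-positive boundary is flagged invalid rather than clamped; the
#' likelihood of such a spec is zero.
#'
#' @param params a [ddm_params()].
#' @param conflict one row of [conflict_features()].
#' @return A list of class `trial_ddm_spec` with `v1`, `a1`, `w1`, `tau` and
#'   `valid`.
#' @export
trial_ddm_spec <- function(params, conflict) {
  v_mb <- system_strength(params$v_mb_base, params$v_mb_cv, params$v_mb_ca,
                          params$v_mb_int, conflict)
  v_mf <- system_strength(params$v_mf_base, params$v_mf_cv, params$v_mf_ca,
                          params$v_mf_int, conflict)
  a1 <- params$a1_base + params$a_cv * conflict$conflict_value +
    params$a_ca * conflict$conflict_action +
    params$a_int * conflict$conflict_value * conflict$conflict_action
  v1 <- v_mf * conflict$dq_mf + v_mb * conflict$dq_mb +
    params$v_rep * conflict$rep
  structure(list(v1 = v1, a1 = a1, w1 = plogis(params$s_rep * conflict$rep),
                 tau = params$tau, valid = a1 > 0),
            class = "trial_ddm_spec")
}

#' Second-stage drift rate
#'
#' `v2 = v2_base * (Q(s2, choice1) - Q(s2, choice2))` for the visited
#' second-stage state; the start point is fixed at 0.5 and the boundary is
#' the free parameter `a2`.  Only the original task variant has a
#' second-stage decision.
#'
#' @param params a [ddm_params()].
#' @param dq2 second-stage value difference of the visited state.
#' @param config a [task_config()].
#' @return Drift rate (numeric).
#' @export
stage2_drift <- function(params, dq2, config) {
  if (config$variant != "original")
    stop("the newer task variant has no second-stage decision")
  params$v2_base * dq2
}

#' Wiener first-passage-time log density
#'
#' Log density of hitting the boundary coded by `choice` (upper = choice 1)
#' at time `rt`, for a diffusion with unit diffusion coefficient, drift
#' `spec$v1`, boundary separation `spec$a1`, start fraction `spec$w1` and
#' non-decision time `spec$tau`.  Small-time/large-time series with
#' truncation tolerance 1e-7.  Data incompatible with the parameters
#' (`rt <= tau`, non-positive boundary) contribute `-Inf`.
#'
#' @param rt observed response time(s), seconds.
#' @param choice 1 (upper boundary) or 2 (lower), vectorized.
#' @param spec a [trial_ddm_spec()] or any list with `v1`, `a1`, `w1`, `tau`.
#' @return Log density, vectorized over `rt`/`choice`.
#' @export
wfpt_log_density <- function(rt, choice, spec) {
  n <- max(length(rt), length(choice))
  if (!isTRUE(spec$valid %||% TRUE) || spec$a1 <= 0)
    return(rep(-Inf, n))
  .wfpt_lpdf_cpp(rep_len(rt, n) - spec$tau, rep_len(as.integer(choice), n),
                 spec$v1, spec$a1, spec$w1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Analytic absorption probability at the upper boundary
#'
#' Closed-form probability that the diffusion is absorbed at the upper
#' boundary: `(1 - exp(-2 v a w)) / (1 - exp(-2 v a))` for nonzero drift,
#' and `w` in the driftless limit.  Serves as an independent oracle for the
#' density and the sampler.
#'
#' @param v drift rate.
#' @param a boundary separation (> 0).
#' @param w start fraction in (0, 1).
#' @return Probability of hitting the upper boundary.
#' @export
absorption_probability <- function(v, a, w) {
  stopifnot(a > 0, w > 0, w < 1)
  if (abs(v) < 1e-12) return(w)
  (1 - exp(-2 * v * a * w)) / (1 - exp(-2 * v * a))
}

#' Sample choices and response times from the diffusion
#'
#' Forward-simulates the two-boundary Wiener process by Euler steps with a
#' Brownian-bridge correction for within-step crossings (step 1e-4 s), adds
#' the non-decision time, and censors at the response deadline: samples whose
#' total time would exceed the deadline are returned as missed.
#'
#' @param spec a [trial_ddm_spec()].
#' @param deadline response deadline in seconds (`Inf` to disable).
#' @param n number of samples.
#' @param dt Euler step in seconds.
#' @return A `data.frame` with `choice` (1/2, `NA` when missed) and `rt`
#'   (seconds including non-decision time, `NA` when missed).
#' @export
sample_ddm <- function(spec, deadline = Inf, n = 1, dt = 1e-4) {
  if (!isTRUE(spec$valid %||% TRUE) || spec$a1 <= 0)
    stop("invalid diffusion spec: non-positive boundary")
  tmax <- if (is.finite(deadline)) max(deadline - spec$tau, 0) else 60
  m <- .wfpt_sample_cpp(n, spec$v1, spec$a1, spec$w1, tmax, dt)
  choice <- ifelse(m[, 1] == 0, NA_integer_, as.integer(m[, 1]))
  rt <- ifelse(m[, 1] == 0, NA_real_, m[, 2] + spec$tau)
  missed <- is.na(choice) | (is.finite(deadline) & rt > deadline)
  choice[missed] <- NA_integer_
  rt[missed] <- NA_real_
  data.frame(choice = choice, rt = rt)
}
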