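#' Hybrid learner parameters
#'
#' Container for the learning-stage free parameters: learning rate `alpha`,
#' eligibility weight `lam` (both in (0, 1)), and the softmax inverse
#' temperatures `beta_mb`, `beta_mf`, `beta_rep`, `beta2`.
#'
#' @param alpha learning rate in (0, 1).
#' @param lam eligibility parameter in (0, 1) weighting how strongly the
#'   end-of-trial reward prediction error reaches the first-stage value.
#' @param beta_mb,beta_mf,beta_rep,beta2 softmax weights (unconstrained).
#' @return A list of class `rl_params`.
#' @export
rl_params <- function(alpha, lam, beta_mb = 0, beta_mf = 0,
                      beta_rep = 0, beta2 = 0) {
  stopifnot(alpha > 0, alpha < 1, lam > 0, lam < 1)
  structure(list(alpha = alpha, lam = lam, beta_mb = beta_mb,
                 beta_mf = beta_mf, beta_rep = beta_rep, beta2 = beta2),
            class = "rl_params")
}

#' Initial cached-value state
#'
#' Creates the learner's cache at the start of a session: model-free
#' first-stage values, shared second-stage values (all at `q_initial`), the
#' transition estimate, and the transition tally.  In the original variant the
#' transition estimate starts in the tie state, which by the literal majority
#' rule maps to the "opposite" assignment `p(s2|a1) = 0.3`; in the newer
#' variant each stimulus pair starts at 0.5/0.5 until its first observed
#' transition.
#'
#' @param config a [task_config()].
#' @return A list of class `q_state` with elements `q_mf1` (stage-1 MF values,
#'   states x 2 actions), `q2` (second-stage values, states 2/3 x actions),
#'   `p_trans` (probability of reaching state 2 per stage-1 state and action),
#'   `counts` (original-variant transition tally) and `pair_known`.
#' @export
q_state_init <- function(config) {
  n_s1 <- if (config$variant == "original") 1L else 2L
  n_a2 <- if (config$variant == "original") 2L else 1L
  p <- if (config$variant == "original") {
    matrix(c(0.3, 0.7), nrow = 1)       # tie -> opposite assignment
  } else {
    matrix(0.5, nrow = 2, ncol = 2)
  }
  structure(list(
    q_mf1 = matrix(config$q_initial, n_s1, 2),
    q2 = matrix(config$q_initial, 2, n_a2),   # rows: states 2 and 3
    p_trans = p,
    counts = c(a1_s2 = 0, a2_s3 = 0, a1_s3 = 0, a2_s2 = 0),
    pair_known = c(FALSE, FALSE),
    variant = config$variant,
    q_initial = config$q_initial
  ), class = "q_state")
}

second_stage_value <- function(q, trial) {
  row <- trial$stage2_state - 1L
  col <- if (q$variant == "original") trial$stage2_choice else 1L
  q$q2[row, col]
}

#' Model-free first-stage update (SARSA with an eligibility-weighted reward step)
#'
#' Two-part update of the chosen first-stage value: first toward the value of
#' the chosen second-stage action, then an eligibility-weighted step toward
#' the trial's reward.  The second-stage value is read at its pre-trial value
#' in both parts, so this must run before [mf_update_stage2()].
#'
#' @param q a [q_state_init()] cache holding pre-trial values.
#' @param trial a single trial (list or one-row data frame with
#'   `stage1_state`, `stage1_choice`, `stage2_state`, `stage2_choice`,
#'   `reward` on the rescaled scale).
#' @param params learning parameters with `alpha` and `lam`.
#' @return The updated `q_state`.
#' @export
mf_update_stage1 <- function(q, trial, params) {
  if (is.na(trial$stage1_choice) ||
      (q$variant == "original" && is.na(trial$stage2_choice)))
    stop("missed trials cannot receive a model-free update")
  s1 <- trial$stage1_state
  c1 <- trial$stage1_choice
  q22 <- second_stage_value(q, trial)
  q11 <- q$q_mf1[s1, c1]
  q_prime <- q11 + params$alpha * (q22 - q11)
  q$q_mf1[s1, c1] <- q_prime + params$lam * params$alpha * (trial$reward - q22)
  q
}

#' Model-free second-stage update
#'
#' Moves the chosen second-stage value toward the obtained reward by `alpha`.
#'
#' @inheritParams mf_update_stage1
#' @return The updated `q_state`.
#' @export
mf_update_stage2 <- function(q, trial, params) {
  if (q$variant == "original" && is.na(trial$stage2_choice))
    stop("missed trials cannot receive a model-free update")
  row <- trial$stage2_state - 1L
  col <- if (q$variant == "original") trial$stage2_choice else 1L
  q$q2[row, col] <- q$q2[row, col] +
    params$alpha * (trial$reward - q$q2[row, col])
  q
}

#' Decay all non-selected cached values toward the initial value
#'
#' Every cached value not selected on this trial (the unchosen first-stage
#' action(s), the unchosen action of the visited second-stage state, and both
#' actions of the unvisited state) relaxes by `alpha` toward `q_initial`.
#' Pass a trial with missing choices to decay everything (missed trials).
#'
#' @inheritParams mf_update_stage1
#' @param q_initial decay target; defaults to the value stored in `q`.
#' @return The updated `q_state`.
#' @export
decay_unchosen <- function(q, trial, params, q_initial = q$q_initial) {
  sel1 <- matrix(FALSE, nrow(q$q_mf1), 2)
  sel2 <- matrix(FALSE, 2, ncol(q$q2))
  c1 <- trial$stage1_choice
  full <- !is.na(c1) &&
    (q$variant == "newer" || !is.na(trial$stage2_choice))
  if (full) {
    sel1[trial$stage1_state, c1] <- TRUE
    col <- if (q$variant == "original") trial$stage2_choice else 1L
    sel2[trial$stage2_state - 1L, col] <- TRUE
  }
  q$q_mf1[!sel1] <- q$q_mf1[!sel1] + params$alpha * (q_initial - q$q_mf1[!sel1])
  q$q2[!sel2] <- q$q2[!sel2] + params$alpha * (q_initial - q$q2[!sel2])
  q
}

#' Model-based first-stage action values
#'
#' Computes each first-stage action's value as the transition-probability
#' weighted expectation of the best value in the reachable second-stage
#' states, using the second-stage table shared with the model-free system.
#'
#' @param q a [q_state_init()] cache.
#' @param stage1_state first-stage state (1, or 1/2 in the newer variant).
#' @return Numeric length 2: the model-based value of actions 1 and 2.
#' @export
mb_values <- function(q, stage1_state = 1L) {
  best <- apply(q$q2, 1, max)
  p2 <- q$p_trans[stage1_state, ]
  p2 * best[1] + (1 - p2) * best[2]
}

#' Update the transition estimate from an observed transition
#'
#' Original variant: tallies the observed (action, second-stage state) pair
#' and assigns the true probabilities 0.7/0.3 by majority — if transitions
#' consistent with "action 1 commonly reaches state 2" outnumber the opposite
#' ones, `p(s2|a1) = p(s3|a2) = 0.7`, otherwise (including ties) the opposite
#' assignment.  Newer variant: a stimulus pair's mapping is set to its
#' veridical 0/1 values as soon as one transition of the pair is observed.
#'
#' @inheritParams mf_update_stage1
#' @param config a [task_config()].
#' @return The updated `q_state`.
#' @export
update_transition_model <- function(q, trial, config) {
  if (is.na(trial$stage1_choice)) return(q)
  c1 <- trial$stage1_choice
  s2 <- trial$stage2_state
  if (q$variant == "original") {
    key <- paste0("a", c1, "_s", s2)
    q$counts[key] <- q$counts[key] + 1
    common <- q$counts["a1_s2"] + q$counts["a2_s3"]
    rare <- q$counts["a1_s3"] + q$counts["a2_s2"]
    q$p_trans[1, ] <- if (common > rare) c(0.7, 0.3) else c(0.3, 0.7)
  } else {
    s1 <- trial$stage1_state
    if (!q$pair_known[s1]) {
      p <- as.numeric(s2 == 2L)
      q$p_trans[s1, c1] <- p
      q$p_trans[s1, 3L - c1] <- 1 - p
      q$pair_known[s1] <- TRUE
    }
  }
  q
}

subject_data <- function(trials, config) {
  na0 <- function(x) { x[is.na(x)] <- 0L; as.integer(x) }
  list(s1 = as.integer(trials$stage1_state),
       c1 = na0(trials$stage1_choice),
       rt1 = as.numeric(trials$stage1_rt),
       s2 = na0(trials$stage2_state),
       c2 = na0(trials$stage2_choice),
       rt2 = as.numeric(trials$stage2_rt),
       rew = as.numeric(trials$reward / config$reward_rescale),
       m1 = as.integer(trials$missed_stage1),
       m2 = as.integer(trials$missed_stage2))
}

split_subjects <- function(trials, config) {
  ids <- unique(trials$subject_id)
  out <- lapply(ids, function(id)
    subject_data(trials[trials$subject_id == id, , drop = FALSE], config))
  names(out) <- ids
  out
}

#' Per-trial Q-value trajectories and decision covariates
#'
#' Runs the hybrid learner forward over each subject's session at fixed
#' `alpha` and `lam` and emits, for every trial, the pre-choice value
#' differences of the two systems, the perseveration covariate, and the
#' second-stage value difference of the visited state (original variant).
#' Within a trial the update order is: read pre-trial values, model-free
#' stage-1 and stage-2 updates (both using pre-trial second-stage values),
#' transition-model update, then decay of all non-selected values.  Missed
#' trials receive no model-free updates; decay applies to every cached value.
#'
#' @param trials trial `data.frame` (raw rewards; rescaling is applied
#'   internally).
#' @param alpha,lam learning parameters, either scalars shared by all
#'   subjects or named vectors indexed by subject id.
#' @param config a [task_config()].
#' @return A `data.frame` with `subject_id`, `trial_index`, `dq_mf`, `dq_mb`,
#'   `rep`, `dq2`.
#' @export
compute_q_trajectories <- function(trials, alpha, lam, config) {
  ids <- unique(trials$subject_id)
  get_par <- function(p, id) {
    if (length(p) == 1L && is.null(names(p))) return(p)
    if (!id %in% names(p)) stop("no parameter value for subject ", id)
    p[[id]]
  }
  out <- lapply(ids, function(id) {
    tr <- trials[trials$subject_id == id, , drop = FALSE]
    d <- subject_data(tr, config)
    m <- .rl_sweep_cpp(d, get_par(alpha, id), get_par(lam, id),
                       variant_code(config), config$q_initial)
    data.frame(subject_id = id, trial_index = tr$trial_index,
               dq_mf = m[, "dq_mf"], dq_mb = m[, "dq_mb"],
               rep = m[, "rep"], dq2 = m[, "dq2"],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
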