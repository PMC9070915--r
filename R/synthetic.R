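#' Group-level generative truth
#'
#' Group means and SDs for every learning and decision-layer parameter, used
#' by [simulate_study()] to draw subject-level parameters.  Defaults are
#' mid-range values typical of two-step studies: moderate learning rate and
#' eligibility weighting (`alpha`, `lam` centred at 0 on the unconstrained
#' scale, i.e. 0.5 after the logistic), a stronger model-based than
#' model-free drift contribution, mild perseveration in drift and start
#' point, boundaries and non-decision time giving sub-second first-stage
#' decisions under the 2 s deadline, and all conflict coefficients at zero
#' (the null generative configuration for calibration runs).
#'
#' @param mu,sigma named lists overriding individual group means / SDs.
#' @return A list of class `group_truth` with named vectors `mu` and `sigma`.
#' @examples
#' truth <- group_truth(mu = list(v_mb_cv = -6))
#' truth$mu[["v_mb_cv"]]
#' @export
group_truth <- function(mu = list(), sigma = list()) {
  mu0 <- c(alpha = -1.5, lam = 3.5,
           beta_mb = 3, beta_mf = 2, beta_rep = 0.3, beta2 = 3,
           v_mb_base = 4, v_mb_cv = 0, v_mb_ca = 0, v_mb_int = 0,
           v_mf_base = 3, v_mf_cv = 0, v_mf_ca = 0, v_mf_int = 0,
           v_rep = 0.8, a1_base = 1.4, a_cv = 0, a_ca = 0, a_int = 0,
           s_rep = 0.5, v2_base = 4, a2 = 1.2, tau = 0.3)
  sd0 <- c(alpha = 0.8, lam = 0.5,
           beta_mb = 1, beta_mf = 1, beta_rep = 0.3, beta2 = 1,
           v_mb_base = 0.8, v_mb_cv = 0.5, v_mb_ca = 0.5, v_mb_int = 0.5,
           v_mf_base = 0.8, v_mf_cv = 0.5, v_mf_ca = 0.5, v_mf_int = 0.5,
           v_rep = 0.3, a1_base = 0.25, a_cv = 0.1, a_ca = 0.1, a_int = 0.1,
           s_rep = 0.2, v2_base = 1, a2 = 0.2, tau = 0.05)
  for (n in names(mu)) mu0[[n]] <- mu[[n]]
  for (n in names(sigma)) sd0[[n]] <- sigma[[n]]
  structure(list(mu = mu0, sigma = sd0), class = "group_truth")
}

#' Synthetic study design
#'
#' Sample sizes, task configuration and seed of one simulated study.  The
#' empirical datasets the defaults are modeled on had 115, 175 and 84
#' retained participants on the original task variant and 179 on the newer
#' one, with 201 trials per session.
#'
#' @param config a [task_config()].
#' @param n_subjects number of simulated participants.
#' @param n_trials trials per session (overrides the config's count).
#' @param seed integer seed; simulation is fully reproducible given it.
#' @param miss_probability optional independent per-trial lapse probability
#'   producing a missed stage-1 response on top of deadline-induced misses.
#' @return A list of class `study_config`.
#' @export
study_config <- function(config = task_config("original"), n_subjects = 115,
                         n_trials = config$n_trials, seed = 1L,
                         miss_probability = 0) {
  stopifnot(n_subjects >= 1, miss_probability >= 0, miss_probability < 1)
  config$n_trials <- as.integer(n_trials)
  structure(list(config = config, n_subjects = as.integer(n_subjects),
                 n_trials = as.integer(n_trials), seed = as.integer(seed),
                 miss_probability = miss_probability),
            class = "study_config")
}

reflect_fold <- function(x, lo, hi) {
  while (x < lo || x > hi) {
    if (x > hi) x <- 2 * hi - x
    if (x < lo) x <- 2 * lo - x
  }
  x
}

#' Simulate reward schedules
#'
#' Original variant: four independent reward probabilities (two options in
#' each second-stage state) following Gaussian random walks with SD 0.025,
#' reflected into \[0.25, 0.75\] by fold-back, initialized uniformly within
#' the bounds.  Newer variant: one integer payoff walk per second-stage state
#' over -4..5 with Gaussian increments (SD 2) rounded to integers and
#' reflected at the range ends.
#'
#' @param config a [task_config()].
#' @param n_trials number of trials.
#' @return A matrix (trials x options): columns `s2_o1, s2_o2, s3_o1, s3_o2`
#'   for the original variant, `s2, s3` for the newer one.
#' @export
simulate_reward_walks <- function(config, n_trials = config$n_trials) {
  lo <- config$walk_bounds[1]; hi <- config$walk_bounds[2]
  n_opt <- if (config$variant == "original") 4L else 2L
  walk <- matrix(NA_real_, n_trials, n_opt)
  colnames(walk) <- if (config$variant == "original")
    c("s2_o1", "s2_o2", "s3_o1", "s3_o2") else c("s2", "s3")
  for (k in seq_len(n_opt)) {
    if (config$variant == "original") {
      x <- runif(1, lo, hi)
      for (t in seq_len(n_trials)) {
        walk[t, k] <- x
        x <- reflect_fold(x + rnorm(1, 0, config$walk_sd), lo, hi)
      }
    } else {
      x <- sample(seq(lo, hi), 1)
      for (t in seq_len(n_trials)) {
        walk[t, k] <- x
        x <- reflect_fold(x + round(rnorm(1, 0, config$walk_sd)), lo, hi)
      }
    }
  }
  walk
}

#' Simulate one session of the two-step task
#'
#' Runs the generative loop of one subject: compute pre-choice Q-values and
#' conflict covariates, draw the first-stage response from the
#' conflict-modulated diffusion (or from the softmax rule), apply the
#' variant's transition, draw the second-stage response (original variant)
#' and reward, then apply the learning updates in the canonical order.
#' Responses whose diffusion passage time exceeds the deadline become missed
#' trials, as do optional independent lapses.
#'
#' @param rl an [rl_params()] (only `alpha`, `lam` and — under the softmax
#'   rule — the betas are used).
#' @param ddm a [ddm_params()].
#' @param study a [study_config()].
#' @param subject_id identifier written into the records.
#' @param choice_rule `"ddm"` (default) or `"softmax"`; the softmax rule
#'   generates choices from the learning-stage model with placeholder RTs,
#'   for recovery checks of the choice-only fit.
#' @param walks optional reward schedule from [simulate_reward_walks()].
#' @return A trial `data.frame` in the canonical log schema (raw rewards).
#' @export
simulate_session <- function(rl, ddm, study, subject_id = "s01",
                             choice_rule = c("ddm", "softmax"),
                             walks = NULL) {
  choice_rule <- match.arg(choice_rule)
  config <- study$config
  orig <- config$variant == "original"
  n <- study$n_trials
  if (is.null(walks)) walks <- simulate_reward_walks(config, n)
  q <- q_state_init(config)
  last_ok <- c(FALSE, FALSE); last_choice <- c(1L, 1L)
  rows <- vector("list", n)
  for (t in seq_len(n)) {
    s1 <- if (orig) 1L else sample(1:2, 1)
    dq_mf <- q$q_mf1[s1, 1] - q$q_mf1[s1, 2]
    qmb <- mb_values(q, s1)
    dq_mb <- qmb[1] - qmb[2]
    rep_t <- if (last_ok[s1]) (if (last_choice[s1] == 1L) 1 else -1) else 0
    conflict <- conflict_features(dq_mb, dq_mf, rep_t)

    lapse <- study$miss_probability > 0 && runif(1) < study$miss_probability
    if (choice_rule == "ddm") {
      spec1 <- trial_ddm_spec(ddm, conflict)
      if (!spec1$valid)
        stop("generative parameters produced a non-positive boundary")
      resp1 <- sample_ddm(spec1, deadline = config$deadline_s)
      c1 <- resp1$choice; rt1 <- resp1$rt
    } else {
      p1 <- plogis(rl$beta_mb * dq_mb + rl$beta_mf * dq_mf +
                     rl$beta_rep * rep_t)
      c1 <- if (runif(1) < p1) 1L else 2L
      rt1 <- 0.5
    }
    if (lapse) { c1 <- NA_integer_; rt1 <- NA_real_ }
    miss1 <- is.na(c1)

    s2 <- NA_integer_; c2 <- NA_integer_; rt2 <- NA_real_
    rew <- NA_real_; miss2 <- FALSE
    if (!miss1) {
      if (orig) {
        common <- runif(1) < config$common_transition_prob
        s2 <- if (c1 == 1L) (if (common) 2L else 3L) else
          (if (common) 3L else 2L)
        dq2 <- q$q2[s2 - 1L, 1] - q$q2[s2 - 1L, 2]
        spec2 <- list(v1 = stage2_drift(ddm, dq2, config), a1 = ddm$a2,
                      w1 = 0.5, tau = ddm$tau, valid = ddm$a2 > 0)
        if (choice_rule == "ddm") {
          resp2 <- sample_ddm(spec2, deadline = config$deadline_s)
          c2 <- resp2$choice; rt2 <- resp2$rt
        } else {
          p2 <- plogis(rl$beta2 * dq2)
          c2 <- if (runif(1) < p2) 1L else 2L
          rt2 <- 0.5
        }
        miss2 <- is.na(c2)
        if (!miss2) {
          pcol <- (s2 - 2L) * 2L + c2
          rew <- as.numeric(runif(1) < walks[t, pcol])
        }
      } else {
        # deterministic mapping: pair 1 sends action 1 to state 2,
        # pair 2 sends action 1 to state 3
        s2 <- if (s1 == 1L) (if (c1 == 1L) 2L else 3L) else
          (if (c1 == 1L) 3L else 2L)
        rew <- walks[t, s2 - 1L]
      }
    }

    rows[[t]] <- data.frame(
      subject_id = subject_id, trial_index = t, stage1_state = s1,
      stage1_choice = c1, stage1_rt = rt1, stage2_state = s2,
      stage2_choice = c2, stage2_rt = rt2, reward = rew,
      missed_stage1 = miss1, missed_stage2 = miss2,
      stringsAsFactors = FALSE)

    # learning updates at the rescaled reward scale
    trial <- list(stage1_state = s1, stage1_choice = c1,
                  stage2_state = s2, stage2_choice = c2,
                  reward = rew / config$reward_rescale)
    full <- !miss1 && !is.na(s2) && (!orig || !miss2)
    if (full) {
      q <- mf_update_stage1(q, trial, rl)
      q <- mf_update_stage2(q, trial, rl)
    }
    if (!miss1 && !is.na(s2)) q <- update_transition_model(q, trial, config)
    if (!full) trial$stage1_choice <- NA_integer_  # decay everything
    q <- decay_unchosen(q, trial, rl)

    last_ok[s1] <- !miss1 && (!orig || !miss2)
    if (!is.na(c1)) last_choice[s1] <- c1
  }
  do.call(rbind, rows)
}

#' Simulate a whole study
#'
#' Draws each subject's parameters from the group-level truth (Gaussian with
#' the stated transforms: logistic for `alpha`/`lam` inside the learner,
#' rejection below zero for boundary separations and non-decision time),
#' simulates one session per subject with an independent reward schedule, and
#' returns the trial log together with a manifest of every true value.
#'
#' @param truth a [group_truth()].
#' @param study a [study_config()].
#' @param choice_rule passed to [simulate_session()].
#' @return A list with `trials` (all subjects' records) and `manifest`
#'   (list: `group` truth and `subjects`, the per-subject draws).
#' @export
simulate_study <- function(truth, study, choice_rule = "ddm") {
  set.seed(study$seed)
  positive <- c("a1_base", "a2", "tau")
  ids <- sprintf("s%03d", seq_len(study$n_subjects))
  subj <- matrix(NA_real_, study$n_subjects, length(truth$mu),
                 dimnames = list(ids, names(truth$mu)))
  for (p in names(truth$mu)) {
    x <- rnorm(study$n_subjects, truth$mu[[p]], truth$sigma[[p]])
    if (p %in% positive) {
      bad <- which(x < 0)
      guard <- 0
      while (length(bad) && guard < 1000) {
        x[bad] <- rnorm(length(bad), truth$mu[[p]], truth$sigma[[p]])
        bad <- which(x < 0)
        guard <- guard + 1
      }
      x <- pmax(x, 1e-3)
    }
    subj[, p] <- x
  }
  trials <- do.call(rbind, lapply(seq_len(study$n_subjects), function(j) {
    pars <- as.list(subj[j, ])
    rl <- rl_params(alpha = plogis(pars$alpha), lam = plogis(pars$lam),
                    beta_mb = pars$beta_mb, beta_mf = pars$beta_mf,
                    beta_rep = pars$beta_rep, beta2 = pars$beta2)
    ddm <- ddm_params(v_mb_base = pars$v_mb_base, v_mb_cv = pars$v_mb_cv,
                      v_mb_ca = pars$v_mb_ca, v_mb_int = pars$v_mb_int,
                      v_mf_base = pars$v_mf_base, v_mf_cv = pars$v_mf_cv,
                      v_mf_ca = pars$v_mf_ca, v_mf_int = pars$v_mf_int,
                      v_rep = pars$v_rep, a1_base = pars$a1_base,
                      a_cv = pars$a_cv, a_ca = pars$a_ca, a_int = pars$a_int,
                      s_rep = pars$s_rep, v2_base = pars$v2_base,
                      a2 = pars$a2, tau = pars$tau)
    simulate_session(rl, ddm, study, subject_id = ids[j],
                     choice_rule = choice_rule)
  }))
  rownames(trials) <- NULL
  list(trials = trials,
       manifest = list(group = truth, subjects = as.data.frame(subj)))
}
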