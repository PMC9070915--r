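# Independent, flat re-implementation of the hybrid learner's forward sweep,
# written directly from the update equations, used as the trace oracle.
oracle_sweep <- function(trials, alpha, lam, config) {
  orig <- config$variant == "original"
  q0 <- config$q_initial
  nS1 <- if (orig) 1 else 2
  nA2 <- if (orig) 2 else 1
  q1 <- matrix(q0, nS1, 2)
  q2 <- matrix(q0, 2, nA2)
  p2 <- if (orig) matrix(c(0.3, 0.7), 1) else matrix(0.5, 2, 2)
  cnt <- c(a1s2 = 0, a2s3 = 0, a1s3 = 0, a2s2 = 0)
  known <- c(FALSE, FALSE)
  last_ok <- c(FALSE, FALSE)
  last_ch <- c(0L, 0L)
  n <- nrow(trials)
  out <- data.frame(dq_mf = numeric(n), dq_mb = numeric(n),
                    rep = numeric(n), dq2 = rep(NA_real_, n))
  for (t in seq_len(n)) {
    s1 <- trials$stage1_state[t]
    c1 <- trials$stage1_choice[t]
    s2 <- trials$stage2_state[t]
    c2 <- trials$stage2_choice[t]
    rew <- trials$reward[t] / config$reward_rescale
    m1 <- trials$missed_stage1[t]
    m2 <- trials$missed_stage2[t]
    out$dq_mf[t] <- q1[s1, 1] - q1[s1, 2]
    mx <- apply(q2, 1, max)
    qmb <- p2[s1, ] * mx[1] + (1 - p2[s1, ]) * mx[2]
    out$dq_mb[t] <- qmb[1] - qmb[2]
    out$rep[t] <- if (last_ok[s1]) (if (last_ch[s1] == 1L) 1 else -1) else 0
    have_c1 <- !m1 && !is.na(c1)
    if (orig && have_c1 && !is.na(s2))
      out$dq2[t] <- q2[s2 - 1, 1] - q2[s2 - 1, 2]
    sel1 <- matrix(FALSE, nS1, 2)
    sel2 <- matrix(FALSE, 2, nA2)
    full <- have_c1 && !is.na(s2) && (!orig || (!m2 && !is.na(c2)))
    if (full) {
      cc2 <- if (orig) c2 else 1L
      q22 <- q2[s2 - 1, cc2]
      q11 <- q1[s1, c1]
      qp <- q11 + alpha * (q22 - q11)
      q1[s1, c1] <- qp + lam * alpha * (rew - q22)
      q2[s2 - 1, cc2] <- q22 + alpha * (rew - q22)
      sel1[s1, c1] <- TRUE
      sel2[s2 - 1, cc2] <- TRUE
    }
    if (have_c1 && !is.na(s2)) {
      if (orig) {
        key <- paste0("a", c1, "s", s2)
        cnt[key] <- cnt[key] + 1
        p2[1, ] <- if (cnt["a1s2"] + cnt["a2s3"] > cnt["a1s3"] + cnt["a2s2"])
          c(0.7, 0.3) else c(0.3, 0.7)
      } else if (!known[s1]) {
        p <- as.numeric(s2 == 2)
        p2[s1, c1] <- p
        p2[s1, 3 - c1] <- 1 - p
        known[s1] <- TRUE
      }
    }
    q1[!sel1] <- q1[!sel1] + alpha * (q0 - q1[!sel1])
    q2[!sel2] <- q2[!sel2] + alpha * (q0 - q2[!sel2])
    last_ok[s1] <- have_c1 && (!orig || !m2)
    if (!is.na(c1)) last_ch[s1] <- c1
  }
  out
}

# Random sessions with arbitrary (non-model) choices, rewards and misses, for
# exercising the sweep over the full input space.
random_trials <- function(n, config, miss_rate = 0.05, subject_id = "s01") {
  orig <- config$variant == "original"
  m1 <- runif(n) < miss_rate
  c1 <- ifelse(m1, NA_integer_, sample(1:2, n, replace = TRUE))
  s1 <- if (orig) rep(1L, n) else sample(1:2, n, replace = TRUE)
  s2 <- ifelse(m1, NA_integer_, sample(2:3, n, replace = TRUE))
  m2 <- !m1 & orig & (runif(n) < miss_rate)
  c2 <- ifelse(m1 | m2, NA_integer_,
               if (orig) sample(1:2, n, replace = TRUE) else NA_integer_)
  full <- !m1 & (!orig | (!m2 & !is.na(c2)))
  rew <- ifelse(full,
                if (orig) rbinom(n, 1, 0.5) else sample(-4:5, n, replace = TRUE),
                NA_real_)
  rt1 <- ifelse(m1, NA_real_, runif(n, 0.25, 1.9))
  rt2 <- ifelse(m1 | m2 | !orig, NA_real_, runif(n, 0.25, 1.9))
  data.frame(subject_id = subject_id, trial_index = seq_len(n),
             stage1_state = s1, stage1_choice = c1, stage1_rt = rt1,
             stage2_state = s2, stage2_choice = c2, stage2_rt = rt2,
             reward = rew, missed_stage1 = m1, missed_stage2 = m2,
             stringsAsFactors = FALSE)
}

# numerical CDF of the first-passage time at one boundary, by quadrature of
# the package density on a fine grid
wfpt_numeric_cdf <- function(grid, choice, spec) {
  dens <- exp(wfpt_log_density(grid, choice, spec))
  c(0, cumsum((dens[-1] + dens[-length(dens)]) / 2 * diff(grid)))
}

# one subject with a controlled number of too-fast trials
make_exclusion_trials <- function(n, n_bad, id = "s01") {
  cfg <- task_config("original", n_trials = n)
  set.seed(2)
  tr <- random_trials(n, cfg, miss_rate = 0, subject_id = id)
  if (n_bad > 0) tr$stage1_rt[seq_len(n_bad)] <- 0.1   # below the 0.2 s floor
  tr
}

# build a minimal fit-shaped object from raw draw matrices
fake_fit <- function(chains, subject_ids = character()) {
  structure(list(chains = chains, rhat = gelman_rubin(chains),
                 subject_ids = subject_ids,
                 mcmc = mcmc_config(n_iter = nrow(chains[[1]]) * 2,
                                    n_warmup = nrow(chains[[1]]),
                                    preset = "desk")),
            class = "rlddm_fit")
}
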