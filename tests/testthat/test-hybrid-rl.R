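cfg_orig <- task_config("original")

trial1 <- list(stage1_state = 1L, stage1_choice = 1L, stage2_state = 2L,
               stage2_choice = 1L, reward = 1)

test_that("first-stage model-free update follows the two-part SARSA rule", {
  q <- q_state_init(cfg_orig)
  q$q_mf1[1, 1] <- 0.5
  q$q2[1, 1] <- 0.8
  p <- rl_params(alpha = 0.5, lam = 0.5)
  q2 <- mf_update_stage1(q, trial1, p)
  # 0.5 + 0.5*(0.8-0.5) = 0.65, then + 0.5*0.5*(1-0.8) = 0.70
  expect_equal(q2$q_mf1[1, 1], 0.70)
  # lambda = 0 drops the reward part
  q3 <- mf_update_stage1(q, trial1, rl_params(alpha = 0.5, lam = 1e-12))
  expect_equal(q3$q_mf1[1, 1], 0.65, tolerance = 1e-9)
  # alpha ~ 0 leaves the value unchanged
  q4 <- mf_update_stage1(q, trial1, rl_params(alpha = 1e-12, lam = 0.5))
  expect_equal(q4$q_mf1[1, 1], 0.5, tolerance = 1e-9)
  expect_error(mf_update_stage1(q, modifyList(trial1,
    list(stage1_choice = NA_integer_)), p), "missed")
})

test_that("second-stage update moves the chosen value toward reward", {
  q <- q_state_init(cfg_orig)
  q$q2[1, 1] <- 0.8
  p <- rl_params(alpha = 0.5, lam = 0.5)
  expect_equal(mf_update_stage2(q, trial1, p)$q2[1, 1], 0.9)
  # zero prediction error: unchanged
  expect_equal(mf_update_stage2(q, modifyList(trial1, list(reward = 0.8)),
                                p)$q2[1, 1], 0.8)
  # full replacement at alpha ~ 1
  expect_equal(mf_update_stage2(q, trial1,
    rl_params(alpha = 1 - 1e-12, lam = 0.5))$q2[1, 1], 1, tolerance = 1e-9)
})

test_that("non-selected values decay toward the initial value", {
  q <- q_state_init(cfg_orig)
  q$q2[2, 2] <- 0.9
  p <- rl_params(alpha = 0.5, lam = 0.5)
  qd <- decay_unchosen(q, trial1, p)
  expect_equal(qd$q2[2, 2], 0.7)                 # 0.9 + 0.5*(0.5-0.9)
  expect_equal(qd$q2[1, 1], q$q2[1, 1])          # chosen cell untouched
  expect_equal(qd$q_mf1[1, 1], q$q_mf1[1, 1])
  # fixed point at the initial value
  expect_equal(qd$q_mf1[1, 2], 0.5)
  # repeated decay converges geometrically
  x <- q
  x$q2[2, 2] <- 0.9
  for (i in 1:60) x <- decay_unchosen(x, trial1, p)
  expect_equal(x$q2[2, 2], 0.5, tolerance = 1e-9)
})

test_that("model-based values take the transition-weighted best successor", {
  q <- q_state_init(cfg_orig)
  q$p_trans[1, ] <- c(0.7, 0.3)
  q$q2[1, ] <- c(0.6, 0.1)   # state 2 max = 0.6
  q$q2[2, ] <- c(0.2, 0.4)   # state 3 max = 0.4
  v <- mb_values(q, 1L)
  expect_equal(v, c(0.54, 0.46))
  expect_equal(v[1] - v[2], 0.08)
  # equal maxima: symmetry
  q$q2[2, ] <- c(0.6, 0.3)
  v2 <- mb_values(q, 1L)
  expect_equal(v2[1], v2[2])
  # deterministic transitions collapse to the reached state's maximum
  cfg_new <- task_config("newer")
  qn <- q_state_init(cfg_new)
  qn$p_trans[1, ] <- c(1, 0)
  qn$q2[, 1] <- c(0.8, 0.2)
  expect_equal(mb_values(qn, 1L), c(0.8, 0.2))
})

test_that("original-variant transition model follows the majority rule", {
  q <- q_state_init(cfg_orig)
  # seed the counts: a1->s2 10, a2->s3 8, a1->s3 3, a2->s2 4
  q$counts <- c(a1_s2 = 9, a2_s3 = 8, a1_s3 = 3, a2_s2 = 4)
  q <- update_transition_model(q, trial1, cfg_orig)   # a1 -> s2
  expect_equal(unname(q$counts["a1_s2"]), 10)
  expect_equal(q$p_trans[1, ], c(0.7, 0.3))           # 18 > 7
  # tie (including all-zero counts) takes the opposite assignment
  q0 <- q_state_init(cfg_orig)
  expect_equal(q0$p_trans[1, ], c(0.3, 0.7))
})

test_that("newer-variant transitions snap to veridical on first observation", {
  cfg_new <- task_config("newer")
  q <- q_state_init(cfg_new)
  expect_equal(q$p_trans[1, ], c(0.5, 0.5))
  tr <- list(stage1_state = 1L, stage1_choice = 2L, stage2_state = 3L,
             stage2_choice = NA, reward = 0.2)
  q <- update_transition_model(q, tr, cfg_new)
  expect_equal(q$p_trans[1, ], c(1, 0))   # complement filled in
  expect_equal(q$p_trans[2, ], c(0.5, 0.5))
  # later conflicting observations do not overwrite the learned mapping
  q <- update_transition_model(q, modifyList(tr, list(stage1_choice = 1L)),
                               cfg_new)
  expect_equal(q$p_trans[1, ], c(1, 0))
})

test_that("trajectories start at zero covariates and match the trace oracle", {
  for (variant in c("original", "newer")) {
    cfg <- task_config(variant, n_trials = 60)
    set.seed(101)
    for (i in 1:50) {
      tr <- random_trials(60, cfg, miss_rate = if (i %% 3) 0.08 else 0)
      alpha <- runif(1, 0.05, 0.95)
      lam <- runif(1, 0.05, 0.95)
      got <- compute_q_trajectories(tr, alpha, lam, cfg)
      want <- oracle_sweep(tr, alpha, lam, cfg)
      expect_equal(got$dq_mf, want$dq_mf, tolerance = 1e-12)
      expect_equal(got$dq_mb, want$dq_mb, tolerance = 1e-12)
      expect_equal(got$rep, want$rep, tolerance = 1e-12)
      expect_equal(got$dq2, want$dq2, tolerance = 1e-12)
      expect_equal(got$dq_mf[1], 0)
      expect_equal(got$dq_mb[1], 0)
      expect_equal(got$rep[1], 0)
    }
  }
})

test_that("missed trials leave no model-free trace, only decay", {
  cfg <- task_config("original", n_trials = 3)
  tr <- random_trials(3, cfg, miss_rate = 0)
  tr$missed_stage2[2] <- TRUE
  tr$stage2_choice[2] <- NA
  tr$stage2_rt[2] <- NA
  tr$reward[2] <- NA
  got <- compute_q_trajectories(tr, 0.5, 0.5, cfg)
  # covariates on trial 3 equal a pure-decay evolution of trial 2's state
  want <- oracle_sweep(tr, 0.5, 0.5, cfg)
  expect_equal(got$dq_mf[3], want$dq_mf[3], tolerance = 1e-12)
  # rep is zeroed after a missed stage
  expect_equal(got$rep[3], 0)
})

test_that("cached values stay inside [0,1] for binary rewards", {
  cfg <- task_config("original", n_trials = 120)
  set.seed(77)
  tr <- random_trials(120, cfg, miss_rate = 0.05)
  q <- q_state_init(cfg)
  p <- rl_params(alpha = 0.7, lam = 0.9)
  for (t in seq_len(nrow(tr))) {
    trial <- as.list(tr[t, ])
    trial$reward <- trial$reward / cfg$reward_rescale
    full <- !trial$missed_stage1 && !is.na(trial$stage2_choice)
    if (full) {
      q <- mf_update_stage1(q, trial, p)
      q <- mf_update_stage2(q, trial, p)
    }
    if (!is.na(trial$stage1_choice)) q <- update_transition_model(q, trial, cfg)
    if (!full) trial$stage1_choice <- NA_integer_
    q <- decay_unchosen(q, trial, p)
    expect_true(all(q$q_mf1 >= 0 & q$q_mf1 <= 1))
    expect_true(all(q$q2 >= 0 & q$q2 <= 1))
  }
})

test_that("a repeatedly chosen option's value converges to its reward rate", {
  cfg <- task_config("original")
  q <- q_state_init(cfg)
  p <- rl_params(alpha = 0.1, lam = 0.5)
  set.seed(12)
  trial <- list(stage1_state = 1L, stage1_choice = 1L, stage2_state = 2L,
                stage2_choice = 1L, reward = NA)
  vals <- numeric(1e4)
  for (t in 1:1e4) {
    trial$reward <- rbinom(1, 1, 0.7)
    q <- mf_update_stage2(q, trial, p)
    vals[t] <- q$q2[1, 1]
  }
  expect_equal(mean(vals[5001:10000]), 0.7, tolerance = 0.02)
})

test_that("model-based values are bounded by the successor-state extremes", {
  cfg <- task_config("original")
  set.seed(9)
  for (i in 1:100) {
    q <- q_state_init(cfg)
    q$q2[] <- runif(4)
    q$p_trans[1, ] <- runif(2)
    v <- mb_values(q, 1L)
    best <- apply(q$q2, 1, max)
    expect_true(all(v >= min(best) - 1e-12 & v <= max(best) + 1e-12))
  }
})
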