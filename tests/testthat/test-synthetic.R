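test_that("reward walks respect their reflecting bounds and increments", {
  cfg <- task_config("original", n_trials = 3000)
  set.seed(71)
  w <- simulate_reward_walks(cfg)
  expect_equal(dim(w), c(3000, 4))
  expect_true(all(w >= 0.25 & w <= 0.75))
  # interior increments are Gaussian with the configured SD
  d <- diff(w[, 1])
  interior <- w[-nrow(w), 1] > 0.3 & w[-nrow(w), 1] < 0.7
  ks <- suppressWarnings(ks.test(d[interior], "pnorm", 0, cfg$walk_sd))
  expect_gt(ks$p.value, 0.01)
  # a zero-SD walk is constant
  cfg0 <- task_config("original", n_trials = 50, walk_sd = 0)
  w0 <- simulate_reward_walks(cfg0)
  expect_true(all(apply(w0, 2, sd) == 0))
})

test_that("newer-variant walks are integer payoffs within -4..5", {
  cfg <- task_config("newer", n_trials = 2000)
  set.seed(72)
  w <- simulate_reward_walks(cfg)
  expect_equal(dim(w), c(2000, 2))
  expect_true(all(w >= -4 & w <= 5))
  expect_true(all(w == round(w)))
})

test_that("null drift produces unbiased first-stage choices", {
  set.seed(73)
  rl <- rl_params(alpha = 0.2, lam = 0.9)
  ddm <- ddm_params(v_mb_base = 0, v_mf_base = 0, v_rep = 0, s_rep = 0,
                    a1_base = 1.2, v2_base = 0, a2 = 1.2, tau = 0.3)
  st <- study_config(task_config("original"), n_subjects = 1, n_trials = 201,
                    seed = 73)
  choices <- unlist(lapply(1:25, function(i)
    simulate_session(rl, ddm, st)$stage1_choice))
  expect_lt(abs(mean(choices == 1, na.rm = TRUE) - 0.5), 0.02)
})

test_that("sessions respect the transition structure and the deadline", {
  set.seed(74)
  st <- study_config(task_config("original"), n_subjects = 10, n_trials = 201,
                    seed = 74)
  sim <- simulate_study(group_truth(), st)
  tr <- sim$trials
  ok <- !tr$missed_stage1
  common <- (tr$stage1_choice[ok] == 1 & tr$stage2_state[ok] == 2) |
    (tr$stage1_choice[ok] == 2 & tr$stage2_state[ok] == 3)
  expect_lt(abs(mean(common) - 0.7), 0.03)
  expect_true(all(tr$stage1_rt[!tr$missed_stage1] <= 2))
  expect_true(all(tr$stage2_rt[!is.na(tr$stage2_rt)] <= 2))
  expect_true(all(tr$reward[!is.na(tr$reward)] %in% c(0, 1)))
  # a session passes its own validator
  validate_trial_log(tr, st$config)
})

test_that("study simulation is deterministic given the seed", {
  st <- study_config(task_config("original"), n_subjects = 3, n_trials = 60,
                    seed = 75)
  s1 <- simulate_study(group_truth(), st)
  s2 <- simulate_study(group_truth(), st)
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$manifest$subjects, s2$manifest$subjects)
  f1 <- tempfile(); f2 <- tempfile()
  write_trial_log(s1$trials, f1); write_trial_log(s2$trials, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("zero group SDs collapse the hierarchy to identical subjects", {
  sigma0 <- as.list(setNames(rep(1e-12, 23), names(group_truth()$mu)))
  truth <- group_truth(sigma = sigma0)
  st <- study_config(task_config("original"), n_subjects = 4, n_trials = 30,
                    seed = 76)
  sim <- simulate_study(truth, st)
  subj <- sim$manifest$subjects
  expect_true(all(apply(subj, 2, function(x) diff(range(x))) < 1e-9))
  expect_true(all(plogis(subj$alpha) > 0 & plogis(subj$alpha) < 1))
})

test_that("lapse probability feeds the exclusion filter", {
  st <- study_config(task_config("original"), n_subjects = 4, n_trials = 100,
                    seed = 77, miss_probability = 0.4)
  sim <- simulate_study(group_truth(), st)
  expect_gt(mean(sim$trials$missed_stage1), 0.2)
  rep <- apply_exclusions(sim$trials, st$config)$report
  expect_true(any(rep$excluded))
})

test_that("action conflict is rarer in the newer task variant", {
  set.seed(78)
  truth <- group_truth()
  st_o <- study_config(task_config("original"), n_subjects = 12,
                       n_trials = 201, seed = 78)
  st_n <- study_config(task_config("newer"), n_subjects = 12, n_trials = 201,
                       seed = 78)
  prop_ac <- function(sim, st) {
    man <- sim$manifest$subjects
    al <- setNames(plogis(man$alpha), rownames(man))
    lm <- setNames(plogis(man$lam), rownames(man))
    qt <- compute_q_trajectories(sim$trials, al, lm, st$config)
    mean(action_conflict(qt$dq_mb, qt$dq_mf))
  }
  p_orig <- prop_ac(simulate_study(truth, st_o), st_o)
  p_new <- prop_ac(simulate_study(truth, st_n), st_n)
  expect_lt(p_new, p_orig)
})

test_that("simulated sessions are likelier under their true parameters", {
  set.seed(79)
  cfg <- task_config("original", n_trials = 150)
  st <- study_config(cfg, n_subjects = 6, n_trials = 150, seed = 79)
  truth <- group_truth()
  sim <- simulate_study(truth, st)
  man <- sim$manifest$subjects
  subj <- rlddmConflict:::split_subjects(sim$trials, cfg)
  names_ddm <- c("v_mb_base", "v_mb_cv", "v_mb_ca", "v_mb_int", "v_mf_base",
                 "v_mf_cv", "v_mf_ca", "v_mf_int", "v_rep", "a1_base", "a_cv",
                 "a_ca", "a_int", "s_rep", "v2_base", "a2", "tau")
  diffs <- vapply(seq_along(subj), function(j) {
    id <- names(subj)[j]
    qt <- compute_q_trajectories(sim$trials[sim$trials$subject_id == id, ],
                                 plogis(man[id, "alpha"]),
                                 plogis(man[id, "lam"]), cfg)
    d <- subj[[j]]
    d$dq_mf <- qt$dq_mf; d$dq_mb <- qt$dq_mb; d$rep <- qt$rep; d$dq2 <- qt$dq2
    th_true <- matrix(unlist(man[id, names_ddm]), ncol = 1,
                      dimnames = list(names_ddm, NULL))
    ll_true <- rlddmConflict:::.ll_ddm_all_cpp(
      list(d), rlddmConflict:::assemble_ddm_theta(th_true), 0L, 0L, 0.2)
    # perturb by two group SDs in a direction keeping constraints satisfied
    th_bad <- th_true
    th_bad["v_mb_base", ] <- th_bad["v_mb_base", ] + 2 * truth$sigma[["v_mb_base"]]
    th_bad["a1_base", ] <- th_bad["a1_base", ] + 2 * truth$sigma[["a1_base"]]
    th_bad["tau", ] <- max(th_bad["tau", ] - 2 * truth$sigma[["tau"]], 0.01)
    ll_bad <- rlddmConflict:::.ll_ddm_all_cpp(
      list(d), rlddmConflict:::assemble_ddm_theta(th_bad), 0L, 0L, 0.2)
    expect_true(is.finite(ll_true))
    ll_true - ll_bad
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})
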