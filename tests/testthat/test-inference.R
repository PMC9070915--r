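test_that("split R-hat separates converged from divergent chain sets", {
  set.seed(61)
  m <- matrix(rnorm(4000), 2000, 2, dimnames = list(NULL, c("a", "b")))
  # identical chains: only the split-half contrast remains
  expect_equal(unname(gelman_rubin(list(m, m))), c(1, 1), tolerance = 1e-2)
  # a constant quantity is reported as converged, not NaN
  k <- matrix(1, 100, 1, dimnames = list(NULL, "c"))
  expect_equal(unname(gelman_rubin(list(k, k))), 1)
  # chains from one distribution: near 1
  c1 <- matrix(rnorm(5000), ncol = 1, dimnames = list(NULL, "x"))
  c2 <- matrix(rnorm(5000), ncol = 1, dimnames = list(NULL, "x"))
  c3 <- matrix(rnorm(5000), ncol = 1, dimnames = list(NULL, "x"))
  expect_lt(gelman_rubin(list(c1, c2, c3))["x"], 1.01)
  # well-separated chains: far above the threshold
  far <- matrix(rnorm(5000, 10), ncol = 1, dimnames = list(NULL, "x"))
  expect_gt(gelman_rubin(list(c1, far))["x"], 3)
  expect_error(gelman_rubin(list(c1)), "two chains")
})

test_that("posterior summaries apply the credible-interval significance rule", {
  set.seed(62)
  draws <- cbind(pos = rnorm(4000, 3, 0.5), zero = rnorm(4000, 0.2, 1))
  fit <- fake_fit(list(draws[1:2000, ], draws[2001:4000, ]))
  s <- summarize_posterior(fit, derived = FALSE)
  expect_true(s$significant[s$parameter == "pos"])
  expect_false(s$significant[s$parameter == "zero"])
  expect_true(all(s$ci_low <= s$median & s$median <= s$ci_high))
})

test_that("derived conflict effects are summarized from per-draw sums", {
  set.seed(63)
  n <- 6000
  # skewed components make the median of the sum differ from summed medians
  base <- exp(rnorm(n, 0, 0.8)) - 1
  draws <- cbind(`mu.v_mb_cv` = base, `mu.v_mb_int` = -2 * base + rnorm(n, 0, 0.1),
                 `mu.v_mf_cv` = rnorm(n), `mu.v_mf_int` = rnorm(n),
                 `mu.v_mb_ca` = rnorm(n), `mu.v_mf_ca` = rnorm(n),
                 `mu.a_cv` = rnorm(n), `mu.a_int` = rnorm(n))
  fit <- fake_fit(list(draws[1:3000, ], draws[3001:6000, ]))
  s <- summarize_posterior(fit)
  got <- s$median[s$parameter == "derived.v_mb_cv_plus_int"]
  want <- median(draws[, "mu.v_mb_cv"] + draws[, "mu.v_mb_int"])
  naive <- median(draws[, "mu.v_mb_cv"]) + median(draws[, "mu.v_mb_int"])
  expect_equal(got, want)
  expect_false(isTRUE(all.equal(got, naive, tolerance = 1e-3)))
})

test_that("subject point estimates are posterior medians on the unit scale", {
  set.seed(64)
  a1 <- rnorm(3000, 0.4, 0.7)
  a2 <- rnorm(3000, -1, 0.5)
  l1 <- rnorm(3000, 2, 1)
  l2 <- rnorm(3000, 0, 1)
  draws <- cbind(`theta.alpha.s01` = a1, `theta.alpha.s02` = a2,
                 `theta.lam.s01` = l1, `theta.lam.s02` = l2)
  fit <- fake_fit(list(draws[1:1500, ], draws[1501:3000, ]),
                  subject_ids = c("s01", "s02"))
  pts <- extract_subject_point_estimates(fit)
  # matches an independent sorting-based median of the transformed draws
  sort_median <- function(x) {
    s <- sort(plogis(x))
    (s[length(s) / 2] + s[length(s) / 2 + 1]) / 2
  }
  expect_equal(unname(pts$alpha["s01"]), sort_median(a1), tolerance = 1e-12)
  expect_equal(unname(pts$alpha["s02"]), sort_median(a2), tolerance = 1e-12)
  expect_equal(unname(pts$lam["s02"]), sort_median(l2), tolerance = 1e-12)
  expect_true(all(unlist(pts) > 0 & unlist(pts) < 1))
})

test_that("null softmax weights predict chance choice probabilities", {
  cfg <- task_config("original", n_trials = 80)
  set.seed(65)
  tr <- random_trials(80, cfg, miss_rate = 0)
  subj <- rlddmConflict:::split_subjects(tr, cfg)
  theta <- matrix(c(0, 0, 0, 0, 0, 0), 6, 1)   # alpha/lam irrelevant here
  ll <- rlddmConflict:::.ll_stage1_all_cpp(subj, theta, 0L, cfg$q_initial, 0.2)
  n_terms <- sum(tr$stage1_rt >= 0.2, na.rm = TRUE) +
    sum(tr$stage2_rt >= 0.2 & !is.na(tr$stage2_choice), na.rm = TRUE)
  expect_equal(ll[1], n_terms * log(0.5))
})

test_that("the choice-only fit recovers generative softmax weights", {
  st <- study_config(task_config("original"), n_subjects = 10, n_trials = 120,
                    seed = 301)
  truth <- group_truth()
  sim <- simulate_study(truth, st, choice_rule = "softmax")
  mc <- mcmc_config(n_iter = 500, n_warmup = 200, seed = 17, n_scans = 2,
                    preset = "desk")
  fit <- fit_stage1_rl(sim$trials, st$config, mc)
  s <- summarize_posterior(fit, derived = FALSE)
  for (p in c("beta_mb", "beta_mf")) {
    row <- s[s$parameter == paste0("mu.", p), ]
    expect_lt(row$ci_low, truth$mu[[p]])
    expect_gt(row$ci_high, truth$mu[[p]])
    expect_gt(row$median, 0)
  }
  # learning parameters on the unit scale land in a sane range
  pts <- extract_subject_point_estimates(fit)
  expect_true(all(pts$alpha > 0 & pts$alpha < 1))
  expect_true(all(pts$lam > 0 & pts$lam < 1))
})

test_that("a strong negative value-conflict drift effect is recovered with a
           consistent sign by the two-step and reduced procedures", {
  st <- study_config(task_config("original"), n_subjects = 8, n_trials = 150,
                    seed = 401)
  truth <- group_truth(mu = list(v_mb_cv = -10), sigma = list(v_mb_cv = 0.5))
  sim <- simulate_study(truth, st)
  tr <- apply_exclusions(sim$trials, st$config)$retained
  mc <- mcmc_config(n_iter = 400, n_warmup = 150, seed = 23, n_scans = 2,
                    preset = "desk")
  fit1 <- fit_stage1_rl(tr, st$config, mc)
  pts <- extract_subject_point_estimates(fit1)
  qt <- compute_q_trajectories(tr, pts$alpha, pts$lam, st$config)
  fit2 <- fit_stage2_ddm(tr, qt, st$config, mc, model = "between")
  s2 <- summarize_posterior(fit2, derived = FALSE)
  med_two_step <- s2$median[s2$parameter == "mu.v_mb_cv"]
  expect_lt(med_two_step, 0)
  fit_red <- fit_reduced_single_step(tr, st$config, mc, model = "between")
  sr <- summarize_posterior(fit_red, derived = FALSE)
  med_reduced <- sr$median[sr$parameter == "mu.v_mb_cvsq"]
  expect_lt(med_reduced, 0)
})

test_that("within-system and newer-variant models fit without degeneracies", {
  mc <- mcmc_config(n_iter = 120, n_warmup = 50, seed = 71, n_scans = 1,
                    preset = "desk")
  # newer variant: two stage-1 pairs, no second-stage decision parameters
  st_n <- study_config(task_config("newer"), n_subjects = 3, n_trials = 60,
                       seed = 501)
  sim_n <- simulate_study(group_truth(), st_n)
  spec_n <- hierarchical_spec("reduced_between", st_n$config)
  expect_false(any(c("v2_base", "a2", "beta2") %in% spec_n$name))
  fit_n <- fit_reduced_single_step(sim_n$trials, st_n$config, mc,
                                   model = "between")
  expect_true(all(is.finite(summarize_posterior(fit_n)$median)))
  # within-system conflict model on the original variant
  st_o <- study_config(task_config("original"), n_subjects = 3, n_trials = 60,
                       seed = 502)
  sim_o <- simulate_study(group_truth(), st_o)
  qt <- compute_q_trajectories(sim_o$trials, 0.2, 0.9, st_o$config)
  fit_w <- fit_stage2_ddm(sim_o$trials, qt, st_o$config, mc, model = "within")
  sw <- summarize_posterior(fit_w)
  expect_true(all(is.finite(sw$median)))
  expect_true(all(c("mu.v_mb_within", "mu.a_mf_within") %in% sw$parameter))
})

test_that("prior-predictive draws give finite likelihoods after rejection", {
  cfg <- task_config("original", n_trials = 40)
  spec <- hierarchical_spec("reduced_between", cfg)
  set.seed(66)
  n_ok <- 0; n_tot <- 40
  st <- study_config(cfg, n_subjects = 1, n_trials = 40, seed = 1)
  sim <- simulate_study(group_truth(), st)
  subj <- rlddmConflict:::split_subjects(sim$trials, cfg)
  for (i in seq_len(n_tot)) {
    # draw subject-level parameters near the prior means at moderate scale
    # (constraint rejection: boundary/tau must stay positive, rt > tau)
    th <- rnorm(nrow(spec), spec$init_mu, pmin(spec$init_sigma, 2))
    repeat {
      bad <- th < spec$theta_lower
      if (!any(bad)) break
      th[bad] <- rnorm(sum(bad), spec$init_mu[bad], 0.1)
    }
    th[spec$name == "tau"] <- min(th[spec$name == "tau"], 0.2)
    thm <- matrix(th, ncol = 1, dimnames = list(spec$name, NULL))
    ll <- rlddmConflict:::.ll_reduced_all_cpp(
      subj, rlddmConflict:::assemble_ddm_theta(thm, 2), 2L, 0L,
      cfg$q_initial, 0.2)
    if (is.finite(ll)) n_ok <- n_ok + 1
  }
  expect_gte(n_ok / n_tot, 0.99)
})
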