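#' MCMC settings
#'
#' Chain settings for the hierarchical fits.  The `"paper"` preset runs 3
#' chains of 10,000 iterations (4,000 for the reduced single-pass models)
#' with 1,000 warmup iterations; the `"desk"` preset (3 chains x 1,500
#' iterations, 500 warmup) is sized for interactive work and the test suite.
#'
#' @param n_chains number of chains (>= 2 for convergence diagnostics).
#' @param n_iter total iterations per chain, warmup included.
#' @param n_warmup warmup (adaptation) iterations, discarded from summaries.
#' @param seed integer seed; each chain derives its own stream from it.
#' @param rhat_threshold convergence flag threshold for split R-hat.
#' @param n_scans full update sweeps (subject and group levels) performed per
#'   recorded iteration; extra sweeps act as internal thinning and improve
#'   mixing per stored draw.
#' @param preset `"paper"` or `"desk"`; explicit arguments override it.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3, n_iter = NULL, n_warmup = NULL,
                        seed = 1L, rhat_threshold = 1.1, n_scans = 3,
                        preset = c("paper", "desk")) {
  preset <- match.arg(preset)
  if (is.null(n_iter)) n_iter <- if (preset == "paper") 10000L else 1500L
  if (is.null(n_warmup)) n_warmup <- if (preset == "paper") 1000L else 500L
  stopifnot(n_warmup < n_iter, n_chains >= 2)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_warmup = as.integer(n_warmup), seed = as.integer(seed),
                 rhat_threshold = rhat_threshold,
                 n_scans = as.integer(n_scans)),
            class = "mcmc_config")
}

# univariate slice sampler (stepping out + shrinkage), used for group-level
# conditionals whose truncation terms break conjugacy
slice_sample1 <- function(x0, logf, w = 1, lower = -Inf, upper = Inf,
                          max_steps = 50) {
  lf0 <- logf(x0)
  if (!is.finite(lf0)) return(x0)
  logy <- lf0 - stats::rexp(1)
  u <- runif(1) * w
  L <- max(x0 - u, lower)
  R <- min(L + w, upper)
  k <- max_steps
  while (k > 0 && L > lower && logf(L) > logy) { L <- max(L - w, lower); k <- k - 1 }
  k <- max_steps
  while (k > 0 && R < upper && logf(R) > logy) { R <- min(R + w, upper); k <- k - 1 }
  for (i in 1:100) {
    x1 <- runif(1, L, R)
    if (logf(x1) > logy) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
  x0
}

# log density of subject-level parameters under the (possibly zero-truncated)
# group-level Gaussian
theta_prior_lp <- function(theta, mu, sigma, lower) {
  lp <- dnorm(theta, mu, sigma, log = TRUE)
  if (lower > -Inf)
    lp <- lp - pnorm(lower, mu, sigma, lower.tail = FALSE, log.p = TRUE)
  lp
}

# One hierarchical model fit by Metropolis-within-Gibbs:
#  - subject-level parameters: per-parameter Gaussian random-walk proposals,
#    proposed for all subjects at once (their conditionals are independent),
#    with Robbins-Monro step adaptation toward 0.44 acceptance during warmup
#  - unconstrained group means: conjugate Gibbs
#  - constrained group means and all group SDs: slice sampling on the exact
#    conditional (including the truncation normalization of the subject prior)
# loglik(theta_matrix) must return the per-subject data log-likelihood.
hier_mcmc <- function(subjects, ptab, loglik, mcmc, init_theta = NULL) {
  P <- nrow(ptab)
  J <- length(subjects)
  ids <- names(subjects)
  if (is.null(ids)) ids <- sprintf("s%02d", seq_len(J))
  qnames <- c(paste0("mu.", ptab$name), paste0("sigma.", ptab$name),
              as.vector(t(outer(ptab$name, ids,
                                function(p, s) paste0("theta.", p, ".", s)))))
  chains <- vector("list", mcmc$n_chains)
  accept <- matrix(0, P, J, dimnames = list(ptab$name, ids))

  for (ch in seq_len(mcmc$n_chains)) {
    set.seed(mcmc$seed + 7919L * ch)
    mu <- ptab$init_mu
    sigma <- ptab$init_sigma
    base <- if (is.null(init_theta)) matrix(mu, P, J) else init_theta
    theta <- base + 0.05 * ptab$init_sigma * matrix(rnorm(P * J), P, J)
    theta <- pmax(theta, ptab$theta_lower + 1e-6 * (ptab$theta_lower > -Inf))
    rownames(theta) <- ptab$name
    ll <- loglik(theta)
    tries <- 0
    while (any(!is.finite(ll)) && tries < 100) {
      bad <- !is.finite(ll)
      theta[, bad] <- base[, bad, drop = FALSE] + 0.9^tries * 0.02 *
        ptab$init_sigma * matrix(rnorm(P * sum(bad)), P, sum(bad))
      theta <- pmax(theta, ptab$theta_lower + 1e-6 * (ptab$theta_lower > -Inf))
      ll <- loglik(theta)
      tries <- tries + 1
    }
    if (any(!is.finite(ll)))
      stop("could not find a finite-likelihood starting point")
    step <- matrix(ptab$step0, P, J)
    n_keep <- mcmc$n_iter - mcmc$n_warmup
    draws <- matrix(NA_real_, n_keep, length(qnames),
                    dimnames = list(NULL, qnames))
    acc_count <- matrix(0, P, J)
    # adaptive joint block proposals per subject (empirical covariance,
    # Haario-style), to cross posterior correlations the scalar updates
    # cannot traverse efficiently
    nc_step <- pmax(ptab$step0, 0.2)
    blk_scale <- rep(0.3, J)
    blk_chol <- replicate(J, diag(ptab$step0, P), simplify = FALSE)
    wf_n <- 0
    wf_mean <- matrix(0, P, J)
    wf_M2 <- array(0, c(P, P, J))

    n_scans <- mcmc$n_scans %||% 1L
    sweep_i <- 0L
    for (iter in seq_len(mcmc$n_iter)) {
      for (scan in seq_len(n_scans)) {
      sweep_i <- sweep_i + 1L
      # subject-level updates, one parameter at a time across all subjects;
      # random-walk proposals most of the time, with occasional independence
      # proposals from the group prior (these traverse likelihood-flat
      # directions, e.g. a saturated eligibility weight, in one move)
      for (p in seq_len(P)) {
        indep <- runif(1) < 0.25
        prop <- theta
        if (indep) {
          prop[p, ] <- rnorm(J, mu[p], sigma[p])
        } else {
          prop[p, ] <- theta[p, ] + step[p, ] * rnorm(J)
        }
        viol <- prop[p, ] < ptab$theta_lower[p]
        llp <- loglik(prop)
        llp[viol] <- -Inf
        logacc <- llp - ll
        if (!indep)
          logacc <- logacc +
            dnorm(prop[p, ], mu[p], sigma[p], log = TRUE) -
            dnorm(theta[p, ], mu[p], sigma[p], log = TRUE)
        acc <- log(runif(J)) < logacc
        acc[!is.finite(logacc) & !acc] <- FALSE
        theta[p, acc] <- prop[p, acc]
        ll[acc] <- llp[acc]
        if (iter <= mcmc$n_warmup) {
          if (!indep) {
            rate <- min(0.25, sweep_i^-0.6)
            step[p, ] <- step[p, ] * exp(rate * (as.numeric(acc) - 0.44))
          }
        } else {
          acc_count[p, ] <- acc_count[p, ] + acc / n_scans
        }
      }
      # joint block update across each subject's full parameter vector
      prop <- theta
      for (j in seq_len(J))
        prop[, j] <- theta[, j] +
          blk_scale[j] * as.vector(blk_chol[[j]] %*% rnorm(P))
      viol <- colSums(prop < ptab$theta_lower) > 0
      llp <- loglik(prop)
      llp[viol] <- -Inf
      logacc <- llp - ll +
        colSums(dnorm(prop, mu, sigma, log = TRUE)) -
        colSums(dnorm(theta, mu, sigma, log = TRUE))
      acc <- log(runif(J)) < logacc
      acc[!is.finite(logacc) & !acc] <- FALSE
      theta[, acc] <- prop[, acc]
      ll[acc] <- llp[acc]
      if (iter <= mcmc$n_warmup) {
        rate <- min(0.25, sweep_i^-0.6)
        blk_scale <- blk_scale * exp(rate * (as.numeric(acc) - 0.234))
        # accumulate running covariance of the subject vectors
        wf_n <- wf_n + 1
        d0 <- theta - wf_mean
        wf_mean <- wf_mean + d0 / wf_n
        for (j in seq_len(J))
          wf_M2[, , j] <- wf_M2[, , j] + tcrossprod(d0[, j], theta[, j] - wf_mean[, j])
        if (wf_n > 50 && sweep_i %% 25 == 0) {
          for (j in seq_len(J)) {
            cv <- wf_M2[, , j] / (wf_n - 1) +
              diag(1e-8 + 1e-4 * ptab$step0^2, P)
            cf <- tryCatch(t(chol(cv)), error = function(e) NULL)
            if (!is.null(cf)) blk_chol[[j]] <- cf
          }
        }
      }
      # group-level updates
      for (p in seq_len(P)) {
        th <- theta[p, ]
        lower <- ptab$theta_lower[p]
        m0 <- ptab$mu_prior_mean[p]; s0 <- ptab$mu_prior_sd[p]
        if (lower == -Inf) {
          prec <- 1 / s0^2 + J / sigma[p]^2
          mn <- (m0 / s0^2 + sum(th) / sigma[p]^2) / prec
          mu[p] <- rnorm(1, mn, sqrt(1 / prec))
        } else {
          sp <- sigma[p]
          lf <- function(m) {
            if (m < ptab$mu_lower[p]) return(-Inf)
            dnorm(m, m0, s0, log = TRUE) + sum(theta_prior_lp(th, m, sp, lower))
          }
          mu[p] <- slice_sample1(mu[p], lf, w = max(sp, 0.1),
                                 lower = ptab$mu_lower[p])
        }
        mp <- mu[p]; ssd <- ptab$sd_prior_sd[p]
        lf_s <- function(s) {
          if (s <= 0) return(-Inf)
          dnorm(s, 0, ssd, log = TRUE) + sum(theta_prior_lp(th, mp, s, lower))
        }
        sigma[p] <- slice_sample1(sigma[p], lf_s,
                                  w = max(sigma[p], 0.1), lower = 1e-8)
      }
      # interweaved non-centered move for unconstrained parameters: update
      # (mu, sigma) with the standardized subject deviations held fixed, so
      # the sampler can move through hierarchy funnels (the subject values
      # translate/rescale along with the group)
      for (p in seq_len(P)) {
        if (ptab$theta_lower[p] > -Inf) next
        z <- (theta[p, ] - mu[p]) / sigma[p]
        mu_s <- mu[p] + nc_step[p] * rnorm(1)
        sg_s <- sigma[p] * exp(0.5 * nc_step[p] * rnorm(1))
        prop <- theta
        prop[p, ] <- mu_s + sg_s * z
        llp <- loglik(prop)
        logacc <- sum(llp - ll) +
          dnorm(mu_s, ptab$mu_prior_mean[p], ptab$mu_prior_sd[p], log = TRUE) -
          dnorm(mu[p], ptab$mu_prior_mean[p], ptab$mu_prior_sd[p], log = TRUE) +
          dnorm(sg_s, 0, ptab$sd_prior_sd[p], log = TRUE) -
          dnorm(sigma[p], 0, ptab$sd_prior_sd[p], log = TRUE) +
          log(sg_s) - log(sigma[p])   # Jacobian of the log-scale step
        acc_nc <- is.finite(logacc) && log(runif(1)) < logacc
        if (acc_nc) {
          mu[p] <- mu_s
          sigma[p] <- sg_s
          theta[p, ] <- prop[p, ]
          ll <- llp
        }
        if (iter <= mcmc$n_warmup)
          nc_step[p] <- nc_step[p] *
            exp(min(0.25, sweep_i^-0.6) * (as.numeric(acc_nc) - 0.3))
      }
      }
      if (iter > mcmc$n_warmup)
        draws[iter - mcmc$n_warmup, ] <- c(mu, sigma, as.vector(t(theta)))
    }
    chains[[ch]] <- draws
    accept <- accept + acc_count / (mcmc$n_iter - mcmc$n_warmup)
  }

  rhat <- gelman_rubin(chains)
  structure(list(chains = chains, rhat = rhat,
                 accept = accept / mcmc$n_chains,
                 param_table = ptab, subject_ids = ids, mcmc = mcmc,
                 converged = all(rhat < mcmc$rhat_threshold, na.rm = TRUE)),
            class = "rlddm_fit")
}

#' @export
print.rlddm_fit <- function(x, ...) {
  cat("hierarchical fit:", nrow(x$param_table), "parameters,",
      length(x$subject_ids), "subjects,", length(x$chains), "chains\n")
  cat("  max split R-hat:", format(max(x$rhat, na.rm = TRUE), digits = 4),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}
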