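#' Split-chain Gelman-Rubin diagnostic
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half, so within-chain drift also registers as non-convergence.  Values
#' near 1 indicate the chains mix over the same distribution; the
#' conventional threshold is 1.1.
#'
#' @param chains a list of draw matrices (iterations x quantities) with
#'   identical column names, or an `rlddm_fit`.
#' @return Named vector of R-hat values, one per quantity.
#' @export
gelman_rubin <- function(chains) {
  if (inherits(chains, "rlddm_fit")) chains <- chains$chains
  if (length(chains) < 2) stop("at least two chains are required")
  n <- nrow(chains[[1]])
  stopifnot(all(vapply(chains, nrow, 1L) == n))
  half <- floor(n / 2)
  split_chains <- unlist(lapply(chains, function(d)
    list(d[seq_len(half), , drop = FALSE],
         d[(n - half + 1):n, , drop = FALSE])), recursive = FALSE)
  m <- length(split_chains)
  nn <- half
  means <- vapply(split_chains, colMeans, numeric(ncol(chains[[1]])))
  vars <- vapply(split_chains, function(d) apply(d, 2, stats::var),
                 numeric(ncol(chains[[1]])))
  if (is.null(dim(means))) {
    means <- matrix(means, nrow = 1)
    vars <- matrix(vars, nrow = 1)
  }
  W <- rowMeans(vars)
  B <- nn * apply(means, 1, stats::var)
  varplus <- (nn - 1) / nn * W + B / nn
  rhat <- sqrt(varplus / W)
  rhat[W == 0] <- 1
  names(rhat) <- colnames(chains[[1]])
  rhat
}

#' Posterior summaries with the credible-interval significance rule
#'
#' Pools the post-warmup draws of all chains and reports, per quantity, the
#' posterior median, the central 95% credible interval, split R-hat, and a
#' significance flag (the interval excludes 0).  For decision-layer fits the
#' derived effects are summarized from per-draw sums/differences of the group
#' means: the value-conflict effect under action conflict
#' (`cv + interaction`) for each system, and the model-based minus model-free
#' difference of each conflict effect.
#'
#' @param fit an `rlddm_fit`.
#' @param prob credible-interval mass.
#' @param derived include derived conflict effects when the fitted model has
#'   them.
#' @return A `data.frame` with `parameter`, `median`, `ci_low`, `ci_high`,
#'   `rhat`, `significant`.
#' @export
summarize_posterior <- function(fit, prob = 0.95, derived = TRUE) {
  draws <- do.call(rbind, fit$chains)
  if (derived && all(c("mu.v_mb_cv", "mu.v_mb_int", "mu.v_mf_cv",
                       "mu.v_mf_int", "mu.v_mb_ca", "mu.v_mf_ca") %in%
                     colnames(draws))) {
    extra <- cbind(
      `derived.v_mb_cv_plus_int` = draws[, "mu.v_mb_cv"] + draws[, "mu.v_mb_int"],
      `derived.v_mf_cv_plus_int` = draws[, "mu.v_mf_cv"] + draws[, "mu.v_mf_int"],
      `derived.diff_cv` = draws[, "mu.v_mb_cv"] - draws[, "mu.v_mf_cv"],
      `derived.diff_cv_plus_int` =
        (draws[, "mu.v_mb_cv"] + draws[, "mu.v_mb_int"]) -
        (draws[, "mu.v_mf_cv"] + draws[, "mu.v_mf_int"]),
      `derived.diff_ca` = draws[, "mu.v_mb_ca"] - draws[, "mu.v_mf_ca"],
      `derived.a_cv_plus_int` = draws[, "mu.a_cv"] + draws[, "mu.a_int"])
    draws <- cbind(draws, extra)
  }
  alpha <- (1 - prob) / 2
  med <- apply(draws, 2, median)
  lo <- apply(draws, 2, quantile, probs = alpha)
  hi <- apply(draws, 2, quantile, probs = 1 - alpha)
  rhat <- rep(NA_real_, ncol(draws))
  names(rhat) <- colnames(draws)
  rhat[names(fit$rhat)] <- fit$rhat
  data.frame(parameter = colnames(draws), median = med, ci_low = lo,
             ci_high = hi, rhat = rhat,
             significant = lo > 0 | hi < 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-subject point estimates of the learning parameters
#'
#' Extracts each subject's marginal posterior median of `alpha` and `lam` on
#' the (0, 1) scale (the logistic transform is applied per draw before taking
#' the median), as consumed by [compute_q_trajectories()] in the second stage
#' of the fitting procedure.
#'
#' @param fit an `rlddm_fit` from [fit_stage1_rl()] or a reduced fit.
#' @return A list with named numeric vectors `alpha` and `lam`.
#' @export
extract_subject_point_estimates <- function(fit) {
  draws <- do.call(rbind, fit$chains)
  grab <- function(par) {
    cols <- paste0("theta.", par, ".", fit$subject_ids)
    out <- vapply(cols, function(cl) median(plogis(draws[, cl])), numeric(1))
    names(out) <- fit$subject_ids
    out
  }
  list(alpha = grab("alpha"), lam = grab("lam"))
}
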