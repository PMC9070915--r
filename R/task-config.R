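#' Task configuration for a two-step experiment variant
#'
#' Bundles the structural constants of one variant of the two-step task.  The
#' `"original"` variant has a single first-stage state whose two options lead
#' probabilistically (0.7/0.3) to one of two second-stage states, each with a
#' binary choice paying 0/1 points; reward probabilities follow Gaussian
#' random walks with reflecting boundaries.  The `"newer"` variant has two
#' first-stage stimulus pairs with deterministic transitions and a single
#' forced second-stage option paying an integer reward in -4..5, which is
#' rescaled by 1/9 so that value differences live on the same scale as in the
#' original variant.
#'
#' @param variant `"original"` or `"newer"`.
#' @param n_trials number of trials per session.
#' @param common_transition_prob probability of the common transition
#'   (original variant); must lie in (0.5, 1].
#' @param walk_sd standard deviation of the Gaussian reward-walk increments.
#' @param walk_bounds length-2 numeric, reflecting boundaries of the walk.
#' @param deadline_s response deadline in seconds (applies to both stages).
#' @param reward_range length-2 numeric, raw reward range of the variant.
#' @param reward_rescale divisor applied to raw rewards before learning.
#' @param q_initial initial cached value; defaults to the midpoint of the
#'   rescaled reward range.
#'
#' @return An object of class `task_config` (a list with the above fields).
#' @examples
#' task_config("original")
#' task_config("newer")$q_initial   # 1/18
#' @export
task_config <- function(variant = c("original", "newer"),
                        n_trials = 201,
                        common_transition_prob = NULL,
                        walk_sd = NULL,
                        walk_bounds = NULL,
                        deadline_s = 2,
                        reward_range = NULL,
                        reward_rescale = NULL,
                        q_initial = NULL) {
  variant <- match.arg(variant)
  if (variant == "original") {
    if (is.null(common_transition_prob)) common_transition_prob <- 0.7
    if (is.null(walk_sd)) walk_sd <- 0.025
    if (is.null(walk_bounds)) walk_bounds <- c(0.25, 0.75)
    if (is.null(reward_range)) reward_range <- c(0, 1)
    if (is.null(reward_rescale)) reward_rescale <- 1
  } else {
    if (is.null(common_transition_prob)) common_transition_prob <- 1
    if (is.null(walk_sd)) walk_sd <- 2
    if (is.null(walk_bounds)) walk_bounds <- c(-4, 5)
    if (is.null(reward_range)) reward_range <- c(-4, 5)
    if (is.null(reward_rescale)) reward_rescale <- 9
  }
  if (is.null(q_initial))
    q_initial <- mean(reward_range / reward_rescale)
  stopifnot(common_transition_prob > 0.5, common_transition_prob <= 1,
            walk_bounds[1] < walk_bounds[2], reward_rescale > 0,
            n_trials >= 1, deadline_s > 0)
  structure(list(variant = variant,
                 n_trials = as.integer(n_trials),
                 common_transition_prob = common_transition_prob,
                 walk_sd = walk_sd,
                 walk_bounds = walk_bounds,
                 deadline_s = deadline_s,
                 reward_range = reward_range,
                 reward_rescale = reward_rescale,
                 q_initial = q_initial),
            class = "task_config")
}

#' @export
print.task_config <- function(x, ...) {
  cat("two-step task config:", x$variant, "variant\n")
  cat("  trials:", x$n_trials, " deadline:", x$deadline_s, "s\n")
  cat("  common transition p:", x$common_transition_prob, "\n")
  cat("  reward range:", paste(x$reward_range, collapse = ".."),
      " rescale: 1/", x$reward_rescale, "\n", sep = "")
  cat("  walk: sd", x$walk_sd, "bounds",
      paste(x$walk_bounds, collapse = "/"), "\n")
  cat("  Q initial:", format(x$q_initial), "\n")
  invisible(x)
}

variant_code <- function(config) if (config$variant == "original") 0L else 1L
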