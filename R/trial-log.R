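TRIAL_LOG_COLUMNS <- c("subject_id", "trial_index", "stage1_state",
                       "stage1_choice", "stage1_rt", "stage2_state",
                       "stage2_choice", "stage2_rt", "reward",
                       "missed_stage1", "missed_stage2")

#' Read a trial log
#'
#' Reads a trial-level behavioral log in the package's CSV dialect: one row
#' per trial with columns `subject_id, trial_index, stage1_state,
#' stage1_choice, stage1_rt, stage2_state, stage2_choice, stage2_rt, reward,
#' missed_stage1, missed_stage2`.  Missing values are written as `NA`,
#' booleans as 0/1.  Rows are validated against the task configuration and
#' returned sorted by subject and trial index.
#'
#' @param path path to a CSV trial log.
#' @param config a [task_config()].
#' @return A `data.frame` of trials, one `TrialRecord` per row.
#' @seealso [write_trial_log()], [apply_exclusions()]
#' @export
read_trial_log <- function(path, config) {
  if (!file.exists(path)) stop("trial log not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), TRIAL_LOG_COLUMNS))
    stop("trial log header does not match the documented schema; expected: ",
         paste(TRIAL_LOG_COLUMNS, collapse = ","))
  df$subject_id <- as.character(df$subject_id)
  for (col in c("trial_index", "stage1_state", "stage1_choice",
                "stage2_state", "stage2_choice", "missed_stage1",
                "missed_stage2")) {
    v <- suppressWarnings(as.integer(df[[col]]))
    bad <- which(!is.na(df[[col]]) & is.na(v))
    if (length(bad))
      stop("malformed value in column '", col, "' at row ", bad[1] + 1L)
    df[[col]] <- v
  }
  for (col in c("stage1_rt", "stage2_rt", "reward")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.na(df[[col]]) & is.na(v))
    if (length(bad))
      stop("malformed value in column '", col, "' at row ", bad[1] + 1L)
    df[[col]] <- v
  }
  df$missed_stage1 <- df$missed_stage1 == 1L
  df$missed_stage2 <- df$missed_stage2 == 1L
  df <- df[order(df$subject_id, df$trial_index), , drop = FALSE]
  rownames(df) <- NULL
  validate_trial_log(df, config)
  df
}

#' Write a trial log
#'
#' Writes trials in the canonical CSV dialect ([read_trial_log()] round-trips
#' such files byte-for-byte).
#'
#' @param trials a trial `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(trials, path) {
  out <- trials[, TRIAL_LOG_COLUMNS]
  out$missed_stage1 <- as.integer(out$missed_stage1)
  out$missed_stage2 <- as.integer(out$missed_stage2)
  for (col in c("stage1_rt", "stage2_rt", "reward"))
    out[[col]] <- ifelse(is.na(out[[col]]), NA,
                         format(out[[col]], digits = 15, trim = TRUE,
                                scientific = FALSE))
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Validate a trial data frame against its task configuration
#'
#' Checks the domain invariants: second-stage states in \{2, 3\}, choices in
#' \{1, 2\} or missing, non-missed RTs in (0, deadline], rewards inside the
#' variant's raw range, and missing choices on missed stages.
#'
#' @param trials trial `data.frame`.
#' @param config a [task_config()].
#' @return `trials`, invisibly, or an error describing the first violation.
#' @export
validate_trial_log <- function(trials, config) {
  fail <- function(i, msg) stop("trial log row ", i, ": ", msg)
  ok_state1 <- if (config$variant == "original") 1L else c(1L, 2L)
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    if (!(tr$stage1_state %in% ok_state1)) fail(i, "bad stage1_state")
    if (is.na(tr$stage2_state)) {
      # no transition happens when stage 1 is missed
      if (!tr$missed_stage1) fail(i, "missing stage2_state on a non-missed trial")
    } else if (!(tr$stage2_state %in% c(2L, 3L))) {
      fail(i, "bad stage2_state")
    }
    if (!is.na(tr$stage1_choice) && !(tr$stage1_choice %in% c(1L, 2L)))
      fail(i, "bad stage1_choice")
    if (!is.na(tr$stage2_choice) && !(tr$stage2_choice %in% c(1L, 2L)))
      fail(i, "bad stage2_choice")
    if (tr$missed_stage1 && !is.na(tr$stage1_choice))
      fail(i, "missed stage 1 must have a missing choice")
    if (!tr$missed_stage1 && !is.na(tr$stage1_rt) &&
        (tr$stage1_rt <= 0 || tr$stage1_rt > config$deadline_s))
      fail(i, "stage1_rt outside (0, deadline]")
    if (config$variant == "original" && !tr$missed_stage2 &&
        !is.na(tr$stage2_rt) &&
        (tr$stage2_rt <= 0 || tr$stage2_rt > config$deadline_s))
      fail(i, "stage2_rt outside (0, deadline]")
    if (!is.na(tr$reward) &&
        (tr$reward < config$reward_range[1] ||
         tr$reward > config$reward_range[2]))
      fail(i, "reward outside the variant's range")
  }
  invisible(trials)
}

#' Participant-level exclusion filter
#'
#' A trial is "bad" when either stage has a reaction time below `rt_floor`
#' seconds or a missing choice (for the newer variant only stage 1 counts:
#' there is no second-stage decision).  A subject is excluded when the
#' fraction of bad trials is strictly greater than `threshold`.
#'
#' @param trials trial `data.frame` covering one or more subjects.
#' @param config a [task_config()].
#' @param rt_floor fastest admissible RT in seconds.
#' @param threshold maximal tolerated bad-trial fraction.
#' @return A list with `retained` (trial data frame restricted to retained
#'   subjects) and `report` (one row per subject: `subject_id`, `n_trials`,
#'   `n_bad`, `bad_fraction`, `excluded`).
#' @examples
#' cfg <- task_config("original", n_trials = 4)
#' trials <- data.frame(
#'   subject_id = "s1", trial_index = 1:4, stage1_state = 1,
#'   stage1_choice = c(1L, 2L, NA, 1L), stage1_rt = c(0.5, 0.1, NA, 0.7),
#'   stage2_state = 2L, stage2_choice = c(1L, 1L, NA, 2L),
#'   stage2_rt = c(0.4, 0.5, NA, 0.6), reward = c(1, 0, NA, 1),
#'   missed_stage1 = c(FALSE, FALSE, TRUE, FALSE),
#'   missed_stage2 = FALSE)
#' apply_exclusions(trials, cfg)$report
#' @export
apply_exclusions <- function(trials, config, rt_floor = 0.2, threshold = 0.2) {
  if (nrow(trials) == 0L) stop("no trials supplied")
  bad1 <- is.na(trials$stage1_choice) |
    (!is.na(trials$stage1_rt) & trials$stage1_rt < rt_floor)
  if (config$variant == "original") {
    bad2 <- is.na(trials$stage2_choice) |
      (!is.na(trials$stage2_rt) & trials$stage2_rt < rt_floor)
  } else {
    bad2 <- FALSE
  }
  bad <- bad1 | bad2
  ids <- unique(trials$subject_id)
  report <- do.call(rbind, lapply(ids, function(id) {
    sel <- trials$subject_id == id
    n <- sum(sel)
    nb <- sum(bad[sel])
    data.frame(subject_id = id, n_trials = n, n_bad = nb,
               bad_fraction = nb / n,
               excluded = (nb / n) > threshold,
               stringsAsFactors = FALSE)
  }))
  keep <- report$subject_id[!report$excluded]
  retained <- trials[trials$subject_id %in% keep, , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained, report = report)
}

#' Rescale rewards to the common learning scale
#'
#' Divides raw rewards by the variant's `reward_rescale` (1 for the original
#' variant, 9 for the newer one), putting value differences of both variants
#' on a comparable scale.
#'
#' @param trials trial `data.frame` with raw rewards.
#' @param config a [task_config()].
#' @return The trials with `reward` divided by the rescale factor.
#' @export
rescale_rewards <- function(trials, config) {
  trials$reward <- trials$reward / config$reward_rescale
  trials
}
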