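# Low-level draw helpers shared by generate_cohort() and simulate_trial().
# All draws are position-indexed (vectorized over participants), so cohort
# content does not depend on the order in which components are generated.

draw_baseline <- function(n, sc) {
  # inverse-CDF sampling from Normal(mean, sd) truncated below at floor
  p_floor <- stats::pnorm(sc$baseline_floor, sc$baseline_mean, sc$baseline_sd)
  u <- stats::runif(n, min = p_floor, max = 1)
  stats::qnorm(u, sc$baseline_mean, sc$baseline_sd)
}

draw_sessions <- function(n, sc) {
  sm <- sc$session_model
  if (sm$type == "complete") return(rep(40L, n))
  full <- stats::runif(n) < sm$p_full
  out <- integer(n)
  out[full] <- 40L
  out[!full] <- stats::rbinom(sum(!full), 40L, sm$partial_rate)
  out
}

draw_followups <- function(post, sc, months = 6L) {
  # monthly score = post + cumulative Normal(drift, sd) increments, floor 0
  n <- length(post)
  inc <- matrix(stats::rnorm(n * months, sc$followup_drift, sc$followup_sd),
                nrow = n)
  traj <- post + t(apply(inc, 1L, cumsum))
  if (n == 1L) traj <- matrix(traj, nrow = 1L)
  pmax(traj, 0)
}

#' Generate a synthetic participant cohort
#'
#' Draws one simulated participant per arm assignment under a generative
#' [scenario()]: baseline MADRS from a truncated normal, pre-treatment
#' attrition with probability `dropout_prob` (non-evaluable participants
#' receive no sessions and have no post score), MADRS improvement
#' `change ~ Normal(arm mean, common SD)` with `post = baseline - change`,
#' a session-completion count out of 40, and six monthly follow-up scores
#' from a cumulative drift-plus-noise walk started at the post score
#' (clamped at zero). The generator is deterministic given
#' `scenario$seed`.
#'
#' @param scenario A [scenario()].
#' @param n Number of participants; must equal `length(arm_assignments)`.
#' @param arm_assignments Character vector of arm labels (see [ARM_LEVELS]).
#' @return A `data.frame` of class `cohort` with one row per participant:
#'   `id`, `arm`, `baseline`, `post`, `change`, `evaluable`,
#'   `sessions_completed`, `followup_1` .. `followup_6`. `post`, `change`
#'   and follow-ups are `NA` for non-evaluable participants.
#' @export
#' @examples
#' sc <- scenario(seed = 42)
#' cohort <- generate_cohort(sc, 6, rep(ARM_LEVELS, 2))
#' cohort[, c("arm", "baseline", "change", "evaluable")]
generate_cohort <- function(scenario, n, arm_assignments) {
  stopifnot(
    "n must be >= 1" = n >= 1,
    "arm_assignments must have length n" = length(arm_assignments) == n
  )
  if (!all(arm_assignments %in% ARM_LEVELS)) {
    bad <- setdiff(unique(arm_assignments), ARM_LEVELS)
    stop("unknown arm label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  sc <- scenario
  set.seed(sc$seed)
  baseline <- draw_baseline(n, sc)
  evaluable <- stats::runif(n) >= sc$dropout_prob
  z <- stats::rnorm(n)
  change <- sc$arm_means[arm_assignments] + sc$common_sd * z
  post <- baseline - change
  if (sc$clamp_post) {
    post <- pmax(post, 0)
    change <- baseline - post
  }
  sessions <- draw_sessions(n, sc)
  fup <- draw_followups(post, sc)

  change[!evaluable] <- NA_real_
  post[!evaluable] <- NA_real_
  sessions[!evaluable] <- 0L
  fup[!evaluable, ] <- NA_real_

  out <- data.frame(
    id = seq_len(n),
    arm = arm_assignments,
    baseline = baseline,
    post = post,
    change = change,
    evaluable = evaluable,
    sessions_completed = sessions,
    stringsAsFactors = FALSE
  )
  colnames(fup) <- paste0("followup_", seq_len(ncol(fup)))
  out <- cbind(out, as.data.frame(fup))
  rownames(out) <- NULL
  class(out) <- c("cohort", "data.frame")
  out
}

#' Write or read a cohort as CSV
#'
#' One row per participant with the columns documented in
#' [generate_cohort()].
#'
#' @param cohort A `cohort` data frame.
#' @param path Output/input CSV path.
#' @return `write_cohort_csv()` returns `path` invisibly;
#'   `read_cohort_csv()` returns a `cohort`.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  out$evaluable <- as.logical(out$evaluable)
  class(out) <- c("cohort", "data.frame")
  out
}
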