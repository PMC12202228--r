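#' Simulate one complete adaptive trial
#'
#' Runs one trial under a generative [scenario()] and a [design_spec()]:
#' permuted-block enrollment, interim looks, decision application and final
#' analysis.
#'
#' Accrual is instantaneous-in-order: outcome availability follows
#' enrollment order with no calendar-time lag. Each participant's
#' pre-treatment attrition and standardized outcome noise are drawn
#' position-indexed up front, so the realized outcomes do not depend on the
#' adaptive path (only the arm labels, and hence the means, do). Look `k`
#' occurs with enrollment paused at `enroll_at_stop[k]` participants; its
#' summaries use the first `interim_evaluable[k]` evaluable participants in
#' enrollment order (all available evaluable participants when attrition
#' leaves fewer than the information target). Participants randomized beyond
#' the information target are enrollment overrun: they count toward the
#' enrolled total and enter later analyses, but not that look's summaries.
#' After an arm drop the remaining positions are re-randomized in 2:1
#' active:sham blocks; the dropped arm's accrued participants are retained
#' in the records but take no further part in comparisons. The final
#' analysis at `n_max` uses every evaluable participant.
#'
#' @param scenario A [scenario()]; its `seed` field is ignored here in
#'   favor of the explicit `seed` argument.
#' @param design A [design_spec()].
#' @param cfg A [posterior_config()].
#' @param seed Integer seed; the trial is a deterministic function of
#'   `(scenario, design, cfg, seed)`.
#' @return A `trial_result`: list with `enrolled_total`, `stop_stage`
#'   (`interim1`/`interim2`/`final`), `stop_reason`
#'   (`success`/`futility`/`max_n`), `success`, `winning_arm`,
#'   `dropped_arm`, `final_posteriors`, `max_final_posterior` (largest
#'   Pr(active > sham) at the deciding look), `arm_n`, `arm_mean`
#'   (per-arm evaluable counts and mean changes over the whole trial),
#'   `evaluable_total` and `history` (the interim decisions).
#' @export
#' @examples
#' res <- simulate_trial(null_scenario(), seed = 7)
#' res$enrolled_total
simulate_trial <- function(scenario, design = design_spec(),
                           cfg = posterior_config(), seed) {
  sc <- scenario
  set.seed(seed)
  n_max <- design$n_max
  n_looks <- length(design$interim_evaluable)

  # position-indexed draws: attrition, standardized outcome noise, arms
  evaluable <- stats::runif(n_max) >= sc$dropout_prob
  z <- stats::rnorm(n_max)
  arm <- allocation_sequence(n_max, ARM_LEVELS)

  live <- ARM_LEVELS
  dropped_arm <- NULL
  history <- list()

  change_for <- function(idx) sc$arm_means[arm[idx]] + sc$common_sd * z[idx]
  summaries_for <- function(idx) {
    ch <- change_for(idx)
    arms_idx <- arm[idx]
    out <- lapply(intersect(live, ARM_LEVELS), function(a) {
      arm_summary(ch[arms_idx == a])
    })
    stats::setNames(out, intersect(live, ARM_LEVELS))
  }

  finish <- function(stage, reason, success, winning_arm, posteriors,
                     enrolled_total) {
    idx_all <- which(evaluable[seq_len(enrolled_total)])
    ch <- change_for(idx_all)
    arms_idx <- arm[idx_all]
    arm_n <- vapply(ARM_LEVELS, function(a) sum(arms_idx == a), integer(1))
    arm_mean <- vapply(ARM_LEVELS, function(a) {
      if (any(arms_idx == a)) mean(ch[arms_idx == a]) else NA_real_
    }, numeric(1))
    p_sham <- unlist(posteriors[grep("_vs_sham$", names(posteriors))])
    structure(
      list(
        enrolled_total = enrolled_total,
        stop_stage = stage, stop_reason = reason,
        success = success, winning_arm = winning_arm,
        dropped_arm = dropped_arm,
        final_posteriors = posteriors,
        max_final_posterior = if (length(p_sham)) max(p_sham) else NA_real_,
        arm_n = arm_n, arm_mean = arm_mean,
        evaluable_total = length(idx_all),
        history = history
      ),
      class = "trial_result"
    )
  }

  for (k in seq_len(n_looks)) {
    enrolled <- design$enroll_at_stop[k]
    ev_idx <- which(evaluable[seq_len(enrolled)])
    if (length(ev_idx) > design$interim_evaluable[k]) {
      ev_idx <- ev_idx[seq_len(design$interim_evaluable[k])]
    }
    dec <- interim_decision(summaries_for(ev_idx), design, cfg)
    history[[k]] <- dec
    if (dec$action == "stop_success") {
      return(finish(paste0("interim", k), "success", TRUE, dec$winning_arm,
                    dec$posteriors, enrolled))
    }
    if (dec$action == "stop_futility") {
      return(finish(paste0("interim", k), "futility", FALSE, NULL,
                    dec$posteriors, enrolled))
    }
    if (dec$action == "drop_arm") {
      dropped_arm <- dec$dropped_arm
      live <- setdiff(live, dropped_arm)
      tail_idx <- (enrolled + 1L):n_max
      arm[tail_idx] <- allocation_sequence(length(tail_idx), live)
    }
  }

  ev_idx <- which(evaluable[seq_len(n_max)])
  fin <- final_decision(summaries_for(ev_idx), design, cfg)
  finish("final", if (fin$success) "success" else "max_n", fin$success,
         fin$winning_arm, fin$posteriors, n_max)
}

#' Simulate many trials into a tidy per-trial table
#'
#' Runs [simulate_trial()] `n_reps` times with independent sub-seeds derived
#' deterministically from `seed`, returning one row per trial. This is the
#' backbone of [run_oc()] and of common-random-number threshold
#' calibration: `interim_success` and `max_final_posterior` are recorded so
#' trials can be re-scored at any candidate final threshold without
#' re-simulation.
#'
#' @inheritParams simulate_trial
#' @param n_reps Number of trials.
#' @param seed Root seed for the batch.
#' @return A `data.frame` with columns `rep`, `seed`, `enrolled_total`,
#'   `stop_stage`, `stop_reason`, `success`, `interim_success`,
#'   `max_final_posterior`, `winning_arm`, `dropped_arm`,
#'   `evaluable_total`.
#' @export
simulate_trials <- function(scenario, design = design_spec(),
                            cfg = posterior_config(), n_reps, seed) {
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  rows <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    r <- simulate_trial(scenario, design, cfg, seed = sub_seeds[i])
    rows[[i]] <- data.frame(
      rep = i, seed = sub_seeds[i],
      enrolled_total = r$enrolled_total,
      stop_stage = r$stop_stage, stop_reason = r$stop_reason,
      success = r$success,
      interim_success = r$stop_reason == "success" &&
        r$stop_stage != "final",
      max_final_posterior = if (r$stop_stage == "final")
        r$max_final_posterior else NA_real_,
      winning_arm = if (is.null(r$winning_arm)) NA_character_ else
        r$winning_arm,
      dropped_arm = if (is.null(r$dropped_arm)) NA_character_ else
        r$dropped_arm,
      evaluable_total = r$evaluable_total,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf("trial: %s at %s, enrolled %d (evaluable %d)\n",
              x$stop_reason, x$stop_stage, x$enrolled_total,
              x$evaluable_total))
  if (!is.null(x$winning_arm)) cat("  winner:", x$winning_arm, "\n")
  if (!is.null(x$dropped_arm)) cat("  dropped:", x$dropped_arm, "\n")
  invisible(x)
}
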