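#' Operating characteristics of the adaptive design
#'
#' Aggregates `n_reps` simulated trials into the design's frequentist
#' behavior under the scenario's assumed truth: success probability (power
#' under an alternative, type-I error under the null), expected enrolled
#' sample size, stopping-stage probabilities, futility and arm-drop rates
#' and the winning-arm distribution, each with a binomial Monte-Carlo
#' standard error.
#'
#' The expected enrolled N satisfies, exactly and by construction,
#' `sum(enroll_at_stop * stop_stage_probs)` -- the average of the three
#' possible trial sizes weighted by the probability each occurs.
#'
#' @inheritParams simulate_trials
#' @return An `oc_report`: list with `n_reps`, `success_prob`,
#'   `success_mc_se`, `expected_enrolled`, `expected_enrolled_mc_se`,
#'   `stop_stage_probs` (named `interim1`/`interim2`/`final`),
#'   `futility_prob`, `arm_drop_prob`, `interim_success_prob`,
#'   `winning_arm_probs`, the `design`, and the per-trial table as
#'   `trials`.
#' @export
#' @examples
#' oc <- run_oc(null_scenario(), n_reps = 200, seed = 1)
#' oc$success_prob
run_oc <- function(scenario, design = design_spec(),
                   cfg = posterior_config(), n_reps = 10000L, seed) {
  stopifnot("n_reps must be >= 1" = n_reps >= 1)
  trials <- simulate_trials(scenario, design, cfg, n_reps, seed)
  oc_report(trials, design)
}

# Aggregate a per-trial table (from simulate_trials) into an oc_report.
oc_report <- function(trials, design) {
  n <- nrow(trials)
  stages <- c(paste0("interim", seq_along(design$interim_evaluable)),
              "final")
  stage_p <- vapply(stages, function(s) mean(trials$stop_stage == s),
                    numeric(1))
  binom_se <- function(p) sqrt(p * (1 - p) / n)
  win_p <- vapply(ACTIVE_ARMS, function(a)
    mean(!is.na(trials$winning_arm) & trials$winning_arm == a), numeric(1))
  structure(
    list(
      n_reps = n,
      success_prob = mean(trials$success),
      success_mc_se = binom_se(mean(trials$success)),
      expected_enrolled = mean(trials$enrolled_total),
      expected_enrolled_mc_se = stats::sd(trials$enrolled_total) / sqrt(n),
      stop_stage_probs = stage_p,
      futility_prob = mean(trials$stop_reason == "futility"),
      arm_drop_prob = mean(!is.na(trials$dropped_arm)),
      interim_success_prob = mean(trials$interim_success),
      winning_arm_probs = win_p,
      design = design,
      trials = trials
    ),
    class = "oc_report"
  )
}

#' Re-score simulated null trials at a candidate final threshold
#'
#' A trial is successful at final threshold `t` iff it stopped for success
#' at an interim (unaffected by `t`) or reached the final analysis with its
#' best active-vs-sham posterior at or above `t`. Futility-stopped trials
#' can never succeed. This is the common-random-numbers device behind
#' [calibrate_final_threshold()].
#'
#' @param trials Per-trial table from [simulate_trials()].
#' @param threshold Candidate final success threshold.
#' @return Fraction of trials successful at that threshold.
#' @export
rescore_success <- function(trials, threshold) {
  final_hit <- !is.na(trials$max_final_posterior) &
    trials$max_final_posterior >= threshold
  mean(trials$interim_success | final_hit)
}

#' Calibrate the final success threshold to a type-I error target
#'
#' Holds the interim rules fixed and searches the final-analysis success
#' threshold so the family-wise type-I error -- the probability, under the
#' null, of declaring any success across both active arms, both interim
#' looks and the final analysis -- is at or below `alpha_target`. One batch
#' of null trials is simulated and re-scored at each candidate (common
#' random numbers), so the calibration is a deterministic function of the
#' seed. Monotone bisection on a `grid_step` grid returns the smallest
#' threshold whose achieved error is within target.
#'
#' @param design A [design_spec()]; its `final_success_threshold` is the
#'   quantity being recovered and is ignored during the search.
#' @param null_scenario A null [scenario()] (all arm means equal).
#' @param cfg A [posterior_config()].
#' @param alpha_target Family-wise type-I error target.
#' @param n_reps Number of null trials to simulate.
#' @param seed Root seed.
#' @param grid_step Threshold grid resolution.
#' @param grid_min Lower end of the searched grid.
#' @return A `calibration_result`: list with `calibrated_final_threshold`,
#'   `achieved_alpha`, `interim_alpha` (error spent by the interim success
#'   rule alone), `n_reps`, `alpha_target` and the bisection `trace`.
#' @export
calibrate_final_threshold <- function(design = design_spec(),
                                      null_scenario = aitbsim::null_scenario(),
                                      cfg = posterior_config(),
                                      alpha_target = 0.025,
                                      n_reps = 10000L, seed,
                                      grid_step = 0.001, grid_min = 0.90) {
  trials <- simulate_trials(null_scenario, design, cfg, n_reps, seed)
  calibrate_from_trials(trials, alpha_target, grid_step, grid_min)
}

# Search over the threshold grid given an already-simulated null batch.
calibrate_from_trials <- function(trials, alpha_target = 0.025,
                                  grid_step = 0.001, grid_min = 0.90) {
  interim_alpha <- mean(trials$interim_success)
  grid <- seq(grid_min, 1, by = grid_step)
  alpha_at <- function(t) rescore_success(trials, t)
  if (alpha_at(grid[length(grid)]) > alpha_target) {
    stop("alpha_target ", alpha_target, " unattainable: interim success ",
         "rule alone spends ", signif(alpha_at(1), 4), call. = FALSE)
  }
  # achieved alpha is nonincreasing in the threshold: bisect for the
  # smallest grid point with alpha <= target
  lo <- 1L
  hi <- length(grid)
  trace <- list()
  if (alpha_at(grid[lo]) <= alpha_target) {
    hi <- lo
  } else {
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      a <- alpha_at(grid[mid])
      trace[[length(trace) + 1L]] <-
        data.frame(threshold = grid[mid], achieved_alpha = a)
      if (a <= alpha_target) hi <- mid else lo <- mid
    }
  }
  thr <- grid[hi]
  structure(
    list(
      calibrated_final_threshold = thr,
      achieved_alpha = alpha_at(thr),
      interim_alpha = interim_alpha,
      n_reps = nrow(trials),
      alpha_target = alpha_target,
      trace = if (length(trace)) do.call(rbind, trace) else
        data.frame(threshold = numeric(0), achieved_alpha = numeric(0))
    ),
    class = "calibration_result"
  )
}

#' Power of a fixed-N two-sample one-sided normal test
#'
#' Closed-form reference used to pin down the outcome SD implied by the
#' design's printed power scenarios. With `n` per arm, known common SD and
#' one-sided level `alpha`, power at true difference `delta` is
#' `pnorm(delta / (sd * sqrt(2/n)) - qnorm(1 - alpha))`. At `n = 66` per
#' arm (one third of 198) and `alpha = 0.025`, SD 8 is the unique integer
#' SD giving power about 0.82 at a 4-point effect and about 0.95 at a
#' 5-point effect simultaneously, which is why 8 is the package's default
#' `common_sd`.
#'
#' @param delta True mean difference (points).
#' @param sd Common outcome SD (points).
#' @param n Per-arm sample size.
#' @param alpha One-sided significance level.
#' @return Power (probability).
#' @export
#' @examples
#' sd_calibration_power(4, sd = 8)   # ~0.82
#' sd_calibration_power(5, sd = 8)   # ~0.95
sd_calibration_power <- function(delta, sd, n = 66, alpha = 0.025) {
  stats::pnorm(delta / (sd * sqrt(2 / n)) - stats::qnorm(1 - alpha))
}

#' Sweep operating characteristics over scenarios
#'
#' Convenience wrapper running [run_oc()] per scenario and returning one
#' tidy long-format row per scenario x metric.
#'
#' @param scenarios Named list of [scenario()] objects.
#' @inheritParams run_oc
#' @return A long `data.frame` with columns `scenario`, `metric`, `value`.
#' @export
oc_sweep <- function(scenarios, design = design_spec(),
                     cfg = posterior_config(), n_reps = 10000L, seed) {
  rows <- lapply(names(scenarios), function(nm) {
    oc <- run_oc(scenarios[[nm]], design, cfg, n_reps,
                 seed = seed + match(nm, names(scenarios)))
    data.frame(
      scenario = nm,
      metric = c("success_prob", "expected_enrolled", "futility_prob",
                 "arm_drop_prob", "p_stop_interim1", "p_stop_interim2",
                 "p_stop_final"),
      value = c(oc$success_prob, oc$expected_enrolled, oc$futility_prob,
                oc$arm_drop_prob, unname(oc$stop_stage_probs)),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' @export
print.oc_report <- function(x, ...) {
  cat(sprintf("operating characteristics (%d simulated trials)\n", x$n_reps))
  cat(sprintf("  success probability: %.4f (MC SE %.4f)\n",
              x$success_prob, x$success_mc_se))
  cat(sprintf("  expected enrolled N: %.1f (MC SE %.2f)\n",
              x$expected_enrolled, x$expected_enrolled_mc_se))
  cat(sprintf("  stop stage: %s\n",
              paste(sprintf("%s=%.3f", names(x$stop_stage_probs),
                            x$stop_stage_probs), collapse = ", ")))
  cat(sprintf("  futility %.3f | arm drop %.3f | interim success %.4f\n",
              x$futility_prob, x$arm_drop_prob, x$interim_success_prob))
  invisible(x)
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("calibrated final success threshold: %.3f\n",
              x$calibrated_final_threshold))
  cat(sprintf("  achieved type-I error %.4f (target %.4f, interim rule alone %.4f, %d null trials)\n",
              x$achieved_alpha, x$alpha_target, x$interim_alpha, x$n_reps))
  invisible(x)
}

#' Write an operating-characteristics report to CSV + JSON
#'
#' Scalars go to a JSON sidecar; the per-trial table to CSV.
#'
#' @param oc An `oc_report`.
#' @param stem Output path stem; writes `<stem>.json` and
#'   `<stem>_trials.csv`.
#' @return The two paths, invisibly.
#' @export
write_oc <- function(oc, stem) {
  scal <- oc[c("n_reps", "success_prob", "success_mc_se",
               "expected_enrolled", "expected_enrolled_mc_se",
               "futility_prob", "arm_drop_prob", "interim_success_prob")]
  scal$stop_stage_probs <- as.list(oc$stop_stage_probs)
  scal$winning_arm_probs <- as.list(oc$winning_arm_probs)
  json_path <- paste0(stem, ".json")
  csv_path <- paste0(stem, "_trials.csv")
  jsonlite::write_json(scal, json_path, auto_unbox = TRUE, digits = NA)
  utils::write.csv(oc$trials, csv_path, row.names = FALSE)
  invisible(c(json_path, csv_path))
}
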