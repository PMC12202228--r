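#' Arm labels used throughout the package
#'
#' The three randomized arms, in fixed canonical order: sham coil,
#' active aiTBS at the scalp-measured Beam F3 target, and active aiTBS at an
#' individualized resting-state fMRI-derived target. The canonical order is
#' also the deterministic tie-break order for decisions.
#'
#' @export
ARM_LEVELS <- c("sham", "active_F3", "active_rsfMRI")

ACTIVE_ARMS <- c("active_F3", "active_rsfMRI")

#' Define a generative scenario for simulated cohorts
#'
#' A scenario is the "true state of the world" a simulated trial is run
#' under: mean MADRS improvement per arm, the common outcome SD, the
#' pre-treatment attrition probability, the baseline-severity distribution,
#' the session-completion model and the monthly follow-up trajectory model.
#' Improvement is scored as baseline minus post-treatment MADRS, so positive
#' values mean the participant got better and "superior" means a larger mean
#' improvement.
#'
#' @param arm_means Named numeric vector of true mean MADRS improvements
#'   (points) for `sham`, `active_F3` and `active_rsfMRI`. An unnamed
#'   length-3 vector is taken in canonical arm order.
#' @param common_sd Common SD of MADRS change (points), shared by all arms.
#'   The default 8 is the value at which a fixed-N two-sample normal test
#'   with 66 per arm at one-sided alpha 0.025 has power 0.82 at a 4-point
#'   effect and 0.95 at a 5-point effect (see [sd_calibration_power()]).
#' @param dropout_prob Probability of attrition between consent and first
#'   treatment session. Dropped participants occupy enrollment slots but
#'   contribute no primary outcome.
#' @param baseline_mean,baseline_sd Mean and SD of the baseline MADRS
#'   distribution before truncation.
#' @param baseline_floor Minimum eligible baseline MADRS; baselines are drawn
#'   from a normal truncated below at this value.
#' @param followup_drift,followup_sd Mean and SD of the monthly increments
#'   added cumulatively to the post-treatment score over six follow-up
#'   months (positive drift = gradual symptom return). Scores are clamped at
#'   zero.
#' @param session_model Session-completion model: `list(type = "complete")`
#'   (all 40 sessions, the default) or
#'   `list(type = "mixture", p_full = , partial_rate = )` where a
#'   non-completer finishes `Binomial(40, partial_rate)` sessions. The
#'   mixture exists to exercise per-protocol filtering.
#' @param clamp_post If `TRUE`, post-treatment MADRS is clamped at 0 (the
#'   scale floor). Off by default so the generative model is exactly normal.
#' @param seed Integer RNG seed used by [generate_cohort()].
#'
#' @return An object of class `scenario` (a validated list).
#' @seealso [null_scenario()], [effect_scenario()], [read_scenario()]
#' @export
#' @examples
#' sc <- scenario(arm_means = c(sham = 5, active_F3 = 9, active_rsfMRI = 5))
#' sc$arm_means
scenario <- function(arm_means = c(sham = 5, active_F3 = 5, active_rsfMRI = 5),
                     common_sd = 8,
                     dropout_prob = 0.10,
                     baseline_mean = 30,
                     baseline_sd = 5,
                     baseline_floor = 20,
                     followup_drift = 0.5,
                     followup_sd = 3,
                     session_model = list(type = "complete"),
                     clamp_post = FALSE,
                     seed = 1L) {
  if (is.null(names(arm_means)) || !any(nzchar(names(arm_means)))) {
    if (length(arm_means) != 3L) {
      stop("unnamed `arm_means` must have exactly 3 entries", call. = FALSE)
    }
    names(arm_means) <- ARM_LEVELS
  }
  if (!setequal(names(arm_means), ARM_LEVELS)) {
    stop("`arm_means` must be named with: ", paste(ARM_LEVELS, collapse = ", "),
         call. = FALSE)
  }
  arm_means <- arm_means[ARM_LEVELS]
  stopifnot(
    "common_sd must be > 0" = is.numeric(common_sd) && common_sd > 0,
    "dropout_prob must be in [0, 1)" =
      dropout_prob >= 0 && dropout_prob < 1,
    "baseline_sd must be > 0" = baseline_sd > 0,
    "baseline_floor must be >= 0" = baseline_floor >= 0,
    "followup_sd must be >= 0" = followup_sd >= 0
  )
  if (!is.list(session_model) ||
      !session_model$type %in% c("complete", "mixture")) {
    stop("`session_model$type` must be \"complete\" or \"mixture\"",
         call. = FALSE)
  }
  if (session_model$type == "mixture") {
    stopifnot(
      "session_model$p_full must be in [0, 1]" =
        session_model$p_full >= 0 && session_model$p_full <= 1,
      "session_model$partial_rate must be in [0, 1]" =
        session_model$partial_rate >= 0 && session_model$partial_rate <= 1
    )
  }
  structure(
    list(
      arm_means = arm_means, common_sd = common_sd,
      dropout_prob = dropout_prob,
      baseline_mean = baseline_mean, baseline_sd = baseline_sd,
      baseline_floor = baseline_floor,
      followup_drift = followup_drift, followup_sd = followup_sd,
      session_model = session_model, clamp_post = clamp_post,
      seed = as.integer(seed)
    ),
    class = "scenario"
  )
}

#' Null scenario: all three arms share the same mean improvement
#'
#' Under the null every arm improves by `shared_mean` points on average, so
#' any declared success is a false positive. Because the posterior engine is
#' pivotal in the outcome SD, the null operating characteristics do not
#' depend on `common_sd`.
#'
#' @param shared_mean Common true mean improvement (points).
#' @inheritParams scenario
#' @param ... Passed on to [scenario()].
#' @return A `scenario`.
#' @export
null_scenario <- function(shared_mean = 5, common_sd = 8, ...) {
  scenario(arm_means = stats::setNames(rep(shared_mean, 3), ARM_LEVELS),
           common_sd = common_sd, ...)
}

#' Single-effective-arm alternative scenario
#'
#' One active arm beats sham by `delta` points; the other active arm equals
#' sham. This is the configuration used in the design's power statements
#' ("a 4-point improvement over sham"). A both-arms-effective variant is
#' available via `delta_other`.
#'
#' @param delta True advantage (points of MADRS improvement) of the
#'   effective arm over sham.
#' @param effective_arm Which active arm carries the effect.
#' @param delta_other Advantage of the other active arm over sham (default 0,
#'   i.e. equal to sham).
#' @param sham_mean Sham mean improvement (points).
#' @inheritParams scenario
#' @param ... Passed on to [scenario()].
#' @return A `scenario`.
#' @export
effect_scenario <- function(delta, effective_arm = "active_rsfMRI",
                            delta_other = 0, sham_mean = 5, common_sd = 8,
                            ...) {
  effective_arm <- match.arg(effective_arm, ACTIVE_ARMS)
  other <- setdiff(ACTIVE_ARMS, effective_arm)
  means <- stats::setNames(rep(sham_mean, 3), ARM_LEVELS)
  means[effective_arm] <- sham_mean + delta
  means[other] <- sham_mean + delta_other
  scenario(arm_means = means, common_sd = common_sd, ...)
}

#' Define the adaptive design constants
#'
#' Encodes the trial's group-sequential skeleton: a maximum of 198
#' participants, interim looks with information targets of 90 and 135
#' evaluable primary outcomes (enrollment pausing at 99 and 148 enrolled,
#' the enrollment overrun implied by 10% attrition), 1:1:1 permuted-block
#' allocation before any arm drop and 2:1 active:sham after, and the
#' posterior-probability decision thresholds: an active arm is dropped when
#' the other active arm has probability >= 0.60 of being superior to it
#' (inclusive boundary), the whole trial stops for futility unless some
#' active arm has probability strictly greater than 0.60 of beating sham,
#' an interim success stop requires 0.9975, and the final analysis declares
#' success at 0.99 -- a threshold calibrated by simulation so the family-wise
#' type-I error is 2.5% across both arms and both looks.
#'
#' @param n_max Maximum enrollment.
#' @param interim_evaluable Evaluable-outcome information targets at the two
#'   interim looks.
#' @param enroll_at_stop Total enrolled if the trial stops at look 1, look 2,
#'   or runs to the final analysis.
#' @param arm_drop_threshold Posterior probability (active i vs active j) at
#'   or above which the inferior arm is dropped.
#' @param futility_threshold Futility boundary: the trial continues only if
#'   some live active arm has Pr(superior to sham) strictly greater than
#'   this.
#' @param interim_success_threshold Pr(superior to sham) at or above which an
#'   interim look stops the trial for success.
#' @param final_success_threshold Pr(superior to sham) at or above which the
#'   final analysis declares success.
#' @param alpha_target Family-wise type-I error target the final threshold
#'   was calibrated to.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(n_max = 198L,
                        interim_evaluable = c(90L, 135L),
                        enroll_at_stop = c(99L, 148L, 198L),
                        arm_drop_threshold = 0.60,
                        futility_threshold = 0.60,
                        interim_success_threshold = 0.9975,
                        final_success_threshold = 0.99,
                        alpha_target = 0.025) {
  interim_evaluable <- as.integer(interim_evaluable)
  enroll_at_stop <- as.integer(enroll_at_stop)
  stopifnot(
    "interim_evaluable must be strictly increasing and < n_max" =
      all(diff(interim_evaluable) > 0) && all(interim_evaluable < n_max),
    "need one enroll_at_stop per look plus the final size" =
      length(enroll_at_stop) == length(interim_evaluable) + 1L,
    "enroll_at_stop must cover the information targets" =
      all(enroll_at_stop[seq_along(interim_evaluable)] >= interim_evaluable),
    "last enroll_at_stop must equal n_max" =
      enroll_at_stop[length(enroll_at_stop)] == n_max,
    "thresholds must satisfy 0.5 < drop <= futility < interim success <= 1" =
      arm_drop_threshold > 0.5 &&
      arm_drop_threshold <= futility_threshold &&
      futility_threshold < interim_success_threshold &&
      interim_success_threshold <= 1,
    "final threshold must be a probability" =
      final_success_threshold > 0 && final_success_threshold <= 1,
    "alpha_target must be in (0, 1]" = alpha_target > 0 && alpha_target <= 1
  )
  structure(
    list(
      n_max = n_max,
      interim_evaluable = interim_evaluable,
      enroll_at_stop = enroll_at_stop,
      arm_drop_threshold = arm_drop_threshold,
      futility_threshold = futility_threshold,
      interim_success_threshold = interim_success_threshold,
      final_success_threshold = final_success_threshold,
      alpha_target = alpha_target
    ),
    class = "design_spec"
  )
}

#' Configure the posterior computation
#'
#' @param method `"normal_plugin"` (default): flat prior on the means with
#'   each arm's variance plugged in at its sample estimate, giving
#'   `pnorm((m_a - m_b) / sqrt(v_a/n_a + v_b/n_b))` -- fast, pivotal, and
#'   accurate at interim sizes of 30+ per arm. `"t_exact"`: full
#'   normal-inverse-gamma posterior under the Jeffreys prior, evaluated by
#'   numerical integration of the difference of two location-scale-t laws.
#'   `"monte_carlo"`: the same posterior by simulation.
#' @param mc_draws Number of posterior draws for `"monte_carlo"`.
#' @param min_n Minimum per-arm evaluable count for a defined probability;
#'   below it [prob_superiority()] throws rather than returning a silent 0.5.
#' @return An object of class `posterior_config`.
#' @export
posterior_config <- function(method = c("normal_plugin", "t_exact",
                                        "monte_carlo"),
                             mc_draws = 10000L, min_n = 2L) {
  method <- match.arg(method)
  if (method == "monte_carlo" && mc_draws < 1000L) {
    stop("mc_draws must be >= 1000 for method = \"monte_carlo\"",
         call. = FALSE)
  }
  stopifnot("min_n must be >= 2" = min_n >= 2L)
  structure(
    list(method = method, mc_draws = as.integer(mc_draws),
         min_n = as.integer(min_n)),
    class = "posterior_config"
  )
}

#' Read a scenario or design from a YAML or JSON config file
#'
#' Field names match the arguments of [scenario()] / [design_spec()];
#' unknown fields are an error so typos do not silently fall back to
#' defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `scenario` or `design_spec`.
#' @export
read_scenario <- function(path) {
  cfg <- read_config_file(path)
  if (!is.null(cfg$arm_means)) cfg$arm_means <- unlist(cfg$arm_means)
  build_from_config(cfg, scenario, "scenario")
}

#' @rdname read_scenario
#' @export
read_design <- function(path) {
  cfg <- read_config_file(path)
  for (f in c("interim_evaluable", "enroll_at_stop")) {
    if (!is.null(cfg[[f]])) cfg[[f]] <- unlist(cfg[[f]])
  }
  build_from_config(cfg, design_spec, "design")
}

read_config_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config extension: .", ext, call. = FALSE)
  }
}

build_from_config <- function(cfg, constructor, what) {
  allowed <- names(formals(constructor))
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    stop("unknown ", what, " fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(constructor, cfg)
}

#' @export
print.scenario <- function(x, ...) {
  cat("Generative scenario\n")
  cat("  mean improvement (points):",
      paste(sprintf("%s=%.4g", names(x$arm_means), x$arm_means),
            collapse = ", "), "\n")
  cat(sprintf("  common SD %.4g | dropout %.3g | baseline N(%.4g, %.4g) floor %.4g\n",
              x$common_sd, x$dropout_prob, x$baseline_mean, x$baseline_sd,
              x$baseline_floor))
  cat(sprintf("  follow-up drift %.4g +/- %.4g per month | sessions: %s | seed %d\n",
              x$followup_drift, x$followup_sd, x$session_model$type, x$seed))
  invisible(x)
}

#' @export
print.design_spec <- function(x, ...) {
  cat("Adaptive design\n")
  cat(sprintf("  max N %d | looks at %s evaluable (enrollment pauses at %s)\n",
              x$n_max, paste(x$interim_evaluable, collapse = "/"),
              paste(x$enroll_at_stop[-length(x$enroll_at_stop)],
                    collapse = "/")))
  cat(sprintf("  drop >= %.4g | futility unless > %.4g | interim success >= %.4g | final success >= %.4g\n",
              x$arm_drop_threshold, x$futility_threshold,
              x$interim_success_threshold, x$final_success_threshold))
  invisible(x)
}
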