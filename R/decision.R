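#' Apply the interim decision rules to a set of posterior probabilities
#'
#' Pure rule layer: given the pairwise posterior probabilities already
#' computed at a look, apply the design's adaptations in precedence order
#'
#' 1. SUCCESS -- if any live active arm has `Pr(> sham) >=`
#'    `interim_success_threshold` (inclusive), stop for success with that
#'    arm; ties broken by the higher posterior, then canonical arm order.
#' 2. FUTILITY -- if no live active arm has `Pr(> sham)` strictly greater
#'    than `futility_threshold`, stop the whole trial for futility.
#' 3. ARM DROP -- with two live active arms, if either has
#'    `Pr(> other active) >= arm_drop_threshold` (inclusive), drop the
#'    inferior arm and continue under 2:1 active:sham allocation.
#' 4. Otherwise continue unchanged.
#'
#' Because the two active-vs-active probabilities are complements and the
#' drop threshold exceeds 0.5, at most one active arm can ever qualify for
#' dropping at a look.
#'
#' @param posteriors Named list/vector with entries
#'   `p_<active>_vs_sham` for each live active arm and, when both are live,
#'   `p_active_F3_vs_active_rsfMRI`.
#' @param design A [design_spec()].
#' @param live_active Character vector of live active arms.
#' @return An `interim_decision`: list with `action` (one of `continue`,
#'   `drop_arm`, `stop_futility`, `stop_success`), `dropped_arm`,
#'   `winning_arm` and the `posteriors` evaluated at the look.
#' @export
decide_interim <- function(posteriors, design, live_active = ACTIVE_ARMS) {
  posteriors <- as.list(posteriors)
  p_sham <- vapply(live_active,
                   function(a) posteriors[[paste0("p_", a, "_vs_sham")]],
                   numeric(1))

  # 1. success stop (inclusive boundary)
  hit <- p_sham >= design$interim_success_threshold
  if (any(hit)) {
    # max posterior wins; canonical order breaks exact ties
    winner <- live_active[hit][which.max(p_sham[hit])]
    return(new_interim_decision("stop_success", winning_arm = winner,
                                posteriors = posteriors))
  }

  # 2. futility: survival requires strictly greater than the boundary
  if (!any(p_sham > design$futility_threshold)) {
    return(new_interim_decision("stop_futility", posteriors = posteriors))
  }

  # 3. arm drop, only while both actives are live (inclusive boundary)
  if (length(live_active) == 2L) {
    p12 <- posteriors[["p_active_F3_vs_active_rsfMRI"]]
    if (!is.null(p12)) {
      if (p12 >= design$arm_drop_threshold) {
        return(new_interim_decision("drop_arm",
                                    dropped_arm = "active_rsfMRI",
                                    posteriors = posteriors))
      }
      if (1 - p12 >= design$arm_drop_threshold) {
        return(new_interim_decision("drop_arm", dropped_arm = "active_F3",
                                    posteriors = posteriors))
      }
    }
  }

  new_interim_decision("continue", posteriors = posteriors)
}

new_interim_decision <- function(action, dropped_arm = NULL,
                                 winning_arm = NULL, posteriors = list()) {
  structure(
    list(action = action, dropped_arm = dropped_arm,
         winning_arm = winning_arm, posteriors = posteriors),
    class = "interim_decision"
  )
}

# Posterior probabilities evaluated at a look: Pr(active > sham) for each
# live active arm, plus Pr(F3 > rsfMRI) when both are live.
look_posteriors <- function(summaries, live_active, cfg) {
  out <- list()
  for (a in live_active) {
    out[[paste0("p_", a, "_vs_sham")]] <-
      prob_superiority(summaries[[a]], summaries[["sham"]], cfg)
  }
  if (length(live_active) == 2L) {
    out[["p_active_F3_vs_active_rsfMRI"]] <-
      prob_superiority(summaries[["active_F3"]],
                       summaries[["active_rsfMRI"]], cfg)
  }
  out
}

#' Interim decision from per-arm summaries
#'
#' Computes the look's posterior probabilities with [prob_superiority()]
#' and applies [decide_interim()].
#'
#' @param summaries Named list of [arm_summary()] objects for the live arms;
#'   must include `sham` and at least one active arm.
#' @param design A [design_spec()].
#' @param cfg A [posterior_config()].
#' @return An `interim_decision`.
#' @export
interim_decision <- function(summaries, design = design_spec(),
                             cfg = posterior_config()) {
  live_active <- intersect(ACTIVE_ARMS, names(summaries))
  check_live(summaries, live_active)
  decide_interim(look_posteriors(summaries, live_active, cfg), design,
                 live_active)
}

#' Final analysis decision
#'
#' At the maximal sample size the trial is successful iff some live active
#' arm reaches `final_success_threshold` posterior probability of
#' superiority to sham; the winner is the argmax. No further multiplicity
#' adjustment is applied -- the threshold itself was calibrated to carry the
#' family-wise type-I error across both arms and both interim looks.
#'
#' @inheritParams interim_decision
#' @return List with `success`, `winning_arm` (NULL if unsuccessful) and
#'   `posteriors`.
#' @export
final_decision <- function(summaries, design = design_spec(),
                           cfg = posterior_config()) {
  live_active <- intersect(ACTIVE_ARMS, names(summaries))
  check_live(summaries, live_active)
  post <- look_posteriors(summaries, live_active, cfg)
  p_sham <- vapply(live_active,
                   function(a) post[[paste0("p_", a, "_vs_sham")]],
                   numeric(1))
  success <- max(p_sham) >= design$final_success_threshold
  list(
    success = success,
    winning_arm = if (success) live_active[which.max(p_sham)] else NULL,
    posteriors = post
  )
}

check_live <- function(summaries, live_active) {
  if (is.null(summaries[["sham"]])) {
    stop("invalid state: sham summary is required", call. = FALSE)
  }
  if (length(live_active) == 0L) {
    stop("invalid state: no live active arms", call. = FALSE)
  }
  invisible(TRUE)
}

#' Permuted-block allocation sequence
#'
#' Generates arm assignments in permuted blocks that guarantee the design's
#' exact allocation ratio within every complete block: one participant per
#' arm (1:1:1) while all three arms are live, and two to the surviving
#' active arm for every one to sham (2:1 active:sham) after an arm drop.
#'
#' @param n Number of assignments to generate.
#' @param live_arms Character vector of live arms (must include `sham`).
#' @return Character vector of length `n`. Consumes the R RNG stream, so it
#'   is reproducible under `set.seed()`.
#' @export
#' @examples
#' set.seed(1)
#' table(allocation_sequence(300, ARM_LEVELS))
allocation_sequence <- function(n, live_arms = ARM_LEVELS) {
  if (!"sham" %in% live_arms) {
    stop("invalid state: sham must be a live arm", call. = FALSE)
  }
  active <- intersect(ACTIVE_ARMS, live_arms)
  block <- if (length(active) == 2L) {
    c("sham", active)                      # 1:1:1
  } else if (length(active) == 1L) {
    c("sham", active, active)              # 2:1 active:sham
  } else {
    stop("invalid state: no live active arms", call. = FALSE)
  }
  n_blocks <- ceiling(n / length(block))
  out <- unlist(lapply(seq_len(n_blocks),
                       function(i) block[sample.int(length(block))]),
                use.names = FALSE)
  out[seq_len(n)]
}

#' @export
print.interim_decision <- function(x, ...) {
  cat("interim decision:", x$action)
  if (!is.null(x$dropped_arm)) cat(" (dropped", x$dropped_arm, "- 2:1 active:sham hereafter)")
  if (!is.null(x$winning_arm)) cat(" (winner", x$winning_arm, ")")
  cat("\n")
  for (nm in names(x$posteriors)) {
    cat(sprintf("  %s = %.4f\n", nm, x$posteriors[[nm]]))
  }
  invisible(x)
}
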