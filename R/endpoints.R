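#' Classify clinical endpoints for simulated participants
#'
#' Applies the trial's depression endpoint definitions to each row of a
#' [generate_cohort()] table:
#'
#' * `response`: at least 50% improvement from baseline,
#'   `(baseline - post) / baseline >= 0.5`;
#' * `remission`: post-treatment MADRS of 10 or less;
#' * `relapse`: any follow-up MADRS of 15 or more;
#' * `itt`: intention-to-treat membership -- received at least one session;
#' * `per_protocol`: completed at least 32 of the 40 sessions (80%);
#' * `maintenance_eligible`: per-protocol completion AND response AND
#'   remission at the post-treatment evaluation AND a subsequent relapse --
#'   the gate for optional maintenance stimulation.
#'
#' Non-evaluable participants (no post score) have all outcome flags
#' `FALSE`; their analysis-set flags still follow their session counts.
#'
#' @param cohort A `cohort` data frame (or any data frame with columns
#'   `baseline`, `post`, `sessions_completed` and `followup_*`).
#' @return A data frame with columns `id`, `response`, `remission`,
#'   `relapse`, `itt`, `per_protocol`, `maintenance_eligible`.
#' @export
#' @examples
#' flags <- classify_endpoints(data.frame(
#'   id = 1, baseline = 32, post = 8, sessions_completed = 34,
#'   followup_1 = 12, followup_2 = 15))
#' flags$maintenance_eligible
classify_endpoints <- function(cohort) {
  if (any(cohort$baseline <= 0, na.rm = TRUE)) {
    stop("invalid record: baseline MADRS must be > 0", call. = FALSE)
  }
  fup_cols <- grep("^followup_", names(cohort), value = TRUE)
  fup <- as.matrix(cohort[, fup_cols, drop = FALSE])
  has_post <- !is.na(cohort$post)
  response <- has_post &
    (cohort$baseline - cohort$post) / cohort$baseline >= 0.5
  remission <- has_post & cohort$post <= 10
  relapse <- if (length(fup_cols)) {
    apply(fup >= 15, 1L, any, na.rm = TRUE)
  } else {
    rep(FALSE, nrow(cohort))
  }
  itt <- cohort$sessions_completed >= 1L
  per_protocol <- cohort$sessions_completed >= 32L
  data.frame(
    id = if (!is.null(cohort$id)) cohort$id else seq_len(nrow(cohort)),
    response = response, remission = remission, relapse = relapse,
    itt = itt, per_protocol = per_protocol,
    maintenance_eligible = per_protocol & response & remission & relapse
  )
}

#' The aiTBS session protocol
#'
#' Constants of the stimulation schedule: each session delivers 60
#' two-second trains of 10 theta bursts (bursts at 5 Hz; each burst three
#' pulses at 50 Hz) separated by 8-second intertrain intervals, eight
#' sessions per day over five business days at 90% of resting motor
#' threshold, with a tolerability titration floor of 70% rMT on sessions
#' 1-2 and 80% on session 3; 90% is mandatory from session 4 on.
#'
#' @param trains_per_session,train_duration_s,bursts_per_train,pulses_per_burst
#'   Train/burst structure.
#' @param pulse_freq_hz,burst_freq_hz Within-burst pulse rate and burst
#'   rate.
#' @param intertrain_interval_s Gap between trains (s).
#' @param sessions_per_day,treatment_days,intersession_interval_min
#'   Accelerated schedule.
#' @param intensity_pct_rmt Target intensity, percent of resting motor
#'   threshold.
#' @param titration_floor Minimum acceptable intensity for sessions 1, 2
#'   and 3; later sessions must be exactly `intensity_pct_rmt`.
#' @return An object of class `session_protocol`.
#' @export
session_protocol <- function(trains_per_session = 60L, train_duration_s = 2,
                             bursts_per_train = 10L, pulses_per_burst = 3L,
                             pulse_freq_hz = 50, burst_freq_hz = 5,
                             intertrain_interval_s = 8,
                             sessions_per_day = 8L, treatment_days = 5L,
                             intersession_interval_min = 60,
                             intensity_pct_rmt = 90,
                             titration_floor = c(70, 70, 80)) {
  counts <- c(trains_per_session, bursts_per_train, pulses_per_burst,
              sessions_per_day, treatment_days)
  stopifnot(
    "protocol counts must be positive" = all(counts > 0),
    "durations must be positive" =
      train_duration_s > 0 && intertrain_interval_s >= 0,
    "titration floors must be nondecreasing" =
      !is.unsorted(c(titration_floor, intensity_pct_rmt))
  )
  structure(
    list(trains_per_session = trains_per_session,
         train_duration_s = train_duration_s,
         bursts_per_train = bursts_per_train,
         pulses_per_burst = pulses_per_burst,
         pulse_freq_hz = pulse_freq_hz, burst_freq_hz = burst_freq_hz,
         intertrain_interval_s = intertrain_interval_s,
         sessions_per_day = sessions_per_day,
         treatment_days = treatment_days,
         intersession_interval_min = intersession_interval_min,
         intensity_pct_rmt = intensity_pct_rmt,
         titration_floor = titration_floor),
    class = "session_protocol"
  )
}

#' Derived quantities of the session protocol
#'
#' Pure arithmetic over the protocol constants: pulses per session
#' (trains x bursts x pulses = 1,800 at defaults), sessions per course
#' (8/day x 5 days = 40), pulses per course (72,000), and session duration
#' `trains * train_duration + (trains - 1) * intertrain_interval` (592 s at
#' defaults; the computed value is reported as-is, with no rounding toward
#' any nominal session length).
#'
#' @param p A [session_protocol()].
#' @return List with `pulses_per_session`, `sessions_per_course`,
#'   `pulses_per_course`, `session_duration_s`.
#' @export
protocol_arithmetic <- function(p = session_protocol()) {
  pulses_session <- p$trains_per_session * p$bursts_per_train *
    p$pulses_per_burst
  sessions_course <- p$sessions_per_day * p$treatment_days
  list(
    pulses_per_session = pulses_session,
    sessions_per_course = sessions_course,
    pulses_per_course = pulses_session * sessions_course,
    session_duration_s = p$trains_per_session * p$train_duration_s +
      (p$trains_per_session - 1) * p$intertrain_interval_s
  )
}

#' Validate a per-session intensity sequence against the titration ladder
#'
#' Sessions 1-2 may be delivered as low as 70% rMT and session 3 as low as
#' 80%, but every session from the fourth on must be delivered at exactly
#' the full target intensity (90% rMT by default).
#'
#' @param intensities_pct_rmt Numeric vector (length <= 40) of delivered
#'   intensities, percent of resting motor threshold.
#' @param protocol A [session_protocol()].
#' @return List with `valid` and `first_violation` (session index, `NA` if
#'   valid).
#' @export
#' @examples
#' validate_titration(c(70, 70, 80, 90, 90))$valid
#' validate_titration(c(90, 90, 90, 80))$first_violation
validate_titration <- function(intensities_pct_rmt,
                               protocol = session_protocol()) {
  x <- intensities_pct_rmt
  n_course <- protocol$sessions_per_day * protocol$treatment_days
  stopifnot("at most one course of sessions" = length(x) <= n_course)
  if (any(x <= 0 | x > 120)) {
    stop("intensities must be in (0, 120] percent of rMT", call. = FALSE)
  }
  floors <- c(protocol$titration_floor,
              rep(protocol$intensity_pct_rmt,
                  max(0L, length(x) - length(protocol$titration_floor))))
  floors <- floors[seq_along(x)]
  target_from <- length(protocol$titration_floor) + 1L
  ok <- x >= floors
  if (length(x) >= target_from) {
    late <- target_from:length(x)
    ok[late] <- x[late] == protocol$intensity_pct_rmt
  }
  first_bad <- if (all(ok)) NA_integer_ else which(!ok)[1L]
  list(valid = all(ok), first_violation = first_bad)
}

#' Adverse-event comparison between sham and pooled active arms
#'
#' Builds the 2x2 table (group x event) and, when the pooled incidence
#' exceeds `incidence_threshold`, tests for increased risk in the active
#' arms with a Pearson chi-squared test (1 df, no continuity correction by
#' default). Below the threshold -- or when a margin is empty -- only
#' descriptive counts and rates are returned, since small-sample testing is
#' not meaningful there.
#'
#' @param active_events,active_n Event count and group size, pooled active
#'   arms.
#' @param sham_events,sham_n Event count and group size, sham arm.
#' @param incidence_threshold Pooled incidence above which a formal test is
#'   run.
#' @param correct Apply the Yates continuity correction.
#' @return An `ae_result`: list with `table` (2x2 counts), `incidence`
#'   (per group and pooled), `analysis` (`"chi_squared"` or
#'   `"descriptive"`), and for the test path `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' ae_analysis(active_events = 30, active_n = 120,
#'             sham_events = 6, sham_n = 60)$statistic  # 5.625
ae_analysis <- function(active_events, active_n, sham_events, sham_n,
                        incidence_threshold = 0.10, correct = FALSE) {
  stopifnot(
    "counts must be >= 0" = all(c(active_events, sham_events) >= 0),
    "event counts cannot exceed group sizes" =
      active_events <= active_n && sham_events <= sham_n,
    "group sizes must be positive" = active_n > 0 && sham_n > 0
  )
  tab <- matrix(c(sham_events, sham_n - sham_events,
                  active_events, active_n - active_events),
                nrow = 2, byrow = TRUE,
                dimnames = list(group = c("sham", "active"),
                                outcome = c("event", "no_event")))
  incidence <- c(sham = sham_events / sham_n,
                 active = active_events / active_n,
                 pooled = (sham_events + active_events) / (sham_n + active_n))
  zero_margin <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  out <- list(table = tab, incidence = incidence)
  if (incidence[["pooled"]] <= incidence_threshold || zero_margin) {
    if (zero_margin && incidence[["pooled"]] > incidence_threshold) {
      warning("degenerate 2x2 margin; falling back to descriptive summary",
              call. = FALSE)
    }
    out$analysis <- "descriptive"
  } else {
    ct <- stats::chisq.test(tab, correct = correct)
    out$analysis <- "chi_squared"
    out$statistic <- unname(ct$statistic)
    out$df <- unname(ct$parameter)
    out$p_value <- ct$p.value
  }
  class(out) <- "ae_result"
  out
}

#' Benjamini-Hochberg adjustment for the secondary outcomes
#'
#' Step-up false-discovery-rate control: with `m` p-values sorted
#' ascending, reject hypotheses 1..k where k is the largest index with
#' `p_(k) <= k * q / m`, and report monotone BH-adjusted p-values
#' (via [stats::p.adjust()]).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param q Target false discovery rate.
#' @return A data.frame with `p_value`, `adjusted`, `reject`, in input
#'   order; zero rows for empty input.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.04, 0.20), q = 0.05)$reject
bh_adjust <- function(p_values, q = 0.05) {
  stopifnot(
    "p-values must be in [0, 1]" =
      all(p_values >= 0 & p_values <= 1, na.rm = TRUE),
    "q must be in (0, 1)" = q > 0 && q < 1
  )
  if (length(p_values) == 0L) {
    return(data.frame(p_value = numeric(0), adjusted = numeric(0),
                      reject = logical(0)))
  }
  adj <- stats::p.adjust(p_values, method = "BH")
  data.frame(p_value = p_values, adjusted = adj, reject = adj <= q)
}

#' Gatekept secondary-outcome testing
#'
#' The design tests secondary outcomes confirmatorily only when the primary
#' analysis succeeded; otherwise the secondaries are exploratory and no
#' rejections are made. The gate is a boolean switch on running the BH
#' procedure, not a hierarchical alpha-passing scheme.
#'
#' @param p_values Secondary-outcome p-values.
#' @param primary_success Did the primary analysis declare success?
#' @param q Target false discovery rate.
#' @return As [bh_adjust()], plus a `tested` column; when the gate is
#'   closed all `reject` are `FALSE` and `tested` is `FALSE`.
#' @export
gatekept_secondary <- function(p_values, primary_success, q = 0.05) {
  out <- bh_adjust(p_values, q)
  out$tested <- rep(isTRUE(primary_success), nrow(out))
  if (!isTRUE(primary_success)) out$reject <- rep(FALSE, nrow(out))
  out
}

#' @export
print.ae_result <- function(x, ...) {
  cat("adverse-event comparison (sham vs pooled active)\n")
  print(x$table)
  cat(sprintf("  incidence: sham %.3f, active %.3f, pooled %.3f\n",
              x$incidence[["sham"]], x$incidence[["active"]],
              x$incidence[["pooled"]]))
  if (x$analysis == "chi_squared") {
    cat(sprintf("  Pearson chi-squared = %.4g on %d df, p = %.4g\n",
                x$statistic, x$df, x$p_value))
  } else {
    cat("  descriptive summary only (low incidence or degenerate table)\n")
  }
  invisible(x)
}
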