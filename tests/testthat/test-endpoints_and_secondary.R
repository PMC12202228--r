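rec <- function(baseline, post, sessions, fup = rep(NA_real_, 6)) {
  df <- data.frame(id = 1L, baseline = baseline, post = post,
                   sessions_completed = sessions)
  for (i in 1:6) df[[paste0("followup_", i)]] <- fup[i]
  df
}

test_that("response, remission and relapse boundaries match the clinical rules", {
  # exactly 50% improvement is a response; post 15 is not remission
  f <- classify_endpoints(rec(30, 15, 40, c(12, 16, NA, NA, NA, NA)))
  expect_true(f$response)
  expect_false(f$remission)
  expect_true(f$relapse)           # follow-up reached 16 >= 15
  expect_false(f$maintenance_eligible)

  # full maintenance pathway: response + remission + relapse + >=32 sessions
  f2 <- classify_endpoints(rec(32, 8, 34, c(10, 15, NA, NA, NA, NA)))
  expect_true(all(f2$response, f2$remission, f2$relapse, f2$per_protocol,
                  f2$maintenance_eligible))

  # post 10 is remission (boundary), baseline 20 -> 10 is exactly 50%
  f3 <- classify_endpoints(rec(20, 10, 40))
  expect_true(f3$response)
  expect_true(f3$remission)
  expect_false(f3$relapse)         # no follow-up at or above 15
  expect_false(f3$maintenance_eligible)

  # follow-ups strictly below 15 never flag relapse
  f4 <- classify_endpoints(rec(32, 8, 40, c(14.9, 14, 13, 12, 11, 10)))
  expect_false(f4$relapse)
})

test_that("per-protocol needs 32 of 40 sessions; one fewer fails", {
  expect_false(classify_endpoints(rec(30, 10, 31))$per_protocol)
  expect_true(classify_endpoints(rec(30, 10, 32))$per_protocol)
  expect_true(classify_endpoints(rec(30, 10, 1))$itt)
  expect_false(classify_endpoints(rec(30, 10, 0))$itt)
})

test_that("per-protocol participants are a subset of ITT on simulated cohorts", {
  sc <- scenario(
    session_model = list(type = "mixture", p_full = 0.7, partial_rate = 0.7),
    dropout_prob = 0.15, seed = 44)
  co <- generate_cohort(sc, 1000, sample(ARM_LEVELS, 1000, replace = TRUE))
  flags <- classify_endpoints(co)
  expect_true(all(!flags$per_protocol | flags$itt))
  expect_true(all(!flags$maintenance_eligible |
                    (flags$per_protocol & flags$response & flags$remission &
                       flags$relapse)))
  # non-evaluable participants have no outcome flags
  out <- flags[!co$evaluable, ]
  expect_true(all(!out$response & !out$remission & !out$itt))
})

test_that("invalid baselines are rejected", {
  expect_error(classify_endpoints(rec(0, 0, 40)), "baseline")
})

test_that("protocol arithmetic reproduces the stimulation dose constants", {
  pa <- protocol_arithmetic(session_protocol())
  expect_equal(pa$pulses_per_session, 1800)
  expect_equal(pa$sessions_per_course, 40)
  expect_equal(pa$pulses_per_course, 72000)
  # 60 trains x 2 s + 59 intertrain intervals x 8 s
  expect_equal(pa$session_duration_s, 592)
  one <- protocol_arithmetic(session_protocol(trains_per_session = 1L))
  expect_equal(one$session_duration_s, 2)
})

test_that("titration ladder is enforced from session four onward", {
  expect_true(validate_titration(c(70, 70, 80, 90, 90, 90))$valid)
  v <- validate_titration(c(90, 90, 90, 80, 90))
  expect_false(v$valid)
  expect_equal(v$first_violation, 4L)
  expect_true(validate_titration(rep(90, 40))$valid)
  w <- validate_titration(c(65, 70, 80, 90))
  expect_false(w$valid)
  expect_equal(w$first_violation, 1L)
  expect_error(validate_titration(c(70, 0)), "intensities")
  expect_error(validate_titration(rep(90, 41)), "course")
})

test_that("adverse-event chi-squared matches the hand-computed Pearson value", {
  res <- ae_analysis(active_events = 30, active_n = 120,
                     sham_events = 6, sham_n = 60)
  expect_equal(res$analysis, "chi_squared")
  expect_equal(res$statistic, 5.625, tolerance = 1e-12)
  expect_equal(res$df, 1)
  # identical rates give a zero statistic
  same <- ae_analysis(20, 100, 10, 50)
  expect_equal(same$statistic, 0, tolerance = 1e-12)
})

test_that("low pooled incidence takes the descriptive path, no test emitted", {
  res <- ae_analysis(active_events = 5, active_n = 120,
                     sham_events = 2, sham_n = 60)
  expect_equal(res$analysis, "descriptive")
  expect_null(res$statistic)
  expect_equal(res$incidence[["pooled"]], 7 / 180)
})

test_that("chi-squared agrees with an independent Pearson oracle on random tables", {
  set.seed(1234)
  for (i in 1:25) {
    na <- sample(40:200, 1)
    ns <- sample(30:100, 1)
    ea <- rbinom(1, na, 0.3)
    es <- rbinom(1, ns, 0.25)
    res <- ae_analysis(ea, na, es, ns)
    if (res$analysis == "chi_squared") {
      expect_equal(res$statistic, pearson_oracle(res$table),
                   tolerance = 1e-9)
      expect_equal(res$p_value,
                   pchisq(res$statistic, 1, lower.tail = FALSE),
                   tolerance = 1e-12)
    }
  }
})

test_that("BH step-up matches its brute-force definition", {
  out <- bh_adjust(c(0.01, 0.02, 0.04, 0.20), q = 0.05)
  expect_equal(out$reject, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(bh_adjust(0.04, q = 0.05)$reject, TRUE)
  expect_equal(bh_adjust(rep(1, 5), q = 0.05)$reject, rep(FALSE, 5))
  expect_equal(nrow(bh_adjust(numeric(0))), 0)

  set.seed(77)
  for (i in 1:30) {
    p <- runif(sample(1:12, 1))^sample(1:3, 1)
    q <- runif(1, 0.01, 0.2)
    out <- bh_adjust(p, q)
    expect_equal(out$reject, bh_oracle_reject(p, q))
    # adjusted p-values are monotone in the raw ordering
    expect_true(!is.unsorted(out$adjusted[order(out$p_value)]))
    bonf <- p <= q / length(p)
    raw <- p <= q
    expect_true(all(!bonf | out$reject))   # BH rejects all Bonferroni picks
    expect_true(all(!out$reject | raw))    # and only unadjusted picks
  }
})

test_that("gatekeeping blocks secondary rejections when the primary fails", {
  p <- c(0.001, 0.01, 0.3)
  open <- gatekept_secondary(p, primary_success = TRUE)
  closed <- gatekept_secondary(p, primary_success = FALSE)
  expect_true(any(open$reject))
  expect_false(any(closed$reject))
  expect_true(all(open$tested))
  expect_false(any(closed$tested))
  expect_equal(open$adjusted, closed$adjusted)  # estimates still reported
})
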