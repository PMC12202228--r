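test_that("a trial is a deterministic function of scenario, design and seed", {
  sc <- effect_scenario(delta = 4)
  a <- simulate_trial(sc, seed = 42)
  b <- simulate_trial(sc, seed = 42)
  expect_identical(a, b)
  c <- simulate_trial(sc, seed = 43)
  expect_false(identical(a, c))
})

test_that("enrolled totals are always one of the three design sizes", {
  design <- design_spec()
  set.seed(1)
  seeds <- sample.int(1e6, 60)
  scens <- list(null_scenario(), effect_scenario(4), effect_scenario(30))
  for (sc in scens) {
    for (s in seeds[1:20]) {
      r <- simulate_trial(sc, design = design, seed = s)
      expect_true(r$enrolled_total %in% design$enroll_at_stop)
      stage_idx <- match(r$stop_stage, c("interim1", "interim2", "final"))
      expect_equal(r$enrolled_total, design$enroll_at_stop[stage_idx])
      expect_lte(r$evaluable_total, r$enrolled_total)
    }
    seeds <- seeds[-(1:20)]
  }
})

test_that("overwhelming separation stops at the first interim for success", {
  sc <- scenario(arm_means = c(sham = 5, active_F3 = 35, active_rsfMRI = 5),
                 common_sd = 1)
  # analytically, at ~30 per arm the posterior vs sham is astronomically
  # above 0.9975: z = 30 / sqrt(2/30) ~ 116
  for (s in 1:10) {
    r <- simulate_trial(sc, seed = s)
    expect_equal(r$stop_stage, "interim1")
    expect_equal(r$stop_reason, "success")
    expect_true(r$success)
    expect_equal(r$winning_arm, "active_F3")
    expect_equal(r$enrolled_total, 99L)
  }
})

test_that("the first look uses exactly the first 90 evaluable outcomes", {
  # with zero dropout, replay the trial's position-indexed draws and
  # recompute the look-1 posteriors from participants 1..90 only
  sc <- null_scenario(dropout_prob = 0)
  seed <- 2
  r <- simulate_trial(sc, seed = seed)
  set.seed(seed)
  invisible(runif(198))          # attrition draws (all evaluable here)
  z <- rnorm(198)
  arm <- allocation_sequence(198, ARM_LEVELS)
  change <- sc$arm_means[arm] + sc$common_sd * z
  idx <- 1:90                    # information target, not the 99 enrolled
  s <- lapply(setNames(ARM_LEVELS, ARM_LEVELS),
              function(a) arm_summary(change[idx][arm[idx] == a]))
  expected <- interim_decision(s, design_spec())
  expect_equal(r$history[[1]]$posteriors, expected$posteriors,
               tolerance = 1e-12)
  # bookkeeping: with no attrition every enrolled participant is evaluable
  expect_equal(r$evaluable_total, r$enrolled_total)
})

test_that("ITT bookkeeping: per-arm evaluable counts sum to the evaluable total", {
  for (s in c(3, 14, 159)) {
    r <- simulate_trial(effect_scenario(5), seed = s)
    expect_equal(sum(r$arm_n), r$evaluable_total)
  }
})

test_that("at most one active arm is ever dropped and sham is never dropped", {
  set.seed(9)
  seeds <- sample.int(1e6, 40)
  for (s in seeds) {
    r <- simulate_trial(null_scenario(), seed = s)
    expect_true(is.null(r$dropped_arm) ||
                  r$dropped_arm %in% c("active_F3", "active_rsfMRI"))
    drops <- sum(vapply(r$history,
                        function(h) h$action == "drop_arm", logical(1)))
    expect_lte(drops, 1L)
  }
})

test_that("null stopping behavior is invariant to the outcome SD (pivotality)", {
  # the plugin posterior depends on the data only through Welch z-statistics,
  # so with common random numbers the decision path is identical under any SD
  reps <- 400
  a <- simulate_trials(null_scenario(common_sd = 4), n_reps = reps, seed = 5)
  b <- simulate_trials(null_scenario(common_sd = 16), n_reps = reps, seed = 5)
  expect_identical(a$stop_stage, b$stop_stage)
  expect_identical(a$stop_reason, b$stop_reason)
  expect_identical(a$success, b$success)
  # and with independent randomness the aggregate rates agree within MC error
  c <- simulate_trials(null_scenario(common_sd = 16), n_reps = reps,
                       seed = 1005)
  p1 <- mean(a$stop_stage == "interim1")
  p2 <- mean(c$stop_stage == "interim1")
  expect_lt(abs(p1 - p2), 3 * sqrt(2 * 0.5 * 0.5 / reps))
})

test_that("under the null, interim-success alone never exceeds overall type-I error", {
  tr <- simulate_trials(null_scenario(), n_reps = 1500, seed = 8)
  expect_lte(mean(tr$interim_success), mean(tr$success))
})

test_that("success at a stop implies a recorded winner and reason coherence", {
  tr <- simulate_trials(effect_scenario(5), n_reps = 300, seed = 12)
  suc <- tr[tr$stop_reason == "success", ]
  expect_true(all(suc$success))
  expect_true(all(!is.na(suc$winning_arm)))
  fut <- tr[tr$stop_reason == "futility", ]
  expect_true(all(!fut$success))
  expect_true(all(is.na(fut$winning_arm)))
})
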