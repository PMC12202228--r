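design <- design_spec()

test_that("futility stops when neither arm clears 60% against sham", {
  d <- decide_interim(post_list(0.55, 0.58, 0.52), design)
  expect_equal(d$action, "stop_futility")
})

test_that("interim success stops at 99.75% with the winning arm recorded", {
  d <- decide_interim(post_list(0.998, 0.70, 0.90), design)
  expect_equal(d$action, "stop_success")
  expect_equal(d$winning_arm, "active_F3")
  # ties in threshold crossing: higher posterior wins
  d2 <- decide_interim(post_list(0.9980, 0.9990, 0.45), design)
  expect_equal(d2$winning_arm, "active_rsfMRI")
})

test_that("a 65% active-vs-active posterior drops the inferior arm", {
  d <- decide_interim(post_list(0.80, 0.70, 0.65), design)
  expect_equal(d$action, "drop_arm")
  expect_equal(d$dropped_arm, "active_rsfMRI")
  d2 <- decide_interim(post_list(0.70, 0.80, 0.35), design)
  expect_equal(d2$dropped_arm, "active_F3")
})

test_that("no threshold met means continue unchanged", {
  d <- decide_interim(post_list(0.70, 0.70, 0.50), design)
  expect_equal(d$action, "continue")
  expect_null(d$dropped_arm)
})

test_that("boundaries: drop is inclusive at 0.60, futility survival is strict", {
  # exactly 0.60 active-vs-active: "60% or greater" drops
  d <- decide_interim(post_list(0.75, 0.70, 0.60), design)
  expect_equal(d$action, "drop_arm")
  expect_equal(d$dropped_arm, "active_rsfMRI")
  # exactly 0.60 vs sham is not "greater than": futility
  d2 <- decide_interim(post_list(0.60, 0.55, 0.50), design)
  expect_equal(d2$action, "stop_futility")
  # just above survives
  d3 <- decide_interim(post_list(0.600001, 0.55, 0.50), design)
  expect_equal(d3$action, "continue")
})

test_that("rule precedence is success, then futility, then arm drop", {
  # success beats a drop-qualifying comparison
  d <- decide_interim(post_list(0.9990, 0.20, 0.99), design)
  expect_equal(d$action, "stop_success")
  # futility beats arm drop (both arms weak but one dominates the other)
  d2 <- decide_interim(post_list(0.55, 0.30, 0.90), design)
  expect_equal(d2$action, "stop_futility")
})

test_that("both active arms can never qualify for dropping at once", {
  # complementarity: p12 and 1-p12 cannot both reach an inclusive 0.60
  for (p12 in c(0, 0.4, 0.5, 0.6, 0.99)) {
    d <- decide_interim(post_list(0.8, 0.8, p12), design)
    expect_lte(sum((p12 >= 0.6) + ((1 - p12) >= 0.6)), 1L)
    expect_true(d$action %in% c("continue", "drop_arm"))
  }
})

test_that("raising the interim success threshold never creates a success", {
  strict <- design_spec(interim_success_threshold = 0.999)
  for (p in c(0.99, 0.997, 0.9975, 0.9989, 0.9995)) {
    lax <- decide_interim(post_list(p, 0.7, 0.5), design)
    hard <- decide_interim(post_list(p, 0.7, 0.5), strict)
    # monotone: success under the stricter bar implies success under 0.9975
    expect_true(hard$action != "stop_success" ||
                  lax$action == "stop_success")
    expect_equal(lax$action == "stop_success", p >= 0.9975)
    expect_equal(hard$action == "stop_success", p >= 0.999)
  }
})

test_that("interim_decision computes posteriors from summaries end to end", {
  s <- list(sham = summ(30, 5, 64), active_F3 = summ(30, 20, 64),
            active_rsfMRI = summ(30, 5.5, 64))
  d <- interim_decision(s, design)
  expect_equal(d$action, "stop_success")
  expect_equal(d$winning_arm, "active_F3")
  expect_named(d$posteriors,
               c("p_active_F3_vs_sham", "p_active_rsfMRI_vs_sham",
                 "p_active_F3_vs_active_rsfMRI"), ignore.order = TRUE)
  # deterministic given summaries and design
  expect_identical(d, interim_decision(s, design))
  # after a drop only the survivor is evaluated; drop rule is vacuous
  s1 <- s[c("sham", "active_F3")]
  d1 <- interim_decision(list(sham = summ(30, 5, 64),
                              active_F3 = summ(30, 7, 64)), design)
  expect_equal(d1$action, "continue")
  expect_named(d1$posteriors, "p_active_F3_vs_sham")
})

test_that("final decision applies the 99% rule with argmax winner", {
  mk <- function(p) {
    # invert the plugin form to build a summary hitting probability p
    z <- qnorm(p)
    list(sham = summ(60, 5, 64),
         active_F3 = summ(60, 5 + z * sqrt(64 / 60 + 64 / 60), 64))
  }
  expect_true(final_decision(mk(0.992), design)$success)
  expect_false(final_decision(mk(0.985), design)$success)
  two <- list(sham = summ(60, 5, 64),
              active_F3 = summ(60, 5 + qnorm(0.991) * sqrt(128 / 60), 64),
              active_rsfMRI = summ(60, 5 + qnorm(0.995) * sqrt(128 / 60), 64))
  fd <- final_decision(two, design)
  expect_true(fd$success)
  expect_equal(fd$winning_arm, "active_rsfMRI")
})

test_that("invalid decision states raise errors", {
  expect_error(interim_decision(list(active_F3 = summ(30, 5, 64)), design),
               "sham")
  expect_error(interim_decision(list(sham = summ(30, 5, 64)), design),
               "no live active arms")
})

test_that("permuted blocks deliver exact allocation ratios", {
  set.seed(10)
  pre <- allocation_sequence(300, ARM_LEVELS)
  expect_equal(unname(table(pre)[ARM_LEVELS]), rep(100L, 3),
               ignore_attr = TRUE)
  post <- allocation_sequence(300, c("sham", "active_F3"))
  expect_equal(sum(post == "active_F3"), 200)
  expect_equal(sum(post == "sham"), 100)
  # exact ratio within every complete block
  blocks <- matrix(pre, nrow = 3)
  expect_true(all(apply(blocks, 2, function(b) setequal(b, ARM_LEVELS))))
  # reproducible under a fixed seed
  set.seed(10)
  expect_identical(pre, allocation_sequence(300, ARM_LEVELS))
  expect_error(allocation_sequence(10, c("active_F3", "active_rsfMRI")),
               "sham")
})
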