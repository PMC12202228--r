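#!/usr/bin/env Rscript
# Step 3 -- recover the final-analysis success threshold by simulation.
#
# With the interim rules held fixed, bisects the final success threshold on
# a 0.001 grid over one common-random-number batch of 10,000 null trials
# until the family-wise type-I error is at or below 2.5%. Finding to
# expect: the calibration lands at ~0.99 -- i.e. the design's stated final
# threshold is exactly what error control dictates -- with roughly 1% of
# the error budget spent by the 0.9975 interim success rule.

library(aitbsim)
dir.create("results", showWarnings = FALSE)

cal <- calibrate_final_threshold(n_reps = 10000L, seed = 20260923L)
print(cal)

jsonlite::write_json(
  list(calibrated_final_threshold = cal$calibrated_final_threshold,
       achieved_alpha = cal$achieved_alpha,
       interim_alpha = cal$interim_alpha,
       alpha_target = cal$alpha_target,
       n_reps = cal$n_reps),
  "results/calibration.json", auto_unbox = TRUE, digits = NA)
utils::write.csv(cal$trace, "results/calibration_trace.csv",
                 row.names = FALSE)
cat("wrote results/calibration.json and results/calibration_trace.csv\n")
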