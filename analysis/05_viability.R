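#!/usr/bin/env Rscript
# Step 5 — graft-viability calls.
#
# Runs the classifier end-to-end on the noiseless table-value cohort
# (3 kidneys/condition, unperfused): per-kidney IS SI ratio, OS ADC and IS
# ADC are measured from simulated images and compared with the published
# CD0h reference at 2-SD margins. Expected: CD0h and CD1h functioning,
# CD2h non-functioning (congestion plus the two-edema pattern), 9/9.

library(renograft)
dir.create("results", showWarnings = FALSE)

cohort <- make_cohort(condition_presets("none", zero_sd = TRUE), seed = 11,
                      rcc_t2star_factor = 1)
ev <- evaluate_rule(cohort)

cat("Confusion matrix (truth x predicted):\n")
print(ev$confusion)
cat("Accuracy:", ev$accuracy, "\n")
conds <- vapply(cohort, `[[`, "", "condition")
jsonlite::write_json(
  list(accuracy = ev$accuracy,
       calls = lapply(seq_along(ev$calls), function(i)
         list(kidney = i, condition = conds[i],
              label = ev$calls[[i]]$label,
              flags = as.list(ev$calls[[i]]$flags),
              metrics = ev$calls[[i]]$metrics))),
  "results/viability.json", auto_unbox = TRUE, digits = NA)
k2 <- which(conds == "CD2h")[1]
cat("Example CD2h kidney: IS SI ratio",
    round(ev$calls[[k2]]$metrics$is_si_ratio, 3),
    "| OS ADC", round(ev$calls[[k2]]$metrics$os_adc, 3),
    "| IS ADC", round(ev$calls[[k2]]$metrics$is_adc, 3),
    "->", ev$calls[[k2]]$label, "\n")
cat("Wrote results/viability.json\n")
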