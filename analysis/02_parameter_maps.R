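#!/usr/bin/env Rscript
# Step 2 — noiseless parameter-map recovery.
#
# Phantoms carry the published compartment values exactly (zero-SD presets);
# multi-echo gradient-echo and two-b diffusion signals are simulated without
# noise, T2* and ADC maps fitted, and compartment ROI means compared with
# the assigned truth. This is the pipeline's calibration experiment: any
# mismatch would be a defect in the simulate -> map -> ROI chain itself.

library(renograft)
dir.create("results", showWarnings = FALSE)

acq <- acquisition_config(TE_list = c(5, 10, 20, 40, 80), b_values = c(0, 134))
rows <- list()
for (cond in c("CD0h", "CD1h", "CD2h")) {
  pr <- condition_preset(cond, zero_sd = TRUE)
  ph <- make_kidney_phantom(preset = pr, seed = 1, rcc_t2star_factor = 1)
  rois <- derive_rois(ph)
  t2 <- transfer_roi(rois, fit_t2star(simulate_gre(ph, acq)))
  adc <- transfer_roi(rois, compute_adc_map(simulate_dwi(ph, acq)))
  rows[[cond]] <- data.frame(
    condition = cond, compartment = compartment_names(),
    t2star_true = unname(pr$t2star), t2star_recovered = t2$mean,
    adc_true = unname(pr$adc), adc_recovered = adc$mean)
}
rec <- do.call(rbind, rows)
rec$t2star_rel_err <- abs(rec$t2star_recovered / rec$t2star_true - 1)
rec$adc_rel_err <- abs(rec$adc_recovered / rec$adc_true - 1)
write.csv(rec, "results/recovery.csv", row.names = FALSE)

cat("Max relative recovery error: T2*", format(max(rec$t2star_rel_err), digits = 3),
    "| ADC", format(max(rec$adc_rel_err), digits = 3), "\n")
cat("Example: CD0h IM T2* recovered", round(rec$t2star_recovered[rec$condition == "CD0h" &
    rec$compartment == "IM"], 4), "ms (assigned 218.1)\n")
cat("Wrote results/recovery.csv\n")
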