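#!/usr/bin/env Rscript

# Step 1: generate the pseudo individual-patient data standing in for the
# two-arm adjuvant trial (invasive-disease-free survival with a cured
# fraction), and check the empirical curves against the published anchors.

suppressPackageStartupMessages(library(tdm1cea))

seed <- 20260921L
dir.create("results", showWarnings = FALSE)

spec <- trial_sim_spec()  # 743/arm, HR 0.54, censoring at 101 months,
                          # cure fractions calibrated to 85.58% / 71.11%
                          # disease-free survival at 84 months
ipd <- simulate_trial_ipd(spec, seed = seed)
write_ipd(ipd, "results/trial_ipd.csv")
write_life_table(synthetic_life_table(), "results/life_table.csv")

message(sprintf("simulated %d patients per arm (seed %d)", spec$n_per_arm,
                seed))
for (arm in c("TDM1", "TRAS")) {
  sub <- ipd[ipd$arm == arm, ]
  km <- km_estimate(sub)
  utils::write.csv(km, sprintf("results/km_%s.csv", arm), row.names = FALSE)
  message(sprintf(
    "  %s: %d events; KM disease-free survival at 84 mo = %.1f%% (anchor %.2f%%)",
    arm, sum(sub$event), 100 * km_survival_at(km, 84),
    100 * spec$anchor_surv[[arm]]))
}
message("wrote results/trial_ipd.csv, results/life_table.csv, results/km_*.csv")
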