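#!/usr/bin/env Rscript
# Step 4 -- statistical calibration of the group-level test: type-I error
# of the Huynh-Feldt-corrected category effect under a compound-symmetric
# null, and power for the default-preset precursor effect at n = 21.

suppressPackageStartupMessages(library(frpdeconv))
dir.create("results", showWarnings = FALSE)

t1 <- anova_type1_sim(n_subjects = 21, n_levels = 3, n_reps = 2000,
                      seed = 401)
pw <- category_power_sim(make_default_truth(), n_subjects = 21,
                         n_reps = 200, seed = 402)
nul <- category_power_sim(make_default_truth("null"), n_subjects = 21,
                          n_reps = 200, seed = 403)

out <- data.frame(
  quantity = c("type1_rate_1factor_null", "power_default_preset",
               "rejection_rate_null_preset"),
  value = c(t1$rate, pw$power, nul$power),
  n_reps = c(t1$n_reps, pw$n_reps, nul$n_reps))
write.csv(out, "results/stats_calibration.csv", row.names = FALSE)
cat("Corrected type-I error at alpha = 0.05 (2000 reps):", t1$rate, "\n")
cat("Power for the configured precursor effect at n = 21:", pw$power, "\n")
cat("Rejection rate under the null preset:", nul$power, "\n")
cat("Wrote results/stats_calibration.csv\n")
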