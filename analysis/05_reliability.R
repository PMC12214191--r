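#!/usr/bin/env Rscript
# Repeated-measurement reliability: re-digitize a 10% subsample of the
# cohort's measurements with realistic landmarking noise (0.5 deg
# angular, 0.15 mm linear) and compute the two-way random-effects,
# absolute-agreement, single-measurement ICC per metric.

library(orthomotion)

dir.create("results", showWarnings = FALSE)
sim <- simulate_cohort(cohort_sim_params(n_patients = 33, seed = 1))

set.seed(2)
idx <- sample(nrow(sim$cohort), ceiling(0.1 * nrow(sim$cohort)))
rows <- lapply(c("MD_deg", "BL_deg", "MD_mm", "BL_mm", "IE_mm"), function(m) {
  s1 <- sim$cohort[[paste0("d_", m)]][idx]
  s2 <- s1 + rnorm(length(idx), 0, if (grepl("deg", m)) 0.5 else 0.15)
  r <- icc_agreement(cbind(s1, s2))
  data.frame(metric = m, n_items = r$n, icc = r$icc,
             ci_low = r$ci_low, ci_high = r$ci_high, model = r$model)
})
icc_tab <- do.call(rbind, rows)
write.csv(icc_tab, "results/icc_report.csv", row.names = FALSE)
print(icc_tab[, 1:5], digits = 4)
cat("wrote results/icc_report.csv\n")
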