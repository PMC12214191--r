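#!/usr/bin/env Rscript
# Influencing-factor analysis: fit the linear mixed model (fixed
# effects: age, gender, overbite, overjet, TADs, crowding, G6,
# attachment, power ridge; random intercept per patient) for every
# tooth type and metric of the simulated cohort, and demonstrate
# parameter recovery of a simulated anchorage effect (TADs absent,
# -1.79 mm on the U1 mesiodistal deviation) at 200 patients.

library(orthomotion)

dir.create("results", showWarnings = FALSE)

## per-tooth models on the study-sized cohort
sim <- simulate_cohort(cohort_sim_params(n_patients = 33, seed = 1))
rows <- list()
for (tid in c("U1", "U2", "U3", "U5", "U6", "U7")) {
  sub <- sim$cohort[sim$cohort$tooth == tid, ]
  for (m in c("MD_deg", "BL_deg", "MD_mm", "BL_mm", "IE_mm")) {
    fit <- fit_lmm(sub, paste0("d_", m))
    co <- fit$coefficients
    co$tooth <- tid; co$metric <- m; co$singular <- fit$singular
    rows[[paste(tid, m)]] <- co
  }
}
lmm_tab <- do.call(rbind, rows)
rownames(lmm_tab) <- NULL
write.csv(lmm_tab, "results/lmm_coefficients.csv", row.names = FALSE)
cat(sprintf("fitted %d mixed models (33 patients each); %d singular fits flagged\n",
            length(rows), sum(vapply(rows, function(r) r$singular[1], logical(1)))))

## recovery of a known effect at n = 200
p <- cohort_sim_params(n_patients = 200, seed = 11, baseline = "zero",
                       beta = list(MD_mm = list(U1 = c(tadsabsent = -1.79))),
                       sigma_patient = 0.5, sigma_residual = 1.0)
fit <- fit_lmm(simulate_cohort(p)$cohort |>
                 (\(d) d[d$tooth == "U1", ])(), "d_MD_mm")
b <- fit$coefficients[fit$coefficients$term == "tadsabsent", ]
cat(sprintf("recovery at n = 200: true beta = -1.79, fitted %.3f (SE %.3f, p = %.1e)\n",
            b$estimate, b$se, b$p))
cat("wrote results/lmm_coefficients.csv\n")
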