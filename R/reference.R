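# Published summary statistics of a 33-patient (396-tooth) maxillary
# first-premolar-extraction clear-aligner cohort: designed and achieved
# movement means/SDs per tooth type and metric, and baseline patient
# characteristics. These figures seed the default simulation scenario
# (the per-tooth deviation pattern: anterior distal tipping, posterior
# mesial tipping, under-expressed buccolingual inclination) and the
# worked-example checks of the designed-minus-achieved arithmetic.

#' Reference cohort movement summary
#'
#' Designed and achieved mean +/- SD, difference (designed - achieved)
#' mean +/- SD and paired-t p-value per tooth type and metric, from a
#' 33-patient premolar-extraction aligner cohort. Used as the default
#' movement prescription scenario of the synthetic generator.
#'
#' @return data.frame with columns `tooth`, `metric`, `designed_mean`,
#'   `designed_sd`, `achieved_mean`, `achieved_sd`, `diff_mean`,
#'   `diff_sd`, `p`
#' @export
reference_cohort_summary <- function() {
  tab <- rbind(
    c("U1", "MD_deg",  -3.75,  2.09,  -3.81,  2.32,  0.06, 2.57, 0.873),
    c("U1", "BL_deg",  39.34,  4.54,  28.46,  5.59, 10.88, 4.55, 0.000),
    c("U1", "MD_mm",   -9.07, 24.35, -10.56, 27.35,  1.49, 3.29, 0.002),
    c("U1", "BL_mm",   -0.01,  4.76,  -0.12,  4.79,  0.11, 0.71, 0.208),
    c("U1", "IE_mm",    0.36,  1.07,   0.77,  1.50, -0.42, 1.37, 0.027),
    c("U2", "MD_deg", -13.28,  4.21, -14.99,  5.17,  1.71, 4.98, 0.013),
    c("U2", "BL_deg",  36.32,  5.66,  25.76,  5.66, 10.56, 5.57, 0.000),
    c("U2", "MD_mm",   -8.33, 21.14,  -9.66, 23.77,  1.33, 3.01, 0.002),
    c("U2", "BL_mm",   -0.18, 13.50,  -0.27, 13.54,  0.09, 0.93, 0.622),
    c("U2", "IE_mm",    0.34,  1.13,   0.35,  1.22, -0.01, 0.99, 0.760),
    c("U3", "MD_deg",  -5.87,  3.90,  -8.23,  4.34,  2.36, 4.21, 0.000),
    c("U3", "BL_deg",  32.20,  4.88,  21.29,  4.93, 10.92, 6.07, 0.000),
    c("U3", "MD_mm",   -6.77, 16.81,  -7.28, 18.85,  0.51, 3.40, 0.053),
    c("U3", "BL_mm",   -0.08, 19.15,  -0.71, 18.95,  0.63, 4.92, 0.941),
    c("U3", "IE_mm",    0.51,  1.34,   0.38,  1.22,  0.13, 1.07, 0.358),
    c("U5", "MD_deg",   3.69,  5.47,  12.14,  5.53, -8.44, 6.38, 0.000),
    c("U5", "BL_deg",  11.44,  4.29,   2.70, 10.74,  8.75, 11.20, 0.000),
    c("U5", "MD_mm",   -3.22,  9.39,  -4.25, 11.77,  1.03, 2.81, 0.012),
    c("U5", "BL_mm",   -1.00, 24.06,  -0.90, 23.77, -0.10, 0.90, 0.211),
    c("U5", "IE_mm",    0.69,  1.84,   0.07,  0.96,  0.62, 1.46, 0.002),
    c("U6", "MD_deg",   1.24,  3.69,  10.15,  5.13, -8.91, 5.04, 0.000),
    c("U6", "BL_deg",   4.07,  4.47,   3.01,  6.13,  1.05, 4.93, 0.116),
    c("U6", "MD_mm",   -1.32,  3.47,  -1.99,  5.69,  0.67, 3.03, 0.041),
    c("U6", "BL_mm",   -1.38, 26.71,  -0.94, 26.96, -0.44, 2.75, 0.223),
    c("U6", "IE_mm",    0.44,  1.40,  -0.10,  0.81,  0.54, 1.39, 0.005),
    c("U7", "MD_deg",  -1.78,  6.35,   5.30,  7.89, -7.08, 6.60, 0.000),
    c("U7", "BL_deg",   9.12,  5.89,  11.24,  9.24, -2.13, 6.14, 0.012),
    c("U7", "MD_mm",    2.71,  9.27,   1.57,  7.40,  1.14, 3.44, 0.016),
    c("U7", "BL_mm",   -1.02, 29.61,  -1.11, 30.29,  0.10, 1.32, 0.593),
    c("U7", "IE_mm",   -0.18,  0.92,  -0.10,  0.72, -0.08, 0.80, 0.260))
  out <- data.frame(tooth = tab[, 1], metric = tab[, 2],
                    stringsAsFactors = FALSE)
  num <- apply(tab[, 3:9], 2, as.numeric)
  colnames(num) <- c("designed_mean", "designed_sd", "achieved_mean",
                     "achieved_sd", "diff_mean", "diff_sd", "p")
  cbind(out, num)
}

#' Reference baseline patient characteristics
#'
#' Cohort-level means and SDs of the patient covariates, used as the
#' default covariate distributions of the cohort simulator.
#'
#' @return named list of distribution parameters
#' @export
reference_baseline <- function() {
  list(
    n_patients = 33L,
    age = c(mean = 24.73, sd = 6.07),
    age_range = c(18, 35),
    p_male = 11 / 33,
    overbite = c(mean = 2.27, sd = 1.57),
    overjet = c(mean = 4.42, sd = 2.24),
    crowding = c(mean = 3.21, sd = 3.34)
  )
}
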