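# Cohort statistics: normality screen, paired designed-vs-achieved
# tests, ICC reliability, and the linear mixed model of influencing
# factors. Alpha is 0.05 throughout with no multiple-testing correction
# by default (a Benjamini-Hochberg option exists on the summary).

#' Shapiro-Wilk normality screen
#'
#' Thin wrapper reporting degeneracy explicitly; used as a screen only,
#' never to switch test families silently.
#'
#' @param values numeric vector, 3 <= n <= 5000
#' @return list: `W`, `p`, `n`, `degenerate`
#' @export
shapiro_screen <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3) stop("shapiro_screen: need at least 3 finite values")
  if (n > 5000) stop("shapiro_screen: n must be <= 5000")
  if (stats::sd(values) == 0)
    return(list(W = NA_real_, p = NA_real_, n = n, degenerate = TRUE))
  sw <- stats::shapiro.test(values)
  list(W = unname(sw$statistic), p = sw$p.value, n = n, degenerate = FALSE)
}

#' Paired t-test of designed versus achieved values
#'
#' Classic paired t on the designed-minus-achieved differences with a
#' two-sided p from the t distribution on n-1 degrees of freedom.
#' Zero-variance differences are flagged degenerate (t = 0, p = 1 when
#' all differences vanish; |t| infinite otherwise).
#'
#' @param designed,achieved equal-length numeric vectors
#' @return list of class `paired_test_result`: `n`, `mean_diff`,
#'   `sd_diff`, `t`, `df`, `p`, `degenerate`
#' @export
paired_t <- function(designed, achieved) {
  if (length(designed) != length(achieved))
    stop("paired_t: unequal lengths")
  ok <- is.finite(designed) & is.finite(achieved)
  d <- designed[ok] - achieved[ok]
  n <- length(d)
  if (n < 2) stop("paired_t: need at least 2 complete pairs")
  paired_t_core(mean(d), stats::sd(d), n)
}

#' Paired t-test from summary statistics of the differences
#'
#' @param mean_diff,sd_diff mean and SD of the paired differences
#' @param n number of pairs (>= 2)
#' @return as [paired_t()]
#' @export
paired_t_from_summary <- function(mean_diff, sd_diff, n) {
  if (n < 2) stop("paired_t_from_summary: n must be >= 2")
  if (!is.finite(sd_diff) || sd_diff <= 0)
    stop("paired_t_from_summary: sd_diff must be positive")
  paired_t_core(mean_diff, sd_diff, n)
}

paired_t_core <- function(mean_diff, sd_diff, n) {
  if (sd_diff == 0) {
    t <- if (mean_diff == 0) 0 else sign(mean_diff) * Inf
    p <- if (mean_diff == 0) 1 else 0
    return(structure(list(n = n, mean_diff = mean_diff, sd_diff = 0,
                          t = t, df = n - 1, p = p, degenerate = TRUE),
                     class = "paired_test_result"))
  }
  t <- mean_diff / (sd_diff / sqrt(n))
  structure(list(n = n, mean_diff = mean_diff, sd_diff = sd_diff,
                 t = t, df = n - 1,
                 p = 2 * stats::pt(-abs(t), df = n - 1),
                 degenerate = FALSE),
            class = "paired_test_result")
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat(sprintf("paired t: mean diff %.4g (SD %.4g), t(%d) = %.3f, p = %.4g%s\n",
              x$mean_diff, x$sd_diff, x$df, x$t, x$p,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Intraclass correlation, two-way random effects, absolute agreement,
#' single measurement (ICC(A,1))
#'
#' Computed from the two-way ANOVA mean squares (subjects x sessions)
#' with the F-based confidence interval. Repeated-measurement
#' reliability of the 3D measurements is assessed by re-digitizing a
#' subsample and treating sessions as random raters.
#'
#' @param ratings complete n x k numeric matrix, items in rows, raters
#'   (sessions) in columns; n >= 5, k >= 2
#' @param conf_level confidence level for the interval
#' @return list of class `icc_result`: `icc`, `ci_low`, `ci_high`,
#'   `model`, `n`, `k`, `ms` (the mean squares)
#' @export
icc_agreement <- function(ratings, conf_level = 0.95) {
  M <- as.matrix(ratings)
  if (any(!is.finite(M))) stop("icc_agreement: ratings matrix must be complete")
  n <- nrow(M); k <- ncol(M)
  if (n < 5) stop("icc_agreement: need at least 5 items")
  if (k < 2) stop("icc_agreement: need at least 2 raters/sessions")
  df_ <- data.frame(y = as.vector(M),
                    item = factor(rep(seq_len(n), k)),
                    rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ item + rater, data = df_))[[1]][["Mean Sq"]]
  MSR <- ms[1]; MSC <- ms[2]; MSE <- ms[3]
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
  alpha <- 1 - conf_level
  if (abs(icc - 1) < 1e-12) {
    lo <- hi <- 1
  } else {
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * MSC + b * MSE)^2 /
      ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
    FL <- stats::qf(1 - alpha / 2, n - 1, v)
    FU <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (MSR - FL * MSE) /
      (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    hi <- n * (FU * MSR - MSE) /
      (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  }
  structure(list(icc = icc, ci_low = lo, ci_high = hi,
                 model = "two-way random, absolute agreement, single measurement (ICC(A,1))",
                 n = n, k = k, ms = c(MSR = MSR, MSC = MSC, MSE = MSE)),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC = %.4f (%.0f%% CI %.4f, %.4f), %s; n = %d items, k = %d sessions\n",
              x$icc, 100 * 0.95, x$ci_low, x$ci_high, x$model, x$n, x$k))
  invisible(x)
}

#' Default covariate set for the influencing-factor models
#' @return character vector of covariate column names
#' @export
default_covariates <- function() {
  c("age", "gender", "overbite", "overjet", "tads", "crowding",
    "g6", "attachment", "power_ridge")
}

#' Linear mixed model of influencing factors for one response metric
#'
#' Fits `response ~ covariates + (1 | patient)` by REML (random intercept
#' per patient absorbs the clustering of teeth within patients) and
#' reports fixed-effect estimates with Wald (normal) p-values, the
#' random-intercept and residual variances and the fit log-likelihood.
#' Categorical covariates use treatment coding; reference levels follow
#' the study conventions (TADs present, G6 present, female, 3 mm
#' vertical rectangular attachment V3).
#'
#' @param cohort cohort table from [build_cohort_table()] (or a
#'   simulated metric table) with a `patient` column
#' @param response response column name, e.g. `"d_MD_mm"`
#' @param covariates character vector of fixed-effect column names
#' @param include_side add side (R/L) as a fixed effect (default off)
#' @return list of class `lmm_result`: `coefficients` data.frame
#'   (term, estimate, se, z, p), `var_patient`, `var_residual`,
#'   `logLik`, `singular`, `n_obs`, `n_patients`, `fit`
#' @export
fit_lmm <- function(cohort, response, covariates = default_covariates(),
                    include_side = FALSE) {
  stopifnot(response %in% names(cohort))
  miss <- setdiff(covariates, names(cohort))
  if (length(miss)) stop("missing covariate column(s): ", paste(miss, collapse = ", "))
  dat <- cohort[stats::complete.cases(cohort[, c(response, covariates, "patient")]),
                , drop = FALSE]
  dat <- set_reference_levels(dat)
  if (include_side) covariates <- c(covariates, "side")
  fixed_form <- stats::as.formula(paste("~", paste(covariates, collapse = " + ")))
  X <- stats::model.matrix(fixed_form, dat)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  form <- stats::as.formula(paste(response, "~",
                                  paste(covariates, collapse = " + "),
                                  "+ (1 | patient)"))
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(form, data = dat, REML = TRUE)))
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- fe / se
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    coefficients = data.frame(term = names(fe), estimate = unname(fe),
                              se = unname(se), z = unname(z),
                              p = 2 * stats::pnorm(-abs(unname(z))),
                              stringsAsFactors = FALSE),
    var_patient = vc$vcov[vc$grp == "patient"],
    var_residual = vc$vcov[vc$grp == "Residual"],
    logLik = as.numeric(stats::logLik(fit)),
    singular = lme4::isSingular(fit),
    n_obs = nrow(dat),
    n_patients = length(unique(dat$patient)),
    response = response,
    fit = fit
  ), class = "lmm_result")
}

set_reference_levels <- function(dat) {
  if ("gender" %in% names(dat))
    dat$gender <- stats::relevel(factor(dat$gender), ref = "female")
  if ("tads" %in% names(dat))
    dat$tads <- stats::relevel(factor(dat$tads), ref = "present")
  if ("g6" %in% names(dat))
    dat$g6 <- stats::relevel(factor(dat$g6), ref = "present")
  if ("attachment" %in% names(dat)) {
    dat$attachment <- factor(dat$attachment)
    if ("V3" %in% levels(dat$attachment))
      dat$attachment <- stats::relevel(dat$attachment, ref = "V3")
  }
  if ("power_ridge" %in% names(dat))
    dat$power_ridge <- stats::relevel(factor(dat$power_ridge), ref = "absent")
  dat
}

#' @export
print.lmm_result <- function(x, ...) {
  cat(sprintf("linear mixed model for %s: %d obs, %d patients%s\n",
              x$response, x$n_obs, x$n_patients,
              if (x$singular) " [singular fit]" else ""))
  print(x$coefficients, digits = 3, row.names = FALSE)
  cat(sprintf("patient variance %.4g, residual variance %.4g\n",
              x$var_patient, x$var_residual))
  invisible(x)
}

significance_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}

#' Designed-versus-achieved summary table
#'
#' Per tooth type and metric (sides pooled): designed and achieved
#' mean +/- SD, the designed-minus-achieved difference mean +/- SD, and
#' the paired-t p-value with significance stars (* < 0.05, ** < 0.01,
#' *** < 0.001).
#'
#' @param cohort cohort table with `designed_*`, `achieved_*`, `d_*`
#'   columns and a `tooth` column
#' @param adjust_bh apply Benjamini-Hochberg correction across rows
#'   (default off, matching an uncorrected alpha of 0.05)
#' @return data.frame with one row per tooth x metric
#' @export
summarize_movements <- function(cohort, adjust_bh = FALSE) {
  rows <- list()
  for (tid in intersect(TOOTH_IDS, unique(cohort$tooth))) {
    sub <- cohort[cohort$tooth == tid, , drop = FALSE]
    for (m in METRICS) {
      des <- sub[[paste0("designed_", m)]]
      ach <- sub[[paste0("achieved_", m)]]
      ok <- is.finite(des) & is.finite(ach)
      des <- des[ok]; ach <- ach[ok]
      dd <- des - ach
      pt_ <- if (length(dd) >= 2 && stats::sd(dd) > 0)
        paired_t(des, ach)$p else NA_real_
      rows[[paste(tid, m)]] <- data.frame(
        tooth = tid, metric = m, n = length(dd),
        designed_mean = mean(des), designed_sd = stats::sd(des),
        achieved_mean = mean(ach), achieved_sd = stats::sd(ach),
        diff_mean = mean(dd), diff_sd = stats::sd(dd),
        p = pt_, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (adjust_bh) out$p <- stats::p.adjust(out$p, method = "BH")
  out$stars <- significance_stars(out$p)
  out
}
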