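# Landmark/covariate file I/O and the end-to-end pipeline runner.
# Landmark files use the fixed vocabulary and mm units; CSVs use period
# decimal separators, UTF-8 and a header row, with bit-stable row
# ordering (tooth, side, metric).

#' Read a landmark file (CSV `name,x,y,z` or JSON map)
#'
#' Names are validated against the fixed landmark vocabulary;
#' coordinates must be finite mm values.
#'
#' @param path .csv or .json path
#' @return named list of length-3 points
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("landmark file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  lm <- if (ext == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("name", "x", "y", "z")
    if (!all(need %in% names(df)))
      stop("malformed landmark CSV (need name,x,y,z columns): ", path)
    stats::setNames(lapply(seq_len(nrow(df)),
                           function(i) as.numeric(df[i, c("x", "y", "z")])),
                    df$name)
  } else if (ext == "json") {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    lapply(raw, as.numeric)
  } else stop("unsupported landmark format: .", ext)
  bad <- setdiff(names(lm), landmark_vocabulary())
  if (length(bad))
    stop("unknown landmark name(s) in ", path, ": ", paste(bad, collapse = ", "))
  if (any(!vapply(lm, function(p) length(p) == 3 && all(is.finite(p)), logical(1))))
    stop("malformed landmark coordinates in ", path)
  lm
}

#' Write landmarks as CSV
#' @param landmarks named list of length-3 points
#' @param path output .csv path
#' @return `path`, invisibly
#' @export
write_landmarks <- function(landmarks, path) {
  df <- data.frame(name = names(landmarks),
                   do.call(rbind, landmarks))
  names(df) <- c("name", "x", "y", "z")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a patient covariate table
#' @param path CSV with a `patient` column plus covariate columns
#' @return data.frame
#' @export
read_covariates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"patient" %in% names(df))
    stop("covariate table needs a 'patient' column: ", path)
  df
}

#' Assemble a maxillary case from files
#'
#' @param stage "pre", "designed" or "achieved"
#' @param landmark_path landmark CSV/JSON
#' @param bone_path optional bone mesh (STL/PLY/OBJ, mm)
#' @param tooth_mesh_paths optional named list `"U1_R" = path, ...`
#' @return a [maxillary_case()]
#' @export
read_case <- function(stage, landmark_path, bone_path = NULL,
                      tooth_mesh_paths = NULL) {
  lm <- read_landmarks(landmark_path)
  teeth <- list()
  for (tid in TOOTH_IDS) {
    for (s in SIDES) {
      crown_nm <- landmark_name(crown_landmark_type(tid), tid, s)
      apex_nm <- landmark_name("apex", tid, s)
      if (crown_nm %in% names(lm) && apex_nm %in% names(lm)) {
        key <- paste(tid, s, sep = "_")
        mesh <- if (!is.null(tooth_mesh_paths) && key %in% names(tooth_mesh_paths))
          read_mesh(tooth_mesh_paths[[key]]) else NULL
        teeth[[key]] <- tooth_model(tid, s, lm[[crown_nm]], lm[[apex_nm]], mesh)
      }
    }
  }
  bone <- if (!is.null(bone_path)) read_mesh(bone_path) else NULL
  maxillary_case(stage, bone = bone, teeth = teeth, landmarks = lm)
}

#' Pipeline configuration
#'
#' @param n_patients simulated cohort size
#' @param seed master seed for all randomness
#' @param sim named list of [cohort_sim_params()] overrides
#' @param icp named list of [icp_config()] overrides
#' @param icc_model label of the ICC flavor (only `"A1"` implemented)
#' @param pool_bilateral pool left/right rows (default) or average per
#'   patient before testing
#' @param adjust_bh Benjamini-Hochberg correction on the summary table
#' @param out_dir output directory for the report bundle
#' @return validated config list of class `pipeline_config`
#' @export
pipeline_config <- function(n_patients = 33L, seed = 1L, sim = list(),
                            icp = list(), icc_model = "A1",
                            pool_bilateral = TRUE, adjust_bh = FALSE,
                            out_dir = tempfile("orthomotion_run_")) {
  if (n_patients < 1) stop("validation error: n_patients must be >= 1")
  if (!identical(icc_model, "A1"))
    stop("validation error: only the ICC(A,1) model is implemented")
  bad_sim <- setdiff(names(sim), names(formals(cohort_sim_params)))
  if (length(bad_sim)) stop("unknown sim config key(s): ", paste(bad_sim, collapse = ", "))
  bad_icp <- setdiff(names(icp), names(formals(icp_config)))
  if (length(bad_icp)) stop("unknown icp config key(s): ", paste(bad_icp, collapse = ", "))
  structure(list(n_patients = as.integer(n_patients), seed = as.integer(seed),
                 sim = sim, icp = icp, icc_model = icc_model,
                 pool_bilateral = pool_bilateral, adjust_bh = adjust_bh,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#' @param path YAML file whose keys match [pipeline_config()] arguments;
#'   unknown keys are rejected
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  bad <- setdiff(names(raw), names(formals(pipeline_config)))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, raw)
}

#' Run the simulated end-to-end pipeline and write the report bundle
#'
#' Simulates a cohort under the configured conditions, measures it,
#' produces the per-tooth metric table, the designed-versus-achieved
#' summary, per-tooth linear-mixed-model coefficient tables and a
#' repeated-measurement ICC report, and writes everything as CSV/JSON
#' with a run log carrying the seed and a config hash.
#'
#' @param config a [pipeline_config()]
#' @return invisible list of the in-memory results
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  sim_args <- utils::modifyList(list(n_patients = config$n_patients,
                                     seed = config$seed), config$sim)
  sim <- simulate_cohort(do.call(cohort_sim_params, sim_args))
  cohort <- sim$cohort
  ord <- order(cohort$patient, cohort$tooth, cohort$side)
  cohort <- cohort[ord, ]
  if (!config$pool_bilateral) {
    agg_cols <- grep("^(designed|achieved|d)_", names(cohort), value = TRUE)
    cohort <- stats::aggregate(cohort[agg_cols],
                               by = cohort[c("patient", "tooth")], mean)
    cohort <- merge(cohort, sim$covariates, by = "patient", sort = FALSE)
  }
  summary_tab <- summarize_movements(cohort, adjust_bh = config$adjust_bh)

  lmm_tables <- list()
  for (tid in TOOTH_IDS) {
    sub <- cohort[cohort$tooth == tid, , drop = FALSE]
    for (m in METRICS) {
      res <- tryCatch(fit_lmm(sub, paste0("d_", m)), error = function(e) NULL)
      if (!is.null(res)) {
        co <- res$coefficients
        co$tooth <- tid; co$metric <- m; co$singular <- res$singular
        lmm_tables[[paste(tid, m)]] <- co
      }
    }
  }
  lmm_tab <- do.call(rbind, lmm_tables)
  rownames(lmm_tab) <- NULL

  # repeated-measurement reliability: second session = first + small
  # digitization noise on a 10% patient subsample
  icc_tab <- with_local_seed(config$seed + 1L, {
    sub_pat <- sample(unique(cohort$patient),
                      max(3L, ceiling(0.1 * length(unique(cohort$patient)))))
    keep <- cohort$patient %in% sub_pat
    if ("measured" %in% names(cohort)) keep <- keep & cohort$measured
    sub <- cohort[keep, ]
    do.call(rbind, lapply(METRICS, function(m) {
      s1 <- sub[[paste0("d_", m)]]
      noise_sd <- if (grepl("deg", m)) 0.5 else 0.15
      s2 <- s1 + stats::rnorm(length(s1), 0, noise_sd)
      r <- icc_agreement(cbind(s1, s2))
      data.frame(metric = m, icc = r$icc, ci_low = r$ci_low,
                 ci_high = r$ci_high, model = r$model)
    }))
  })

  write_csv_atomic <- function(df, name) {
    tmp <- file.path(config$out_dir, paste0(".", name, ".tmp"))
    utils::write.csv(df, tmp, row.names = FALSE)
    file.rename(tmp, file.path(config$out_dir, name))
  }
  write_csv_atomic(cohort, "cohort_metrics.csv")
  write_csv_atomic(summary_tab, "movement_summary.csv")
  write_csv_atomic(lmm_tab, "lmm_coefficients.csv")
  write_csv_atomic(icc_tab, "icc_report.csv")
  write_truth_manifest(sim$truth, file.path(config$out_dir, "truth_manifest.json"))

  cfg_path <- file.path(config$out_dir, "config.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  log_lines <- c(sprintf("orthomotion run %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                 sprintf("seed: %d", config$seed),
                 sprintf("n_patients: %d", config$n_patients),
                 sprintf("config_hash: %s", unname(tools::md5sum(cfg_path))),
                 sprintf("cohort_rows: %d", nrow(cohort)))
  writeLines(log_lines, file.path(config$out_dir, "run.log"))

  invisible(list(cohort = cohort, summary = summary_tab, lmm = lmm_tab,
                 icc = icc_tab, truth = sim$truth, out_dir = config$out_dir))
}
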