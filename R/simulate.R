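# Synthetic maxillary-arch generator: parabolic arch geometry, bone band
# and tooth meshes, analytic landmarks, prescribed designed/achieved
# movements realized as rigid per-tooth transforms, and covariate-linked
# cohort simulation with a machine-readable truth manifest.
#
# Geometry convention of the synthetic world: +z occlusal (away from the
# root apices), +y anterior, +x toward the patient's left; crowns near
# z = 0, apices at negative z. Tooth meshes are capped frustums with a
# cusp bump -- the minimum geometry carrying the required landmarks;
# anatomical realism is a non-goal. All landmarks are analytic, so
# prescribed movements round-trip exactly through the measurement
# pipeline.

#' Arch geometry parameters
#'
#' @param half_positions named numeric: per tooth type, the |x| of the
#'   tooth along the arch (mm); U4 positions are left as extraction gaps
#' @param arch_coeff parabola coefficient: the arch midline follows
#'   `y = -arch_coeff * x^2`
#' @param root_length named numeric per tooth type (mm)
#' @param crown_radius crown radius of the frustum meshes (mm)
#' @param bone_half_extent bone band half-extent along x (mm)
#' @param bone_top,bone_bottom vertical extent of the bone band (mm)
#' @param bone_half_width half thickness of the band cross-section (mm)
#' @param bone_segments stations along the band (mesh resolution)
#' @param tooth_segments radial segments of each tooth frustum
#' @param scallop_amp amplitude of the band's top-edge scallops (mm);
#'   gives the surface tangential texture
#' @param seed integer; the pretreatment geometry itself is
#'   deterministic, the seed feeds optional downstream perturbations
#' @return list of class `arch_params`
#' @export
arch_params <- function(half_positions = c(U1 = 4.5, U2 = 13, U3 = 17.5,
                                           U5 = 23, U6 = 25, U7 = 26.5),
                        arch_coeff = 0.048,
                        root_length = c(U1 = 13, U2 = 13, U3 = 16,
                                        U5 = 14, U6 = 13, U7 = 12),
                        crown_radius = 3,
                        bone_half_extent = 28,
                        bone_top = -4, bone_bottom = -16,
                        bone_half_width = 4,
                        bone_segments = 80L,
                        tooth_segments = 12L,
                        scallop_amp = 1.5,
                        seed = 1L) {
  stopifnot(all(TOOTH_IDS %in% names(half_positions)),
            all(TOOTH_IDS %in% names(root_length)),
            arch_coeff > 0, crown_radius > 0, bone_half_width > 0,
            bone_segments >= 8, tooth_segments >= 6,
            bone_top > bone_bottom)
  structure(as.list(environment()), class = "arch_params")
}

arch_y <- function(x, params) -params$arch_coeff * x^2

#' Generate a pretreatment synthetic case
#'
#' Builds the bone band mesh, the 12 tooth models (U1-U3, U5-U7
#' bilateral; U4 sites left as gaps) with frustum meshes, and the full
#' analytic landmark set. Pretreatment long axes are vertical.
#'
#' @param params an [arch_params()]
#' @param with_meshes build tooth/bone meshes (set FALSE for fast
#'   landmark-only cases)
#' @return a pretreatment [maxillary_case()]
#' @export
synth_case <- function(params = arch_params(), with_meshes = TRUE) {
  teeth <- list()
  landmarks <- list()
  for (tid in TOOTH_IDS) {
    for (s in SIDES) {
      x <- params$half_positions[[tid]] * (if (s == "L") 1 else -1)
      pos <- c(x, arch_y(abs(params$half_positions[[tid]]), params), 0)
      crown <- pos
      apex <- pos - c(0, 0, params$root_length[[tid]])
      mesh <- if (with_meshes) tooth_frustum_mesh(pos, params) else NULL
      tm <- tooth_model(tid, s, crown, apex, mesh)
      teeth[[paste(tid, s, sep = "_")]] <- tm
      landmarks[[landmark_name(crown_landmark_type(tid), tid, s)]] <- crown
      landmarks[[landmark_name("apex", tid, s)]] <- apex
    }
  }
  bone <- if (with_meshes) bone_band_mesh(params) else NULL
  maxillary_case("pre", bone = bone, teeth = teeth, landmarks = landmarks)
}

tooth_frustum_mesh <- function(center, params) {
  ns <- params$tooth_segments
  th <- 2 * pi * (seq_len(ns) - 1) / ns
  rim <- cbind(center[1] + params$crown_radius * cos(th),
               center[2] + params$crown_radius * sin(th),
               center[3])
  apex <- center - c(0, 0, 10)          # mesh root tapers, landmark apex is analytic
  cusp <- center + c(0, 0, 1)           # cusp bump capping the crown
  V <- rbind(rim, apex, cusp)
  ia <- ns + 1L; ic <- ns + 2L
  side <- cbind(seq_len(ns), c(seq_len(ns)[-1], 1L), ia)
  cap <- cbind(c(seq_len(ns)[-1], 1L), seq_len(ns), ic)
  tri_mesh(V, rbind(side, cap))
}

bone_band_mesh <- function(params) {
  n <- params$bone_segments
  t_ <- seq(-1, 1, length.out = n + 1)
  x <- params$bone_half_extent * t_
  y <- arch_y(x, params)
  # outward in-plane normal of the parabola
  dydx <- -2 * params$arch_coeff * x
  nx <- -dydx / sqrt(1 + dydx^2)
  ny <- 1 / sqrt(1 + dydx^2)
  # flip so the normal points away from the arch interior (outward)
  flip <- sign(x * nx + (y - mean(y)) * ny)
  flip[flip == 0] <- 1
  nx <- nx * flip; ny <- ny * flip
  ztop <- params$bone_top + params$scallop_amp * cos(6 * pi * t_)
  zbot <- params$bone_bottom
  w <- params$bone_half_width
  corners <- function(i) {
    ox <- nx[i] * w; oy <- ny[i] * w
    rbind(c(x[i] + ox, y[i] + oy, ztop[i]),   # outer top
          c(x[i] - ox, y[i] - oy, ztop[i]),   # inner top
          c(x[i] - ox, y[i] - oy, zbot),      # inner bottom
          c(x[i] + ox, y[i] + oy, zbot))      # outer bottom
  }
  V <- do.call(rbind, lapply(seq_len(n + 1), corners))
  quads <- list()
  for (i in seq_len(n)) {
    a <- (i - 1) * 4
    b <- i * 4
    for (k in 1:4) {
      k2 <- if (k == 4) 1 else k + 1
      quads[[length(quads) + 1]] <- rbind(c(a + k, b + k, b + k2),
                                          c(a + k, b + k2, a + k2))
    }
  }
  # end caps
  quads[[length(quads) + 1]] <- rbind(c(1, 2, 3), c(1, 3, 4))
  e <- n * 4
  quads[[length(quads) + 1]] <- rbind(c(e + 1, e + 3, e + 2), c(e + 1, e + 4, e + 3))
  tri_mesh(V, do.call(rbind, quads))
}

## ---- movement prescriptions ------------------------------------------

#' Default movement prescription from the reference cohort
#'
#' Per-tooth designed and achieved target metrics equal to the reference
#' cohort means (same on both sides), realizing the reference deviation
#' pattern: anterior distal tipping, posterior mesial tipping,
#' under-expressed buccolingual inclination.
#'
#' @return data.frame keyed by `tooth` and `side` with columns
#'   `designed_<metric>` and `achieved_<metric>`
#' @export
default_prescription <- function() {
  ref <- reference_cohort_summary()
  out <- expand.grid(tooth = TOOTH_IDS, side = SIDES,
                     stringsAsFactors = FALSE)
  for (m in METRICS) {
    sub <- ref[ref$metric == m, ]
    out[[paste0("designed_", m)]] <- sub$designed_mean[match(out$tooth, sub$tooth)]
    out[[paste0("achieved_", m)]] <- sub$achieved_mean[match(out$tooth, sub$tooth)]
  }
  out
}

#' Zero prescription (designed and achieved identical to pretreatment)
#' @return prescription data.frame as [default_prescription()]
#' @export
zero_prescription <- function() {
  out <- default_prescription()
  out[, -(1:2)] <- 0
  out
}

# direction whose mesiodistal- and buccolingual-plane projected angles
# equal the prescribed angulation/inclination exactly
axis_direction_for_angles <- function(md_deg, bl_deg, fr) {
  if (abs(md_deg) >= 89 || abs(bl_deg) >= 89)
    stop("prescribed angles must lie in (-89, 89) degrees")
  vunit(tan(md_deg * pi / 180) * fr$mesial_pos +
          tan(bl_deg * pi / 180) * fr$buccal_pos +
          fr$extrusion_pos)
}

#' Realize a movement prescription as designed and achieved cases
#'
#' Each tooth's stage pose is reached by (i) rotating its pretreatment
#' long axis, about the reference point, onto the direction whose
#' projected mesiodistal and buccolingual angles equal the prescribed
#' absolute angulation/inclination, then (ii) translating by the
#' prescribed anatomical displacement. Rotations are centered on the
#' reference point, so angular prescriptions leave linear metrics
#' untouched and the full pipeline recovers every prescribed value
#' exactly in the noiseless case. The achieved case can additionally be
#' moved by a known global rigid perturbation to exercise bone
#' superimposition.
#'
#' @param case a pretreatment [maxillary_case()] from [synth_case()]
#' @param prescription data.frame as [default_prescription()]
#' @param bone_perturbation optional [rigid_transform()] applied to the
#'   whole achieved case (bone, teeth, landmarks); when given the
#'   achieved case is returned un-registered
#' @return list: `designed`, `achieved` ([maxillary_case()]s) and
#'   `truth` (per-tooth transforms and prescribed metrics, the
#'   perturbation, schema-versioned)
#' @export
apply_prescription <- function(case, prescription, bone_perturbation = NULL) {
  stopifnot(case$stage == "pre")
  world <- build_world_frame(case$landmarks)
  make_stage <- function(stage_name) {
    prefix <- if (stage_name == "designed") "designed_" else "achieved_"
    out <- case
    out$stage <- stage_name
    truth <- list()
    for (key in names(case$teeth)) {
      tm <- case$teeth[[key]]
      row <- prescription[prescription$tooth == tm$tooth_id &
                            prescription$side == tm$side, , drop = FALSE]
      if (nrow(row) != 1)
        stop("prescription must cover every tooth; missing ", key)
      fr <- build_tooth_frame(tm$ref_point, world, tooth_class(tm$tooth_id), tm$side)
      target_dir <- axis_direction_for_angles(row[[paste0(prefix, "MD_deg")]],
                                              row[[paste0(prefix, "BL_deg")]], fr)
      pre_dir <- vunit(tm$crown_point - tm$apex_point)
      R <- rotation_between(pre_dir, target_dir)
      disp <- row[[paste0(prefix, "MD_mm")]] * fr$mesial_pos +
        row[[paste0(prefix, "BL_mm")]] * fr$buccal_pos +
        row[[paste0(prefix, "IE_mm")]] * fr$extrusion_pos
      tr <- rigid_transform(R, tm$ref_point + disp - as.numeric(R %*% tm$ref_point))
      new_tm <- tm
      new_tm$crown_point <- rt_apply(tr, tm$crown_point)
      new_tm$apex_point <- rt_apply(tr, tm$apex_point)
      new_tm$ref_point <- new_tm$crown_point
      if (!is.null(tm$mesh)) new_tm$mesh <- transform_mesh(tm$mesh, tr)
      out$teeth[[key]] <- new_tm
      out$landmarks[[landmark_name(crown_landmark_type(tm$tooth_id),
                                   tm$tooth_id, tm$side)]] <- new_tm$crown_point
      out$landmarks[[landmark_name("apex", tm$tooth_id, tm$side)]] <- new_tm$apex_point
      truth[[key]] <- list(rotation = R, translation = tr$t,
                           metrics = as.list(stats::setNames(
                             as.numeric(row[paste0(prefix, METRICS)]), METRICS)))
    }
    out$registered <- TRUE
    list(case = out, truth = truth)
  }
  des <- make_stage("designed")
  ach <- make_stage("achieved")
  ach$case$stage <- "achieved"
  if (!is.null(bone_perturbation)) {
    ach$case <- transform_case(ach$case, bone_perturbation)
    ach$case$registered <- FALSE
  }
  list(designed = des$case, achieved = ach$case,
       truth = list(schema_version = 1L,
                    designed = des$truth, achieved = ach$truth,
                    bone_perturbation = if (is.null(bone_perturbation)) NULL
                    else list(R = bone_perturbation$R, t = bone_perturbation$t)))
}

## ---- cohort simulation ------------------------------------------------

#' Cohort simulation parameters
#'
#' Defaults reproduce the reference study conditions: 33 patients,
#' bilateral U1-U3/U5-U7 (396 teeth), covariates drawn from the
#' reference baseline distributions, per-tooth deviation baselines equal
#' to the reference difference means, patient random intercept SD 0.5
#' and residual SD 1.0 in the units of each metric.
#'
#' @param n_patients number of simulated patients
#' @param beta named list: `beta[[metric]][[tooth]]` is a named numeric
#'   of true covariate effects on the designed-minus-achieved deviation
#'   (term names as in the fitted model, e.g. `tadsabsent`,
#'   `gendermale`, `overbite`, `age`, `g6absent`, `attachmentO1`,
#'   `attachmentH3`, `attachmentnone`, `power_ridgepresent`,
#'   `overjet`, `crowding`)
#' @param baseline `"reference"` (per tooth x metric reference
#'   difference means) or `"zero"`
#' @param sigma_patient SD of the patient random intercept
#' @param sigma_residual SD of the per-tooth residual
#' @param sigma_designed SD of the simulated designed values around the
#'   reference designed means
#' @param p_tads,p_g6,p_power_ridge prevalence of TADs, G6, power ridge
#' @param p_attachment named probabilities over attachment types
#' @param seed integer seed
#' @return list of class `cohort_sim_params`
#' @export
cohort_sim_params <- function(n_patients = 33L,
                              beta = list(),
                              baseline = c("reference", "zero"),
                              sigma_patient = 0.5,
                              sigma_residual = 1.0,
                              sigma_designed = 1.0,
                              p_tads = 0.6, p_g6 = 0.5, p_power_ridge = 0.3,
                              p_attachment = c(V3 = 0.4, O1 = 0.25,
                                               H3 = 0.2, none = 0.15),
                              seed = 1L) {
  baseline <- match.arg(baseline)
  if (n_patients < 1) stop("n_patients must be positive")
  stopifnot(sigma_patient >= 0, sigma_residual >= 0, sigma_designed >= 0,
            abs(sum(p_attachment) - 1) < 1e-9)
  structure(as.list(environment()), class = "cohort_sim_params")
}

simulate_covariates <- function(n, params) {
  base <- reference_baseline()
  clip <- function(x, lo, hi) pmin(hi, pmax(lo, x))
  data.frame(
    patient = sprintf("P%03d", seq_len(n)),
    age = round(clip(stats::rnorm(n, base$age["mean"], base$age["sd"]),
                     base$age_range[1], base$age_range[2]), 1),
    gender = ifelse(stats::runif(n) < base$p_male, "male", "female"),
    overbite = round(stats::rnorm(n, base$overbite["mean"], base$overbite["sd"]), 2),
    overjet = round(stats::rnorm(n, base$overjet["mean"], base$overjet["sd"]), 2),
    crowding = round(pmax(0, stats::rnorm(n, base$crowding["mean"],
                                          base$crowding["sd"])), 2),
    tads = ifelse(stats::runif(n) < params$p_tads, "present", "absent"),
    g6 = ifelse(stats::runif(n) < params$p_g6, "present", "absent"),
    attachment = sample(names(params$p_attachment), n, replace = TRUE,
                        prob = params$p_attachment),
    power_ridge = ifelse(stats::runif(n) < params$p_power_ridge,
                         "present", "absent"),
    stringsAsFactors = FALSE)
}

covariate_term_value <- function(term, covs) {
  switch(term,
         age = covs$age,
         overbite = covs$overbite,
         overjet = covs$overjet,
         crowding = covs$crowding,
         gendermale = as.numeric(covs$gender == "male"),
         tadsabsent = as.numeric(covs$tads == "absent"),
         g6absent = as.numeric(covs$g6 == "absent"),
         attachmentO1 = as.numeric(covs$attachment == "O1"),
         attachmentH3 = as.numeric(covs$attachment == "H3"),
         attachmentnone = as.numeric(covs$attachment == "none"),
         power_ridgepresent = as.numeric(covs$power_ridge == "present"),
         stop("unknown beta term: ", term))
}

#' Simulate a cohort of designed-minus-achieved deviations
#'
#' Fast mode draws the metric table directly from the generative model
#' deviation = baseline + sum(beta * covariate) + patient intercept +
#' residual; full mode realizes each patient geometrically (synthetic
#' arch, prescribed movements, measurement pipeline), exercising the
#' geometry stack, and is correspondingly slower.
#'
#' @param params a [cohort_sim_params()]
#' @param mode `"fast"` (metric table) or `"full"` (geometric cases,
#'   landmark-based, measured through the pipeline)
#' @return list of class `cohort_sim`: `cohort` (cohort table with
#'   covariates joined), `covariates`, `truth` (a truth manifest list)
#' @export
simulate_cohort <- function(params = cohort_sim_params(), mode = c("fast", "full")) {
  mode <- match.arg(mode)
  with_local_seed(params$seed, {
    covs <- simulate_covariates(params$n_patients, params)
    ref <- reference_cohort_summary()
    base_tab <- expand.grid(tooth = TOOTH_IDS, metric = METRICS,
                            stringsAsFactors = FALSE)
    base_tab$baseline <- if (params$baseline == "reference") {
      ref$diff_mean[match(paste(base_tab$tooth, base_tab$metric),
                          paste(ref$tooth, ref$metric))]
    } else 0
    intercepts <- matrix(stats::rnorm(params$n_patients * length(METRICS),
                                      0, params$sigma_patient),
                         params$n_patients, length(METRICS),
                         dimnames = list(NULL, METRICS))
    grid <- expand.grid(tooth = TOOTH_IDS, side = SIDES,
                        stringsAsFactors = FALSE)
    pat_idx <- rep(seq_len(params$n_patients), each = nrow(grid))
    tab <- data.frame(patient = covs$patient[pat_idx],
                      tooth = rep(grid$tooth, params$n_patients),
                      side = rep(grid$side, params$n_patients),
                      stringsAsFactors = FALSE)
    nr <- nrow(tab)
    for (m in METRICS) {
      sub <- ref[ref$metric == m, ]
      des_mean <- sub$designed_mean[match(tab$tooth, sub$tooth)]
      base_m <- base_tab$baseline[base_tab$metric == m][
        match(tab$tooth, base_tab$tooth[base_tab$metric == m])]
      fx <- numeric(nr)
      bm <- params$beta[[m]]
      if (!is.null(bm)) {
        for (tid in names(bm)) {
          bt <- bm[[tid]]
          eff <- numeric(params$n_patients)
          for (term in names(bt))
            eff <- eff + bt[[term]] * covariate_term_value(term, covs)
          sel <- tab$tooth == tid
          fx[sel] <- eff[pat_idx[sel]]
        }
      }
      delta <- base_m + fx + intercepts[cbind(pat_idx, match(m, METRICS))] +
        stats::rnorm(nr, 0, params$sigma_residual)
      designed <- des_mean + stats::rnorm(nr, 0, params$sigma_designed)
      tab[[paste0("designed_", m)]] <- designed
      tab[[paste0("achieved_", m)]] <- designed - delta
      tab[[paste0("d_", m)]] <- delta
    }
    tab$measured <- TRUE
    if (mode == "full") tab <- realize_cohort_geometry(tab, covs)
    cohort <- build_cohort_table(tab, covs)
    truth <- list(schema_version = 1L, mode = mode,
                  n_patients = params$n_patients,
                  baseline = params$baseline,
                  beta = params$beta,
                  sigma_patient = params$sigma_patient,
                  sigma_residual = params$sigma_residual,
                  sigma_designed = params$sigma_designed,
                  seed = params$seed,
                  patient_intercepts = intercepts)
    structure(list(cohort = cohort, covariates = covs, truth = truth),
              class = "cohort_sim")
  })
}

# replace the drawn metric table by one measured through the geometric
# pipeline: realize each patient's drawn designed/achieved metrics as
# rigid tooth movements on a synthetic arch and re-measure them
realize_cohort_geometry <- function(tab, covs) {
  ap <- arch_params()
  pre <- synth_case(ap, with_meshes = FALSE)
  world <- build_world_frame(pre$landmarks)
  out <- list()
  for (pid in unique(tab$patient)) {
    sub <- tab[tab$patient == pid, , drop = FALSE]
    presc <- sub[, c("tooth", "side",
                     paste0("designed_", METRICS), paste0("achieved_", METRICS))]
    # angular prescriptions are projected angles; keep them in range
    for (cn in grep("_(MD|BL)_deg$", names(presc), value = TRUE))
      presc[[cn]] <- pmin(85, pmax(-85, presc[[cn]]))
    stages <- apply_prescription(pre, presc)
    rec <- case_movement_records(pre, stages$designed, stages$achieved, world)
    rec$patient <- pid
    out[[pid]] <- rec
  }
  do.call(rbind, out)
}

#' Write a truth manifest to JSON
#'
#' The manifest fully determines the expected outputs of a simulated
#' case or cohort (schema-versioned); reading it back reproduces the
#' same list.
#'
#' @param truth truth list from [apply_prescription()] or
#'   [simulate_cohort()]
#' @param path output .json path
#' @return `path`, invisibly
#' @export
write_truth_manifest <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", matrix = "rowmajor")
  invisible(path)
}

#' Read a truth manifest written by [write_truth_manifest()]
#' @param path .json path
#' @return the truth list
#' @export
read_truth_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
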