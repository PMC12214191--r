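# The five per-tooth movement metrics and their designed-minus-achieved
# differences.
#
# Sign conventions (fixed throughout):
#   mesial tipping / mesial movement positive, distal negative;
#   buccal inclination / buccal movement positive, lingual negative;
#   extrusion positive, intrusion negative.
# Angular metrics are the absolute long-axis angulation/inclination of
# the designed and achieved models (measured in each stage's own tooth
# frame, shared world frame); linear metrics are the displacement of the
# tooth reference point from the pretreatment position. The difference is
# always designed minus achieved.

METRICS <- c("MD_deg", "BL_deg", "MD_mm", "BL_mm", "IE_mm")

#' Mesiodistal angulation of a tooth long axis
#'
#' Signed angle between the long axis and the vertical line, both
#' projected into the mesiodistal plane; mesial crown tip positive.
#'
#' @param axis a [tooth_long_axis()]
#' @param frame a [build_tooth_frame()]
#' @return angle in degrees
#' @export
mesiodistal_angulation <- function(axis, frame) {
  signed_angle_in_plane(axis$direction, frame$vertical_dir,
                        frame$md_plane, frame$sign_md)
}

#' Buccolingual inclination of a tooth long axis
#'
#' Signed angle between the long axis and the vertical line projected
#' into the buccolingual plane; buccal crown tip (lingual root torque)
#' positive.
#'
#' @inheritParams mesiodistal_angulation
#' @return angle in degrees
#' @export
buccolingual_inclination <- function(axis, frame) {
  signed_angle_in_plane(axis$direction, frame$vertical_dir,
                        frame$bl_plane, frame$sign_bl)
}

#' Anatomical components of a reference-point displacement
#'
#' @param ref_before,ref_after reference point at the earlier and later
#'   stage, mm
#' @param frame a [build_tooth_frame()]
#' @return named numeric: `MD_mm` (mesial +), `BL_mm` (buccal +),
#'   `IE_mm` (extrusion +)
#' @export
linear_components <- function(ref_before, ref_after, frame) {
  d <- as.numeric(ref_after) - as.numeric(ref_before)
  c(MD_mm = vdot(d, frame$mesial_pos),
    BL_mm = vdot(d, frame$buccal_pos),
    IE_mm = vdot(d, frame$extrusion_pos))
}

stage_metrics <- function(pre_tooth, stage_tooth, world) {
  fr <- build_tooth_frame(stage_tooth$ref_point, world,
                          tooth_class(stage_tooth$tooth_id), stage_tooth$side)
  ax <- tooth_long_axis(stage_tooth, world)
  lin <- linear_components(pre_tooth$ref_point, stage_tooth$ref_point, fr)
  c(MD_deg = mesiodistal_angulation(ax, fr),
    BL_deg = buccolingual_inclination(ax, fr),
    lin)
}

#' Movement record for one tooth across the three stages
#'
#' Angular metrics are absolute angulation/inclination on the designed
#' and achieved models; linear metrics are stage-minus-pretreatment
#' displacements of the reference point; differences are designed minus
#' achieved for every metric. Tooth frames are rebuilt on each stage's
#' own reference point.
#'
#' @param pre,designed,achieved [tooth_model()]s of the same tooth
#' @param world the (transferred) [world_frame()]
#' @return one-row data.frame with columns `tooth`, `side`,
#'   `designed_<metric>`, `achieved_<metric>`, `d_<metric>`
#' @export
movement_record <- function(pre, designed, achieved, world) {
  if (is.null(pre) || is.null(designed) || is.null(achieved))
    stop("movement_record: all three stages are required")
  stopifnot(pre$tooth_id == designed$tooth_id, pre$tooth_id == achieved$tooth_id,
            pre$side == designed$side, pre$side == achieved$side)
  des <- stage_metrics(pre, designed, world)
  ach <- stage_metrics(pre, achieved, world)
  out <- data.frame(tooth = pre$tooth_id, side = pre$side,
                    stringsAsFactors = FALSE)
  for (m in METRICS) {
    out[[paste0("designed_", m)]] <- unname(des[[m]])
    out[[paste0("achieved_", m)]] <- unname(ach[[m]])
    out[[paste0("d_", m)]] <- unname(des[[m]] - ach[[m]])
  }
  out
}

#' Movement records for all teeth of a co-registered case triple
#'
#' @param pre,designed,achieved [maxillary_case()]s; designed and
#'   achieved must be co-registered (see [superimpose_case()])
#' @param world optional [world_frame()]; built from the pretreatment
#'   landmarks when omitted
#' @return data.frame with one row per measurable tooth and a logical
#'   `measured` column; teeth with missing landmarks get an NA row
#' @export
case_movement_records <- function(pre, designed, achieved, world = NULL) {
  for (st in list(designed, achieved)) {
    if (!isTRUE(st$registered))
      stop("stage '", st$stage, "' is not co-registered; run superimpose_case() first")
  }
  if (is.null(world)) world <- build_world_frame(pre$landmarks)
  world_d <- transfer_world_frame(world, designed)
  world_a <- transfer_world_frame(world, achieved)
  stopifnot(identical(world_d, world_a))
  rows <- list()
  for (tid in TOOTH_IDS) {
    for (s in SIDES) {
      key <- paste(tid, s, sep = "_")
      rec <- tryCatch(
        movement_record(pre$teeth[[key]], designed$teeth[[key]],
                        achieved$teeth[[key]], world),
        error = function(e) NULL)
      if (is.null(rec)) {
        rec <- data.frame(tooth = tid, side = s, stringsAsFactors = FALSE)
        for (m in METRICS) {
          rec[[paste0("designed_", m)]] <- NA_real_
          rec[[paste0("achieved_", m)]] <- NA_real_
          rec[[paste0("d_", m)]] <- NA_real_
        }
        rec$measured <- FALSE
      } else {
        rec$measured <- TRUE
      }
      rows[[key]] <- rec
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble the cohort table of per-tooth differences and covariates
#'
#' One row per tooth (12 per fully measured patient: U1-U3, U5-U7
#' bilateral), joining the designed-minus-achieved differences with the
#' patient covariate row.
#'
#' @param records named list (by patient id) of [case_movement_records()]
#'   outputs, or a single data.frame with a `patient` column
#' @param covariates data.frame with one row per patient and a `patient`
#'   id column
#' @return data.frame of cohort rows
#' @export
build_cohort_table <- function(records, covariates) {
  if (is.data.frame(records)) {
    tab <- records
    if (!"patient" %in% names(tab)) stop("records data.frame needs a 'patient' column")
  } else {
    tab <- do.call(rbind, Map(function(df, id) {
      df$patient <- id
      df
    }, records, names(records)))
    rownames(tab) <- NULL
  }
  if (!"patient" %in% names(covariates))
    stop("covariates need a 'patient' column")
  if (anyDuplicated(covariates$patient))
    stop("duplicate patient ids in covariates")
  miss <- setdiff(unique(tab$patient), covariates$patient)
  if (length(miss))
    stop("covariate join error: no covariate row for patient(s) ",
         paste(miss, collapse = ", "))
  merge(tab, covariates, by = "patient", sort = FALSE)
}
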