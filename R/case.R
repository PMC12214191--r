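# Patient-stage model set: bone mesh, tooth models and named landmarks.
# Tooth identity follows the maxillary notation U1..U7 (first premolar U4
# extracted in this protocol) with sides R/L.

TOOTH_IDS <- c("U1", "U2", "U3", "U5", "U6", "U7")
SIDES <- c("R", "L")

#' Crown landmark type for a tooth
#'
#' Incisors use the incisal-edge midpoint, canines the cusp tip, second
#' premolars the buccal cusp, molars the mesiobuccal cusp. This named
#' crown landmark doubles as the tooth's linear-measurement reference
#' point.
#'
#' @param tooth_id one of U1, U2, U3, U5, U6, U7
#' @return landmark type string
#' @export
crown_landmark_type <- function(tooth_id) {
  switch(tooth_id,
         U1 = , U2 = "incisal_mid",
         U3 = "cusp_tip",
         U5 = "buccal_cusp",
         U6 = , U7 = "MB_cusp",
         stop("unknown tooth id: ", tooth_id))
}

#' Canonical landmark name
#' @param type landmark type (e.g. "MB_cusp", "apex")
#' @param tooth_id,side tooth identity
#' @return string like `"MB_cusp_U6_R"`
#' @export
landmark_name <- function(type, tooth_id, side) paste(type, tooth_id, side, sep = "_")

#' The fixed landmark vocabulary
#'
#' All crown landmarks and root-apex landmarks for the 12 study teeth.
#' @return character vector of valid landmark names
#' @export
landmark_vocabulary <- function() {
  unlist(lapply(TOOTH_IDS, function(tid)
    lapply(SIDES, function(s)
      c(landmark_name(crown_landmark_type(tid), tid, s),
        landmark_name("apex", tid, s)))))
}

#' Construct a tooth model
#'
#' @param tooth_id one of U1, U2, U3, U5, U6, U7
#' @param side "R" or "L"
#' @param crown_point crown landmark (incisal midpoint / cusp tip /
#'   buccal cusp / mesiobuccal cusp), mm; also the reference point
#' @param apex_point root apex (for molars, the mesiobuccal root apex), mm
#' @param mesh optional crown+root [tri_mesh()]
#' @return object of class `tooth_model`
#' @export
tooth_model <- function(tooth_id, side, crown_point, apex_point, mesh = NULL) {
  stopifnot(tooth_id %in% TOOTH_IDS, side %in% SIDES)
  structure(list(tooth_id = tooth_id, side = side,
                 crown_point = as.numeric(crown_point),
                 apex_point = as.numeric(apex_point),
                 ref_point = as.numeric(crown_point),
                 mesh = mesh),
            class = "tooth_model")
}

#' Anterior/posterior class of a tooth
#' @param tooth_id one of U1..U7
#' @return "anterior" (U1-U3) or "posterior" (U5-U7)
#' @export
tooth_class <- function(tooth_id) {
  if (tooth_id %in% c("U1", "U2", "U3")) "anterior"
  else if (tooth_id %in% c("U5", "U6", "U7")) "posterior"
  else stop("unknown tooth id: ", tooth_id)
}

#' Construct a patient-stage model set
#'
#' @param stage "pre", "designed" or "achieved"
#' @param bone maxillary bone [tri_mesh()] (may be NULL for landmark-only
#'   analyses)
#' @param teeth named list of [tooth_model()]s keyed `"U1_R"`, ...
#' @param landmarks named list/map of landmark name to length-3 point
#' @param registered is the case co-registered with the pretreatment
#'   coordinate space? (pre and designed are by construction)
#' @return object of class `maxillary_case`
#' @export
maxillary_case <- function(stage, bone = NULL, teeth = list(),
                           landmarks = list(),
                           registered = stage %in% c("pre", "designed")) {
  stopifnot(stage %in% c("pre", "designed", "achieved"))
  bad <- setdiff(names(landmarks), landmark_vocabulary())
  if (length(bad)) stop("unknown landmark name(s): ", paste(bad, collapse = ", "))
  structure(list(stage = stage, bone = bone, teeth = teeth,
                 landmarks = landmarks, registered = registered),
            class = "maxillary_case")
}

#' @export
print.maxillary_case <- function(x, ...) {
  cat(sprintf("maxillary_case (%s): %d teeth, %d landmarks, bone %s, %sregistered\n",
              x$stage, length(x$teeth), length(x$landmarks),
              if (is.null(x$bone)) "absent" else "present",
              if (x$registered) "" else "not "))
  invisible(x)
}

#' Apply one global rigid motion to every component of a case
#' @param case a [maxillary_case()]
#' @param tr a [rigid_transform()]
#' @return transformed case
#' @export
transform_case <- function(case, tr) {
  if (!is.null(case$bone)) case$bone <- transform_mesh(case$bone, tr)
  case$teeth <- lapply(case$teeth, function(tm) {
    tm$crown_point <- rt_apply(tr, tm$crown_point)
    tm$apex_point <- rt_apply(tr, tm$apex_point)
    tm$ref_point <- rt_apply(tr, tm$ref_point)
    if (!is.null(tm$mesh)) tm$mesh <- transform_mesh(tm$mesh, tr)
    tm
  })
  case$landmarks <- lapply(case$landmarks, function(p) rt_apply(tr, p))
  case
}
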