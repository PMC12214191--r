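# World and per-tooth measurement frames.
#
# The world coordinate system is built once on the pretreatment model:
#   occlusal (transverse) plane -- best-fit plane of the bilateral first
#     molar mesiobuccal cusps and the central-incisor mesioincisal point;
#   coronal plane -- contains the bilateral U6 mesiobuccal-cusp line,
#     perpendicular to the occlusal plane;
#   midsagittal plane -- perpendicular to both, through the mesioincisal
#     point.
# Plane normals are canonically oriented: occlusal normal occlusally
# (away from the root apices), coronal normal anteriorly, midsagittal
# normal toward the patient's left. The frame triad is right-handed with
# Z = occlusal normal, Y = coronal normal (anteroposterior) and
# X completing the triad (transverse).

#' Build the world coordinate system from named landmarks
#'
#' Requires the bilateral U6 mesiobuccal cusps and at least one U1
#' incisal midpoint. The single "mesioincisal point of the central
#' incisor" is taken as the midpoint of the bilateral U1 incisal-edge
#' midpoints when both are present (they coincide at the midline on a
#' symmetric arch). Occlusal-normal orientation is resolved by any apex
#' landmarks present, else by `up_hint`.
#'
#' @param landmarks named list of landmark name to length-3 point (mm)
#' @param up_hint fallback occlusal direction used only when no apex
#'   landmark is available
#' @return object of class `world_frame` with fields `frame` ([frame3()])
#'   and the `occlusal`, `coronal`, `midsagittal` [plane()]s
#' @export
build_world_frame <- function(landmarks, up_hint = c(0, 0, 1)) {
  need <- c("MB_cusp_U6_R", "MB_cusp_U6_L")
  miss <- setdiff(need, names(landmarks))
  if (length(miss)) stop("missing landmark(s): ", paste(miss, collapse = ", "))
  u1 <- intersect(c("incisal_mid_U1_R", "incisal_mid_U1_L"), names(landmarks))
  if (!length(u1)) stop("missing landmark(s): incisal_mid_U1_R/L")
  mbr <- landmarks[["MB_cusp_U6_R"]]
  mbl <- landmarks[["MB_cusp_U6_L"]]
  inc <- colMeans(do.call(rbind, landmarks[u1]))

  occl <- fit_plane(rbind(mbr, mbl, inc))
  # orient occlusally: away from the root apices when known
  apexes <- landmarks[grepl("^apex_", names(landmarks))]
  up <- if (length(apexes)) {
    colMeans(rbind(mbr, mbl, inc)) - colMeans(do.call(rbind, apexes))
  } else up_hint
  if (vdot(occl$normal, up) < 0) occl$normal <- -occl$normal

  z <- occl$normal
  u_molar <- vunit(mbl - mbr)
  n_cor <- vunit(vcross(z, u_molar))
  if (vdot(n_cor, inc - (mbr + mbl) / 2) < 0) n_cor <- -n_cor
  y <- n_cor
  x <- vcross(y, z)                         # right-handed triad
  origin <- project_point_onto_plane(inc, occl)

  # midsagittal plane normal oriented toward the patient's left
  n_mid <- if (vdot(x, mbl - mbr) >= 0) x else -x
  structure(list(
    frame = frame3(origin, cbind(x, y, z)),
    occlusal = plane(origin, z),
    coronal = plane((mbr + mbl) / 2, n_cor),
    midsagittal = plane(inc, n_mid)
  ), class = "world_frame")
}

#' Transfer the pretreatment world frame to another stage
#'
#' After bone-based superimposition all stages share the pretreatment
#' coordinate space, so the transfer is the identity; this function
#' enforces the ordering (a stage must be co-registered first).
#'
#' @param world a [world_frame()] built on the pretreatment case
#' @param stage a co-registered [maxillary_case()]
#' @return the same `world_frame`
#' @export
transfer_world_frame <- function(world, stage) {
  if (!isTRUE(stage$registered))
    stop("stage '", stage$stage,
         "' is not co-registered with the pretreatment model; run superimpose_case() first")
  world
}

#' Tooth long axis from crown and apex landmarks
#'
#' The line through the crown landmark (incisal midpoint, cusp tip,
#' buccal cusp or mesiobuccal cusp) and the corresponding root apex;
#' direction points apex to crown, i.e. occlusally.
#'
#' @param tooth a [tooth_model()]
#' @param world optional [world_frame()]; when given, checks the axis
#'   points occlusally
#' @param min_length_mm sanity floor on crown-apex distance
#' @return object of class `tooth_axis`: `crown_point`, `apex_point`,
#'   unit `direction`
#' @export
tooth_long_axis <- function(tooth, world = NULL, min_length_mm = 5) {
  if (is.null(tooth$crown_point) || is.null(tooth$apex_point) ||
      !all(is.finite(c(tooth$crown_point, tooth$apex_point))))
    stop("tooth ", tooth$tooth_id, "_", tooth$side,
         ": crown and apex landmarks are required")
  d <- tooth$crown_point - tooth$apex_point
  if (vnorm(d) < min_length_mm)
    stop("tooth ", tooth$tooth_id, "_", tooth$side,
         sprintf(": crown-apex distance %.2f mm below the %.1f mm sanity floor",
                 vnorm(d), min_length_mm))
  dir <- vunit(d)
  if (!is.null(world) && vdot(dir, world$occlusal$normal) <= 0)
    stop("tooth ", tooth$tooth_id, "_", tooth$side,
         ": long axis does not point occlusally")
  structure(list(crown_point = tooth$crown_point, apex_point = tooth$apex_point,
                 direction = dir), class = "tooth_axis")
}

#' Per-tooth measurement frame
#'
#' The mesiodistal plane passes through the tooth reference point, is
#' perpendicular to the occlusal plane, and is parallel to the coronal
#' plane for anterior teeth (U1-U3) or to the midsagittal plane for
#' posterior teeth (U5-U7); the buccolingual plane is the perpendicular
#' counterpart. The vertical line is their intersection (the occlusal
#' normal through the reference point). Anatomical unit vectors fix the
#' sign conventions: mesial, buccal and extrusion (occlusal) positive.
#'
#' @param ref_point the tooth's reference point, mm
#' @param world a [world_frame()]
#' @param tooth_class "anterior" or "posterior"
#' @param side "R" or "L"
#' @return object of class `tooth_frame`: `ref_point`, `md_plane`,
#'   `bl_plane`, `vertical_dir`, `mesial_pos`, `buccal_pos`,
#'   `extrusion_pos`, and the angle sign axes `sign_md`, `sign_bl`
#' @export
build_tooth_frame <- function(ref_point, world, tooth_class, side) {
  stopifnot(side %in% SIDES)
  if (!tooth_class %in% c("anterior", "posterior"))
    stop("unknown tooth class: ", tooth_class)
  ref_point <- as.numeric(ref_point)
  if (!all(is.finite(ref_point))) stop("reference point must be finite")
  e_left <- world$midsagittal$normal     # toward patient's left
  e_ant <- world$coronal$normal          # anteriorly
  e_occ <- world$occlusal$normal         # occlusally
  side_sign <- point_plane_distance(ref_point, world$midsagittal)
  if (abs(side_sign) < 1e-9) side_sign <- if (side == "L") 1 else -1
  if (tooth_class == "anterior") {
    md_normal <- e_ant                    # md plane parallel to coronal
    bl_normal <- e_left                   # bl plane parallel to midsagittal
    mesial <- -sign(side_sign) * e_left   # toward the midsagittal plane
    buccal <- e_ant                       # labially, away from arch center
  } else {
    md_normal <- e_left                   # md plane parallel to midsagittal
    bl_normal <- e_ant                    # bl plane parallel to coronal
    mesial <- e_ant                       # anteriorly, toward coronal plane
    buccal <- sign(side_sign) * e_left    # away from the midsagittal plane
  }
  structure(list(
    ref_point = ref_point,
    md_plane = plane(ref_point, md_normal),
    bl_plane = plane(ref_point, bl_normal),
    vertical_dir = e_occ,
    mesial_pos = mesial, buccal_pos = buccal, extrusion_pos = e_occ,
    sign_md = vcross(mesial, e_occ),      # mesial crown tip positive
    sign_bl = vcross(buccal, e_occ),      # buccal crown tip positive
    tooth_class = tooth_class, side = side
  ), class = "tooth_frame")
}
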