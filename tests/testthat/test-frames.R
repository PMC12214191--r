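# World coordinate system and per-tooth measurement frames.

test_that("the world frame of a symmetric arch has the canonical planes", {
  lm <- symmetric_world_landmarks()
  w <- build_world_frame(lm)
  expect_equal(abs(w$occlusal$normal), c(0, 0, 1), tolerance = 1e-12)
  # midsagittal: plane x = 0 with normal toward the patient's left (+x here)
  expect_equal(w$midsagittal$normal, c(1, 0, 0), tolerance = 1e-12)
  expect_equal(point_plane_distance(c(0, 5, 3), w$midsagittal), 0, tolerance = 1e-12)
  # coronal: plane y = -30 with anterior normal
  expect_equal(w$coronal$normal, c(0, 1, 0), tolerance = 1e-12)
  expect_equal(point_plane_distance(c(4, -30, 1), w$coronal), 0, tolerance = 1e-12)
  expect_equal(w$frame$origin, c(0, 0, 0), tolerance = 1e-12)
  # pairwise perpendicular planes
  expect_lt(abs(vdot(w$occlusal$normal, w$coronal$normal)), 1e-9)
  expect_lt(abs(vdot(w$occlusal$normal, w$midsagittal$normal)), 1e-9)
  expect_lt(abs(vdot(w$coronal$normal, w$midsagittal$normal)), 1e-9)
})

test_that("asymmetric cusp heights give the exact three-point plane", {
  lm <- list(MB_cusp_U6_R = c(-25, -30, 0), MB_cusp_U6_L = c(25, -30, 1),
             incisal_mid_U1_R = c(0, 0, 0), incisal_mid_U1_L = c(0, 0, 0))
  w <- build_world_frame(lm)
  for (p in list(lm$MB_cusp_U6_R, lm$MB_cusp_U6_L, c(0, 0, 0)))
    expect_lt(abs(point_plane_distance(p, w$occlusal)), 1e-9)
})

test_that("the world frame is equivariant under rigid motion of the landmarks", {
  case <- synth_case(with_meshes = FALSE)
  w0 <- build_world_frame(case$landmarks)
  set.seed(23)
  for (i in 1:5) {
    tr <- random_rigid(max_angle_deg = 30, max_trans_mm = 20)
    w1 <- build_world_frame(lapply(case$landmarks, function(p) rt_apply(tr, p)))
    expect_equal(w1$frame$origin, rt_apply(tr, w0$frame$origin), tolerance = 1e-6)
    expect_equal(w1$occlusal$normal, rt_apply_dir(tr, w0$occlusal$normal),
                 tolerance = 1e-6)
    expect_equal(w1$midsagittal$normal, rt_apply_dir(tr, w0$midsagittal$normal),
                 tolerance = 1e-6)
  }
})

test_that("world-frame construction validates its landmarks", {
  lm <- symmetric_world_landmarks()
  expect_error(build_world_frame(lm[c("MB_cusp_U6_R", "incisal_mid_U1_R")]),
               "missing landmark")
  collinear <- list(MB_cusp_U6_R = c(-25, 0, 0), MB_cusp_U6_L = c(25, 0, 0),
                    incisal_mid_U1_R = c(0, 0, 0), incisal_mid_U1_L = c(0, 0, 0))
  expect_error(build_world_frame(collinear), "collinear")
})

test_that("frame transfer requires co-registration and is the identity", {
  case <- synth_case(with_meshes = FALSE)
  w <- build_world_frame(case$landmarks)
  st <- apply_prescription(case, default_prescription())
  expect_identical(transfer_world_frame(w, st$designed), w)
  un <- st$achieved
  un$registered <- FALSE
  expect_error(transfer_world_frame(w, un), "not co-registered")
})

test_that("tooth long axes point apex-to-crown with the sanity floor enforced", {
  tm <- tooth_model("U3", "R", c(0, 0, 0), c(0, 0, -20))
  ax <- tooth_long_axis(tm)
  expect_equal(ax$direction, c(0, 0, 1))
  tm2 <- tooth_model("U1", "L", c(1, 0, 0), c(0, 0, -10))
  expect_equal(tooth_long_axis(tm2)$direction, vunit(c(1, 0, 10)), tolerance = 1e-12)
  short <- tooth_model("U1", "R", c(0, 0, 0), c(0, 0, -2))
  expect_error(tooth_long_axis(short), "sanity floor")
  noapex <- tooth_model("U1", "R", c(0, 0, 0), c(0, 0, -20))
  noapex$apex_point <- NULL
  expect_error(tooth_long_axis(noapex), "apex")
})

test_that("tooth frames follow the anterior/posterior plane rules", {
  w <- build_world_frame(symmetric_world_landmarks())
  ant <- build_tooth_frame(c(-4, -1, 0), w, "anterior", "R")
  # anterior: md plane parallel to coronal, bl plane parallel to midsagittal
  expect_equal(abs(vdot(ant$md_plane$normal, w$coronal$normal)), 1, tolerance = 1e-9)
  expect_equal(abs(vdot(ant$bl_plane$normal, w$midsagittal$normal)), 1, tolerance = 1e-9)
  post <- build_tooth_frame(c(-23, -25, 0), w, "posterior", "R")
  expect_equal(abs(vdot(post$md_plane$normal, w$midsagittal$normal)), 1, tolerance = 1e-9)
  expect_equal(abs(vdot(post$bl_plane$normal, w$coronal$normal)), 1, tolerance = 1e-9)
  expect_error(build_tooth_frame(c(0, 0, 0), w, "premolarish", "R"), "tooth class")
})

test_that("anatomical direction vectors obey the sign conventions and mirror", {
  w <- build_world_frame(symmetric_world_landmarks())
  antR <- build_tooth_frame(c(-4, -1, 0), w, "anterior", "R")
  antL <- build_tooth_frame(c(4, -1, 0), w, "anterior", "L")
  # anterior mesial points toward the midsagittal plane
  expect_equal(antR$mesial_pos, c(1, 0, 0), tolerance = 1e-9)
  expect_equal(antL$mesial_pos, c(-1, 0, 0), tolerance = 1e-9)
  postR <- build_tooth_frame(c(-23, -25, 0), w, "posterior", "R")
  postL <- build_tooth_frame(c(23, -25, 0), w, "posterior", "L")
  # posterior mesial points anteriorly; buccal away from the arch center
  expect_equal(postR$mesial_pos, c(0, 1, 0), tolerance = 1e-9)
  expect_equal(postL$mesial_pos, c(0, 1, 0), tolerance = 1e-9)
  expect_equal(postR$buccal_pos, -postL$buccal_pos, tolerance = 1e-9)
  for (fr in list(antR, antL, postR, postL)) {
    expect_lt(abs(vdot(fr$md_plane$normal, fr$bl_plane$normal)), 1e-9)
    # both measurement planes contain the vertical direction
    expect_lt(abs(vdot(fr$vertical_dir, fr$md_plane$normal)), 1e-9)
    expect_lt(abs(vdot(fr$vertical_dir, fr$bl_plane$normal)), 1e-9)
    # anatomical triad is orthogonal
    expect_lt(abs(vdot(fr$mesial_pos, fr$buccal_pos)), 1e-9)
    expect_lt(abs(vdot(fr$mesial_pos, fr$extrusion_pos)), 1e-9)
  }
})

test_that("the synthetic arch is mirror-symmetric about the midsagittal plane", {
  case <- synth_case(with_meshes = FALSE)
  for (nm in grep("_R$", names(case$landmarks), value = TRUE)) {
    l <- case$landmarks[[sub("_R$", "_L", nm)]]
    r <- case$landmarks[[nm]]
    expect_equal(l * c(-1, 1, 1), r, tolerance = 1e-9)
  }
})
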