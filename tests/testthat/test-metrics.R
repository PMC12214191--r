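# The five movement metrics, their sign conventions and the
# designed-minus-achieved differencing.

test_that("angulation and inclination read constructed tips with anatomical signs", {
  w <- build_world_frame(symmetric_world_landmarks())
  fr <- build_tooth_frame(c(-4, -1, 0), w, "anterior", "R")
  vertical <- tooth_model("U1", "R", c(-4, -1, 0), c(-4, -1, -15))
  ax <- tooth_long_axis(vertical, w)
  expect_equal(mesiodistal_angulation(ax, fr), 0, tolerance = 1e-9)
  expect_equal(buccolingual_inclination(ax, fr), 0, tolerance = 1e-9)

  # 7 deg mesial crown tip (toward midline, +x for a right anterior tooth)
  tipped <- tooth_model("U1", "R",
                        c(-4, -1, 0) + 15 * vunit(c(sin(7 * pi / 180), 0, cos(7 * pi / 180))),
                        c(-4, -1, 0))
  expect_equal(mesiodistal_angulation(tooth_long_axis(tipped, w), fr), 7,
               tolerance = 1e-9)
  # 25 deg buccal (labial, +y) and 5 deg lingual crown tip
  bucc <- tooth_model("U1", "R",
                      c(-4, -1, 0) + 15 * vunit(c(0, sin(25 * pi / 180), cos(25 * pi / 180))),
                      c(-4, -1, 0))
  expect_equal(buccolingual_inclination(tooth_long_axis(bucc, w), fr), 25,
               tolerance = 1e-9)
  ling <- tooth_model("U1", "R",
                      c(-4, -1, 0) + 15 * vunit(c(0, -sin(5 * pi / 180), cos(5 * pi / 180))),
                      c(-4, -1, 0))
  expect_equal(buccolingual_inclination(tooth_long_axis(ling, w), fr), -5,
               tolerance = 1e-9)
})

test_that("linear components decompose displacements along anatomical axes", {
  w <- build_world_frame(symmetric_world_landmarks())
  fr <- build_tooth_frame(c(-23, -25, 0), w, "posterior", "R")
  p0 <- c(-23, -25, 0)
  expect_equal(linear_components(p0, p0, fr),
               c(MD_mm = 0, BL_mm = 0, IE_mm = 0))
  expect_equal(linear_components(p0, p0 + 2 * fr$mesial_pos, fr),
               c(MD_mm = 2, BL_mm = 0, IE_mm = 0), tolerance = 1e-12)
  d <- -1.2 * fr$mesial_pos + 0.4 * fr$buccal_pos + 0.8 * fr$extrusion_pos
  expect_equal(linear_components(p0, p0 + d, fr),
               c(MD_mm = -1.2, BL_mm = 0.4, IE_mm = 0.8), tolerance = 1e-9)
})

test_that("noiseless prescribed movements are recovered within 0.01 units on all teeth", {
  case <- synth_case(with_meshes = FALSE)
  presc <- default_prescription()
  st <- apply_prescription(case, presc)
  rec <- case_movement_records(case, st$designed, st$achieved)
  expect_true(all(rec$measured))
  pr <- merge(rec, presc, by = c("tooth", "side"))
  for (m in c("MD_deg", "BL_deg", "MD_mm", "BL_mm", "IE_mm")) {
    expect_lt(max(abs(pr[[paste0("designed_", m, ".x")]] -
                        pr[[paste0("designed_", m, ".y")]])), 0.01)
    expect_lt(max(abs(pr[[paste0("achieved_", m, ".x")]] -
                        pr[[paste0("achieved_", m, ".y")]])), 0.01)
    expect_equal(pr[[paste0("d_", m)]],
                 pr[[paste0("designed_", m, ".y")]] - pr[[paste0("achieved_", m, ".y")]],
                 tolerance = 1e-9)
  }
})

test_that("metrics are invariant under a global rigid motion of the co-registered triple", {
  case <- synth_case(with_meshes = FALSE)
  st <- apply_prescription(case, default_prescription())
  rec0 <- case_movement_records(case, st$designed, st$achieved)
  set.seed(29)
  tr <- random_rigid(max_angle_deg = 40, max_trans_mm = 30)
  rec1 <- case_movement_records(transform_case(case, tr),
                                transform_case(st$designed, tr),
                                transform_case(st$achieved, tr))
  for (cn in grep("^(designed|achieved|d)_", names(rec0), value = TRUE))
    expect_lt(max(abs(rec0[[cn]] - rec1[[cn]])), 1e-6)
})

test_that("swapping designed and achieved negates every difference", {
  case <- synth_case(with_meshes = FALSE)
  st <- apply_prescription(case, default_prescription())
  rec <- case_movement_records(case, st$designed, st$achieved)
  swp <- case_movement_records(case, st$achieved, st$designed)
  for (m in c("MD_deg", "BL_deg", "MD_mm", "BL_mm", "IE_mm"))
    expect_equal(swp[[paste0("d_", m)]], -rec[[paste0("d_", m)]], tolerance = 1e-9)
})

test_that("mirrored teeth report identical anatomical-sign metrics", {
  case <- synth_case(with_meshes = FALSE)
  st <- apply_prescription(case, default_prescription())  # same prescription both sides
  rec <- case_movement_records(case, st$designed, st$achieved)
  for (m in grep("^d_", names(rec), value = TRUE)) {
    r <- rec[rec$side == "R", ]; l <- rec[rec$side == "L", ]
    expect_equal(r[[m]][order(r$tooth)], l[[m]][order(l$tooth)], tolerance = 1e-9)
  }
})

test_that("a designed/achieved pair equal by construction gives zero differences", {
  case <- synth_case(with_meshes = FALSE)
  presc <- default_prescription()
  for (m in c("MD_deg", "BL_deg", "MD_mm", "BL_mm", "IE_mm"))
    presc[[paste0("achieved_", m)]] <- presc[[paste0("designed_", m)]]
  st <- apply_prescription(case, presc)
  rec <- case_movement_records(case, st$designed, st$achieved)
  for (m in grep("^d_", names(rec), value = TRUE))
    expect_lt(max(abs(rec[[m]])), 1e-9)
})

test_that("the cohort table has 12 rows per patient and flags missing teeth", {
  sim <- simulate_cohort(cohort_sim_params(n_patients = 1, seed = 4))
  expect_equal(nrow(sim$cohort), 12)
  sim33 <- simulate_cohort(cohort_sim_params(n_patients = 33, seed = 4))
  expect_equal(nrow(sim33$cohort), 396)

  # geometric patient with an injected missing U6 landmark
  case <- synth_case(with_meshes = FALSE)
  st <- apply_prescription(case, default_prescription())
  broken <- st$achieved
  broken$teeth$U6_R$apex_point <- NULL
  rec <- case_movement_records(case, st$designed, broken)
  expect_equal(nrow(rec), 12)
  expect_equal(sum(!rec$measured), 1)
  expect_true(is.na(rec$d_MD_deg[rec$tooth == "U6" & rec$side == "R"]))

  covs <- data.frame(patient = "P001", age = 25)
  rec$patient <- "P001"
  tab <- build_cohort_table(rec, covs)
  expect_equal(nrow(tab), 12)
  rec2 <- rec; rec2$patient <- "P999"
  expect_error(build_cohort_table(rec2, covs), "join error|no covariate")
})
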