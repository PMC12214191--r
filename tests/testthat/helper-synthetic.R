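# Shared fixture builders; everything is generated in code.

random_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

random_rigid <- function(max_angle_deg = 180, max_trans_mm = 10) {
  rigid_transform(
    rotation_about_axis(random_unit(), stats::runif(1, -max_angle_deg, max_angle_deg)),
    stats::runif(3, -max_trans_mm, max_trans_mm))
}

# symmetric three-landmark world-frame fixture: bilateral U6 cusps and a
# midline incisor point
symmetric_world_landmarks <- function() {
  list(MB_cusp_U6_R = c(-25, -30, 0),
       MB_cusp_U6_L = c(25, -30, 0),
       incisal_mid_U1_R = c(0, 0, 0),
       incisal_mid_U1_L = c(0, 0, 0))
}

expect_rigid_equal <- function(t1, t2, tol = 1e-6) {
  expect_lt(max(abs(t1$R - t2$R)), tol)
  expect_lt(max(abs(t1$t - t2$t)), tol)
}
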