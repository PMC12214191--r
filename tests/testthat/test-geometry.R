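# Geometric primitives: plane fitting, projections, signed angles,
# rigid transforms, Kabsch landmark fit, orthonormal frames.

test_that("fit_plane recovers exact planes from minimal point sets", {
  pl <- fit_plane(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  expect_equal(abs(pl$normal), c(0, 0, 1), tolerance = 1e-12)
  expect_equal(attr(pl, "rms"), 0, tolerance = 1e-12)

  pl2 <- fit_plane(rbind(c(0, 0, 2), c(1, 0, 2), c(0, 1, 2), c(3, -2, 2)))
  expect_equal(abs(pl2$normal), c(0, 0, 1), tolerance = 1e-12)
  expect_equal(vdot(pl2$point, pl2$normal), 2 * sign(pl2$normal[3]), tolerance = 1e-12)
  expect_equal(attr(pl2, "rms"), 0, tolerance = 1e-12)

  expect_error(fit_plane(rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2))),
               "collinear")
  expect_error(fit_plane(rbind(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))),
               "collinear|coincident")
})

test_that("fit_plane matches an independent covariance eigen-decomposition", {
  set.seed(11)
  pts <- cbind(stats::rnorm(20, sd = 5), stats::rnorm(20, sd = 5),
               stats::rnorm(20, sd = 0.01))
  pl <- fit_plane(pts)
  # oracle: eigenvector of the covariance matrix with smallest eigenvalue
  ctr <- colMeans(pts)
  C <- crossprod(sweep(pts, 2, ctr)) / nrow(pts)
  ev <- eigen(C, symmetric = TRUE)
  n_oracle <- ev$vectors[, 3]
  expect_lt(min(vnorm(pl$normal - n_oracle), vnorm(pl$normal + n_oracle)), 1e-6)
  rms_oracle <- sqrt(ev$values[3])
  expect_equal(attr(pl, "rms"), rms_oracle, tolerance = 1e-9)
})

test_that("fit_plane is equivariant under rigid motion of its inputs", {
  set.seed(21)
  pts <- cbind(stats::rnorm(15), stats::rnorm(15), 0.1 * stats::rnorm(15))
  pl <- fit_plane(pts)
  for (i in 1:5) {
    tr <- random_rigid()
    pl2 <- fit_plane(rt_apply(tr, pts))
    n_moved <- rt_apply_dir(tr, pl$normal)
    expect_lt(min(vnorm(pl2$normal - n_moved), vnorm(pl2$normal + n_moved)), 1e-9)
    expect_lt(abs(point_plane_distance(rt_apply(tr, pl$point), pl2)), 1e-9)
  }
})

test_that("vector projection onto a plane follows the direct formula and is idempotent", {
  pl <- plane(c(0, 0, 0), c(0, 0, 1))
  expect_equal(project_vector_onto_plane(c(0, 0, 1), pl), c(0, 0, 0))
  expect_equal(project_vector_onto_plane(c(1, 0, 1), pl), c(1, 0, 0))
  set.seed(5)
  for (i in 1:20) {
    v <- stats::rnorm(3, sd = 4)
    p <- plane(stats::rnorm(3), random_unit())
    got <- project_vector_onto_plane(v, p)
    expect_equal(got, v - vdot(v, p$normal) * p$normal, tolerance = 1e-12)
    expect_lt(abs(vdot(got, p$normal)), 1e-9)
    expect_equal(project_vector_onto_plane(got, p), got, tolerance = 1e-12)
  }
})

test_that("signed angles match an atan2 oracle and are antisymmetric", {
  pl <- plane(c(0, 0, 0), c(1, 0, 0))
  a <- c(0, sin(10 * pi / 180), cos(10 * pi / 180))
  expect_equal(signed_angle_in_plane(a, c(0, 0, 1), pl, c(1, 0, 0)), 10,
               tolerance = 1e-9)
  expect_equal(signed_angle_in_plane(a, a, pl, c(1, 0, 0)), 0, tolerance = 1e-12)

  set.seed(31)
  for (i in 1:25) {
    n <- random_unit()
    p <- plane(stats::rnorm(3), n)
    a <- stats::rnorm(3); b <- stats::rnorm(3)
    ap <- a - vdot(a, n) * n; bp <- b - vdot(b, n) * n
    if (vnorm(ap) < 1e-3 || vnorm(bp) < 1e-3) next
    oracle <- atan2(vdot(vcross(ap, bp), n), vdot(ap, bp)) * 180 / pi
    got <- signed_angle_in_plane(a, b, p, n)
    expect_equal(got, oracle, tolerance = 1e-9)
    expect_equal(signed_angle_in_plane(b, a, p, n), -oracle, tolerance = 1e-9)
  }
  expect_error(signed_angle_in_plane(c(1, 0, 0), c(0, 0, 1), pl, c(1, 0, 0)),
               "degenerate")
})

test_that("rigid transforms compose like 4x4 homogeneous matrices", {
  id <- rigid_identity()
  set.seed(41)
  t1 <- random_rigid(); t2 <- random_rigid()
  expect_rigid_equal(rt_compose(id, t1), t1, tol = 1e-12)
  expect_rigid_equal(rt_compose(t1, rt_inverse(t1)), id, tol = 1e-9)

  H <- function(tr) rbind(cbind(tr$R, tr$t), c(0, 0, 0, 1))
  for (i in 1:10) {
    a <- random_rigid(); b <- random_rigid(); p <- stats::rnorm(3, sd = 8)
    Hc <- H(a) %*% H(b)
    got <- rt_apply(rt_compose(a, b), p)
    expect_equal(got, as.numeric(Hc %*% c(p, 1))[1:3], tolerance = 1e-9)
    expect_equal(got, rt_apply(a, rt_apply(b, p)), tolerance = 1e-9)
  }
  expect_error(rigid_transform(matrix(1:9, 3), c(0, 0, 0)), "orthonormal")
})

test_that("Kabsch landmark fit recovers exact and noisy transforms", {
  set.seed(51)
  S <- matrix(stats::rnorm(30, sd = 10), ncol = 3)
  tr0 <- fit_rigid_landmarks(S, S)
  expect_rigid_equal(tr0, rigid_identity(), tol = 1e-9)
  expect_equal(attr(tr0, "rms"), 0, tolerance = 1e-9)

  truth <- random_rigid()
  tr1 <- fit_rigid_landmarks(S, rt_apply(truth, S))
  expect_rigid_equal(tr1, truth, tol = 1e-9)

  # round trip: composing with the inverse maps source to source
  back <- rt_apply(rt_compose(rt_inverse(tr1), tr1), S)
  expect_lt(max(abs(back - S)), 1e-9)

  expect_error(fit_rigid_landmarks(cbind(1:5, 1:5, 1:5), cbind(1:5, 1:5, 1:5)),
               "collinear")
})

test_that("Kabsch RMS matches a brute-force rotation-grid search on a planar instance", {
  set.seed(61)
  S <- cbind(stats::rnorm(8, sd = 5), stats::rnorm(8, sd = 5), 0)
  Rz <- rotation_about_axis(c(0, 0, 1), 14)
  T_ <- sweep(S %*% t(Rz), 2, c(2, -1, 0), `+`)
  T_[, 1:2] <- T_[, 1:2] + matrix(stats::rnorm(16, sd = 0.2), ncol = 2)
  got <- attr(fit_rigid_landmarks(S, T_), "rms")
  # oracle: 1D grid over in-plane rotation angle with centroid-matching
  # translation (the optimum for planar data lies in this family)
  cs <- colMeans(S); ct <- colMeans(T_)
  grid_rms <- vapply(seq(-180, 180, by = 0.01), function(th) {
    R <- rotation_about_axis(c(0, 0, 1), th)
    M <- sweep(sweep(S, 2, cs) %*% t(R), 2, ct, `+`)
    sqrt(mean(rowSums((M - T_)^2)))
  }, numeric(1))
  expect_lt(abs(got - min(grid_rms)), 1e-4)
  expect_lte(got, min(grid_rms) + 1e-9)
})

test_that("orthonormal frames are right-handed and scale-invariant", {
  f <- build_orthonormal_frame(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_equal(f$axes, diag(3), tolerance = 1e-12, ignore_attr = TRUE)
  f2 <- build_orthonormal_frame(c(0, 0, 0), c(2, 0, 0), c(0, 1, 0))
  expect_equal(f2$axes, f$axes, tolerance = 1e-12)

  set.seed(71)
  for (i in 1:15) {
    f3 <- build_orthonormal_frame(stats::rnorm(3), stats::rnorm(3), stats::rnorm(3))
    G <- crossprod(f3$axes)
    expect_lt(max(abs(G - diag(3))), 1e-9)
    expect_equal(vdot(vcross(f3$axes[, 1], f3$axes[, 2]), f3$axes[, 3]), 1,
                 tolerance = 1e-9)
  }
  expect_error(build_orthonormal_frame(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
               "parallel")
})
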