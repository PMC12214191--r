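# Algebraic identities are held to .TOL_ALG; fitted quantities to .TOL_FIT
# (mm or degrees). Units are mm and degrees at every API boundary.
.TOL_ALG <- 1e-9
.TOL_FIT <- 1e-6

#' Construct a 3D point or vector
#'
#' Points and vectors are plain numeric length-3 vectors in mm (points) or
#' dimensionless components (directions); no class wrapper is used so that
#' they compose freely with matrix algebra.
#'
#' @param x,y,z finite numeric scalars
#' @return numeric length-3 vector
#' @export
vec3 <- function(x, y, z) {
  v <- c(x, y, z)
  if (!all(is.finite(v))) stop("vec3: components must be finite")
  v
}

#' Euclidean norm of a 3-vector
#' @param v numeric length-3
#' @return non-negative scalar
#' @export
vnorm <- function(v) sqrt(sum(v * v))

#' Normalize a 3-vector to unit length
#' @param v numeric length-3
#' @param tol vectors shorter than this are degenerate
#' @return unit vector
#' @export
vunit <- function(v, tol = 1e-12) {
  n <- vnorm(v)
  if (n < tol) stop("degenerate geometry: cannot normalize near-zero vector")
  v / n
}

#' Cross product of two 3-vectors
#' @param a,b numeric length-3
#' @return numeric length-3
#' @export
vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Dot product
#' @param a,b numeric length-3
#' @return scalar
#' @export
vdot <- function(a, b) sum(a * b)

## ---- planes -----------------------------------------------------------

#' An infinite plane through a point with a unit normal
#'
#' @param point numeric length-3, a point on the plane (mm)
#' @param normal numeric length-3; normalized internally
#' @return object of class `plane`
#' @export
plane <- function(point, normal) {
  structure(list(point = as.numeric(point), normal = vunit(as.numeric(normal))),
            class = "plane")
}

#' Signed distance from a point to a plane
#'
#' Positive on the side the normal points to.
#' @param p numeric length-3 point
#' @param pl a [plane()]
#' @return signed distance in mm
#' @export
point_plane_distance <- function(p, pl) vdot(p - pl$point, pl$normal)

#' Orthogonal projection of a point onto a plane
#' @inheritParams point_plane_distance
#' @return numeric length-3
#' @export
project_point_onto_plane <- function(p, pl) {
  p - point_plane_distance(p, pl) * pl$normal
}

#' Project a vector onto a plane
#'
#' Removes the component along the plane normal: `v - (v . n) n`. Idempotent.
#'
#' @param v numeric length-3 direction
#' @param pl a [plane()]
#' @return numeric length-3 lying in the plane
#' @export
project_vector_onto_plane <- function(v, pl) {
  v - vdot(v, pl$normal) * pl$normal
}

#' Least-squares plane through a set of points
#'
#' Minimizes the sum of squared orthogonal distances (total least squares):
#' the plane passes through the centroid and its normal is the singular
#' vector of the centered coordinates with the smallest singular value.
#' The returned normal is canonically oriented so that its component of
#' largest magnitude is positive; anatomical orientation (occlusal,
#' anterior, left) is applied by the callers that know the anatomy.
#'
#' @param points n x 3 numeric matrix (n >= 3) or list of length-3 vectors
#' @return a [plane()] with attribute `rms` (orthogonal-residual RMS, mm)
#' @export
fit_plane <- function(points) {
  pts <- as_point_matrix(points)
  if (nrow(pts) < 3) stop("fit_plane: need at least 3 points")
  ctr <- colMeans(pts)
  x <- sweep(pts, 2, ctr)
  sv <- svd(x)
  # collinear or coincident points: second singular value vanishes
  if (sv$d[2] <= max(sv$d[1], 1) * 1e-10)
    stop("degenerate geometry: points are collinear or coincident")
  n <- sv$v[, 3]
  k <- which.max(abs(n))
  if (n[k] < 0) n <- -n
  pl <- plane(ctr, n)
  attr(pl, "rms") <- sv$d[3] / sqrt(nrow(pts))
  pl
}

as_point_matrix <- function(points) {
  if (is.list(points)) points <- do.call(rbind, points)
  pts <- as.matrix(points)
  storage.mode(pts) <- "double"
  if (ncol(pts) != 3) stop("points must be n x 3")
  if (!all(is.finite(pts))) stop("points must be finite")
  pts
}

#' Signed angle between two directions after projection into a plane
#'
#' Both vectors are projected into the plane; the returned angle in
#' (-180, 180] degrees is positive when the rotation carrying `a`'s
#' projection onto `b`'s projection is right-handed about `sign_axis`
#' (which must be parallel to the plane normal).
#'
#' @param a,b numeric length-3 directions
#' @param pl a [plane()]
#' @param sign_axis numeric length-3, parallel (up to sign) to the plane normal
#' @param tol projections shorter than this fraction are degenerate
#' @return angle in degrees
#' @export
signed_angle_in_plane <- function(a, b, pl, sign_axis, tol = 1e-6) {
  s <- vunit(sign_axis)
  if (abs(abs(vdot(s, pl$normal)) - 1) > 1e-6)
    stop("sign_axis must be parallel to the plane normal")
  ap <- project_vector_onto_plane(a, pl)
  bp <- project_vector_onto_plane(b, pl)
  if (vnorm(ap) < tol * max(vnorm(a), 1) || vnorm(bp) < tol * max(vnorm(b), 1))
    stop("degenerate geometry: vector is (near-)perpendicular to the plane")
  ang <- atan2(vdot(vcross(ap, bp), s), vdot(ap, bp)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

## ---- rigid transforms -------------------------------------------------

#' A rigid (rotation + translation) transform
#'
#' @param rotation 3 x 3 orthonormal matrix with det +1
#' @param translation numeric length-3, mm
#' @return object of class `rigid_transform`
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  R <- as.matrix(rotation)
  if (!all(dim(R) == c(3, 3))) stop("rotation must be 3 x 3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-8 || det(R) < 0)
    stop("rotation must be orthonormal with det +1")
  structure(list(R = R, t = as.numeric(translation)), class = "rigid_transform")
}

#' Identity rigid transform
#' @return a [rigid_transform()]
#' @export
rigid_identity <- function() rigid_transform()

#' Compose two rigid transforms
#'
#' `rt_apply(rt_compose(t1, t2), p)` equals `rt_apply(t1, rt_apply(t2, p))`.
#' @param t1,t2 [rigid_transform()]s
#' @return their composition t1 o t2
#' @export
rt_compose <- function(t1, t2) {
  rigid_transform(t1$R %*% t2$R, as.numeric(t1$R %*% t2$t) + t1$t)
}

#' Invert a rigid transform
#' @param tr a [rigid_transform()]
#' @return the inverse transform
#' @export
rt_inverse <- function(tr) {
  rigid_transform(t(tr$R), as.numeric(-t(tr$R) %*% tr$t))
}

#' Apply a rigid transform to points
#' @param tr a [rigid_transform()]
#' @param p length-3 vector or n x 3 matrix of points
#' @return same shape as `p`
#' @export
rt_apply <- function(tr, p) {
  if (is.matrix(p)) {
    sweep(p %*% t(tr$R), 2, tr$t, `+`)
  } else {
    as.numeric(tr$R %*% p) + tr$t
  }
}

#' Apply a rigid transform to a direction (rotation only)
#' @inheritParams rt_apply
#' @param v length-3 direction
#' @return rotated direction
#' @export
rt_apply_dir <- function(tr, v) as.numeric(tr$R %*% v)

#' Rotation matrix about an arbitrary axis (Rodrigues)
#' @param axis numeric length-3, normalized internally
#' @param angle_deg rotation angle, degrees, right-handed about `axis`
#' @return 3 x 3 rotation matrix
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  u <- vunit(axis)
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Minimal rotation carrying one direction onto another
#' @param a,b numeric length-3 directions (normalized internally)
#' @return 3 x 3 rotation matrix with `R a_hat = b_hat`
#' @export
rotation_between <- function(a, b) {
  a <- vunit(a); b <- vunit(b)
  ax <- vcross(a, b)
  s <- vnorm(ax)
  c_ <- vdot(a, b)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate 180 deg about any perpendicular axis
    p <- if (abs(a[1]) < 0.9) vunit(vcross(a, c(1, 0, 0))) else vunit(vcross(a, c(0, 1, 0)))
    return(rotation_about_axis(p, 180))
  }
  rotation_about_axis(ax, atan2(s, c_) * 180 / pi)
}

## ---- frames -----------------------------------------------------------

#' A right-handed orthonormal frame
#'
#' @param origin numeric length-3, mm
#' @param axes 3 x 3 matrix whose columns are the x, y, z unit axes
#' @return object of class `frame3`
#' @export
frame3 <- function(origin, axes) {
  A <- as.matrix(axes)
  if (max(abs(crossprod(A) - diag(3))) > 1e-8)
    stop("frame axes must be orthonormal")
  if (vdot(vcross(A[, 1], A[, 2]), A[, 3]) < 0)
    stop("frame must be right-handed")
  structure(list(origin = as.numeric(origin), axes = A), class = "frame3")
}

#' Build a right-handed orthonormal frame from two directions
#'
#' First axis is the normalized `primary`; the second is the Gram-Schmidt
#' orthogonalization of `secondary`; the third completes the right-handed
#' triad.
#'
#' @param origin numeric length-3
#' @param primary,secondary non-parallel directions
#' @return a [frame3()]
#' @export
build_orthonormal_frame <- function(origin, primary, secondary) {
  e1 <- vunit(primary)
  s <- secondary - vdot(secondary, e1) * e1
  if (vnorm(s) < 1e-9 * max(vnorm(secondary), 1))
    stop("degenerate geometry: primary and secondary directions are parallel")
  e2 <- vunit(s)
  frame3(origin, cbind(e1, e2, vcross(e1, e2)))
}

## ---- landmark-based rigid fit (Kabsch) --------------------------------

#' Least-squares rigid transform between corresponding landmark sets
#'
#' Closed-form Kabsch/Procrustes solution without scaling: finds the
#' rotation and translation minimizing the sum of squared distances
#' between `rt_apply(tr, source)` and `target`.
#'
#' @param source,target n x 3 matrices (or lists) of corresponding points,
#'   n >= 3, not all collinear
#' @return a [rigid_transform()] with attribute `rms` (mm)
#' @export
fit_rigid_landmarks <- function(source, target) {
  S <- as_point_matrix(source)
  T_ <- as_point_matrix(target)
  if (nrow(S) != nrow(T_)) stop("source and target must have equal point counts")
  if (nrow(S) < 3) stop("need at least 3 correspondences")
  cs <- colMeans(S); ct <- colMeans(T_)
  S0 <- sweep(S, 2, cs); T0 <- sweep(T_, 2, ct)
  if (svd(S0)$d[2] <= max(svd(S0)$d[1], 1) * 1e-10)
    stop("degenerate geometry: source points are collinear")
  H <- crossprod(S0, T0)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- rigid_transform(R, ct - as.numeric(R %*% cs))
  res <- rt_apply(tr, S) - T_
  attr(tr, "rms") <- sqrt(mean(rowSums(res^2)))
  tr
}
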