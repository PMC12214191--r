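# Best-fit rigid registration of the achieved maxillary model to the
# pretreatment model on the bone surface. The registration is a trimmed
# point-to-plane ICP; teeth and landmarks are passengers moved by the
# same global rigid motion.

#' ICP configuration
#'
#' @param n_samples number of source vertices used per iteration (uniform
#'   random subsample, seeded; all vertices if the mesh is smaller)
#' @param max_iter iteration cap
#' @param rel_tol convergence threshold on the relative RMS change
#' @param trim fraction of closest correspondences kept each iteration
#'   (robustness against partial overlap)
#' @param max_init_rms registrations whose initial RMS exceeds this (mm)
#'   are rejected as non-overlapping
#' @param seed integer seed for the subsampling
#' @return a list of class `icp_config`
#' @export
icp_config <- function(n_samples = 5000, max_iter = 100, rel_tol = 1e-6,
                       trim = 0.8, max_init_rms = 20, seed = 1L) {
  stopifnot(n_samples >= 10, max_iter >= 1, rel_tol > 0,
            trim > 0, trim <= 1, max_init_rms > 0)
  structure(list(n_samples = n_samples, max_iter = max_iter, rel_tol = rel_tol,
                 trim = trim, max_init_rms = max_init_rms, seed = as.integer(seed)),
            class = "icp_config")
}

# nearest target vertex for each row of P (brute force, chunked)
nearest_vertex <- function(P, TV) {
  t2 <- rowSums(TV^2)
  n <- nrow(P)
  idx <- integer(n)
  step <- max(1L, floor(2e6 / nrow(TV)))
  for (s in seq(1L, n, by = step)) {
    e <- min(n, s + step - 1L)
    D <- outer(rowSums(P[s:e, , drop = FALSE]^2), t2, `+`) -
      2 * P[s:e, , drop = FALSE] %*% t(TV)
    idx[s:e] <- max.col(-D, ties.method = "first")
  }
  idx
}

with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Trimmed point-to-plane ICP registration
#'
#' Iteratively matches a subsample of source vertices to their nearest
#' target vertex, minimizes the linearized point-to-plane error over the
#' kept (trimmed) correspondences, and accepts an update only if the
#' trimmed RMS decreases, so the reported RMS sequence is non-increasing.
#'
#' @param source,target [tri_mesh()]es (mm)
#' @param init initial [rigid_transform()] (source to target)
#' @param config an [icp_config()]
#' @return list of class `registration_result`: `transform`, `rms_mm`,
#'   `iterations`, `converged`, `rms_trace`
#' @export
icp_register <- function(source, target, init = rigid_identity(),
                         config = icp_config()) {
  if (nrow(source$vertices) == 0 || nrow(target$vertices) == 0)
    stop("icp_register: empty mesh")
  TV <- target$vertices
  TN <- mesh_vertex_normals(target)
  nv <- nrow(source$vertices)
  samp <- if (nv > config$n_samples) {
    with_local_seed(config$seed, sample.int(nv, config$n_samples))
  } else seq_len(nv)
  S <- source$vertices[samp, , drop = FALSE]

  trimmed_resid <- function(P) {
    idx <- nearest_vertex(P, TV)
    r <- rowSums((P - TV[idx, , drop = FALSE]) * TN[idx, , drop = FALSE])
    keep <- order(abs(r))[seq_len(max(6L, floor(length(r) * config$trim)))]
    list(idx = idx, r = r, keep = keep, rms = sqrt(mean(r[keep]^2)))
  }

  tr <- init
  P <- rt_apply(tr, S)
  st <- trimmed_resid(P)
  if (st$rms > config$max_init_rms)
    stop(sprintf("registration failure: initial RMS %.2f mm exceeds %.2f mm (surfaces do not overlap?)",
                 st$rms, config$max_init_rms))
  rms_trace <- st$rms
  converged <- FALSE
  iter <- 0L
  while (iter < config$max_iter) {
    if (st$rms < 1e-9) { converged <- TRUE; break }
    iter <- iter + 1L
    k <- st$keep
    Pk <- P[k, , drop = FALSE]
    Nk <- TN[st$idx[k], , drop = FALSE]
    b <- -st$r[k]
    # rows: [ (p x n) , n ] for the 6-dof twist (omega, tau)
    Cx <- cbind(Pk[, 2] * Nk[, 3] - Pk[, 3] * Nk[, 2],
                Pk[, 3] * Nk[, 1] - Pk[, 1] * Nk[, 3],
                Pk[, 1] * Nk[, 2] - Pk[, 2] * Nk[, 1])
    A <- cbind(Cx, Nk)
    x <- tryCatch(solve(crossprod(A), crossprod(A, b)),
                  error = function(e) NULL)
    if (is.null(x)) break
    w <- x[1:3]; tau <- x[4:6]
    ang <- vnorm(w)
    Rd <- if (ang < 1e-10) diag(3) else rotation_about_axis(w / ang, ang * 180 / pi)
    cand <- rt_compose(rigid_transform(Rd, tau), tr)
    Pc <- rt_apply(cand, S)
    stc <- trimmed_resid(Pc)
    if (stc$rms > st$rms) break        # no further improvement
    small_change <- (st$rms - stc$rms) < config$rel_tol * max(st$rms, 1e-12)
    tr <- cand; P <- Pc; st <- stc
    rms_trace <- c(rms_trace, st$rms)
    if (small_change) { converged <- TRUE; break }
  }
  structure(list(transform = tr, rms_mm = st$rms, iterations = iter,
                 converged = converged, rms_trace = rms_trace),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("ICP registration: RMS %.4g mm after %d iterations (%s)\n",
              x$rms_mm, x$iterations,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Signed per-vertex deviation of one surface from another
#'
#' For each vertex of `moved`, the point-to-plane distance to its nearest
#' vertex on `target`, signed by the target's outward vertex normal
#' (positive outside the target surface).
#'
#' @param moved,target [tri_mesh()]es
#' @return list of class `deviation_map`: `distances` (mm, per vertex of
#'   `moved`), and `summary` (percentiles and max |d|)
#' @export
deviation_map <- function(moved, target) {
  if (nrow(moved$vertices) == 0 || nrow(target$vertices) == 0)
    stop("deviation_map: empty mesh")
  TV <- target$vertices
  TN <- mesh_vertex_normals(target)
  idx <- nearest_vertex(moved$vertices, TV)
  d <- rowSums((moved$vertices - TV[idx, , drop = FALSE]) * TN[idx, , drop = FALSE])
  qs <- stats::quantile(d, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
  structure(list(distances = d,
                 summary = c(p05 = qs[1], p25 = qs[2], median = qs[3],
                             p75 = qs[4], p95 = qs[5],
                             max_abs = max(abs(d)), rms = sqrt(mean(d^2)))),
            class = "deviation_map")
}

#' Export a deviation map as a PLY mesh with a per-vertex scalar
#' @param map a [deviation_map()]
#' @param mesh the mesh the map was computed on
#' @param path output .ply path
#' @return `path`, invisibly
#' @export
write_deviation_ply <- function(map, mesh, path) {
  write_mesh(mesh, path, scalars = map$distances)
}

#' Superimpose an achieved-stage case onto the pretreatment case
#'
#' Registers the achieved bone surface to the pretreatment bone by
#' trimmed point-to-plane ICP and applies that single global rigid motion
#' to the bone, every tooth mesh, every tooth's landmarks and the named
#' landmark set. Designed-stage cases are returned unchanged (they share
#' the pretreatment coordinate space by construction of the virtual
#' setup) apart from having their co-registration flag set.
#'
#' @param pre pretreatment [maxillary_case()]
#' @param stage designed- or achieved-stage [maxillary_case()]
#' @param config an [icp_config()]
#' @return the stage case, co-registered (`registered = TRUE`), with the
#'   registration result attached as attribute `registration` for
#'   achieved stages
#' @export
superimpose_case <- function(pre, stage, config = icp_config()) {
  if (stage$stage == "designed") {
    stage$registered <- TRUE
    return(stage)
  }
  if (is.null(pre$bone) || is.null(stage$bone))
    stop("superimpose_case: both cases must carry a bone mesh")
  reg <- icp_register(stage$bone, pre$bone, config = config)
  out <- transform_case(stage, reg$transform)
  out$registered <- TRUE
  attr(out, "registration") <- reg
  out
}
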