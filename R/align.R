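# Rigid alignment of sampled to unsampled colony models by iterative
# closest point, so face segmentations correspond across the two
# reconstructions of the same colony.

#' Rigid transform
#'
#' A rotation (proper orthonormal 3 x 3 matrix) plus translation, applied as
#' `x -> R x + t`.
#'
#' @param rotation 3 x 3 rotation matrix with determinant +1.
#' @param translation length-3 numeric vector.
#' @return An object of class `coral_rigid`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (abs(det(rotation) - 1) > 1e-6 ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation must be orthonormal with determinant +1", call. = FALSE)
  structure(list(rotation = rotation, translation = translation),
            class = "coral_rigid")
}

#' @export
print.coral_rigid <- function(x, ...) {
  ang <- rotation_angle(x$rotation)
  cat(sprintf("<coral_rigid> rotation %.4f deg, translation (%.4g, %.4g, %.4g)\n",
              180 / pi * ang, x$translation[1L], x$translation[2L],
              x$translation[3L]))
  invisible(x)
}

#' Compose / invert / apply rigid transforms
#'
#' `compose_rigid(a, b)` returns the transform equivalent to applying `b`
#' first, then `a`. `invert_rigid` returns the inverse transform.
#' `apply_rigid` applies a transform to a point matrix or a mesh.
#'
#' @param a,b,tf [rigid_transform()] objects.
#' @return A `coral_rigid`, or the transformed points/mesh.
#' @export
compose_rigid <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' @rdname compose_rigid
#' @export
invert_rigid <- function(tf) {
  rt <- t(tf$rotation)
  rigid_transform(rt, -as.numeric(rt %*% tf$translation))
}

#' @rdname compose_rigid
#' @param x an `n x 3` point matrix or a [coral_mesh()].
#' @export
apply_rigid <- function(tf, x) {
  if (inherits(x, "coral_mesh"))
    return(transform_mesh(x, tf$rotation, tf$translation))
  sweep(as.matrix(x) %*% t(tf$rotation), 2L, tf$translation, "+")
}

#' Rotation angle of a rotation matrix
#' @param r 3 x 3 rotation matrix.
#' @return Angle in radians in `[0, pi]`.
#' @export
rotation_angle <- function(r) {
  acos(max(-1, min(1, (sum(diag(r)) - 1) / 2)))
}

#' Serialize a rigid transform as 12 row-major numbers
#'
#' The 3 x 4 matrix `[R | t]` flattened row-major, the interchange form used
#' in alignment logs.
#'
#' @param tf a [rigid_transform()].
#' @return `rigid_to_numbers`: numeric vector of length 12.
#' @export
rigid_to_numbers <- function(tf) {
  as.numeric(t(cbind(tf$rotation, tf$translation)))
}

#' @rdname rigid_to_numbers
#' @param x numeric vector of length 12.
#' @export
rigid_from_numbers <- function(x) {
  stopifnot(length(x) == 12L)
  m <- matrix(x, 3L, 4L, byrow = TRUE)
  rigid_transform(m[, 1:3], m[, 4L])
}

# Deterministic stride subsample of at most n_max rows.
stride_sample <- function(x, n_max) {
  n <- nrow(x)
  if (n <= n_max) return(x)
  x[seq(1L, n, by = ceiling(n / n_max)), , drop = FALSE]
}

# Closed-form orthogonal-Procrustes (Kabsch) fit mapping p onto q.
procrustes_fit <- function(p, q) {
  cp <- colMeans(p)
  cq <- colMeans(q)
  h <- crossprod(sweep(p, 2L, cp), sweep(q, 2L, cq))
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  r <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rigid_transform(r, cq - as.numeric(r %*% cp))
}

# Nearest fixed point for each moving point (brute force, vectorized over
# the fixed set); returns the matched fixed coordinates.
nearest_points <- function(moving, fixed) {
  f2 <- rowSums(fixed^2)
  idx <- integer(nrow(moving))
  # chunked to bound the distance-matrix size
  chunk <- max(1L, floor(4e6 / nrow(fixed)))
  for (s in seq(1L, nrow(moving), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(moving))
    m <- moving[s:e, , drop = FALSE]
    d2 <- outer(rowSums(m^2), f2, "+") - 2 * m %*% t(fixed)
    idx[s:e] <- max.col(-d2, ties.method = "first")
  }
  fixed[idx, , drop = FALSE]
}

# Principal-axes initialisation: centroid alignment plus the sign-resolved
# eigenvector rotation with the lowest starting RMS (deterministic).
init_principal_axes <- function(mp, fp) {
  cm <- colMeans(mp)
  cf <- colMeans(fp)
  em <- eigen(stats::cov(mp), symmetric = TRUE)$vectors
  ef <- eigen(stats::cov(fp), symmetric = TRUE)$vectors
  best <- NULL
  best_rms <- Inf
  for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
    s3 <- 1 / (s1 * s2 * det(ef) * det(em))   # force det(R) = +1
    r <- ef %*% diag(c(s1, s2, sign(s3))) %*% t(em)
    if (abs(det(r) - 1) > 1e-6) next
    tf <- rigid_transform(r, cf - as.numeric(r %*% cm))
    moved <- apply_rigid(tf, mp)
    rms <- sqrt(mean(rowSums((moved - nearest_points(moved, fp))^2)))
    if (rms < best_rms) {
      best_rms <- rms
      best <- tf
    }
  }
  best
}

#' Align one mesh onto another by iterative closest point
#'
#' Point-to-point ICP on deterministic stride subsamples of the vertex sets:
#' each iteration matches every (subsampled) moving vertex to its nearest
#' fixed vertex and solves the closed-form orthogonal-Procrustes update,
#' stopping when the RMS residual improves by less than `tol` or after
#' `max_iter` iterations. When no initial transform is supplied the meshes
#' are pre-aligned by centroid translation plus a principal-axes rotation.
#' Intended for the near-aligned unsampled/sampled model pairs of a single
#' colony, not for arbitrary pose recovery.
#'
#' @param moving,fixed [coral_mesh()] objects with at least 4 vertices each,
#'   in the same units.
#' @param init optional [rigid_transform()] starting estimate.
#' @param max_iter maximum ICP iterations.
#' @param tol RMS improvement (in mesh units) below which iteration stops.
#' @param n_sample ceiling on the number of subsampled points per mesh.
#' @param rms_ceiling RMS above which a result that hit `max_iter` is
#'   flagged as not converged.
#' @return A list with `transform` (mapping `moving` onto `fixed`), `rms`
#'   (final RMS residual), `rms_history`, `iterations` and `converged`.
#' @export
align_rigid <- function(moving, fixed, init = NULL, max_iter = 50L,
                        tol = 1e-7, n_sample = 1500L, rms_ceiling = Inf) {
  validate_mesh(moving)
  validate_mesh(fixed)
  if (n_vertices(moving) < 4L || n_vertices(fixed) < 4L)
    stop("both meshes need at least 4 vertices", call. = FALSE)
  if (moving$units != fixed$units)
    stop("meshes must be in the same units", call. = FALSE)
  mp <- stride_sample(moving$vertices, n_sample)
  fp <- stride_sample(fixed$vertices, 4L * n_sample)
  tf <- if (is.null(init)) init_principal_axes(mp, fp) else init
  rms_hist <- numeric(0)
  rms <- Inf
  iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    moved <- apply_rigid(tf, mp)
    target <- nearest_points(moved, fp)
    step <- procrustes_fit(moved, target)
    tf <- compose_rigid(step, tf)
    moved <- apply_rigid(tf, mp)
    new_rms <- sqrt(mean(rowSums((moved - nearest_points(moved, fp))^2)))
    rms_hist <- c(rms_hist, new_rms)
    if (is.finite(rms) && rms - new_rms < tol) {
      rms <- min(rms, new_rms)
      break
    }
    rms <- new_rms
  }
  converged <- !(iters == max_iter && rms > rms_ceiling)
  list(transform = tf, rms = rms, rms_history = rms_hist,
       iterations = iters, converged = converged)
}
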