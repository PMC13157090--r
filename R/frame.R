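#' PCA plane frame of a point set
#'
#' Principal component analysis of the ring cloud: the eigenvectors of the
#' covariance matrix, sorted by descending eigenvalue, define the axes of a
#' new coordinate system with origin at the centroid. For a (near-)planar
#' set the third axis `e3` — the smallest-eigenvalue eigenvector — is the
#' plane normal. The frame is forced right-handed by flipping `e3` when
#' needed; the sign of the normal is otherwise arbitrary and is
#' disambiguated later against the plant position (see
#' [build_metric_transform()]).
#'
#' @param points M x 3 matrix, M >= 3, not all collinear.
#' @return A `plane_frame` list: `origin` (centroid), orthonormal `e1`,
#'   `e2`, `e3` (descending eigenvalue order), and `eigenvalues`.
#' @export
pca_frame <- function(points) {
  points <- as_xyz_matrix(points, "points")
  m <- nrow(points)
  if (m < 3L) stop("need at least 3 points for a plane frame", call. = FALSE)
  origin <- colMeans(points)
  cc <- sweep(points, 2L, origin)
  ev <- eigen(crossprod(cc) / m, symmetric = TRUE)
  vals <- ev$values
  scale2 <- max(vals[1], 0)
  if (scale2 <= 0 || vals[2] <= 1e-12 * scale2) {
    stop(errorCondition(
      "degenerate geometry: points are (near-)collinear, no plane is defined",
      class = c("ringcal_degenerate", "ringcal_error")))
  }
  V <- ev$vectors
  if (det(V) < 0) V[, 3] <- -V[, 3]
  structure(list(origin = origin, e1 = V[, 1], e2 = V[, 2], e3 = V[, 3],
                 eigenvalues = vals),
            class = "plane_frame")
}

#' @export
print.plane_frame <- function(x, ...) {
  cat(sprintf("<plane_frame> origin (%.5g, %.5g, %.5g), normal (%.4f, %.4f, %.4f)\n",
              x$origin[1], x$origin[2], x$origin[3],
              x$e3[1], x$e3[2], x$e3[3]))
  invisible(x)
}

#' Rodrigues rotation aligning one unit vector with another
#'
#' Closed-form rotation `R = I + sin(theta) K + (1 - cos(theta)) K^2`,
#' where `K` is the skew-symmetric matrix of the unit axis
#' `k = (z_old x z_target) / ||z_old x z_target||` and
#' `theta = acos(z_old . z_target)`. Satisfies `R %*% z_old == z_target`
#' to 1e-10 and `R` is in SO(3).
#'
#' Degenerate cases: parallel inputs (`theta < 1e-9`) return the identity
#' exactly; antiparallel inputs (cross product vanishes, the formula is
#' undefined) return a 180-degree rotation about a deterministic axis
#' orthogonal to `z_old` (the larger of `z_old x (1,0,0)` and
#' `z_old x (0,1,0)`, normalized).
#'
#' @param z_old,z_target unit 3-vectors (norm within 1e-6 of 1).
#' @return 3 x 3 rotation matrix.
#' @export
rodrigues_rotation <- function(z_old, z_target) {
  z_old <- as.numeric(z_old); z_target <- as.numeric(z_target)
  if (length(z_old) != 3L || length(z_target) != 3L) {
    stop("inputs must be 3-vectors", call. = FALSE)
  }
  if (abs(sqrt(sum(z_old^2)) - 1) > 1e-6 ||
      abs(sqrt(sum(z_target^2)) - 1) > 1e-6) {
    stop("inputs must be unit vectors (within 1e-6)", call. = FALSE)
  }
  d <- sum(z_old * z_target)
  d <- min(1, max(-1, d))
  theta <- acos(d)
  if (theta < 1e-9) return(diag(3))
  k <- cross3(z_old, z_target)
  nk <- sqrt(sum(k^2))
  if (nk < 1e-12) {
    # antiparallel: 180 degrees about any axis orthogonal to z_old
    a1 <- cross3(z_old, c(1, 0, 0))
    a2 <- cross3(z_old, c(0, 1, 0))
    k <- if (sum(a1^2) >= sum(a2^2)) a1 else a2
    k <- k / sqrt(sum(k^2))
    theta <- pi
  } else {
    k <- k / nk
  }
  K <- matrix(c(0, k[3], -k[2],
                -k[3], 0, k[1],
                k[2], -k[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Project points onto a plane frame
#'
#' Row `i` of the result is `((p_i - origin) . e1, (p_i - origin) . e2)`:
#' in-plane coordinates in the frame's basis. For points lying on the
#' plane this is an isometry.
#'
#' @param points M x 3 matrix.
#' @param frame a [pca_frame()] result.
#' @return M x 2 matrix of plane coordinates.
#' @export
project_to_plane <- function(points, frame) {
  stopifnot(inherits(frame, "plane_frame"))
  points <- as_xyz_matrix(points, "points")
  cc <- sweep(points, 2L, frame$origin)
  cbind(cc %*% frame$e1, cc %*% frame$e2)
}
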