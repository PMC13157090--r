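#' Colored point cloud
#'
#' The central container of the package: `N` points with 3D coordinates and
#' per-point RGB colors. Coordinates are either in the arbitrary units of a
#' photogrammetric reconstruction (`units = "reconstruction"`) or in
#' millimeters after metric calibration (`units = "mm"`). Colors are stored
#' as doubles in `[0, 1]` regardless of the precision of the source file.
#'
#' Rows containing non-finite coordinates are dropped (with a message giving
#' the count): multi-view-stereo outputs routinely contain a few such points.
#'
#' @param points numeric matrix, N x 3 (x, y, z).
#' @param colors numeric matrix, N x 3 (r, g, b) in `[0, 1]`, or `NULL` to
#'   fill with mid-gray (0.5, 0.5, 0.5).
#' @param units `"reconstruction"` or `"mm"`.
#' @return An object of class `colored_point_cloud`: a list with elements
#'   `points` (N x 3), `colors` (N x 3) and `units`.
#' @examples
#' pc <- colored_point_cloud(matrix(rnorm(30), 10, 3))
#' n_points(pc)
#' @export
colored_point_cloud <- function(points, colors = NULL,
                                units = c("reconstruction", "mm")) {
  units <- match.arg(units)
  points <- as_xyz_matrix(points, "points")
  n <- nrow(points)
  if (is.null(colors)) {
    colors <- matrix(0.5, n, 3)
  } else {
    colors <- as_xyz_matrix(colors, "colors")
    if (nrow(colors) != n) {
      stop("`points` and `colors` must have the same number of rows",
           call. = FALSE)
    }
    if (n > 0L) {
      if (anyNA(colors)) stop("`colors` must not contain NA", call. = FALSE)
      if (max(colors) > 1 + 1e-9 || min(colors) < -1e-9) {
        stop("`colors` must lie in [0, 1] (divide 8-bit values by 255)",
             call. = FALSE)
      }
      colors[colors < 0] <- 0
      colors[colors > 1] <- 1
    }
  }
  keep <- if (n > 0L) is.finite(points[, 1]) & is.finite(points[, 2]) &
    is.finite(points[, 3]) else logical(0)
  n_bad <- sum(!keep)
  if (n_bad > 0L) {
    message("dropping ", n_bad, " point(s) with non-finite coordinates")
    points <- points[keep, , drop = FALSE]
    colors <- colors[keep, , drop = FALSE]
  }
  structure(list(points = points, colors = colors, units = units),
            class = "colored_point_cloud")
}

as_xyz_matrix <- function(x, what) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.vector(x) && length(x) == 3L) x <- matrix(x, 1L, 3L)
  if (length(x) == 0L) x <- matrix(numeric(0), 0L, 3L)
  if (!is.matrix(x) || ncol(x) != 3L || !is.numeric(x)) {
    stop("`", what, "` must be an N x 3 numeric matrix", call. = FALSE)
  }
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  x
}

#' @rdname colored_point_cloud
#' @param x a `colored_point_cloud`.
#' @export
n_points <- function(x) {
  stopifnot(inherits(x, "colored_point_cloud"))
  nrow(x$points)
}

#' Subset a colored point cloud by point index
#'
#' Keeps the relative input order of the surviving points and the `units`
#' tag.
#'
#' @param cloud a `colored_point_cloud`.
#' @param idx integer or logical index into the points.
#' @return A `colored_point_cloud` with the selected points.
#' @export
subset_cloud <- function(cloud, idx) {
  stopifnot(inherits(cloud, "colored_point_cloud"))
  structure(list(points = cloud$points[idx, , drop = FALSE],
                 colors = cloud$colors[idx, , drop = FALSE],
                 units = cloud$units),
            class = "colored_point_cloud")
}

#' @export
print.colored_point_cloud <- function(x, ...) {
  cat("<colored_point_cloud> ", nrow(x$points), " points, units = ",
      x$units, "\n", sep = "")
  if (nrow(x$points) > 0L) {
    rng <- apply(x$points, 2L, range)
    cat(sprintf("  x: [%.4g, %.4g]  y: [%.4g, %.4g]  z: [%.4g, %.4g]\n",
                rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2],
                rng[1, 3], rng[2, 3]))
  }
  invisible(x)
}

#' Merge point clouds
#'
#' @param ... `colored_point_cloud` objects with identical `units`.
#' @return A single concatenated cloud.
#' @export
merge_clouds <- function(...) {
  clouds <- list(...)
  stopifnot(length(clouds) > 0L,
            all(vapply(clouds, inherits, TRUE, "colored_point_cloud")))
  units <- unique(vapply(clouds, function(c) c$units, ""))
  if (length(units) != 1L) stop("clouds have mixed units", call. = FALSE)
  structure(list(points = do.call(rbind, lapply(clouds, `[[`, "points")),
                 colors = do.call(rbind, lapply(clouds, `[[`, "colors")),
                 units = units),
            class = "colored_point_cloud")
}

#' Remove statistical outliers from a point cloud
#'
#' Classic mean-k-nearest-neighbor-distance filter: for every point the mean
#' distance to its `k` nearest neighbors is computed; points whose mean
#' distance exceeds `mean + sigma_mult * sd` of the population are removed.
#' Intended to strip the sparse floaters that multi-view stereo leaves
#' around the true surfaces before the ring is fitted.
#'
#' Distances are computed by chunked brute force, adequate for the
#' tens-of-thousands-of-points clouds the pipeline targets.
#'
#' @param cloud a `colored_point_cloud` with more than `k` points.
#' @param k neighbor count (default 8).
#' @param sigma_mult threshold in population standard deviations (default 2).
#' @return The filtered cloud; surviving points keep their input order.
#' @export
remove_statistical_outliers <- function(cloud, k = 8L, sigma_mult = 2) {
  stopifnot(inherits(cloud, "colored_point_cloud"))
  n <- n_points(cloud)
  if (n <= k) {
    stop("cloud has ", n, " points; need more than k = ", k, call. = FALSE)
  }
  d <- knn_mean_distances(cloud$points, k)
  thr <- mean(d) + sigma_mult * stats::sd(d)
  subset_cloud(cloud, d <= thr)
}

# Mean distance to the k nearest neighbors of every row of an N x 3 matrix.
# Chunked O(N^2) with bounded memory.
knn_mean_distances <- function(pts, k) {
  n <- nrow(pts)
  k <- as.integer(k)
  stopifnot(k >= 1L, n > k)
  out <- numeric(n)
  chunk <- max(1L, floor(2e6 / n))
  sq <- rowSums(pts^2)
  i <- 1L
  while (i <= n) {
    j <- min(n, i + chunk - 1L)
    block <- pts[i:j, , drop = FALSE]
    d2 <- outer(rowSums(block^2), sq, "+") - 2 * tcrossprod(block, pts)
    d2[d2 < 0] <- 0
    for (r in seq_len(j - i + 1L)) {
      v <- d2[r, ]
      v[i + r - 1L] <- Inf  # exclude self
      out[i + r - 1L] <- mean(sqrt(sort(v, partial = k)[seq_len(k)]))
    }
    i <- j + 1L
  }
  out
}

# Median nearest-neighbor distance of a point set (k = 1 case).
median_nn_distance <- function(pts) {
  if (nrow(pts) < 2L) return(NA_real_)
  stats::median(knn_mean_distances(pts, 1L))
}
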