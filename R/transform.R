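#' Scale factor from the fitted ring diameter
#'
#' The reconstruction is metrically ambiguous; the ring's known physical
#' diameter pins it down: `s = d_true / d_fitted` converts reconstruction
#' units into millimeters.
#'
#' @param d_fitted fitted ring diameter in reconstruction units (> 0).
#' @param d_true true printed diameter in millimeters (> 0); the default
#'   ring is 200 mm.
#' @return The scale factor `s > 0`.
#' @export
scale_factor <- function(d_fitted, d_true = 200) {
  if (!is.finite(d_fitted) || d_fitted <= 0) {
    stop("d_fitted must be positive", call. = FALSE)
  }
  if (!is.finite(d_true) || d_true <= 0) {
    stop("d_true must be positive", call. = FALSE)
  }
  d_true / d_fitted
}

#' Assemble the metric transform from a fitted ring
#'
#' Combines the three calibration ingredients into a single similarity
#' transform from reconstruction coordinates to a metric, upright world
#' frame:
#' * rotation — the ring-plane normal `e3` is sign-corrected so that the
#'   plant centroid lies on its positive side (plants grow above the ring
#'   plane), then rotated onto world `+z` by [rodrigues_rotation()];
#' * scale — `s = d_true / d_fitted` from the fitted circle;
#' * translation — the fitted circle center is placed at the world origin,
#'   so the ring plane becomes `z = 0` and heights are measured from the
#'   ground plane. Disable with `translate = FALSE` (then `t = 0`).
#'
#' The stored rotation follows the convention that its **transpose** maps
#' reconstruction coordinates to world coordinates (`p' = R^T p`, then
#' `p'' = s p'`, then `+ t`), i.e. `R` itself maps world to reconstruction;
#' see [apply_transform()].
#'
#' @param ring_frame [pca_frame()] of the ring cloud.
#' @param circle `circle_fit` of the projected ring (in `ring_frame`'s
#'   plane coordinates).
#' @param plant_cloud non-empty [colored_point_cloud] used only to pick the
#'   upward normal sign.
#' @param d_true true ring diameter, mm (default 200).
#' @param translate place the ring center at the origin (default `TRUE`).
#' @return A `metric_transform` list: `R` (3 x 3, SO(3)), `s` (> 0), `t`
#'   (3-vector, mm), plus `d_true_mm`, `d_fitted`, `rms_residual`.
#' @export
build_metric_transform <- function(ring_frame, circle, plant_cloud,
                                   d_true = 200, translate = TRUE) {
  stopifnot(inherits(ring_frame, "plane_frame"),
            inherits(circle, "circle_fit"),
            inherits(plant_cloud, "colored_point_cloud"))
  if (n_points(plant_cloud) == 0L) {
    stop("plant cloud is empty", call. = FALSE)
  }
  z_old <- ring_frame$e3
  plant_ctr <- colMeans(plant_cloud$points)
  side <- sum((plant_ctr - ring_frame$origin) * z_old)
  ring_scale <- max(abs(circle$radius), 1)
  if (abs(side) < 1e-9 * ring_scale) {
    stop(errorCondition(
      "ambiguous orientation: plant centroid lies on the ring plane",
      class = c("ringcal_degenerate", "ringcal_error")))
  }
  if (side < 0) z_old <- -z_old
  R_align <- rodrigues_rotation(z_old, c(0, 0, 1))
  s <- scale_factor(circle$d_fitted, d_true)
  center3d <- ring_frame$origin +
    circle$center2d[1] * ring_frame$e1 + circle$center2d[2] * ring_frame$e2
  t <- if (translate) -s * as.numeric(R_align %*% center3d) else c(0, 0, 0)
  new_metric_transform(t(R_align), s, t, d_true = d_true,
                       d_fitted = circle$d_fitted,
                       rms_residual = circle$rms_residual)
}

new_metric_transform <- function(R, s, t, d_true = NA_real_,
                                 d_fitted = NA_real_,
                                 rms_residual = NA_real_) {
  R <- matrix(as.numeric(R), 3, 3)
  orth <- max(abs(crossprod(R) - diag(3)))
  if (orth > 1e-8 || abs(det(R) - 1) > 1e-8) {
    stop("R is not a rotation matrix", call. = FALSE)
  }
  if (!is.finite(s) || s <= 0) stop("s must be positive", call. = FALSE)
  structure(list(R = R, s = as.numeric(s), t = as.numeric(t),
                 d_true_mm = d_true, d_fitted = d_fitted,
                 rms_residual = rms_residual),
            class = "metric_transform")
}

#' @export
print.metric_transform <- function(x, ...) {
  cat(sprintf("<metric_transform> s = %.8g, t = (%.5g, %.5g, %.5g)\n",
              x$s, x$t[1], x$t[2], x$t[3]))
  if (is.finite(x$d_fitted)) {
    cat(sprintf("  d_fitted = %.8g -> d_true = %g mm (rms %.3g)\n",
                x$d_fitted, x$d_true_mm, x$rms_residual))
  }
  invisible(x)
}

#' Apply a metric transform to a point cloud
#'
#' Maps every point by `p_world = s * (R^T p) + t` — reorientation by the
#' transposed rotation, then isotropic rescaling to millimeters, then the
#' translation that puts the ring center at the origin. Colors are
#' untouched; the output carries `units = "mm"`. Applying a transform to a
#' cloud already in mm is a usage error (double application).
#'
#' @param cloud a [colored_point_cloud] with `units = "reconstruction"`.
#' @param transform a `metric_transform`.
#' @return The transformed cloud, `units = "mm"`.
#' @export
apply_transform <- function(cloud, transform) {
  stopifnot(inherits(cloud, "colored_point_cloud"),
            inherits(transform, "metric_transform"))
  if (cloud$units == "mm") {
    stop("cloud is already metric (units = \"mm\"); refusing double application",
         call. = FALSE)
  }
  pts <- transform$s * (cloud$points %*% transform$R)  # (R^T p)^T = p^T R
  pts <- sweep(pts, 2L, transform$t, "+")
  structure(list(points = pts, colors = cloud$colors, units = "mm"),
            class = "colored_point_cloud")
}

#' Serialize / deserialize a metric transform as JSON
#'
#' The JSON object stores `R` row-major, `s`, `t`, `d_true_mm`, `d_fitted`
#' and `rms_residual` at full double precision, so a write/read round trip
#' is bit-exact.
#'
#' @param transform a `metric_transform`.
#' @param path JSON file path.
#' @return `write_transform`: `path` invisibly. `read_transform`: the
#'   `metric_transform`.
#' @export
write_transform <- function(transform, path) {
  stopifnot(inherits(transform, "metric_transform"))
  obj <- list(R = as.vector(t(transform$R)),
              s = transform$s,
              t = transform$t,
              d_true_mm = transform$d_true_mm,
              d_fitted = transform$d_fitted,
              rms_residual = transform$rms_residual)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("R", "s", "t")
  miss <- setdiff(need, names(obj))
  if (length(miss)) {
    stop("transform JSON is missing field(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (length(obj$R) != 9L || length(obj$t) != 3L || length(obj$s) != 1L) {
    stop("transform JSON has malformed fields", call. = FALSE)
  }
  new_metric_transform(matrix(obj$R, 3, 3, byrow = TRUE), obj$s, obj$t,
                       d_true = obj$d_true_mm %||% NA_real_,
                       d_fitted = obj$d_fitted %||% NA_real_,
                       rms_residual = obj$rms_residual %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
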