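#' @title Canopy trait extraction
#' @description Trait extractors for a metric (`units = "mm"`), upright
#'   plant cloud — the ring plane is `z = 0` and `+z` points up. Three
#'   groups are covered: spatial dimensions (height, canopy width,
#'   vertical distribution), area features (surface area, convex and
#'   concave projected areas) and morphological envelopes (compactness,
#'   spatial occupancy).
#' @name phenotypes
NULL

check_metric <- function(cloud, n_min = 1L) {
  stopifnot(inherits(cloud, "colored_point_cloud"))
  if (cloud$units != "mm") {
    stop("cloud must be metric (units = \"mm\"); run the calibration first",
         call. = FALSE)
  }
  if (n_points(cloud) < n_min) {
    stop("cloud has ", n_points(cloud), " points; need at least ", n_min,
         call. = FALSE)
  }
  invisible(cloud)
}

#' Plant height from z-percentiles
#'
#' `quantile(z, hi_pct) - quantile(z, lo_pct)`. The default 99.9/0.1
#' percentile pair discards the isolated floaters multi-view stereo leaves
#' above the canopy while keeping the span bias negligible (a wider trim
#' such as 0.5/99.5 shaves a full 1% off a uniformly filled canopy);
#' pass 100/0 for the raw bounding-box height.
#'
#' @param cloud metric upright cloud, N >= 2.
#' @param lo_pct,hi_pct percentiles in `[0, 100]` (defaults 0.1 and 99.9).
#' @return Height in mm.
#' @export
plant_height <- function(cloud, lo_pct = 0.1, hi_pct = 99.9) {
  check_metric(cloud, 2L)
  stopifnot(lo_pct >= 0, hi_pct <= 100, lo_pct <= hi_pct)
  q <- stats::quantile(cloud$points[, 3], c(lo_pct, hi_pct) / 100,
                       names = FALSE)
  q[2] - q[1]
}

#' Canopy width: diameter of the projected convex hull
#'
#' Maximum pairwise distance among the vertices of the convex hull of the
#' xy projection (the hull makes the pairwise search exact and cheap).
#'
#' @param cloud metric upright cloud, N >= 2.
#' @return Width in mm; 0 if all points project to one xy location.
#' @export
canopy_width <- function(cloud) {
  check_metric(cloud, 2L)
  xy <- unique(cloud$points[, 1:2, drop = FALSE])
  if (nrow(xy) < 2L) return(0)
  h <- if (nrow(xy) > 2L) grDevices::chull(xy) else seq_len(nrow(xy))
  v <- xy[h, , drop = FALSE]
  d2 <- outer(rowSums(v^2), rowSums(v^2), "+") - 2 * tcrossprod(v)
  sqrt(max(d2, 0))
}

#' Vertical distribution of canopy points
#'
#' Histogram of z from the ring plane (`z = 0`) to the top of the plant,
#' normalized to fractions. Points below the ring plane (e.g. substrate
#' noise) land in the first bin.
#'
#' @param cloud metric upright cloud, N >= 1.
#' @param n_bins number of bins (default 20).
#' @return A list with `bin_edges` (length `n_bins + 1`, mm) and
#'   `fraction` (length `n_bins`, sums to 1).
#' @export
vertical_distribution <- function(cloud, n_bins = 20L) {
  check_metric(cloud, 1L)
  stopifnot(n_bins >= 1L)
  z <- cloud$points[, 3]
  top <- max(z, 0)
  if (top <= 0) top <- max(abs(z), 1e-9)
  edges <- seq(0, top, length.out = n_bins + 1L)
  idx <- findInterval(z, edges, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  idx[idx > n_bins] <- n_bins
  counts <- tabulate(idx, nbins = n_bins)
  list(bin_edges = edges, fraction = counts / length(z))
}

#' Canopy projection area (convex)
#'
#' Area of the convex hull of the xy projection (shoelace formula on the
#' hull polygon).
#'
#' @param cloud metric upright cloud, N >= 3 non-collinear in xy.
#' @return Area in mm^2; 0 (with a warning) for xy-collinear clouds.
#' @export
canopy_projection_area <- function(cloud) {
  check_metric(cloud, 3L)
  xy <- unique(cloud$points[, 1:2, drop = FALSE])
  if (nrow(xy) < 3L) {
    warning("xy projection is degenerate; area = 0", call. = FALSE)
    return(0)
  }
  h <- grDevices::chull(xy)
  v <- xy[h, , drop = FALSE]
  a <- polygon_area(v)
  if (a <= 0) warning("xy projection is collinear; area = 0", call. = FALSE)
  a
}

polygon_area <- function(v) {
  n <- nrow(v)
  if (n < 3L) return(0)
  j <- c(2:n, 1L)
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
}

#' Main projection area (concave, occupancy grid)
#'
#' Occupancy-grid area of the xy projection: the count of
#' `grid_res x grid_res` cells containing at least one point, times the
#' cell area. Unlike the convex [canopy_projection_area()], holes and
#' concavities in the canopy silhouette are excluded, which is the reading
#' this package adopts for the "main" projected area; both variants are
#' reported so either convention is available.
#'
#' @param cloud metric upright cloud, N >= 1.
#' @param grid_res cell edge, mm (default 2).
#' @return Area in mm^2.
#' @export
main_projection_area <- function(cloud, grid_res = 2) {
  check_metric(cloud, 1L)
  stopifnot(grid_res > 0)
  xy <- cloud$points[, 1:2, drop = FALSE]
  cells <- paste0(floor(xy[, 1] / grid_res), "_", floor(xy[, 2] / grid_res))
  length(unique(cells)) * grid_res^2
}

#' Total surface area from local triangulation
#'
#' Estimates the surface area of the cloud (for a plant: leaves plus stem)
#' by meshing local neighborhoods: the cloud is partitioned into cubic
#' patches sized relative to the point spacing, each patch (plus a margin
#' of neighboring points so the mesh has no seams) is projected onto its
#' PCA plane and Delaunay-triangulated, long-edged sliver triangles are
#' pruned, and each triangle is kept exactly once (assigned to the patch
#' containing its centroid, with duplicate vertex-triples deduplicated).
#' Triangle areas are summed in 3D.
#'
#' All length thresholds are multiples of the measured median
#' nearest-neighbor spacing, so the estimator is scale-equivariant. The
#' contract, exercised in the tests: a densely sampled planar disk of
#' radius `r` recovers `pi r^2` within 5%.
#'
#' @param cloud metric cloud with at least ~50 points.
#' @param patch_factor patch cube edge in units of point spacing (default 15).
#' @param margin_factor patch overlap margin in spacings (default 6).
#' @param edge_factor prune triangles with an edge longer than this many
#'   spacings (default 8; Delaunay edges of uniform surface sampling run
#'   2-4 spacings, so the threshold removes only slivers that bridge
#'   gaps, holes or separate surfaces).
#' @return Area in mm^2.
#' @export
total_leaf_area <- function(cloud, patch_factor = 15, margin_factor = 6,
                            edge_factor = 8) {
  check_metric(cloud, 1L)
  pts <- unique(cloud$points)
  n <- nrow(pts)
  if (n < 50L) {
    stop("cloud too sparse to mesh: ", n,
         " distinct points (need at least 50)", call. = FALSE)
  }
  sub <- if (n > 5000L) {
    pts[sort(with_preserved_rng(n, sample.int(n, 5000L))), , drop = FALSE]
  } else pts
  spacing <- median_nn_distance(sub)
  if (n > 5000L) spacing <- spacing * sqrt(5000 / n)  # subsample density correction
  if (!is.finite(spacing) || spacing <= 0) {
    stop("cannot estimate point spacing", call. = FALSE)
  }
  h <- patch_factor * spacing
  margin <- margin_factor * spacing
  max_edge2 <- (edge_factor * spacing)^2
  cell <- floor(pts / h)
  key <- paste0(cell[, 1], "_", cell[, 2], "_", cell[, 3])
  cell_of <- split(seq_len(n), key)
  # index points by cell for margin lookup
  lookup <- new.env(parent = emptyenv())
  for (k in names(cell_of)) lookup[[k]] <- cell_of[[k]]
  area <- 0
  seen <- new.env(parent = emptyenv())
  for (k in names(cell_of)) {
    core <- cell_of[[k]]
    c0 <- cell[core[1], ]
    lo <- c0 * h; hi <- lo + h
    cand <- integer(0)
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      kk <- paste0(c0[1] + dx, "_", c0[2] + dy, "_", c0[3] + dz)
      v <- lookup[[kk]]
      if (!is.null(v)) cand <- c(cand, v)
    }
    p <- pts[cand, , drop = FALSE]
    inbox <- p[, 1] >= lo[1] - margin & p[, 1] <= hi[1] + margin &
      p[, 2] >= lo[2] - margin & p[, 2] <= hi[2] + margin &
      p[, 3] >= lo[3] - margin & p[, 3] <= hi[3] + margin
    patch_idx <- cand[inbox]
    if (length(patch_idx) < 3L) next
    p <- pts[patch_idx, , drop = FALSE]
    ctr <- colMeans(p)
    cc <- sweep(p, 2L, ctr)
    ev <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)
    if (ev$values[2] <= 1e-10 * max(ev$values[1], 1e-300)) next  # line-like
    p2 <- cc %*% ev$vectors[, 1:2]
    tri <- delaunay2d(p2)
    if (nrow(tri) == 0L) next
    for (r in seq_len(nrow(tri))) {
      f <- patch_idx[tri[r, ]]
      a <- pts[f[1], ]; b <- pts[f[2], ]; d <- pts[f[3], ]
      if (sum((a - b)^2) > max_edge2 || sum((b - d)^2) > max_edge2 ||
          sum((a - d)^2) > max_edge2) next
      cen <- (a + b + d) / 3
      if (any(cen < lo) || any(cen >= hi)) next  # not this patch's triangle
      fk <- paste(sort(f), collapse = "_")
      if (!is.null(seen[[fk]])) next
      seen[[fk]] <- TRUE
      area <- area + sqrt(sum(cross3(b - a, d - a)^2)) / 2
    }
  }
  area
}

#' Plant compactness
#'
#' Ratio of the occupied-voxel volume to the 3D convex-hull volume of the
#' cloud — near 1 for a solid, space-filling habit, small for sparse,
#' open architectures. Clipped to `[0, 1]` (voxel discretization can
#' nudge the raw ratio above 1).
#'
#' @param cloud metric cloud, N >= 4 non-coplanar.
#' @param voxel voxel edge, mm (default 5).
#' @return Dimensionless value in `[0, 1]`.
#' @export
compactness <- function(cloud, voxel = 5) {
  check_metric(cloud, 4L)
  stopifnot(voxel > 0)
  occ <- occupied_voxels(cloud$points, voxel)
  vol_vox <- occ * voxel^3
  vol_hull <- convex_hull_volume(cloud$points)
  min(1, vol_vox / vol_hull)
}

#' Spatial occupancy
#'
#' Fraction of the axis-aligned bounding-box voxel grid that contains at
#' least one point.
#'
#' @param cloud metric cloud, N >= 1.
#' @param voxel voxel edge, mm (default 5).
#' @return Dimensionless value in `(0, 1]`.
#' @export
spatial_occupancy <- function(cloud, voxel = 5) {
  check_metric(cloud, 1L)
  stopifnot(voxel > 0)
  pts <- cloud$points
  ext <- apply(pts, 2L, function(v) diff(range(v)))
  n_cells <- pmax(1, ceiling(ext / voxel - 1e-9))
  occ <- occupied_voxels(pts, voxel)
  min(1, occ / prod(n_cells))
}

occupied_voxels <- function(pts, voxel) {
  idx <- floor(sweep(pts, 2L, apply(pts, 2L, min)) / voxel)
  length(unique(paste0(idx[, 1], "_", idx[, 2], "_", idx[, 3])))
}

#' Extract the full phenotype report
#'
#' Runs every trait extractor on a metric upright cloud; per-trait failures
#' are recorded as `NULL` values with their error messages instead of
#' aborting the report. All resolutions and percentiles used are echoed in
#' `$parameters` for reproducibility.
#'
#' @param cloud metric upright [colored_point_cloud].
#' @param config a [pipeline_config()] (its `traits` block supplies
#'   percentiles, bin count, grid and voxel resolutions).
#' @return A `phenotype_report` list: trait values (`NULL` where a trait
#'   failed), `errors` (named messages), `parameters`.
#' @export
extract_report <- function(cloud, config = pipeline_config()) {
  stopifnot(inherits(cloud, "colored_point_cloud"))
  tp <- config$traits
  params <- list(height_lo_pct = tp$height_lo_pct,
                 height_hi_pct = tp$height_hi_pct,
                 n_bins = tp$n_bins, grid_res_mm = tp$grid_res_mm,
                 voxel_mm = tp$voxel_mm)
  traits <- list(
    plant_height = function() plant_height(cloud, tp$height_lo_pct,
                                           tp$height_hi_pct),
    canopy_width = function() canopy_width(cloud),
    vertical_distribution = function() vertical_distribution(cloud, tp$n_bins),
    total_leaf_area = function() total_leaf_area(cloud),
    canopy_projection_area = function() canopy_projection_area(cloud),
    main_projection_area = function() main_projection_area(cloud,
                                                           tp$grid_res_mm),
    compactness = function() compactness(cloud, tp$voxel_mm),
    spatial_occupancy = function() spatial_occupancy(cloud, tp$voxel_mm))
  out <- list()
  errors <- list()
  for (nm in names(traits)) {
    res <- tryCatch(list(value = traits[[nm]]()),
                    error = function(e) list(error = conditionMessage(e)))
    if (is.null(res$error)) out[[nm]] <- res$value
    else { out[nm] <- list(NULL); errors[[nm]] <- res$error }
  }
  structure(c(out, list(errors = errors, parameters = params)),
            class = "phenotype_report")
}

#' @export
print.phenotype_report <- function(x, ...) {
  cat("<phenotype_report>\n")
  fmt <- function(v, unit) if (is.null(v)) "failed" else
    sprintf("%.4g %s", v, unit)
  cat("  plant height:           ", fmt(x$plant_height, "mm"), "\n")
  cat("  canopy width:           ", fmt(x$canopy_width, "mm"), "\n")
  cat("  total leaf area:        ", fmt(x$total_leaf_area, "mm^2"), "\n")
  cat("  canopy projection area: ", fmt(x$canopy_projection_area, "mm^2"), "\n")
  cat("  main projection area:   ", fmt(x$main_projection_area, "mm^2"), "\n")
  cat("  compactness:            ", fmt(x$compactness, ""), "\n")
  cat("  spatial occupancy:      ", fmt(x$spatial_occupancy, ""), "\n")
  if (length(x$errors)) {
    cat("  failed traits:", paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Serialize a phenotype report
#'
#' Writes the report as JSON (full detail, including the vertical
#' distribution and the parameter record), plus optionally a one-row CSV
#' of the scalar traits and a two-column CSV of the vertical distribution.
#'
#' @param report a `phenotype_report`.
#' @param json_path output JSON path.
#' @param csv_path optional one-row CSV path for the scalar traits.
#' @param dist_csv_path optional CSV path for the vertical distribution
#'   (columns `z_mid_mm`, `fraction`).
#' @return `json_path`, invisibly.
#' @export
write_report <- function(report, json_path, csv_path = NULL,
                         dist_csv_path = NULL) {
  stopifnot(inherits(report, "phenotype_report"))
  jsonlite::write_json(unclass(report), json_path, digits = NA,
                       auto_unbox = TRUE, null = "null")
  scalars <- c("plant_height", "canopy_width", "total_leaf_area",
               "canopy_projection_area", "main_projection_area",
               "compactness", "spatial_occupancy")
  if (!is.null(csv_path)) {
    row <- lapply(report[scalars], function(v) if (is.null(v)) NA_real_ else v)
    utils::write.csv(as.data.frame(row), csv_path, row.names = FALSE)
  }
  if (!is.null(dist_csv_path) && !is.null(report$vertical_distribution)) {
    vd <- report$vertical_distribution
    mid <- (vd$bin_edges[-1] + vd$bin_edges[-length(vd$bin_edges)]) / 2
    utils::write.csv(data.frame(z_mid_mm = mid, fraction = vd$fraction),
                     dist_csv_path, row.names = FALSE)
  }
  invisible(json_path)
}
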