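#' Convert RGB colors to HSV with hue in degrees
#'
#' Thin wrapper around [grDevices::rgb2hsv()] that returns hue in degrees
#' `[0, 360)` — the convention used by the segmentation thresholds. Gray
#' points (zero chroma) get hue 0 and saturation 0.
#'
#' @param colors N x 3 matrix of RGB values in `[0, 1]`.
#' @return N x 3 matrix with columns `h` (degrees), `s`, `v`.
#' @export
rgb_to_hsv <- function(colors) {
  colors <- as_xyz_matrix(colors, "colors")
  if (nrow(colors) == 0L) {
    return(matrix(numeric(0), 0L, 3L, dimnames = list(NULL, c("h", "s", "v"))))
  }
  hsv <- t(grDevices::rgb2hsv(t(colors), maxColorValue = 1))
  hsv[, 1] <- (hsv[, 1] * 360) %% 360
  colnames(hsv) <- c("h", "s", "v")
  hsv
}

#' Color thresholds for ring segmentation
#'
#' Red wraps around the hue circle, so the selection is the union of two hue
#' intervals. Defaults select saturated, reasonably bright red —
#' `[0, 20) U [340, 360)` degrees, saturation >= 0.4, value >= 0.2 — and are
#' deliberately config-exposed: print pigments and illumination shift the
#' observed hue/value in the field.
#'
#' @param hue_low_1,hue_high_1 first hue interval, degrees in `[0, 360)`.
#' @param hue_low_2,hue_high_2 second hue interval, degrees in `[0, 360)`.
#' @param sat_min minimum saturation in `[0, 1]`.
#' @param val_min minimum value (brightness) in `[0, 1]`.
#' @return A `color_thresholds` list.
#' @export
color_thresholds <- function(hue_low_1 = 0, hue_high_1 = 20,
                             hue_low_2 = 340, hue_high_2 = 360,
                             sat_min = 0.4, val_min = 0.2) {
  stopifnot(hue_low_1 < hue_high_1, hue_low_2 < hue_high_2,
            sat_min >= 0, sat_min <= 1, val_min >= 0, val_min <= 1)
  structure(list(hue_low_1 = hue_low_1, hue_high_1 = hue_high_1,
                 hue_low_2 = hue_low_2, hue_high_2 = hue_high_2,
                 sat_min = sat_min, val_min = val_min),
            class = "color_thresholds")
}

#' Segment candidate ring points by color
#'
#' Selects the points whose HSV color falls inside either hue interval of
#' `thr` with saturation and value above the minima. Returns an index set;
#' an empty result is not an error (the caller decides what failure means).
#'
#' @param cloud a [colored_point_cloud] with colors.
#' @param thr a [color_thresholds] object.
#' @return Integer vector of point indices (1-based, increasing).
#' @export
segment_red <- function(cloud, thr = color_thresholds()) {
  stopifnot(inherits(cloud, "colored_point_cloud"),
            inherits(thr, "color_thresholds"))
  hsv <- rgb_to_hsv(cloud$colors)
  h <- hsv[, 1]; s <- hsv[, 2]; v <- hsv[, 3]
  in_hue <- (h >= thr$hue_low_1 & h < thr$hue_high_1) |
    (h >= thr$hue_low_2 & h < thr$hue_high_2)
  which(in_hue & s >= thr$sat_min & v >= thr$val_min)
}

#' Select the ring cluster among color-segmented points
#'
#' The color-segmented subset may contain, besides the ring, red clutter
#' (pots, labels, soil reflections). The subset is partitioned by
#' single-linkage Euclidean clustering at radius `eps`; each cluster of at
#' least `min_cluster` points is scored by
#' * **planarity** — smallest/largest eigenvalue ratio of the cluster
#'   covariance (near 0 for a plane, 1 for a sphere), and
#' * **annularity** — coefficient of variation (sd/mean) of in-plane radial
#'   distances about the center of an algebraic (Kasa) circle fit (near 0
#'   for a ring or ring arc, large for filled shapes).
#'
#' The largest cluster passing both thresholds is returned; ties are broken
#' by lower annularity, then lower planarity. Distances about a fitted
#' circle center (rather than the cluster centroid) keep the annularity
#' score meaningful for heavily occluded arcs, whose centroid lies far from
#' the circle center.
#'
#' @param cloud the scene cloud.
#' @param red_indices indices from [segment_red()].
#' @param eps clustering radius in cloud units; `NULL` (default) uses 4 x
#'   the median nearest-neighbor distance of the red subset. The multiplier
#'   is scale-free (the cloud units are unknown before calibration) and
#'   sits comfortably above the percolation radius of uniform surface
#'   sampling — a smaller multiple (2 x) fragments a finite-width ring
#'   stroke into arc pieces at realistic densities.
#' @param min_cluster minimum cluster size considered (default 100).
#' @param planarity_max acceptance threshold on planarity (default 0.05).
#' @param annularity_max acceptance threshold on annularity (default 0.25).
#' @return A `ring_candidate` list: `indices` (into the scene cloud),
#'   `planarity`, `annularity`, `n_points`, and `diagnostics` (a data frame
#'   scoring every cluster).
#' @export
select_ring_cluster <- function(cloud, red_indices, eps = NULL,
                                min_cluster = 100L,
                                planarity_max = 0.05,
                                annularity_max = 0.25) {
  stopifnot(inherits(cloud, "colored_point_cloud"))
  red_indices <- as.integer(red_indices)
  if (length(red_indices) < min_cluster) {
    stop_no_ring(sprintf(
      "only %d red points segmented; min_cluster = %d",
      length(red_indices), min_cluster), diagnostics = NULL)
  }
  pts <- cloud$points[red_indices, , drop = FALSE]
  if (is.null(eps)) eps <- 4 * median_nn_distance(pts)
  labels <- eps_cluster(pts, eps)
  sizes <- tabulate(labels)
  diag_rows <- list()
  best <- NULL
  for (cl in order(sizes, decreasing = TRUE)) {
    if (sizes[cl] < min_cluster) next
    member <- labels == cl
    sub <- pts[member, , drop = FALSE]
    sc <- score_ring_cluster(sub)
    diag_rows[[length(diag_rows) + 1L]] <-
      data.frame(cluster = cl, n_points = sizes[cl],
                 planarity = sc$planarity, annularity = sc$annularity,
                 pass = sc$planarity <= planarity_max &&
                   sc$annularity <= annularity_max)
    if (sc$planarity <= planarity_max && sc$annularity <= annularity_max) {
      cand <- list(n = sizes[cl], annularity = sc$annularity,
                   planarity = sc$planarity, member = member)
      if (is.null(best) ||
          cand$n > best$n ||
          (cand$n == best$n && (cand$annularity < best$annularity ||
            (cand$annularity == best$annularity &&
             cand$planarity < best$planarity)))) {
        best <- cand
      }
    }
  }
  diagnostics <- if (length(diag_rows)) do.call(rbind, diag_rows) else
    data.frame(cluster = integer(), n_points = integer(),
               planarity = numeric(), annularity = numeric(),
               pass = logical())
  if (is.null(best)) {
    stop_no_ring("no cluster passed the planarity/annularity thresholds",
                 diagnostics = diagnostics)
  }
  structure(list(indices = red_indices[best$member],
                 planarity = best$planarity,
                 annularity = best$annularity,
                 n_points = best$n,
                 diagnostics = diagnostics),
            class = "ring_candidate")
}

score_ring_cluster <- function(sub) {
  ctr <- colMeans(sub)
  cc <- sweep(sub, 2L, ctr)
  ev <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)
  vals <- pmax(ev$values, 0)
  planarity <- if (vals[1] > 0) vals[3] / vals[1] else 0
  # in-plane radial distances about a Kasa circle-fit center
  p2 <- cc %*% ev$vectors[, 1:2]
  fit <- kasa_circle(p2)
  r <- sqrt((p2[, 1] - fit$center[1])^2 + (p2[, 2] - fit$center[2])^2)
  annularity <- if (mean(r) > 0) stats::sd(r) / mean(r) else Inf
  list(planarity = planarity, annularity = annularity)
}

# Single-linkage clustering at radius eps = connected components of the
# eps-neighborhood graph. Pairs are found by chunked brute force and the
# components by igraph.
eps_cluster <- function(pts, eps) {
  n <- nrow(pts)
  if (n == 1L) return(1L)
  sq <- rowSums(pts^2)
  eps2 <- eps^2
  chunk <- max(1L, floor(2e6 / n))
  from <- list(); to <- list(); b <- 0L
  i <- 1L
  while (i <= n) {
    j <- min(n, i + chunk - 1L)
    block <- pts[i:j, , drop = FALSE]
    d2 <- outer(rowSums(block^2), sq, "+") - 2 * tcrossprod(block, pts)
    hit <- which(d2 <= eps2, arr.ind = TRUE)
    gi <- hit[, 1] + i - 1L
    keep <- gi < hit[, 2]          # each pair once, no self-loops
    if (any(keep)) {
      b <- b + 1L
      from[[b]] <- gi[keep]
      to[[b]] <- hit[keep, 2]
    }
    i <- j + 1L
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (b > 0L) {
    g <- igraph::add_edges(g, rbind(unlist(from), unlist(to)))
  }
  igraph::components(g)$membership
}

stop_no_ring <- function(msg, diagnostics = NULL) {
  stop(errorCondition(
    paste0("NoRingFound: ", msg,
           if (!is.null(diagnostics) && nrow(diagnostics)) {
             paste0("\ncluster diagnostics:\n",
                    paste(utils::capture.output(print(diagnostics)),
                          collapse = "\n"))
           } else ""),
    class = c("ringcal_no_ring", "ringcal_error"),
    diagnostics = diagnostics))
}

stop_fit_failed <- function(msg, best_fraction = NA_real_) {
  stop(errorCondition(
    paste0("FitFailed: ", msg),
    class = c("ringcal_fit_failed", "ringcal_error"),
    best_fraction = best_fraction))
}
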