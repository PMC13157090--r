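#' @title In-package computational geometry
#' @description Two primitives the trait extractors need — the volume of a
#'   3D convex hull (incremental hull) and a 2D Delaunay triangulation
#'   (Bowyer-Watson) — implemented here because no pre-built hull/Delaunay
#'   package is part of the package's dependency footprint. Both are exact
#'   enough for trait work on clouds of up to a few thousand points and are
#'   validated against analytic shapes in the test suite.
#' @name geometry_internals
NULL

#' Volume of the 3D convex hull of a point set
#'
#' Incremental convex hull: starting from an extreme-point tetrahedron,
#' each remaining point outside the current hull replaces its visible
#' faces via the horizon edges. The volume is the sum of signed
#' tetrahedra from the interior centroid. For large clouds the input is
#' subsampled (deterministically seeded) to `max_points`; hull volume is
#' dominated by extreme points, so the subsample bias is negligible at the
#' sampling densities the traits use.
#'
#' @param points M x 3 matrix, M >= 4, not all coplanar.
#' @param max_points subsample cap (default 2000).
#' @return Hull volume (cubic input units).
#' @export
convex_hull_volume <- function(points, max_points = 2000L) {
  points <- as_xyz_matrix(points, "points")
  points <- unique(points)
  m <- nrow(points)
  if (m < 4L) stop("need at least 4 distinct points", call. = FALSE)
  if (m > max_points) {
    idx <- with_preserved_rng(max_points + m, sample.int(m, max_points))
    points <- points[sort(idx), , drop = FALSE]
    m <- max_points
  }
  faces <- incremental_hull(points)
  ctr <- colMeans(points)
  vol <- 0
  for (f in faces) {
    a <- points[f[1], ] - ctr
    b <- points[f[2], ] - ctr
    c3 <- points[f[3], ] - ctr
    vol <- vol + abs(sum(a * cross3(b, c3))) / 6
  }
  vol
}

# Returns list of faces (index triples) of the convex hull.
incremental_hull <- function(pts) {
  m <- nrow(pts)
  scale <- max(apply(pts, 2L, function(v) diff(range(v))))
  if (scale <= 0) stop("degenerate (single) point set", call. = FALSE)
  eps <- 1e-10 * scale
  # initial simplex: two extremes on x, farthest point from the segment,
  # farthest from that plane
  i1 <- which.min(pts[, 1]); i2 <- which.max(pts[, 1])
  if (i1 == i2) { i1 <- which.min(pts[, 2]); i2 <- which.max(pts[, 2]) }
  seg <- pts[i2, ] - pts[i1, ]
  rel <- sweep(pts, 2L, pts[i1, ])
  crossn <- sqrt(rowSums(t(apply(rel, 1L, cross3, b = seg))^2))
  i3 <- which.max(crossn)
  if (crossn[i3] < eps * sqrt(sum(seg^2))) {
    stop(errorCondition("degenerate geometry: points are collinear",
                        class = c("ringcal_degenerate", "ringcal_error")))
  }
  n0 <- cross3(pts[i2, ] - pts[i1, ], pts[i3, ] - pts[i1, ])
  h <- abs(rel %*% n0) / sqrt(sum(n0^2))
  i4 <- which.max(h)
  if (h[i4] < eps) {
    stop(errorCondition("degenerate geometry: points are coplanar",
                        class = c("ringcal_degenerate", "ringcal_error")))
  }
  verts <- c(i1, i2, i3, i4)
  faces <- list(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  interior <- colMeans(pts[verts, , drop = FALSE])
  orient_face <- function(f) {
    n <- cross3(pts[f[2], ] - pts[f[1], ], pts[f[3], ] - pts[f[1], ])
    if (sum(n * (interior - pts[f[1], ])) > 0) f[c(1, 3, 2)] else f
  }
  faces <- lapply(faces, orient_face)
  face_normal <- function(f) {
    n <- cross3(pts[f[2], ] - pts[f[1], ], pts[f[3], ] - pts[f[1], ])
    n
  }
  normals <- lapply(faces, face_normal)
  for (p in setdiff(seq_len(m), verts)) {
    pt <- pts[p, ]
    vis <- vapply(seq_along(faces), function(i) {
      sum(normals[[i]] * (pt - pts[faces[[i]][1], ])) > eps *
        sqrt(sum(normals[[i]]^2))
    }, TRUE)
    if (!any(vis)) next
    # horizon: edges of visible faces not shared with another visible face
    edge_key <- function(a, b) paste0(min(a, b), "_", max(a, b))
    counts <- new.env(parent = emptyenv())
    store <- new.env(parent = emptyenv())
    for (i in which(vis)) {
      f <- faces[[i]]
      ed <- list(c(f[1], f[2]), c(f[2], f[3]), c(f[3], f[1]))
      for (e in ed) {
        k <- edge_key(e[1], e[2])
        counts[[k]] <- (counts[[k]] %||% 0L) + 1L
        store[[k]] <- e  # keep orientation of (a) visible face
      }
    }
    horizon <- list()
    for (k in ls(counts)) {
      if (counts[[k]] == 1L) horizon[[length(horizon) + 1L]] <- store[[k]]
    }
    faces <- faces[!vis]
    normals <- normals[!vis]
    for (e in horizon) {
      # visible face had edge e in CCW-from-outside order; the new face
      # (e1, e2, p) with the same order faces outward
      f <- c(e[1], e[2], p)
      n <- face_normal(f)
      if (sum(n * (interior - pts[f[1], ])) > 0) {
        f <- f[c(1, 3, 2)]
        n <- -n
      }
      faces[[length(faces) + 1L]] <- f
      normals[[length(normals) + 1L]] <- n
    }
  }
  faces
}

#' 2D Delaunay triangulation (Bowyer-Watson)
#'
#' @param pts M x 2 matrix of distinct points, M >= 3.
#' @return Integer matrix, one row per triangle (vertex indices into
#'   `pts`), or a 0-row matrix if the input is degenerate (collinear).
#' @keywords internal
delaunay2d <- function(pts) {
  pts <- as.matrix(pts)
  m <- nrow(pts)
  empty <- matrix(integer(0), 0L, 3L)
  if (m < 3L) return(empty)
  rng <- apply(pts, 2L, range)
  span <- max(rng[2, ] - rng[1, ], 1e-12)
  ctr <- colMeans(t(rng))
  # super-triangle comfortably containing everything
  big <- 100 * span
  sup <- rbind(ctr + c(-big, -big / 2), ctr + c(big, -big / 2),
               ctr + c(0, big))
  P <- rbind(pts, sup)
  si <- m + 1:3
  tri <- list(c(si[1], si[2], si[3]))
  cc <- list(tri_circum(P, tri[[1]]))
  for (p in seq_len(m)) {
    px <- P[p, 1]; py <- P[p, 2]
    bad <- vapply(seq_along(tri), function(i) {
      c0 <- cc[[i]]
      if (is.null(c0)) return(FALSE)
      (px - c0[1])^2 + (py - c0[2])^2 <= c0[3] * (1 + 1e-12)
    }, TRUE)
    if (!any(bad)) next  # degenerate duplicate/collinear insert; skip
    # boundary polygon = edges of bad triangles appearing exactly once
    edges <- list()
    for (i in which(bad)) {
      f <- tri[[i]]
      edges[[length(edges) + 1L]] <- c(f[1], f[2])
      edges[[length(edges) + 1L]] <- c(f[2], f[3])
      edges[[length(edges) + 1L]] <- c(f[3], f[1])
    }
    em <- do.call(rbind, edges)
    key <- paste0(pmin(em[, 1], em[, 2]), "_", pmax(em[, 1], em[, 2]))
    once <- key %in% names(which(table(key) == 1L))
    tri <- tri[!bad]
    cc <- cc[!bad]
    for (i in which(once)) {
      f <- c(em[i, 1], em[i, 2], p)
      tri[[length(tri) + 1L]] <- f
      cc[[length(cc) + 1L]] <- tri_circum(P, f)
    }
  }
  keep <- vapply(tri, function(f) !any(f %in% si), TRUE)
  tri <- tri[keep]
  if (!length(tri)) return(empty)
  do.call(rbind, tri)
}

# circumcenter + squared radius of triangle f in P; NULL if collinear
tri_circum <- function(P, f) {
  cc <- circumcircle(P[f[1], ], P[f[2], ], P[f[3], ])
  if (is.null(cc)) return(NULL)
  c(cc$center, cc$radius^2)
}
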