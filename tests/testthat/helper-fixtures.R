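# Fixture builders and independent oracles shared across the test files.
# Everything is generated in code; no binary fixtures.

cloud_mm <- function(pts, colors = NULL) {
  colored_point_cloud(pts, colors, units = "mm")
}

# points on an exact circle (2D)
circle_points2d <- function(n, center = c(0, 0), r = 1,
                            arc = c(0, 2 * pi)) {
  th <- seq(arc[1], arc[2], length.out = n + 1L)[-(n + 1L)]
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

# uniformly sampled solid disk in the z = z0 plane
disk_cloud <- function(n, r = 50, z0 = 0, seed = 1) {
  set.seed(seed)
  rr <- r * sqrt(runif(n))
  aa <- runif(n, 0, 2 * pi)
  cbind(rr * cos(aa), rr * sin(aa), z0)
}

# Independent geometric-LS circle oracle: for a fixed center the optimal
# radius is the mean distance, so the objective is minimized over the
# center alone by a shrinking-grid pattern search (no Gauss-Newton, no
# Jacobians -- independent of the implementation under test).
oracle_circle <- function(points2d, tol = 1e-9) {
  obj <- function(c0) {
    d <- sqrt((points2d[, 1] - c0[1])^2 + (points2d[, 2] - c0[2])^2)
    r <- mean(d)
    sum((d - r)^2)
  }
  ctr <- colMeans(points2d)
  span <- max(apply(points2d, 2, function(v) diff(range(v))))
  step <- span
  best <- ctr
  fbest <- obj(best)
  while (step > tol) {
    improved <- FALSE
    for (dx in c(-1, 0, 1)) for (dy in c(-1, 0, 1)) {
      if (dx == 0 && dy == 0) next
      cand <- best + step * c(dx, dy)
      fc <- obj(cand)
      if (fc < fbest) { best <- cand; fbest <- fc; improved <- TRUE }
    }
    if (!improved) step <- step / 2
  }
  d <- sqrt((points2d[, 1] - best[1])^2 + (points2d[, 2] - best[2])^2)
  list(center = best, radius = mean(d))
}

# random unit 3-vector
runit3 <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

expect_rotation <- function(R, tol = 1e-10) {
  expect_lt(max(abs(crossprod(R) - diag(3))), tol)
  expect_lt(abs(det(R) - 1), tol)
}
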