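test_that("pca_frame recovers axis-aligned and rotated planes", {
  set.seed(31)
  base <- cbind(runif(200, -3, 3), runif(200, -1, 1), 5)
  fr <- pca_frame(base)
  expect_equal(abs(fr$e3), c(0, 0, 1), tolerance = 1e-9)
  expect_equal(fr$origin[3], 5, tolerance = 1e-12)
  # orthonormal right-handed frame
  V <- cbind(fr$e1, fr$e2, fr$e3)
  expect_lt(max(abs(crossprod(V) - diag(3))), 1e-9)
  expect_equal(det(V), 1, tolerance = 1e-9)

  Rstar <- rodrigues_rotation(c(0, 0, 1), c(2, -1, 2) / 3)
  fr2 <- pca_frame(base %*% t(Rstar))
  n_exp <- as.numeric(Rstar %*% c(0, 0, 1))
  expect_lt(min(sqrt(sum((fr2$e3 - n_exp)^2)),
                sqrt(sum((fr2$e3 + n_exp)^2))), 1e-6)
})

test_that("pca_frame on three points gives the cross-product normal", {
  p <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 1))
  fr <- pca_frame(p)
  n_exp <- c(0, -1, 1) / sqrt(2)  # (p2-p1) x (p3-p1), normalized
  expect_lt(min(sqrt(sum((fr$e3 - n_exp)^2)),
                sqrt(sum((fr$e3 + n_exp)^2))), 1e-9)
  expect_error(pca_frame(cbind(1:10, 2 * (1:10), 3 * (1:10))),
               class = "ringcal_degenerate")
  expect_error(pca_frame(rbind(c(0, 0, 0), c(1, 1, 1))), "at least 3")
})

test_that("rodrigues_rotation matches the closed form and its contract", {
  expect_identical(rodrigues_rotation(c(0, 0, 1), c(0, 0, 1)), diag(3))
  # z -> x: axis (0,1,0), angle pi/2, hand-evaluated matrix
  R <- rodrigues_rotation(c(0, 0, 1), c(1, 0, 0))
  expect_equal(R, matrix(c(0, 0, -1, 0, 1, 0, 1, 0, 0), 3, 3),
               tolerance = 1e-12)
  expect_equal(as.numeric(R %*% c(0, 0, 1)), c(1, 0, 0), tolerance = 1e-12)
  # antiparallel degenerate case keeps the contract
  R2 <- rodrigues_rotation(c(0, 0, 1), c(0, 0, -1))
  expect_rotation(R2)
  expect_equal(as.numeric(R2 %*% c(0, 0, 1)), c(0, 0, -1), tolerance = 1e-10)
  expect_error(rodrigues_rotation(c(0, 0, 2), c(1, 0, 0)), "unit")
})

test_that("rodrigues_rotation satisfies SO(3) + alignment over random pairs", {
  set.seed(32)
  for (i in 1:1000) {
    a <- runit3(); b <- runit3()
    R <- rodrigues_rotation(a, b)
    expect_lt(max(abs(R %*% a - b)), 1e-10)
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-10)
    expect_lt(abs(det(R) - 1), 1e-10)
  }
})

test_that("plane projection is the frame-basis isometry", {
  set.seed(33)
  fr <- pca_frame(cbind(runif(100, -2, 2), runif(100, -1, 1), 0))
  expect_equal(as.numeric(project_to_plane(rbind(fr$origin), fr)), c(0, 0))
  p <- fr$origin + 3 * fr$e1
  expect_equal(as.numeric(project_to_plane(rbind(p), fr)), c(3, 0),
               tolerance = 1e-12)
  # a planar circle projects to a centered circle of the same radius
  th <- seq(0, 2 * pi, length.out = 73)[-73]
  circ3 <- t(sapply(th, function(a) {
    fr$origin + 4 * cos(a) * fr$e1 + 4 * sin(a) * fr$e2
  }))
  p2 <- project_to_plane(circ3, fr)
  ctr <- colMeans(p2)
  expect_lt(max(abs(sqrt((p2[, 1] - ctr[1])^2 + (p2[, 2] - ctr[2])^2) - 4)),
            1e-9)
})

test_that("scale factor is the diameter ratio", {
  expect_identical(scale_factor(200, 200), 1)
  expect_identical(scale_factor(100, 200), 2)
  expect_identical(scale_factor(400, 200), 0.5)
  expect_error(scale_factor(0, 200), "positive")
  expect_error(scale_factor(100, -1), "positive")
})

test_that("apply_transform follows the rotate-scale-translate contract", {
  cube <- colored_point_cloud(as.matrix(expand.grid(0:1, 0:1, 0:1)))
  ident <- ringcal:::new_metric_transform(diag(3), 1, c(0, 0, 0))
  out <- apply_transform(cube, ident)
  expect_identical(out$points, cube$points)
  expect_identical(out$units, "mm")
  expect_error(apply_transform(out, ident), "already metric")

  doubling <- ringcal:::new_metric_transform(diag(3), 2, c(0, 0, 0))
  expect_equal(max(dist(apply_transform(cube, doubling)$points)),
               2 * sqrt(3))

  # similarity property: all pairwise distances scale by s
  set.seed(34)
  pc <- colored_point_cloud(matrix(rnorm(60), 20, 3))
  R <- rodrigues_rotation(runit3(), runit3())
  tr <- ringcal:::new_metric_transform(R, 3.7, c(1, -2, 0.5))
  d0 <- dist(pc$points)
  d1 <- dist(apply_transform(pc, tr)$points)
  expect_equal(as.numeric(d1), 3.7 * as.numeric(d0), tolerance = 1e-12)
})

test_that("build_metric_transform puts the ring at z = 0, center at origin", {
  sp <- scene_spec(seed = 35, similarity = random_similarity(35))
  sc <- make_scene(sp)
  cal <- calibrate_cloud(sc$cloud)
  ring <- subset_cloud(sc$cloud, sc$truth$labels == "ring")
  m <- apply_transform(ring, cal$transform)
  expect_lt(max(abs(m$points[, 3])), 1e-9)
  expect_lt(max(abs(colMeans(m$points[, 1:2]))), 1e-6)
  # plant ends up above the plane
  plant <- subset_cloud(sc$cloud, sc$truth$labels == "plant")
  expect_gt(min(apply_transform(plant, cal$transform)$points[, 3]), -1e-6)
  expect_rotation(cal$transform$R)
})

test_that("normal sign correction makes mirrored scenes agree", {
  sp <- scene_spec(seed = 36)
  sc <- make_scene(sp)
  cal1 <- calibrate_cloud(sc$cloud)
  # mirror the whole scene through the ring plane z -> -z: the plant now
  # hangs below; calibration must flip the normal and recover the same
  # world geometry
  mirrored <- sc$cloud
  mirrored$points[, 3] <- -mirrored$points[, 3]
  cal2 <- calibrate_cloud(mirrored)
  plant_idx <- sc$truth$labels == "plant"
  m1 <- apply_transform(subset_cloud(sc$cloud, plant_idx), cal1$transform)
  m2 <- apply_transform(subset_cloud(mirrored, plant_idx), cal2$transform)
  expect_equal(sort(m1$points[, 3]), sort(m2$points[, 3]), tolerance = 1e-9)
  expect_equal(cal1$transform$s, cal2$transform$s, tolerance = 1e-12)
})

test_that("an extra similarity changes the result only by a z-rotation", {
  sp <- scene_spec(seed = 37, similarity = random_similarity(37))
  sc <- make_scene(sp)
  plant_idx <- sc$truth$labels == "plant"
  base <- apply_transform(subset_cloud(sc$cloud, plant_idx),
                          calibrate_cloud(sc$cloud)$transform)
  extra <- random_similarity(137, scale_range = c(0.2, 5), t_max = 100)
  warped <- sc$cloud
  warped$points <- sweep(extra$s * (sc$cloud$points %*% t(extra$R)), 2L,
                         extra$t, "+")
  again <- apply_transform(subset_cloud(warped, plant_idx),
                           calibrate_cloud(warped)$transform)
  # z-invariant summaries agree: heights and radial distances from axis
  expect_equal(sort(base$points[, 3]), sort(again$points[, 3]),
               tolerance = 1e-6)
  expect_equal(sort(sqrt(rowSums(base$points[, 1:2]^2))),
               sort(sqrt(rowSums(again$points[, 1:2]^2))),
               tolerance = 1e-6)
})

test_that("metric transforms round-trip through JSON bit-exactly", {
  sp <- scene_spec(seed = 38, similarity = random_similarity(38))
  cal <- calibrate_cloud(make_scene(sp)$cloud)
  path <- withr::local_tempfile(fileext = ".json")
  write_transform(cal$transform, path)
  back <- read_transform(path)
  expect_identical(back$R, cal$transform$R)
  expect_identical(back$s, cal$transform$s)
  expect_identical(back$t, cal$transform$t)
  expect_identical(back$d_fitted, cal$transform$d_fitted)
  # malformed files are rejected with the offending field named
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"R": [1,0,0], "s": 2}', bad)
  expect_error(read_transform(bad), "missing field|malformed")
})

test_that("ambiguous orientation (plant on the ring plane) is an error", {
  sp <- scene_spec(seed = 39, plant = list(kind = "none"))
  sc <- make_scene(sp)
  fr <- pca_frame(sc$cloud$points)
  p2 <- project_to_plane(sc$cloud$points, fr)
  fit <- lsq_refine_circle(p2, rep(TRUE, nrow(p2)),
                           ransac_circle(p2, inlier_tol = 20, seed = 0))
  coplanar <- colored_point_cloud(sc$cloud$points[1:50, , drop = FALSE])
  expect_error(build_metric_transform(fr, fit, coplanar),
               class = "ringcal_degenerate")
})
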