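test_that("ring generator respects the annulus geometry", {
  sp <- scene_spec(seed = 61)
  ring <- make_ring(sp)
  r <- sqrt(rowSums(ring$cloud$points[, 1:2]^2))
  expect_true(all(r >= 95 - 1e-9 & r <= 105 + 1e-9))
  expect_true(all(ring$cloud$points[, 3] == 0))
  expect_equal(ring$normal, c(0, 0, 1))
  # reproducibility is bit-exact
  expect_identical(make_ring(sp)$cloud$points, ring$cloud$points)
  expect_identical(make_ring(sp)$cloud$colors, ring$cloud$colors)
})

test_that("occlusion removes one contiguous arc; inclination tilts the plane", {
  sp <- scene_spec(seed = 62, occlusion_frac = 0.5)
  pts <- make_ring(sp)$cloud$points
  th <- atan2(pts[, 2], pts[, 1])
  # remaining angular support spans at most pi
  th_sorted <- sort(th)
  gaps <- diff(c(th_sorted, th_sorted[1] + 2 * pi))
  expect_gte(max(gaps), pi - 1e-6)

  sp2 <- scene_spec(seed = 62, inclination_deg = 60)
  ring2 <- make_ring(sp2)
  expect_equal(sum(ring2$normal * c(0, 0, 1)), cos(pi / 3), tolerance = 1e-12)
  fr <- pca_frame(ring2$cloud$points)
  expect_lt(min(sqrt(sum((fr$e3 - ring2$normal)^2)),
                sqrt(sum((fr$e3 + ring2$normal)^2))), 1e-9)
})

test_that("noiseless rings fit their centerline exactly under occlusion", {
  # the +/- paired radial sampling makes the geometric-LS circle of any
  # contiguous arc exactly the centerline -- the property the end-to-end
  # ground truth relies on
  for (occ in c(0, 0.3, 0.75)) {
    sp <- scene_spec(seed = 63, occlusion_frac = occ)
    pts <- make_ring(sp)$cloud$points
    fit <- lsq_refine_circle(pts[, 1:2], rep(TRUE, nrow(pts)),
                             ransac_circle(pts[, 1:2], inlier_tol = 20,
                                           seed = 0))
    expect_lt(abs(fit$radius - 100), 1e-8)
    expect_lt(max(abs(fit$center2d)), 1e-8)
  }
})

test_that("stylized plants carry analytic ground truth", {
  sp <- scene_spec(seed = 64, plant = list(kind = "disk_leaf", height = 100,
                                           leaf_radius = 50,
                                           stem_points = 0L))
  pl <- make_plant(sp)
  expect_equal(pl$leaf_area, 2500 * pi)
  expect_equal(pl$height, 100)
  expect_equal(pl$surface_area, pl$leaf_area)
  expect_true(all(pl$cloud$points[, 3] <= 100 + 1e-9))

  spb <- scene_spec(seed = 64, plant = list(kind = "box", height = 300))
  plb <- make_plant(spb)
  expect_equal(plb$height, 300)
  expect_equal(plb$projection_area, 1e4)

  # plants are green: never inside the red thresholds
  expect_length(segment_red(pl$cloud), 0L)
  sps <- scene_spec(seed = 65, plant = list(kind = "stem_and_leaves",
                                            leaf_count = 4L))
  pls <- make_plant(sps)
  expect_equal(pls$leaf_area, 4 * pi * 50 * 30)
  expect_length(segment_red(pls$cloud), 0L)
})

test_that("scenes carry consistent labels, similarity and expected scale", {
  sim <- random_similarity(66)
  sp <- scene_spec(seed = 66, similarity = sim,
                   clutter = list(list(kind = "cube", size = 60,
                                       center = c(400, 0, 30),
                                       n_points = 500L)))
  sc <- make_scene(sp)
  expect_equal(length(sc$truth$labels), n_points(sc$cloud))
  expect_setequal(unique(sc$truth$labels), c("ring", "plant", "clutter"))
  expect_equal(sc$truth$expected_scale, 1 / sim$s)
  expect_identical(sc$cloud$units, "reconstruction")
  # undo the similarity by hand: ring points return to the annulus
  ring <- sc$cloud$points[sc$truth$labels == "ring", ]
  undone <- sweep(ring, 2L, sim$t) %*% sim$R / sim$s
  rr <- sqrt(rowSums(undone[, 1:2]^2))
  expect_true(all(rr >= 95 - 1e-6 & rr <= 105 + 1e-6))
})

test_that("recovered transform reproduces the generated geometry", {
  sp <- scene_spec(seed = 67, similarity = random_similarity(67),
                   noise_sigma = 0.5)
  sc <- make_scene(sp)
  cal <- calibrate_cloud(sc$cloud)
  metric <- apply_transform(sc$cloud, cal$transform)
  # up to a z-rotation: compare z and axis distance per labeled point
  gen <- make_scene(scene_spec(seed = 67, noise_sigma = 0.5))$cloud$points
  tol <- 10 * 0.5 + 1e-6
  expect_lt(max(abs(metric$points[, 3] - gen[, 3])), tol)
  expect_lt(max(abs(sqrt(rowSums(metric$points[, 1:2]^2)) -
                      sqrt(rowSums(gen[, 1:2]^2)))), tol)
})

test_that("growth sequences are monotone and step-reproducible", {
  base <- scene_spec(seed = 68, plant = list(kind = "box", height = 150,
                                             n_points = 1500L))
  seq6 <- growth_sequence(base, growth_factors = seq(1, 2, length.out = 6))
  expect_length(seq6, 6L)
  heights <- vapply(seq6, function(s) s$truth$plant_height, 0)
  expect_false(is.unsorted(heights))
  again <- growth_sequence(base, growth_factors = seq(1, 2, length.out = 6))
  expect_identical(seq6[[3]]$cloud$points, again[[3]]$cloud$points)
  expect_error(growth_sequence(base, growth_factors = c(2, 1)), "unsorted")
})

test_that("scene PLY + truth sidecar survive a disk round trip", {
  sp <- scene_spec(seed = 69, similarity = random_similarity(69))
  sc <- make_scene(sp)
  ply <- withr::local_tempfile(fileext = ".ply")
  tj <- withr::local_tempfile(fileext = ".json")
  write_scene(sc, ply, tj)
  back <- read_ply(ply)
  expect_identical(back$points, sc$cloud$points)  # double-precision PLY
  truth <- jsonlite::read_json(tj, simplifyVector = TRUE)
  expect_equal(truth$expected_scale, sc$truth$expected_scale)
  expect_equal(length(truth$labels), n_points(back))
})
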