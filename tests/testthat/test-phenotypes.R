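test_that("plant height uses robust z-percentiles", {
  set.seed(41)
  box <- cloud_mm(cbind(runif(2000, -50, 50), runif(2000, -50, 50),
                        runif(2000, 0, 300)))
  expect_equal(plant_height(box, 0, 100), diff(range(box$points[, 3])))
  # one gross outlier high above the canopy barely moves the default
  spiked <- cloud_mm(rbind(box$points, c(0, 0, 900)))
  expect_lt(abs(plant_height(spiked) - 300) / 300, 0.01)
  # degenerate: a single z value
  flat <- cloud_mm(cbind(runif(10), runif(10), 5))
  expect_equal(plant_height(flat), 0)
  expect_error(plant_height(cloud_mm(matrix(numeric(0), 0, 3))), "at least")
})

test_that("canopy width is the xy hull diameter, independent of z", {
  two <- cloud_mm(rbind(c(0, 0, 0), c(90, 120, 50)))
  expect_equal(canopy_width(two), 150)
  set.seed(42)
  disk <- cloud_mm(disk_cloud(8000, r = 80, seed = 42))
  expect_lt(abs(canopy_width(disk) - 160) / 160, 0.01)
  shuffled <- disk
  shuffled$points[, 3] <- sample(shuffled$points[, 3])
  expect_identical(canopy_width(shuffled), canopy_width(disk))
})

test_that("vertical distribution is a normalized histogram from the ground", {
  set.seed(43)
  pc <- cloud_mm(cbind(runif(20000), runif(20000), runif(20000, 0, 100)))
  vd <- vertical_distribution(pc, 10)
  expect_equal(sum(vd$fraction), 1, tolerance = 1e-9)
  expect_true(all(abs(vd$fraction - 0.1) < 0.01))
  expect_equal(vd$bin_edges[1], 0)
  one <- vertical_distribution(cloud_mm(cbind(1:5, 1:5, 7)), 5)
  expect_equal(sum(one$fraction == 1), 1L)
})

test_that("projection areas: convex hull vs occupancy grid", {
  sq <- cloud_mm(rbind(c(0, 0, 0), c(1, 0, 2), c(1, 1, 1), c(0, 1, 5)))
  expect_equal(canopy_projection_area(sq), 1)
  shifted <- sq
  shifted$points[, 1:2] <- shifted$points[, 1:2] + 1000
  expect_equal(canopy_projection_area(shifted), 1, tolerance = 1e-9)

  set.seed(44)
  disk <- cloud_mm(disk_cloud(40000, r = 100, seed = 44))
  expect_lt(abs(canopy_projection_area(disk) - pi * 1e4) / (pi * 1e4), 0.02)
  expect_lt(abs(main_projection_area(disk, 2) - pi * 1e4) / (pi * 1e4), 0.05)

  expect_equal(main_projection_area(cloud_mm(rbind(c(0.5, 0.5, 1))), 2), 4)

  # concavity: an annulus loses its hole in the convex reading only
  set.seed(45)
  th <- runif(20000, 0, 2 * pi)
  rr <- runif(20000, 60, 100)
  ann <- cloud_mm(cbind(rr * cos(th), rr * sin(th), 0))
  expect_lt(main_projection_area(ann, 2), canopy_projection_area(ann))

  line <- cloud_mm(cbind(1:10, 2 * (1:10), 0))
  expect_warning(a <- canopy_projection_area(line), "collinear|degenerate")
  expect_equal(a, 0)
})

test_that("surface area recovers analytic disks and is additive", {
  disk <- cloud_mm(disk_cloud(5000, r = 50, seed = 46))
  a1 <- total_leaf_area(disk)
  expect_lt(abs(a1 - pi * 2500) / (pi * 2500), 0.05)
  # two disjoint parallel disks sum
  both <- cloud_mm(rbind(disk$points,
                         cbind(disk_cloud(5000, r = 50, seed = 47)[, 1:2], 40)))
  expect_lt(abs(total_leaf_area(both) - 2 * pi * 2500) / (2 * pi * 2500),
            0.05)
  expect_error(total_leaf_area(cloud_mm(disk_cloud(30, r = 10))), "sparse")
})

test_that("surface area scales quadratically (dimensional analysis)", {
  disk <- cloud_mm(disk_cloud(3000, r = 40, seed = 48))
  a1 <- total_leaf_area(disk)
  a2 <- total_leaf_area(cloud_mm(disk$points * 2))
  expect_lt(abs(a2 / a1 - 4) / 4, 0.01)
})

test_that("compactness separates solid from bladed architectures", {
  set.seed(49)
  cube <- cloud_mm(matrix(runif(60000, 0, 100), 20000, 3))
  cc <- compactness(cube)
  expect_gte(cc, 0.9)
  expect_lte(cc, 1)
  # two exactly planar orthogonal blades spanning a cube-shaped hull
  m <- 4000
  corners <- as.matrix(expand.grid(c(-50, 50), c(-50, 50), c(0, 100)))
  cross <- cloud_mm(rbind(
    cbind(runif(m, -50, 50), 0, runif(m, 0, 100)),
    cbind(0, runif(m, -50, 50), runif(m, 0, 100)),
    corners))
  expect_lte(compactness(cross), 0.3)
  expect_error(compactness(cloud_mm(cbind(runif(10), runif(10), 0))),
               class = "ringcal_degenerate")
})

test_that("spatial occupancy fills the bounding grid as expected", {
  expect_equal(spatial_occupancy(cloud_mm(rbind(c(1, 2, 3)))), 1)
  set.seed(50)
  cube <- cloud_mm(matrix(runif(60000, 0, 100), 20000, 3))
  expect_gt(spatial_occupancy(cube), 0.9)
  expect_lte(spatial_occupancy(cube), 1)
})

test_that("traits scale coherently and are azimuth-robust", {
  sp <- scene_spec(seed = 51, plant = list(kind = "stem_and_leaves"))
  plant <- make_plant(sp)$cloud
  a <- 2
  scaled <- cloud_mm(plant$points * a, plant$colors)
  expect_equal(plant_height(scaled), a * plant_height(plant),
               tolerance = 1e-9)
  expect_equal(canopy_width(scaled), a * canopy_width(plant),
               tolerance = 1e-9)
  expect_equal(canopy_projection_area(scaled),
               a^2 * canopy_projection_area(plant), tolerance = 1e-9)
  expect_lt(abs(compactness(scaled, voxel = 5 * a) - compactness(plant, 5)),
            0.1)
  th <- 0.7
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  spun <- cloud_mm(plant$points %*% t(Rz), plant$colors)
  expect_equal(plant_height(spun), plant_height(plant), tolerance = 1e-12)
  expect_identical(vertical_distribution(spun, 20)$fraction,
                   vertical_distribution(plant, 20)$fraction)
  expect_lt(abs(canopy_width(spun) / canopy_width(plant) - 1), 0.01)
  expect_lt(abs(canopy_projection_area(spun) /
                  canopy_projection_area(plant) - 1), 0.01)
})

test_that("extract_report survives per-trait failures and is deterministic", {
  empty <- cloud_mm(matrix(numeric(0), 0, 3))
  rep0 <- extract_report(empty)
  expect_null(rep0$plant_height)
  expect_gt(length(rep0$errors), 0)

  sp <- scene_spec(seed = 52, plant = list(kind = "box", height = 300,
                                           n_points = 3000L))
  plant <- make_plant(sp)$cloud
  r1 <- extract_report(plant)
  r2 <- extract_report(plant)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_report(r1, p1)
  write_report(r2, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_lt(abs(r1$plant_height - 300) / 300, 0.01)
  expect_lt(abs(r1$canopy_projection_area - 1e4) / 1e4, 0.02)
  expect_true(all(unlist(r1[c("compactness", "spatial_occupancy")]) <= 1))
  # parameters are recorded
  expect_equal(r1$parameters$grid_res_mm, 2)
  # csv outputs
  csvp <- withr::local_tempfile(fileext = ".csv")
  dcsv <- withr::local_tempfile(fileext = ".csv")
  write_report(r1, withr::local_tempfile(fileext = ".json"),
               csv_path = csvp, dist_csv_path = dcsv)
  tab <- read.csv(csvp)
  expect_equal(nrow(tab), 1L)
  expect_true("plant_height" %in% names(tab))
  expect_equal(sum(read.csv(dcsv)$fraction), 1, tolerance = 1e-9)
})
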