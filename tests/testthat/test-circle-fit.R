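test_that("RANSAC recovers a noiseless circle exactly", {
  pts <- circle_points2d(100, center = c(2, -1), r = 5)
  fit <- ransac_circle(pts, inlier_tol = 1e-6, seed = 1)
  expect_lt(max(abs(fit$center2d - c(2, -1))), 1e-6)
  expect_lt(abs(fit$radius - 5), 1e-6)
  expect_equal(fit$d_fitted, 2 * fit$radius)
  expect_true(all(fit$inlier_mask))
})

test_that("three points give their circumcircle", {
  pts <- rbind(c(1, 0), c(0, 1), c(-1, 0))
  fit <- ransac_circle(pts, n_iter = 10, inlier_tol = 1e-9, seed = 0)
  expect_lt(max(abs(fit$center2d)), 1e-12)
  expect_equal(fit$radius, 1, tolerance = 1e-12)
})

test_that("RANSAC + refinement tolerate 40% background outliers", {
  for (seed in 1:20) {
    set.seed(seed)
    n_c <- 150
    circ <- circle_points2d(n_c, center = c(2, -1), r = 5)
    n_out <- round(n_c * 0.4 / 0.6)
    bg <- cbind(runif(n_out, -4, 8), runif(n_out, -7, 5))
    pts <- rbind(circ, bg)
    fit <- ransac_circle(pts, inlier_tol = 0.05 * 5, seed = seed)
    fit <- lsq_refine_circle(pts, fit$inlier_mask, fit)
    expect_gte(sum(fit$inlier_mask[1:n_c]), 0.95 * n_c)
    expect_lt(abs(fit$radius - 5) / 5, 0.01)
  }
})

test_that("fit fails cleanly when no circle reaches the inlier fraction", {
  set.seed(7)
  pts <- matrix(runif(200), 100, 2)
  err <- tryCatch(
    ransac_circle(pts, n_iter = 200, inlier_tol = 1e-6,
                  min_inlier_frac = 0.5, seed = 7),
    ringcal_fit_failed = function(e) e)
  expect_s3_class(err, "ringcal_fit_failed")
  expect_lt(err$best_fraction, 0.5)
  expect_error(ransac_circle(matrix(0, 2, 2)), "at least 3")
})

test_that("RANSAC is deterministic given its seed and leaves the RNG alone", {
  set.seed(123)
  pts <- rbind(circle_points2d(60, r = 3), matrix(runif(40, -3, 3), 20, 2))
  before <- runif(1)
  set.seed(123); runif(1)  # same RNG position
  f1 <- ransac_circle(pts, seed = 5, inlier_tol = 0.1)
  after <- runif(1)
  f2 <- ransac_circle(pts, seed = 5, inlier_tol = 0.1)
  expect_identical(f1[c("center2d", "radius", "inlier_mask")],
                   f2[c("center2d", "radius", "inlier_mask")])
  set.seed(123); runif(1)
  expect_identical(runif(1), after)  # RNG stream was not consumed
})

test_that("geometric refinement is a fixed point on exact circles", {
  pts <- circle_points2d(50, center = c(1, 2), r = 4)
  init <- ransac_circle(pts, inlier_tol = 1e-9, seed = 0)
  ref <- lsq_refine_circle(pts, rep(TRUE, 50), init)
  expect_lt(max(abs(ref$center2d - init$center2d)), 1e-10)
  expect_lt(abs(ref$radius - init$radius), 1e-10)
  expect_lt(ref$rms_residual, 1e-10)
})

test_that("refined radius concentrates at the noise-limited rate", {
  # radial Gaussian noise sd 0.05 on r = 5 with 500 points: the radius
  # estimate should land within 3 sd / sqrt(n) of the truth
  for (seed in 1:20) {
    set.seed(seed)
    th <- runif(500, 0, 2 * pi)
    r <- 5 + rnorm(500, 0, 0.05)
    pts <- cbind(r * cos(th), r * sin(th))
    init <- ransac_circle(pts, inlier_tol = 0.5, seed = seed)
    fit <- lsq_refine_circle(pts, rep(TRUE, 500), init)
    expect_lt(abs(fit$radius - 5), 3 * 0.05 / sqrt(500))
  }
})

test_that("noiseless half arcs are fitted exactly (occlusion kernel)", {
  pts <- circle_points2d(80, center = c(-3, 7), r = 12, arc = c(0.3, 0.3 + pi))
  init <- ransac_circle(pts, inlier_tol = 1e-6, seed = 2)
  fit <- lsq_refine_circle(pts, rep(TRUE, 80), init)
  expect_lt(max(abs(fit$center2d - c(-3, 7))), 1e-8)
  expect_lt(abs(fit$radius - 12), 1e-8)
})

test_that("refinement never worsens the objective and flags non-convergence", {
  set.seed(9)
  th <- runif(200, 0, 2 * pi)
  r <- 3 + rnorm(200, 0, 0.2)
  pts <- cbind(1 + r * cos(th), -2 + r * sin(th))
  obj <- function(c0, r0) {
    d <- sqrt((pts[, 1] - c0[1])^2 + (pts[, 2] - c0[2])^2)
    sum((d - r0)^2)
  }
  init <- ransac_circle(pts, inlier_tol = 1, seed = 3)
  ref <- suppressWarnings(lsq_refine_circle(pts, rep(TRUE, 200), init))
  expect_lte(obj(ref$center2d, ref$radius), obj(init$center2d, init$radius))
  # with a 1-iteration cap the fit cannot fully converge on noisy data
  expect_warning(lsq_refine_circle(pts, rep(TRUE, 200), init, max_iter = 2L),
                 "convergence")
})

test_that("two-stage fit matches the pattern-search oracle on small instances", {
  cases <- list(
    list(pts = circle_points2d(40, center = c(1.5, -0.5), r = 2)),
    list(pts = circle_points2d(50, center = c(-2, 3), r = 7,
                               arc = c(1, 1 + pi))))
  for (cs in cases) {
    pts <- cs$pts
    fit <- lsq_refine_circle(pts, rep(TRUE, nrow(pts)),
                             ransac_circle(pts, inlier_tol = 0.2, seed = 1))
    orc <- oracle_circle(pts)
    expect_lt(max(abs(fit$center2d - orc$center)), 1e-3)
    expect_lt(abs(fit$radius - orc$radius), 1e-3)
  }
})
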