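#' Specification of a synthetic validation scene
#'
#' Describes a scene with exact ground truth: a planar red ring of known
#' diameter at the origin of the "generated world" (mm units), a stylized
#' plant above the plane, optional red clutter, and the perturbations the
#' robustness analysis varies — additive coordinate noise, contiguous arc
#' occlusion, ring inclination, chromatic jitter — plus an unknown
#' similarity transform (rotation, uniform scale, translation) applied to
#' the whole scene to emulate the arbitrary coordinates of a monocular
#' reconstruction.
#'
#' The stylized plants are parametric shapes with analytic surface areas
#' and heights, not realistic plant models: validation needs exact ground
#' truth, not realism.
#'
#' @param d_true ring centerline diameter, mm (default 200 — an A4-printable
#'   ring).
#' @param annulus_width radial width of the printed stroke, mm (default 10).
#' @param ring_points number of ring points (default 1500; rounded down to
#'   an even count).
#' @param plant plant description: `list(kind, height, leaf_radius,
#'   leaf_count, n_points, stem_points)` with `kind` one of `"none"`,
#'   `"disk_leaf"`, `"stem_and_leaves"`, `"box"`. See [make_plant()].
#' @param noise_sigma isotropic Gaussian coordinate noise, mm (default 0).
#' @param occlusion_frac fraction of the ring arc removed as one contiguous
#'   block, `[0, 1)` (default 0) — the hardest occlusion geometry for
#'   corner-based markers, emulating a leaf lying over one side.
#' @param inclination_deg ring tilt relative to the world horizontal,
#'   degrees (default 0).
#' @param clutter list of red distractor primitives, each
#'   `list(kind = "sphere"|"cube", size, center, n_points)`.
#' @param color_jitter chromatic jitter scales,
#'   `list(hue_sd, sat_sd, val_sd)` (hue in degrees, wrap-aware);
#'   illumination variation is emulated as value/saturation shifts.
#' @param similarity the unknown similarity, `list(R, s, t)`; default
#'   identity. See [random_similarity()].
#' @param seed integer; every random draw in the generators derives from
#'   it, so scenes are bit-reproducible.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(d_true = 200, annulus_width = 10, ring_points = 1500L,
                       plant = list(kind = "disk_leaf"),
                       noise_sigma = 0, occlusion_frac = 0,
                       inclination_deg = 0, clutter = list(),
                       color_jitter = list(hue_sd = 4, sat_sd = 0.05,
                                           val_sd = 0.05),
                       similarity = list(R = diag(3), s = 1, t = c(0, 0, 0)),
                       seed = 1L) {
  stopifnot(d_true > 0, annulus_width >= 0, annulus_width < d_true,
            ring_points >= 4L, occlusion_frac >= 0, occlusion_frac < 1,
            similarity$s > 0)
  plant <- utils::modifyList(
    list(kind = "disk_leaf", height = 100, leaf_radius = 50, leaf_count = 5L,
         n_points = 2000L, stem_points = 300L, stem_radius = 2),
    plant)
  plant$kind <- match.arg(plant$kind,
                          c("none", "disk_leaf", "stem_and_leaves", "box"))
  color_jitter <- utils::modifyList(
    list(hue_sd = 4, sat_sd = 0.05, val_sd = 0.05, val_shift = 0),
    color_jitter)
  structure(list(d_true = d_true, annulus_width = annulus_width,
                 ring_points = as.integer(ring_points), plant = plant,
                 noise_sigma = noise_sigma, occlusion_frac = occlusion_frac,
                 inclination_deg = inclination_deg, clutter = clutter,
                 color_jitter = color_jitter, similarity = similarity,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# hsv (hue in degrees) -> rgb matrix in [0,1], with wrap-aware Gaussian
# jitter applied around the base color
jittered_color <- function(n, h0, s0, v0, jit) {
  v0 <- v0 + (jit$val_shift %||% 0)  # illumination as a brightness offset
  h <- (h0 + stats::rnorm(n, 0, jit$hue_sd)) %% 360
  s <- pmin(1, pmax(0, s0 + stats::rnorm(n, 0, jit$sat_sd)))
  v <- pmin(1, pmax(0, v0 + stats::rnorm(n, 0, jit$val_sd)))
  t(grDevices::col2rgb(grDevices::hsv(h / 360, s, v))) / 255
}

rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}

#' Generate the ring point cloud (generated-world mm, pre-similarity)
#'
#' Points lie on a uniform angular grid over the annulus
#' `[d_true/2 - w/2, d_true/2 + w/2]`; at each grid angle a pair of points
#' is placed at symmetric radial offsets `centerline +/- delta` so that,
#' noiselessly, the geometric least-squares circle of any contiguous arc
#' is exactly the centerline — the generator's diameter ground truth is
#' analytic by construction. Occlusion removes a contiguous arc of angle
#' `2 pi * occlusion_frac` starting at a seeded random angle; inclination
#' tilts the ring plane about the x-axis; Gaussian noise (sd
#' `noise_sigma`) is added last.
#'
#' @param spec a [scene_spec()].
#' @return A list: `cloud` ([colored_point_cloud], `units = "mm"` in the
#'   generated world), `normal` (ring plane normal), `center` (c(0,0,0)).
#' @export
make_ring <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_preserved_rng(spec$seed, {
    n_pairs <- spec$ring_points %/% 2L
    theta <- 2 * pi * (seq_len(n_pairs) - 1L) / n_pairs
    delta <- stats::runif(n_pairs, 0, spec$annulus_width / 2)
    if (spec$occlusion_frac > 0) {
      start <- stats::runif(1, 0, 2 * pi)
      gap <- 2 * pi * spec$occlusion_frac
      rel <- (theta - start) %% (2 * pi)
      keep <- rel >= gap
      theta <- theta[keep]
      delta <- delta[keep]
    }
    r0 <- spec$d_true / 2
    radii <- c(r0 + delta, r0 - delta)
    ang <- c(theta, theta)
    pts <- cbind(radii * cos(ang), radii * sin(ang), 0)
    normal <- c(0, 0, 1)
    if (spec$inclination_deg != 0) {
      Rx <- rot_x(spec$inclination_deg)
      pts <- pts %*% t(Rx)
      normal <- as.numeric(Rx %*% normal)
    }
    if (spec$noise_sigma > 0) {
      pts <- pts + matrix(stats::rnorm(length(pts), 0, spec$noise_sigma),
                          ncol = 3L)
    }
    cols <- jittered_color(nrow(pts), 0, 0.85, 0.8, spec$color_jitter)
    list(cloud = colored_point_cloud(pts, cols, units = "mm"),
         normal = normal, center = c(0, 0, 0))
  })
}

#' Generate a stylized plant point cloud (generated-world mm)
#'
#' Plant kinds:
#' * `disk_leaf` — a vertical cylindrical stem (radius `stem_radius`,
#'   `stem_points` points; 0 for a stemless fixture) topped by one
#'   horizontal disk leaf of radius `leaf_radius` at `z = height`.
#' * `stem_and_leaves` — the stem plus `leaf_count` planar elliptical
#'   leaves (semi-axes `leaf_radius` and `0.6 * leaf_radius`) at evenly
#'   spread heights, tilted 30 degrees from horizontal at staggered
#'   azimuths.
#' * `box` — a solid axis-aligned box, footprint 100 x 100 mm, height
#'   `height`.
#' * `none` — empty cloud.
#'
#' Ground truth is analytic: exact top height, per-leaf areas
#' (`pi a b`), stem lateral area (`2 pi r h`), and for the box its
#' footprint area.
#'
#' @param spec a [scene_spec()].
#' @return A list: `cloud` (green-colored [colored_point_cloud]),
#'   `height`, `leaf_area` (leaves only), `surface_area` (leaves + stem
#'   lateral), `projection_area` (analytic where defined, else `NA`).
#' @export
make_plant <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  p <- spec$plant
  with_preserved_rng(spec$seed + 1L, {
    pts <- matrix(numeric(0), 0L, 3L)
    leaf_area <- 0
    stem_area <- 0
    proj <- NA_real_
    if (p$kind == "none") {
      # empty
    } else if (p$kind == "box") {
      n <- p$n_points
      pts <- cbind(stats::runif(n, -50, 50), stats::runif(n, -50, 50),
                   stats::runif(n, 0, p$height))
      proj <- 100 * 100
    } else {
      if (p$stem_points > 0L) {
        a <- stats::runif(p$stem_points, 0, 2 * pi)
        z <- stats::runif(p$stem_points, 0, p$height)
        pts <- rbind(pts, cbind(p$stem_radius * cos(a),
                                p$stem_radius * sin(a), z))
        stem_area <- 2 * pi * p$stem_radius * p$height
      }
      if (p$kind == "disk_leaf") {
        n <- p$n_points
        rr <- p$leaf_radius * sqrt(stats::runif(n))
        aa <- stats::runif(n, 0, 2 * pi)
        pts <- rbind(pts, cbind(rr * cos(aa), rr * sin(aa), p$height))
        leaf_area <- pi * p$leaf_radius^2
        if (p$stem_points == 0L) proj <- pi * p$leaf_radius^2
      } else {  # stem_and_leaves
        nl <- p$leaf_count
        per <- max(50L, p$n_points %/% nl)
        b <- 0.6 * p$leaf_radius
        tilt <- rot_x(30)
        for (i in seq_len(nl)) {
          u <- sqrt(stats::runif(per))
          aa <- stats::runif(per, 0, 2 * pi)
          ell <- cbind(p$leaf_radius * u * cos(aa), b * u * sin(aa), 0)
          # tilt from horizontal, then azimuth, then attach along the stem
          az <- 2 * pi * (i - 1) / nl
          Rz <- matrix(c(cos(az), sin(az), 0, -sin(az), cos(az), 0, 0, 0, 1),
                       3, 3)
          h_i <- p$height * (0.35 + 0.6 * (i - 1) / max(1L, nl - 1L))
          ctr <- as.numeric(Rz %*% c(p$leaf_radius, 0, 0))
          leaf <- sweep(ell %*% t(tilt) %*% t(Rz), 2L,
                        c(ctr[1], ctr[2], h_i), "+")
          pts <- rbind(pts, leaf)
          leaf_area <- leaf_area + pi * p$leaf_radius * b
        }
      }
    }
    # analytic top: box and disk_leaf peak at the nominal height; tilted
    # elliptical leaves rise half their semi-minor axis above the highest
    # attachment point (0.95 h)
    height <- switch(p$kind,
                     none = 0,
                     box = p$height,
                     disk_leaf = p$height,
                     stem_and_leaves = 0.95 * p$height +
                       0.5 * 0.6 * p$leaf_radius)
    if (spec$noise_sigma > 0 && nrow(pts)) {
      pts <- pts + matrix(stats::rnorm(length(pts), 0, spec$noise_sigma),
                          ncol = 3L)
    }
    cols <- jittered_color(nrow(pts), 120, 0.7, 0.55, spec$color_jitter)
    list(cloud = colored_point_cloud(pts, cols, units = "mm"),
         height = height, leaf_area = leaf_area,
         surface_area = leaf_area + stem_area, projection_area = proj)
  })
}

make_clutter <- function(spec) {
  if (!length(spec$clutter)) {
    return(colored_point_cloud(matrix(numeric(0), 0L, 3L), units = "mm"))
  }
  with_preserved_rng(spec$seed + 2L, {
    parts <- lapply(spec$clutter, function(cl) {
      n <- cl$n_points %||% 2000L
      size <- cl$size %||% 80
      ctr <- cl$center %||% c(3 * size, 0, size)
      kind <- cl$kind %||% "sphere"
      pts <- if (kind == "sphere") {
        v <- matrix(stats::rnorm(3 * n), ncol = 3L)
        v <- v / sqrt(rowSums(v^2))
        size * v
      } else {  # cube
        matrix(stats::runif(3 * n, -size / 2, size / 2), ncol = 3L)
      }
      sweep(pts, 2L, ctr, "+")
    })
    pts <- do.call(rbind, parts)
    cols <- jittered_color(nrow(pts), 0, 0.85, 0.8, spec$color_jitter)
    colored_point_cloud(pts, cols, units = "mm")
  })
}

#' Generate a full synthetic scene with ground truth
#'
#' Merges ring, plant and clutter in the generated world (mm), then
#' applies the spec's similarity `p -> s * R p + t` to every point —
#' emulating the arbitrary coordinate system of a monocular
#' reconstruction. The correct scale factor a calibration must recover is
#' therefore exactly `1 / s`.
#'
#' @param spec a [scene_spec()].
#' @return A list with `cloud` (the transformed scene,
#'   `units = "reconstruction"`) and `truth`, a `ground_truth` list:
#'   `labels` (`"ring"`/`"plant"`/`"clutter"` per point), ring `center`,
#'   `normal`, `diameter` (generated world), `plant_height`, `leaf_area`,
#'   `surface_area`, `projection_area`, `expected_scale` (= `1/s`), and
#'   the applied `similarity`.
#' @export
make_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  ring <- make_ring(spec)
  plant <- make_plant(spec)
  clutter <- make_clutter(spec)
  labels <- c(rep("ring", n_points(ring$cloud)),
              rep("plant", n_points(plant$cloud)),
              rep("clutter", n_points(clutter)))
  world <- merge_clouds(ring$cloud, plant$cloud, clutter)
  sim <- spec$similarity
  pts <- sim$s * (world$points %*% t(sim$R))
  pts <- sweep(pts, 2L, sim$t, "+")
  cloud <- structure(list(points = pts, colors = world$colors,
                          units = "reconstruction"),
                     class = "colored_point_cloud")
  truth <- structure(list(labels = labels, center = ring$center,
                          normal = ring$normal, diameter = spec$d_true,
                          plant_height = plant$height,
                          leaf_area = plant$leaf_area,
                          surface_area = plant$surface_area,
                          projection_area = plant$projection_area,
                          expected_scale = 1 / sim$s,
                          similarity = sim, spec = spec),
                     class = "ground_truth")
  list(cloud = cloud, truth = truth)
}

#' Random similarity transform
#'
#' Uniform random rotation (QR of a Gaussian matrix, sign-corrected to
#' det +1), a scale drawn log-uniformly from `scale_range`, and a
#' translation uniform in `[-t_max, t_max]^3` (in post-scale units).
#'
#' @param seed integer seed.
#' @param scale_range range for the log-uniform scale draw (default
#'   `c(0.01, 100)`).
#' @param t_max translation bound (default 1000).
#' @return `list(R, s, t)` suitable for [scene_spec()]'s `similarity`.
#' @export
random_similarity <- function(seed, scale_range = c(0.01, 100),
                              t_max = 1000) {
  with_preserved_rng(seed, {
    M <- matrix(stats::rnorm(9), 3, 3)
    qr_ <- qr(M)
    R <- qr.Q(qr_)
    R <- R %*% diag(sign(diag(qr.R(qr_))))
    if (det(R) < 0) R[, 3] <- -R[, 3]
    s <- exp(stats::runif(1, log(scale_range[1]), log(scale_range[2])))
    t <- stats::runif(3, -t_max, t_max)
    list(R = R, s = s, t = t)
  })
}

#' Synthetic growth sequence
#'
#' Scenes sharing one ring but with the plant scaled by a monotone factor
#' per step — the synthetic analogue of re-imaging a potted plant across
#' days after sowing. Each step draws fresh point samples from a seed
#' derived from `(base seed, step)`, so steps are independently
#' reproducible.
#'
#' @param base_spec a [scene_spec()]; its plant is scaled per step.
#' @param growth_factors monotone nondecreasing numeric vector, one entry
#'   per step.
#' @return List of [make_scene()] results, one per step.
#' @export
growth_sequence <- function(base_spec, growth_factors = seq(1, 2, length.out = 6)) {
  stopifnot(inherits(base_spec, "scene_spec"),
            !is.unsorted(growth_factors))
  lapply(seq_along(growth_factors), function(i) {
    g <- growth_factors[i]
    sp <- base_spec
    sp$plant$height <- base_spec$plant$height * g
    sp$plant$leaf_radius <- base_spec$plant$leaf_radius * g
    sp$plant$n_points <- as.integer(round(base_spec$plant$n_points * g))
    sp$seed <- base_spec$seed + 1000L * i
    sp <- do.call(scene_spec, unclass(sp))  # re-validate
    make_scene(sp)
  })
}

#' Write a scene and its ground truth to disk
#'
#' The cloud goes to PLY (double precision, so the similarity obfuscation
#' survives the round trip at any scale); the ground truth to a sidecar
#' JSON.
#'
#' @param scene a [make_scene()] result.
#' @param ply_path,truth_path output paths.
#' @return `ply_path`, invisibly.
#' @export
write_scene <- function(scene, ply_path, truth_path = NULL) {
  write_ply(scene$cloud, ply_path, binary = FALSE, precision = "double")
  if (!is.null(truth_path)) {
    tr <- scene$truth
    obj <- list(labels = tr$labels, center = tr$center, normal = tr$normal,
                diameter = tr$diameter, plant_height = tr$plant_height,
                leaf_area = tr$leaf_area, surface_area = tr$surface_area,
                expected_scale = tr$expected_scale,
                similarity = list(R = as.vector(t(tr$similarity$R)),
                                  s = tr$similarity$s, t = tr$similarity$t))
    jsonlite::write_json(obj, truth_path, digits = NA, auto_unbox = TRUE)
  }
  invisible(ply_path)
}
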