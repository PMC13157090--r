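#' Pipeline configuration
#'
#' Every tunable of the calibrate/apply/phenotype workflow in one nested
#' list, with documented defaults. Unknown keys are rejected (a typo in a
#' config file must not silently fall back to a default), and the full
#' effective configuration is echoed into every output artifact.
#'
#' Blocks:
#' * `d_true` — true ring diameter, mm (200).
#' * `color` — HSV thresholds for [segment_red()].
#' * `cluster` — [select_ring_cluster()] parameters (`eps = NULL` means
#'   scale-free: 2 x median nearest-neighbor distance of the red subset).
#' * `clean` — statistical-outlier removal of the ring cluster before the
#'   plane fit (`enabled` default `TRUE`; `k`, `sigma_mult`).
#' * `ransac` — `n_iter`, `inlier_tol` (`NULL` = adaptive: the larger of
#'   2% of the radius guess and 2.5 x the robust (MAD) radial spread, so
#'   a wide printed stroke is fitted to its centerline), `min_inlier_frac`,
#'   `seed`.
#' * `translate` — place the ring center at the world origin (`TRUE`).
#' * `traits` — percentiles and resolutions for [extract_report()].
#'
#' @param ... named overrides, e.g. `pipeline_config(d_true = 150,
#'   ransac = list(seed = 7))`. Nested lists are merged.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    d_true = 200,
    color = list(hue_low_1 = 0, hue_high_1 = 20, hue_low_2 = 340,
                 hue_high_2 = 360, sat_min = 0.4, val_min = 0.2),
    cluster = list(eps = NULL, min_cluster = 100L, planarity_max = 0.05,
                   annularity_max = 0.25),
    clean = list(enabled = TRUE, k = 8L, sigma_mult = 2),
    ransac = list(n_iter = 2000L, inlier_tol = NULL, min_inlier_frac = 0.3,
                  seed = 0L),
    translate = TRUE,
    traits = list(height_lo_pct = 0.1, height_hi_pct = 99.9, n_bins = 20L,
                  grid_res_mm = 2, voxel_mm = 5))
  overrides <- list(...)
  if (length(overrides) == 1L && is.null(names(overrides)) &&
      is.list(overrides[[1]])) {
    overrides <- overrides[[1]]
  }
  check_config_keys(overrides, defaults, "config")
  cfg <- utils::modifyList(defaults, overrides)
  structure(cfg, class = "pipeline_config")
}

check_config_keys <- function(given, known, path) {
  if (!length(given)) return(invisible())
  nm <- names(given)
  if (is.null(nm) || any(nm == "")) {
    stop_config(paste0("all entries under '", path, "' must be named"))
  }
  bad <- setdiff(nm, names(known))
  if (length(bad)) {
    stop_config(paste0("unknown config key(s) under '", path, "': ",
                       paste(bad, collapse = ", ")))
  }
  for (k in nm) {
    if (is.list(known[[k]]) && !is.null(names(known[[k]]))) {
      if (!is.list(given[[k]])) {
        stop_config(paste0("'", path, ".", k, "' must be a block"))
      }
      check_config_keys(given[[k]], known[[k]], paste0(path, ".", k))
    }
  }
  invisible()
}

stop_config <- function(msg) {
  stop(errorCondition(msg, class = c("ringcal_config", "ringcal_error")))
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file; keys mirror [pipeline_config()] and unknown keys
#'   are rejected.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop_config(paste0("config file not found: ", path))
  }
  obj <- yaml::read_yaml(path)
  if (is.null(obj)) obj <- list()
  pipeline_config(obj)
}

#' Calibrate a scene cloud: detect the ring and build the metric transform
#'
#' The full calibration chain on an in-memory cloud: color segmentation,
#' cluster selection, optional outlier cleaning of the ring cluster, PCA
#' plane frame, projection, RANSAC circle search, iterated geometric
#' least-squares refinement (the inlier set is recomputed about each
#' refined circle until it stabilizes), and assembly of the metric
#' transform using the known ring diameter.
#'
#' If `inlier_tol` is not set in the config, it defaults to
#' `max(0.02 * r_guess, 2.5 * mad(radial distances))` — wide enough that
#' the whole printed stroke of the ring counts as inlier, so the
#' refinement converges to the stroke centerline rather than an arbitrary
#' radial sub-band.
#'
#' @param cloud a [colored_point_cloud] in reconstruction units containing
#'   ring and plant.
#' @param config a [pipeline_config()].
#' @param plant_cloud optional pre-separated plant cloud used for the
#'   upward-normal disambiguation; by default the non-ring points of
#'   `cloud` are used.
#' @return A `calibration` list: `transform` ([build_metric_transform()]
#'   result), `ring` (the ring candidate), `frame`, `circle`, and
#'   `config` (the effective configuration).
#' @export
calibrate_cloud <- function(cloud, config = pipeline_config(),
                            plant_cloud = NULL) {
  stopifnot(inherits(cloud, "colored_point_cloud"),
            inherits(config, "pipeline_config"))
  thr <- do.call(color_thresholds, config$color)
  red <- segment_red(cloud, thr)
  cand <- select_ring_cluster(cloud, red,
                              eps = config$cluster$eps,
                              min_cluster = config$cluster$min_cluster,
                              planarity_max = config$cluster$planarity_max,
                              annularity_max = config$cluster$annularity_max)
  ring_raw <- subset_cloud(cloud, cand$indices)
  ring_cloud <- ring_raw
  if (isTRUE(config$clean$enabled) &&
      n_points(ring_cloud) > config$clean$k + 1L) {
    ring_cloud <- remove_statistical_outliers(ring_cloud, config$clean$k,
                                              config$clean$sigma_mult)
  }
  frame <- pca_frame(ring_cloud$points)
  # The cleaned subset stabilizes the plane estimate; the circle is then
  # fitted on every raw cluster point consistent with that plane (gated by
  # the robust out-of-plane spread), so no valid stroke point is wasted.
  w_clean <- sweep(ring_cloud$points, 2L, frame$origin) %*% frame$e3
  gate <- max(3 * stats::mad(w_clean),
              1e-7 * sqrt(max(frame$eigenvalues[1], 0)))
  w_raw <- sweep(ring_raw$points, 2L, frame$origin) %*% frame$e3
  fit_pool <- subset_cloud(ring_raw, abs(w_raw) <= gate)
  if (n_points(fit_pool) < 3L) fit_pool <- ring_cloud
  p2 <- project_to_plane(fit_pool$points, frame)
  tol <- config$ransac$inlier_tol
  if (is.null(tol)) {
    d_ctr <- sqrt(rowSums(sweep(p2, 2L, colMeans(p2))^2))
    tol <- max(0.02 * stats::median(d_ctr), 2.5 * stats::mad(d_ctr))
  }
  fit <- ransac_circle(p2, n_iter = config$ransac$n_iter, inlier_tol = tol,
                       min_inlier_frac = config$ransac$min_inlier_frac,
                       seed = config$ransac$seed)
  for (round in 1:5) {
    fit <- lsq_refine_circle(p2, fit$inlier_mask, fit)
    resid <- abs(sqrt((p2[, 1] - fit$center2d[1])^2 +
                        (p2[, 2] - fit$center2d[2])^2) - fit$radius)
    mask <- resid <= tol
    if (sum(mask) < 3L || identical(mask, fit$inlier_mask)) break
    fit$inlier_mask <- mask
  }
  if (is.null(plant_cloud)) {
    keep <- rep(TRUE, n_points(cloud))
    keep[cand$indices] <- FALSE
    plant_cloud <- subset_cloud(cloud, keep)
  }
  transform <- build_metric_transform(frame, fit, plant_cloud,
                                      d_true = config$d_true,
                                      translate = isTRUE(config$translate))
  structure(list(transform = transform, ring = cand, frame = frame,
                 circle = fit, config = config),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat("<calibration>\n  ring cluster:", x$ring$n_points, "points, planarity",
      signif(x$ring$planarity, 3), ", annularity",
      signif(x$ring$annularity, 3), "\n")
  print(x$transform)
  invisible(x)
}

# ---- command-level operations ---------------------------------------------

#' Pipeline commands
#'
#' File-to-file operations behind the command-line interface (see
#' `inst/cli/ringcal.R`). Each command reads and writes the formats named
#' in its arguments and raises classed conditions (`ringcal_no_ring`,
#' `ringcal_fit_failed`, `ringcal_config`) that the CLI maps to distinct
#' exit codes so that field batches can be triaged mechanically.
#'
#' * `cmd_calibrate` — scene PLY in, metric-transform JSON out (with the
#'   effective config and per-cluster diagnostics embedded).
#' * `cmd_apply` — plant PLY + transform JSON in, metric PLY out (the
#'   header carries a `units mm` comment).
#' * `cmd_phenotype` — metric PLY in, phenotype report JSON/CSV out.
#' * `cmd_simulate` — scene-spec YAML in, scene PLY + ground-truth JSON out.
#' * `cmd_run` — calibrate, apply to the non-ring points and phenotype in
#'   one pass.
#' * `cmd_sweep` — robustness-sweep YAML in, per-scene results CSV out.
#'
#' @param scene_ply,plant_ply,metric_ply,transform_json input paths.
#' @param out,out_dir output path / directory.
#' @param config a [pipeline_config()] or a YAML path.
#' @param csv,dist_csv optional extra outputs of `cmd_phenotype`.
#' @return The principal result of each command, invisibly
#'   (`cmd_calibrate`: the `calibration`; `cmd_apply`: the metric cloud;
#'   `cmd_phenotype`: the report; `cmd_simulate`: the scene;
#'   `cmd_run`: a list with all three; `cmd_sweep`: the results data
#'   frame).
#' @name pipeline_commands
NULL

as_config <- function(config) {
  if (inherits(config, "pipeline_config")) return(config)
  if (is.character(config)) return(read_config(config))
  if (is.list(config)) return(pipeline_config(config))
  stop_config("config must be a pipeline_config, a list, or a YAML path")
}

#' @rdname pipeline_commands
#' @export
cmd_calibrate <- function(scene_ply, out, config = pipeline_config()) {
  config <- as_config(config)
  cloud <- read_ply(scene_ply)
  cal <- calibrate_cloud(cloud, config)
  write_transform(cal$transform, out)
  # sidecar diagnostics as a JSON log block
  diag <- list(config = unclass(config),
               ring_cluster = list(n_points = cal$ring$n_points,
                                   planarity = cal$ring$planarity,
                                   annularity = cal$ring$annularity),
               clusters = cal$ring$diagnostics,
               rms_residual = cal$circle$rms_residual)
  message(jsonlite::toJSON(diag, digits = 10, auto_unbox = TRUE,
                           dataframe = "rows"))
  invisible(cal)
}

#' @rdname pipeline_commands
#' @export
cmd_apply <- function(plant_ply, transform_json, out) {
  cloud <- read_ply(plant_ply)
  transform <- read_transform(transform_json)
  metric <- apply_transform(cloud, transform)
  write_ply(metric, out, binary = FALSE, precision = "double")
  invisible(metric)
}

#' @rdname pipeline_commands
#' @export
cmd_phenotype <- function(metric_ply, out, config = pipeline_config(),
                          csv = NULL, dist_csv = NULL) {
  config <- as_config(config)
  cloud <- read_ply(metric_ply)
  if (n_points(cloud) == 0L) {
    stop("metric cloud is empty; nothing to phenotype", call. = FALSE)
  }
  if (cloud$units != "mm") {
    warning("input PLY lacks the 'units mm' comment; assuming metric",
            call. = FALSE)
    cloud$units <- "mm"
  }
  report <- extract_report(cloud, config)
  write_report(report, out, csv_path = csv, dist_csv_path = dist_csv)
  invisible(report)
}

#' @rdname pipeline_commands
#' @param spec_yaml scene-spec YAML for `cmd_simulate`; keys mirror
#'   [scene_spec()] (the `similarity` block as `R` row-major, `s`, `t`;
#'   `seed` is mandatory).
#' @param truth_json ground-truth sidecar path for `cmd_simulate`.
#' @export
cmd_simulate <- function(spec_yaml, out, truth_json = NULL) {
  if (!file.exists(spec_yaml)) {
    stop_config(paste0("scene spec not found: ", spec_yaml))
  }
  obj <- yaml::read_yaml(spec_yaml)
  if (is.null(obj$seed)) stop_config("scene spec must set 'seed'")
  if (!is.null(obj$similarity)) {
    sim <- obj$similarity
    if (!is.null(sim$R)) sim$R <- matrix(unlist(sim$R), 3, 3, byrow = TRUE)
    obj$similarity <- utils::modifyList(
      list(R = diag(3), s = 1, t = c(0, 0, 0)), sim)
  }
  spec <- tryCatch(do.call(scene_spec, obj), error = function(e) {
    stop_config(paste0("invalid scene spec: ", conditionMessage(e)))
  })
  scene <- make_scene(spec)
  write_scene(scene, out, truth_json)
  invisible(scene)
}

#' @rdname pipeline_commands
#' @export
cmd_run <- function(scene_ply, out_dir, config = pipeline_config()) {
  config <- as_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cloud <- read_ply(scene_ply)
  cal <- calibrate_cloud(cloud, config)
  write_transform(cal$transform, file.path(out_dir, "transform.json"))
  keep <- rep(TRUE, n_points(cloud))
  keep[cal$ring$indices] <- FALSE
  plant <- subset_cloud(cloud, keep)
  metric <- apply_transform(plant, cal$transform)
  write_ply(metric, file.path(out_dir, "metric.ply"), binary = FALSE,
            precision = "double")
  report <- extract_report(metric, config)
  write_report(report, file.path(out_dir, "report.json"),
               csv_path = file.path(out_dir, "report.csv"),
               dist_csv_path = file.path(out_dir, "vertical_distribution.csv"))
  invisible(list(calibration = cal, metric = metric, report = report))
}
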