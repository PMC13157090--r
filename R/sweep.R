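#' Robustness sweep over scene perturbations
#'
#' Full-factorial sweep over the four robustness axes — coordinate noise,
#' contiguous arc occlusion, ring inclination and red clutter — plus an
#' illumination (brightness-shift) axis, each crossed with `replicates`
#' seeds. Every generated scene is pushed through the full calibration;
#' single-scene failures are recorded in their row, never aborting the
#' sweep.
#'
#' @param factors named list of factor levels; recognized names:
#'   `noise_sigma` (mm), `occlusion_frac`, `inclination_deg`, `clutter`
#'   (logical: add a red sphere distractor of the ring's point count),
#'   `val_shift` (brightness offset applied to the generated colors).
#'   Missing factors sit at their [scene_spec()] defaults.
#' @param replicates seeds per factor combination (default 5).
#' @param base_seed first seed (default 1); scene `i` of a combination
#'   uses `base_seed + i - 1` and a fresh random similarity derived from
#'   the same seed.
#' @param base_spec template [scene_spec()] supplying everything the
#'   factors do not vary.
#' @param config a [pipeline_config()].
#' @return A data frame, one row per scene: factor levels, `seed`,
#'   `success`, `failure` (condition class on failure), `scale_rel_error`,
#'   `normal_error_deg`, `height_rel_error` (plant height from ground
#'   truth; NA where the scene has no plant or calibration failed).
#' @export
run_sweep <- function(factors = list(), replicates = 5L, base_seed = 1L,
                      base_spec = scene_spec(), config = pipeline_config()) {
  stopifnot(inherits(base_spec, "scene_spec"),
            inherits(config, "pipeline_config"))
  known <- c("noise_sigma", "occlusion_frac", "inclination_deg", "clutter",
             "val_shift")
  bad <- setdiff(names(factors), known)
  if (length(bad)) {
    stop_config(paste0("unknown sweep factor(s): ",
                       paste(bad, collapse = ", ")))
  }
  cols <- c(known, "seed", "success", "failure", "scale_rel_error",
            "normal_error_deg", "height_rel_error")
  if (length(factors) && any(lengths(factors) == 0L)) {
    stop_config("sweep factors must have at least one level each")
  }
  grid <- if (length(factors)) {
    do.call(expand.grid, c(factors, KEEP.OUT.ATTRS = FALSE,
                           stringsAsFactors = FALSE))
  } else data.frame(row.names = 1L)
  rows <- list()
  for (g in seq_len(max(1L, nrow(grid)))) {
    for (rep_i in seq_len(replicates)) {
      seed <- base_seed + (g - 1L) * replicates + rep_i - 1L
      sp <- unclass(base_spec)
      lev <- if (nrow(grid)) as.list(grid[g, , drop = FALSE]) else list()
      if (!is.null(lev$noise_sigma)) sp$noise_sigma <- lev$noise_sigma
      if (!is.null(lev$occlusion_frac)) sp$occlusion_frac <- lev$occlusion_frac
      if (!is.null(lev$inclination_deg)) {
        sp$inclination_deg <- lev$inclination_deg
      }
      if (isTRUE(lev$clutter)) {
        sp$clutter <- list(list(kind = "sphere", size = 80,
                                center = c(450, 0, 80),
                                n_points = sp$ring_points))
      }
      if (!is.null(lev$val_shift)) {
        sp$color_jitter$val_shift <- lev$val_shift
      }
      sp$seed <- seed
      sp$similarity <- random_similarity(seed, scale_range = c(0.1, 10),
                                         t_max = 500)
      spec <- do.call(scene_spec, sp)
      scene <- make_scene(spec)
      res <- tryCatch(list(cal = calibrate_cloud(scene$cloud, config)),
                      error = function(e) list(err = e))
      row <- list(noise_sigma = spec$noise_sigma,
                  occlusion_frac = spec$occlusion_frac,
                  inclination_deg = spec$inclination_deg,
                  clutter = length(spec$clutter) > 0L,
                  val_shift = spec$color_jitter$val_shift,
                  seed = seed, success = is.null(res$err),
                  failure = NA_character_,
                  scale_rel_error = NA_real_,
                  normal_error_deg = NA_real_,
                  height_rel_error = NA_real_)
      if (is.null(res$err)) {
        err <- sweep_errors(res$cal, scene, config)
        row[names(err)] <- err
      } else {
        row$failure <- class(res$err)[1]
      }
      rows[[length(rows) + 1L]] <- as.data.frame(row)
    }
  }
  if (!length(rows)) {
    return(stats::setNames(
      as.data.frame(matrix(nrow = 0L, ncol = length(cols))), cols))
  }
  do.call(rbind, rows)
}

sweep_errors <- function(cal, scene, config) {
  truth <- scene$truth
  s_rec <- cal$transform$s
  scale_rel_error <- abs(s_rec - truth$expected_scale) / truth$expected_scale
  # recovered up-axis in reconstruction coordinates is the third column of
  # the stored rotation (z_world pulled back through R^T)
  up_rec <- cal$transform$R[, 3]
  up_true <- as.numeric(truth$similarity$R %*% truth$normal)
  cosang <- abs(sum(up_rec * up_true)) /
    (sqrt(sum(up_rec^2)) * sqrt(sum(up_true^2)))
  normal_error_deg <- acos(min(1, cosang)) * 180 / pi
  height_rel_error <- NA_real_
  if (truth$plant_height > 0 && any(truth$labels == "plant")) {
    plant <- subset_cloud(scene$cloud, truth$labels == "plant")
    metric <- apply_transform(plant, cal$transform)
    h <- plant_height(metric, config$traits$height_lo_pct,
                      config$traits$height_hi_pct)
    height_rel_error <- abs(h - truth$plant_height) / truth$plant_height
  }
  list(scale_rel_error = scale_rel_error,
       normal_error_deg = normal_error_deg,
       height_rel_error = height_rel_error)
}

#' @rdname pipeline_commands
#' @param sweep_yaml sweep configuration YAML for `cmd_sweep`: top-level
#'   keys `factors` (named lists of levels), `replicates`, `base_seed`,
#'   plus optional `scene` ([scene_spec()] overrides) and `config`
#'   ([pipeline_config()] overrides).
#' @export
cmd_sweep <- function(sweep_yaml, out) {
  if (!file.exists(sweep_yaml)) {
    stop_config(paste0("sweep config not found: ", sweep_yaml))
  }
  obj <- yaml::read_yaml(sweep_yaml)
  if (is.null(obj)) obj <- list()
  known <- c("factors", "replicates", "base_seed", "scene", "config")
  bad <- setdiff(names(obj), known)
  if (length(bad)) {
    stop_config(paste0("unknown sweep key(s): ", paste(bad, collapse = ", ")))
  }
  base_spec <- if (is.null(obj$scene)) scene_spec() else
    do.call(scene_spec, obj$scene)
  config <- pipeline_config(obj$config %||% list())
  res <- run_sweep(factors = obj$factors %||% list(),
                   replicates = obj$replicates %||% 5L,
                   base_seed = obj$base_seed %||% 1L,
                   base_spec = base_spec, config = config)
  utils::write.csv(res, out, row.names = FALSE)
  invisible(res)
}
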