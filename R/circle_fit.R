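#' @title Circle fitting in the ring plane
#' @description After the ring cloud is projected onto its PCA plane, the
#'   ring diameter is estimated by a two-stage 2D circle fit: RANSAC over
#'   3-point hypotheses finds an initial circle robustly, then a geometric
#'   (orthogonal-distance) least-squares refinement on the inliers yields
#'   the high-precision radius from which the scale factor is computed.
#' @name circle_fitting
NULL

# Algebraic (Kasa) circle fit: linear least squares on
# x^2 + y^2 + a x + b y + c = 0. Biased on noisy partial arcs but an
# excellent, closed-form initializer; exact on noiseless arcs.
kasa_circle <- function(points2d) {
  x <- points2d[, 1]; y <- points2d[, 2]
  A <- cbind(x, y, 1)
  b <- -(x^2 + y^2)
  sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (is.null(sol)) return(list(center = colMeans(points2d), radius = NA_real_))
  cx <- -sol[1] / 2; cy <- -sol[2] / 2
  r2 <- cx^2 + cy^2 - sol[3]
  list(center = c(cx, cy), radius = if (r2 > 0) sqrt(r2) else NA_real_)
}

# Circumcircle of three 2D points; NULL if (near-)collinear.
circumcircle <- function(p1, p2, p3) {
  ax <- p1[1]; ay <- p1[2]; bx <- p2[1]; by <- p2[2]; cx <- p3[1]; cy <- p3[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  scale <- max(abs(c(ax, ay, bx, by, cx, cy)), 1)
  if (abs(d) < 1e-12 * scale^2) return(NULL)
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  list(center = c(ux, uy), radius = sqrt((ax - ux)^2 + (ay - uy)^2))
}

new_circle_fit <- function(center, radius, inlier_mask, rms_residual,
                           converged = TRUE) {
  structure(list(center2d = as.numeric(center),
                 radius = as.numeric(radius),
                 d_fitted = 2 * as.numeric(radius),
                 inlier_mask = inlier_mask,
                 rms_residual = as.numeric(rms_residual),
                 converged = converged),
            class = "circle_fit")
}

#' @export
print.circle_fit <- function(x, ...) {
  cat(sprintf(
    "<circle_fit> center (%.6g, %.6g), r = %.6g (D = %.6g), %d/%d inliers, rms = %.3g\n",
    x$center2d[1], x$center2d[2], x$radius, x$d_fitted,
    sum(x$inlier_mask), length(x$inlier_mask), x$rms_residual))
  invisible(x)
}

#' Robust circle search by RANSAC
#'
#' Draws `n_iter` random 3-point samples, scores each circumcircle by the
#' number of points within `inlier_tol` of it (ties broken by lower RMS
#' inlier residual) and returns the best hypothesis. Deterministic given
#' `seed`; the caller's RNG state is left untouched.
#'
#' @param points2d M x 2 matrix of plane coordinates.
#' @param n_iter number of hypotheses (default 2000).
#' @param inlier_tol absolute distance-to-circle tolerance, same units as
#'   `points2d`. `NULL` (default) uses 2% of the initial radius guess (the
#'   median distance of the points to their centroid) — callers fitting a
#'   ring with a wide printed stroke should pass a tolerance that covers
#'   the stroke (see [calibrate_cloud()]).
#' @param min_inlier_frac minimum acceptable inlier fraction (default 0.3,
#'   tolerant of heavy occlusion); below it the fit fails.
#' @param seed integer RNG seed (default 0).
#' @return A `circle_fit` object (center, radius, diameter `d_fitted`,
#'   inlier mask, RMS inlier residual).
#' @export
ransac_circle <- function(points2d, n_iter = 2000L, inlier_tol = NULL,
                          min_inlier_frac = 0.3, seed = 0L) {
  points2d <- as.matrix(points2d)
  m <- nrow(points2d)
  if (m < 3L) stop("need at least 3 points to fit a circle", call. = FALSE)
  ctr <- colMeans(points2d)
  d_ctr <- sqrt((points2d[, 1] - ctr[1])^2 + (points2d[, 2] - ctr[2])^2)
  r_guess <- stats::median(d_ctr)
  if (is.null(inlier_tol)) inlier_tol <- 0.02 * r_guess
  x <- points2d[, 1]; y <- points2d[, 2]
  best <- NULL
  with_preserved_rng(seed, {
    samples <- matrix(0L, n_iter, 3L)
    for (it in seq_len(n_iter)) samples[it, ] <- sample.int(m, 3L)
    for (it in seq_len(n_iter)) {
      s <- samples[it, ]
      cc <- circumcircle(points2d[s[1], ], points2d[s[2], ], points2d[s[3], ])
      if (is.null(cc)) next
      resid <- abs(sqrt((x - cc$center[1])^2 + (y - cc$center[2])^2) -
                     cc$radius)
      mask <- resid <= inlier_tol
      n_in <- sum(mask)
      if (n_in < 3L) next
      rms <- sqrt(mean(resid[mask]^2))
      if (is.null(best) || n_in > best$n_in ||
          (n_in == best$n_in && rms < best$rms)) {
        best <- list(center = cc$center, radius = cc$radius,
                     mask = mask, n_in = n_in, rms = rms)
      }
    }
  })
  if (is.null(best)) {
    stop_fit_failed("no valid 3-point circle hypothesis found",
                    best_fraction = 0)
  }
  frac <- best$n_in / m
  if (frac < min_inlier_frac) {
    stop_fit_failed(sprintf(
      "best inlier fraction %.3f < min_inlier_frac %.3f", frac,
      min_inlier_frac), best_fraction = frac)
  }
  new_circle_fit(best$center, best$radius, best$mask, best$rms)
}

#' Geometric least-squares circle refinement
#'
#' Gauss-Newton minimization of the sum of squared radial residuals
#' `sum((||p - c|| - r)^2)` over the inliers only, initialized at `init`
#' (typically the RANSAC result; a Kasa algebraic fit is used as fallback
#' initializer if `init` carries no radius). Geometric — as opposed to
#' algebraic — least squares is unbiased on partial arcs, which is what
#' makes the fit robust to heavy ring occlusion. The returned objective is
#' never worse than the initialization (steps are halved until the
#' objective decreases).
#'
#' @param points2d M x 2 matrix of plane coordinates.
#' @param inlier_mask logical vector selecting the points to fit (>= 3).
#' @param init a `circle_fit` to initialize from.
#' @param max_iter Gauss-Newton iteration cap (default 100).
#' @param tol relative step/objective convergence tolerance (default 1e-14).
#' @return A refined `circle_fit`; `converged = FALSE` flags hitting
#'   `max_iter`, in which case the best iterate is returned with a warning.
#' @export
lsq_refine_circle <- function(points2d, inlier_mask, init,
                              max_iter = 100L, tol = 1e-14) {
  points2d <- as.matrix(points2d)
  stopifnot(length(inlier_mask) == nrow(points2d))
  pts <- points2d[inlier_mask, , drop = FALSE]
  if (nrow(pts) < 3L) stop("need at least 3 inliers", call. = FALSE)
  if (inherits(init, "circle_fit") && is.finite(init$radius) &&
      init$radius > 0) {
    par <- c(init$center2d, init$radius)
  } else {
    k <- kasa_circle(pts)
    if (!is.finite(k$radius)) {
      stop("degenerate inlier set: cannot initialize circle", call. = FALSE)
    }
    par <- c(k$center, k$radius)
  }
  objective <- function(par) {
    d <- sqrt((pts[, 1] - par[1])^2 + (pts[, 2] - par[2])^2)
    sum((d - par[3])^2)
  }
  f <- objective(par)
  scale0 <- max(abs(par), 1e-12)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    dx <- pts[, 1] - par[1]; dy <- pts[, 2] - par[2]
    d <- sqrt(dx^2 + dy^2)
    d[d < 1e-300] <- 1e-300
    r <- d - par[3]
    J <- cbind(-dx / d, -dy / d, -1)
    step <- tryCatch(qr.solve(J, -r), error = function(e) NULL)
    if (is.null(step)) break
    # damped acceptance: never move uphill
    lam <- 1
    repeat {
      cand <- par + lam * step
      fc <- objective(cand)
      if (fc <= f || lam < 1e-8) break
      lam <- lam / 2
    }
    if (fc > f) break
    moved <- sqrt(sum((lam * step)^2))
    par <- cand
    if (f - fc <= tol * max(f, 1e-300) && moved <= tol * scale0) {
      f <- fc
      converged <- TRUE
      break
    }
    f <- fc
    if (moved <= 1e-15 * scale0) { converged <- TRUE; break }
  }
  if (!converged && max_iter > 1L) {
    warning("circle refinement stopped before full convergence",
            call. = FALSE)
  }
  resid_all <- abs(sqrt((points2d[, 1] - par[1])^2 +
                          (points2d[, 2] - par[2])^2) - par[3])
  rms <- sqrt(mean(resid_all[inlier_mask]^2))
  new_circle_fit(par[1:2], par[3], inlier_mask, rms, converged = converged)
}

# Evaluate a block of code with a fixed seed, restoring the caller's RNG.
with_preserved_rng <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
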