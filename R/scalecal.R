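#' Triangulate a marker from multiple posed observations
#'
#' Least-squares ray intersection: each observation back-projects to a ray
#' from its camera center; the returned point minimizes the sum of squared
#' perpendicular distances to all rays. Mirrors the manual step of placing
#' ruler markers in a few of the capture photos.
#'
#' @param observations tibble/data.frame with `image_id`, `u`, `v` (pixel
#'   coordinates) — at least 2 rows from distinct poses.
#' @param poses named list of [camera_pose] objects keyed by image id, in the
#'   scene units the reconstruction uses (model units).
#' @param condition_max reject near-parallel ray bundles whose normal-equation
#'   condition number exceeds this (default 1e8).
#' @return list with `point` (length-3, model units), `residual_px` (mean
#'   reprojection error) and `n_views`.
#' @export
triangulate_marker <- function(observations, poses, condition_max = 1e8) {
  observations <- as.data.frame(observations)
  if (nrow(observations) < 2)
    stop("triangulation error: need at least 2 observations")
  A <- matrix(0, 3, 3)
  b <- numeric(3)
  used <- list()
  for (i in seq_len(nrow(observations))) {
    pose <- poses[[observations$image_id[i]]]
    if (is.null(pose)) stop("no pose for image ", observations$image_id[i])
    d_cam <- c((observations$u[i] - pose$cx) / pose$fx,
               (observations$v[i] - pose$cy) / pose$fy, 1)
    d <- as.vector(t(pose$rotation) %*% d_cam)
    d <- d / sqrt(sum(d^2))
    cpos <- -as.vector(t(pose$rotation) %*% pose$translation)
    P <- diag(3) - tcrossprod(d)
    A <- A + P
    b <- b + as.vector(P %*% cpos)
    used[[i]] <- pose
  }
  cond <- kappa(A, exact = TRUE)
  if (!is.finite(cond) || cond > condition_max)
    stop("triangulation error: near-parallel rays (condition number ",
         format(cond, digits = 3), ")")
  point <- solve(A, b)
  # mean reprojection residual
  resid <- vapply(seq_len(nrow(observations)), function(i) {
    pr <- project_points(used[[i]], point)
    sqrt((pr$u - observations$u[i])^2 + (pr$v - observations$v[i])^2)
  }, numeric(1))
  list(point = point, residual_px = mean(resid), n_views = nrow(observations))
}

#' Solve the model-to-millimeter scale from two triangulated markers
#'
#' @param marker_a,marker_b length-3 triangulated marker positions (model
#'   units).
#' @param known_length_mm physical separation of the markers on the ruler.
#' @param residual_px optional mean reprojection residual to carry into the
#'   solution.
#' @return A `scale_solution`: `factor` (mm per model unit),
#'   `marker_points_3d`, `residual_px`.
#' @export
solve_scale <- function(marker_a, marker_b, known_length_mm, residual_px = 0) {
  if (known_length_mm <= 0) stop("known_length_mm must be positive")
  d <- sqrt(sum((marker_a - marker_b)^2))
  if (d < 1e-12) stop("degenerate-scale error: coincident marker points")
  structure(list(factor = known_length_mm / d,
                 marker_points_3d = rbind(A = marker_a, B = marker_b),
                 residual_px = residual_px),
            class = "scale_solution")
}

#' @export
print.scale_solution <- function(x, ...) {
  cat(sprintf("<scale_solution> %.6g mm/unit (residual %.3g px)\n",
              x$factor, x$residual_px))
  invisible(x)
}

#' Rescale a mesh to physical millimeters
#' @param mesh a [trimesh] in model units.
#' @param solution a `scale_solution` (or a bare positive factor).
#' @return The mesh with vertices multiplied by the factor and units set to
#'   `"mm"`.
#' @export
apply_scale <- function(mesh, solution) {
  stopifnot_trimesh(mesh)
  factor <- if (inherits(solution, "scale_solution")) solution$factor else solution
  if (!is.numeric(factor) || factor <= 0) stop("scale factor must be positive")
  out <- mesh
  out$vertices <- mesh$vertices * factor
  out$units <- "mm"
  out
}

#' Calibrate scale from a capture's ruler annotations
#'
#' Emulates placing markers on the ruler in a few photos: picks `n_views`
#' images spread over the turntable schedule, triangulates both ruler
#' endpoints and solves for mm-per-model-unit.
#'
#' @param capture a `turntable_capture` with ruler annotations.
#' @param n_views number of photos to mark (3-5 is typical practice; default
#'   4).
#' @param noise_px optional Gaussian pixel noise added to the marker clicks
#'   (emulating manual placement), with `seed`.
#' @param seed seed for the click noise.
#' @param report_path optional path to write the calibration report JSON.
#' @return A `scale_solution`.
#' @export
calibrate_scale <- function(capture, n_views = 4L, noise_px = 0, seed = 1L,
                            report_path = NULL) {
  stopifnot(inherits(capture, "turntable_capture"))
  ann <- capture$ruler$annotations
  if (is.null(ann)) stop("capture has no ruler annotations")
  ids_avail <- unique(ann$image_id)
  # view choice mimics the operator: prefer photos where the ruler is seen
  # clearly (large projected endpoint separation) while keeping wide
  # triangulation baselines (greedy azimuth spacing)
  sep <- vapply(ids_avail, function(id) {
    a <- ann[ann$image_id == id, , drop = FALSE]
    if (nrow(a) < 2) return(0)
    sqrt(diff(a$u)^2 + diff(a$v)^2)
  }, numeric(1))
  azim <- capture$schedule$azimuth_deg[match(ids_avail, capture$schedule$id)]
  spacing <- max(30, 300 / n_views)
  pick <- character(0)
  repeat {
    for (i in order(-sep, ids_avail)) {
      if (length(pick) >= n_views) break
      if (ids_avail[i] %in% pick) next
      gaps <- vapply(match(pick, ids_avail), function(j) {
        d <- abs(azim[i] - azim[j]); min(d, 360 - d)
      }, numeric(1))
      if (!length(gaps) || all(gaps >= spacing)) pick <- c(pick, ids_avail[i])
    }
    if (length(pick) >= n_views || spacing <= 1) break
    spacing <- spacing / 2
  }
  obs <- ann[ann$image_id %in% pick, , drop = FALSE]
  if (noise_px > 0) {
    rng <- local_rng(seed)
    obs$u <- obs$u + rng$rnorm(nrow(obs), 0, noise_px)
    obs$v <- obs$v + rng$rnorm(nrow(obs), 0, noise_px)
  }
  poses <- capture$poses
  names(poses) <- capture$ids
  ta <- triangulate_marker(obs[obs$marker_id == "ruler_A", ], poses)
  tb <- triangulate_marker(obs[obs$marker_id == "ruler_B", ], poses)
  sol <- solve_scale(ta$point, tb$point, capture$ruler$length_mm,
                     residual_px = mean(c(ta$residual_px, tb$residual_px)))
  if (!is.null(report_path))
    jsonlite::write_json(list(factor_mm_per_unit = sol$factor,
                              residual_px = sol$residual_px,
                              n_views = n_views,
                              marker_points = as.data.frame(sol$marker_points_3d)),
                         report_path, auto_unbox = TRUE, digits = NA)
  sol
}

#' Read marker observations from CSV
#'
#' Expected columns: `marker_id`, `image_id`, `u`, `v`.
#' @param path CSV path.
#' @return tibble of observations.
#' @export
read_marker_observations <- function(path) {
  df <- utils::read.csv(path)
  need <- c("marker_id", "image_id", "u", "v")
  if (!all(need %in% names(df)))
    stop("marker CSV must have columns: ", paste(need, collapse = ", "))
  tibble::as_tibble(df)
}
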