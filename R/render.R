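#' Camera poses
#'
#' A `camera_pose` holds pinhole intrinsics (focal lengths and principal point
#' in pixels) and world-to-camera extrinsics: `x_cam = R x_world + t`, camera
#' looking along +z, image u = fx*x/z + cx, v = fy*y/z + cy (v grows downward).
#'
#' @param rotation 3 x 3 world-to-camera rotation (orthonormal, det +1 within
#'   1e-8).
#' @param translation length-3 translation (scene units).
#' @param fx,fy,cx,cy pinhole intrinsics in pixels.
#' @param width,height image size in pixels.
#' @export
camera_pose <- function(rotation, translation, fx, fy, cx, cy, width, height) {
  rotation <- as.matrix(rotation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8 ||
      abs(det(rotation) - 1) > 1e-8)
    stop("rotation must be orthonormal with determinant +1")
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 fx = fx, fy = fy, cx = cx, cy = cy,
                 width = as.integer(width), height = as.integer(height)),
            class = "camera_pose")
}

# pose looking from `eye` toward `target`, world +z as up reference
look_at_pose <- function(eye, target, fx, fy, cx, cy, width, height) {
  fwd <- target - eye
  fwd <- fwd / sqrt(sum(fwd^2))
  up <- c(0, 0, 1)
  right <- c(fwd[2] * up[3] - fwd[3] * up[2],
             fwd[3] * up[1] - fwd[1] * up[3],
             fwd[1] * up[2] - fwd[2] * up[1])
  rn <- sqrt(sum(right^2))
  if (rn < 1e-9) stop("degenerate view direction (parallel to up)")
  right <- right / rn
  down <- c(fwd[2] * right[3] - fwd[3] * right[2],
            fwd[3] * right[1] - fwd[1] * right[3],
            fwd[1] * right[2] - fwd[2] * right[1])
  R <- rbind(right, down, fwd)
  dimnames(R) <- NULL
  camera_pose(R, -as.vector(R %*% eye), fx, fy, cx, cy, width, height)
}

#' Project world points through a camera pose
#' @param pose a [camera_pose].
#' @param points n x 3 matrix (or length-3 vector) in the pose's scene units.
#' @return tibble with `u`, `v` (pixels) and `z` (camera depth); points behind
#'   the camera get `NA` pixels.
#' @export
project_points <- function(pose, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  pc <- sweep(points %*% t(pose$rotation), 2, pose$translation, "+")
  ok <- pc[, 3] > 1e-9
  u <- ifelse(ok, pose$fx * pc[, 1] / pc[, 3] + pose$cx, NA_real_)
  v <- ifelse(ok, pose$fy * pc[, 2] / pc[, 3] + pose$cy, NA_real_)
  tibble::tibble(u = u, v = v, z = ifelse(ok, pc[, 3], NA_real_))
}

#' Reference color chart
#'
#' The synthetic stand-in for the physical chart photographed with each
#' specimen. Chips are matte sRGB references; `gray_75` is the neutral 75%
#' gray chip used for exposure/white-balance standardization.
#'
#' @return tibble with `chip`, `r`, `g`, `b` (sRGB in `[0,1]`).
#' @export
chart_reference <- function() {
  tibble::tribble(
    ~chip,      ~r,   ~g,   ~b,
    "white",    0.95, 0.95, 0.95,
    "gray_75",  0.75, 0.75, 0.75,
    "gray_50",  0.50, 0.50, 0.50,
    "gray_25",  0.25, 0.25, 0.25,
    "red",      0.70, 0.25, 0.20,
    "green",    0.25, 0.60, 0.30,
    "blue",     0.25, 0.35, 0.70)
}

render_lights <- function() {
  # two softboxes riding with the camera, slightly left/right and above;
  # with ambient 0.7208 + diffuse 0.34 the shade of a camera-facing surface
  # is exactly 1 (0.7208 + 0.34 / |(0.6, 0.35, 1)| = 1), emulating the even,
  # exposure-standardized studio lighting of a capture rig
  l1 <- c(-0.6, -0.35, -1); l2 <- c(0.6, -0.35, -1)
  rbind(l1 / sqrt(sum(l1^2)), l2 / sqrt(sum(l2^2)))
}

#' Render a synthetic turntable capture
#'
#' Rasterizes the specimen over a uniform backdrop from a full turntable
#' schedule (`round(360/step_deg)` azimuths per elevation), with exactly known
#' pinhole poses, flat Lambertian shading from two camera-riding lights, an
#' overlaid color chart, a ruler of known physical length with per-image pixel
#' annotations of its endpoints, and (optionally) a seeded per-image
#' gain/color-cast perturbation for the standardization stage to correct.
#' Ground-truth silhouette masks are kept alongside the images; they are test
#' oracles, never pipeline inputs.
#'
#' Scene units: the specimen mesh is in mm; poses, ruler endpoints and the
#' poses CSV are stored in *model units* (`model_scale` units per mm),
#' emulating the arbitrary scale of a photogrammetric reconstruction. Pixel
#' content is invariant to `model_scale`; the capture records
#' `true_factor_mm_per_unit = 1/model_scale` as the scale-calibration truth.
#'
#' @param truth a `specimen_truth` from [generate_specimen()].
#' @param step_deg turntable step in degrees (must tile 360).
#' @param elevations_deg camera elevations in degrees.
#' @param include_chart,include_ruler render the chart overlay / ruler.
#' @param backdrop_rgb sRGB backdrop color.
#' @param image_size square image size in pixels (>= 256).
#' @param seed integer seed for the photometric perturbation.
#' @param perturb apply the seeded gain/color-cast perturbation.
#' @param model_scale model units per mm for pose/ruler bookkeeping.
#' @param ruler_length_mm physical separation of the two ruler markers.
#' @param out_dir optional directory: writes numbered PNGs, silhouettes, a
#'   poses CSV and a truth JSON, and the capture then references files rather
#'   than keeping rasters in memory. Captures too large to hold in memory are
#'   spilled to a temporary directory automatically.
#' @return A `turntable_capture` object.
#' @export
render_turntable <- function(truth, step_deg = 3.75,
                             elevations_deg = c(-45, 0, 45),
                             include_chart = TRUE, include_ruler = TRUE,
                             backdrop_rgb = c(0.72, 0.80, 0.88),
                             image_size = 256L, seed = 1L, perturb = TRUE,
                             model_scale = 1, ruler_length_mm = 50,
                             out_dir = NULL) {
  stopifnot(inherits(truth, "specimen_truth"))
  if (step_deg <= 0) stop("step_deg must be positive")
  n_steps <- round(360 / step_deg)
  if (abs(n_steps * step_deg - 360) > 1e-6)
    stop("step_deg must tile the circle: round(360/step_deg) * step_deg != 360")
  if (image_size < 256) stop("image_size must be >= 256")

  mesh <- truth$mesh
  center <- colMeans(mesh$vertices)
  ext <- max(apply(mesh$vertices, 2, function(c) diff(range(c))))
  dist <- 2.4 * ext
  fx <- fy <- 1.2 * image_size
  cx <- cy <- image_size / 2
  n_img <- n_steps * length(elevations_deg)

  schedule <- tibble::tibble(
    index = seq_len(n_img),
    id = sprintf("IMG_%04d", seq_len(n_img)),
    elevation_deg = rep(elevations_deg, each = n_steps),
    azimuth_deg = rep((seq_len(n_steps) - 1) * step_deg, length(elevations_deg)))

  rng <- local_rng(seed)
  if (perturb) {
    cast <- rng$runif(3, 0.94, 1.06)
    g <- rng$runif(n_img, 0.85, 1.15)
    gains <- outer(g, cast)
  } else {
    gains <- matrix(1, n_img, 3)
  }

  zmin <- min(mesh$vertices[, 3])
  ruler_mm <- rbind(c(-ruler_length_mm / 2, 0, zmin - 8),
                    c(ruler_length_mm / 2, 0, zmin - 8))

  in_memory <- is.null(out_dir) &&
    (as.double(n_img) * image_size^2 <= 64 * 256^2)
  if (!in_memory && is.null(out_dir)) out_dir <- tempfile("capture_")
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(out_dir, "silhouettes"), recursive = TRUE, showWarnings = FALSE)
  }

  chart_regions <- NULL
  if (include_chart) {
    ref <- chart_reference()
    cs <- max(10L, round(image_size / 18))
    gap <- max(2L, round(cs / 5))
    x0 <- gap + (seq_len(nrow(ref)) - 1) * (cs + gap)
    chart_regions <- tibble::tibble(
      chip = ref$chip,
      x0 = x0 + 1L, x1 = x0 + cs,                       # 1-based pixel cols
      y0 = image_size - cs - gap + 1L, y1 = image_size - gap)
  }

  bg_lin <- srgb_to_linear(backdrop_rgb)
  albedo_lin <- srgb_to_linear(truth$albedo_face_rgb)
  lights <- render_lights()
  poses <- vector("list", n_img)
  images <- if (in_memory) vector("list", n_img) else NULL
  sils <- if (in_memory) vector("list", n_img) else NULL
  annots <- list()

  for (i in seq_len(n_img)) {
    el <- schedule$elevation_deg[i] * pi / 180
    az <- schedule$azimuth_deg[i] * pi / 180
    eye <- center + dist * c(cos(el) * cos(az), cos(el) * sin(az), sin(el))
    pose_mm <- look_at_pose(eye, center, fx, fy, cx, cy, image_size, image_size)
    res <- .cpp_render(mesh$vertices, faces0(mesh), pose_mm$rotation,
                       pose_mm$translation, fx, fy, cx, cy,
                       image_size, image_size, albedo_lin,
                       0.7208, 0.34, lights, TRUE)
    faceid <- matrix(res$faceid, image_size, image_size)
    img <- array(res$rgb, dim = c(image_size, image_size, 3))
    bg <- faceid < 0
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[bg] <- bg_lin[ch]
      img[, , ch] <- plane
    }

    if (include_ruler) {
      pr <- project_points(pose_mm, ruler_mm)
      if (!anyNA(pr$u)) {
        img <- draw_ruler(img, faceid, pr$u, pr$v)
        annots[[length(annots) + 1]] <- tibble::tibble(
          image_id = schedule$id[i], marker_id = c("ruler_A", "ruler_B"),
          u = pr$u, v = pr$v)
      }
    }
    if (include_chart) {
      for (k in seq_len(nrow(chart_regions))) {
        chip_lin <- srgb_to_linear(as.numeric(chart_reference()[k, c("r", "g", "b")]))
        img[chart_regions$y0[k]:chart_regions$y1[k],
            chart_regions$x0[k]:chart_regions$x1[k], ] <-
          rep(chip_lin, each = (chart_regions$y1[k] - chart_regions$y0[k] + 1) *
                (chart_regions$x1[k] - chart_regions$x0[k] + 1))
      }
    }

    for (ch in 1:3) img[, , ch] <- pmin(1, pmax(0, img[, , ch] * gains[i, ch]))
    img <- linear_to_srgb(img)
    img <- round(img * 255) / 255   # 8-bit quantization, identical to the PNG path

    sil <- faceid >= 0
    # scale pose bookkeeping into model units
    poses[[i]] <- camera_pose(pose_mm$rotation, pose_mm$translation * model_scale,
                              fx, fy, cx, cy, image_size, image_size)
    if (in_memory) {
      images[[i]] <- img
      sils[[i]] <- sil
    } else {
      png::writePNG(img, file.path(out_dir, "images",
                                   paste0(schedule$id[i], ".png")))
      png::writePNG(sil * 1, file.path(out_dir, "silhouettes",
                                       paste0(schedule$id[i], "_silhouette.png")))
    }
  }

  capture <- structure(list(
    ids = schedule$id, schedule = schedule, poses = poses,
    images = images, silhouettes = sils,
    image_dir = if (!is.null(out_dir)) file.path(out_dir, "images") else NULL,
    silhouette_dir = if (!is.null(out_dir)) file.path(out_dir, "silhouettes") else NULL,
    step_deg = step_deg, elevations_deg = elevations_deg,
    image_size = as.integer(image_size),
    chart = if (include_chart) list(reference = chart_reference(),
                                    regions = chart_regions) else NULL,
    ruler = if (include_ruler) list(
      length_mm = ruler_length_mm,
      endpoints = ruler_mm * model_scale,
      annotations = if (length(annots)) dplyr::bind_rows(annots) else NULL) else NULL,
    backdrop_rgb = backdrop_rgb, gains = gains,
    model_scale = model_scale,
    true_factor_mm_per_unit = 1 / model_scale,
    seed = as.integer(seed)), class = "turntable_capture")

  if (!is.null(out_dir)) write_capture_metadata(capture, truth, out_dir)
  capture
}

draw_ruler <- function(img, faceid, u, v, col = c(0.05, 0.05, 0.06)) {
  S <- nrow(img)
  # keep 5 px clearance from the specimen (wider than the masking stage's
  # closing diameter) so the drawn ruler never merges with the subject
  # silhouette; the pixel annotations carry the geometry regardless
  occ <- faceid >= 0
  dil <- occ
  for (dy in -5:5) for (dx in -5:5) {
    if (dy == 0 && dx == 0) next
    ys <- pmin(pmax(seq_len(S) + dy, 1), S)
    xs <- pmin(pmax(seq_len(S) + dx, 1), S)
    dil <- dil | occ[ys, xs]
  }
  faceid <- ifelse(dil, 0L, -1L)
  n <- 4L * S
  tt <- seq(0, 1, length.out = n)
  px <- floor(u[1] + tt * (u[2] - u[1])) + 1L
  py <- floor(v[1] + tt * (v[2] - v[1])) + 1L
  for (dy in 0:1) for (dx in 0:1) {
    xx <- px + dx; yy <- py + dy
    ok <- xx >= 1 & xx <= S & yy >= 1 & yy <= S
    ok[ok] <- faceid[cbind(yy[ok], xx[ok])] < 0   # specimen occludes the ruler
    if (any(ok)) for (ch in 1:3)
      img[cbind(yy[ok], xx[ok], ch)] <- col[ch]
  }
  # endpoint markers
  mcol <- c(0.30, 0.06, 0.06)
  for (e in 1:2) {
    xx <- floor(u[e]) + 1L + (-1:1); yy <- floor(v[e]) + 1L + (-1:1)
    xx <- xx[xx >= 1 & xx <= S]; yy <- yy[yy >= 1 & yy <= S]
    grid <- expand.grid(y = yy, x = xx)
    ok <- faceid[cbind(grid$y, grid$x)] < 0
    if (any(ok)) for (ch in 1:3)
      img[cbind(grid$y[ok], grid$x[ok], ch)] <- mcol[ch]
  }
  img
}

#' @export
print.turntable_capture <- function(x, ...) {
  cat(sprintf("<turntable_capture> %d images (%d x %d), step %.4g deg, elevations %s\n",
              length(x$ids), x$image_size, x$image_size, x$step_deg,
              paste(x$elevations_deg, collapse = "/")))
  invisible(x)
}

#' Access one image / silhouette of a capture
#' @param capture a `turntable_capture`.
#' @param i image index.
#' @return sRGB array (H x W x 3) or logical silhouette matrix.
#' @export
capture_image <- function(capture, i) {
  if (!is.null(capture$images)) return(capture$images[[i]])
  img <- png::readPNG(file.path(capture$image_dir, paste0(capture$ids[i], ".png")))
  img[, , 1:3, drop = TRUE]
}

#' @rdname capture_image
#' @export
capture_silhouette <- function(capture, i) {
  if (!is.null(capture$silhouettes)) return(capture$silhouettes[[i]])
  m <- png::readPNG(file.path(capture$silhouette_dir,
                              paste0(capture$ids[i], "_silhouette.png")))
  if (length(dim(m)) == 3) m <- m[, , 1]
  m > 0.5
}

write_capture_metadata <- function(capture, truth, out_dir) {
  rows <- lapply(seq_along(capture$poses), function(i) {
    p <- capture$poses[[i]]
    data.frame(image = capture$ids[i],
               r11 = p$rotation[1, 1], r12 = p$rotation[1, 2], r13 = p$rotation[1, 3],
               r21 = p$rotation[2, 1], r22 = p$rotation[2, 2], r23 = p$rotation[2, 3],
               r31 = p$rotation[3, 1], r32 = p$rotation[3, 2], r33 = p$rotation[3, 3],
               t1 = p$translation[1], t2 = p$translation[2], t3 = p$translation[3],
               fx = p$fx, fy = p$fy, cx = p$cx, cy = p$cy)
  })
  utils::write.csv(do.call(rbind, rows), file.path(out_dir, "poses.csv"),
                   row.names = FALSE)
  cap_json <- list(step_deg = capture$step_deg,
                   elevations_deg = capture$elevations_deg,
                   image_size = capture$image_size,
                   backdrop_rgb = capture$backdrop_rgb,
                   ruler_length_mm = if (!is.null(capture$ruler)) capture$ruler$length_mm else NULL,
                   seed = capture$seed)
  jsonlite::write_json(cap_json, file.path(out_dir, "capture.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(capture$chart))
    utils::write.csv(capture$chart$regions,
                     file.path(out_dir, "chart_regions.csv"), row.names = FALSE)
  truth_json <- list(
    landmarks_mm = as.data.frame(truth$landmarks),
    bill_length_mm = truth$bill_length_mm,
    true_factor_mm_per_unit = capture$true_factor_mm_per_unit,
    ruler_length_mm = if (!is.null(capture$ruler)) capture$ruler$length_mm else NULL,
    backdrop_rgb = capture$backdrop_rgb,
    chart = if (!is.null(capture$chart)) capture$chart$reference else NULL)
  jsonlite::write_json(truth_json, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(capture$ruler$annotations))
    utils::write.csv(capture$ruler$annotations,
                     file.path(out_dir, "markers.csv"), row.names = FALSE)
  invisible(out_dir)
}

#' Read a turntable capture from disk
#'
#' Reconstructs a `turntable_capture` from a directory written by
#' [render_turntable()] (or laid out the same way by any other source):
#' `images/*.png`, `poses.csv`, `capture.json`, optional `chart_regions.csv`,
#' `markers.csv` and `silhouettes/`. Images stay on disk and are loaded
#' lazily by [capture_image()].
#'
#' @param dir capture directory.
#' @return A `turntable_capture`.
#' @export
read_capture <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "capture.json"), simplifyVector = TRUE)
  poses <- read_poses_csv(file.path(dir, "poses.csv"),
                          meta$image_size, meta$image_size)
  ids <- names(poses)
  n_steps <- round(360 / meta$step_deg)
  schedule <- tibble::tibble(
    index = seq_along(ids), id = ids,
    elevation_deg = rep(meta$elevations_deg, each = n_steps)[seq_along(ids)],
    azimuth_deg = rep((seq_len(n_steps) - 1) * meta$step_deg,
                      length(meta$elevations_deg))[seq_along(ids)])
  chart <- NULL
  crf <- file.path(dir, "chart_regions.csv")
  if (file.exists(crf))
    chart <- list(reference = chart_reference(),
                  regions = tibble::as_tibble(utils::read.csv(crf)))
  ruler <- NULL
  mkf <- file.path(dir, "markers.csv")
  if (file.exists(mkf))
    ruler <- list(length_mm = meta$ruler_length_mm, endpoints = NULL,
                  annotations = tibble::as_tibble(utils::read.csv(mkf)))
  truth_path <- file.path(dir, "truth.json")
  true_factor <- NA_real_
  if (file.exists(truth_path)) {
    tj <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    if (!is.null(tj$true_factor_mm_per_unit))
      true_factor <- tj$true_factor_mm_per_unit
  }
  structure(list(
    ids = ids, schedule = schedule, poses = unname(poses),
    images = NULL, silhouettes = NULL,
    image_dir = file.path(dir, "images"),
    silhouette_dir = if (dir.exists(file.path(dir, "silhouettes")))
      file.path(dir, "silhouettes") else NULL,
    step_deg = meta$step_deg, elevations_deg = meta$elevations_deg,
    image_size = as.integer(meta$image_size),
    chart = chart, ruler = ruler,
    backdrop_rgb = as.numeric(meta$backdrop_rgb), gains = NULL,
    model_scale = if (is.na(true_factor)) NA_real_ else 1 / true_factor,
    true_factor_mm_per_unit = true_factor,
    seed = meta$seed), class = "turntable_capture")
}

#' Read camera poses from a capture's poses CSV
#' @param path path to a `poses.csv` written by [render_turntable()].
#' @param width,height image size the poses refer to.
#' @return named list of [camera_pose] objects keyed by image id.
#' @export
read_poses_csv <- function(path, width, height) {
  df <- utils::read.csv(path)
  out <- lapply(seq_len(nrow(df)), function(i) {
    R <- matrix(as.numeric(df[i, c("r11", "r12", "r13", "r21", "r22", "r23",
                                   "r31", "r32", "r33")]), 3, 3, byrow = TRUE)
    camera_pose(R, as.numeric(df[i, c("t1", "t2", "t3")]),
                df$fx[i], df$fy[i], df$cx[i], df$cy[i], width, height)
  })
  names(out) <- df$image
  out
}
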