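#' Texture map objects
#'
#' A square sRGB albedo raster addressed by UV coordinates (texel row 1 is
#' v = 1, matching PNG row order; `vt` records written by [export_obj()] use
#' the bottom-left v origin consistently).
#'
#' @param pixels S x S x 3 sRGB array in `[0,1]`; S a power of two.
#' @param coverage S x S logical: texels backed by geometry.
#' @param unseen_fraction fraction of covered texels seen by zero views.
#' @param mean_views mean number of contributing views per covered texel.
#' @export
texture_map <- function(pixels, coverage, unseen_fraction = 0,
                        mean_views = NA_real_) {
  S <- dim(pixels)[1]
  stopifnot(length(dim(pixels)) == 3, dim(pixels)[2] == S, dim(pixels)[3] == 3,
            identical(dim(coverage), dim(pixels)[1:2]))
  if (S < 64 || bitwAnd(S, S - 1L) != 0)
    stop("texture size must be a power of two (>= 64)")
  structure(list(pixels = pixels, coverage = coverage,
                 unseen_fraction = unseen_fraction, mean_views = mean_views),
            class = "texture_map")
}

#' @export
print.texture_map <- function(x, ...) {
  cat(sprintf("<texture_map> %d x %d, %.1f%% covered, unseen %.2f%%\n",
              dim(x$pixels)[1], dim(x$pixels)[2], 100 * mean(x$coverage),
              100 * x$unseen_fraction))
  invisible(x)
}

#' Per-face visibility from a camera pose
#'
#' Depth-buffer visibility: the mesh is rasterized from the pose and a face
#' is visible iff its centroid projects inside the frame, faces the camera,
#' and its depth matches the buffer within tolerance (i.e. it is not
#' occluded).
#'
#' @param mesh a [trimesh] in the pose's scene units.
#' @param pose a [camera_pose].
#' @param image_size raster resolution (defaults to the pose's width).
#' @param depth_tol relative depth tolerance for the occlusion test.
#' @return tibble with `face`, `visible`, and `view_angle` (radians between
#'   the face normal and the direction to the camera).
#' @export
face_visibility <- function(mesh, pose, image_size = pose$width,
                            depth_tol = 0.02) {
  stopifnot_trimesh(mesh)
  sc <- image_size / pose$width
  res <- .cpp_render(mesh$vertices, faces0(mesh), pose$rotation,
                     pose$translation, pose$fx * sc, pose$fy * sc,
                     pose$cx * sc, pose$cy * sc, image_size, image_size,
                     matrix(0, nrow(mesh$faces), 3), 0, 0,
                     matrix(c(0, 0, -1), 1), FALSE)
  depth <- matrix(res$depth, image_size, image_size)
  cen <- face_centroids(mesh)
  n <- face_normals(mesh)
  campos <- -as.vector(t(pose$rotation) %*% pose$translation)
  to_cam <- sweep(-cen, 2, campos, "+")
  to_cam <- to_cam / sqrt(rowSums(to_cam^2))
  cosang <- rowSums(n * to_cam)
  pr <- project_points(camera_pose(pose$rotation, pose$translation,
                                   pose$fx * sc, pose$fy * sc, pose$cx * sc,
                                   pose$cy * sc, image_size, image_size), cen)
  inside <- !is.na(pr$u) & pr$u >= 0.5 & pr$u <= image_size - 0.5 &
    pr$v >= 0.5 & pr$v <= image_size - 0.5
  vis <- rep(FALSE, nrow(cen))
  idx <- which(inside)
  if (length(idx)) {
    pi_ <- pmin(pmax(floor(pr$v[idx]), 0), image_size - 1) + 1
    pj <- pmin(pmax(floor(pr$u[idx]), 0), image_size - 1) + 1
    dbuf <- depth[cbind(pi_, pj)]
    vis[idx] <- pr$z[idx] <= dbuf * (1 + depth_tol) & cosang[idx] > 0
  }
  tibble::tibble(face = seq_len(nrow(cen)), visible = vis,
                 view_angle = acos(pmin(pmax(cosang, -1), 1)))
}

# texel table: for each covered texel the owning face, 3D position and normal
bake_texel_table <- function(mesh, atlas, size) {
  res <- .cpp_uv_rasterize(atlas$uv, as.integer(nrow(atlas$uv) / 3),
                           as.integer(size))
  fid <- matrix(res$faceid, size, size)
  bary <- array(res$bary, dim = c(size, size, 3))
  covered <- fid >= 0
  idx <- which(covered)
  f1 <- fid[idx] + 1L
  w <- cbind(bary[, , 1][idx], bary[, , 2][idx], bary[, , 3][idx])
  v <- mesh$vertices; f <- mesh$faces
  P <- w[, 1] * v[f[f1, 1], , drop = FALSE] +
    w[, 2] * v[f[f1, 2], , drop = FALSE] +
    w[, 3] * v[f[f1, 3], , drop = FALSE]
  N <- face_normals(mesh)[f1, , drop = FALSE]
  list(index = idx, face = f1, P = P, N = N, coverage = covered)
}

#' Bake an albedo texture from calibrated, masked capture images
#'
#' Visibility-aware projective baking: every covered texel corresponds to a
#' surface point; its color is the weight-normalized blend of all views that
#' see that point (depth-buffer occlusion test, masked pixels excluded),
#' with weight `cos^2` of the view angle and bilinear image sampling in
#' linear light. Texels seen by no view, and the inter-chart gutter, are
#' in-painted from the nearest covered texels (4-texel gutter dilation).
#' Deterministic and order-independent in the image list.
#'
#' @param mesh the low-poly [trimesh], in the same units as the poses after
#'   `pose_scale` is applied.
#' @param atlas the mesh's `uv_atlas`.
#' @param capture a `turntable_capture` providing poses and image ids.
#' @param photos the standardized, masked images: a directory containing
#'   `<id>_masked.png` files (from [prep_capture()]), a list of [photo]
#'   objects with masks, or `NULL` to use the capture's raw images with
#'   silhouette masks (fixture shortcut).
#' @param size texture resolution (power of two; 4096 and 8192 are the
#'   production choices, smaller sizes are fine for tests).
#' @param pose_scale factor converting capture pose translations into the
#'   mesh's units (mm-per-model-unit from the scale solution, when the mesh
#'   is in mm; default uses the capture's ground truth).
#' @return A [texture_map].
#' @export
bake_texture <- function(mesh, atlas, capture, photos = NULL, size = 4096,
                         pose_scale = NULL) {
  stopifnot_trimesh(mesh)
  stopifnot(inherits(atlas, "uv_atlas"), inherits(capture, "turntable_capture"))
  if (is.null(pose_scale))
    pose_scale <- if (mesh$units == "mm") capture$true_factor_mm_per_unit else 1
  tab <- bake_texel_table(mesh, atlas, size)
  nt <- length(tab$face)
  if (nt == 0) stop("atlas covers no texels at this size")
  accum <- matrix(0, nt, 3)
  wsum <- numeric(nt)
  vcount <- integer(nt)

  get_photo <- function(i) {
    id <- capture$ids[i]
    if (is.null(photos)) {
      photo(capture_image(capture, i), id, mask = capture_silhouette(capture, i))
    } else if (is.character(photos)) {
      read_masked(file.path(photos, paste0(id, "_masked.png")))
    } else {
      photos[[i]]
    }
  }

  for (i in seq_along(capture$ids)) {
    ph <- get_photo(i)
    if (is.null(ph$mask)) stop("photo ", ph$id, " has no mask; bake needs masked images")
    pose <- capture$poses[[i]]
    tmm <- pose$translation * pose_scale
    dres <- .cpp_render(mesh$vertices, faces0(mesh), pose$rotation, tmm,
                        pose$fx, pose$fy, pose$cx, pose$cy,
                        pose$width, pose$height,
                        matrix(0, nrow(mesh$faces), 3), 0, 0,
                        matrix(c(0, 0, -1), 1), FALSE)
    lin <- srgb_to_linear(ph$pixels)
    .cpp_bake_accumulate(tab$P, tab$N, as.numeric(lin), as.numeric(ph$mask * 1),
                         pose$rotation, tmm, pose$fx, pose$fy, pose$cx, pose$cy,
                         pose$width, pose$height, dres$depth,
                         0.02, 1e-9, accum, wsum, vcount)
  }

  S <- as.integer(size)
  seen <- wsum > 0
  cols <- matrix(0, nt, 3)
  cols[seen, ] <- accum[seen, , drop = FALSE] / wsum[seen]
  planes <- array(0, dim = c(S, S, 3))
  filled <- matrix(FALSE, S, S)
  filled[tab$index[seen]] <- TRUE
  for (ch in 1:3) {
    pl <- matrix(0, S, S)
    pl[tab$index[seen]] <- cols[seen, ch]
    planes[, , ch] <- pl
  }
  # in-paint unseen covered texels until none remain, then 4 more passes of
  # gutter dilation beyond the coverage border
  need <- tab$coverage & !filled
  pass <- 0L
  while ((any(need) || pass < 4L) && pass < 256L) {
    grown <- dilate_colors(planes, filled)
    planes <- grown$planes
    newly <- grown$filled & !filled
    if (!any(newly) && !any(need)) break
    filled <- grown$filled
    need <- tab$coverage & !filled
    pass <- pass + 1L
  }
  texture_map(linear_to_srgb(pmin(pmax(planes, 0), 1)), tab$coverage,
              unseen_fraction = mean(!seen),
              mean_views = mean(vcount))
}

# one 8-neighbor dilation of filled texels into unfilled ones (mean color)
dilate_colors <- function(planes, filled) {
  S <- nrow(filled)
  acc <- array(0, dim = dim(planes))
  cnt <- matrix(0, S, S)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    ys <- pmin(pmax(seq_len(S) + dy, 1), S)
    xs <- pmin(pmax(seq_len(S) + dx, 1), S)
    w <- filled[ys, xs] * 1
    cnt <- cnt + w
    for (ch in 1:3) acc[, , ch] <- acc[, , ch] + planes[ys, xs, ch] * w
  }
  new_fill <- !filled & cnt > 0
  for (ch in 1:3) {
    pl <- planes[, , ch]
    pl[new_fill] <- acc[, , ch][new_fill] / cnt[new_fill]
    planes[, , ch] <- pl
  }
  list(planes = planes, filled = filled | new_fill)
}

#' Paint a texture directly from per-face albedo (no photographs)
#'
#' Fills every covered texel with its owning face's color; useful as a
#' reference texture for tests and for color-cloud extraction from ground
#' truth.
#'
#' @param mesh a [trimesh].
#' @param atlas its `uv_atlas`.
#' @param face_rgb M x 3 sRGB matrix.
#' @param size texture resolution.
#' @return A [texture_map].
#' @export
texture_from_albedo <- function(mesh, atlas, face_rgb, size = 1024) {
  tab <- bake_texel_table(mesh, atlas, size)
  S <- as.integer(size)
  planes <- array(0, dim = c(S, S, 3))
  for (ch in 1:3) {
    pl <- matrix(0, S, S)
    pl[tab$index] <- face_rgb[tab$face, ch]
    planes[, , ch] <- pl
  }
  texture_map(planes, tab$coverage, unseen_fraction = 0, mean_views = 0)
}

#' Export the textured model (OBJ + MTL + PNG)
#'
#' Writes `<catalog>_lowpoly.obj`, `<catalog>.mtl` (one `map_Kd` entry) and
#' `<catalog>_albedo.png` side by side in `out_dir`.
#'
#' @param mesh low-poly [trimesh].
#' @param atlas its `uv_atlas` (must match the mesh).
#' @param texmap a [texture_map].
#' @param out_dir output directory.
#' @param catalog catalog number used as the filename stem.
#' @return Named list of the three paths.
#' @export
export_textured <- function(mesh, atlas, texmap, out_dir, catalog) {
  stopifnot_trimesh(mesh)
  if (nrow(atlas$uv) != 3 * nrow(mesh$faces))
    stop("consistency error: atlas does not match mesh face count")
  stopifnot(inherits(texmap, "texture_map"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  png_name <- sprintf("%s_albedo.png", catalog)
  mtl_name <- sprintf("%s.mtl", catalog)
  obj_path <- file.path(out_dir, sprintf("%s_lowpoly.obj", catalog))
  write_obj(mesh, obj_path, uv = atlas$uv, mtl = mtl_name, material = "albedo")
  mtl_path <- file.path(out_dir, mtl_name)
  writeLines(c("newmtl albedo", "Ka 1 1 1", "Kd 1 1 1",
               paste("map_Kd", png_name)), mtl_path)
  png_path <- file.path(out_dir, png_name)
  png::writePNG(texmap$pixels, png_path)
  list(obj = obj_path, mtl = mtl_path, texture = png_path)
}
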