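#' Generate a UV atlas by simultaneous planar projections
#'
#' Assigns every face to the projection direction maximizing
#' `|normal . direction|` (ties to the lowest direction index), splits each
#' direction's faces into connected sub-charts, flattens each sub-chart by
#' planar projection followed by a conformal relaxation pass (per-face
#' isometric embeddings fitted by similarity transforms and averaged), scales
#' charts to their true 3D area and packs them into the unit square by shelf
#' packing with a gutter. The default 8 directions are the normalized
#' centroid-to-bounding-box-corner directions, which cover oblique surfaces
#' like bills and tails better than the 6 axis directions
#' (`n_projections = 6`).
#'
#' @param mesh a 2-manifold [trimesh].
#' @param n_projections 8 (bounding-box corners) or 6 (axes).
#' @param gutter_texels padding between packed charts, in texels of
#'   `atlas_size`.
#' @param atlas_size texture resolution the gutter refers to.
#' @param relax_iterations conformal relaxation passes per sub-chart.
#' @return A `uv_atlas`: `uv` ((3M) x 2 per-corner coordinates in `[0,1]`),
#'   `chart` (chart id per face), `chart_direction` (per chart), `n_charts`,
#'   plus packing metadata.
#' @export
generate_uv <- function(mesh, n_projections = 8, gutter_texels = 4,
                        atlas_size = 1024, relax_iterations = 1) {
  stopifnot_trimesh(mesh)
  if (nrow(mesh$faces) < 1) stop("empty mesh")
  if (!n_projections %in% c(6, 8))
    stop("n_projections must be 8 (bounding-box corners) or 6 (axes)")
  v <- mesh$vertices; f <- mesh$faces
  if (n_projections == 6) {
    dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                  c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  } else {
    cen <- colMeans(v)
    corners <- as.matrix(expand.grid(x = range(v[, 1]), y = range(v[, 2]),
                                     z = range(v[, 3])))
    dirs <- sweep(corners, 2, cen)
    dirs <- dirs / sqrt(rowSums(dirs^2))
  }
  n <- face_normals(mesh)
  score <- abs(n %*% t(dirs))
  dir_of_face <- max.col(score, ties.method = "first")

  # connected sub-charts within each direction
  et <- mesh_edge_table(mesh)
  ord <- order(et$edge_of_half)
  eh <- et$edge_of_half[ord]; fh <- et$face_of_half[ord]
  first <- which(!duplicated(eh))
  ends <- c(first[-1] - 1L, length(eh))
  pair_a <- integer(0); pair_b <- integer(0)
  for (i in seq_along(first)) {
    fs <- fh[first[i]:ends[i]]
    if (length(fs) == 2 && dir_of_face[fs[1]] == dir_of_face[fs[2]]) {
      pair_a <- c(pair_a, fs[1]); pair_b <- c(pair_b, fs[2])
    }
  }
  g <- igraph::make_graph(rbind(pair_a, pair_b), n = nrow(f), directed = FALSE)
  chart <- as.integer(igraph::components(g)$membership)
  # relabel charts in deterministic order of first face
  chart <- match(chart, unique(chart))
  n_charts <- max(chart)

  uv <- matrix(0, 3 * nrow(f), 2)
  chart_dir <- integer(n_charts)
  for (ci in seq_len(n_charts)) {
    faces_ci <- which(chart == ci)
    d <- dirs[dir_of_face[faces_ci[1]], ]
    chart_dir[ci] <- dir_of_face[faces_ci[1]]
    ax <- diag(3)[which.min(abs(d)), ]
    e1 <- c(d[2] * ax[3] - d[3] * ax[2], d[3] * ax[1] - d[1] * ax[3],
            d[1] * ax[2] - d[2] * ax[1])
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(d[2] * e1[3] - d[3] * e1[2], d[3] * e1[1] - d[1] * e1[3],
            d[1] * e1[2] - d[2] * e1[1])
    if (mean(n[faces_ci, , drop = FALSE] %*% d) < 0) e2 <- -e2
    vid <- sort(unique(as.vector(f[faces_ci, , drop = FALSE])))
    lmap <- integer(nrow(v)); lmap[vid] <- seq_along(vid)
    p <- cbind(v[vid, , drop = FALSE] %*% e1, v[vid, , drop = FALSE] %*% e2)
    lf <- matrix(lmap[f[faces_ci, , drop = FALSE]], ncol = 3)
    for (it in seq_len(relax_iterations))
      p <- conformal_relax(p, lf, v[vid, , drop = FALSE])
    # scale chart so UV area equals 3D area
    a3 <- sum(face_areas(mesh)[faces_ci])
    a2 <- sum(abs((p[lf[, 2], 1] - p[lf[, 1], 1]) * (p[lf[, 3], 2] - p[lf[, 1], 2]) -
                    (p[lf[, 3], 1] - p[lf[, 1], 1]) * (p[lf[, 2], 2] - p[lf[, 1], 2])) / 2)
    if (a2 > 0) p <- p * sqrt(a3 / a2)
    rows <- rep((faces_ci - 1) * 3, each = 3) + rep(1:3, length(faces_ci))
    uv[rows, ] <- p[t(lf), ]
  }

  packed <- pack_charts(uv, chart, f, gutter_texels / atlas_size)
  atlas <- structure(list(uv = packed$uv, chart = chart,
                          chart_direction = chart_dir,
                          directions = dirs, n_charts = n_charts,
                          atlas_size = as.integer(atlas_size),
                          gutter_texels = gutter_texels,
                          pack_scale = packed$scale),
                     class = "uv_atlas")
  atlas
}

# one pass of conformal relaxation: fit each face's isometric 2D embedding to
# the current UVs by a similarity transform, then average the predictions
conformal_relax <- function(p, lf, v3) {
  pred_sum <- matrix(0, nrow(p), 2)
  pred_n <- numeric(nrow(p))
  for (fi in seq_len(nrow(lf))) {
    tri <- lf[fi, ]
    q3 <- v3[tri, , drop = FALSE]
    l12 <- sqrt(sum((q3[2, ] - q3[1, ])^2))
    l13 <- sqrt(sum((q3[3, ] - q3[1, ])^2))
    l23 <- sqrt(sum((q3[3, ] - q3[2, ])^2))
    if (l12 < 1e-12) next
    x3 <- (l13^2 + l12^2 - l23^2) / (2 * l12)
    y3 <- sqrt(max(0, l13^2 - x3^2))
    q <- rbind(c(0, 0), c(l12, 0), c(x3, y3))
    # complex similarity fit q -> current uv
    zq <- complex(real = q[, 1], imaginary = q[, 2])
    zp <- complex(real = p[tri, 1], imaginary = p[tri, 2])
    zqc <- zq - mean(zq); zpc <- zp - mean(zp)
    denom <- sum(Mod(zqc)^2)
    a <- if (denom > 1e-18) sum(zpc * Conj(zqc)) / denom else 1 + 0i
    pred <- a * zqc + mean(zp)
    pred_sum[tri, 1] <- pred_sum[tri, 1] + Re(pred)
    pred_sum[tri, 2] <- pred_sum[tri, 2] + Im(pred)
    pred_n[tri] <- pred_n[tri] + 1
  }
  ok <- pred_n > 0
  p[ok, ] <- pred_sum[ok, , drop = FALSE] / pred_n[ok]
  p
}

# shelf packing into the unit square with a gutter; binary search the global
# scale. uv is per-corner (3M x 2), chart is per face.
pack_charts <- function(uv, chart, faces, gutter) {
  n_charts <- max(chart)
  corner_chart <- rep(chart, each = 3)
  boxes <- t(vapply(seq_len(n_charts), function(ci) {
    rows <- which(corner_chart == ci)
    c(min(uv[rows, 1]), max(uv[rows, 1]), min(uv[rows, 2]), max(uv[rows, 2]))
  }, numeric(4)))
  w <- boxes[, 2] - boxes[, 1]
  h <- boxes[, 4] - boxes[, 3]
  if (n_charts * (2 * gutter)^2 > 1)
    stop("packing overflow: too many charts for this atlas size; ",
         "increase atlas_size or use fewer projections")
  ord <- order(-h, seq_len(n_charts))
  try_pack <- function(s) {
    x <- gutter; y <- gutter; shelf_h <- 0
    pos <- matrix(NA_real_, n_charts, 2)
    for (ci in ord) {
      cw <- w[ci] * s; ch <- h[ci] * s
      if (cw + 2 * gutter > 1 || ch + 2 * gutter > 1) return(NULL)
      if (x + cw + gutter > 1) { x <- gutter; y <- y + shelf_h + gutter; shelf_h <- 0 }
      if (y + ch + gutter > 1) return(NULL)
      pos[ci, ] <- c(x, y)
      x <- x + cw + gutter
      shelf_h <- max(shelf_h, ch)
    }
    pos
  }
  lo <- 0; hi <- 1 / max(c(w, h, 1e-12))
  pos <- NULL; s_best <- NULL
  for (i in 1:48) {
    mid <- (lo + hi) / 2
    p <- try_pack(mid)
    if (!is.null(p)) { lo <- mid; pos <- p; s_best <- mid } else hi <- mid
  }
  if (is.null(pos)) stop("packing overflow: increase atlas_size or use fewer charts")
  out <- uv
  for (ci in seq_len(n_charts)) {
    rows <- which(corner_chart == ci)
    out[rows, 1] <- (uv[rows, 1] - boxes[ci, 1]) * s_best + pos[ci, 1]
    out[rows, 2] <- (uv[rows, 2] - boxes[ci, 3]) * s_best + pos[ci, 2]
  }
  out <- pmin(pmax(out, 0), 1)
  list(uv = out, scale = s_best)
}

#' @export
print.uv_atlas <- function(x, ...) {
  cat(sprintf("<uv_atlas> %d charts over %d face corners (atlas %d, gutter %d texels)\n",
              x$n_charts, nrow(x$uv), x$atlas_size, x$gutter_texels))
  invisible(x)
}

#' Per-face area distortion of a UV atlas
#'
#' Ratio of 3D face area to UV face area, normalized by the atlas-wide
#' median; 1 = perfectly area-preserving.
#'
#' @param mesh the [trimesh] the atlas belongs to.
#' @param atlas a `uv_atlas`.
#' @return numeric vector, one normalized ratio per face.
#' @export
uv_area_distortion <- function(mesh, atlas) {
  a3 <- face_areas(mesh)
  uv <- atlas$uv
  i1 <- seq(1, nrow(uv), by = 3); i2 <- i1 + 1; i3 <- i1 + 2
  a2 <- abs((uv[i2, 1] - uv[i1, 1]) * (uv[i3, 2] - uv[i1, 2]) -
              (uv[i3, 1] - uv[i1, 1]) * (uv[i2, 2] - uv[i1, 2])) / 2
  r <- a3 / pmax(a2, 1e-300)
  r / median(r)
}

#' Rasterize chart ownership per texel
#'
#' @param atlas a `uv_atlas`.
#' @param size raster size (defaults to the atlas size).
#' @return integer matrix (size x size): chart id per texel, 0 = empty.
#' @export
rasterize_charts <- function(atlas, size = atlas$atlas_size) {
  res <- .cpp_uv_rasterize(atlas$uv, as.integer(nrow(atlas$uv) / 3),
                           as.integer(size))
  fid <- matrix(res$faceid, size, size)
  out <- matrix(0L, size, size)
  covered <- fid >= 0
  out[covered] <- atlas$chart[fid[covered] + 1L]
  out
}

#' Export a mesh as OBJ with pipeline suffix conventions
#'
#' Writes `<catalog>_<stage>.obj` (e.g. `MLZ12342_lowpoly.obj`), with `vt`
#' records when an atlas is supplied. Path collisions are refused.
#'
#' @param mesh a [trimesh].
#' @param atlas optional `uv_atlas`.
#' @param out_dir output directory.
#' @param stage `"highpoly"` or `"lowpoly"`.
#' @param catalog specimen catalog number used as the filename stem.
#' @param ... passed to [write_obj()].
#' @return The output path.
#' @export
export_obj <- function(mesh, atlas = NULL, out_dir, stage = c("highpoly", "lowpoly"),
                       catalog, ...) {
  stage <- match.arg(stage)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(out_dir, sprintf("%s_%s.obj", catalog, stage))
  write_obj(mesh, path, uv = if (!is.null(atlas)) atlas$uv else NULL, ...)
  path
}
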