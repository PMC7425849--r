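#' Measure a landmark distance on a mesh
#'
#' The digital analogue of calipers: both landmarks are snapped to the
#' nearest surface point (they must lie within `snap_tol` of the surface) and
#' the straight-line (chord) distance between the snapped points is returned.
#' A graph geodesic along mesh edges is available as an alternative for
#' surface-bound traits.
#'
#' @param mesh a [trimesh] in mm.
#' @param landmark_a,landmark_b length-3 points (mm) or single vertex
#'   indices.
#' @param snap_tol maximum allowed landmark-to-surface distance in mm
#'   (default 1).
#' @param method `"chord"` (default, calipers analogue) or `"geodesic"`
#'   (shortest edge path between the nearest vertices).
#' @return distance in mm.
#' @export
measure <- function(mesh, landmark_a, landmark_b, snap_tol = 1,
                    method = c("chord", "geodesic")) {
  stopifnot_trimesh(mesh)
  method <- match.arg(method)
  as_point <- function(lm) {
    if (length(lm) == 1) mesh$vertices[as.integer(lm), ] else as.numeric(lm)
  }
  pts <- rbind(as_point(landmark_a), as_point(landmark_b))
  cp <- closest_points(mesh, pts)
  if (any(cp$distance > snap_tol))
    stop(sprintf("snap error: landmark %.3f mm from surface (tolerance %.3f)",
                 max(cp$distance), snap_tol))
  if (method == "chord")
    return(sqrt(sum((cp$point[1, ] - cp$point[2, ])^2)))
  # geodesic: shortest path over the edge graph between nearest vertices
  vid <- vapply(1:2, function(i) {
    tri <- mesh$faces[cp$face[i], ]
    d2 <- rowSums(sweep(mesh$vertices[tri, , drop = FALSE], 2, cp$point[i, ])^2)
    tri[which.min(d2)]
  }, integer(1))
  et <- mesh_edge_table(mesh)
  len <- sqrt(rowSums((mesh$vertices[et$a, , drop = FALSE] -
                         mesh$vertices[et$b, , drop = FALSE])^2))
  g <- igraph::make_graph(rbind(et$a, et$b), n = nrow(mesh$vertices),
                          directed = FALSE)
  igraph::distances(g, v = vid[1], to = vid[2], weights = len)[1, 1]
}

#' Compare digital and reference measurements
#'
#' Summary statistics for paired digital-vs-hand measurements: mean absolute
#' difference (mm), mean relative error, a naive repeatability fraction
#' `1 - mean_abs_diff / mean(reference)`, and a two-way absolute-agreement
#' intraclass correlation ICC(A,1) on the pairs (the naive fraction and the
#' ICC are both reported because informal "repeatability" figures in
#' collections practice rarely state their formula).
#'
#' @param records data frame / tibble with columns `digital_mm` and
#'   `reference_mm` (optionally `specimen_id`, `trait`).
#' @return A `measurement_stats` object; see [tidy.measurement_stats()].
#' @export
compare_measurements <- function(records) {
  records <- as.data.frame(records)
  if (nrow(records) < 1) stop("no measurement records")
  stopifnot(all(c("digital_mm", "reference_mm") %in% names(records)))
  if (any(records$digital_mm <= 0) || any(records$reference_mm <= 0))
    stop("measurements must be positive")
  d <- records$digital_mm; r <- records$reference_mm
  diff <- abs(d - r)
  stats <- list(
    n = nrow(records),
    mean_abs_diff_mm = mean(diff),
    mean_rel_err_fraction = mean(diff / r),
    repeatability_fraction = max(0, 1 - mean(diff) / mean(r)),
    icc = icc_a1(cbind(d, r)),
    records = tibble::as_tibble(records))
  class(stats) <- "measurement_stats"
  stats
}

# ICC(A,1): two-way, absolute agreement, single rater (McGraw & Wong)
icc_a1 <- function(x) {
  n <- nrow(x); k <- ncol(x)
  if (n < 2) return(NA_real_)
  grand <- mean(x)
  rm_ <- rowMeans(x); cm <- colMeans(x)
  msr <- k * sum((rm_ - grand)^2) / (n - 1)
  msc <- n * sum((cm - grand)^2) / (k - 1)
  sse <- sum((x - outer(rm_, rep(1, k)) - outer(rep(1, n), cm) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k / n * (msc - mse)
  if (abs(denom) < 1e-300) return(NA_real_)
  (msr - mse) / denom
}

#' @export
print.measurement_stats <- function(x, ...) {
  cat(sprintf(
    "<measurement_stats> n = %d | mean abs diff %.3f mm | mean rel err %.2f%% | repeatability %.1f%% | ICC(A,1) %.3f\n",
    x$n, x$mean_abs_diff_mm, 100 * x$mean_rel_err_fraction,
    100 * x$repeatability_fraction, x$icc))
  invisible(x)
}

#' Tidiers for measurement statistics
#'
#' `tidy()` returns one row per statistic; `glance()` a one-row summary.
#'
#' @param x a `measurement_stats` object.
#' @param ... unused.
#' @method tidy measurement_stats
#' @export
tidy.measurement_stats <- function(x, ...) {
  tibble::tibble(
    statistic = c("mean_abs_diff_mm", "mean_rel_err_fraction",
                  "repeatability_fraction", "icc"),
    value = c(x$mean_abs_diff_mm, x$mean_rel_err_fraction,
              x$repeatability_fraction, x$icc))
}

#' @rdname tidy.measurement_stats
#' @method glance measurement_stats
#' @export
glance.measurement_stats <- function(x, ...) {
  tibble::tibble(n = x$n, mean_abs_diff_mm = x$mean_abs_diff_mm,
                 mean_rel_err_fraction = x$mean_rel_err_fraction,
                 repeatability_fraction = x$repeatability_fraction,
                 icc = x$icc)
}

#' Extract an area-weighted color cloud from a textured model
#'
#' Every covered texel (sub-sampled per face by `sample_stride`) contributes
#' its color, weighted by the 3D surface area it represents (face area
#' divided by the number of sampled texels on that face) — so the cloud is
#' unbiased by UV stretch, the classic flattening artifact. Colors are
#' reported in sRGB and CIELAB (D65, 2 degrees).
#'
#' @param mesh a [trimesh] (mm).
#' @param atlas its `uv_atlas`.
#' @param texmap a [texture_map].
#' @param sample_stride keep every `sample_stride`-th texel of each face (at
#'   least one per covered face).
#' @param specimen_id optional id stored with the cloud.
#' @return A `color_cloud` tibble: `r`, `g`, `b`, `L`, `a`, `b_lab`,
#'   `weight` (mm^2), `face`; total weight equals the covered surface area.
#' @export
extract_color_cloud <- function(mesh, atlas, texmap, sample_stride = 1L,
                                specimen_id = NULL) {
  stopifnot_trimesh(mesh)
  S <- dim(texmap$pixels)[1]
  tab <- bake_texel_table(mesh, atlas, S)
  if (length(tab$face) == 0) stop("empty coverage: no texels backed by geometry")
  ord <- order(tab$face, tab$index)
  fid <- tab$face[ord]; idx <- tab$index[ord]
  within <- sequence(rle(fid)$lengths)
  keep <- (within - 1L) %% sample_stride == 0L
  fid <- fid[keep]; idx <- idx[keep]
  n_per_face <- tabulate(fid, nbins = nrow(mesh$faces))
  fa <- face_areas(mesh)
  w <- fa[fid] / n_per_face[fid]
  px <- matrix(texmap$pixels, ncol = 3)[idx, , drop = FALSE]
  lab <- srgb_to_lab(px)
  cloud <- tibble::tibble(r = px[, 1], g = px[, 2], b = px[, 3],
                          L = lab[, 1], a = lab[, 2], b_lab = lab[, 3],
                          weight = w, face = fid)
  attr(cloud, "specimen_id") <- specimen_id
  attr(cloud, "total_area") <- sum(fa[n_per_face > 0])
  class(cloud) <- c("color_cloud", class(cloud))
  cloud
}

#' Summarize a color cloud
#'
#' Weighted mean and covariance in CIELAB plus a weighted 3D histogram over
#' Lab bins.
#'
#' @param cloud a `color_cloud`.
#' @param bins number of histogram bins per Lab axis.
#' @return A `color_summary` list: `mean_lab`, `cov_lab`, `histogram`
#'   (tibble of non-empty bins), `total_weight`.
#' @export
summarize_color <- function(cloud, bins = 16L) {
  stopifnot(inherits(cloud, "color_cloud"), nrow(cloud) > 0)
  lab <- cbind(cloud$L, cloud$a, cloud$b_lab)
  w <- cloud$weight / sum(cloud$weight)
  mu <- colSums(lab * w)
  cen <- sweep(lab, 2, mu)
  cv <- crossprod(cen * sqrt(w), cen * sqrt(w))
  brk <- function(x, lo, hi) pmin(pmax(floor((x - lo) / (hi - lo) * bins) + 1L, 1L), bins)
  bin <- tibble::tibble(L_bin = brk(cloud$L, 0, 100),
                        a_bin = brk(cloud$a, -110, 110),
                        b_bin = brk(cloud$b_lab, -110, 110),
                        weight = cloud$weight)
  hist <- dplyr::summarise(dplyr::group_by(bin, .data$L_bin, .data$a_bin, .data$b_bin),
                           weight = sum(.data$weight), .groups = "drop")
  structure(list(mean_lab = stats::setNames(mu, c("L", "a", "b")),
                 cov_lab = cv, histogram = hist,
                 total_weight = sum(cloud$weight)),
            class = "color_summary")
}

#' @export
print.color_summary <- function(x, ...) {
  cat(sprintf("<color_summary> mean Lab (%.1f, %.1f, %.1f), total weight %.1f mm^2\n",
              x$mean_lab[1], x$mean_lab[2], x$mean_lab[3], x$total_weight))
  invisible(x)
}

#' Plot a color cloud in CIELAB a*-b* space
#'
#' Points are placed at their (a*, b*) chroma coordinates, colored by their
#' own sRGB value and sized by the surface area they represent.
#'
#' @param object a `color_cloud`.
#' @param max_points subsample cap for plotting.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot color_cloud
#' @export
autoplot.color_cloud <- function(object, max_points = 5000L, ...) {
  df <- as.data.frame(object)
  if (nrow(df) > max_points)
    df <- df[seq(1, nrow(df), length.out = max_points), ]
  df$col <- grDevices::rgb(df$r, df$g, df$b)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b_lab,
                                   size = .data$weight)) +
    ggplot2::geom_point(color = df$col, alpha = 0.7, show.legend = FALSE) +
    ggplot2::scale_size_area(max_size = 3) +
    ggplot2::labs(x = "a* (green-red)", y = "b* (blue-yellow)",
                  title = attr(object, "specimen_id")) +
    ggplot2::theme_minimal()
}

#' Plot digital vs reference measurements
#'
#' @param stats a `measurement_stats` object (from [compare_measurements()]).
#' @param ... unused.
#' @return a ggplot object with the identity line.
#' @method autoplot measurement_stats
#' @export
autoplot.measurement_stats <- function(stats, ...) {
  ggplot2::ggplot(stats$records,
                  ggplot2::aes(x = .data$reference_mm, y = .data$digital_mm)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, color = "grey50") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "hand-taken (mm)", y = "digital (mm)") +
    ggplot2::theme_minimal()
}

#' Write a color cloud as CSV (and optionally a PLY point cloud)
#'
#' @param cloud a `color_cloud`.
#' @param path CSV output path.
#' @param ply_path optional PLY output (positions are Lab coordinates,
#'   colors 8-bit sRGB) for external viewers.
#' @return `path`, invisibly.
#' @export
write_color_cloud <- function(cloud, path, ply_path = NULL) {
  utils::write.csv(as.data.frame(cloud)[, c("r", "g", "b", "L", "a", "b_lab",
                                            "weight")], path, row.names = FALSE)
  if (!is.null(ply_path)) {
    n <- nrow(cloud)
    hdr <- c("ply", "format ascii 1.0", paste("element vertex", n),
             "property float x", "property float y", "property float z",
             "property uchar red", "property uchar green", "property uchar blue",
             "end_header")
    body <- sprintf("%.3f %.3f %.3f %d %d %d", cloud$L, cloud$a, cloud$b_lab,
                    round(cloud$r * 255), round(cloud$g * 255), round(cloud$b * 255))
    writeLines(c(hdr, body), ply_path)
  }
  invisible(path)
}
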