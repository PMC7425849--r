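#' Capture-plan geometry
#'
#' Photo count and (elevation, azimuth) schedule for a turntable session:
#' `round(360 / step_deg)` stops per rotation, repeated at each elevation.
#' The default 3.75 degree step gives 96 photos per rotation and 288 over
#' three elevations.
#'
#' @param step_deg turntable step in degrees; must tile the circle.
#' @param elevations_deg camera elevations in degrees.
#' @return list with `count` and `schedule` (tibble of `index`,
#'   `elevation_deg`, `azimuth_deg` in capture order).
#' @export
capture_plan <- function(step_deg = 3.75, elevations_deg = c(-45, 0, 45)) {
  if (step_deg <= 0) stop("step_deg must be positive")
  n_steps <- round(360 / step_deg)
  if (abs(n_steps * step_deg - 360) > 1e-6)
    stop("step_deg must tile the circle")
  schedule <- tibble::tibble(
    index = seq_len(n_steps * length(elevations_deg)),
    elevation_deg = rep(elevations_deg, each = n_steps),
    azimuth_deg = rep((seq_len(n_steps) - 1) * step_deg,
                      length(elevations_deg)))
  list(count = nrow(schedule), schedule = schedule)
}

#' Pipeline configuration
#'
#' All tunables of the end-to-end pipeline in one validated list; round-trips
#' losslessly through YAML ([write_config()] / [read_config()]).
#'
#' @param step_deg,elevations_deg capture plan (defaults 3.75 and -45/0/45).
#' @param image_size render size for fixture captures (px).
#' @param voxel_size remeshing voxel in mm.
#' @param target_faces absolute decimation target, or `NULL` to use
#'   `target_fraction` of the remeshed count.
#' @param target_fraction decimation target as a fraction (default 0.1).
#' @param taubin list with `lam`, `mu`, `iterations`.
#' @param n_projections UV projections (8 or 6).
#' @param k_quality decimation quality multiplier.
#' @param texture_size baked texture resolution (power of two).
#' @param gutter_texels UV chart gutter.
#' @param mask_threshold backdrop mask deltaE fraction.
#' @param debris_threshold small-component area fraction for [clean()].
#' @param hole_perimeter max hole perimeter to fill (`NULL` = 10% of bbox
#'   diagonal).
#' @param n_scale_views photos used for ruler marker triangulation.
#' @param snap_tol landmark snap tolerance in mm.
#' @param stand_plane cutting plane for stand removal (`NULL` to skip).
#' @param seed integer seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(step_deg = 3.75, elevations_deg = c(-45, 0, 45),
                            image_size = 256L, voxel_size = 0.5,
                            target_faces = NULL, target_fraction = 0.1,
                            taubin = list(lam = 0.5, mu = -0.53, iterations = 10L),
                            n_projections = 8L, k_quality = 9,
                            texture_size = 4096L, gutter_texels = 4L,
                            mask_threshold = 0.12, debris_threshold = 0.01,
                            hole_perimeter = NULL, n_scale_views = 4L,
                            snap_tol = 1, stand_plane = list(point = c(0, 0, 0),
                                                             normal = c(0, 0, 1)),
                            seed = 1L) {
  cfg <- list(step_deg = step_deg, elevations_deg = elevations_deg,
              image_size = as.integer(image_size), voxel_size = voxel_size,
              target_faces = target_faces, target_fraction = target_fraction,
              taubin = taubin, n_projections = as.integer(n_projections),
              k_quality = k_quality, texture_size = as.integer(texture_size),
              gutter_texels = as.integer(gutter_texels),
              mask_threshold = mask_threshold,
              debris_threshold = debris_threshold,
              hole_perimeter = hole_perimeter,
              n_scale_views = as.integer(n_scale_views), snap_tol = snap_tol,
              stand_plane = stand_plane, seed = as.integer(seed))
  stopifnot(cfg$step_deg > 0, cfg$image_size >= 256, cfg$voxel_size > 0,
            cfg$target_fraction > 0, cfg$taubin$lam > 0,
            cfg$taubin$mu < -cfg$taubin$lam, cfg$taubin$iterations >= 1,
            cfg$mask_threshold > 0, cfg$mask_threshold < 1)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw[!vapply(raw, is.null, logical(1))])
}

config_hash <- function(config) rlang::hash(unclass(config))

#' Generate a complete fixture input directory
#'
#' Writes everything [run_specimen()] expects for one synthetic specimen: a
#' rendered capture (images, poses, chart regions, ruler markers), the raw
#' "scan" mesh in arbitrary model units with injected defects and stand
#' (emulating a photogrammetric reconstruction before any processing), and a
#' landmark manifest with the known reference measurement.
#'
#' @param seed specimen seed.
#' @param dir output directory.
#' @param config a `pipeline_config`.
#' @return `dir`, invisibly; the ground truth is stored in `truth.json`.
#' @export
fixture_input <- function(seed, dir, config = pipeline_config()) {
  truth <- generate_specimen(seed)
  def <- inject_defects(truth, seed)
  rng <- local_rng(seed + 104729L)
  model_scale <- rng$runif(1, 0.5, 2)
  render_turntable(truth, step_deg = config$step_deg,
                   elevations_deg = config$elevations_deg,
                   image_size = config$image_size, seed = seed,
                   model_scale = model_scale, out_dir = dir)
  scan <- def$mesh
  scan$vertices <- scan$vertices * model_scale
  scan$units <- "model"
  write_obj(scan, file.path(dir, "scan.obj"), overwrite = TRUE)
  lm <- truth$landmarks
  utils::write.csv(data.frame(
    trait = "bill_length",
    ax = lm["bill_tip", 1], ay = lm["bill_tip", 2], az = lm["bill_tip", 3],
    bx = lm["bill_base", 1], by = lm["bill_base", 2], bz = lm["bill_base", 3],
    reference_mm = truth$bill_length_mm),
    file.path(dir, "landmarks.csv"), row.names = FALSE)
  invisible(dir)
}

#' Run the full pipeline on one specimen
#'
#' Executes image preparation, scale calibration, mesh processing, texture
#' baking and phenomic extraction in order, writing every intermediate with
#' the pipeline's suffix conventions (`_masked.png`, `_highpoly.obj`,
#' `_lowpoly.obj`, `_albedo.png`, `measurements.csv`). A failed stage is
#' recorded with its cause and later stages are skipped; rerunning skips
#' stages whose outputs exist and whose config hash matches.
#'
#' @param config a `pipeline_config`.
#' @param input_dir directory with `images/`, `poses.csv`, `capture.json`,
#'   `markers.csv`, `scan.obj` and optionally `landmarks.csv` (see
#'   [fixture_input()]).
#' @param out_dir output directory for this specimen.
#' @param catalog catalog number (filename stem).
#' @return One-row manifest tibble: per-stage status and wall time, output
#'   paths.
#' @export
run_specimen <- function(config, input_dir, out_dir, catalog) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  stages <- c("imageprep", "scalecal", "meshproc", "texture", "phenomics")
  status <- stats::setNames(rep("pending", length(stages)), stages)
  secs <- stats::setNames(rep(NA_real_, length(stages)), stages)
  outputs <- character(0)
  state <- new.env()

  marker_path <- function(stage) file.path(out_dir, sprintf(".stage_%s.json", stage))
  cached <- function(stage, files) {
    mp <- marker_path(stage)
    file.exists(mp) && all(file.exists(files)) &&
      identical(jsonlite::read_json(mp)$hash, hash)
  }
  mark <- function(stage) jsonlite::write_json(list(hash = hash), marker_path(stage),
                                               auto_unbox = TRUE)

  run_stage <- function(stage, fun) {
    t0 <- Sys.time()
    res <- tryCatch({ r <- fun(); if (identical(r, "cached")) "ok (cached)" else "ok" },
                    error = function(e) paste0("failed: ", conditionMessage(e)))
    status[stage] <<- res
    secs[stage] <<- as.numeric(Sys.time() - t0, units = "secs")
    startsWith(res, "ok")
  }

  cap <- read_capture(input_dir)
  masked_dir <- file.path(out_dir, "masked")

  # whole-specimen fast path: everything already produced under this config
  final_outputs <- c(file.path(out_dir, sprintf("%s_highpoly.obj", catalog)),
                     file.path(out_dir, sprintf("%s_lowpoly.obj", catalog)),
                     file.path(out_dir, sprintf("%s_albedo.png", catalog)),
                     file.path(out_dir, "color_cloud.csv"))
  if (cached("phenomics", final_outputs)) {
    return(tibble::tibble(
      catalog_number = catalog, specimen_id = basename(input_dir),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
      !!!stats::setNames(as.list(rep("ok (cached)", length(stages))),
                         paste0("status_", stages)),
      !!!stats::setNames(as.list(rep(0, length(stages))), paste0("secs_", stages)),
      outputs = paste(final_outputs, collapse = ";"),
      config_hash = hash))
  }

  ok <- run_stage("imageprep", function() {
    files <- file.path(masked_dir, paste0(cap$ids, "_masked.png"))
    if (cached("imageprep", files)) return("cached")
    unlink(masked_dir, recursive = TRUE)
    prep_capture(cap, masked_dir, threshold = config$mask_threshold)
    mark("imageprep")
    "ok"
  })
  outputs <- c(outputs, masked_dir)

  scale_path <- file.path(out_dir, "scale.json")
  if (ok) ok <- run_stage("scalecal", function() {
    was_cached <- cached("scalecal", scale_path)
    if (!was_cached) {
      calibrate_scale(cap, n_views = config$n_scale_views,
                      report_path = scale_path)
      mark("scalecal")
    }
    rep <- jsonlite::read_json(scale_path, simplifyVector = TRUE)
    state$factor <- rep$factor_mm_per_unit
    if (was_cached) "cached" else "ok"
  })
  outputs <- c(outputs, scale_path)

  high_path <- file.path(out_dir, sprintf("%s_highpoly.obj", catalog))
  low_stub <- file.path(out_dir, sprintf("%s_lowpoly.obj", catalog))
  if (ok) ok <- run_stage("meshproc", function() {
    scan <- read_obj(file.path(input_dir, "scan.obj"))$mesh
    mesh_mm <- apply_scale(scan, state$factor)
    if (!is.null(config$stand_plane)) {
      cen <- face_centroids(mesh_mm)
      nrm <- config$stand_plane$normal
      below <- sweep(cen, 2, config$stand_plane$point) %*% nrm < 0
      if (any(below)) mesh_mm <- remove_stand(mesh_mm, plane = config$stand_plane)
    }
    mesh_mm <- clean(mesh_mm, component_area_threshold = config$debris_threshold,
                     max_hole_perimeter = config$hole_perimeter)$mesh
    if (file.exists(high_path)) unlink(high_path)
    write_obj(mesh_mm, high_path)
    remeshed <- voxel_remesh(mesh_mm, config$voxel_size)
    q <- build_quality(remeshed)
    target <- if (!is.null(config$target_faces)) config$target_faces else
      max(4L, round(nrow(remeshed$faces) * config$target_fraction))
    dec <- decimate(remeshed, target, q, k = config$k_quality)
    dec <- clean(dec, component_area_threshold = config$debris_threshold,
                 max_hole_perimeter = config$hole_perimeter)$mesh
    state$lowpoly <- taubin_smooth(dec, config$taubin$lam, config$taubin$mu,
                                   config$taubin$iterations)
    state$atlas <- generate_uv(state$lowpoly, n_projections = config$n_projections,
                               gutter_texels = config$gutter_texels,
                               atlas_size = config$texture_size)
    mark("meshproc")
  })
  outputs <- c(outputs, high_path)

  if (ok) ok <- run_stage("texture", function() {
    state$texmap <- bake_texture(state$lowpoly, state$atlas, cap,
                                 photos = masked_dir, size = config$texture_size,
                                 pose_scale = state$factor)
    aligned <- align_canonical(state$lowpoly)
    if (file.exists(low_stub)) unlink(low_stub)
    paths <- export_textured(aligned, state$atlas, state$texmap, out_dir, catalog)
    mark("texture")
  })
  outputs <- c(outputs, low_stub,
               file.path(out_dir, sprintf("%s_albedo.png", catalog)))

  meas_path <- file.path(out_dir, "measurements.csv")
  cloud_path <- file.path(out_dir, "color_cloud.csv")
  if (ok) ok <- run_stage("phenomics", function() {
    lm_path <- file.path(input_dir, "landmarks.csv")
    if (file.exists(lm_path)) {
      lms <- utils::read.csv(lm_path)
      recs <- lapply(seq_len(nrow(lms)), function(i) {
        d <- measure(state$lowpoly, as.numeric(lms[i, c("ax", "ay", "az")]),
                     as.numeric(lms[i, c("bx", "by", "bz")]),
                     snap_tol = config$snap_tol)
        tibble::tibble(specimen_id = catalog, trait = lms$trait[i],
                       digital_mm = d, reference_mm = lms$reference_mm[i])
      })
      utils::write.csv(dplyr::bind_rows(recs), meas_path, row.names = FALSE)
    }
    cloud <- extract_color_cloud(state$lowpoly, state$atlas, state$texmap,
                                 sample_stride = 4L, specimen_id = catalog)
    write_color_cloud(cloud, cloud_path)
    mark("phenomics")
  })
  outputs <- c(outputs, meas_path, cloud_path)

  tibble::tibble(
    catalog_number = catalog, specimen_id = basename(input_dir),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    !!!stats::setNames(as.list(status), paste0("status_", stages)),
    !!!stats::setNames(as.list(round(secs, 2)), paste0("secs_", stages)),
    outputs = paste(outputs, collapse = ";"),
    config_hash = hash)
}

#' Run a batch of specimens
#'
#' Sequential batch driver: one manifest row per specimen; a failed specimen
#' does not halt the batch. Shared outputs are all per-specimen, so
#' independent specimens may also be dispatched concurrently by the caller.
#'
#' @param config a `pipeline_config`.
#' @param input_dirs named character vector of input directories (names =
#'   catalog numbers).
#' @param out_root output root; each specimen gets a subdirectory.
#' @return The manifest tibble; also written to `out_root/manifest.csv`.
#' @export
run_batch <- function(config, input_dirs, out_root) {
  stopifnot(length(input_dirs) >= 1, !is.null(names(input_dirs)))
  dir.create(out_root, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(names(input_dirs), function(catalog) {
    run_specimen(config, input_dirs[[catalog]],
                 file.path(out_root, catalog), catalog)
  })
  manifest <- dplyr::bind_rows(rows)
  utils::write.csv(manifest, file.path(out_root, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
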