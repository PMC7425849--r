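#' Photo objects
#'
#' A `photo` is an sRGB raster in `[0,1]` with an id and an optional binary
#' foreground mask of the same size.
#'
#' @param pixels H x W x 3 array, sRGB in `[0,1]`.
#' @param id image identifier (used in output filenames).
#' @param mask optional H x W logical matrix.
#' @export
photo <- function(pixels, id, mask = NULL) {
  stopifnot(length(dim(pixels)) == 3, dim(pixels)[3] == 3)
  if (!is.null(mask))
    stopifnot(identical(dim(mask), dim(pixels)[1:2]))
  structure(list(pixels = pixels, id = id, mask = mask), class = "photo")
}

#' @export
print.photo <- function(x, ...) {
  cat(sprintf("<photo> %s (%d x %d)%s\n", x$id, dim(x$pixels)[1],
              dim(x$pixels)[2], if (is.null(x$mask)) "" else ", masked"))
  invisible(x)
}

#' Observe color-chart chips in a photo
#'
#' Averages each chip over the inner 60% of its annotated pixel region
#' (border pixels are dropped to avoid bleed).
#'
#' @param ph a [photo].
#' @param regions tibble with `chip`, `x0`, `x1`, `y0`, `y1` (1-based pixel
#'   rects), e.g. `capture$chart$regions`. `NULL` raises a chart-detection
#'   error: the pipeline may proceed uncalibrated with a warning.
#' @return tibble with `chip` and observed sRGB means `r`, `g`, `b`.
#' @export
locate_chart <- function(ph, regions) {
  stopifnot(inherits(ph, "photo"))
  if (is.null(regions) || nrow(regions) == 0)
    stop(errorCondition(paste0("chart-detection error: no chart region for image ", ph$id),
                        class = c("chart_detection_error", "error", "condition")))
  obs <- lapply(seq_len(nrow(regions)), function(k) {
    w <- regions$x1[k] - regions$x0[k] + 1
    h <- regions$y1[k] - regions$y0[k] + 1
    ix <- round(regions$x0[k] + 0.2 * w):round(regions$x1[k] - 0.2 * w)
    iy <- round(regions$y0[k] + 0.2 * h):round(regions$y1[k] - 0.2 * h)
    patch <- ph$pixels[iy, ix, , drop = FALSE]
    tibble::tibble(chip = regions$chip[k],
                   r = mean(patch[, , 1]), g = mean(patch[, , 2]),
                   b = mean(patch[, , 3]))
  })
  dplyr::bind_rows(obs)
}

#' Standardize exposure and white balance against a gray reference
#'
#' Applies per-channel gains `g_c = reference_gray_c / observed_gray_c` in
#' linear light (inverse sRGB companding, gain, re-encode, clip to `[0,1]`).
#' Both gray arguments are *linear-light* RGB values; use
#' [srgb_to_linear()] on chip means observed by [locate_chart()]. After
#' standardization the chart's gray chip matches the reference within 1/255
#' per channel (8-bit quantization).
#'
#' @param ph a [photo].
#' @param observed_gray length-3 linear RGB of the observed 75% gray chip
#'   (all channels > 0).
#' @param reference_gray length-3 linear RGB of the reference (defaults to
#'   the linearized 75% neutral chip).
#' @return The standardized [photo]; per-channel gains in `attr(, "gains")`.
#' @export
standardize <- function(ph, observed_gray,
                        reference_gray = srgb_to_linear(c(0.75, 0.75, 0.75))) {
  stopifnot(inherits(ph, "photo"))
  observed_gray <- as.numeric(observed_gray)
  if (any(observed_gray <= 0))
    stop("calibration error: observed gray has non-positive channel")
  gains <- as.numeric(reference_gray) / observed_gray
  lin <- srgb_to_linear(ph$pixels)
  for (ch in 1:3) lin[, , ch] <- lin[, , ch] * gains[ch]
  out <- ph
  out$pixels <- linear_to_srgb(pmin(pmax(lin, 0), 1))
  attr(out, "gains") <- gains
  out
}

#' Mask the backdrop, isolating the specimen
#'
#' Foreground = pixels whose CIELAB distance to the backdrop color exceeds
#' `threshold * 100` deltaE units, followed by morphological closing (disc
#' radius 2 px) and retention of the largest foreground component plus any
#' component touching it. Run after [standardize()] so the backdrop matches
#' its nominal color.
#'
#' @param ph a [photo].
#' @param backdrop_rgb sRGB backdrop color.
#' @param threshold color-distance threshold as a fraction of deltaE = 100;
#'   default 0.12 (deltaE 12), robust to mild shading on a matte backdrop.
#' @return The [photo] with `mask` set.
#' @export
mask_background <- function(ph, backdrop_rgb, threshold = 0.12) {
  stopifnot(inherits(ph, "photo"))
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
  dims <- dim(ph$pixels)[1:2]
  px <- matrix(ph$pixels, ncol = 3)
  lab <- srgb_to_lab(px)
  lab_bg <- srgb_to_lab(backdrop_rgb)
  de <- delta_e(lab, lab_bg)
  fg <- matrix(de > threshold * 100, dims[1], dims[2])
  if (!any(fg))
    stop(errorCondition(paste0("masking error: empty foreground in image ", ph$id),
                        class = c("masking_error", "error", "condition")))
  closed <- EBImage::closing(EBImage::Image(fg * 1),
                             EBImage::makeBrush(5, shape = "disc"))
  lab_img <- EBImage::bwlabel(closed)
  labm <- EBImage::imageData(lab_img)
  sizes <- tabulate(labm[labm > 0])
  main <- which.max(sizes)
  main_mask <- labm == main
  grown <- EBImage::imageData(EBImage::dilate(
    EBImage::Image(main_mask * 1), EBImage::makeBrush(3, shape = "box"))) > 0.5
  touching <- unique(labm[grown & labm > 0])
  out <- ph
  out$mask <- matrix(labm %in% touching, dims[1], dims[2])
  out
}

#' Write a masked photo
#'
#' Writes `<id>_masked.png` with backdrop pixels zeroed and the mask stored in
#' the alpha channel (lossless PNG, exact round-trip). Refuses to overwrite.
#'
#' @param ph a [photo] with a mask.
#' @param out_dir output directory (created if missing).
#' @return The output path.
#' @export
write_masked <- function(ph, out_dir) {
  stopifnot(inherits(ph, "photo"))
  if (is.null(ph$mask)) stop("missing mask: run mask_background() first")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(out_dir, paste0(ph$id, "_masked.png"))
  if (file.exists(path))
    stop("refusing to overwrite existing masked image: ", path)
  rgba <- array(0, dim = c(dim(ph$pixels)[1:2], 4))
  m <- ph$mask * 1
  for (ch in 1:3) rgba[, , ch] <- ph$pixels[, , ch] * m
  rgba[, , 4] <- m
  png::writePNG(rgba, path)
  path
}

#' Standardize and mask a whole capture
#'
#' The batch image-preparation stage: for each image, observe the chart's 75%
#' gray chip, standardize exposure/white balance in linear light, mask the
#' backdrop and write `<id>_masked.png`. If the capture has no chart the
#' images are masked uncalibrated, with a warning.
#'
#' @param capture a `turntable_capture`.
#' @param out_dir directory for masked PNGs and the batch log.
#' @param threshold mask color-distance threshold (see [mask_background()]).
#' @return tibble log: one row per image with gains, gray-chip residual
#'   (sRGB, after standardization) and mask area fraction; also written to
#'   `prep_log.csv` in `out_dir`.
#' @export
prep_capture <- function(capture, out_dir, threshold = 0.12) {
  stopifnot(inherits(capture, "turntable_capture"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ref_gray_lin <- srgb_to_linear(c(0.75, 0.75, 0.75))
  rows <- vector("list", length(capture$ids))
  for (i in seq_along(capture$ids)) {
    ph <- photo(capture_image(capture, i), capture$ids[i])
    gains <- c(NA_real_, NA_real_, NA_real_)
    resid <- NA_real_
    ph2 <- tryCatch({
      obs <- locate_chart(ph, capture$chart$regions)
      gray <- as.numeric(obs[obs$chip == "gray_75", c("r", "g", "b")])
      std <- standardize(ph, srgb_to_linear(gray), ref_gray_lin)
      gains <- attr(std, "gains")
      post <- locate_chart(std, capture$chart$regions)
      resid <- max(abs(as.numeric(post[post$chip == "gray_75",
                                       c("r", "g", "b")]) - 0.75))
      std
    }, chart_detection_error = function(e) {
      warning("proceeding uncalibrated: ", conditionMessage(e))
      ph
    })
    ph2 <- mask_background(ph2, capture$backdrop_rgb, threshold)
    path <- write_masked(ph2, out_dir)
    rows[[i]] <- tibble::tibble(
      image_id = ph$id, gain_r = gains[1], gain_g = gains[2], gain_b = gains[3],
      chip_residual = resid, mask_fraction = mean(ph2$mask), path = path)
  }
  log <- dplyr::bind_rows(rows)
  utils::write.csv(log, file.path(out_dir, "prep_log.csv"), row.names = FALSE)
  log
}

#' Read a masked photo written by [write_masked()]
#' @param path path to a `*_masked.png`.
#' @return a [photo] with mask restored from the alpha channel.
#' @export
read_masked <- function(path) {
  px <- png::readPNG(path)
  stopifnot(length(dim(px)) == 3, dim(px)[3] == 4)
  id <- sub("_masked\\.png$", "", basename(path))
  photo(px[, , 1:3, drop = FALSE], id, mask = px[, , 4] > 0.5)
}
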