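#' Color-space helpers
#'
#' `srgb_to_linear()` / `linear_to_srgb()` apply the standard sRGB transfer
#' function (IEC 61966-2-1) elementwise; `srgb_to_lab()` converts sRGB triples
#' to CIELAB under D65 / 2-degree observer; `delta_e()` is the Euclidean
#' CIE76 color difference in Lab.
#'
#' @param x numeric vector/matrix/array of sRGB (or linear) values in `[0,1]`.
#' @return Same shape as the input (or an n x 3 Lab matrix for
#'   `srgb_to_lab()`).
#' @export
srgb_to_linear <- function(x) {
  out <- ifelse(x <= 0.04045, x / 12.92, ((x + 0.055) / 1.055)^2.4)
  dim(out) <- dim(x)
  out
}

#' @rdname srgb_to_linear
#' @export
linear_to_srgb <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  out <- ifelse(x <= 0.0031308, 12.92 * x, 1.055 * x^(1 / 2.4) - 0.055)
  dim(out) <- dim(x)
  out
}

#' @rdname srgb_to_linear
#' @param srgb n x 3 matrix (or length-3 vector) of sRGB values in `[0,1]`.
#' @export
srgb_to_lab <- function(srgb) {
  if (is.null(dim(srgb))) srgb <- matrix(srgb, ncol = 3)
  grDevices::convertColor(srgb, from = "sRGB", to = "Lab")
}

#' @rdname srgb_to_linear
#' @param lab_a,lab_b n x 3 CIELAB matrices (or length-3 vectors).
#' @export
delta_e <- function(lab_a, lab_b) {
  if (is.null(dim(lab_a))) lab_a <- matrix(lab_a, ncol = 3)
  if (is.null(dim(lab_b))) lab_b <- matrix(lab_b, ncol = 3)
  if (nrow(lab_b) == 1 && nrow(lab_a) > 1)
    lab_b <- lab_b[rep(1, nrow(lab_a)), , drop = FALSE]
  sqrt(rowSums((lab_a - lab_b)^2))
}
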