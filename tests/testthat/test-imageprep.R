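test_that("chart observation follows the linear gain model", {
  cap <- capture_small(1)
  img <- capture_image(cap, 1)
  ph <- photo(img, "a")
  obs <- locate_chart(ph, cap$chart$regions)
  gray <- as.numeric(obs[obs$chip == "gray_75", c("r", "g", "b")])
  # observed chip in linear light = gain * linear(reference)
  expect_lt(max(abs(srgb_to_linear(gray) -
                      cap$gains[1, ] * srgb_to_linear(rep(0.75, 3)))), 1.5 / 255)
  expect_error(locate_chart(ph, NULL), class = "chart_detection_error")
})

test_that("standardize applies per-channel linear gains exactly", {
  # forced by the gain definition: reference/observed
  px <- array(0.5, dim = c(8, 8, 3))
  ph <- photo(px, "x")
  out <- standardize(ph, observed_gray = c(0.6, 0.5, 0.4),
                     reference_gray = c(0.75, 0.75, 0.75))
  expect_equal(attr(out, "gains"), c(1.25, 1.5, 1.875))
  # identity case
  same <- standardize(ph, c(0.4, 0.4, 0.4), c(0.4, 0.4, 0.4))
  expect_equal(same$pixels, ph$pixels, tolerance = 1e-12)
  expect_error(standardize(ph, c(0, 0.5, 0.5)), "calibration error")
})

test_that("standardization is idempotent and agrees across a capture", {
  cap <- capture_small(1)
  grays <- sapply(seq_along(cap$ids), function(i) {
    p <- photo(capture_image(cap, i), cap$ids[i])
    o <- locate_chart(p, cap$chart$regions)
    g <- srgb_to_linear(as.numeric(o[o$chip == "gray_75", c("r", "g", "b")]))
    s <- standardize(p, g)
    o2 <- locate_chart(s, cap$chart$regions)
    g2 <- as.numeric(o2[o2$chip == "gray_75", c("r", "g", "b")])
    # post-standardization chip equals the reference
    expect_lt(max(abs(g2 - 0.75)), 1 / 255)
    # idempotence: a second pass with the updated gray changes nothing
    s2 <- standardize(s, srgb_to_linear(g2))
    expect_lt(max(abs(s2$pixels - s$pixels)), 1 / 255)
    g2
  })
  expect_lt(max(grays) - min(grays), 2 / 255)
})

test_that("masking recovers the true silhouette", {
  cap <- capture_small(1)
  for (i in c(1, 10, 20)) {
    p <- photo(capture_image(cap, i), cap$ids[i])
    o <- locate_chart(p, cap$chart$regions)
    s <- standardize(p, srgb_to_linear(as.numeric(
      o[o$chip == "gray_75", c("r", "g", "b")])))
    m <- mask_background(s, cap$backdrop_rgb)
    sil <- capture_silhouette(cap, i)
    iou <- sum(m$mask & sil) / sum(m$mask | sil)
    expect_gte(iou, 0.95)
  }
})

test_that("masking error paths and threshold monotonicity", {
  flat <- photo(array(rep(c(0.72, 0.80, 0.88), each = 64 * 64),
                      dim = c(64, 64, 3)), "flat")
  expect_error(mask_background(flat, c(0.72, 0.80, 0.88)),
               class = "masking_error")
  expect_error(mask_background(flat, c(0.72, 0.80, 0.88), threshold = 1.2),
               "in \\(0,1\\)")
  # pre-morphology foreground never grows as the threshold increases
  cap <- capture_small(1)
  p <- photo(capture_image(cap, 1), "x")
  lab <- srgb_to_lab(matrix(p$pixels, ncol = 3))
  de <- delta_e(lab, srgb_to_lab(cap$backdrop_rgb))
  fgs <- sapply(c(0.05, 0.12, 0.3, 0.6), function(thr) sum(de > thr * 100))
  expect_true(all(diff(fgs) <= 0))
})

test_that("masked photos round-trip losslessly with the _masked convention", {
  cap <- capture_small(1)
  p <- mask_background(photo(capture_image(cap, 1), "IMG_0001"),
                       cap$backdrop_rgb)
  d <- tempfile("masked_")
  path <- write_masked(p, d)
  expect_equal(basename(path), "IMG_0001_masked.png")
  rt <- read_masked(path)
  expect_identical(rt$mask, p$mask)
  expect_error(write_masked(p, d), "refusing to overwrite")
  expect_error(write_masked(photo(capture_image(cap, 1), "y"), d), "missing mask")
})
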