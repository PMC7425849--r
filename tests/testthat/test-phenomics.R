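test_that("measure matches closed forms and construction truths", {
  b <- mesh_box(c(1, 1, 1)); b$units <- "mm"
  expect_equal(measure(b, c(-0.5, -0.5, -0.5), c(0.5, 0.5, 0.5)), sqrt(3),
               tolerance = 1e-9)
  tr <- specimen_small(1)
  expect_equal(measure(tr$mesh, tr$landmarks["bill_tip", ],
                       tr$landmarks["bill_base", ]),
               tr$bill_length_mm, tolerance = 1e-12)
  # vertex-id form and rigid invariance
  d0 <- measure(tr$mesh, 1L, 2L)
  th <- 1.1
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  moved <- transform_mesh(tr$mesh, R, c(3, -8, 12))
  expect_equal(measure(moved, 1L, 2L), d0, tolerance = 1e-9)
  # geodesic is at least the chord
  g <- measure(tr$mesh, tr$landmarks["bill_tip", ], tr$landmarks["bill_base", ],
               method = "geodesic")
  expect_gte(g, tr$bill_length_mm - 1e-9)
  # snap error for a point far off the surface
  expect_error(measure(tr$mesh, c(0, 0, 500), c(0, 0, -500)), "snap error")
})

test_that("measurement statistics match hand arithmetic and recomputation", {
  same <- compare_measurements(tibble::tibble(digital_mm = c(10, 12, 14),
                                              reference_mm = c(10, 12, 14)))
  expect_equal(same$mean_abs_diff_mm, 0)
  expect_equal(same$mean_rel_err_fraction, 0)
  expect_equal(same$repeatability_fraction, 1)

  two <- compare_measurements(tibble::tibble(digital_mm = c(14, 14),
                                             reference_mm = c(13.5, 14.5)))
  expect_equal(two$mean_abs_diff_mm, 0.5)
  expect_equal(two$mean_rel_err_fraction, mean(c(0.5 / 13.5, 0.5 / 14.5)),
               tolerance = 1e-12)

  rng <- specimen3d:::local_rng(11)
  r <- rng$runif(20, 10, 18)
  d <- r * (1 + rng$rnorm(20, 0, 0.03))
  st <- compare_measurements(tibble::tibble(digital_mm = d, reference_mm = r))
  expect_equal(st$mean_abs_diff_mm, mean(abs(d - r)), tolerance = 1e-12)
  expect_equal(st$mean_rel_err_fraction, mean(abs(d - r) / r), tolerance = 1e-12)
  expect_equal(st$repeatability_fraction, 1 - mean(abs(d - r)) / mean(r),
               tolerance = 1e-12)
  expect_gt(st$icc, 0.9)
  expect_error(compare_measurements(tibble::tibble(digital_mm = numeric(0),
                                                   reference_mm = numeric(0))),
               "no measurement")
  gl <- glance(st)
  expect_equal(gl$n, 20)
  td <- tidy(st)
  expect_equal(nrow(td), 4)
})

test_that("color clouds are area-weighted and stride-invariant", {
  lp <- lowpoly_small(1)
  frgb <- lp$truth$albedo_face_rgb[
    closest_points(lp$truth$mesh, face_centroids(lp$mesh))$face, ]
  tm <- texture_from_albedo(lp$mesh, lp$atlas, frgb, 256)
  for (stride in c(1L, 3L)) {
    cl <- extract_color_cloud(lp$mesh, lp$atlas, tm, sample_stride = stride)
    expect_lt(abs(sum(cl$weight) - attr(cl, "total_area")) /
                attr(cl, "total_area"), 1e-9)
    expect_lt(abs(attr(cl, "total_area") - mesh_area(lp$mesh)) /
                mesh_area(lp$mesh), 0.01)
  }
})

test_that("color summaries match direct moment computation", {
  # single color: zero variance
  one <- tibble::tibble(r = 0.8, g = 0.1, b = 0.1)
  lab1 <- srgb_to_lab(as.matrix(one))
  cl1 <- tibble::tibble(r = rep(0.8, 5), g = 0.1, b = 0.1,
                        L = lab1[1], a = lab1[2], b_lab = lab1[3],
                        weight = rep(2, 5), face = 1:5)
  class(cl1) <- c("color_cloud", class(cl1))
  s1 <- summarize_color(cl1)
  expect_lt(max(abs(s1$cov_lab)), 1e-12)
  expect_equal(unname(s1$mean_lab), as.numeric(lab1), tolerance = 1e-9)

  # two equal-weight colors: mean = midpoint in Lab
  labs <- srgb_to_lab(rbind(c(0.9, 0.1, 0.1), c(0.1, 0.1, 0.9)))
  cl2 <- tibble::tibble(r = c(0.9, 0.1), g = 0.1, b = c(0.1, 0.9),
                        L = labs[, 1], a = labs[, 2], b_lab = labs[, 3],
                        weight = c(1, 1), face = 1:2)
  class(cl2) <- c("color_cloud", class(cl2))
  s2 <- summarize_color(cl2)
  expect_equal(unname(s2$mean_lab), unname(colMeans(labs)), tolerance = 1e-9)

  # seeded random cloud: weighted moments equal direct recomputation
  rng <- specimen3d:::local_rng(5)
  n <- 200
  px <- matrix(rng$runif(3 * n), ncol = 3)
  lab <- srgb_to_lab(px)
  w <- rng$runif(n, 0.5, 2)
  cl3 <- tibble::tibble(r = px[, 1], g = px[, 2], b = px[, 3],
                        L = lab[, 1], a = lab[, 2], b_lab = lab[, 3],
                        weight = w, face = seq_len(n))
  class(cl3) <- c("color_cloud", class(cl3))
  s3 <- summarize_color(cl3)
  wn <- w / sum(w)
  mu <- colSums(lab * wn)
  expect_equal(unname(s3$mean_lab), unname(mu), tolerance = 1e-9)
  cen <- sweep(lab, 2, mu)
  expect_equal(unname(s3$cov_lab), unname(crossprod(cen * sqrt(wn))),
               tolerance = 1e-9)
  expect_equal(sum(s3$histogram$weight), sum(w), tolerance = 1e-9)
})

test_that("cloud export and plots work", {
  lp <- lowpoly_small(1)
  frgb <- matrix(rep(c(0.6, 0.4, 0.2), each = nrow(lp$mesh$faces)), ncol = 3)
  tm <- texture_from_albedo(lp$mesh, lp$atlas, frgb, 256)
  cl <- extract_color_cloud(lp$mesh, lp$atlas, tm, sample_stride = 4)
  csv <- tempfile(fileext = ".csv"); ply <- tempfile(fileext = ".ply")
  write_color_cloud(cl, csv, ply)
  back <- read.csv(csv)
  expect_equal(nrow(back), nrow(cl))
  expect_equal(readLines(ply, n = 1), "ply")
  expect_s3_class(autoplot(cl), "gg")
  st <- compare_measurements(tibble::tibble(digital_mm = c(13, 14),
                                            reference_mm = c(13.5, 14)))
  expect_s3_class(autoplot(st), "gg")
})
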