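test_that("noiseless triangulation recovers exact marker positions", {
  cap <- capture_small(1)
  poses <- stats::setNames(cap$poses, cap$ids)
  truth_pt <- cap$ruler$endpoints[1, ]
  ann <- cap$ruler$annotations
  obs <- ann[ann$marker_id == "ruler_A", ][c(2, 8, 14), ]
  tri <- triangulate_marker(obs, poses)
  expect_lt(max(abs(tri$point - truth_pt)), 1e-6)
  expect_lt(tri$residual_px, 1e-6)
})

test_that("triangulation error paths: too few views and parallel rays", {
  cap <- capture_small(1)
  poses <- stats::setNames(cap$poses, cap$ids)
  ann <- cap$ruler$annotations
  one <- ann[ann$marker_id == "ruler_A", ][1, ]
  expect_error(triangulate_marker(one, poses), "at least 2")
  # same pose twice = identical rays
  dup <- rbind(one, one)
  expect_error(triangulate_marker(dup, poses), "near-parallel")
})

test_that("solve_scale arithmetic, identity and degenerate cases", {
  # distance 0.5 model units, known 10 mm -> factor 20
  s <- solve_scale(c(0, 0, 0), c(0.5, 0, 0), 10)
  expect_equal(s$factor, 20)
  expect_equal(solve_scale(c(0, 0, 0), c(10, 0, 0), 10)$factor, 1)
  expect_error(solve_scale(c(1, 1, 1), c(1, 1, 1), 10), "degenerate-scale")
  expect_error(solve_scale(c(0, 0, 0), c(1, 0, 0), -5), "positive")
})

test_that("apply_scale scales lengths linearly and areas quadratically", {
  m <- mesh_irregular()
  m$units <- "model"
  s <- solve_scale(c(0, 0, 0), c(0.5, 0, 0), 10)
  out <- apply_scale(m, s)
  expect_equal(out$units, "mm")
  expect_equal(mesh_area(out), mesh_area(m) * s$factor^2, tolerance = 1e-12)
  e1 <- sqrt(sum((m$vertices[1, ] - m$vertices[2, ])^2))
  e2 <- sqrt(sum((out$vertices[1, ] - out$vertices[2, ])^2))
  expect_equal(e2, e1 * s$factor, tolerance = 1e-12)
  ident <- apply_scale(m, 1)
  expect_equal(ident$vertices, m$vertices, tolerance = 1e-15)
})

test_that("end-to-end calibration recovers the renderer's true scale", {
  tr <- specimen_small(1)
  cap <- render_turntable(tr, step_deg = 45, elevations_deg = 0, seed = 1,
                          model_scale = 0.61)
  sol <- calibrate_scale(cap, n_views = 4)
  expect_lt(abs(sol$factor - cap$true_factor_mm_per_unit) /
              cap$true_factor_mm_per_unit, 0.001)
})

test_that("scale recovery stays within 0.5% under 0.5 px click noise", {
  tr <- specimen_small(1)
  cap <- render_turntable(tr, step_deg = 15, elevations_deg = 0, seed = 1)
  errs <- vapply(1:100, function(s) {
    sol <- calibrate_scale(cap, n_views = 5, noise_px = 0.5, seed = s)
    abs(sol$factor - cap$true_factor_mm_per_unit) / cap$true_factor_mm_per_unit
  }, numeric(1))
  expect_lt(median(errs), 0.005)
})

test_that("marker CSV reader validates its schema", {
  p <- tempfile(fileext = ".csv")
  write.csv(data.frame(marker_id = "A", image_id = "IMG_0001", u = 1, v = 2),
            p, row.names = FALSE)
  obs <- read_marker_observations(p)
  expect_equal(nrow(obs), 1)
  bad <- tempfile(fileext = ".csv")
  write.csv(data.frame(x = 1), bad, row.names = FALSE)
  expect_error(read_marker_observations(bad), "columns")
})
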