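test_that("capture count law holds across schedules", {
  tr <- specimen_small(1)
  cases <- list(list(step = 90, el = 0, n = 4),
                list(step = 120, el = c(-45, 45), n = 6),
                list(step = 45, el = c(-45, 0, 45), n = 24))
  for (cs in cases) {
    cap <- render_turntable(tr, step_deg = cs$step, elevations_deg = cs$el,
                            seed = 1)
    expect_length(cap$ids, cs$n)
    expect_length(cap$poses, cs$n)
  }
  expect_error(render_turntable(tr, step_deg = -3), "positive")
  expect_error(render_turntable(tr, step_deg = 7), "tile the circle")
  expect_error(render_turntable(tr, step_deg = 90, image_size = 128), ">= 256")
})

test_that("poses are orthonormal and reproject landmarks into the subject", {
  tr <- specimen_small(1)
  cap <- capture_small(1)
  for (i in c(1, 9, 17)) {
    R <- cap$poses[[i]]$rotation
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-8)
    expect_lt(abs(det(R) - 1), 1e-8)
    # specimen centroid projects inside the frame
    pr <- project_points(cap$poses[[i]], colMeans(tr$mesh$vertices))
    expect_true(pr$u > 0 && pr$u < cap$image_size &&
                  pr$v > 0 && pr$v < cap$image_size)
  }
  # each landmark projects within 1 px of the ID-buffer footprint of its
  # nearest face, whenever that face rasterizes to any pixel at all
  # ring of faces around each landmark (they are mesh vertices by design)
  near <- closest_points(tr$mesh, tr$landmarks)
  ring <- lapply(seq_len(nrow(tr$landmarks)), function(k) {
    tri <- tr$mesh$faces[near$face[k], ]
    d2 <- rowSums(sweep(tr$mesh$vertices[tri, , drop = FALSE], 2,
                        near$point[k, ])^2)
    vk <- tri[which.min(d2)]
    which(rowSums(matrix(tr$mesh$faces == vk, ncol = 3)) > 0)
  })
  S <- cap$image_size
  checked <- 0L
  for (i in seq_along(cap$ids)) {
    pose <- cap$poses[[i]]
    res <- specimen3d:::.cpp_render(
      tr$mesh$vertices, tr$mesh$faces - 1L, pose$rotation, pose$translation,
      pose$fx, pose$fy, pose$cx, pose$cy, S, S,
      matrix(0, nrow(tr$mesh$faces), 3), 0, 0, matrix(c(0, 0, -1), 1), FALSE)
    fid <- matrix(res$faceid, S, S) + 1L
    pr <- project_points(pose, tr$landmarks)
    for (k in seq_len(nrow(tr$landmarks))) {
      hits <- which(matrix(fid %in% ring[[k]], S, S), arr.ind = TRUE)
      # skip views where the ring is occluded or so edge-on that fewer than a
      # few pixel centers sample its footprint (quantization dominates there)
      if (nrow(hits) < 4) next
      dpx <- sqrt((hits[, 2] - 0.5 - pr$u[k])^2 + (hits[, 1] - 0.5 - pr$v[k])^2)
      expect_lte(min(dpx), 1.5)
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 10)  # the property was actually exercised
})

test_that("rendered chart chips carry their reference values under the gain", {
  cap <- capture_small(1)
  img <- capture_image(cap, 2)
  ph <- photo(img, cap$ids[2])
  obs <- locate_chart(ph, cap$chart$regions)
  ref <- chart_reference()
  expected <- linear_to_srgb(srgb_to_linear(as.matrix(ref[, c("r", "g", "b")])) *
                               rep(cap$gains[2, ], each = nrow(ref)))
  expect_lt(max(abs(as.matrix(obs[, c("r", "g", "b")]) - expected)), 1 / 255)
})

test_that("rendering is deterministic and written captures read back", {
  tr <- specimen_small(2)
  a <- render_turntable(tr, step_deg = 120, elevations_deg = 0, seed = 5)
  b <- render_turntable(tr, step_deg = 120, elevations_deg = 0, seed = 5)
  expect_identical(capture_image(a, 3), capture_image(b, 3))
  d <- tempfile("capio_")
  render_turntable(tr, step_deg = 120, elevations_deg = 0, seed = 5,
                   out_dir = d)
  rc <- read_capture(d)
  expect_identical(capture_image(rc, 3), capture_image(a, 3))
  expect_equal(rc$poses[[2]]$rotation, a$poses[[2]]$rotation, tolerance = 1e-12)
  expect_equal(rc$true_factor_mm_per_unit, a$true_factor_mm_per_unit)
  # ruler annotations present with both markers
  expect_setequal(unique(rc$ruler$annotations$marker_id), c("ruler_A", "ruler_B"))
})
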