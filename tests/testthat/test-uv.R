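test_that("an axis-aligned cube unwraps into 6 distortion-free charts", {
  b <- mesh_box(c(2, 2, 2))
  at <- generate_uv(b, n_projections = 6, relax_iterations = 0)
  expect_equal(at$n_charts, 6)
  expect_true(all(at$uv >= 0 & at$uv <= 1))
  d <- uv_area_distortion(b, at)
  expect_equal(unname(d), rep(1, nrow(b$faces)), tolerance = 1e-9)
})

test_that("fixture atlases assign every face with bounded distortion", {
  lp <- lowpoly_small(1)
  at <- lp$atlas
  expect_equal(nrow(at$uv), 3 * nrow(lp$mesh$faces))
  expect_length(at$chart, nrow(lp$mesh$faces))
  expect_true(all(at$chart >= 1 & at$chart <= at$n_charts))
  expect_true(all(at$uv >= 0 & at$uv <= 1))
  d <- uv_area_distortion(lp$mesh, at)
  expect_gte(mean(d >= 0.5 & d <= 2), 0.95)
})

test_that("rasterized charts are pairwise disjoint with a gutter", {
  lp <- lowpoly_small(1)
  size <- 512L
  cr <- rasterize_charts(lp$atlas, size)
  # every covered texel belongs to exactly one chart by construction of the
  # raster; disjointness with a gutter = no two charts touch even after
  # 1-texel dilation
  for (ci in seq_len(lp$atlas$n_charts)) {
    m <- cr == ci
    if (!any(m)) next
    dil <- m
    for (dy in -1:1) for (dx in -1:1) {
      ys <- pmin(pmax(seq_len(size) + dy, 1), size)
      xs <- pmin(pmax(seq_len(size) + dx, 1), size)
      dil <- dil | m[ys, xs]
    }
    expect_false(any(dil & cr > 0 & cr != ci))
  }
})

test_that("6-projection preset also covers the fixture", {
  lp <- lowpoly_small(1)
  at6 <- generate_uv(lp$mesh, n_projections = 6)
  expect_true(all(at6$uv >= 0 & at6$uv <= 1))
  expect_true(all(at6$chart_direction %in% 1:6))
  expect_error(generate_uv(lp$mesh, n_projections = 5), "8.*or 6")
})

test_that("OBJ export honors suffix conventions and round-trips", {
  lp <- lowpoly_small(1)
  d <- tempfile("uvobj_")
  p <- export_obj(lp$mesh, lp$atlas, d, "lowpoly", "MLZ12342")
  expect_equal(basename(p), "MLZ12342_lowpoly.obj")
  expect_error(export_obj(lp$mesh, lp$atlas, d, "lowpoly", "MLZ12342"),
               "refusing to overwrite")
  rt <- read_obj(p)
  expect_identical(rt$mesh$faces, lp$mesh$faces)
  expect_lt(max(abs(rt$uv - lp$atlas$uv)), 1e-7)
  # vt record count equals the number of distinct face-corner UVs
  key <- paste(sprintf("%.8f", lp$atlas$uv[, 1]),
               sprintf("%.8f", lp$atlas$uv[, 2]))
  expect_equal(rt$n_vt, length(unique(key)))
})
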