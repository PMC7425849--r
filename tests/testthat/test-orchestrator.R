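test_that("capture plans reproduce the standard schedules", {
  expect_equal(capture_plan(3.75, 0)$count, 96)
  expect_equal(capture_plan(3.75, c(-45, 0, 45))$count, 288)
  expect_equal(capture_plan(120, 0)$count, 3)
  plan <- capture_plan(90, c(0, 45))
  expect_equal(plan$schedule$azimuth_deg, c(0, 90, 180, 270, 0, 90, 180, 270))
  expect_equal(plan$schedule$elevation_deg, rep(c(0, 45), each = 4))
  expect_error(capture_plan(-1), "positive")
  expect_error(capture_plan(7), "tile")
})

test_that("pipeline configuration validates and round-trips through YAML", {
  cfg <- pipeline_config(step_deg = 30, voxel_size = 0.8, texture_size = 512L)
  p <- tempfile(fileext = ".yaml")
  write_config(cfg, p)
  cfg2 <- read_config(p)
  expect_equal(unclass(cfg)[sort(names(cfg))], unclass(cfg2)[sort(names(cfg2))])
  expect_error(pipeline_config(step_deg = -3))
  expect_error(pipeline_config(taubin = list(lam = 0.5, mu = -0.3,
                                             iterations = 10)))
})

test_that("a fixtures-backed run produces every expected artifact", {
  cfg <- pipeline_config(step_deg = 45, elevations_deg = c(0, 45),
                         voxel_size = 0.8, texture_size = 512L)
  indir <- tempfile("fxin_")
  outdir <- tempfile("fxout_")
  fixture_input(11, indir, cfg)
  expect_true(all(file.exists(file.path(indir, c("poses.csv", "capture.json",
                                                 "markers.csv", "scan.obj",
                                                 "landmarks.csv")))))
  row <- run_specimen(cfg, indir, outdir, "MLZ0011")
  expect_true(all(unlist(row[, grep("^status_", names(row))]) == "ok"))
  expect_true(file.exists(file.path(outdir, "MLZ0011_highpoly.obj")))
  expect_true(file.exists(file.path(outdir, "MLZ0011_lowpoly.obj")))
  expect_true(file.exists(file.path(outdir, "MLZ0011_albedo.png")))
  expect_true(file.exists(file.path(outdir, "measurements.csv")))
  expect_gt(length(list.files(file.path(outdir, "masked"),
                              pattern = "_masked\\.png$")), 0)
  # the measured bill is commensurate with the reference
  meas <- read.csv(file.path(outdir, "measurements.csv"))
  expect_lt(abs(meas$digital_mm - meas$reference_mm) / meas$reference_mm, 0.1)

  # rerun: cached stages, and fully deterministic artifacts in a fresh dir
  row2 <- run_specimen(cfg, indir, outdir, "MLZ0011")
  expect_true(all(unlist(row2[, grep("^status_", names(row2))]) == "ok (cached)"))
  outdir2 <- tempfile("fxout2_")
  row3 <- run_specimen(cfg, indir, outdir2, "MLZ0011")
  same_bytes <- function(f) {
    identical(readBin(file.path(outdir, f), "raw", file.size(file.path(outdir, f))),
              readBin(file.path(outdir2, f), "raw", file.size(file.path(outdir2, f))))
  }
  expect_true(same_bytes("MLZ0011_lowpoly.obj"))
  expect_true(same_bytes("measurements.csv"))
  expect_true(same_bytes("color_cloud.csv"))
})

test_that("a missing marker file fails scale calibration but not the batch", {
  cfg <- pipeline_config(step_deg = 90, elevations_deg = 0,
                         texture_size = 512L)
  good <- tempfile("ok_"); bad <- tempfile("bad_")
  fixture_input(12, good, cfg)
  fixture_input(13, bad, cfg)
  file.remove(file.path(bad, "markers.csv"))
  manifest <- run_batch(cfg, c(G12 = good, B13 = bad), tempfile("batch_"))
  expect_equal(nrow(manifest), 2)
  expect_equal(manifest$status_scalecal[1], "ok")
  expect_match(manifest$status_scalecal[2], "failed")
  expect_equal(manifest$status_meshproc[2], "pending")
  expect_equal(manifest$status_phenomics[1], "ok")
})
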