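test_that("visibility culls back faces and occluded geometry", {
  s <- mesh_icosphere(3, 1)
  pose <- specimen3d:::look_at_pose(c(6, 0, 0), c(0, 0, 0),
                                    300, 300, 128, 128, 256, 256)
  vis <- face_visibility(s, pose)
  n <- face_normals(s)
  cen <- face_centroids(s)
  to_cam <- sweep(-cen, 2, c(6, 0, 0), "+")
  back <- rowSums(n * to_cam) < 0
  expect_false(any(vis$visible & back))
  expect_gt(mean(vis$visible[!back]), 0.8)
  # nested spheres: the inner one is fully occluded
  both <- merge_meshes(mesh_icosphere(2, 0.5), mesh_icosphere(2, 1))
  vb <- face_visibility(both, pose)
  expect_false(any(vb$visible[seq_len(80)]))
})

test_that("bill-tip faces are visible head-on and hidden from behind", {
  lp <- lowpoly_small(1)
  tr <- lp$truth
  cap <- capture_small(1)
  tip_faces <- which(face_centroids(lp$mesh)[, 1] >
                       max(lp$mesh$vertices[, 1]) - 2)
  front <- which(cap$schedule$elevation_deg == 0 &
                   cap$schedule$azimuth_deg == 0)   # camera on +x, facing bill
  back <- which(cap$schedule$elevation_deg == 0 &
                  cap$schedule$azimuth_deg == 180)
  vf <- face_visibility(lp$mesh, cap$poses[[front]])
  vb <- face_visibility(lp$mesh, cap$poses[[back]])
  expect_gt(mean(vf$visible[tip_faces]), 0.3)
  expect_equal(sum(vb$visible[tip_faces]), 0)
})

test_that("baking is order-independent and flags unseen texels", {
  lp <- lowpoly_small(1)
  tr <- lp$truth
  cap <- render_turntable(tr, step_deg = 90, elevations_deg = 0, seed = 4,
                          perturb = FALSE)
  tm <- bake_texture(lp$mesh, lp$atlas, cap, size = 256)
  # permuting the image list changes nothing (weights are symmetric)
  cap_rev <- cap
  ord <- rev(seq_along(cap$ids))
  cap_rev$ids <- cap$ids[ord]; cap_rev$poses <- cap$poses[ord]
  cap_rev$images <- cap$images[ord]; cap_rev$silhouettes <- cap$silhouettes[ord]
  tm_rev <- bake_texture(lp$mesh, lp$atlas, cap_rev, size = 256)
  expect_identical(tm$pixels, tm_rev$pixels)

  # a single view leaves the far side unseen; more views never increase it
  cap1 <- cap
  cap1$ids <- cap$ids[1]; cap1$poses <- cap$poses[1]
  cap1$images <- cap$images[1]; cap1$silhouettes <- cap$silhouettes[1]
  tm1 <- bake_texture(lp$mesh, lp$atlas, cap1, size = 256)
  expect_gt(tm1$unseen_fraction, 0.2)
  expect_lt(tm$unseen_fraction, tm1$unseen_fraction)
})

test_that("textured export writes OBJ + MTL + PNG side by side", {
  lp <- lowpoly_small(1)
  frgb <- matrix(rep(c(0.5, 0.4, 0.3), each = nrow(lp$mesh$faces)), ncol = 3)
  tm <- texture_from_albedo(lp$mesh, lp$atlas, frgb, 256)
  d <- tempfile("tex_")
  paths <- export_textured(lp$mesh, lp$atlas, tm, d, "MLZ8631")
  expect_true(all(file.exists(unlist(paths))))
  expect_equal(basename(paths$obj), "MLZ8631_lowpoly.obj")
  expect_equal(dirname(paths$texture), dirname(paths$obj))
  mtl <- readLines(paths$mtl)
  expect_length(grep("^map_Kd", mtl), 1)
  expect_match(grep("^map_Kd", mtl, value = TRUE), "MLZ8631_albedo.png")
  rt <- read_obj(paths$obj)
  expect_identical(rt$mesh$faces, lp$mesh$faces)
  expect_equal(rt$mtllib, "MLZ8631.mtl")
  # mesh/atlas mismatch is refused
  expect_error(export_textured(mesh_box(), lp$atlas, tm, d, "X"),
               "consistency error")
})
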