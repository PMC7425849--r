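test_that("primitive meshes have exact analytic geometry", {
  b <- mesh_box(c(10, 10, 10))
  expect_true(is_watertight(b))
  expect_equal(mesh_volume(b), 1000)
  expect_equal(mesh_area(b), 600)
  expect_equal(euler_characteristic(b), 2)

  s <- mesh_icosphere(3, 2)
  expect_true(is_watertight(s))
  expect_true(is_edge_manifold(s))
  expect_equal(euler_characteristic(s), 2)
  # inscribed polyhedron: slightly under the smooth sphere, converging
  expect_lt(abs(mesh_area(s) - 4 * pi * 4) / (4 * pi * 4), 0.01)
  expect_lt(abs(mesh_volume(s) - 4 / 3 * pi * 8) / (4 / 3 * pi * 8), 0.01)
})

test_that("closest_points projects exactly onto the surface", {
  s <- mesh_icosphere(3, 1)
  cp <- closest_points(s, rbind(c(3, 0, 0), c(0, 0, 0), c(0, 0.2, 0.1)))
  # outside point: nearest point has |p| ~ 1, distance ~ 2
  expect_lt(abs(cp$distance[1] - 2), 5e-3)
  expect_lt(abs(sqrt(sum(cp$point[1, ]^2)) - 1), 5e-3)
  # points project onto actual faces
  expect_true(all(cp$face >= 1 & cp$face <= nrow(s$faces)))
  # a vertex of the mesh is at distance zero
  cp2 <- closest_points(s, s$vertices[5, , drop = FALSE])
  expect_lt(cp2$distance, 1e-12)
})

test_that("boundary loops and components are detected", {
  s <- mesh_icosphere(2, 1)
  expect_length(boundary_loops(s), 0)
  holed <- trimesh(s$vertices, s$faces[-1, , drop = FALSE])
  lp <- boundary_loops(holed)
  expect_length(lp, 1)
  expect_length(lp[[1]], 3)
  two <- merge_meshes(s, mesh_icosphere(1, 0.2, c(5, 0, 0)))
  expect_equal(max(mesh_components(two)), 2)
  # component 1 is the larger one
  comp <- mesh_components(two)
  expect_true(all(comp[seq_len(nrow(s$faces))] == 1))
})

test_that("transform_mesh is rigid and sample_surface is deterministic", {
  s <- mesh_icosphere(2, 1)
  th <- 0.4
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  t2 <- transform_mesh(s, R, c(1, 2, 3))
  expect_equal(mesh_area(t2), mesh_area(s), tolerance = 1e-12)
  expect_equal(mesh_volume(t2), mesh_volume(s), tolerance = 1e-12)
  p1 <- sample_surface(s, 50, seed = 9)
  p2 <- sample_surface(s, 50, seed = 9)
  expect_identical(p1, p2)
  expect_false(identical(p1, sample_surface(s, 50, seed = 10)))
})

test_that("OBJ writing round-trips and refuses collisions", {
  m <- mesh_irregular()
  path <- file.path(tempdir(), "rt.obj")
  if (file.exists(path)) unlink(path)
  write_obj(m, path)
  rt <- read_obj(path)
  expect_identical(rt$mesh$faces, m$faces)
  expect_lt(max(abs(rt$mesh$vertices - m$vertices)), 1e-6 * max(abs(m$vertices)) + 1e-6)
  expect_error(write_obj(m, path), "refusing to overwrite")
})
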