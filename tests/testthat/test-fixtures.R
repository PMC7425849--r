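test_that("generated specimens carry exact landmark ground truth", {
  tr <- specimen_small(1)
  d <- sqrt(sum((tr$landmarks["bill_tip", ] - tr$landmarks["bill_base", ])^2))
  expect_equal(d, tr$bill_length_mm, tolerance = 1e-12)
  expect_true(is_watertight(tr$mesh))
  expect_true(is_edge_manifold(tr$mesh))
  expect_equal(euler_characteristic(tr$mesh), 2)
  # all landmarks lie on the surface
  expect_lt(max(closest_points(tr$mesh, tr$landmarks)$distance), 1e-9)
})

test_that("specimen generation is deterministic and seed-sensitive", {
  a <- generate_specimen(3, subdivisions = 2)
  b <- generate_specimen(3, subdivisions = 2)
  c <- generate_specimen(4, subdivisions = 2)
  expect_identical(a$mesh$vertices, b$mesh$vertices)
  expect_identical(a$mesh$faces, b$mesh$faces)
  expect_false(identical(a$mesh$vertices, c$mesh$vertices))
})

test_that("parameter validation rejects impossible specimens", {
  expect_error(generate_specimen(1, bill_length_mm = -2), "positive")
  expect_error(generate_specimen(1, body_diameter_mm = 0), "positive")
  expect_error(generate_specimen(1, subdivisions = 1), "subdivisions")
})

test_that("balanced albedo splits surface area 50/50 to within one face", {
  tr <- generate_specimen(2, subdivisions = 3, albedo = "balanced")
  fr <- tr$tone_areas / sum(tr$tone_areas)
  expect_lt(max(abs(fr - 0.5)), 0.01)
})

test_that("defect injection produces exactly the reported defects", {
  tr <- specimen_small(1)
  def <- inject_defects(tr, seed = 2, n_holes = 3, n_debris = 2,
                        add_stand = TRUE)
  expect_equal(def$report$holes_added, 3L)
  expect_equal(def$report$debris_components_added, 2L)
  expect_length(boundary_loops(def$mesh), 3)
  # body + 2 debris + stand
  expect_equal(max(mesh_components(def$mesh)), 4)
  # stand faces exist and are disjoint from the original face range
  expect_true(all(def$report$stand_faces > nrow(tr$mesh$faces)))
  # debris components are each below 1% of the specimen area
  comp <- mesh_components(def$mesh)
  fa <- face_areas(def$mesh)
  areas <- rowsum(fa, comp)[, 1]
  debris_areas <- sort(areas)[1:2]
  expect_true(all(debris_areas < 0.01 * mesh_area(tr$mesh)))
})

test_that("zero requested defects returns the input unchanged", {
  tr <- specimen_small(1)
  def <- inject_defects(tr, seed = 1, n_holes = 0, n_debris = 0,
                        add_stand = FALSE)
  expect_identical(def$mesh$vertices, tr$mesh$vertices)
  expect_identical(def$mesh$faces, tr$mesh$faces)
  expect_equal(def$report$holes_added, 0L)
})

test_that("a single hole drops the Euler characteristic from 2 to 1", {
  s <- mesh_icosphere(2, 1)
  truthlike <- specimen_small(1)
  holed <- trimesh(s$vertices, s$faces[-10, , drop = FALSE])
  expect_equal(euler_characteristic(s), 2)
  expect_equal(euler_characteristic(holed), 1)
  # and via the injector on a real fixture
  def <- inject_defects(truthlike, seed = 5, n_holes = 1, n_debris = 0,
                        add_stand = FALSE)
  expect_equal(euler_characteristic(def$mesh),
               euler_characteristic(truthlike$mesh) - 1L)
})

test_that("impossible hole requests raise a defect-injection error", {
  tr <- specimen_small(1)
  expect_error(inject_defects(tr, 1, n_holes = 10000L),
               "defect-injection error")
  expect_error(inject_defects(tr, 1, n_holes = -1), "non-negative")
})

test_that("non-manifold fin injection is counted and detectable", {
  tr <- specimen_small(1)
  def <- inject_defects(tr, seed = 3, n_holes = 0, n_debris = 0,
                        add_stand = FALSE, n_nonmanifold = 2)
  expect_equal(def$report$nonmanifold_edges_added, 2L)
  expect_false(is_edge_manifold(def$mesh))
})
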