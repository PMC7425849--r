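# Shared fixtures, built once per test file and memoized.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, .fixture_cache)) assign(key, builder(), .fixture_cache)
  get(key, .fixture_cache)
}

specimen_small <- function(seed = 1L, ...) {
  memo(paste0("spec_", seed, "_", paste(c(...), collapse = "_")),
       function() generate_specimen(seed, subdivisions = 3L, ...))
}

capture_small <- function(seed = 1L) {
  memo(paste0("cap_", seed), function()
    render_turntable(specimen_small(seed), step_deg = 45,
                     elevations_deg = c(-45, 0, 45), seed = seed))
}

# low-poly processed mesh + atlas for texture/phenomics tests
lowpoly_small <- function(seed = 1L) {
  memo(paste0("low_", seed), function() {
    tr <- specimen_small(seed)
    m <- decimate(voxel_remesh(tr$mesh, 0.8), 4000)
    list(truth = tr, mesh = m, atlas = generate_uv(m))
  })
}

# regular grid plane (open mesh), n x n quads in the z = 0 plane
mesh_plane <- function(n = 6) {
  gr <- expand.grid(x = 0:n, y = 0:n)
  v <- cbind(gr$x, gr$y, 0)
  f <- do.call(rbind, lapply(0:(n - 1), function(i)
    do.call(rbind, lapply(0:(n - 1), function(j) {
      a <- i * (n + 1) + j + 1
      rbind(c(a, a + 1, a + n + 2), c(a, a + n + 2, a + n + 1))
    }))))
  trimesh(v, f)
}

# irregular closed mesh: icosphere with anisotropic stretch and varied edges
mesh_irregular <- function() {
  memo("irregular", function() {
    s <- mesh_icosphere(3, 1)
    s$vertices <- s$vertices %*% diag(c(2.5, 1, 0.6))
    d <- decimate(s, 900)
    d$vertices <- d$vertices * 10
    d$units <- "mm"
    d
  })
}
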