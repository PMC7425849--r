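#' Triangle mesh objects
#'
#' A `trimesh` is the geometry container passed between every mesh-processing
#' stage: an N x 3 vertex matrix (millimeters once scale-calibrated), an M x 3
#' integer face matrix (1-based vertex indices, counter-clockwise winding =
#' outward normal), and a units flag (`"model"` for arbitrary reconstruction
#' units, `"mm"` for calibrated physical units).
#'
#' @param vertices numeric N x 3 matrix of vertex positions.
#' @param faces integer M x 3 matrix of 1-based vertex indices.
#' @param units `"model"` or `"mm"`.
#' @return An object of class `trimesh`.
#' @export
trimesh <- function(vertices, faces, units = c("model", "mm")) {
  units <- match.arg(units)
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3) stop("vertices must have 3 columns")
  if (ncol(faces) != 3) stop("faces must have 3 columns")
  if (nrow(faces) > 0 && (min(faces) < 1 || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces, units = units),
            class = "trimesh")
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("<trimesh> %d vertices, %d faces [%s]\n",
              nrow(x$vertices), nrow(x$faces), x$units))
  invisible(x)
}

#' @rdname trimesh
#' @param x object to test.
#' @export
is_trimesh <- function(x) inherits(x, "trimesh")

stopifnot_trimesh <- function(mesh) {
  if (!is_trimesh(mesh)) stop("expected a trimesh object")
}

faces0 <- function(mesh) mesh$faces - 1L

#' Per-face and whole-mesh geometric quantities
#'
#' `face_areas()`, `face_normals()` and `face_centroids()` are per-face;
#' `mesh_area()` is the total surface area and `mesh_volume()` the signed
#' volume by the divergence theorem (positive for a closed, outward-wound
#' surface; meaningful only for watertight meshes).
#'
#' @param mesh a [trimesh].
#' @return numeric vector / matrix / scalar as appropriate.
#' @export
face_areas <- function(mesh) {
  stopifnot_trimesh(mesh)
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' @rdname face_areas
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh))

#' @rdname face_areas
#' @export
mesh_volume <- function(mesh) {
  stopifnot_trimesh(mesh)
  v <- mesh$vertices; f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  sum(p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
      p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
      p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])) / 6
}

#' @rdname face_areas
#' @export
face_normals <- function(mesh) {
  stopifnot_trimesh(mesh)
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
             a[, 3] * b[, 1] - a[, 1] * b[, 3],
             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' @rdname face_areas
#' @export
face_centroids <- function(mesh) {
  stopifnot_trimesh(mesh)
  v <- mesh$vertices; f <- mesh$faces
  (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
     v[f[, 3], , drop = FALSE]) / 3
}

#' Area-weighted per-vertex normals
#' @param mesh a [trimesh].
#' @return N x 3 matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  stopifnot_trimesh(mesh)
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  fn <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1]) # area-weighted (unnormalized)
  n <- matrix(0, nrow(v), 3)
  for (c in 1:3) {
    idx <- f[, c]
    n[, 1] <- n[, 1] + tapply_add(fn[, 1], idx, nrow(v))
    n[, 2] <- n[, 2] + tapply_add(fn[, 2], idx, nrow(v))
    n[, 3] <- n[, 3] + tapply_add(fn[, 3], idx, nrow(v))
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

tapply_add <- function(values, idx, n) {
  out <- numeric(n)
  s <- rowsum(values, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

# undirected edge table: one row per unique edge (a < b), with face count
mesh_edge_table <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- pmin(e[, 1], e[, 2]) * (nrow(mesh$vertices) + 1) + pmax(e[, 1], e[, 2])
  face_of <- rep(seq_len(nrow(f)), 3)
  ord <- order(key, face_of)
  key <- key[ord]; e <- e[ord, , drop = FALSE]; face_of <- face_of[ord]
  first <- !duplicated(key)
  counts <- as.vector(table(factor(key, levels = key[first])))
  list(a = pmin(e[first, 1], e[first, 2]),
       b = pmax(e[first, 1], e[first, 2]),
       count = counts,
       key = key, edge_of_half = match(key, key[first]),
       face_of_half = face_of,
       half_a = e[, 1], half_b = e[, 2])
}

#' Topology predicates and statistics
#'
#' `is_watertight()`: every edge borders exactly two faces (closed 2-manifold
#' edge condition). `is_edge_manifold()`: no edge borders more than two faces.
#' `euler_characteristic()`: V - E + F. `boundary_loops()` returns the closed
#' vertex cycles bounding holes. `edge_length_cv()` is the coefficient of
#' variation of edge lengths (a uniformity score used by the voxel remesher
#' contract).
#'
#' @param mesh a [trimesh].
#' @export
is_watertight <- function(mesh) {
  stopifnot_trimesh(mesh)
  if (nrow(mesh$faces) == 0) return(FALSE)
  et <- mesh_edge_table(mesh)
  all(et$count == 2L)
}

#' @rdname is_watertight
#' @export
is_edge_manifold <- function(mesh) {
  stopifnot_trimesh(mesh)
  et <- mesh_edge_table(mesh)
  all(et$count <= 2L)
}

#' @rdname is_watertight
#' @export
euler_characteristic <- function(mesh) {
  stopifnot_trimesh(mesh)
  used <- sort(unique(as.vector(mesh$faces)))
  et <- mesh_edge_table(mesh)
  length(used) - length(et$a) + nrow(mesh$faces)
}

#' @rdname is_watertight
#' @export
edge_length_cv <- function(mesh) {
  stopifnot_trimesh(mesh)
  et <- mesh_edge_table(mesh)
  len <- sqrt(rowSums((mesh$vertices[et$a, , drop = FALSE] -
                         mesh$vertices[et$b, , drop = FALSE])^2))
  sd(len) / mean(len)
}

#' @rdname is_watertight
#' @export
boundary_loops <- function(mesh) {
  stopifnot_trimesh(mesh)
  et <- mesh_edge_table(mesh)
  bnd <- which(et$count == 1L)
  if (length(bnd) == 0) return(list())
  # directed boundary half-edges (each appears once, in face order);
  # chain half-edge to half-edge so non-simple loops still close
  half_is_bnd <- et$edge_of_half %in% bnd
  ha <- et$half_a[half_is_bnd]
  hb <- et$half_b[half_is_bnd]
  ord <- order(ha, hb)
  ha <- ha[ord]; hb <- hb[ord]
  visited <- rep(FALSE, length(ha))
  loops <- list()
  for (s in seq_along(ha)) {
    if (visited[s]) next
    loop <- integer(0)
    cur <- s
    repeat {
      visited[cur] <- TRUE
      loop <- c(loop, ha[cur])
      cand <- which(ha == hb[cur] & !visited)
      if (!length(cand)) break
      cur <- cand[1]
      if (length(loop) > length(ha)) break
    }
    if (length(loop) >= 3 && hb[cur] == ha[s])
      loops[[length(loops) + 1]] <- loop
  }
  loops
}

#' Connected components of a mesh
#'
#' Components are sets of faces connected through shared edges.
#'
#' @param mesh a [trimesh].
#' @return integer vector: component id per face (1-based, by decreasing area).
#' @export
mesh_components <- function(mesh) {
  stopifnot_trimesh(mesh)
  nf <- nrow(mesh$faces)
  if (nf == 0) return(integer(0))
  et <- mesh_edge_table(mesh)
  # faces sharing an edge: group half-edges by edge id
  g <- igraph::make_empty_graph(n = nf, directed = FALSE)
  ord <- order(et$edge_of_half)
  eh <- et$edge_of_half[ord]
  fh <- et$face_of_half[ord]
  first <- !duplicated(eh)
  starts <- which(first)
  ends <- c(starts[-1] - 1L, length(eh))
  pairs <- list()
  for (i in seq_along(starts)) {
    fs <- fh[starts[i]:ends[i]]
    if (length(fs) >= 2) {
      base <- fs[1]
      pairs[[length(pairs) + 1]] <- rbind(base, fs[-1])
    }
  }
  if (length(pairs) > 0) {
    ep <- do.call(cbind, pairs)
    g <- igraph::add_edges(g, as.vector(ep))
  }
  comp <- igraph::components(g)$membership
  # relabel by decreasing component area
  fa <- face_areas(mesh)
  areas <- rowsum(fa, comp)
  rank <- rank(-areas[, 1], ties.method = "first")
  as.integer(rank[comp])
}

#' Extract a sub-mesh containing only the given faces
#' @param mesh a [trimesh].
#' @param keep integer or logical face selector.
#' @export
subset_faces <- function(mesh, keep) {
  stopifnot_trimesh(mesh)
  f <- mesh$faces[keep, , drop = FALSE]
  used <- sort(unique(as.vector(f)))
  map <- integer(nrow(mesh$vertices))
  map[used] <- seq_along(used)
  trimesh(mesh$vertices[used, , drop = FALSE],
          matrix(map[f], ncol = 3), units = mesh$units)
}

#' Concatenate meshes into one (disjoint union)
#' @param ... trimesh objects.
#' @export
merge_meshes <- function(...) {
  ms <- list(...)
  stopifnot(length(ms) >= 1)
  vs <- list(); fs <- list(); off <- 0L
  for (m in ms) {
    stopifnot_trimesh(m)
    vs[[length(vs) + 1]] <- m$vertices
    fs[[length(fs) + 1]] <- m$faces + off
    off <- off + nrow(m$vertices)
  }
  trimesh(do.call(rbind, vs), do.call(rbind, fs), units = ms[[1]]$units)
}

#' Closest points on a mesh surface
#'
#' Grid-accelerated exact point-to-triangle projection.
#'
#' @param mesh a [trimesh].
#' @param query numeric Q x 3 matrix (or length-3 vector) of query points.
#' @return list with `point` (Q x 3 nearest surface points), `distance`, and
#'   `face` (1-based owning face index).
#' @export
closest_points <- function(mesh, query) {
  stopifnot_trimesh(mesh)
  if (is.null(dim(query))) query <- matrix(query, ncol = 3)
  storage.mode(query) <- "double"
  res <- .cpp_closest_points(mesh$vertices, faces0(mesh), query)
  res$face <- res$face + 1L
  res
}

#' Uniform random samples on a mesh surface
#'
#' Area-weighted face choice plus uniform barycentric sampling; deterministic
#' for a fixed seed.
#'
#' @param mesh a [trimesh].
#' @param n number of samples.
#' @param seed integer seed.
#' @return n x 3 matrix of surface points.
#' @export
sample_surface <- function(mesh, n, seed = 1L) {
  stopifnot_trimesh(mesh)
  fa <- face_areas(mesh)
  rs <- local_rng(seed)
  fi <- rs$sample_int(length(fa), n, replace = TRUE, prob = fa)
  r1 <- sqrt(rs$runif(n))
  r2 <- rs$runif(n)
  w1 <- 1 - r1; w2 <- r1 * (1 - r2); w3 <- r1 * r2
  v <- mesh$vertices; f <- mesh$faces
  w1 * v[f[fi, 1], , drop = FALSE] + w2 * v[f[fi, 2], , drop = FALSE] +
    w3 * v[f[fi, 3], , drop = FALSE]
}

# scoped RNG: evaluates random draws under a local seed without touching
# the global .Random.seed stream state observed by callers
local_rng <- function(seed) {
  env <- new.env()
  env$state <- NULL
  run <- function(expr_fun, ...) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    if (is.null(env$state)) set.seed(seed) else assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    })
    expr_fun(...)
  }
  list(
    runif = function(n, min = 0, max = 1) run(stats::runif, n, min, max),
    rnorm = function(n, mean = 0, sd = 1) run(stats::rnorm, n, mean, sd),
    sample_int = function(n, size, replace = FALSE, prob = NULL)
      run(sample.int, n, size, replace, prob)
  )
}

#' Symmetric Hausdorff distance between two meshes (sampled)
#'
#' Directed distances are estimated from vertices, face centroids and `n`
#' random surface samples per mesh, each projected exactly onto the other
#' surface; the symmetric value is the larger of the two directions.
#'
#' @param mesh_a,mesh_b [trimesh] objects.
#' @param n random surface samples per direction.
#' @param seed integer seed for the samples.
#' @export
hausdorff_distance <- function(mesh_a, mesh_b, n = 2000L, seed = 1L) {
  d_ab <- directed_hausdorff(mesh_a, mesh_b, n, seed)
  d_ba <- directed_hausdorff(mesh_b, mesh_a, n, seed + 1L)
  max(d_ab, d_ba)
}

directed_hausdorff <- function(a, b, n, seed) {
  pts <- rbind(a$vertices, face_centroids(a), sample_surface(a, n, seed))
  max(closest_points(b, pts)$distance)
}

#' Apply a rigid (or scaling) transform to a mesh
#' @param mesh a [trimesh].
#' @param rotation 3 x 3 matrix (applied as `v %*% t(rotation)`).
#' @param translation length-3 vector.
#' @param scale scalar multiplier applied before rotation.
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0),
                           scale = 1) {
  stopifnot_trimesh(mesh)
  v <- (mesh$vertices * scale) %*% t(rotation)
  v <- sweep(v, 2, translation, "+")
  out <- mesh
  out$vertices <- v
  out
}

#' Primitive meshes
#'
#' `mesh_icosphere()` is a subdivided icosahedron projected onto a sphere;
#' `mesh_box()` an axis-aligned box; both watertight with outward winding.
#'
#' @param subdivisions icosphere subdivision level (0 = icosahedron).
#' @param radius sphere radius.
#' @param center length-3 center.
#' @export
mesh_icosphere <- function(subdivisions = 2, radius = 1, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    edge_key <- function(a, b) pmin(a, b) * (nv + 1) + pmax(a, b)
    keys <- c(edge_key(f[, 1], f[, 2]), edge_key(f[, 2], f[, 3]), edge_key(f[, 3], f[, 1]))
    ek <- unique(keys)
    mid_idx <- match(keys, ek) + nv
    ea <- ek %/% (nv + 1); eb <- ek %% (nv + 1)
    mids <- (v[ea, , drop = FALSE] + v[eb, , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    v <- rbind(v, mids)
    m12 <- mid_idx[seq_len(nrow(f))]
    m23 <- mid_idx[nrow(f) + seq_len(nrow(f))]
    m31 <- mid_idx[2 * nrow(f) + seq_len(nrow(f))]
    f <- rbind(cbind(f[, 1], m12, m31),
               cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23),
               cbind(m12, m23, m31))
  }
  v <- sweep(v * radius, 2, center, "+")
  trimesh(v, f)
}

#' @rdname mesh_icosphere
#' @param dims length-3 box edge lengths.
#' @export
mesh_box <- function(dims = c(1, 1, 1), center = c(0, 0, 0)) {
  h <- dims / 2
  v <- as.matrix(expand.grid(x = c(-h[1], h[1]), y = c(-h[2], h[2]),
                             z = c(-h[3], h[3])))
  colnames(v) <- NULL
  # corner order: 1 (---), 2 (+--), 3 (-+-), 4 (++-), 5 (--+), 6 (+-+), 7 (-++), 8 (+++)
  f <- rbind(
    c(1, 3, 4), c(1, 4, 2),   # z-
    c(5, 6, 8), c(5, 8, 7),   # z+
    c(1, 2, 6), c(1, 6, 5),   # y-
    c(3, 7, 8), c(3, 8, 4),   # y+
    c(1, 5, 7), c(1, 7, 3),   # x-
    c(2, 4, 8), c(2, 8, 6))   # x+
  trimesh(sweep(v, 2, center, "+"), f)
}
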