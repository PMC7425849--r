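#' Voxel remesh: uniform retopology through a voxel grid
#'
#' Re-samples the surface through a signed voxelization (x-ray parity fill)
#' and surface-nets isosurface extraction, then projects every new vertex
#' onto the nearest point of the input surface so no detail is displaced by
#' more than the voxel quantization. The result has near-uniform edge lengths
#' (~ the voxel size) and is watertight for closed input, which is what the
#' downstream decimator wants to see.
#'
#' @param mesh a [trimesh] (closed; open meshes fall back to an unsigned
#'   distance shell with a warning).
#' @param voxel_size voxel edge length, in the mesh's units; must be less
#'   than 1/10 of the bounding-box diagonal.
#' @return A [trimesh]; `attr(, "remesh_warning")` is set when the unsigned
#'   fallback or a degenerate fill column was hit.
#' @export
voxel_remesh <- function(mesh, voxel_size) {
  stopifnot_trimesh(mesh)
  diag_len <- sqrt(sum(apply(mesh$vertices, 2, function(c) diff(range(c)))^2))
  if (voxel_size <= 0 || voxel_size >= diag_len / 10)
    stop("voxel_size must be positive and < 1/10 of the bounding-box diagonal")
  closed <- is_watertight(mesh)
  warn <- NULL
  if (!closed) {
    warning("input is not closed; remeshing an unsigned distance shell")
    warn <- "unsigned_shell"
  }
  res <- .cpp_voxel_surface_nets(mesh$vertices, faces0(mesh), voxel_size, closed)
  if (isTRUE(res$degenerate_columns)) warn <- c(warn, "degenerate_fill_column")
  out <- trimesh(res$vertices, res$faces + 1L, units = mesh$units)
  attr(out, "remesh_warning") <- warn
  out
}

#' Build a per-vertex quality (preservation) map
#'
#' The default heatmap scores each vertex by the magnitude of the normal
#' component of its uniform Laplacian (a discrete mean-curvature measure),
#' robustly normalized to `[0,1]` by the 95th percentile, so ridges, bill
#' tips and other thin features score high and flat plumage scores low.
#' Painted regions override the score to 1.0 — the digitizer "painting on"
#' areas of interest to protect from decimation.
#'
#' @param mesh a [trimesh].
#' @param painted_regions optional list of regions; each element is a list
#'   with `type = "sphere"` (`center`, `radius`), `type = "box"` (`min`,
#'   `max`), or `type = "vertices"` (`indices`).
#' @return numeric vector in `[0,1]`, one weight per vertex (1 = preserve).
#' @export
build_quality <- function(mesh, painted_regions = NULL) {
  stopifnot_trimesh(mesh)
  if (nrow(mesh$vertices) == 0 || nrow(mesh$faces) == 0) stop("empty mesh")
  hn <- mean_curvature(mesh)
  q95 <- stats::quantile(hn, 0.95, names = FALSE)
  q <- if (q95 > 1e-12) pmin(1, hn / q95) else rep(0, length(hn))
  for (reg in painted_regions) {
    idx <- switch(reg$type,
      sphere = which(sqrt(rowSums(sweep(mesh$vertices, 2, reg$center)^2)) <= reg$radius),
      box = which(mesh$vertices[, 1] >= reg$min[1] & mesh$vertices[, 1] <= reg$max[1] &
                  mesh$vertices[, 2] >= reg$min[2] & mesh$vertices[, 2] <= reg$max[2] &
                  mesh$vertices[, 3] >= reg$min[3] & mesh$vertices[, 3] <= reg$max[3]),
      vertices = reg$indices,
      stop("unknown region type: ", reg$type))
    q[idx] <- 1
  }
  q
}

#' Discrete mean-curvature magnitude
#'
#' Cotangent-Laplacian estimate `|H| = |sum (cot a + cot b)(v_j - v_i)| /
#' (4 A_i)` with barycentric vertex areas: correct on anisotropic meshes
#' (e.g. densely ringed cones), units 1/length.
#'
#' @param mesh a [trimesh].
#' @return numeric vector, one non-negative curvature per vertex.
#' @export
mean_curvature <- function(mesh) {
  stopifnot_trimesh(mesh)
  v <- mesh$vertices; f <- mesh$faces
  nv <- nrow(v)
  K <- matrix(0, nv, 3)
  Aacc <- numeric(nv)
  fa <- face_areas(mesh)
  for (c in 1:3) {
    i <- f[, c]; j <- f[, c %% 3 + 1]; k <- f[, (c + 1) %% 3 + 1]
    # angle at k, opposite edge (i,j)
    e1 <- v[i, , drop = FALSE] - v[k, , drop = FALSE]
    e2 <- v[j, , drop = FALSE] - v[k, , drop = FALSE]
    cosn <- rowSums(e1 * e2)
    cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    sinn <- pmax(sqrt(rowSums(cr^2)), 1e-12)
    cot <- cosn / sinn
    d <- v[j, , drop = FALSE] - v[i, , drop = FALSE]
    for (ch in 1:3) {
      K[, ch] <- K[, ch] + tapply_add(cot * d[, ch], i, nv)
      K[, ch] <- K[, ch] + tapply_add(-cot * d[, ch], j, nv)
    }
    Aacc <- Aacc + tapply_add(fa / 3, i, nv)
  }
  h <- sqrt(rowSums(K^2)) / pmax(4 * Aacc, 1e-300)
  # the cotan sum is only a curvature estimate at interior vertices; boundary
  # vertices lack the closing angles and would read as spuriously curved
  et <- mesh_edge_table(mesh)
  bnd <- which(et$count == 1L)
  if (length(bnd))
    h[unique(c(et$a[bnd], et$b[bnd]))] <- 0
  h
}

# one uniform-Laplacian displacement L(v) = mean(neighbors) - v
uniform_laplacian_step <- function(mesh, adj = NULL) {
  if (is.null(adj)) adj <- mesh_adjacency(mesh)
  nb_mean <- as.matrix(adj %*% mesh$vertices) / pmax(Matrix::rowSums(adj), 1)
  nb_mean - mesh$vertices
}

mesh_adjacency <- function(mesh) {
  et <- mesh_edge_table(mesh)
  n <- nrow(mesh$vertices)
  Matrix::sparseMatrix(i = c(et$a, et$b), j = c(et$b, et$a),
                       x = 1, dims = c(n, n))
}

#' Quality-weighted mesh decimation
#'
#' Quadric-error-metric edge collapse; each candidate collapse's cost is
#' multiplied by `1 + k * max(quality at endpoints)`, so vertices painted (or
#' scored) near 1 are roughly `1 + k` times more expensive to remove and
#' areas of interest keep their face density. Collapse order is
#' deterministic (cost, then lowest vertex index).
#'
#' @param mesh a [trimesh].
#' @param target_faces target face count (>= 4); meshes already at or below
#'   target are returned unchanged.
#' @param quality optional per-vertex weights in `[0,1]` from
#'   [build_quality()]; default all zero (uniform decimation).
#' @param k quality cost multiplier (default 9: a fully painted vertex costs
#'   10x to collapse).
#' @return A [trimesh]; if the topological floor was hit before reaching the
#'   target, `attr(, "floor_hit")` is `TRUE` and a warning is raised.
#' @export
decimate <- function(mesh, target_faces, quality = NULL, k = 9) {
  stopifnot_trimesh(mesh)
  if (target_faces < 4) stop("target_faces must be >= 4")
  if (nrow(mesh$faces) <= target_faces) return(mesh)
  if (is.null(quality)) quality <- rep(0, nrow(mesh$vertices))
  stopifnot(length(quality) == nrow(mesh$vertices))
  quality <- pmin(pmax(quality, 0), 1)
  res <- .cpp_decimate_qem(mesh$vertices, faces0(mesh), quality,
                           as.integer(target_faces), k)
  out <- trimesh(res$vertices, res$faces + 1L, units = mesh$units)
  attr(out, "quality") <- res$quality
  if (isTRUE(res$floor_hit)) {
    warning("decimation stopped at the topological floor (",
            nrow(out$faces), " faces) before reaching ", target_faces)
    attr(out, "floor_hit") <- TRUE
  }
  out
}

#' Clean mesh topology
#'
#' The automated stand-in for manual mesh repair: removes small disconnected
#' components (extraneous scan data), deletes faces incident to non-manifold
#' edges, drops degenerate and duplicate faces, and fills boundary loops
#' whose perimeter is at most `max_hole_perimeter` by centroid-fan
#' triangulation (larger holes are reported, not filled). Always returns a
#' best-effort mesh plus a report; `clean()` is idempotent.
#'
#' @param mesh a [trimesh].
#' @param component_area_threshold components smaller than this fraction of
#'   total surface area are removed (default 0.01).
#' @param max_hole_perimeter largest hole perimeter to fill; default 10% of
#'   the bounding-box diagonal.
#' @return list with `mesh` and `report` (a `clean_report`: `holes_filled`,
#'   `nonmanifold_edges_removed`, `components_removed`,
#'   `area_removed_fraction`, `holes_skipped`).
#' @export
clean <- function(mesh, component_area_threshold = 0.01,
                  max_hole_perimeter = NULL) {
  stopifnot_trimesh(mesh)
  if (component_area_threshold <= 0) stop("thresholds must be positive")
  diag_len <- sqrt(sum(apply(mesh$vertices, 2, function(c) diff(range(c)))^2))
  if (is.null(max_hole_perimeter)) max_hole_perimeter <- 0.1 * diag_len
  if (max_hole_perimeter <= 0) stop("thresholds must be positive")

  report <- list(holes_filled = 0L, nonmanifold_edges_removed = 0L,
                 components_removed = 0L, area_removed_fraction = 0,
                 holes_skipped = 0L)
  total_area <- mesh_area(mesh)

  # 1. drop small components
  comp <- mesh_components(mesh)
  fa <- face_areas(mesh)
  carea <- rowsum(fa, comp)
  small <- as.integer(rownames(carea))[carea[, 1] < component_area_threshold * total_area]
  if (length(small)) {
    keep <- !(comp %in% small)
    report$components_removed <- length(small)
    report$area_removed_fraction <- sum(fa[!keep]) / total_area
    mesh <- trimesh(mesh$vertices, mesh$faces[keep, , drop = FALSE], mesh$units)
  }

  # 2. faces incident to non-manifold edges
  et <- mesh_edge_table(mesh)
  bad_edges <- which(et$count > 2L)
  if (length(bad_edges)) {
    bad_faces <- unique(et$face_of_half[et$edge_of_half %in% bad_edges])
    report$nonmanifold_edges_removed <- length(bad_edges)
    mesh <- trimesh(mesh$vertices,
                    mesh$faces[-bad_faces, , drop = FALSE], mesh$units)
  }

  # 3. degenerate geometry: weld coincident vertices, collapse exactly
  # degenerate faces, drop index-degenerate faces and fold pairs (two faces
  # over the same vertex triple) -- these arise where a voxel shell around a
  # sub-voxel-thin feature collapsed onto the surface; handled by collapse
  # rather than deletion so the surface stays closed
  mesh <- collapse_slivers(mesh)

  # 4. fill small boundary loops by centroid fan
  loops <- boundary_loops(mesh)
  if (length(loops)) {
    v <- mesh$vertices
    newv <- list(); newf <- list()
    for (loop in loops) {
      per <- sum(sqrt(rowSums((v[loop, , drop = FALSE] -
                                 v[c(loop[-1], loop[1]), , drop = FALSE])^2)))
      if (per <= max_hole_perimeter) {
        cen <- colMeans(v[loop, , drop = FALSE])
        ci <- nrow(v) + length(newv) + 1L
        newv[[length(newv) + 1]] <- cen
        # boundary half-edge x->y is in face order; fill opposes it
        newf[[length(newf) + 1]] <- cbind(c(loop[-1], loop[1]), loop, ci)
        report$holes_filled <- report$holes_filled + 1L
      } else {
        report$holes_skipped <- report$holes_skipped + 1L
      }
    }
    if (length(newv))
      mesh <- trimesh(rbind(v, do.call(rbind, newv)),
                      rbind(mesh$faces, do.call(rbind, newf)), mesh$units)
  }

  # 5. drop unreferenced vertices
  mesh <- subset_faces(mesh, seq_len(nrow(mesh$faces)))
  class(report) <- "clean_report"
  list(mesh = mesh, report = report)
}

collapse_slivers <- function(mesh, max_rounds = 5L) {
  for (round in seq_len(max_rounds)) {
    v <- mesh$vertices
    diag_len <- sqrt(sum(apply(v, 2, function(c) diff(range(c)))^2))
    eps <- 1e-9 * max(diag_len, 1)
    # weld coincident vertices
    key <- paste(round(v[, 1] / eps), round(v[, 2] / eps), round(v[, 3] / eps))
    first <- !duplicated(key)
    map <- match(key, key[first])
    v2 <- v[first, , drop = FALSE]
    f <- matrix(map[mesh$faces], ncol = 3)
    # collapse the shortest edge of exactly-degenerate (collinear) faces
    m2 <- trimesh(v2, pmax(f, 1L))
    fa <- face_areas(m2)
    zero <- which(fa < 1e-10 * max(mean(fa), 1e-300) &
                    f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3])
    remap <- seq_len(nrow(v2))
    for (fi in zero) {
      tri <- f[fi, ]
      e <- rbind(tri[c(1, 2)], tri[c(2, 3)], tri[c(3, 1)])
      len <- sqrt(rowSums((v2[e[, 1], , drop = FALSE] - v2[e[, 2], , drop = FALSE])^2))
      sh <- e[which.min(len), ]
      keepv <- min(sh); dropv <- max(sh)
      remap[remap == dropv] <- keepv
    }
    f <- matrix(remap[f], ncol = 3)
    # drop faces with repeated indices and fold pairs
    ok <- f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3]
    f <- f[ok, , drop = FALSE]
    keyf <- apply(f, 1, function(r) paste(sort(r), collapse = "_"))
    tab <- table(keyf)
    f <- f[keyf %in% names(tab)[tab == 1L], , drop = FALSE]
    out <- subset_faces(trimesh(v2, f, mesh$units), seq_len(nrow(f)))
    changed <- nrow(out$vertices) != nrow(mesh$vertices) ||
      nrow(out$faces) != nrow(mesh$faces)
    mesh <- out
    if (!changed) break
  }
  mesh
}

#' @export
print.clean_report <- function(x, ...) {
  cat(sprintf(
    "<clean_report> holes filled %d (skipped %d), non-manifold edges %d, components removed %d (%.2f%% area)\n",
    x$holes_filled, x$holes_skipped, x$nonmanifold_edges_removed,
    x$components_removed, 100 * x$area_removed_fraction))
  invisible(x)
}

#' Remove the specimen stand (and similar attached geometry)
#'
#' Either cuts with a plane (faces whose centroid lies on the negative side
#' of `normal` are removed) or grows a region from a seed point by flood
#' fill across edges, stopping at dihedral creases. The result is passed
#' through [clean()] so leftover slivers are dropped and the cut loop is
#' filled.
#'
#' @param mesh a [trimesh].
#' @param plane list with `point` and `normal` (normal points toward the
#'   geometry to keep), or `NULL`.
#' @param seed_point length-3 point near the stand surface (used when
#'   `plane` is `NULL`).
#' @param crease_deg dihedral angle (degrees) bounding the flood fill.
#' @return A cleaned [trimesh].
#' @export
remove_stand <- function(mesh, plane = NULL, seed_point = NULL,
                         crease_deg = 40) {
  stopifnot_trimesh(mesh)
  if (is.null(plane) && is.null(seed_point))
    stop("provide a cutting plane or a seed point")
  cen <- face_centroids(mesh)
  if (!is.null(plane)) {
    nrm <- plane$normal / sqrt(sum(plane$normal^2))
    side <- as.vector(sweep(cen, 2, plane$point) %*% nrm)
    drop <- side < 0
    if (!any(drop)) stop("selector error: cutting plane does not intersect the mesh")
  } else {
    cp <- closest_points(mesh, seed_point)
    if (cp$distance > 0.05 * sqrt(sum(apply(mesh$vertices, 2,
                                            function(c) diff(range(c)))^2)))
      stop("selector error: seed point is far from the mesh surface")
    fn <- face_normals(mesh)
    cos_crease <- cos(crease_deg * pi / 180)
    et <- mesh_edge_table(mesh)
    # face adjacency restricted to smooth (non-crease) edges
    ord <- order(et$edge_of_half)
    eh <- et$edge_of_half[ord]; fh <- et$face_of_half[ord]
    first <- which(!duplicated(eh))
    ends <- c(first[-1] - 1L, length(eh))
    nf <- nrow(mesh$faces)
    adj <- vector("list", nf)
    for (i in seq_along(first)) {
      fs <- fh[first[i]:ends[i]]
      if (length(fs) == 2 && sum(fn[fs[1], ] * fn[fs[2], ]) > cos_crease) {
        adj[[fs[1]]] <- c(adj[[fs[1]]], fs[2])
        adj[[fs[2]]] <- c(adj[[fs[2]]], fs[1])
      }
    }
    drop <- rep(FALSE, nf)
    queue <- cp$face
    drop[queue] <- TRUE
    while (length(queue)) {
      f <- queue[1]; queue <- queue[-1]
      nb <- adj[[f]]
      nb <- nb[!drop[nb]]
      drop[nb] <- TRUE
      queue <- c(queue, nb)
    }
  }
  fa <- face_areas(mesh)
  if (sum(fa[drop]) > 0.5 * sum(fa))
    stop("refusing to remove more than 50% of the surface area")
  kept <- trimesh(mesh$vertices, mesh$faces[!drop, , drop = FALSE], mesh$units)
  clean(kept)$mesh
}

#' Taubin smoothing
#'
#' Alternating uniform-Laplacian steps `v <- v + lambda * L(v)` then
#' `v <- v + mu * L(v)` with `mu < -lambda`, the classic
#' shrink-compensating pair: noise is attenuated like low-pass filtering
#' while closed-surface volume stays within a couple of percent, unlike pure
#' Laplacian smoothing which visibly shrinks the model. Connectivity is
#' unchanged.
#'
#' @param mesh a [trimesh].
#' @param lam positive smoothing step (default 0.5).
#' @param mu negative un-shrinking step, `mu < -lam` (default -0.53).
#' @param iterations number of lambda/mu pairs (>= 1, default 10).
#' @return A smoothed [trimesh].
#' @export
taubin_smooth <- function(mesh, lam = 0.5, mu = -0.53, iterations = 10L) {
  stopifnot_trimesh(mesh)
  if (!(lam > 0) || !(mu < -lam)) stop("need 0 < lam and mu < -lam")
  if (iterations < 1) stop("iterations must be >= 1")
  smooth_laplacian(mesh, steps = rep(c(lam, mu), iterations))
}

#' @rdname taubin_smooth
#' @param steps explicit sequence of Laplacian step sizes (used internally by
#'   `taubin_smooth()`; a plain Laplacian smoother is `steps = rep(lam, n)`).
#' @export
smooth_laplacian <- function(mesh, steps) {
  stopifnot_trimesh(mesh)
  adj <- mesh_adjacency(mesh)
  deg <- pmax(Matrix::rowSums(adj), 1)
  v <- mesh$vertices
  for (s in steps) {
    L <- as.matrix(adj %*% v) / deg - v
    v <- v + s * L
  }
  out <- mesh
  out$vertices <- v
  out
}

#' Canonical PCA alignment
#'
#' Centers the mesh at its centroid and maps principal axes of the vertex
#' cloud (descending variance) to x, y, z with a rigid rotation (det +1).
#' Axis signs follow the sign of the third moment (skewness) of the vertex
#' coordinates along each axis — for the fixtures this points the bill-ward
#' long-axis end toward +x — with a deterministic lowest-vertex-index
#' tie-break when a distribution is symmetric. Near-isotropic covariance
#' (e.g. a sphere) is flagged ambiguous.
#'
#' @param mesh a [trimesh].
#' @return The aligned [trimesh]; `attr(, "alignment")` holds `rotation`,
#'   `translation` (applied as `v %*% t(rotation) + translation`... the
#'   transform mapping input to output), and `ambiguous`.
#' @export
align_canonical <- function(mesh) {
  stopifnot_trimesh(mesh)
  v <- mesh$vertices
  cen <- colMeans(v)
  vc <- sweep(v, 2, cen)
  cv <- crossprod(vc) / nrow(vc)
  if (any(!is.finite(cv)) || max(abs(cv)) < 1e-24)
    stop("degenerate vertex covariance")
  eg <- eigen(cv, symmetric = TRUE)
  ambiguous <- min(abs(diff(eg$values))) < 1e-8 * max(eg$values)
  R <- t(eg$vectors) # rows = principal axes
  proj <- vc %*% t(R)
  for (a in 1:2) {
    sk <- mean(proj[, a]^3)
    if (abs(sk) > 1e-8 * mean(proj[, a]^2)^1.5) {
      if (sk < 0) R[a, ] <- -R[a, ]
    } else {
      # symmetric axis: deterministic tie-break on the first off-center vertex
      i <- which(abs(proj[, a]) > 1e-12)[1]
      if (!is.na(i) && proj[i, a] < 0) R[a, ] <- -R[a, ]
      ambiguous <- TRUE
    }
  }
  R[3, ] <- c(R[1, 2] * R[2, 3] - R[1, 3] * R[2, 2],
              R[1, 3] * R[2, 1] - R[1, 1] * R[2, 3],
              R[1, 1] * R[2, 2] - R[1, 2] * R[2, 1])
  out <- mesh
  out$vertices <- vc %*% t(R)
  attr(out, "alignment") <- list(rotation = R, translation = -as.vector(R %*% cen),
                                 ambiguous = ambiguous)
  out
}
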