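#' Generate a parametric specimen with known ground truth
#'
#' Builds a closed, 2-manifold, bird-like surface of revolution around the x
#' axis: an ellipsoidal body, a tapered conical "bill" at +x and a flattened
#' tail fin at -x. The mesh stands in for a physical study skin: it keeps the
#' geometric challenges of real scans (a thin protrusion whose landmark
#' separation is the measured trait, a thin fin, smooth plumage) while every
#' quantity downstream stages estimate is known exactly.
#'
#' Landmarks are vertices by construction: `bill_tip` (the +x apex),
#' `bill_base` (on the bill/body junction ring) and `tail_tip`. The Euclidean
#' distance from `bill_tip` to `bill_base` equals `bill_length_mm` exactly.
#' Seeded variation perturbs body proportions and adds smooth radial bumps to
#' the body only, so the landmark construction stays exact for every seed.
#'
#' The albedo is two-tone per face. `albedo = "region"` colors bill + tail in
#' a dark slate and the body in a warm brown; `albedo = "balanced"` splits the
#' tones at the cumulative half of surface area along x, giving a known ~50/50
#' area split (exact to one face) for color-cloud tests.
#'
#' @param seed integer seed; identical seeds and parameters reproduce the
#'   output bit for bit.
#' @param bill_length_mm bill landmark separation in mm (default 14, a typical
#'   small-passerine bill).
#' @param body_diameter_mm nominal body diameter in mm.
#' @param subdivisions resolution multiplier (>= 2); face count grows roughly
#'   with its square.
#' @param albedo `"region"` or `"balanced"` (see Details).
#' @return A `specimen_truth` object: `mesh` (a [trimesh], mm), `landmarks`
#'   (named 3 x 3 matrix), `bill_length_mm`, `albedo_face_rgb` (M x 3 sRGB),
#'   `tone` (factor per face), `tone_areas`, `seed`.
#' @export
generate_specimen <- function(seed = 1L, bill_length_mm = 14,
                              body_diameter_mm = 40, subdivisions = 4L,
                              albedo = c("region", "balanced")) {
  albedo <- match.arg(albedo)
  if (bill_length_mm <= 0 || body_diameter_mm <= 0)
    stop("dimensions must be positive")
  if (subdivisions < 2) stop("subdivisions must be >= 2")
  rng <- local_rng(seed)

  # seeded body proportions
  b <- body_diameter_mm / 2 * rng$runif(1, 0.92, 1.08)  # body semi-minor axis
  a <- b * rng$runif(1, 1.35, 1.65)                     # body semi-major (x)
  r0 <- max(0.16 * bill_length_mm, 1.2)                 # bill base ring radius
  r0 <- min(r0, 0.5 * b)
  h <- sqrt(bill_length_mm^2 - r0^2)                    # bill axial extent
  x_b <- a * sqrt(1 - (r0 / b)^2)                       # bill junction
  r_t <- 0.30 * b                                       # tail junction radius
  x_t <- -a * sqrt(1 - (r_t / b)^2)
  tail_len <- b * rng$runif(1, 0.9, 1.3)
  x_tail <- x_t - tail_len

  nb <- max(3L, 2L * subdivisions)          # bill stations
  nbod <- 10L * subdivisions                # body stations
  ntl <- 4L * subdivisions                  # tail stations
  n_theta <- 12L * subdivisions

  # smooth seeded bumps on the body radius, windowed to vanish at junctions
  n_bump <- 3L
  bump_amp <- rng$runif(n_bump, 0, 0.03)
  bump_k <- rng$sample_int(4L, n_bump, replace = TRUE) + 1L
  bump_ph <- rng$runif(n_bump, 0, 2 * pi)

  body_radius <- function(x) {
    r <- b * sqrt(pmax(0, 1 - (x / a)^2))
    s <- (x - x_t) / (x_b - x_t)
    win <- sin(pi * pmin(pmax(s, 0), 1))^2
    mod <- rep(1, length(x))
    for (i in seq_len(n_bump))
      mod <- mod + bump_amp[i] * win * sin(bump_k[i] * pi * s + bump_ph[i])
    r * mod
  }

  # stations tail tip -> bill tip (junction x values included exactly)
  x_tailp <- x_tail + (x_t - x_tail) * seq(0, 1, length.out = ntl + 1)
  x_bodyp <- x_t + (x_b - x_t) * seq(0, 1, length.out = nbod + 1)
  x_billp <- x_b + h * seq(0, 1, length.out = nb + 1)
  xs <- c(x_tailp, x_bodyp[-1], x_billp[-1])
  region <- c(rep("tail", length(x_tailp)), rep("body", nbod), rep("bill", nb))

  radius <- numeric(length(xs))
  ez <- rep(1, length(xs))
  for (i in seq_along(xs)) {
    x <- xs[i]
    if (region[i] == "tail") {
      s <- (x - x_tail) / (x_t - x_tail)
      radius[i] <- r_t * s^0.7
      ez[i] <- 0.18 + 0.82 * s
    } else if (region[i] == "bill") {
      radius[i] <- r0 * (x_billp[length(x_billp)] - x) / h
    } else {
      radius[i] <- body_radius(x)
    }
  }
  radius[1] <- 0                       # tail tip pole
  radius[length(radius)] <- 0          # bill tip pole
  # exact junction ring: bill base
  i_bill <- length(x_tailp) + nbod     # index of x_b station
  radius[i_bill] <- r0

  theta <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  nring <- length(xs) - 2
  verts <- matrix(0, 2 + nring * n_theta, 3)
  verts[1, ] <- c(xs[1], 0, 0)                     # tail tip
  verts[2, ] <- c(xs[length(xs)], 0, 0)            # bill tip
  idx <- function(i, j) 2L + (i - 2L) * n_theta + j  # ring i (2..len-1), slot j (1..n_theta)
  for (i in 2:(length(xs) - 1)) {
    r <- radius[i]
    verts[idx(i, seq_len(n_theta)), ] <- cbind(
      xs[i], r * cos(theta), r * ez[i] * sin(theta))
  }

  faces <- list()
  # tail pole fan (outward = -x side)
  j2 <- c(2:n_theta, 1)
  faces[[1]] <- cbind(1L, idx(2, seq_len(n_theta)), idx(2, j2))
  # ring strips
  for (i in 2:(length(xs) - 2)) {
    aa <- idx(i, seq_len(n_theta)); bb <- idx(i, j2)
    cc <- idx(i + 1, seq_len(n_theta)); dd <- idx(i + 1, j2)
    faces[[length(faces) + 1]] <- cbind(aa, cc, dd)
    faces[[length(faces) + 1]] <- cbind(aa, dd, bb)
  }
  # bill pole fan
  last <- length(xs) - 1
  faces[[length(faces) + 1]] <- cbind(2L, idx(last, j2), idx(last, seq_len(n_theta)))
  f <- do.call(rbind, faces)
  mesh <- trimesh(verts, f, units = "mm")
  if (mesh_volume(mesh) < 0) mesh$faces <- mesh$faces[, c(1, 3, 2)]
  # seat the specimen just above the z = 0 turntable plane (the stand
  # occupies z < 0, matching how mounts sit under real skins)
  lift <- 0.5 - min(mesh$vertices[, 3])
  mesh$vertices[, 3] <- mesh$vertices[, 3] + lift

  landmarks <- rbind(
    bill_tip = c(xs[length(xs)], 0, lift),
    bill_base = c(x_b, r0, lift),
    tail_tip = c(xs[1], 0, lift))

  # per-face tones
  cen <- face_centroids(mesh)
  fa <- face_areas(mesh)
  tone_body <- c(0.55, 0.35, 0.20)   # warm brown plumage
  tone_dark <- c(0.17, 0.17, 0.22)   # slate bill/tail
  if (albedo == "region") {
    tone <- ifelse(cen[, 1] > x_b - 1e-9, "dark",
                   ifelse(cen[, 1] < x_t + 1e-9, "dark", "body"))
  } else {
    ord <- order(cen[, 1], seq_along(fa))
    cum <- cumsum(fa[ord])
    split_at <- which(cum >= sum(fa) / 2)[1]
    tone <- character(length(fa))
    tone[ord[seq_len(split_at)]] <- "dark"
    tone[ord[-seq_len(split_at)]] <- "body"
  }
  albedo_face_rgb <- matrix(0, nrow(f), 3)
  albedo_face_rgb[tone == "body", ] <- matrix(tone_body, sum(tone == "body"), 3, byrow = TRUE)
  albedo_face_rgb[tone == "dark", ] <- matrix(tone_dark, sum(tone == "dark"), 3, byrow = TRUE)
  tone_areas <- c(body = sum(fa[tone == "body"]), dark = sum(fa[tone == "dark"]))

  structure(list(
    mesh = mesh, landmarks = landmarks, bill_length_mm = bill_length_mm,
    albedo_face_rgb = albedo_face_rgb, tone = factor(tone),
    tone_rgb = rbind(body = tone_body, dark = tone_dark),
    tone_areas = tone_areas, seed = as.integer(seed),
    params = list(a = a, b = b, r0 = r0, x_b = x_b, x_t = x_t,
                  x_tail = x_tail, subdivisions = subdivisions, albedo = albedo)),
    class = "specimen_truth")
}

#' @export
print.specimen_truth <- function(x, ...) {
  cat(sprintf("<specimen_truth> seed %d, bill %.2f mm, %d faces\n",
              x$seed, x$bill_length_mm, nrow(x$mesh$faces)))
  invisible(x)
}

#' Inject realistic scan defects into a specimen mesh
#'
#' Emulates what raw photogrammetry meshes look like before cleanup: open
#' holes, small floating debris shells, a stand tube under the specimen and
#' (optionally) non-manifold fin faces. Every defect is enumerated in the
#' returned report so repair stages can be tested exactly.
#'
#' @param truth a `specimen_truth` from [generate_specimen()].
#' @param seed integer seed.
#' @param n_holes number of single-face holes to open (placed on the body,
#'   vertex-disjoint, so each adds exactly one boundary loop).
#' @param n_debris number of floating debris shells (< 1% of specimen area
#'   each).
#' @param add_stand attach a closed stand tube under the body, penetrating the
#'   underside the way a mount does in a real scan.
#' @param n_nonmanifold number of extra "fin" faces glued onto interior edges
#'   (each makes one edge non-manifold).
#' @return list with `mesh` (the defective [trimesh]) and `report`, a
#'   `defect_report`: `holes_added`, `debris_components_added`, `stand_faces`
#'   (face indices in the returned mesh), `nonmanifold_edges_added`, `seed`.
#' @export
inject_defects <- function(truth, seed = 1L, n_holes = 3L, n_debris = 2L,
                           add_stand = TRUE, n_nonmanifold = 0L) {
  stopifnot(inherits(truth, "specimen_truth"))
  if (n_holes < 0 || n_debris < 0 || n_nonmanifold < 0)
    stop("defect counts must be non-negative")
  mesh <- truth$mesh
  rng <- local_rng(seed + 7919L)
  report <- list(holes_added = 0L, debris_components_added = 0L,
                 stand_faces = integer(0), nonmanifold_edges_added = 0L,
                 seed = as.integer(seed))

  if (n_holes == 0 && n_debris == 0 && !add_stand && n_nonmanifold == 0) {
    class(report) <- "defect_report"
    return(list(mesh = mesh, report = report))
  }

  # holes: remove vertex-disjoint single faces on the body
  drop_faces <- integer(0)
  if (n_holes > 0) {
    cen <- face_centroids(mesh)
    cand <- which(cen[, 1] > truth$params$x_t * 0.8 &
                    cen[, 1] < truth$params$x_b * 0.8 &
                    cen[, 3] > -truth$params$b * 0.5)
    cand <- cand[order(rng$runif(length(cand)))]
    used_v <- integer(0)
    for (fi in cand) {
      if (length(drop_faces) >= n_holes) break
      vs <- mesh$faces[fi, ]
      if (any(vs %in% used_v)) next
      drop_faces <- c(drop_faces, fi)
      # exclude the whole 1-ring so loops stay disjoint
      ring <- which(rowSums(matrix(mesh$faces %in% vs, ncol = 3)) > 0)
      used_v <- c(used_v, unique(as.vector(mesh$faces[ring, ])))
    }
    if (length(drop_faces) < n_holes)
      stop("defect-injection error: not enough disjoint face patches for requested holes")
    report$holes_added <- length(drop_faces)
  }

  keep <- setdiff(seq_len(nrow(mesh$faces)), drop_faces)
  out <- trimesh(mesh$vertices, mesh$faces[keep, , drop = FALSE], units = mesh$units)

  # non-manifold fins: extra triangle on an interior edge
  if (n_nonmanifold > 0) {
    et <- mesh_edge_table(out)
    inner <- which(et$count == 2L)
    pick <- inner[floor(rng$runif(n_nonmanifold, 1, length(inner) + 0.999))]
    newv <- list(); newf <- list()
    nv <- nrow(out$vertices)
    for (i in seq_along(pick)) {
      aa <- et$a[pick[i]]; bb <- et$b[pick[i]]
      mid <- (out$vertices[aa, ] + out$vertices[bb, ]) / 2
      apex <- mid + c(0, 0, 1) * 1.5
      newv[[i]] <- apex
      newf[[i]] <- c(aa, bb, nv + i)
    }
    out <- trimesh(rbind(out$vertices, do.call(rbind, newv)),
                   rbind(out$faces, do.call(rbind, newf)), units = out$units)
    report$nonmanifold_edges_added <- length(pick)
  }

  # floating debris shells
  if (n_debris > 0) {
    area <- mesh_area(truth$mesh)
    r_d <- sqrt(0.008 * area / (4 * pi))
    ext <- apply(truth$mesh$vertices, 2, range)
    for (i in seq_len(n_debris)) {
      center <- c(rng$runif(1, ext[1, 1], ext[2, 1]),
                  rng$runif(1, ext[2, 2] + 3 * r_d, ext[2, 2] + 10 * r_d),
                  rng$runif(1, ext[1, 3], ext[2, 3]))
      out <- merge_meshes(out, mesh_icosphere(1, r_d, center))
    }
    report$debris_components_added <- as.integer(n_debris)
  }

  # stand tube: closed cylinder penetrating the body underside
  if (add_stand) {
    zmin <- min(truth$mesh$vertices[, 3])
    tube <- stand_tube(radius = 1.5, z0 = zmin - 15, z1 = zmin + 3,
                       x = 0, y = 0)
    n_before <- nrow(out$faces)
    out <- merge_meshes(out, tube)
    report$stand_faces <- seq.int(n_before + 1L, nrow(out$faces))
  }

  class(report) <- "defect_report"
  list(mesh = out, report = report)
}

# closed vertical cylinder (tube plus cap fans)
stand_tube <- function(radius, z0, z1, x = 0, y = 0, n = 12L, m = 6L) {
  zs <- seq(z0, z1, length.out = m + 1)
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  v <- do.call(rbind, lapply(zs, function(z)
    cbind(x + radius * cos(th), y + radius * sin(th), z)))
  v <- rbind(v, c(x, y, z0), c(x, y, z1))
  bot <- nrow(v) - 1L; top <- nrow(v)
  idx <- function(i, j) (i - 1L) * n + j
  j2 <- c(2:n, 1)
  f <- list()
  for (i in seq_len(m)) {
    aa <- idx(i, seq_len(n)); bb <- idx(i, j2)
    cc <- idx(i + 1, seq_len(n)); dd <- idx(i + 1, j2)
    f[[length(f) + 1]] <- cbind(aa, bb, dd)
    f[[length(f) + 1]] <- cbind(aa, dd, cc)
  }
  f[[length(f) + 1]] <- cbind(bot, idx(1, j2), idx(1, seq_len(n)))
  f[[length(f) + 1]] <- cbind(top, idx(m + 1, seq_len(n)), idx(m + 1, j2))
  tube <- trimesh(v, do.call(rbind, f), units = "mm")
  if (mesh_volume(tube) < 0) tube$faces <- tube$faces[, c(1, 3, 2)]
  tube
}

#' @export
print.defect_report <- function(x, ...) {
  cat(sprintf("<defect_report> holes %d, debris %d, stand faces %d, non-manifold %d\n",
              x$holes_added, x$debris_components_added,
              length(x$stand_faces), x$nonmanifold_edges_added))
  invisible(x)
}
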