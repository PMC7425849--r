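#' Read and write Wavefront OBJ files
#'
#' Minimal OBJ support for the formats this pipeline exchanges: `v` records
#' (written at 6 decimal places), optional `vt` records with per-corner
#' texture coordinates (v-origin bottom-left), `f` records with 1-based
#' `v` or `v/vt` indices, and optional `mtllib`/`usemtl` references.
#'
#' @param mesh a [trimesh].
#' @param path output file path (refused if it already exists unless
#'   `overwrite = TRUE`).
#' @param uv optional (3M) x 2 matrix of per-face-corner texture coordinates
#'   (rows grouped per face in corner order), e.g. from a [generate_uv()].
#' @param mtl optional name of an `.mtl` file to reference (`mtllib`).
#' @param material optional material name (`usemtl`).
#' @param overwrite logical; allow replacing an existing file.
#' @return `path`, invisibly.
#' @export
write_obj <- function(mesh, path, uv = NULL, mtl = NULL, material = NULL,
                      overwrite = FALSE) {
  stopifnot_trimesh(mesh)
  if (file.exists(path) && !overwrite)
    stop("refusing to overwrite existing file: ", path)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(mtl)) writeLines(paste("mtllib", mtl), con)
  writeLines(sprintf("v %.6f %.6f %.6f",
                     mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]), con)
  f <- mesh$faces
  if (is.null(uv)) {
    if (!is.null(material)) writeLines(paste("usemtl", material), con)
    writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  } else {
    stopifnot(nrow(uv) == 3 * nrow(f))
    key <- paste(sprintf("%.8f", uv[, 1]), sprintf("%.8f", uv[, 2]))
    uniq <- !duplicated(key)
    vt_idx <- match(key, key[uniq])
    vt <- uv[uniq, , drop = FALSE]
    writeLines(sprintf("vt %.8f %.8f", vt[, 1], vt[, 2]), con)
    if (!is.null(material)) writeLines(paste("usemtl", material), con)
    i1 <- vt_idx[seq(1, length(vt_idx), by = 3)]
    i2 <- vt_idx[seq(2, length(vt_idx), by = 3)]
    i3 <- vt_idx[seq(3, length(vt_idx), by = 3)]
    writeLines(sprintf("f %d/%d %d/%d %d/%d",
                       f[, 1], i1, f[, 2], i2, f[, 3], i3), con)
  }
  invisible(path)
}

#' @rdname write_obj
#' @return For `read_obj()`: a list with `mesh` (a [trimesh]), `uv`
#'   ((3M) x 2 per-corner coordinates or `NULL`), `n_vt` (number of `vt`
#'   records), and `mtllib` (referenced material file or `NULL`).
#' @export
read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  tag <- sub("^([a-zA-Z_]+).*", "\\1", lines)
  parse_num <- function(sel, n) {
    if (!any(sel)) return(NULL)
    body <- sub("^[a-zA-Z_]+\\s+", "", lines[sel])
    mat <- do.call(rbind, lapply(strsplit(body, "\\s+"), function(x)
      as.numeric(x[seq_len(n)])))
    mat
  }
  v <- parse_num(tag == "v", 3)
  vt <- parse_num(tag == "vt", 2)
  fl <- lines[tag == "f"]
  if (length(fl) == 0) stop("no faces in OBJ: ", path)
  fparts <- strsplit(sub("^f\\s+", "", fl), "\\s+")
  fv <- matrix(0L, length(fparts), 3)
  ft <- matrix(NA_integer_, length(fparts), 3)
  for (i in seq_along(fparts)) {
    for (c in 1:3) {
      bits <- strsplit(fparts[[i]][c], "/")[[1]]
      fv[i, c] <- as.integer(bits[1])
      if (length(bits) >= 2 && nzchar(bits[2])) ft[i, c] <- as.integer(bits[2])
    }
  }
  uv <- NULL
  if (!is.null(vt) && !anyNA(ft)) {
    uv <- matrix(0, 3 * nrow(ft), 2)
    uv[seq(1, nrow(uv), by = 3), ] <- vt[ft[, 1], , drop = FALSE]
    uv[seq(2, nrow(uv), by = 3), ] <- vt[ft[, 2], , drop = FALSE]
    uv[seq(3, nrow(uv), by = 3), ] <- vt[ft[, 3], , drop = FALSE]
  }
  mtl <- lines[tag == "mtllib"]
  list(mesh = trimesh(v, fv),
       uv = uv,
       n_vt = if (is.null(vt)) 0L else nrow(vt),
       mtllib = if (length(mtl)) sub("^mtllib\\s+", "", mtl[1]) else NULL)
}
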