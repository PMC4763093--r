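#' Indexed triangle mesh
#'
#' The central container of the package: an indexed triangle mesh as exported
#' by structure-from-motion software. Vertices are stored as an `n x 3`
#' numeric matrix, faces as an `m x 3` integer matrix of 1-based vertex
#' indices, with optional per-vertex texture coordinates. The `units` flag
#' records whether coordinates are still in arbitrary model units or have
#' been calibrated to centimetres (see [apply_scale()]).
#'
#' @param vertices numeric matrix (`n x 3`) of vertex positions.
#' @param faces integer matrix (`m x 3`) of 1-based vertex indices; every
#'   face must reference three distinct vertices.
#' @param texcoords optional numeric matrix (`n x 2`) of per-vertex texture
#'   coordinates.
#' @param units `"model"` (uncalibrated) or `"cm"`.
#' @return An object of class `coral_mesh`.
#' @examples
#' m <- coral_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
#'                 rbind(c(1L, 2L, 3L)))
#' surface_area(m)
#' @export
coral_mesh <- function(vertices, faces, texcoords = NULL,
                       units = c("model", "cm")) {
  units <- match.arg(units)
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L)
    stop("vertices must be an n x 3 matrix", call. = FALSE)
  if (length(faces) == 0L) {
    faces <- matrix(integer(0), ncol = 3L)
  } else {
    faces <- as.matrix(faces)
    storage.mode(faces) <- "integer"
  }
  if (ncol(faces) != 3L)
    stop("faces must be an m x 3 matrix of vertex indices", call. = FALSE)
  if (!is.null(texcoords)) {
    texcoords <- as.matrix(texcoords)
    storage.mode(texcoords) <- "double"
    if (nrow(texcoords) != nrow(vertices) || ncol(texcoords) != 2L)
      stop("texcoords must be an n x 2 matrix matching the vertex count",
           call. = FALSE)
  }
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  mesh <- structure(
    list(vertices = vertices, faces = faces, texcoords = texcoords,
         units = units),
    class = "coral_mesh")
  validate_mesh(mesh)
  mesh
}

#' Validate the structural invariants of a mesh
#'
#' Checks that all face indices are in range, that no face references the
#' same vertex twice, and that coordinates are finite.
#'
#' @param mesh a [coral_mesh()].
#' @return The mesh, invisibly. Errors on violation.
#' @export
validate_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "coral_mesh"))
  f <- mesh$faces
  nv <- nrow(mesh$vertices)
  if (length(f) > 0L) {
    if (anyNA(f) || min(f) < 1L || max(f) > nv)
      stop("face index out of range [1, ", nv, "]", call. = FALSE)
    dup <- f[, 1L] == f[, 2L] | f[, 1L] == f[, 3L] | f[, 2L] == f[, 3L]
    if (any(dup))
      stop("face(s) ", paste(utils::head(which(dup), 5L), collapse = ", "),
           " reference the same vertex twice", call. = FALSE)
  }
  if (nrow(mesh$vertices) > 0L && !all(is.finite(mesh$vertices)))
    stop("non-finite vertex coordinates", call. = FALSE)
  invisible(mesh)
}

#' @export
print.coral_mesh <- function(x, ...) {
  cat(sprintf("<coral_mesh> %d vertices, %d faces, units = %s%s\n",
              nrow(x$vertices), nrow(x$faces), x$units,
              if (is.null(x$texcoords)) "" else ", textured"))
  invisible(x)
}

#' Number of vertices / faces of a mesh
#' @param mesh a [coral_mesh()].
#' @return Integer count.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' @rdname n_vertices
#' @export
n_faces <- function(mesh) nrow(mesh$faces)

# Undirected edge table of a mesh: one row per face-edge occurrence with
# columns a, b (a < b), face, and a numeric key unique per undirected edge.
mesh_edges <- function(mesh) {
  f <- mesh$faces
  m <- nrow(f)
  va <- c(f[, 1L], f[, 2L], f[, 3L])
  vb <- c(f[, 2L], f[, 3L], f[, 1L])
  a <- pmin(va, vb)
  b <- pmax(va, vb)
  nv <- nrow(mesh$vertices)
  list(from = va, to = vb, a = a, b = b,
       face = rep.int(seq_len(m), 3L),
       key = (as.numeric(a) - 1) * nv + as.numeric(b))
}

#' Read a Wavefront OBJ file
#'
#' Parses `v`, `vt` and `f` records. Faces with more than three corners are
#' fan-triangulated from their first corner; negative (relative) OBJ indices
#' are resolved; material and grouping statements (`mtllib`, `usemtl`, `o`,
#' `g`, `s`, `vn`) are ignored. OBJ indices are 1-based and are kept 1-based
#' internally. When texture-coordinate indices are present, texture
#' coordinates are resolved to one coordinate pair per vertex (the last
#' assignment wins, which is exact for the one-to-one mappings produced by
#' photogrammetry exporters).
#'
#' @param path path to an OBJ file.
#' @param units units to stamp on the mesh, `"model"` by default.
#' @return A [coral_mesh()].
#' @export
read_obj <- function(path, units = "model") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  toks <- strsplit(trimws(lines), "[ \t]+")
  kind <- vapply(toks, function(t) if (length(t)) t[[1L]] else "", "")

  vlines <- toks[kind == "v"]
  nv <- length(vlines)
  verts <- matrix(NA_real_, nv, 3L)
  for (i in seq_len(nv)) {
    xyz <- suppressWarnings(as.numeric(vlines[[i]][2:4]))
    if (anyNA(xyz))
      stop("malformed vertex line ", which(kind == "v")[i], call. = FALSE)
    verts[i, ] <- xyz
  }

  vtlines <- toks[kind == "vt"]
  nvt <- length(vtlines)
  vt <- if (nvt) {
    m <- matrix(NA_real_, nvt, 2L)
    for (i in seq_len(nvt)) m[i, ] <- as.numeric(vtlines[[i]][2:3])
    m
  } else NULL

  fidx <- which(kind == "f")
  face_list <- vector("list", length(fidx))
  tc_assign <- if (!is.null(vt)) matrix(NA_real_, nv, 2L) else NULL
  for (i in seq_along(fidx)) {
    t <- toks[[fidx[i]]][-1L]
    if (length(t) < 3L)
      stop("malformed face line ", fidx[i], ": fewer than 3 vertices",
           call. = FALSE)
    parts <- strsplit(t, "/", fixed = TRUE)
    vi <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 1L)))
    if (anyNA(vi))
      stop("malformed face line ", fidx[i], call. = FALSE)
    vi <- ifelse(vi < 0L, nv + vi + 1L, vi)
    if (any(vi < 1L | vi > nv))
      stop("face index out of range on line ", fidx[i], call. = FALSE)
    if (!is.null(tc_assign)) {
      ti <- vapply(parts, function(p)
        if (length(p) >= 2L && nzchar(p[2L])) p[2L] else NA_character_, "")
      ti <- suppressWarnings(as.integer(ti))
      ti <- ifelse(!is.na(ti) & ti < 0L, nvt + ti + 1L, ti)
      ok <- !is.na(ti)
      if (any(ok)) {
        if (any(ti[ok] < 1L | ti[ok] > nvt))
          stop("texture index out of range on line ", fidx[i], call. = FALSE)
        tc_assign[vi[ok], ] <- vt[ti[ok], , drop = FALSE]
      }
    }
    # fan triangulation of polygons
    k <- length(vi)
    tri <- cbind(vi[1L], vi[2:(k - 1L)], vi[3:k])
    face_list[[i]] <- tri
  }
  faces <- if (length(face_list)) do.call(rbind, face_list) else
    matrix(integer(0), ncol = 3L)
  if (!is.null(tc_assign) && all(is.na(tc_assign))) tc_assign <- NULL
  if (!is.null(tc_assign)) tc_assign[is.na(tc_assign)] <- 0
  coral_mesh(verts, faces, texcoords = tc_assign, units = units)
}

#' Write a mesh to a Wavefront OBJ file
#'
#' Writes `v`, optional `vt`, and `f` records with 1-based indices, fixed
#' decimal formatting and deterministic ordering, so identical meshes yield
#' byte-identical files across runs.
#'
#' @param mesh a [coral_mesh()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_obj <- function(mesh, path) {
  validate_mesh(mesh)
  con <- file(path, open = "wb")
  on.exit(close(con))
  v <- mesh$vertices
  out <- sprintf("v %.8f %.8f %.8f", v[, 1L], v[, 2L], v[, 3L])
  if (!is.null(mesh$texcoords)) {
    tc <- mesh$texcoords
    out <- c(out, sprintf("vt %.8f %.8f", tc[, 1L], tc[, 2L]))
    f <- mesh$faces
    out <- c(out, sprintf("f %d/%d %d/%d %d/%d",
                          f[, 1L], f[, 1L], f[, 2L], f[, 2L],
                          f[, 3L], f[, 3L]))
  } else {
    f <- mesh$faces
    out <- c(out, sprintf("f %d %d %d", f[, 1L], f[, 2L], f[, 3L]))
  }
  writeLines(out, con, sep = "\n")
  invisible(path)
}

#' Rigidly transform or uniformly scale a mesh
#'
#' `transform_mesh` applies `x -> R x + t`; `scale_mesh` multiplies all
#' vertex coordinates by a scalar (keeping the units flag; see
#' [apply_scale()] for the calibration step that sets units to cm).
#'
#' @param mesh a [coral_mesh()].
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 numeric vector.
#' @return The transformed mesh.
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  mesh$vertices <- sweep(mesh$vertices %*% t(rotation), 2L,
                         as.numeric(translation), "+")
  mesh
}

#' @rdname transform_mesh
#' @param s positive scalar.
#' @export
scale_mesh <- function(mesh, s) {
  stopifnot(is.numeric(s), length(s) == 1L, s > 0)
  mesh$vertices <- mesh$vertices * s
  mesh
}
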