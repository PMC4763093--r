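# Geometric primitives on triangle meshes: per-face areas and normals,
# total / label-restricted surface area, divergence-theorem enclosed volume,
# boundary-loop extraction and flat hole filling.

# Per-face cross products (m x 3); |cross|/2 is the triangle area.
face_cross <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  p1 <- v[f[, 1L], , drop = FALSE]
  e1 <- v[f[, 2L], , drop = FALSE] - p1
  e2 <- v[f[, 3L], , drop = FALSE] - p1
  cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
        e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
        e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
}

#' Per-face triangle areas
#' @param mesh a [coral_mesh()].
#' @return Numeric vector of length `n_faces(mesh)`.
#' @export
face_areas <- function(mesh) {
  cr <- face_cross(mesh)
  0.5 * sqrt(rowSums(cr * cr))
}

#' Surface area of a mesh, optionally restricted to labelled face classes
#'
#' Sums triangle areas (half cross-product magnitude) over all faces, or —
#' when a [face_labels()] mask and a class set are given — over the faces
#' whose label is in `classes`. Total surface area (TSA) is the unrestricted
#' sum; effective surface area (ESA), the living-tissue surface, is the sum
#' over `classes = "living"`. Degenerate (zero-area) faces contribute zero
#' and raise a warning with their count.
#'
#' @param mesh a [coral_mesh()].
#' @param mask optional [face_labels()] mask for `mesh`.
#' @param classes character vector of label classes to include; required
#'   when `mask` is given.
#' @return Surface area in squared mesh units (cm^2 after calibration).
#' @seealso [enclosed_volume()], [segment_mesh()]
#' @export
surface_area <- function(mesh, mask = NULL, classes = NULL) {
  validate_mesh(mesh)
  areas <- face_areas(mesh)
  if (!is.null(mask)) {
    if (is.null(classes) || length(classes) == 0L)
      stop("a non-empty class set is required when a mask is given",
           call. = FALSE)
    check_labels(mask, mesh)
    classes <- match.arg(classes, label_classes(), several.ok = TRUE)
    areas <- areas[mask$labels %in% classes]
  }
  ndeg <- sum(areas == 0)
  if (ndeg > 0L)
    warning(ndeg, " degenerate zero-area face(s) contribute no area",
            call. = FALSE)
  sum(areas)
}

#' Boundary loops of an edge-manifold mesh
#'
#' A boundary edge borders exactly one face. This function chains all
#' boundary edges into closed loops and returns them as ordered vertex-index
#' cycles; a watertight mesh yields an empty list. Edges shared by three or
#' more faces are a structural error.
#'
#' @param mesh a [coral_mesh()].
#' @return List of integer vectors, each an ordered closed cycle of vertex
#'   indices (first vertex not repeated at the end).
#' @export
boundary_loops <- function(mesh) {
  validate_mesh(mesh)
  if (n_faces(mesh) == 0L) return(list())
  ed <- mesh_edges(mesh)
  cnt <- table(ed$key)
  bad <- names(cnt)[cnt > 2L]
  if (length(bad)) {
    nv <- nrow(mesh$vertices)
    k <- as.numeric(bad)
    a <- floor(k / nv) + 1
    b <- k - (a - 1) * nv
    stop("non-manifold edge(s): ",
         paste(sprintf("(%d,%d)", as.integer(a), as.integer(b))[
           seq_len(min(5L, length(bad)))], collapse = " "),
         call. = FALSE)
  }
  is_boundary <- ed$key %in% names(cnt)[cnt == 1L]
  if (!any(is_boundary)) return(list())
  # directed boundary edges, as wound in their unique face
  from <- ed$from[is_boundary]
  to <- ed$to[is_boundary]
  nv <- nrow(mesh$vertices)
  edge_at <- integer(nv)             # outgoing boundary edge per vertex
  edge_at[from] <- seq_along(from)   # (duplicates: holes touching at a
  visited <- rep(FALSE, length(from))#  vertex; one overwrites, loops still
  loops <- list()                    #  close because successors are unique)
  for (start_i in seq_along(from)) {
    if (visited[start_i]) next
    loop <- integer(0)
    v0 <- from[start_i]
    v <- v0
    i <- start_i
    repeat {
      if (i == 0L || visited[i])
        stop("open boundary chain: mesh is not edge-manifold along its ",
             "boundary", call. = FALSE)
      visited[i] <- TRUE
      loop <- c(loop, v)
      v <- to[i]
      if (v == v0) break
      i <- edge_at[v]
    }
    loops[[length(loops) + 1L]] <- loop
  }
  loops
}

#' Test whether a mesh is watertight
#' @param mesh a [coral_mesh()].
#' @return `TRUE` if no edge borders fewer than two faces.
#' @export
is_watertight <- function(mesh) {
  if (n_faces(mesh) == 0L) return(FALSE)
  ed <- mesh_edges(mesh)
  cnt <- table(ed$key)
  all(cnt == 2L)
}

# Re-orient faces to consistent winding by flood fill over the face adjacency
# graph, starting from the largest face of each connected component. Errors
# on non-orientable surfaces. Returns the mesh with possibly flipped faces.
orient_faces <- function(mesh) {
  m <- n_faces(mesh)
  if (m == 0L) return(mesh)
  ed <- mesh_edges(mesh)
  # adjacency: faces sharing an undirected edge, with the direction each
  # face uses for that edge
  o <- order(ed$key)
  key <- ed$key[o]; face <- ed$face[o]
  from <- ed$from[o]; to <- ed$to[o]
  same <- key[-1L] == key[-length(key)]
  i1 <- which(same)            # pairs (i1, i1+1) share an edge
  fa <- face[i1]; fb <- face[i1 + 1L]
  # TRUE when both faces traverse the shared edge in the same direction,
  # i.e. their windings disagree
  agree_dir <- from[i1] == from[i1 + 1L]
  adj <- vector("list", m)
  for (k in seq_along(fa)) {
    adj[[fa[k]]] <- c(adj[[fa[k]]], k)
    adj[[fb[k]]] <- c(adj[[fb[k]]], k)
  }
  areas <- face_areas(mesh)
  flip <- rep(NA, m)           # NA = unvisited
  for (comp_seed in order(-areas)) {
    if (!is.na(flip[comp_seed])) next
    flip[comp_seed] <- FALSE
    queue <- comp_seed
    while (length(queue)) {
      fcur <- queue[[1L]]; queue <- queue[-1L]
      for (k in adj[[fcur]]) {
        other <- if (fa[k] == fcur) fb[k] else fa[k]
        want <- if (agree_dir[k]) !flip[fcur] else flip[fcur]
        if (is.na(flip[other])) {
          flip[other] <- want
          queue <- c(queue, other)
        } else if (flip[other] != want) {
          stop("mesh surface is non-orientable; volume undefined",
               call. = FALSE)
        }
      }
    }
  }
  if (any(flip)) {
    f <- mesh$faces
    f[flip, c(2L, 3L)] <- f[flip, c(3L, 2L)]
    mesh$faces <- f
  }
  mesh
}

#' Enclosed volume of a watertight mesh
#'
#' Divergence-theorem (signed tetrahedron) volume: the sum over faces of
#' `det(v1, v2, v3) / 6`, returned as an absolute value so the result does
#' not depend on global orientation. The mesh must be watertight; faces are
#' first re-oriented to consistent winding by flood fill (an error is raised
#' for non-orientable surfaces). Open meshes — e.g. foliose colony models
#' whose thin fronds never close — raise a distinct `coralmesh_open_mesh`
#' error; fill their holes first with [fill_holes_flat()] if a volume is
#' genuinely wanted.
#'
#' @param mesh a [coral_mesh()].
#' @return Volume in cubed mesh units (cm^3 after calibration).
#' @seealso [fill_holes_flat()], [boundary_loops()]
#' @export
enclosed_volume <- function(mesh) {
  validate_mesh(mesh)
  if (n_faces(mesh) == 0L)
    stop_open_mesh("mesh has no faces; volume not computable")
  ed <- mesh_edges(mesh)
  cnt <- table(ed$key)
  if (any(cnt > 2L))
    stop("non-manifold mesh: some edges border more than two faces",
         call. = FALSE)
  if (any(cnt == 1L)) {
    nb <- sum(cnt == 1L)
    stop_open_mesh(sprintf(
      "mesh is not watertight (%d boundary edge%s); volume not computable",
      nb, if (nb == 1L) "" else "s"))
  }
  mesh <- orient_faces(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  p1 <- v[f[, 1L], , drop = FALSE]
  p2 <- v[f[, 2L], , drop = FALSE]
  p3 <- v[f[, 3L], , drop = FALSE]
  det6 <- p1[, 1L] * (p2[, 2L] * p3[, 3L] - p2[, 3L] * p3[, 2L]) -
          p1[, 2L] * (p2[, 1L] * p3[, 3L] - p2[, 3L] * p3[, 1L]) +
          p1[, 3L] * (p2[, 1L] * p3[, 2L] - p2[, 2L] * p3[, 1L])
  abs(sum(det6)) / 6
}

stop_open_mesh <- function(msg) {
  stop(structure(class = c("coralmesh_open_mesh", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Close every boundary loop with a flat centroid fan
#'
#' Each boundary loop is closed by a fan of triangles from the loop's vertex
#' centroid — the flat patch a mesh editor's "flat remesh" hole repair
#' produces on the planar break surfaces of sampled colonies. Original faces
#' are untouched; the indices of the added faces are returned so callers can
#' label them as non-living contact surface (they are artificial, not coral
#' tissue). Applying the repair to a watertight mesh is a no-op, and the
#' operation is idempotent.
#'
#' @param mesh an edge-manifold [coral_mesh()].
#' @param loops optional list of boundary loops (as returned by
#'   [boundary_loops()]) to fill; by default every boundary loop is filled.
#' @return A list with elements `mesh` (the repaired mesh, watertight when
#'   all loops were filled) and `added_faces` (integer indices of the new
#'   faces in the repaired mesh; empty if the input was already watertight).
#' @export
fill_holes_flat <- function(mesh, loops = NULL) {
  if (is.null(loops)) loops <- boundary_loops(mesh)
  if (length(loops) == 0L)
    return(list(mesh = mesh, added_faces = integer(0)))
  v <- mesh$vertices
  f <- mesh$faces
  tc <- mesh$texcoords
  added <- integer(0)
  for (loop in loops) {
    centroid <- colMeans(v[loop, , drop = FALSE])
    v <- rbind(v, centroid)
    ci <- nrow(v)
    if (!is.null(tc)) tc <- rbind(tc, colMeans(tc[loop, , drop = FALSE]))
    k <- length(loop)
    nxt <- c(loop[-1L], loop[1L])
    # boundary edges run a -> b as wound in their face; the patch triangle
    # reverses them (b, a, centroid) so the patch winding is consistent
    new_f <- cbind(nxt, loop, ci)
    first <- nrow(f) + 1L
    f <- rbind(f, new_f)
    added <- c(added, first:nrow(f))
  }
  out <- coral_mesh(v, f, texcoords = tc, units = mesh$units)
  list(mesh = out, added_faces = added)
}

#' Extract the submesh of selected label classes
#'
#' Returns the faces whose label is in `classes`, with unreferenced vertices
#' dropped and indices compacted; texture coordinates are carried over. This
#' is the digital analogue of segmenting a colony from its surrounding
#' environment.
#'
#' @param mesh a [coral_mesh()].
#' @param mask a [face_labels()] mask for `mesh`.
#' @param classes label classes to keep (non-empty).
#' @return A list with elements `mesh` (the submesh), `mask` (labels of the
#'   kept faces) and `face_map` (for each submesh face, its index in the
#'   input mesh).
#' @export
segment_mesh <- function(mesh, mask, classes) {
  validate_mesh(mesh)
  check_labels(mask, mesh)
  classes <- match.arg(classes, label_classes(), several.ok = TRUE)
  keep <- which(mask$labels %in% classes)
  if (length(keep) == 0L)
    stop("empty selection: no face carries a label in {",
         paste(classes, collapse = ", "), "}", call. = FALSE)
  f <- mesh$faces[keep, , drop = FALSE]
  used <- sort(unique(as.vector(f)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  f2 <- matrix(remap[f], ncol = 3L)
  v2 <- mesh$vertices[used, , drop = FALSE]
  tc2 <- if (!is.null(mesh$texcoords))
    mesh$texcoords[used, , drop = FALSE] else NULL
  list(mesh = coral_mesh(v2, f2, texcoords = tc2, units = mesh$units),
       mask = face_labels(mask$labels[keep]),
       face_map = keep)
}
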