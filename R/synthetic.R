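# Parametric synthetic colonies with analytic ground truth. Each generator
# emulates one coral growth form as an assembly of primitives whose surface
# area and volume have closed forms, sitting above a background seafloor
# plane with the basal contact labelled non-living. Realism is secondary to
# testability: branched and tabular assemblies are kept overlap-free so the
# closed-form sums are exact, and the foliose form is deliberately an open
# shell to exercise the volume-refusal path.

#' Specification of a synthetic colony
#'
#' @param growth_form one of `"massive"` (hemisphere on a base disc),
#'   `"branched"` (tapered branch frusta around a trunk), `"tabular"` (thin
#'   plate over a stalk), `"foliose"` (open thin shell, intentionally
#'   non-watertight).
#' @param size_cm characteristic radius/height in cm (default 5).
#' @param resolution subdivision level, >= 1 (default 3); azimuthal segment
#'   counts scale as `8 * 2^resolution`.
#' @param seed integer seed driving the (small) stochastic placement
#'   choices; generators are deterministic given the seed.
#' @param sample_patch_fraction fraction of the living area detached by
#'   [apply_sampling()], in `[0, 0.5]` (default 0.05, the small
#'   hammer-and-chisel sample of a field campaign).
#' @param tissue_thickness_cm tissue layer eroded by [apply_bleaching()]
#'   (default 0.1 cm).
#' @return An object of class `synthetic_colony_spec`.
#' @export
synthetic_colony_spec <- function(growth_form = c("massive", "branched",
                                                  "tabular", "foliose"),
                                  size_cm = 5, resolution = 3L, seed = 1L,
                                  sample_patch_fraction = 0.05,
                                  tissue_thickness_cm = 0.1) {
  growth_form <- match.arg(growth_form)
  stopifnot(size_cm > 0, resolution >= 1L,
            sample_patch_fraction >= 0, sample_patch_fraction <= 0.5,
            tissue_thickness_cm >= 0)
  structure(list(growth_form = growth_form, size_cm = size_cm,
                 resolution = as.integer(resolution), seed = as.integer(seed),
                 sample_patch_fraction = sample_patch_fraction,
                 tissue_thickness_cm = tissue_thickness_cm),
            class = "synthetic_colony_spec")
}

# ---- primitive builders -----------------------------------------------
# Each returns list(v = vertices, f = faces, label = per-face class).

# Closed hemisphere: spherical cap plus base disc sharing the equator ring.
prim_hemisphere <- function(r, nseg, with_base = TRUE) {
  m <- max(2L, nseg %/% 4L)           # latitude rings
  phi <- 2 * pi * (seq_len(nseg) - 1L) / nseg
  v <- rbind(c(0, 0, r))
  for (i in seq_len(m)) {
    th <- i * (pi / 2) / m
    v <- rbind(v, cbind(r * sin(th) * cos(phi), r * sin(th) * sin(phi),
                        r * cos(th)))
  }
  ring <- function(i) 1L + (i - 1L) * nseg + seq_len(nseg)  # i in 1..m
  f <- NULL
  r1 <- ring(1L)
  nxt <- c(seq_len(nseg)[-1L], 1L)
  f <- rbind(f, cbind(1L, r1, r1[nxt]))
  for (i in seq_len(m - 1L)) {
    up <- ring(i); lo <- ring(i + 1L)
    f <- rbind(f,
               cbind(lo, lo[nxt], up[nxt]),
               cbind(lo, up[nxt], up))
  }
  label <- rep("living", nrow(f))
  if (with_base) {
    eq <- ring(m)
    v <- rbind(v, c(0, 0, 0))
    ci <- nrow(v)
    base <- cbind(ci, eq[nxt], eq)    # wound so the normal faces -z
    f <- rbind(f, base)
    label <- c(label, rep("nonliving_contact", nseg))
  }
  list(v = v, f = f, label = label)
}

# Open spherical-cap shell (no base): polar angle 0..theta_max.
prim_shell <- function(r, nseg, theta_max = pi / 2) {
  m <- max(2L, nseg %/% 4L)
  phi <- 2 * pi * (seq_len(nseg) - 1L) / nseg
  v <- rbind(c(0, 0, r))
  for (i in seq_len(m)) {
    th <- i * theta_max / m
    v <- rbind(v, cbind(r * sin(th) * cos(phi), r * sin(th) * sin(phi),
                        r * cos(th)))
  }
  ring <- function(i) 1L + (i - 1L) * nseg + seq_len(nseg)
  nxt <- c(seq_len(nseg)[-1L], 1L)
  f <- cbind(1L, ring(1L), ring(1L)[nxt])
  for (i in seq_len(m - 1L)) {
    up <- ring(i); lo <- ring(i + 1L)
    f <- rbind(f, cbind(lo, lo[nxt], up[nxt]), cbind(lo, up[nxt], up))
  }
  list(v = v, f = f, label = rep("living", nrow(f)))
}

# Closed frustum: bottom radius r1 at z = 0, top radius r2 at z = h,
# both caps filled. base_label labels the bottom cap.
prim_frustum <- function(r1, r2, h, nseg, base_label = "living") {
  phi <- 2 * pi * (seq_len(nseg) - 1L) / nseg
  bot <- cbind(r1 * cos(phi), r1 * sin(phi), 0)
  top <- cbind(r2 * cos(phi), r2 * sin(phi), h)
  v <- rbind(bot, top, c(0, 0, 0), c(0, 0, h))
  bi <- seq_len(nseg)
  ti <- nseg + seq_len(nseg)
  cb <- 2L * nseg + 1L
  ct <- 2L * nseg + 2L
  nxt <- c(seq_len(nseg)[-1L], 1L)
  f <- rbind(
    cbind(bi, bi[nxt], ti[nxt]),       # side quads
    cbind(bi, ti[nxt], ti),
    cbind(cb, bi[nxt], bi),            # bottom cap, normal -z
    cbind(ct, ti, ti[nxt]))            # top cap, normal +z
  label <- c(rep("living", 2L * nseg),
             rep(base_label, nseg),
             rep("living", nseg))
  list(v = v, f = f, label = label)
}

# Closed axis-aligned box with each face a g x g quad grid.
prim_box <- function(wx, wy, wz, g, base_label = "living") {
  s <- seq(0, 1, length.out = g + 1L)
  vlist <- NULL
  flist <- NULL
  label <- character(0)
  add_face <- function(origin, du, dv, lab) {
    pts <- matrix(0, (g + 1L)^2, 3L)
    k <- 1L
    for (j in 0:g) for (i in 0:g) {
      pts[k, ] <- origin + s[i + 1L] * du + s[j + 1L] * dv
      k <- k + 1L
    }
    off <- if (is.null(vlist)) 0L else nrow(vlist)
    idx <- function(i, j) off + j * (g + 1L) + i + 1L
    fc <- NULL
    for (j in 0:(g - 1L)) for (i in 0:(g - 1L)) {
      a <- idx(i, j); b <- idx(i + 1L, j)
      c2 <- idx(i + 1L, j + 1L); d <- idx(i, j + 1L)
      fc <- rbind(fc, c(a, b, c2), c(a, c2, d))
    }
    vlist <<- rbind(vlist, pts)
    flist <<- rbind(flist, fc)
    label <<- c(label, rep(lab, nrow(fc)))
  }
  ex <- c(wx, 0, 0); ey <- c(0, wy, 0); ez <- c(0, 0, wz)
  add_face(c(0, 0, 0), ey, ex, base_label)   # bottom (z = 0), normal -z
  add_face(ez, ex, ey, "living")             # top
  add_face(c(0, 0, 0), ex, ez, "living")     # y = 0 side
  add_face(ey, ez, ex, "living")             # y = wy side
  add_face(c(0, 0, 0), ez, ey, "living")     # x = 0 side
  add_face(ex, ey, ez, "living")             # x = wx side
  list(v = vlist, f = flist, label = label)
}

# Open seafloor plane: square sheet of 2 g^2 triangles centred on origin.
prim_plane <- function(half, g, z = 0) {
  s <- seq(-half, half, length.out = g + 1L)
  pts <- as.matrix(expand.grid(x = s, y = s))
  v <- cbind(pts, z)
  idx <- function(i, j) j * (g + 1L) + i + 1L
  f <- NULL
  for (j in 0:(g - 1L)) for (i in 0:(g - 1L)) {
    a <- idx(i, j); b <- idx(i + 1L, j)
    c2 <- idx(i + 1L, j + 1L); d <- idx(i, j + 1L)
    f <- rbind(f, c(a, b, c2), c(a, c2, d))
  }
  list(v = v, f = f, label = rep("background", nrow(f)))
}

# Weld coincident vertices (primitive assemblies build faces with their own
# vertex grids; shared edges must reference shared vertices to be manifold).
prim_weld <- function(p, digits = 9L) {
  key <- paste(round(p$v[, 1L], digits), round(p$v[, 2L], digits),
               round(p$v[, 3L], digits))
  uk <- unique(key)
  remap <- match(key, uk)
  p$v <- p$v[match(uk, key), , drop = FALSE]
  p$f <- matrix(remap[p$f], ncol = 3L)
  p
}

rot_z <- function(a) rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0),
                           c(0, 0, 1))
rot_y <- function(a) rbind(c(cos(a), 0, sin(a)), c(0, 1, 0),
                           c(-sin(a), 0, cos(a)))

prim_transform <- function(p, rot = diag(3), shift = c(0, 0, 0)) {
  p$v <- sweep(p$v %*% t(rot), 2L, shift, "+")
  p
}

prim_merge <- function(...) {
  parts <- list(...)
  v <- NULL; f <- NULL; label <- character(0)
  for (p in parts) {
    off <- if (is.null(v)) 0L else nrow(v)
    v <- rbind(v, p$v)
    f <- rbind(f, p$f + off)
    label <- c(label, p$label)
  }
  list(v = v, f = f, label = label)
}

# Closed-form frustum surface area (lateral + both caps) and volume.
frustum_sa <- function(r1, r2, h) {
  pi * (r1 + r2) * sqrt((r1 - r2)^2 + h^2) + pi * r1^2 + pi * r2^2
}
frustum_v <- function(r1, r2, h) pi * h / 3 * (r1^2 + r1 * r2 + r2^2)

#' Generate a synthetic colony scene
#'
#' Builds the colony of the requested growth form above a background
#' seafloor plane, with the basal contact labelled `nonliving_contact`, the
#' coral surface `living` and the seafloor `background`. The returned
#' ground truth carries the analytic (closed-form) surface area and volume
#' of the colony — discretization makes the mesh approach these from below
#' as `resolution` grows. The foliose form is an open shell whose enclosed
#' volume is genuinely not computable (`true_v` is `NA`), mirroring colony
#' morphologies whose photogrammetric models never close.
#'
#' @param spec a [synthetic_colony_spec()].
#' @return A list with elements `mesh` (the scene, units cm), `mask`
#'   ([face_labels()] over the scene faces) and `truth` (list with
#'   `true_sa`, `true_v`, `removed_patch_sa`, `removed_fragment_v`).
#' @export
make_colony <- function(spec) {
  stopifnot(inherits(spec, "synthetic_colony_spec"))
  nseg <- 8L * 2L^spec$resolution
  if (nseg < 16L) stop("resolution too low to realise the growth form",
                       call. = FALSE)
  r <- spec$size_cm
  set.seed(spec$seed)
  colony <- switch(spec$growth_form,
    massive = {
      part <- prim_hemisphere(r, nseg)
      truth <- list(true_sa = 3 * pi * r^2, true_v = 2 / 3 * pi * r^3)
      list(part = part, truth = truth)
    },
    branched = {
      rt <- 0.18 * r                  # trunk radius (bottom)
      rtt <- 0.12 * r                 # trunk radius (top)
      ht <- r
      trunk <- prim_frustum(rt, rtt, ht, nseg,
                            base_label = "nonliving_contact")
      sa <- frustum_sa(rt, rtt, ht)
      vv <- frustum_v(rt, rtt, ht)
      nb <- 5L
      parts <- list(trunk)
      for (j in seq_len(nb)) {
        rb1 <- 0.12 * r
        rb2 <- 0.05 * r
        lb <- 0.8 * r
        az <- 2 * pi * (j - 1L) / nb + stats::runif(1L, -0.15, 0.15)
        tilt <- stats::runif(1L, 0.35, 0.6)        # radians from vertical
        zb <- (0.25 + 0.1 * (j %% 3L)) * ht
        br <- prim_frustum(rb1, rb2, lb, max(16L, nseg %/% 2L))
        br <- prim_transform(br, rot_z(az) %*% rot_y(tilt),
                             c(0.55 * r * cos(az), 0.55 * r * sin(az), zb))
        parts <- c(parts, list(br))
        sa <- sa + frustum_sa(rb1, rb2, lb)
        vv <- vv + frustum_v(rb1, rb2, lb)
      }
      list(part = do.call(prim_merge, parts),
           truth = list(true_sa = sa, true_v = vv))
    },
    tabular = {
      g <- 2L^spec$resolution
      ws <- 0.25 * r; hs <- 0.5 * r                 # stalk
      wp <- 1.6 * r; tp <- 0.1 * r                  # plate
      stalk <- prim_box(ws, ws, hs, g, base_label = "nonliving_contact")
      stalk <- prim_transform(stalk, shift = c(-ws / 2, -ws / 2, 0))
      plate <- prim_box(wp, wp, tp, g)
      plate <- prim_transform(plate, shift = c(-wp / 2, -wp / 2, hs + 0.05 * r))
      sa <- 2 * (ws * ws + 2 * ws * hs) + 2 * (wp * wp + 2 * wp * tp)
      vv <- ws * ws * hs + wp * wp * tp
      list(part = prim_merge(stalk, plate),
           truth = list(true_sa = sa, true_v = vv))
    },
    foliose = {
      part <- prim_shell(r, nseg, theta_max = pi / 2)
      list(part = part,
           truth = list(true_sa = 2 * pi * r^2, true_v = NA_real_))
    })
  floor_half <- 2.2 * r
  seafloor <- prim_plane(floor_half, 4L, z = -0.05 * r)
  scene <- prim_merge(prim_weld(colony$part), seafloor)
  mesh <- coral_mesh(scene$v, scene$f, units = "cm")
  truth <- c(colony$truth,
             list(removed_patch_sa = 0, removed_fragment_v = 0))
  list(mesh = mesh, mask = face_labels(scene$label), truth = truth)
}

# Face adjacency (faces sharing an undirected edge) as an index list.
face_adjacency <- function(mesh) {
  ed <- mesh_edges(mesh)
  o <- order(ed$key)
  key <- ed$key[o]; face <- ed$face[o]
  same <- which(key[-1L] == key[-length(key)])
  adj <- vector("list", n_faces(mesh))
  for (k in same) {
    fa <- face[k]; fb <- face[k + 1L]
    adj[[fa]] <- c(adj[[fa]], fb)
    adj[[fb]] <- c(adj[[fb]], fa)
  }
  adj
}

#' Detach a connected living patch from a colony scene
#'
#' Emulates the hammer-and-chisel sampling of a living patch: a connected
#' set of living faces of the requested area fraction is grown breadth-first
#' from the topmost living face, detached into its own sample mesh, and the
#' resulting break surfaces on both meshes are closed with flat patches
#' labelled `nonliving_contact`. Ground truth records the detached patch
#' area and the enclosed volume of the closed sample fragment.
#'
#' @param mesh scene mesh from [make_colony()].
#' @param mask its [face_labels()] mask.
#' @param spec the [synthetic_colony_spec()]; `sample_patch_fraction` must
#'   be positive.
#' @return A list with `sampled` (scene with the patch removed and the
#'   break filled), `sampled_mask`, `sample` (the closed detached fragment),
#'   `sample_mask`, and `truth` (`removed_patch_sa`, `removed_fragment_v`).
#' @export
apply_sampling <- function(mesh, mask, spec) {
  stopifnot(inherits(spec, "synthetic_colony_spec"))
  if (spec$sample_patch_fraction <= 0)
    stop("sample_patch_fraction must be positive to sample", call. = FALSE)
  check_labels(mask, mesh)
  areas <- face_areas(mesh)
  living <- which(mask$labels == "living")
  if (!length(living)) stop("no living faces to sample", call. = FALSE)
  target <- spec$sample_patch_fraction * sum(areas[living])
  # seed face: topmost living face centroid (deterministic)
  cz <- (mesh$vertices[mesh$faces[living, 1L], 3L] +
         mesh$vertices[mesh$faces[living, 2L], 3L] +
         mesh$vertices[mesh$faces[living, 3L], 3L]) / 3
  seed_face <- living[order(-cz, living)[1L]]
  adj <- face_adjacency(mesh)
  is_living <- mask$labels == "living"
  in_patch <- logical(n_faces(mesh))
  queue <- seed_face
  in_patch[seed_face] <- TRUE
  acc <- areas[seed_face]
  while (acc < target) {
    if (!length(queue))
      stop("connected living patch cannot reach the requested fraction",
           call. = FALSE)
    fcur <- queue[[1L]]; queue <- queue[-1L]
    for (nb in adj[[fcur]]) {
      if (!in_patch[nb] && is_living[nb]) {
        in_patch[nb] <- TRUE
        queue <- c(queue, nb)
        acc <- acc + areas[nb]
        if (acc >= target) break
      }
    }
  }
  patch <- which(in_patch)
  patch_sa <- sum(areas[patch])

  # sample fragment: segment the patch out, close its rim
  patch_mask <- face_labels(ifelse(in_patch, "living", "background"))
  seg <- segment_mesh(mesh, patch_mask, "living")
  sample_fill <- fill_holes_flat(seg$mesh)
  sample_mesh <- sample_fill$mesh
  sample_labels <- c(rep("living", n_faces(seg$mesh)),
                     rep("nonliving_contact",
                         length(sample_fill$added_faces)))
  fragment_v <- enclosed_volume(sample_mesh)

  # sampled scene: drop the patch faces, fill only the loops the removal
  # created (the seafloor sheet keeps its open rim)
  keep <- !in_patch
  scene2 <- coral_mesh(mesh$vertices, mesh$faces[keep, , drop = FALSE],
                       texcoords = mesh$texcoords, units = mesh$units)
  labels2 <- mask$labels[keep]
  canon <- function(loop) {
    i <- which.min(loop)
    paste(c(loop[i:length(loop)], loop[seq_len(i - 1L)]), collapse = ",")
  }
  before <- vapply(boundary_loops(mesh), canon, "")
  after <- boundary_loops(scene2)
  new_loops <- after[!(vapply(after, canon, "") %in% before)]
  scene_fill <- fill_holes_flat(scene2, loops = new_loops)
  sampled_mesh <- scene_fill$mesh
  labels2 <- c(labels2, rep("nonliving_contact",
                            length(scene_fill$added_faces)))
  list(sampled = sampled_mesh, sampled_mask = face_labels(labels2),
       sample = sample_mesh, sample_mask = face_labels(sample_labels),
       truth = list(removed_patch_sa = patch_sa,
                    removed_fragment_v = fragment_v))
}

# Connected components of the face graph; integer component id per face.
face_components <- function(mesh, adj = face_adjacency(mesh)) {
  comp <- integer(n_faces(mesh))
  cid <- 0L
  for (s in seq_len(n_faces(mesh))) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      fcur <- queue[[1L]]; queue <- queue[-1L]
      for (nb in adj[[fcur]]) if (comp[nb] == 0L) {
        comp[nb] <- cid
        queue <- c(queue, nb)
      }
    }
  }
  comp
}

# Outward-oriented copy of a mesh: consistent winding per component, then
# each closed component flipped if its signed volume is negative.
orient_outward <- function(mesh) {
  mesh <- orient_faces(mesh)
  comp <- face_components(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  p1 <- v[f[, 1L], , drop = FALSE]
  p2 <- v[f[, 2L], , drop = FALSE]
  p3 <- v[f[, 3L], , drop = FALSE]
  det6 <- p1[, 1L] * (p2[, 2L] * p3[, 3L] - p2[, 3L] * p3[, 2L]) -
          p1[, 2L] * (p2[, 1L] * p3[, 3L] - p2[, 3L] * p3[, 1L]) +
          p1[, 3L] * (p2[, 1L] * p3[, 2L] - p2[, 2L] * p3[, 1L])
  for (cid in unique(comp)) {
    sel <- comp == cid
    if (sum(det6[sel]) < 0)
      f[sel, c(2L, 3L)] <- f[sel, c(3L, 2L)]
  }
  mesh$faces <- f
  mesh
}

#' Erode the living surface to emulate bleaching
#'
#' Offsets every vertex of the living surface inward along its (living-face,
#' area-weighted) vertex normal by the tissue thickness, emulating the
#' tissue layer lost when a sample is bleached to its skeleton. Vertices not
#' on any living face (bases, break patches) stay put, so contact surfaces
#' are preserved. A thickness of 0 is the identity. Thicknesses beyond a
#' quarter of the smallest bounding-box extent are clamped with a warning,
#' as such offsets would fold the surface through itself.
#'
#' @param mesh a closed sample or colony mesh (units cm).
#' @param mask its [face_labels()] mask.
#' @param thickness tissue thickness in cm (>= 0); defaults taken from
#'   `spec` when given.
#' @param spec optional [synthetic_colony_spec()] supplying
#'   `tissue_thickness_cm`.
#' @return The skeleton mesh (same topology, eroded vertices).
#' @export
apply_bleaching <- function(mesh, mask, thickness = NULL, spec = NULL) {
  check_labels(mask, mesh)
  if (is.null(thickness)) {
    stopifnot(inherits(spec, "synthetic_colony_spec"))
    thickness <- spec$tissue_thickness_cm
  }
  stopifnot(thickness >= 0)
  if (thickness == 0) return(mesh)
  ext <- apply(mesh$vertices, 2L, function(x) diff(range(x)))
  cap <- 0.25 * min(ext[ext > 0])
  if (thickness > cap) {
    warning(sprintf(
      "tissue thickness %.3g clamped to %.3g to avoid self-intersection",
      thickness, cap), call. = FALSE)
    thickness <- cap
  }
  mesh <- orient_outward(mesh)
  living <- which(mask$labels == "living")
  cr <- face_cross(mesh)              # outward, length 2*area
  nrm <- matrix(0, nrow(mesh$vertices), 3L)
  for (j in living) {
    vi <- mesh$faces[j, ]
    nrm[vi, ] <- nrm[vi, ] + matrix(cr[j, ], 3L, 3L, byrow = TRUE)
  }
  len <- sqrt(rowSums(nrm^2))
  move <- len > 0
  unit <- nrm[move, , drop = FALSE] / len[move]
  mesh$vertices[move, ] <- mesh$vertices[move, , drop = FALSE] -
    thickness * unit
  mesh
}

#' Icosphere mesh
#'
#' Subdivided icosahedron projected to a sphere — the standard analytic
#' test body: surface area and volume converge to `4*pi*r^2` and
#' `(4/3)*pi*r^3` from below as the subdivision level grows.
#'
#' @param radius sphere radius.
#' @param subdivisions number of 4-to-1 triangle subdivisions (0 = raw
#'   icosahedron; 5 gives 20480 faces).
#' @param units mesh units flag.
#' @return A watertight [coral_mesh()].
#' @export
make_icosphere <- function(radius = 1, subdivisions = 3L, units = "cm") {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  t, 0), c(1,  t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1,  t), c(0, 1,  t), c(0, -1, -t), c(0, 1, -t),
    c( t, 0, -1), c(t, 0,  1), c(-t, 0, -1), c(-t, 0,  1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(subdivisions)) {
    a <- f[, 1L]; b <- f[, 2L]; c2 <- f[, 3L]
    nv <- nrow(v)
    ea <- cbind(c(a, b, c2), c(b, c2, a))
    key <- (pmin(ea[, 1L], ea[, 2L]) - 1) * nv + pmax(ea[, 1L], ea[, 2L])
    uk <- unique(key)
    first <- match(uk, key)
    mids <- (v[ea[first, 1L], , drop = FALSE] +
             v[ea[first, 2L], , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    mid_idx <- nv + match(key, uk)
    v <- rbind(v, mids)
    m <- nrow(f)
    mab <- mid_idx[seq_len(m)]
    mbc <- mid_idx[m + seq_len(m)]
    mca <- mid_idx[2L * m + seq_len(m)]
    f <- rbind(cbind(a, mab, mca), cbind(b, mbc, mab),
               cbind(c2, mca, mbc), cbind(mab, mbc, mca))
  }
  coral_mesh(v * radius, f, units = units)
}

#' Run the full synthetic measurement study for one colony
#'
#' The desk-scale analogue of a field campaign on one colony: generate the
#' scene, segment the colony, detach a sample patch, close the breaks,
#' erode the tissue layer, and measure every raw quantity of the derived-
#' metric suite with the package's own area/volume primitives. The
#' underwater "unsampled" quantities use the segmented colony: its living
#' area for surface area and its closed-model volume. `tv_water` is left
#' absent — water displacement is a physical measurement with no digital
#' counterpart.
#'
#' @param spec a [synthetic_colony_spec()] with a positive
#'   `sample_patch_fraction`.
#' @return A list with `measurements` (a [colony_measurements()] record),
#'   `truth` (the updated ground truth) and `report`
#'   (the [full_report()] of the measurements).
#' @export
measure_synthetic_colony <- function(spec) {
  gen <- make_colony(spec)
  col_seg <- segment_mesh(gen$mesh, gen$mask,
                          c("living", "nonliving_contact"))
  unsampled_sa <- surface_area(gen$mesh, gen$mask, "living")
  unsampled_v <- if (is.na(gen$truth$true_v)) NA_real_ else
    enclosed_volume(col_seg$mesh)

  samp <- apply_sampling(gen$mesh, gen$mask, spec)
  samp_seg <- segment_mesh(samp$sampled, samp$sampled_mask,
                           c("living", "nonliving_contact"))
  tsa_sampled <- surface_area(samp_seg$mesh)
  esa_sampled <- surface_area(samp$sampled, samp$sampled_mask, "living")
  tv_sampled <- if (is.na(gen$truth$true_v)) NA_real_ else
    enclosed_volume(samp_seg$mesh)

  tissue <- samp$sample
  tissue_mask <- samp$sample_mask
  tsa_tissue <- surface_area(tissue)
  esa_tissue <- surface_area(tissue, tissue_mask, "living")
  tv_tissue <- enclosed_volume(tissue)

  skeleton <- apply_bleaching(tissue, tissue_mask, spec = spec)
  tsa_skeleton <- surface_area(skeleton)
  esa_skeleton <- surface_area(skeleton, tissue_mask, "living")
  tv_skeleton <- enclosed_volume(skeleton)

  m <- colony_measurements(
    name = paste0("synthetic_", spec$growth_form),
    growth_form = if (spec$growth_form %in% growth_forms)
      spec$growth_form else NA_character_,
    unsampled_sa = unsampled_sa, tsa_sampled = tsa_sampled,
    esa_sampled = esa_sampled, tsa_tissue = tsa_tissue,
    esa_tissue = esa_tissue, tsa_skeleton = tsa_skeleton,
    esa_skeleton = esa_skeleton, unsampled_v = unsampled_v,
    tv_sampled = tv_sampled, tv_tissue = tv_tissue,
    tv_skeleton = tv_skeleton, tv_water = NA_real_)
  truth <- utils::modifyList(gen$truth, samp$truth)
  list(measurements = m, truth = truth, report = full_report(m))
}
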