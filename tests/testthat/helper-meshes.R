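# Shared fixtures built in code: canonical meshes, the expected derived
# table for the ten reference colonies, and a brute-force voxel volume
# oracle independent of the divergence-theorem implementation.

# Axis-aligned unit cube with consistent outward winding.
unit_cube <- function(units = "cm") {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  dimnames(v) <- NULL
  f <- rbind(
    c(1, 3, 4), c(1, 4, 2),   # z = 0
    c(5, 6, 8), c(5, 8, 7),   # z = 1
    c(1, 2, 6), c(1, 6, 5),   # y = 0
    c(3, 7, 8), c(3, 8, 4),   # y = 1
    c(1, 5, 7), c(1, 7, 3),   # x = 0
    c(2, 4, 8), c(2, 8, 6))   # x = 1
  coral_mesh(v, f, units = units)
}

# Arbitrary (but fixed) proper rotation for invariance checks.
fixed_rotation <- function() {
  a <- 0.61; b <- -1.13; c2 <- 2.4
  rz <- rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
  ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  rx <- rbind(c(1, 0, 0), c(0, cos(c2), -sin(c2)), c(0, sin(c2), cos(c2)))
  rz %*% ry %*% rx
}

rot_z_angle <- function(a) {
  rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
}

# The segmented colony mesh (living + contact faces) of a synthetic scene.
segmented_colony <- function(spec) {
  gen <- make_colony(spec)
  seg <- segment_mesh(gen$mesh, gen$mask, c("living", "nonliving_contact"))
  list(mesh = seg$mesh, mask = seg$mask, truth = gen$truth)
}

# Path to the packaged ten-colony raw measurement table.
measurements_csv_path <- function() {
  system.file("extdata", "colony_measurements.csv", package = "coralmesh",
              mustWork = TRUE)
}

# Printed derived cells for the ten reference colonies, in CSV row order.
# NA marks cells that are genuinely absent (colonies without closed
# underwater volume models).
expected_derived <- function() {
  data.frame(
    name = c("Platygyra daedalea", "Gardineroseris planulata",
             "Porites lutea", "Porites lobata", "Pocillopora verrucosa",
             "Acropora 1", "Acropora 2", "Acropora hyacynthus",
             "Echinopora lamellosa", "Diploastrea heliopora"),
    thsa = c(30.17, 143.53, -105.50, 151.89, 130.20, 235.05, 254.35,
             1013.43, 104.45, 107.67),
    biosurface = c(-0.46, 57.32, 2.95, 0.05, 61.50, 47.87, 20.90, 75.00,
                   -4.15, 22.14),
    pct_scale_sa = c(12.39, 4.86, 0.91, 0.25, 39.44, 21.92, 4.75, 0.80,
                     6.71, 1.97),
    theoretical_error_sa = c(36.17, 9.16, 218.00, 239.07, 62.25, 43.98,
                             67.48, 171.78, 15.27, 103.48),
    thv = c(47.90, 236.00, 1259.40, 883.60, 507.40, 527.30, 932.90, NA,
            NA, 591.30),
    biomass = c(3.39, 51.21, 2.71, -1.08, -4.66, 32.63, 0.31, 1.46, 1.61,
                5.01),
    pct_scale_v = c(6.59, 2.82, 0.13, 0.02, 4.05, 7.97, 0.51, NA, NA,
                    3.93),
    theoretical_error_v = c(9.40, 35.52, 871.64, 2339.54, 635.03, 110.89,
                            2971.52, NA, NA, 229.47),
    error_tvw = c(49.61, 31.16, 51.08, 33.23, 33.98, 224.49, 58.22,
                  296.46, 6.34, 37.37),
    stringsAsFactors = FALSE)
}

# Tolerance for reproducing a printed derived cell: the looser of 0.02
# absolute (printed 2-dp rounding of intermediates) and 0.1% relative.
expect_matches_printed <- function(actual, printed, label = "") {
  tol <- pmax(0.02, 0.001 * abs(printed))
  expect_true(all(abs(actual - printed) <= tol, na.rm = TRUE),
              label = paste0(label, ": |", paste(round(actual, 4),
                             collapse = ","), " - printed| within tol"))
}

# Independent brute-force volume oracle: column (pencil) integration on an
# xy grid of spacing h. For each grid column the z-crossings with all
# (non-vertical) triangles are collected, sorted and paired; the column
# volume is h^2 times the summed inside intervals. Shares nothing with the
# divergence-theorem path.
voxel_volume <- function(mesh, h) {
  v <- mesh$vertices
  f <- mesh$faces
  xr <- range(v[, 1]); yr <- range(v[, 2])
  # irrational-ish offsets keep grid points off triangle edges
  xs <- seq(xr[1] + h * 0.51234, xr[2], by = h)
  ys <- seq(yr[1] + h * 0.53571, yr[2], by = h)
  nx <- length(xs)
  col_z <- vector("list", nx * length(ys))
  for (t in seq_len(nrow(f))) {
    p1 <- v[f[t, 1], ]; p2 <- v[f[t, 2], ]; p3 <- v[f[t, 3], ]
    d <- (p2[1] - p1[1]) * (p3[2] - p1[2]) -
         (p3[1] - p1[1]) * (p2[2] - p1[2])
    if (abs(d) < 1e-12) next               # vertical / degenerate in xy
    xi <- which(xs >= min(p1[1], p2[1], p3[1]) &
                xs <= max(p1[1], p2[1], p3[1]))
    yi <- which(ys >= min(p1[2], p2[2], p3[2]) &
                ys <= max(p1[2], p2[2], p3[2]))
    if (!length(xi) || !length(yi)) next
    for (j in yi) {
      py <- ys[j]
      for (i in xi) {
        px <- xs[i]
        l1 <- ((p2[1] - px) * (p3[2] - py) -
               (p3[1] - px) * (p2[2] - py)) / d
        l2 <- ((p3[1] - px) * (p1[2] - py) -
               (p1[1] - px) * (p3[2] - py)) / d
        l3 <- 1 - l1 - l2
        if (l1 >= 0 && l2 >= 0 && l3 >= 0) {
          z <- l1 * p1[3] + l2 * p2[3] + l3 * p3[3]
          k <- (j - 1L) * nx + i
          col_z[[k]] <- c(col_z[[k]], z)
        }
      }
    }
  }
  total <- 0
  for (zl in col_z) {
    if (length(zl) < 2L) next
    zl <- sort(zl)
    npair <- length(zl) %/% 2L
    total <- total + sum(zl[2 * seq_len(npair)] -
                         zl[2 * seq_len(npair) - 1L])
  }
  total * h^2
}
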