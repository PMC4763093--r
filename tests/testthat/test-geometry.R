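# Surface area, enclosed volume and their invariances.

test_that("cube surface area and volume are exact", {
  cube <- unit_cube()
  expect_identical(surface_area(cube), 6)
  expect_identical(enclosed_volume(cube), 1)
})

test_that("label-restricted area excludes non-living faces", {
  cube <- unit_cube()
  labels <- rep("living", 12)
  labels[1:2] <- "nonliving_contact"        # one full side
  mask <- face_labels(labels)
  expect_equal(surface_area(cube, mask, "living"), 5)
  expect_equal(surface_area(cube, mask,
                            c("living", "nonliving_contact")), 6)
})

test_that("icosphere area and volume converge monotonically to the sphere", {
  r <- 2
  sa_err <- v_err <- numeric(4)
  for (k in 2:5) {
    s <- make_icosphere(r, k)
    sa_err[k - 1] <- abs(surface_area(s) - 4 * pi * r^2)
    v_err[k - 1] <- abs(enclosed_volume(s) - 4 / 3 * pi * r^3)
  }
  expect_true(all(diff(sa_err) < 0))
  expect_true(all(diff(v_err) < 0))
  expect_lt(sa_err[4] / (4 * pi * r^2), 0.001)
  expect_lt(v_err[4] / (4 / 3 * pi * r^3), 0.002)
})

test_that("area obeys the s^2 law and volume the s^3 law", {
  spec <- synthetic_colony_spec("massive", size_cm = 1, resolution = 2)
  col <- segmented_colony(spec)
  sa0 <- surface_area(col$mesh)
  v0 <- enclosed_volume(col$mesh)
  for (s in c(0.1, 2.5, 23)) {
    scaled <- scale_mesh(col$mesh, s)
    expect_equal(surface_area(scaled), s^2 * sa0, tolerance = 1e-9)
    expect_equal(enclosed_volume(scaled), s^3 * v0, tolerance = 1e-9)
  }
})

test_that("volume is invariant under translation and rotation", {
  cube <- unit_cube()
  moved <- transform_mesh(cube, diag(3), c(1000, -500, 3))
  expect_equal(enclosed_volume(moved), 1, tolerance = 1e-9)
  rotated <- transform_mesh(cube, fixed_rotation(), c(-3.2, 0.7, 11))
  expect_equal(enclosed_volume(rotated), 1, tolerance = 1e-9)
  sph <- make_icosphere(1.3, 3)
  vref <- enclosed_volume(sph)
  sph2 <- transform_mesh(sph, fixed_rotation(), c(250, 0, -41.5))
  expect_equal(enclosed_volume(sph2), vref, tolerance = 1e-9)
})

test_that("volume is recovered despite scrambled face winding", {
  cube <- unit_cube()
  set.seed(42)
  flip <- sample(c(TRUE, FALSE), 12, replace = TRUE)
  f <- cube$faces
  f[flip, c(2, 3)] <- f[flip, c(3, 2)]
  scrambled <- coral_mesh(cube$vertices, f, units = "cm")
  expect_equal(enclosed_volume(scrambled), 1, tolerance = 1e-12)
})

test_that("open meshes refuse volume with a distinct condition", {
  cube <- unit_cube()
  open_cube <- coral_mesh(cube$vertices, cube$faces[-(1:2), ], units = "cm")
  expect_error(enclosed_volume(open_cube), class = "coralmesh_open_mesh")
  expect_false(is_watertight(open_cube))
  expect_true(is_watertight(cube))
})

test_that("degenerate faces contribute zero area and are tallied", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(2, 0, 0))
  f <- rbind(c(1L, 2L, 3L), c(1L, 2L, 4L))   # second face is collinear
  m <- coral_mesh(v, f)
  expect_warning(a <- surface_area(m), "degenerate")
  expect_equal(a, 0.5)
})

test_that("effective area never exceeds total area", {
  spec <- synthetic_colony_spec("branched", size_cm = 4, resolution = 2,
                                seed = 5)
  gen <- make_colony(spec)
  tsa <- surface_area(gen$mesh, gen$mask, c("living", "nonliving_contact"))
  esa <- surface_area(gen$mesh, gen$mask, "living")
  expect_lte(esa, tsa)
  all_mask <- face_labels(rep("living", n_faces(gen$mesh)))
  expect_equal(surface_area(gen$mesh, all_mask, "living"),
               surface_area(gen$mesh))
})

test_that("segmentation compacts indices and preserves area", {
  spec <- synthetic_colony_spec("massive", size_cm = 3, resolution = 2)
  gen <- make_colony(spec)
  seg <- segment_mesh(gen$mesh, gen$mask, "living")
  expect_equal(surface_area(seg$mesh),
               surface_area(gen$mesh, gen$mask, "living"))
  expect_equal(max(seg$mesh$faces), n_vertices(seg$mesh))
  # identity segmentation keeps every face
  all_seg <- segment_mesh(gen$mesh, gen$mask, label_classes())
  expect_equal(n_faces(all_seg$mesh), n_faces(gen$mesh))
  expect_equal(surface_area(all_seg$mesh), surface_area(gen$mesh))
  expect_error(segment_mesh(seg$mesh, seg$mask, "background"),
               "empty selection")
})
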