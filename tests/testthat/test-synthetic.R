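# Synthetic colony generators: analytic ground truth, determinism,
# sampling and bleaching perturbations.

test_that("generator rejects invalid specifications", {
  expect_error(synthetic_colony_spec("massive", size_cm = 0))
  expect_error(synthetic_colony_spec("massive", sample_patch_fraction = 0.6))
  expect_error(synthetic_colony_spec("massive", resolution = 0))
})

test_that("massive colony matches hemisphere closed forms", {
  spec <- synthetic_colony_spec("massive", size_cm = 5, resolution = 3)
  col <- segmented_colony(spec)
  r <- 5
  expect_equal(surface_area(col$mesh), 3 * pi * r^2, tolerance = 0.005)
  expect_equal(enclosed_volume(col$mesh), 2 / 3 * pi * r^3,
               tolerance = 0.005)
  expect_equal(col$truth$true_sa, 3 * pi * r^2)
  expect_equal(col$truth$true_v, 2 / 3 * pi * r^3)
})

test_that("branched and tabular colonies match their closed-form sums", {
  for (gf in c("branched", "tabular")) {
    spec <- synthetic_colony_spec(gf, size_cm = 5, resolution = 3, seed = 7)
    col <- segmented_colony(spec)
    expect_equal(surface_area(col$mesh), col$truth$true_sa,
                 tolerance = 0.005, label = gf)
    expect_equal(enclosed_volume(col$mesh), col$truth$true_v,
                 tolerance = 0.005, label = gf)
  }
})

test_that("the foliose form is open and refuses a volume", {
  spec <- synthetic_colony_spec("foliose", size_cm = 5, resolution = 2)
  gen <- make_colony(spec)
  expect_true(is.na(gen$truth$true_v))
  col <- segment_mesh(gen$mesh, gen$mask,
                      c("living", "nonliving_contact"))$mesh
  expect_error(enclosed_volume(col), class = "coralmesh_open_mesh")
  expect_gt(length(boundary_loops(col)), 0L)
})

test_that("scenes carry background seafloor and basal contact labels", {
  for (gf in c("massive", "branched", "tabular")) {
    gen <- make_colony(synthetic_colony_spec(gf, resolution = 2, seed = 4))
    tab <- table(gen$mask$labels)
    expect_true(tab[["background"]] > 0, label = gf)
    expect_true(tab[["nonliving_contact"]] > 0, label = gf)
    expect_true(tab[["living"]] > 0, label = gf)
  }
})

test_that("generation is deterministic: same seed, byte-identical OBJ", {
  spec <- synthetic_colony_spec("branched", size_cm = 4, resolution = 2,
                                seed = 11)
  p1 <- withr::local_tempfile(fileext = ".obj")
  p2 <- withr::local_tempfile(fileext = ".obj")
  write_obj(make_colony(spec)$mesh, p1)
  write_obj(make_colony(spec)$mesh, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("divergence-theorem volume agrees with the voxel-column oracle", {
  for (gf in c("massive", "branched", "tabular")) {
    spec <- synthetic_colony_spec(gf, size_cm = 5, resolution = 2, seed = 7)
    col <- segmented_colony(spec)$mesh
    h <- 0.35
    v_div <- enclosed_volume(col)
    v_vox <- voxel_volume(col, h)
    expect_lt(abs(v_div - v_vox), 3 * h * surface_area(col), label = gf)
  }
})

test_that("sampling detaches the requested patch and conserves volume", {
  spec <- synthetic_colony_spec("massive", size_cm = 5, resolution = 3,
                                seed = 2, sample_patch_fraction = 0.05)
  gen <- make_colony(spec)
  living_before <- surface_area(gen$mesh, gen$mask, "living")
  samp <- apply_sampling(gen$mesh, gen$mask, spec)
  # the patch is at least the requested fraction, and close to it
  expect_gte(samp$truth$removed_patch_sa, 0.05 * living_before)
  expect_lt(samp$truth$removed_patch_sa, 0.07 * living_before)
  # living area splits exactly between colony and sample
  living_after <- surface_area(samp$sampled, samp$sampled_mask, "living")
  expect_equal(living_after + samp$truth$removed_patch_sa, living_before,
               tolerance = 1e-9)
  # volumes: colony + fragment = original within 1%
  v0 <- enclosed_volume(segment_mesh(gen$mesh, gen$mask,
                        c("living", "nonliving_contact"))$mesh)
  v1 <- enclosed_volume(segment_mesh(samp$sampled, samp$sampled_mask,
                        c("living", "nonliving_contact"))$mesh)
  v2 <- enclosed_volume(samp$sample)
  expect_equal(v1 + v2, v0, tolerance = 0.01)
  expect_true(is_watertight(samp$sample))
})

test_that("a zero sampling fraction is rejected", {
  spec <- synthetic_colony_spec("massive", sample_patch_fraction = 0)
  gen <- make_colony(spec)
  expect_error(apply_sampling(gen$mesh, gen$mask, spec), "positive")
})

test_that("bleaching with zero thickness is the identity", {
  spec <- synthetic_colony_spec("massive", size_cm = 3, resolution = 2,
                                tissue_thickness_cm = 0)
  col <- segmented_colony(spec)
  skel <- apply_bleaching(col$mesh, col$mask, thickness = 0)
  expect_identical(skel$vertices, col$mesh$vertices)
  m <- colony_measurements(tsa_tissue = surface_area(col$mesh),
                           tsa_skeleton = surface_area(skel),
                           tv_tissue = enclosed_volume(col$mesh),
                           tv_skeleton = enclosed_volume(skel))
  expect_equal(biosurface(m), 0)
  expect_equal(biomass(m), 0)
})

test_that("bleaching erodes the analytic tissue shell of a hemisphere", {
  spec <- synthetic_colony_spec("massive", size_cm = 5, resolution = 3,
                                tissue_thickness_cm = 0.1)
  col <- segmented_colony(spec)
  skel <- apply_bleaching(col$mesh, col$mask, thickness = 0.1)
  shell <- enclosed_volume(col$mesh) - enclosed_volume(skel)
  expect_equal(shell, 2 / 3 * pi * (5^3 - 4.9^3), tolerance = 0.05)
})

test_that("biomass grows monotonically with tissue thickness", {
  spec <- synthetic_colony_spec("massive", size_cm = 5, resolution = 2)
  col <- segmented_colony(spec)
  v0 <- enclosed_volume(col$mesh)
  shells <- vapply(c(0.05, 0.1, 0.2, 0.4), function(t)
    v0 - enclosed_volume(apply_bleaching(col$mesh, col$mask,
                                         thickness = t)), 0)
  expect_true(all(diff(shells) > 0))
  expect_true(all(shells > 0))
})

test_that("excessive thickness is clamped with a warning", {
  spec <- synthetic_colony_spec("massive", size_cm = 2, resolution = 2)
  col <- segmented_colony(spec)
  expect_warning(apply_bleaching(col$mesh, col$mask, thickness = 5),
                 "clamped")
})

test_that("the full synthetic study recovers its own ground truth", {
  spec <- synthetic_colony_spec("massive", size_cm = 5, resolution = 3,
                                seed = 2, sample_patch_fraction = 0.05,
                                tissue_thickness_cm = 0.1)
  res <- measure_synthetic_colony(spec)
  # theoretic SA = removed patch area; theoretic V = fragment volume
  expect_equal(res$report$thsa, res$truth$removed_patch_sa,
               tolerance = 0.02)
  expect_equal(res$report$thv, res$truth$removed_fragment_v,
               tolerance = 0.02)
  # water-displacement volume has no digital counterpart
  expect_true(is.na(res$report$error_tvw))
})
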