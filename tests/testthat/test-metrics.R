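# The derived-metric suite: signed differences, scale percentages, error
# statistics and absent-value propagation.

test_that("theoretic surface area is the signed unsampled-sampled difference", {
  m <- colony_measurements(unsampled_sa = 2703.69, esa_sampled = 2560.16)
  expect_equal(theoretic_sa(m), 143.53)
  m2 <- colony_measurements(unsampled_sa = 9821.73, esa_sampled = 9927.23)
  expect_equal(theoretic_sa(m2), -105.50)   # sampled model came out larger
  expect_equal(theoretic_sa(colony_measurements(unsampled_sa = 5,
                                                esa_sampled = 5)), 0)
  expect_true(is.na(theoretic_sa(colony_measurements(unsampled_sa = 5))))
})

test_that("theoretic volume mirrors the surface-area logic", {
  expect_equal(theoretic_v(colony_measurements(unsampled_v = 664.18,
                                               tv_sampled = 616.28)), 47.90)
  expect_equal(theoretic_v(colony_measurements(unsampled_v = 12978.50,
                                               tv_sampled = 12742.50)), 236.00)
  expect_true(is.na(theoretic_v(colony_measurements(tv_sampled = 616.28))))
})

test_that("biosurface and biomass are signed tissue-skeleton differences", {
  expect_equal(biosurface(colony_measurements(tsa_tissue = 347.13,
                                              tsa_skeleton = 285.63)), 61.50)
  expect_equal(biosurface(colony_measurements(tsa_tissue = 191.17,
                                              tsa_skeleton = 195.32)), -4.15)
  expect_equal(biomass(colony_measurements(tv_tissue = 250.04,
                                           tv_skeleton = 217.41)), 32.63)
  expect_true(is.na(biomass(colony_measurements(tv_tissue = 250.04))))
})

test_that("scale percentages use the unsampled denominators", {
  expect_equal(round(pct_scale_sa(colony_measurements(
    esa_tissue = 344.93, unsampled_sa = 874.50)), 2), 39.44)
  expect_equal(round(pct_scale_v(colony_measurements(
    tv_tissue = 365.99, unsampled_v = 12978.50)), 2), 2.82)
  expect_equal(pct_scale_sa(colony_measurements(esa_tissue = 7,
                                                unsampled_sa = 7)), 100)
  expect_true(is.na(pct_scale_v(colony_measurements(tv_tissue = 10))))
})

test_that("theoretical errors are relative to the dry tissue measurement", {
  m <- colony_measurements(unsampled_sa = 2703.69, esa_sampled = 2560.16,
                           esa_tissue = 131.49)
  expect_equal(round(theoretical_error_sa(m), 2), 9.16)
  m2 <- colony_measurements(unsampled_v = 4571.90, tv_sampled = 3980.60,
                            tv_tissue = 179.47)
  expect_equal(round(theoretical_error_v(m2), 2), 229.47)
  # signed theoretic estimate enters the absolute difference
  m3 <- colony_measurements(unsampled_sa = 9821.73, esa_sampled = 9927.23,
                            esa_tissue = 89.41)
  expect_equal(round(theoretical_error_sa(m3), 2), 218.00)
  m4 <- colony_measurements(unsampled_sa = 10, esa_sampled = 5,
                            esa_tissue = 5)
  expect_equal(theoretical_error_sa(m4), 0)
})

test_that("skeleton-vs-water error uses the water volume as denominator", {
  expect_equal(round(error_tvw(colony_measurements(
    tv_skeleton = 314.78, tv_water = 240)), 2), 31.16)
  expect_equal(round(error_tvw(colony_measurements(
    tv_skeleton = 217.41, tv_water = 67)), 2), 224.49)
  expect_equal(error_tvw(colony_measurements(tv_skeleton = 55,
                                             tv_water = 55)), 0)
  expect_true(is.na(error_tvw(colony_measurements(tv_skeleton = 55))))
})

test_that("error statistics are non-negative and zero only at agreement", {
  set.seed(3)
  for (i in 1:20) {
    m <- colony_measurements(unsampled_sa = runif(1, 10, 1000),
                             esa_sampled = runif(1, 10, 1000),
                             esa_tissue = runif(1, 10, 1000),
                             tv_skeleton = runif(1, 10, 1000),
                             tv_water = runif(1, 10, 1000))
    expect_gte(theoretical_error_sa(m), 0)
    expect_gte(error_tvw(m), 0)
    expect_identical(theoretical_error_sa(m) == 0,
                     theoretic_sa(m) == m$esa_tissue)
  }
})

test_that("absent operands propagate as absent, never as zero", {
  m <- colony_measurements(name = "empty")
  rep_ <- full_report(m)
  for (col in c("thsa", "thv", "biosurface", "biomass", "pct_scale_sa",
                "pct_scale_v", "theoretical_error_sa",
                "theoretical_error_v", "error_tvw"))
    expect_true(is.na(rep_[[col]]), label = col)
})

test_that("raw measurements must be non-negative", {
  expect_error(colony_measurements(tsa_tissue = -1), "non-negative")
})

test_that("full_report is pure: identical input, identical serialized output", {
  ms <- read_measurements(measurements_csv_path())
  r1 <- report_table(ms)
  r2 <- report_table(read_measurements(measurements_csv_path()))
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_report(r1, p1)
  write_report(r2, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("the ten-colony table reproduces every printed derived cell", {
  ms <- read_measurements(measurements_csv_path())
  got <- report_table(ms)
  exp <- expected_derived()
  expect_identical(got$name, exp$name)
  for (col in setdiff(names(exp), "name")) {
    expect_identical(is.na(got[[col]]), is.na(exp[[col]]), label = col)
    expect_matches_printed(got[[col]][!is.na(exp[[col]])],
                           exp[[col]][!is.na(exp[[col]])], label = col)
  }
})
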