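test_that("phantom generation is a pure function of its spec", {
  a <- generate_phantom(phantom_spec(seed = 7L))
  b <- generate_phantom(phantom_spec(seed = 7L))
  expect_identical(a$raw$grid, b$raw$grid)
  expect_identical(a$truth_labels$grid, b$truth_labels$grid)
  expect_false(identical(
    a$raw$grid, generate_phantom(phantom_spec(seed = 8L))$raw$grid))
})

test_that("phantom spec validation rejects bad mixtures, shapes and severities", {
  expect_error(phantom_spec(lung_aeration_profile = c(0.5, 0.5, 0.1, 0)),
               "summing to 1")
  expect_error(phantom_spec(lung_aeration_profile = c(-0.1, 1.0, 0.05, 0.05)),
               "non-negative")
  expect_error(phantom_spec(shape = c(16, 64, 64)), ">= 32")
  expect_error(phantom_spec(fibrosis_severity = 1.5), "0, 1")
  expect_error(phantom_spec(noise_sd = -1), "non-negative")
})

test_that("noiseless phantoms hit the airway and heart grey-level anchors exactly", {
  s <- small_phantom(seed = 3L, noise_sd = 0)
  lab <- s$truth_labels$grid
  expect_equal(mean(s$raw$grid[lab == 4L]), 801.8)
  expect_equal(mean(s$raw$grid[lab == 3L]), 2250.19)
})

test_that("noisy airway and heart means stay within the sampling error of the anchors", {
  s <- small_phantom(seed = 11L, noise_sd = 20)
  lab <- s$truth_labels$grid
  for (spec_mean_code in list(c(801.8, 4), c(2250.19, 3))) {
    m <- lab == spec_mean_code[2]
    se <- 20 / sqrt(sum(m))
    expect_lt(abs(mean(s$raw$grid[m]) - spec_mean_code[1]), 4 * se)
  }
})

test_that("phantom anatomy is well formed: connected disjoint lungs, mediastinal gap, cranial airway", {
  s <- small_phantom(seed = 5L)
  lab <- s$truth_labels$grid
  left <- lab == 1L; right <- lab == 2L
  expect_false(any(left & right))
  expect_equal(max(connected_components(left)), 1L)
  expect_equal(max(connected_components(right)), 1L)
  # at least one voxel of mediastinal gap between each lung and the heart
  near_heart <- muridens:::.dilate_box(lab == 3L, 1L)
  expect_equal(sum(near_heart & (left | right)), 0L)
  # airway tree reaches the cranial face
  expect_true(any(lab[1, , ] == 4L))
})

test_that("noise-free compartment fractions recover the mixture to within a percentage point", {
  w <- c(hyper = 0.20, normo = 0.70, hypo = 0.08, non = 0.02)
  s <- generate_phantom(phantom_spec(seed = 21L, noise_sd = 0,
                                     lung_aeration_profile = w))
  rep_ <- truth_densitometry(s)
  got <- vapply(rep_$structures$total$compartments, `[[`, 0, "percent")
  expect_lt(max(abs(got - 100 * w)), 1)
})

test_that("fibrosis severity monotonically shifts weight toward the dense compartments", {
  s0 <- small_phantom(seed = 9L, severity = 0)
  s1 <- generate_phantom(phantom_spec(seed = 9L, fibrosis_severity = 1))
  frac_non <- function(s) {
    r <- truth_densitometry(s)
    r$structures$total$compartments$non$percent
  }
  expect_gt(frac_non(s1), frac_non(s0))
  mid <- generate_phantom(phantom_spec(seed = 9L, fibrosis_severity = 0.5))
  expect_gt(frac_non(s1), frac_non(mid))
  expect_gt(frac_non(mid), frac_non(s0))
})

test_that("end-inspiration variants have more, darker lung and untouched heart/airways", {
  s <- small_phantom(seed = 13L)
  p01 <- phase_variant(s, "P01")
  lab0 <- s$truth_labels$grid; lab1 <- p01$truth_labels$grid
  expect_gt(sum(lab1 %in% 1:2), sum(lab0 %in% 1:2))
  expect_lt(mean(p01$raw$grid[lab1 %in% 1:2]), mean(s$raw$grid[lab0 %in% 1:2]))
  expect_equal(p01$raw$grid[lab0 == 3L], s$raw$grid[lab0 == 3L])
  expect_equal(p01$raw$grid[lab0 == 4L], s$raw$grid[lab0 == 4L])
  expect_identical(p01$spec$phase, "P01")
  expect_error(phase_variant(p01, "P01"), "already")
})

test_that("cohorts are deterministic, correctly sized, and share anatomy within a mouse", {
  co <- generate_cohort(4, c(0, 0.6), base_seed = 31L, timepoints = 3L)
  expect_length(co, 12)
  expect_length(unique(vapply(co, function(s) s$meta$mouse_id, "")), 4)
  co2 <- generate_cohort(4, c(0, 0.6), base_seed = 31L, timepoints = 3L)
  expect_identical(co[[5]]$raw$grid, co2[[5]]$raw$grid)
  # same mouse, different timepoints: same anatomy seed, increasing severity
  m1 <- Filter(function(s) s$meta$mouse_id == "M001", co)
  expect_equal(length(unique(vapply(m1, function(s) s$spec$seed, 0L))), 1L)
  sev <- vapply(m1, function(s) s$meta$severity, 0)
  expect_true(all(diff(sev) > 0))
  expect_error(generate_cohort(0, c(0, 1)), "at least 1")
  expect_error(generate_cohort(2, c(0.5, 0.2)), "interval")
})

test_that("a zero-severity cohort is healthy: dense compartments stay minor", {
  co <- generate_cohort(2, c(0, 0), base_seed = 41L, timepoints = 2L)
  expect_true(all(vapply(co, function(s) s$meta$severity, 0) == 0))
  r <- truth_densitometry(co[[1]])
  cmp <- vapply(r$structures$total$compartments, `[[`, 0, "percent")
  expect_lt(cmp[["non"]], cmp[["normo"]] + cmp[["hypo"]])
  expect_gt(cmp[["normo"]], 50)
})

test_that("ground-truth HU is the exact calibration line applied to the raw grid", {
  s <- small_phantom(seed = 17L)
  tf <- phantom_truth_transfer(s$spec)
  expect_equal(s$truth_hu$grid, s$raw$grid * tf$slope + tf$intercept)
})
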