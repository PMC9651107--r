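test_that("the two-point calibration line matches independently computed parameters", {
  tf <- fit_transfer_function(801.8, 2250.19)
  # frozen oracle: unique line through (801.8, -1000) and (2250.19, +50)
  expect_equal(tf$slope, 0.7249428676, tolerance = 1e-9)
  expect_equal(tf$intercept, -1581.259191, tolerance = 1e-6)

  tf2 <- fit_transfer_function(0, 1)
  expect_equal(tf2$slope, 1050)
  expect_equal(tf2$intercept, -1000)

  err <- tryCatch(fit_transfer_function(1000, 1000), condition = identity)
  expect_s3_class(err, "muridens_calibration_error")
})

test_that("applying the fitted line maps the anchor grey levels to -1000 and +50 HU", {
  tf <- fit_transfer_function(801.8, 2250.19)
  v <- raw_volume(array(c(801.8, 2250.19, 1500), c(3, 1, 1)) * array(1, c(3, 1, 1)))
  hu <- apply_transfer(v, tf)
  expect_equal(hu$grid[1, 1, 1], -1000)
  expect_equal(hu$grid[2, 1, 1], 50)
  ident <- transfer_function(1, 0)
  expect_equal(apply_transfer(v, ident)$grid, v$grid)
  expect_identical(hu$transfer, tf)
})

test_that("region means average the masked voxels and reject absent classes", {
  g <- array(0, c(4, 4, 4)); g[1, 1, 1:2] <- c(0, 100)
  lab <- array(0L, c(4, 4, 4)); lab[1, 1, 1:2] <- 1L
  lm <- label_map(lab, c(background = 0L, left_lung = 1L))
  expect_equal(region_mean(raw_volume(g), lm, 1L), 50)
  expect_error(region_mean(raw_volume(g), lm, 3L), "absent")
  const <- raw_volume(array(801.8, c(4, 4, 4)))
  lm2 <- label_map(array(4L, c(4, 4, 4)),
                   c(background = 0L, airways = 4L))
  expect_equal(region_mean(const, lm2, 4L), 801.8)
})

test_that("the transfer is affine and order preserving", {
  tf <- fit_transfer_function(801.8, 2250.19)
  set.seed(4)
  g <- array(runif(6^3, 0, 4000), c(6, 6, 6))
  hu <- apply_transfer(raw_volume(g), tf)
  # region means commute with the affine map to machine precision
  m <- g > 1000
  expect_equal(mean(hu$grid[m]), tf$slope * mean(g[m]) + tf$intercept)
  expect_true(all(order(g) == order(hu$grid)))
})

test_that("fit-then-apply on exact masks recovers the phantom truth HU to 1e-6", {
  s <- small_phantom(seed = 19L)
  lab <- s$truth_labels
  gl_air <- region_mean(s$raw, lab, 4L)
  gl_heart <- region_mean(s$raw, lab, 3L)
  tf <- fit_transfer_function(gl_air, gl_heart)
  hu <- apply_transfer(s$raw, tf)
  truth_tf <- phantom_truth_transfer(s$spec)
  # with noise the region means drift from the anchors; compare to the line
  # fitted through the realised means
  expect_equal(tf$slope * gl_air + tf$intercept, -1000, tolerance = 1e-9)
  expect_equal(tf$slope * gl_heart + tf$intercept, 50, tolerance = 1e-9)
  s0 <- small_phantom(seed = 19L, noise_sd = 0)
  tf0 <- fit_transfer_function(region_mean(s0$raw, s0$truth_labels, 4L),
                               region_mean(s0$raw, s0$truth_labels, 3L))
  hu0 <- apply_transfer(s0$raw, tf0)
  expect_lt(max(abs(hu0$grid - s0$truth_hu$grid)), 1e-6)
  expect_equal(truth_tf$slope, tf0$slope, tolerance = 1e-12)
})

test_that("conversion evaluation reports definitional percentage errors", {
  tf <- fit_transfer_function(801.8, 2250.19)
  s <- small_phantom(seed = 23L)
  ev <- evaluate_conversion(tf, tf, s$raw, s$truth_labels)
  expect_equal(ev$slope_err_pct, 0)
  expect_equal(ev$intercept_err_pct, 0)
  expect_equal(unname(ev$compartment_err_pp), rep(0, 4))

  tf_biased <- transfer_function(tf$slope * 1.05, tf$intercept)
  ev2 <- evaluate_conversion(tf_biased, tf, s$raw, s$truth_labels)
  expect_equal(ev2$slope_err_pct, 5, tolerance = 1e-9)
})

test_that("calibration from corrupted-oracle coarse masks stays within 10 percent", {
  s <- small_phantom(seed = 29L)
  coarse <- to_coarse_labels(s$truth_labels)
  corrupted <- backend_oracle(coarse, erode = 1L, flip_frac = 0.05, seed = 1L)
  masks <- label_map(corrupted$grid, muridens_classes("coarse"))
  tf_auto <- fit_transfer_function(region_mean(s$raw, masks, 3L),
                                   region_mean(s$raw, masks, 2L))
  tf_manual <- phantom_truth_transfer(s$spec)
  ev <- evaluate_conversion(tf_auto, tf_manual, s$raw, s$truth_labels)
  expect_lt(ev$slope_err_pct, 10)
  expect_lt(ev$intercept_err_pct, 10)
  expect_gt(ev$slope_err_pct, 0)
})
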