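make_probmap <- function(arrs) {
  classes <- muridens_classes("coarse")
  bg <- 1 - Reduce(`+`, arrs)
  probability_map(c(list(background = bg), arrs), classes)
}

test_that("binarize picks the dominant above-threshold class with ties to the lower code", {
  dm <- c(1L, 1L, 3L)
  mk <- function(l, h, a) list(lung = array(l, dm), heart = array(h, dm),
                               airways = array(a, dm))
  p <- make_probmap(mk(c(0.9, 0.1, 0.5), c(0.1, 0.2, 0.5), c(0, 0.1, 0)))
  lab <- binarize(p, c(0.45, 0.45, 0.45))
  expect_equal(as.integer(lab$grid), c(1L, 0L, 1L))  # third voxel: tie -> lung
  expect_error(binarize(p, c(0.45, 0.45)), "one threshold per")
  expect_error(binarize(p, c(0.45, 0.45, 1.2)), "0, 1")
})

test_that("indicator probability maps reproduce the truth for any thresholds", {
  s <- small_phantom(seed = 12L)
  coarse <- to_coarse_labels(s$truth_labels)
  ds <- downsample(coarse, 2L, "label", "yx")
  pm <- muridens:::.predict_stack(backend_oracle(ds),
                                  downsample(s$raw$grid, 2L, dims = "yx"),
                                  "axial")
  for (t in c(0.1, 0.5, 0.9)) {
    lab <- binarize(pm, rep(t, 3))
    expect_identical(lab$grid, ds$grid)
  }
})

test_that("threshold optimization maximizes Dice over the grid with the documented tie rule", {
  s <- small_phantom(seed = 14L)
  coarse <- to_coarse_labels(s$truth_labels)
  ds <- downsample(coarse, 2L, "label", "yx")
  # indicator map: every threshold ties at DSC 1 -> tie rule returns 0.5
  pm <- muridens:::.predict_stack(backend_oracle(ds),
                                  downsample(s$raw$grid, 2L, dims = "yx"),
                                  "axial")
  th <- optimize_thresholds(pm, ds)
  expect_equal(unname(th), rep(0.5, 3))

  # scaled indicator at 0.6: all grid points below 0.6 tie at DSC 1; the
  # maximizer closest to 0.5 wins
  pm2 <- probability_map(lapply(pm$maps, function(m) 0.6 * m), pm$classes)
  th2 <- optimize_thresholds(pm2, ds)
  expect_equal(unname(th2), rep(0.5, 3))

  # brute-force verification of the selection rule for one class
  grid <- seq(0.05, 0.95, by = 0.05)
  dsc <- vapply(grid, function(t)
    dice_masks(ds$grid == 1L, pm2$maps$lung > t), 0)
  best <- grid[dsc >= max(dsc) - 1e-12]
  expect_equal(th2[["lung"]], best[which.min(abs(best - 0.5))])

  expect_error(optimize_thresholds(list(), list()), "non-empty")
  expect_error(optimize_thresholds(pm, ds, grid = c(0, 0.5)), "0, 1")
})

test_that("bounding boxes centre on the lung centroid and clamp to the grid", {
  mask <- array(FALSE, c(128L, 128L, 128L))
  mask[65L, 65L, 65L] <- TRUE               # centroid (64, 64, 64), 0-based
  box <- compute_bounding_box(mask, extent = c(96L, 80L, 96L))
  expect_equal(box$origin, c(16L, 24L, 16L))
  expect_equal(box$extent, c(96L, 80L, 96L))

  mask2 <- array(FALSE, c(128L, 128L, 128L))
  mask2[11L, 11L, 11L] <- TRUE              # near the corner: clamped to 0
  box2 <- compute_bounding_box(mask2, extent = c(96L, 80L, 96L))
  expect_equal(box2$origin, c(0L, 0L, 0L))

  err <- tryCatch(compute_bounding_box(array(FALSE, c(32, 32, 32))),
                  condition = identity)
  expect_s3_class(err, "muridens_localization_error")
})

test_that("the default box contains the whole lung of phantoms that fit the extent", {
  s <- small_phantom(seed = 16L)
  box <- compute_bounding_box(s$truth_labels, fixture_extent,
                              lung_codes = c(1L, 2L))
  lab_crop <- crop(s$truth_labels, box)
  expect_equal(sum(lab_crop$grid %in% 1:2), sum(s$truth_labels$grid %in% 1:2))
})

test_that("cropping preserves values, pads out-of-grid voxels and inverts with uncrop", {
  s <- small_phantom(seed = 18L)
  box <- compute_bounding_box(s$truth_labels, c(48L, 40L, 48L),
                              lung_codes = c(1L, 2L))
  cr <- crop(s$raw, box)
  expect_equal(dim(cr$grid), c(48L, 40L, 48L))
  back <- uncrop(s$raw, cr, box)
  expect_equal(back$grid, s$raw$grid)

  # box hanging off the grid: HU volumes pad with the -1040 air floor
  hu <- apply_transfer(s$raw, phantom_truth_transfer(s$spec))
  big <- structure(list(origin = c(-8L, 0L, 0L), extent = c(16L, 16L, 16L)),
                   class = "bounding_box")
  hc <- crop(hu, big)
  expect_true(all(hc$grid[1:8, , ] == -1040))
  rc <- crop(s$raw, big)
  expect_true(all(rc$grid[1:8, , ] == min(s$raw$grid)))
})

test_that("a trained coarse model localizes held-out lungs with Dice at least 0.85", {
  fx <- trained_fixture()
  dscs <- vapply(seq_along(fx$test), function(i) {
    pm <- predict_coarse(fx$cb, fx$filt_te[[i]], 2L)
    lab <- binarize(pm, fx$cfg$coarse_thresholds)
    truth_c <- downsample(to_coarse_labels(fx$test[[i]]$truth_labels), 2L,
                          "label", "yx")
    dice(truth_c, lab, 1L)
  }, 0)
  expect_gt(mean(dscs), 0.85)
  # and the derived bounding box contains at least 99 percent of the lung
  contained <- vapply(seq_along(fx$test), function(i) {
    run <- fx$runs[[i]]
    truth <- fx$test[[i]]$truth_labels
    inbox <- crop(truth, run$box)
    sum(inbox$grid %in% 1:2) / sum(truth$grid %in% 1:2)
  }, 0)
  expect_true(all(contained >= 0.99))
})
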