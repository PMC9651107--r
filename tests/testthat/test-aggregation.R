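lr_classes <- muridens_classes("lr")

lmap <- function(g) label_map(g, lr_classes)

test_that("majority voting follows the two-of-three rule", {
  dm <- c(1L, 1L, 3L)
  a <- lmap(array(c(1L, 2L, 1L), dm))
  s <- lmap(array(c(1L, 2L, 0L), dm))
  co <- lmap(array(c(0L, 2L, 0L), dm))
  out <- majority_vote(a, s, co)
  expect_equal(as.integer(out$grid), c(1L, 2L, 0L))
  expect_error(majority_vote(a, s, lmap(array(0L, c(1, 1, 2)))), "shape")
})

test_that("three-way disagreement uses mean probabilities, else background", {
  dm <- c(1L, 1L, 1L)
  a <- lmap(array(1L, dm)); s <- lmap(array(2L, dm)); co <- lmap(array(0L, dm))
  expect_equal(as.integer(majority_vote(a, s, co)$grid), 0L)
  mkp <- function(b, l, r) probability_map(
    list(background = array(b, dm), left_lung = array(l, dm),
         right_lung = array(r, dm)), lr_classes)
  probs <- list(axial = mkp(0.2, 0.5, 0.3), sagittal = mkp(0.2, 0.5, 0.3),
                coronal = mkp(0.2, 0.5, 0.3))
  expect_equal(as.integer(majority_vote(a, s, co, probs)$grid), 1L)
})

test_that("voting is idempotent, permutation symmetric and matches the brute-force oracle", {
  set.seed(33)
  for (rep in 1:3) {
    dm <- c(10L, 10L, 10L)
    g <- function() array(sample(0:2, prod(dm), replace = TRUE), dm)
    a <- lmap(g()); s <- lmap(g()); co <- lmap(g())
    m <- majority_vote(a, s, co)
    expect_identical(majority_vote(m, m, m)$grid, m$grid)
    expect_identical(majority_vote(s, co, a)$grid, m$grid)
    expect_identical(majority_vote(co, a, s)$grid, m$grid)
    expect_identical(m$grid, brute_force_vote(a$grid, s$grid, co$grid,
                                              classes = lr_classes))
  }
})

test_that("combining sides unions label maps and thresholds summed probabilities", {
  dm <- c(1L, 1L, 3L)
  l <- lmap(array(c(1L, 0L, 0L), dm))
  r <- lmap(array(c(0L, 1L, 0L), dm))
  expect_equal(as.integer(combine_total(l, r)$grid), c(1L, 1L, 0L))
  pl <- array(c(0.3, 0.1, 0), dm); pr <- array(c(0.3, 0.1, 0), dm)
  expect_equal(as.integer(combine_total(pl, pr, threshold = 0.5)$grid),
               c(1L, 0L, 0L))
  empty <- lmap(array(0L, dm))
  expect_equal(sum(combine_total(empty, empty)$grid), 0L)
})

test_that("cleaning removes exactly the lung voxels with out-of-range HU", {
  dm <- c(2L, 2L, 2L)
  lab <- lmap(array(c(1L, 1L, 2L, 2L, 0L, 0L, 1L, 2L), dm))
  hu <- array(c(500, -500, -1041, 50, 5000, -2000, 121, -1040), dm)
  out <- clean_segmentation(lab, hu_volume(hu))
  expect_equal(as.integer(out$grid), c(0L, 1L, 0L, 2L, 0L, 0L, 1L, 2L))
  # never adds voxels; non-lung labels untouched
  expect_true(all(out$grid[lab$grid == 0L] == 0L))
  expect_true(all(which(out$grid != 0) %in% which(lab$grid != 0)))
})

test_that("compartment bins are half-open with the documented edge ownership", {
  dm <- c(1L, 1L, 7L)
  hu <- array(c(-900, -500, -300, -121, 121, -860, -1040), dm)
  lab <- lmap(array(1L, dm))
  comp <- compartmentalize(lab, hu_volume(hu))
  #            hyper normo hypo  non  non  normo hyper
  expect_equal(as.integer(comp), c(1L, 2L, 3L, 4L, 4L, 2L, 1L))
  bad <- hu_volume(array(c(hu[1:6], 200), dm))
  expect_error(compartmentalize(lab, bad), "clean_segmentation")
  expect_error(compartmentalize(lab, hu_volume(hu),
                                thresholds = c(-1040, -860, -860, -121, 121)),
               "strictly increasing")
})

test_that("densitometry volumes use the voxel volume and sum exactly to the lung volume", {
  dm <- c(1L, 1L, 1L)
  lab <- lmap(array(1L, dm))
  comp <- compartmentalize(lab, hu_volume(array(-500, dm)))
  rep1 <- densitometry_report(comp, lab, voxel_size_um = 50)
  expect_equal(rep1$voxel_volume_mm3, 12.5e-5)
  expect_equal(rep1$structures$left$volume_mm3, 12.5e-5)

  dm2 <- c(20L, 20L, 20L)
  lab2 <- lmap(array(1L, dm2))
  comp2 <- compartmentalize(lab2, hu_volume(array(-500, dm2)))
  rep2 <- densitometry_report(comp2, lab2, 50)
  expect_equal(rep2$structures$left$compartments$normo$percent, 100)
  expect_equal(rep2$structures$left$compartments$hyper$percent, 0)

  s <- small_phantom(seed = 24L, severity = 0.4)
  r <- truth_densitometry(s)
  for (nm in names(r$structures)) {
    st <- r$structures[[nm]]
    vols <- vapply(st$compartments, `[[`, 0, "volume_mm3")
    expect_equal(sum(vols), st$volume_mm3, tolerance = 1e-12)
    if (st$n_voxels > 0)
      expect_equal(sum(vapply(st$compartments, `[[`, 0, "percent")), 100,
                   tolerance = 1e-9)
  }
  expect_equal(r$structures$left$volume_mm3 + r$structures$right$volume_mm3,
               r$structures$total$volume_mm3)
})

test_that("an empty segmentation yields zero volumes with flagged percentages", {
  dm <- c(4L, 4L, 4L)
  lab <- lmap(array(0L, dm))
  comp <- compartmentalize(lab, hu_volume(array(-500, dm)))
  r <- densitometry_report(comp, lab, 50)
  expect_true(r$empty)
  expect_equal(r$structures$total$volume_mm3, 0)
  expect_true(is.na(r$structures$total$compartments$normo$percent))
})

test_that("phantom densitometry recovers the generating mixture", {
  w <- c(hyper = 0.2, normo = 0.7, hypo = 0.08, non = 0.02)
  s <- generate_phantom(phantom_spec(seed = 26L, lung_aeration_profile = w))
  r <- truth_densitometry(s)
  got <- vapply(r$structures$total$compartments, `[[`, 0, "percent")
  expect_lt(max(abs(got - 100 * w)), 2)
})
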