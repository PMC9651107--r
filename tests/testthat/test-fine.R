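test_that("transfer learning freezes the encoder bit for bit", {
  fx <- trained_fixture()
  for (vw in c("axial", "sagittal", "coronal")) {
    expect_identical(fx$joint[[vw]]$W1, fx$lr[[vw]]$W1)
    expect_identical(fx$joint[[vw]]$b1, fx$lr[[vw]]$b1)
    expect_identical(encoder_digest(fx$joint[[vw]]), encoder_digest(fx$lr[[vw]]))
    expect_false(identical(dim(fx$joint[[vw]]$W2), dim(fx$lr[[vw]]$W2)))
  }
  expect_error(transfer_learn_left_right(backend_mlp(muridens_classes("joint")),
                                         fx$trP, fx$vaP), "untrained")
  expect_error(transfer_learn_left_right(fx$joint$axial, fx$trP, fx$vaP,
                                         view = "coronal"), "view mismatch")
})

test_that("single-view predictions are normalized probability volumes on the input grid", {
  fx <- trained_fixture()
  s <- fx$teP[[1]]
  for (vw in c("axial", "sagittal", "coronal")) {
    pm <- predict_view(fx$lr[[vw]], s$hu, vw)
    expect_identical(pm$dim, dim(s$hu$grid))
    tot <- Reduce(`+`, pm$maps)
    expect_lt(max(abs(tot - 1)), 1e-6)
    expect_gte(min(vapply(pm$maps, min, 0)), 0)
  }
})

test_that("joint models segment held-out lungs and transfer separates the sides", {
  fx <- trained_fixture()
  joint_dsc <- side_dsc <- c()
  for (s in fx$teP) {
    for (vw in c("axial", "sagittal", "coronal")) {
      pj <- predict_view(fx$joint[[vw]], s$hu, vw)
      lj <- binarize(pj, 0.5)
      joint_dsc <- c(joint_dsc, dice_masks(s$labels$grid %in% 1:2,
                                           lj$grid == 1L))
      pl <- predict_view(fx$lr[[vw]], s$hu, vw)
      ll <- binarize_view(pl, fx$vm$thresholds[[vw]])
      side_dsc <- c(side_dsc, dice(s$labels, ll, 1L), dice(s$labels, ll, 2L))
    }
  }
  expect_gt(mean(joint_dsc), 0.85)
  expect_gt(mean(side_dsc), 0.80)
  # the transferred model beats a naive midline split of the joint mask
  s <- fx$teP[[1]]
  pj <- predict_view(fx$joint$axial, s$hu, "axial")
  lj <- binarize(pj, 0.5)$grid
  midline <- dim(lj)[3] %/% 2
  naive <- array(0L, dim(lj))
  naive[, , 1:midline][lj[, , 1:midline] == 1L] <- 1L
  naive[, , (midline + 1):dim(lj)[3]][lj[, , (midline + 1):dim(lj)[3]] == 1L] <- 2L
  pl <- predict_view(fx$lr$axial, s$hu, "axial")
  ll <- binarize_view(pl, c(0.45, 0.45))
  tr_dsc <- (dice(s$labels, ll, 1L) + dice(s$labels, ll, 2L)) / 2
  nv_dsc <- (dice_masks(s$labels$grid == 1L, naive == 1L) +
               dice_masks(s$labels$grid == 2L, naive == 2L)) / 2
  expect_gte(tr_dsc, nv_dsc - 0.02)
})

test_that("oracle single-view probabilities binarize back to the exact truth", {
  s <- small_phantom(seed = 22L)
  box <- compute_bounding_box(s$truth_labels, fixture_extent,
                              lung_codes = c(1L, 2L))
  prep <- prepare_fine_input(apply_transfer(s$raw,
                                            phantom_truth_transfer(s$spec)),
                             s$truth_labels, box, 2L)
  lr_truth <- relabel(prep$labels, c(left_lung = 1L, right_lung = 2L))
  b <- backend_oracle(lr_truth)
  pm <- predict_view(b, prep$hu, "sagittal")
  for (th in list(c(0.45, 0.45), c(0.40, 0.40), c(0.9, 0.1)))
    expect_identical(binarize_view(pm, th)$grid, lr_truth$grid)
})

test_that("left/right ties resolve by probability then lower class code", {
  classes <- muridens_classes("lr")
  dm <- c(1L, 1L, 2L)
  p <- probability_map(list(background = array(c(0, 0.2), dm),
                            left_lung = array(c(0.5, 0.5), dm),
                            right_lung = array(c(0.5, 0.3), dm)), classes)
  lab <- binarize_view(p, c(0.45, 0.45))
  expect_equal(as.integer(lab$grid), c(1L, 1L))  # exact tie -> left (lower code)
  expect_error(binarize_view(p, 0.45), "two thresholds")
})

test_that("view model sets validate stage, training state and thresholds", {
  fx <- trained_fixture()
  expect_s3_class(fx$vm, "view_model_set")
  expect_error(view_model_set(fx$lr$axial, fx$lr$sagittal,
                              backend_mlp(muridens_classes("lr")), "lr"),
               "trained")
  expect_error(view_model_set(fx$lr$axial, fx$lr$sagittal, fx$lr$coronal,
                              thresholds = list(axial = c(1.2, 0.4),
                                                sagittal = c(0.4, 0.4),
                                                coronal = c(0.4, 0.4))),
               "0, 1")
})

test_that("augmentation does not cost more than 0.05 held-out Dice", {
  fx <- trained_fixture()
  cfg_plain <- fixture_fine_cfg(seed = 77L)
  cfg_plain$max_epochs <- 120L
  cfg_aug <- cfg_plain
  cfg_aug$augment <- TRUE
  sub <- fx$trP[1:6]
  b_plain <- train_view_joint(sub, fx$vaP, "axial", cfg_plain)
  b_aug <- train_view_joint(sub, fx$vaP, "axial", cfg_aug)
  dsc <- function(b) mean(vapply(fx$teP[1:3], function(s) {
    lab <- binarize(predict_view(b, s$hu, "axial"), 0.5)
    dice_masks(s$labels$grid %in% 1:2, lab$grid == 1L)
  }, 0))
  expect_gt(dsc(b_aug), dsc(b_plain) - 0.05)
})
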