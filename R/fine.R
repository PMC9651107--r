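# Fine single-view segmentation.
#
# Three backends, one per orthogonal view, operate on HU-converted volumes
# cropped to the lung bounding box and isotropically down-sampled by factor 2.
# They are first trained to segment the lungs jointly (two-class, so the
# softmax cross-entropy coincides with binary cross-entropy on the lung
# probability), then specialised to left/right segmentation by retraining
# only the decoder while the encoder is frozen.

#' Prepare a sample for fine-stage training or prediction
#'
#' Crops the HU volume and labels to the bounding box and down-samples both
#' isotropically by `factor`.
#'
#' @param hu An [hu_volume()] at full resolution.
#' @param labels Optional [label_map()] on the same grid.
#' @param box A [bounding_box()].
#' @param factor Isotropic down-sampling factor (default 2).
#' @return List with `hu` (down-sampled crop) and, when labels are given,
#'   `labels` (same grid).
#' @export
prepare_fine_input <- function(hu, labels = NULL, box, factor = 2L) {
  out <- list(hu = downsample(crop(hu, box), factor, "intensity", "all"))
  if (!is.null(labels))
    out$labels <- downsample(crop(labels, box), factor, "label", "all")
  out
}

.fine_slices <- function(sample, view, cfg, stage) {
  lab <- sample$labels
  want <- muridens_classes(stage)
  if (!identical(lab$class_codes, want)) {
    lab <- if (stage == "joint")
      relabel(lab, c(lung = 1L, lung2 = 2L), c(1L, 1L))
    else relabel(lab, c(left_lung = 1L, right_lung = 2L))
    lab$class_codes <- want
  }
  imgs <- extract_view_stack(sample$hu$grid, view)
  labs <- extract_view_stack(lab$grid, view)
  idx <- seq(1L, length(imgs), by = cfg$slice_stride)
  lapply(idx, function(i)
    list(img = imgs[[i]], lab = labs[[i]], frac = (i - 0.5) / length(imgs)))
}

#' Train a single-view joint-lung model
#'
#' @param train,val Lists of prepared samples (see [prepare_fine_input()])
#'   with joint-lung (or fine) labels.
#' @param view `"axial"`, `"sagittal"` or `"coronal"`.
#' @param cfg A [training_config()]; fine batches default to 4 slices.
#' @param backend Optional pre-built backend over the joint classes.
#' @return A trained backend tagged with the view and stage.
#' @export
train_view_joint <- function(train, val, view = c("axial", "sagittal", "coronal"),
                             cfg = training_config(batch_slices = 4L),
                             backend = NULL) {
  view <- match.arg(view)
  if (!length(train)) stop("empty training set", call. = FALSE)
  if (!length(val)) stop("empty validation set", call. = FALSE)
  b <- backend %||% backend_mlp(muridens_classes("joint"), cfg$hidden)
  tr <- unlist(lapply(train, .fine_slices, view = view, cfg = cfg,
                      stage = "joint"), recursive = FALSE)
  va <- unlist(lapply(val, .fine_slices, view = view, cfg = cfg,
                      stage = "joint"), recursive = FALSE)
  b <- .train_mlp(b, tr, va, cfg)
  b$view <- view; b$stage <- "joint"
  b
}

#' Specialise a joint-lung model to left/right segmentation
#'
#' Retrains only the decoder (output layer) of a trained joint-lung backend
#' for the three classes background/left/right, with categorical
#' cross-entropy; the encoder weights and feature normalisation are frozen
#' and bit-identical before and after.
#'
#' @param base A trained joint-stage backend.
#' @param trainB,valB Lists of prepared samples with left/right labels.
#' @param view View of the base model (checked if the base carries one).
#' @param cfg A [training_config()].
#' @return A trained left/right backend sharing the base encoder.
#' @export
transfer_learn_left_right <- function(base, trainB, valB, view = base$view,
                                      cfg = training_config(batch_slices = 4L)) {
  stopifnot(inherits(base, "mlp_backend"))
  if (!isTRUE(base$trained)) stop("base backend is untrained", call. = FALSE)
  if (!is.null(base$view) && !is.null(view) && !identical(base$view, view))
    stop("view mismatch between base model and request", call. = FALSE)
  b <- backend_mlp(muridens_classes("lr"), base$hidden)
  b$W1 <- base$W1; b$b1 <- base$b1
  b$feat_center <- base$feat_center; b$feat_scale <- base$feat_scale
  tr <- unlist(lapply(trainB, .fine_slices, view = view, cfg = cfg,
                      stage = "lr"), recursive = FALSE)
  va <- unlist(lapply(valB, .fine_slices, view = view, cfg = cfg,
                      stage = "lr"), recursive = FALSE)
  b <- .train_mlp(b, tr, va, cfg, freeze_encoder = TRUE)
  b$view <- view; b$stage <- "lr"
  b
}

#' Predict a single view over a prepared HU crop
#'
#' @param b A trained backend.
#' @param hu_crop An [hu_volume()] already cropped and down-sampled by the
#'   fine-stage factor (see [prepare_fine_input()]).
#' @param view View to slice along; defaults to the backend's view.
#' @return A [probability_map()] on the crop grid.
#' @export
predict_view <- function(b, hu_crop, view = b$view) {
  if (is.null(view)) stop("view must be given", call. = FALSE)
  g <- if (is.list(hu_crop)) hu_crop$grid else hu_crop
  .predict_stack(b, g, view)
}

#' Binarize a left/right probability map
#'
#' Same rule as [binarize()], restricted to the two foreground classes:
#' a voxel is assigned the higher-probability side among those above their
#' threshold (ties to the lower class code), else background.
#'
#' @param p A [probability_map()] over background/left/right.
#' @param thresholds Two values in (0, 1), ordered (left, right); reference
#'   operating points are 0.45/0.45 axial and 0.40/0.40 sagittal/coronal.
#' @param voxel_size_um Voxel size stamp.
#' @return A [label_map()].
#' @export
binarize_view <- function(p, thresholds, voxel_size_um = 50) {
  if (length(thresholds) != 2L)
    stop("binarize_view needs exactly two thresholds", call. = FALSE)
  binarize(p, thresholds, voxel_size_um)
}

#' Bundle of the three single-view models
#'
#' @param axial,sagittal,coronal Trained backends for the three views.
#' @param stage `"joint"` or `"lr"`.
#' @param thresholds Named list of per-view binarization thresholds, e.g.
#'   `list(axial = c(0.45, 0.45), sagittal = c(0.40, 0.40), coronal =
#'   c(0.40, 0.40))`.
#' @return An object of class `view_model_set`.
#' @export
view_model_set <- function(axial, sagittal, coronal, stage = c("lr", "joint"),
                           thresholds = list(axial = c(0.45, 0.45),
                                             sagittal = c(0.40, 0.40),
                                             coronal = c(0.40, 0.40))) {
  stage <- match.arg(stage)
  for (b in list(axial, sagittal, coronal))
    if (!inherits(b, "muridens_backend") || !isTRUE(b$trained))
      stop("all three views need trained backends", call. = FALSE)
  for (t in thresholds)
    if (any(t <= 0 | t >= 1)) stop("thresholds must lie in (0, 1)", call. = FALSE)
  structure(list(axial = axial, sagittal = sagittal, coronal = coronal,
                 stage = stage, thresholds = thresholds),
            class = "view_model_set")
}
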