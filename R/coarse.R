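#' Per-class probability map
#'
#' @param maps Named list of 3-D arrays in `[0, 1]`, one per class
#'   (background included), sharing one grid.
#' @param classes Named integer class codes matching `names(maps)`.
#' @return An object of class `probability_map`.
#' @export
probability_map <- function(maps, classes) {
  stopifnot(is.list(maps), length(maps) == length(classes),
            identical(names(maps), names(classes)))
  dm <- dim(maps[[1]])
  for (m in maps) {
    if (!identical(dim(m), dm)) stop("probability maps differ in shape", call. = FALSE)
    if (min(m) < -1e-9 || max(m) > 1 + 1e-9)
      stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(list(maps = maps, classes = classes, dim = dm),
            class = "probability_map")
}

#' @export
print.probability_map <- function(x, ...) {
  cat(sprintf("<probability_map> %s, classes %s\n",
              paste(x$dim, collapse = "x"),
              paste(names(x$classes), collapse = "/")))
  invisible(x)
}

# run a backend over a view stack and assemble per-class probability arrays
.predict_stack <- function(b, grid, view) {
  slices <- extract_view_stack(grid, view)
  n <- length(slices)
  per_class <- NULL
  for (i in seq_len(n)) {
    meta <- list(view = view, index = i, n = n, frac = (i - 0.5) / n)
    p <- .backend_predict_slice(b, slices[[i]], meta)
    if (is.null(per_class))
      per_class <- lapply(p, function(x) vector("list", n))
    for (k in names(p)) per_class[[k]][[i]] <- p[[k]]
  }
  maps <- lapply(per_class, restack_views, view = view)
  probability_map(maps, b$classes)
}

#' Train the coarse multi-class localization model
#'
#' Trains a backend to segment joint lungs, heart and airways on axial slices
#' down-sampled in-plane by `factor` (default 4, i.e. 512x512 slices become
#' 128x128).  Training uses categorical cross-entropy over the four coarse
#' classes with Adam and early stopping on validation loss.
#'
#' @param train,val Lists of samples: either `phantom_sample`s or lists with
#'   elements `volume` (a [raw_volume()], ideally median-filtered) and
#'   `labels` (a [label_map()], fine or coarse coding).
#' @param cfg A [training_config()]; coarse batches default to 24 slices.
#' @param factor In-plane down-sampling factor.
#' @param backend Optional pre-built backend; defaults to a fresh
#'   [backend_mlp()] over the coarse classes.
#' @return A trained backend carrying the training log in `$log`.
#' @export
train_coarse <- function(train, val, cfg = training_config(batch_slices = 24L),
                         factor = 4L, backend = NULL) {
  if (!length(val)) stop("empty validation set", call. = FALSE)
  if (!length(train)) stop("empty training set", call. = FALSE)
  b <- backend %||% backend_mlp(muridens_classes("coarse"), cfg$hidden)
  tr <- unlist(lapply(train, .coarse_slices, factor = factor, cfg = cfg),
               recursive = FALSE)
  va <- unlist(lapply(val, .coarse_slices, factor = factor, cfg = cfg),
               recursive = FALSE)
  .train_mlp(b, tr, va, cfg)
}

.coarse_slices <- function(sample, factor, cfg) {
  sv <- .sample_parts(sample)
  lab <- sv$labels
  if (!identical(lab$class_codes, muridens_classes("coarse")))
    lab <- to_coarse_labels(lab)
  vol_ds <- downsample(sv$volume$grid, factor, "intensity", "yx")
  lab_ds <- downsample(lab$grid, factor, "label", "yx")
  imgs <- extract_view_stack(vol_ds, "axial")
  labs <- extract_view_stack(lab_ds, "axial")
  idx <- seq(1L, length(imgs), by = cfg$slice_stride)
  lapply(idx, function(i)
    list(img = imgs[[i]], lab = labs[[i]], frac = (i - 0.5) / length(imgs)))
}

.sample_parts <- function(sample) {
  if (inherits(sample, "phantom_sample"))
    list(volume = sample$raw, labels = sample$truth_labels)
  else list(volume = sample$volume, labels = sample$labels)
}

#' Coarse prediction over a whole volume
#'
#' Applies the coarse backend slice-wise over the axial stack of the in-plane
#' down-sampled volume.
#'
#' @param b A trained backend over the coarse classes.
#' @param v A [raw_volume()] (median-filtered upstream).
#' @param factor In-plane down-sampling factor used at training time.
#' @return A [probability_map()] at the down-sampled resolution.
#' @export
predict_coarse <- function(b, v, factor = 4L) {
  g <- if (is.list(v)) v$grid else v
  .predict_stack(b, downsample(g, factor, "intensity", "yx"), "axial")
}

#' Optimize per-class binarization thresholds on a validation set
#'
#' For each foreground class independently, picks the grid threshold
#' maximizing the mean per-volume Dice coefficient between the thresholded
#' probability map and the truth.  Ties are broken toward 0.5, then toward
#' the larger threshold.
#'
#' @param probmaps List of [probability_map()]s (or a single one).
#' @param truths List of [label_map()]s matching `probmaps`.
#' @param grid Candidate thresholds in (0, 1).
#' @return Named numeric vector, one threshold per foreground class.
#' @export
optimize_thresholds <- function(probmaps, truths,
                                grid = seq(0.05, 0.95, by = 0.05)) {
  if (inherits(probmaps, "probability_map")) probmaps <- list(probmaps)
  if (inherits(truths, "label_map")) truths <- list(truths)
  if (!length(probmaps) || length(probmaps) != length(truths))
    stop("need matching, non-empty probmaps and truths", call. = FALSE)
  if (!length(grid) || any(grid <= 0 | grid >= 1))
    stop("threshold grid values must lie in (0, 1)", call. = FALSE)
  classes <- probmaps[[1]]$classes
  fg <- classes[classes != 0L]
  out <- vapply(names(fg), function(cn) {
    code <- fg[[cn]]
    mean_dsc <- vapply(grid, function(t) {
      mean(vapply(seq_along(probmaps), function(i) {
        pred <- probmaps[[i]]$maps[[cn]] > t
        dice_masks(truths[[i]]$grid == code, pred)
      }, 0))
    }, 0)
    best <- which(mean_dsc >= max(mean_dsc) - 1e-12)
    d <- abs(grid[best] - 0.5)
    cand <- best[d == min(d)]
    grid[max(cand)]
  }, 0)
  out
}

#' Binarize a probability map into a label map
#'
#' Each voxel is assigned the highest-probability class among the foreground
#' classes whose probability exceeds their threshold; ties go to the lowest
#' class code; voxels with no class above threshold become background.
#'
#' @param p A [probability_map()].
#' @param thresholds Numeric vector, one value in (0, 1) per foreground
#'   class, ordered (or named) by class.
#' @param voxel_size_um Voxel size to stamp on the output.
#' @return A [label_map()].
#' @export
binarize <- function(p, thresholds, voxel_size_um = 50) {
  stopifnot(inherits(p, "probability_map"))
  fg <- p$classes[p$classes != 0L]
  if (length(thresholds) != length(fg))
    stop("need one threshold per foreground class", call. = FALSE)
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("thresholds must lie in (0, 1)", call. = FALSE)
  if (!is.null(names(thresholds))) thresholds <- thresholds[names(fg)]
  nv <- prod(p$dim)
  P <- vapply(names(fg), function(cn) as.numeric(p$maps[[cn]]), numeric(nv))
  P <- matrix(P, nv, length(fg))
  elig <- sweep(P, 2, thresholds, `>`)
  P[!elig] <- -Inf
  pick <- max.col(P, ties.method = "first")   # ties -> lowest class code
  code <- as.integer(fg)[pick]
  code[!apply(elig, 1, any)] <- 0L
  label_map(array(code, p$dim), c(background = 0L, fg), voxel_size_um)
}

# ---- bounding box ----------------------------------------------------------

#' Fixed-size bounding box centred on a lung mask
#'
#' The box (default 384 x 320 x 384 voxels in (z, y, x)) is centred on the
#' centroid of the lung mask, rounded to integer voxel coordinates, then
#' translated minimally so it fits the grid; if an extent exceeds the grid the
#' box is centred and [crop()] pads the overhang.
#'
#' @param lung A [label_map()] or logical/integer array; non-zero voxels (or
#'   `lung_codes`) define the mask at full resolution.
#' @param extent Integer 3-vector (z, y, x) box size.
#' @param lung_codes Codes counting as lung when `lung` is a label map.
#' @return An object of class `bounding_box` with 0-based `origin` and
#'   `extent`.
#' @export
compute_bounding_box <- function(lung, extent = c(384L, 320L, 384L),
                                 lung_codes = NULL) {
  g <- if (is.list(lung)) lung$grid else lung
  mask <- if (is.null(lung_codes)) g != 0 else array(g %in% lung_codes, dim(g))
  if (!any(mask))
    .err("lung localization failed: empty lung mask",
         "muridens_localization_error")
  extent <- as.integer(extent)
  dm <- dim(mask)
  idx <- arrayInd(which(mask), dm)
  centroid <- colMeans(idx) - 1          # 0-based voxel coordinates
  origin <- round(centroid - extent / 2)
  for (a in 1:3) {
    if (extent[a] <= dm[a]) {
      origin[a] <- min(max(origin[a], 0L), dm[a] - extent[a])
    } else {
      origin[a] <- round((dm[a] - extent[a]) / 2)
    }
  }
  structure(list(origin = as.integer(origin), extent = extent),
            class = "bounding_box")
}

#' @export
print.bounding_box <- function(x, ...) {
  cat(sprintf("<bounding_box> origin (%s), extent (%s)\n",
              paste(x$origin, collapse = ", "),
              paste(x$extent, collapse = ", ")))
  invisible(x)
}

#' Crop a volume to a bounding box
#'
#' Voxels of the box falling outside the grid are filled with -1040 HU for HU
#' volumes (the air floor of the densitometric range), the grid minimum for
#' raw volumes, and background for label maps.
#'
#' @param v A volume object or 3-D array.
#' @param box A [bounding_box()].
#' @param fill Optional override for the out-of-grid fill value.
#' @return Same type as the input, with grid dimensions `box$extent`.
#' @export
crop <- function(v, box, fill = NULL) {
  stopifnot(inherits(box, "bounding_box"))
  g <- if (is.list(v)) v$grid else v
  if (is.null(fill)) {
    fill <- if (inherits(v, "hu_volume")) -1040
            else if (inherits(v, "label_map")) 0L
            else min(g)
  }
  dm <- dim(g)
  out <- array(fill, box$extent)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    s0 <- max(box$origin[a], 0L); s1 <- min(box$origin[a] + box$extent[a], dm[a])
    if (s0 >= s1) return(.rewrap(v, out))   # fully outside
    src[[a]] <- (s0 + 1L):s1
    dst[[a]] <- (s0 - box$origin[a] + 1L):(s1 - box$origin[a])
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- g[src[[1]], src[[2]], src[[3]]]
  .rewrap(v, out)
}

#' Paste a cropped grid back into a full-size volume
#'
#' Inverse companion of [crop()] for the in-grid region.
#'
#' @param full The original full-size volume (or array) to paste into.
#' @param cropped The cropped volume (or array).
#' @param box The [bounding_box()] used for the crop.
#' @return Same type as `full`.
#' @export
uncrop <- function(full, cropped, box) {
  g <- if (is.list(full)) full$grid else full
  cg <- if (is.list(cropped)) cropped$grid else cropped
  dm <- dim(g)
  for (a in 1:3) stopifnot(dim(cg)[a] == box$extent[a])
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    s0 <- max(box$origin[a], 0L); s1 <- min(box$origin[a] + box$extent[a], dm[a])
    src[[a]] <- (s0 + 1L):s1
    dst[[a]] <- (s0 - box$origin[a] + 1L):(s1 - box$origin[a])
  }
  g[src[[1]], src[[2]], src[[3]]] <- cg[dst[[1]], dst[[2]], dst[[3]]]
  .rewrap(full, g)
}
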