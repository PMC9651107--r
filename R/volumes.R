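#' @useDynLib muridens, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rmultinom sd lm median
#' @importFrom utils write.csv
"_PACKAGE"

# Axis convention used throughout the package: grids are stored (z, y, x) with
# z the axial (cranio-caudal) index, y the dorso-ventral index and x the
# left-right index.  Axial slices fix z, sagittal slices fix x, coronal slices
# fix y.  Voxel indexing is 0-based in all user-facing coordinates (centroids,
# bounding boxes); bounding boxes are half-open [origin, origin + extent).

#' Micro-CT volume in raw detector grey levels
#'
#' A `raw_volume` wraps a 3-D numeric array of detector grey levels together
#' with its isotropic voxel size and the breathing phase of the retrospectively
#' gated reconstruction (`"P01"` end-inspiration, `"P02"` end-expiration).
#'
#' @param grid 3-D numeric array, axis order (z, y, x); all values must be
#'   non-negative (detector grey levels are dimensionless counts).
#' @param voxel_size_um Positive scalar, isotropic voxel edge in micrometres.
#' @param phase Breathing phase tag, `"P01"` or `"P02"`.
#' @return An object of class `raw_volume`.
#' @export
raw_volume <- function(grid, voxel_size_um = 50, phase = c("P02", "P01")) {
  phase <- match.arg(phase)
  .check_grid(grid)
  if (any(grid < 0)) stop("raw grey levels must be non-negative", call. = FALSE)
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L || voxel_size_um <= 0)
    stop("voxel_size_um must be a positive scalar", call. = FALSE)
  structure(list(grid = grid, voxel_size_um = as.numeric(voxel_size_um),
                 phase = phase),
            class = c("raw_volume", "muridens_volume"))
}

#' Micro-CT volume in Hounsfield units
#'
#' @param grid 3-D numeric array (z, y, x) of finite HU values.
#' @param voxel_size_um Positive scalar, micrometres.
#' @param transfer Optional [transfer_function()] recording the grey-level to
#'   HU calibration the volume was produced with (provenance).
#' @return An object of class `hu_volume`.
#' @export
hu_volume <- function(grid, voxel_size_um = 50, transfer = NULL) {
  .check_grid(grid)
  if (!all(is.finite(grid))) stop("HU grid must be finite", call. = FALSE)
  if (!is.null(transfer) && !inherits(transfer, "transfer_function"))
    stop("transfer must be a transfer_function or NULL", call. = FALSE)
  structure(list(grid = grid, voxel_size_um = as.numeric(voxel_size_um),
                 transfer = transfer),
            class = c("hu_volume", "muridens_volume"))
}

#' Integer label map over anatomical classes
#'
#' The default class coding is 0 background, 1 left lung, 2 right lung,
#' 3 heart, 4 airways.  Coarse-stage maps use the reduced coding 0 background,
#' 1 lungs (joint), 2 heart, 3 airways.
#'
#' @param grid 3-D integer array (z, y, x).
#' @param class_codes Named integer vector mapping class names to codes; must
#'   cover every code present in `grid`.
#' @param voxel_size_um Positive scalar, micrometres.
#' @return An object of class `label_map`.
#' @export
label_map <- function(grid, class_codes = muridens_classes("fine"),
                      voxel_size_um = 50) {
  .check_grid(grid)
  grid <- array(as.integer(grid), dim = dim(grid))
  present <- sort(unique(as.integer(grid)))
  if (!all(present %in% class_codes))
    stop("label map contains codes absent from class_codes: ",
         paste(setdiff(present, class_codes), collapse = ", "), call. = FALSE)
  structure(list(grid = grid, class_codes = class_codes,
                 voxel_size_um = as.numeric(voxel_size_um)),
            class = c("label_map", "muridens_volume"))
}

#' Standard class codings
#'
#' @param stage `"fine"` (background/left/right/heart/airways), `"coarse"`
#'   (background/lung/heart/airways), `"joint"` (background/lung) or `"lr"`
#'   (background/left/right).
#' @return Named integer vector of class codes.
#' @export
muridens_classes <- function(stage = c("fine", "coarse", "joint", "lr")) {
  stage <- match.arg(stage)
  switch(stage,
    fine   = c(background = 0L, left_lung = 1L, right_lung = 2L,
               heart = 3L, airways = 4L),
    coarse = c(background = 0L, lung = 1L, heart = 2L, airways = 3L),
    joint  = c(background = 0L, lung = 1L),
    lr     = c(background = 0L, left_lung = 1L, right_lung = 2L))
}

#' Reduce a full (five-class) label map to the coarse coding
#'
#' Left and right lung merge into a single joint-lung class; heart and airways
#' are re-coded to the coarse codes.
#'
#' @param labels A [label_map()] in the fine coding.
#' @return A [label_map()] in the coarse coding.
#' @export
to_coarse_labels <- function(labels) {
  g <- labels$grid
  out <- array(0L, dim(g))
  out[g == 1L | g == 2L] <- 1L
  out[g == 3L] <- 2L
  out[g == 4L] <- 3L
  label_map(out, muridens_classes("coarse"), labels$voxel_size_um)
}

#' Reduce a label map to a given foreground subset
#'
#' @param labels A [label_map()].
#' @param keep Named integer vector of codes to keep (others become
#'   background); names give the new class names, values the original codes.
#' @param recode Optional integer vector of new codes, parallel to `keep`.
#' @return A [label_map()].
#' @export
relabel <- function(labels, keep, recode = seq_along(keep)) {
  g <- labels$grid
  out <- array(0L, dim(g))
  for (i in seq_along(keep)) out[g == keep[[i]]] <- as.integer(recode[[i]])
  codes <- c(background = 0L, structure(as.integer(recode), names = names(keep)))
  label_map(out, codes, labels$voxel_size_um)
}

.check_grid <- function(grid) {
  if (!is.array(grid) || length(dim(grid)) != 3L || any(dim(grid) < 1L))
    stop("grid must be a non-empty 3-D array", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.muridens_volume <- function(x, ...) {
  d <- dim(x$grid)
  kind <- class(x)[1L]
  cat(sprintf("<%s> %d x %d x %d (z,y,x), voxel %.3g um", kind,
              d[1], d[2], d[3], x$voxel_size_um))
  if (!is.null(x$phase)) cat(", phase", x$phase)
  cat("\n")
  if (kind == "label_map") {
    tab <- table(factor(x$grid, levels = x$class_codes,
                        labels = names(x$class_codes)))
    cat("  voxels:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  } else {
    cat(sprintf("  range [%.4g, %.4g]\n", min(x$grid), max(x$grid)))
  }
  invisible(x)
}

# ---- view stacks -----------------------------------------------------------

#' Extract a stack of 2-D slices along one anatomical view
#'
#' Axial slices are indexed by z and have dimensions (y, x); sagittal slices
#' are indexed by x with dimensions (z, y); coronal slices are indexed by y
#' with dimensions (z, x).  [restack_views()] is the exact inverse.
#'
#' @param v A volume object or bare 3-D array.
#' @param view `"axial"`, `"sagittal"` or `"coronal"`.
#' @return List of 2-D matrices, ordered by slice index.
#' @export
extract_view_stack <- function(v, view = c("axial", "sagittal", "coronal")) {
  view <- match.arg(view)
  g <- if (is.list(v)) v$grid else v
  n <- switch(view, axial = dim(g)[1], coronal = dim(g)[2], sagittal = dim(g)[3])
  lapply(seq_len(n), function(i) switch(view,
    axial    = g[i, , , drop = TRUE],
    coronal  = g[, i, , drop = TRUE],
    sagittal = g[, , i, drop = TRUE]))
}

#' Reassemble a volume from a view stack
#'
#' @param slices List of 2-D matrices as produced by [extract_view_stack()].
#' @param view The view the stack was extracted along.
#' @return A 3-D array in the package's (z, y, x) convention.
#' @export
restack_views <- function(slices, view = c("axial", "sagittal", "coronal")) {
  view <- match.arg(view)
  n <- length(slices)
  d2 <- dim(slices[[1]])
  dm <- switch(view,
    axial    = c(n, d2[1], d2[2]),
    coronal  = c(d2[1], n, d2[2]),
    sagittal = c(d2[1], d2[2], n))
  out <- array(slices[[1]][1] * 0, dm)
  for (i in seq_len(n)) switch(view,
    axial    = {out[i, , ] <- slices[[i]]},
    coronal  = {out[, i, ] <- slices[[i]]},
    sagittal = {out[, , i] <- slices[[i]]})
  out
}

# ---- resampling ------------------------------------------------------------

#' Down-sample a volume by integer block aggregation
#'
#' Intensity volumes are averaged over factor-sized blocks; label maps take
#' the block mode (ties resolved toward the lowest class code).  By default
#' only the in-plane axes (y, x) are reduced, matching the coarse-stage
#' slice resizing; `dims = "all"` reduces all three axes, matching the
#' fine-stage isotropic down-sampling.  Dimensions not divisible by the factor
#' are padded to the next multiple with the volume minimum (intensity) or
#' background (labels) before aggregation; the raw background of a thorax scan
#' is dark, so the pad is inert.
#'
#' @param v A volume object or 3-D array.
#' @param factor Positive integer reduction factor.
#' @param mode `"intensity"` (block mean) or `"label"` (block mode).
#' @param dims `"yx"` (in-plane only, default) or `"all"`.
#' @return Same type as the input, with reduced grid.
#' @export
downsample <- function(v, factor, mode = c("intensity", "label"),
                       dims = c("yx", "all")) {
  mode <- match.arg(mode); dims <- match.arg(dims)
  if (!is.numeric(factor) || factor < 1 || factor != round(factor))
    stop("factor must be a positive integer", call. = FALSE)
  factor <- as.integer(factor)
  g <- if (is.list(v)) v$grid else v
  if (is.matrix(g)) {                      # a single 2-D slice
    out <- .block_reduce(array(g, c(1L, dim(g))), c(1L, factor, factor),
                         mode, if (mode == "label") 0 else min(g))
    return(matrix(out, dim(out)[2], dim(out)[3]))
  }
  f <- if (dims == "yx") c(1L, factor, factor) else rep(factor, 3L)
  pad <- if (mode == "label") 0 else min(g)
  out <- .block_reduce(g, f, mode, pad)
  .rewrap(v, out)
}

.block_reduce <- function(g, f, mode, pad) {
  dm <- dim(g)
  dm2 <- ceiling(dm / f) * f
  if (any(dm2 != dm)) {
    gg <- array(pad, dm2)
    gg[seq_len(dm[1]), seq_len(dm[2]), seq_len(dm[3])] <- g
    g <- gg
  }
  out_dim <- dm2 %/% f
  dim(g) <- c(f[1], out_dim[1], f[2], out_dim[2], f[3], out_dim[3])
  g <- aperm(g, c(1, 3, 5, 2, 4, 6))
  dim(g) <- c(prod(f), prod(out_dim))
  res <- if (mode == "intensity") {
    colMeans(g)
  } else {
    apply(g, 2, function(col) {
      tb <- table(col)
      as.numeric(names(tb)[which.max(tb)])  # ties -> lowest code (table sorted)
    })
  }
  array(res, out_dim)
}

#' Up-sample a volume by nearest-neighbour replication
#'
#' Inverse companion of [downsample()]; used to bring coarse masks and fused
#' fine-stage predictions back to the resolution densitometry runs at.
#'
#' @inheritParams downsample
#' @param target_dim Optional final dimensions to crop the replicated grid to
#'   (when the original extent was not a multiple of the factor).
#' @return Same type as the input.
#' @export
upsample_nearest <- function(v, factor, dims = c("yx", "all"),
                             target_dim = NULL) {
  dims <- match.arg(dims)
  factor <- as.integer(factor)
  g <- if (is.list(v)) v$grid else v
  f <- if (dims == "yx") c(1L, factor, factor) else rep(factor, 3L)
  idx <- lapply(1:3, function(a) rep(seq_len(dim(g)[a]), each = f[a]))
  out <- g[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  if (!is.null(target_dim))
    out <- out[seq_len(target_dim[1]), seq_len(target_dim[2]),
               seq_len(target_dim[3]), drop = FALSE]
  .rewrap(v, out)
}

.rewrap <- function(v, grid) {
  if (!is.list(v)) return(grid)
  out <- v
  out$grid <- if (inherits(v, "label_map"))
    array(as.integer(round(grid)), dim(grid)) else grid
  out
}

# ---- morphology helpers ----------------------------------------------------

# binary dilation/erosion with a (2r+1)^3 box structuring element, done as
# three separable 1-D running max/min passes via shifted overlays
.dilate_box <- function(mask, r = 1L) {
  m <- mask
  for (axis in 1:3) {
    acc <- m
    for (s in seq_len(r)) {
      acc <- acc | .shift3(m, axis, s) | .shift3(m, axis, -s)
    }
    m <- acc
  }
  m
}

.erode_box <- function(mask, r = 1L) !.dilate_box(!mask, r)

.shift3 <- function(m, axis, s) {
  dm <- dim(m)
  out <- array(FALSE, dm)
  n <- dm[axis]
  if (abs(s) >= n) return(out)
  src <- if (s > 0) 1:(n - s) else (1 - s):n
  dst <- if (s > 0) (1 + s):n else 1:(n + s)
  if (axis == 1) { out[dst, , ] <- m[src, , ] }
  else if (axis == 2) { out[, dst, ] <- m[, src, ] }
  else { out[, , dst] <- m[, , src] }
  out
}

#' Label 6-connected components of a binary mask
#'
#' @param mask Logical 3-D array.
#' @return Integer array of component labels (0 = background), ordered by
#'   discovery.
#' @export
connected_components <- function(mask) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  .cc_label_cpp(array(as.logical(mask), dim(mask)))
}
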