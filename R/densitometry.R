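#' Aeration compartment breakpoints
#'
#' The densitometric range `[-1040, +121]` HU is partitioned into four
#' aeration compartments: hyper-inflated `[-1040, -860)`, normo-aerated
#' `[-860, -435)`, hypo-aerated `[-435, -121)` and non-aerated
#' `[-121, +121]`.  Bins are half-open, closed on the left, with the top bin
#' closed on both ends, so the partition is exact with no double counting.
#'
#' @return Named numeric vector of the five strictly increasing breakpoints.
#' @export
compartment_thresholds <- function() {
  c(hyper = -1040, normo = -860, hypo = -435, non = -121, top = 121)
}

.compartment_names <- c("hyper", "normo", "hypo", "non")

#' Fuse three single-view label maps by per-voxel majority voting
#'
#' A voxel takes the label at least two views agree on.  Three-way
#' disagreement is resolved by the highest mean class probability across the
#' views when probability maps are supplied (ties to the lowest class code),
#' and falls back to background otherwise.
#'
#' @param axial,sagittal,coronal [label_map()]s on one grid.
#' @param probs Optional named list of the three [probability_map()]s
#'   (`axial`, `sagittal`, `coronal`) used for tie arbitration.
#' @return A fused [label_map()].
#' @export
majority_vote <- function(axial, sagittal, coronal, probs = NULL) {
  ga <- axial$grid; gs <- sagittal$grid; gc_ <- coronal$grid
  if (!identical(dim(ga), dim(gs)) || !identical(dim(ga), dim(gc_)))
    stop("view label maps differ in shape", call. = FALSE)
  out <- array(0L, dim(ga))
  agree_a <- ga == gs | ga == gc_
  out[agree_a] <- ga[agree_a]
  agree_s <- !agree_a & gs == gc_
  out[agree_s] <- gs[agree_s]
  tie <- !agree_a & !agree_s
  if (any(tie)) {
    if (!is.null(probs)) {
      classes <- probs$axial$classes
      ti <- which(tie)
      M <- vapply(names(classes), function(cn)
        (probs$axial$maps[[cn]][ti] + probs$sagittal$maps[[cn]][ti] +
           probs$coronal$maps[[cn]][ti]) / 3,
        numeric(length(ti)))
      M <- matrix(M, length(ti), length(classes))
      ord <- order(as.integer(classes))      # columns by ascending code
      pick <- max.col(M[, ord, drop = FALSE], ties.method = "first")
      out[ti] <- as.integer(classes)[ord][pick]
    }                                        # else: background
  }
  label_map(out, axial$class_codes, axial$voxel_size_um)
}

#' Combine left and right lung evidence into a total-lung mask
#'
#' Label-map inputs reduce to the set union of the two sides.  Probability
#' inputs are summed and binarized: a voxel is lung when the combined
#' left + right probability exceeds the threshold.
#'
#' @param p_left,p_right 3-D probability arrays, or [label_map()]s /
#'   logical arrays.
#' @param threshold Binarization threshold for probability inputs; a natural
#'   choice is the mean of the two per-view operating points.
#' @param voxel_size_um Voxel size stamp.
#' @return A binary [label_map()] (0 background, 1 lung).
#' @export
combine_total <- function(p_left, p_right, threshold = 0.5,
                          voxel_size_um = 50) {
  is_lab <- function(x) inherits(x, "label_map") ||
    (is.array(x) && (is.logical(x) || is.integer(x)))
  gl <- if (inherits(p_left, "label_map")) p_left$grid != 0 else p_left
  gr <- if (inherits(p_right, "label_map")) p_right$grid != 0 else p_right
  lung <- if (is_lab(p_left) && is_lab(p_right)) {
    (gl != 0) | (gr != 0)
  } else {
    (gl + gr) > threshold
  }
  label_map(array(as.integer(lung), dim(gl)),
            c(background = 0L, lung = 1L), voxel_size_um)
}

#' Remove lung-labelled voxels with out-of-range HU
#'
#' Lung voxels whose HU value falls outside the closed densitometric range
#' (default `[-1040, +121]`) are reassigned to background: they are typically
#' rib fragments or airway-wall tissue bled into the segmentation.  Non-lung
#' labels are untouched, and no voxel is ever added.
#'
#' @param labels A [label_map()].
#' @param hu An [hu_volume()] on the same grid.
#' @param range Closed HU interval retained.
#' @param lung_codes Codes treated as lung.
#' @return The cleaned [label_map()].
#' @export
clean_segmentation <- function(labels, hu, range = c(-1040, 121),
                               lung_codes = NULL) {
  g <- labels$grid
  h <- if (is.list(hu)) hu$grid else hu
  if (!identical(dim(g), dim(h)))
    stop("label map and HU volume shapes differ", call. = FALSE)
  if (is.null(lung_codes))
    lung_codes <- intersect(c(1L, 2L), labels$class_codes)
  bad <- (g %in% lung_codes) & (h < range[1] | h > range[2])
  g[bad] <- 0L
  label_map(array(g, dim(g)), labels$class_codes, labels$voxel_size_um)
}

#' Assign each lung voxel to an aeration compartment
#'
#' Requires a cleaned segmentation: a lung voxel outside the densitometric
#' range is a contract violation and raises an error.
#'
#' @param labels A cleaned [label_map()].
#' @param hu An [hu_volume()] on the same grid.
#' @param thresholds Breakpoints from [compartment_thresholds()].
#' @param lung_codes Codes treated as lung.
#' @return Integer array: 0 outside the lungs, 1 hyper-inflated, 2
#'   normo-aerated, 3 hypo-aerated, 4 non-aerated.
#' @export
compartmentalize <- function(labels, hu, thresholds = compartment_thresholds(),
                             lung_codes = NULL) {
  if (length(thresholds) != 5L || any(diff(thresholds) <= 0))
    stop("need five strictly increasing breakpoints", call. = FALSE)
  g <- labels$grid
  h <- if (is.list(hu)) hu$grid else hu
  if (is.null(lung_codes))
    lung_codes <- intersect(c(1L, 2L), labels$class_codes)
  lung <- g %in% lung_codes
  vals <- h[lung]
  if (length(vals) && (min(vals) < thresholds[1] || max(vals) > thresholds[5]))
    stop("lung voxels outside the densitometric range: run clean_segmentation first",
         call. = FALSE)
  comp <- array(0L, dim(g))
  # half-open bins closed on the left; findInterval puts the top edge (+121)
  # into the last bin, closing it on both ends
  comp[lung] <- findInterval(vals, thresholds[1:4])
  comp
}

#' Whole-lung compartmental densitometry report
#'
#' Volumes are voxel counts times the voxel volume
#' `(voxel_size_um * 1e-3)^3` mm^3 (12.5e-5 mm^3 at 50 um).  For each
#' structure (left, right, total) the report carries the structure volume and
#' per-compartment volumes with percentages of the structure volume and of
#' the total lung volume.
#'
#' @param comp Compartment array from [compartmentalize()].
#' @param labels The [label_map()] the compartments were derived from.
#' @param voxel_size_um Isotropic voxel size in micrometres.
#' @param lung_codes Named integer codes of the per-side structures.
#' @return An object of class `densitometry_report`.
#' @export
densitometry_report <- function(comp, labels, voxel_size_um = labels$voxel_size_um,
                                lung_codes = c(left = 1L, right = 2L)) {
  if (voxel_size_um <= 0) stop("voxel_size_um must be positive", call. = FALSE)
  vox_mm3 <- (voxel_size_um * 1e-3)^3
  g <- labels$grid
  total_mask <- g %in% lung_codes
  total_n <- sum(total_mask)
  one <- function(mask) {
    n <- sum(mask)
    counts <- vapply(1:4, function(k) sum(comp[mask] == k), 0L)
    names(counts) <- .compartment_names
    comps <- lapply(.compartment_names, function(nm) {
      ct <- counts[[nm]]
      list(volume_mm3 = ct * vox_mm3,
           percent = if (n > 0) 100 * ct / n else NA_real_,
           percent_of_total = if (total_n > 0) 100 * ct / total_n else NA_real_)
    })
    names(comps) <- .compartment_names
    list(volume_mm3 = n * vox_mm3, n_voxels = n, compartments = comps)
  }
  structures <- list()
  for (nm in names(lung_codes)) structures[[nm]] <- one(g == lung_codes[[nm]])
  structures$total <- one(total_mask)
  structure(list(structures = structures, voxel_volume_mm3 = vox_mm3,
                 voxel_size_um = voxel_size_um,
                 empty = total_n == 0L),
            class = "densitometry_report")
}

#' @export
print.densitometry_report <- function(x, ...) {
  cat("<densitometry_report> voxel volume",
      format(x$voxel_volume_mm3, digits = 6), "mm^3\n")
  for (nm in names(x$structures)) {
    s <- x$structures[[nm]]
    cat(sprintf("  %-5s %10.3f mm^3 :", nm, s$volume_mm3))
    for (cn in .compartment_names)
      cat(sprintf(" %s %.1f%%", cn,
                  s$compartments[[cn]]$percent))
    cat("\n")
  }
  invisible(x)
}

#' Flatten a densitometry report to a data frame
#'
#' @param x A `densitometry_report`.
#' @param ... Unused.
#' @return Data frame with one row per structure x compartment.
#' @export
as.data.frame.densitometry_report <- function(x, ...) {
  rows <- list()
  for (nm in names(x$structures)) {
    s <- x$structures[[nm]]
    for (cn in .compartment_names) {
      cc <- s$compartments[[cn]]
      rows[[length(rows) + 1L]] <- data.frame(
        structure = nm, compartment = cn,
        structure_volume_mm3 = s$volume_mm3,
        volume_mm3 = cc$volume_mm3, percent = cc$percent,
        percent_of_total = cc$percent_of_total)
    }
  }
  do.call(rbind, rows)
}
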