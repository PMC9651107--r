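#' Linear grey-level to Hounsfield-unit transfer function
#'
#' @param slope HU per grey level; must be positive and finite.
#' @param intercept HU offset.
#' @return An object of class `transfer_function`.
#' @export
transfer_function <- function(slope, intercept) {
  if (!is.finite(slope) || !is.finite(intercept) || slope <= 0)
    stop("transfer function needs a finite positive slope", call. = FALSE)
  structure(list(slope = slope, intercept = intercept),
            class = "transfer_function")
}

#' @export
print.transfer_function <- function(x, ...) {
  cat(sprintf("<transfer_function> HU = %.6g * GL + %.6g\n", x$slope, x$intercept))
  invisible(x)
}

#' Mean grey level of one labelled structure
#'
#' @param v A [raw_volume()] (typically median-filtered).
#' @param labels A [label_map()] on the same grid.
#' @param class_code Integer code of the structure.
#' @param erode Non-negative integer: erode the mask by this many voxels
#'   before averaging, trimming boundary partial-volume voxels.  If erosion
#'   empties the mask the un-eroded mask is used instead.
#' @return Scalar mean grey level.
#' @export
region_mean <- function(v, labels, class_code, erode = 0L) {
  g <- if (is.list(v)) v$grid else v
  lg <- if (is.list(labels)) labels$grid else labels
  if (!identical(dim(g), dim(lg)))
    stop("volume and label map shapes differ", call. = FALSE)
  m <- lg == class_code
  if (!any(m)) stop("class ", class_code, " absent from label map", call. = FALSE)
  if (erode > 0L) {
    me <- .erode_box(m, as.integer(erode))
    if (any(me)) m <- me
  }
  mean(g[m])
}

#' Fit the grey-level to HU calibration line
#'
#' The calibration imposes that the mean grey level of the airway lumen maps
#' to -1000 HU (air) and the mean grey level of the heart maps to +50 HU
#' (blood/soft tissue), and takes the unique line through those two points.
#'
#' @param gl_air Mean airway grey level.
#' @param gl_heart Mean heart grey level; must exceed `gl_air`.
#' @param hu_air,hu_heart Anchor HU values.
#' @return A [transfer_function()].
#' @export
fit_transfer_function <- function(gl_air, gl_heart,
                                  hu_air = -1000, hu_heart = 50) {
  if (!is.finite(gl_air) || !is.finite(gl_heart) || gl_heart <= gl_air)
    .err("calibration failed: heart grey level must exceed airway grey level",
         "muridens_calibration_error")
  slope <- (hu_heart - hu_air) / (gl_heart - gl_air)
  transfer_function(slope, hu_air - slope * gl_air)
}

#' Apply a transfer function voxel-wise
#'
#' @param v A [raw_volume()] or 3-D array of grey levels.
#' @param tf A [transfer_function()].
#' @return An [hu_volume()] with the calibration recorded as provenance.
#' @export
apply_transfer <- function(v, tf) {
  stopifnot(inherits(tf, "transfer_function"))
  g <- if (is.list(v)) v$grid else v
  hu_volume(g * tf$slope + tf$intercept,
            voxel_size_um = if (is.list(v)) v$voxel_size_um else 50,
            transfer = tf)
}

#' Compare an automatic calibration against a manual reference
#'
#' Reports absolute percentage errors of the slope and intercept, and the
#' per-compartment absolute densitometry error (percentage points) obtained
#' by converting the same volume with both calibrations under the same lung
#' mask.
#'
#' @param auto_tf,manual_tf Two [transfer_function()]s.
#' @param v A [raw_volume()].
#' @param lung_truth A [label_map()]; codes 1 and 2 are taken as lung.
#' @return List with `slope_err_pct`, `intercept_err_pct` and
#'   `compartment_err_pp` (named vector, percentage points per compartment).
#' @export
evaluate_conversion <- function(auto_tf, manual_tf, v, lung_truth) {
  stopifnot(inherits(auto_tf, "transfer_function"),
            inherits(manual_tf, "transfer_function"))
  if (manual_tf$slope == 0 || manual_tf$intercept == 0)
    stop("manual transfer function has a zero parameter; percentage error undefined",
         call. = FALSE)
  pct <- function(a, m) abs(a - m) / abs(m) * 100
  frac <- function(tf) {
    hu <- apply_transfer(v, tf)
    lm2 <- relabel(lung_truth, c(left_lung = 1L, right_lung = 2L))
    cleaned <- clean_segmentation(lm2, hu)
    comp <- compartmentalize(cleaned, hu)
    rep_ <- densitometry_report(comp, cleaned, v$voxel_size_um)
    vapply(rep_$structures$total$compartments, function(cc) cc$percent, 0)
  }
  fa <- frac(auto_tf); fm <- frac(manual_tf)
  list(slope_err_pct = pct(auto_tf$slope, manual_tf$slope),
       intercept_err_pct = pct(auto_tf$intercept, manual_tf$intercept),
       compartment_err_pp = abs(fa - fm))
}
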