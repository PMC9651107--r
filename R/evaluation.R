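#' Dice similarity coefficient
#'
#' `DSC = 2|GT intersect Pred| / (|GT| + |Pred|)`.  Two empty masks are in
#' perfect agreement on absence, so their DSC is defined as 1.
#'
#' @param gt,pred [label_map()]s (with `class_code`) or logical arrays.
#' @param class_code Class compared when label maps are given.
#' @return Scalar in `[0, 1]`, symmetric in its two arguments.
#' @export
dice <- function(gt, pred, class_code = NULL) {
  mg <- .as_mask(gt, class_code)
  mp <- .as_mask(pred, class_code)
  if (!identical(dim(mg), dim(mp)))
    stop("mask shapes differ", call. = FALSE)
  dice_masks(mg, mp)
}

#' @rdname dice
#' @export
dice_masks <- function(gt, pred) {
  s <- sum(gt) + sum(pred)
  if (s == 0) return(1)
  2 * sum(gt & pred) / s
}

.as_mask <- function(x, class_code) {
  g <- if (inherits(x, "label_map")) x$grid else x
  if (is.logical(g)) return(g)
  if (is.null(class_code)) g != 0 else g == class_code
}

#' Absolute percent volume error
#'
#' `|V_pred - V_gt| / V_gt * 100`; the voxel volume cancels, so the result is
#' voxel-size invariant.
#'
#' @inheritParams dice
#' @return Non-negative scalar percentage.
#' @export
volume_percent_error <- function(gt, pred, class_code = NULL) {
  ng <- sum(.as_mask(gt, class_code))
  np <- sum(.as_mask(pred, class_code))
  if (ng == 0) stop("ground-truth mask is empty: volume error undefined",
                    call. = FALSE)
  abs(np - ng) / ng * 100
}

#' Per-compartment absolute percentage error between two reports
#'
#' For each structure and compartment, the absolute difference in percentage
#' points between the compartment share in the predicted and the
#' ground-truth report.  Set `signed = TRUE` to keep the sign (predicted
#' minus truth) as Bland-Altman input.
#'
#' @param report_gt,report_pred Two [densitometry_report()]s.
#' @param structure Structure to compare (`"total"`, `"left"`, `"right"`).
#' @param signed Keep signs instead of absolute values.
#' @return Named numeric vector over compartments (percentage points).
#' @export
compartment_percent_error <- function(report_gt, report_pred,
                                      structure = "total", signed = FALSE) {
  sg <- report_gt$structures[[structure]]
  sp <- report_pred$structures[[structure]]
  if (is.null(sg) || is.null(sp))
    stop("structure ", structure, " missing from a report", call. = FALSE)
  out <- vapply(.compartment_names, function(cn) {
    a <- sp$compartments[[cn]]$percent
    b <- sg$compartments[[cn]]$percent
    if (is.null(a) || is.null(b))
      stop("compartment ", cn, " missing from a report", call. = FALSE)
    a - b
  }, 0)
  if (signed) out else abs(out)
}

#' Bland-Altman agreement statistics
#'
#' @param pairs Two-column matrix or data frame of (manual, automatic)
#'   measurements, or a list of length-2 vectors.
#' @return List with `bias` (mean automatic - manual difference), `sd_diff`,
#'   and the 95 percent limits of agreement `loa = bias +/- 1.96 sd`.
#' @export
bland_altman <- function(pairs) {
  if (is.list(pairs) && !is.data.frame(pairs))
    pairs <- do.call(rbind, lapply(pairs, function(p) c(p[1], p[2])))
  pairs <- as.matrix(pairs)
  if (nrow(pairs) < 2L)
    stop("Bland-Altman needs at least 2 pairs", call. = FALSE)
  d <- pairs[, 2] - pairs[, 1]
  bias <- mean(d)
  s <- sd(d)
  list(bias = bias, sd_diff = s,
       loa = c(lower = bias - 1.96 * s, upper = bias + 1.96 * s),
       mean = rowMeans(pairs), diff = d)
}

#' Coefficient of determination of the least-squares trend line
#'
#' @param x,y Numeric vectors (at least 3 points; `x` must vary).
#' @return Scalar R-squared.
#' @export
r_squared <- function(x, y) {
  if (length(x) < 3L || length(x) != length(y))
    stop("need at least 3 paired points", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance: R-squared undefined", call. = FALSE)
  suppressWarnings(summary(lm(y ~ x))$r.squared)
}

#' Grouped k-fold assignment at the mouse level
#'
#' All scans of one mouse share a fold, so longitudinal scans never leak
#' between training and evaluation; fold sizes differ by at most one mouse.
#'
#' @param mouse_ids Character vector, one entry per sample.
#' @param k Number of folds (default 5); at most the number of mice.
#' @param seed Integer seed for the mouse shuffle.
#' @return List with `fold` (integer per sample) and `mouse_fold` (named
#'   integer per mouse).
#' @export
grouped_kfold <- function(mouse_ids, k = 5L, seed = 1L) {
  mice <- unique(mouse_ids)
  if (k > length(mice))
    stop("k exceeds the number of mice", call. = FALSE)
  perm <- withr::with_seed(as.integer(seed), sample(mice))
  mouse_fold <- structure(rep(seq_len(k), length.out = length(mice)),
                          names = perm)
  mouse_fold <- mouse_fold[mice]
  list(fold = unname(mouse_fold[mouse_ids]), mouse_fold = mouse_fold)
}

#' Evaluate a cohort of predictions against ground truth
#'
#' Builds one record per sample (per-class DSC, absolute percent volume
#' error, per-compartment absolute percentage error) plus mean/sd/median
#' summaries stratified by timepoint and phase.
#'
#' @param truths List of [label_map()]s (left/right coding).
#' @param preds List of predicted [label_map()]s.
#' @param reports_gt,reports_pred Optional lists of
#'   [densitometry_report()]s for the compartment errors.
#' @param meta Optional data frame with columns `sample`, `timepoint`,
#'   `phase` (recycled defaults otherwise).
#' @return List with `records` and `summary` data frames; failed samples are
#'   recorded with `ok = FALSE`, never silently dropped.
#' @export
evaluate_cohort <- function(truths, preds, reports_gt = NULL,
                            reports_pred = NULL, meta = NULL) {
  n <- length(truths)
  if (length(preds) != n) stop("truths and preds differ in length", call. = FALSE)
  if (is.null(meta))
    meta <- data.frame(sample = sprintf("S%03d", seq_len(n)),
                       timepoint = 1L, phase = "P02")
  rows <- list()
  for (i in seq_len(n)) {
    rec <- data.frame(sample = meta$sample[i], timepoint = meta$timepoint[i],
                      phase = meta$phase[i], ok = TRUE,
                      dsc_left = NA_real_, dsc_right = NA_real_,
                      dsc_both = NA_real_, vol_err_pct = NA_real_,
                      hyper_err = NA_real_, normo_err = NA_real_,
                      hypo_err = NA_real_, non_err = NA_real_)
    if (is.null(preds[[i]])) {
      rec$ok <- FALSE
    } else {
      gt <- truths[[i]]; pr <- preds[[i]]
      rec$dsc_left <- dice(gt, pr, 1L)
      rec$dsc_right <- dice(gt, pr, 2L)
      both_gt <- gt$grid %in% c(1L, 2L); both_pr <- pr$grid %in% c(1L, 2L)
      rec$dsc_both <- dice_masks(both_gt, both_pr)
      rec$vol_err_pct <- abs(sum(both_pr) - sum(both_gt)) / sum(both_gt) * 100
      if (!is.null(reports_gt) && !is.null(reports_pred) &&
          !is.null(reports_pred[[i]])) {
        ce <- compartment_percent_error(reports_gt[[i]], reports_pred[[i]])
        rec$hyper_err <- ce[["hyper"]]; rec$normo_err <- ce[["normo"]]
        rec$hypo_err <- ce[["hypo"]]; rec$non_err <- ce[["non"]]
      }
    }
    rows[[i]] <- rec
  }
  records <- do.call(rbind, rows)
  num_cols <- setdiff(names(records), c("sample", "timepoint", "phase", "ok"))
  strata <- split(records, interaction(records$timepoint, records$phase,
                                       drop = TRUE))
  summary <- do.call(rbind, lapply(strata, function(df) {
    out <- data.frame(timepoint = df$timepoint[1], phase = df$phase[1],
                      n = nrow(df), n_failed = sum(!df$ok))
    for (cl in num_cols) {
      v <- df[[cl]][df$ok]
      out[[paste0(cl, "_mean")]] <- mean(v, na.rm = TRUE)
      out[[paste0(cl, "_sd")]] <- sd(v, na.rm = TRUE)
      out[[paste0(cl, "_median")]] <- stats::median(v, na.rm = TRUE)
    }
    out
  }))
  rownames(summary) <- NULL
  list(records = records, summary = summary)
}
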