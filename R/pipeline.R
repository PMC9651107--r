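# End-to-end orchestration: median filter -> coarse localization -> HU
# calibration -> bounding-box crop -> three single-view predictions ->
# majority vote -> HU-range cleaning -> compartmental densitometry.

.err <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "muridens_error")))
}

# High-confidence heart/airway masks for HU calibration; falls back to the
# binarized class masks when the confidence cut empties a structure.
.calibration_masks <- function(pm, coarse_full, confidence, full_dim, factor) {
  heart <- pm$maps$heart > confidence
  airways <- pm$maps$airways > confidence
  g <- array(0L, dim(heart))
  g[heart] <- 2L
  g[airways] <- 3L
  out <- upsample_nearest(label_map(g, muridens_classes("coarse")),
                          factor, "yx", target_dim = full_dim)
  for (code in c(2L, 3L)) {
    if (!any(out$grid == code))
      out$grid[coarse_full$grid == code] <- code
  }
  out
}

#' Pipeline configuration
#'
#' Bundles the trained models and the numeric parameters of every stage.
#' Defaults are the reference operating points: in-plane coarse down-sampling
#' factor 4, isotropic fine factor 2, 5x5x5 median kernel, 384x320x384 crop,
#' coarse thresholds 0.45 per class, cleaning range `[-1040, +121]` HU.
#'
#' @param coarse_backend Trained coarse backend.
#' @param view_models A [view_model_set()] at the left/right stage.
#' @param coarse_thresholds Per-class coarse binarization thresholds
#'   (lung, heart, airways).
#' @param coarse_factor,fine_factor Down-sampling factors.
#' @param median_kernel Median pre-filter kernel (odd).
#' @param crop_extent Bounding-box extent (z, y, x).
#' @param clean_range Closed HU range retained by the cleaning step.
#' @param compartments Breakpoints from [compartment_thresholds()].
#' @param calibration_erode Voxels of erosion applied to the heart/airway
#'   masks before grey-level averaging (reduces boundary partial-volume
#'   bias); 0 disables.
#' @param calibration_confidence Minimum class probability for a voxel to
#'   enter a calibration mask.  The calibration only needs a representative
#'   core sample of each reference structure, and the high-confidence core
#'   excludes boundary and carina false positives that bias the means; set
#'   to 0 to calibrate on the full binarized masks.
#' @param seed Seed recorded in the provenance block.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(coarse_backend, view_models,
                            coarse_thresholds = c(lung = 0.45, heart = 0.45,
                                                  airways = 0.45),
                            coarse_factor = 4L, fine_factor = 2L,
                            median_kernel = 5L,
                            crop_extent = c(384L, 320L, 384L),
                            clean_range = c(-1040, 121),
                            compartments = compartment_thresholds(),
                            calibration_erode = 1L,
                            calibration_confidence = 0.9, seed = 1L) {
  stopifnot(inherits(view_models, "view_model_set"))
  if (view_models$stage != "lr")
    stop("view_models must be at the left/right stage", call. = FALSE)
  if (coarse_factor < 1 || fine_factor < 1)
    stop("down-sampling factors must be >= 1", call. = FALSE)
  structure(list(coarse_backend = coarse_backend, view_models = view_models,
                 coarse_thresholds = coarse_thresholds,
                 coarse_factor = as.integer(coarse_factor),
                 fine_factor = as.integer(fine_factor),
                 median_kernel = as.integer(median_kernel),
                 crop_extent = as.integer(crop_extent),
                 clean_range = clean_range, compartments = compartments,
                 calibration_erode = as.integer(calibration_erode),
                 calibration_confidence = calibration_confidence,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full segmentation and densitometry pipeline on one scan
#'
#' @param raw A [raw_volume()] in detector grey levels.
#' @param cfg A [pipeline_config()].
#' @param keep_intermediates Keep per-stage artifacts (coarse labels, crop,
#'   per-view maps) in the result.
#' @return List with `labels` (left/right [label_map()] on the crop grid),
#'   `labels_full` (pasted back into the full grid), `hu` ([hu_volume()]),
#'   `tf` ([transfer_function()]), `box`, `report`
#'   ([densitometry_report()]), `provenance` and `stages` (per-stage voxel
#'   summaries).
#' @export
run_pipeline <- function(raw, cfg, keep_intermediates = FALSE) {
  stopifnot(inherits(raw, "raw_volume"), inherits(cfg, "pipeline_config"))
  stages <- list()
  note <- function(name, ...) stages[[name]] <<- list(...)

  filtered <- median_filter_3d(raw, cfg$median_kernel)
  note("median_filter", kernel = cfg$median_kernel)

  pm <- predict_coarse(cfg$coarse_backend, filtered, cfg$coarse_factor)
  coarse_lab <- binarize(pm, cfg$coarse_thresholds, raw$voxel_size_um)
  coarse_full <- upsample_nearest(coarse_lab, cfg$coarse_factor, "yx",
                                  target_dim = dim(raw$grid))
  note("coarse", lung_voxels = sum(coarse_full$grid == 1L),
       heart_voxels = sum(coarse_full$grid == 2L),
       airway_voxels = sum(coarse_full$grid == 3L))
  if (!any(coarse_full$grid == 1L))
    .err("coarse localization found no lung voxels", "muridens_localization_error")
  if (!any(coarse_full$grid == 2L) || !any(coarse_full$grid == 3L))
    .err("coarse localization missed heart or airways; cannot calibrate",
         "muridens_calibration_error")

  calib <- .calibration_masks(pm, coarse_full, cfg$calibration_confidence,
                              dim(raw$grid), cfg$coarse_factor)
  gl_air <- region_mean(filtered, calib, 3L, cfg$calibration_erode)
  gl_heart <- region_mean(filtered, calib, 2L, cfg$calibration_erode)
  tf <- fit_transfer_function(gl_air, gl_heart)
  hu <- apply_transfer(filtered, tf)
  note("hu_conversion", gl_air = gl_air, gl_heart = gl_heart,
       slope = tf$slope, intercept = tf$intercept)

  box <- compute_bounding_box(coarse_full, cfg$crop_extent, lung_codes = 1L)
  hu_crop <- crop(hu, box)
  hu_ds <- downsample(hu_crop, cfg$fine_factor, "intensity", "all")
  note("crop", origin = box$origin, extent = box$extent)

  vm <- cfg$view_models
  views <- c("axial", "sagittal", "coronal")
  probs <- lapply(views, function(vw) predict_view(vm[[vw]], hu_ds, vw))
  names(probs) <- views
  labs <- lapply(views, function(vw)
    binarize_view(probs[[vw]], vm$thresholds[[vw]], raw$voxel_size_um))
  names(labs) <- views
  fused <- majority_vote(labs$axial, labs$sagittal, labs$coronal, probs)
  note("multi_view", left_voxels = sum(fused$grid == 1L),
       right_voxels = sum(fused$grid == 2L))

  fused_full <- upsample_nearest(fused, cfg$fine_factor, "all",
                                 target_dim = cfg$crop_extent)
  before <- sum(fused_full$grid %in% c(1L, 2L))
  cleaned <- clean_segmentation(fused_full, hu_crop, cfg$clean_range)
  after <- sum(cleaned$grid %in% c(1L, 2L))
  note("clean", removed_voxels = before - after,
       removed_pct = if (before > 0) 100 * (before - after) / before else 0)

  comp <- compartmentalize(cleaned, hu_crop, cfg$compartments)
  report <- densitometry_report(comp, cleaned, raw$voxel_size_um)

  labels_full <- uncrop(label_map(array(0L, dim(raw$grid)),
                                  cleaned$class_codes, raw$voxel_size_um),
                        cleaned, box)
  out <- list(labels = cleaned, labels_full = labels_full, hu = hu, tf = tf,
              box = box, report = report, stages = stages,
              provenance = list(
                config_hash = rlang::hash(cfg[setdiff(names(cfg),
                                                      c("coarse_backend",
                                                        "view_models"))]),
                coarse_encoder = if (inherits(cfg$coarse_backend, "mlp_backend"))
                  encoder_digest(cfg$coarse_backend) else cfg$coarse_backend$type,
                seed = cfg$seed, phase = raw$phase))
  if (keep_intermediates) {
    out$coarse_labels <- coarse_full
    out$hu_crop <- hu_crop
    out$view_probs <- probs
    out$view_labels <- labs
  }
  out
}

#' Run the pipeline over a batch of scans
#'
#' Per-sample failures are isolated in a manifest and do not stop the batch.
#'
#' @param x Directory of volume files (`.nii`, `.nii.gz`, `.tif`) or a list
#'   of [raw_volume()]s / `phantom_sample`s.
#' @param cfg A [pipeline_config()].
#' @param out_dir Optional directory for per-sample report JSON and the
#'   aggregate CSV.
#' @return List with `results` (per-sample pipeline outputs or NULL),
#'   `manifest` (data frame with per-sample status) and `table` (aggregate
#'   densitometry data frame).
#' @export
run_batch <- function(x, cfg, out_dir = NULL) {
  if (is.character(x)) {
    files <- list.files(x, pattern = "\\.(nii(\\.gz)?|tiff?)$",
                        full.names = TRUE)
    names(files) <- basename(files)
    loader <- function(f) read_volume(f)
    items <- files
  } else {
    items <- x
    if (is.null(names(items)))
      names(items) <- sprintf("S%03d", seq_along(items))
    loader <- function(s) if (inherits(s, "phantom_sample")) s$raw else s
  }
  results <- vector("list", length(items)); names(results) <- names(items)
  manifest <- data.frame(sample = names(items), ok = FALSE, error = "")
  tables <- list()
  for (i in seq_along(items)) {
    res <- tryCatch({
      rv <- loader(items[[i]])
      run_pipeline(rv, cfg)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      manifest$error[i] <- conditionMessage(res)
    } else {
      manifest$ok[i] <- TRUE
      results[[i]] <- res
      tb <- as.data.frame(res$report)
      tb <- cbind(sample = names(items)[i], tb)
      tables[[length(tables) + 1L]] <- tb
      if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        jsonlite::write_json(report_to_list(res$report),
                             file.path(out_dir, paste0(names(items)[i],
                                                       "_report.json")),
                             auto_unbox = TRUE, digits = NA)
      }
    }
  }
  table <- if (length(tables)) do.call(rbind, tables) else NULL
  if (!is.null(out_dir) && !is.null(table))
    write.csv(table, file.path(out_dir, "densitometry.csv"), row.names = FALSE)
  list(results = results, manifest = manifest, table = table)
}

#' Serializable form of a densitometry report
#'
#' @param report A [densitometry_report()].
#' @return Nested list mirroring the JSON schema
#'   `{structure: {volume_mm3, compartments: {name: {volume_mm3, percent}}}}`.
#' @export
report_to_list <- function(report) {
  lapply(report$structures, function(s)
    list(volume_mm3 = s$volume_mm3,
         compartments = lapply(s$compartments, function(cc)
           list(volume_mm3 = cc$volume_mm3, percent = cc$percent,
                percent_of_total = cc$percent_of_total))))
}
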