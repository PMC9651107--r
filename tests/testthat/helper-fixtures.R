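# Shared fixtures.  Everything is generated in code; the expensive trained
# fixture (cohorts + coarse model + six single-view models + end-to-end runs)
# is built once per test run and reused across files.

fixture_cache <- new.env(parent = emptyenv())

memoise_fixture <- function(key, build) {
  if (is.null(fixture_cache[[key]])) fixture_cache[[key]] <- build()
  fixture_cache[[key]]
}

# a small deterministic phantom for cheap unit tests
small_phantom <- function(seed = 7L, noise_sd = 20, severity = 0,
                          shape = c(64L, 64L, 64L), phase = "P02") {
  key <- paste("ph", seed, noise_sd, severity, paste(shape, collapse = "x"),
               phase, sep = "_")
  memoise_fixture(key, function()
    generate_phantom(phantom_spec(shape = shape, noise_sd = noise_sd,
                                  fibrosis_severity = severity,
                                  phase = phase, seed = seed)))
}

# scaled-down study conditions: 64^3 phantoms, mild-to-moderate fibrosis,
# grey-level noise sd 20; 16 training / 4 validation / 6 held-out scans.
# The training recipe (lr 3e-3, max 300 epochs) is the scaled-down recipe
# described in the methods vignette; the coarse stage runs at in-plane
# factor 2 so 64^2 slices become 32^2.
fixture_extent <- c(48L, 40L, 48L)

fixture_coarse_cfg <- function(seed = 42L)
  training_config(learning_rate = 3e-3, batch_slices = 24L,
                  pixels_per_slice = 200L, slice_stride = 2L,
                  max_epochs = 300L, seed = seed)

fixture_fine_cfg <- function(seed = 43L)
  training_config(learning_rate = 3e-3, batch_slices = 4L,
                  pixels_per_slice = 150L, max_epochs = 300L, seed = seed)

prepare_fine_truth <- function(sample, filtered, extent = fixture_extent) {
  box <- compute_bounding_box(sample$truth_labels, extent,
                              lung_codes = c(1L, 2L))
  hu <- apply_transfer(filtered, phantom_truth_transfer(sample$spec))
  c(prepare_fine_input(hu, sample$truth_labels, box, 2L), list(box = box))
}

truth_densitometry <- function(sample) {
  tl <- relabel(sample$truth_labels, c(left_lung = 1L, right_lung = 2L))
  tcl <- clean_segmentation(tl, sample$truth_hu)
  comp <- compartmentalize(tcl, sample$truth_hu)
  densitometry_report(comp, tcl, sample$spec$voxel_size_um)
}

trained_fixture <- function() memoise_fixture("trained", function() {
  train <- generate_cohort(8, c(0, 0.6), base_seed = 101L, timepoints = 2L)
  val <- generate_cohort(2, c(0, 0.6), base_seed = 202L, timepoints = 2L)
  test <- generate_cohort(3, c(0, 0.6), base_seed = 303L, timepoints = 2L)
  filt <- function(ss) lapply(ss, function(s) median_filter_3d(s$raw))
  filt_tr <- filt(train); filt_va <- filt(val); filt_te <- filt(test)
  mk <- function(ss, ff) Map(function(s, f)
    list(volume = f, labels = s$truth_labels), ss, ff)

  cb <- train_coarse(mk(train, filt_tr), mk(val, filt_va),
                     fixture_coarse_cfg(), factor = 2L)

  trP <- Map(prepare_fine_truth, train, filt_tr)
  vaP <- Map(prepare_fine_truth, val, filt_va)
  teP <- Map(prepare_fine_truth, test, filt_te)
  joint <- list(); lr <- list()
  for (vw in c("axial", "sagittal", "coronal")) {
    joint[[vw]] <- train_view_joint(trP, vaP, vw, fixture_fine_cfg())
    lr[[vw]] <- transfer_learn_left_right(joint[[vw]], trP, vaP, vw,
                                          fixture_fine_cfg())
  }
  vm <- view_model_set(lr$axial, lr$sagittal, lr$coronal, "lr")
  cfg <- pipeline_config(cb, vm, coarse_factor = 2L,
                         crop_extent = fixture_extent)
  runs <- lapply(test, function(s) run_pipeline(s$raw, cfg))
  list(train = train, val = val, test = test,
       filt_te = filt_te, trP = trP, vaP = vaP, teP = teP,
       cb = cb, joint = joint, lr = lr, vm = vm, cfg = cfg, runs = runs)
})

# brute-force per-voxel majority voter used as the oracle for the fused
# aggregation; enumerates the rule independently of the implementation
brute_force_vote <- function(a, s, co, probs = NULL, classes) {
  out <- array(0L, dim(a))
  for (i in seq_along(a)) {
    votes <- c(a[i], s[i], co[i])
    tab <- table(votes)
    if (max(tab) >= 2) {
      out[i] <- as.integer(names(tab)[which.max(tab)])
    } else if (!is.null(probs)) {
      mp <- vapply(seq_along(classes), function(k) {
        cn <- names(classes)[k]
        (probs$axial$maps[[cn]][i] + probs$sagittal$maps[[cn]][i] +
           probs$coronal$maps[[cn]][i]) / 3
      }, 0)
      ord <- order(as.integer(classes))
      out[i] <- as.integer(classes)[ord][which.max(mp[ord])]
    }
  }
  out
}
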