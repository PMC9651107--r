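# Synthetic murine-thorax phantoms.
#
# Geometry: a superellipsoid thorax with a thin high-density (rib-like) shell,
# two ellipsoidal lungs left and right of the midline, an ellipsoidal heart on
# the midline, and a three-generation cylindrical airway tree entering at the
# cranial face.  Fibrotic involvement is modelled as Gaussian lesion blobs
# seeded preferentially subpleurally: compartment quotas are drawn from the
# aeration mixture and placed by ranking lung voxels on the lesion field, so
# that denser compartments form spatially coherent, severity-nested lesions
# while the marginal compartment fractions follow the mixture.
#
# Intensities are raw detector grey levels.  The ground-truth grey-level to HU
# relation is the exact line through (airway mean, -1000) and (heart mean,
# +50), so the automatic calibration has an exact oracle.

#' Specification of a synthetic thorax phantom
#'
#' @param shape Integer 3-vector (z, y, x); each dimension at least 32.
#' @param voxel_size_um Isotropic voxel edge, micrometres.
#' @param airway_gl_mean Mean raw grey level of the airway lumen.
#' @param heart_gl_mean Mean raw grey level of the heart.
#' @param soft_tissue_gl_mean Mean raw grey level of non-lung soft tissue.
#' @param lung_aeration_profile Baseline mixture weights over the four
#'   aeration compartments, ordered (hyper-inflated, normo-aerated,
#'   hypo-aerated, non-aerated); non-negative, summing to 1.
#' @param fibrosis_severity Scalar in `[0, 1]`; 0 leaves the baseline profile,
#'   1 moves it fully to the internal fibrotic profile (weight shifted from
#'   normo-/hyper- toward hypo-/non-aerated).
#' @param noise_sd Standard deviation of additive Gaussian grey-level noise.
#' @param phase Breathing phase of the generated scan.
#' @param seed Integer seed controlling anatomy and lesion placement.
#' @param noise_seed Integer seed controlling noise and per-voxel compartment
#'   texture; defaults to `seed`.  Separating the two lets a cohort share
#'   anatomy across timepoints while varying acquisition noise.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64L, 64L, 64L), voxel_size_um = 50,
                         airway_gl_mean = 801.8, heart_gl_mean = 2250.19,
                         soft_tissue_gl_mean = 2200,
                         lung_aeration_profile = c(hyper = 0.20, normo = 0.70,
                                                   hypo = 0.08, non = 0.02),
                         fibrosis_severity = 0, noise_sd = 20,
                         phase = c("P02", "P01"), seed = 1L,
                         noise_seed = seed) {
  phase <- match.arg(phase)
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 32L))
    stop("shape must be three integers, each >= 32", call. = FALSE)
  w <- as.numeric(lung_aeration_profile)
  if (length(w) != 4L || any(w < 0) || abs(sum(w) - 1) > 1e-9)
    stop("lung_aeration_profile must be 4 non-negative weights summing to 1",
         call. = FALSE)
  names(w) <- c("hyper", "normo", "hypo", "non")
  if (fibrosis_severity < 0 || fibrosis_severity > 1)
    stop("fibrosis_severity must lie in [0, 1]", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  if (heart_gl_mean <= airway_gl_mean)
    stop("heart_gl_mean must exceed airway_gl_mean", call. = FALSE)
  structure(list(shape = shape, voxel_size_um = voxel_size_um,
                 airway_gl_mean = airway_gl_mean, heart_gl_mean = heart_gl_mean,
                 soft_tissue_gl_mean = soft_tissue_gl_mean,
                 lung_aeration_profile = w,
                 fibrosis_severity = fibrosis_severity, noise_sd = noise_sd,
                 phase = phase, seed = as.integer(seed),
                 noise_seed = as.integer(noise_seed)),
            class = "phantom_spec")
}

# mixture weights after applying fibrotic involvement
.severity_profile <- function(base, severity) {
  fibrotic <- c(hyper = 0.02, normo = 0.28, hypo = 0.35, non = 0.35)
  w <- (1 - severity) * base + severity * fibrotic
  w / sum(w)
}

#' Ground-truth grey-level to HU transfer function of a phantom
#'
#' The exact line through (airway mean, -1000 HU) and (heart mean, +50 HU).
#'
#' @param spec A [phantom_spec()].
#' @return A [transfer_function()].
#' @export
phantom_truth_transfer <- function(spec) {
  fit_transfer_function(spec$airway_gl_mean, spec$heart_gl_mean)
}

#' Generate a synthetic thorax phantom
#'
#' Deterministic for a fixed spec (including its seeds).  The returned sample
#' bundles the raw grey-level volume, the ground-truth label map (left lung,
#' right lung, heart, airways) and the ground-truth HU volume obtained by the
#' exact calibration line.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom_sample` with elements `raw`,
#'   `truth_labels`, `truth_hu`, `spec` and `meta`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  geo <- withr::with_seed(spec$seed, .phantom_geometry(spec$shape))
  tf <- phantom_truth_transfer(spec)
  dm <- spec$shape
  grid <- array(spec$airway_gl_mean, dm)          # air outside the body
  grid[geo$body] <- spec$soft_tissue_gl_mean
  grid[geo$shell] <- spec$soft_tissue_gl_mean + 1100   # rib/spine shell
  grid[geo$heart] <- spec$heart_gl_mean
  grid[geo$airways] <- spec$airway_gl_mean

  lung_mask <- geo$left | geo$right
  n_lung <- sum(lung_mask)
  w <- .severity_profile(spec$lung_aeration_profile, spec$fibrosis_severity)
  grid <- withr::with_seed(spec$noise_seed, {
    comp <- .assign_compartments(lung_mask, geo$lesion_field, n_lung, w)
    hu_draw <- .draw_compartment_hu(comp)
    gl_lung <- (hu_draw - tf$intercept) / tf$slope
    grid[lung_mask] <- gl_lung
    if (spec$noise_sd > 0)
      grid <- grid + array(rnorm(prod(dm), 0, spec$noise_sd), dm)
    grid
  })
  grid[grid < 0] <- 0

  lab <- array(0L, dm)
  lab[geo$left] <- 1L; lab[geo$right] <- 2L
  lab[geo$heart] <- 3L; lab[geo$airways] <- 4L

  raw <- raw_volume(grid, spec$voxel_size_um, spec$phase)
  structure(list(
    raw = raw,
    truth_labels = label_map(lab, muridens_classes("fine"), spec$voxel_size_um),
    truth_hu = apply_transfer(raw, tf),
    spec = spec,
    meta = list(mouse_id = NA_character_, timepoint = NA_integer_,
                severity = spec$fibrosis_severity)),
    class = "phantom_sample")
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("<phantom_sample> %s, severity %.2f, phase %s, seed %d\n",
              paste(x$spec$shape, collapse = "x"), x$spec$fibrosis_severity,
              x$spec$phase, x$spec$seed))
  invisible(x)
}

# ---- geometry --------------------------------------------------------------

.coord_arrays <- function(dm) {
  zt <- (seq_len(dm[1]) - 0.5) / dm[1]
  yt <- (seq_len(dm[2]) - 0.5) / dm[2]
  xt <- (seq_len(dm[3]) - 0.5) / dm[3]
  list(z = array(zt, dm),
       y = array(rep(yt, each = dm[1]), dm),
       x = array(rep(xt, each = dm[1] * dm[2]), dm))
}

.phantom_geometry <- function(dm) {
  cc <- .coord_arrays(dm)
  Z <- cc$z; Y <- cc$y; X <- cc$x

  s <- 0.80 + 0.20 * sin(pi * Z)            # cranio-caudal taper
  q <- (abs(Y - 0.5) / (0.40 * s))^2.5 + (abs(X - 0.5) / (0.45 * s))^2.5
  body <- q <= 1
  shell <- q > 0.86 & q <= 1
  interior <- q <= 0.86

  ell <- function(c0, r0) ((Z - c0[1]) / r0[1])^2 +
    ((Y - c0[2]) / r0[2])^2 + ((X - c0[3]) / r0[3])^2

  heart_q <- ell(c(0.58, 0.52, 0.50), c(0.17, 0.14, 0.13))
  heart <- heart_q <= 1 & interior
  left_q  <- ell(c(0.47, 0.50, 0.30), c(0.27, 0.24, 0.15))
  right_q <- ell(c(0.47, 0.50, 0.70), c(0.29, 0.26, 0.16))

  # airway tree: trachea + two bronchi + four generation-3 branches
  vox <- function(p) p * dm                  # normalised -> voxel units
  Zv <- Z * dm[1]; Yv <- Y * dm[2]; Xv <- X * dm[3]
  n0 <- min(dm)
  seg <- function(a, b, r) .capsule(Zv, Yv, Xv, vox(a), vox(b), r * n0)
  # radii keep the trachea lumen wider than the 5-voxel median pre-filter at
  # the >= 64^3 grids the phantom is used at, as in real scans where the
  # trachea spans an order of magnitude more voxels than the filter kernel
  airways <- seg(c(0.00, 0.50, 0.50), c(0.42, 0.50, 0.50), 0.055) |
    seg(c(0.42, 0.50, 0.50), c(0.54, 0.50, 0.34), 0.036) |
    seg(c(0.42, 0.50, 0.50), c(0.54, 0.50, 0.66), 0.036) |
    seg(c(0.54, 0.50, 0.34), c(0.64, 0.42, 0.28), 0.022) |
    seg(c(0.54, 0.50, 0.34), c(0.64, 0.58, 0.28), 0.022) |
    seg(c(0.54, 0.50, 0.66), c(0.64, 0.42, 0.74), 0.022) |
    seg(c(0.54, 0.50, 0.66), c(0.64, 0.58, 0.74), 0.022)
  airways <- airways & body

  carve <- .dilate_box(heart, 2L) | .dilate_box(airways, 1L) | shell
  left  <- left_q  <= 1 & interior & !carve
  right <- right_q <= 1 & interior & !carve
  heart <- heart & !airways

  lung_mask <- left | right
  lesion_field <- .lesion_field(dm, lung_mask,
                                list(left_q = left_q, right_q = right_q))
  list(body = body, shell = shell, interior = interior, heart = heart,
       left = left, right = right, airways = airways,
       lesion_field = lesion_field)
}

# distance-to-segment capsule in voxel units
.capsule <- function(Zv, Yv, Xv, a, b, r) {
  ab <- b - a
  len2 <- sum(ab^2)
  t <- ((Zv - a[1]) * ab[1] + (Yv - a[2]) * ab[2] + (Xv - a[3]) * ab[3]) / len2
  t[t < 0] <- 0; t[t > 1] <- 1
  d2 <- (Zv - a[1] - t * ab[1])^2 + (Yv - a[2] - t * ab[2])^2 +
    (Xv - a[3] - t * ab[3])^2
  d2 <= r^2
}

# Gaussian lesion blobs seeded preferentially subpleurally (outer shell of the
# lung ellipsoids); consumes the anatomy RNG stream
.lesion_field <- function(dm, lung_mask, qforms, n_blobs = 5L) {
  field <- array(0, dm)
  idx <- which(lung_mask)
  if (!length(idx)) return(field)
  zyx <- arrayInd(idx, dm)
  sigma <- 0.07 * min(dm)
  for (side in c("left_q", "right_q")) {
    q <- qforms[[side]][idx]
    subpleural <- which(q >= 0.40 & q <= 1)
    if (!length(subpleural)) subpleural <- seq_along(idx)
    centers <- sample(subpleural, n_blobs, replace = length(subpleural) < n_blobs)
    for (ci in centers) {
      c0 <- zyx[ci, ]
      d2 <- (zyx[, 1] - c0[1])^2 + (zyx[, 2] - c0[2])^2 + (zyx[, 3] - c0[3])^2
      field[idx] <- field[idx] + exp(-d2 / (2 * sigma^2))
    }
  }
  field
}

# ---- compartments ----------------------------------------------------------

# Draw compartment quotas from the mixture, then place them by lesion-field
# rank: densest compartments claim the most lesion-laden voxels.  Returns an
# integer vector over lung voxels: 1 hyper, 2 normo, 3 hypo, 4 non.
.assign_compartments <- function(lung_mask, lesion_field, n_lung, w) {
  counts <- as.integer(rmultinom(1, n_lung, w))
  jitter <- runif(n_lung, 0, 1e-3)
  rank_order <- order(lesion_field[lung_mask] + jitter, decreasing = TRUE)
  comp <- integer(n_lung)
  pos <- 1L
  for (k in c(4L, 3L, 2L, 1L)) {             # non, hypo, normo, hyper
    if (counts[k] > 0L) {
      comp[rank_order[pos:(pos + counts[k] - 1L)]] <- k
      pos <- pos + counts[k]
    }
  }
  comp
}

.draw_compartment_hu <- function(comp) {
  br <- compartment_thresholds()
  lo <- br[comp]; hi <- br[comp + 1L]
  runif(length(comp), lo, hi)
}

# ---- phase variant ---------------------------------------------------------

#' Derive the end-inspiration variant of an end-expiration phantom
#'
#' End-inspiration lungs are darker (more air) and stretched caudally.  The
#' lung masks are dilated toward larger z into available soft tissue, the
#' newly claimed voxels inherit lung-like grey levels, and all lung grey
#' levels are compressed 15 percent toward the air value.  Heart, airway and
#' shell intensities are untouched.
#'
#' @param s A `phantom_sample` with phase `"P02"`.
#' @param phase Target phase; only `"P01"` is meaningful.
#' @return A new `phantom_sample` tagged `"P01"`.
#' @export
phase_variant <- function(s, phase = "P01") {
  stopifnot(inherits(s, "phantom_sample"))
  if (!identical(phase, "P01"))
    stop("only the P01 (end-inspiration) variant is defined", call. = FALSE)
  if (s$spec$phase != "P02")
    stop("sample is already end-inspiration (P01)", call. = FALSE)
  dm <- s$spec$shape
  lab <- s$truth_labels$grid
  grid <- s$raw$grid
  k <- max(1L, round(0.06 * dm[1]))
  geo <- withr::with_seed(s$spec$seed, .phantom_geometry(dm))
  blocked <- lab == 3L | lab == 4L | geo$shell
  body <- geo$interior
  for (side in c(1L, 2L)) {
    m <- lab == side
    for (sh in seq_len(k)) {
      new_vox <- .shift3(m, 1L, sh) & !m & body & !blocked & lab == 0L
      src <- .shift3(new_vox, 1L, -sh)       # voxel the value is copied from
      grid[new_vox] <- grid[src]
      lab[new_vox] <- side
    }
  }
  lung <- lab == 1L | lab == 2L
  air <- s$spec$airway_gl_mean
  grid[lung] <- air + 0.85 * (grid[lung] - air)
  grid[grid < 0] <- 0

  spec <- s$spec; spec$phase <- "P01"
  raw <- raw_volume(grid, spec$voxel_size_um, "P01")
  structure(list(
    raw = raw,
    truth_labels = label_map(lab, muridens_classes("fine"), spec$voxel_size_um),
    truth_hu = apply_transfer(raw, phantom_truth_transfer(spec)),
    spec = spec,
    meta = c(s$meta[setdiff(names(s$meta), "phase")], list(phase = "P01"))),
    class = "phantom_sample")
}

# ---- cohorts ---------------------------------------------------------------

#' Generate a longitudinal phantom cohort
#'
#' Each synthetic mouse keeps one anatomy (one geometry seed) across
#' `timepoints` scans of increasing fibrotic severity, emulating longitudinal
#' disease progression; acquisition noise differs between timepoints.
#'
#' @param n Number of mice.
#' @param severity_range Length-2 interval of fibrotic severity spanned from
#'   the first to the last timepoint.
#' @param base_seed Integer seed from which all per-mouse seeds derive.
#' @param timepoints Number of scans per mouse (at least 2).
#' @param ... Further arguments passed to [phantom_spec()] (shape, noise_sd,
#'   intensity means, ...).
#' @return List of `phantom_sample`s with `meta$mouse_id` and
#'   `meta$timepoint` filled in.
#' @export
generate_cohort <- function(n, severity_range = c(0, 0.6), base_seed = 1L,
                            timepoints = 3L, ...) {
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  if (length(severity_range) != 2L || severity_range[2] < severity_range[1])
    stop("severity_range must be a non-empty interval", call. = FALSE)
  if (timepoints < 2L) stop("each mouse needs at least 2 timepoints", call. = FALSE)
  base_seed <- as.integer(base_seed) %% 1000000L
  lo <- severity_range[1]; hi <- severity_range[2]
  u <- withr::with_seed(base_seed, runif(n, 0.7, 1))
  out <- list()
  for (m in seq_len(n)) {
    for (t in seq_len(timepoints)) {
      sev <- lo + (hi - lo) * ((t - 1) / (timepoints - 1)) * u[m]
      spec <- phantom_spec(fibrosis_severity = sev,
                           seed = base_seed + 1000L + m,
                           noise_seed = base_seed + 100000L + 100L * m + t,
                           ...)
      smp <- generate_phantom(spec)
      smp$meta$mouse_id <- sprintf("M%03d", m)
      smp$meta$timepoint <- t
      smp$meta$severity <- sev
      out[[length(out) + 1L]] <- smp
    }
  }
  out
}
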