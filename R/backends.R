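# Segmentation backends.
#
# A backend is any object that turns a 2-D slice into per-class probability
# maps.  Three implementations ship:
#
#  * mlp  - a small trainable encoder/decoder network over per-pixel
#           multi-scale features (intensity, Gaussian context at two scales,
#           gradient magnitude, normalised slice coordinates, stack position,
#           radial distance).  The single hidden layer is the encoder; the
#           softmax output layer is the decoder.  Transfer learning to a new
#           label set retrains the decoder while the encoder (and the feature
#           normalisation it was trained under) stays frozen.
#  * oracle - passes stored ground truth through, with optional boundary
#           corruption; used to test downstream stages in isolation.
#  * classical - non-learned grey-level band + connected components +
#           morphology baseline.
#
# All training is deterministic given the training-config seed.

#' Training configuration
#'
#' Defaults mirror the pipeline's reference training recipe: Adam with
#' learning rate 1e-4, mini-batches of whole slices (24 slices for the coarse
#' model, 4 for the single-view models), early stopping on validation loss
#' with patience 10 epochs, and augmentation ranges of +/-5 degrees rotation,
#' +/-5 percent shift and +/-15 percent zoom.
#'
#' @param learning_rate Adam step size.
#' @param batch_slices Slices per mini-batch.
#' @param patience Early-stopping patience in epochs (>= 1).
#' @param max_epochs Upper bound on training epochs.
#' @param augment Logical; add randomly rotated/shifted/zoomed copies of the
#'   training slices to the pool.
#' @param rotation_deg,shift_frac,zoom_frac Symmetric augmentation ranges.
#' @param pixels_per_slice Pixels sampled per slice (class-balanced).
#' @param slice_stride Use every `slice_stride`-th slice of each stack.
#' @param hidden Width of the encoder (hidden layer).
#' @param val_cap Maximum validation pixels used for the early-stopping loss.
#' @param seed Integer seed for sampling, initialisation and augmentation.
#' @return An object of class `training_config`.
#' @export
training_config <- function(learning_rate = 1e-4, batch_slices = 4L,
                            patience = 10L, max_epochs = 200L,
                            augment = FALSE,
                            rotation_deg = c(-5, 5),
                            shift_frac = c(-0.05, 0.05),
                            zoom_frac = c(-0.15, 0.15),
                            pixels_per_slice = 200L, slice_stride = 1L,
                            hidden = 16L, val_cap = 50000L, seed = 1L) {
  if (patience < 1) stop("patience must be >= 1", call. = FALSE)
  for (rg in list(rotation_deg, shift_frac, zoom_frac))
    if (length(rg) != 2L || rg[1] > rg[2])
      stop("augmentation ranges must be increasing length-2 vectors", call. = FALSE)
  structure(list(learning_rate = learning_rate,
                 batch_slices = as.integer(batch_slices),
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 augment = isTRUE(augment),
                 rotation_deg = rotation_deg, shift_frac = shift_frac,
                 zoom_frac = zoom_frac,
                 pixels_per_slice = as.integer(pixels_per_slice),
                 slice_stride = as.integer(slice_stride),
                 hidden = as.integer(hidden),
                 val_cap = as.integer(val_cap),
                 seed = as.integer(seed)),
            class = "training_config")
}

# ---- constructors ----------------------------------------------------------

#' Trainable slice-segmentation backend
#'
#' @param classes Named integer class codes (background first).
#' @param hidden Encoder width.
#' @return An untrained backend of class `mlp_backend`.
#' @export
backend_mlp <- function(classes, hidden = 16L) {
  structure(list(type = "mlp", classes = classes, hidden = as.integer(hidden),
                 W1 = NULL, b1 = NULL, W2 = NULL, b2 = NULL,
                 feat_center = NULL, feat_scale = NULL,
                 trained = FALSE, log = NULL),
            class = c("mlp_backend", "muridens_backend"))
}

#' Ground-truth oracle backend
#'
#' Predicts the stored truth label map as indicator probabilities, optionally
#' after boundary corruption (per-class erosion plus random flips on the
#' one-voxel boundary ring), for testing downstream stages with a known
#' error level.
#'
#' @param truth A [label_map()] at the grid predictions will be requested on.
#' @param classes Named class codes; defaults to the truth's codes.
#' @param erode Integer: voxels of per-class erosion (negative = dilation).
#' @param flip_frac Fraction of one-voxel dilation-ring voxels flipped into
#'   each class mask (simulates boundary over-segmentation).
#' @param seed Seed for the random flips.
#' @return A backend of class `oracle_backend`.
#' @export
backend_oracle <- function(truth, classes = NULL, erode = 0L, flip_frac = 0,
                           seed = 1L) {
  stopifnot(inherits(truth, "label_map"))
  classes <- classes %||% truth$class_codes
  g <- truth$grid
  if (erode != 0L || flip_frac > 0) {
    g <- withr::with_seed(as.integer(seed), {
      out <- array(0L, dim(g))
      for (code in setdiff(sort(unique(as.integer(g))), 0L)) {
        m <- g == code
        if (erode > 0L) m <- .erode_box(m, erode)
        if (erode < 0L) m <- .dilate_box(m, -erode)
        if (flip_frac > 0) {
          ring <- which(.dilate_box(m, 1L) & !m)
          grab <- sample(ring, round(flip_frac * length(ring)))
          m[grab] <- TRUE
          drop_ring <- which(m & !.erode_box(m, 1L))
          lose <- sample(drop_ring, round(flip_frac * length(drop_ring)))
          m[lose] <- FALSE
        }
        out[m] <- code
      }
      out
    })
  }
  structure(list(type = "oracle", classes = classes, grid = g,
                 dim = dim(g), trained = TRUE),
            class = c("oracle_backend", "muridens_backend"))
}

#' Classical grey-level band baseline backend
#'
#' A non-learned coarse-stage baseline: lungs are mid-band grey levels inside
#' the body, airways are interior air (air-band components not touching the
#' slice border), and the heart is soft-tissue band inside the inter-lung
#' midline region.  Probabilities are smoothed indicators.
#'
#' @param classes Named class codes (coarse coding).
#' @param lung_band,airway_band,heart_band Grey-level intervals.
#' @return A backend of class `classical_backend`.
#' @export
backend_classical <- function(classes = muridens_classes("coarse"),
                              lung_band = c(860, 1990),
                              airway_band = c(0, 900),
                              heart_band = c(2100, 2600)) {
  structure(list(type = "classical", classes = classes,
                 lung_band = lung_band, airway_band = airway_band,
                 heart_band = heart_band, trained = TRUE),
            class = c("classical_backend", "muridens_backend"))
}

#' @export
print.muridens_backend <- function(x, ...) {
  cat(sprintf("<%s backend> classes: %s%s\n", x$type,
              paste(names(x$classes), collapse = "/"),
              if (isTRUE(x$trained)) " [trained]" else " [untrained]"))
  invisible(x)
}

#' Digest of a trained backend's encoder state
#'
#' Hash of the encoder weights, bias and feature normalisation; used to
#' assert that transfer learning leaves the encoder untouched.
#'
#' @param b An `mlp_backend`.
#' @return Character hash.
#' @export
encoder_digest <- function(b) {
  stopifnot(inherits(b, "mlp_backend"))
  rlang::hash(list(b$W1, b$b1, b$feat_center, b$feat_scale))
}

# ---- per-pixel features ----------------------------------------------------

.n_features <- 8L

.slice_features <- function(img, frac) {
  nr <- nrow(img); nc <- ncol(img)
  b1 <- .gauss_blur_2d(img, 1)
  b3 <- .gauss_blur_2d(img, 3)
  gz <- rbind(b1[2, , drop = FALSE], b1[3:nr, , drop = FALSE] -
                b1[1:(nr - 2), , drop = FALSE], b1[nr - 1, , drop = FALSE])
  gc <- cbind(b1[, 2, drop = FALSE], b1[, 3:nc, drop = FALSE] -
                b1[, 1:(nc - 2), drop = FALSE], b1[, nc - 1, drop = FALSE])
  grad <- sqrt(gz^2 + gc^2)
  rr <- (row(img) - 0.5) / nr
  cc <- (col(img) - 0.5) / nc
  rad <- sqrt((rr - 0.5)^2 + (cc - 0.5)^2)
  cbind(as.numeric(img), as.numeric(b1), as.numeric(b3), as.numeric(grad),
        as.numeric(rr), as.numeric(cc), rep(frac, nr * nc), as.numeric(rad))
}

# ---- slice augmentation ----------------------------------------------------

# affine warp about the slice centre; inverse mapping with bilinear (image)
# or nearest (labels) interpolation
.affine_slice <- function(img, rot_deg, shift_rc, zoom, fill,
                          interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  nr <- nrow(img); nc <- ncol(img)
  th <- rot_deg * pi / 180
  sc <- 1 / (1 + zoom)
  cr <- (nr + 1) / 2; ccn <- (nc + 1) / 2
  r_out <- rep(seq_len(nr), nc) - cr
  c_out <- rep(seq_len(nc), each = nr) - ccn
  r_out <- r_out - shift_rc[1] * nr
  c_out <- c_out - shift_rc[2] * nc
  r_in <- sc * (cos(th) * r_out - sin(th) * c_out) + cr
  c_in <- sc * (sin(th) * r_out + cos(th) * c_out) + ccn
  if (interp == "nearest") {
    ri <- round(r_in); ci <- round(c_in)
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    out <- rep(fill, nr * nc)
    out[ok] <- img[cbind(ri[ok], ci[ok])]
  } else {
    ok <- r_in >= 1 & r_in <= nr & c_in >= 1 & c_in <= nc
    r0 <- pmin(pmax(floor(r_in), 1), nr - 1)
    c0 <- pmin(pmax(floor(c_in), 1), nc - 1)
    fr <- r_in - r0; fc <- c_in - c0
    out <- rep(fill, nr * nc)
    g <- function(ri, ci) img[cbind(ri, ci)]
    out[ok] <- (1 - fr[ok]) * (1 - fc[ok]) * g(r0[ok], c0[ok]) +
      (1 - fr[ok]) * fc[ok] * g(r0[ok], c0[ok] + 1) +
      fr[ok] * (1 - fc[ok]) * g(r0[ok] + 1, c0[ok]) +
      fr[ok] * fc[ok] * g(r0[ok] + 1, c0[ok] + 1)
  }
  matrix(out, nr, nc)
}

.random_augment <- function(img, lab, cfg) {
  rot <- runif(1, cfg$rotation_deg[1], cfg$rotation_deg[2])
  sh <- runif(2, cfg$shift_frac[1], cfg$shift_frac[2])
  zm <- runif(1, cfg$zoom_frac[1], cfg$zoom_frac[2])
  list(img = .affine_slice(img, rot, sh, zm, fill = min(img), "bilinear"),
       lab = .affine_slice(lab, rot, sh, zm, fill = 0, "nearest"))
}

# ---- pixel dataset ---------------------------------------------------------

# slices: list of list(img, lab, frac).  Samples up to pixels_per_slice
# pixels per slice, balanced over the classes present in that slice.
.sample_slice_pixels <- function(slices, classes, cfg, augment = FALSE) {
  X <- vector("list", 0); y <- integer(0); sid <- integer(0)
  codes <- as.integer(classes)
  s_index <- 0L
  for (sl in slices) {
    pool <- list(sl)
    if (augment) pool <- c(pool, list(.random_augment(sl$img, sl$lab, cfg)))
    for (p in pool) {
      s_index <- s_index + 1L
      feats <- .slice_features(p$img, sl$frac)
      labv <- as.integer(p$lab)
      present <- codes[codes %in% unique(labv)]
      quota <- max(1L, ceiling(cfg$pixels_per_slice / length(present)))
      take <- integer(0)
      for (code in present) {
        idx <- which(labv == code)
        take <- c(take, if (length(idx) <= quota) idx
                  else sample(idx, quota))
      }
      X[[length(X) + 1L]] <- feats[take, , drop = FALSE]
      y <- c(y, match(labv[take], codes))
      sid <- c(sid, rep(s_index, length(take)))
    }
  }
  list(X = do.call(rbind, X), y = y, slice = sid)
}

# ---- MLP training ----------------------------------------------------------

.softmax <- function(S) {
  m <- S[, 1]
  for (k in seq_len(ncol(S))[-1]) m <- pmax(m, S[, k])
  E <- exp(S - m)
  E / rowSums(E)
}

.mlp_forward <- function(b, X) {
  Z <- tanh(sweep(X %*% b$W1, 2, b$b1, `+`))
  P <- .softmax(sweep(Z %*% b$W2, 2, b$b2, `+`))
  list(Z = Z, P = P)
}

.ce_loss <- function(P, y) -mean(log(pmax(P[cbind(seq_along(y), y)], 1e-12)))

# Adam mini-batch training with early stopping on validation cross-entropy.
# Mini-batches are groups of whole slices, mirroring slice-wise batching.
.train_mlp <- function(b, train_slices, val_slices, cfg,
                       freeze_encoder = FALSE) {
  if (!length(train_slices)) stop("empty training set", call. = FALSE)
  if (!length(val_slices)) stop("empty validation set", call. = FALSE)
  K <- length(b$classes)
  withr::with_seed(cfg$seed, {
    tr <- .sample_slice_pixels(train_slices, b$classes, cfg,
                               augment = cfg$augment)
    va <- .sample_slice_pixels(val_slices, b$classes, cfg, augment = FALSE)
    if (length(va$y) > cfg$val_cap) {
      keep <- sample(length(va$y), cfg$val_cap)
      va$X <- va$X[keep, , drop = FALSE]; va$y <- va$y[keep]
    }
    if (is.null(b$feat_center)) {
      b$feat_center <- colMeans(tr$X)
      b$feat_scale <- pmax(apply(tr$X, 2, sd), 1e-8)
    }
    std <- function(X) sweep(sweep(X, 2, b$feat_center), 2, b$feat_scale, `/`)
    Xtr <- std(tr$X); Xva <- std(va$X)
    d <- ncol(Xtr); H <- b$hidden
    if (is.null(b$W1)) {
      b$W1 <- matrix(rnorm(d * H, 0, 1 / sqrt(d)), d, H)
      b$b1 <- rep(0, H)
    }
    b$W2 <- matrix(rnorm(H * K, 0, 1 / sqrt(H)), H, K)
    b$b2 <- rep(0, K)

    Ytr <- matrix(0, length(tr$y), K); Ytr[cbind(seq_along(tr$y), tr$y)] <- 1
    slice_ids <- unique(tr$slice)
    rows_of <- split(seq_along(tr$slice), tr$slice)
    n_batches <- ceiling(length(slice_ids) / cfg$batch_slices)
    adam <- list(); step <- 0L
    upd <- function(name, par, grad) {
      st <- adam[[name]] %||% list(m = par * 0, v = par * 0)
      st$m <- 0.9 * st$m + 0.1 * grad
      st$v <- 0.999 * st$v + 0.001 * grad^2
      adam[[name]] <<- st
      mh <- st$m / (1 - 0.9^step); vh <- st$v / (1 - 0.999^step)
      par - cfg$learning_rate * mh / (sqrt(vh) + 1e-8)
    }
    best <- list(val = Inf, epoch = 0L, W1 = b$W1, b1 = b$b1,
                 W2 = b$W2, b2 = b$b2)
    log_ <- data.frame(epoch = integer(0), train_loss = numeric(0),
                       val_loss = numeric(0))
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample(slice_ids)
      tr_loss <- 0; nb <- 0L
      for (bi in seq_len(n_batches)) {
        ids <- ord[((bi - 1L) * cfg$batch_slices + 1L):
                     min(bi * cfg$batch_slices, length(ord))]
        rows <- unlist(rows_of[as.character(ids)], use.names = FALSE)
        X <- Xtr[rows, , drop = FALSE]; Y <- Ytr[rows, , drop = FALSE]
        fw <- .mlp_forward(b, X)
        n <- nrow(X)
        dS <- (fw$P - Y) / n
        gW2 <- crossprod(fw$Z, dS); gb2 <- colSums(dS)
        dZ <- dS %*% t(b$W2)
        dA <- dZ * (1 - fw$Z^2)
        step <- step + 1L
        if (!freeze_encoder) {
          gW1 <- crossprod(X, dA); gb1 <- colSums(dA)
          b$W1 <- upd("W1", b$W1, gW1); b$b1 <- upd("b1", b$b1, gb1)
        }
        b$W2 <- upd("W2", b$W2, gW2); b$b2 <- upd("b2", b$b2, gb2)
        tr_loss <- tr_loss + .ce_loss(fw$P, tr$y[rows]); nb <- nb + 1L
      }
      val_loss <- .ce_loss(.mlp_forward(b, Xva)$P, va$y)
      log_ <- rbind(log_, data.frame(epoch = epoch, train_loss = tr_loss / nb,
                                     val_loss = val_loss))
      if (val_loss < best$val - 1e-9) {
        best <- list(val = val_loss, epoch = epoch, W1 = b$W1, b1 = b$b1,
                     W2 = b$W2, b2 = b$b2)
      } else if (epoch - best$epoch >= cfg$patience) break
    }
    b$W1 <- best$W1; b$b1 <- best$b1; b$W2 <- best$W2; b$b2 <- best$b2
    b$trained <- TRUE
    b$log <- log_
    b$best_epoch <- best$epoch
    b
  })
}

# ---- prediction ------------------------------------------------------------

# Predict per-class probability matrices for one slice.  meta carries the
# view, slice index and stack length so index-aware backends (oracle) can
# locate the slice.
.backend_predict_slice <- function(b, img, meta) {
  UseMethod(".backend_predict_slice")
}

#' @export
.backend_predict_slice.mlp_backend <- function(b, img, meta) {
  if (!isTRUE(b$trained)) stop("backend is untrained", call. = FALSE)
  X <- .slice_features(img, meta$frac)
  X <- sweep(sweep(X, 2, b$feat_center), 2, b$feat_scale, `/`)
  P <- .mlp_forward(b, X)$P
  out <- lapply(seq_along(b$classes), function(k)
    matrix(P[, k], nrow(img), ncol(img)))
  names(out) <- names(b$classes)
  out
}

#' @export
.backend_predict_slice.oracle_backend <- function(b, img, meta) {
  sl <- switch(meta$view,
    axial    = b$grid[meta$index, , ],
    coronal  = b$grid[, meta$index, ],
    sagittal = b$grid[, , meta$index])
  if (!identical(dim(sl), dim(img)))
    stop("oracle truth grid does not match the prediction grid", call. = FALSE)
  out <- lapply(b$classes, function(code)
    matrix(as.numeric(sl == code), nrow(img), ncol(img)))
  names(out) <- names(b$classes)
  out
}

#' @export
.backend_predict_slice.classical_backend <- function(b, img, meta) {
  nr <- nrow(img); nc <- ncol(img)
  in_band <- function(band) img >= band[1] & img <= band[2]
  air <- in_band(b$airway_band)
  cc <- connected_components(array(air, c(1L, nr, nc)))
  border <- unique(c(cc[1, 1, ], cc[1, nr, ], cc[1, , 1], cc[1, , nc]))
  interior_air <- matrix(cc[1, , ] > 0 & !(cc[1, , ] %in% border), nr, nc)
  lung <- in_band(b$lung_band) & !interior_air
  lung <- .gauss_blur_2d(lung * 1, 1) > 0.5
  heart <- matrix(FALSE, nr, nc)
  if (any(lung)) {
    rows <- range(which(rowSums(lung) > 0))
    cols <- range(which(colSums(lung) > 0))
    mid <- round(cols[1] + diff(cols) * c(0.33, 0.67))
    heart[rows[1]:rows[2], mid[1]:mid[2]] <-
      in_band(b$heart_band)[rows[1]:rows[2], mid[1]:mid[2]]
  }
  smooth <- function(m) pmin(pmax(.gauss_blur_2d(m * 1, 1), 0), 1)
  p <- list(lung = smooth(lung), heart = smooth(heart),
            airways = smooth(interior_air))
  fg <- pmin(p$lung + p$heart + p$airways, 1)
  tot <- p$lung + p$heart + p$airways
  over <- tot > 1
  for (k in names(p)) p[[k]][over] <- p[[k]][over] / tot[over]
  out <- c(list(background = 1 - fg), p)
  out[match(names(b$classes), names(out))]
}
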