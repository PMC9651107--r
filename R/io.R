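# Volume file dialects.
#
# NIfTI (.nii / .nii.gz): the primary, lossless format. The grid is stored
# as-is in (z, y, x) axis order; the isotropic voxel size is carried in the
# header pixdim in millimetres.  Label maps are integer NIfTI.
#
# Multi-page TIFF (.tif / .tiff): one page per axial slice.  TIFF floating
# point storage is limited to [0, 1], so grids are written as 32-bit float
# after an affine rescale whose offset/scale live in a JSON sidecar
# (<file>.json) together with the voxel size and phase; reading inverts the
# rescale.  Integer grids round-trip exactly; floating grids round-trip to
# 32-bit float precision.

#' Read a volume from NIfTI or multi-page TIFF
#'
#' @param path File path (`.nii`, `.nii.gz`, `.tif`, `.tiff`).
#' @param format `"auto"` (from extension), `"nifti"` or `"tiff"`.
#' @param voxel_size_um Override for the voxel size; required for TIFF stacks
#'   without a sidecar.  NIfTI headers with anisotropic pixdim are rejected
#'   unless an override is given.
#' @param phase Breathing phase override; defaults to the sidecar/`"P02"`.
#' @param kind `"raw"`, `"hu"` or `"label"`: which container to return.
#' @return A [raw_volume()], [hu_volume()] or [label_map()].
#' @export
read_volume <- function(path, format = c("auto", "nifti", "tiff"),
                        voxel_size_um = NULL, phase = NULL,
                        kind = c("raw", "hu", "label")) {
  format <- match.arg(format); kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") format <- .guess_format(path)
  meta <- list(voxel_size_um = voxel_size_um, phase = phase)
  if (format == "nifti") {
    img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                    error = function(e) stop("unreadable NIfTI file: ", path,
                                             " (", conditionMessage(e), ")",
                                             call. = FALSE))
    grid <- array(as.numeric(img), dim(img))
    pd <- RNifti::pixdim(img)[seq_len(3)]
    if (is.null(meta$voxel_size_um)) {
      if (max(pd) - min(pd) > 1e-9 * max(pd))
        stop("anisotropic voxels in header; supply voxel_size_um", call. = FALSE)
      meta$voxel_size_um <- round(pd[1] * 1000, 3)  # header is float32 mm
    }
  } else {
    pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                      error = function(e) stop("unreadable TIFF file: ", path,
                                               " (", conditionMessage(e), ")",
                                               call. = FALSE))
    if (!is.list(pages)) pages <- list(pages)
    side <- .sidecar_path(path)
    sc <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
          else list()
    grid <- restack_views(pages, "axial")
    off <- sc$offset %||% 0; scl <- sc$scale %||% 1
    grid <- grid * scl + off
    if (is.null(meta$voxel_size_um)) meta$voxel_size_um <- sc$voxel_size_um
    if (is.null(meta$phase)) meta$phase <- sc$phase
    if (is.null(meta$voxel_size_um))
      stop("TIFF stack without sidecar: supply voxel_size_um", call. = FALSE)
  }
  if (is.null(meta$phase)) meta$phase <- "P02"
  switch(kind,
    raw   = raw_volume(grid, meta$voxel_size_um, meta$phase),
    hu    = hu_volume(grid, meta$voxel_size_um),
    label = label_map(array(as.integer(round(grid)), dim(grid)),
                      voxel_size_um = meta$voxel_size_um))
}

#' Write a volume to NIfTI or multi-page TIFF
#'
#' @param v A [raw_volume()], [hu_volume()] or [label_map()].
#' @param path Destination path.
#' @param format `"auto"`, `"nifti"` or `"tiff"`.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(v, path, format = c("auto", "nifti", "tiff")) {
  format <- match.arg(format)
  if (format == "auto") format <- .guess_format(path)
  if (!dir.exists(dirname(path)))
    stop("destination directory does not exist: ", dirname(path), call. = FALSE)
  if (format == "nifti") {
    storage <- if (inherits(v, "label_map")) "int16" else "double"
    img <- RNifti::asNifti(v$grid)
    mm <- v$voxel_size_um / 1000
    RNifti::pixdim(img) <- c(mm, mm, mm)
    ok <- tryCatch({RNifti::writeNifti(img, path, datatype = storage); TRUE},
                   error = function(e) stop("cannot write ", path, " (",
                                            conditionMessage(e), ")", call. = FALSE))
  } else {
    g <- v$grid
    lo <- min(g); hi <- max(g)
    scl <- if (hi > lo) hi - lo else 1
    norm <- (g - lo) / scl
    pages <- extract_view_stack(norm, "axial")
    pages <- lapply(pages, function(p) matrix(p, nrow(p), ncol(p)))
    ok <- tryCatch({tiff::writeTIFF(pages, path, bits.per.sample = 32L); TRUE},
                   error = function(e) stop("cannot write ", path, " (",
                                            conditionMessage(e), ")", call. = FALSE))
    jsonlite::write_json(
      list(offset = lo, scale = scl, voxel_size_um = v$voxel_size_um,
           phase = v$phase %||% "P02",
           kind = class(v)[1]),
      .sidecar_path(path), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

.guess_format <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) return("nifti")
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) return("tiff")
  stop("unsupported volume format: ", path, call. = FALSE)
}

.sidecar_path <- function(path) paste0(path, ".json")

`%||%` <- function(a, b) if (is.null(a)) b else a
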