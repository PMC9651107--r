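#' 3-D median filter
#'
#' Denoises a volume with a cubic median filter (default 5x5x5, the kernel
#' used to pre-process scans before both manual annotation and automated
#' analysis).  Borders are handled by reflect padding so the output keeps the
#' input shape without edge darkening.
#'
#' @param v A volume object or 3-D array.
#' @param kernel Odd positive integer edge length of the cubic kernel.
#' @return Same type as the input, filtered.
#' @export
median_filter_3d <- function(v, kernel = 5L) {
  if (!is.numeric(kernel) || length(kernel) != 1L || kernel < 1 ||
      kernel != round(kernel) || kernel %% 2 == 0)
    stop("kernel must be an odd positive integer", call. = FALSE)
  g <- if (is.list(v)) v$grid else v
  if (kernel == 1L) return(.rewrap(v, g))
  out <- .median3d_cpp(array(as.numeric(g), dim(g)), as.integer(kernel))
  .rewrap(v, out)
}

# Separable 2-D Gaussian blur used by the slice feature extractor; the
# truncated kernel (3 sigma) is renormalised row-wise, which is equivalent to
# nearest-edge padding.
.gauss_blur_2d <- function(img, sigma) {
  if (sigma <= 0) return(img)
  .gmat(nrow(img), sigma) %*% img %*% t(.gmat(ncol(img), sigma))
}

.gmat_cache <- new.env(parent = emptyenv())
.gmat <- function(n, sigma) {
  key <- paste0(n, "_", sigma)
  if (!is.null(.gmat_cache[[key]])) return(.gmat_cache[[key]])
  h <- max(1L, ceiling(3 * sigma))
  i <- seq_len(n)
  M <- outer(i, i, function(a, b) {
    d <- a - b
    ifelse(abs(d) <= h, exp(-d^2 / (2 * sigma^2)), 0)
  })
  M <- M / rowSums(M)
  .gmat_cache[[key]] <- M
  M
}
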