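#' Threshold an angiogram into a binary perfusion slab
#'
#' Applies a thresholding algorithm to an en face angiogram, assigning each
#' pixel 1 (perfused) when its intensity exceeds the threshold and 0
#' (background) otherwise. Three methods are available:
#'
#' * `"otsu"` (default): global Otsu threshold on the intensity histogram.
#' * `"fixed"`: a caller-supplied threshold, `params$threshold`.
#' * `"local_mean"`: adaptive threshold against the local mean intensity in
#'   a `params$window_px` square window (default 15), minus
#'   `params$offset` (default 0.02).
#'
#' With a constant (zero-contrast) image an adaptive method has no valid
#' threshold; the function then returns an all-background slab and emits a
#' warning instead of failing, so batch runs continue.
#'
#' @param image An [angiogram_image].
#' @param method Threshold method identifier.
#' @param params List of method parameters (see above).
#' @return A [binary_slab] with the same geometry as `image`.
#' @examples
#' img <- angiogram_image(matrix(rep(c(0, 1), each = 32), 8, 8))
#' slab <- binarize_angiogram(img, "fixed", list(threshold = 0.5))
#' mean(slab$pixels)  # 0.5
#' @export
binarize_angiogram <- function(image, method = c("otsu", "fixed", "local_mean"),
                               params = list()) {
  stopifnot(inherits(image, "angiogram_image"))
  method <- match.arg(method)
  px <- image$pixels
  if (method == "fixed") {
    thr <- params$threshold
    if (is.null(thr) || !is.finite(thr))
      stop("fixed method requires params$threshold")
    fg <- px > thr
  } else if (method == "otsu") {
    if (diff(range(px)) < .Machine$double.eps) {
      warning("constant image: no contrast for Otsu thresholding; returning all-background slab")
      return(binary_slab(matrix(0, nrow(px), ncol(px)), image$pixel_spacing_mm))
    }
    thr <- EBImage::otsu(EBImage::Image(px), range = c(0, 1))
    fg <- px > thr
  } else {
    if (diff(range(px)) < .Machine$double.eps) {
      warning("constant image: local-mean thresholding is degenerate; returning all-background slab")
      return(binary_slab(matrix(0, nrow(px), ncol(px)), image$pixel_spacing_mm))
    }
    w <- if (is.null(params$window_px)) 15L else as.integer(params$window_px)
    off <- if (is.null(params$offset)) 0.02 else params$offset
    half <- max(1L, w %/% 2L)
    local_mean <- as.matrix(EBImage::filter2(
      EBImage::Image(px), matrix(1 / (2 * half + 1)^2, 2 * half + 1, 2 * half + 1)))
    fg <- px > local_mean + off
  }
  binary_slab(fg * 1, image$pixel_spacing_mm)
}
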