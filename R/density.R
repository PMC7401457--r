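#' Perfusion density
#'
#' Fraction of area occupied by perfused vasculature within a region of
#' interest: the mean of the binary slab over the ROI. Dimensionless, in
#' \[0, 1\].
#'
#' @param slab A [binary_slab].
#' @param roi An [roi_mask] with the same geometry, or `NULL` for the full
#'   image (the entire scanned area).
#' @return Perfusion density as a fraction in \[0, 1\].
#' @export
perfusion_density <- function(slab, roi = NULL) {
  stopifnot(inherits(slab, "binary_slab") || inherits(slab, "skeleton_slab"))
  sel <- roi_selection(slab, roi)
  mean(slab$pixels[sel])
}

#' Vessel density
#'
#' Total length of perfused vasculature per unit area, estimated as the mean
#' of the skeletonized slab within the ROI divided by the pixel spacing
#' (for the standard grid, 245 pixels per 3 mm). This is a first-order
#' length estimate: each skeleton pixel contributes one pixel-spacing of
#' length regardless of local orientation, so diagonal runs are not given a
#' sqrt(2) weight. Units: mm^-1. The attainable maximum is
#' `1 / pixel_spacing_mm` (every pixel foreground).
#'
#' @param skeleton A [skeleton_slab].
#' @param roi An [roi_mask] matching the skeleton geometry, or `NULL` for
#'   the full image.
#' @return Vessel density in mm^-1.
#' @examples
#' px <- matrix(0, 245, 245); px[123, ] <- 1  # one full-width vessel trace
#' vessel_density(skeleton_slab(px))          # 3 mm of vessel in 9 mm^2 = 1/3
#' @export
vessel_density <- function(skeleton, roi = NULL) {
  stopifnot(inherits(skeleton, "skeleton_slab"))
  sel <- roi_selection(skeleton, roi)
  mean(skeleton$pixels[sel]) / skeleton$pixel_spacing_mm
}

roi_selection <- function(slab, roi) {
  if (is.null(roi)) return(rep(TRUE, length(slab$pixels)))
  stopifnot(inherits(roi, "roi_mask"))
  if (!same_geometry(slab, roi))
    stop("roi geometry does not match slab geometry")
  if (sum(roi$pixels) < 1) stop("empty region of interest")
  roi$pixels == 1
}
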