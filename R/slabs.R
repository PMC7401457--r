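#' octaquant: quantification of OCTA en face angiograms
#'
#' Skeleton-based vessel density and perfusion density, FAZ area and
#' circularity, disease-pathway phenotyping and longitudinal cohort
#' statistics for early nonproliferative diabetic retinopathy, together
#' with synthetic angiogram and cohort generators that carry ground truth.
#'
#' @section Coordinate convention:
#' All slabs are numeric matrices indexed `[row, col]`, 1-based, with pixel
#' centers at integer coordinates. The physical scale is carried by
#' `pixel_spacing_mm` (default 3/245 mm: 245 pixels across a 3 mm scan).
#' Area per pixel is `pixel_spacing_mm^2`.
#'
#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm rbinom runif sd qt pf pt pchisq pnorm cor
#'   complete.cases aggregate
#' @importFrom utils head write.csv read.csv
NULL

PLEXUS_LEVELS <- c("SCP", "DCP", "FR")

#' Construct an en face angiogram image
#'
#' An `angiogram_image` is a grayscale en face OCTA slab: a matrix of
#' intensities in \[0, 1\] with a physical pixel scale, a plexus label
#' (superficial capillary plexus, deep capillary plexus, or full retina)
#' and the device-reported signal strength.
#'
#' @param pixels Numeric matrix with values in \[0, 1\]; at least 8 x 8.
#' @param pixel_spacing_mm Physical distance between pixel centers in mm.
#'   The default corresponds to 245 pixels spanning 3 mm.
#' @param plexus One of `"SCP"`, `"DCP"`, `"FR"`.
#' @param signal_strength Integer scan-quality score in 0-10 as reported by
#'   the device; consumed by the quality filter, never recomputed.
#' @return An object of class `angiogram_image`.
#' @export
angiogram_image <- function(pixels, pixel_spacing_mm = 3 / 245,
                            plexus = "FR", signal_strength = 10L) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (nrow(pixels) < 8 || ncol(pixels) < 8)
    stop("angiogram must be at least 8 x 8 pixels")
  if (!all(is.finite(pixels)))
    stop("angiogram intensities must all be finite")
  if (min(pixels) < 0 || max(pixels) > 1)
    stop("angiogram intensities must lie in [0, 1]")
  if (!is.numeric(pixel_spacing_mm) || pixel_spacing_mm <= 0)
    stop("pixel_spacing_mm must be > 0")
  plexus <- match.arg(plexus, PLEXUS_LEVELS)
  signal_strength <- as.integer(signal_strength)
  if (is.na(signal_strength) || signal_strength < 0 || signal_strength > 10)
    stop("signal_strength must be an integer in 0..10")
  structure(
    list(pixels = pixels, pixel_spacing_mm = pixel_spacing_mm,
         plexus = plexus, signal_strength = signal_strength),
    class = "angiogram_image")
}

#' Construct a binary perfusion slab
#'
#' Per-pixel perfusion mask: 1 = perfused, 0 = background, on the same grid
#' as the angiogram it was thresholded from.
#'
#' @param pixels Matrix of 0/1 (logical accepted).
#' @param pixel_spacing_mm Physical pixel spacing in mm.
#' @return An object of class `binary_slab`.
#' @export
binary_slab <- function(pixels, pixel_spacing_mm = 3 / 245) {
  pixels <- as.matrix(pixels) * 1
  if (!all(pixels %in% c(0, 1)))
    stop("binary slab pixels must be exactly 0 or 1")
  if (pixel_spacing_mm <= 0) stop("pixel_spacing_mm must be > 0")
  structure(list(pixels = pixels, pixel_spacing_mm = pixel_spacing_mm),
            class = "binary_slab")
}

#' Construct a skeleton slab
#'
#' One-pixel-wide vessel trace on the same grid as its binary source.
#' Enforces the unit-width property: no 2 x 2 block may be entirely
#' foreground.
#'
#' @inheritParams binary_slab
#' @return An object of class `skeleton_slab`.
#' @export
skeleton_slab <- function(pixels, pixel_spacing_mm = 3 / 245) {
  pixels <- as.matrix(pixels) * 1
  if (!all(pixels %in% c(0, 1)))
    stop("skeleton pixels must be exactly 0 or 1")
  if (any_full_2x2(pixels))
    stop("skeleton violates the 1-px-width property (a 2x2 block is all foreground)")
  structure(list(pixels = pixels, pixel_spacing_mm = pixel_spacing_mm),
            class = "skeleton_slab")
}

#' Construct a region-of-interest mask
#'
#' @param pixels 0/1 matrix selecting the region of measurement; must select
#'   at least one pixel.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(pixels) {
  pixels <- as.matrix(pixels) * 1
  if (!all(pixels %in% c(0, 1))) stop("roi pixels must be 0 or 1")
  if (sum(pixels) < 1) stop("roi must select at least one pixel")
  structure(list(pixels = pixels), class = "roi_mask")
}

#' Full-image region of interest
#'
#' The default measurement region: the entire scanned area (for the standard
#' grid, the whole central 3 x 3 mm).
#'
#' @param slab A `binary_slab`, `skeleton_slab` or `angiogram_image` whose
#'   geometry the ROI should match.
#' @return An `roi_mask` selecting every pixel.
#' @export
full_roi <- function(slab) {
  roi_mask(matrix(1, nrow(slab$pixels), ncol(slab$pixels)))
}

#' @export
print.angiogram_image <- function(x, ...) {
  cat(sprintf("<angiogram_image> %d x %d px, %s, %.4f mm/px, signal strength %d\n",
              nrow(x$pixels), ncol(x$pixels), x$plexus,
              x$pixel_spacing_mm, x$signal_strength))
  invisible(x)
}

#' @export
print.binary_slab <- function(x, ...) {
  cat(sprintf("<binary_slab> %d x %d px, foreground fraction %.3f\n",
              nrow(x$pixels), ncol(x$pixels), mean(x$pixels)))
  invisible(x)
}

#' @export
print.skeleton_slab <- function(x, ...) {
  cat(sprintf("<skeleton_slab> %d x %d px, %d skeleton pixels\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels)))
  invisible(x)
}

# TRUE if any 2x2 block is entirely foreground
any_full_2x2 <- function(m) {
  if (nrow(m) < 2 || ncol(m) < 2) return(FALSE)
  nr <- nrow(m); nc <- ncol(m)
  blk <- m[-nr, -nc] + m[-1, -nc] + m[-nr, -1] + m[-1, -1]
  any(blk == 4)
}

same_geometry <- function(a, b) {
  identical(dim(a$pixels), dim(b$pixels))
}

# Label 4- or 8-connected components of a 0/1 matrix. Frontier-based flood
# fill; adequate for the 245 x 245 grids this package works at.
label_components <- function(m, connectivity = 8) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  idx <- which(m == 1)
  if (length(idx) == 0) return(lab)
  current <- 0L
  for (seed in idx) {
    if (lab[seed] != 0L) next
    current <- current + 1L
    lab[flood_select_idx(m, seed, connectivity)] <- current
  }
  lab
}

# Linear indices of the connected component of `m` containing linear index
# `seed` (seed must be foreground).
flood_select_idx <- function(m, seed, connectivity = 4) {
  nr <- nrow(m); nc <- ncol(m)
  stopifnot(m[seed] == 1)
  visited <- matrix(FALSE, nr, nc)
  visited[seed] <- TRUE
  frontier <- seed
  if (connectivity == 4) {
    dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  } else {
    dr <- c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L)
    dc <- c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L)
  }
  out <- seed
  while (length(frontier) > 0) {
    r <- (frontier - 1L) %% nr + 1L
    c <- (frontier - 1L) %/% nr + 1L
    nxt <- integer(0)
    for (k in seq_along(dr)) {
      rr <- r + dr[k]; cc <- c + dc[k]
      ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
      if (!any(ok)) next
      cand <- (cc[ok] - 1L) * nr + rr[ok]
      cand <- cand[m[cand] == 1 & !visited[cand]]
      if (length(cand)) {
        visited[cand] <- TRUE
        nxt <- c(nxt, cand)
      }
    }
    frontier <- unique(nxt)
    out <- c(out, frontier)
  }
  out
}

n_components <- function(m, connectivity = 8) max(label_components(m, connectivity))
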