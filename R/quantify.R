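#' Quantify a set of angiogram images
#'
#' Batch driver: binarizes every image, skeletonizes, and measures
#' perfusion density and vessel density over the full scan area; for SCP
#' images it additionally detects the FAZ and computes its area and
#' circularity (FAZ metrics are reported for the superficial plexus only;
#' other plexuses get NA in those columns).
#'
#' @param images List of [angiogram_image] objects; each must carry
#'   `patient_id`, `eye`, `visit` attributes (set them with [attr()] or use
#'   [read_image_set]).
#' @param config List of settings: `binarize$method`, `binarize$params`,
#'   `faz$closing_radius_px` (default 2), `faz$center_window_px` (default
#'   21).
#' @return A data.frame keyed by (patient_id, eye, visit, plexus) with
#'   `perfusion_density`, `vessel_density_mm1`, `faz_area_mm2`,
#'   `faz_circularity`, `signal_strength`.
#' @export
quantify_image_set <- function(images, config = list()) {
  cols <- c("patient_id", "eye", "visit", "plexus", "perfusion_density",
            "vessel_density_mm1", "faz_area_mm2", "faz_circularity",
            "signal_strength")
  if (length(images) == 0) {
    out <- as.data.frame(stats::setNames(rep(list(logical(0)), length(cols)), cols))
    return(out)
  }
  meta <- t(vapply(images, function(im) c(
    patient_id = as.character(attr(im, "patient_id")),
    eye = as.character(attr(im, "eye")),
    visit = as.character(attr(im, "visit")),
    plexus = im$plexus), character(4)))
  keys <- apply(meta, 1, paste, collapse = "|")
  if (anyDuplicated(keys))
    stop("duplicate image metadata: ",
         paste(unique(keys[duplicated(keys)]), collapse = "; "))
  bm <- if (is.null(config$binarize$method)) "otsu" else config$binarize$method
  bp <- if (is.null(config$binarize$params)) list() else config$binarize$params
  faz_r <- if (is.null(config$faz$closing_radius_px)) 2L else config$faz$closing_radius_px
  faz_w <- if (is.null(config$faz$center_window_px)) 21L else config$faz$center_window_px
  rows <- lapply(seq_along(images), function(i) {
    im <- images[[i]]
    slab <- binarize_angiogram(im, bm, bp)
    sk <- skeletonize_slab(slab)
    faz_area <- NA_real_; faz_circ <- NA_real_
    if (im$plexus == "SCP") {
      fz <- tryCatch(detect_faz(slab, faz_r, faz_w), error = function(e) NULL)
      if (!is.null(fz)) {
        fm <- faz_metrics(fz, im$pixel_spacing_mm)
        faz_area <- fm$area_mm2; faz_circ <- fm$circularity
      }
    }
    data.frame(patient_id = meta[i, "patient_id"], eye = meta[i, "eye"],
               visit = as.integer(meta[i, "visit"]), plexus = im$plexus,
               perfusion_density = perfusion_density(slab),
               vessel_density_mm1 = vessel_density(sk),
               faz_area_mm2 = faz_area, faz_circularity = faz_circ,
               signal_strength = im$signal_strength,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Write an image set as PNG files plus a JSON manifest
#'
#' @param images List of [angiogram_image] with `patient_id`, `eye`,
#'   `visit` attributes.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_image_set <- function(images, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(seq_along(images), function(i) {
    im <- images[[i]]
    fn <- sprintf("img_%03d.png", i)
    png::writePNG(im$pixels, file.path(dir, fn))
    list(file = fn,
         patient_id = as.character(attr(im, "patient_id")),
         eye = as.character(attr(im, "eye")),
         visit = as.integer(attr(im, "visit")),
         plexus = im$plexus,
         signal_strength = im$signal_strength,
         pixel_spacing_mm = im$pixel_spacing_mm)
  })
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image set from a JSON manifest
#'
#' Reads grayscale PNG (or, with the tiff package, TIFF) images listed in a
#' manifest, mapping 8- or 16-bit samples linearly to \[0, 1\], and attaches
#' the sidecar metadata.
#'
#' @param manifest_path Path to `manifest.json` (entries with `file`,
#'   `patient_id`, `eye`, `visit`, `plexus`, `signal_strength`,
#'   `pixel_spacing_mm`).
#' @return List of [angiogram_image].
#' @export
read_image_set <- function(manifest_path) {
  entries <- jsonlite::fromJSON(manifest_path, simplifyVector = FALSE)
  base <- dirname(manifest_path)
  lapply(entries, function(e) {
    path <- file.path(base, e$file)
    px <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("the tiff package is required to read TIFF images")
      tiff::readTIFF(path)
    } else {
      png::readPNG(path)
    }
    if (length(dim(px)) == 3) px <- px[, , 1]  # first channel of RGB(A)
    im <- angiogram_image(px, e$pixel_spacing_mm, e$plexus, e$signal_strength)
    attr(im, "patient_id") <- e$patient_id
    attr(im, "eye") <- e$eye
    attr(im, "visit") <- e$visit
    im
  })
}
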