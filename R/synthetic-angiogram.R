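#' Parameters for the synthetic angiogram generator
#'
#' Collects and validates the knobs of [generate_angiogram]. Defaults
#' emulate a healthy 3 x 3 mm macular scan: a handful of arterioles/venules
#' entering from the scan border, a fine capillary mesh filling roughly a
#' third of the area, a central avascular zone of typical area, and mild
#' multiplicative speckle.
#'
#' @param n_seed_vessels Number of larger vessels grown inward from the
#'   border.
#' @param branching_prob Per-step probability that a growing vessel spawns a
#'   branch.
#' @param capillary_fill_target Target foreground fraction of the clean
#'   binary mask, in (0, 0.8].
#' @param vessel_width_px Width of the seed vessels in pixels on the
#'   reference 245-px grid (capillaries are drawn 1 px wide).
#' @param faz_area_mm2 Area of the carved central avascular ellipse; 0
#'   disables the FAZ.
#' @param faz_eccentricity Eccentricity of the avascular ellipse, in \[0, 1).
#' @param noise_sd Multiplicative speckle scale; the effective noise is
#'   additionally scaled up as signal strength falls below 10.
#' @param signal_strength Device-style quality score 0-10 attached to the
#'   output image.
#' @param rng_seed Integer seed; the generator is deterministic given it.
#' @return A validated list of class `angiogram_params`.
#' @export
angiogram_params <- function(n_seed_vessels = 14, branching_prob = 0.12,
                             capillary_fill_target = 0.32,
                             vessel_width_px = 2.5,
                             faz_area_mm2 = 0.24, faz_eccentricity = 0.55,
                             noise_sd = 0.12, signal_strength = 9L,
                             rng_seed = 1L) {
  p <- list(n_seed_vessels = as.integer(n_seed_vessels),
            branching_prob = branching_prob,
            capillary_fill_target = capillary_fill_target,
            vessel_width_px = vessel_width_px,
            faz_area_mm2 = faz_area_mm2,
            faz_eccentricity = faz_eccentricity,
            noise_sd = noise_sd,
            signal_strength = as.integer(signal_strength),
            rng_seed = as.integer(rng_seed))
  stopifnot(p$n_seed_vessels >= 0, p$branching_prob >= 0, p$branching_prob <= 1,
            p$capillary_fill_target > 0, p$capillary_fill_target <= 0.8,
            p$vessel_width_px > 0, p$faz_area_mm2 >= 0,
            p$faz_eccentricity >= 0, p$faz_eccentricity < 1,
            p$noise_sd >= 0, p$signal_strength >= 0, p$signal_strength <= 10)
  if (p$faz_area_mm2 >= 9)
    stop("faz_area_mm2 must be smaller than the 9 mm^2 image area")
  class(p) <- "angiogram_params"
  p
}

SCAN_MM <- 3  # physical scan width

#' Generate a synthetic en face angiogram with ground truth
#'
#' Builds a vascular network in continuous millimetre coordinates — seeded
#' random branching vessels growing from the border inward, plus a fine
#' capillary mesh added until the rasterized mask reaches
#' `capillary_fill_target` — carves an elliptical avascular zone ringed by a
#' perifoveal capillary arcade, rasterizes it, and then degrades the clean
#' image with multiplicative speckle whose magnitude grows as signal
#' strength falls. The clean rasterized mask, the FAZ mask, and the
#' skeleton-based vessel density of the clean mask are returned as ground
#' truth, so measurement code can be validated against what was drawn.
#'
#' Deterministic given `params$rng_seed`.
#'
#' @param params An [angiogram_params] object.
#' @param n_px Grid size (pixels across 3 mm); default 245.
#' @param plexus Plexus label attached to the image.
#' @return A list:
#'   `image` ([angiogram_image]), and `truth` with `mask` ([binary_slab]
#'   before noise), `faz_mask` ([roi_mask] or `NULL` when `faz_area_mm2 = 0`),
#'   `true_vd` (mm^-1), `network` (the continuous network, reusable with
#'   [rasterize_network] at another resolution).
#' @export
generate_angiogram <- function(params = angiogram_params(), n_px = 245L,
                               plexus = "FR") {
  stopifnot(inherits(params, "angiogram_params"))
  set.seed(params$rng_seed)
  net <- grow_vessel_network(params, n_px = n_px)
  ras <- rasterize_network(net, n_px)
  clean_mask <- ras$mask
  spacing <- SCAN_MM / n_px
  sk <- skeletonize_slab(binary_slab(clean_mask, spacing))
  true_vd <- vessel_density(sk)

  bg <- 0.15; fgl <- 0.85
  clean <- bg + (fgl - bg) * clean_mask
  sd_eff <- params$noise_sd * (1 + (10 - params$signal_strength) / 5)
  noisy <- clean * exp(stats::rnorm(length(clean), 0, sd_eff))
  noisy <- matrix(pmin(1, pmax(0, noisy)), n_px, n_px)
  img <- angiogram_image(noisy, spacing, plexus, params$signal_strength)
  faz_mask <- if (sum(ras$faz) > 0) roi_mask(ras$faz) else NULL
  list(image = img,
       truth = list(mask = binary_slab(clean_mask, spacing),
                    faz_mask = faz_mask, true_vd = true_vd, network = net))
}

# Continuous-coordinate network: data.frame of segments (x0,y0,x1,y1,w_mm)
# plus the FAZ ellipse. Capillary segments are appended until the mask
# rasterized at n_px reaches the fill target.
grow_vessel_network <- function(params, n_px = 245L, max_batches = 400L) {
  w_mm <- params$vessel_width_px * SCAN_MM / 245
  cap_w_mm <- 1.0 * SCAN_MM / 245
  faz <- faz_ellipse(params)

  segs <- grow_seed_vessels(params, w_mm, faz)
  if (!is.null(faz)) segs <- rbind(segs, faz_ring_segments(faz, cap_w_mm))

  # incremental capillary mesh until fill target reached at native grid
  acc <- rasterize_segments(segs, n_px)
  if (!is.null(faz)) acc[as.logical(ellipse_mask(faz, n_px))] <- 0
  fill <- mean(acc)
  batch <- 0L
  all_caps <- NULL
  while (fill < params$capillary_fill_target && batch < max_batches) {
    batch <- batch + 1L
    caps <- capillary_batch(60L, cap_w_mm, faz)
    all_caps <- rbind(all_caps, caps)
    add <- rasterize_segments(caps, n_px)
    if (!is.null(faz)) add[as.logical(ellipse_mask(faz, n_px))] <- 0
    acc <- pmax(acc, add)
    fill <- mean(acc)
  }
  if (fill < params$capillary_fill_target)
    stop(sprintf("capillary fill target %.2f unreachable (reached %.2f after %d batches)",
                 params$capillary_fill_target, fill, batch))
  structure(list(segments = rbind(segs, all_caps), faz = faz),
            class = "vessel_network")
}

faz_ellipse <- function(params) {
  if (params$faz_area_mm2 <= 0) return(NULL)
  ratio <- sqrt(1 - params$faz_eccentricity^2)  # b/a
  a <- sqrt(params$faz_area_mm2 / (pi * ratio))
  list(cx = SCAN_MM / 2, cy = SCAN_MM / 2, a = a, b = a * ratio,
       theta = stats::runif(1, 0, pi))
}

# pixel-center mask of the ellipse interior at resolution n_px
ellipse_mask <- function(faz, n_px) {
  s <- SCAN_MM / n_px
  xy <- (seq_len(n_px) - 0.5) * s
  X <- matrix(xy, n_px, n_px) - faz$cx          # rows = x
  Y <- matrix(xy, n_px, n_px, byrow = TRUE) - faz$cy
  u <- X * cos(faz$theta) + Y * sin(faz$theta)
  v <- -X * sin(faz$theta) + Y * cos(faz$theta)
  ((u / faz$a)^2 + (v / faz$b)^2 <= 1) * 1
}

inside_faz <- function(faz, x, y) {
  if (is.null(faz)) return(rep(FALSE, length(x)))
  u <- (x - faz$cx) * cos(faz$theta) + (y - faz$cy) * sin(faz$theta)
  v <- -(x - faz$cx) * sin(faz$theta) + (y - faz$cy) * cos(faz$theta)
  (u / faz$a)^2 + (v / faz$b)^2 <= 1
}

# larger vessels: random walks from the border toward the center, with
# branching; polylines broken into short segments
grow_seed_vessels <- function(params, w_mm, faz) {
  segs <- NULL
  if (params$n_seed_vessels < 1) return(empty_segments())
  step <- 0.06
  queue <- list()
  for (i in seq_len(params$n_seed_vessels)) {
    side <- sample(4, 1)
    t <- stats::runif(1, 0.1, 0.9) * SCAN_MM
    start <- switch(side, c(t, 0.01), c(t, SCAN_MM - 0.01),
                    c(0.01, t), c(SCAN_MM - 0.01, t))
    head_angle <- atan2(SCAN_MM / 2 - start[2], SCAN_MM / 2 - start[1]) +
      stats::runif(1, -0.5, 0.5)
    queue[[length(queue) + 1]] <- list(p = start, ang = head_angle,
                                       w = w_mm, life = 40L, depth = 0L)
  }
  while (length(queue) > 0) {
    st <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    p <- st$p; ang <- st$ang
    for (k in seq_len(st$life)) {
      ang <- ang + stats::rnorm(1, 0, 0.35)
      q <- p + step * c(cos(ang), sin(ang))
      if (q[1] < 0 || q[1] > SCAN_MM || q[2] < 0 || q[2] > SCAN_MM) break
      segs <- rbind(segs, c(p[1], p[2], q[1], q[2], st$w))
      p <- q
      # at most one branching generation keeps the tree sparse: the fine
      # mesh is the capillary stage's job, not the arteriole walk's
      if (st$depth == 0L && stats::runif(1) < params$branching_prob) {
        queue[[length(queue) + 1]] <-
          list(p = p, ang = ang + sample(c(-1, 1), 1) * stats::runif(1, 0.5, 1.1),
               w = st$w * 0.75, life = 15L, depth = 1L)
      }
    }
  }
  as_segments(segs)
}

capillary_batch <- function(n, w_mm, faz) {
  x0 <- stats::runif(n, 0, SCAN_MM)
  y0 <- stats::runif(n, 0, SCAN_MM)
  len <- stats::runif(n, 0.08, 0.25)
  ang <- stats::runif(n, 0, 2 * pi)
  x1 <- pmin(SCAN_MM, pmax(0, x0 + len * cos(ang)))
  y1 <- pmin(SCAN_MM, pmax(0, y0 + len * sin(ang)))
  keep <- !(inside_faz(faz, x0, y0) & inside_faz(faz, x1, y1))
  as_segments(cbind(x0, y0, x1, y1, w_mm)[keep, , drop = FALSE])
}

# perifoveal arcade: a capillary ring just outside the avascular ellipse
faz_ring_segments <- function(faz, w_mm) {
  tt <- seq(0, 2 * pi, length.out = 180)
  off <- w_mm
  u <- (faz$a + off) * cos(tt)
  v <- (faz$b + off) * sin(tt)
  x <- faz$cx + u * cos(faz$theta) - v * sin(faz$theta)
  y <- faz$cy + u * sin(faz$theta) + v * cos(faz$theta)
  n <- length(tt) - 1
  as_segments(cbind(x[1:n], y[1:n], x[2:(n + 1)], y[2:(n + 1)], w_mm))
}

empty_segments <- function() {
  as_segments(matrix(numeric(0), ncol = 5))
}

as_segments <- function(m) {
  m <- matrix(m, ncol = 5)
  colnames(m) <- c("x0", "y0", "x1", "y1", "w_mm")
  m
}

#' Rasterize a continuous vessel network at a given resolution
#'
#' Stamps every network segment onto an `n_px` x `n_px` grid covering the
#' 3 x 3 mm scan, with each segment's physical width, then carves the
#' avascular ellipse. Rasterizing the same network at two resolutions gives
#' density metrics that agree up to discretization.
#'
#' @param network A `vessel_network` from [generate_angiogram]'s truth or
#'   built internally.
#' @param n_px Grid size.
#' @return A list with `mask` (0/1 matrix) and `faz` (0/1 matrix of the
#'   avascular interior; all zero when the network has no FAZ).
#' @export
rasterize_network <- function(network, n_px = 245L) {
  stopifnot(inherits(network, "vessel_network"))
  mask <- rasterize_segments(network$segments, n_px)
  faz <- matrix(0, n_px, n_px)
  if (!is.null(network$faz)) {
    faz <- ellipse_mask(network$faz, n_px)
    mask[as.logical(faz)] <- 0
  }
  list(mask = mask, faz = faz)
}

rasterize_segments <- function(segs, n_px) {
  m <- matrix(0, n_px, n_px)
  if (nrow(segs) == 0) return(m)
  s <- SCAN_MM / n_px
  for (i in seq_len(nrow(segs))) {
    x0 <- segs[i, 1]; y0 <- segs[i, 2]; x1 <- segs[i, 3]; y1 <- segs[i, 4]
    w_px <- segs[i, 5] / s
    len_px <- sqrt((x1 - x0)^2 + (y1 - y0)^2) / s
    npts <- max(2L, ceiling(len_px / 0.4))
    tt <- seq(0, 1, length.out = npts)
    px <- (x0 + tt * (x1 - x0)) / s + 0.5
    py <- (y0 + tt * (y1 - y0)) / s + 0.5
    r <- max(0.5, w_px / 2)
    ir <- ceiling(r - 0.5)
    offs <- expand.grid(dr = -ir:ir, dc = -ir:ir)
    offs <- offs[offs$dr^2 + offs$dc^2 <= r^2 + 1e-9, , drop = FALSE]
    if (nrow(offs) == 0) offs <- data.frame(dr = 0, dc = 0)
    rr <- outer(round(px), offs$dr, `+`)
    cc <- outer(round(py), offs$dc, `+`)
    ok <- rr >= 1 & rr <= n_px & cc >= 1 & cc <= n_px
    m[cbind(rr[ok], cc[ok])] <- 1
  }
  m
}
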