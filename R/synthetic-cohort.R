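#' Generate a synthetic longitudinal cohort
#'
#' Draws, per patient, sex and demographics from group-specific
#' distributions, then a three-visit trajectory of every eye-level metric.
#' The three vessel densities (SCP, DCP, FR) are drawn jointly from a
#' trivariate normal whose correlation matrix carries the configured
#' inter-plexus targets; visit-to-visit dependence of every metric is an
#' AR(1) on the standardized deviation with persistence `rho_visit`, so the
#' marginal distribution at each visit matches the configured per-visit
#' mean and SD exactly. Diabetic eyes additionally fail scan quality per
#' visit, independently, with probability `quality_fail_p` (either a low
#' signal strength or a motion-artifact flag); controls always pass.
#'
#' More diabetic eyes are generated than will survive the three-visit
#' quality rule: enrolled group sizes are the analyzed targets scaled to
#' `enrolled_total` (default 62), so the expected retention matches the
#' configured quality-failure rate.
#'
#' Deterministic given `rng_seed`.
#'
#' @param config A [cohort_config].
#' @param rng_seed Integer seed; defaults to the one in `config`.
#' @param enrolled If `FALSE`, generate the analyzed group sizes directly
#'   (all eyes passing quality); useful for statistical tests that need
#'   fixed group sizes.
#' @return A data.frame, one row per (patient, visit), with columns
#'   `patient_id, eye, visit, sex, age, drss_group, vd_scp, vd_dcp, vd_fr,
#'   faz_area_mm2, faz_circularity, crt_um, rnfl_um, gcl_ipl_um, hba1c_pct,
#'   bcva_letters, diabetes_duration_y, signal_strength, artifact_flag`.
#' @export
generate_cohort <- function(config = cohort_config(),
                            rng_seed = config$rng_seed,
                            enrolled = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(as.integer(rng_seed))
  sizes <- config$group_sizes
  dia_groups <- c("10-20", "35", "43-47")
  n_by_group <- c(control = unname(sizes["control"]),
                  if (enrolled) stats::setNames(enrolled_group_sizes(config), dia_groups)
                  else sizes[dia_groups])
  out <- list()
  pid0 <- 0L
  for (g in names(n_by_group)) {
    n <- n_by_group[[g]]
    out[[g]] <- simulate_group(g, n, config, pid0)
    pid0 <- pid0 + n
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

simulate_group <- function(g, n, config, pid0) {
  tr <- config$trajectories[[g]]
  dm <- config$demographics[[g]]
  rho <- config$rho_visit
  sex <- ifelse(stats::runif(n) < dm$female_prop, "F", "M")
  age <- stats::rnorm(n, dm$age[1], dm$age[2])
  duration <- if (is.na(dm$duration[1])) rep(NA_real_, n) else
    pmax(0.5, stats::rnorm(n, dm$duration[1], dm$duration[2]))
  hba1c <- if (is.na(dm$hba1c[1])) rep(NA_real_, n) else
    pmax(4, stats::rnorm(n, dm$hba1c[1], dm$hba1c[2]))
  bcva <- if (is.na(dm$bcva[1])) rep(NA_real_, n) else
    pmin(100, stats::rnorm(n, dm$bcva[1], dm$bcva[2]))
  faz_area0 <- pmax(0.02, stats::rnorm(n, dm$faz_area[1], dm$faz_area[2]))
  eye <- sample(c("OD", "OS"), n, replace = TRUE)

  # latent standardized deviations: visit 1 draw, then AR(1) persistence
  zvd <- array(NA_real_, c(n, 3, 3))  # patient x plexus x visit
  zvd[, , 1] <- MASS::mvrnorm(n, rep(0, 3), config$corr)
  for (v in 2:3)
    zvd[, , v] <- rho * zvd[, , v - 1] +
      sqrt(1 - rho^2) * MASS::mvrnorm(n, rep(0, 3), config$corr)
  zuni <- function() {
    z <- matrix(NA_real_, n, 3)
    z[, 1] <- stats::rnorm(n)
    for (v in 2:3) z[, v] <- rho * z[, v - 1] + sqrt(1 - rho^2) * stats::rnorm(n)
    z
  }
  z_circ <- zuni(); z_rnfl <- zuni(); z_gcl <- zuni(); z_crt <- zuni()

  is_dia <- g != "control"
  rows <- list()
  for (v in 1:3) {
    val <- function(metric, z) tr[[metric]]$mean[v] + tr[[metric]]$sd[v] * z
    crt_mean_shift <- ifelse(sex == "M", config$crt_sex_offset_um,
                             -config$crt_sex_offset_um)
    fail <- if (is_dia) stats::runif(n) < config$quality_fail_p else rep(FALSE, n)
    low_ss <- fail & stats::runif(n) < 0.7
    ss <- ifelse(low_ss, sample(4:6, n, replace = TRUE),
                 sample(7:10, n, replace = TRUE, prob = c(0.15, 0.3, 0.35, 0.2)))
    artifact <- fail & !low_ss
    rows[[v]] <- data.frame(
      patient_id = sprintf("P%03d", pid0 + seq_len(n)),
      eye = eye, visit = v, sex = sex, age = round(age, 1),
      drss_group = g,
      vd_scp = pmax(0, val("vd_scp", zvd[, 1, v])),
      vd_dcp = pmax(0, val("vd_dcp", zvd[, 2, v])),
      vd_fr = pmax(0, val("vd_fr", zvd[, 3, v])),
      faz_area_mm2 = pmax(0, faz_area0 + stats::rnorm(n, 0, 0.01)),
      faz_circularity = pmin(1, pmax(0, val("faz_circularity", z_circ[, v]))),
      crt_um = pmax(120, val("crt_um", z_crt[, v]) + crt_mean_shift),
      rnfl_um = pmax(0.1, val("rnfl_um", z_rnfl[, v])),
      gcl_ipl_um = pmax(30, val("gcl_ipl_um", z_gcl[, v])),
      hba1c_pct = round(hba1c, 1),
      bcva_letters = round(bcva),
      diabetes_duration_y = round(duration, 1),
      signal_strength = as.integer(ss),
      artifact_flag = artifact,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  res[order(res$patient_id, res$visit), ]
}

#' Render cohort records as synthetic angiograms
#'
#' For each (patient, visit) record, calibrates the generator's capillary
#' fill target by bisection until the measured full-retina vessel density
#' of the rendered image (Otsu binarization, skeletonization, skeleton-mean
#' scaling) is within `tol_frac` of the record's `vd_fr`. Used as an
#' end-to-end integration fixture tying the cohort table to the image
#' pipeline.
#'
#' @param records Cohort data.frame rows (see [generate_cohort]).
#' @param base_params An [angiogram_params] supplying everything except the
#'   fill target and seed.
#' @param n_px Grid size; coarser grids render faster.
#' @param tol_frac Relative tolerance on the measured vessel density.
#' @param max_iter Bisection iterations per record.
#' @return A list with `images` (list of [angiogram_image]) and `manifest`
#'   (data.frame of patient_id, eye, visit, plexus, target_vd, measured_vd,
#'   signal_strength).
#' @export
cohort_to_images <- function(records, base_params = angiogram_params(),
                             n_px = 245L, tol_frac = 0.05, max_iter = 10L) {
  if (nrow(records) == 0)
    return(list(images = list(),
                manifest = data.frame(patient_id = character(0),
                                      eye = character(0), visit = integer(0),
                                      plexus = character(0),
                                      target_vd = numeric(0),
                                      measured_vd = numeric(0),
                                      signal_strength = integer(0))))
  spacing <- SCAN_MM / n_px
  vd_max <- 1 / spacing
  images <- list()
  man <- NULL
  for (i in seq_len(nrow(records))) {
    target <- records$vd_fr[i]
    if (!is.finite(target) || target < 0 || target >= vd_max)
      stop(sprintf("record vd_fr = %.1f outside achievable range [0, %.1f)",
                   target, vd_max))
    seed <- as.integer((base_params$rng_seed + i * 1000L) %% .Machine$integer.max)
    lo <- 0.02; hi <- 0.78
    best <- NULL
    for (it in seq_len(max_iter)) {
      mid <- (lo + hi) / 2
      p <- base_params
      p$capillary_fill_target <- mid
      p$rng_seed <- seed
      p$signal_strength <- records$signal_strength[i]
      gen <- generate_angiogram(p, n_px = n_px)
      slab <- binarize_angiogram(gen$image, "otsu")
      vd <- vessel_density(skeletonize_slab(slab))
      best <- list(gen = gen, vd = vd)
      if (abs(vd - target) / target <= tol_frac) break
      if (vd < target) lo <- mid else hi <- mid
    }
    images[[i]] <- best$gen$image
    man <- rbind(man, data.frame(
      patient_id = records$patient_id[i], eye = records$eye[i],
      visit = records$visit[i], plexus = "FR",
      target_vd = target, measured_vd = best$vd,
      signal_strength = records$signal_strength[i],
      stringsAsFactors = FALSE))
  }
  list(images = images, manifest = man)
}
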