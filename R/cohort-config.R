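#' Default configuration of the synthetic longitudinal cohort
#'
#' Encodes the study conditions the generator emulates: three diabetic
#' severity groups on the Diabetic Retinopathy Severity Scale (DRSS/ETDRS
#' 10-20, 35 and 43-47, analyzed n = 18/17/9) plus 84 healthy-control eyes;
#' per-group per-visit means and SDs of the vessel-density, FAZ and
#' thickness metrics; the inter-plexus correlation structure of vessel
#' density (SCP-DCP 0.77, SCP-FR 0.96, DCP-FR 0.84); and a per-visit
#' scan-quality failure probability calibrated so that, over three visits,
#' the expected retention of diabetic eyes is 44 of 62 enrolled.
#'
#' @param group_sizes Named analyzed-group sizes.
#' @param enrolled_total Total diabetic eyes enrolled before the
#'   three-visit quality rule; enrolled per-group sizes are obtained by
#'   largest-remainder scaling of the analyzed sizes.
#' @param rho_plexus Inter-plexus correlation targets, order
#'   (SCP-DCP, SCP-FR, DCP-FR).
#' @param rho_visit Within-eye visit-to-visit persistence (AR(1)) of each
#'   metric's standardized deviation.
#' @param quality_fail_p Per-visit, per-eye probability that a diabetic
#'   eye's scan fails quality; default solves (1 - p)^3 = 44/62.
#' @param crt_sex_offset_um Central-retinal-thickness shift applied +/- by
#'   sex (men thicker), consistent with the sex-specific edema thresholds
#'   being 15 um apart.
#' @param rng_seed Integer seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(group_sizes = c(control = 84L, `10-20` = 18L,
                                          `35` = 17L, `43-47` = 9L),
                          enrolled_total = 62L,
                          rho_plexus = c(0.77, 0.96, 0.84),
                          rho_visit = 0.8,
                          quality_fail_p = 1 - (44 / 62)^(1 / 3),
                          crt_sex_offset_um = 7.5,
                          rng_seed = 1L) {
  groups <- c("control", "10-20", "35", "43-47")
  stopifnot(all(groups %in% names(group_sizes)), all(group_sizes >= 1))
  R <- matrix(c(1, rho_plexus[1], rho_plexus[2],
                rho_plexus[1], 1, rho_plexus[3],
                rho_plexus[2], rho_plexus[3], 1), 3, 3,
              dimnames = list(c("scp", "dcp", "fr"), c("scp", "dcp", "fr")))
  if (any(eigen(R, symmetric = TRUE, only.values = TRUE)$values <= 1e-10))
    stop("inter-plexus correlation matrix is not positive definite")

  # per-group, per-visit means/SDs of the longitudinal metrics; controls are
  # stationary at their cross-sectional values
  v3 <- function(m1, m2, m3, s1, s2, s3)
    list(mean = c(m1, m2, m3), sd = c(s1, s2, s3))
  flat <- function(m, s) v3(m, m, m, s, s, s)
  traj <- list(
    control = list(
      vd_scp = flat(21.1, 0.7), vd_dcp = flat(16.1, 1.8), vd_fr = flat(22.4, 0.6),
      faz_circularity = flat(0.65, 0.07), rnfl_um = flat(7.0, 3.4),
      gcl_ipl_um = flat(82.7, 5.5), crt_um = flat(260.6, 18.3)),
    `10-20` = list(
      vd_scp = v3(20.5, 19.4, 18.8, 1.0, 1.3, 1.5),
      vd_dcp = v3(16.0, 14.7, 13.9, 1.5, 2.1, 1.9),
      vd_fr  = v3(22.2, 21.3, 20.7, 0.8, 1.1, 1.2),
      faz_circularity = v3(0.7, 0.7, 0.6, 0.1, 0.1, 0.1),
      rnfl_um = v3(6.3, 6.0, 6.0, 2.9, 2.8, 3.0),
      gcl_ipl_um = v3(82.0, 81.4, 81.7, 6.6, 6.1, 6.6),
      crt_um = v3(261.6, 261.7, 261.8, 25.2, 26.5, 26.2)),
    `35` = list(
      vd_scp = v3(19.4, 18.6, 17.9, 1.6, 2.1, 1.7),
      vd_dcp = v3(15.5, 14.8, 13.7, 2.1, 2.5, 2.3),
      vd_fr  = v3(21.4, 20.5, 20.0, 1.5, 2.0, 1.6),
      faz_circularity = v3(0.6, 0.6, 0.6, 0.1, 0.1, 0.1),
      rnfl_um = v3(7.1, 7.1, 6.0, 3.4, 3.9, 3.0),
      gcl_ipl_um = v3(76.2, 76.5, 76.5, 7.4, 6.7, 7.2),
      crt_um = v3(270.4, 270.5, 271.1, 30.1, 29.2, 29.9)),
    `43-47` = list(
      vd_scp = v3(19.5, 18.9, 17.9, 1.8, 1.6, 2.4),
      vd_dcp = v3(14.8, 14.1, 13.3, 2.9, 2.9, 2.6),
      vd_fr  = v3(21.1, 20.7, 19.5, 1.6, 1.6, 2.1),
      faz_circularity = v3(0.6, 0.6, 0.5, 0.1, 0.1, 0.1),
      rnfl_um = v3(6.3, 6.9, 6.7, 1.8, 2.4, 4.5),
      gcl_ipl_um = v3(81.3, 81.7, 81.7, 8.4, 8.2, 8.3),
      crt_um = v3(260.7, 262.7, 263.3, 27.0, 29.0, 28.5)))

  demo <- list(
    control = list(age = c(69.2, 4.5), female_prop = 45 / 84,
                   duration = c(NA, NA), hba1c = c(NA, NA), bcva = c(NA, NA),
                   faz_area = c(0.24, 0.11)),
    `10-20` = list(age = c(66.4, 6.6), female_prop = 8 / 18,
                   duration = c(17.9, 7.5), hba1c = c(6.7, 0.9),
                   bcva = c(82.8, 5.2), faz_area = c(0.27, 0.12)),
    `35` = list(age = c(64.9, 6.0), female_prop = 2 / 17,
                duration = c(16.1, 5.9), hba1c = c(6.9, 1.1),
                bcva = c(84.1, 3.2), faz_area = c(0.23, 0.12)),
    `43-47` = list(age = c(62.4, 8.5), female_prop = 3 / 9,
                   duration = c(16.1, 5.5), hba1c = c(7.6, 1.2),
                   bcva = c(82.8, 4.4), faz_area = c(0.23, 0.08)))

  structure(list(groups = groups,
                 group_sizes = group_sizes[groups],
                 enrolled_total = as.integer(enrolled_total),
                 corr = R, rho_visit = rho_visit,
                 quality_fail_p = quality_fail_p,
                 crt_sex_offset_um = crt_sex_offset_um,
                 trajectories = traj, demographics = demo,
                 rng_seed = as.integer(rng_seed)),
            class = "cohort_config")
}

# enrolled diabetic group sizes by largest-remainder scaling to the total
enrolled_group_sizes <- function(config) {
  analyzed <- config$group_sizes[c("10-20", "35", "43-47")]
  total <- config$enrolled_total
  raw <- analyzed * total / sum(analyzed)
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}
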