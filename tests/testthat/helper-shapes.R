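# Geometric fixtures and small cohort helpers shared across test files.

make_disk <- function(n, r, cx = ceiling(n / 2)) {
  outer(seq_len(n) - cx, seq_len(n) - cx, function(a, b) (a^2 + b^2 <= r^2) * 1)
}

make_square <- function(n, side, at = 20) {
  m <- matrix(0, n, n)
  m[at:(at + side - 1), at:(at + side - 1)] <- 1
  m
}

make_ellipse <- function(n, a, b, cx = ceiling(n / 2)) {
  outer(seq_len(n) - cx, seq_len(n) - cx,
        function(x, y) ((x / a)^2 + (y / b)^2 <= 1) * 1)
}

make_cross <- function(n, arm_len, arm_w, cx = ceiling(n / 2)) {
  m <- matrix(0, n, n)
  h <- arm_w %/% 2
  m[(cx - arm_len):(cx + arm_len), (cx - h):(cx + h)] <- 1
  m[(cx - h):(cx + h), (cx - arm_len):(cx + arm_len)] <- 1
  m
}

# reference with round numbers for threshold tests
test_reference <- function(k_sd = 2) {
  vals <- list(
    vd_scp = list(F = c(mean = 21.1, sd = 0.7), M = c(mean = 21.1, sd = 0.7)),
    vd_dcp = list(F = c(mean = 16.1, sd = 1.8), M = c(mean = 16.1, sd = 1.8)),
    vd_fr = list(F = c(mean = 22.4, sd = 0.6), M = c(mean = 22.4, sd = 0.6)),
    rnfl_um = list(F = c(mean = 7.0, sd = 3.4), M = c(mean = 7.0, sd = 3.4)),
    gcl_ipl_um = list(F = c(mean = 82.7, sd = 5.5), M = c(mean = 82.7, sd = 5.5)),
    crt_um = list(F = c(mean = 260.6, sd = 18.3), M = c(mean = 260.6, sd = 18.3)),
    faz_circularity = list(F = c(mean = 0.65, sd = 0.07), M = c(mean = 0.65, sd = 0.07)))
  control_reference(k_sd = k_sd, values = vals)
}

# one eye's visit rows with chosen vessel densities, quality fields clean
make_eye_records <- function(patient_id = "P001", vd_scp = c(20.5, 19.4, 18.8),
                             vd_dcp = c(16.0, 14.7, 13.9),
                             vd_fr = c(22.2, 21.3, 20.7),
                             sex = "M", ss = c(9, 9, 9),
                             artifact = c(FALSE, FALSE, FALSE),
                             n_visits = 3) {
  v <- seq_len(n_visits)
  data.frame(patient_id = patient_id, eye = "OD", visit = v, sex = sex,
             age = 65, drss_group = "10-20",
             vd_scp = vd_scp[v], vd_dcp = vd_dcp[v], vd_fr = vd_fr[v],
             faz_area_mm2 = 0.25, faz_circularity = 0.65,
             crt_um = 260, rnfl_um = 7, gcl_ipl_um = 82,
             hba1c_pct = 6.8, bcva_letters = 84, diabetes_duration_y = 15,
             signal_strength = ss[v], artifact_flag = artifact[v],
             stringsAsFactors = FALSE)
}

# cohort config with no longitudinal decline: every diabetic group holds its
# baseline mean/SD across all three visits
null_decline_config <- function(...) {
  cfg <- cohort_config(...)
  for (g in c("10-20", "35", "43-47")) {
    for (m in names(cfg$trajectories[[g]])) {
      tr <- cfg$trajectories[[g]][[m]]
      cfg$trajectories[[g]][[m]]$mean <- rep(tr$mean[1], 3)
      cfg$trajectories[[g]][[m]]$sd <- rep(tr$sd[1], 3)
    }
  }
  cfg
}

# config where every group shares the control distributions (global null)
null_group_config <- function(group_sizes = c(control = 20L, `10-20` = 15L,
                                              `35` = 15L, `43-47` = 15L)) {
  cfg <- cohort_config(group_sizes = group_sizes)
  for (g in c("10-20", "35", "43-47")) {
    cfg$trajectories[[g]] <- cfg$trajectories[["control"]]
    cfg$demographics[[g]]$age <- cfg$demographics[["control"]]$age
  }
  cfg
}
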