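test_that("cohort generation is deterministic and carries the full schema", {
  cfg <- cohort_config()
  a <- generate_cohort(cfg, rng_seed = 5)
  b <- generate_cohort(cfg, rng_seed = 5)
  expect_identical(a, b)
  expect_true(all(c("patient_id", "eye", "visit", "sex", "age", "drss_group",
                    "vd_scp", "vd_dcp", "vd_fr", "faz_area_mm2",
                    "faz_circularity", "crt_um", "rnfl_um", "gcl_ipl_um",
                    "hba1c_pct", "bcva_letters", "diabetes_duration_y",
                    "signal_strength", "artifact_flag") %in% names(a)))
  expect_true(all(a$visit %in% 1:3))
  expect_true(all(a$vd_scp >= 0 & a$vd_dcp >= 0 & a$vd_fr >= 0))
})

test_that("an invalid correlation target is rejected by name", {
  expect_error(cohort_config(rho_plexus = c(0.99, 0.99, -0.9)),
               "positive definite")
})

test_that("group means and SDs are recovered at 10x group sizes", {
  cfg <- cohort_config(group_sizes = c(control = 840L, `10-20` = 180L,
                                       `35` = 170L, `43-47` = 90L))
  co <- generate_cohort(cfg, rng_seed = 2, enrolled = FALSE)
  for (g in c("35", "10-20")) {
    for (v in c(1, 3)) {
      x <- co$vd_scp[co$drss_group == g & co$visit == v]
      target <- cfg$trajectories[[g]]$vd_scp
      se <- target$sd[v] / sqrt(length(x))
      expect_lt(abs(mean(x) - target$mean[v]), 3 * se)
      expect_lt(abs(sd(x) - target$sd[v]) / target$sd[v], 0.15)
    }
  }
})

test_that("inter-plexus correlations converge to their targets", {
  cfg <- cohort_config(group_sizes = c(control = 840L, `10-20` = 180L,
                                       `35` = 170L, `43-47` = 90L))
  co <- generate_cohort(cfg, rng_seed = 3, enrolled = FALSE)
  ctl <- co[co$drss_group == "control" & co$visit == 1, ]
  expect_lt(abs(cor(ctl$vd_scp, ctl$vd_dcp) - 0.77), 0.06)
  expect_lt(abs(cor(ctl$vd_scp, ctl$vd_fr) - 0.96), 0.02)
  expect_lt(abs(cor(ctl$vd_dcp, ctl$vd_fr) - 0.84), 0.05)
})

test_that("with zero decline, per-visit group means agree within 3 SE", {
  cfg <- null_decline_config(group_sizes = c(control = 84L, `10-20` = 180L,
                                             `35` = 170L, `43-47` = 90L))
  co <- generate_cohort(cfg, rng_seed = 4, enrolled = FALSE)
  g <- co[co$drss_group == "35", ]
  m1 <- mean(g$vd_scp[g$visit == 1]); m3 <- mean(g$vd_scp[g$visit == 3])
  n <- sum(g$visit == 1)
  se_diff <- 1.6 * sqrt(2 * (1 - cfg$rho_visit^2)) / sqrt(n)
  expect_lt(abs(m1 - m3), 3 * se_diff)
})

test_that("expected retention under the three-visit quality rule is ~44/62", {
  cfg <- cohort_config()
  ret <- vapply(1:40, function(s) {
    co <- generate_cohort(cfg, rng_seed = 4000 + s)
    dia <- co[co$drss_group != "control", ]
    qf <- quality_filter(dia)
    length(qf$retained) / (length(qf$retained) + length(qf$excluded))
  }, numeric(1))
  expect_lt(abs(mean(ret) - 44 / 62), 0.1)
})

test_that("cohort records render to images whose measured VD hits the target", {
  rec <- make_eye_records(vd_fr = c(21.7, 21.7, 21.7))[1, ]
  out <- cohort_to_images(rec, angiogram_params(rng_seed = 31), n_px = 245)
  expect_equal(nrow(out$manifest), 1)
  expect_gte(out$manifest$measured_vd, 21.7 * 0.95)
  expect_lte(out$manifest$measured_vd, 21.7 * 1.05)
})

test_that("unachievable record densities and empty inputs are handled", {
  rec <- make_eye_records()[1, ]
  rec$vd_fr <- 500
  expect_error(cohort_to_images(rec), "achievable range")
  empty <- make_eye_records()[0, ]
  out <- cohort_to_images(empty)
  expect_equal(length(out$images), 0)
  expect_equal(nrow(out$manifest), 0)
})
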