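test_that("edema classification honors the sex-specific CRT cutpoints", {
  expect_equal(classify_edema(292, "F"), "clinical")
  expect_equal(classify_edema(280, "M"), "subclinical")
  expect_equal(classify_edema(259.9, "F"), "none")
  # boundaries: lower bounds closed, clinical takes ">="
  expect_equal(classify_edema(290, "F"), "clinical")
  expect_equal(classify_edema(289.99, "F"), "subclinical")
  expect_equal(classify_edema(260, "F"), "subclinical")
  expect_equal(classify_edema(305, "M"), "clinical")
  expect_equal(classify_edema(275, "M"), "subclinical")
  expect_equal(classify_edema(274.9, "M"), "none")
  expect_error(classify_edema(0, "F"), "positive")
})

test_that("increasing CRT never moves the edema call toward milder", {
  lev <- c(none = 1, subclinical = 2, clinical = 3)
  for (sex in c("F", "M")) {
    calls <- lev[classify_edema(seq(200, 350, by = 0.5), sex)]
    expect_true(all(diff(calls) >= 0))
  }
})

test_that("neurodegeneration uses strict k-SD bounds with OR semantics", {
  ref <- test_reference()
  # exactly at mean - 2 SD: not flagged (strict inequality)
  expect_false(classify_neurodegeneration(7.0 - 2 * 3.4, 82.7, "F", ref))
  # either layer below suffices
  expect_true(classify_neurodegeneration(7.0, 82.7 - 3 * 5.5, "M", ref))
  expect_true(classify_neurodegeneration(7.0 - 2.1 * 3.4, 82.7, "F", ref))
  expect_false(classify_neurodegeneration(7.0, 82.7, "F", ref))
  bad_ref <- control_reference(values = list(
    rnfl_um = list(F = c(mean = 7, sd = 3.4), M = c(mean = 7, sd = 3.4))))
  expect_error(classify_neurodegeneration(7, 82, "F", bad_ref), "gcl_ipl_um")
})

test_that("capillary dropout threshold sits at mean - k SD, strict", {
  ref <- test_reference()
  expect_true(classify_dropout(19.6, "vd_scp", "F", ref))   # threshold 19.7
  expect_false(classify_dropout(21.1, "vd_scp", "F", ref))
  expect_false(classify_dropout(19.7, "vd_scp", "F", ref))  # boundary
})

test_that("flag rates on control-distributed values match the normal tail", {
  ref <- test_reference()
  set.seed(99)
  n <- 2000
  vd <- rnorm(n, 21.1, 0.7)
  rate <- mean(classify_dropout(vd, "vd_scp", "F", ref))
  expect_lt(abs(rate - pnorm(-2)), 0.02)
  rnfl <- rnorm(n, 7.0, 3.4); gcl <- rnorm(n, 82.7, 5.5)
  nd_rate <- mean(classify_neurodegeneration(rnfl, gcl, "F", ref))
  expect_lt(abs(nd_rate - (1 - (1 - pnorm(-2))^2)), 0.02)
})

test_that("the relative decrease threshold reproduces the 3-SD = 10% rule", {
  x <- relative_decrease_threshold(21.1, 0.7, 3)
  expect_lt(abs(x - 9.95), 0.01)
  expect_equal(round_half_up(x), 10)
  expect_equal(relative_decrease_threshold(21.1, 0.7, 0), 0)
  expect_equal(relative_decrease_threshold(10, 1, 3), 30)
  expect_error(relative_decrease_threshold(0, 1, 3), "ref_mean")
  expect_error(relative_decrease_threshold(10, 0, 3), "ref_sd")
})

test_that("progression uses a strict more-than comparison", {
  expect_true(progression_flag(20.0, 17.9))   # 10.5%
  expect_false(progression_flag(20.0, 18.1))  # 9.5%
  expect_false(progression_flag(20.0, 18.0))  # exactly 10%
  expect_error(progression_flag(0, 10), "positive")
})

test_that("decreasing follow-up VD never unsets the progression flag", {
  fu <- seq(19, 15, by = -0.1)
  flags <- progression_flag(20, fu)
  expect_true(all(diff(as.integer(flags)) >= 0))
})

test_that("the quality filter retains only clean three-visit eyes", {
  good <- make_eye_records("P001", ss = c(8, 7, 9))
  bad_ss <- make_eye_records("P002", ss = c(9, 6, 9))
  bad_art <- make_eye_records("P003", artifact = c(FALSE, TRUE, FALSE))
  short <- make_eye_records("P004", n_visits = 2)
  qf <- quality_filter(rbind(good, bad_ss, bad_art, short))
  expect_equal(qf$retained, "P001:OD")
  expect_setequal(qf$excluded, c("P002:OD", "P003:OD", "P004:OD"))
  expect_match(qf$reasons$reason[qf$reasons$eye_key == "P002:OD"], "signal")
  dup <- rbind(good, good[1, ])
  expect_error(quality_filter(dup), "duplicate")
})

test_that("a 62-eye cohort with 18 failing eyes retains 44", {
  recs <- do.call(rbind, lapply(1:62, function(i)
    make_eye_records(sprintf("P%03d", i),
                     ss = if (i <= 18) c(9, 6, 9) else c(8, 9, 7))))
  qf <- quality_filter(recs)
  expect_equal(length(qf$retained), 44)
  expect_equal(length(qf$excluded), 18)
})

test_that("phenotype_eye computes baseline calls and progression flags", {
  ref <- test_reference()
  # group-mean trajectory: SCP 20.5 -> 18.8 is an 8.3% decrease, not flagged
  eye <- make_eye_records(vd_scp = c(20.5, 19.4, 18.8),
                          vd_dcp = c(16.0, 14.7, 13.9))
  ph <- phenotype_eye(eye, ref)
  expect_false(ph$prog_scp_v31)   # 8.29% < 10%
  expect_true(ph$prog_dcp_v31)    # 13.1% > 10%
  expect_false(ph$prog_scp_v21)
  # a control-like stable eye raises no flags
  ctl <- make_eye_records(vd_scp = c(21.1, 21.0, 21.2),
                          vd_dcp = c(16.1, 16.0, 16.2),
                          vd_fr = c(22.4, 22.3, 22.5))
  pc <- phenotype_eye(ctl, ref)
  expect_equal(pc$edema_status, "none")
  expect_false(pc$neurodeg); expect_false(pc$dropout)
  expect_false(any(unlist(pc[grep("prog_", names(pc))])))
  # progression flags only exist for visits that exist
  two <- make_eye_records(n_visits = 2)
  p2 <- phenotype_eye(two, ref)
  expect_true(is.na(p2$prog_scp_v31))
})

test_that("phenotype_cohort joins quality and per-eye calls", {
  recs <- rbind(make_eye_records("P001"),
                make_eye_records("P002", ss = c(6, 9, 9)))
  ph <- phenotype_cohort(recs, test_reference())
  expect_equal(nrow(ph), 2)
  expect_equal(ph$passed_quality, c(TRUE, FALSE))
})
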