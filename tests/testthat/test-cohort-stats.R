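test_that("Mann-Whitney exact p values match full enumeration", {
  r <- mann_whitney(c(1, 2, 3), c(10, 11, 12))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)  # 2/20 labelings as extreme
  set.seed(11)
  for (i in 1:4) {
    a <- rnorm(8); b <- rnorm(sample(5:8, 1)) + runif(1, -1, 1)
    mine <- mann_whitney(a, b)
    expect_equal(mine$p_value, brute_mann_whitney_p(a, b))
    expect_equal(mine$p_value, wilcox.test(a, b, exact = TRUE)$p.value)
  }
})

test_that("Mann-Whitney handles degenerate and large-sample inputs", {
  expect_warning(r <- mann_whitney(rep(1, 5), rep(1, 6)), "tied")
  expect_equal(r$p_value, 1)
  set.seed(12)
  a <- rnorm(30); b <- rnorm(30) + 0.6
  mine <- mann_whitney(a, b)
  expect_equal(mine$method, "normal")
  expect_equal(mine$p_value,
               wilcox.test(a, b, exact = FALSE, correct = FALSE)$p.value)
})

test_that("Wilcoxon signed-rank exact p values match sign-flip enumeration", {
  r <- wilcoxon_signed_rank(rep(0, 5), 1:5)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 2 / 32)
  set.seed(13)
  for (i in 1:4) {
    x <- rnorm(10); y <- x + rnorm(10, 0.3)
    mine <- wilcoxon_signed_rank(x, y)
    expect_equal(mine$p_value, brute_signed_rank_p(x, y))
    expect_equal(mine$p_value,
                 wilcox.test(y, x, paired = TRUE, exact = TRUE)$p.value)
  }
})

test_that("Wilcoxon degenerate and approximate paths behave", {
  expect_warning(r <- wilcoxon_signed_rank(1:5, 1:5), "zero")
  expect_equal(r$p_value, 1)
  set.seed(14)
  x <- rnorm(40); y <- x + rnorm(40, 0.2)
  mine <- wilcoxon_signed_rank(x, y)
  expect_equal(mine$method, "normal")
  expect_equal(mine$p_value,
               wilcox.test(y, x, paired = TRUE, exact = FALSE,
                           correct = FALSE)$p.value)
  # exact and approximate paths agree near the switchover
  x <- rnorm(24); y <- x + rnorm(24, 0.25)
  ex <- wilcoxon_signed_rank(x, y)$p_value
  ap <- wilcox.test(y, x, paired = TRUE, exact = FALSE, correct = FALSE)$p.value
  expect_lt(abs(ex - ap), 0.03)
})

test_that("one-way ANOVA matches the base-R fit", {
  g <- list(a = rnorm(10), b = rnorm(10) + 1, c = rnorm(12))
  mine <- anova_oneway(g)
  base <- summary(aov(unlist(g) ~ factor(rep(names(g), lengths(g)))))[[1]]
  expect_equal(mine$statistic, base[1, "F value"])
  expect_equal(mine$p_value, base[1, "Pr(>F)"])
  same <- list(c(1, 2, 3), c(1, 2, 3))
  expect_equal(anova_oneway(same)$statistic, 0)
  expect_error(anova_oneway(list(c(1, 1), c(2, 2))), "variance")
})

test_that("chi-squared uses no continuity correction and scales linearly", {
  t1 <- matrix(c(10, 0, 0, 10), 2)
  expect_equal(chi_square(t1)$statistic, 20)
  t2 <- matrix(c(12, 5, 7, 9), 2)
  expect_equal(chi_square(t2)$statistic,
               unname(chisq.test(t2, correct = FALSE)$statistic))
  expect_equal(chi_square(3 * t2)$statistic, 3 * chi_square(t2)$statistic)
})

test_that("Pearson correlation and significance match cor.test", {
  x <- 1:10
  expect_equal(pearson(x, 2 * x + 3)$r, 1)
  set.seed(15)
  x <- rnorm(25); y <- x + rnorm(25)
  mine <- pearson(x, y)
  base <- cor.test(x, y)
  expect_equal(mine$r, unname(base$estimate))
  expect_equal(mine$p_value, base$p.value)
})

test_that("single-outcome Wilks' lambda reproduces one-way ANOVA exactly", {
  set.seed(16)
  y <- rnorm(30); g <- factor(rep(1:3, 10))
  res <- mancova_wilks(matrix(y), g)
  f <- anova_oneway(split(y, g))
  lam_from_f <- 1 / (1 + f$statistic * f$df1 / f$df2)
  expect_equal(res$wilks_lambda, lam_from_f, tolerance = 1e-10)
  expect_equal(res$p_value, f$p_value, tolerance = 1e-10)
})

test_that("covariate-adjusted Wilks' lambda matches the Type II SSCP route", {
  set.seed(17)
  n <- 60
  Y <- matrix(rnorm(3 * n), n, 3)
  grp <- factor(sample(1:3, n, TRUE))
  cv <- data.frame(age = rnorm(n, 65, 5),
                   sex = factor(sample(c("F", "M"), n, TRUE)))
  mine <- mancova_wilks(Y, grp, cv)
  fit <- lm(Y ~ age + sex + grp, data = cbind(cv, grp = grp))
  w <- summary(car::Manova(fit, type = 2),
               multivariate = TRUE)$multivariate.tests$grp
  expect_equal(mine$wilks_lambda, det(w$SSPE) / det(w$SSPE + w$SSPH),
               tolerance = 1e-10)
})

test_that("under permuted labels lambda stays near 1 and rejections near alpha", {
  set.seed(18)
  n <- 90
  Y <- matrix(rnorm(3 * n, 20, 1.5), n, 3)
  rej <- 0; lams <- numeric(40)
  for (i in 1:40) {
    g <- factor(sample(rep(1:3, each = n / 3)))
    r <- mancova_wilks(Y, g)
    lams[i] <- r$wilks_lambda
    if (r$p_value < 0.05) rej <- rej + 1
  }
  expect_gt(min(lams), 0.7)
  expect_lte(rej / 40, 0.2)
})

test_that("pooled means aggregate by size and reproduce the grand mean", {
  expect_equal(round_half_up(pooled_mean(c(20.5, 19.4, 19.5), c(18, 17, 9)), 1), 19.9)
  expect_equal(pooled_mean(c(1, 3), c(5, 5)), 2)
  expect_error(pooled_mean(c(1, 2), c(1, 2, 3)), "length")
  expect_error(pooled_mean(c(1, 2), c(1, 0)), "positive")
  set.seed(19)
  x <- rnorm(50); g <- sample(1:3, 50, TRUE)
  expect_equal(pooled_mean(tapply(x, g, mean), tabulate(g)), mean(x))
})

test_that("group summaries recover configured means and center on controls", {
  cfg <- cohort_config()
  means <- replicate(50, {
    co <- generate_cohort(cfg, rng_seed = sample.int(1e6, 1), enrolled = FALSE)
    b <- co[co$visit == 1 & co$drss_group == "35", ]
    mean(b$vd_scp)
  })
  se <- 1.6 / sqrt(17) / sqrt(50)
  expect_lt(abs(mean(means) - 19.4), 3 * se)
  # normalized difference is exactly zero for a group measured against a
  # reference built from its own pooled sample
  co <- generate_cohort(cfg, rng_seed = 20, enrolled = FALSE)
  ctl <- co[co$drss_group == "control" & co$visit == 1, ]
  vals <- list(vd_scp = list(
    F = c(mean = mean(ctl$vd_scp), sd = sd(ctl$vd_scp)),
    M = c(mean = mean(ctl$vd_scp), sd = sd(ctl$vd_scp))))
  gs <- group_summaries(ctl, control_reference(values = vals),
                        metrics = "vd_scp")
  expect_equal(gs$norm_diff[gs$group == "control"], 0, tolerance = 1e-12)
  # n = 2 closed form: SD = |a - b| / sqrt(2)
  two <- ctl[1:2, ]
  g2 <- group_summaries(two, control_reference(values = vals),
                        metrics = "vd_scp")
  expect_equal(g2$sd, abs(diff(two$vd_scp)) / sqrt(2))
})

test_that("progression tabulation formats counts like the study table", {
  expect_equal(format_count_pct(5, 18, 1), "27.8 (5/18)")
  expect_equal(format_count_pct(0, 12, 1), "0.0 (0/12)")
  expect_equal(format_count_pct(9, 26, 0), "35 (9/26)")
  ref <- test_reference()
  recs <- do.call(rbind, lapply(1:18, function(i) {
    drop <- if (i <= 5) 0.89 else 0.95  # 5 eyes decrease > 10%
    make_eye_records(sprintf("P%03d", i),
                     vd_scp = 20 * c(1, 0.97, drop),
                     vd_dcp = 16 * c(1, 0.98, 0.95),
                     vd_fr = 22 * c(1, 0.98, 0.95))
  }))
  ph <- phenotype_cohort(recs, ref)
  tab <- progression_table(ph)
  scp <- tab[tab$plexus == "SCP", ]
  expect_equal(scp$formatted, "27.8 (5/18)")
  expect_equal(scp$n_flagged, 5)
})
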