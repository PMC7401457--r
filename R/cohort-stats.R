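#' Round half away from zero
#'
#' Table formatting uses commercial rounding (half away from zero), not the
#' IEEE half-to-even rule of [round()].
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Size-weighted pooled mean
#'
#' Aggregates per-group means into the all-patients value by weighting with
#' group sizes; with the true sizes this reproduces the grand mean exactly.
#'
#' @param means Per-group means.
#' @param sizes Per-group sizes (> 0), same length.
#' @return The pooled mean (unrounded).
#' @examples
#' pooled_mean(c(20.5, 19.4, 19.5), c(18, 17, 9))  # 19.87 -> prints 19.9
#' @export
pooled_mean <- function(means, sizes) {
  if (length(means) != length(sizes))
    stop("means and sizes must have the same length")
  if (any(sizes <= 0)) stop("sizes must be positive")
  sum(means * sizes) / sum(sizes)
}

#' Two-sided Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. For small samples
#' (combined n <= 20) with no ties the exact null distribution of U is
#' obtained by enumerating all group labelings; otherwise the
#' tie-corrected normal approximation is used (no continuity correction).
#' Two-sided p is `2 * min(P(U <= u), P(U >= u))`, capped at 1.
#'
#' @param sample_a,sample_b Numeric vectors (nonempty).
#' @return A list: `test`, `statistic` (U of `sample_a`), `p_value`,
#'   `method` ("exact" or "normal").
#' @export
mann_whitney <- function(sample_a, sample_b) {
  stopifnot(length(sample_a) >= 1, length(sample_b) >= 1)
  n1 <- length(sample_a); n2 <- length(sample_b)
  pooled <- c(sample_a, sample_b)
  if (length(unique(pooled)) == 1) {
    warning("all values tied across both samples; p = 1")
    return(list(test = "mann_whitney", statistic = n1 * n2 / 2, p_value = 1,
                method = "degenerate"))
  }
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(pooled))
  if (!ties && n1 + n2 <= 20) {
    combs <- utils::combn(n1 + n2, n1)
    allr <- rank(pooled)  # no ties: a permutation of 1..N
    us <- colSums(matrix(sort(allr)[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- 2 * min(mean(us <= u), mean(us >= u))
    return(list(test = "mann_whitney", statistic = u, p_value = min(1, p),
                method = "exact"))
  }
  N <- n1 + n2
  tab <- table(pooled)
  tie_term <- sum(tab^3 - tab) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  z <- (u - n1 * n2 / 2) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(z))
  list(test = "mann_whitney", statistic = u, p_value = min(1, p),
       method = "normal")
}

#' Two-sided Wilcoxon signed-rank test
#'
#' Paired within-group comparison across visits. Zero differences are
#' dropped (classic convention; set `zero_method = "pratt"` to rank them
#' and then discard their contribution). The exact null is used for n <= 25
#' untied absolute differences (convolution of the signed-rank generating
#' function); with ties, sign patterns are enumerated exactly up to n = 15;
#' beyond that the tie-corrected normal approximation applies.
#'
#' @param paired_before,paired_after Equal-length numeric vectors.
#' @param zero_method `"drop"` (default) or `"pratt"`.
#' @return A list: `test`, `statistic` (W = smaller signed-rank sum),
#'   `p_value`, `method`, `n_effective`.
#' @export
wilcoxon_signed_rank <- function(paired_before, paired_after,
                                 zero_method = c("drop", "pratt")) {
  zero_method <- match.arg(zero_method)
  stopifnot(length(paired_before) == length(paired_after))
  d <- paired_after - paired_before
  if (all(d == 0)) {
    warning("all paired differences are zero; p = 1")
    return(list(test = "wilcoxon_signed_rank", statistic = 0, p_value = 1,
                method = "degenerate", n_effective = 0))
  }
  if (zero_method == "drop") {
    d <- d[d != 0]
    r <- rank(abs(d))
  } else {
    r <- rank(abs(d))
    r <- r[d != 0]
    d <- d[d != 0]
  }
  n <- length(d)
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  w <- min(w_pos, w_neg)
  ties <- any(duplicated(abs(d)))
  if (!ties && zero_method == "drop" && n <= 25) {
    # exact distribution of the positive-rank sum by convolution
    counts <- rep(0, n * (n + 1) / 2 + 1)  # counts[k+1] = #patterns with sum k
    counts[1] <- 1
    for (k in seq_len(n)) {
      shifted <- c(rep(0, k), counts)[seq_along(counts)]
      counts <- counts + shifted
    }
    probs <- counts / 2^n
    sums <- seq_along(counts) - 1
    p <- 2 * min(sum(probs[sums <= w_pos]), sum(probs[sums >= w_pos]))
    return(list(test = "wilcoxon_signed_rank", statistic = w,
                p_value = min(1, p), method = "exact", n_effective = n))
  }
  if (n <= 15) {
    # ties (or Pratt): enumerate all sign patterns of the observed ranks
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    sums <- as.vector(signs %*% r)
    p <- 2 * min(mean(sums <= w_pos), mean(sums >= w_pos))
    return(list(test = "wilcoxon_signed_rank", statistic = w,
                p_value = min(1, p), method = "exact_enumeration",
                n_effective = n))
  }
  mu <- n * (n + 1) / 4
  tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tab^3 - tab) / 48
  z <- (w_pos - mu) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(z))
  list(test = "wilcoxon_signed_rank", statistic = w, p_value = min(1, p),
       method = "normal", n_effective = n)
}

#' One-way ANOVA
#'
#' Classic between/within decomposition: F = MS_between / MS_within with
#' (g - 1, N - g) degrees of freedom.
#'
#' @param groups A list of numeric vectors, one per group.
#' @return A list: `test`, `statistic` (F), `df1`, `df2`, `p_value`.
#' @export
anova_oneway <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  ns <- lengths(groups)
  if (any(ns < 1)) stop("every group needs at least one value")
  all_v <- unlist(groups)
  N <- length(all_v); g <- length(groups)
  grand <- mean(all_v)
  ssb <- sum(ns * (vapply(groups, mean, numeric(1)) - grand)^2)
  ssw <- sum(vapply(groups, function(x) sum((x - mean(x))^2), numeric(1)))
  if (ssw <= 0) stop("zero within-group variance everywhere")
  f <- (ssb / (g - 1)) / (ssw / (N - g))
  list(test = "anova_oneway", statistic = f, df1 = g - 1, df2 = N - g,
       p_value = stats::pf(f, g - 1, N - g, lower.tail = FALSE))
}

#' Pearson chi-squared test of independence
#'
#' `sum((O - E)^2 / E)` on a contingency table, no continuity correction,
#' df = (r - 1)(c - 1).
#'
#' @param tab Contingency table (matrix of counts).
#' @return A list: `test`, `statistic`, `df`, `p_value`.
#' @export
chi_square <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be nonnegative")
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(E == 0)) stop("degenerate table: a margin is zero")
  x2 <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(test = "chi_square", statistic = x2, df = df,
       p_value = stats::pchisq(x2, df, lower.tail = FALSE))
}

#' Pearson correlation with t-based significance
#'
#' @param x,y Equal-length numeric vectors (n >= 3).
#' @return A list: `r`, `statistic` (t), `df`, `p_value`.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  if (abs(r) >= 1) {
    return(list(r = r, statistic = Inf * sign(r), df = n - 2, p_value = 0))
  }
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, statistic = t, df = n - 2,
       p_value = 2 * stats::pt(-abs(t), n - 2))
}

#' Multivariate ANCOVA with Wilks' lambda
#'
#' Tests whether a multivariate outcome (e.g. the SCP/DCP/FR vessel-density
#' triplet) differs between groups after adjusting for covariates. Outcomes
#' and the group indicator columns are residualized on the covariate design
#' (intercept + covariates, factors expanded to indicators), which yields
#' the Type II/III test of the group term in the additive model. Wilks'
#' lambda = det(E) / det(E + H) from the error and hypothesis cross-product
#' matrices of the residualized fit; the p value uses Rao's F
#' approximation.
#'
#' @param outcomes Numeric matrix (n x p), one column per outcome.
#' @param group Factor (>= 2 levels) of length n.
#' @param covariates Optional data.frame of adjustment covariates (numeric
#'   or factor columns), e.g. age, sex, HbA1c, visual acuity, diabetes
#'   duration.
#' @return A list: `wilks_lambda`, `statistic` (approximate F), `df1`,
#'   `df2`, `p_value`, `covariates` (names used).
#' @export
mancova_wilks <- function(outcomes, group, covariates = NULL) {
  Y <- as.matrix(outcomes)
  group <- droplevels(as.factor(group))
  n <- nrow(Y); p <- ncol(Y)
  if (nlevels(group) < 2) stop("group must have at least 2 levels")
  Xc <- matrix(1, n, 1)
  cov_names <- character(0)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    cov_names <- names(covariates)
    mm <- stats::model.matrix(~ ., data = covariates)
    Xc <- mm  # includes intercept
  }
  G <- stats::model.matrix(~ group)[, -1, drop = FALSE]
  q <- ncol(G)
  if (n <= ncol(Xc) + q + p)
    stop("too few rows for ", p, " outcomes and ", ncol(Xc) + q, " predictors")
  qr_c <- qr(Xc)
  Yr <- qr.resid(qr_c, Y)
  Gr <- qr.resid(qr_c, G)
  qr_g <- qr(Gr)
  H <- crossprod(qr.fitted(qr_g, Yr))
  E <- crossprod(qr.resid(qr_g, Yr))
  if (abs(det(E)) < 1e-300)
    stop("singular error matrix E: outcomes may be collinear")
  lambda <- det(E) / det(E + H)
  v <- n - qr_c$rank - qr_g$rank  # error df
  s <- if (p^2 + q^2 - 5 > 0) sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5)) else 1
  t1 <- v - (p - q + 1) / 2
  df1 <- p * q
  df2 <- t1 * s - (p * q) / 2 + 1
  lam_s <- lambda^(1 / s)
  fstat <- (1 - lam_s) / lam_s * df2 / df1
  list(wilks_lambda = lambda, statistic = fstat, df1 = df1, df2 = df2,
       p_value = stats::pf(fstat, df1, df2, lower.tail = FALSE),
       covariates = cov_names)
}

#' Per-group summaries with sex-adjusted normalized difference
#'
#' For each group and metric at a chosen visit: n, mean, SD, t-based 95%
#' confidence interval, and the normalized mean difference from control
#' adjusted by sex — the sex-composition-weighted average, over the sexes
#' present in the group, of (group mean for that sex - control mean for
#' that sex) / control SD for that sex.
#'
#' @param cohort Cohort data.frame (see [generate_cohort]).
#' @param ref A [control_reference].
#' @param metrics Metric columns to summarize.
#' @param visit Visit to summarize (default 1, baseline).
#' @param conf_level Confidence level for the CI (default 0.95).
#' @return A data.frame with one row per (group, metric).
#' @export
group_summaries <- function(cohort, ref = control_reference(),
                            metrics = c("vd_scp", "vd_dcp", "vd_fr",
                                        "faz_circularity", "rnfl_um",
                                        "gcl_ipl_um", "crt_um"),
                            visit = 1, conf_level = 0.95) {
  cc <- cohort[cohort$visit == visit, ]
  out <- NULL
  for (g in unique(cc$drss_group)) {
    gg <- cc[cc$drss_group == g, ]
    for (m in metrics) {
      x <- gg[[m]]
      x <- x[is.finite(x)]
      n <- length(x)
      mu <- mean(x); s <- if (n >= 2) stats::sd(x) else NA_real_
      if (n >= 2) {
        half <- stats::qt(1 - (1 - conf_level) / 2, n - 1) * s / sqrt(n)
        ci <- c(mu - half, mu + half)
      } else {
        warning("group ", g, " has n < 2; CI omitted for ", m)
        ci <- c(NA_real_, NA_real_)
      }
      nd <- 0
      for (sx in c("F", "M")) {
        xs <- gg[[m]][gg$sex == sx & is.finite(gg[[m]])]
        if (length(xs) == 0) next
        e <- ref_entry(ref, m, sx)
        nd <- nd + length(xs) / n * (mean(xs) - e["mean"]) / e["sd"]
      }
      out <- rbind(out, data.frame(
        group = g, metric = m, n = n, mean = mu, sd = s,
        ci_lo = ci[1], ci_hi = ci[2], norm_diff = unname(nd),
        stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

#' Tabulate eyes with a more-than-threshold vessel-density decrease
#'
#' Per-group, per-plexus percentage of eyes whose visit-3-vs-baseline
#' vessel-density decrease exceeds the threshold, formatted
#' `"percent (count/total)"` with one decimal (half-away-from-zero
#' rounding).
#'
#' @param phenotypes Output of [phenotype_cohort] (retained eyes only are
#'   counted when `retained_only` is TRUE).
#' @param retained_only Restrict to eyes that passed quality (default TRUE).
#' @return A data.frame: group, plexus, n_flagged, n_total, percent,
#'   formatted.
#' @export
progression_table <- function(phenotypes, retained_only = TRUE) {
  ph <- if (retained_only) phenotypes[phenotypes$passed_quality, ] else phenotypes
  out <- NULL
  for (g in unique(ph$drss_group)) {
    gg <- ph[ph$drss_group == g, ]
    if (nrow(gg) == 0) {
      warning("group ", g, " empty; row omitted")
      next
    }
    for (plx in c("scp", "dcp", "fr")) {
      fl <- gg[[sprintf("prog_%s_v31", plx)]]
      fl <- fl[!is.na(fl)]
      k <- sum(fl); n <- length(fl)
      out <- rbind(out, data.frame(
        group = g, plexus = toupper(plx), n_flagged = k, n_total = n,
        percent = if (n > 0) 100 * k / n else NA_real_,
        formatted = format_count_pct(k, n, digits = 1),
        stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

#' Format a count as "percent (count/total)"
#'
#' @param k Count flagged.
#' @param n Total.
#' @param digits Decimals of the percentage (0 gives integer percent).
#' @return Character scalar, e.g. `format_count_pct(5, 18)` is
#'   `"27.8 (5/18)"` and `format_count_pct(9, 26, 0)` is `"35 (9/26)"`.
#' @export
format_count_pct <- function(k, n, digits = 1) {
  if (n <= 0) stop("total must be positive")
  pct <- round_half_up(100 * k / n, digits)
  sprintf("%s (%d/%d)", formatC(pct, format = "f", digits = digits), k, n)
}
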