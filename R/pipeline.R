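#' Simulate a cohort to disk
#'
#' Generates the synthetic cohort and writes `cohort.csv` plus a
#' `provenance.json` recording the seed and the size/rate settings, so a
#' run can be reproduced exactly.
#'
#' @param out_dir Output directory.
#' @param config A [cohort_config].
#' @param rng_seed Seed (defaults to the config's).
#' @return Invisibly, the cohort data.frame.
#' @export
octa_simulate <- function(out_dir, config = cohort_config(),
                          rng_seed = config$rng_seed) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(config, rng_seed = rng_seed)
  utils::write.csv(cohort, file.path(out_dir, "cohort.csv"), row.names = FALSE)
  prov <- list(rng_seed = as.integer(rng_seed),
               group_sizes = as.list(config$group_sizes),
               enrolled_total = config$enrolled_total,
               rho_plexus = c(config$corr[1, 2], config$corr[1, 3],
                              config$corr[2, 3]),
               rho_visit = config$rho_visit,
               quality_fail_p = config$quality_fail_p)
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(cohort)
}

#' Quantify an image set to a metrics CSV
#'
#' Wraps [quantify_image_set] over a manifest. Unreadable images are
#' reported and skipped; the run continues and the failures are returned so
#' a caller (or the command-line wrapper) can exit nonzero.
#'
#' @param manifest_path Path to the image-set manifest.
#' @param out_csv Output CSV path.
#' @param config Quantification settings (see [quantify_image_set]).
#' @param min_signal_strength Quality cutoff used for the `fail_quality`
#'   column (default 7).
#' @return Invisibly, a list with `metrics` (data.frame) and `failures`
#'   (character vector of files that could not be read).
#' @export
octa_quantify <- function(manifest_path, out_csv, config = list(),
                          min_signal_strength = 7) {
  entries <- jsonlite::fromJSON(manifest_path, simplifyVector = FALSE)
  base <- dirname(manifest_path)
  images <- list(); failures <- character(0)
  for (e in entries) {
    im <- tryCatch({
      tmp <- read_image_set_entry(e, base)
      tmp
    }, error = function(err) {
      message("skipping unreadable image ", e$file, ": ", conditionMessage(err))
      NULL
    })
    if (is.null(im)) failures <- c(failures, e$file) else
      images[[length(images) + 1]] <- im
  }
  metrics <- quantify_image_set(images, config)
  metrics$fail_quality <- metrics$signal_strength < min_signal_strength
  utils::write.csv(metrics, out_csv, row.names = FALSE)
  invisible(list(metrics = metrics, failures = failures))
}

read_image_set_entry <- function(e, base) {
  path <- file.path(base, e$file)
  px <- png::readPNG(path)
  if (length(dim(px)) == 3) px <- px[, , 1]
  im <- angiogram_image(px, e$pixel_spacing_mm, e$plexus, e$signal_strength)
  attr(im, "patient_id") <- e$patient_id
  attr(im, "eye") <- e$eye
  attr(im, "visit") <- e$visit
  im
}

#' Run the full longitudinal analysis
#'
#' Applies the three-visit quality filter, phenotypes every retained eye,
#' and produces the study-style summaries: per-group baseline summaries
#' with sex-adjusted normalized differences (baseline-characteristics
#' analog), per-visit group means with Wilcoxon signed-rank p values for
#' visit 2 vs 1 and visit 3 vs 1 including the pooled all-patients rows
#' (progression analog), the per-group percentage of eyes with a
#' more-than-10% vessel-density decrease (progression-tabulation analog),
#' and an exclusion-accounting line. A MANCOVA (Wilks' lambda) of the
#' baseline vessel-density triplet on severity group, adjusted for age,
#' sex, HbA1c, visual acuity and diabetes duration, is included when the
#' retained cohort is large enough.
#'
#' All unrounded numbers are also written to `results.json` when `out_dir`
#' is given; two runs from the same simulated cohort produce byte-identical
#' JSON.
#'
#' @param cohort Cohort data.frame or path to a cohort CSV.
#' @param ref A [control_reference].
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @param threshold_pct Progression threshold (default 10).
#' @return A list: `exclusion` (enrolled/excluded/analyzed counts and
#'   percent), `phenotypes`, `summaries`, `visit_means`, `progression`,
#'   `mancova` (or NULL), `progression_detection` (flagged/total across
#'   retained diabetic eyes).
#' @export
octa_analyze <- function(cohort, ref = control_reference(), out_dir = NULL,
                         threshold_pct = 10) {
  if (is.character(cohort)) cohort <- utils::read.csv(cohort)
  dia <- cohort[cohort$drss_group != "control", ]
  qf <- quality_filter(dia)
  enrolled <- length(qf$retained) + length(qf$excluded)
  excluded <- length(qf$excluded)
  analyzed <- enrolled - excluded
  exclusion <- list(enrolled = enrolled, excluded = excluded,
                    analyzed = analyzed,
                    pct_excluded = unname(round_half_up(100 * excluded / enrolled)))

  ph <- phenotype_cohort(cohort, ref, threshold_pct)
  ph_dia <- ph[ph$drss_group != "control" & ph$passed_quality, ]

  keep_key <- paste(cohort$patient_id, cohort$eye, sep = ":") %in% qf$retained |
    cohort$drss_group == "control"
  kept <- cohort[keep_key, ]
  summaries <- group_summaries(kept, ref)
  visit_means <- visit_means_table(kept[kept$drss_group != "control", ])
  progression <- progression_table(ph)

  mancova <- NULL
  base_dia <- kept[kept$visit == 1 & kept$drss_group != "control", ]
  cov_ok <- stats::complete.cases(base_dia[, c("age", "sex", "hba1c_pct",
                                               "bcva_letters",
                                               "diabetes_duration_y")])
  if (sum(cov_ok) > 12 && length(unique(base_dia$drss_group[cov_ok])) >= 2) {
    bd <- base_dia[cov_ok, ]
    mancova <- mancova_wilks(
      as.matrix(bd[, c("vd_scp", "vd_dcp", "vd_fr")]),
      bd$drss_group,
      bd[, c("age", "sex", "hba1c_pct", "bcva_letters", "diabetes_duration_y")])
  }

  fl <- ph_dia$prog_scp_v31 | ph_dia$prog_dcp_v31 | ph_dia$prog_fr_v31
  fl <- fl[!is.na(fl)]
  detection <- list(n_flagged = sum(fl), n_total = length(fl),
                    formatted = if (length(fl) > 0)
                      format_count_pct(sum(fl), length(fl), 0) else NA)

  res <- list(exclusion = exclusion, phenotypes = ph, summaries = summaries,
              visit_means = visit_means, progression = progression,
              mancova = mancova, progression_detection = detection)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(ph, file.path(out_dir, "phenotypes.csv"), row.names = FALSE)
    utils::write.csv(summaries, file.path(out_dir, "group_summaries.csv"),
                     row.names = FALSE)
    utils::write.csv(visit_means, file.path(out_dir, "visit_means.csv"),
                     row.names = FALSE)
    utils::write.csv(progression, file.path(out_dir, "progression_table.csv"),
                     row.names = FALSE)
    json <- res
    json$phenotypes <- NULL  # tabular artifacts live in the CSVs
    jsonlite::write_json(json, file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
    writeLines(sprintf("%d enrolled, %d excluded (%d%%), %d analyzed",
                       enrolled, excluded, exclusion$pct_excluded, analyzed),
               file.path(out_dir, "run_log.txt"))
  }
  res
}

# per-group and pooled per-visit means/SDs with paired signed-rank p values
visit_means_table <- function(dia) {
  metrics <- c("vd_scp", "vd_dcp", "vd_fr", "faz_circularity", "rnfl_um",
               "gcl_ipl_um", "crt_um")
  groups <- unique(dia$drss_group)
  out <- NULL
  add_rows <- function(d, label) {
    res <- NULL
    key <- paste(d$patient_id, d$eye, sep = ":")
    for (m in metrics) {
      wide <- do.call(rbind, lapply(unique(key), function(k) {
        rr <- d[key == k, ]
        vapply(1:3, function(v) {
          x <- rr[[m]][rr$visit == v]
          if (length(x) == 1) x else NA_real_
        }, numeric(1))
      }))
      cc <- stats::complete.cases(wide)
      p21 <- if (sum(cc) >= 2)
        suppressWarnings(wilcoxon_signed_rank(wide[cc, 1], wide[cc, 2])$p_value)
        else NA_real_
      p31 <- if (sum(cc) >= 2)
        suppressWarnings(wilcoxon_signed_rank(wide[cc, 1], wide[cc, 3])$p_value)
        else NA_real_
      res <- rbind(res, data.frame(
        group = label, metric = m, n = sum(cc),
        mean_v1 = mean(wide[cc, 1]), sd_v1 = stats::sd(wide[cc, 1]),
        mean_v2 = mean(wide[cc, 2]), sd_v2 = stats::sd(wide[cc, 2]),
        mean_v3 = mean(wide[cc, 3]), sd_v3 = stats::sd(wide[cc, 3]),
        p_v21 = p21, p_v31 = p31, stringsAsFactors = FALSE))
    }
    res
  }
  for (g in groups) out <- rbind(out, add_rows(dia[dia$drss_group == g, ], g))
  out <- rbind(out, add_rows(dia, "all"))
  rownames(out) <- NULL
  out
}
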