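#' Classify macular edema from central retinal thickness
#'
#' Sex-specific CRT cutpoints: clinical macular edema is CRT >= 290 um in
#' women and >= 305 um in men; subclinical macular edema is CRT in
#' \[260, 290) um in women and \[275, 305) um in men; below the subclinical
#' bound is no edema. Lower bounds are closed and upper bounds open, so the
#' categories never overlap and increasing CRT never moves the call toward
#' a milder category.
#'
#' @param crt_um Central retinal thickness in micrometers (> 0).
#' @param sex `"F"` or `"M"`.
#' @return One of `"none"`, `"subclinical"`, `"clinical"`.
#' @export
classify_edema <- function(crt_um, sex) {
  if (any(!is.finite(crt_um)) || any(crt_um <= 0))
    stop("crt_um must be positive and finite")
  sex <- match.arg(sex, c("F", "M"))
  lo <- if (sex == "F") 260 else 275
  hi <- if (sex == "F") 290 else 305
  ifelse(crt_um >= hi, "clinical", ifelse(crt_um >= lo, "subclinical", "none"))
}

#' Flag neurodegeneration from inner-retinal layer thickness
#'
#' Neurodegeneration is called when the retinal nerve fiber layer (RNFL)
#' or the ganglion cell + inner plexiform layer (GCL-IPL) thickness lies
#' strictly below the sex-matched control mean minus `k_sd` control SDs
#' (OR semantics: thinning of either layer suffices).
#'
#' @param rnfl_um,gcl_ipl_um Layer thickness values (um).
#' @param sex `"F"` or `"M"`.
#' @param ref A [control_reference].
#' @param k_sd SD multiplier; defaults to `ref$k_sd`.
#' @return Logical.
#' @export
classify_neurodegeneration <- function(rnfl_um, gcl_ipl_um, sex, ref,
                                       k_sd = ref$k_sd) {
  rn <- ref_entry(ref, "rnfl_um", sex)
  gc <- ref_entry(ref, "gcl_ipl_um", sex)
  strictly_below(rnfl_um, rn["mean"] - k_sd * rn["sd"]) |
    strictly_below(gcl_ipl_um, gc["mean"] - k_sd * gc["sd"])
}

# strict "<" that treats values at the threshold (up to floating-point
# representation of the printed reference numbers) as not below it
strictly_below <- function(x, threshold) {
  unname(x < threshold - 1e-9 * pmax(1, abs(threshold)))
}

#' Flag capillary dropout from a vessel-density value
#'
#' Capillary dropout (the ischemia pathway) is called when vessel density
#' lies strictly below the sex-matched control mean minus `k_sd` control
#' SDs for that plexus metric.
#'
#' @param vd Vessel density (mm^-1).
#' @param metric One of `"vd_scp"`, `"vd_dcp"`, `"vd_fr"`.
#' @param sex `"F"` or `"M"`.
#' @param ref A [control_reference].
#' @param k_sd SD multiplier; defaults to `ref$k_sd`.
#' @return Logical.
#' @examples
#' ref <- control_reference()
#' classify_dropout(19.6, "vd_scp", "F", ref)  # TRUE: threshold 21.1 - 2*0.7
#' @export
classify_dropout <- function(vd, metric, sex, ref, k_sd = ref$k_sd) {
  e <- ref_entry(ref, metric, sex)
  strictly_below(vd, e["mean"] - k_sd * e["sd"])
}

#' Relative decrease equivalent to k control SDs
#'
#' Converts a k-SD decrease of the control reference into a percentage of
#' the control mean: `100 * k * sd / mean`. With the healthy-eye vessel
#' density reference 21.1 +/- 0.7 mm^-1 and k = 3 this gives 9.95%, i.e.
#' the 10% progression threshold equals a 3-SD decrease.
#'
#' @param ref_mean,ref_sd Control mean and SD (> 0).
#' @param k SD multiplier (> 0 allowed to be 0 for the trivial case).
#' @return Percentage.
#' @export
relative_decrease_threshold <- function(ref_mean, ref_sd, k) {
  if (!is.finite(ref_mean) || ref_mean <= 0) stop("ref_mean must be > 0")
  if (!is.finite(ref_sd) || ref_sd <= 0) stop("ref_sd must be > 0")
  if (!is.finite(k) || k < 0) stop("k must be >= 0")
  100 * k * ref_sd / ref_mean
}

#' Flag a more-than-threshold vessel-density decrease
#'
#' TRUE when the relative decrease from baseline exceeds `threshold_pct`
#' strictly ("more than 10%"): a decrease of exactly the threshold is not
#' flagged.
#'
#' @param vd_baseline Baseline vessel density (> 0).
#' @param vd_followup Follow-up vessel density.
#' @param threshold_pct Relative decrease threshold in percent (default 10).
#' @return Logical.
#' @export
progression_flag <- function(vd_baseline, vd_followup, threshold_pct = 10) {
  if (any(!is.finite(vd_baseline)) || any(vd_baseline <= 0))
    stop("vd_baseline must be positive")
  100 * (vd_baseline - vd_followup) / vd_baseline > threshold_pct
}

#' Apply the three-visit scan-quality rule
#'
#' An eye is retained for longitudinal analysis only if all three visits
#' are present and every visit has signal strength >= 7 and no motion
#' artifact. Returns the retained and excluded eye keys plus a per-eye
#' reason table.
#'
#' @param records Cohort data.frame with columns `patient_id`, `eye`,
#'   `visit`, `signal_strength`, `artifact_flag`.
#' @param min_signal_strength Quality cutoff (default 7).
#' @param n_visits Required number of visits (default 3).
#' @return A list with `retained`, `excluded` (character vectors of
#'   `patient_id:eye` keys) and `reasons` (data.frame).
#' @export
quality_filter <- function(records, min_signal_strength = 7, n_visits = 3) {
  key <- paste(records$patient_id, records$eye, sep = ":")
  if (anyDuplicated(paste(key, records$visit)))
    stop("duplicate (eye, visit) rows: ",
         paste(unique(paste(key, records$visit)[duplicated(paste(key, records$visit))]),
               collapse = ", "))
  ukeys <- unique(key)
  reasons <- character(length(ukeys))
  ok <- logical(length(ukeys))
  for (i in seq_along(ukeys)) {
    rr <- records[key == ukeys[i], ]
    if (nrow(rr) < n_visits) {
      reasons[i] <- sprintf("only %d of %d visits", nrow(rr), n_visits)
    } else if (any(rr$signal_strength < min_signal_strength)) {
      reasons[i] <- sprintf("signal strength < %d at visit %s",
                            min_signal_strength,
                            paste(rr$visit[rr$signal_strength < min_signal_strength],
                                  collapse = ","))
    } else if (any(rr$artifact_flag)) {
      reasons[i] <- sprintf("motion artifact at visit %s",
                            paste(rr$visit[rr$artifact_flag], collapse = ","))
    } else {
      ok[i] <- TRUE
      reasons[i] <- "passed"
    }
  }
  list(retained = ukeys[ok], excluded = ukeys[!ok],
       reasons = data.frame(eye_key = ukeys, retained = ok,
                            reason = reasons, stringsAsFactors = FALSE))
}

#' Phenotype one eye across its visits
#'
#' Baseline (visit 1) classifications of the three disease pathways —
#' macular edema from CRT, neurodegeneration from RNFL/GCL-IPL, capillary
#' dropout from vessel density in any plexus — plus per-plexus
#' more-than-`threshold_pct` progression flags for visit 2 vs 1 and visit 3
#' vs 1 (present only when the respective follow-up visit exists).
#'
#' @param records Rows of one eye (1-3 visits) with the cohort schema.
#' @param ref A [control_reference].
#' @param threshold_pct Progression threshold in percent (default 10, the
#'   3-SD-equivalent decrease of the control vessel-density reference).
#' @return A one-row data.frame: `edema_status`, `neurodeg`, `dropout`,
#'   `prog_<plexus>_v21`, `prog_<plexus>_v31` for scp/dcp/fr, and
#'   `n_visits`.
#' @export
phenotype_eye <- function(records, ref, threshold_pct = 10) {
  stopifnot(nrow(records) >= 1)
  records <- records[order(records$visit), ]
  b <- records[records$visit == 1, ]
  if (nrow(b) != 1) stop("exactly one baseline (visit 1) row required")
  sex <- b$sex
  out <- data.frame(
    edema_status = classify_edema(b$crt_um, sex),
    neurodeg = classify_neurodegeneration(b$rnfl_um, b$gcl_ipl_um, sex, ref),
    dropout = classify_dropout(b$vd_scp, "vd_scp", sex, ref) |
      classify_dropout(b$vd_dcp, "vd_dcp", sex, ref) |
      classify_dropout(b$vd_fr, "vd_fr", sex, ref),
    n_visits = nrow(records), stringsAsFactors = FALSE)
  for (plx in c("scp", "dcp", "fr")) {
    m <- paste0("vd_", plx)
    for (v in 2:3) {
      fu <- records[records$visit == v, ]
      out[[sprintf("prog_%s_v%d1", plx, v)]] <-
        if (nrow(fu) == 1) progression_flag(b[[m]], fu[[m]], threshold_pct)
        else NA
    }
  }
  out
}

#' Phenotype every eye of a cohort
#'
#' Applies the quality filter, then [phenotype_eye] to each eye (all eyes
#' are phenotyped; `passed_quality` records the filter outcome so callers
#' can restrict longitudinal claims to retained eyes).
#'
#' @inheritParams phenotype_eye
#' @param records Full cohort data.frame.
#' @return A data.frame, one row per eye, with `patient_id`, `eye`,
#'   `drss_group`, `sex`, the [phenotype_eye] columns and `passed_quality`.
#' @export
phenotype_cohort <- function(records, ref = control_reference(),
                             threshold_pct = 10) {
  qf <- quality_filter(records)
  key <- paste(records$patient_id, records$eye, sep = ":")
  out <- lapply(unique(key), function(k) {
    rr <- records[key == k, ]
    ph <- phenotype_eye(rr, ref, threshold_pct)
    cbind(data.frame(patient_id = rr$patient_id[1], eye = rr$eye[1],
                     drss_group = rr$drss_group[1], sex = rr$sex[1],
                     stringsAsFactors = FALSE),
          ph,
          data.frame(passed_quality = k %in% qf$retained))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
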