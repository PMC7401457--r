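#' Healthy-control reference values
#'
#' Per-metric, per-sex mean and SD of the healthy control population, used
#' for every thresholded classification: a metric is flagged when it lies
#' more than `k_sd` SDs on the pathological side of the sex-matched control
#' mean, and the "relevant" longitudinal decrease is defined as
#' `k_sd_progression` SDs of the control reference (see
#' [relative_decrease_threshold]).
#'
#' The shipped defaults are the pooled control values (women and men share
#' one entry, since the default reference table is not sex-stratified);
#' callers with sex-specific normative data can supply their own `values`.
#'
#' @param k_sd SD multiplier for the cross-sectional flags (default 2).
#' @param k_sd_progression SD multiplier defining the relevant longitudinal
#'   decrease (fixed at 3 by the progression rule).
#' @param values Optional named list: `values[[metric]][[sex]] = c(mean, sd)`.
#'   Metrics: vd_scp, vd_dcp, vd_fr, rnfl_um, gcl_ipl_um, crt_um,
#'   faz_circularity. Defaults are read from the packaged reference file.
#' @return A list of class `control_reference`.
#' @export
control_reference <- function(k_sd = 2, k_sd_progression = 3, values = NULL) {
  if (is.null(values)) {
    path <- system.file("extdata", "control_reference.json",
                        package = "octaquant")
    raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    values <- lapply(raw$metrics, function(m)
      list(F = c(mean = m$F[[1]], sd = m$F[[2]]),
           M = c(mean = m$M[[1]], sd = m$M[[2]])))
  }
  for (m in names(values)) for (s in c("F", "M")) {
    v <- values[[m]][[s]]
    if (is.null(v) || length(v) != 2 || v[2] <= 0)
      stop("invalid reference entry for ", m, "/", s, " (need mean and sd > 0)")
  }
  stopifnot(k_sd > 0, k_sd_progression > 0)
  structure(list(values = values, k_sd = k_sd,
                 k_sd_progression = k_sd_progression),
            class = "control_reference")
}

ref_entry <- function(ref, metric, sex) {
  sex <- match.arg(sex, c("F", "M"))
  v <- ref$values[[metric]]
  if (is.null(v) || is.null(v[[sex]]))
    stop("no control reference entry for metric '", metric, "' and sex '",
         sex, "'")
  v[[sex]]
}
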