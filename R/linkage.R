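#' Per-hospital completeness summary of clinical vs administrative counts
#'
#' Links the two registries by facility code and computes, for every
#' facility present in the administrative registry, the case and death
#' counts in each registry and the completeness ratios
#' `ratio_cases = n_clinical / n_admin` and
#' `ratio_deaths = d_clinical / d_admin`.  Under-reporting in the
#' clinical registry therefore gives ratios below 1.
#'
#' Conventions: a facility absent from the clinical registry gets
#' clinical counts 0; a 0/0 death ratio is 1 (no evidence of
#' under-reporting); more clinical than administrative deaths with zero
#' administrative deaths yields an infinite ratio and an anomaly flag.
#' Facilities appearing only in the clinical registry are linkage
#' anomalies: they are returned in the `anomalies` attribute and excluded
#' from the summary.
#'
#' @param clinical,admin Registry tables with `facility_id` and `death`.
#' @return Tibble with one row per administrative facility: counts,
#'   ratios and an `anomaly` note (`NA` when none); attribute
#'   `"anomalies"` lists clinical-only facilities.
#' @export
summarize_by_hospital <- function(clinical, admin) {
  stopifnot(all(c("facility_id", "death") %in% names(clinical)),
            all(c("facility_id", "death") %in% names(admin)))
  agg <- function(tab) {
    dplyr::summarise(dplyr::group_by(tab, .data$facility_id),
                     n = dplyr::n(), d = sum(.data$death), .groups = "drop")
  }
  a <- agg(admin)
  cl <- agg(clinical)
  clinical_only <- setdiff(cl$facility_id, a$facility_id)
  if (length(clinical_only) > 0L) {
    warning(length(clinical_only),
            " facility(ies) present only in the clinical registry; ",
            "excluded from classification")
  }
  out <- dplyr::left_join(a, cl, by = "facility_id",
                          suffix = c("_admin", "_clinical"))
  out$n_clinical <- ifelse(is.na(out$n_clinical), 0L, out$n_clinical)
  out$d_clinical <- ifelse(is.na(out$d_clinical), 0L, out$d_clinical)
  out$ratio_cases <- out$n_clinical / out$n_admin
  out$ratio_deaths <- ifelse(
    out$d_admin == 0 & out$d_clinical == 0, 1,
    out$d_clinical / out$d_admin)
  out$anomaly <- ifelse(out$d_admin == 0 & out$d_clinical > 0,
                        "clinical deaths with no administrative deaths",
                        NA_character_)
  out <- out[, c("facility_id", "n_clinical", "n_admin", "d_clinical",
                 "d_admin", "ratio_cases", "ratio_deaths", "anomaly")]
  attr(out, "anomalies") <- clinical_only
  out
}

#' Classify hospitals into good- vs low-quality-data groups
#'
#' A hospital is classified GQD (good-quality data) when both its case
#' ratio and its death ratio lie in `[threshold, 1 + upper_tolerance]`;
#' otherwise LQD (at least one ratio below the threshold, or an
#' anomalous excess of clinical over administrative counts).
#'
#' @param summaries Output of [summarize_by_hospital()].
#' @param threshold Completeness cutoff, default 0.7 (closed bound: a
#'   ratio of exactly 0.7 is good quality).
#' @param upper_tolerance Allowed excess above 1 before a ratio is
#'   flagged anomalous, default 0.05.
#' @return `summaries` with a `quality_class` column (`"GQD"`/`"LQD"`)
#'   and anomaly notes for ratios above `1 + upper_tolerance`.
#' @export
classify_quality <- function(summaries, threshold = 0.7,
                             upper_tolerance = 0.05) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1) {
    stop("'threshold' must lie in (0, 1]")
  }
  hi <- 1 + upper_tolerance
  over <- summaries$ratio_cases > hi | summaries$ratio_deaths > hi
  summaries$anomaly <- ifelse(
    over & is.na(summaries$anomaly),
    "ratio exceeds 1 + tolerance", summaries$anomaly)
  ok <- summaries$ratio_cases >= threshold & summaries$ratio_cases <= hi &
    summaries$ratio_deaths >= threshold & summaries$ratio_deaths <= hi &
    is.na(summaries$anomaly)
  summaries$quality_class <- ifelse(ok, "GQD", "LQD")
  summaries
}
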