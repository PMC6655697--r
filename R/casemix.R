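#' Case-mix configuration for the synthetic cohort
#'
#' Marginal covariate distributions used by the registry generator.
#' Defaults reproduce the published patient characteristics of the
#' good-quality-data hospital group: age 64 +/- 10 years; 34% female; ASA
#' 1/2/>=3 at 15.5/52/32.5%; performance status 0/1/>=2 at 44/46/10%;
#' dyspnea 0/1/2/>=3 at 42.5/36/18/3.5%; FEV 83 +/- 21% predicted with
#' 10% missing; BMI 25.45 +/- 4.5 kg/m2; procedure limited/lobectomy/
#' bilobectomy/pneumonectomy at 14/74/3.5/8.5%; 28% VATS; staging and
#' resection-quality frequencies including their baseline "Missing"
#' fractions (~10-12%); and the 28 comorbidity prevalences.
#'
#' Covariates are drawn independently per patient.  An optional positive
#' dependence between the ASA score and comorbidity prevalence is
#' available via `asa_comorbidity_dependence` (multiplier `1 + d*(asa-2)`
#' on each prevalence, clipped to \[0,1\]); the default 0 keeps covariates
#' independent.
#'
#' @param ... Named overrides of any default field.
#' @return Object of class `casemix_config`.
#' @export
casemix_config <- function(...) {
  cfg <- list(
    age_mean = 64, age_sd = 10,
    sex_female = 0.34,
    asa_freq = c("1" = 0.155, "2" = 0.52, "3" = 0.325),
    ps_freq = c("0" = 0.44, "1" = 0.46, "2" = 0.10),
    dyspnea_freq = c("0" = 0.425, "1" = 0.36, "2" = 0.18, "3" = 0.035),
    fev_mean = 83, fev_sd = 21, fev_missing_prob = 0.10,
    bmi_mean = 25.45, bmi_sd = 4.5,
    procedure_freq = c(limited = 0.14, lobectomy = 0.74,
                       bilobectomy = 0.035, pneumonectomy = 0.085),
    approach_freq = c(thoracotomy = 0.72, vats = 0.28),
    ptumor_freq = c(I = 0.39, II = 0.30, III = 0.15, IV = 0.05,
                    Missing = 0.10),
    pnodes_freq = c("0" = 0.63, "1" = 0.12, "2" = 0.13, Missing = 0.12),
    resection_freq = c(R0 = 0.85, R1 = 0.03, R2 = 0.02, Missing = 0.10),
    comorbidity_prev = c(
      coronary_disease = 0.09, tobacco = 0.255, chronic_bronchitis = 0.22,
      arrhythmia = 0.057, chronic_heart_failure = 0.024,
      peripheral_artery_disease = 0.019, alcoholism = 0.05,
      cirrhosis = 0.007, stroke = 0.03, diabetes = 0.103,
      coagulopathy = 0.07, hematologic_disease = 0.019,
      history_of_neoplasm = 0.29, surgical_history = 0.084,
      severe_malnutrition = 0.007, pulmonary_embolism = 0.013,
      infectious_disease = 0.025, endocrine_disorder = 0.035,
      anemia = 0.002, steroids = 0.004, immunosuppression = 0.006,
      cardiac_malformation = 0.0006, chronic_renal_disease = 0.018,
      valvulopathy = 0.008, neurological_disorder = 0.012,
      psychiatric_disorder = 0.033, asthma = 0.0125,
      respiratory_failure = 0.06),
    asa_comorbidity_dependence = 0
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(cfg))
  if (length(bad) > 0L) {
    stop("unknown casemix field(s): ", paste(bad, collapse = ", "))
  }
  cfg[names(overrides)] <- overrides

  for (f in c("asa_freq", "ps_freq", "dyspnea_freq", "procedure_freq",
              "approach_freq", "ptumor_freq", "pnodes_freq",
              "resection_freq")) {
    s <- sum(cfg[[f]])
    if (abs(s - 1) > 0.05) {
      stop("'", f, "' frequencies sum to ", signif(s, 4), ", not ~1")
    }
    cfg[[f]] <- cfg[[f]] / s
  }
  p <- c(cfg$sex_female, cfg$fev_missing_prob, cfg$comorbidity_prev)
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0,1]")
  stopifnot(setequal(names(cfg$comorbidity_prev), comorbidity_fields()))
  structure(cfg, class = "casemix_config")
}

#' @export
print.casemix_config <- function(x, ...) {
  cat("Case-mix configuration:",
      "\n  age", x$age_mean, "+/-", x$age_sd, "y;",
      round(100 * x$sex_female), "% female;",
      round(100 * x$approach_freq[["vats"]]), "% VATS;",
      round(100 * x$procedure_freq[["pneumonectomy"]], 1), "% pneumonectomy",
      "\n  FEV", x$fev_mean, "+/-", x$fev_sd, "% predicted,",
      round(100 * x$fev_missing_prob), "% missing;",
      length(x$comorbidity_prev), "comorbidity flags\n")
  invisible(x)
}
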