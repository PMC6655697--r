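#' Reference logistic coefficients for 30-day surgical mortality
#'
#' Published case-mix coefficients (log-odds) on the coded-term scale of
#' [code_covariates()], for the model estimated on the good-quality-data
#' (GQD) hospital group and, for comparison, on the low-quality-data
#' (LQD) group.  Terms screened out of the published models (the
#' remaining comorbidities, nodal stage, FEV) have coefficient 0 and are
#' omitted.
#'
#' @param group `"gqd"` (default) or `"lqd"`.
#' @return Named numeric vector of log-odds coefficients (no intercept).
#' @export
default_risk_coefficients <- function(group = c("gqd", "lqd")) {
  group <- match.arg(group)
  if (group == "gqd") {
    c(age_c = 0.044, sex_female = -0.944, asa = 0.31, ps_geq2 = 0.6,
      dyspnea_geq3 = 0.62, pneumonectomy = 0.77, vats = -0.59,
      bmi_24_28 = -0.55, bmi_gt28 = -0.67,
      chronic_heart_failure = 0.97, alcoholism = 0.58, cirrhosis = 0.94,
      history_of_neoplasm = 0.33, respiratory_failure = 0.79,
      ptumor_ii = 0.04, ptumor_iii = 0.5, ptumor_iv = 0.75,
      ptumor_missing = 0.79,
      resection_r1 = -0.11, resection_r2 = 0.22, resection_missing = -0.74)
  } else {
    c(age_c = 0.054, sex_female = -0.755, asa = 0.67, ps_geq2 = -0.004,
      dyspnea_geq3 = 1.62, pneumonectomy = 0.63, vats = -0.68,
      bmi_24_28 = -0.21, bmi_gt28 = -0.27,
      chronic_heart_failure = -0.07, alcoholism = 0.23, cirrhosis = 1.35,
      history_of_neoplasm = -0.03, respiratory_failure = 0.71,
      ptumor_ii = -0.17, ptumor_iii = 0.33, ptumor_iv = 0.63,
      ptumor_missing = 0.54,
      resection_r1 = 0.62, resection_r2 = 0.26, resection_missing = -0.19)
  }
}

#' Define the true mortality model of the synthetic cohort
#'
#' A logistic model on coded case-mix terms used as the data-generating
#' truth.  Defaults to the published GQD coefficients with intercept
#' -4.4 log-odds and age centered at 64 years.  ASA enters as the raw
#' 1-3 score, so the intercept corresponds to an (extrapolated) ASA of 0.
#'
#' @param coefficients Named log-odds vector on coded-term names.
#' @param intercept Intercept, log-odds.
#' @param age_center Age centering constant, years.
#' @return Object of class `true_model`.
#' @examples
#' m <- true_model()
#' # reference patient: male, age at center, ASA 0, everything else at
#' # reference level
#' plogis(m$intercept)  # ~0.0121
#' @export
true_model <- function(coefficients = default_risk_coefficients("gqd"),
                       intercept = -4.4, age_center = 64) {
  stopifnot(is.numeric(coefficients), !is.null(names(coefficients)),
            is.numeric(intercept), length(intercept) == 1L,
            is.numeric(age_center), length(age_center) == 1L)
  known <- unlist(risk_term_groups(), use.names = FALSE)
  bad <- setdiff(names(coefficients), known)
  if (length(bad) > 0L) {
    stop("coefficients name terms outside the covariate coding: ",
         paste(bad, collapse = ", "))
  }
  structure(list(coefficients = coefficients, intercept = intercept,
                 age_center = age_center),
            class = "true_model")
}

#' Per-patient death probability under a model
#'
#' Codes the registry covariates with the model's own age center and
#' evaluates the logistic linear predictor; no refitting.  This is the
#' linear-predictor transfer used to score one population with a model
#' estimated on another.
#'
#' @param model A `true_model` or a [fit_risk_model()] fit.
#' @param data Registry table.
#' @return Numeric vector of probabilities in (0,1).
#' @export
predict_risk <- function(model, data) {
  UseMethod("predict_risk")
}

#' @export
predict_risk.true_model <- function(model, data) {
  coded <- code_covariates(data, age_center = model$age_center)
  X <- coded_design(coded, names(model$coefficients))
  as.numeric(plogis(model$intercept + X %*% model$coefficients))
}

#' @export
predict_risk.risk_model_fit <- function(model, data) {
  coded <- code_covariates(data, age_center = model$age_center)
  X <- coded_design(coded, names(model$coefficients))
  as.numeric(plogis(model$intercept + X %*% model$coefficients))
}

#' @export
print.true_model <- function(x, ...) {
  cat("True mortality model:", length(x$coefficients),
      "non-zero terms; intercept", x$intercept,
      "log-odds; age centered at", x$age_center, "years\n")
  invisible(x)
}
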