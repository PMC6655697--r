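#' Comorbidity fields carried by the clinical registry
#'
#' Names of the binary comorbidity flags in a clinical registry record.
#' Flags are coded 0/1; absence of a record means "No".
#'
#' @return Character vector of column names.
#' @export
comorbidity_fields <- function() {
  c("coronary_disease", "tobacco", "chronic_bronchitis", "arrhythmia",
    "chronic_heart_failure", "peripheral_artery_disease", "alcoholism",
    "cirrhosis", "stroke", "diabetes", "coagulopathy",
    "hematologic_disease", "history_of_neoplasm", "surgical_history",
    "severe_malnutrition", "pulmonary_embolism", "infectious_disease",
    "endocrine_disorder", "anemia", "steroids", "immunosuppression",
    "cardiac_malformation", "chronic_renal_disease", "valvulopathy",
    "neurological_disorder", "psychiatric_disorder", "asthma",
    "respiratory_failure")
}

#' Coded-term groups of the risk-adjustment coding
#'
#' The covariate coder maps each raw registry variable to one or more
#' numeric 0/1 (or linear) columns.  Model selection operates on these
#' groups so that all indicator columns of a categorical variable enter
#' or leave a model together.
#'
#' @return Named list: group name -> character vector of coded columns.
#' @export
risk_term_groups <- function() {
  com <- comorbidity_fields()
  c(list(
    age = "age_c",
    sex = "sex_female",
    asa = "asa",
    performance_status = "ps_geq2",
    dyspnea = "dyspnea_geq3",
    bmi = c("bmi_24_28", "bmi_gt28"),
    fev = "fev",
    procedure = "pneumonectomy",
    approach = "vats",
    ptumor = c("ptumor_ii", "ptumor_iii", "ptumor_iv", "ptumor_missing"),
    pnodes = c("pnodes_1", "pnodes_2", "pnodes_missing"),
    resection = c("resection_r1", "resection_r2", "resection_missing")
  ), stats::setNames(as.list(com), com))
}

#' Default candidate variables for model building
#'
#' All coded-term groups except lung function (FEV), which is only a
#' candidate once multiple imputation has completed it.
#'
#' @param include_fev Include the FEV group (requires complete FEV).
#' @return Character vector of group names.
#' @export
candidate_terms <- function(include_fev = FALSE) {
  g <- names(risk_term_groups())
  if (!include_fev) g <- setdiff(g, "fev")
  g
}

stage_levels <- list(
  ptumor = c("I", "II", "III", "IV", "Missing"),
  pnodes = c("0", "1", "2", "Missing"),
  resection = c("R0", "R1", "R2", "Missing")
)

#' Code raw registry covariates into model terms
#'
#' Applies the fixed case-mix coding: age centered (years); sex with male
#' as reference; ASA as a linear 1-3 score; performance status
#' dichotomized 0-1 vs >=2; dyspnea dichotomized 0-2 vs >=3; BMI in three
#' classes (<24, 24-28, >28 kg/m2, reference <24); procedure other vs
#' pneumonectomy; approach thoracotomy vs video-assisted thoracoscopy
#' (VATS); pathological tumour stage, nodal stage and resection quality as
#' indicator sets with reference levels I / 0 / R0 and an explicit
#' "Missing" level; comorbidity flags passed through as 0/1.
#'
#' Stage and resection columns must not contain blanks: run
#' [add_missing_categories()] first so that missingness is an explicit
#' category.
#'
#' @param data Registry table (one row per patient).
#' @param age_center Centering constant for age, in years.  `NULL`
#'   (default) centers at the sample mean of `data$age`; a fitted or
#'   reference model supplies its own center when its coefficients are
#'   transferred.
#' @return A tibble of coded numeric columns, with `facility_id` and
#'   `death` carried through when present, and attribute `"age_center"`.
#' @export
code_covariates <- function(data, age_center = NULL) {
  required <- c("sex", "age", "asa", "performance_status", "dyspnea",
                "bmi", "procedure", "approach", "ptumor", "pnodes",
                "resection")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0L) {
    stop("registry table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  for (v in names(stage_levels)) {
    x <- data[[v]]
    if (anyNA(x) || any(!is.na(x) & x == "")) {
      stop("column '", v, "' contains blanks; run add_missing_categories() first")
    }
    bad <- setdiff(unique(x), stage_levels[[v]])
    if (length(bad) > 0L) {
      stop("column '", v, "' has unmappable levels: ", paste(bad, collapse = ", "))
    }
  }
  if (is.null(age_center)) age_center <- mean(data$age)

  out <- tibble::tibble(
    age_c = data$age - age_center,
    sex_female = as.numeric(data$sex == "female"),
    asa = as.numeric(data$asa),
    ps_geq2 = as.numeric(data$performance_status >= 2),
    dyspnea_geq3 = as.numeric(data$dyspnea >= 3),
    bmi_24_28 = as.numeric(data$bmi >= 24 & data$bmi <= 28),
    bmi_gt28 = as.numeric(data$bmi > 28),
    pneumonectomy = as.numeric(data$procedure == "pneumonectomy"),
    vats = as.numeric(data$approach == "vats"),
    ptumor_ii = as.numeric(data$ptumor == "II"),
    ptumor_iii = as.numeric(data$ptumor == "III"),
    ptumor_iv = as.numeric(data$ptumor == "IV"),
    ptumor_missing = as.numeric(data$ptumor == "Missing"),
    pnodes_1 = as.numeric(data$pnodes == "1"),
    pnodes_2 = as.numeric(data$pnodes == "2"),
    pnodes_missing = as.numeric(data$pnodes == "Missing"),
    resection_r1 = as.numeric(data$resection == "R1"),
    resection_r2 = as.numeric(data$resection == "R2"),
    resection_missing = as.numeric(data$resection == "Missing")
  )
  if ("fev" %in% names(data)) out$fev <- as.numeric(data$fev)
  for (v in intersect(comorbidity_fields(), names(data))) {
    out[[v]] <- as.numeric(data[[v]])
  }
  if ("facility_id" %in% names(data)) {
    out <- tibble::add_column(out, facility_id = data$facility_id, .before = 1)
  }
  if ("death" %in% names(data)) out$death <- as.integer(data$death)
  attr(out, "age_center") <- age_center
  out
}

# Expand coded columns for a coefficient name set: plain coded columns are
# taken as-is, "a:b" names are products of two coded columns (pairwise
# interaction terms retained by the model search).
coded_design <- function(coded, term_names) {
  X <- matrix(NA_real_, nrow = nrow(coded), ncol = length(term_names),
              dimnames = list(NULL, term_names))
  for (tn in term_names) {
    if (tn %in% names(coded)) {
      X[, tn] <- coded[[tn]]
    } else if (grepl(":", tn, fixed = TRUE)) {
      parts <- strsplit(tn, ":", fixed = TRUE)[[1]]
      if (!all(parts %in% names(coded))) {
        stop("cannot map interaction term '", tn, "' onto coded data")
      }
      X[, tn] <- coded[[parts[1]]] * coded[[parts[2]]]
    } else {
      stop("cannot map term '", tn, "' onto coded data; unmappable terms: ",
           paste(setdiff(term_names, names(coded)), collapse = ", "))
    }
  }
  X
}
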