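#' Per-hospital expected deaths under the group's own model
#'
#' E1(h) is the sum of model-predicted death probabilities over hospital
#' h's patients, using a model fitted on the same group the hospitals
#' belong to.  Because the logistic MLE with intercept is calibrated in
#' the large, the expected deaths summed over the whole fitting group
#' equal the observed deaths.
#'
#' @param fit `risk_model_fit` trained on the same group as `data`.
#' @param data Registry table of the group's patients.
#' @return Tibble with `facility_id`, `n`, `E`.
#' @export
expected_deaths_internal <- function(fit, data) {
  expected_deaths(predict_risk(fit, data), data)
}

#' Per-hospital expected deaths under a transferred reference model
#'
#' E2(h) scores the target patients with the linear predictor of a model
#' estimated on a reference population (coefficients and age center taken
#' as-is, no refitting) and sums the resulting probabilities per
#' hospital.  Target records must be codable with the reference coding;
#' unmappable levels raise an error naming them.
#'
#' @param reference_fit `risk_model_fit` (or [true_model()]) from the
#'   reference group.
#' @param target_data Registry table of the target group's patients.
#' @return Tibble with `facility_id`, `n`, `E`.
#' @export
expected_deaths_transferred <- function(reference_fit, target_data) {
  expected_deaths(predict_risk(reference_fit, target_data), target_data)
}

expected_deaths <- function(probs, data) {
  stopifnot(length(probs) == nrow(data))
  out <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(facility_id = data$facility_id, p = probs),
                    .data$facility_id),
    n = dplyr::n(), E = sum(.data$p), .groups = "drop")
  out
}

#' SMR and its standard error for one hospital
#'
#' The standardized mortality ratio is O/E with E the sum of per-patient
#' predicted probabilities.  The variance of O treats deaths as
#' independent Bernoulli draws, Var(O) = sum p_i (1 - p_i), giving
#' se(SMR) = sqrt(Var(O)) / E, and the standard-normal deviate
#' z = (O - E) / sqrt(Var(O)) used by the outlier test.
#'
#' Conventions: O = 0 gives SMR 0 whatever E > 0; E = 0 with O = 0 is
#' reported as SMR 0 with zero weight (NA se); E = 0 with O > 0 is
#' undefined and errors.
#'
#' @param O Observed deaths (count).
#' @param per_patient_probs Predicted probabilities of the hospital's
#'   patients.
#' @return One-row tibble: `O`, `E`, `smr`, `var_o`, `se`, `z`.
#' @export
smr_with_se <- function(O, per_patient_probs) {
  E <- sum(per_patient_probs)
  v <- sum(per_patient_probs * (1 - per_patient_probs))
  if (E == 0) {
    if (O > 0) stop("SMR undefined: expected deaths 0 with observed deaths > 0")
    return(tibble::tibble(O = O, E = 0, smr = 0, var_o = 0,
                          se = NA_real_, z = NA_real_))
  }
  tibble::tibble(O = O, E = E, smr = O / E, var_o = v,
                 se = sqrt(v) / E,
                 z = if (v > 0) (O - E) / sqrt(v) else NA_real_)
}

#' Per-hospital SMR profile under one estimator
#'
#' Computes O, E, SMR, standard error and outlier status for every
#' hospital in `data`.  Probabilities come either from `model` (fitted
#' internally, or transferred — pass the reference fit) or directly via
#' `probs` (e.g. averaged over multiply imputed datasets).
#'
#' @param data Registry table with `facility_id` and `death`.
#' @param model Model used to predict per-patient risk (ignored when
#'   `probs` is given).
#' @param probs Optional vector of per-patient probabilities.
#' @param estimator Label stored in the output, e.g. `"SMR1"` (internal
#'   model) or `"SMR2"` (transferred reference model).
#' @param alpha Two-sided outlier level, default 0.05.
#' @param method `"normal"` z-test (default) or `"midp"` exact Poisson
#'   mid-p test for small expected counts.
#' @param bonferroni Divide `alpha` by the number of hospitals.
#' @return Tibble, one row per hospital: `facility_id`, `n`, `O`, `E`,
#'   `smr`, `se`, `z`, `status`, `estimator`.
#' @export
hospital_smr <- function(data, model = NULL, probs = NULL,
                         estimator = "SMR1", alpha = 0.05,
                         method = c("normal", "midp"), bonferroni = FALSE) {
  method <- match.arg(method)
  if (is.null(probs)) {
    if (is.null(model)) stop("supply either 'model' or 'probs'")
    probs <- predict_risk(model, data)
  }
  stopifnot(length(probs) == nrow(data))
  df <- tibble::tibble(facility_id = data$facility_id,
                       death = as.integer(data$death), p = probs)
  per <- split(df, df$facility_id)
  rows <- lapply(per, function(d) {
    r <- smr_with_se(sum(d$death), d$p)
    tibble::add_column(r, facility_id = d$facility_id[1], n = nrow(d),
                       .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  out$estimator <- estimator
  outlier_test(out, alpha = alpha, method = method, bonferroni = bonferroni)
}

#' Flag low-/high-mortality outliers
#'
#' Normal-deviate test on z = (O - E)/sqrt(Var(O)): a hospital is a
#' high-mortality outlier when z exceeds the upper alpha/2 normal
#' quantile (its SMR is then necessarily above 1), a low-mortality
#' outlier when z is below the lower quantile, and a non-outlier
#' otherwise.  Hospitals with Var(O) = 0 are non-outliers with a
#' warning.  `method = "midp"` replaces the normal test by an exact
#' Poisson mid-p test of O against mean E, preferable when E is small.
#' No multiplicity correction is applied unless `bonferroni = TRUE`.
#'
#' @param smr Tibble from [hospital_smr()] / [smr_with_se()] with
#'   columns `O`, `E`, `smr`, `z`.
#' @param alpha Two-sided level, default 0.05.
#' @param method `"normal"` or `"midp"`.
#' @param bonferroni Divide `alpha` by the number of hospitals tested.
#' @return `smr` with a `status` column: `"low-outlier"`,
#'   `"non-outlier"` or `"high-outlier"`.
#' @export
outlier_test <- function(smr, alpha = 0.05, method = c("normal", "midp"),
                         bonferroni = FALSE) {
  method <- match.arg(method)
  stopifnot(alpha > 0, alpha < 1)
  if (bonferroni) alpha <- alpha / nrow(smr)
  if (any(is.na(smr$z) & smr$E > 0)) {
    warning("hospital(s) with zero outcome variance: classified non-outlier")
  }
  if (method == "normal") {
    zc <- qnorm(1 - alpha / 2)
    status <- ifelse(!is.na(smr$z) & smr$z > zc & smr$smr > 1, "high-outlier",
              ifelse(!is.na(smr$z) & smr$z < -zc & smr$smr < 1, "low-outlier",
                     "non-outlier"))
  } else {
    p_up <- ppois(smr$O - 1, smr$E, lower.tail = FALSE) -
      0.5 * dpois(smr$O, smr$E)
    p_lo <- ppois(smr$O, smr$E) - 0.5 * dpois(smr$O, smr$E)
    status <- ifelse(smr$E > 0 & p_up < alpha / 2 & smr$smr > 1, "high-outlier",
              ifelse(smr$E > 0 & p_lo < alpha / 2 & smr$smr < 1, "low-outlier",
                     "non-outlier"))
  }
  smr$status <- factor(status,
                       levels = c("low-outlier", "non-outlier", "high-outlier"))
  smr
}

#' Between-hospital SMR dispersion
#'
#' 25th and 75th percentiles (linear-interpolation convention) and their
#' difference, summarizing between-hospital variation of the SMR.
#'
#' @param smrs Numeric SMR values, or a tibble with an `smr` column.
#' @return Named numeric vector: `q25`, `q75`, `iqr`.
#' @export
smr_dispersion <- function(smrs) {
  x <- if (is.data.frame(smrs)) smrs$smr else smrs
  q <- quantile(x, probs = c(0.25, 0.75), type = 7, names = FALSE)
  c(q25 = q[1], q75 = q[2], iqr = q[2] - q[1])
}
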