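#' Variable groups of the published case-mix model
#'
#' The case-mix variables retained in the reference risk-adjustment
#' model: demographics, functional scores, procedure, approach, BMI
#' classes, five comorbidities, tumour stage and resection quality.
#' Used as the fixed term set when the study pipeline is run without
#' re-doing variable selection (e.g. in replicated simulations).
#'
#' @return Character vector of group names.
#' @export
published_model_groups <- function() {
  c("age", "sex", "asa", "performance_status", "dyspnea", "bmi",
    "procedure", "approach", "chronic_heart_failure", "alcoholism",
    "cirrhosis", "history_of_neoplasm", "respiratory_failure",
    "ptumor", "resection")
}

#' Average predicted risk over an imputation set
#'
#' @param fit A `risk_model_fit`.
#' @param iset An [impute_fev()] imputation set.
#' @return Per-patient probabilities averaged across completed datasets.
#' @export
predict_risk_mi <- function(fit, iset) {
  stopifnot(inherits(iset, "imputation_set"))
  P <- vapply(iset$completed, function(d) predict_risk(fit, d),
              numeric(nrow(iset$completed[[1]])))
  rowMeans(P)
}

#' Run the full hospital-profiling study pipeline
#'
#' End-to-end analysis on a paired registry set: link and classify
#' hospitals by completeness; split the clinical registry into GQD and
#' LQD patients; categorize missing staging and (optionally) multiply
#' impute FEV; build the case-mix model per group (univariate screening
#' at `screen_alpha`, AIC step-down, optional interaction search); score
#' LQD hospitals under the internally fitted LQD model (SMR1) and under
#' the transferred GQD model (SMR2); test for mortality outliers;
#' summarize dispersion, cross-classification, kappa agreement and the
#' group mortality contrast.
#'
#' @param admin Administrative cohort table.
#' @param clinical Clinical registry table.
#' @param threshold Completeness cutoff for GQD, default 0.7.
#' @param select Run screening + AIC selection (default `TRUE`); when
#'   `FALSE`, both models fit the fixed [published_model_groups()].
#' @param impute Multiply impute FEV (default `TRUE` when selecting;
#'   forced off when `select = FALSE` since FEV is outside the fixed
#'   term set).
#' @param m Imputed datasets, default 5.
#' @param screen_alpha Univariate screening level, default 0.1.
#' @param direction Selection direction, default `"backward"`.
#' @param interactions Pairwise interaction search, default `FALSE`.
#' @param alpha Outlier test level, default 0.05.
#' @param seed Seed for the imputation draws.
#' @return List of class `profiling_study` with elements `summaries`,
#'   `fit_gqd`, `fit_lqd`, `smr1`, `smr2`, `iqr1`, `iqr2`, `agreement`,
#'   `kappa`, `mortality`, `n_gqd`, `n_lqd`.
#' @export
run_study <- function(admin, clinical, threshold = 0.7, select = TRUE,
                      impute = select, m = 5, screen_alpha = 0.1,
                      direction = "backward", interactions = FALSE,
                      alpha = 0.05, seed = 1) {
  summaries <- classify_quality(summarize_by_hospital(clinical, admin),
                                threshold = threshold)
  gqd_ids <- summaries$facility_id[summaries$quality_class == "GQD"]
  lqd_ids <- summaries$facility_id[summaries$quality_class == "LQD"]
  if (length(gqd_ids) == 0L || length(lqd_ids) == 0L) {
    stop("classification produced an empty hospital group (",
         length(gqd_ids), " GQD, ", length(lqd_ids), " LQD)")
  }
  gqd <- add_missing_categories(clinical[clinical$facility_id %in% gqd_ids, ])
  lqd <- add_missing_categories(clinical[clinical$facility_id %in% lqd_ids, ])

  if (impute && !select) impute <- FALSE
  if (impute) {
    iset_g <- impute_fev(gqd, m = m, seed = hospital_seed(seed, 1L, 9L))
    iset_l <- impute_fev(lqd, m = m, seed = hospital_seed(seed, 2L, 9L))
    fit_gqd <- fit_risk_model_mi(iset_g, alpha = screen_alpha,
                                 direction = direction,
                                 interactions = interactions)
    fit_lqd <- fit_risk_model_mi(iset_l, alpha = screen_alpha,
                                 direction = direction,
                                 interactions = interactions)
    p1 <- predict_risk_mi(fit_lqd, iset_l)
    p2 <- predict_risk_mi(fit_gqd, iset_l)
  } else {
    terms <- if (select) {
      NULL  # screened below, per group
    } else published_model_groups()
    fit1 <- function(d) {
      tt <- terms
      if (is.null(tt)) tt <- univariate_screen(d, alpha = screen_alpha)
      fit_risk_model(d, terms = tt,
                     direction = if (select) direction else "none",
                     interactions = interactions)
    }
    fit_gqd <- fit1(gqd)
    fit_lqd <- fit1(lqd)
    p1 <- predict_risk(fit_lqd, lqd)
    p2 <- predict_risk(fit_gqd, lqd)
  }

  smr1 <- hospital_smr(lqd, probs = p1, estimator = "SMR1", alpha = alpha)
  smr2 <- hospital_smr(lqd, probs = p2, estimator = "SMR2", alpha = alpha)
  agreement <- cross_classify(smr1, smr2)
  kappa <- cohen_kappa(agreement)
  structure(list(
    summaries = summaries,
    fit_gqd = fit_gqd, fit_lqd = fit_lqd,
    smr1 = smr1, smr2 = smr2,
    iqr1 = smr_dispersion(smr1), iqr2 = smr_dispersion(smr2),
    agreement = agreement, kappa = kappa,
    mortality = compare_group_mortality(gqd, lqd),
    n_gqd = nrow(gqd), n_lqd = nrow(lqd)
  ), class = "profiling_study")
}

#' @export
print.profiling_study <- function(x, ...) {
  s <- x$summaries
  cat("Hospital profiling study\n")
  cat(sprintf("  %d GQD hospitals (%d patients), %d LQD hospitals (%d patients)\n",
              sum(s$quality_class == "GQD"), x$n_gqd,
              sum(s$quality_class == "LQD"), x$n_lqd))
  cat(sprintf("  mortality %.1f%% (GQD) vs %.1f%% (LQD), p = %.2g\n",
              100 * x$mortality$rate_gqd, 100 * x$mortality$rate_lqd,
              x$mortality$pvalue))
  cat(sprintf("  SMR1 IQR %.3f-%.3f; SMR2 IQR %.3f-%.3f\n",
              x$iqr1[["q25"]], x$iqr1[["q75"]],
              x$iqr2[["q25"]], x$iqr2[["q75"]]))
  cat(sprintf("  high-mortality outliers: %d (SMR1), %d (SMR2); kappa %.2f (%s)\n",
              sum(x$smr1$status == "high-outlier"),
              sum(x$smr2$status == "high-outlier"),
              x$kappa$kappa, x$kappa$band))
  invisible(x)
}

#' Write the study report files
#'
#' Renders the pipeline outputs as files in `dir`:
#' `hospital_summary.csv` (completeness ratios and quality class),
#' `model_gqd.json` / `model_lqd.json` (serialized fits),
#' `smr_profiles.csv` (both estimators' per-hospital SMR rows),
#' `agreement.json` (cross-classification, kappa, band, mortality
#' contrast) and a human-readable `report.txt`.
#'
#' @param study A [run_study()] result.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
build_report <- function(study, dir) {
  stopifnot(inherits(study, "profiling_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("hospital_summary.csv", "model_gqd.json",
                            "model_lqd.json", "smr_profiles.csv",
                            "agreement.json", "report.txt"))
  write.csv(study$summaries, paths[1], row.names = FALSE, na = "")
  write_risk_model(study$fit_gqd, paths[2])
  write_risk_model(study$fit_lqd, paths[3])
  write.csv(dplyr::bind_rows(study$smr1, study$smr2), paths[4],
            row.names = FALSE, na = "")
  jsonlite::write_json(list(
    matrix = unclass(study$agreement),
    n = attr(study$agreement, "n"),
    kappa = study$kappa$kappa, band = study$kappa$band,
    mortality = list(rate_gqd = study$mortality$rate_gqd,
                     rate_lqd = study$mortality$rate_lqd,
                     pvalue = study$mortality$pvalue,
                     test = study$mortality$test),
    iqr_smr1 = as.list(study$iqr1), iqr_smr2 = as.list(study$iqr2)
  ), paths[5], auto_unbox = TRUE, digits = NA)

  con <- file(paths[6], "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  s <- study$summaries
  w("Hospital profiling report")
  w("=========================")
  w("")
  w("Data quality classification")
  w("  GQD hospitals: %d   LQD hospitals: %d   anomalies: %d",
    sum(s$quality_class == "GQD"), sum(s$quality_class == "LQD"),
    sum(!is.na(s$anomaly)))
  w("  median case ratio %.3f (GQD) / %.3f (LQD)",
    stats::median(s$ratio_cases[s$quality_class == "GQD"]),
    stats::median(s$ratio_cases[s$quality_class == "LQD"]))
  w("")
  w("Observed mortality")
  w("  GQD %.1f%% vs LQD %.1f%% (%s test p = %.3g)",
    100 * study$mortality$rate_gqd, 100 * study$mortality$rate_lqd,
    study$mortality$test, study$mortality$pvalue)
  w("")
  w("Risk-adjustment models")
  for (g in c("gqd", "lqd")) {
    f <- study[[paste0("fit_", g)]]
    w("  %s: n = %d, deaths = %d, C = %.2f, R2 = %.2f, HL = %.2f (p = %.2f)",
      toupper(g), f$n, f$deaths, f$c_statistic, f$r2,
      f$hl_statistic, f$hl_pvalue)
  }
  w("")
  w("SMR profiling of LQD hospitals")
  w("  SMR1 (internal model):    IQR %.3f-%.3f, %d high / %d low outliers",
    study$iqr1[["q25"]], study$iqr1[["q75"]],
    sum(study$smr1$status == "high-outlier"),
    sum(study$smr1$status == "low-outlier"))
  w("  SMR2 (transferred model): IQR %.3f-%.3f, %d high / %d low outliers",
    study$iqr2[["q25"]], study$iqr2[["q75"]],
    sum(study$smr2$status == "high-outlier"),
    sum(study$smr2$status == "low-outlier"))
  w("")
  w("Agreement between estimators (rows SMR1, columns SMR2)")
  m <- study$agreement
  w("              %12s %12s %12s", colnames(m)[1], colnames(m)[2],
    colnames(m)[3])
  for (i in 1:3) w("  %12s %12d %12d %12d", rownames(m)[i],
                   m[i, 1], m[i, 2], m[i, 3])
  w("  kappa = %.2f (%s agreement)", study$kappa$kappa, study$kappa$band)
  invisible(paths)
}
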