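#' Turn blank staging/resection fields into an explicit "Missing" category
#'
#' Blanks (`NA` or empty strings) in `ptumor`, `pnodes` and
#' `resection` are replaced by the category `"Missing"`, which then
#' participates in the model coding as its own level.  Columns that end
#' up single-level ("Missing" everywhere) are degenerate for modeling and
#' trigger a warning.
#'
#' @param clinical Clinical registry table.
#' @return The table with no blanks left in the three staging columns.
#' @export
add_missing_categories <- function(clinical) {
  for (v in c("ptumor", "pnodes", "resection")) {
    if (!v %in% names(clinical)) stop("column '", v, "' not found")
    x <- as.character(clinical[[v]])
    x[is.na(x) | x == ""] <- "Missing"
    clinical[[v]] <- x
    if (all(x == "Missing")) {
      warning("column '", v, "' is entirely 'Missing'; degenerate for modeling")
    }
  }
  clinical
}

#' Multiple imputation of missing FEV
#'
#' Completes the forced-expiratory-volume column by stochastic regression
#' imputation: a linear model of FEV on the other coded model covariates
#' plus the outcome is fitted on complete cases; for each of the `m`
#' completed datasets, residual variance and coefficients are drawn from
#' their large-sample posterior (scaled inverse-chi-squared and normal,
#' respectively) and missing values are replaced by the posterior
#' predictive draw.  Draws are truncated to \[10, 160\]% predicted.
#' Only FEV is imputed; all other columns are identical across the `m`
#' datasets.
#'
#' @param clinical Clinical registry table (staging already categorized
#'   via [add_missing_categories()]).
#' @param m Number of completed datasets (default 5).
#' @param seed Integer seed.
#' @return Object of class `imputation_set`: list with `m`,
#'   `completed` (list of m tables), `imputation_model_terms`, and the
#'   index of imputed rows.
#' @export
impute_fev <- function(clinical, m = 5, seed = 1) {
  stopifnot(m >= 1, "fev" %in% names(clinical))
  miss <- is.na(clinical$fev)
  if (all(miss)) stop("FEV is entirely missing; cannot build an imputation model")
  terms <- setdiff(unlist(risk_term_groups(), use.names = FALSE), "fev")
  if (!any(miss)) {
    return(structure(list(m = m, completed = rep(list(clinical), m),
                          imputation_model_terms = c(terms, "death"),
                          imputed_rows = integer(0)),
                     class = "imputation_set"))
  }
  coded <- code_covariates(clinical)
  X <- cbind(1, coded_design(coded, terms), death = as.numeric(clinical$death))
  colnames(X)[1] <- "(Intercept)"
  obs <- which(!miss)
  fit <- stats::lm.fit(X[obs, , drop = FALSE], clinical$fev[obs])
  keep <- !is.na(fit$coefficients)          # drop aliased columns
  Xk <- X[, keep, drop = FALSE]
  fit <- stats::lm.fit(Xk[obs, , drop = FALSE], clinical$fev[obs])
  beta_hat <- fit$coefficients
  df_res <- length(obs) - fit$rank
  sigma2_hat <- sum(fit$residuals^2) / df_res
  R <- chol(crossprod(Xk[obs, , drop = FALSE]))

  completed <- with_seed(seed, lapply(seq_len(m), function(k) {
    sigma2_star <- sigma2_hat * df_res / rchisq(1, df_res)
    beta_star <- beta_hat +
      sqrt(sigma2_star) * backsolve(R, rnorm(length(beta_hat)))
    draws <- Xk[miss, , drop = FALSE] %*% beta_star +
      rnorm(sum(miss), 0, sqrt(sigma2_star))
    out <- clinical
    out$fev[miss] <- pmin(160, pmax(10, as.numeric(draws)))
    out
  }))
  structure(list(m = m, completed = completed,
                 imputation_model_terms = c(names(beta_hat)[-1]),
                 imputed_rows = which(miss)),
            class = "imputation_set")
}

#' @export
print.imputation_set <- function(x, ...) {
  cat("Imputation set: m =", x$m, "completed datasets;",
      length(x$imputed_rows), "FEV values imputed per dataset\n")
  invisible(x)
}

#' Pool fitted models across imputed datasets by Rubin's rules
#'
#' Pooled coefficient = mean across datasets; pooled variance =
#' within-imputation variance + (1 + 1/m) x between-imputation variance.
#' Fit diagnostics (C-statistic, R2, Hosmer-Lemeshow) are averaged.
#'
#' @param per_dataset_fits List of [fit_risk_model()] fits sharing one
#'   term set.
#' @return A pooled `risk_model_fit`.
#' @export
pool_estimates <- function(per_dataset_fits) {
  stopifnot(length(per_dataset_fits) >= 1)
  m <- length(per_dataset_fits)
  term_sets <- lapply(per_dataset_fits, function(f) names(f$coefficients))
  if (!all(vapply(term_sets, identical, logical(1), y = term_sets[[1]]))) {
    stop("per-dataset fits have mismatched term sets; pooling requires a ",
         "common set")
  }
  getB <- function(f) c("(Intercept)" = f$intercept, f$coefficients)
  getS <- function(f) c("(Intercept)" = f$intercept_se, f$standard_errors)
  B <- do.call(rbind, lapply(per_dataset_fits, getB))
  S <- do.call(rbind, lapply(per_dataset_fits, getS))
  qbar <- colMeans(B)
  W <- colMeans(S^2)
  Bvar <- if (m > 1) apply(B, 2, stats::var) else rep(0, ncol(B))
  Tvar <- W + (1 + 1 / m) * Bvar
  se <- sqrt(Tvar)

  f1 <- per_dataset_fits[[1]]
  avg <- function(field) mean(vapply(per_dataset_fits, function(f)
    f[[field]] %||% NA_real_, numeric(1)))
  structure(list(
    terms = names(f1$coefficients),
    groups = f1$groups,
    coefficients = qbar[-1],
    standard_errors = se[-1],
    intercept = unname(qbar[1]),
    intercept_se = unname(se[1]),
    age_center = f1$age_center,
    c_statistic = avg("c_statistic"),
    r2 = avg("r2"),
    hl_statistic = avg("hl_statistic"),
    hl_pvalue = avg("hl_pvalue"),
    aic = avg("aic"),
    n = f1$n, deaths = f1$deaths, m = m
  ), class = "risk_model_fit")
}
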