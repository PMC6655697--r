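# ---- low-level logistic fitting on a coded design -------------------------

# Fit a logistic MLE on an explicit design matrix (intercept added here).
# Returns coefficients, SEs, log-likelihoods, AIC, fitted values and a
# separation flag.  Errors on non-convergence or aliased columns, which in
# this coding arise only from degenerate inputs.
fit_logistic <- function(X, y, allow_separation = FALSE) {
  Xi <- cbind("(Intercept)" = 1, X)
  fit <- suppressWarnings(stats::glm.fit(Xi, y, family = binomial()))
  if (!fit$converged && !allow_separation) {
    stop("logistic fit did not converge for terms: ",
         paste(colnames(X), collapse = ", "))
  }
  if (fit$rank < ncol(Xi)) {
    stop("aliased (collinear) terms in logistic fit: ",
         paste(colnames(Xi)[is.na(fit$coefficients)], collapse = ", "))
  }
  separated <- max(abs(fit$coefficients)) > 15 || !fit$converged
  complete_sep <- all(abs(fit$fitted.values - y) < 1e-8)
  if (complete_sep && !allow_separation) {
    stop("complete separation in logistic fit for terms: ",
         paste(colnames(X), collapse = ", "))
  }
  R <- qr.R(fit$qr)
  covm <- chol2inv(R)
  se <- numeric(ncol(Xi))
  se[fit$qr$pivot] <- sqrt(diag(covm))
  names(se) <- colnames(Xi)
  ll <- (2 * fit$rank - fit$aic) / 2
  list(coefficients = fit$coefficients, se = se, loglik = ll,
       aic = fit$aic, fitted = fit$fitted.values, rank = fit$rank,
       separated = separated)
}

loglik_null <- function(y) {
  p <- mean(y)
  if (p <= 0 || p >= 1) stop("outcome has no variation")
  sum(y * log(p) + (1 - y) * log(1 - p))
}

# ---- univariate screening --------------------------------------------------

#' Univariate screening of candidate case-mix variables
#'
#' Tests each candidate variable (coded-term group) one at a time against
#' the death outcome with a likelihood-ratio test and keeps those with
#' p <= `alpha`.  Constant (no-information) candidates are excluded with
#' a warning; candidates whose univariate fit shows separation are
#' flagged and retained for multivariate consideration with a warning.
#'
#' @param data Registry table (staging categorized; FEV complete if the
#'   `fev` group is among the candidates).
#' @param candidates Character vector of group names from
#'   [risk_term_groups()]; defaults to all groups except FEV.
#' @param alpha Screening level, default 0.1.
#' @param age_center Age centering; `NULL` = sample mean.
#' @return Character vector of retained group names, with attribute
#'   `"pvalues"` (named, all candidates) and `"separation"` (flagged
#'   groups).
#' @export
univariate_screen <- function(data, candidates = candidate_terms(),
                              alpha = 0.1, age_center = NULL) {
  groups <- risk_term_groups()
  bad <- setdiff(candidates, names(groups))
  if (length(bad) > 0L) stop("unknown candidate group(s): ",
                             paste(bad, collapse = ", "))
  coded <- code_covariates(data, age_center = age_center)
  y <- coded$death
  ll0 <- loglik_null(y)
  pvals <- stats::setNames(rep(NA_real_, length(candidates)), candidates)
  sep_flags <- character(0)
  kept <- character(0)
  for (g in candidates) {
    cols <- groups[[g]]
    X <- coded_design(coded, cols)
    keep_col <- apply(X, 2, function(v) stats::var(v) > 0)
    if (!any(keep_col)) {
      warning("candidate '", g, "' is constant; excluded from screening")
      next
    }
    if (anyNA(X)) {
      stop("candidate '", g, "' contains missing values; impute first")
    }
    f <- fit_logistic(X[, keep_col, drop = FALSE], y, allow_separation = TRUE)
    pvals[g] <- pchisq(2 * (f$loglik - ll0), df = sum(keep_col),
                       lower.tail = FALSE)
    if (f$separated) {
      warning("separation in univariate fit of '", g,
              "'; retained for multivariate consideration")
      sep_flags <- c(sep_flags, g)
      kept <- c(kept, g)
    } else if (!is.na(pvals[g]) && pvals[g] <= alpha) {
      kept <- c(kept, g)
    }
  }
  structure(unique(kept), pvalues = pvals, separation = sep_flags)
}

#' Linear-gradient conformity check for an ordered score
#'
#' Compares the linear (score) coding of an ordinal variable against its
#' categorical (factor) coding by a likelihood-ratio chi-squared test.
#' When the categorical coding does not fit significantly better
#' (p >= `level`), the variable conforms to a linear gradient and is
#' entered as a linear score.
#'
#' @param data Registry table with a `death` column.
#' @param term Name of a raw ordinal column (e.g. `"asa"`, `"dyspnea"`,
#'   `"performance_status"`) with at least 3 observed levels.
#' @param level Decision level, default 0.05.
#' @return `"linear"` or `"categorical"`, with attribute `"pvalue"`.
#' @export
linear_gradient_check <- function(data, term, level = 0.05) {
  x <- data[[term]]
  if (is.null(x)) stop("column '", term, "' not found")
  lev <- sort(unique(x))
  if (length(lev) < 3L) {
    stop("linear-gradient check not applicable: '", term,
         "' has fewer than 3 observed levels")
  }
  y <- data$death
  f_lin <- fit_logistic(cbind(score = as.numeric(x)), y)
  F <- stats::model.matrix(~ factor(x))[, -1, drop = FALSE]
  f_cat <- fit_logistic(F, y)
  df <- (length(lev) - 1L) - 1L
  p <- pchisq(2 * (f_cat$loglik - f_lin$loglik), df = df, lower.tail = FALSE)
  structure(if (p >= level) "linear" else "categorical", pvalue = p)
}

# ---- model fit with AIC-guided selection -----------------------------------

#' Fit the case-mix logistic risk-adjustment model
#'
#' Maximum-likelihood logistic regression of the death flag on the coded
#' case-mix terms, with variable selection at the level of coded-term
#' groups (all indicator columns of a categorical variable move
#' together).  The default `direction = "backward"` removes, one group at
#' a time, the group whose removal most decreases the Akaike information
#' criterion, stopping when no removal decreases it (AIC step-down
#' stopping rule).  `"forward"` builds up from the intercept-only model;
#' `"none"` fits the given terms as-is.  With `interactions = TRUE`,
#' pairwise products of the retained groups' columns are then sought
#' greedily and kept only while they decrease the AIC.
#'
#' Diagnostics: rank-based C-statistic ([c_statistic()]), Nagelkerke R2
#' ([nagelkerke_r2()]) and the Hosmer-Lemeshow test
#' ([hosmer_lemeshow()]) with `hl_groups` risk groups.
#'
#' @param data Registry table with `death` (staging categorized; FEV
#'   complete if the `fev` group is requested).
#' @param terms Character vector of candidate group names (typically the
#'   output of [univariate_screen()]).
#' @param age_center Age centering constant; `NULL` = sample mean of the
#'   fitting data (the center is stored and reused when the model is
#'   transferred).
#' @param direction `"backward"` (default), `"forward"` or `"none"`.
#' @param interactions Search pairwise interactions among retained
#'   groups (default `FALSE`).
#' @param hl_groups Hosmer-Lemeshow groups, default 10.
#' @return Object of class `risk_model_fit`.
#' @export
fit_risk_model <- function(data, terms = candidate_terms(),
                           age_center = NULL,
                           direction = c("backward", "forward", "none"),
                           interactions = FALSE, hl_groups = 10) {
  direction <- match.arg(direction)
  groups <- risk_term_groups()
  bad <- setdiff(terms, names(groups))
  if (length(bad) > 0L) stop("unknown term group(s): ",
                             paste(bad, collapse = ", "))
  coded <- code_covariates(data, age_center = age_center)
  age_center <- attr(coded, "age_center")
  y <- coded$death
  group_cols <- lapply(groups[terms], function(cols) {
    X <- coded_design(coded, cols)
    cols[apply(X, 2, function(v) stats::var(v) > 0)]
  })
  empty <- vapply(group_cols, length, integer(1)) == 0L
  if (any(empty)) {
    warning("constant term group(s) dropped: ",
            paste(terms[empty], collapse = ", "))
    group_cols <- group_cols[!empty]
  }
  aic_of <- function(cols) {
    if (length(cols) == 0L) {
      ll <- loglik_null(y)
      return(-2 * ll + 2)
    }
    fit_logistic(coded_design(coded, cols), y)$aic
  }
  flatten <- function(gc) unname(unlist(gc))

  aic_full <- aic_of(flatten(group_cols))
  current <- group_cols
  current_aic <- if (direction == "forward") aic_of(character(0)) else aic_full

  if (direction == "backward") {
    repeat {
      if (length(current) == 0L) break
      trial <- vapply(names(current), function(g) {
        aic_of(flatten(current[setdiff(names(current), g)]))
      }, numeric(1))
      if (min(trial) < current_aic) {
        drop_g <- names(current)[which.min(trial)]
        current <- current[setdiff(names(current), drop_g)]
        current_aic <- min(trial)
      } else break
    }
  } else if (direction == "forward") {
    remaining <- group_cols
    current <- list()
    repeat {
      if (length(remaining) == 0L) break
      trial <- vapply(names(remaining), function(g) {
        aic_of(flatten(c(current, remaining[g])))
      }, numeric(1))
      if (min(trial) < current_aic) {
        add_g <- names(remaining)[which.min(trial)]
        current <- c(current, remaining[add_g])
        remaining <- remaining[setdiff(names(remaining), add_g)]
        current_aic <- min(trial)
      } else break
    }
  }

  final_cols <- flatten(current)

  if (interactions && length(current) >= 2L) {
    pairs <- utils::combn(names(current), 2, simplify = FALSE)
    repeat {
      best_gain <- 0; best_cols <- NULL; best_pair <- NULL
      for (pr in pairs) {
        icols <- as.vector(outer(current[[pr[1]]], current[[pr[2]]],
                                 paste, sep = ":"))
        X <- coded_design(coded, c(final_cols, icols))
        ok <- apply(X[, icols, drop = FALSE], 2,
                    function(v) stats::var(v) > 0)
        icols <- icols[ok]
        if (length(icols) == 0L) next
        a <- tryCatch(aic_of(c(final_cols, icols)), error = function(e) Inf)
        if (current_aic - a > best_gain) {
          best_gain <- current_aic - a
          best_cols <- icols
          best_pair <- pr
        }
      }
      if (is.null(best_cols)) break
      final_cols <- c(final_cols, best_cols)
      current_aic <- current_aic - best_gain
      pairs <- Filter(function(pr) !identical(pr, best_pair), pairs)
    }
  }

  if (length(final_cols) == 0L) {
    p0 <- mean(y)
    fit <- list(coefficients = c("(Intercept)" = qlogis(p0)),
                se = c("(Intercept)" = sqrt(1 / (length(y) * p0 * (1 - p0)))),
                loglik = loglik_null(y), aic = -2 * loglik_null(y) + 2,
                fitted = rep(p0, length(y)))
  } else {
    fit <- fit_logistic(coded_design(coded, final_cols), y)
  }

  hl <- hosmer_lemeshow(fit$fitted, y, g = hl_groups)
  structure(list(
    terms = final_cols,
    groups = names(current),
    coefficients = fit$coefficients[-1],
    standard_errors = fit$se[-1],
    intercept = unname(fit$coefficients[1]),
    intercept_se = unname(fit$se[1]),
    age_center = age_center,
    c_statistic = c_statistic(fit$fitted, y),
    r2 = nagelkerke_r2(fit$loglik, loglik_null(y), length(y)),
    hl_statistic = hl$statistic,
    hl_pvalue = hl$pvalue,
    aic = fit$aic,
    aic_full = aic_full,
    loglik = fit$loglik,
    n = length(y),
    deaths = sum(y),
    fitted = fit$fitted
  ), class = "risk_model_fit")
}

#' @export
print.risk_model_fit <- function(x, ...) {
  cat("Case-mix logistic risk-adjustment model\n",
      " n = ", x$n, " patients, ", x$deaths, " deaths; ",
      length(x$coefficients), " coded terms\n",
      " C-statistic ", round(x$c_statistic, 3),
      "; Nagelkerke R2 ", round(x$r2, 3),
      "; Hosmer-Lemeshow ", round(x$hl_statistic, 2),
      " (p = ", round(x$hl_pvalue, 2), ")\n", sep = "")
  invisible(x)
}

# ---- diagnostics -----------------------------------------------------------

#' Rank-based C-statistic (area under the ROC curve)
#'
#' The probability that a randomly chosen death carries a higher
#' predicted risk than a randomly chosen survivor, ties counting one
#' half; computed from ranks in O(n log n).
#'
#' @param predictions Predicted probabilities (or any risk scores).
#' @param outcomes 0/1 death flags.
#' @return C-statistic in \[0, 1\].
#' @export
c_statistic <- function(predictions, outcomes) {
  if (inherits(predictions, "risk_model_fit")) {
    stop("pass predicted probabilities; use predict_risk(fit, data) first")
  }
  y <- as.integer(outcomes)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("C-statistic undefined: need at least one death and one survivor")
  }
  r <- rank(predictions)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Groups patients into `g` groups by deciles of predicted risk and
#' compares observed to expected deaths with the grouped chi-squared
#' statistic (equivalent to summing (O-E)^2/E over the 2g death/survival
#' cells), referred to a chi-squared distribution with g-2 degrees of
#' freedom.  Empty groups (tied predictions) are merged with a warning.
#'
#' @param predictions Predicted probabilities.
#' @param outcomes 0/1 death flags.
#' @param g Number of risk groups, default 10 (>= 3).
#' @return List with `statistic`, `pvalue`, `df`, `g`.
#' @export
hosmer_lemeshow <- function(predictions, outcomes, g = 10) {
  stopifnot(g >= 3)
  y <- as.integer(outcomes)
  br <- unique(quantile(predictions, probs = seq(0, 1, length.out = g + 1),
                        type = 7))
  if (length(br) < g + 1) {
    warning("tied predicted risks: ", g + 1 - length(br),
            " empty group(s) merged with neighbours")
  }
  if (length(br) < 2) {  # constant predictions: a single degenerate group
    E <- sum(predictions); n <- length(y); O <- sum(y)
    denom <- E * (1 - E / n)
    statistic <- if (denom > 0) (O - E)^2 / denom else 0
    return(list(statistic = statistic,
                pvalue = pchisq(statistic, df = 1, lower.tail = FALSE),
                df = 1L, g = 1L))
  }
  grp <- cut(predictions, breaks = br, include.lowest = TRUE)
  O <- tapply(y, grp, sum)
  E <- tapply(predictions, grp, sum)
  n_g <- tapply(y, grp, length)
  keep <- !is.na(O) & n_g > 0
  O <- O[keep]; E <- E[keep]; n_g <- n_g[keep]
  denom <- E * (1 - E / n_g)
  ok <- denom > 0
  statistic <- sum((O[ok] - E[ok])^2 / denom[ok])
  g_eff <- sum(keep)
  df <- max(1L, g_eff - 2L)
  list(statistic = unname(statistic),
       pvalue = unname(pchisq(statistic, df = df, lower.tail = FALSE)),
       df = df, g = g_eff)
}

#' Nagelkerke R-squared of a logistic model
#'
#' Cox-Snell R2 rescaled to a \[0, 1\] maximum:
#' R2 = (1 - exp(2(ll0 - ll1)/n)) / (1 - exp(2 ll0 / n)).
#'
#' @param loglik Model log-likelihood.
#' @param loglik_null Intercept-only log-likelihood.
#' @param n Number of observations.
#' @return R2 in \[0, 1\].
#' @export
nagelkerke_r2 <- function(loglik, loglik_null, n) {
  r2_cs <- 1 - exp(2 * (loglik_null - loglik) / n)
  r2_max <- 1 - exp(2 * loglik_null / n)
  r2_cs / r2_max
}

#' @rdname nagelkerke_r2
#' @param fit A `risk_model_fit`.
#' @export
r2_nagelkerke <- function(fit) {
  stopifnot(inherits(fit, "risk_model_fit"))
  fit$r2
}

# ---- multiple-imputation wrapper -------------------------------------------

#' Screen, select and fit across multiply imputed datasets
#'
#' Runs univariate screening on each completed dataset and keeps the
#' variables retained in a majority of them; runs AIC selection on each
#' completed dataset over the majority-screened variables and again takes
#' the majority vote; then fits the voted term set to every completed
#' dataset and pools coefficients and variances by Rubin's rules
#' ([pool_estimates()]).
#'
#' @param iset An [impute_fev()] imputation set.
#' @param candidates Candidate group names (FEV included by default since
#'   the completed datasets have no missing FEV).
#' @param alpha Screening level, default 0.1.
#' @param age_center Age centering; `NULL` = sample mean.
#' @param direction,interactions,hl_groups Passed to [fit_risk_model()].
#' @return A pooled `risk_model_fit` with attribute `"screened"`.
#' @export
fit_risk_model_mi <- function(iset, candidates = candidate_terms(include_fev = TRUE),
                              alpha = 0.1, age_center = NULL,
                              direction = "backward", interactions = FALSE,
                              hl_groups = 10) {
  stopifnot(inherits(iset, "imputation_set"))
  m <- iset$m
  votes <- table(unlist(lapply(iset$completed, function(d) {
    as.character(univariate_screen(d, candidates, alpha = alpha,
                                   age_center = age_center))
  })))
  screened <- candidates[candidates %in% names(votes)[votes >= m / 2]]
  if (length(screened) == 0L) stop("no variable passed univariate screening")

  if (direction == "none") {
    selected <- screened
  } else {
    votes2 <- table(unlist(lapply(iset$completed, function(d) {
      fit_risk_model(d, terms = screened, age_center = age_center,
                     direction = direction, interactions = FALSE,
                     hl_groups = hl_groups)$groups
    })))
    selected <- screened[screened %in% names(votes2)[votes2 >= m / 2]]
    if (length(selected) == 0L) selected <- screened
  }

  fits <- lapply(iset$completed, function(d) {
    fit_risk_model(d, terms = selected, age_center = age_center,
                   direction = "none", interactions = interactions,
                   hl_groups = hl_groups)
  })
  pooled <- pool_estimates(fits)
  attr(pooled, "screened") <- screened
  pooled
}

# ---- serialization ---------------------------------------------------------

#' Serialize / restore a fitted risk model as JSON
#'
#' The JSON document carries the coded terms, coefficients, standard
#' errors, intercept, age center and diagnostics — everything needed to
#' transfer the linear predictor to another dataset.
#'
#' @param fit A `risk_model_fit`.
#' @param path Output / input file path.
#' @return `write_risk_model` invisibly returns `path`;
#'   `read_risk_model` returns a `risk_model_fit`.
#' @export
write_risk_model <- function(fit, path) {
  stopifnot(inherits(fit, "risk_model_fit"))
  doc <- list(
    terms = fit$terms, groups = fit$groups,
    coefficients = as.list(fit$coefficients),
    standard_errors = as.list(fit$standard_errors),
    intercept = fit$intercept, intercept_se = fit$intercept_se,
    age_center = fit$age_center,
    diagnostics = list(c_statistic = fit$c_statistic, r2 = fit$r2,
                       hl_statistic = fit$hl_statistic,
                       hl_pvalue = fit$hl_pvalue, aic = fit$aic),
    n = fit$n, deaths = fit$deaths
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_risk_model
#' @export
read_risk_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    terms = doc$terms, groups = doc$groups,
    coefficients = unlist(doc$coefficients),
    standard_errors = unlist(doc$standard_errors),
    intercept = doc$intercept, intercept_se = doc$intercept_se,
    age_center = doc$age_center,
    c_statistic = doc$diagnostics$c_statistic,
    r2 = doc$diagnostics$r2,
    hl_statistic = doc$diagnostics$hl_statistic,
    hl_pvalue = doc$diagnostics$hl_pvalue,
    aic = doc$diagnostics$aic,
    n = doc$n, deaths = doc$deaths
  ), class = "risk_model_fit")
}
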