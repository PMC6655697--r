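#' Cross-classify hospital outlier status under two SMR estimators
#'
#' Builds the 3x3 contingency matrix of paired outlier status (rows =
#' first estimator, columns = second; order low/non/high).  Both inputs
#' must cover exactly the same facilities.
#'
#' @param smr1,smr2 Tibbles from [hospital_smr()] with `facility_id`
#'   and `status`.
#' @return 3x3 integer matrix with an `"n"` attribute.
#' @export
cross_classify <- function(smr1, smr2) {
  if (nrow(smr1) == 0L || nrow(smr2) == 0L) stop("empty SMR input")
  if (!setequal(smr1$facility_id, smr2$facility_id) ||
      nrow(smr1) != nrow(smr2)) {
    stop("the two estimators cover different facility sets")
  }
  lev <- c("low-outlier", "non-outlier", "high-outlier")
  s2 <- smr2$status[match(smr1$facility_id, smr2$facility_id)]
  m <- table(factor(smr1$status, levels = lev),
             factor(s2, levels = lev))
  m <- matrix(as.integer(m), 3, 3, dimnames = dimnames(m))
  attr(m, "n") <- sum(m)
  m
}

#' Cohen's kappa with interpretation band
#'
#' Unweighted chance-corrected agreement for a square contingency
#' matrix: kappa = (Po - Pe)/(1 - Pe) with Po the observed agreement
#' (trace/n) and Pe the chance agreement from the margins.  The band
#' follows the conventional cutpoints: above 0.8 excellent, 0.6-0.8
#' satisfactory, 0.41-0.6 moderate, 0.21-0.4 low, otherwise poor.
#'
#' If the margins concentrate all mass in a single cell (Pe = 1) kappa is
#' formally undefined; the perfect-agreement special case (all mass on
#' the diagonal) is reported as kappa 1.
#'
#' @param matrix Square count matrix (rows = rater/estimator 1).
#' @return List of class `cohen_kappa`: `kappa`, `band`, `po`, `pe`, `n`.
#' @examples
#' m <- matrix(c(0, 0, 0, 1, 66, 1, 0, 4, 3), 3, 3, byrow = TRUE)
#' cohen_kappa(m)  # 0.46, moderate
#' @export
cohen_kappa <- function(matrix) {
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix),
            all(matrix >= 0))
  n <- sum(matrix)
  if (n == 0) stop("empty contingency matrix")
  po <- sum(diag(matrix)) / n
  pe <- sum(rowSums(matrix) * colSums(matrix)) / n^2
  if (pe >= 1) {
    if (po == 1) {
      k <- 1
      warning("all mass in a single diagonal cell; perfect agreement ",
              "reported as kappa = 1")
    } else {
      k <- NA_real_
      warning("chance agreement is 1; kappa undefined")
    }
  } else {
    k <- (po - pe) / (1 - pe)
  }
  structure(list(kappa = k, band = kappa_band(k), po = po, pe = pe, n = n),
            class = "cohen_kappa")
}

kappa_band <- function(kappa) {
  if (is.na(kappa)) return(NA_character_)
  if (kappa > 0.8) "excellent"
  else if (kappa > 0.6) "satisfactory"
  else if (kappa >= 0.41) "moderate"
  else if (kappa >= 0.21) "low"
  else "poor"
}

#' @export
print.cohen_kappa <- function(x, ...) {
  cat("Cohen's kappa:", round(x$kappa, 3), paste0("(", x$band, " agreement)"),
      "on n =", x$n, "\n")
  invisible(x)
}

#' Compare observed mortality between two hospital groups
#'
#' Observed 30-day/in-hospital mortality proportions in the two groups
#' and a Pearson chi-square test without continuity correction on the
#' 2x2 table (Fisher's exact test is substituted automatically when any
#' expected cell count is below 5).
#'
#' @param gqd,lqd Registry tables with a `death` column (or use
#'   `compare_mortality_counts()` with raw counts).
#' @return List: `rate_gqd`, `rate_lqd`, `pvalue`, `test`, `table`.
#' @export
compare_group_mortality <- function(gqd, lqd) {
  compare_mortality_counts(sum(gqd$death), nrow(gqd),
                           sum(lqd$death), nrow(lqd))
}

#' @rdname compare_group_mortality
#' @param d1,n1 Deaths and patients in the first group.
#' @param d2,n2 Deaths and patients in the second group.
#' @export
compare_mortality_counts <- function(d1, n1, d2, n2) {
  stopifnot(n1 > 0, n2 > 0, d1 >= 0, d2 >= 0, d1 <= n1, d2 <= n2)
  tab <- matrix(c(d1, n1 - d1, d2, n2 - d2), nrow = 2, byrow = TRUE,
                dimnames = list(group = c("group1", "group2"),
                                outcome = c("death", "alive")))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    test <- "fisher"
    p <- fisher.test(tab)$p.value
  } else {
    test <- "chi-square"
    p <- chisq.test(tab, correct = FALSE)$p.value
  }
  list(rate_gqd = d1 / n1, rate_lqd = d2 / n2, pvalue = p,
       test = test, table = tab)
}
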