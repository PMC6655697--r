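# helper: registry with a controllable binary covariate -> death contingency
two_by_two <- function(a, b, c, d) {
  # vats: a deaths / b alive ; thoracotomy: c deaths / d alive
  df <- ref_patients(a + b + c + d)
  df$approach <- c(rep("vats", a + b), rep("thoracotomy", c + d))
  df$death <- c(rep(1L, a), rep(0L, b), rep(1L, c), rep(0L, d))
  df
}

test_that("single-covariate fit equals the closed-form 2x2 log odds ratio", {
  df <- two_by_two(20, 80, 15, 185)
  fit <- fit_risk_model(df, terms = "approach", direction = "none")
  log_or <- log((20 / 80) / (15 / 185))
  expect_equal(unname(fit$coefficients["vats"]), log_or, tolerance = 1e-6)
  expect_equal(unname(fit$intercept), log(15 / 185), tolerance = 1e-6)
})

test_that("the fitted model is calibrated in the large", {
  df <- sim_patients(5000, seed = 23)
  fit <- fit_risk_model(df, terms = c("age", "sex", "asa", "bmi"),
                        direction = "none")
  expect_lt(abs(sum(fit$fitted) - sum(df$death)), 1e-6 * nrow(df))
})

test_that("univariate screening keeps signal and drops constants", {
  df <- sim_patients(4000, seed = 25)
  # an outcome-defining covariate must survive screening
  df$diabetes <- df$death
  expect_warning(
    kept <- univariate_screen(df, candidates = c("age", "asa", "diabetes",
                                                 "cardiac_malformation")),
    "constant|separation")
  expect_true("diabetes" %in% kept)
  pv <- attr(kept, "pvalues")
  expect_true(all(is.na(pv) | (pv >= 0 & pv <= 1)))
})

test_that("screening excludes a null covariate at the nominal rate", {
  excl <- vapply(1:200, function(r) {
    set.seed(3000 + r)
    df <- ref_patients(400)
    df$death <- rbinom(400, 1, 0.3)
    df$diabetes <- rbinom(400, 1, 0.5)
    !("diabetes" %in% univariate_screen(df, candidates = "diabetes",
                                        alpha = 0.1))
  }, logical(1))
  # exclusion probability ~0.9; 99% band over 200 replicates
  expect_gt(mean(excl), 0.83)
  expect_lt(mean(excl), 0.97)
})

test_that("linear-gradient check accepts a truly linear score", {
  res <- vapply(1:25, function(r) {
    set.seed(4000 + r)
    df <- ref_patients(10000)
    df$asa <- sample(1:3, 10000, replace = TRUE)
    df$death <- rbinom(10000, 1, plogis(-3 + 0.5 * df$asa))
    linear_gradient_check(df, "asa") == "linear"
  }, logical(1))
  expect_gte(mean(res), 0.8)
})

test_that("linear-gradient check rejects a threshold effect", {
  res <- vapply(1:5, function(r) {
    set.seed(4100 + r)
    df <- ref_patients(10000)
    df$asa <- sample(1:3, 10000, replace = TRUE)
    df$death <- rbinom(10000, 1, ifelse(df$asa == 3, 0.25, 0.02))
    linear_gradient_check(df, "asa") == "categorical"
  }, logical(1))
  expect_true(all(res))
})

test_that("linear-gradient check needs three observed levels", {
  df <- ref_patients(100)
  df$asa <- rep(1:2, 50)
  df$death <- rbinom(100, 1, 0.2)
  expect_error(linear_gradient_check(df, "asa"), "not applicable")
})

test_that("backward AIC step-down removes noise and never raises AIC", {
  intercept_only <- vapply(1:10, function(r) {
    set.seed(5000 + r)
    df <- ref_patients(800)
    df$death <- rbinom(800, 1, 0.05)
    df$sex <- sample(c("male", "female"), 800, replace = TRUE)
    df$diabetes <- rbinom(800, 1, 0.3)
    df$approach <- sample(c("thoracotomy", "vats"), 800, replace = TRUE)
    fit <- fit_risk_model(df, terms = c("sex", "diabetes", "approach"),
                          direction = "backward")
    expect_lte(fit$aic, fit$aic_full + 1e-8)
    length(fit$groups) == 0
  }, logical(1))
  expect_gte(mean(intercept_only), 0.6)
})

test_that("step-down on informative data keeps the strong predictors", {
  df <- sim_patients(10000, seed = 29)
  fit <- fit_risk_model(df, terms = c("age", "sex", "asa", "pnodes",
                                      "diabetes", "stroke"),
                        direction = "backward")
  expect_true(all(c("age", "sex", "asa") %in% fit$groups))
  expect_lte(fit$aic, fit$aic_full)
  # forward selection agrees on this clear-cut case
  fwd <- fit_risk_model(df, terms = c("age", "sex", "asa", "pnodes",
                                      "diabetes", "stroke"),
                        direction = "forward")
  expect_true(all(c("age", "sex", "asa") %in% fwd$groups))
})

test_that("interaction search only ever lowers AIC", {
  df <- sim_patients(4000, seed = 33)
  base <- fit_risk_model(df, terms = c("age", "sex", "asa"),
                         direction = "none")
  withint <- fit_risk_model(df, terms = c("age", "sex", "asa"),
                            direction = "none", interactions = TRUE)
  expect_lte(withint$aic, base$aic + 1e-8)
  if (length(withint$terms) > length(base$terms)) {
    expect_true(any(grepl(":", withint$terms, fixed = TRUE)))
  }
})

test_that("coefficients simulated from the reference model are recovered", {
  df <- sim_patients(10597, seed = 37)
  fit <- fit_risk_model(df, terms = published_model_groups(),
                        direction = "none")
  truth <- default_risk_coefficients("gqd")
  est <- fit$coefficients[names(truth)]
  se <- fit$standard_errors[names(truth)]
  expect_true(all(abs(est - truth) < 4 * se))
  expect_lt(abs(fit$intercept - (-4.4)), 4 * fit$intercept_se)
})

test_that("C-statistic follows the rank definition", {
  expect_equal(c_statistic(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0)), 0.75)
  expect_equal(c_statistic(rep(0.3, 10), rep(c(0, 1), 5)), 0.5)
  expect_equal(c_statistic(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1.0)
  expect_error(c_statistic(c(0.1, 0.2), c(0, 0)), "undefined")
  set.seed(1)
  p <- runif(200); y <- rbinom(200, 1, p)
  expect_equal(c_statistic(p, y),
               as.numeric(suppressMessages(pROC::auc(y, p))),
               tolerance = 1e-10)
})

test_that("Hosmer-Lemeshow p-values are uniform for a well-specified fit", {
  # the g - 2 df reference applies to fitted probabilities
  pv <- vapply(1:100, function(r) {
    set.seed(6000 + r)
    x <- rnorm(2000)
    y <- rbinom(2000, 1, plogis(-2 + 0.8 * x))
    p <- fitted(glm(y ~ x, family = binomial()))
    hosmer_lemeshow(p, y, g = 10)$pvalue
  }, numeric(1))
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.001)
})

test_that("Hosmer-Lemeshow merges tied risk groups with a warning", {
  p <- rep(c(0.1, 0.2), each = 500)
  set.seed(8)
  y <- rbinom(1000, 1, p)
  expect_warning(hl <- hosmer_lemeshow(p, y, g = 10), "merged")
  expect_lt(hl$g, 10)
  expect_true(hl$pvalue >= 0 && hl$pvalue <= 1)
})

test_that("Nagelkerke R2 spans its range and matches hand arithmetic", {
  df <- sim_patients(2000, seed = 41)
  fit0 <- fit_risk_model(df, terms = character(0), direction = "none")
  expect_equal(fit0$r2, 0, tolerance = 1e-10)
  # perfect prediction: model log-likelihood 0
  y <- c(1, 0, 1, 0); n <- 4
  ll0 <- sum(y * log(0.5) + (1 - y) * log(0.5))
  expect_equal(nagelkerke_r2(0, ll0, n), 1, tolerance = 1e-12)
  # hand case: 4 rows, model loglik from explicit probabilities
  p <- c(0.8, 0.3, 0.6, 0.2)
  ll1 <- sum(y * log(p) + (1 - y) * log(1 - p))
  r2_cs <- 1 - exp(2 * (ll0 - ll1) / n)
  expect_equal(nagelkerke_r2(ll1, ll0, n),
               r2_cs / (1 - exp(2 * ll0 / n)), tolerance = 1e-12)
})

test_that("a fitted model survives a JSON round-trip and transfers exactly", {
  df <- sim_patients(3000, seed = 43)
  fit <- fit_risk_model(df, terms = c("age", "sex", "asa", "procedure"),
                        direction = "none")
  path <- withr::local_tempfile(fileext = ".json")
  write_risk_model(fit, path)
  back <- read_risk_model(path)
  expect_equal(back$coefficients, fit$coefficients, tolerance = 1e-12)
  expect_equal(back$age_center, fit$age_center, tolerance = 1e-12)
  expect_equal(predict_risk(back, df), predict_risk(fit, df),
               tolerance = 1e-12)
})

test_that("transfer errors when coded terms cannot be mapped", {
  df <- sim_patients(500, seed = 47)
  fit <- fit_risk_model(df, terms = c("age", "sex"), direction = "none")
  fit$coefficients <- c(fit$coefficients, made_up_term = 1)
  expect_error(predict_risk(fit, df), "unmappable|cannot map")
})
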