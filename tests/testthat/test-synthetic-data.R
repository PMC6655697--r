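test_that("clean scenario sets every reporting mechanism to full fidelity", {
  h <- generate_hospitals(100, seed = 1, degradation_scenario = "clean")
  expect_equal(nrow(h), 100)
  expect_true(all(h$case_report_prob == 1))
  expect_true(all(h$death_report_prob == 1))
  expect_true(all(h$comorbidity_report_prob == 1))
  expect_true(all(h$tnm_missing_prob == 0))
  expect_true(all(h$volume > 0))
})

test_that("hospital generation is deterministic and stable under extension", {
  expect_identical(generate_hospitals(2, seed = 7, "clean"),
                   generate_hospitals(2, seed = 7, "clean"))
  h3 <- generate_hospitals(3, seed = 3, "paper-like")
  h5 <- generate_hospitals(5, seed = 3, "paper-like")
  expect_equal(as.data.frame(h5[1:3, ]), as.data.frame(h3))
})

test_that("unknown degradation scenario is a configuration error", {
  expect_error(generate_hospitals(10, 1, "bogus"))
  expect_error(generate_hospitals(1, 1, "clean"))
})

test_that("paper-like profiles bound reporting as specified", {
  h <- generate_hospitals(200, seed = 5, "paper-like")
  p <- h[, c("case_report_prob", "death_report_prob",
             "comorbidity_report_prob")]
  expect_true(all(p >= 0 & p <= 1))
  expect_true(all(h$tnm_missing_prob >= 0 & h$tnm_missing_prob <= 1))
  good <- h$case_report_prob >= 0.9 & h$death_report_prob >= 0.9 &
    h$comorbidity_report_prob >= 0.9
  expect_gt(mean(good), 0.10)   # a well-reporting stratum exists
  expect_lt(mean(good), 0.45)   # but most hospitals are degraded
})

test_that("reference-level patients die at the intercept rate", {
  df <- ref_patients(50)
  p <- predict_risk(true_model(), df)
  expect_equal(p, rep(plogis(-4.4), 50), tolerance = 1e-12)
})

test_that("simulated death rate matches an intercept-only truth", {
  m <- true_model(coefficients = c(age_c = 0), intercept = -4.4)
  adm <- sim_patients(10000, seed = 42, model = m)
  p <- plogis(-4.4)
  band <- 2.58 * sqrt(p * (1 - p) / nrow(adm))   # 99% binomial band
  expect_lt(abs(mean(adm$death) - p), band)
})

test_that("cohort generation is deterministic and rejects zero volumes", {
  h <- mk_hospitals(c(50, 80))
  a1 <- generate_admin_registry(h, seed = 9)
  a2 <- generate_admin_registry(h, seed = 9)
  expect_identical(a1, a2)
  expect_error(generate_admin_registry(mk_hospitals(c(50, 0)), seed = 1),
               "volume")
})

test_that("degradation with all probabilities one is the identity", {
  h <- mk_hospitals(300)
  adm <- generate_admin_registry(h, seed = 3)
  cl <- degrade_to_clinical_registry(adm, h, seed = 3)
  expect_equal(as.data.frame(cl), as.data.frame(adm))
})

test_that("degradation rejects orphan facilities", {
  h <- mk_hospitals(50)
  adm <- generate_admin_registry(h, seed = 2)
  adm$facility_id[1] <- "NOPE"
  expect_error(degrade_to_clinical_registry(adm, h, seed = 2), "NOPE")
})

test_that("patients are retained at the case-report rate", {
  h <- mk_hospitals(10000, cr = 0.5)
  adm <- generate_admin_registry(h, seed = 11)
  cl <- degrade_to_clinical_registry(adm, h, seed = 11)
  n <- nrow(adm)
  band <- 2.58 * sqrt(n * 0.25)   # 99% binomial band around n/2
  expect_lt(abs(nrow(cl) - n / 2), band)
})

test_that("deaths among retained patients are recorded at the death-report rate", {
  h <- mk_hospitals(10000, cr = 1, dr = 0.5)
  adm <- generate_admin_registry(h, seed = 13)
  cl <- degrade_to_clinical_registry(adm, h, seed = 13)
  D <- sum(adm$death)
  expect_gt(D, 150)  # enough true deaths for the band to be meaningful
  band <- 2.58 * sqrt(D * 0.25)
  expect_lt(abs(sum(cl$death) - D / 2), band)
})

test_that("comorbidity under-coding and staging blanking act as configured", {
  h <- mk_hospitals(8000, mr = 0.6, tm = 0.3)
  adm <- generate_admin_registry(h, seed = 17)
  cl <- degrade_to_clinical_registry(adm, h, seed = 17)
  # cr = 1, so rows align one-to-one: flags can only be switched off
  expect_equal(nrow(cl), nrow(adm))
  expect_true(all(cl$history_of_neoplasm <= adm$history_of_neoplasm))
  on_true <- sum(adm$history_of_neoplasm)
  on_rec <- sum(cl$history_of_neoplasm)
  expect_lt(abs(on_rec / on_true - 0.6), 0.05)
  extra_missing <- mean(is.na(cl$ptumor))
  expect_lt(abs(extra_missing - 0.3), 0.03)
})

test_that("recorded clinical deaths do not exceed administrative deaths on average", {
  h <- mk_hospitals(c(60, 60, 60), cr = 0.8, dr = 0.8)
  d_adm <- d_cl <- matrix(0, 200, 3)
  for (r in 1:200) {
    adm <- generate_admin_registry(h, seed = 1000 + r)
    cl <- degrade_to_clinical_registry(adm, h, seed = 1000 + r)
    d_adm[r, ] <- sapply(h$facility_id, function(f)
      sum(adm$death[adm$facility_id == f]))
    d_cl[r, ] <- sapply(h$facility_id, function(f)
      sum(cl$death[cl$facility_id == f]))
  }
  expect_true(all(colMeans(d_cl) <= colMeans(d_adm)))
})

test_that("clean clinical registry reproduces the configured marginals", {
  cm <- casemix_config()
  h <- mk_hospitals(10000)
  adm <- generate_admin_registry(h, cm, true_model(), seed = 21)
  cl <- degrade_to_clinical_registry(adm, h, seed = 21)
  n <- nrow(cl)
  se_p <- function(p) sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(cl$sex == "female") - 0.34), 3 * se_p(0.34))
  expect_lt(abs(mean(cl$approach == "vats") - 0.28), 3 * se_p(0.28))
  expect_lt(abs(mean(cl$procedure == "pneumonectomy") - 0.085),
            3 * se_p(0.085))
  expect_lt(abs(mean(cl$diabetes) - 0.103), 3 * se_p(0.103))
  expect_lt(abs(mean(is.na(cl$fev)) - 0.10), 3 * se_p(0.10))
  expect_lt(abs(mean(cl$age) - 64), 3 * 10 / sqrt(n))
  expect_lt(abs(mean(cl$ptumor == "Missing") - 0.10 / 0.99),
            3 * se_p(0.10))
})

test_that("paper-like scenario classifies roughly a quarter of hospitals as GQD", {
  fr <- vapply(1:10, function(r) {
    reg <- simulate_registries(simulation_config(n_hospitals = 100, seed = r))
    s <- classify_quality(summarize_by_hospital(reg$clinical, reg$admin))
    mean(s$quality_class == "GQD")
  }, numeric(1))
  expect_gt(mean(fr), 0.15)
  expect_lt(mean(fr), 0.35)
})

test_that("risk-selective omission lowers the recorded death rate further", {
  h <- mk_hospitals(20000, cr = 0.7)
  adm <- generate_admin_registry(h, seed = 31)
  cl0 <- degrade_to_clinical_registry(adm, h, seed = 31)
  cl1 <- degrade_to_clinical_registry(adm, h, seed = 31,
                                      omission_risk_coef = 2)
  expect_lt(mean(cl1$death), mean(cl0$death))
})

test_that("registry round-trip through CSV preserves content and blanks", {
  dir <- withr::local_tempdir()
  h <- mk_hospitals(150, tm = 0.3)
  adm <- generate_admin_registry(h, seed = 5)
  cl <- degrade_to_clinical_registry(adm, h, seed = 5)
  write_registries(adm, cl, dir)
  expect_true(all(file.exists(file.path(dir,
    c("admin.csv", "clinical.csv", "data_dictionary.csv")))))
  back <- read_registry(file.path(dir, "clinical.csv"))
  expect_equal(nrow(back), nrow(cl))
  expect_equal(sum(is.na(back$ptumor)), sum(is.na(cl$ptumor)))
  expect_equal(back$death, cl$death)
  av <- read_registry(file.path(dir, "admin.csv"))
  expect_named(av, c("facility_id", "procedure", "approach", "death"))
})

test_that("yaml configuration round-trips into the generator", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_hospitals: 4", "seed: 2", "scenario: clean",
               "casemix:", "  sex_female: 0.5"), path)
  cfg <- read_simulation_config(path)
  expect_equal(cfg$n_hospitals, 4)
  reg <- simulate_registries(cfg)
  expect_equal(length(unique(reg$admin$facility_id)), 4)
  expect_lt(abs(mean(reg$admin$sex == "female") - 0.5), 0.1)
})
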