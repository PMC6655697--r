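#' Simulate the complete (administrative-truth) patient cohort
#'
#' Draws, for each hospital, a Poisson number of patients around its
#' expected volume, samples covariates from the case-mix configuration,
#' and simulates the 30-day/in-hospital death flag as Bernoulli with the
#' probability given by the true mortality model.  The result is the
#' administrative reference: complete, with no omissions or
#' misclassification.  The full covariate set is carried so that the
#' clinical registry can be derived from it by [degrade_to_clinical_registry()];
#' the columns actually exported in an administrative file are the subset
#' returned by [admin_view()].
#'
#' Baseline missingness that belongs to the case mix itself — the FEV
#' measurement not being available for some patients, and the baseline
#' "Missing" fractions of staging/resection — is generated here, so it is
#' shared by both registries.  Hospital-specific under-reporting is
#' applied only by the degradation step.
#'
#' @param hospitals Profiles from [generate_hospitals()] (volume > 0).
#' @param casemix A [casemix_config()].
#' @param model A [true_model()].
#' @param seed Integer master seed (split per hospital).
#' @return Tibble of patient records, one row per patient.
#' @export
generate_admin_registry <- function(hospitals, casemix = casemix_config(),
                                    model = true_model(), seed = 1) {
  stopifnot(inherits(casemix, "casemix_config"), inherits(model, "true_model"),
            nrow(hospitals) > 0)
  if (any(hospitals$volume <= 0)) {
    stop("hospitals with volume <= 0 must be excluded before simulation")
  }
  com <- comorbidity_fields()
  rows <- lapply(seq_len(nrow(hospitals)), function(i) {
    h <- hospitals[i, ]
    with_seed(hospital_seed(seed, i, purpose = 2L), {
      n <- rpois(1, h$volume)
      if (n == 0L) return(NULL)
      df <- tibble::tibble(
        facility_id = rep(h$facility_id, n),
        sex = ifelse(runif(n) < casemix$sex_female, "female", "male"),
        age = rnorm(n, casemix$age_mean, casemix$age_sd),
        asa = as.integer(sample_levels(n, casemix$asa_freq)),
        performance_status = as.integer(sample_levels(n, casemix$ps_freq)),
        dyspnea = as.integer(sample_levels(n, casemix$dyspnea_freq)),
        fev = rnorm(n, casemix$fev_mean, casemix$fev_sd),
        bmi = rnorm(n, casemix$bmi_mean, casemix$bmi_sd),
        procedure = sample_levels(n, casemix$procedure_freq),
        approach = sample_levels(n, casemix$approach_freq),
        ptumor = sample_levels(n, casemix$ptumor_freq),
        pnodes = sample_levels(n, casemix$pnodes_freq),
        resection = sample_levels(n, casemix$resection_freq)
      )
      dep <- casemix$asa_comorbidity_dependence
      for (v in com) {
        p <- casemix$comorbidity_prev[[v]]
        if (dep != 0) p <- pmin(1, pmax(0, p * (1 + dep * (df$asa - 2))))
        df[[v]] <- as.integer(runif(n) < p)
      }
      df$fev[runif(n) < casemix$fev_missing_prob] <- NA_real_
      df$death <- as.integer(runif(n) < predict_risk(model, df))
      df
    })
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "seed") <- seed
  out
}

#' Administrative-registry file view
#'
#' The administrative reference exports only the facility code, the
#' procedure, the surgical approach and the death indicator.
#'
#' @param admin Cohort table from [generate_admin_registry()].
#' @return Tibble with columns facility_id, procedure, approach, death.
#' @export
admin_view <- function(admin) {
  tibble::as_tibble(admin[, c("facility_id", "procedure", "approach", "death")])
}

#' Degrade the complete cohort into a voluntary clinical registry
#'
#' Applies each hospital's reporting mechanisms: a patient is entered in
#' the clinical registry with probability `case_report_prob`; among
#' entered patients who truly died, the death is recorded with
#' probability `death_report_prob` (otherwise the record shows alive —
#' outcome misclassification on top of omission); each true comorbidity
#' flag survives coding with probability `comorbidity_report_prob`;
#' staging and resection-quality fields are blanked (set to `NA`) with
#' probability `tnm_missing_prob` in addition to their baseline
#' missingness.
#'
#' Optionally, omission can be made selective in patient risk:
#' `omission_risk_coef > 0` shifts the retention probability of patients
#' who died by `-omission_risk_coef` on the logit scale (sicker patients
#' less likely to be entered).  The default 0 keeps omission
#' non-selective.
#'
#' @param admin Cohort from [generate_admin_registry()].
#' @param hospitals The same profiles used to generate the cohort.
#' @param seed Integer master seed (split per hospital).
#' @param omission_risk_coef Logit shift of retention for true deaths.
#' @return Tibble of clinical registry records (same columns as the
#'   cohort; blanked fields are `NA`).
#' @export
degrade_to_clinical_registry <- function(admin, hospitals, seed = 1,
                                         omission_risk_coef = 0) {
  orphan <- setdiff(unique(admin$facility_id), hospitals$facility_id)
  if (length(orphan) > 0L) {
    stop("administrative records reference unknown facility_id(s): ",
         paste(orphan, collapse = ", "))
  }
  stage_cols <- c("ptumor", "pnodes", "resection")
  rows <- lapply(seq_len(nrow(hospitals)), function(i) {
    h <- hospitals[i, ]
    df <- admin[admin$facility_id == h$facility_id, , drop = FALSE]
    if (nrow(df) == 0L) return(NULL)
    with_seed(hospital_seed(seed, i, purpose = 3L), {
      retain_p <- rep(h$case_report_prob, nrow(df))
      if (omission_risk_coef != 0) {
        retain_p <- plogis(qlogis(retain_p) - omission_risk_coef * df$death)
      }
      df <- df[runif(nrow(df)) < retain_p, , drop = FALSE]
      if (nrow(df) == 0L) return(NULL)
      died <- which(df$death == 1L)
      df$death[died[runif(length(died)) >= h$death_report_prob]] <- 0L
      if (h$comorbidity_report_prob < 1) {
        for (v in comorbidity_fields()) {
          on <- which(df[[v]] == 1L)
          df[[v]][on[runif(length(on)) >= h$comorbidity_report_prob]] <- 0L
        }
      }
      if (h$tnm_missing_prob > 0) {
        for (v in stage_cols) {
          df[[v]][runif(nrow(df)) < h$tnm_missing_prob] <- NA_character_
        }
      }
      df
    })
  })
  dplyr::bind_rows(rows)
}

#' Simulation configuration
#'
#' Bundles scenario, size, seed and case-mix overrides for
#' [simulate_registries()]; readable from a YAML file with
#' [read_simulation_config()].
#'
#' @param n_hospitals Number of hospitals.
#' @param seed Master seed.
#' @param scenario Degradation scenario label.
#' @param casemix Named list of [casemix_config()] overrides.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_hospitals = 100, seed = 1,
                              scenario = "paper-like", casemix = list()) {
  structure(list(n_hospitals = n_hospitals, seed = seed,
                 scenario = scenario, casemix = casemix),
            class = "simulation_config")
}

#' @rdname simulation_config
#' @param path Path to a YAML file with fields n_hospitals, seed,
#'   scenario, casemix.
#' @export
read_simulation_config <- function(path) {
  y <- yaml::read_yaml(path)
  cm <- y$casemix %||% list()
  # YAML maps come back as lists; frequency vectors need names preserved
  cm <- lapply(cm, function(x) if (is.list(x)) unlist(x) else x)
  simulation_config(n_hospitals = y$n_hospitals %||% 100,
                    seed = y$seed %||% 1,
                    scenario = y$scenario %||% "paper-like",
                    casemix = cm)
}

#' Generate a paired administrative/clinical registry set
#'
#' @param config A [simulation_config()].
#' @param model True mortality model.
#' @return List with elements `hospitals`, `admin` (complete cohort) and
#'   `clinical` (degraded registry).
#' @export
simulate_registries <- function(config = simulation_config(),
                                model = true_model()) {
  stopifnot(inherits(config, "simulation_config"))
  casemix <- do.call(casemix_config, config$casemix)
  hospitals <- generate_hospitals(config$n_hospitals, config$seed,
                                  config$scenario)
  admin <- generate_admin_registry(hospitals, casemix, model, config$seed)
  clinical <- degrade_to_clinical_registry(admin, hospitals, config$seed)
  list(hospitals = hospitals, admin = admin, clinical = clinical)
}

#' Write a registry pair to CSV
#'
#' Writes `admin.csv` (the administrative file view), `clinical.csv`
#' (full clinical records) and `data_dictionary.csv` into `dir`.
#' Missing values are encoded as empty fields; the death flag is 0/1;
#' `facility_id` is the shared string key.
#'
#' @param admin,clinical Registry tables.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_registries <- function(admin, clinical, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("admin.csv", "clinical.csv", "data_dictionary.csv"))
  write.csv(admin_view(admin), paths[1], row.names = FALSE, na = "")
  write.csv(clinical, paths[2], row.names = FALSE, na = "")
  write.csv(registry_dictionary(), paths[3], row.names = FALSE)
  invisible(paths)
}

#' Column dictionary of the registry CSV files
#' @return Tibble with column name, registry, type and description.
#' @export
registry_dictionary <- function() {
  base <- tibble::tribble(
    ~column, ~registry, ~type, ~description,
    "facility_id", "both", "string", "hospital facility code, shared key",
    "procedure", "both", "category", "limited/lobectomy/bilobectomy/pneumonectomy",
    "approach", "both", "category", "thoracotomy or vats",
    "death", "both", "0/1", "death within 30 days or during the same stay",
    "sex", "clinical", "category", "male or female",
    "age", "clinical", "years", "age at surgery",
    "asa", "clinical", "score 1-3", "ASA physical status (3 = 3 or more)",
    "performance_status", "clinical", "score 0-2", "WHO performance status (2 = 2 or more)",
    "dyspnea", "clinical", "score 0-3", "dyspnea grade (3 = 3 or more)",
    "fev", "clinical", "% predicted", "forced expiratory volume; empty if missing",
    "bmi", "clinical", "kg/m2", "body mass index",
    "ptumor", "clinical", "category", "pathological tumour stage I/II/III/IV; empty if missing",
    "pnodes", "clinical", "category", "pathological nodal stage 0/1/2; empty if missing",
    "resection", "clinical", "category", "resection quality R0/R1/R2; empty if missing"
  )
  com <- tibble::tibble(column = comorbidity_fields(), registry = "clinical",
                        type = "0/1", description = "comorbidity flag")
  dplyr::bind_rows(base, com)
}

#' Read a registry CSV written by [write_registries()]
#' @param path CSV path.
#' @return Tibble; empty fields become `NA`.
#' @export
read_registry <- function(path) {
  df <- read.csv(path, na.strings = c("", "NA"), stringsAsFactors = FALSE,
                 colClasses = c(facility_id = "character"))
  tibble::as_tibble(df)
}
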