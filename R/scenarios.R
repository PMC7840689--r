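# Ready-made simulation scenarios emulating the structure of the two
# motivating cohorts: a smaller discovery cohort with ~90 candidate
# variables in correlated blocks, and a larger replication cohort with 34.
# Marginal moments and level frequencies follow the published descriptive
# table; effect sizes are sparse with |beta| in [0.1, 0.5] per SD.

.pad_lab_specs <- function(specs, target, start_block) {
  i <- 0
  while (length(specs) < target) {
    b <- start_block + i %/% 3
    i <- i + 1
    specs[[length(specs) + 1]] <- covariate_spec(
      sprintf("lab_extra_%02d", i), "continuous", mean = 0, sd = 1,
      block_id = b, block_rho = 0.5)
  }
  specs
}

#' Discovery-cohort ("kora_like") simulation scenario
#'
#' 400 participants (370 after the packaged exclusion flow) and 90 candidate
#' variables: sociodemographics, anthropometry, blood pressure, glycemic
#' measures, lipids, medication, lifestyle and sleep in correlated latent
#' blocks, padded with generic laboratory covariates. The ground truth is
#' sparse: ten nonzero count-part effects (including age, controlled and
#' unknown hypertension, HbA1c, prediabetes, widowed status) with
#' |beta| between 0.1 and 0.5 per SD, dispersion theta = 0.8, and a
#' structural-zero probability driven by age (older participants are less
#' likely to be lesion-free).
#'
#' @return a list with elements `n`, `specs`, `truth`, `name`.
#' @export
scenario_kora_like <- function() {
  cs <- covariate_spec
  specs <- list(
    cs("age", "continuous", mean = 55.7, sd = 9.1),
    cs("male", "binary", prevalence = 0.578),
    # anthropometry
    cs("weight", "continuous", mean = 82.7, sd = 15.9, block_id = 1, block_rho = 0.6),
    cs("height", "continuous", mean = 171.8, sd = 9.6, block_id = 1, block_rho = 0.3),
    cs("bmi", "continuous", mean = 28.0, sd = 4.7, block_id = 1, block_rho = 0.6),
    cs("waist_circumference", "continuous", mean = 98.2, sd = 13.7, block_id = 1, block_rho = 0.6),
    cs("hip_circumference", "continuous", mean = 106.7, sd = 8.8, block_id = 1, block_rho = 0.6),
    cs("waist_to_hip_ratio", "continuous", mean = 0.92, sd = 0.09, block_id = 1, block_rho = 0.5),
    # blood pressure block (collinear by design)
    cs("systolic_bp", "continuous", mean = 120.7, sd = 16.7, block_id = 2, block_rho = 0.7),
    cs("diastolic_bp", "continuous", mean = 75.5, sd = 10.0, block_id = 2, block_rho = 0.7),
    cs("pulse_pressure", "continuous", mean = 71.2, sd = 10.0, block_id = 2, block_rho = 0.6),
    cs("hypertension_status", "categorical",
       levels = c("no_hypertension", "controlled_hypertension",
                  "uncontrolled_hypertension", "untreated_hypertension",
                  "unknown_hypertension"),
       probs = c(0.664, 0.187, 0.057, 0.051, 0.041),
       block_id = 2, block_rho = 0.5),
    cs("antihypertensive_medication", "binary", prevalence = 0.243,
       block_id = 2, block_rho = 0.5),
    # glycemic block
    cs("hba1c", "continuous", mean = 5.6, sd = 0.7, block_id = 3, block_rho = 0.6),
    cs("fasting_glucose", "continuous", mean = 104.4, sd = 23.2, block_id = 3, block_rho = 0.6),
    cs("fasting_insulin", "continuous", mean = 10.9, sd = 6.8, block_id = 3, block_rho = 0.4),
    cs("glycemic_status", "categorical",
       levels = c("normal", "prediabetes", "diabetes"),
       probs = c(0.619, 0.243, 0.138), block_id = 3, block_rho = 0.5),
    cs("antidiabetic_medication", "binary", prevalence = 0.078,
       block_id = 3, block_rho = 0.4),
    # lipids / renal
    cs("total_cholesterol", "continuous", mean = 217.9, sd = 35.9, block_id = 4, block_rho = 0.5),
    cs("hdl_cholesterol", "continuous", mean = 62.0, sd = 17.4, block_id = 4, block_rho = 0.3),
    cs("ldl_cholesterol", "continuous", mean = 139.7, sd = 32.5, block_id = 4, block_rho = 0.6),
    cs("triglycerides", "continuous", mean = 130.5, sd = 83.2, block_id = 4, block_rho = 0.4),
    cs("uric_acid", "continuous", mean = 5.6, sd = 1.5),
    cs("gfr", "continuous", mean = 87.0, sd = 12.8, block_id = 5, block_rho = 0.6),
    cs("creatinine", "continuous", mean = 0.88, sd = 0.15, block_id = 5, block_rho = 0.6),
    # adipose tissue
    cs("hepatic_fat", "continuous", mean = 8.6, sd = 7.8, block_id = 6, block_rho = 0.7),
    cs("visceral_fat", "continuous", mean = 4.5, sd = 2.7, block_id = 6, block_rho = 0.7),
    # social environment
    cs("family_status", "categorical",
       levels = c("married_living_with_partner", "unmarried_living_alone",
                  "unmarried_living_with_partner", "divorced", "widowed"),
       probs = c(0.748, 0.092, 0.041, 0.078, 0.041)),
    cs("schooling", "categorical",
       levels = c("lower_secondary", "secondary", "higher_secondary"),
       probs = c(0.454, 0.232, 0.314), block_id = 7, block_rho = 0.5),
    cs("schooling_years", "continuous", mean = 12.3, sd = 2.6, block_id = 7, block_rho = 0.5),
    cs("per_capita_income", "continuous", mean = 1374.4, sd = 712.2, block_id = 8, block_rho = 0.7),
    cs("equivalence_income", "continuous", mean = 1521.0, sd = 718.8, block_id = 8, block_rho = 0.7),
    cs("social_stratum", "continuous", mean = 15.7, sd = 5.0, block_id = 8, block_rho = 0.5),
    # lifestyle
    cs("smoking", "categorical", levels = c("never", "ex_smoker", "smoker"),
       probs = c(0.365, 0.432, 0.203), block_id = 9, block_rho = 0.5),
    cs("packyears", "continuous", mean = 18.0, sd = 15.0, block_id = 9, block_rho = 0.5),
    cs("alcohol", "categorical",
       levels = c("none", "upto_20g", "upto_40g", "over_40g"),
       probs = c(0.238, 0.395, 0.189, 0.178), block_id = 10, block_rho = 0.6),
    cs("alcohol_g_day", "continuous", mean = 18.8, sd = 24.2, block_id = 10, block_rho = 0.6),
    cs("physical_activity", "categorical",
       levels = c("no", "sporadic", "regular_1h", "regular_2h"),
       probs = c(0.254, 0.151, 0.308, 0.287), block_id = 11, block_rho = 0.6),
    cs("physically_active", "binary", prevalence = 0.595, block_id = 11, block_rho = 0.6),
    # somatic / depressive symptoms
    cs("sf12_somatic", "continuous", mean = 49.7, sd = 7.4, block_id = 12, block_rho = 0.4),
    cs("phq9", "continuous", mean = 3.0, sd = 2.7, block_id = 12, block_rho = 0.4),
    cs("deex_scale", "continuous", mean = 7.3, sd = 4.7, block_id = 12, block_rho = 0.4),
    cs("angina_pectoris", "binary", prevalence = 0.051),
    cs("right_handed", "binary", prevalence = 0.922),
    # medication
    cs("anticoagulant_medication", "binary", prevalence = 0.016),
    cs("antiplatelet_medication", "binary", prevalence = 0.038),
    cs("thyroid_medication", "binary", prevalence = 0.168),
    cs("nsaid_medication", "binary", prevalence = 0.022),
    cs("ass_medication", "binary", prevalence = 0.035),
    # sleep
    cs("sleep_hours", "continuous", mean = 7.1, sd = 1.1, block_id = 13, block_rho = 0.4),
    cs("problems_falling_asleep", "categorical",
       levels = c("never", "sometimes", "often"),
       probs = c(0.641, 0.260, 0.099), block_id = 13, block_rho = 0.4),
    cs("problems_keeping_asleep", "categorical",
       levels = c("never", "sometimes", "often"),
       probs = c(0.449, 0.343, 0.208), block_id = 13, block_rho = 0.4),
    cs("tired_from_sleep_problems", "categorical",
       levels = c("never", "sometimes", "often"),
       probs = c(0.638, 0.300, 0.062), block_id = 13, block_rho = 0.4)
  )
  specs <- .pad_lab_specs(specs, 90, start_block = 50)
  truth <- ground_truth(
    beta = c(age = 0.5,
             "hypertension_status.controlled_hypertension" = 0.35,
             hba1c = 0.3,
             "family_status.widowed" = 0.3,
             "glycemic_status.prediabetes" = 0.25,
             antiplatelet_medication = 0.25,
             "hypertension_status.unknown_hypertension" = 0.2,
             nsaid_medication = 0.15,
             "physical_activity.regular_2h" = -0.15,
             "alcohol.upto_20g" = 0.1),
    gamma = c(age = -0.8),
    beta0 = log(1500), gamma0 = -0.6, theta = 0.8)
  list(n = 400L, specs = specs, truth = truth, name = "kora_like")
}

#' Replication-cohort ("ship_like") simulation scenario
#'
#' 854 participants and 34 candidate variables with the replication cohort's
#' marginals; the ground truth shares the discovery scenario's effects for
#' every variable present in both panels (same signs and sizes), so that
#' replication of shared effects is the expected outcome.
#'
#' @return a list with elements `n`, `specs`, `truth`, `name`.
#' @export
scenario_ship_like <- function() {
  cs <- covariate_spec
  specs <- list(
    cs("age", "continuous", mean = 53.9, sd = 9.3),
    cs("male", "binary", prevalence = 0.381),
    cs("weight", "continuous", mean = 79.5, sd = 15.1, block_id = 1, block_rho = 0.6),
    cs("height", "continuous", mean = 168.4, sd = 9.0, block_id = 1, block_rho = 0.3),
    cs("bmi", "continuous", mean = 27.9, sd = 4.5, block_id = 1, block_rho = 0.6),
    cs("waist_circumference", "continuous", mean = 89.8, sd = 12.7, block_id = 1, block_rho = 0.6),
    cs("systolic_bp", "continuous", mean = 125.8, sd = 16.5, block_id = 2, block_rho = 0.7),
    cs("diastolic_bp", "continuous", mean = 77.6, sd = 9.7, block_id = 2, block_rho = 0.7),
    cs("hypertension_status", "categorical",
       levels = c("no_hypertension", "controlled_hypertension",
                  "uncontrolled_hypertension", "untreated_hypertension",
                  "unknown_hypertension"),
       probs = c(0.550, 0.225, 0.091, 0.048, 0.086),
       block_id = 2, block_rho = 0.5),
    cs("hba1c", "continuous", mean = 5.3, sd = 0.7, block_id = 3, block_rho = 0.6),
    cs("glycemic_status", "categorical",
       levels = c("normal", "prediabetes", "diabetes"),
       probs = c(0.678, 0.225, 0.097), block_id = 3, block_rho = 0.5),
    cs("family_status", "categorical",
       levels = c("living_with_partner", "living_alone",
                  "married_not_living_with_partner", "divorced", "widowed"),
       probs = c(0.810, 0.062, 0.024, 0.071, 0.033)),
    cs("smoking", "categorical", levels = c("never", "ex_smoker", "smoker"),
       probs = c(0.452, 0.361, 0.187)),
    cs("alcohol", "categorical",
       levels = c("none", "upto_20g", "upto_40g", "over_40g"),
       probs = c(0.111, 0.783, 0.075, 0.031)),
    cs("physical_activity", "categorical",
       levels = c("no", "sporadic", "regular_1h", "regular_2h"),
       probs = c(0.267, 0.170, 0.322, 0.241)),
    cs("antiplatelet_medication", "binary", prevalence = 0.046),
    cs("nsaid_medication", "binary", prevalence = 0.085)
  )
  specs <- .pad_lab_specs(specs, 34, start_block = 50)
  kora <- scenario_kora_like()$truth
  present <- function(nm) {
    var <- sub("\\..*$", "", nm)
    var %in% vapply(specs, function(s) s$name, character(1))
  }
  truth <- ground_truth(
    beta = kora$beta[vapply(names(kora$beta), present, logical(1))],
    gamma = c(age = -0.8),
    beta0 = log(250), gamma0 = -0.4, theta = 0.6)
  list(n = 854L, specs = specs, truth = truth, name = "ship_like")
}
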