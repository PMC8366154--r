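#' Configuration for the synthetic multi-facility cohort generator
#'
#' Defines the population the generator emulates: a multi-facility cohort of
#' older, mostly male primary-care patients in which transfer to a
#' geriatrics-style team (the "treatment clinic") is driven by observed
#' covariates — age, frailty (JFI), hospitalization-risk percentile (CAN),
#' dementia and prior hospitalizations — so that the transferred and
#' non-transferred arms are imbalanced before matching. Defaults target the
#' marginal summaries of the motivating study population (mean age about 80,
#' CAN about 50, JFI about 4, roughly 2% female and 83% white).
#'
#' @param n_facilities Number of facilities (>= 1).
#' @param patients_per_facility Patients generated per facility (>= 1).
#' @param seed Integer seed; the generator is fully deterministic given the
#'   config (including the seed).
#' @param age_mean,age_sd Age distribution in years (normal, floored at 18).
#' @param race_probs Named probability vector over
#'   `black`, `white`, `other_or_missing`; must sum to 1.
#' @param female_prob,advance_directive_prob,dementia_prob Bernoulli
#'   probabilities of the respective flags.
#' @param hospitalization_rate Mean hospitalization count in the prior year
#'   (Poisson).
#' @param can_mean,can_sd CAN score distribution; generated values are rounded
#'   and clamped to 0-99.
#' @param jfi_mean,jfi_sd JFI score distribution; rounded and clamped to 0-13.
#' @param can_jfi_correlation Latent correlation between the CAN and JFI
#'   draws (the joint distribution is otherwise unspecified in the field;
#'   0.3 is a plausibility choice, see the methods vignette).
#' @param selection_coefficients Named log-odds weights of the logistic
#'   transfer model: `intercept`, `age`, `can_score`, `jfi_score`, `dementia`,
#'   `n_hospitalizations`, and an optional `unobserved` term (default weight 0)
#'   for studying residual confounding. Continuous covariates enter
#'   standardized by their configured mean/SD.
#' @param exclusion_probs Named probabilities for the `hospice`, `palliative`
#'   and `institutionalized` exclusion flags.
#' @param visit_intensity Mean clinic visits per patient per one-year window;
#'   every patient is guaranteed at least 2 visits per window so that
#'   designated arm membership is expressible in visit counts.
#' @return A validated list of class `pm_cohort_config`.
#' @seealso [generate_cohort()], [confounding_report()]
#' @export
cohort_config <- function(n_facilities = 4,
                          patients_per_facility = 3500,
                          seed = 1,
                          age_mean = 80, age_sd = 7,
                          race_probs = c(black = 0.124, white = 0.833,
                                         other_or_missing = 0.043),
                          female_prob = 0.018,
                          advance_directive_prob = 0.28,
                          dementia_prob = 0.033,
                          hospitalization_rate = 0.12,
                          can_mean = 50, can_sd = 30,
                          jfi_mean = 4, jfi_sd = 2,
                          can_jfi_correlation = 0.3,
                          selection_coefficients = c(intercept = -3.0,
                                                     age = 0.3,
                                                     can_score = 0.4,
                                                     jfi_score = 0.4,
                                                     dementia = 0.7,
                                                     n_hospitalizations = 0.3,
                                                     unobserved = 0),
                          exclusion_probs = c(hospice = 0.02,
                                              palliative = 0.02,
                                              institutionalized = 0.02),
                          visit_intensity = 4) {
  cfg <- list(
    n_facilities = check_count(n_facilities, "n_facilities", min = 1),
    patients_per_facility = check_count(patients_per_facility,
                                        "patients_per_facility", min = 1),
    seed = check_number(seed, "seed"),
    age_mean = check_number(age_mean, "age_mean", min = 18),
    age_sd = check_number(age_sd, "age_sd", min = 1e-8),
    race_probs = as_named_numeric(race_probs, "race_probs"),
    female_prob = check_prob(female_prob, "female_prob"),
    advance_directive_prob = check_prob(advance_directive_prob,
                                        "advance_directive_prob"),
    dementia_prob = check_prob(dementia_prob, "dementia_prob"),
    hospitalization_rate = check_number(hospitalization_rate,
                                        "hospitalization_rate", min = 1e-8),
    can_mean = check_number(can_mean, "can_mean", min = 0, max = 99),
    can_sd = check_number(can_sd, "can_sd", min = 1e-8),
    jfi_mean = check_number(jfi_mean, "jfi_mean", min = 0, max = 13),
    jfi_sd = check_number(jfi_sd, "jfi_sd", min = 1e-8),
    can_jfi_correlation = check_number(can_jfi_correlation,
                                       "can_jfi_correlation", min = -1, max = 1),
    selection_coefficients = as_named_numeric(selection_coefficients,
                                              "selection_coefficients"),
    exclusion_probs = as_named_numeric(exclusion_probs, "exclusion_probs"),
    visit_intensity = check_number(visit_intensity, "visit_intensity", min = 2)
  )
  race_names <- c("black", "white", "other_or_missing")
  if (!setequal(names(cfg$race_probs), race_names))
    pm_stop("prospmatch_config_error",
            "'race_probs' must be named: %s", paste(race_names, collapse = ", "))
  cfg$race_probs <- cfg$race_probs[race_names]
  if (any(cfg$race_probs < 0) || any(cfg$race_probs > 1) ||
      abs(sum(cfg$race_probs) - 1) > 1e-9)
    pm_stop("prospmatch_config_error",
            "'race_probs' must be probabilities summing to 1 (within 1e-9)")
  needed <- c("intercept", "age", "can_score", "jfi_score", "dementia",
              "n_hospitalizations")
  missing_b <- setdiff(needed, names(cfg$selection_coefficients))
  if (length(missing_b))
    pm_stop("prospmatch_config_error",
            "'selection_coefficients' is missing: %s",
            paste(missing_b, collapse = ", "))
  if (!"unobserved" %in% names(cfg$selection_coefficients))
    cfg$selection_coefficients[["unobserved"]] <- 0
  ex_names <- c("hospice", "palliative", "institutionalized")
  if (!setequal(names(cfg$exclusion_probs), ex_names))
    pm_stop("prospmatch_config_error",
            "'exclusion_probs' must be named: %s", paste(ex_names, collapse = ", "))
  cfg$exclusion_probs <- cfg$exclusion_probs[ex_names]
  for (nm in ex_names) check_prob(cfg$exclusion_probs[[nm]],
                                  paste0("exclusion_probs$", nm))
  structure(cfg, class = "pm_cohort_config")
}

#' Generate a synthetic cohort of patients and visit histories
#'
#' Draws one patient table and one visit-event table under `config`. Transfer
#' to the treatment clinic is assigned stochastically from a logistic model on
#' the observed covariates (plus an optional unobserved term), and a patient's
#' transfer status drives the clinic type of their exposure-period visits:
#' transferred patients receive treatment-clinic visits in the exposure year,
#' everyone else continues in the usual clinic. Every patient gets at least
#' two visits per one-year window, so designated arm membership is always
#' expressible under the downstream visit-count eligibility rules.
#'
#' Time convention: day 0 is the start of the exposure period; the
#' pre-exposure window is days `[-365, 0)` and the exposure window `[0, 365)`
#' (half-open).
#'
#' @param config A [cohort_config()].
#' @return A list of class `pm_cohort` with elements
#'   \describe{
#'     \item{patients}{One row per patient: `patient_id`, `facility_id`,
#'       `age`, `race`, `female`, `advance_directive`, `dementia`,
#'       `n_hospitalizations`, `any_hospitalization`, `can_score`,
#'       `jfi_score`, `excluded`, `latent_transfer_propensity` (generator
#'       internal; never used by matching), `transferred` (generator truth).}
#'     \item{visits}{One row per visit: `patient_id`, `day` (integer offset
#'       from the exposure start), `clinic`
#'       (`"treatment_clinic"`/`"usual_clinic"`).}
#'     \item{config}{The validated config.}
#'   }
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "pm_cohort_config")) config <- do.call(cohort_config, config)
  set.seed(as.integer(config$seed %% 2147483629))
  nf <- config$n_facilities
  ppf <- config$patients_per_facility
  n <- nf * ppf

  patients <- data.frame(
    patient_id = sprintf("P%06d", seq_len(n)),
    facility_id = rep(sprintf("F%02d", seq_len(nf)), each = ppf),
    stringsAsFactors = FALSE
  )
  patients$age <- pmax(18, stats::rnorm(n, config$age_mean, config$age_sd))
  patients$race <- sample(names(config$race_probs), n, replace = TRUE,
                          prob = config$race_probs)
  patients$female <- stats::runif(n) < config$female_prob
  patients$advance_directive <- stats::runif(n) < config$advance_directive_prob
  patients$dementia <- stats::runif(n) < config$dementia_prob
  patients$n_hospitalizations <- stats::rpois(n, config$hospitalization_rate)
  patients$any_hospitalization <- patients$n_hospitalizations > 0L

  rho <- config$can_jfi_correlation
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  patients$can_score <- round(clamp(config$can_mean + config$can_sd * z1, 0, 99))
  patients$jfi_score <- round(clamp(config$jfi_mean + config$jfi_sd * z2, 0, 13))

  ex <- config$exclusion_probs
  patients$excluded <- (stats::runif(n) < ex[["hospice"]]) |
    (stats::runif(n) < ex[["palliative"]]) |
    (stats::runif(n) < ex[["institutionalized"]])

  b <- config$selection_coefficients
  u <- stats::rnorm(n)
  lp <- b[["intercept"]] +
    b[["age"]] * (patients$age - config$age_mean) / config$age_sd +
    b[["can_score"]] * (patients$can_score - config$can_mean) / config$can_sd +
    b[["jfi_score"]] * (patients$jfi_score - config$jfi_mean) / config$jfi_sd +
    b[["dementia"]] * as.numeric(patients$dementia) +
    b[["n_hospitalizations"]] *
      (patients$n_hospitalizations - config$hospitalization_rate) /
      sqrt(config$hospitalization_rate) +
    b[["unobserved"]] * u
  patients$latent_transfer_propensity <- stats::plogis(lp)
  patients$transferred <- stats::runif(n) < patients$latent_transfer_propensity

  # Visit counts: >= 2 per window, Poisson excess around the configured
  # intensity. Visit days are uniform integers within each half-open window.
  lam <- max(config$visit_intensity - 2, 0)
  n_pre <- 2L + stats::rpois(n, lam)
  n_exp <- 2L + stats::rpois(n, lam)
  exposure_clinic <- ifelse(patients$transferred, "treatment_clinic", "usual_clinic")
  visits <- data.frame(
    patient_id = c(rep(patients$patient_id, n_pre),
                   rep(patients$patient_id, n_exp)),
    day = c(as.integer(floor(stats::runif(sum(n_pre), -365, 0))),
            as.integer(floor(stats::runif(sum(n_exp), 0, 365)))),
    clinic = c(rep("usual_clinic", sum(n_pre)),
               rep(exposure_clinic, n_exp)),
    stringsAsFactors = FALSE
  )
  visits <- visits[order(visits$patient_id, visits$day, visits$clinic), ]
  rownames(visits) <- NULL

  structure(list(patients = patients, visits = visits, config = config),
            class = "pm_cohort")
}

#' @export
print.pm_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d patients at %d facilities, %d visits\n",
              nrow(x$patients), x$config$n_facilities, nrow(x$visits)))
  cat(sprintf("  transferred to treatment clinic: %d (%.1f%%); excluded flags: %d\n",
              sum(x$patients$transferred),
              100 * mean(x$patients$transferred),
              sum(x$patients$excluded)))
  invisible(x)
}

#' Pre-matching confounding report for a synthetic cohort
#'
#' Computes unmatched standardized mean differences of every matching
#' covariate between transferred and non-transferred patients, i.e. the
#' imbalance the matching stage is supposed to remove. Group 1 is the
#' transferred (treated) arm, so the SMD sign convention matches
#' [balance_table()].
#'
#' @param cohort A `pm_cohort` from [generate_cohort()], or any list with a
#'   `patients` data frame carrying a logical `transferred` column.
#' @return A `pm_balance_table` (see [balance_table()]).
#' @export
confounding_report <- function(cohort) {
  patients <- if (is.data.frame(cohort)) cohort else cohort$patients
  if (is.null(patients$transferred))
    pm_stop("prospmatch_input_error", "cohort has no 'transferred' column")
  g1 <- patients[patients$transferred, , drop = FALSE]
  g2 <- patients[!patients$transferred, , drop = FALSE]
  if (nrow(g1) == 0L || nrow(g2) == 0L)
    pm_stop("prospmatch_degenerate_error",
            "confounding report needs at least one patient in each arm")
  balance_table(g1, g2, matching_covariate_spec())
}
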