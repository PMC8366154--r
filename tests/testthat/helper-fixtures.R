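# Programmatic fixtures shared across test files.

# A hand-built match pool (already sorted the way build_pool() sorts).
make_pool <- function(treated_id = "T001", n = 5, tiers = rep(1L, n),
                      distances = seq(0.01, by = 0.01, length.out = n),
                      eligible = NULL, pull_week = 0L, prefix = "C") {
  ids <- sprintf("%s%03d", prefix, seq_len(n))
  ord <- order(tiers, distances, ids)
  cand <- data.frame(control_id = ids[ord], distance = distances[ord],
                     tier = as.integer(tiers[ord]), stringsAsFactors = FALSE)
  cand$rank_within_tier <- ave(seq_len(nrow(cand)), cand$tier, FUN = seq_along)
  structure(list(treated_id = treated_id, candidates = cand,
                 eligible_for_recruitment = if (is.null(eligible)) n >= 5 else eligible,
                 pull_week = as.integer(pull_week)),
            class = "pm_match_pool")
}

# Random patient records with valid fields (no cohort machinery involved).
random_patients <- function(n, seed = 1, n_facilities = 1, prefix = "P") {
  set.seed(seed)
  df <- data.frame(
    patient_id = sprintf("%s%04d", prefix, seq_len(n)),
    facility_id = sample(sprintf("F%02d", seq_len(n_facilities)), n, replace = TRUE),
    age = round(runif(n, 70, 95), 1),
    race = sample(c("black", "white", "other_or_missing"), n, replace = TRUE,
                  prob = c(0.12, 0.83, 0.05)),
    female = runif(n) < 0.02,
    advance_directive = runif(n) < 0.28,
    dementia = runif(n) < 0.03,
    n_hospitalizations = rpois(n, 0.15),
    can_score = round(runif(n, 0, 99)),
    jfi_score = round(runif(n, 0, 13)),
    stringsAsFactors = FALSE
  )
  df$any_hospitalization <- df$n_hospitalizations > 0
  df$excluded <- FALSE
  df
}

make_visits <- function(patient_id, days, clinics) {
  data.frame(patient_id = rep_len(patient_id, length(days)), day = days,
             clinic = rep_len(clinics, length(days)), stringsAsFactors = FALSE)
}

withr_local_tempfile <- function(ext) withr::local_tempfile(fileext = ext,
                                                            .local_envir = parent.frame())

# A small but complete study configuration for fast end-to-end tests.
small_study_config <- function(seed = 1) {
  cfg <- default_study_config()
  cfg$cohort$n_facilities <- 2L
  cfg$cohort$patients_per_facility <- 400L
  cfg$cohort$seed <- seed
  cfg$eligibility$min_facility_treatment_visits <- 20
  cfg$recruitment$target_dyads <- 30L
  cfg$power$n_replicates <- 5L
  cfg
}
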