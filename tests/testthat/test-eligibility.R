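w_default <- study_windows()

test_that("study windows enforce contiguity and positive length", {
  expect_error(study_windows(c(-365, 0), c(10, 365)),
               class = "prospmatch_config_error")
  expect_error(study_windows(c(0, 0), c(0, 365)),
               class = "prospmatch_config_error")
})

test_that("visit-count rules classify treated, control and ineligible patients", {
  # transferred pattern: usual pre, treatment exposure
  v <- make_visits("A", c(-300, -200, 30, 90),
                   c("usual_clinic", "usual_clinic",
                     "treatment_clinic", "treatment_clinic"))
  expect_equal(classify_patient(v, w_default)$arm, "treated_eligible")

  # stayed in usual care both windows
  v <- make_visits("B", c(-300, -200, 30, 90), "usual_clinic")
  expect_equal(classify_patient(v, w_default)$arm, "control_eligible")

  # only one treatment visit in the exposure year: below the >= 2 rule
  v <- make_visits("C", c(-300, -200, 30),
                   c("usual_clinic", "usual_clinic", "treatment_clinic"))
  res <- classify_patient(v, w_default)
  expect_equal(res$arm, "ineligible")
  expect_match(res$reason, "insufficient_exposure")
})

test_that("half-open windows put a boundary-day visit in the later window", {
  v <- make_visits("A", c(-365, -200, 0, 100),
                   c("usual_clinic", "usual_clinic",
                     "treatment_clinic", "treatment_clinic"))
  expect_equal(classify_patient(v, w_default)$arm, "treated_eligible")
  # a visit at day 365 is outside both windows and ignored
  v2 <- rbind(v, make_visits("A", 365, "usual_clinic"))
  expect_equal(classify_patient(v2, w_default)$arm, "treated_eligible")
})

test_that("exclusion flags and mixed inputs are handled", {
  v <- make_visits("A", c(-300, -200, 30, 90),
                   c("usual_clinic", "usual_clinic",
                     "treatment_clinic", "treatment_clinic"))
  rec <- data.frame(patient_id = "A", excluded = TRUE, stringsAsFactors = FALSE)
  res <- classify_patient(v, w_default, rec)
  expect_equal(res$arm, "ineligible")
  expect_equal(res$reason, "excluded_flag")

  v_mixed <- rbind(v, make_visits("B", 10, "usual_clinic"))
  expect_error(classify_patient(v_mixed, w_default),
               class = "prospmatch_input_error")
})

test_that("vectorized classification agrees with per-patient classification", {
  co <- generate_cohort(cohort_config(n_facilities = 2, patients_per_facility = 150,
                                      seed = 21))
  all_cls <- classify_cohort(co$patients, co$visits, w_default)
  idx <- seq(1, nrow(co$patients), by = 7)
  for (i in idx) {
    rec <- co$patients[i, ]
    v <- co$visits[co$visits$patient_id == rec$patient_id, ]
    one <- classify_patient(v, w_default, rec)
    expect_equal(all_cls$arm[i], one$arm)
    expect_equal(all_cls$reason[i], one$reason)
  }
})

test_that("facility volume filter applies the threshold at the boundary", {
  p <- data.frame(patient_id = c("A", "B"), facility_id = c("F01", "F02"),
                  stringsAsFactors = FALSE)
  v <- rbind(make_visits("A", seq_len(499) %% 365, "treatment_clinic"),
             make_visits("B", seq_len(500) %% 365, "treatment_clinic"))
  expect_identical(filter_facilities(v, p, w_default, 500), "F02")
  expect_identical(filter_facilities(v, p, w_default, 0), c("F01", "F02"))
})

test_that("facility filter equals a brute-force recount on a generated cohort", {
  co <- generate_cohort(cohort_config(n_facilities = 4, patients_per_facility = 300,
                                      seed = 5))
  thr <- 150
  kept <- filter_facilities(co$visits, co$patients, w_default, thr)
  # independent recount: loop over facilities and visits
  fac <- sort(unique(co$patients$facility_id))
  manual <- character(0)
  for (f in fac) {
    ids <- co$patients$patient_id[co$patients$facility_id == f]
    n <- 0L
    for (i in seq_len(nrow(co$visits))) {
      if (co$visits$patient_id[i] %in% ids &&
          co$visits$clinic[i] == "treatment_clinic" &&
          co$visits$day[i] >= 0 && co$visits$day[i] < 365) n <- n + 1L
    }
    if (n >= thr) manual <- c(manual, f)
  }
  expect_identical(kept, manual)
})

test_that("a single pull after all windows close equals full-data classification", {
  co <- generate_cohort(cohort_config(n_facilities = 2, patients_per_facility = 200,
                                      seed = 31))
  full <- classify_cohort(co$patients, co$visits, w_default)
  full_elig <- full[full$arm != "ineligible", c("patient_id", "arm")]
  pulled <- rolling_pull(co$patients, co$visits, w_default, 400)
  expect_equal(pulled$patient_id, full_elig$patient_id)
  expect_equal(pulled$arm, full_elig$arm)
  expect_true(all(pulled$pull_index == 1L))
})

test_that("a patient is censored until their qualifying visit is observed", {
  p <- data.frame(patient_id = "A", excluded = FALSE, stringsAsFactors = FALSE)
  v <- make_visits("A", c(-300, -200, 30, 100),
                   c("usual_clinic", "usual_clinic",
                     "treatment_clinic", "treatment_clinic"))
  res <- rolling_pull(p, v, w_default, c(95, 190))
  expect_equal(nrow(res), 1L)
  expect_equal(res$pull_index, 2L)
  expect_equal(res$arm, "treated_eligible")
})

test_that("quarterly pulls partition the eventually-eligible set", {
  co <- generate_cohort(cohort_config(n_facilities = 2, patients_per_facility = 250,
                                      seed = 17))
  sched <- seq(91, 455, by = 91)
  pulled <- rolling_pull(co$patients, co$visits, w_default, sched)
  expect_false(anyDuplicated(pulled$patient_id) > 0)
  full <- classify_cohort(co$patients, co$visits, w_default)
  full_elig <- sort(full$patient_id[full$arm != "ineligible"])
  expect_identical(sort(pulled$patient_id), full_elig)
  # no patient is both treated- and control-eligible
  expect_false(any(duplicated(pulled[c("patient_id")])))
})

test_that("an unsorted pull schedule is rejected", {
  p <- data.frame(patient_id = "A", excluded = FALSE)
  expect_error(rolling_pull(p, make_visits("A", 1, "usual_clinic"), w_default,
                            c(100, 50)),
               class = "prospmatch_input_error")
})

test_that("shrinking the exposure window cannot qualify a patient with a disqualifying visit inside it", {
  # usual-clinic visit at day 30 disqualifies the treated arm in any
  # exposure window that contains day 30
  for (end in c(60, 120, 365)) {
    w <- study_windows(c(-365, 0), c(0, end))
    v <- make_visits("A", c(-300, -200, 10, 20, 30),
                     c("usual_clinic", "usual_clinic", "treatment_clinic",
                       "treatment_clinic", "usual_clinic"))
    expect_false(classify_patient(v, w)$arm == "treated_eligible")
  }
})
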