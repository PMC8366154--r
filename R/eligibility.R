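#' Study windows for eligibility classification
#'
#' Half-open integer-day windows on the study timeline. Day 0 is the start of
#' the exposure period; the defaults fix the one-year pre-exposure window to
#' days `[-365, 0)` and the one-year exposure window to `[0, 365)`. A visit on
#' the boundary day belongs to the later window (half-open convention, which
#' avoids double counting).
#'
#' @param pre_exposure Length-2 integer vector `c(start, end)`.
#' @param exposure Length-2 integer vector `c(start, end)`; must begin where
#'   the pre-exposure window ends.
#' @return A list of class `pm_study_windows`.
#' @export
study_windows <- function(pre_exposure = c(-365, 0), exposure = c(0, 365)) {
  pre_exposure <- as_named_numeric(pre_exposure, "pre_exposure")
  exposure <- as_named_numeric(exposure, "exposure")
  for (w in list(pre_exposure = pre_exposure, exposure = exposure)) {
    if (length(w) != 2L || any(is.na(w)) || any(w != floor(w)))
      pm_stop("prospmatch_config_error",
              "windows must be length-2 integer vectors")
  }
  if (pre_exposure[2] <= pre_exposure[1] || exposure[2] <= exposure[1])
    pm_stop("prospmatch_config_error", "windows must have positive length")
  if (pre_exposure[2] != exposure[1])
    pm_stop("prospmatch_config_error",
            "'pre_exposure' must end where 'exposure' begins")
  structure(list(pre_exposure = as.integer(pre_exposure),
                 exposure = as.integer(exposure)),
            class = "pm_study_windows")
}

in_window <- function(day, w) day >= w[1] & day < w[2]

# Vectorized core of the eligibility rules, shared by classify_patient()
# and classify_cohort(). Treated: >=2 usual & 0 treatment visits pre-exposure
# AND >=2 treatment & 0 usual visits in exposure. Control: >=2 usual & 0
# treatment visits in BOTH windows. Exclusion flags disqualify either arm.
classify_counts <- function(pre_usual, pre_treat, exp_usual, exp_treat, excluded) {
  n <- length(pre_usual)
  arm <- rep("ineligible", n)
  reason <- rep("", n)
  treated <- pre_usual >= 2L & pre_treat == 0L &
    exp_treat >= 2L & exp_usual == 0L & !excluded
  control <- pre_usual >= 2L & pre_treat == 0L &
    exp_usual >= 2L & exp_treat == 0L & !excluded
  arm[treated] <- "treated_eligible"
  arm[control] <- "control_eligible"
  inel <- !(treated | control)
  reason[inel & excluded] <- "excluded_flag"
  r <- inel & !excluded
  reason[r & pre_usual < 2L] <- "insufficient_pre_exposure_usual_visits"
  r <- r & pre_usual >= 2L
  reason[r & pre_treat > 0L] <- "treatment_visit_in_pre_exposure"
  r <- r & pre_treat == 0L
  reason[r & exp_usual > 0L & exp_treat > 0L] <- "mixed_clinic_exposure_visits"
  reason[r & exp_treat == 1L & exp_usual == 0L] <- "insufficient_exposure_treatment_visits"
  reason[r & exp_treat == 0L & exp_usual < 2L] <- "insufficient_exposure_visits"
  data.frame(arm = arm, reason = reason, stringsAsFactors = FALSE)
}

#' Classify one patient into a study arm from their visit history
#'
#' Applies the rolling-pull eligibility rules: a patient is
#' `treated_eligible` with at least two usual-clinic visits and no
#' treatment-clinic visits in the pre-exposure window, plus at least two
#' treatment-clinic visits and no usual-clinic visits in the exposure window;
#' `control_eligible` with at least two usual-clinic and no treatment-clinic
#' visits in both windows; otherwise `ineligible` with a reason code. Patients
#' with an exclusion flag (hospice/palliative/institutionalized) are
#' ineligible regardless of visits. Visits outside both windows are ignored.
#'
#' @param visits Data frame of this patient's visits (`patient_id`, `day`,
#'   `clinic`); all rows must share one `patient_id`.
#' @param windows A [study_windows()].
#' @param record One-row patient data frame (needs `patient_id` and
#'   `excluded`); may be omitted for a never-excluded patient, in which case
#'   the id is taken from `visits`.
#' @return One-row data frame: `patient_id`, `arm`, `reason`.
#' @export
classify_patient <- function(visits, windows = study_windows(), record = NULL) {
  ids <- unique(visits$patient_id)
  if (length(ids) > 1L)
    pm_stop("prospmatch_input_error",
            "visits contain multiple patient ids: %s",
            paste(utils::head(ids, 3), collapse = ", "))
  pid <- if (!is.null(record)) record$patient_id else ids
  if (length(pid) != 1L)
    pm_stop("prospmatch_input_error", "cannot determine the patient id")
  if (!is.null(record) && length(ids) == 1L && ids != pid)
    pm_stop("prospmatch_input_error",
            "visits belong to '%s' but record is for '%s'", ids, pid)
  excluded <- if (!is.null(record)) isTRUE(record$excluded) else FALSE
  pre <- in_window(visits$day, windows$pre_exposure)
  expo <- in_window(visits$day, windows$exposure)
  usual <- visits$clinic == "usual_clinic"
  res <- classify_counts(sum(pre & usual), sum(pre & !usual),
                         sum(expo & usual), sum(expo & !usual), excluded)
  data.frame(patient_id = pid, arm = res$arm, reason = res$reason,
             stringsAsFactors = FALSE)
}

#' Classify every patient in a cohort
#'
#' Vectorized [classify_patient()] over a patient table and a combined visit
#' table. Patients with no visits are classified from zero counts.
#'
#' @param patients Patient data frame (`patient_id`, `excluded`, ...).
#' @param visits Visit data frame (`patient_id`, `day`, `clinic`).
#' @param windows A [study_windows()].
#' @return Data frame: `patient_id`, `arm`, `reason` (one row per patient, in
#'   the order of `patients`).
#' @export
classify_cohort <- function(patients, visits, windows = study_windows()) {
  f <- factor(visits$patient_id, levels = patients$patient_id)
  pre <- in_window(visits$day, windows$pre_exposure)
  expo <- in_window(visits$day, windows$exposure)
  usual <- visits$clinic == "usual_clinic"
  cnt <- function(mask) as.integer(table(f[mask]))
  res <- classify_counts(cnt(pre & usual), cnt(pre & !usual),
                         cnt(expo & usual), cnt(expo & !usual),
                         as.logical(patients$excluded))
  data.frame(patient_id = patients$patient_id, arm = res$arm,
             reason = res$reason, stringsAsFactors = FALSE)
}

#' Facility volume filter
#'
#' Retains facilities whose total treatment-clinic visit count within the
#' exposure window meets a minimum volume threshold; the downstream pipeline
#' drops patients at excluded facilities. This abstracts the fielded rule of
#' requiring a minimum number of specialty-clinic visits per year for a
#' facility to participate.
#'
#' @param visits Visit data frame.
#' @param patients Patient data frame (supplies each visit's facility).
#' @param windows A [study_windows()].
#' @param min_treatment_visits Volume threshold (>= 0), default 500.
#' @return Sorted character vector of retained facility ids (possibly empty).
#' @export
filter_facilities <- function(visits, patients, windows = study_windows(),
                              min_treatment_visits = 500) {
  check_number(min_treatment_visits, "min_treatment_visits", min = 0)
  facs <- sort(unique(patients$facility_id))
  fac_of_visit <- patients$facility_id[match(visits$patient_id, patients$patient_id)]
  mask <- in_window(visits$day, windows$exposure) &
    visits$clinic == "treatment_clinic"
  counts <- table(factor(fac_of_visit[mask], levels = facs))
  names(counts)[counts >= min_treatment_visits]
}

#' Rolling quarterly data pulls
#'
#' Re-runs eligibility classification at each pull day using only visits that
#' occurred strictly before the pull day (the information available at that
#' pull). Each patient is emitted at the first pull at which their arm
#' criteria are satisfied and is never re-emitted, so the pulls partition the
#' eventually-eligible set.
#'
#' @param patients Patient data frame.
#' @param visits Visit data frame.
#' @param windows A [study_windows()].
#' @param pull_schedule Strictly increasing vector of pull days.
#' @return Data frame: `patient_id`, `arm` (`treated_eligible` or
#'   `control_eligible`), `pull_index`.
#' @export
rolling_pull <- function(patients, visits, windows = study_windows(),
                         pull_schedule) {
  if (length(pull_schedule) == 0L || any(is.na(pull_schedule)) ||
      is.unsorted(pull_schedule, strictly = TRUE))
    pm_stop("prospmatch_input_error",
            "'pull_schedule' must be strictly increasing")
  emitted <- character(0)
  out <- vector("list", length(pull_schedule))
  for (i in seq_along(pull_schedule)) {
    seen <- visits[visits$day < pull_schedule[i], , drop = FALSE]
    cls <- classify_cohort(patients, seen, windows)
    new <- cls[cls$arm != "ineligible" & !(cls$patient_id %in% emitted), ,
               drop = FALSE]
    out[[i]] <- data.frame(patient_id = new$patient_id, arm = new$arm,
                           pull_index = rep.int(i, nrow(new)),
                           stringsAsFactors = FALSE)
    emitted <- c(emitted, new$patient_id)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
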