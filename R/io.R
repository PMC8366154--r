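# Plain-text artifact readers and writers. All tabular artifacts are UTF-8
# CSV with explicit headers and empty fields for missing values; event
# streams are JSON lines; reports are JSON. Every writer round-trips through
# the matching reader.

#' Write / read the patient table
#'
#' Columns: `patient_id`, `facility_id`, `age`, `race`, `female`,
#' `advance_directive`, `dementia`, `n_hospitalizations`,
#' `any_hospitalization`, `can_score`, `jfi_score`, `excluded`,
#' `latent_transfer_propensity`, `transferred`.
#'
#' @param patients Patient data frame.
#' @param path File path.
#' @return `read_patients()` returns the data frame; writers return the path
#'   invisibly.
#' @export
write_patients <- function(patients, path) {
  utils::write.csv(patients, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_patients
#' @export
read_patients <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read the visit table
#'
#' Columns: `patient_id`, `day` (integer day offset from the exposure start),
#' `clinic` (`treatment_clinic`/`usual_clinic`).
#'
#' @param visits Visit data frame.
#' @param path File path.
#' @export
write_visits <- function(visits, path) {
  utils::write.csv(visits, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_visits
#' @export
read_visits <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read eligibility assignments
#'
#' Columns: `patient_id`, `arm`, `pull_index` (and `reason` when present).
#'
#' @param eligibility Data frame from [rolling_pull()] or [classify_cohort()].
#' @param path File path.
#' @export
write_eligibility <- function(eligibility, path) {
  utils::write.csv(eligibility, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_eligibility
#' @export
read_eligibility <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Flatten match pools to a data frame / write / read
#'
#' Long format, one row per (treated, candidate) pair: `treated_id`,
#' `control_id`, `distance`, `tier`, `rank_within_tier`, `pull_week`.
#' Empty pools contribute no rows and are therefore not reconstructed by
#' `read_pools()`.
#'
#' @param pools List of `pm_match_pool`.
#' @param path File path.
#' @param min_pool_size Used by `read_pools()` to restore the
#'   `eligible_for_recruitment` flag.
#' @return `pools_to_frame()` the long data frame; `read_pools()` a list of
#'   `pm_match_pool`.
#' @export
pools_to_frame <- function(pools) {
  rows <- lapply(pools, function(p) {
    if (nrow(p$candidates) == 0L) return(NULL)
    cbind(data.frame(treated_id = p$treated_id, stringsAsFactors = FALSE),
          p$candidates,
          data.frame(pull_week = as.integer(p$pull_week %||% 0L)))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(treated_id = character(0), control_id = character(0),
                      distance = numeric(0), tier = integer(0),
                      rank_within_tier = integer(0), pull_week = integer(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @rdname pools_to_frame
#' @export
write_pools <- function(pools, path) {
  utils::write.csv(pools_to_frame(pools), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname pools_to_frame
#' @export
read_pools <- function(path, min_pool_size = 5) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  ids <- unique(long$treated_id)
  lapply(ids, function(tid) {
    cand <- long[long$treated_id == tid,
                 c("control_id", "distance", "tier", "rank_within_tier")]
    rownames(cand) <- NULL
    structure(list(treated_id = tid, candidates = cand,
                   eligible_for_recruitment = nrow(cand) >= min_pool_size,
                   pull_week = long$pull_week[long$treated_id == tid][1]),
              class = "pm_match_pool")
  })
}

#' Write / read the dyad table
#'
#' Columns: `treated_id`, `control_id`, `tier_of_enrollment`,
#' `days_between_enrollments`, `distance`.
#'
#' @param dyads Dyad data frame from [simulate_recruitment()].
#' @param path File path.
#' @export
write_dyads <- function(dyads, path) {
  utils::write.csv(dyads, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_dyads
#' @export
read_dyads <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read the recruitment event stream (JSON lines)
#'
#' One JSON object per line with fields `week`, `kind`, and where applicable
#' `treated_id`, `control_id`, `tier`.
#'
#' @param log Event data frame from [simulate_recruitment()].
#' @param path File path.
#' @export
write_events <- function(log, path) {
  lines <- vapply(seq_len(nrow(log)), function(i) {
    row <- as.list(log[i, , drop = FALSE])
    row <- row[!vapply(row, function(v) is.na(v), logical(1))]
    as.character(jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  lines <- readLines(path)
  cols <- c("week", "kind", "treated_id", "control_id", "tier")
  rows <- lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    for (nm in cols) if (is.null(x[[nm]]))
      x[[nm]] <- if (nm %in% c("week", "tier")) NA_integer_ else NA_character_
    as.data.frame(x[cols], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$week <- as.integer(out$week)
  out$tier <- as.integer(out$tier)
  out
}

#' Write a study report as JSON
#'
#' @param report A report list (e.g. from [run_full_study()]).
#' @param path File path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE, na = "null")
  invisible(path)
}
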