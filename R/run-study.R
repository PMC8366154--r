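#' Run the full study pipeline on a synthetic cohort
#'
#' End-to-end driver: generate a cohort, apply the facility volume filter,
#' classify patients through rolling quarterly pulls, build match pools per
#' pull (standardizer refitted on the control-eligible patients accumulated
#' up to each pull), simulate tiered recruitment to the dyad target, and
#' compute pre- and post-matching balance tables. Deterministic given `seed`,
#' which is split into per-stage substreams with [derive_seed()].
#'
#' @param config A `pm_study_config` (or a path to one); see
#'   [default_study_config()].
#' @param seed Optional master seed overriding the per-stage seeds in
#'   `config`.
#' @param out_dir Optional output directory; when given, all artifacts are
#'   written: `patients.csv`, `visits.csv`, `eligibility.csv`, `pools.csv`,
#'   `pool_summary.json`, `dyads.csv`, `events.jsonl`, `balance_pre.csv`,
#'   `balance_post.csv`, `report.json`.
#' @return A list of class `pm_study`: `report` (plain-list summary),
#'   `cohort`, `eligibility`, `pools`, `recruitment`, `balance_pre`,
#'   `balance_post`, `facilities_retained`.
#' @export
run_full_study <- function(config = default_study_config(), seed = NULL,
                           out_dir = NULL) {
  if (is.character(config)) config <- load_config(config)
  if (!inherits(config, "pm_study_config")) config <- as_study_config(config)
  if (!is.null(seed)) {
    config$cohort$seed <- derive_seed(seed, "cohort")
    config$recruitment$seed <- derive_seed(seed, "recruitment")
    config$power$seed <- derive_seed(seed, "power")
  }

  cohort <- generate_cohort(config$cohort)
  windows <- config$windows

  kept <- filter_facilities(cohort$visits, cohort$patients, windows,
                            config$eligibility$min_facility_treatment_visits)
  patients <- cohort$patients[cohort$patients$facility_id %in% kept, , drop = FALSE]
  visits <- cohort$visits[cohort$visits$patient_id %in% patients$patient_id, ,
                          drop = FALSE]

  q <- config$eligibility$pull_interval_days
  n_pulls <- ceiling((windows$exposure[2] - windows$exposure[1]) / q) + 1L
  schedule <- windows$exposure[1] + q * seq_len(n_pulls)
  eligibility <- rolling_pull(patients, visits, windows, schedule)

  treated_ids <- eligibility$patient_id[eligibility$arm == "treated_eligible"]
  control_ids <- eligibility$patient_id[eligibility$arm == "control_eligible"]

  balance_pre <- NULL
  if (length(treated_ids) > 0L && length(control_ids) > 0L)
    balance_pre <- balance_table(
      patients[match(treated_ids, patients$patient_id), , drop = FALSE],
      patients[match(control_ids, patients$patient_id), , drop = FALSE])

  pools <- list()
  for (k in sort(unique(eligibility$pull_index[eligibility$arm == "treated_eligible"]))) {
    tr_k <- eligibility$patient_id[eligibility$arm == "treated_eligible" &
                                     eligibility$pull_index == k]
    co_k <- eligibility$patient_id[eligibility$arm == "control_eligible" &
                                     eligibility$pull_index <= k]
    if (length(co_k) < 2L) next
    controls_k <- patients[match(co_k, patients$patient_id), , drop = FALSE]
    std_k <- fit_standardizer(controls_k)
    pools_k <- build_pools(patients[match(tr_k, patients$patient_id), , drop = FALSE],
                           controls_k, config$matching, std_k)
    week_k <- as.integer(schedule[k] %/% 7)
    for (p in pools_k) {
      p$pull_week <- week_k
      pools[[length(pools) + 1L]] <- p
    }
  }

  pstats <- if (length(pools))
    pool_statistics(pools, config$matching$min_pool_size) else NULL

  recruitment <- simulate_recruitment(pools, config$recruitment)
  dyads <- recruitment$dyads
  rsummary <- recruitment_summary(recruitment)

  balance_post <- NULL
  balance_note <- NULL
  if (nrow(dyads) > 0L) {
    balance_post <- balance_table(
      patients[match(dyads$treated_id, patients$patient_id), , drop = FALSE],
      patients[match(dyads$control_id, patients$patient_id), , drop = FALSE])
  } else {
    balance_note <- "no dyads formed; post-matching balance skipped"
  }

  report <- list(
    schema_version = config$schema_version,
    seed = seed,
    n_patients = nrow(cohort$patients),
    n_facilities = cohort$config$n_facilities,
    n_facilities_retained = length(kept),
    n_treated_eligible = length(treated_ids),
    n_control_eligible = length(control_ids),
    pool_statistics = pstats,
    n_dyads = nrow(dyads),
    n_unmatched_treated = length(recruitment$unmatched),
    recruitment = list(
      n_enrolled_treated = rsummary$n_enrolled_treated,
      fraction_matched = rsummary$fraction_matched,
      tier_distribution_percent = as.list(rsummary$tier_distribution),
      median_days_between = rsummary$median_days_between
    ),
    balance_pre = if (!is.null(balance_pre)) as.data.frame(balance_pre),
    balance_post = if (!is.null(balance_post)) as.data.frame(balance_post),
    balance_note = balance_note
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_patients(cohort$patients, file.path(out_dir, "patients.csv"))
    write_visits(cohort$visits, file.path(out_dir, "visits.csv"))
    write_eligibility(eligibility, file.path(out_dir, "eligibility.csv"))
    write_pools(pools, file.path(out_dir, "pools.csv"))
    if (!is.null(pstats))
      jsonlite::write_json(pstats, file.path(out_dir, "pool_summary.json"),
                           auto_unbox = TRUE, digits = NA)
    write_dyads(dyads, file.path(out_dir, "dyads.csv"))
    write_events(recruitment$log, file.path(out_dir, "events.jsonl"))
    if (!is.null(balance_pre))
      utils::write.csv(as.data.frame(balance_pre),
                       file.path(out_dir, "balance_pre.csv"), row.names = FALSE)
    if (!is.null(balance_post))
      utils::write.csv(as.data.frame(balance_post),
                       file.path(out_dir, "balance_post.csv"), row.names = FALSE)
    write_report(report, file.path(out_dir, "report.json"))
  }

  structure(list(report = report, cohort = cohort, eligibility = eligibility,
                 pools = pools, recruitment = recruitment,
                 balance_pre = balance_pre, balance_post = balance_post,
                 facilities_retained = kept, config = config),
            class = "pm_study")
}

#' @export
print.pm_study <- function(x, ...) {
  r <- x$report
  cat(sprintf("Full-study run: %d patients, %d/%d facilities retained\n",
              r$n_patients, r$n_facilities_retained, r$n_facilities))
  cat(sprintf("  eligible: %d treated, %d control\n",
              r$n_treated_eligible, r$n_control_eligible))
  if (!is.null(r$pool_statistics))
    cat(sprintf("  pools: median size %g (range %g-%g), %d lacking minimum\n",
                r$pool_statistics$median_size, r$pool_statistics$size_range[1],
                r$pool_statistics$size_range[2], r$pool_statistics$n_lacking))
  cat(sprintf("  dyads formed: %d (%d treated unmatched)\n",
              r$n_dyads, r$n_unmatched_treated))
  if (!is.null(r$balance_note)) cat(" ", r$balance_note, "\n")
  invisible(x)
}
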