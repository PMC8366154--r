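#' Default full-study configuration
#'
#' The schema-versioned nested configuration of the whole pipeline:
#' `cohort` ([cohort_config()]), `windows` ([study_windows()]), `matching`
#' ([match_params()]), `recruitment` ([recruitment_params()]), `power`
#' ([power_spec()]), `eligibility` (facility volume threshold and pull
#' spacing) and `io` (output directory).
#'
#' @return A list of class `pm_study_config`.
#' @export
default_study_config <- function() {
  structure(list(
    schema_version = "1.0",
    cohort = cohort_config(),
    windows = study_windows(),
    matching = match_params(),
    recruitment = recruitment_params(),
    power = power_spec(),
    eligibility = list(min_facility_treatment_visits = 500,
                       pull_interval_days = 91L),
    io = list(out_dir = ".")
  ), class = "pm_study_config")
}

section_from <- function(raw, constructor, section) {
  if (is.null(raw)) return(constructor())
  if (!is.list(raw))
    pm_stop("prospmatch_config_error", "section '%s' must be a mapping", section)
  allowed <- names(formals(constructor))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown))
    pm_stop("prospmatch_config_error", "unknown key(s) in '%s': %s",
            section, paste(unknown, collapse = ", "))
  do.call(constructor, raw)
}

as_study_config <- function(raw) {
  if (!is.list(raw))
    pm_stop("prospmatch_parse_error", "config must be a mapping")
  known <- c("schema_version", "cohort", "windows", "matching", "recruitment",
             "power", "eligibility", "io")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    pm_stop("prospmatch_config_error", "unknown top-level key(s): %s",
            paste(unknown, collapse = ", "))
  elig <- raw$eligibility %||% list()
  unknown_e <- setdiff(names(elig),
                       c("min_facility_treatment_visits", "pull_interval_days"))
  if (length(unknown_e))
    pm_stop("prospmatch_config_error", "unknown key(s) in 'eligibility': %s",
            paste(unknown_e, collapse = ", "))
  version <- raw$schema_version %||% "1.0"
  if (!is.character(version) || length(version) != 1L || !nzchar(version))
    pm_stop("prospmatch_config_error", "'schema_version' must be a nonempty string")
  structure(list(
    schema_version = version,
    cohort = section_from(raw$cohort, cohort_config, "cohort"),
    windows = section_from(raw$windows, study_windows, "windows"),
    matching = section_from(raw$matching, match_params, "matching"),
    recruitment = section_from(raw$recruitment, recruitment_params, "recruitment"),
    power = section_from(raw$power, power_spec, "power"),
    eligibility = list(
      min_facility_treatment_visits =
        check_number(elig$min_facility_treatment_visits %||% 500,
                     "eligibility$min_facility_treatment_visits", min = 0),
      pull_interval_days =
        check_count(elig$pull_interval_days %||% 91,
                    "eligibility$pull_interval_days", min = 1)
    ),
    io = list(out_dir = as.character((raw$io %||% list())$out_dir %||% "."))
  ), class = "pm_study_config")
}

#' Load a study configuration from YAML or JSON
#'
#' Reads, validates and default-fills a configuration file. Unknown keys are
#' rejected and every nested invariant is enforced at load time; validation
#' errors name the offending key.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `pm_study_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    pm_stop("prospmatch_io_error", "config file not found: %s", path)
  raw <- tryCatch({
    if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::read_json(path, simplifyVector = TRUE)
    else
      yaml::read_yaml(path)
  }, error = function(e)
    pm_stop("prospmatch_parse_error", "cannot parse config '%s': %s",
            path, conditionMessage(e)))
  as_study_config(raw)
}

strip_classes <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_classes)
    attributes(x) <- list(names = names(x))
  } else if (is.atomic(x) && !is.null(names(x))) {
    x <- as.list(x)  # yaml keeps names only for maps, not sequences
  }
  x
}

#' Serialize a study configuration to YAML
#'
#' Writes a configuration such that `load_config()` of the written file
#' yields an identical configuration (round-trip identity).
#'
#' @param config A `pm_study_config`.
#' @param path Output path.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(strip_classes(unclass(config)), path, precision = 15)
  invisible(path)
}
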