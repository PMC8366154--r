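#' Matching parameters
#'
#' Controls the coarsened-exact plus minimum-distance match-pool construction:
#' the coarsened criteria are exact agreement on facility, race, sex, advance
#' directive, dementia and any-hospitalization, plus an age caliper; the
#' remaining closeness is a standardized distance on age, hospitalization
#' count, CAN score and JFI score, banded into recruitment priority tiers.
#'
#' @param age_caliper Maximum absolute age difference in years for exact
#'   compatibility (default 5, read as pairwise proximity rather than 5-year
#'   bins; see `age_bins`).
#' @param age_bins If `TRUE`, replace the symmetric caliper by 5-year bins
#'   (`floor(age / age_caliper)` agreement) — provided for sensitivity
#'   analyses; binning creates boundary artifacts.
#' @param min_pool_size Minimum candidate count for a treated patient to be
#'   recruitable (default 5, reflecting an expected 20% telephone enrollment
#'   rate).
#' @param tier_ladder Strictly increasing distance thresholds; tier k collects
#'   distances in `[ladder[k-1], ladder[k])` with an implicit leading 0 and an
#'   unbounded last tier. Default `c(0.1, 0.25, 0.5, 1, 2, Inf)`.
#' @param distance_mode `"diagonal"` (Euclidean on standardized variables,
#'   i.e. Mahalanobis with diagonal covariance; the default) or `"full"`
#'   (Mahalanobis with the covariance of the standardized variables in the
#'   standardizer's reference population).
#' @return A validated list of class `pm_match_params`.
#' @export
match_params <- function(age_caliper = 5,
                         age_bins = FALSE,
                         min_pool_size = 5,
                         tier_ladder = c(0.1, 0.25, 0.5, 1, 2, Inf),
                         distance_mode = c("diagonal", "full")) {
  tier_ladder <- as_named_numeric(tier_ladder, "tier_ladder")
  if (length(tier_ladder) < 1L || any(is.na(tier_ladder)) ||
      any(tier_ladder <= 0) || is.unsorted(tier_ladder, strictly = TRUE))
    pm_stop("prospmatch_config_error",
            "'tier_ladder' must be a strictly increasing vector of positive thresholds (ladder must be increasing)")
  structure(list(
    age_caliper = check_number(age_caliper, "age_caliper", min = 0),
    age_bins = isTRUE(age_bins),
    min_pool_size = check_count(min_pool_size, "min_pool_size", min = 1),
    tier_ladder = tier_ladder,
    distance_mode = match.arg(distance_mode)
  ), class = "pm_match_params")
}

distance_variables <- function() c("age", "n_hospitalizations", "can_score", "jfi_score")

#' Coarsened exact-matching key
#'
#' Projects patient records onto the coarsened characteristics that must agree
#' exactly between a treated patient and a candidate control: facility, race,
#' sex, advance-directive flag, dementia flag, and any-hospitalization flag.
#' Age is handled separately by the caliper (see [exact_compatible()]).
#'
#' @param records Patient data frame (one or more rows).
#' @return Character vector of keys, one per record.
#' @export
exact_key <- function(records) {
  paste(records$facility_id, records$race, records$female,
        records$advance_directive, records$dementia,
        records$any_hospitalization, sep = "|")
}

#' Exact compatibility of two records
#'
#' Two records are exact-compatible when their [exact_key()]s agree and their
#' ages are within the caliper (|difference| <= `age_caliper`), or fall in the
#' same age bin when `age_bins = TRUE`. The relation is symmetric.
#'
#' @param a,b One-row patient data frames.
#' @param params A [match_params()].
#' @return Logical scalar.
#' @export
exact_compatible <- function(a, b, params = match_params()) {
  if (exact_key(a) != exact_key(b)) return(FALSE)
  if (params$age_bins) {
    floor(a$age / params$age_caliper) == floor(b$age / params$age_caliper)
  } else {
    abs(a$age - b$age) <= params$age_caliper
  }
}

#' Fit the distance standardizer on a reference population
#'
#' Estimates per-variable means and sample standard deviations of the four
#' distance variables (age, hospitalization count, CAN, JFI) on a reference
#' population — by convention the control-eligible patients at the current
#' pull — plus the covariance of the standardized variables (used by the
#' `"full"` distance mode). The applied transform is `(x - mean) / SD`.
#'
#' @param controls Patient data frame with at least 2 rows.
#' @return A list of class `pm_standardizer` (`means`, `sds`, `cov`).
#' @export
fit_standardizer <- function(controls) {
  vars <- distance_variables()
  if (nrow(controls) < 2L)
    pm_stop("prospmatch_input_error",
            "standardizer needs at least 2 reference records")
  means <- vapply(vars, function(v) mean(controls[[v]]), numeric(1))
  sds <- vapply(vars, function(v) stats::sd(controls[[v]]), numeric(1))
  zero <- vars[sds <= 0 | !is.finite(sds)]
  if (length(zero))
    pm_stop("prospmatch_degenerate_error",
            "zero variance in standardizer variable(s): %s",
            paste(zero, collapse = ", "))
  z <- scale(as.matrix(controls[vars]), center = means, scale = sds)
  structure(list(means = means, sds = sds, cov = stats::cov(z)),
            class = "pm_standardizer")
}

#' Standardize the distance variables of patient records
#'
#' @param standardizer A [fit_standardizer()] object.
#' @param records Patient data frame.
#' @return Numeric matrix (rows = records, columns = distance variables).
#' @export
standardize_records <- function(standardizer, records) {
  if (!inherits(standardizer, "pm_standardizer"))
    pm_stop("prospmatch_state_error", "standardizer has not been fitted")
  vars <- distance_variables()
  z <- as.matrix(records[vars])
  sweep(sweep(z, 2L, standardizer$means, "-"), 2L, standardizer$sds, "/")
}

# Distances from one treated record to a matrix of standardized controls.
distances_to <- function(zt, zc, standardizer, mode) {
  d2 <- if (mode == "full") {
    stats::mahalanobis(zc, center = as.numeric(zt), cov = standardizer$cov)
  } else {
    rowSums(sweep(zc, 2L, as.numeric(zt), "-")^2)
  }
  unname(sqrt(pmax(d2, 0)))
}

#' Standardized matching distance between two patients
#'
#' Distance over the four standardized variables (age, hospitalization count,
#' CAN, JFI). The default `"diagonal"` mode is Euclidean distance on the
#' standardized values — equivalently Mahalanobis distance with a diagonal
#' covariance; `"full"` uses the covariance of the standardized variables in
#' the standardizer's reference population. Symmetric, and zero iff the two
#' records agree on all four variables.
#'
#' @param treated,control One-row patient data frames.
#' @param standardizer A [fit_standardizer()] object.
#' @param mode `"diagonal"` or `"full"`.
#' @return Nonnegative scalar.
#' @export
match_distance <- function(treated, control, standardizer,
                           mode = c("diagonal", "full")) {
  mode <- match.arg(mode)
  zt <- standardize_records(standardizer, treated)
  zc <- standardize_records(standardizer, control)
  distances_to(zt, zc, standardizer, mode)[1]
}

#' Assign recruitment priority tiers from distances
#'
#' Tier k collects distances in the half-open band
#' `[ladder[k-1], ladder[k])` with an implicit leading 0; the last tier is
#' unbounded, so every candidate receives a tier. With the default ladder the
#' highest-priority tier is distance < 0.1, the second < 0.25, the third
#' < 0.5, and so on.
#'
#' @param distances Nonnegative numeric vector.
#' @param ladder Strictly increasing thresholds (may end in `Inf`).
#' @return Integer tiers (1-based).
#' @export
assign_tiers <- function(distances, ladder = match_params()$tier_ladder) {
  ladder <- as_named_numeric(ladder, "ladder")
  if (length(ladder) < 1L || any(is.na(ladder)) ||
      is.unsorted(ladder, strictly = TRUE))
    pm_stop("prospmatch_config_error", "ladder must be increasing")
  finite <- ladder[is.finite(ladder)]
  findInterval(distances, finite) + 1L
}

#' Build the candidate pool for one treated patient
#'
#' Candidates are the controls passing exact-key compatibility including the
#' age caliper; each receives a standardized distance and a priority tier, and
#' the pool is sorted by (tier, distance, control_id) with distance ties
#' broken lexicographically by control id for reproducibility. A pool with
#' fewer than `min_pool_size` candidates is flagged not recruitable (the
#' treated patient is excluded from recruitment), mirroring the at-least-5-
#' matches rule.
#'
#' @param treated One-row patient data frame.
#' @param controls Patient data frame of control-eligible candidates.
#' @param params A [match_params()].
#' @param standardizer A [fit_standardizer()]; fitted on `controls` when
#'   omitted.
#' @return A list of class `pm_match_pool`: `treated_id`, `candidates`
#'   (data frame `control_id`, `distance`, `tier`, `rank_within_tier`),
#'   `eligible_for_recruitment`.
#' @export
build_pool <- function(treated, controls, params = match_params(),
                       standardizer = NULL) {
  if (is.null(standardizer)) standardizer <- fit_standardizer(controls)
  key_t <- exact_key(treated)
  keep <- exact_key(controls) == key_t & controls$patient_id != treated$patient_id
  if (params$age_bins) {
    keep <- keep & (floor(controls$age / params$age_caliper) ==
                      floor(treated$age / params$age_caliper))
  } else {
    keep <- keep & abs(controls$age - treated$age) <= params$age_caliper
  }
  cand <- controls[keep, , drop = FALSE]
  if (nrow(cand) > 0L) {
    zt <- standardize_records(standardizer, treated)
    zc <- standardize_records(standardizer, cand)
    d <- distances_to(zt, zc, standardizer, params$distance_mode)
    tier <- assign_tiers(d, params$tier_ladder)
    ord <- order(tier, d, cand$patient_id)
    candidates <- data.frame(control_id = cand$patient_id[ord],
                             distance = d[ord],
                             tier = tier[ord],
                             stringsAsFactors = FALSE)
    candidates$rank_within_tier <- stats::ave(seq_len(nrow(candidates)),
                                              candidates$tier,
                                              FUN = seq_along)
  } else {
    candidates <- data.frame(control_id = character(0), distance = numeric(0),
                             tier = integer(0), rank_within_tier = integer(0),
                             stringsAsFactors = FALSE)
  }
  structure(list(treated_id = treated$patient_id,
                 candidates = candidates,
                 eligible_for_recruitment = nrow(candidates) >= params$min_pool_size),
            class = "pm_match_pool")
}

#' @export
print.pm_match_pool <- function(x, ...) {
  cat(sprintf("Match pool for %s: %d candidates%s\n", x$treated_id,
              nrow(x$candidates),
              if (x$eligible_for_recruitment) "" else " (below minimum; not recruitable)"))
  if (nrow(x$candidates)) print(utils::head(x$candidates, 5))
  invisible(x)
}

#' Build match pools for a set of treated patients
#'
#' @param treated Patient data frame of treated-eligible patients.
#' @param controls Patient data frame of control-eligible candidates.
#' @param params A [match_params()].
#' @param standardizer Optional pre-fitted [fit_standardizer()]; fitted on
#'   `controls` when omitted.
#' @return List of `pm_match_pool`, one per treated row, with the
#'   standardizer attached as an attribute.
#' @export
build_pools <- function(treated, controls, params = match_params(),
                        standardizer = NULL) {
  if (is.null(standardizer)) standardizer <- fit_standardizer(controls)
  pools <- lapply(seq_len(nrow(treated)), function(i)
    build_pool(treated[i, , drop = FALSE], controls, params, standardizer))
  attr(pools, "standardizer") <- standardizer
  pools
}

#' Summary statistics over a set of match pools
#'
#' Reports how many treated patients lack the minimum number of suitable
#' matches, and the median and range of pool sizes — the feasibility surface
#' of the design.
#'
#' @param pools List of `pm_match_pool`.
#' @param min_pool_size Minimum pool size (default 5).
#' @return List: `n_pools`, `n_lacking`, `fraction_lacking`, `median_size`,
#'   `size_range` (length-2).
#' @export
pool_statistics <- function(pools, min_pool_size = 5) {
  if (length(pools) == 0L)
    pm_stop("prospmatch_degenerate_error", "pool_statistics needs at least one pool")
  sizes <- vapply(pools, function(p) nrow(p$candidates), integer(1))
  n_lacking <- sum(sizes < min_pool_size)
  list(n_pools = length(pools),
       n_lacking = n_lacking,
       fraction_lacking = n_lacking / length(pools),
       median_size = as.numeric(stats::median(sizes)),
       size_range = c(min(sizes), max(sizes)))
}
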