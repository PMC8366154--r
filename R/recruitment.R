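#' Recruitment protocol parameters
#'
#' Parameters of the discrete-event enrollment simulation. Time is discretized
#' to weeks: after a treated patient enrolls at week w, only their
#' highest-priority tier is contactable for `escalation_interval` weeks;
#' every further `escalation_interval` weeks without an enrolled match opens
#' the next tier (cumulatively), and the recruitment window closes
#' unconditionally `match_window` weeks after the treated enrollment.
#'
#' @param p_enroll_treated Probability a contacted treated patient enrolls
#'   (default 1; the real design only proceeds once the treated patient is in).
#' @param p_enroll_control Probability a contacted candidate control enrolls
#'   (default 0.20, the expected telephone recruitment rate).
#' @param escalation_interval Weeks between tier escalations (default 2).
#' @param match_window Weeks a treated patient's recruitment window stays open
#'   (default 5).
#' @param contacts_per_week Candidates contacted per open window per week
#'   (default 3; simultaneous multi-candidate contact).
#' @param target_dyads Stop once this many dyads are formed (default 275).
#' @param seed Integer seed.
#' @param confirm_eligible_prob Probability a contacted candidate passes the
#'   medical-record eligibility confirmation (attrition gate, default 1).
#' @return A validated list of class `pm_recruitment_params`.
#' @export
recruitment_params <- function(p_enroll_treated = 1,
                               p_enroll_control = 0.20,
                               escalation_interval = 2,
                               match_window = 5,
                               contacts_per_week = 3,
                               target_dyads = 275,
                               seed = 1,
                               confirm_eligible_prob = 1) {
  structure(list(
    p_enroll_treated = check_prob(p_enroll_treated, "p_enroll_treated"),
    p_enroll_control = check_prob(p_enroll_control, "p_enroll_control"),
    escalation_interval = check_count(escalation_interval, "escalation_interval", min = 1),
    match_window = check_count(match_window, "match_window", min = 1),
    contacts_per_week = check_count(contacts_per_week, "contacts_per_week", min = 1),
    target_dyads = check_count(target_dyads, "target_dyads", min = 1),
    seed = check_number(seed, "seed"),
    confirm_eligible_prob = check_prob(confirm_eligible_prob, "confirm_eligible_prob")
  ), class = "pm_recruitment_params")
}

#' Simulate the tiered recruitment protocol
#'
#' Weekly discrete-event simulation of enrollment. Treated patients are
#' attempted at their pull's opening week in pull order; each enrolled treated
#' patient opens a recruitment window over their match pool. Within an open
#' window, up to `contacts_per_week` not-yet-attempted candidates in the
#' currently open tiers are contacted each week in (tier, distance, id) order;
#' each contacted candidate passes the eligibility-confirmation gate and then
#' enrolls with `p_enroll_control`. The first enrollment forms the dyad and
#' closes the window; otherwise the window closes `match_window` weeks after
#' the treated enrollment and the treated patient remains in the study
#' unmatched. An enrolled control is removed from every other pool
#' immediately (each patient joins at most one dyad). The simulation stops
#' when `target_dyads` dyads are formed or all pools are exhausted.
#'
#' @param pools List of `pm_match_pool` (see [build_pool()]); each pool may
#'   carry a `pull_week` element giving the week its treated patient becomes
#'   available (default 0). Pools flagged not recruitable are skipped.
#' @param params A [recruitment_params()].
#' @return A list of class `pm_recruitment`:
#'   \describe{
#'     \item{dyads}{Data frame `treated_id`, `control_id`,
#'       `tier_of_enrollment`, `days_between_enrollments` (7 x week lag),
#'       `distance`.}
#'     \item{unmatched}{Treated ids enrolled but never matched.}
#'     \item{log}{Event data frame `week`, `kind`, `treated_id`,
#'       `control_id`, `tier` with kinds `pull_opened`, `enrolled_treated`,
#'       `letter_sent`, `escalation`, `contact_attempt`, `enrolled_control`,
#'       `dyad_formed`, `window_closed`.}
#'     \item{params}{The parameters used.}
#'   }
#' @export
simulate_recruitment <- function(pools, params = recruitment_params()) {
  if (!inherits(params, "pm_recruitment_params")) params <- do.call(recruitment_params, params)
  set.seed(as.integer(params$seed %% 2147483629))

  ev <- vector("list", 256L)
  n_ev <- 0L
  add_event <- function(week, kind, treated_id = NA_character_,
                        control_id = NA_character_, tier = NA_integer_) {
    n_ev <<- n_ev + 1L
    if (n_ev > length(ev)) length(ev) <<- 2L * length(ev)
    ev[[n_ev]] <<- list(week = week, kind = kind, treated_id = treated_id,
                        control_id = control_id, tier = as.integer(tier))
  }
  collect <- function() {
    if (n_ev == 0L)
      return(data.frame(week = integer(0), kind = character(0),
                        treated_id = character(0), control_id = character(0),
                        tier = integer(0), stringsAsFactors = FALSE))
    e <- ev[seq_len(n_ev)]
    data.frame(week = vapply(e, `[[`, integer(1), "week"),
               kind = vapply(e, `[[`, character(1), "kind"),
               treated_id = vapply(e, `[[`, character(1), "treated_id"),
               control_id = vapply(e, `[[`, character(1), "control_id"),
               tier = vapply(e, `[[`, integer(1), "tier"),
               stringsAsFactors = FALSE)
  }

  n <- length(pools)
  empty <- function() structure(
    list(dyads = data.frame(treated_id = character(0), control_id = character(0),
                            tier_of_enrollment = integer(0),
                            days_between_enrollments = integer(0),
                            distance = numeric(0), stringsAsFactors = FALSE),
         unmatched = character(0), log = collect(), params = params),
    class = "pm_recruitment")
  if (n == 0L) return(empty())

  pull_week <- vapply(pools, function(p) as.integer(p$pull_week %||% 0L), integer(1))
  ord <- order(pull_week, seq_len(n))
  status <- rep("pending", n)
  w0 <- rep(NA_integer_, n)
  open_tier <- rep(1L, n)
  attempted <- vector("list", n)
  enrolled_controls <- new.env(parent = emptyenv())

  dy_treated <- character(0); dy_control <- character(0)
  dy_tier <- integer(0); dy_days <- integer(0); dy_dist <- numeric(0)
  target_reached <- FALSE

  w <- min(pull_week)
  guard <- max(pull_week) + params$match_window + 10L
  while (!target_reached && any(status %in% c("pending", "active")) && w <= guard) {
    if (any(pull_week == w & status == "pending")) add_event(w, "pull_opened")
    # treated enrollment attempts for pulls opening this week
    for (i in ord) {
      if (status[i] != "pending" || pull_week[i] != w) next
      pool <- pools[[i]]
      if (!isTRUE(pool$eligible_for_recruitment)) { status[i] <- "skipped"; next }
      if (stats::runif(1) < params$p_enroll_treated) {
        status[i] <- "active"
        w0[i] <- w
        attempted[[i]] <- rep(FALSE, nrow(pool$candidates))
        add_event(w, "enrolled_treated", pool$treated_id)
        nl <- min(20L, nrow(pool$candidates))
        for (j in seq_len(nl))
          add_event(w, "letter_sent", pool$treated_id,
                    pool$candidates$control_id[j], pool$candidates$tier[j])
      } else {
        status[i] <- "skipped"
      }
    }
    # contacts within open windows, earliest-enrolled treated first
    act <- which(status == "active")
    act <- act[order(w0[act], act)]
    for (i in act) {
      if (target_reached) break
      pool <- pools[[i]]
      if (w - w0[i] >= params$match_window) {
        status[i] <- "unmatched"
        add_event(w, "window_closed", pool$treated_id)
        next
      }
      tier_now <- 1L + (w - w0[i]) %/% params$escalation_interval
      if (tier_now > open_tier[i]) {
        open_tier[i] <- tier_now
        add_event(w, "escalation", pool$treated_id, tier = tier_now)
      }
      cand <- pool$candidates
      k <- 0L
      for (j in seq_len(nrow(cand))) {
        if (k >= params$contacts_per_week) break
        if (cand$tier[j] > tier_now) break  # sorted by tier: nothing further is open
        if (attempted[[i]][j]) next
        cid <- cand$control_id[j]
        if (!is.null(enrolled_controls[[cid]])) { attempted[[i]][j] <- TRUE; next }
        attempted[[i]][j] <- TRUE
        k <- k + 1L
        add_event(w, "contact_attempt", pool$treated_id, cid, cand$tier[j])
        if (stats::runif(1) < params$confirm_eligible_prob &&
            stats::runif(1) < params$p_enroll_control) {
          add_event(w, "enrolled_control", pool$treated_id, cid, cand$tier[j])
          add_event(w, "dyad_formed", pool$treated_id, cid, cand$tier[j])
          enrolled_controls[[cid]] <- TRUE
          dy_treated <- c(dy_treated, pool$treated_id)
          dy_control <- c(dy_control, cid)
          dy_tier <- c(dy_tier, cand$tier[j])
          dy_days <- c(dy_days, 7L * (w - w0[i]))
          dy_dist <- c(dy_dist, cand$distance[j])
          status[i] <- "matched"
          if (length(dy_treated) >= params$target_dyads) target_reached <- TRUE
          break
        }
      }
    }
    w <- w + 1L
  }

  unmatched <- vapply(pools[status %in% c("unmatched", "active")],
                      function(p) p$treated_id, character(1))
  structure(list(
    dyads = data.frame(treated_id = dy_treated, control_id = dy_control,
                       tier_of_enrollment = dy_tier,
                       days_between_enrollments = dy_days,
                       distance = dy_dist, stringsAsFactors = FALSE),
    unmatched = unname(unmatched),
    log = collect(),
    params = params
  ), class = "pm_recruitment")
}

#' @export
print.pm_recruitment <- function(x, ...) {
  cat(sprintf("Recruitment simulation: %d dyads formed, %d treated unmatched, %d events\n",
              nrow(x$dyads), length(x$unmatched), nrow(x$log)))
  invisible(x)
}

#' Summarize a recruitment simulation
#'
#' @param dyads A `pm_recruitment` object, or a dyad data frame (columns
#'   `tier_of_enrollment`, `days_between_enrollments`).
#' @param log Optional event log (supplied automatically when `dyads` is a
#'   `pm_recruitment`); needed for the matched fraction and the weekly curves.
#' @return A list of class `pm_recruitment_summary`: `n_dyads`,
#'   `n_enrolled_treated` (NA without a log), `fraction_matched`,
#'   `tier_distribution` (percentages over enrolled dyads),
#'   `median_days_between`, and `weekly` (cumulative dyads per tier by week;
#'   NULL without a log).
#' @export
recruitment_summary <- function(dyads, log = NULL) {
  if (inherits(dyads, "pm_recruitment")) {
    log <- dyads$log
    dyads <- dyads$dyads
  }
  n_dyads <- nrow(dyads)
  n_treated <- if (!is.null(log)) sum(log$kind == "enrolled_treated") else NA_integer_
  tier_distribution <- if (n_dyads > 0L) {
    tab <- table(dyads$tier_of_enrollment)
    stats::setNames(100 * as.numeric(tab) / n_dyads, names(tab))
  } else {
    stats::setNames(numeric(0), character(0))
  }
  weekly <- NULL
  if (!is.null(log)) {
    formed <- log[log$kind == "dyad_formed", , drop = FALSE]
    if (nrow(formed) > 0L) {
      grid <- expand.grid(week = sort(unique(formed$week)),
                          tier = sort(unique(formed$tier)))
      grid$cumulative_dyads <- mapply(function(wk, tr)
        sum(formed$week <= wk & formed$tier == tr), grid$week, grid$tier)
      weekly <- grid[order(grid$tier, grid$week), ]
      rownames(weekly) <- NULL
    }
  }
  structure(list(
    n_dyads = n_dyads,
    n_enrolled_treated = n_treated,
    fraction_matched = if (is.na(n_treated) || n_treated == 0L) NA_real_
                       else n_dyads / n_treated,
    tier_distribution = tier_distribution,
    median_days_between = if (n_dyads > 0L)
      as.numeric(stats::median(dyads$days_between_enrollments)) else NA_real_,
    weekly = weekly
  ), class = "pm_recruitment_summary")
}

#' @export
print.pm_recruitment_summary <- function(x, ...) {
  cat(sprintf("Dyads: %d", x$n_dyads))
  if (!is.na(x$n_enrolled_treated))
    cat(sprintf(" (%.0f%% of %d enrolled treated patients matched)",
                100 * x$fraction_matched, x$n_enrolled_treated))
  cat("\n")
  if (length(x$tier_distribution)) {
    cat("Tier of enrollment:\n")
    for (t in names(x$tier_distribution))
      cat(sprintf("  tier %s: %.1f%%\n", t, x$tier_distribution[[t]]))
  }
  if (!is.na(x$median_days_between))
    cat(sprintf("Median days between enrollments: %g\n", x$median_days_between))
  invisible(x)
}
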