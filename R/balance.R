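#' Standardized mean difference for a continuous covariate
#'
#' `(mean2 - mean1) / sqrt((sd1^2 + sd2^2) / 2)`, the unweighted two-group
#' pooled-SD form. Group 1 is the treated arm by convention, so a covariate
#' that is higher among treated patients has a negative SMD. Values with
#' |SMD| < 0.2 are conventionally read as adequate balance; the statistic is
#' insensitive to sample size.
#'
#' @param mean1,sd1 Mean and SD in group 1 (treated).
#' @param mean2,sd2 Mean and SD in group 2 (control).
#' @return The SMD. Zero when the means are equal; if both SDs are zero with
#'   unequal means the SMD is undefined and an error is raised.
#' @export
smd_continuous <- function(mean1, sd1, mean2, sd2) {
  if (sd1 < 0 || sd2 < 0)
    pm_stop("prospmatch_input_error", "standard deviations must be nonnegative")
  if (mean1 == mean2) return(0)
  pooled <- sqrt((sd1^2 + sd2^2) / 2)
  if (pooled == 0)
    pm_stop("prospmatch_degenerate_error",
            "SMD undefined: zero variance in both groups with unequal means")
  (mean2 - mean1) / pooled
}

#' Standardized mean difference for a binary covariate
#'
#' `(p2 - p1) / sqrt((p1 (1 - p1) + p2 (1 - p2)) / 2)`; exactly 0 when the
#' proportions are equal (including degenerate proportions of 0 or 1).
#'
#' @param p1 Proportion in group 1 (treated).
#' @param p2 Proportion in group 2 (control).
#' @return The standardized difference of proportions.
#' @export
smd_binary <- function(p1, p2) {
  check_prob(p1, "p1"); check_prob(p2, "p2")
  if (p1 == p2) return(0)
  denom <- sqrt((p1 * (1 - p1) + p2 * (1 - p2)) / 2)
  if (denom == 0)
    pm_stop("prospmatch_degenerate_error",
            "SMD undefined: zero variance in both groups with unequal proportions")
  (p2 - p1) / denom
}

#' Default covariate specification for balance reporting
#'
#' The covariates of the matching model: the coarsened exact characteristics
#' plus the four distance variables.
#'
#' @return Data frame with columns `name` and `kind`
#'   (`continuous`/`binary`/`categorical`).
#' @export
matching_covariate_spec <- function() {
  data.frame(
    name = c("age", "race", "female", "advance_directive", "dementia",
             "any_hospitalization", "n_hospitalizations", "jfi_score",
             "can_score"),
    kind = c("continuous", "categorical", "binary", "binary", "binary",
             "binary", "continuous", "continuous", "continuous"),
    stringsAsFactors = FALSE
  )
}

#' Covariates matched exactly (zero-SMD guarantee)
#'
#' The coarsened exact-matching characteristics; in any dyad set produced by
#' the pipeline these have SMD exactly 0.
#'
#' @return Data frame with columns `name` and `kind`.
#' @export
exact_covariate_spec <- function() {
  data.frame(
    name = c("facility_id", "race", "female", "advance_directive", "dementia",
             "any_hospitalization"),
    kind = c("categorical", "categorical", "binary", "binary", "binary",
             "binary"),
    stringsAsFactors = FALSE
  )
}

balance_row <- function(label, kind, x1, x2) {
  m1 <- sum(is.na(x1)); m2 <- sum(is.na(x2))
  x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
  out <- data.frame(covariate = label, kind = kind,
                    group1_mean = NA_real_, group1_sd = NA_real_,
                    group2_mean = NA_real_, group2_sd = NA_real_,
                    group1_n_missing = m1, group2_n_missing = m2,
                    smd = NA_real_, flagged = FALSE, undefined = FALSE,
                    stringsAsFactors = FALSE)
  if (length(x1) == 0L || length(x2) == 0L) {
    out$undefined <- TRUE
    return(out)
  }
  if (kind == "continuous") {
    out$group1_mean <- mean(x1)
    out$group1_sd <- if (length(x1) > 1L) stats::sd(x1) else 0
    out$group2_mean <- mean(x2)
    out$group2_sd <- if (length(x2) > 1L) stats::sd(x2) else 0
    out$smd <- tryCatch(
      smd_continuous(out$group1_mean, out$group1_sd, out$group2_mean, out$group2_sd),
      prospmatch_error = function(e) NA_real_)
  } else {
    out$group1_mean <- mean(as.numeric(x1))
    out$group2_mean <- mean(as.numeric(x2))
    out$smd <- tryCatch(smd_binary(out$group1_mean, out$group2_mean),
                        prospmatch_error = function(e) NA_real_)
  }
  out$undefined <- is.na(out$smd)
  out$flagged <- is.finite(out$smd) && abs(out$smd) >= 0.2
  out
}

#' Covariate balance table for two groups of patients
#'
#' Computes per-covariate summaries and standardized mean differences between
#' two groups (group 1 = treated by convention), in the style of a baseline-
#' characteristics table. Summaries are pairwise-complete: each covariate is
#' summarized on its non-missing values per group, with missing counts
#' reported per group; no imputation is performed. Categorical covariates are
#' expanded to one binary row per level. Rows with |SMD| >= 0.2 are flagged;
#' a covariate entirely missing in a group yields an undefined-SMD row with
#' `undefined = TRUE`.
#'
#' @param group1,group2 Patient data frames (group 1 = treated).
#' @param covariates Data frame with columns `name` and `kind`
#'   (`continuous`, `binary`, or `categorical`); defaults to
#'   [matching_covariate_spec()].
#' @return A data frame of class `pm_balance_table`: `covariate`, `kind`,
#'   `group1_mean`, `group1_sd`, `group2_mean`, `group2_sd` (proportions in
#'   the mean columns for binary rows), missing counts, `smd`, `flagged`,
#'   `undefined`.
#' @export
balance_table <- function(group1, group2, covariates = matching_covariate_spec()) {
  if (nrow(group1) == 0L || nrow(group2) == 0L)
    pm_stop("prospmatch_degenerate_error", "both groups must be nonempty")
  missing_cov <- setdiff(covariates$name, intersect(names(group1), names(group2)))
  if (length(missing_cov))
    pm_stop("prospmatch_input_error", "covariate(s) not present in both groups: %s",
            paste(missing_cov, collapse = ", "))
  rows <- list()
  for (i in seq_len(nrow(covariates))) {
    nm <- covariates$name[i]
    kind <- covariates$kind[i]
    x1 <- group1[[nm]]; x2 <- group2[[nm]]
    if (kind == "categorical") {
      levels <- sort(unique(c(as.character(x1[!is.na(x1)]),
                              as.character(x2[!is.na(x2)]))))
      for (lev in levels) {
        rows[[length(rows) + 1L]] <- balance_row(
          paste0(nm, ":", lev), "binary",
          ifelse(is.na(x1), NA, as.character(x1) == lev),
          ifelse(is.na(x2), NA, as.character(x2) == lev))
      }
    } else if (kind %in% c("continuous", "binary")) {
      rows[[length(rows) + 1L]] <- balance_row(nm, kind, x1, x2)
    } else {
      pm_stop("prospmatch_config_error", "unknown covariate kind '%s' for '%s'",
              kind, nm)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("pm_balance_table", "data.frame")
  out
}

#' @export
print.pm_balance_table <- function(x, digits = 2, ...) {
  shown <- as.data.frame(x)
  for (col in intersect(c("group1_mean", "group1_sd", "group2_mean",
                          "group2_sd", "smd"), names(shown)))
    shown[[col]] <- round(shown[[col]], digits)
  print(shown, row.names = FALSE)
  if (any(x$flagged, na.rm = TRUE))
    cat("Rows with |SMD| >= 0.2 are flagged.\n")
  invisible(x)
}

#' Render a balance table as plain-text markdown
#'
#' A baseline-characteristics style report: one row per covariate with
#' mean (SD) or N-free proportion summaries and the SMD to 2 decimals.
#'
#' @param x A `pm_balance_table`.
#' @param group_labels Length-2 character labels for the columns.
#' @return Character vector of markdown lines.
#' @export
format_balance_markdown <- function(x, group_labels = c("Treated", "Control")) {
  fmt <- function(m, s, kind) {
    if (is.na(m)) return("--")
    if (kind == "binary") sprintf("%.1f%%", 100 * m) else sprintf("%.1f (%.1f)", m, s)
  }
  lines <- c(
    sprintf("| Characteristic | %s | %s | SMD |", group_labels[1], group_labels[2]),
    "|---|---|---|---|")
  for (i in seq_len(nrow(x))) {
    lines <- c(lines, sprintf(
      "| %s | %s | %s | %s |",
      x$covariate[i],
      fmt(x$group1_mean[i], x$group1_sd[i], x$kind[i]),
      fmt(x$group2_mean[i], x$group2_sd[i], x$kind[i]),
      if (is.na(x$smd[i])) "undefined" else sprintf("%.2f", x$smd[i])))
  }
  lines
}
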