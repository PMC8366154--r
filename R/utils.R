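`%||%` <- function(a, b) if (is.null(a)) b else a

# Structured error helper: every prospmatch condition carries a specific class
# plus "prospmatch_error" so callers can catch broadly or narrowly.
pm_stop <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "prospmatch_error")))
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    pm_stop("prospmatch_config_error",
            "'%s' must be a single probability in [0, 1]", name)
  invisible(as.numeric(x))
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    pm_stop("prospmatch_config_error",
            "'%s' must be a single integer >= %s", name, format(min))
  invisible(as.integer(x))
}

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max)
    pm_stop("prospmatch_config_error",
            "'%s' must be a single number in [%s, %s]", name, format(min), format(max))
  invisible(as.numeric(x))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Coerce YAML/JSON scalar lists back to named numeric vectors.
as_named_numeric <- function(x, name) {
  if (is.list(x)) x <- unlist(x)
  if (!is.numeric(x)) pm_stop("prospmatch_config_error", "'%s' must be numeric", name)
  x
}

#' Derive a stage-specific random seed from one master seed
#'
#' A single study seed is split into deterministic per-stage substreams so each
#' pipeline stage (cohort generation, recruitment, power simulation, ...) is
#' independently reproducible. The result is always a valid 32-bit integer seed.
#'
#' @param seed Master integer seed.
#' @param stage One of `"cohort"`, `"eligibility"`, `"matching"`,
#'   `"recruitment"`, `"power"`, `"outcomes"`.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stages <- c(cohort = 1, eligibility = 2, matching = 3,
              recruitment = 4, power = 5, outcomes = 6)
  if (!is.character(stage) || length(stage) != 1L || !stage %in% names(stages))
    pm_stop("prospmatch_input_error", "unknown seed stage '%s'", paste(stage, collapse = ","))
  check_number(seed, "seed")
  as.integer(((abs(as.numeric(seed)) %% 100000) * 9973 + stages[[stage]] * 7919) %% 2147483629)
}
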