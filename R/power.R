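#' Specification of the simulation-based power calculation
#'
#' Parameters of the Monte-Carlo sample-size simulation for a two-arm
#' comparison of "days not at home" style zero-inflated counts: outcomes are
#' drawn from a zero-inflated Poisson (ZIP) or zero-inflated negative binomial
#' (ZINB) model whose non-zero-component rate is solved so the *marginal* mean
#' equals each arm's target (`lambda = mean / (1 - pi)`), with an optional
#' shared multiplicative log-normal facility frailty whose variance is solved
#' from the target intra-class correlation.
#'
#' The zero-inflation probability, dispersion, ICC and analysis model are
#' reconstruction choices, not quantities fixed by the motivating design (see
#' the methods vignette); all are exposed here.
#'
#' @param n_dyads Dyads (patients per arm), default 275.
#' @param n_replicates Monte-Carlo replicates, default 1000.
#' @param mean_control,mean_treated Marginal mean counts per arm (defaults
#'   5.5 and 4.0 days not at home over the outcome interval).
#' @param family `"zip"` or `"zinb"`.
#' @param zero_inflation Structural-zero probability (both arms), default 0.3.
#' @param nb_dispersion ZINB size parameter theta; when `NULL` it is solved
#'   with [calibrate_nb_dispersion()] so the ZINB marginal variance is
#'   `variance_ratio` times the ZIP variance at the control mean.
#' @param variance_ratio Target ZINB/ZIP marginal variance ratio used when
#'   `nb_dispersion` is `NULL` (default 12).
#' @param n_clusters Number of facilities (default 57).
#' @param icc Target within-facility intra-class correlation of the outcome
#'   (default 0.05; set 0 or `n_clusters = 1` for independence).
#' @param alpha Two-sided significance level (default 0.05).
#' @param analysis Analysis model; `"zi_regression"` fits a zero-inflated
#'   count regression with a treatment indicator and uses a cluster-robust
#'   Wald test when `n_clusters > 1`.
#' @param seed Integer seed.
#' @return A validated list of class `pm_power_spec`.
#' @export
power_spec <- function(n_dyads = 275,
                       n_replicates = 1000,
                       mean_control = 5.5,
                       mean_treated = 4.0,
                       family = c("zip", "zinb"),
                       zero_inflation = 0.3,
                       nb_dispersion = NULL,
                       variance_ratio = 12,
                       n_clusters = 57,
                       icc = 0.05,
                       alpha = 0.05,
                       analysis = "zi_regression",
                       seed = 1) {
  family <- match.arg(family)
  spec <- list(
    n_dyads = check_count(n_dyads, "n_dyads", min = 2),
    n_replicates = check_count(n_replicates, "n_replicates", min = 1),
    mean_control = check_number(mean_control, "mean_control", min = 0),
    mean_treated = check_number(mean_treated, "mean_treated", min = 0),
    family = family,
    zero_inflation = check_prob(zero_inflation, "zero_inflation"),
    nb_dispersion = nb_dispersion,
    variance_ratio = check_number(variance_ratio, "variance_ratio", min = 1 + 1e-9),
    n_clusters = check_count(n_clusters, "n_clusters", min = 1),
    icc = check_number(icc, "icc", min = 0, max = 1 - 1e-9),
    alpha = check_prob(alpha, "alpha"),
    analysis = analysis,
    seed = check_number(seed, "seed")
  )
  if (!identical(analysis, "zi_regression"))
    pm_stop("prospmatch_config_error", "unknown analysis '%s'", analysis)
  if (spec$zero_inflation >= 1 &&
      (spec$mean_control > 0 || spec$mean_treated > 0))
    pm_stop("prospmatch_config_error",
            "infeasible spec: zero_inflation of 1 with a positive target mean")
  if (family == "zinb") {
    if (is.null(spec$nb_dispersion))
      spec$nb_dispersion <- calibrate_nb_dispersion(spec$mean_control,
                                                    spec$zero_inflation,
                                                    spec$variance_ratio)
    check_number(spec$nb_dispersion, "nb_dispersion", min = 1e-12)
  }
  structure(spec, class = "pm_power_spec")
}

#' Closed-form ZIP marginal moments
#'
#' For a zero-inflated Poisson with structural-zero probability `pi` and
#' marginal mean `mu` (Poisson rate `lambda = mu / (1 - pi)`):
#' `E[Y] = (1 - pi) lambda = mu` and
#' `Var[Y] = (1 - pi) lambda (1 + pi lambda)`.
#'
#' @param mean Marginal mean.
#' @param zero_inflation Structural-zero probability in `[0, 1)`.
#' @return Named vector `c(mean, var)`.
#' @export
zip_moments <- function(mean, zero_inflation) {
  check_number(mean, "mean", min = 0)
  check_number(zero_inflation, "zero_inflation", min = 0, max = 1 - 1e-12)
  lambda <- mean / (1 - zero_inflation)
  c(mean = mean, var = (1 - zero_inflation) * lambda * (1 + zero_inflation * lambda))
}

#' Solve the ZINB dispersion for a target variance inflation
#'
#' The ZINB marginal variance at marginal mean `mu` is
#' `(1 - pi) lambda (1 + lambda (pi + 1/theta))`; setting it equal to
#' `ratio` times the ZIP variance `(1 - pi) lambda (1 + pi lambda)` gives the
#' closed form `theta = lambda / ((ratio - 1) (1 + pi lambda))`.
#'
#' @param mean Marginal mean.
#' @param zero_inflation Structural-zero probability.
#' @param ratio Target ZINB/ZIP variance ratio (> 1), e.g. 12.
#' @return The negative-binomial size parameter theta.
#' @export
calibrate_nb_dispersion <- function(mean, zero_inflation, ratio = 12) {
  check_number(mean, "mean", min = 1e-12)
  check_number(zero_inflation, "zero_inflation", min = 0, max = 1 - 1e-12)
  check_number(ratio, "ratio", min = 1 + 1e-9)
  lambda <- mean / (1 - zero_inflation)
  lambda / ((ratio - 1) * (1 + zero_inflation * lambda))
}

# Variance of the shared log-normal frailty implied by the target ICC.
# With u ~ N(-s/2, s) (so E[e^u] = 1), outcomes in a cluster share
# cov = mu^2 (e^s - 1), and the total variance is the expected conditional
# variance plus that between-cluster part; s solves cov/total = icc.
icc_to_sigma2 <- function(spec) {
  if (spec$icc <= 0 || spec$n_clusters <= 1) return(0)
  mu <- spec$mean_control
  pi <- spec$zero_inflation
  lambda <- mu / (1 - pi)
  vw <- function(s) {
    if (spec$family == "zip") mu + pi * lambda * mu * exp(s)
    else mu + lambda * mu * (pi + 1 / spec$nb_dispersion) * exp(s)
  }
  f <- function(s) {
    vb <- mu^2 * (exp(s) - 1)
    vb / (vb + vw(s)) - spec$icc
  }
  root <- tryCatch(stats::uniroot(f, c(1e-12, 20), tol = 1e-12)$root,
                   error = function(e)
                     pm_stop("prospmatch_config_error",
                             "requested icc %.3f is not attainable under this outcome model",
                             spec$icc))
  root
}

# One arm of counts given per-observation log-frailties (uses the current
# RNG stream; callers manage seeding).
draw_zi_counts <- function(n, mean, spec, log_frailty = 0) {
  if (spec$zero_inflation >= 1) {
    if (mean > 0)
      pm_stop("prospmatch_config_error",
              "infeasible spec: zero_inflation of 1 with a positive target mean")
    return(integer(n))
  }
  lambda <- mean / (1 - spec$zero_inflation) * exp(log_frailty)
  y <- if (spec$family == "zip") {
    stats::rpois(n, lambda)
  } else {
    stats::rnbinom(n, size = spec$nb_dispersion, mu = lambda)
  }
  y[stats::runif(n) < spec$zero_inflation] <- 0L
  y
}

#' Generate one arm of zero-inflated count outcomes
#'
#' Draws `n` counts for one arm under the spec's outcome model, including the
#' facility frailty when clustering is configured. Deterministic given
#' `spec$seed`.
#'
#' @param spec A [power_spec()].
#' @param arm `"control"` or `"treated"`.
#' @param n Number of observations (defaults to `spec$n_dyads`).
#' @return Integer vector of counts.
#' @export
generate_outcomes <- function(spec, arm = c("control", "treated"), n = NULL) {
  arm <- match.arg(arm)
  if (!inherits(spec, "pm_power_spec")) spec <- do.call(power_spec, spec)
  n <- n %||% spec$n_dyads
  set.seed(derive_seed(spec$seed, "outcomes"))
  mu <- if (arm == "control") spec$mean_control else spec$mean_treated
  s2 <- icc_to_sigma2(spec)
  cl <- rep_len(seq_len(spec$n_clusters), n)
  u <- if (s2 > 0) stats::rnorm(spec$n_clusters, -s2 / 2, sqrt(s2)) else
    rep(0, spec$n_clusters)
  draw_zi_counts(n, mu, spec, u[cl])
}

# One replicate trial: both arms with shared facility frailties (dyads at the
# same facility). Uses the current RNG stream.
generate_trial <- function(spec, n_dyads = spec$n_dyads, sigma2 = icc_to_sigma2(spec)) {
  cl <- rep_len(seq_len(spec$n_clusters), n_dyads)
  u <- if (sigma2 > 0) stats::rnorm(spec$n_clusters, -sigma2 / 2, sqrt(sigma2)) else
    rep(0, spec$n_clusters)
  y_c <- draw_zi_counts(n_dyads, spec$mean_control, spec, u[cl])
  y_t <- draw_zi_counts(n_dyads, spec$mean_treated, spec, u[cl])
  data.frame(y = c(y_c, y_t),
             treat = rep(c(0L, 1L), each = n_dyads),
             cluster = rep(cl, 2L),
             dyad = rep(seq_len(n_dyads), 2L))
}

# Per-observation log-likelihood of the zero-inflated count regression
# (log-link rate regression on treat; constant zero-inflation logit).
zi_loglik_obs <- function(par, y, X, family, is0) {
  lambda <- exp(drop(X %*% par[1:2]))
  p <- stats::plogis(par[3])
  ll <- numeric(length(y))
  if (family == "zip") {
    ll[is0] <- log(p + (1 - p) * exp(-lambda[is0]))
    ll[!is0] <- log1p(-p) + stats::dpois(y[!is0], lambda[!is0], log = TRUE)
  } else {
    size <- exp(par[4])
    ll[is0] <- log(p + (1 - p) * stats::dnbinom(0, size = size, mu = lambda[is0]))
    ll[!is0] <- log1p(-p) +
      stats::dnbinom(y[!is0], size = size, mu = lambda[!is0], log = TRUE)
  }
  ll
}

# Per-observation score matrix by central finite differences.
zi_score_matrix <- function(par, y, X, family, is0) {
  k <- length(par)
  S <- matrix(0, length(y), k)
  h <- 1e-6 * pmax(1, abs(par))
  for (j in seq_len(k)) {
    up <- par; up[j] <- up[j] + h[j]
    dn <- par; dn[j] <- dn[j] - h[j]
    S[, j] <- (zi_loglik_obs(up, y, X, family, is0) -
                 zi_loglik_obs(dn, y, X, family, is0)) / (2 * h[j])
  }
  S
}

#' Fit a zero-inflated count regression with a treatment indicator
#'
#' Maximum-likelihood fit of a zero-inflated Poisson or negative-binomial
#' regression with a log-link rate model `log lambda = b0 + b1 treat` and a
#' constant zero-inflation probability (the ZINB dispersion is estimated on
#' the log scale). With a `cluster` vector the variance of the treatment
#' coefficient is a CR1-type cluster-robust sandwich (per-cluster score sums,
#' small-sample factor G/(G-1)) and the Wald test uses a t reference with
#' G - 1 degrees of freedom; otherwise the model-based ML variance and a
#' normal reference are used.
#'
#' @param y Nonnegative integer outcomes.
#' @param treat 0/1 treatment indicator.
#' @param cluster Optional cluster ids.
#' @param family `"zip"` or `"zinb"`.
#' @return List: `coefficients` (rate intercept, treatment log-rate-ratio,
#'   zero-inflation logit, and `log_theta` for ZINB), `treat_estimate`, `se`,
#'   `statistic`, `df`, `p_value`, `vcov`, `logLik`, `convergence`.
#' @export
fit_zi_count <- function(y, treat, cluster = NULL, family = c("zip", "zinb")) {
  family <- match.arg(family)
  if (length(y) != length(treat))
    pm_stop("prospmatch_input_error", "'y' and 'treat' must have equal length")
  if (any(y < 0) || any(y != floor(y)))
    pm_stop("prospmatch_input_error", "'y' must contain nonnegative integers")
  X <- cbind(1, as.numeric(treat))
  is0 <- y == 0
  if (all(is0))
    pm_stop("prospmatch_fit_error", "degenerate outcome: all counts are zero")
  ybar <- mean(y)
  p0_excess <- (mean(is0) - exp(-ybar)) / max(1e-6, 1 - exp(-ybar))
  start <- c(log(max(mean(y[!is0]), 0.1)), 0,
             stats::qlogis(clamp(p0_excess, 0.02, 0.95)))
  if (family == "zinb") start <- c(start, 0)
  negll <- function(par) -sum(zi_loglik_obs(par, y, X, family, is0))
  opt <- stats::optim(start, negll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  if (opt$convergence != 0)
    pm_stop("prospmatch_fit_error", "optimizer failed to converge (code %d)",
            opt$convergence)
  H <- stats::optimHess(opt$par, negll)
  A <- tryCatch(solve(H), error = function(e)
    pm_stop("prospmatch_fit_error", "singular information matrix"))
  if (!is.null(cluster) && length(unique(cluster)) > 1L) {
    S <- zi_score_matrix(opt$par, y, X, family, is0)
    Sg <- rowsum(S, cluster)
    G <- nrow(Sg)
    B <- crossprod(Sg) * G / (G - 1)
    V <- A %*% B %*% A
    df <- G - 1
  } else {
    V <- A
    df <- Inf
  }
  est <- opt$par[2]
  se <- sqrt(V[2, 2])
  if (!is.finite(se) || se <= 0)
    pm_stop("prospmatch_fit_error", "non-finite standard error")
  stat <- est / se
  coefs <- c(rate_intercept = opt$par[1], treat = est, zi_logit = opt$par[3])
  if (family == "zinb") coefs <- c(coefs, log_theta = opt$par[4])
  list(coefficients = coefs, treat_estimate = est, se = se, statistic = stat,
       df = df, p_value = 2 * stats::pt(-abs(stat), df), vcov = V,
       logLik = -opt$value, convergence = opt$convergence)
}

#' Estimate power by Monte-Carlo simulation
#'
#' For each replicate, generates a two-arm trial under the spec's outcome
#' model (shared facility frailties across arms when clustering is on), fits
#' the zero-inflated count regression with [fit_zi_count()] (cluster-robust
#' when `n_clusters > 1`), and records rejection of the null of no arm
#' difference at `alpha`. Replicates whose fit fails are excluded and counted;
#' more than 10% failures raises a simulation error. Deterministic given
#' `spec$seed`.
#'
#' @param spec A [power_spec()].
#' @return A list of class `pm_power_result`: `power_estimate`, `mc_se`
#'   (`sqrt(p (1 - p) / R)` over the used replicates), `n_replicates_used`,
#'   `rejections` (logical per used replicate), `n_failed`, `spec`.
#' @export
estimate_power <- function(spec = power_spec()) {
  if (!inherits(spec, "pm_power_spec")) spec <- do.call(power_spec, spec)
  set.seed(derive_seed(spec$seed, "power"))
  sigma2 <- icc_to_sigma2(spec)
  rejections <- logical(0)
  n_failed <- 0L
  for (r in seq_len(spec$n_replicates)) {
    dat <- generate_trial(spec, sigma2 = sigma2)
    fit <- tryCatch(
      fit_zi_count(dat$y, dat$treat,
                   cluster = if (spec$n_clusters > 1L) dat$cluster,
                   family = spec$family),
      error = function(e) NULL)
    if (is.null(fit)) n_failed <- n_failed + 1L
    else rejections <- c(rejections, fit$p_value < spec$alpha)
  }
  if (n_failed > 0.1 * spec$n_replicates)
    pm_stop("prospmatch_simulation_error",
            "%d of %d replicates failed to fit", n_failed, spec$n_replicates)
  p <- mean(rejections)
  structure(list(power_estimate = p,
                 mc_se = sqrt(p * (1 - p) / length(rejections)),
                 n_replicates_used = length(rejections),
                 rejections = rejections,
                 n_failed = n_failed,
                 spec = spec),
            class = "pm_power_result")
}

#' @export
print.pm_power_result <- function(x, ...) {
  cat(sprintf("Estimated power: %.3f (MC SE %.3f) from %d replicates",
              x$power_estimate, x$mc_se, x$n_replicates_used))
  if (x$n_failed > 0L) cat(sprintf("; %d failed fits excluded", x$n_failed))
  cat(sprintf("\n  %s, means %.2f vs %.2f, %d dyads, alpha %.3g\n",
              toupper(x$spec$family), x$spec$mean_control, x$spec$mean_treated,
              x$spec$n_dyads, x$spec$alpha))
  invisible(x)
}

#' Power curve over a grid of sample sizes
#'
#' Runs the power simulation at each dyad count in `n_grid` under common
#' random numbers: each replicate draws one trial at the largest grid size
#' and analyzes nested subsets, so the curve is (near) monotone in n by
#' construction.
#'
#' @param spec A [power_spec()].
#' @param n_grid Increasing vector of dyad counts.
#' @return Data frame: `n`, `power`, `mc_se`.
#' @export
power_curve <- function(spec = power_spec(), n_grid) {
  if (!inherits(spec, "pm_power_spec")) spec <- do.call(power_spec, spec)
  if (length(n_grid) == 0L || is.unsorted(n_grid, strictly = TRUE))
    pm_stop("prospmatch_input_error", "'n_grid' must be strictly increasing")
  set.seed(derive_seed(spec$seed, "power"))
  sigma2 <- icc_to_sigma2(spec)
  n_max <- max(n_grid)
  rej <- matrix(NA, spec$n_replicates, length(n_grid))
  for (r in seq_len(spec$n_replicates)) {
    big <- generate_trial(spec, n_dyads = n_max, sigma2 = sigma2)
    for (k in seq_along(n_grid)) {
      sub <- big[big$dyad <= n_grid[k], , drop = FALSE]
      fit <- tryCatch(
        fit_zi_count(sub$y, sub$treat,
                     cluster = if (spec$n_clusters > 1L) sub$cluster,
                     family = spec$family),
        error = function(e) NULL)
      if (!is.null(fit)) rej[r, k] <- fit$p_value < spec$alpha
    }
  }
  power <- colMeans(rej, na.rm = TRUE)
  used <- colSums(!is.na(rej))
  data.frame(n = n_grid, power = power,
             mc_se = sqrt(power * (1 - power) / used))
}
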