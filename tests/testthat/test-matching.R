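test_that("the exact key ignores distance variables and separates facilities", {
  a <- random_patients(1, seed = 1)
  b <- a
  b$can_score <- a$can_score + 20
  expect_identical(exact_key(a), exact_key(b))
  b2 <- a
  b2$facility_id <- "F99"
  expect_false(exact_key(a) == exact_key(b2))
})

test_that("the age caliper admits 5-year differences and rejects 6-year ones", {
  a <- random_patients(1, seed = 2)
  b <- a
  b$patient_id <- "Q0001"
  a$age <- 80
  b$age <- 85
  expect_true(exact_compatible(a, b))
  b$age <- 86
  expect_false(exact_compatible(a, b))
})

test_that("exact compatibility is symmetric over random pairs", {
  p <- random_patients(40, seed = 3, n_facilities = 2)
  for (k in 1:20) {
    i <- sample(40, 2)
    a <- p[i[1], ]; b <- p[i[2], ]
    expect_identical(exact_compatible(a, b), exact_compatible(b, a))
  }
})

test_that("the standardizer reproduces hand-computed moments and normalizes its fitting population", {
  controls <- random_patients(2, seed = 4)
  controls$age <- c(70, 90)
  std <- fit_standardizer(controls)
  expect_equal(unname(std$means["age"]), 80)
  expect_equal(unname(std$sds["age"]), sqrt(200), tolerance = 1e-12)

  pop <- random_patients(200, seed = 5)
  std2 <- fit_standardizer(pop)
  z <- standardize_records(std2, pop)
  expect_equal(unname(colMeans(z)), rep(0, 4), tolerance = 1e-10)
  expect_equal(unname(apply(z, 2, sd)), rep(1, 4), tolerance = 1e-10)
})

test_that("a zero-variance variable is a degenerate error naming the variable", {
  controls <- random_patients(5, seed = 6)
  controls$jfi_score <- 4
  expect_error(fit_standardizer(controls), "jfi_score",
               class = "prospmatch_degenerate_error")
})

test_that("the distance is zero at identity, symmetric, and matches element-by-element arithmetic", {
  pop <- random_patients(100, seed = 7)
  std <- fit_standardizer(pop)
  a <- pop[1, ]
  b <- a
  b$patient_id <- "X0001"
  expect_equal(match_distance(a, b, std), 0)

  vars <- c("age", "n_hospitalizations", "can_score", "jfi_score")
  set.seed(8)
  for (k in 1:20) {
    i <- sample(100, 2)
    t1 <- pop[i[1], ]; c1 <- pop[i[2], ]
    d <- match_distance(t1, c1, std)
    expect_equal(d, match_distance(c1, t1, std), tolerance = 1e-14)
    # independent recomputation: standardize, difference, square, sum, root
    acc <- 0
    for (v in vars) {
      zt <- (t1[[v]] - std$means[[v]]) / std$sds[[v]]
      zc <- (c1[[v]] - std$means[[v]]) / std$sds[[v]]
      acc <- acc + (zt - zc)^2
    }
    expect_equal(d, sqrt(acc), tolerance = 1e-12)
  }
})

test_that("the full-covariance mode is symmetric and zero at identity", {
  pop <- random_patients(120, seed = 9)
  std <- fit_standardizer(pop)
  a <- pop[3, ]; b <- pop[4, ]
  expect_equal(match_distance(a, b, std, mode = "full"),
               match_distance(b, a, std, mode = "full"), tolerance = 1e-12)
  b2 <- a; b2$patient_id <- "Y0001"
  expect_equal(match_distance(a, b2, std, mode = "full"), 0)
})

test_that("an unfitted standardizer is a state error", {
  a <- random_patients(1, seed = 10)
  expect_error(standardize_records(list(), a), class = "prospmatch_state_error")
})

test_that("tier assignment follows the half-open priority ladder", {
  expect_identical(assign_tiers(c(0.05, 0.10, 0.30)), c(1L, 2L, 3L))
  expect_identical(assign_tiers(c(0.0, 0.249999, 0.5, 1.999, 2.0, 50)),
                   c(1L, 2L, 4L, 5L, 6L, 6L))
  expect_error(assign_tiers(0.2, ladder = c(0.5, 0.1)),
               "ladder must be increasing", class = "prospmatch_config_error")
})

test_that("pool construction respects compatibility, the minimum-pool rule and deterministic ordering", {
  controls <- random_patients(200, seed = 11, n_facilities = 2)
  std <- fit_standardizer(controls)
  treated <- random_patients(1, seed = 12, prefix = "T")
  treated$facility_id <- "F09"  # no same-facility controls
  pool <- build_pool(treated, controls, standardizer = std)
  expect_equal(nrow(pool$candidates), 0L)
  expect_false(pool$eligible_for_recruitment)

  # a pool below the minimum size is flagged not recruitable
  treated2 <- controls[1, ]
  treated2$patient_id <- "T0001"
  few <- controls[2:5, ]
  few$facility_id <- treated2$facility_id
  few$race <- treated2$race; few$female <- treated2$female
  few$advance_directive <- treated2$advance_directive
  few$dementia <- treated2$dementia
  few$any_hospitalization <- treated2$any_hospitalization
  few$n_hospitalizations <- as.integer(treated2$any_hospitalization)
  few$age <- treated2$age
  pool2 <- build_pool(treated2, few, standardizer = std)
  expect_equal(nrow(pool2$candidates), 4L)
  expect_false(pool2$eligible_for_recruitment)

  # determinism and tie-break by control id
  tie <- rbind(few, few)
  tie$patient_id <- sprintf("C%04d", 1:8)
  tie$can_score <- treated2$can_score + c(3, -3, 3, -3, 3, -3, 3, -3)
  tie$jfi_score <- treated2$jfi_score
  tie$age <- treated2$age
  tie$n_hospitalizations <- as.integer(treated2$any_hospitalization)
  pool3a <- build_pool(treated2, tie, standardizer = std)
  pool3b <- build_pool(treated2, tie, standardizer = std)
  expect_identical(pool3a$candidates, pool3b$candidates)
  d <- pool3a$candidates$distance
  same <- abs(d - d[1]) < 1e-12
  expect_true(all(diff(order(pool3a$candidates$control_id[same])) > 0))
})

test_that("pools equal exhaustive enumeration on a 200-control instance", {
  controls <- random_patients(200, seed = 13, n_facilities = 2)
  std <- fit_standardizer(controls)
  params <- match_params()
  treated <- controls[7, ]
  treated$patient_id <- "T0001"
  pool <- build_pool(treated, controls, params, std)

  # brute force over every control
  vars <- c("age", "n_hospitalizations", "can_score", "jfi_score")
  rows <- list()
  for (i in seq_len(nrow(controls))) {
    c1 <- controls[i, ]
    if (c1$patient_id == treated$patient_id) next
    if (!(c1$facility_id == treated$facility_id && c1$race == treated$race &&
          c1$female == treated$female &&
          c1$advance_directive == treated$advance_directive &&
          c1$dementia == treated$dementia &&
          c1$any_hospitalization == treated$any_hospitalization &&
          abs(c1$age - treated$age) <= 5)) next
    acc <- 0
    for (v in vars)
      acc <- acc + ((treated[[v]] - c1[[v]]) / std$sds[[v]])^2
    d <- sqrt(acc)
    tier <- if (d < 0.1) 1L else if (d < 0.25) 2L else if (d < 0.5) 3L else
      if (d < 1) 4L else if (d < 2) 5L else 6L
    rows[[length(rows) + 1L]] <- data.frame(control_id = c1$patient_id,
                                            distance = d, tier = tier,
                                            stringsAsFactors = FALSE)
  }
  oracle <- do.call(rbind, rows)
  oracle <- oracle[order(oracle$tier, oracle$distance, oracle$control_id), ]
  expect_identical(pool$candidates$control_id, oracle$control_id)
  expect_equal(pool$candidates$distance, oracle$distance, tolerance = 1e-12)
  expect_identical(pool$candidates$tier, oracle$tier)
  # tiers are non-decreasing in distance within the sorted pool
  expect_true(all(diff(pool$candidates$tier) >= 0))
})

test_that("pool statistics reproduce hand counts", {
  pools <- list(make_pool(n = 3, "T001"), make_pool(n = 5, treated_id = "T002"),
                make_pool(n = 129, treated_id = "T003"))
  s <- pool_statistics(pools, min_pool_size = 5)
  expect_equal(s$n_lacking, 1L)
  expect_equal(s$fraction_lacking, 1 / 3)
  expect_equal(s$median_size, 5)
  expect_equal(s$size_range, c(3L, 129L))

  s2 <- pool_statistics(list(make_pool(n = 8)), min_pool_size = 5)
  expect_equal(s2$fraction_lacking, 0)
  expect_equal(s2$median_size, 8)
  expect_error(pool_statistics(list()), class = "prospmatch_degenerate_error")
})
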