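test_that("certain enrollment forms a tier-1 dyad in the opening week", {
  pool <- make_pool(n = 5)
  rec <- simulate_recruitment(list(pool),
                              recruitment_params(p_enroll_control = 1, seed = 1))
  expect_equal(nrow(rec$dyads), 1L)
  expect_equal(rec$dyads$tier_of_enrollment, 1L)
  expect_lte(rec$dyads$days_between_enrollments, 7L)
  expect_equal(length(rec$unmatched), 0L)
})

test_that("impossible enrollment leaves every treated patient unmatched after the window closes", {
  pools <- list(make_pool(n = 6, treated_id = "T001"),
                make_pool(n = 6, treated_id = "T002"))
  rec <- simulate_recruitment(pools,
                              recruitment_params(p_enroll_control = 0, seed = 2))
  expect_equal(nrow(rec$dyads), 0L)
  expect_setequal(rec$unmatched, c("T001", "T002"))
  closed <- rec$log[rec$log$kind == "window_closed", ]
  expect_equal(sort(closed$treated_id), c("T001", "T002"))
  expect_true(all(closed$week == 5))
})

test_that("an empty pool list and non-recruitable pools yield zero dyads without error", {
  expect_equal(nrow(simulate_recruitment(list())$dyads), 0L)
  rec <- simulate_recruitment(list(make_pool(n = 3)),
                              recruitment_params(p_enroll_control = 1, seed = 3))
  expect_equal(nrow(rec$dyads), 0L)
  expect_equal(sum(rec$log$kind == "enrolled_treated"), 0L)
})

test_that("the matched fraction matches the geometric closed form (sequential weekly contacts)", {
  # 5 tier-1 candidates, 1 contact/week, 5-week window: 5 trials at p = 0.2
  params <- function(s) recruitment_params(p_enroll_control = 0.2,
                                           contacts_per_week = 1, seed = s)
  hits <- vapply(1:2000, function(s)
    nrow(simulate_recruitment(list(make_pool(n = 5)), params(s))$dyads) == 1L,
    logical(1))
  p_true <- 1 - 0.8^5
  mc_se <- sqrt(p_true * (1 - p_true) / length(hits))
  expect_lt(abs(mean(hits) - p_true), 3 * mc_se)
})

test_that("escalation, window and conservation laws hold on the event log", {
  set.seed(4)
  # 60 treated sharing a common candidate supply to force contention
  pools <- lapply(1:60, function(i) {
    n <- sample(5:12, 1)
    pool <- make_pool(n = n, treated_id = sprintf("T%03d", i),
                      tiers = sample(1:4, n, replace = TRUE),
                      distances = sort(runif(n, 0, 2)),
                      pull_week = sample(0:3, 1))
    # overlap candidate ids across pools
    pool$candidates$control_id <- sprintf("C%03d", sample(1:40, n))
    pool$candidates <- pool$candidates[order(pool$candidates$tier,
                                             pool$candidates$distance,
                                             pool$candidates$control_id), ]
    pool
  })
  params <- recruitment_params(p_enroll_control = 0.5, contacts_per_week = 2,
                               seed = 5, target_dyads = 40)
  rec <- simulate_recruitment(pools, params)
  dy <- rec$dyads
  log <- rec$log

  # conservation: each patient id in at most one dyad
  expect_false(anyDuplicated(dy$treated_id) > 0)
  expect_false(anyDuplicated(dy$control_id) > 0)
  # stopping law
  expect_lte(nrow(dy), params$target_dyads)
  # enrolled controls are never contacted again
  contacts <- log[log$kind == "contact_attempt", ]
  enroll_week <- tapply(log$week[log$kind == "enrolled_control"],
                        log$control_id[log$kind == "enrolled_control"], min)
  for (cid in names(enroll_week))
    expect_true(all(contacts$week[contacts$control_id == cid] <= enroll_week[[cid]]))

  # window and escalation laws relative to each treated enrollment week
  w0 <- setNames(log$week[log$kind == "enrolled_treated"],
                 log$treated_id[log$kind == "enrolled_treated"])
  formed <- log[log$kind == "dyad_formed", ]
  expect_true(all(formed$week - w0[formed$treated_id] < params$match_window))
  expect_true(all(contacts$week - w0[contacts$treated_id] >=
                    (contacts$tier - 1) * params$escalation_interval))

  # tier recorded in the dyad equals the pool's tier for that control
  for (i in seq_len(nrow(dy))) {
    pool <- pools[[which(vapply(pools, `[[`, character(1), "treated_id") ==
                           dy$treated_id[i])]]
    expect_equal(dy$tier_of_enrollment[i],
                 pool$candidates$tier[pool$candidates$control_id == dy$control_id[i]])
  }

  # full replay: the event log reconstructs the dyad list
  replay <- data.frame(treated_id = formed$treated_id,
                       control_id = formed$control_id,
                       tier_of_enrollment = formed$tier,
                       days_between_enrollments =
                         7L * (formed$week - unname(w0[formed$treated_id])),
                       stringsAsFactors = FALSE)
  expect_equal(replay, dy[names(replay)])
})

test_that("the matched fraction is monotone in the control enrollment probability", {
  mean_dyads <- function(p) {
    mean(vapply(1:30, function(s) {
      pools <- lapply(1:20, function(i)
        make_pool(n = 6, treated_id = sprintf("T%03d", i), prefix = sprintf("K%02d", i)))
      nrow(simulate_recruitment(pools,
                                recruitment_params(p_enroll_control = p,
                                                   seed = s))$dyads)
    }, numeric(1)))
  }
  m <- vapply(c(0.05, 0.2, 0.8), mean_dyads, numeric(1))
  expect_true(all(diff(m) > 0))
  # certain enrollment with ample pools matches everyone
  pools <- lapply(1:20, function(i)
    make_pool(n = 6, treated_id = sprintf("T%03d", i), prefix = sprintf("K%02d", i)))
  rec <- simulate_recruitment(pools, recruitment_params(p_enroll_control = 1, seed = 1))
  expect_equal(nrow(rec$dyads), 20L)
})

test_that("recruitment is deterministic given the seed", {
  pools <- lapply(1:10, function(i)
    make_pool(n = 8, treated_id = sprintf("T%03d", i), prefix = sprintf("K%02d", i)))
  a <- simulate_recruitment(pools, recruitment_params(seed = 11))
  b <- simulate_recruitment(pools, recruitment_params(seed = 11))
  expect_identical(a$dyads, b$dyads)
  expect_identical(a$log, b$log)
})

test_that("recruitment summaries reproduce hand counts", {
  dy <- data.frame(treated_id = sprintf("T%03d", 1:4),
                   control_id = sprintf("C%03d", 1:4),
                   tier_of_enrollment = c(1L, 1L, 2L, 3L),
                   days_between_enrollments = c(0L, 7L, 30L, 7L),
                   distance = c(0.01, 0.02, 0.2, 0.4),
                   stringsAsFactors = FALSE)
  s <- recruitment_summary(dy)
  expect_equal(unname(s$tier_distribution[c("1", "2", "3")]), c(50, 25, 25))
  expect_equal(s$median_days_between, 7)
  expect_true(is.na(s$fraction_matched))

  s1 <- recruitment_summary(dy[1:2, ])
  expect_equal(unname(s1$tier_distribution), 100)

  s3 <- recruitment_summary(data.frame(treated_id = character(0),
                                       control_id = character(0),
                                       tier_of_enrollment = integer(0),
                                       days_between_enrollments = integer(0)))
  expect_equal(s3$n_dyads, 0L)
  expect_equal(length(s3$tier_distribution), 0L)

  expect_equal(recruitment_summary(data.frame(
    treated_id = "a", control_id = "b", tier_of_enrollment = 1L,
    days_between_enrollments = c(0L)))$median_days_between, 0)
  md <- recruitment_summary(data.frame(
    treated_id = letters[1:3], control_id = LETTERS[1:3],
    tier_of_enrollment = c(1L, 1L, 1L),
    days_between_enrollments = c(0L, 7L, 30L)))
  expect_equal(md$median_days_between, 7)
})
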