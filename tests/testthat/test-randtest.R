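test_that("block counts follow the signed-offset block definitions", {
  params <- test_params()
  t0 <- ts_utc("2020-01-05 12:00:00")
  prey <- mk_det(c(
    "2020-01-02 13:00:00", # -71 h -> [-72,-48)
    "2020-01-04 06:00:00", # -30 h -> [-48,-24)
    "2020-01-05 18:00:00", # +6 h  -> (0,24]
    "2020-01-06 18:00:00"  # +30 h -> (24,48]
  ))
  expect_equal(block_counts(prey, t0, params)$count, c(1L, 1L, 0L, 1L, 1L, 0L))
  expect_equal(block_counts(empty_det(), t0, params)$count, rep(0L, 6))
  # a prey detection exactly at t0 belongs to no block
  expect_equal(block_counts(mk_det("2020-01-05 12:00:00"), t0, params)$count,
               rep(0L, 6))
  # boundary membership: -72 h is inside the first block, +72 h inside the
  # last, +72 h + 1 min is outside
  edge <- mk_det(c("2020-01-02 12:00:00", "2020-01-08 12:00:00",
                   "2020-01-08 12:01:00"))
  expect_equal(block_counts(edge, t0, params)$count, c(1L, 0L, 0L, 0L, 0L, 1L))
})

test_that("block counting matches direct enumeration on random patterns", {
  params <- test_params()
  t0 <- ts_utc("2020-02-15 07:30:00")
  for (seed in 1:10) {
    set.seed(seed)
    prey_t <- t0 + floor(runif(60, -100 * 3600, 100 * 3600))
    prey <- tibble::tibble(site_id = "S1", camera_id = "C1",
                           roll_id = "C1-R1", species = "baboon",
                           timestamp = prey_t)
    expect_equal(block_counts(prey, t0, params)$count,
                 count_blocks_direct(prey_t, t0))
  }
})

test_that("eligible dates span the roll minus both margins", {
  params <- test_params()
  roll90 <- mk_rolls(end = "2020-03-31 00:00:00")
  d <- eligible_dates(roll90, "12:00", params)
  expect_true(length(d) %in% c(84, 85))
  expect_true(all(d >= as.Date("2020-01-04") & d <= as.Date("2020-03-28")))

  roll30 <- mk_rolls(end = "2020-01-31 00:00:00")
  expect_true(length(eligible_dates(roll30, "12:00", params)) %in% c(24, 25))

  short <- mk_rolls(end = "2020-01-05 00:00:00")
  expect_length(eligible_dates(short, "12:00", params), 0)
})

test_that("randomization preserves event counts and clock times exactly", {
  roll <- mk_rolls(end = "2020-03-31 00:00:00")
  ev <- mk_det(c("2020-01-20 03:15:00", "2020-02-01 14:50:00",
                 "2020-03-10 22:05:00"), species = "lion")
  out <- randomize_once(ev, roll, test_params(), seed = 5)
  expect_equal(nrow(out), nrow(ev))
  expect_equal(sort(as.numeric(out$timestamp) %% 86400),
               sort(as.numeric(ev$timestamp) %% 86400))
  # relocated times stay inside the margin-trimmed roll
  expect_true(all(out$timestamp >= ts_utc("2020-01-04 00:00:00") &
                    out$timestamp <= ts_utc("2020-03-28 23:59:59")))
})

test_that("a single eligible date forces the relocation, and draws are with replacement", {
  # margin-trimmed window of exactly one day
  roll <- mk_rolls(end = "2020-01-08 00:00:00") # 7-day roll, 72 h margins
  ev <- mk_det(c("2020-01-04 09:00:00", "2020-01-04 15:00:00"),
               species = "lion")
  out <- randomize_once(ev, roll, test_params(), seed = 1)
  expect_equal(as.Date(out$timestamp), rep(as.Date("2020-01-04"), 2))

  # two events in a wide roll can land on the same date (independent draws)
  wide <- mk_rolls(end = "2020-03-31 00:00:00")
  ev2 <- mk_det(c("2020-01-20 03:15:00", "2020-02-01 14:50:00"),
                species = "lion")
  same_date <- vapply(1:200, function(s) {
    o <- randomize_once(ev2, wide, test_params(), seed = s)
    length(unique(as.Date(o$timestamp))) == 1
  }, logical(1))
  expect_true(any(same_date))
})

test_that("empirical p-values count ties on both sides", {
  params <- test_params(n_iterations = 10)
  null <- matrix(rep(c(0, 1, 2, 2, 3, 4, 5, 5, 6, 7), 6), ncol = 6)
  observed <- c(5L, 5L, 5L, 2L, 2L, 2L)
  res <- p_values(observed, null, params)
  # before-blocks: #{>= 5} = 4 of 10; after-blocks: #{<= 2} = 4 of 10
  expect_equal(res$p, rep(0.4, 6))

  flat <- matrix(rep(3L, 60), ncol = 6)
  res2 <- p_values(rep(3L, 6), flat, params)
  expect_equal(res2$p, rep(1, 6))

  expect_error(p_values(observed, null[0, , drop = FALSE], params),
               "at least one iteration")
})

test_that("per-block tie identity holds on real null matrices", {
  scn <- scenario(n_cameras = 6, roll_days = 60, seed = 3)
  fit <- run_site_test(simulate_interacting(scn), "baboon", "lion",
                       test_params(n_iterations = 300, seed = 8))
  for (j in seq_along(fit$observed)) {
    expect_equal(
      sum(fit$null[, j] <= fit$observed[j]) +
        sum(fit$null[, j] >= fit$observed[j]),
      fit$n_iterations + sum(fit$null[, j] == fit$observed[j])
    )
  }
  # internal consistency: the two one-sided p-values of a block sum to >= 1
  side <- fit$result$side
  p_lower <- vapply(seq_along(side), function(j) {
    mean(fit$null[, j] <= fit$observed[j])
  }, numeric(1))
  p_upper <- vapply(seq_along(side), function(j) {
    mean(fit$null[, j] >= fit$observed[j])
  }, numeric(1))
  expect_true(all(p_lower + p_upper >= 1))
})

test_that("the observed statistic is deterministic and seed-independent", {
  scn <- scenario(n_cameras = 6, roll_days = 60, seed = 3)
  sv <- simulate_interacting(scn)
  f1 <- run_site_test(sv, "baboon", "lion", test_params(n_iterations = 50, seed = 1))
  f2 <- run_site_test(sv, "baboon", "lion", test_params(n_iterations = 50, seed = 99))
  expect_identical(f1$observed, f2$observed)
})

test_that("species that never co-occur on a roll yield a no-data result", {
  rolls <- dplyr::bind_rows(
    mk_rolls(),
    mk_rolls(roll_id = "C2-R1", camera_id = "C2")
  )
  det <- dplyr::bind_rows(
    mk_det("2020-01-20 08:00:00"), # prey on C1
    mk_det("2020-02-20 08:00:00", species = "lion",
           camera_id = "C2", roll_id = "C2-R1") # predator on C2
  )
  sv <- camtrap_survey(det, rolls,
                       species_roles = c(baboon = "prey", lion = "predator"),
                       quiet = TRUE)
  fit <- run_site_test(sv, "baboon", "lion", test_params(n_iterations = 10))
  expect_true(fit$no_data)
  expect_error(p_values(fit$observed, structure(unclass(fit),
                                                class = "avoidance_null")),
               "no data")
})

test_that("a species missing from species_roles is rejected before computing", {
  sv <- simulate_interacting(scenario(n_cameras = 2, roll_days = 40, seed = 1))
  expect_error(run_site_test(sv, "zebra", "lion", test_params()),
               class = "avoidr_config_error")
})

test_that("Monte-Carlo null matches exhaustive enumeration on a small fixture", {
  fx <- oracle_fixture()
  params <- test_params(n_iterations = 2000, min_lifespan_days = 16, seed = 7)
  fit <- run_site_test(fx$survey, "baboon", "lion", params)
  expect_equal(fit$n_predator_events, 1L)

  dates <- eligible_dates(mk_rolls(start = "2020-01-01 00:00:00",
                                   end = "2020-01-17 00:00:00"),
                          "12:00", params)
  expect_length(dates, 10)
  t0s <- as.POSIXct(paste(dates, "12:00:00"), tz = "UTC")
  enum <- t(vapply(t0s, function(t0) {
    count_blocks_direct(fx$prey$timestamp, t0)
  }, numeric(6)))
  obs <- count_blocks_direct(fx$prey$timestamp, fx$pred$timestamp)
  expect_equal(fit$observed, as.integer(obs))
  p_exact <- vapply(1:6, function(j) {
    if (j <= 3) mean(enum[, j] >= obs[j]) else mean(enum[, j] <= obs[j])
  }, numeric(1))
  expect_true(all(abs(fit$result$p - p_exact) < 0.05))
})

test_that("mean p in the first after-block decreases with avoidance strength", {
  mean_p <- vapply(c(0, 0.5, 0.9), function(e) {
    ps <- vapply(1:4, function(s) {
      scn <- scenario(n_cameras = 10, roll_days = 90, prey_rate = 1.5,
                      predator_rate = 0.2, avoidance_effect = e, seed = 100 + s)
      fit <- run_site_test(simulate_interacting(scn), "baboon", "lion",
                           test_params(n_iterations = 300, seed = 200 + s))
      fit$result$p[fit$result$side == "after"][1]
    }, numeric(1))
    mean(ps)
  }, numeric(1))
  expect_true(mean_p[2] <= mean_p[1] + 0.05)
  expect_true(mean_p[3] <= mean_p[2] + 0.05)
  expect_lt(mean_p[3], mean_p[1])
})
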