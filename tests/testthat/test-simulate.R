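test_that("simulate_rolls lays out one exact-duration roll per camera", {
  expect_equal(nrow(simulate_rolls(scenario(n_cameras = 0))), 0)

  scn <- scenario(n_cameras = 20, roll_days = 90)
  rolls <- simulate_rolls(scn)
  expect_equal(nrow(rolls), 20)
  expect_equal(dplyr::n_distinct(rolls$camera_id), 20)
  expect_true(all(as.numeric(rolls$end - rolls$start, units = "days") == 90))
  expect_identical(rolls, simulate_rolls(scn))
})

test_that("simulate_species respects rate, diel support and the daily mean", {
  rolls <- simulate_rolls(scenario(n_cameras = 1, roll_days = 30))
  expect_equal(nrow(simulate_species(rolls, 0, rep(1, 24), seed = 1)), 0)
  expect_error(simulate_species(rolls, 1, rep(0, 24), seed = 1), "positive")

  # diel weights zero outside 06:00-18:00 confine every detection there
  diel <- c(rep(0, 6), rep(1, 12), rep(0, 6))
  det <- simulate_species(rolls, 5, diel, seed = 2)
  hrs <- lubridate::hour(det$timestamp)
  expect_true(all(hrs >= 6 & hrs < 18))

  # rate 2/day on a 30-day roll: mean count 60 across 100 seeds within
  # 3 * sqrt(60) / sqrt(100)
  counts <- vapply(1:100, function(s) {
    nrow(simulate_species(rolls, 2, diel_profile("diurnal"), seed = s))
  }, numeric(1))
  expect_lt(abs(mean(counts) - 60), 3 * sqrt(60) / sqrt(100))
})

test_that("the null scenario equals two independent species simulations", {
  scn <- scenario(n_cameras = 5, roll_days = 60, seed = 11,
                  avoidance_effect = 0, attraction_effect = 0)
  sv <- simulate_interacting(scn)
  rolls <- simulate_rolls(scn)
  pred <- simulate_species(rolls, scn$predator_rate, scn$predator_diel,
                           seed = avoidr:::derive_seed(scn$seed, 1),
                           species = scn$predator_species)
  prey <- simulate_species(rolls, scn$prey_rate, scn$prey_diel,
                           seed = avoidr:::derive_seed(scn$seed, 2),
                           species = scn$prey_species)
  composed <- camtrap_survey(dplyr::bind_rows(pred, prey), rolls,
                             species_roles = sv$species_roles, quiet = TRUE)
  expect_identical(sv$detections, composed$detections)

  # determinism: same scenario, bit-identical survey
  expect_identical(simulate_interacting(scn)$detections, sv$detections)
})

test_that("complete avoidance leaves no prey within the suppression window", {
  scn <- scenario(n_cameras = 10, roll_days = 60, prey_rate = 3,
                  predator_rate = 0.5, avoidance_effect = 1,
                  avoidance_duration = 24, seed = 4)
  sv <- simulate_interacting(scn)
  det <- sv$detections
  for (cam in unique(det$camera_id)) {
    q <- as.numeric(det$timestamp[det$camera_id == cam & det$species == "lion"])
    p <- as.numeric(det$timestamp[det$camera_id == cam & det$species == "baboon"])
    for (t in p) {
      gaps <- t - q
      expect_false(any(gaps > 0 & gaps <= 24 * 3600))
    }
  }
})

test_that("partial avoidance halves the prey rate inside suppression windows", {
  scn <- scenario(n_cameras = 20, roll_days = 90, prey_rate = 2,
                  predator_rate = 0.3, prey_diel = rep(1, 24),
                  predator_diel = rep(1, 24), avoidance_effect = 0.5,
                  avoidance_duration = 24, seed = 9)
  sv <- simulate_interacting(scn)
  det <- sv$detections
  dur_s <- 24 * 3600
  in_hours <- out_hours <- in_count <- out_count <- 0
  for (cam in unique(sv$rolls$camera_id)) {
    roll <- sv$rolls[sv$rolls$camera_id == cam, ]
    q <- sort(as.numeric(det$timestamp[det$camera_id == cam &
                                         det$species == "lion"]))
    p <- as.numeric(det$timestamp[det$camera_id == cam &
                                    det$species == "baboon"])
    # union of suppression windows, clipped to the roll
    if (length(q) > 0) {
      s <- pmin(q + dur_s, as.numeric(roll$end))
      merged <- list()
      cur <- c(q[1], s[1])
      for (i in seq_along(q)[-1]) {
        if (q[i] <= cur[2]) cur[2] <- max(cur[2], s[i])
        else { merged <- c(merged, list(cur)); cur <- c(q[i], s[i]) }
      }
      merged <- c(merged, list(cur))
      win <- do.call(rbind, merged)
      in_hours <- in_hours + sum(win[, 2] - win[, 1]) / 3600
      inside <- vapply(p, function(t) any(t > win[, 1] & t <= win[, 2]),
                       logical(1))
      in_count <- in_count + sum(inside)
      out_count <- out_count + sum(!inside)
      total_h <- as.numeric(roll$end - roll$start, units = "hours")
      out_hours <- out_hours + total_h - sum(win[, 2] - win[, 1]) / 3600
    }
  }
  expect_gt(in_hours, 1e4) # enough exposure for a tight Monte-Carlo estimate
  ratio <- (in_count / in_hours) / (out_count / out_hours)
  expect_lt(abs(ratio - 0.5), 0.1)
})

test_that("attraction elevates the predator rate after prey passages", {
  scn <- scenario(n_cameras = 20, roll_days = 90, prey_rate = 0.5,
                  predator_rate = 1, prey_diel = rep(1, 24),
                  predator_diel = rep(1, 24), attraction_effect = 2,
                  attraction_duration = 12, seed = 13)
  sv <- simulate_interacting(scn)
  det <- sv$detections
  # baseline prey drives attraction; compare predator rate in the 12 h after
  # observed prey events to the overall rate (windows cover a minority of
  # time, so elevation should be clearly visible)
  n_in <- 0; h_in <- 0
  for (cam in unique(sv$rolls$camera_id)) {
    p <- sort(as.numeric(det$timestamp[det$camera_id == cam &
                                         det$species == "baboon"]))
    q <- as.numeric(det$timestamp[det$camera_id == cam &
                                    det$species == "lion"])
    if (length(p) == 0) next
    inside <- vapply(q, function(t) {
      i <- findInterval(t, p, left.open = TRUE)
      i > 0 && (t - p[i]) <= 12 * 3600
    }, logical(1))
    n_in <- n_in + sum(inside)
  }
  overall <- sum(det$species == "lion")
  expect_gt(n_in / overall, 0.35) # null coverage of the windows is ~22%
})

test_that("burst triggers land inside the independence gap and are filtered out", {
  scn <- scenario(n_cameras = 5, roll_days = 60, prey_rate = 0,
                  predator_rate = 0.5, burst_prob = 0.6, seed = 21)
  base <- scenario(n_cameras = 5, roll_days = 60, prey_rate = 0,
                   predator_rate = 0.5, burst_prob = 0, seed = 21)
  sv <- simulate_interacting(scn)
  sv0 <- simulate_interacting(base)
  expect_gt(nrow(sv$detections), nrow(sv0$detections))
  # every burst sits within 15 min of a parent, so the 30-min filter
  # recovers at most the burst-free event count
  pp <- preprocess_survey(sv, test_params())
  pp0 <- preprocess_survey(sv0, test_params())
  expect_lte(nrow(pp$detections), nrow(pp0$detections) + 1)
})
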