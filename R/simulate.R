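#' Define a synthetic predator-prey survey scenario
#'
#' A scenario fixes every parameter of the synthetic camera-trap survey
#' generator: the survey layout, the baseline detection processes of one
#' prey and one predator species (inhomogeneous Poisson with hourly diel
#' activity profiles), an injected reactive-avoidance effect (prey intensity
#' multiplied by `1 - avoidance_effect` for `avoidance_duration` hours after
#' each predator passage at the same camera), an optional predator-following
#' effect (predator intensity multiplied by `1 + attraction_effect` for
#' `attraction_duration` hours after each prey passage), and burst
#' triggering (clusters of near-simultaneous triggers around one event, to
#' exercise the time-to-independence filter).
#'
#' The defaults describe a medium-sized survey of the kind run by savanna
#' monitoring programmes: 20 cameras, one 90-day roll per camera (a typical
#' service interval), a diurnal prey detected about once per day and a
#' mostly nocturnal predator detected about 0.3 times per day, with no
#' injected interaction.
#'
#' @param n_cameras Number of cameras (one roll each).
#' @param roll_days Roll duration in days.
#' @param prey_rate,predator_rate Expected baseline detections per day.
#' @param prey_diel,predator_diel 24 non-negative hourly weights (hour of
#'   day, starting at midnight); intensity within each hour is constant and
#'   proportional to the weight, scaled so it integrates to the daily rate.
#' @param avoidance_effect Fraction in `[0, 1]` by which prey intensity is
#'   reduced after a predator event (0 = no avoidance).
#' @param avoidance_duration Duration of the suppression window, hours.
#'   Overlapping windows do not compound: suppression applies on the union.
#' @param attraction_effect Non-negative extra multiplier minus one applied
#'   to predator intensity after a prey event (0 = none); models a predator
#'   following prey, which shows up as elevated prey counts *before*
#'   predator detections.
#' @param attraction_duration Duration of the attraction window, hours.
#' @param burst_prob Probability that a detection spawns 1-3 extra triggers.
#' @param burst_gap Half-window for burst triggers is `burst_gap / 2`
#'   minutes around the parent event (default 30, matching the independence
#'   gap the bursts are meant to exercise).
#' @param prey_species,predator_species Species labels used in the output.
#' @param site_id Site label.
#' @param origin Calendar date-time at which every roll starts.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   scenario.
#'
#' @return An object of class `scenario` (a named list).
#' @export
scenario <- function(n_cameras = 20, roll_days = 90,
                     prey_rate = 1.0, predator_rate = 0.3,
                     prey_diel = diel_profile("diurnal"),
                     predator_diel = diel_profile("nocturnal"),
                     avoidance_effect = 0, avoidance_duration = 24,
                     attraction_effect = 0, attraction_duration = 24,
                     burst_prob = 0, burst_gap = 30,
                     prey_species = "baboon", predator_species = "lion",
                     site_id = "S1",
                     origin = as.POSIXct("2020-01-01 00:00:00", tz = "UTC"),
                     seed = 1L) {
  check_scalar_number(n_cameras, "n_cameras", 0)
  check_scalar_number(roll_days, "roll_days", 0, strict_lower = TRUE)
  check_scalar_number(prey_rate, "prey_rate", 0)
  check_scalar_number(predator_rate, "predator_rate", 0)
  check_scalar_number(avoidance_effect, "avoidance_effect", 0, 1)
  check_scalar_number(avoidance_duration, "avoidance_duration", 0)
  check_scalar_number(attraction_effect, "attraction_effect", 0)
  check_scalar_number(attraction_duration, "attraction_duration", 0)
  check_scalar_number(burst_prob, "burst_prob", 0, 1)
  check_scalar_number(burst_gap, "burst_gap", 0, strict_lower = TRUE)
  check_diel(prey_diel, "prey_diel")
  check_diel(predator_diel, "predator_diel")
  structure(
    list(
      n_cameras = as.integer(n_cameras), roll_days = roll_days,
      prey_rate = prey_rate, predator_rate = predator_rate,
      prey_diel = as.numeric(prey_diel),
      predator_diel = as.numeric(predator_diel),
      avoidance_effect = avoidance_effect,
      avoidance_duration = avoidance_duration,
      attraction_effect = attraction_effect,
      attraction_duration = attraction_duration,
      burst_prob = burst_prob, burst_gap = burst_gap,
      prey_species = prey_species, predator_species = predator_species,
      site_id = site_id, origin = origin, seed = as.integer(seed)
    ),
    class = "scenario"
  )
}

check_diel <- function(w, name) {
  if (!is.numeric(w) || length(w) != 24 || any(is.na(w)) || any(w < 0)) {
    abort(sprintf("`%s` must be 24 non-negative hourly weights", name))
  }
  if (all(w == 0)) {
    abort(sprintf("`%s` must have at least one positive weight", name))
  }
  invisible(w)
}

#' Canned hourly diel activity profiles
#'
#' @param type `"diurnal"` (active 06:00-18:00 with low residual activity at
#'   night), `"nocturnal"` (the complement) or `"uniform"`.
#' @return A numeric vector of 24 hourly weights.
#' @export
diel_profile <- function(type = c("diurnal", "nocturnal", "uniform")) {
  type <- match.arg(type)
  switch(type,
    diurnal = c(rep(0.1, 6), rep(1, 12), rep(0.1, 6)),
    nocturnal = c(rep(1, 6), rep(0.15, 12), rep(1, 6)),
    uniform = rep(1, 24)
  )
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf(
    "<scenario> %d camera(s) x %g d | prey %s %.3g/d | predator %s %.3g/d\n",
    x$n_cameras, x$roll_days, x$prey_species, x$prey_rate,
    x$predator_species, x$predator_rate
  ))
  cat(sprintf(
    "  avoidance e = %g over %g h | attraction a = %g over %g h | burst p = %g | seed %d\n",
    x$avoidance_effect, x$avoidance_duration, x$attraction_effect,
    x$attraction_duration, x$burst_prob, x$seed
  ))
  invisible(x)
}

#' Simulate the roll layout of a scenario
#'
#' One roll per camera, all starting at the scenario origin and lasting
#' `roll_days` days. Deterministic.
#'
#' @param scn A [scenario()].
#' @return A roll tibble (`roll_id`, `camera_id`, `site_id`, `start`, `end`).
#' @export
simulate_rolls <- function(scn) {
  stopifnot(inherits(scn, "scenario"))
  n <- scn$n_cameras
  if (n == 0) {
    return(tibble(roll_id = character(), camera_id = character(),
                  site_id = character(),
                  start = as.POSIXct(character(), tz = "UTC"),
                  end = as.POSIXct(character(), tz = "UTC")))
  }
  cam <- sprintf("C%02d", seq_len(n))
  tibble(
    roll_id = paste0(cam, "-R1"),
    camera_id = cam,
    site_id = scn$site_id,
    start = rep(scn$origin, n),
    end = rep(scn$origin + scn$roll_days * 86400, n)
  )
}

# intensity per hour (events/hour) at second-of-day s, given daily rate and
# normalized hourly weights u (sum(u) == 1)
diel_u <- function(diel) diel / sum(diel)

# simulate one inhomogeneous Poisson process on [start, end) by thinning;
# returns sorted numeric times (whole seconds)
sim_pp_times <- function(start_s, end_s, rate, u, extra_max = 1,
                         accept_extra = NULL) {
  if (rate <= 0) return(numeric())
  lmax <- rate * max(u) * extra_max # events per hour
  dur_h <- (end_s - start_s) / 3600
  n_cand <- rpois(1, lmax * dur_h)
  if (n_cand == 0) return(numeric())
  t <- start_s + floor(runif(n_cand) * (end_s - start_s))
  hour <- floor((t %% 86400) / 3600) + 1
  p <- u[hour] / (max(u) * extra_max)
  if (!is.null(accept_extra)) p <- p * accept_extra(t)
  keep <- runif(n_cand) < p
  sort(t[keep])
}

#' Simulate detections of one species over a set of rolls
#'
#' Draws an inhomogeneous Poisson process on each roll whose intensity is
#' piecewise-constant per hour of day, proportional to the diel weights and
#' scaled so it integrates to `rate` detections per day. Sampling uses
#' thinning of a homogeneous process at the peak intensity, so the hourly
#' acceptance probability never exceeds one.
#'
#' @param rolls Roll tibble (as from [simulate_rolls()]).
#' @param rate Expected detections per day.
#' @param diel 24 non-negative hourly weights; at least one positive.
#' @param seed Integer seed.
#' @param species Species label for the output rows.
#' @return A detection tibble sorted by camera and time, timestamps at whole
#'   seconds within roll bounds.
#' @export
simulate_species <- function(rolls, rate, diel, seed, species = "species") {
  check_scalar_number(rate, "rate", 0)
  check_diel(diel, "diel")
  u <- diel_u(diel)
  set.seed(seed)
  out <- purrr::pmap(rolls, function(roll_id, camera_id, site_id, start, end) {
    t <- sim_pp_times(ts_num(start), ts_num(end), rate, u)
    tibble(site_id = site_id, camera_id = camera_id, roll_id = roll_id,
           species = species, timestamp = num_to_ts(t))
  })
  dplyr::bind_rows(out) |>
    dplyr::arrange(.data$camera_id, .data$timestamp)
}

# is each time t inside the union of windows (q, q + dur_s] over events q?
in_window_after <- function(t, q_sorted, dur_s) {
  if (length(q_sorted) == 0 || length(t) == 0) {
    return(rep(FALSE, length(t)))
  }
  i <- findInterval(t, q_sorted, left.open = TRUE) # count of q strictly < t
  i > 0 & (t - q_sorted[pmax(i, 1)]) <= dur_s
}

#' Simulate an interacting predator-prey survey
#'
#' Generates a full synthetic survey under a scenario. The baseline prey and
#' predator processes are drawn from independent, deterministically derived
#' substreams of the scenario seed. Reactive avoidance is injected by
#' thinning: each baseline prey detection falling within `avoidance_duration`
#' hours after any predator detection at the same camera is kept with
#' probability `1 - avoidance_effect` (suppression applies on the union of
#' windows, so overlapping predator passages do not compound). Attraction
#' (predator following prey) modulates the predator intensity upward by
#' `1 + attraction_effect` within `attraction_duration` hours after baseline
#' prey events. Burst triggers finally add 1-3 extra near-simultaneous
#' detections around selected events of both species.
#'
#' With `avoidance_effect = 0` and `attraction_effect = 0` the output is
#' bit-identical to two independent [simulate_species()] runs on the same
#' derived substreams, composed into one survey.
#'
#' @param scn A [scenario()].
#' @return A `camtrap_survey` with `species_roles` set to the scenario's
#'   prey and predator species.
#' @export
simulate_interacting <- function(scn) {
  stopifnot(inherits(scn, "scenario"))
  rolls <- simulate_rolls(scn)
  seed_pred <- derive_seed(scn$seed, 1)
  seed_prey <- derive_seed(scn$seed, 2)
  seed_thin <- derive_seed(scn$seed, 3)
  seed_burst <- derive_seed(scn$seed, 4)

  # baseline prey; also drives attraction when requested
  prey0 <- simulate_species(rolls, scn$prey_rate, scn$prey_diel,
                            seed = seed_prey, species = scn$prey_species)

  if (scn$attraction_effect > 0) {
    a <- scn$attraction_effect
    dur_s <- scn$attraction_duration * 3600
    u <- diel_u(scn$predator_diel)
    set.seed(seed_pred)
    pred_rows <- purrr::pmap(rolls, function(roll_id, camera_id, site_id,
                                             start, end) {
      q <- ts_num(prey0$timestamp[prey0$camera_id == camera_id])
      t <- sim_pp_times(
        ts_num(start), ts_num(end), scn$predator_rate, u,
        extra_max = 1 + a,
        accept_extra = function(tt) {
          ifelse(in_window_after(tt, q, dur_s), 1 + a, 1)
        }
      )
      tibble(site_id = site_id, camera_id = camera_id, roll_id = roll_id,
             species = scn$predator_species, timestamp = num_to_ts(t))
    })
    pred <- dplyr::bind_rows(pred_rows) |>
      dplyr::arrange(.data$camera_id, .data$timestamp)
  } else {
    pred <- simulate_species(rolls, scn$predator_rate, scn$predator_diel,
                             seed = seed_pred, species = scn$predator_species)
  }

  # avoidance thinning of the baseline prey process
  prey <- prey0
  if (scn$avoidance_effect > 0 && nrow(prey0) > 0 && nrow(pred) > 0) {
    dur_s <- scn$avoidance_duration * 3600
    set.seed(seed_thin)
    suppressed <- logical(nrow(prey0))
    for (cam in unique(prey0$camera_id)) {
      sel <- prey0$camera_id == cam
      q <- ts_num(pred$timestamp[pred$camera_id == cam])
      suppressed[sel] <- in_window_after(ts_num(prey0$timestamp[sel]), q, dur_s)
    }
    drop <- suppressed & runif(nrow(prey0)) < scn$avoidance_effect
    prey <- prey0[!drop, ]
  }

  det <- dplyr::bind_rows(pred, prey)

  if (scn$burst_prob > 0 && nrow(det) > 0) {
    set.seed(seed_burst)
    half <- scn$burst_gap / 2 * 60
    parent <- which(runif(nrow(det)) < scn$burst_prob)
    if (length(parent) > 0) {
      n_extra <- sample(1:3, length(parent), replace = TRUE)
      extra <- det[rep(parent, n_extra), ]
      p0 <- ts_num(extra$timestamp)
      t_new <- p0 + floor(runif(nrow(extra), -half, half))
      idx <- match(extra$roll_id, rolls$roll_id)
      t_new <- pmin(pmax(t_new, ts_num(rolls$start)[idx]),
                    ts_num(rolls$end)[idx])
      extra$timestamp <- num_to_ts(t_new)
      det <- dplyr::bind_rows(det, extra)
    }
  }

  roles <- stats::setNames(c("prey", "predator"),
                           c(scn$prey_species, scn$predator_species))
  camtrap_survey(det, rolls, species_roles = roles, quiet = TRUE)
}
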