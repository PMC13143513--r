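# In-code fixtures shared across test files.

ts_utc <- function(x) as.POSIXct(x, tz = "UTC")

mk_rolls <- function(roll_id = "C1-R1", camera_id = "C1", site_id = "S1",
                     start = "2020-01-01 00:00:00",
                     end = "2020-04-01 00:00:00") {
  tibble::tibble(roll_id = roll_id, camera_id = camera_id, site_id = site_id,
                 start = ts_utc(start), end = ts_utc(end))
}

mk_det <- function(times, species = "baboon", camera_id = "C1",
                   roll_id = "C1-R1", site_id = "S1") {
  tibble::tibble(site_id = site_id, camera_id = camera_id, roll_id = roll_id,
                 species = species, timestamp = ts_utc(times))
}

empty_det <- function() mk_det(character(0))

# direct block counting by explicit comparisons, independent of the
# findInterval implementation path; six 24-h blocks
count_blocks_direct <- function(prey_times, t0) {
  off <- as.numeric(difftime(prey_times, t0, units = "hours"))
  c(
    sum(off >= -72 & off < -48),
    sum(off >= -48 & off < -24),
    sum(off >= -24 & off < 0),
    sum(off > 0 & off <= 24),
    sum(off > 24 & off <= 48),
    sum(off > 48 & off <= 72)
  )
}

# fixture for the exhaustive-enumeration oracle: a 16-day roll whose 72-h
# margins leave exactly 10 eligible dates at 12:00, one predator event at
# the central date, and a fixed irregular prey pattern
oracle_fixture <- function() {
  rolls <- mk_rolls(start = "2020-01-01 00:00:00", end = "2020-01-17 00:00:00")
  pred <- mk_det("2020-01-08 12:00:00", species = "lion")
  prey <- mk_det(c(
    "2020-01-02 03:10:00", "2020-01-03 14:45:00", "2020-01-04 06:30:00",
    "2020-01-05 12:00:00", "2020-01-05 21:15:00", "2020-01-07 08:05:00",
    "2020-01-08 11:59:00", "2020-01-08 18:40:00", "2020-01-10 02:25:00",
    "2020-01-11 16:50:00", "2020-01-13 07:35:00", "2020-01-15 22:10:00"
  ))
  survey <- camtrap_survey(
    dplyr::bind_rows(prey, pred), rolls,
    species_roles = c(baboon = "prey", lion = "predator"), quiet = TRUE
  )
  list(survey = survey, rolls = rolls, pred = pred, prey = prey)
}
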