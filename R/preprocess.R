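#' Partition detections into clusters of consecutive events
#'
#' Detections of one species at one camera whose consecutive gaps are all
#' strictly shorter than the independence gap chain transitively into one
#' cluster. Clustering is the first half of the time-to-independence filter;
#' [independence_filter()] then keeps one representative per cluster.
#'
#' @param events Detection tibble for a single camera and single species,
#'   sorted ascending by `timestamp`.
#' @param gap Independence gap in minutes (default 30).
#' @return `events` with an integer `cluster` column (1-based, chronological).
#' @examples
#' ev <- tibble::tibble(
#'   site_id = "S", camera_id = "C", roll_id = "R", species = "lion",
#'   timestamp = as.POSIXct("2020-01-01", tz = "UTC") +
#'     c(0, 10, 20, 100) * 60
#' )
#' cluster_events(ev)$cluster  # 1 1 1 2
#' @export
cluster_events <- function(events, gap = 30) {
  events <- as_tibble(events)
  stopifnot_cols(events, c("camera_id", "species", "timestamp"), "event table")
  if (dplyr::n_distinct(events$camera_id) > 1 ||
      dplyr::n_distinct(events$species) > 1) {
    abort("`events` must contain a single camera and a single species")
  }
  t <- ts_num(events$timestamp)
  if (is.unsorted(t)) {
    abort("`events` must be sorted ascending by timestamp")
  }
  gap_s <- gap * 60
  if (nrow(events) == 0) {
    events$cluster <- integer()
    return(events)
  }
  # new cluster wherever the gap to the previous event reaches the threshold
  events$cluster <- cumsum(c(TRUE, diff(t) >= gap_s))
  events
}

#' Time-to-independence filter
#'
#' Collapses each cluster of consecutive detections (see [cluster_events()])
#' to its central detection: the element at 1-based position `ceiling(k / 2)`
#' of a size-`k` cluster, i.e. the earlier of the two middle elements when
#' `k` is even. Retaining the centre rather than the first detection keeps
#' the representative symmetric with respect to the before/after windows of
#' the avoidance test. The operation is idempotent.
#'
#' @inheritParams cluster_events
#' @return The retained detections, sorted by timestamp.
#' @export
independence_filter <- function(events, gap = 30) {
  ev <- cluster_events(events, gap = gap)
  if (nrow(ev) == 0) {
    ev$cluster <- NULL
    return(ev)
  }
  out <- ev |>
    dplyr::group_by(.data$cluster) |>
    dplyr::slice(ceiling(dplyr::n() / 2)) |>
    dplyr::ungroup()
  out$cluster <- NULL
  dplyr::arrange(out, .data$timestamp)
}

#' Exclude detections near the ends of a roll
#'
#' Keeps only events whose timestamp lies in the closed interval
#' `[start + margin, end - margin]` of their roll, so that a full
#' before/after observation window exists for every retained event.
#'
#' @param events Detection tibble; all rows must belong to `roll`.
#' @param roll A one-row roll tibble (or list) with `start` and `end`.
#' @param margin Margin in hours (default 72).
#' @return The retained detections. When the margin reaches half the roll
#'   length the retained interval is empty; an empty result is returned with
#'   a warning.
#' @export
edge_exclusion <- function(events, roll, margin = 72) {
  events <- as_tibble(events)
  start <- ts_num(roll$start[[1]])
  end <- ts_num(roll$end[[1]])
  m <- margin * 3600
  if (nrow(events) > 0 &&
      !all(events$roll_id == roll$roll_id[[1]])) {
    abort("`events` must all belong to `roll`")
  }
  if (2 * m >= end - start) {
    warn(sprintf(
      "edge margin %g h is at least half the roll length; no event can be retained",
      margin
    ))
    return(events[0, ])
  }
  t <- ts_num(events$timestamp)
  events[t >= start + m & t <= end - m, ]
}

#' Drop rolls with a short lifespan
#'
#' Rolls whose lifespan `(end - start)` is strictly shorter than `min_days`
#' are removed: their dates could only be randomized within a narrow window,
#' which makes the null distribution unreliable. The boundary is inclusive
#' (a lifespan of exactly `min_days` is retained).
#'
#' @param rolls Roll tibble.
#' @param min_days Minimum lifespan in days (default 30).
#' @return The retained rolls.
#' @export
lifespan_filter <- function(rolls, min_days = 30) {
  rolls <- as_tibble(rolls)
  span_days <- (ts_num(rolls$end) - ts_num(rolls$start)) / 86400
  rolls[span_days >= min_days, ]
}

#' Predator co-detection rate on camera-days
#'
#' Over all (camera, calendar-day) pairs with at least one detection of a
#' predator species, the percentage of pairs on which at least two distinct
#' predator species were detected. A low rate indicates that testing prey
#' response to each predator species separately carries little risk of
#' attributing one species' effect to another (e.g. via kleptoparasitic
#' following).
#'
#' @param detections Detection tibble.
#' @param predator_species Character vector of predator species names.
#' @return A single percentage (e.g. `50` for 50%), or `NA` when no predator
#'   detection exists.
#' @examples
#' det <- tibble::tibble(
#'   site_id = "S", camera_id = "A", roll_id = "R",
#'   species = c("lion", "hyena", "lion"),
#'   timestamp = as.POSIXct(c(
#'     "2020-01-01 08:00", "2020-01-01 20:00", "2020-01-02 08:00"
#'   ), tz = "UTC")
#' )
#' co_detection_rate(det, c("lion", "hyena"))  # 50
#' @export
co_detection_rate <- function(detections, predator_species) {
  det <- dplyr::filter(as_tibble(detections),
                       .data$species %in% predator_species)
  if (nrow(det) == 0) {
    inform("no predator detections: co-detection rate not applicable")
    return(NA_real_)
  }
  days <- det |>
    dplyr::mutate(day = day_num(.data$timestamp)) |>
    dplyr::group_by(.data$camera_id, .data$day) |>
    dplyr::summarise(n_sp = dplyr::n_distinct(.data$species), .groups = "drop")
  100 * mean(days$n_sp >= 2)
}

#' Apply the full preprocessing pipeline to a survey
#'
#' Applies, in order: (1) the minimum-lifespan filter to rolls, removing all
#' detections (any species) on dropped rolls; (2) the time-to-independence
#' filter to predator detections only, per camera and species; (3) edge
#' exclusion of predator detections within `edge_margin` hours of their
#' roll's start or end. Prey and other species pass through steps 2-3
#' untouched. Which species are predators is taken from the survey's
#' `species_roles`.
#'
#' @param survey A `camtrap_survey` with `species_roles` set.
#' @param params A [test_params()] object.
#' @return A `camtrap_survey` with an added `filter_report` element: a tibble
#'   of before/after counts per stage, site and species.
#' @export
preprocess_survey <- function(survey, params = test_params()) {
  stopifnot(inherits(survey, "camtrap_survey"))
  if (is.null(survey$species_roles)) {
    abort("`survey` must carry species_roles to identify predator species")
  }
  predators <- names(survey$species_roles)[survey$species_roles == "predator"]
  det <- survey$detections
  report <- list()
  count_by <- function(d) dplyr::count(d, .data$site_id, .data$species)

  record <- function(stage, before, after) {
    dplyr::full_join(
      dplyr::rename(count_by(before), n_before = "n"),
      dplyr::rename(count_by(after), n_after = "n"),
      by = c("site_id", "species")
    ) |>
      dplyr::mutate(
        stage = stage,
        n_before = dplyr::coalesce(.data$n_before, 0L),
        n_after = dplyr::coalesce(.data$n_after, 0L)
      )
  }

  # 1. lifespan filter (drops detections of every species on short rolls)
  rolls_kept <- lifespan_filter(survey$rolls, params$min_lifespan_days)
  det1 <- dplyr::filter(det, .data$roll_id %in% rolls_kept$roll_id)
  report$lifespan <- record("lifespan_filter", det, det1)

  # 2. independence filter, predators only
  is_pred <- det1$species %in% predators
  pred <- det1[is_pred, ]
  other <- det1[!is_pred, ]
  pred2 <- pred |>
    dplyr::arrange(.data$camera_id, .data$species, .data$timestamp) |>
    dplyr::group_by(.data$camera_id, .data$species) |>
    dplyr::group_split() |>
    purrr::map(~ independence_filter(.x, gap = params$independence_gap)) |>
    dplyr::bind_rows()
  if (nrow(pred2) == 0) pred2 <- pred[0, ]
  det2 <- dplyr::bind_rows(other, pred2)
  report$independence <- record("independence_filter", det1, det2)

  # 3. edge exclusion, predators only
  is_pred2 <- det2$species %in% predators
  pred_in <- det2[is_pred2, ]
  other2 <- det2[!is_pred2, ]
  m <- params$edge_margin * 3600
  idx <- match(pred_in$roll_id, rolls_kept$roll_id)
  t <- ts_num(pred_in$timestamp)
  keep <- t >= ts_num(rolls_kept$start)[idx] + m &
    t <= ts_num(rolls_kept$end)[idx] - m
  pred3 <- pred_in[keep, ]
  det3 <- dplyr::bind_rows(other2, pred3)
  report$edge <- record("edge_exclusion", det2, det3)

  out <- camtrap_survey(det3, rolls_kept,
                        species_roles = survey$species_roles,
                        excluded_cameras = survey$excluded_cameras,
                        quiet = TRUE)
  out$filter_report <- dplyr::bind_rows(report) |>
    dplyr::select("stage", "site_id", "species", "n_before", "n_after") |>
    dplyr::arrange(factor(.data$stage, levels = c(
      "lifespan_filter", "independence_filter", "edge_exclusion"
    )), .data$site_id, .data$species)
  out
}
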