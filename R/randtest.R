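# Core statistic and randomization null.
#
# Block convention (defaults): six 24-h blocks spanning 72 h before and
# after a reference predator detection at time t0. Before-blocks are
# closed-left/open-right, [-72,-48), [-48,-24), [-24,0); after-blocks are
# open-left/closed-right, (0,24], (24,48], (48,72]. A prey detection exactly
# at t0 belongs to no block. All counting runs on numeric seconds through
# findInterval on a sorted prey vector, so each boundary costs O(log n).

# counts in all 2B blocks for each reference time t0s (numeric seconds);
# returns length(t0s) x 2B integer matrix
block_count_matrix <- function(t0s, prey_sorted, width_h, B) {
  m <- length(t0s)
  offs <- (-B:B) * width_h * 3600
  bnd <- outer(t0s, offs, "+")
  le <- matrix(findInterval(bnd, prey_sorted), nrow = m)
  lt <- matrix(findInterval(bnd, prey_sorted, left.open = TRUE), nrow = m)
  before <- lt[, 2:(B + 1), drop = FALSE] - lt[, 1:B, drop = FALSE]
  after <- le[, (B + 2):(2 * B + 1), drop = FALSE] -
    le[, (B + 1):(2 * B), drop = FALSE]
  cbind(before, after)
}

#' Prey counts in time blocks around a reference detection
#'
#' Counts prey detections in `2 * n_blocks_per_side` consecutive blocks of
#' `block_width` hours centred on the reference time `t0` (by default six
#' 24-h blocks spanning 72 h before and after). Before-blocks include their
#' left boundary and exclude their right; after-blocks exclude their left
#' boundary and include their right; a detection exactly at `t0` is counted
#' in no block.
#'
#' @param detections Prey detection tibble from the same camera as the
#'   reference detection.
#' @param t0 Reference date-time (`POSIXct`).
#' @param params A [test_params()].
#' @return A tibble with columns `block` (1-based chronological index),
#'   `window` (label in hours relative to `t0`), `side` (`"before"` /
#'   `"after"`) and `count`.
#' @examples
#' params <- test_params()
#' prey <- tibble::tibble(
#'   site_id = "S", camera_id = "C", roll_id = "R", species = "baboon",
#'   timestamp = as.POSIXct("2020-01-05 12:00", tz = "UTC") +
#'     c(-71, -30, 6, 30) * 3600
#' )
#' block_counts(prey, as.POSIXct("2020-01-05 12:00", tz = "UTC"), params)
#' @export
block_counts <- function(detections, t0, params = test_params()) {
  detections <- as_tibble(detections)
  prey_sorted <- sort(ts_num(detections$timestamp))
  cnt <- block_count_matrix(ts_num(t0), prey_sorted,
                            params$block_width, params$n_blocks_per_side)
  tibble(
    block = seq_len(2 * params$n_blocks_per_side),
    window = block_labels(params),
    side = block_sides(params),
    count = as.integer(cnt[1, ])
  )
}

# numeric day numbers d such that d*86400 + tod_s lies in
# [start + margin, end - margin]
eligible_day_nums <- function(start_s, end_s, tod_s, margin_s) {
  lo <- start_s + margin_s
  hi <- end_s - margin_s
  if (lo > hi) return(numeric())
  d_lo <- ceiling((lo - tod_s) / 86400)
  d_hi <- floor((hi - tod_s) / 86400)
  if (d_lo > d_hi) return(numeric())
  seq(d_lo, d_hi)
}

#' Calendar dates eligible for relocating a detection
#'
#' The dates `d` such that the date-time combining `d` with the detection's
#' original clock time lies inside `[start + edge_margin, end - edge_margin]`
#' of the roll. Confining randomized dates to the same margin applied to
#' observed events gives observed and null statistics identical exposure
#' near roll edges.
#'
#' @param roll One-row roll tibble (or list) with `start` and `end`.
#' @param time_of_day Clock time to preserve: a `POSIXct` (its clock time is
#'   used), a `"HH:MM"` / `"HH:MM:SS"` string, or seconds since midnight.
#' @param params A [test_params()].
#' @return A `Date` vector (possibly empty; an empty set means the roll
#'   cannot support randomization at that clock time).
#' @export
eligible_dates <- function(roll, time_of_day, params = test_params()) {
  tod_s <- time_of_day_seconds(time_of_day)
  d <- eligible_day_nums(ts_num(roll$start[[1]]), ts_num(roll$end[[1]]),
                         tod_s, params$edge_margin * 3600)
  as.Date(d, origin = "1970-01-01")
}

time_of_day_seconds <- function(x) {
  if (inherits(x, "POSIXct")) {
    return(sec_of_day(x))
  }
  if (is.character(x)) {
    p <- as.numeric(strsplit(x, ":", fixed = TRUE)[[1]])
    return(sum(p * c(3600, 60, 1)[seq_along(p)]))
  }
  as.numeric(x)
}

#' Relocate predator events to random dates within their roll
#'
#' Each event is independently reassigned a date drawn uniformly (with
#' replacement across events) from its [eligible_dates()], while its clock
#' time is preserved exactly, so the diel activity pattern of the species is
#' untouched. The number of events is conserved.
#'
#' @param events Detection tibble of events in one roll.
#' @param roll The one-row roll the events belong to.
#' @param params A [test_params()].
#' @param seed Optional seed; when `NULL` the current RNG state is used.
#' @return `events` with relocated timestamps.
#' @export
randomize_once <- function(events, roll, params = test_params(), seed = NULL) {
  events <- as_tibble(events)
  if (!is.null(seed)) set.seed(seed)
  if (nrow(events) == 0) return(events)
  t <- ts_num(events$timestamp)
  tod <- t %% 86400
  margin_s <- params$edge_margin * 3600
  start_s <- ts_num(roll$start[[1]])
  end_s <- ts_num(roll$end[[1]])
  new_t <- vapply(tod, function(s) {
    d <- eligible_day_nums(start_s, end_s, s, margin_s)
    if (length(d) == 0) {
      abort(sprintf("roll %s has no eligible date at clock time %05.0f s; exclude it from the test",
                    roll$roll_id[[1]], s),
            class = "avoidr_no_eligible_dates")
    }
    d[sample.int(length(d), 1)] * 86400 + s
  }, numeric(1))
  events$timestamp <- num_to_ts(new_t)
  events
}

#' Observed block counts and their randomization null distribution
#'
#' For one prey species and one predator species, restricts the survey to
#' rolls on which both were detected, sums [block_counts()] over every
#' predator event (counts are camera-local: only prey detections from the
#' event's own camera contribute, and a prey detection inside the windows of
#' two predator events is counted for both), and builds the null
#' distribution by relocating every predator event to a uniformly drawn
#' eligible date (clock time preserved) `n_iterations` times, recomputing
#' the same sum each time.
#'
#' The survey is expected to be preprocessed already (see
#' [preprocess_survey()]); this function applies no filtering beyond the
#' both-species roll restriction.
#'
#' @param survey A preprocessed `camtrap_survey`.
#' @param prey,predator Species names.
#' @param params A [test_params()].
#' @return An object of class `avoidance_null`: a list with `observed`
#'   (integer vector over blocks), `null` (an `n_iterations` x blocks
#'   integer matrix), block metadata, `n_predator_events`, `n_rolls_used`
#'   and `no_data` (`TRUE` when no roll holds both species, in which case no
#'   p-value is defined).
#' @export
null_distribution <- function(survey, prey, predator, params = test_params()) {
  stopifnot(inherits(survey, "camtrap_survey"))
  det <- survey$detections
  prey_det <- det[det$species == prey, ]
  pred_det <- det[det$species == predator, ]

  rolls_both <- intersect(unique(prey_det$roll_id), unique(pred_det$roll_id))
  pred_det <- pred_det[pred_det$roll_id %in% rolls_both, ]
  nb <- 2L * params$n_blocks_per_side
  base <- list(
    observed = integer(nb), null = NULL,
    window = block_labels(params), side = block_sides(params),
    n_predator_events = 0L, n_rolls_used = 0L,
    n_iterations = params$n_iterations, seed = params$seed,
    prey = prey, predator = predator, params = params
  )
  if (nrow(pred_det) == 0) {
    base$no_data <- TRUE
    return(structure(base, class = "avoidance_null"))
  }

  rolls <- survey$rolls[survey$rolls$roll_id %in% rolls_both, ]
  margin_s <- params$edge_margin * 3600
  n_iter <- params$n_iterations
  # camera-local sorted prey times
  prey_by_cam <- split(ts_num(prey_det$timestamp), prey_det$camera_id)
  prey_by_cam <- lapply(prey_by_cam, sort)

  observed <- numeric(nb)
  acc <- matrix(0, nrow = n_iter, ncol = nb)
  set.seed(derive_seed(params$seed, 101))
  dropped <- 0L
  for (k in seq_len(nrow(pred_det))) {
    ev <- pred_det[k, ]
    roll <- rolls[rolls$roll_id == ev$roll_id, ]
    t <- ts_num(ev$timestamp)
    tod <- t %% 86400
    d <- eligible_day_nums(ts_num(roll$start), ts_num(roll$end), tod, margin_s)
    if (length(d) == 0) {
      warn(sprintf("predator event in roll %s has no eligible date; dropped",
                   ev$roll_id))
      dropped <- dropped + 1L
      next
    }
    prey_sorted <- prey_by_cam[[ev$camera_id]] %||% numeric()
    M <- block_count_matrix(d * 86400 + tod, prey_sorted,
                            params$block_width, params$n_blocks_per_side)
    observed <- observed +
      block_count_matrix(t, prey_sorted, params$block_width,
                         params$n_blocks_per_side)[1, ]
    if (n_iter > 0) {
      idx <- sample.int(length(d), n_iter, replace = TRUE)
      acc <- acc + M[idx, , drop = FALSE]
    }
  }

  n_events <- nrow(pred_det) - dropped
  if (n_events == 0) {
    base$no_data <- TRUE
    return(structure(base, class = "avoidance_null"))
  }
  base$observed <- as.integer(observed)
  base$null <- acc
  storage.mode(base$null) <- "integer"
  base$n_predator_events <- as.integer(n_events)
  base$n_rolls_used <- nrow(rolls)
  base$no_data <- FALSE
  structure(base, class = "avoidance_null")
}

#' Empirical one-sided p-values from a null distribution
#'
#' For each after-block the p-value is the proportion of null iterations
#' with a count less than or equal to the observed count (low prey counts
#' after a predator are the avoidance-side extreme); for each before-block
#' it is the proportion greater than or equal to the observed count.
#' Ties are counted on both sides, so the two one-sided p-values of a block
#' always sum to at least one.
#'
#' @param observed Integer vector of observed block counts (chronological).
#' @param null Either an `avoidance_null` or an iterations x blocks matrix.
#' @param params A [test_params()] (ignored when `null` is an
#'   `avoidance_null`, which carries its own).
#' @return A tibble with `block`, `window`, `side`, `observed`, `null_mean`,
#'   `null_sd` and `p`.
#' @export
p_values <- function(observed, null, params = test_params()) {
  if (inherits(null, "avoidance_null")) {
    params <- null$params
    if (isTRUE(null$no_data)) {
      abort("no data: no roll holds both species, no p-value is defined")
    }
    if (missing(observed)) observed <- null$observed
    null <- null$null
  }
  if (is.null(dim(null)) || nrow(null) == 0) {
    abort("`null` must contain at least one iteration")
  }
  nb <- 2L * params$n_blocks_per_side
  stopifnot(length(observed) == nb, ncol(null) == nb)
  side <- block_sides(params)
  p <- vapply(seq_len(nb), function(j) {
    if (side[j] == "after") mean(null[, j] <= observed[j])
    else mean(null[, j] >= observed[j])
  }, numeric(1))
  tibble(
    block = seq_len(nb),
    window = block_labels(params),
    side = side,
    observed = as.integer(observed),
    null_mean = colMeans(null),
    null_sd = apply(null, 2, sd),
    p = p
  )
}

#' Run the full avoidance randomization test for one site
#'
#' Composes [preprocess_survey()], [null_distribution()] and [p_values()]
#' for one prey x predator pair at one site. Blocks with `p < alpha` are
#' flagged; before-block flags indicate prey presence *higher* than expected
#' before the predator detection (e.g. a predator following its prey),
#' after-block flags indicate reactive avoidance.
#'
#' @param survey A raw `camtrap_survey` with `species_roles` set.
#' @param prey,predator Species names (must appear in `species_roles`).
#' @param params A [test_params()].
#' @param site Site to analyse; required only when the survey spans several
#'   sites.
#' @param preprocessed Set to `TRUE` when `survey` has already been through
#'   [preprocess_survey()] (it will not be filtered again).
#' @return An object of class `avoidance_test` with the observed counts, the
#'   null matrix, per-block p-values, and bookkeeping (`n_predator_events`,
#'   `n_rolls_used`, `n_iterations`, `seed`). `no_data` is `TRUE` when no
#'   roll holds both species. Methods: [tidy()], [glance()], [autoplot()].
#' @export
run_site_test <- function(survey, prey, predator, params = test_params(),
                          site = NULL, preprocessed = FALSE) {
  stopifnot(inherits(survey, "camtrap_survey"))
  roles <- survey$species_roles
  if (!is.null(roles)) {
    for (sp in c(prey, predator)) {
      if (!sp %in% names(roles)) {
        abort(sprintf("species '%s' is absent from species_roles", sp),
              class = "avoidr_config_error")
      }
    }
  }
  sites <- unique(survey$rolls$site_id)
  if (is.null(site)) {
    if (length(sites) > 1) {
      abort("survey spans several sites; supply `site`")
    }
    site <- sites
  } else {
    survey$detections <- survey$detections[survey$detections$site_id == site, ]
    survey$rolls <- survey$rolls[survey$rolls$site_id == site, ]
  }

  if (!preprocessed) {
    survey <- preprocess_survey(survey, params)
  }
  nd <- null_distribution(survey, prey, predator, params)
  res <- unclass(nd)
  res$site_id <- site
  res$prey_species <- prey
  res$predator_species <- predator
  res$filter_report <- survey$filter_report
  if (!isTRUE(nd$no_data)) {
    res$result <- p_values(nd$observed, nd) |>
      dplyr::mutate(significant = .data$p < params$alpha)
  } else {
    res$result <- NULL
  }
  structure(res, class = "avoidance_test")
}

#' @export
print.avoidance_test <- function(x, ...) {
  cat(sprintf("<avoidance_test> site %s | prey %s | predator %s\n",
              x$site_id, x$prey_species, x$predator_species))
  if (isTRUE(x$no_data)) {
    cat("  no data: no roll holds both species\n")
    return(invisible(x))
  }
  cat(sprintf("  %d predator event(s) over %d roll(s), %d iterations, seed %d\n",
              x$n_predator_events, x$n_rolls_used, x$n_iterations, x$seed))
  df <- as.data.frame(x$result[c("window", "side", "observed", "p",
                                 "significant")])
  df$p <- sprintf("%.3f%s", df$p, ifelse(df$significant, " *", ""))
  df$significant <- NULL
  print(df, row.names = FALSE)
  invisible(x)
}

#' @describeIn run_site_test Per-block tidy summary: one row per time block
#'   with observed count, null mean/SD, p-value and significance flag.
#' @param x An `avoidance_test`.
#' @param ... Unused.
#' @export
tidy.avoidance_test <- function(x, ...) {
  if (isTRUE(x$no_data)) {
    return(tibble(
      site_id = character(), prey = character(), predator = character(),
      block = integer(), window = character(), side = character(),
      observed = integer(), null_mean = numeric(), null_sd = numeric(),
      p = numeric(), significant = logical()
    ))
  }
  dplyr::bind_cols(
    tibble(site_id = x$site_id, prey = x$prey_species,
           predator = x$predator_species),
    x$result
  )
}

#' @describeIn run_site_test One-row summary of the test.
#' @export
glance.avoidance_test <- function(x, ...) {
  tibble(
    site_id = x$site_id, prey = x$prey_species, predator = x$predator_species,
    no_data = isTRUE(x$no_data),
    n_predator_events = x$n_predator_events,
    n_rolls_used = x$n_rolls_used,
    n_iterations = x$n_iterations,
    alpha = x$params$alpha,
    min_p_after = if (isTRUE(x$no_data)) NA_real_ else {
      min(x$result$p[x$result$side == "after"])
    },
    n_significant = if (isTRUE(x$no_data)) NA_integer_ else {
      sum(x$result$significant)
    },
    seed = x$seed
  )
}

#' Null counts of an avoidance test in long form
#'
#' One row per iteration x block, the machine-readable data behind the
#' null-distribution density panels.
#'
#' @param x An `avoidance_test` (or `avoidance_null`).
#' @return A tibble with `block`, `window`, `side`, `iteration`, `count`.
#' @export
null_counts_long <- function(x) {
  if (isTRUE(x$no_data)) {
    abort("no data: null distribution was not computed")
  }
  nb <- ncol(x$null)
  tibble(
    block = rep(seq_len(nb), each = nrow(x$null)),
    window = rep(x$window, each = nrow(x$null)),
    side = rep(x$side, each = nrow(x$null)),
    iteration = rep(seq_len(nrow(x$null)), times = nb),
    count = as.integer(x$null)
  )
}

#' @describeIn run_site_test Density panels of the null counts per block
#'   with the observed count as a vertical line.
#' @param object An `avoidance_test`.
#' @export
autoplot.avoidance_test <- function(object, ...) {
  if (isTRUE(object$no_data)) {
    abort("no data: nothing to plot")
  }
  long <- null_counts_long(object)
  long$window <- factor(long$window, levels = object$window)
  obs <- tibble(window = factor(object$window, levels = object$window),
                observed = object$observed)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$count)) +
    ggplot2::geom_density(fill = "grey70", colour = NA) +
    ggplot2::geom_vline(data = obs,
                        ggplot2::aes(xintercept = .data$observed),
                        colour = "red") +
    ggplot2::facet_wrap(~window, scales = "free", nrow = 1) +
    ggplot2::labs(
      x = "prey detections per block (null iterations)", y = "density",
      title = sprintf("%s around %s detections, site %s",
                      object$prey_species, object$predator_species,
                      object$site_id)
    ) +
    ggplot2::theme_minimal()
}
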