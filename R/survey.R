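#' Assemble and validate a camera-trap survey
#'
#' A survey bundles a detection table (one row per motion-triggered capture
#' event), a roll table (one row per continuous operating interval of a
#' camera between two services), an optional species-role map and an optional
#' camera exclusion list (e.g. cameras placed at waterholes, where
#' predator-prey dynamics differ). Detections on excluded cameras are dropped
#' at construction time and the drop is reported.
#'
#' @param detections A data frame with columns `site_id`, `camera_id`,
#'   `roll_id`, `species` (character) and `timestamp` (`POSIXct`, naive local
#'   clock time stored as UTC).
#' @param rolls A data frame with columns `roll_id`, `camera_id`, `site_id`,
#'   `start`, `end` (`POSIXct`).
#' @param species_roles Optional named character vector mapping species to one
#'   of `"prey"`, `"predator"`, `"other"`.
#' @param excluded_cameras Character vector of `camera_id`s to drop.
#' @param quiet Suppress informational messages about dropped rows.
#'
#' @return An object of class `camtrap_survey`: a list with tibbles
#'   `detections` and `rolls`, plus `species_roles` and `excluded_cameras`.
#'
#' @details Validation enforces: `end > start` for every roll; rolls of the
#'   same camera do not overlap; every detection references an existing roll
#'   of its own camera; every detection timestamp lies within its roll's
#'   `[start, end]`; species labels are non-empty. Violations are reported
#'   with the offending row numbers.
#'
#' @examples
#' rolls <- tibble::tibble(
#'   roll_id = "C01-R1", camera_id = "C01", site_id = "S1",
#'   start = as.POSIXct("2020-01-01 00:00", tz = "UTC"),
#'   end = as.POSIXct("2020-04-01 00:00", tz = "UTC")
#' )
#' det <- tibble::tibble(
#'   site_id = "S1", camera_id = "C01", roll_id = "C01-R1",
#'   species = "baboon",
#'   timestamp = as.POSIXct("2020-02-01 10:00", tz = "UTC")
#' )
#' camtrap_survey(det, rolls)
#' @export
camtrap_survey <- function(detections, rolls, species_roles = NULL,
                           excluded_cameras = character(), quiet = FALSE) {
  det_cols <- c("site_id", "camera_id", "roll_id", "species", "timestamp")
  roll_cols <- c("roll_id", "camera_id", "site_id", "start", "end")
  detections <- as_tibble(detections)
  rolls <- as_tibble(rolls)
  stopifnot_cols(detections, det_cols, "detection table")
  stopifnot_cols(rolls, roll_cols, "roll table")
  detections <- detections[det_cols]
  rolls <- rolls[roll_cols]

  if (!inherits(detections$timestamp, "POSIXct")) {
    abort("`detections$timestamp` must be POSIXct")
  }
  if (!inherits(rolls$start, "POSIXct") || !inherits(rolls$end, "POSIXct")) {
    abort("`rolls$start` and `rolls$end` must be POSIXct")
  }
  if (anyDuplicated(rolls$roll_id)) {
    abort("duplicated roll_id in roll table")
  }
  bad_span <- which(!(ts_num(rolls$end) > ts_num(rolls$start)))
  if (length(bad_span) > 0) {
    abort(sprintf("roll(s) with end <= start at roll-table row(s): %s",
                  paste(bad_span, collapse = ", ")))
  }
  # per-camera non-overlap
  by_cam <- split(rolls, rolls$camera_id)
  for (cam in by_cam) {
    if (nrow(cam) > 1) {
      o <- order(ts_num(cam$start))
      s <- ts_num(cam$start)[o]; e <- ts_num(cam$end)[o]
      if (any(s[-1] < e[-length(e)])) {
        abort(sprintf("overlapping rolls for camera %s", cam$camera_id[[1]]))
      }
    }
  }

  excluded_cameras <- unique(as.character(excluded_cameras))
  if (length(excluded_cameras) > 0) {
    n_det_drop <- sum(detections$camera_id %in% excluded_cameras)
    detections <- dplyr::filter(detections, !.data$camera_id %in% excluded_cameras)
    rolls <- dplyr::filter(rolls, !.data$camera_id %in% excluded_cameras)
    if (!quiet) {
      inform(sprintf("excluded %d camera(s): dropped %d detection(s)",
                     length(excluded_cameras), n_det_drop))
    }
  }

  if (nrow(detections) > 0) {
    if (any(is.na(detections$species) | detections$species == "")) {
      abort(sprintf(
        "empty species label at detection row(s): %s",
        paste(which(is.na(detections$species) | detections$species == ""),
              collapse = ", ")
      ))
    }
    idx <- match(detections$roll_id, rolls$roll_id)
    if (anyNA(idx)) {
      abort(sprintf(
        "detection row(s) reference unknown roll_id: %s",
        paste(which(is.na(idx)), collapse = ", ")
      ), class = "avoidr_validation_error")
    }
    t <- ts_num(detections$timestamp)
    out_of_roll <- which(t < ts_num(rolls$start)[idx] | t > ts_num(rolls$end)[idx])
    if (length(out_of_roll) > 0) {
      abort(sprintf(
        "detection timestamp outside its roll at detection row(s): %s",
        paste(out_of_roll, collapse = ", ")
      ), class = "avoidr_validation_error")
    }
  }

  if (!is.null(species_roles)) {
    if (is.null(names(species_roles)) || any(names(species_roles) == "")) {
      abort("`species_roles` must be a named character vector")
    }
    bad <- !species_roles %in% c("prey", "predator", "other")
    if (any(bad)) {
      abort(sprintf("invalid role(s): %s (must be prey/predator/other)",
                    paste(unique(species_roles[bad]), collapse = ", ")))
    }
    species_roles <- stats::setNames(as.character(species_roles),
                                     names(species_roles))
  }

  structure(
    list(
      detections = dplyr::arrange(detections, .data$camera_id, .data$timestamp),
      rolls = dplyr::arrange(rolls, .data$camera_id, .data$start),
      species_roles = species_roles,
      excluded_cameras = excluded_cameras
    ),
    class = "camtrap_survey"
  )
}

#' @export
print.camtrap_survey <- function(x, ...) {
  cat(sprintf(
    "<camtrap_survey> %d detections | %d rolls | %d cameras | %d site(s)\n",
    nrow(x$detections), nrow(x$rolls),
    dplyr::n_distinct(x$rolls$camera_id), dplyr::n_distinct(x$rolls$site_id)
  ))
  if (nrow(x$detections) > 0) {
    tab <- dplyr::count(x$detections, .data$species)
    cat(paste0("  ", tab$species, ": ", tab$n, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Read a survey from delimited text files
#'
#' Reads a detection CSV and a roll CSV (comma-separated, UTF-8, header row
#' mandatory, timestamps ISO 8601 `YYYY-MM-DDTHH:MM` with optional `:SS`),
#' then validates and assembles them with [camtrap_survey()]. Timestamps are
#' treated as naive local clock time; second precision is preserved when
#' present.
#'
#' @param detections_path Path to the detection CSV
#'   (`site_id,camera_id,roll_id,species,timestamp`).
#' @param rolls_path Path to the roll CSV
#'   (`roll_id,camera_id,site_id,start,end`).
#' @param config Optional analysis configuration, either a path to a YAML file
#'   or a list as returned by [read_config()]; supplies `species_roles` and
#'   `excluded_cameras` when the explicit arguments are `NULL`.
#' @param species_roles,excluded_cameras Passed to [camtrap_survey()];
#'   override the config when non-`NULL`.
#' @param quiet Suppress row-count messages.
#'
#' @return A `camtrap_survey`.
#' @seealso [write_survey()] for the inverse operation.
#' @export
read_survey <- function(detections_path, rolls_path, config = NULL,
                        species_roles = NULL, excluded_cameras = NULL,
                        quiet = FALSE) {
  if (!file.exists(detections_path)) {
    abort(sprintf("detection file not found: %s", detections_path))
  }
  if (!file.exists(rolls_path)) {
    abort(sprintf("roll file not found: %s", rolls_path))
  }
  if (is.character(config)) config <- read_config(config)
  if (is.null(species_roles)) species_roles <- config$species_roles
  if (is.null(excluded_cameras)) {
    excluded_cameras <- config$excluded_cameras %||% character()
  }

  det <- readr::read_csv(detections_path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  rolls <- readr::read_csv(rolls_path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  stopifnot_cols(det, c("site_id", "camera_id", "roll_id", "species", "timestamp"),
                 "detection file")
  stopifnot_cols(rolls, c("roll_id", "camera_id", "site_id", "start", "end"),
                 "roll file")

  parse_col <- function(x, what, file) {
    t <- parse_iso_ts(x)
    bad <- which(is.na(t) & !is.na(x))
    if (length(bad) > 0 || anyNA(x)) {
      bad <- sort(unique(c(bad, which(is.na(x)))))
      abort(sprintf("unparseable %s timestamp in %s at data row(s): %s",
                    what, file, paste(bad, collapse = ", ")))
    }
    t
  }
  det$timestamp <- parse_col(det$timestamp, "detection", basename(detections_path))
  rolls$start <- parse_col(rolls$start, "roll start", basename(rolls_path))
  rolls$end <- parse_col(rolls$end, "roll end", basename(rolls_path))

  if (!quiet) {
    inform(sprintf("read %d detection(s) and %d roll(s)", nrow(det), nrow(rolls)))
  }
  camtrap_survey(det, rolls, species_roles = species_roles,
                 excluded_cameras = excluded_cameras, quiet = quiet)
}

#' Write a survey to delimited text files
#'
#' Serializes the detection and roll tables of a survey as the CSV dialect
#' read by [read_survey()]. Timestamps are written as ISO 8601 minute strings
#' (`YYYY-MM-DDTHH:MM`) when every time in the survey falls on a whole
#' minute, and with seconds otherwise, so that
#' `read_survey(write_survey(x))` round-trips exactly at the declared
#' resolution.
#'
#' @param survey A `camtrap_survey`.
#' @param dir Output directory (created if absent).
#' @param stem File-name stem; files are `<stem>_detections.csv` and
#'   `<stem>_rolls.csv`.
#' @return Invisibly, a named character vector with the two paths.
#' @export
write_survey <- function(survey, dir, stem = "survey") {
  stopifnot(inherits(survey, "camtrap_survey"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  all_t <- c(ts_num(survey$detections$timestamp),
             ts_num(survey$rolls$start), ts_num(survey$rolls$end))
  with_sec <- any(all_t %% 60 != 0)

  det <- survey$detections
  det$timestamp <- format_iso_ts(det$timestamp, with_seconds = with_sec)
  rolls <- survey$rolls
  rolls$start <- format_iso_ts(rolls$start, with_seconds = with_sec)
  rolls$end <- format_iso_ts(rolls$end, with_seconds = with_sec)

  det_path <- file.path(dir, paste0(stem, "_detections.csv"))
  roll_path <- file.path(dir, paste0(stem, "_rolls.csv"))
  readr::write_csv(det, det_path, progress = FALSE)
  readr::write_csv(rolls, roll_path, progress = FALSE)
  invisible(c(detections = det_path, rolls = roll_path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
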