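#' Read an analysis configuration from YAML
#'
#' The configuration bundles file paths, the species-role map, the camera
#' exclusion list, the test parameters and (optionally) a synthetic-survey
#' scenario. Recognised keys:
#'
#' * `detections`, `rolls`: paths to the survey CSVs
#' * `species_roles`: mapping species -> prey/predator/other
#' * `excluded_cameras`: list of camera ids dropped at load
#' * `params`: any field of [test_params()]
#' * `scenario`: any field of [scenario()] (for the simulate stage)
#' * `output_dir`: directory for stage artifacts
#' * `prey`, `predators`, `site`: defaults for the test/power stages
#' * `power`: list with `n` and `n_subsets` for the power stage
#'
#' @param path Path to a YAML file.
#' @return A named list of class `analysis_config` with `params` as a
#'   `test_params` object and `scenario` (when present) as a `scenario`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  cfg <- raw
  cfg$params <- do.call(test_params, raw$params %||% list())
  if (!is.null(raw$scenario)) {
    sc <- raw$scenario
    if (!is.null(sc$origin)) sc$origin <- parse_iso_ts(sc$origin)
    cfg$scenario <- do.call(scenario, sc)
  }
  if (!is.null(raw$species_roles)) {
    cfg$species_roles <- unlist(raw$species_roles)
  }
  cfg$excluded_cameras <- as.character(raw$excluded_cameras %||% character())
  structure(cfg, class = "analysis_config")
}

validate_config_species <- function(cfg, species) {
  roles <- cfg$species_roles
  if (is.null(roles)) abort("config lacks species_roles",
                            class = "avoidr_config_error")
  missing <- setdiff(species, names(roles))
  if (length(missing) > 0) {
    abort(sprintf("species absent from species_roles: %s",
                  paste(missing, collapse = ", ")),
          class = "avoidr_config_error")
  }
  invisible(cfg)
}

write_manifest <- function(out_dir, cfg, stage, counts) {
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("avoidr")),
    seed = cfg$params$seed,
    config_hash = rlang::hash(unclass(cfg)),
    counts = counts
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

load_survey_from_config <- function(cfg) {
  if (is.null(cfg$detections) || is.null(cfg$rolls)) {
    abort("config must name `detections` and `rolls` files",
          class = "avoidr_config_error")
  }
  read_survey(cfg$detections, cfg$rolls,
              species_roles = cfg$species_roles,
              excluded_cameras = cfg$excluded_cameras, quiet = TRUE)
}

#' Run one stage of the analysis pipeline
#'
#' A single entry point wiring configuration, logging and the pipeline
#' stages; every artifact is a CSV (plus a JSON run manifest recording the
#' config hash, seed, package version and row counts), and every stage is
#' deterministic given the config seed.
#'
#' Stages:
#' * `simulate`: generate a synthetic survey from `config$scenario` and
#'   write it in the survey CSV dialect.
#' * `preprocess`: read the survey, apply the detection filters, write the
#'   filtered survey and a per-stage filter report.
#' * `test`: run the avoidance randomization test for each predator at each
#'   site; write the significance table (`table.csv`), full-precision
#'   results (`results.csv`) and the null-count histograms
#'   (`null_counts.csv`).
#' * `power`: run [downsampling_study()]; write the p-matrix and summary.
#' * `report`: reformat a previously written `results.csv` as the
#'   significance table.
#'
#' @param config An `analysis_config` (see [read_config()]) or a path to a
#'   YAML file.
#' @param stage One of `"simulate"`, `"preprocess"`, `"test"`, `"power"`,
#'   `"report"`.
#' @param out_dir Output directory; defaults to `config$output_dir`.
#' @return Invisibly, a named character vector of written file paths.
#' @export
run_pipeline <- function(config, stage = c("simulate", "preprocess", "test",
                                           "power", "report"),
                         out_dir = NULL) {
  stage <- match.arg(stage)
  if (is.character(config)) config <- read_config(config)
  cfg <- config
  out_dir <- out_dir %||% cfg$output_dir %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  inform(sprintf("[%s] starting (seed %d)", stage, cfg$params$seed))

  paths <- withCallingHandlers(
    switch(stage,
      simulate = stage_simulate(cfg, out_dir),
      preprocess = stage_preprocess(cfg, out_dir),
      test = stage_test(cfg, out_dir),
      power = stage_power(cfg, out_dir),
      report = stage_report(cfg, out_dir)
    ),
    error = function(e) {
      abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
            parent = e)
    }
  )
  inform(sprintf("[%s] wrote %s", stage,
                 paste(basename(paths), collapse = ", ")))
  invisible(paths)
}

stage_simulate <- function(cfg, out_dir) {
  if (is.null(cfg$scenario)) {
    abort("config lacks a `scenario` block", class = "avoidr_config_error")
  }
  sv <- simulate_interacting(cfg$scenario)
  paths <- write_survey(sv, out_dir, stem = "simulated")
  write_manifest(out_dir, cfg, "simulate",
                 list(detections = nrow(sv$detections), rolls = nrow(sv$rolls)))
  c(paths, manifest = file.path(out_dir, "manifest.json"))
}

stage_preprocess <- function(cfg, out_dir) {
  sv <- load_survey_from_config(cfg)
  pp <- preprocess_survey(sv, cfg$params)
  paths <- write_survey(pp, out_dir, stem = "filtered")
  rep_path <- file.path(out_dir, "filter_report.csv")
  readr::write_csv(pp$filter_report, rep_path, progress = FALSE)
  predators <- names(cfg$species_roles)[cfg$species_roles == "predator"]
  cdr <- co_detection_rate(pp$detections, predators)
  inform(sprintf("[preprocess] predator co-detection rate: %s",
                 if (is.na(cdr)) "not applicable" else sprintf("%.1f%%", cdr)))
  write_manifest(out_dir, cfg, "preprocess", list(
    detections_in = nrow(sv$detections),
    detections_out = nrow(pp$detections),
    co_detection_rate_pct = cdr
  ))
  c(paths, filter_report = rep_path,
    manifest = file.path(out_dir, "manifest.json"))
}

stage_test <- function(cfg, out_dir) {
  prey <- cfg$prey %||% abort("config lacks `prey`",
                              class = "avoidr_config_error")
  predators <- cfg$predators %||%
    names(cfg$species_roles)[cfg$species_roles == "predator"]
  validate_config_species(cfg, c(prey, predators))
  sv <- load_survey_from_config(cfg)
  sites <- cfg$site %||% unique(sv$rolls$site_id)

  grid <- tidyr::expand_grid(site = sites, predator = predators)
  fits <- purrr::pmap(grid, function(site, predator) {
    run_site_test(sv, prey, predator, cfg$params, site = site)
  })

  tab_path <- file.path(out_dir, "table.csv")
  report_table(fits, path = tab_path)
  res_path <- file.path(out_dir, "results.csv")
  readr::write_csv(dplyr::bind_rows(purrr::map(fits, tidy)), res_path,
                   progress = FALSE)
  null_path <- file.path(out_dir, "null_counts.csv")
  nulls <- purrr::map(fits, function(f) {
    if (isTRUE(f$no_data)) return(NULL)
    dplyr::mutate(
      dplyr::count(null_counts_long(f), .data$block, .data$window,
                   .data$side, .data$count),
      site = f$site_id, predator = f$predator_species, .before = 1
    )
  })
  readr::write_csv(dplyr::bind_rows(nulls), null_path, progress = FALSE)
  write_manifest(out_dir, cfg, "test", list(
    n_results = length(fits),
    n_no_data = sum(purrr::map_lgl(fits, ~ isTRUE(.x$no_data)))
  ))
  c(table = tab_path, results = res_path, null_counts = null_path,
    manifest = file.path(out_dir, "manifest.json"))
}

stage_power <- function(cfg, out_dir) {
  prey <- cfg$prey %||% abort("config lacks `prey`",
                              class = "avoidr_config_error")
  predator <- (cfg$predators %||%
    names(cfg$species_roles)[cfg$species_roles == "predator"])[[1]]
  validate_config_species(cfg, c(prey, predator))
  pw <- cfg$power %||% abort("config lacks a `power` block",
                             class = "avoidr_config_error")
  sv <- load_survey_from_config(cfg)
  ds <- downsampling_study(sv, prey, predator, n = pw$n,
                           n_subsets = pw$n_subsets, params = cfg$params,
                           site = cfg$site)
  pm_path <- file.path(out_dir, "p_matrix.csv")
  readr::write_csv(ds$p_matrix, pm_path, progress = FALSE)
  sm_path <- file.path(out_dir, "power_summary.csv")
  readr::write_csv(tidy(ds), sm_path, progress = FALSE)
  write_manifest(out_dir, cfg, "power", list(
    subset_size = ds$subset_size, n_subsets = ds$n_subsets
  ))
  c(p_matrix = pm_path, summary = sm_path,
    manifest = file.path(out_dir, "manifest.json"))
}

stage_report <- function(cfg, out_dir) {
  res_path <- file.path(out_dir, "results.csv")
  if (!file.exists(res_path)) {
    abort(sprintf("no results.csv in %s; run the test stage first", out_dir))
  }
  res <- readr::read_csv(res_path, show_col_types = FALSE, progress = FALSE)
  alpha <- cfg$params$alpha
  wide <- res |>
    dplyr::mutate(cell = sprintf("%.3f%s", .data$p,
                                 ifelse(.data$p < alpha, "*", ""))) |>
    dplyr::select("site_id", "prey", "predator", "window", "cell") |>
    tidyr::pivot_wider(names_from = "window", values_from = "cell")
  tab_path <- file.path(out_dir, "table_formatted.csv")
  readr::write_csv(wide, tab_path, progress = FALSE)
  c(table = tab_path)
}
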