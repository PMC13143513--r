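#' Format a collection of test results as a significance table
#'
#' One row per site x prey x predator, one column per time block in
#' chronological order, p-values printed to three decimals with a `*` marker
#' for blocks significant at `alpha`. Full-precision values are available
#' through [tidy()] on the individual results.
#'
#' @param results A single `avoidance_test` or a list of them. All results
#'   must share the same block structure, iteration count and alpha.
#' @param path Optional CSV path to write the formatted table to.
#' @return The formatted tibble (invisibly when `path` is given). No-data
#'   results render as `"no data"` in every block column.
#' @export
report_table <- function(results, path = NULL) {
  if (inherits(results, "avoidance_test")) results <- list(results)
  if (length(results) > 0) {
    ref <- results[[1]]$params
    for (r in results) {
      p <- r$params
      same <- identical(p$n_iterations, ref$n_iterations) &&
        identical(p$alpha, ref$alpha) &&
        identical(p$block_width, ref$block_width) &&
        identical(p$n_blocks_per_side, ref$n_blocks_per_side)
      if (!same) {
        abort("results were produced with inconsistent test parameters")
      }
    }
    labels <- block_labels(ref)
  } else {
    labels <- block_labels(test_params())
  }

  rows <- purrr::map(results, function(r) {
    base <- tibble(site = r$site_id, prey = r$prey_species,
                   predator = r$predator_species)
    vals <- if (isTRUE(r$no_data)) {
      rep("no data", length(labels))
    } else {
      sprintf("%.3f%s", r$result$p,
              ifelse(r$result$p < r$params$alpha, "*", ""))
    }
    dplyr::bind_cols(base, tibble::as_tibble_row(
      stats::setNames(as.list(vals), labels)
    ))
  })
  out <- if (length(rows) > 0) {
    dplyr::bind_rows(rows)
  } else {
    dplyr::bind_cols(
      tibble(site = character(), prey = character(), predator = character()),
      tibble::as_tibble(stats::setNames(
        replicate(length(labels), character(), simplify = FALSE), labels
      ))
    )
  }
  if (!is.null(path)) {
    readr::write_csv(out, path, progress = FALSE)
    return(invisible(out))
  }
  out
}
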