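#' Subsample prey detections
#'
#' Uniform sample without replacement of exactly `n` detections, returned in
#' timestamp order.
#'
#' @param detections Detection tibble.
#' @param n Target sample size; must not exceed the number of rows.
#' @param seed Optional seed; when `NULL` the current RNG state is used.
#' @return The sampled rows, sorted by timestamp.
#' @export
downsample <- function(detections, n, seed = NULL) {
  detections <- as_tibble(detections)
  check_scalar_number(n, "n", 0)
  if (n > nrow(detections)) {
    abort(sprintf("cannot downsample to n = %d from %d detections",
                  n, nrow(detections)))
  }
  if (!is.null(seed)) set.seed(seed)
  keep <- sort(sample.int(nrow(detections), n))
  out <- detections[keep, ]
  dplyr::arrange(out, .data$timestamp)
}

#' Downsampling power study
#'
#' Quantifies how much significance the avoidance test loses when the prey
#' sample shrinks: the prey detections are repeatedly subsampled to a target
#' size, the full randomization test is re-run on each subset with an
#' independent derived substream (for both the subsetting and the
#' randomization), and the per-block p-values are summarized as mean, SD and
#' the fraction of subsets significant at `alpha`.
#'
#' Only prey detections are subsampled; predator events are untouched.
#'
#' @param survey A raw `camtrap_survey` with `species_roles` set.
#' @param prey,predator Species names.
#' @param n Prey sample size of each subset.
#' @param n_subsets Number of subsets.
#' @param params A [test_params()]; its seed drives every substream.
#' @param site Site to analyse when the survey spans several.
#' @return An object of class `downsampling_result`: `p_matrix` (a long
#'   tibble, one row per subset x block), a per-block `summary` tibble
#'   (`mean_p`, `sd_p`, `frac_significant`; `sd_p` is `NA` when
#'   `n_subsets = 1`), `subset_size` and `n_subsets`. Methods: [tidy()],
#'   [glance()], [autoplot()].
#' @export
downsampling_study <- function(survey, prey, predator, n, n_subsets,
                               params = test_params(), site = NULL) {
  stopifnot(inherits(survey, "camtrap_survey"))
  check_scalar_number(n_subsets, "n_subsets", 1)
  is_prey <- survey$detections$species == prey
  prey_det <- survey$detections[is_prey, ]
  other_det <- survey$detections[!is_prey, ]
  if (n > nrow(prey_det)) {
    abort(sprintf("cannot downsample to n = %d from %d prey detections",
                  n, nrow(prey_det)))
  }

  rows <- purrr::map(seq_len(n_subsets), function(j) {
    sub_seed <- derive_seed(params$seed, 500, j)
    sub <- downsample(prey_det, n, seed = derive_seed(sub_seed, 1))
    sv <- survey
    sv$detections <- dplyr::bind_rows(other_det, sub)
    pj <- params
    pj$seed <- derive_seed(sub_seed, 2)
    fit <- run_site_test(sv, prey, predator, pj, site = site)
    if (isTRUE(fit$no_data)) {
      return(NULL)
    }
    dplyr::mutate(tidy(fit)[c("block", "window", "side", "observed", "p",
                              "significant")],
                  subset = j, .before = 1)
  })
  p_matrix <- dplyr::bind_rows(rows)
  if (nrow(p_matrix) == 0) {
    abort("every subset produced a no-data result; nothing to summarize")
  }
  summary <- p_matrix |>
    dplyr::group_by(.data$block, .data$window, .data$side) |>
    dplyr::summarise(
      mean_p = mean(.data$p),
      sd_p = if (dplyr::n() > 1) sd(.data$p) else NA_real_,
      frac_significant = mean(.data$significant),
      .groups = "drop"
    )
  structure(
    list(
      p_matrix = p_matrix, summary = summary,
      subset_size = as.integer(n), n_subsets = as.integer(n_subsets),
      prey = prey, predator = predator, params = params,
      alpha = params$alpha
    ),
    class = "downsampling_result"
  )
}

#' @export
print.downsampling_result <- function(x, ...) {
  cat(sprintf(
    "<downsampling_result> %s vs %s | %d subsets of n = %d prey detections\n",
    x$prey, x$predator, x$n_subsets, x$subset_size
  ))
  print(as.data.frame(x$summary), row.names = FALSE, digits = 3)
  invisible(x)
}

#' @describeIn downsampling_study Per-block summary across subsets.
#' @param x A `downsampling_result`.
#' @param ... Unused.
#' @export
tidy.downsampling_result <- function(x, ...) {
  dplyr::mutate(x$summary, subset_size = x$subset_size,
                n_subsets = x$n_subsets)
}

#' @describeIn downsampling_study One-row summary (first after-block).
#' @export
glance.downsampling_result <- function(x, ...) {
  first_after <- dplyr::filter(x$summary, .data$side == "after") |>
    dplyr::slice_min(.data$block, n = 1)
  tibble(
    prey = x$prey, predator = x$predator,
    subset_size = x$subset_size, n_subsets = x$n_subsets,
    alpha = x$alpha,
    mean_p_first_after = first_after$mean_p,
    sd_p_first_after = first_after$sd_p,
    frac_significant_first_after = first_after$frac_significant
  )
}

#' @describeIn downsampling_study Histogram of subset p-values in the first
#'   after-block with the significance threshold marked.
#' @param object A `downsampling_result`.
#' @export
autoplot.downsampling_result <- function(object, ...) {
  first_after <- min(object$p_matrix$block[object$p_matrix$side == "after"])
  df <- dplyr::filter(object$p_matrix, .data$block == first_after)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$p)) +
    ggplot2::geom_histogram(breaks = seq(0, 1, by = 0.05),
                            fill = "grey60", colour = "white") +
    ggplot2::geom_vline(xintercept = object$alpha, colour = "red",
                        linetype = "dashed") +
    ggplot2::labs(
      x = sprintf("p-value in block %s", df$window[[1]]),
      y = "number of subsets",
      title = sprintf("significance after downsampling %s to n = %d (%d subsets)",
                      object$prey, object$subset_size, object$n_subsets)
    ) +
    ggplot2::theme_minimal()
}
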