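#' Parameters of the avoidance randomization test
#'
#' Collects every tunable of the filtering and testing pipeline with the
#' defaults used throughout: a 30-minute time-to-independence gap, a 72-hour
#' edge margin at both ends of each roll, three 24-hour blocks on each side
#' of a predator detection, 1000 randomization iterations, a 0.05
#' significance level and a 30-day minimum roll lifespan.
#'
#' @param independence_gap Gap defining a cluster of consecutive detections,
#'   in minutes. Consecutive detections of one species at one camera closer
#'   than this chain into a single cluster, of which only the central
#'   detection is retained.
#' @param edge_margin Margin excluded at both ends of each roll, in hours, so
#'   that the full before/after observation window is available for every
#'   retained predator detection.
#' @param block_width Width of one counting block, in hours.
#' @param n_blocks_per_side Number of blocks before and after the reference
#'   detection. A warning is raised when
#'   `n_blocks_per_side * block_width != edge_margin`, since the observation
#'   window then no longer matches the guaranteed margin.
#' @param n_iterations Number of date-randomization iterations.
#' @param alpha Significance level used to flag blocks.
#' @param min_lifespan_days Minimum roll lifespan in days; shorter rolls are
#'   dropped because their dates can only be randomized within a narrow
#'   window.
#' @param seed Master seed; every random draw in the pipeline derives a
#'   substream from it deterministically.
#'
#' @return An object of class `test_params` (a named list).
#' @export
test_params <- function(independence_gap = 30, edge_margin = 72,
                        block_width = 24, n_blocks_per_side = 3,
                        n_iterations = 1000, alpha = 0.05,
                        min_lifespan_days = 30, seed = 1L) {
  check_scalar_number(independence_gap, "independence_gap", 0, strict_lower = TRUE)
  check_scalar_number(edge_margin, "edge_margin", 0, strict_lower = TRUE)
  check_scalar_number(block_width, "block_width", 0, strict_lower = TRUE)
  check_scalar_number(n_blocks_per_side, "n_blocks_per_side", 1)
  check_scalar_number(n_iterations, "n_iterations", 0)
  check_scalar_number(alpha, "alpha", 0, 1, strict_lower = TRUE)
  if (alpha >= 1) abort("`alpha` must lie strictly between 0 and 1")
  check_scalar_number(min_lifespan_days, "min_lifespan_days", 0)
  check_scalar_number(seed, "seed")
  if (n_blocks_per_side * block_width != edge_margin) {
    warn(sprintf(
      "n_blocks_per_side * block_width = %g h does not equal edge_margin = %g h; blocks will extend beyond the guaranteed margin",
      n_blocks_per_side * block_width, edge_margin
    ))
  }
  structure(
    list(
      independence_gap = independence_gap,
      edge_margin = edge_margin,
      block_width = block_width,
      n_blocks_per_side = as.integer(n_blocks_per_side),
      n_iterations = as.integer(n_iterations),
      alpha = alpha,
      min_lifespan_days = min_lifespan_days,
      seed = as.integer(seed)
    ),
    class = "test_params"
  )
}

#' @export
print.test_params <- function(x, ...) {
  cat("<test_params>\n")
  cat(sprintf("  independence gap : %g min\n", x$independence_gap))
  cat(sprintf("  edge margin      : %g h\n", x$edge_margin))
  cat(sprintf("  blocks           : %d x %g h per side\n",
              x$n_blocks_per_side, x$block_width))
  cat(sprintf("  iterations       : %d, alpha = %g, seed = %d\n",
              x$n_iterations, x$alpha, x$seed))
  cat(sprintf("  min roll lifespan: %g days\n", x$min_lifespan_days))
  invisible(x)
}

# chronological block labels, before then after
block_labels <- function(params) {
  b <- params$n_blocks_per_side
  w <- params$block_width
  before <- sprintf("[%g,%g)", -w * (b:1), w * (1 - b:1))
  after <- sprintf("(%g,%g]", w * (1:b - 1), w * (1:b))
  c(before, after)
}

block_sides <- function(params) {
  rep(c("before", "after"), each = params$n_blocks_per_side)
}
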