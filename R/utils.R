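# Internal helpers: seed derivation, timestamp arithmetic, shared checks.
# All timestamps are naive local clock time stored as POSIXct in UTC, so
# second-of-day arithmetic is exact and no DST transitions exist.

# Deterministic substream seeds from one master seed. Fixed multiplicative
# mixer modulo 2^31 - 1; result always a valid positive integer seed.
derive_seed <- function(seed, ...) {
  ks <- c(...)
  x <- (abs(as.double(seed)) %% 2147483647) + 1
  for (k in ks) {
    x <- (x * 48271 + (abs(as.double(k)) + 1) * 9973) %% 2147483647
  }
  as.integer(x)
}

ts_num <- function(t) as.numeric(t)

# second of day, exact under UTC storage
sec_of_day <- function(t) as.numeric(t) %% 86400

# day number since epoch
day_num <- function(t) floor(as.numeric(t) / 86400)

num_to_ts <- function(x) {
  as.POSIXct(x, origin = "1970-01-01", tz = "UTC")
}

# parse ISO 8601 local timestamps ("YYYY-MM-DDTHH:MM[:SS]", T or space)
parse_iso_ts <- function(x) {
  suppressWarnings(lubridate::ymd_hms(x, tz = "UTC", truncated = 1, quiet = TRUE))
}

# ISO 8601 at minute resolution, or second resolution when needed
format_iso_ts <- function(t, with_seconds = NULL) {
  if (is.null(with_seconds)) {
    with_seconds <- any(as.numeric(t) %% 60 != 0)
  }
  fmt <- if (with_seconds) "%Y-%m-%dT%H:%M:%S" else "%Y-%m-%dT%H:%M"
  format(t, fmt, tz = "UTC")
}

stopifnot_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column%s: %s",
      what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ), class = "avoidr_schema_error")
  }
  invisible(df)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x)) {
    abort(sprintf("`%s` must be a single number", name))
  }
  ok_low <- if (strict_lower) x > lower else x >= lower
  if (!ok_low || x > upper) {
    abort(sprintf("`%s` = %s is outside its valid range", name, format(x)))
  }
  invisible(x)
}
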