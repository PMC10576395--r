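# Internal helpers shared across the pipeline.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
.zones <- c("river_up", "lake", "river_down")

# Parse ISO-8601 timestamps with explicit offset ("Z" or "+HH:MM"/"+HHMM")
# into POSIXct stored in UTC.  Returns NA for unparseable entries.
parse_utc <- function(x) {
  x <- as.character(x)
  y <- sub("Z$", "+0000", x)
  y <- sub("([+-][0-9]{2}):([0-9]{2})$", "\\1\\2", y)
  out <- as.POSIXct(strptime(y, "%Y-%m-%dT%H:%M:%OS%z", tz = "UTC"))
  # fall back to space-separated UTC (convenience for hand-written fixtures)
  bad <- is.na(out) & !is.na(x)
  if (any(bad)) {
    out[bad] <- as.POSIXct(strptime(x[bad], "%Y-%m-%d %H:%M:%OS", tz = "UTC"))
  }
  out
}

# Format POSIXct as ISO-8601 UTC with exactly millisecond precision.
# Manual second handling avoids strftime's truncation of fractional seconds.
format_utc_ms <- function(t) {
  n <- round(as.numeric(t) * 1000)
  base <- floor(n / 1000)
  ms <- n - base * 1000
  paste0(
    format(as.POSIXct(base, origin = "1970-01-01", tz = "UTC"),
           "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    sprintf(".%03dZ", as.integer(ms))
  )
}

as_utc <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  if (inherits(x, "Date")) {
    return(as.POSIXct(as.character(x), tz = "UTC"))
  }
  out <- parse_utc(x)
  if (anyNA(out) && !all(is.na(x))) {
    stop("unparseable timestamp(s): ", paste(utils::head(x[is.na(out)], 3),
                                             collapse = ", "))
  }
  out
}

# Deterministic 31-bit sub-seed derived from a global seed and a named
# substream key, so any subset of fish/receivers replays identically.
substream_seed <- function(seed, key) {
  b <- utf8ToInt(as.character(key))
  h <- 0
  for (v in b) h <- (h * 31 + v) %% 2147483647
  as.integer((h + (as.numeric(seed) %% 2147483647) * 97) %% 2147483646 + 1)
}

stop_missing_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
}

# Euclidean distance between two receiver ids given a receiver table.
receiver_dist <- function(receivers, id_a, id_b) {
  i <- match(id_a, receivers$receiver_id)
  j <- match(id_b, receivers$receiver_id)
  sqrt((receivers$x_m[i] - receivers$x_m[j])^2 +
       (receivers$y_m[i] - receivers$y_m[j])^2)
}
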