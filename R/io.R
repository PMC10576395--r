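#' Read a detection table
#'
#' Reads a CSV of receiver detections into the canonical detection
#' data frame used throughout the pipeline.  Timestamps must be ISO-8601
#' with an explicit offset (e.g. \code{2021-07-21T10:15:30.123Z}); they are
#' stored in UTC.  Rows are sorted by \code{(tag_id, timestamp_utc)}.
#'
#' @param path path to a CSV file with columns \code{timestamp_utc,
#'   receiver_id, tag_id, protocol, raw_value, sensor_type} (or renamed
#'   columns mapped via \code{schema}).
#' @param schema optional named character vector mapping canonical field
#'   names to the column names used in the file, e.g.
#'   \code{c(timestamp_utc = "DateTime")}.
#' @return a data frame of detections: \code{timestamp_utc} (POSIXct, UTC),
#'   \code{receiver_id}, \code{tag_id}, \code{protocol} (character),
#'   \code{raw_value} (integer or NA), \code{sensor_type} (one of
#'   \code{"accel"}, \code{"depth"}, \code{"temp"}, \code{"none"}).
#' @seealso [write_detections()], [trim_to_study()]
#' @export
read_detections <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                         colClasses = "character")
  cols <- c("timestamp_utc", "receiver_id", "tag_id", "protocol",
            "raw_value", "sensor_type")
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      if (schema[[canon]] %in% names(raw)) {
        names(raw)[names(raw) == schema[[canon]]] <- canon
      }
    }
  }
  stop_missing_cols(raw, cols, basename(path))
  ts <- parse_utc(raw$timestamp_utc)
  if (anyNA(ts)) {
    bad <- which(is.na(ts))
    stop(sprintf("%d unparseable timestamp(s) in %s; first offending data rows: %s",
                 length(bad), basename(path),
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  rv <- suppressWarnings(as.numeric(raw$raw_value))
  bad_rv <- which(!is.na(raw$raw_value) &
                  (is.na(rv) | rv < 0 | rv > 255 | rv != round(rv)))
  if (length(bad_rv)) {
    stop(sprintf("raw_value outside 0-255 integer range in %s at data row(s): %s",
                 basename(path), paste(utils::head(bad_rv, 10), collapse = ", ")))
  }
  out <- data.frame(
    timestamp_utc = ts,
    receiver_id = raw$receiver_id,
    tag_id = raw$tag_id,
    protocol = raw$protocol,
    raw_value = as.integer(rv),
    sensor_type = raw$sensor_type,
    stringsAsFactors = FALSE
  )
  validate_detections(out)
  out[order(out$tag_id, out$timestamp_utc), , drop = FALSE] |>
    `rownames<-`(NULL)
}

validate_detections <- function(dets) {
  ok_types <- c("accel", "depth", "temp", "none")
  bad <- which(!is.na(dets$sensor_type) & !dets$sensor_type %in% ok_types)
  if (length(bad)) {
    stop("invalid sensor_type at row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  if (any(!is.na(dets$raw_value) & (dets$raw_value < 0 | dets$raw_value > 255))) {
    stop("raw_value outside [0, 255]")
  }
  invisible(dets)
}

#' Write a detection table
#'
#' Writes detections as CSV with ISO-8601 UTC timestamps at millisecond
#' precision.  \code{write_detections} followed by [read_detections()]
#' round-trips every field exactly (timestamps to the millisecond).
#'
#' @param dets detection data frame (see [read_detections()]).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_detections <- function(dets, path) {
  out <- data.frame(
    timestamp_utc = format_utc_ms(dets$timestamp_utc),
    receiver_id = dets$receiver_id,
    tag_id = dets$tag_id,
    protocol = dets$protocol,
    raw_value = ifelse(is.na(dets$raw_value), "", as.character(dets$raw_value)),
    sensor_type = dets$sensor_type,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read receiver station metadata
#'
#' @param path CSV with columns \code{receiver_id, x_m, y_m, habitat,
#'   deploy_date, has_sync_tag}.  Coordinates are planar projected metres;
#'   \code{habitat} is one of \code{"river_up"}, \code{"lake"},
#'   \code{"river_down"}.
#' @return data frame of receiver stations with unique \code{receiver_id}.
#' @export
read_receivers <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stop_missing_cols(df, c("receiver_id", "x_m", "y_m", "habitat",
                          "deploy_date", "has_sync_tag"), basename(path))
  df$receiver_id <- as.character(df$receiver_id)
  if (anyDuplicated(df$receiver_id)) stop("duplicate receiver_id in ", path)
  if (!all(df$habitat %in% .zones)) {
    stop("habitat must be one of: ", paste(.zones, collapse = ", "))
  }
  df$deploy_date <- as.Date(df$deploy_date)
  df$has_sync_tag <- as.logical(df$has_sync_tag)
  df
}

#' @rdname read_receivers
#' @param receivers receiver data frame.
#' @export
write_receivers <- function(receivers, path) {
  utils::write.csv(receivers, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read fish/tag metadata
#'
#' @param path CSV with columns \code{tag_id, total_length_mm,
#'   fork_length_mm, tagging_site, release_time, release_habitat}.
#' @return data frame of tagged fish.
#' @export
read_fish <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stop_missing_cols(df, c("tag_id", "total_length_mm", "fork_length_mm",
                          "tagging_site", "release_time", "release_habitat"),
                    basename(path))
  df$tag_id <- as.character(df$tag_id)
  if (any(df$fork_length_mm <= 0 | df$total_length_mm < df$fork_length_mm)) {
    stop("lengths must satisfy total_length_mm >= fork_length_mm > 0")
  }
  if (any(!df$tagging_site %in% 1:9)) stop("tagging_site must be in 1..9")
  df$release_time <- as_utc(df$release_time)
  df
}

#' @rdname read_fish
#' @param fish fish data frame.
#' @export
write_fish <- function(fish, path) {
  out <- fish
  out$release_time <- format_utc_ms(out$release_time)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read sync-tag metadata
#'
#' @param path CSV with columns \code{tag_id, x_m, y_m,
#'   colocated_receiver_id}.  Sync tags sit at fixed positions for the whole
#'   study and anchor the clock-drift synchronisation.
#' @return data frame of sync tags.
#' @export
read_sync_tags <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stop_missing_cols(df, c("tag_id", "x_m", "y_m", "colocated_receiver_id"),
                    basename(path))
  df$tag_id <- as.character(df$tag_id)
  df$colocated_receiver_id <- as.character(df$colocated_receiver_id)
  df
}

#' @rdname read_sync_tags
#' @param sync_tags sync tag data frame.
#' @export
write_sync_tags <- function(sync_tags, path) {
  utils::write.csv(sync_tags, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a discharge time series
#'
#' @param path CSV with columns \code{timestamp_utc, discharge_m3s}.
#' @return data frame with POSIXct \code{timestamp_utc} and numeric
#'   \code{discharge_m3s}.
#' @export
read_discharge <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stop_missing_cols(df, c("timestamp_utc", "discharge_m3s"), basename(path))
  df$timestamp_utc <- as_utc(df$timestamp_utc)
  df$discharge_m3s <- as.numeric(df$discharge_m3s)
  df[order(df$timestamp_utc), , drop = FALSE]
}

#' Trim detections to the study window
#'
#' Applies per-tag end-of-record overrides (e.g. a fish known to have died,
#' whose later detections are tag-only noise) and then the global study
#' window.  Both bounds are inclusive.  The numbers of rows removed by each
#' step are attached as the \code{"removed"} attribute.
#'
#' @param dets detection data frame.
#' @param window length-2 vector (POSIXct or ISO-8601 strings):
#'   \code{c(start, end)} of the study period.
#' @param truncations optional named list/vector mapping \code{tag_id} to an
#'   inclusive end override (detections after it are dropped for that tag).
#'   Overrides must fall inside the window.
#' @return trimmed detection data frame with attribute \code{removed =
#'   list(override = n1, window = n2)}.  Idempotent.
#' @export
trim_to_study <- function(dets, window, truncations = NULL) {
  start <- as_utc(window[[1]]); end <- as_utc(window[[2]])
  if (!(start < end)) stop("study window start must precede end")
  removed_override <- 0L
  if (length(truncations)) {
    for (tag in names(truncations)) {
      cutoff <- as_utc(truncations[[tag]])
      if (cutoff < start || cutoff > end) {
        stop(sprintf("truncation override for tag %s (%s) lies outside the study window",
                     tag, format(cutoff)))
      }
      drop <- dets$tag_id == tag & dets$timestamp_utc > cutoff
      removed_override <- removed_override + sum(drop)
      dets <- dets[!drop, , drop = FALSE]
    }
  }
  inside <- dets$timestamp_utc >= start & dets$timestamp_utc <= end
  out <- dets[inside, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- list(override = removed_override,
                               window = sum(!inside))
  out
}

#' Remove manually excluded detections
#'
#' Per-row exclusion list for detections removed after manual inspection;
#' the criteria live with whoever curated the list, never inferred here.
#'
#' @param dets detection data frame.
#' @param exclusions data frame with columns \code{tag_id, timestamp_utc,
#'   receiver_id} identifying rows to drop (timestamps matched to the
#'   millisecond).
#' @return detections with the listed rows removed; attribute
#'   \code{"removed_manual"} gives the count.
#' @export
remove_manual_exclusions <- function(dets, exclusions) {
  if (is.null(exclusions) || nrow(exclusions) == 0) {
    attr(dets, "removed_manual") <- 0L
    return(dets)
  }
  key <- function(d) paste(d$tag_id, format_utc_ms(as_utc(d$timestamp_utc)),
                           d$receiver_id)
  drop <- key(dets) %in% key(exclusions)
  out <- dets[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed_manual") <- sum(drop)
  out
}
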