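# Per-minute habitat timelines.  Every minute from a fish's release to
# the study end gets a binary habitat label (lake/river; the two river
# zones are pooled for the budget, zone detail is kept for migration
# events).  Minutes with a detection take the habitat of the last
# detection in that minute; silent gaps are forward-filled from the
# previous detected habitat; the stretch between release and first
# detection is back-filled from the first detected habitat.

zone_to_label <- function(zone) ifelse(zone == "lake", "lake", "river")

floor_minute <- function(t) {
  as.POSIXct(floor(as.numeric(t) / 60) * 60, origin = "1970-01-01",
             tz = "UTC")
}

#' Build one fish's per-minute habitat timeline
#'
#' @param dets filtered detections of a single fish.
#' @param fish one-row fish record (gives release time).
#' @param receivers receiver data frame (habitat zones).
#' @param window study window \code{c(start, end)}.
#' @param start_rule \code{"release"} starts the grid at the release
#'   minute; \code{"day_after"} at the first midnight after release.
#' @return data frame \code{tag_id, minute_utc, habitat
#'   ("lake"/"river"), source ("detected"/"forward_fill"/"back_fill")}.
#'   A fish never detected yields a zero-row timeline with attribute
#'   \code{never_detected = TRUE}.
#' @export
build_timeline <- function(dets, fish, receivers, window,
                           start_rule = c("release", "day_after")) {
  start_rule <- match.arg(start_rule)
  stopifnot(nrow(fish) == 1)
  end <- as_utc(window[[2]])
  rel <- as_utc(fish$release_time)
  grid0 <- if (start_rule == "release") floor_minute(rel) else
    as.POSIXct(trunc(rel + 86400, units = "days"), tz = "UTC")
  dets <- dets[dets$tag_id == fish$tag_id, , drop = FALSE]
  if (nrow(dets) == 0) {
    out <- data.frame(tag_id = character(),
                      minute_utc = as.POSIXct(character(), tz = "UTC"),
                      habitat = character(), source = character())
    attr(out, "never_detected") <- TRUE
    return(out)
  }
  dets <- dets[order(dets$timestamp_utc), , drop = FALSE]
  zone <- receivers$habitat[match(dets$receiver_id, receivers$receiver_id)]
  if (anyNA(zone)) stop("detection at unknown receiver")
  minutes <- seq(grid0, floor_minute(end), by = 60)
  n <- length(minutes)
  lab <- rep(NA_character_, n)
  src <- rep(NA_character_, n)
  mi <- as.integer((as.numeric(floor_minute(dets$timestamp_utc)) -
                      as.numeric(grid0)) / 60) + 1L
  ok <- mi >= 1 & mi <= n
  # last detection within each minute wins (dets are time-ordered)
  for (k in which(ok)) {
    lab[mi[k]] <- zone_to_label(zone[k])
    src[mi[k]] <- "detected"
  }
  # forward fill, then back fill the leading stretch
  first_det <- which(!is.na(lab))[1]
  if (is.na(first_det)) {
    # detections exist but none inside the grid: fill from the nearest one
    nearest <- which.min(abs(as.numeric(dets$timestamp_utc) -
                               as.numeric(grid0)))
    lab[] <- zone_to_label(zone[nearest])
    src[] <- if (dets$timestamp_utc[nearest] < grid0) "forward_fill" else
      "back_fill"
    return(data.frame(tag_id = fish$tag_id, minute_utc = minutes,
                      habitat = lab, source = src, stringsAsFactors = FALSE))
  }
  if (first_det > 1) {
    lab[seq_len(first_det - 1)] <- lab[first_det]
    src[seq_len(first_det - 1)] <- "back_fill"
  }
  for (k in seq_len(n)) {
    if (is.na(lab[k])) {
      lab[k] <- lab[k - 1]
      src[k] <- "forward_fill"
    }
  }
  data.frame(tag_id = fish$tag_id, minute_utc = minutes, habitat = lab,
             source = src, stringsAsFactors = FALSE)
}

#' Build timelines for a whole cohort
#'
#' @param dets filtered detections (all fish).
#' @param fish fish data frame.
#' @inheritParams build_timeline
#' @return row-bound timelines; fish never detected are skipped and their
#'   ids recorded in the \code{"never_detected"} attribute.
#' @export
build_timelines <- function(dets, fish, receivers, window,
                            start_rule = "release") {
  out <- list(); missed <- character()
  for (i in seq_len(nrow(fish))) {
    tl <- build_timeline(dets, fish[i, ], receivers, window, start_rule)
    if (nrow(tl) == 0) missed <- c(missed, fish$tag_id[i]) else
      out[[length(out) + 1]] <- tl
  }
  res <- do.call(rbind, out)
  attr(res, "never_detected") <- missed
  res
}

#' Residence time budget
#'
#' Days in lake and river per fish (labelled minutes / 1440) and cohort
#' summary statistics over fish with nonzero timelines.
#'
#' @param timelines output of [build_timelines()] (or one timeline).
#' @return list: \code{per_fish} (tag_id, days_lake, days_river,
#'   days_total) and \code{cohort} (habitat, mean, sd, median, min, max of
#'   days).
#' @export
residence_summary <- function(timelines) {
  per <- do.call(rbind, lapply(split(timelines, timelines$tag_id),
    function(tl) {
      data.frame(tag_id = tl$tag_id[1],
                 days_lake = sum(tl$habitat == "lake") / 1440,
                 days_river = sum(tl$habitat == "river") / 1440,
                 days_total = nrow(tl) / 1440,
                 stringsAsFactors = FALSE)
    }))
  rownames(per) <- NULL
  stat <- function(x) c(mean = mean(x), sd = stats::sd(x),
                        median = stats::median(x), min = min(x), max = max(x))
  cohort <- rbind(
    data.frame(habitat = "lake", t(stat(per$days_lake))),
    data.frame(habitat = "river", t(stat(per$days_river))))
  list(per_fish = per, cohort = cohort)
}

#' Classify migration events relative to the weir elevation
#'
#' Walks each fish's detected zone sequence (river_down / lake /
#' river_up) and emits an event at every zone transition: ascents into
#' the lake and upper river, descents back.  A direct river-to-river jump
#' in the detections is decomposed through the lake (both events stamped
#' at the transition time).  Events at or after the weir elevation
#' instant count as \code{"after"}.
#'
#' @param dets filtered detections.
#' @param receivers receiver data frame.
#' @param weir_date weir elevation instant (events exactly at it are
#'   "after").
#' @return data frame \code{tag_id, event_type, event_time,
#'   relative_to_weir}.
#' @export
classify_events <- function(dets, receivers, weir_date) {
  weir <- as_utc(weir_date)
  dets <- dets[order(dets$tag_id, dets$timestamp_utc), , drop = FALSE]
  zone <- receivers$habitat[match(dets$receiver_id, receivers$receiver_id)]
  rows <- list()
  step_events <- function(from, to) {
    key <- paste(from, to)
    switch(key,
      "river_down lake" = "ascent_to_lake",
      "lake river_down" = "descent_to_river",
      "lake river_up" = "ascent_to_upper_river",
      "river_up lake" = "descent_from_upper_river",
      "river_down river_up" = c("ascent_to_lake", "ascent_to_upper_river"),
      "river_up river_down" = c("descent_from_upper_river",
                                "descent_to_river"),
      character())
  }
  for (idx in split(seq_len(nrow(dets)), dets$tag_id)) {
    z <- zone[idx]; tt <- dets$timestamp_utc[idx]
    chg <- which(z[-1] != z[-length(z)]) + 1
    for (k in chg) {
      for (ev in step_events(z[k - 1], z[k])) {
        rows[[length(rows) + 1]] <- data.frame(
          tag_id = dets$tag_id[idx[1]], event_type = ev,
          event_time = tt[k],
          relative_to_weir = if (tt[k] >= weir) "after" else "before",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(tag_id = character(), event_type = character(),
                      event_time = as.POSIXct(character(), tz = "UTC"),
                      relative_to_weir = character()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Before/after fractions for migration events
#'
#' Percentage of events of each type occurring before and after the weir
#' elevation, computed from counts.  Also usable directly on published
#' count pairs, e.g. \code{event_fractions(8, 6)} gives 57.1% before.
#'
#' @param n_before,n_after event counts.
#' @return list \code{pct_before, pct_after} (percent).
#' @export
event_fractions <- function(n_before, n_after) {
  tot <- n_before + n_after
  if (tot == 0) stop("no events to take fractions of")
  list(pct_before = 100 * n_before / tot, pct_after = 100 * n_after / tot)
}

#' Per-minute lake occupancy series
#'
#' For every minute covered by at least one timeline: the number of fish
#' in the lake and the number whose timeline covers that minute (the
#' at-risk total used as the model offset).
#'
#' @param timelines output of [build_timelines()].
#' @return data frame \code{minute_utc, n_lake, n_total}, with
#'   \code{n_lake <= n_total} everywhere.
#' @export
lake_count_series <- function(timelines) {
  if (nrow(timelines) == 0) stop("need at least one timeline")
  key <- as.numeric(timelines$minute_utc)
  tot <- table(key)
  lk <- table(key[timelines$habitat == "lake"])
  minutes <- sort(unique(key))
  n_lake <- integer(length(minutes))
  hit <- match(names(lk), as.character(minutes))
  n_lake[hit] <- as.integer(lk)
  data.frame(minute_utc = as.POSIXct(minutes, origin = "1970-01-01",
                                     tz = "UTC"),
             n_lake = n_lake,
             n_total = as.integer(tot[as.character(minutes)]))
}
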