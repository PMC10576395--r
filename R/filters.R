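# Rule-based false-detection filtering.  Metrics are sequential per fish:
# straight-line distance between the current and previous receiver and the
# implied speed.  Three rules remove implausible jumps:
#   1) river detection whose previous detection was in the lake, > 1000 m;
#   2) lake detection whose previous detection was in a river, > 1000 m;
#   3) any detection > 800 m from the previous one at > 5 m/s
# (salmonids do not sustain more than ~5 m/s over such distances).

is_river <- function(habitat) habitat %in% c("river_up", "river_down")

#' Sequential distance/speed metrics per fish
#'
#' For every detection, the Euclidean distance (m) between its receiver
#' and the previous detection's receiver, elapsed time (s), and speed
#' (m/s).  The first detection of each fish has distance and speed zero.
#' Simultaneous arrivals at distant receivers (dt = 0, distance > 0) get
#' infinite speed.
#'
#' @param dets detections sorted by (tag, time); resorted if not.
#' @param receivers receiver data frame (positions and habitat).
#' @return \code{dets} plus columns \code{prev_receiver_id, distance_m,
#'   dt_s, speed_mps}.
#' @export
compute_sequential_metrics <- function(dets, receivers) {
  if (!all(dets$receiver_id %in% receivers$receiver_id)) {
    stop("detection at unknown receiver: ",
         paste(utils::head(setdiff(dets$receiver_id, receivers$receiver_id)),
               collapse = ", "))
  }
  dets <- dets[order(dets$tag_id, dets$timestamp_utc), , drop = FALSE]
  n <- nrow(dets)
  prev <- c(NA_character_, dets$receiver_id[-n])
  same_fish <- c(FALSE, dets$tag_id[-1] == dets$tag_id[-n])
  prev[!same_fish] <- NA
  dist <- rep(0, n); dt <- rep(0, n)
  sel <- which(same_fish)
  dist[sel] <- receiver_dist(receivers, dets$receiver_id[sel], prev[sel])
  dt[sel] <- as.numeric(dets$timestamp_utc[sel]) -
    as.numeric(dets$timestamp_utc[sel - 1])
  speed <- ifelse(dt > 0, dist / dt, ifelse(dist > 0, Inf, 0))
  dets$prev_receiver_id <- prev
  dets$distance_m <- dist
  dets$dt_s <- dt
  dets$speed_mps <- speed
  rownames(dets) <- NULL
  dets
}

fire_rule <- function(cur_hab, prev_hab, dist, speed, thresholds) {
  if (!is.na(prev_hab)) {
    if (is_river(cur_hab) && prev_hab == "lake" &&
        dist > thresholds$river_lake_dist_m) return(1L)
    if (cur_hab == "lake" && is_river(prev_hab) &&
        dist > thresholds$lake_river_dist_m) return(2L)
  }
  if (dist > thresholds$speed_dist_m && speed > thresholds$speed_mps)
    return(3L)
  0L
}

#' Remove false detections by the three distance/speed rules
#'
#' A single time-ordered pass per fish.  In \code{"streaming"} mode
#' (default) each detection is tested against the last \emph{retained}
#' detection, so removing a row immediately updates the metrics of the
#' next; \code{"precomputed"} tests every row against its original
#' predecessor in one shot (kept for sensitivity analysis).  Streaming
#' output is a fixpoint: no retained consecutive pair violates any rule.
#'
#' @param dets detection data frame (sorted internally by tag and time).
#' @param receivers receiver data frame.
#' @param thresholds rule thresholds; defaults are the operational values
#'   1000 m (rules 1-2), 800 m and 5 m/s (rule 3).
#' @param mode \code{"streaming"} or \code{"precomputed"}.
#' @return list: \code{retained} (detections with sequential metrics as
#'   finally evaluated) and \code{removals} (one row per removed
#'   detection: \code{tag_id, timestamp, receiver_id, rule_fired,
#'   distance_m, speed_mps}).
#' @export
apply_false_detection_filters <- function(dets, receivers,
                                          thresholds = list(
                                            river_lake_dist_m = 1000,
                                            lake_river_dist_m = 1000,
                                            speed_dist_m = 800,
                                            speed_mps = 5),
                                          mode = c("streaming",
                                                   "precomputed")) {
  mode <- match.arg(mode)
  dets <- dets[order(dets$tag_id, dets$timestamp_utc), , drop = FALSE]
  rownames(dets) <- NULL
  hab <- receivers$habitat[match(dets$receiver_id, receivers$receiver_id)]
  if (anyNA(hab)) stop("detection at unknown receiver")
  t <- as.numeric(dets$timestamp_utc)
  rid <- match(dets$receiver_id, receivers$receiver_id)
  keep <- rep(TRUE, nrow(dets))
  log_rows <- list()
  for (idx in split(seq_len(nrow(dets)), dets$tag_id)) {
    last <- idx[1]  # first detection always retained (metrics are 0/0)
    prev_orig <- idx[1]
    for (k in idx[-1]) {
      ref <- if (mode == "streaming") last else prev_orig
      dist <- sqrt((receivers$x_m[rid[k]] - receivers$x_m[rid[ref]])^2 +
                   (receivers$y_m[rid[k]] - receivers$y_m[rid[ref]])^2)
      dt <- t[k] - t[ref]
      speed <- if (dt > 0) dist / dt else if (dist > 0) Inf else 0
      rule <- fire_rule(hab[k], hab[ref], dist, speed, thresholds)
      if (rule > 0L) {
        keep[k] <- FALSE
        log_rows[[length(log_rows) + 1]] <- data.frame(
          tag_id = dets$tag_id[k], timestamp = dets$timestamp_utc[k],
          receiver_id = dets$receiver_id[k], rule_fired = rule,
          distance_m = dist, speed_mps = speed, stringsAsFactors = FALSE)
      } else {
        last <- k
      }
      prev_orig <- k
    }
  }
  retained <- compute_sequential_metrics(dets[keep, , drop = FALSE],
                                         receivers)
  removals <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(tag_id = character(),
               timestamp = as.POSIXct(character(), tz = "UTC"),
               receiver_id = character(), rule_fired = integer(),
               distance_m = numeric(), speed_mps = numeric())
  list(retained = retained, removals = removals)
}
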