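# Receiver clock synchronisation from fixed sync tags.
#
# A sync tag at a known position is heard by its co-located reference
# receiver essentially every transmission; the reference clock defines the
# time base (its offset is the gauge, fixed at zero).  For any other
# receiver, each shared reception yields one sample of that receiver's
# clock offset:
#   offset_j(t) = arrival_j - (arrival_ref - range_ref/c) - range_j/c.
# The offset is modelled as a continuous piecewise-linear function of time
# with regularly spaced breakpoints (daily by default), fitted by least
# squares with iterative exclusion of residuals beyond eps robust SDs.

tent_basis <- function(t, knots) {
  m <- length(knots)
  if (m == 1) return(matrix(1, length(t), 1))
  B <- matrix(0, length(t), m)
  for (k in seq_len(m)) {
    if (k > 1) {
      sel <- t >= knots[k - 1] & t <= knots[k]
      B[sel, k] <- (t[sel] - knots[k - 1]) / (knots[k] - knots[k - 1])
    } else {
      B[t <= knots[1], 1] <- 1
    }
    if (k < m) {
      sel <- t > knots[k] & t <= knots[k + 1]
      B[sel, k] <- (knots[k + 1] - t[sel]) / (knots[k + 1] - knots[k])
    }
  }
  B
}

#' Fit per-receiver clock models from sync-tag detections
#'
#' Estimates a continuous piecewise-linear clock offset for every receiver
#' that shares sync-tag receptions with the reference receiver (the one
#' co-located with the first sync tag, unless overridden).  Residuals
#' beyond \code{eps} robust standard deviations are excluded iteratively
#' until the retained set is stable, which removes occasional gross
#' outliers without touching the bulk of the receptions.
#'
#' @param sync_dets detections of sync tags (see
#'   [simulate_sync_transmissions()] or real downloads).
#' @param sync_tags sync tag metadata with fixed positions.
#' @param receivers receiver metadata.
#' @param sound_speed_mps speed of sound used for range corrections.
#' @param reference_receiver receiver id whose clock defines the time
#'   base; default: the receiver co-located with the first sync tag.
#' @param breakpoint_spacing_s spacing of the piecewise-linear breakpoints
#'   (default one day).
#' @param eps outlier threshold in robust-SD units (default 10).
#' @param pair_window_s window for pairing an arrival with the matching
#'   reference arrival of the same transmission.
#' @param min_obs minimum retained receptions for a receiver to count as
#'   synchronised.
#' @return object of class \code{"clock_model_set"}: per-receiver models
#'   (knots, offsets at knots, residual SD, counts), the reference id, and
#'   the ids of receivers that could not be synchronised (never silently
#'   passed through).
#' @export
fit_clock_models <- function(sync_dets, sync_tags, receivers,
                             sound_speed_mps = 1450,
                             reference_receiver = NULL,
                             breakpoint_spacing_s = 86400,
                             eps = 10, pair_window_s = 120, min_obs = 5) {
  reference_receiver <- reference_receiver %||%
    sync_tags$colocated_receiver_id[1]
  if (!reference_receiver %in% receivers$receiver_id) {
    stop("reference receiver not in receiver table: ", reference_receiver)
  }
  c_mps <- sound_speed_mps
  t_num <- as.numeric(sync_dets$timestamp_utc)
  span <- range(t_num)

  fit_one <- function(id, sm) {
    # piecewise-linear offset with iterative eps-rule outlier exclusion
    t0 <- min(sm$t); t1 <- max(sm$t)
    knots <- seq(t0, t1, by = breakpoint_spacing_s)
    if (length(knots) < 2 || knots[length(knots)] < t1) knots <- c(knots, t1)
    keep <- rep(TRUE, nrow(sm))
    theta <- NULL
    for (it in 1:25) {
      B <- tent_basis(sm$t[keep], knots)
      fit <- stats::lm.fit(B, sm$resid[keep])
      theta <- fit$coefficients
      theta[is.na(theta)] <- 0
      res_all <- sm$resid - tent_basis(sm$t, knots) %*% theta
      s <- stats::mad(res_all[keep])
      if (s == 0) break
      keep_new <- abs(res_all) <= eps * s
      if (sum(keep_new) < length(knots) + 1) break  # refuse to overtrim
      if (identical(keep_new, keep)) break
      keep <- keep_new
    }
    res_keep <- sm$resid[keep] - tent_basis(sm$t[keep], knots) %*% theta
    list(receiver_id = id, knots = knots, theta = as.numeric(theta),
         residual_sd_s = stats::sd(res_keep),
         n_obs = sum(keep), n_excluded = sum(!keep))
  }

  # Samples of offset_j(t) come from transmissions whose emission time is
  # known in the reference timebase.  A sync tag provides them once its
  # co-located receiver is synchronised (the reference trivially is), so
  # synchronisation chains outward tag by tag.
  models <- list()
  models[[reference_receiver]] <- list(receiver_id = reference_receiver,
                                       knots = span, theta = c(0, 0),
                                       residual_sd_s = 0,
                                       n_obs = sum(t_num > 0), n_excluded = 0L)
  samples <- data.frame(receiver_id = character(), t = numeric(),
                        resid = numeric())
  tag_used <- rep(FALSE, nrow(sync_tags))
  offset_of <- function(m, t) {
    if (length(m$knots) < 2) rep(m$theta[1], length(t)) else
      stats::approx(m$knots, m$theta, t, rule = 2)$y
  }
  for (round in seq_len(nrow(sync_tags) + 1)) {
    progress <- FALSE
    for (i in which(!tag_used)) {
      st <- sync_tags[i, ]
      dist <- sqrt((st$x_m - receivers$x_m)^2 + (st$y_m - receivers$y_m)^2)
      names(dist) <- receivers$receiver_id
      sel_tag <- sync_dets$tag_id == st$tag_id
      # anchor: a synchronised receiver hearing this tag (prefer the
      # co-located one, else the best-covered one)
      heard <- table(sync_dets$receiver_id[sel_tag])
      cand <- intersect(names(heard)[heard >= min_obs], names(models))
      if (!length(cand)) next
      anchor <- if (st$colocated_receiver_id %in% cand)
        st$colocated_receiver_id else cand[which.max(heard[cand])]
      t_anchor <- sort(t_num[sel_tag & sync_dets$receiver_id == anchor])
      if (!length(t_anchor)) next
      emission <- t_anchor - offset_of(models[[anchor]], t_anchor) -
        dist[[anchor]] / c_mps
      oth <- which(sel_tag & sync_dets$receiver_id != anchor)
      if (length(oth)) {
        t_oth <- t_num[oth]
        k <- findInterval(t_oth, t_anchor)
        lo <- pmax(k, 1); hi <- pmin(k + 1, length(t_anchor))
        near <- ifelse(abs(t_oth - t_anchor[lo]) <= abs(t_anchor[hi] - t_oth),
                       lo, hi)
        ok <- abs(t_oth - t_anchor[near]) <= pair_window_s
        if (any(ok)) {
          oth <- oth[ok]; near <- near[ok]
          rid <- sync_dets$receiver_id[oth]
          samples <- rbind(samples, data.frame(
            receiver_id = rid, t = t_num[oth],
            resid = t_num[oth] - emission[near] - dist[rid] / c_mps,
            stringsAsFactors = FALSE))
        }
      }
      tag_used[i] <- TRUE
      progress <- TRUE
    }
    for (id in setdiff(unique(samples$receiver_id), reference_receiver)) {
      sm <- samples[samples$receiver_id == id, , drop = FALSE]
      if (nrow(sm) >= min_obs) models[[id]] <- fit_one(id, sm)
    }
    if (!progress) break
  }
  unsynchronized <- setdiff(unique(receivers$receiver_id), names(models))
  structure(list(models = models, reference_receiver = reference_receiver,
                 unsynchronized = unsynchronized,
                 sound_speed_mps = sound_speed_mps, eps = eps,
                 breakpoint_spacing_s = breakpoint_spacing_s),
            class = "clock_model_set")
}

#' Evaluate a fitted clock offset
#'
#' @param models a \code{clock_model_set}.
#' @param receiver_id single receiver id.
#' @param times POSIXct or numeric (epoch seconds).
#' @return offset in seconds at each time (piecewise-linear, extrapolated
#'   flat at the segment-end slopes' boundary values).
#' @export
clock_offset_at <- function(models, receiver_id, times) {
  m <- models$models[[receiver_id]]
  if (is.null(m)) stop("no clock model for receiver ", receiver_id)
  t <- as.numeric(times)
  if (length(m$knots) == 1) return(rep(m$theta[1], length(t)))
  stats::approx(m$knots, m$theta, t, rule = 2)$y
}

#' Overall linear drift of a fitted clock model
#'
#' End-to-end slope of the piecewise-linear offset (s per s), relative to
#' the reference clock; a diagnostic for drift-recovery checks.
#'
#' @inheritParams clock_offset_at
#' @return drift in s/s (NA if the receiver has no usable model).
#' @export
clock_overall_drift <- function(models, receiver_id) {
  m <- models$models[[receiver_id]]
  if (is.null(m) || length(m$knots) < 2) return(NA_real_)
  (m$theta[length(m$theta)] - m$theta[1]) / (m$knots[length(m$knots)] - m$knots[1])
}

#' @export
print.clock_model_set <- function(x, ...) {
  cat("Clock model set\n")
  cat("  reference receiver:", x$reference_receiver, "\n")
  cat("  synchronised receivers:", length(x$models) - 1, "\n")
  if (length(x$unsynchronized)) {
    cat("  UNSYNCHRONISED:", paste(x$unsynchronized, collapse = ", "), "\n")
  }
  sds <- vapply(x$models, function(m) m$residual_sd_s, numeric(1))
  cat(sprintf("  residual SD (s): median %.2g, max %.2g\n",
              stats::median(sds), max(sds)))
  invisible(x)
}

#' @export
as.data.frame.clock_model_set <- function(x, ...) {
  rows <- list()
  for (m in x$models) {
    k <- m$knots
    if (length(k) < 2) next
    for (i in seq_len(length(k) - 1)) {
      rows[[length(rows) + 1]] <- data.frame(
        receiver_id = m$receiver_id,
        segment_start = as.POSIXct(k[i], origin = "1970-01-01", tz = "UTC"),
        segment_end = as.POSIXct(k[i + 1], origin = "1970-01-01", tz = "UTC"),
        offset_intercept_s = m$theta[i],
        offset_slope_s_per_s = (m$theta[i + 1] - m$theta[i]) / (k[i + 1] - k[i]),
        residual_sd_s = m$residual_sd_s,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Apply clock models to detections
#'
#' Adds a \code{corrected_time} column: \code{logged time - offset(logged
#' time)}.  The original timestamp is retained, so the correction is
#' invertible given the model.  Receivers without a model must be listed
#' in \code{pass_through} (their times are kept as-is and flagged), so an
#' unsynchronised receiver can never slip into positioning unnoticed.
#'
#' @param dets detection data frame.
#' @param models a \code{clock_model_set} from [fit_clock_models()].
#' @param pass_through receiver ids allowed through uncorrected (e.g.
#'   river receivers used for presence only, never positioned).
#' @return \code{dets} with \code{corrected_time} (POSIXct) and
#'   \code{synchronized} (logical) columns.
#' @export
apply_clock_models <- function(dets, models, pass_through = character()) {
  ids <- unique(dets$receiver_id)
  unmodeled <- setdiff(ids, names(models$models))
  bad <- setdiff(unmodeled, pass_through)
  if (length(bad)) {
    stop("no clock model and no pass-through flag for receiver(s): ",
         paste(bad, collapse = ", "))
  }
  t <- as.numeric(dets$timestamp_utc)
  corrected <- t
  synced <- rep(FALSE, nrow(dets))
  for (id in intersect(ids, names(models$models))) {
    sel <- dets$receiver_id == id
    corrected[sel] <- t[sel] - clock_offset_at(models, id, t[sel])
    synced[sel] <- TRUE
  }
  dets$corrected_time <- as.POSIXct(corrected, origin = "1970-01-01",
                                    tz = "UTC")
  dets$synchronized <- synced
  dets
}
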