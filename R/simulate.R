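# Seeded simulator for the lake-river telemetry system.  Geometry is a
# desk-scale stand-in for the study system: a rectangular lake (3300 m x
# 580 m, ~1.9 km^2) joined at opposite ends to an upstream and a
# downstream river, both modelled as straight polylines.  A single axis
# coordinate runs along the watercourse: negative through the downstream
# river, 0..lake_length through the lake, beyond that the upstream river.

# NOTE: expr is evaluated lazily in the caller's frame; do not use
# return() inside it (wrap logic in a function instead).
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

default_geometry <- function() {
  list(lake_length_m = 3300, lake_width_m = 580,
       river_down_length_m = 6700, river_up_length_m = 5000,
       river_y_m = 290, lake_max_depth_m = 65, river_max_depth_m = 2)
}

habitat_of_x <- function(x, geometry) {
  ifelse(x < 0, "river_down",
         ifelse(x <= geometry$lake_length_m, "lake", "river_up"))
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic telemetry generator.  Defaults are
#' the study conditions: ~30 tagged sea trout, a July 20 -- November 14
#' study window, a 22-receiver array over river/lake/river, 90 s nominal
#' transmission delay, range-dependent detection, per-receiver clock
#' offset and drift, sporadic false detections, and 0--255 quantised
#' acceleration/depth sensors.  Movement emulates the reported behaviour:
#' higher activity in the rivers (0.373 m/s^2) than the lake (0.183), a
#' diel activity cycle peaking at hour 14 with trough at hour 4, and
#' shallow lake depth use (mean 3.7 m).
#'
#' @param seed integer global seed; every stochastic draw flows from it
#'   through named substreams per fish/receiver, so any subset replays
#'   identically.
#' @param n_fish number of tagged fish.
#' @param study_start,study_end study window (UTC).
#' @param weir_elevation_date date the flap weir at the lake outlet is
#'   raised; the travelling direction bias flips from upstream-dominated
#'   to slightly downstream after it.
#' @param nominal_delay_s mean interval between tag transmissions (s).
#' @param delay_jitter transmission delay jitter as a fraction of nominal:
#'   delays are uniform on nominal x (1 +/- delay_jitter).
#' @param sound_speed_mps speed of sound in fresh water (m/s).
#' @param detection_halfrange_m range at which detection probability is
#'   0.5 (logistic in range); \code{Inf} forces certain detection.
#' @param detection_scale_m logistic range-scale (m).
#' @param sync_halfrange_m,sync_scale_m the same for the high-power sync
#'   tags, whose range must span neighbouring receivers; the effective
#'   sync half-range is never below \code{detection_halfrange_m}.
#' @param clock_offset_sd_s,clock_drift_sd_s_per_s SDs of per-receiver
#'   clock offset (s) and linear drift (s/s); zero gives perfect clocks.
#' @param false_rate_per_receiver_per_day Poisson rate of spurious
#'   detections injected per receiver per day.
#' @param sync_interval_s,sync_jitter sync-tag transmission interval and
#'   its fractional jitter.
#' @param track_dt_s movement-model time step (s).
#' @param movement named list of movement parameters (see source); pass a
#'   partial list to override individual entries.
#' @param geometry named list describing the lake/river geometry; pass a
#'   partial list to override individual entries.
#' @return object of class \code{"sim_config"}.
#' @export
sim_config <- function(seed = 1L,
                       n_fish = 30L,
                       study_start = "2021-07-20T00:00:00Z",
                       study_end = "2021-11-14T23:59:59Z",
                       weir_elevation_date = "2021-09-15T00:00:00Z",
                       nominal_delay_s = 90,
                       delay_jitter = 0.5,
                       sound_speed_mps = 1450,
                       detection_halfrange_m = 400,
                       detection_scale_m = 60,
                       sync_halfrange_m = 1500,
                       sync_scale_m = 100,
                       clock_offset_sd_s = 0.5,
                       clock_drift_sd_s_per_s = 2e-5,
                       false_rate_per_receiver_per_day = 2,
                       sync_interval_s = 600,
                       sync_jitter = 0.1,
                       track_dt_s = 60,
                       movement = list(),
                       geometry = list()) {
  geom <- utils::modifyList(default_geometry(), geometry)
  mv <- utils::modifyList(list(
    p_travel = c(river_down = 0.060, lake = 0.010, river_up = 0.015),
    p_hold = 0.15,
    travel_speed_mps = 0.55,
    hold_speed_mps = 0.03,
    upstream_bias_before = c(river_down = 0.90, lake = 0.50, river_up = 0.20),
    upstream_bias_after = c(river_down = 0.80, lake = 0.42, river_up = 0.15),
    lateral_sd_m = 120,
    # lake depth walk is folded at the surface; with centre 2.0 m and
    # scale 3.7 m the occupied-depth mean is ~3.7 m (right-skewed, as
    # reported for upper-water-column use with occasional deep excursions)
    depth_mean_m = c(river_down = 0.9, lake = 2.0, river_up = 0.7),
    depth_sd_m = c(river_down = 0.35, lake = 3.7, river_up = 0.3),
    accel_mean_ms2 = c(river_down = 0.373, lake = 0.183, river_up = 0.373),
    accel_diel_amp_ms2 = c(river_down = 0.067, lake = 0.0225,
                           river_up = 0.067),
    accel_sd_ms2 = 0.05,
    diel_peak_hour = 14
  ), movement)
  cfg <- list(seed = as.integer(seed), n_fish = as.integer(n_fish),
              study_start = as_utc(study_start),
              study_end = as_utc(study_end),
              weir_elevation_date = as_utc(weir_elevation_date),
              nominal_delay_s = nominal_delay_s,
              delay_jitter = delay_jitter,
              sound_speed_mps = sound_speed_mps,
              detection_halfrange_m = detection_halfrange_m,
              detection_scale_m = detection_scale_m,
              sync_halfrange_m = sync_halfrange_m,
              sync_scale_m = sync_scale_m,
              clock_offset_sd_s = clock_offset_sd_s,
              clock_drift_sd_s_per_s = clock_drift_sd_s_per_s,
              false_rate_per_receiver_per_day = false_rate_per_receiver_per_day,
              sync_interval_s = sync_interval_s,
              sync_jitter = sync_jitter,
              track_dt_s = track_dt_s,
              movement = mv, geometry = geom)
  stopifnot(cfg$nominal_delay_s > 0, cfg$sound_speed_mps > 0,
            cfg$false_rate_per_receiver_per_day >= 0,
            cfg$n_fish >= 1, cfg$study_start < cfg$study_end,
            cfg$track_dt_s > 0)
  class(cfg) <- "sim_config"
  cfg
}

#' Default receiver array
#'
#' 22 stations: 8 along the downstream river (three of them deployed
#' September 2, after tagging), 11 through the lake (two carrying sync
#' tags), and 3 in the upstream river.
#'
#' @param config a [sim_config()].
#' @return receiver data frame (see [read_receivers()]).
#' @export
default_receivers <- function(config = sim_config()) {
  g <- config$geometry
  rd_x <- c(-6500, -5500, -4300, -3100, -2000, -1200, -600, -150)
  rd_deploy <- rep(as.Date("2021-07-01"), 8)
  rd_deploy[c(2, 4, 6)] <- as.Date("2021-09-02")
  lk_x <- seq(150, g$lake_length_m - 150, length.out = 11)
  lk_y <- rep(c(150, 430), length.out = 11)
  ru_x <- g$lake_length_m + c(150, 900, 2200)
  df <- data.frame(
    receiver_id = sprintf("R%02d", 1:22),
    x_m = c(rd_x, lk_x, ru_x),
    y_m = c(rep(g$river_y_m, 8), lk_y, rep(g$river_y_m, 3)),
    habitat = c(rep("river_down", 8), rep("lake", 11), rep("river_up", 3)),
    deploy_date = c(rd_deploy, rep(as.Date("2021-07-01"), 14)),
    has_sync_tag = FALSE,
    stringsAsFactors = FALSE
  )
  df$has_sync_tag[c(11, 17)] <- TRUE  # two lake stations carry sync tags
  df
}

#' Default sync tags co-located with flagged receivers
#'
#' @param receivers receiver data frame with \code{has_sync_tag}.
#' @return sync tag data frame (see [read_sync_tags()]).
#' @export
default_sync_tags <- function(receivers) {
  host <- receivers[receivers$has_sync_tag, , drop = FALSE]
  if (nrow(host) == 0) stop("no receiver flagged has_sync_tag")
  data.frame(tag_id = sprintf("sync%d", seq_len(nrow(host))),
             x_m = host$x_m, y_m = host$y_m,
             colocated_receiver_id = host$receiver_id,
             stringsAsFactors = FALSE)
}

#' Default tagged-fish cohort
#'
#' Fish are captured by angling in the downstream river at nine sites
#' between the confluence (site 1) and near the river mouth (site 9), and
#' released where caught between July 20 and August 12.  Total lengths are
#' drawn around 540 +/- 102 mm with the 415 mm minimum actually tagged.
#'
#' @param config a [sim_config()].
#' @return fish data frame (see [read_fish()]).
#' @export
default_fish <- function(config = sim_config()) {
  n <- config$n_fish
  with_seed(substream_seed(config$seed, "fish"), {
    total <- round(pmax(415, stats::rnorm(n, 540, 102)))
    site <- sample(1:9, n, replace = TRUE)
    rel <- config$study_start +
      stats::runif(n, 0, min(23 * 86400,
                             as.numeric(config$study_end - config$study_start,
                                        units = "secs")))
    data.frame(tag_id = as.character(4670 + seq_len(n)),
               total_length_mm = total,
               fork_length_mm = round(total * 0.95),
               tagging_site = site,
               release_time = rel,
               release_habitat = "river_down",
               stringsAsFactors = FALSE)
  })
}

release_axis_position <- function(site, geometry) {
  # site 1 at the confluence, site 9 near the river mouth
  -50 - (site - 1) / 8 * (geometry$river_down_length_m - 300)
}

#' Simulate true fish tracks
#'
#' Two-state (holding/travelling) correlated walk along the watercourse
#' axis with lateral freedom inside the lake only; habitat changes happen
#' only by crossing the river-lake confluences.  Depth follows a
#' mean-reverting walk around a per-habitat mean; true acceleration RMS is
#' the per-habitat mean plus a diel sinusoid (peak hour 14, trough hour 4)
#' plus AR(1) noise, floored just above zero.
#'
#' @param config a [sim_config()].
#' @param fish fish data frame; default [default_fish()].
#' @return data frame of class \code{"true_tracks"}: \code{tag_id, time,
#'   x_m, y_m, depth_m, habitat, accel_rms}, one row per track step from
#'   release to study end.  Deterministic for a fixed seed.
#' @export
simulate_tracks <- function(config = sim_config(), fish = NULL) {
  fish <- fish %||% default_fish(config)
  g <- config$geometry
  mv <- config$movement
  dt <- config$track_dt_s
  weir <- as.numeric(config$weir_elevation_date)
  out <- vector("list", nrow(fish))
  for (i in seq_len(nrow(fish))) {
    f <- fish[i, ]
    t0 <- as.numeric(f$release_time)
    t1 <- as.numeric(config$study_end)
    if (t0 >= t1) { out[[i]] <- NULL; next }
    times <- seq(t0, t1, by = dt)
    n <- length(times)
    out[[i]] <- with_seed(substream_seed(config$seed, paste0("track:", f$tag_id)), {
      s <- numeric(n); y <- numeric(n); z <- numeric(n); a <- numeric(n)
      s[1] <- if (identical(f$release_habitat, "lake"))
        stats::runif(1, 100, g$lake_length_m - 100)
      else release_axis_position(f$tagging_site, g)
      y[1] <- g$river_y_m
      travelling <- FALSE
      dir <- 1
      hab <- habitat_of_x(s[1], g)
      z[1] <- abs(stats::rnorm(1, mv$depth_mean_m[[hab]], mv$depth_sd_m[[hab]]))
      eps <- 0
      # pre-draw the cheap vectors
      u_state <- stats::runif(n); u_dir <- stats::runif(n)
      step_noise <- stats::rnorm(n); lat_noise <- stats::rnorm(n)
      z_noise <- stats::rnorm(n); a_noise <- stats::rnorm(n)
      phi <- 0.1
      for (k in seq_len(n)) {
        hab <- habitat_of_x(s[k], g)
        if (travelling) {
          if (u_state[k] < mv$p_hold) travelling <- FALSE
        } else if (u_state[k] < mv$p_travel[[hab]]) {
          travelling <- TRUE
          bias <- if (times[k] < weir) mv$upstream_bias_before[[hab]]
                  else mv$upstream_bias_after[[hab]]
          dir <- if (u_dir[k] < bias) 1 else -1
        }
        speed <- if (travelling) mv$travel_speed_mps else mv$hold_speed_mps
        drift <- if (travelling) dir * speed * dt else 0
        if (k < n) {
          s[k + 1] <- s[k] + drift + step_noise[k] * speed * dt * 0.3
          lo <- -g$river_down_length_m
          hi <- g$lake_length_m + g$river_up_length_m
          if (s[k + 1] < lo) s[k + 1] <- 2 * lo - s[k + 1]
          if (s[k + 1] > hi) s[k + 1] <- 2 * hi - s[k + 1]
          hab_next <- habitat_of_x(s[k + 1], g)
          if (hab_next == "lake") {
            yc <- if (hab == "lake") y[k] else g$river_y_m
            y[k + 1] <- yc + 0.1 * (g$river_y_m - yc) +
              lat_noise[k] * mv$lateral_sd_m * 0.12
            y[k + 1] <- min(max(y[k + 1], 10), g$lake_width_m - 10)
          } else y[k + 1] <- g$river_y_m
          mu <- mv$depth_mean_m[[hab_next]]
          sig <- mv$depth_sd_m[[hab_next]] * sqrt(2 * phi - phi^2)
          z[k + 1] <- abs(z[k] + phi * (mu - z[k]) + z_noise[k] * sig)
          zmax <- if (hab_next == "lake") g$lake_max_depth_m else g$river_max_depth_m
          if (z[k + 1] > zmax) z[k + 1] <- max(0, 2 * zmax - z[k + 1])
        }
        hour <- (times[k] %% 86400) / 3600
        diel <- cos(2 * pi * (hour - mv$diel_peak_hour) / 24)
        eps <- 0.5 * eps + a_noise[k] * mv$accel_sd_ms2
        a[k] <- max(0.02, mv$accel_mean_ms2[[hab]] +
                      mv$accel_diel_amp_ms2[[hab]] * diel + eps)
      }
      data.frame(tag_id = f$tag_id,
                 time = as.POSIXct(times, origin = "1970-01-01", tz = "UTC"),
                 x_m = s, y_m = y, depth_m = z,
                 habitat = habitat_of_x(s, g), accel_rms = a,
                 stringsAsFactors = FALSE)
    })
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("true_tracks", class(res))
  res
}

#' Simulated per-receiver clock errors
#'
#' Each receiver clock reads true time plus \code{offset + drift * (t -
#' study_start)}.  Drawn once per receiver from a named substream so the
#' same truth underlies fish and sync transmissions.
#'
#' @param receivers receiver data frame.
#' @param config a [sim_config()].
#' @return data frame \code{receiver_id, offset_s, drift_s_per_s}.
#' @export
simulate_clock_errors <- function(receivers, config) {
  off <- drift <- numeric(nrow(receivers))
  for (i in seq_len(nrow(receivers))) {
    id <- receivers$receiver_id[i]
    draws <- with_seed(substream_seed(config$seed, paste0("clock:", id)),
                       stats::rnorm(2))
    off[i] <- draws[1] * config$clock_offset_sd_s
    drift[i] <- draws[2] * config$clock_drift_sd_s_per_s
  }
  data.frame(receiver_id = receivers$receiver_id, offset_s = off,
             drift_s_per_s = drift, stringsAsFactors = FALSE)
}

clock_error_at <- function(clock_truth, receiver_id, t_num, config) {
  i <- match(receiver_id, clock_truth$receiver_id)
  clock_truth$offset_s[i] +
    clock_truth$drift_s_per_s[i] * (t_num - as.numeric(config$study_start))
}

detect_prob <- function(d, config, sync = FALSE) {
  # sync tags transmit at high power, so their range exceeds fish tags'
  halfrange <- if (sync) max(config$sync_halfrange_m,
                             config$detection_halfrange_m) else
    config$detection_halfrange_m
  scale <- if (sync) config$sync_scale_m else config$detection_scale_m
  if (is.infinite(halfrange)) return(rep(1, length(d)))
  stats::plogis((halfrange - d) / scale)
}

interp_track <- function(tr, t_num) {
  tt <- as.numeric(tr$time)
  data.frame(
    x_m = stats::approx(tt, tr$x_m, t_num, rule = 2)$y,
    y_m = stats::approx(tt, tr$y_m, t_num, rule = 2)$y,
    depth_m = stats::approx(tt, tr$depth_m, t_num, rule = 2)$y,
    accel_rms = stats::approx(tt, tr$accel_rms, t_num, rule = 2)$y
  )
}

#' Simulate the detection process
#'
#' Each tag transmits at its nominal delay with uniform jitter, alternating
#' acceleration and depth payloads (encoded through the 0--255 codec with
#' saturation).  A transmission is logged at a receiver with probability
#' logistic in range; the logged time is emission + range/sound_speed +
#' the receiver's clock error.  Spurious detections are injected per
#' receiver as a Poisson process and flagged in the truth table.
#'
#' @param tracks output of [simulate_tracks()].
#' @param receivers receiver data frame.
#' @param config a [sim_config()].
#' @param clock_truth output of [simulate_clock_errors()]; computed from
#'   the config seed when NULL.
#' @return list with \code{detections} (canonical detection data frame
#'   plus a \code{det_id} column) and \code{truth} (one row per detection:
#'   \code{det_id, tag_id, emission_time, true_x, true_y, true_depth,
#'   true_accel, receiver_id, is_false}).
#' @export
simulate_detections <- function(tracks, receivers, config,
                                clock_truth = NULL) {
  if (nrow(receivers) == 0) stop("receivers must be non-empty")
  clock_truth <- clock_truth %||% simulate_clock_errors(receivers, config)
  start_num <- as.numeric(config$study_start)
  end_num <- as.numeric(config$study_end)
  deploy_num <- as.numeric(as_utc(receivers$deploy_date))
  res_det <- list(); res_truth <- list(); idx <- 1L
  for (tag in unique(tracks$tag_id)) {
    tr <- tracks[tracks$tag_id == tag, , drop = FALSE]
    t0 <- as.numeric(tr$time[1]); t1 <- as.numeric(tr$time[nrow(tr)])
    sim_one_tag <- function() {
      n_max <- ceiling((t1 - t0) / (config$nominal_delay_s *
                                      max(1e-6, 1 - config$delay_jitter))) + 2
      gaps <- config$nominal_delay_s *
        (1 + stats::runif(n_max, -config$delay_jitter, config$delay_jitter))
      em <- t0 + cumsum(gaps)
      em <- em[em <= t1]
      if (!length(em)) return(NULL)
      pos <- interp_track(tr, em)
      stype <- rep(c("accel", "depth"), length.out = length(em))
      raw <- integer(length(em))
      ia <- stype == "accel"
      raw[ia] <- encode_sensor(pos$accel_rms[ia], sensor_scale("accel"))
      raw[!ia] <- encode_sensor(pos$depth_m[!ia], sensor_scale("depth"))
      # detection draws: emissions x receivers
      dx <- outer(pos$x_m, receivers$x_m, "-")
      dy <- outer(pos$y_m, receivers$y_m, "-")
      dist <- sqrt(dx^2 + dy^2)
      p <- detect_prob(dist, config)
      dim(p) <- dim(dist)
      active <- outer(em, deploy_num, ">=")
      hit <- (matrix(stats::runif(length(dist)), nrow(dist)) < p) & active
      ij <- which(hit, arr.ind = TRUE)
      if (!nrow(ij)) return(NULL)
      e <- ij[, 1]; r <- ij[, 2]
      arr <- em[e] + dist[ij] / config$sound_speed_mps
      logged <- arr + clock_error_at(clock_truth, receivers$receiver_id[r],
                                     arr, config)
      list(det = data.frame(
             timestamp_utc = as.POSIXct(logged, origin = "1970-01-01",
                                        tz = "UTC"),
             receiver_id = receivers$receiver_id[r],
             tag_id = tag, protocol = "S64K-69kHz",
             raw_value = raw[e], sensor_type = stype[e],
             stringsAsFactors = FALSE),
           truth = data.frame(
             tag_id = tag,
             emission_time = as.POSIXct(em[e], origin = "1970-01-01",
                                        tz = "UTC"),
             true_x = pos$x_m[e], true_y = pos$y_m[e],
             true_depth = pos$depth_m[e], true_accel = pos$accel_rms[e],
             receiver_id = receivers$receiver_id[r],
             is_false = FALSE, stringsAsFactors = FALSE))
    }
    rows <- with_seed(substream_seed(config$seed, paste0("det:", tag)),
                      sim_one_tag())
    if (!is.null(rows)) { res_det[[idx]] <- rows$det
                          res_truth[[idx]] <- rows$truth; idx <- idx + 1L }
  }
  # false detections: random tag/receiver, Poisson in time
  tags <- unique(tracks$tag_id)
  days <- (end_num - start_num) / 86400
  for (i in seq_len(nrow(receivers))) {
    id <- receivers$receiver_id[i]
    sim_false <- function() {
      nf <- stats::rpois(1, config$false_rate_per_receiver_per_day * days)
      if (nf == 0) return(NULL)
      tt <- start_num + stats::runif(nf, 0, end_num - start_num)
      list(det = data.frame(
             timestamp_utc = as.POSIXct(tt, origin = "1970-01-01", tz = "UTC"),
             receiver_id = id,
             tag_id = sample(tags, nf, replace = TRUE),
             protocol = "S64K-69kHz",
             raw_value = sample(0:255, nf, replace = TRUE),
             sensor_type = sample(c("accel", "depth"), nf, replace = TRUE),
             stringsAsFactors = FALSE))
    }
    rows <- with_seed(substream_seed(config$seed, paste0("false:", id)),
                      sim_false())
    if (!is.null(rows)) {
      tr <- rows$det
      res_det[[idx]] <- tr
      res_truth[[idx]] <- data.frame(
        tag_id = tr$tag_id, emission_time = as.POSIXct(NA, tz = "UTC"),
        true_x = NA_real_, true_y = NA_real_, true_depth = NA_real_,
        true_accel = NA_real_, receiver_id = id, is_false = TRUE,
        stringsAsFactors = FALSE)
      idx <- idx + 1L
    }
  }
  det <- do.call(rbind, res_det)
  truth <- do.call(rbind, res_truth)
  if (is.null(det)) {
    det <- data.frame(timestamp_utc = as.POSIXct(character(), tz = "UTC"),
                      receiver_id = character(), tag_id = character(),
                      protocol = character(), raw_value = integer(),
                      sensor_type = character())
    truth <- det[0, 0]
    det$det_id <- integer()
    return(list(detections = det, truth = truth))
  }
  ord <- order(det$tag_id, det$timestamp_utc)
  det <- det[ord, , drop = FALSE]; truth <- truth[ord, , drop = FALSE]
  det$det_id <- seq_len(nrow(det)); truth$det_id <- det$det_id
  rownames(det) <- rownames(truth) <- NULL
  list(detections = det, truth = truth)
}

#' Simulate sync-tag transmissions
#'
#' Regular (jittered) transmissions from the fixed sync-tag positions,
#' received under the same propagation + clock-error model as fish tags.
#' These anchor [fit_clock_models()].
#'
#' @inheritParams simulate_detections
#' @param sync_tags sync tag data frame (see [default_sync_tags()]).
#' @return detection data frame (sensor_type \code{"none"}); the
#'   \code{"truth"} attribute holds \code{tag_id, emission_time,
#'   receiver_id, logged_time} per detection.
#' @export
simulate_sync_transmissions <- function(sync_tags, receivers, config,
                                        clock_truth = NULL) {
  clock_truth <- clock_truth %||% simulate_clock_errors(receivers, config)
  start_num <- as.numeric(config$study_start)
  end_num <- as.numeric(config$study_end)
  deploy_num <- as.numeric(as_utc(receivers$deploy_date))
  out <- list(); tru <- list()
  for (i in seq_len(nrow(sync_tags))) {
    st <- sync_tags[i, ]
    sim_sync <- function() {
      n_max <- ceiling((end_num - start_num) /
                         (config$sync_interval_s * (1 - config$sync_jitter))) + 2
      gaps <- config$sync_interval_s *
        (1 + stats::runif(n_max, -config$sync_jitter, config$sync_jitter))
      em <- start_num + cumsum(gaps)
      em <- em[em <= end_num]
      dist <- sqrt((st$x_m - receivers$x_m)^2 + (st$y_m - receivers$y_m)^2)
      p <- detect_prob(dist, config, sync = TRUE)
      hitm <- matrix(stats::runif(length(em) * length(dist)),
                     length(em)) < rep(p, each = length(em))
      hitm <- hitm & outer(em, deploy_num, ">=")
      ij <- which(hitm, arr.ind = TRUE)
      if (!nrow(ij)) return(NULL)
      e <- ij[, 1]; rr <- ij[, 2]
      arr <- em[e] + dist[rr] / config$sound_speed_mps
      logged <- arr + clock_error_at(clock_truth, receivers$receiver_id[rr],
                                     arr, config)
      list(det = data.frame(
             timestamp_utc = as.POSIXct(logged, origin = "1970-01-01",
                                        tz = "UTC"),
             receiver_id = receivers$receiver_id[rr],
             tag_id = st$tag_id, protocol = "S64K-69kHz",
             raw_value = NA_integer_, sensor_type = "none",
             stringsAsFactors = FALSE),
           truth = data.frame(
             tag_id = st$tag_id,
             emission_time = as.POSIXct(em[e], origin = "1970-01-01",
                                        tz = "UTC"),
             receiver_id = receivers$receiver_id[rr],
             logged_time = as.POSIXct(logged, origin = "1970-01-01",
                                      tz = "UTC"),
             stringsAsFactors = FALSE))
    }
    r <- with_seed(substream_seed(config$seed, paste0("sync:", st$tag_id)),
                   sim_sync())
    if (!is.null(r)) { out[[length(out) + 1]] <- r$det
                       tru[[length(tru) + 1]] <- r$truth }
  }
  det <- do.call(rbind, out)
  ord <- order(det$tag_id, det$timestamp_utc)
  det <- det[ord, , drop = FALSE]
  rownames(det) <- NULL
  truth <- do.call(rbind, tru)[ord, , drop = FALSE]
  rownames(truth) <- NULL
  attr(det, "truth") <- truth
  det
}

#' Simulate a complete telemetry dataset
#'
#' Convenience wrapper running the whole generator: fish cohort, receiver
#' array, sync tags, true tracks, per-receiver clock errors, fish-tag
#' detections (with injected false detections and truth table), and
#' sync-tag detections.
#'
#' @param config a [sim_config()].
#' @param receivers,fish optional overrides of [default_receivers()] /
#'   [default_fish()].
#' @return named list: \code{config, receivers, fish, sync_tags, tracks,
#'   clock_truth, detections, truth, sync_detections}.
#' @export
simulate_telemetry <- function(config = sim_config(), receivers = NULL,
                               fish = NULL) {
  receivers <- receivers %||% default_receivers(config)
  fish <- fish %||% default_fish(config)
  sync_tags <- default_sync_tags(receivers)
  clock_truth <- simulate_clock_errors(receivers, config)
  tracks <- simulate_tracks(config, fish)
  det <- simulate_detections(tracks, receivers, config, clock_truth)
  sync <- simulate_sync_transmissions(sync_tags, receivers, config,
                                      clock_truth)
  list(config = config, receivers = receivers, fish = fish,
       sync_tags = sync_tags, tracks = tracks, clock_truth = clock_truth,
       detections = det$detections, truth = det$truth,
       sync_detections = sync)
}
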