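# Time-of-arrival multilateration.  A transmission heard at n receivers
# gives arrival times a_i = t0 + ||p - r_i||/c (+ noise); emission time t0
# is unknown (tags are not synchronised to receivers), so the objective
#   S(p, t0) = sum_i (a_i - t0 - d_i(p)/c)^2
# is minimised over (x, y, t0).  For fixed p the optimal t0 is the mean
# residual, so the search is over (x, y) only, with the curvature-based
# standard errors computed for the full 3-parameter problem.

#' Group detections into ping groups
#'
#' Arrivals of one tag within the maximum propagation window (largest
#' inter-receiver distance / sound speed + a guard) are attributed to one
#' transmission.  When a receiver appears more than once in a group the
#' earliest arrival is kept.  Singleton groups are retained: they cannot
#' be positioned but still carry presence information.
#'
#' @param dets clock-corrected detections (column \code{corrected_time},
#'   e.g. from [apply_clock_models()]; falls back to
#'   \code{timestamp_utc}).
#' @param receivers receiver data frame (defines the maximum range).
#' @param sound_speed_mps speed of sound (m/s).
#' @param guard_s additive guard on the grouping window (s).
#' @return \code{dets} with columns \code{ping_id} (unique across tags)
#'   and \code{dup_receiver} (TRUE for later duplicate arrivals of the
#'   same receiver within a group, which positioning ignores).
#' @export
group_pings <- function(dets, receivers, sound_speed_mps = 1450,
                        guard_s = 0.1) {
  tcol <- if ("corrected_time" %in% names(dets)) "corrected_time" else
    "timestamp_utc"
  dx <- outer(receivers$x_m, receivers$x_m, "-")
  dy <- outer(receivers$y_m, receivers$y_m, "-")
  window <- max(sqrt(dx^2 + dy^2)) / sound_speed_mps + guard_s
  ord <- order(dets$tag_id, dets[[tcol]])
  dets <- dets[ord, , drop = FALSE]
  t <- as.numeric(dets[[tcol]])
  new_group <- c(TRUE, diff(t) > window | dets$tag_id[-1] !=
                   dets$tag_id[-nrow(dets)])
  dets$ping_id <- cumsum(new_group)
  dup <- logical(nrow(dets))
  for (g in split(seq_len(nrow(dets)), dets$ping_id)) {
    dup[g] <- duplicated(dets$receiver_id[g])
  }
  dets$dup_receiver <- dup
  rownames(dets) <- NULL
  attr(dets, "group_window_s") <- window
  dets
}

# concentrated objective over p = (x, y); t0 profiled out analytically
toa_objective <- function(p, arrivals, rx, ry, c_mps) {
  d <- sqrt((p[1] - rx)^2 + (p[2] - ry)^2)
  r <- arrivals - d / c_mps
  sum((r - mean(r))^2)
}

toa_gradient <- function(p, arrivals, rx, ry, c_mps) {
  d <- pmax(sqrt((p[1] - rx)^2 + (p[2] - ry)^2), 1e-9)
  r <- arrivals - d / c_mps
  e <- r - mean(r)
  gx <- sum(-2 * e * (p[1] - rx) / (c_mps * d))
  gy <- sum(-2 * e * (p[2] - ry) / (c_mps * d))
  c(gx, gy)
}

#' Multilaterate one ping group
#'
#' Minimises the sum of squared time residuals over position and emission
#' time.  Standard errors come from the Gauss-Newton curvature of the
#' 3-parameter objective at the optimum, scaled by the residual variance
#' (with \code{sigma_floor_s} substituted when the fit is exactly
#' determined, i.e. three receivers).
#'
#' @param arrivals numeric arrival times (s) at distinct receivers.
#' @param rx,ry receiver coordinates (m), same length as \code{arrivals}.
#' @param sound_speed_mps speed of sound (m/s).
#' @param init optional starting position \code{c(x, y)}; default is the
#'   receiver centroid.
#' @param sigma_floor_s assumed timing noise when residual degrees of
#'   freedom are zero (default 1 ms, ~1.45 m of range).
#' @return list: \code{x, y, t0, se_x, se_y, objective, n_receivers,
#'   converged}.
#' @export
multilaterate <- function(arrivals, rx, ry, sound_speed_mps = 1450,
                          init = NULL, sigma_floor_s = 1e-3) {
  n <- length(arrivals)
  if (n < 3) {
    return(list(x = NA_real_, y = NA_real_, t0 = NA_real_,
                se_x = Inf, se_y = Inf, objective = NA_real_,
                n_receivers = n, converged = FALSE))
  }
  # exactly collinear receivers admit a mirror solution with identical
  # objective: the transverse coordinate is unidentifiable
  sv <- svd(cbind(rx - mean(rx), ry - mean(ry)), nu = 0, nv = 0)$d
  degenerate <- sv[2] <= 1e-8 * max(sv[1], 1)
  init <- init %||% c(mean(rx), mean(ry))
  opt <- stats::optim(init, toa_objective, gr = toa_gradient,
                      arrivals = arrivals, rx = rx, ry = ry,
                      c_mps = sound_speed_mps, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-14))
  # Levenberg-Marquardt polish: quasi-Newton steps stall in the shallow
  # valleys near-collinear receiver geometries produce; Gauss-Newton on
  # the full (x, y, t0) residuals converges there.
  p <- opt$par
  obj <- opt$value
  lambda <- 1e-8
  for (it in 1:60) {
    d <- pmax(sqrt((p[1] - rx)^2 + (p[2] - ry)^2), 1e-9)
    r <- arrivals - d / sound_speed_mps
    e <- r - mean(r)
    J2 <- cbind(-(p[1] - rx) / (sound_speed_mps * d),
                -(p[2] - ry) / (sound_speed_mps * d))
    J2 <- sweep(J2, 2, colMeans(J2))  # project out the t0 direction
    step <- tryCatch(
      solve(crossprod(J2) + lambda * diag(2), -crossprod(J2, e)),
      error = function(err) NULL)
    if (is.null(step)) break
    p_new <- p + as.numeric(step)
    obj_new <- toa_objective(p_new, arrivals, rx, ry, sound_speed_mps)
    if (obj_new < obj) {
      if (obj - obj_new < 1e-18 * (1 + obj)) { p <- p_new; obj <- obj_new; break }
      p <- p_new; obj <- obj_new
      lambda <- max(lambda / 10, 1e-12)
    } else {
      lambda <- lambda * 10
      if (lambda > 1e6) break
    }
  }
  opt$value <- obj
  d <- pmax(sqrt((p[1] - rx)^2 + (p[2] - ry)^2), 1e-9)
  r <- arrivals - d / sound_speed_mps
  t0 <- mean(r)
  # Jacobian of residuals e_i = a_i - t0 - d_i/c wrt (x, y, t0)
  J <- cbind(-(p[1] - rx) / (sound_speed_mps * d),
             -(p[2] - ry) / (sound_speed_mps * d),
             rep(-1, n))
  sigma2 <- if (n > 3) opt$value / (n - 3) else sigma_floor_s^2
  cov <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) NULL)
  se <- if (degenerate || is.null(cov) || any(diag(cov)[1:2] < 0))
    c(Inf, Inf) else sqrt(diag(cov)[1:2])
  list(x = p[1], y = p[2], t0 = t0, se_x = se[1], se_y = se[2],
       objective = opt$value, n_receivers = n,
       converged = opt$convergence == 0)
}

#' Position all ping groups of one fish-day
#'
#' Solves every positionable group (three or more distinct receivers)
#' with five seeded random initialisations uniform over the lake bounding
#' box and keeps the lowest-objective solution.  A fix is accepted when
#' its standard error passes the 20 m rule: under the default
#' \code{"both"} rule a fix is discarded only when the error exceeds the
#' threshold in both the x and the y dimension; \code{"either"} is the
#' stricter variant.
#'
#' @param groups detections of one tag (or tag-day) carrying
#'   \code{ping_id} from [group_pings()].
#' @param receivers receiver data frame.
#' @param sound_speed_mps speed of sound (m/s).
#' @param n_restarts number of random initialisations per group.
#' @param bbox bounding box \code{c(xmin, xmax, ymin, ymax)} for the
#'   initialisations; default: receiver bounding box + 100 m.
#' @param max_se_m acceptance threshold on the positional standard error.
#' @param accept_rule \code{"both"} (discard when se > threshold on both
#'   axes) or \code{"either"}.
#' @param min_receivers_accept minimum receivers for an accepted fix
#'   (default 4).  Three-receiver fixes are exactly determined, so their
#'   residuals carry no error information, and near-collinear receiver
#'   geometries leave a genuine mirror/valley ambiguity that a local
#'   standard error cannot flag; they are therefore solved and reported
#'   but not accepted unless this is lowered to 3.
#' @param seed integer seed for the restart draws.
#' @param sigma_floor_s see [multilaterate()].
#' @return data frame of position fixes: \code{tag_id, ping_id,
#'   emission_time, x_m, y_m, se_x_m, se_y_m, n_receivers, objective,
#'   accepted}.
#' @export
fit_fish_day <- function(groups, receivers, sound_speed_mps = 1450,
                         n_restarts = 5, bbox = NULL, max_se_m = 20,
                         accept_rule = c("both", "either"),
                         min_receivers_accept = 4, seed = 1L,
                         sigma_floor_s = 1e-3) {
  accept_rule <- match.arg(accept_rule)
  tcol <- if ("corrected_time" %in% names(groups)) "corrected_time" else
    "timestamp_utc"
  bbox <- bbox %||% c(min(receivers$x_m) - 100, max(receivers$x_m) + 100,
                      min(receivers$y_m) - 100, max(receivers$y_m) + 100)
  ri <- match(groups$receiver_id, receivers$receiver_id)
  if (anyNA(ri)) stop("detection at unknown receiver")
  rows <- list()
  with_seed(seed, {
    for (g in split(seq_len(nrow(groups)), groups$ping_id)) {
      g <- g[!groups$dup_receiver[g]]
      if (length(g) < 3) next
      arr <- as.numeric(groups[[tcol]][g])
      rx <- receivers$x_m[ri[g]]; ry <- receivers$y_m[ri[g]]
      inits <- cbind(stats::runif(n_restarts, bbox[1], bbox[2]),
                     stats::runif(n_restarts, bbox[3], bbox[4]))
      fits <- lapply(seq_len(n_restarts), function(s) {
        multilaterate(arr, rx, ry, sound_speed_mps,
                      init = inits[s, ], sigma_floor_s = sigma_floor_s)
      })
      conv <- vapply(fits, `[[`, logical(1), "converged")
      pool <- if (any(conv)) fits[conv] else fits
      best <- pool[[which.min(vapply(pool, `[[`, numeric(1), "objective"))]]
      acc <- if (accept_rule == "both") {
        !(best$se_x > max_se_m & best$se_y > max_se_m)
      } else {
        !(best$se_x > max_se_m | best$se_y > max_se_m)
      }
      rows[[length(rows) + 1]] <- data.frame(
        tag_id = groups$tag_id[g[1]],
        ping_id = groups$ping_id[g[1]],
        emission_time = as.POSIXct(best$t0, origin = "1970-01-01",
                                   tz = "UTC"),
        x_m = best$x, y_m = best$y,
        se_x_m = best$se_x, se_y_m = best$se_y,
        n_receivers = best$n_receivers, objective = best$objective,
        accepted = acc && best$converged &&
          best$n_receivers >= max(3, min_receivers_accept),
        stringsAsFactors = FALSE)
    }
  })
  if (!length(rows)) {
    return(data.frame(tag_id = character(), ping_id = integer(),
                      emission_time = as.POSIXct(character(), tz = "UTC"),
                      x_m = numeric(), y_m = numeric(), se_x_m = numeric(),
                      se_y_m = numeric(), n_receivers = integer(),
                      objective = numeric(), accepted = logical()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Position every fish over the whole record
#'
#' Splits clock-corrected lake detections by tag and calendar day and runs
#' [fit_fish_day()] on each, with a per-fish-day seed derived from the
#' global seed so any subset reproduces identically.
#'
#' @param dets clock-corrected detections (lake receivers; river
#'   detections carry presence only and should not be passed here).
#' @param receivers receiver data frame.
#' @param seed global integer seed.
#' @param ... passed to [fit_fish_day()].
#' @inheritParams fit_fish_day
#' @return data frame of position fixes (see [fit_fish_day()]).
#' @export
position_fish <- function(dets, receivers, sound_speed_mps = 1450,
                          seed = 1L, ...) {
  grouped <- group_pings(dets, receivers, sound_speed_mps)
  tcol <- if ("corrected_time" %in% names(grouped)) "corrected_time" else
    "timestamp_utc"
  day <- format(grouped[[tcol]], "%Y-%m-%d", tz = "UTC")
  out <- list()
  for (key in unique(paste(grouped$tag_id, day))) {
    sel <- paste(grouped$tag_id, day) == key
    out[[key]] <- fit_fish_day(grouped[sel, , drop = FALSE], receivers,
                               sound_speed_mps,
                               seed = substream_seed(seed, paste0("pos:", key)),
                               ...)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Brute-force grid-search multilateration (reference oracle)
#'
#' Evaluates the concentrated time-of-arrival objective on a regular
#' lattice and returns the minimising node.  Exhaustive and slow; used to
#' validate the optimiser, never for production positioning.
#'
#' @inheritParams multilaterate
#' @param bbox lattice extent \code{c(xmin, xmax, ymin, ymax)}.
#' @param resolution_m lattice spacing (m).
#' @return list \code{x, y, objective}.
#' @export
multilaterate_grid <- function(arrivals, rx, ry, sound_speed_mps = 1450,
                               bbox, resolution_m = 1) {
  xs <- seq(bbox[1], bbox[2], by = resolution_m)
  ys <- seq(bbox[3], bbox[4], by = resolution_m)
  best <- list(x = NA_real_, y = NA_real_, objective = Inf)
  for (yv in ys) {  # row-wise to bound memory
    d <- sqrt(outer(xs, rx, "-")^2 + outer(rep(yv, length(xs)), ry, "-")^2)
    r <- -sweep(d / sound_speed_mps, 2, arrivals, "-")
    obj <- rowSums((r - rowMeans(r))^2)
    i <- which.min(obj)
    if (obj[i] < best$objective) {
      best <- list(x = xs[i], y = yv, objective = obj[i])
    }
  }
  best
}
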