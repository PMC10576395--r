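# Shared fixtures, built in code.

utc <- function(x) as.POSIXct(x, tz = "UTC")

# minimal receiver table: two river-down, three lake, one river-up
tiny_receivers <- function() {
  data.frame(
    receiver_id = c("RD1", "RD2", "LK1", "LK2", "LK3", "RU1"),
    x_m = c(-1200, -100, 300, 900, 1500, 3500),
    y_m = c(290, 290, 150, 430, 150, 290),
    habitat = c("river_down", "river_down", "lake", "lake", "lake",
                "river_up"),
    deploy_date = as.Date("2021-07-01"),
    has_sync_tag = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

make_dets <- function(times, receiver_id, tag_id = "4701",
                      raw_value = NA_integer_, sensor_type = "none") {
  n <- length(times)
  data.frame(
    timestamp_utc = utc(times),
    receiver_id = rep_len(as.character(receiver_id), n),
    tag_id = rep_len(as.character(tag_id), n),
    protocol = rep_len("S64K-69kHz", n),
    raw_value = rep_len(as.integer(raw_value), n),
    sensor_type = rep_len(sensor_type, n),
    stringsAsFactors = FALSE
  )
}

# small simulated scenario reused across tests (cheap: ~4 fish-days)
scenario <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 42, n_fish = 3,
                        study_start = "2021-07-20T00:00:00Z",
                        study_end = "2021-07-24T00:00:00Z",
                        false_rate_per_receiver_per_day = 2)
      cache <<- c(simulate_telemetry(cfg), list(cfg = cfg))
    }
    cache
  }
})

# noise-free arrival set from a known point
exact_arrivals <- function(px, py, rx, ry, c_mps = 1450, t0 = 1000) {
  t0 + sqrt((px - rx)^2 + (py - ry)^2) / c_mps
}
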