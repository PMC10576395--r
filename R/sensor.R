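#' Sensor payload scales
#'
#' Acoustic tags transmit one integer payload per ping, quantised to the
#' 0--255 range of the sensor.  The accelerometer payload is the root mean
#' square of tri-axial acceleration over the sampling window, with full
#' scale 3.456 m/s^2 at count 255; the depth payload has 0.1 m per count,
#' so count 255 is the 25.5 m tag depth limit.  Values beyond full scale
#' are registered as 255 by the tag.
#'
#' @param sensor_type one of \code{"accel"}, \code{"depth"}, \code{"temp"}.
#' @param units_per_count physical units per integer count.  Required for
#'   \code{"temp"} (no conventional default); optional override otherwise.
#' @return an object of class \code{"sensor_scale"} with fields
#'   \code{sensor_type}, \code{units_per_count}, \code{max_count}.
#' @examples
#' decode_sensor(255L, sensor_scale("accel"))  # 3.456
#' decode_sensor(255L, sensor_scale("depth"))  # 25.5
#' @export
sensor_scale <- function(sensor_type = c("accel", "depth", "temp"),
                         units_per_count = NULL) {
  sensor_type <- match.arg(sensor_type)
  if (is.null(units_per_count)) {
    units_per_count <- switch(sensor_type,
      accel = 3.456 / 255,
      depth = 0.1,
      temp = stop("temperature decoding needs an explicit units_per_count; ",
                  "there is no conventional scale", call. = FALSE)
    )
  }
  if (!is.numeric(units_per_count) || units_per_count <= 0) {
    stop("units_per_count must be a positive number")
  }
  structure(list(sensor_type = sensor_type,
                 units_per_count = units_per_count,
                 max_count = 255L),
            class = "sensor_scale")
}

check_raw <- function(raw) {
  if (any(is.na(raw)) || any(raw < 0 | raw > 255) || any(raw != round(raw))) {
    stop("raw sensor value must be an integer in [0, 255]")
  }
  as.integer(raw)
}

#' Decode sensor payloads to physical units
#'
#' @param raw integer payload(s) in 0--255.
#' @param scale a [sensor_scale()].
#' @return decoded value(s): \code{raw * units_per_count}.
#' @export
decode_sensor <- function(raw, scale) {
  stopifnot(inherits(scale, "sensor_scale"))
  check_raw(raw) * scale$units_per_count
}

#' @rdname decode_sensor
#' @details \code{decode_accel} applies RMS = raw x 3.456/255 (m/s^2);
#'   \code{decode_depth} applies raw x 0.1 (m).
#' @export
decode_accel <- function(raw) decode_sensor(raw, sensor_scale("accel"))

#' @rdname decode_sensor
#' @export
decode_depth <- function(raw) decode_sensor(raw, sensor_scale("depth"))

#' Encode a physical value to a 0--255 payload
#'
#' Nearest-count quantisation with saturation: values above full scale are
#' registered as the maximum count (255), as the tag firmware does.
#'
#' @param value non-negative physical value(s).
#' @param scale a [sensor_scale()].
#' @return integer count(s) in 0--255.
#' @export
encode_sensor <- function(value, scale) {
  stopifnot(inherits(scale, "sensor_scale"))
  if (any(is.na(value)) || any(value < 0)) {
    stop("sensor values must be non-negative")
  }
  as.integer(pmin(round(value / scale$units_per_count), scale$max_count))
}

#' Append decoded sensor columns to a detection table
#'
#' Adds \code{accel_ms2} and \code{depth_m} columns, decoded from
#' \code{raw_value} where \code{sensor_type} matches, NA elsewhere.
#'
#' @param dets detection data frame.
#' @param accel,depth sensor scales (defaults: the tag's published scales).
#' @return \code{dets} with two extra numeric columns.
#' @export
add_decoded_columns <- function(dets, accel = sensor_scale("accel"),
                                depth = sensor_scale("depth")) {
  dets$accel_ms2 <- NA_real_
  dets$depth_m <- NA_real_
  ia <- which(dets$sensor_type == "accel" & !is.na(dets$raw_value))
  id <- which(dets$sensor_type == "depth" & !is.na(dets$raw_value))
  if (length(ia)) dets$accel_ms2[ia] <- decode_sensor(dets$raw_value[ia], accel)
  if (length(id)) dets$depth_m[id] <- decode_sensor(dets$raw_value[id], depth)
  dets
}

#' Tag burden from Fulton's condition factor
#'
#' Body mass is predicted from total length via Fulton's condition factor
#' K = 100 W / L^3 (W in g, L in cm), i.e. W = K L^3 / 100; burden is tag
#' mass as a percentage of that body mass.  With the 11.5 g tag used here
#' and K = 1, the smallest tagged fish (41.5 cm) carries about 1.6%.
#'
#' @param tag_mass_g tag mass in air (g).
#' @param total_length_cm fish total length (cm).
#' @param condition_k Fulton's condition factor (default 1).
#' @return burden in percent of body mass.
#' @examples
#' tag_burden(11.5, 41.5)  # ~1.61
#' @export
tag_burden <- function(tag_mass_g, total_length_cm, condition_k = 1) {
  if (any(total_length_cm <= 0)) stop("total_length_cm must be positive")
  if (any(condition_k <= 0)) stop("condition_k must be positive")
  if (any(tag_mass_g < 0)) stop("tag_mass_g must be non-negative")
  body_mass_g <- condition_k * total_length_cm^3 / 100
  100 * tag_mass_g / body_mass_g
}

#' Minimum fish length for a tag-burden ceiling
#'
#' Inverts [tag_burden()]: the total length at which a tag of the given
#' mass is exactly \code{max_burden_pct} of predicted body mass.
#'
#' @param tag_mass_g tag mass (g).
#' @param max_burden_pct burden ceiling in percent (default 2).
#' @param condition_k Fulton's condition factor (default 1).
#' @return total length in cm.
#' @export
min_length_for_burden <- function(tag_mass_g, max_burden_pct = 2,
                                  condition_k = 1) {
  if (max_burden_pct <= 0) stop("max_burden_pct must be positive")
  (100 * 100 * tag_mass_g / (max_burden_pct * condition_k))^(1 / 3)
}
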