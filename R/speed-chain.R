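# Conversions between batted-ball speed, bat-head speed and the
# sensor-reported bat speed. The sensor measures a point 0.15 m from the
# distal end of the bat, so it reads lower than the head speed by the
# along-bat speed gradient times that offset.

#' Speed-chain configuration
#'
#' @param regression_slope Slope of the batted-ball vs bat-head speed
#'   regression (batted = slope * head + intercept). Default 0.865.
#' @param regression_intercept Intercept of that regression, m/s.
#'   Default 6.425.
#' @param speed_gradient Along-bat speed gradient, m/s per 0.01 m of offset
#'   from the head. Default 0.28.
#' @param sensor_offset_distance Distance of the sensor's measured point from
#'   the bat head, m. Default 0.15.
#'
#' @return A list of class `speed_chain_config`.
#' @export
speed_chain_config <- function(regression_slope = 0.865,
                               regression_intercept = 6.425,
                               speed_gradient = 0.28,
                               sensor_offset_distance = 0.15) {
  stop_if_not_finite(
    c(regression_slope, regression_intercept, speed_gradient,
      sensor_offset_distance), "speed_chain_config")
  if (regression_slope == 0) {
    stop("`regression_slope` must be non-zero", call. = FALSE)
  }
  if (sensor_offset_distance < 0) {
    stop("`sensor_offset_distance` must be >= 0", call. = FALSE)
  }
  structure(
    list(regression_slope = regression_slope,
         regression_intercept = regression_intercept,
         speed_gradient = speed_gradient,
         sensor_offset_distance = sensor_offset_distance),
    class = "speed_chain_config"
  )
}

#' Batted-ball speed from bat-head speed
#'
#' Applies the linear regression `batted = slope * head + intercept`.
#'
#' @param head_speed Bat-head speed, m/s.
#' @param cfg A [speed_chain_config()].
#' @return Batted-ball speed, m/s.
#' @export
batted_speed_from_head_speed <- function(head_speed,
                                         cfg = speed_chain_config()) {
  cfg$regression_slope * head_speed + cfg$regression_intercept
}

#' Bat-head speed from batted-ball speed
#'
#' Inverse of [batted_speed_from_head_speed()].
#'
#' @param batted_speed Batted-ball speed, m/s.
#' @inheritParams batted_speed_from_head_speed
#' @return Bat-head speed, m/s.
#' @export
head_speed_from_batted_speed <- function(batted_speed,
                                         cfg = speed_chain_config()) {
  (batted_speed - cfg$regression_intercept) / cfg$regression_slope
}

#' Sensor speed offset
#'
#' How much lower the sensor-reported bat speed is than the bat-head speed:
#' the along-bat speed gradient (per 0.01 m) times the sensor's measured
#' point offset from the head.
#'
#' @inheritParams batted_speed_from_head_speed
#' @return Offset in m/s.
#' @export
sensor_offset <- function(cfg = speed_chain_config()) {
  cfg$speed_gradient * (cfg$sensor_offset_distance / 0.01)
}

#' Sensor bat-speed threshold for a home run
#'
#' Chains the flight simulation and the speed conversions: find the minimum
#' batted-ball speed whose carry reaches `target_distance`, convert it to a
#' bat-head speed through the inverse regression, then subtract the sensor
#' offset. All arithmetic is done at full precision; round only for display.
#'
#' @param target_distance Carry distance defining a home run, m. Default 100.
#' @param cfg A [speed_chain_config()].
#' @inheritParams min_speed_for_distance
#'
#' @return A one-row tibble with `batted_speed`, `head_speed`, `offset` and
#'   `blast_speed` (all m/s).
#' @export
blast_speed_for_home_run <- function(target_distance = 100,
                                     cfg = speed_chain_config(),
                                     start_speed = 37.5,
                                     step = 0.28,
                                     launch_template = reference_launch(),
                                     schedule = anchor_schedule(),
                                     props = ball_properties(),
                                     env = aero_environment(),
                                     dt = 1e-3) {
  ms <- min_speed_for_distance(
    target = target_distance, start_speed = start_speed, step = step,
    launch_template = launch_template, schedule = schedule,
    props = props, env = env, dt = dt
  )
  head <- head_speed_from_batted_speed(ms$speed, cfg)
  off <- sensor_offset(cfg)
  tibble::tibble(
    batted_speed = ms$speed,
    head_speed = head,
    offset = off,
    blast_speed = head - off
  )
}
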