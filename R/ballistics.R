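# Rigid-ball flight under gravity, Magnus lift, drag and side force.
#
# Coordinate frame: x is the horizontal direction of travel, y is left-right,
# z is height. A launch with zero spray angle stays in the x-z plane.

#' Physical properties of the ball
#'
#' @param mass Ball mass in kg. Default 0.14 kg (official ball).
#' @param radius Ball radius in m. Default 0.0365 m, corresponding to a
#'   circumference of about 22.9 cm. The cross-sectional area is
#'   `pi * radius^2`.
#'
#' @return A list with `mass`, `radius` and `cross_section_area`.
#' @export
ball_properties <- function(mass = 0.14, radius = 0.0365) {
  stopifnot(is.numeric(mass), is.numeric(radius))
  stop_if_not_finite(c(mass, radius), "ball_properties")
  if (mass <= 0) stop("`mass` must be > 0", call. = FALSE)
  if (radius <= 0) stop("`radius` must be > 0", call. = FALSE)
  structure(
    list(mass = mass, radius = radius, cross_section_area = pi * radius^2),
    class = "ball_properties"
  )
}

#' Aerodynamic environment
#'
#' @param air_density Mass density of air in kg/m^3. Default 1.205 (dry air
#'   at about 20 degrees C).
#' @param gravity Gravitational acceleration magnitude in m/s^2, acting along
#'   -z. Default 9.81.
#'
#' @return A list with `air_density` and `gravity`.
#' @export
aero_environment <- function(air_density = 1.205, gravity = 9.81) {
  stop_if_not_finite(c(air_density, gravity), "aero_environment")
  if (air_density <= 0) stop("`air_density` must be > 0", call. = FALSE)
  if (gravity <= 0) stop("`gravity` must be > 0", call. = FALSE)
  structure(list(air_density = air_density, gravity = gravity),
            class = "aero_environment")
}

#' Dimensionless aerodynamic coefficients
#'
#' @param lift Lift coefficient C_L (any sign).
#' @param drag Drag coefficient C_D (must be >= 0).
#' @param side Side-force coefficient C_Y (any sign).
#'
#' @return A list with `lift`, `drag`, `side`.
#' @export
aero_coefficients <- function(lift, drag, side) {
  stop_if_not_finite(c(lift, drag, side), "aero_coefficients")
  if (drag < 0) stop("`drag` must be >= 0", call. = FALSE)
  structure(list(lift = lift, drag = drag, side = side),
            class = "aero_coefficients")
}

#' Aerodynamic coefficient schedule
#'
#' Coefficients are evaluated as a function of the spin parameter
#' `r * |omega| / |v|` (ratio of the ball's equatorial surface speed to its
#' translational speed). `anchors` gives the coefficients at reference spin
#' parameters; between anchors they are interpolated (linearly or held
#' constant) and clamped outside the anchored range. A schedule with one
#' anchor is a constant-coefficient schedule.
#'
#' @param anchors A data frame with columns `spin_parameter`, `lift`, `drag`,
#'   `side`, sorted (or sortable) by `spin_parameter`.
#' @param interpolation Either `"linear"` or `"constant"` (step function,
#'   left-continuous from the anchor at or below the query).
#'
#' @return An object of class `coefficient_schedule`.
#' @seealso [constant_coefficients()], [anchor_schedule()]
#' @export
coefficient_schedule <- function(anchors,
                                 interpolation = c("linear", "constant")) {
  interpolation <- match.arg(interpolation)
  anchors <- tibble::as_tibble(anchors)
  needed <- c("spin_parameter", "lift", "drag", "side")
  if (!all(needed %in% names(anchors))) {
    stop("`anchors` needs columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(anchors) < 1) stop("need at least one anchor", call. = FALSE)
  anchors <- dplyr::arrange(anchors, .data$spin_parameter)
  structure(list(anchors = anchors, interpolation = interpolation),
            class = "coefficient_schedule")
}

#' Constant-coefficient schedule
#'
#' Convenience wrapper for a schedule whose coefficients do not depend on the
#' spin parameter, used to reproduce single-flight endpoints at their printed
#' coefficient values.
#'
#' @inheritParams aero_coefficients
#' @return A `coefficient_schedule` with one anchor.
#' @export
constant_coefficients <- function(lift, drag, side) {
  coefficient_schedule(
    tibble::tibble(spin_parameter = 0, lift = lift, drag = drag, side = side),
    interpolation = "constant"
  )
}

#' Two-anchor schedule at the published flight endpoints
#'
#' Linear interpolation in the spin parameter between the coefficient sets
#' printed for the 40.8 m/s flight (C_L 0.21, C_D 0.40, C_Y -0.06; spin
#' parameter 0.0365 * 225 / 40.8) and the 37.5 m/s flight (C_L 0.23, C_D
#' 0.40, C_Y -0.05; spin parameter 0.0365 * 225 / 37.5), clamped outside.
#'
#' @param radius Ball radius used to place the anchors, m.
#' @param spin_rate Spin rate used to place the anchors, rad/s.
#' @return A `coefficient_schedule`.
#' @export
anchor_schedule <- function(radius = 0.0365, spin_rate = 225) {
  coefficient_schedule(
    tibble::tibble(
      spin_parameter = c(radius * spin_rate / 40.8, radius * spin_rate / 37.5),
      lift = c(0.21, 0.23),
      drag = c(0.40, 0.40),
      side = c(-0.06, -0.05)
    ),
    interpolation = "linear"
  )
}

# Evaluate a schedule at a spin parameter; returns c(lift, drag, side).
eval_schedule <- function(schedule, spin_parameter) {
  a <- schedule$anchors
  if (nrow(a) == 1L) {
    return(c(a$lift, a$drag, a$side))
  }
  sp <- a$spin_parameter
  if (schedule$interpolation == "linear") {
    c(stats::approx(sp, a$lift, spin_parameter, rule = 2)$y,
      stats::approx(sp, a$drag, spin_parameter, rule = 2)$y,
      stats::approx(sp, a$side, spin_parameter, rule = 2)$y)
  } else {
    i <- max(1L, findInterval(spin_parameter, sp))
    c(a$lift[i], a$drag[i], a$side[i])
  }
}

#' Launch conditions of a batted ball
#'
#' @param speed Batted-ball speed, m/s (> 0).
#' @param launch_angle Angle above the horizontal, degrees, in `[-90, 90]`.
#' @param spray_angle Horizontal angle from the +x direction of travel,
#'   degrees. Default 0 (flight in the x-z plane).
#' @param spin_rate Magnitude of the ball's angular velocity, rad/s (>= 0).
#' @param spin_axis_elevation Elevation of the spin axis above the horizontal
#'   plane, degrees.
#' @param spin_axis_azimuth Azimuth of the spin axis, degrees, measured in
#'   the horizontal plane from the pure-backspin orientation (-y) toward +x.
#'   With elevation = azimuth = 0 the spin is pure backspin and the Magnus
#'   force on a ball moving along +x points up.
#' @param initial_height Height of the ball at launch, m.
#'
#' @return An object of class `launch_conditions`.
#' @export
launch_conditions <- function(speed,
                              launch_angle,
                              spray_angle = 0,
                              spin_rate = 0,
                              spin_axis_elevation = 0,
                              spin_axis_azimuth = 0,
                              initial_height = 0) {
  vals <- c(speed, launch_angle, spray_angle, spin_rate,
            spin_axis_elevation, spin_axis_azimuth, initial_height)
  stop_if_not_finite(vals, "launch_conditions")
  if (speed <= 0) stop("`speed` must be > 0", call. = FALSE)
  if (abs(launch_angle) > 90) {
    stop("`launch_angle` must lie in [-90, 90] degrees", call. = FALSE)
  }
  if (spin_rate < 0) stop("`spin_rate` must be >= 0", call. = FALSE)
  structure(
    list(speed = speed, launch_angle = launch_angle, spray_angle = spray_angle,
         spin_rate = spin_rate, spin_axis_elevation = spin_axis_elevation,
         spin_axis_azimuth = spin_axis_azimuth,
         initial_height = initial_height),
    class = "launch_conditions"
  )
}

#' Launch conditions used for the published carry-distance validation
#'
#' Launch angle 33.2 degrees, spin 225 rad/s, spin-axis elevation 13.3 and
#' azimuth 15.4 degrees, initial height 1.0 m; only the speed varies.
#'
#' @param speed Batted-ball speed, m/s.
#' @return A `launch_conditions` object.
#' @export
reference_launch <- function(speed = 37.5) {
  launch_conditions(
    speed = speed, launch_angle = 33.2, spray_angle = 0,
    spin_rate = 225, spin_axis_elevation = 13.3, spin_axis_azimuth = 15.4,
    initial_height = 1.0
  )
}

#' Initial ball state from launch conditions
#'
#' Position is `(0, 0, initial_height)`. With launch angle `theta` and spray
#' angle `phi`, velocity is `speed * (cos th cos ph, cos th sin ph, sin th)`.
#' The angular velocity is `spin_rate` times the unit spin axis
#' `(cos e sin a, -cos e cos a, sin e)` built from the axis elevation `e` and
#' azimuth `a`.
#'
#' @param launch A [launch_conditions()] object.
#' @return A list with numeric length-3 vectors `position`, `velocity` and
#'   `angular_velocity`.
#' @export
launch_to_state <- function(launch) {
  stopifnot(inherits(launch, "launch_conditions"))
  th <- launch$launch_angle * pi / 180
  ph <- launch$spray_angle * pi / 180
  e <- launch$spin_axis_elevation * pi / 180
  a <- launch$spin_axis_azimuth * pi / 180
  axis <- c(cos(e) * sin(a), -cos(e) * cos(a), sin(e))
  list(
    position = c(0, 0, launch$initial_height),
    velocity = launch$speed * c(cos(th) * cos(ph), cos(th) * sin(ph), sin(th)),
    angular_velocity = launch$spin_rate * axis
  )
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Aerodynamic forces on the ball
#'
#' Lift has magnitude `rho C_L A |v|^2 / 2` and is directed along the unit
#' vector of `omega x v`, so it is perpendicular to both the angular and
#' translational velocities. Drag is `-rho C_D A |v| v / 2`, opposite the
#' translational velocity. The side force has magnitude
#' `rho C_Y A |v|^2 / 2` along the unit vector of `L x D`, perpendicular to
#' both. When the lift direction is undefined (zero spin, or spin parallel
#' to the velocity) the lift and side forces are zero vectors.
#'
#' @param state A list with `velocity` and `angular_velocity` (length-3
#'   numeric vectors), as returned by [launch_to_state()].
#' @param coeffs An [aero_coefficients()] object.
#' @param props A [ball_properties()] object.
#' @param env An [aero_environment()] object.
#'
#' @return A list of length-3 force vectors `lift`, `drag`, `side`, in N.
#' @export
aero_forces <- function(state, coeffs, props, env) {
  v <- state$velocity
  w <- state$angular_velocity
  speed <- sqrt(sum(v * v))
  if (speed <= 0) stop("`velocity` must be non-zero", call. = FALSE)
  q <- 0.5 * env$air_density * props$cross_section_area * speed^2
  wxv <- cross3(w, v)
  nwxv <- sqrt(sum(wxv * wxv))
  lift <- if (nwxv > 0) q * coeffs$lift * wxv / nwxv else c(0, 0, 0)
  drag <- -0.5 * env$air_density * coeffs$drag *
    props$cross_section_area * speed * v
  lxd <- cross3(lift, drag)
  nlxd <- sqrt(sum(lxd * lxd))
  side <- if (nlxd > 0) q * coeffs$side * lxd / nlxd else c(0, 0, 0)
  list(lift = lift, drag = drag, side = side)
}

#' Translational acceleration of the ball
#'
#' Newton's second law for the ball in flight:
#' `m g + L + D + Y = m a`, so the acceleration is gravity plus the sum of
#' the aerodynamic forces divided by the ball mass.
#'
#' @inheritParams aero_forces
#' @return Length-3 acceleration vector, m/s^2.
#' @export
ball_acceleration <- function(state, coeffs, props, env) {
  f <- aero_forces(state, coeffs, props, env)
  c(0, 0, -env$gravity) + (f$lift + f$drag + f$side) / props$mass
}

# Fast internal acceleration: avoids list construction inside the RK4 loop.
accel_fast <- function(v, w, cl, cd, cy, halfRhoA, mass, gz) {
  speed2 <- v[1] * v[1] + v[2] * v[2] + v[3] * v[3]
  speed <- sqrt(speed2)
  q <- halfRhoA * speed2
  wxv <- c(w[2] * v[3] - w[3] * v[2],
           w[3] * v[1] - w[1] * v[3],
           w[1] * v[2] - w[2] * v[1])
  nwxv <- sqrt(sum(wxv * wxv))
  if (nwxv > 0) {
    L <- (q * cl / nwxv) * wxv
  } else {
    L <- c(0, 0, 0)
  }
  D <- (-halfRhoA * cd * speed) * v
  lxd <- c(L[2] * D[3] - L[3] * D[2],
           L[3] * D[1] - L[1] * D[3],
           L[1] * D[2] - L[2] * D[1])
  nlxd <- sqrt(sum(lxd * lxd))
  if (nlxd > 0) {
    Y <- (q * cy / nlxd) * lxd
  } else {
    Y <- c(0, 0, 0)
  }
  c(0, 0, gz) + (L + D + Y) / mass
}

#' Simulate a batted-ball trajectory
#'
#' Integrates the equation of motion with a fixed-step fourth-order
#' Runge-Kutta scheme from the launch state until the ball's height crosses
#' zero from above (the landing point is interpolated linearly within the
#' final step) or `max_time` is reached. The aerodynamic coefficients are
#' re-evaluated every step from the current spin parameter
#' `r |omega| / |v|` through the schedule; the ball's angular velocity is
#' held constant during flight (no spin decay).
#'
#' @param launch A [launch_conditions()] object.
#' @param schedule A [coefficient_schedule()].
#' @param props A [ball_properties()] object.
#' @param env An [aero_environment()] object.
#' @param dt Integration step, s. Default 1e-3.
#' @param max_time Maximum simulated time, s. Default 15.
#' @param keep_samples Keep the full time history? Set `FALSE` to save time
#'   and memory when only the carry distance is needed.
#'
#' @return An object of class `swing_flight`: a list with `samples` (a tibble
#'   with columns `time, x, y, z, vx, vy, vz`), `landed` (logical),
#'   `carry_distance` (horizontal distance in m from the launch point's
#'   ground projection to the landing point; when `landed` is `FALSE` it is
#'   taken from the last sample and flagged by `carry_valid = FALSE`),
#'   `flight_time`, and the inputs.
#' @export
simulate_flight <- function(launch,
                            schedule = anchor_schedule(),
                            props = ball_properties(),
                            env = aero_environment(),
                            dt = 1e-3,
                            max_time = 15,
                            keep_samples = TRUE) {
  stopifnot(dt > 0, max_time > 0)
  state <- launch_to_state(launch)
  pos <- state$position
  vel <- state$velocity
  w <- state$angular_velocity
  wn <- sqrt(sum(w * w))
  halfRhoA <- 0.5 * env$air_density * props$cross_section_area
  mass <- props$mass
  gz <- -env$gravity
  radius <- props$radius

  n_max <- ceiling(max_time / dt) + 1L
  if (keep_samples) {
    hist <- matrix(NA_real_, n_max + 1L, 7L)
    hist[1L, ] <- c(0, pos, vel)
  }
  n_kept <- 1L
  t <- 0
  landed <- FALSE
  land_pos <- NULL
  land_t <- NA_real_

  for (i in seq_len(n_max)) {
    sp <- radius * wn / sqrt(sum(vel * vel))
    cf <- eval_schedule(schedule, sp)
    cl <- cf[1]; cd <- cf[2]; cy <- cf[3]

    k1v <- accel_fast(vel, w, cl, cd, cy, halfRhoA, mass, gz)
    v2 <- vel + (dt / 2) * k1v
    k2v <- accel_fast(v2, w, cl, cd, cy, halfRhoA, mass, gz)
    v3 <- vel + (dt / 2) * k2v
    k3v <- accel_fast(v3, w, cl, cd, cy, halfRhoA, mass, gz)
    v4 <- vel + dt * k3v
    k4v <- accel_fast(v4, w, cl, cd, cy, halfRhoA, mass, gz)

    new_pos <- pos + (dt / 6) * (vel + 2 * v2 + 2 * v3 + v4)
    new_vel <- vel + (dt / 6) * (k1v + 2 * k2v + 2 * k3v + k4v)
    t <- t + dt

    if (new_pos[3] <= 0 && pos[3] > 0) {
      f <- pos[3] / (pos[3] - new_pos[3])
      land_pos <- pos + f * (new_pos - pos)
      land_pos[3] <- 0
      land_t <- (t - dt) + f * dt
      landed <- TRUE
      if (keep_samples) {
        n_kept <- n_kept + 1L
        hist[n_kept, ] <- c(land_t, land_pos, vel + f * (new_vel - vel))
      }
      break
    }
    pos <- new_pos
    vel <- new_vel
    if (keep_samples) {
      n_kept <- n_kept + 1L
      hist[n_kept, ] <- c(t, pos, vel)
    }
    if (t >= max_time) break
  }

  if (landed) {
    carry <- sqrt(land_pos[1]^2 + land_pos[2]^2)
    carry_valid <- TRUE
    flight_time <- land_t
  } else {
    carry <- sqrt(pos[1]^2 + pos[2]^2)
    carry_valid <- FALSE
    flight_time <- t
    warning("ball did not land within `max_time`; carry distance is the ",
            "ground projection of the last sample", call. = FALSE)
  }

  samples <- if (keep_samples) {
    tibble::as_tibble(setNames(
      as.data.frame(hist[seq_len(n_kept), , drop = FALSE]),
      c("time", "x", "y", "z", "vx", "vy", "vz")
    ))
  } else {
    NULL
  }

  structure(
    list(samples = samples, landed = landed, carry_distance = carry,
         carry_valid = carry_valid, flight_time = flight_time,
         launch = launch, schedule = schedule, props = props, env = env,
         dt = dt),
    class = "swing_flight"
  )
}

#' @export
print.swing_flight <- function(x, ...) {
  cat(sprintf(
    "<swing_flight> speed %.2f m/s, angle %.1f deg: carry %.2f m in %.2f s%s\n",
    x$launch$speed, x$launch$launch_angle, x$carry_distance, x$flight_time,
    if (x$landed) "" else " (did not land)"
  ))
  invisible(x)
}

#' @method tidy swing_flight
#' @export
tidy.swing_flight <- function(x, ...) {
  if (is.null(x$samples)) {
    stop("trajectory was simulated with `keep_samples = FALSE`",
         call. = FALSE)
  }
  x$samples
}

#' Minimum batted-ball speed whose carry reaches a target distance
#'
#' Scans the speed grid `start_speed + k * step` (k = 0, 1, ...) and returns
#' the first grid speed whose simulated carry distance reaches `target`.
#' All other launch parameters are taken from `launch_template`.
#'
#' @param target Target carry distance, m (> 0).
#' @param start_speed First grid speed, m/s. Default 37.5.
#' @param step Grid increment, m/s. Default 0.28.
#' @param launch_template A [launch_conditions()] object whose speed is
#'   replaced by each grid value.
#' @param speed_cap Largest speed tried before giving up, m/s.
#' @inheritParams simulate_flight
#'
#' @return A one-row tibble with `speed` (first grid speed reaching the
#'   target), `carry_distance`, and `n_evaluated` (number of grid points
#'   simulated).
#' @export
min_speed_for_distance <- function(target,
                                   start_speed = 37.5,
                                   step = 0.28,
                                   launch_template = reference_launch(),
                                   schedule = anchor_schedule(),
                                   props = ball_properties(),
                                   env = aero_environment(),
                                   dt = 1e-3,
                                   max_time = 15,
                                   speed_cap = 60) {
  stopifnot(target > 0, step > 0)
  speed <- start_speed
  n <- 0L
  while (speed <= speed_cap) {
    lc <- launch_template
    lc$speed <- speed
    fl <- simulate_flight(lc, schedule, props, env, dt = dt,
                          max_time = max_time, keep_samples = FALSE)
    n <- n + 1L
    if (fl$landed && fl$carry_distance >= target) {
      return(tibble::tibble(speed = speed,
                            carry_distance = fl$carry_distance,
                            n_evaluated = n))
    }
    speed <- start_speed + n * step
  }
  stop(sprintf(
    "no grid speed below the cap (%.1f m/s) carries %.1f m", speed_cap, target
  ), call. = FALSE)
}

#' @method autoplot swing_flight
#' @export
autoplot.swing_flight <- function(object, ...) {
  if (is.null(object$samples)) {
    stop("trajectory was simulated with `keep_samples = FALSE`",
         call. = FALSE)
  }
  ggplot2::ggplot(object$samples, ggplot2::aes(x = .data$x, y = .data$z)) +
    ggplot2::geom_path(colour = "steelblue") +
    ggplot2::labs(
      x = "direction of travel x (m)", y = "height z (m)",
      title = sprintf("carry %.1f m at %.1f m/s",
                      object$carry_distance, object$launch$speed)
    ) +
    ggplot2::theme_minimal()
}
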