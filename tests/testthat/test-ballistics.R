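test_that("launch geometry places the ball and resolves speed components", {
  lc <- launch_conditions(speed = 40.8, launch_angle = 33.2,
                          initial_height = 1.0)
  st <- launch_to_state(lc)
  expect_equal(st$position, c(0, 0, 1.0))
  expect_equal(st$velocity[3], 40.8 * sin(33.2 * pi / 180), tolerance = 1e-9)
  expect_equal(st$velocity[3], 22.34, tolerance = 1e-3)

  st2 <- launch_to_state(launch_conditions(speed = 10, launch_angle = 0))
  expect_equal(st2$velocity, c(10, 0, 0))
  expect_equal(st2$angular_velocity, c(0, 0, 0))

  # speed is preserved for arbitrary launches
  set.seed(1)
  for (i in 1:20) {
    lc <- launch_conditions(speed = runif(1, 5, 60),
                            launch_angle = runif(1, -80, 80),
                            spray_angle = runif(1, -180, 180),
                            spin_rate = runif(1, 0, 400),
                            spin_axis_elevation = runif(1, -90, 90),
                            spin_axis_azimuth = runif(1, -180, 180),
                            initial_height = runif(1, 0, 2))
    st <- launch_to_state(lc)
    expect_equal(sqrt(sum(st$velocity^2)), lc$speed, tolerance = 1e-9)
    expect_equal(sqrt(sum(st$angular_velocity^2)), lc$spin_rate,
                 tolerance = 1e-9)
  }
})

test_that("pure backspin gives upward lift on a ball moving along +x", {
  st <- list(velocity = c(37.5, 0, 0), angular_velocity = c(0, -225, 0))
  f <- aero_forces(st, aero_coefficients(0.23, 0.40, -0.05),
                   ball_properties(), aero_environment())
  expect_gt(f$lift[3], 0)
  expect_equal(f$lift[1], 0, tolerance = 1e-12)
  # the default axis convention reduces to pure backspin at zero angles
  st0 <- launch_to_state(launch_conditions(speed = 37.5, launch_angle = 0,
                                           spin_rate = 225))
  expect_equal(st0$angular_velocity, c(0, -225, 0), tolerance = 1e-9)
})

test_that("aerodynamic force magnitudes and orthogonality match the model", {
  props <- ball_properties()
  env <- aero_environment()
  st <- list(velocity = c(40.8, 0, 0), angular_velocity = c(0, -225, 0))
  f <- aero_forces(st, aero_coefficients(0, 0.40, 0), props, env)
  expect_equal(sqrt(sum(f$drag^2)),
               0.5 * 1.205 * 0.40 * props$cross_section_area * 40.8^2,
               tolerance = 1e-9)
  expect_equal(sqrt(sum(f$drag^2)), 1.68, tolerance = 0.01)
  expect_equal(f$lift, c(0, 0, 0))
  expect_equal(f$side, c(0, 0, 0))

  # orthogonality for random states
  set.seed(2)
  for (i in 1:20) {
    st <- list(velocity = rnorm(3, sd = 20), angular_velocity = rnorm(3, sd = 100))
    cf <- aero_coefficients(0.2, 0.4, -0.05)
    f <- aero_forces(st, cf, props, env)
    nl <- sqrt(sum(f$lift^2)); nd <- sqrt(sum(f$drag^2)); ny <- sqrt(sum(f$side^2))
    if (nl > 0) {
      expect_lt(abs(sum(f$lift * st$velocity)) / (nl * sqrt(sum(st$velocity^2))), 1e-9)
      expect_lt(abs(sum(f$lift * st$angular_velocity)) /
                  (nl * sqrt(sum(st$angular_velocity^2))), 1e-9)
    }
    if (ny > 0) {
      expect_lt(abs(sum(f$side * f$lift)) / (ny * nl), 1e-9)
      expect_lt(abs(sum(f$side * f$drag)) / (ny * nd), 1e-9)
    }
  }
})

test_that("degenerate spin directions yield zero lift and side force", {
  props <- ball_properties(); env <- aero_environment()
  cf <- aero_coefficients(0.2, 0.4, -0.05)
  # zero spin
  f0 <- aero_forces(list(velocity = c(30, 0, 0),
                         angular_velocity = c(0, 0, 0)), cf, props, env)
  expect_equal(f0$lift, c(0, 0, 0))
  expect_equal(f0$side, c(0, 0, 0))
  # spin parallel to velocity (gyroball)
  fp <- aero_forces(list(velocity = c(30, 0, 0),
                         angular_velocity = c(200, 0, 0)), cf, props, env)
  expect_equal(fp$lift, c(0, 0, 0))
  expect_equal(fp$side, c(0, 0, 0))
})

test_that("acceleration obeys Newton's second law", {
  props <- ball_properties(); env <- aero_environment()
  st <- list(velocity = c(30, 0, 10), angular_velocity = c(0, -200, 50))
  # vacuum limit
  a0 <- ball_acceleration(st, aero_coefficients(0, 0, 0), props, env)
  expect_equal(a0, c(0, 0, -9.81))
  # m (a - g) = L + D + Y
  cf <- aero_coefficients(0.21, 0.40, -0.06)
  a <- ball_acceleration(st, cf, props, env)
  f <- aero_forces(st, cf, props, env)
  expect_equal(props$mass * (a - c(0, 0, -9.81)),
               f$lift + f$drag + f$side, tolerance = 1e-9)
})

test_that("vacuum trajectories reproduce the closed-form projectile range", {
  for (case in list(c(20, 45, 0), c(35, 33.2, 1.0), c(15, 60, 0.5))) {
    lc <- launch_conditions(speed = case[1], launch_angle = case[2],
                            initial_height = case[3])
    fl <- simulate_flight(lc, zero_coeffs(), keep_samples = FALSE)
    expected <- vacuum_range(case[1], case[2], case[3])
    expect_equal(fl$carry_distance, expected, tolerance = 1e-3)
  }
  # the classic v^2/g check at 45 degrees
  fl45 <- simulate_flight(launch_conditions(20, 45), zero_coeffs(),
                          keep_samples = FALSE)
  expect_equal(fl45$carry_distance, 20^2 / 9.81, tolerance = 1e-3)
})

test_that("trajectory bookkeeping: landing, monotone time, interpolated touchdown", {
  fl <- simulate_flight(reference_launch(37.5),
                        constant_coefficients(0.23, 0.40, -0.05))
  expect_true(fl$landed)
  expect_true(all(diff(fl$samples$time) > 0))
  expect_lt(abs(fl$samples$z[nrow(fl$samples)]), 1e-6)
  expect_gte(fl$carry_distance, 0)
  # tidy() returns the sample table
  expect_identical(tidy(fl), fl$samples)
  # a ball that cannot land in time is flagged
  expect_warning(
    fl2 <- simulate_flight(launch_conditions(30, 45, initial_height = 1),
                           zero_coeffs(), max_time = 0.5),
    "did not land")
  expect_false(fl2$landed)
  expect_false(fl2$carry_valid)
})

test_that("carry distance decreases with drag at fixed launch", {
  carries <- vapply(c(0.2, 0.4, 0.6), function(cd) {
    simulate_flight(reference_launch(37.5),
                    constant_coefficients(0, cd, 0),
                    keep_samples = FALSE)$carry_distance
  }, numeric(1))
  expect_true(all(diff(carries) < 0))
})

test_that("halving the integration step changes carry by less than 1 cm", {
  sch <- constant_coefficients(0.23, 0.40, -0.05)
  c1 <- simulate_flight(reference_launch(37.5), sch, dt = 1e-3,
                        keep_samples = FALSE)$carry_distance
  c2 <- simulate_flight(reference_launch(37.5), sch, dt = 5e-4,
                        keep_samples = FALSE)$carry_distance
  expect_lt(abs(c1 - c2), 0.01)
})

test_that("coefficient schedules interpolate and clamp in the spin parameter", {
  sch <- anchor_schedule()
  a <- sch$anchors
  # interpolation is exact at the anchors and linear between them
  expect_equal(swinghr:::eval_schedule(sch, a$spin_parameter[1]),
               c(0.21, 0.40, -0.06))
  expect_equal(swinghr:::eval_schedule(sch, a$spin_parameter[2]),
               c(0.23, 0.40, -0.05))
  mid <- mean(a$spin_parameter)
  expect_equal(swinghr:::eval_schedule(sch, mid),
               c(0.22, 0.40, -0.055), tolerance = 1e-9)
  # clamped outside the anchored range
  expect_equal(swinghr:::eval_schedule(sch, 0), c(0.21, 0.40, -0.06))
  expect_equal(swinghr:::eval_schedule(sch, 1), c(0.23, 0.40, -0.05))
  # constant mode ignores the spin parameter
  cc <- constant_coefficients(0.1, 0.2, -0.3)
  expect_equal(swinghr:::eval_schedule(cc, 0.7), c(0.1, 0.2, -0.3))
})

test_that("minimum-speed search agrees with a brute-force grid scan", {
  sch <- constant_coefficients(0.21, 0.40, -0.06)
  target <- 80
  res <- min_speed_for_distance(target, start_speed = 30, step = 1,
                                schedule = sch, dt = 5e-3)
  # independent scan of the same grid
  speed <- 30
  repeat {
    lc <- reference_launch(speed)
    carry <- simulate_flight(lc, sch, dt = 5e-3,
                             keep_samples = FALSE)$carry_distance
    if (carry >= target) break
    speed <- speed + 1
  }
  expect_equal(res$speed, speed)
  # a target already met at the start returns the start speed
  easy <- min_speed_for_distance(10, start_speed = 30, step = 1,
                                 schedule = sch, dt = 5e-3)
  expect_equal(easy$speed, 30)
  expect_equal(easy$n_evaluated, 1L)
  # an unreachable target errors
  expect_error(
    min_speed_for_distance(1000, start_speed = 30, step = 5, schedule = sch,
                           dt = 5e-3, speed_cap = 50),
    "no grid speed")
})

test_that("constructors reject invalid physics", {
  expect_error(ball_properties(mass = -1), "mass")
  expect_error(aero_environment(air_density = 0), "air_density")
  expect_error(aero_coefficients(0.2, -0.1, 0), "drag")
  expect_error(launch_conditions(speed = 0, launch_angle = 30), "speed")
  expect_error(launch_conditions(speed = 30, launch_angle = 120), "launch_angle")
  expect_error(launch_conditions(speed = Inf, launch_angle = 10), "finite")
  # area invariant
  bp <- ball_properties(radius = 0.05)
  expect_equal(bp$cross_section_area, pi * 0.05^2, tolerance = 1e-9)
})
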