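# Shared fixtures, all generated in code.

# Closed-form projectile range from launch height h (no aerodynamics).
vacuum_range <- function(speed, angle_deg, h = 0, g = 9.81) {
  th <- angle_deg * pi / 180
  vx <- speed * cos(th)
  vz <- speed * sin(th)
  vx * (vz + sqrt(vz^2 + 2 * g * h)) / g
}

zero_coeffs <- function() constant_coefficients(0, 0, 0)

# A tiny hand-built cohort: one player, chosen bat speeds.
manual_cohort <- function(speeds, player_id = "P001", season = 2023,
                          home_runs = 5) {
  n <- length(speeds)
  tibble::tibble(
    player_id = player_id,
    season = as.integer(season),
    swing = seq_len(n),
    swing_id = sprintf("%s-%d-%02d", player_id, season, seq_len(n)),
    bat_speed = speeds,
    bat_mass = 0.88,
    attack_angle = 10,
    on_plane_efficiency = 80,
    rotational_acceleration = 150,
    home_runs = home_runs
  )
}

# A small synthetic train/test pair used by several model tests.
small_tables <- function(seed = 42, n_train = 40, n_test = 12) {
  cfg <- swing_cohort_config(n_players_train = n_train,
                             n_players_test = n_test, seed = seed)
  tab <- build_feature_table(filter_outliers(generate_cohort(cfg))$swings)
  list(train = dplyr::filter(tab, season == 2023),
       test = dplyr::filter(tab, season == 2024))
}

# Prediction functions with known structure, for explanation oracles.
f_linear_speed <- function(d) 2 * d$bat_speed
f_constant <- function(d) rep(7, nrow(d))
f_additive <- function(d) 2 * d$bat_speed + 100 * d$bat_mass - 0.5 * d$attack_angle
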