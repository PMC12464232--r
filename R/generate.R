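# Synthetic swing-cohort generator. Emulates the statistical structure the
# downstream analysis assumes: a training cohort of 31 players and a test
# cohort of 10 players from a later season, 10 swings per player, bat mass
# 0.88 +/- 0.02 kg, overdispersed home-run counts (mean ~3, SD ~6), and
# nonlinear feature-outcome relationships with breakpoints at 33.3 m/s (bat
# speed), 0.91 kg (bat-mass optimum) and 157 m/s^2 (rotational acceleration).

#' Configuration of the synthetic swing-cohort generator
#'
#' Each player has latent (season-level) feature values drawn from cohort
#' distributions; individual swings add within-player measurement noise.
#' Expected home runs follow a log-link response with a saturating hinge in
#' bat speed, a saturating quadratic penalty around the bat-mass optimum,
#' a saturating hinge in rotational acceleration, and small linear effects
#' of attack angle and on-plane efficiency; counts are negative binomial.
#' Defaults are calibrated so that the cohort home-run distribution has mean
#' about 3.0 and standard deviation about 6.1.
#'
#' @param n_players_train,n_players_test Players in the training (default 31)
#'   and test (default 10) cohorts.
#' @param swings_per_player Swings recorded per player. Default 10.
#' @param train_season,test_season Season labels. Defaults 2023 / 2024.
#' @param feature_means,feature_sds Named numeric vectors (names
#'   [swing_features()]) of latent player-level means and SDs.
#' @param speed_mass_cor Correlation between latent bat speed and bat mass
#'   (heavier bats swing slower). Default -0.3.
#' @param swing_noise_sds Named numeric vector of within-player swing noise
#'   SDs.
#' @param speed_breakpoint,speed_effect,speed_ramp_width Bat-speed hinge:
#'   the log-response rises linearly by `speed_effect` over
#'   `speed_ramp_width` m/s starting at `speed_breakpoint`, then saturates.
#' @param mass_optimum,mass_curvature,mass_penalty_cap Bat-mass penalty:
#'   `min(mass_curvature * (mass - mass_optimum)^2, mass_penalty_cap)` is
#'   subtracted from the log-response, so the response peaks at
#'   `mass_optimum` and the penalty saturates away from it.
#' @param rotacc_breakpoint,rotacc_effect,rotacc_ramp_width Rotational-
#'   acceleration hinge, analogous to the bat-speed hinge.
#' @param attack_effect,onplane_effect Small linear log-response slopes for
#'   attack angle and on-plane efficiency (per unit above their means).
#' @param intercept Log-response intercept.
#' @param dispersion Negative-binomial size parameter (> 0); smaller means
#'   more overdispersion.
#' @param mu_cap Upper bound on the expected count (seasons are finite).
#' @param count_cap Upper bound on drawn counts.
#' @param seed Integer seed making the cohort fully reproducible.
#'
#' @return A list of class `swing_cohort_config`.
#' @export
swing_cohort_config <- function(
    n_players_train = 31,
    n_players_test = 10,
    swings_per_player = 10,
    train_season = 2023,
    test_season = 2024,
    feature_means = c(bat_speed = 31.0, bat_mass = 0.88, attack_angle = 10,
                      on_plane_efficiency = 82, rotational_acceleration = 140),
    feature_sds = c(bat_speed = 2.5, bat_mass = 0.02, attack_angle = 4,
                    on_plane_efficiency = 6, rotational_acceleration = 20),
    speed_mass_cor = -0.3,
    swing_noise_sds = c(bat_speed = 1.0, bat_mass = 0.002, attack_angle = 2,
                        on_plane_efficiency = 3,
                        rotational_acceleration = 5),
    speed_breakpoint = 33.3,
    speed_effect = 2.2,
    speed_ramp_width = 0.6,
    mass_optimum = 0.91,
    mass_curvature = 2500,
    mass_penalty_cap = 1.2,
    rotacc_breakpoint = 157,
    rotacc_effect = 1.4,
    rotacc_ramp_width = 2,
    attack_effect = 0.01,
    onplane_effect = 0.005,
    intercept = 0.88,
    dispersion = 2,
    mu_cap = 40,
    count_cap = 55,
    seed = 1) {
  feats <- swing_features()
  feature_means <- feature_means[feats]
  feature_sds <- feature_sds[feats]
  swing_noise_sds <- swing_noise_sds[feats]
  if (anyNA(feature_means) || anyNA(feature_sds) || anyNA(swing_noise_sds)) {
    stop("`feature_means`, `feature_sds` and `swing_noise_sds` must be ",
         "named for all of: ", paste(feats, collapse = ", "), call. = FALSE)
  }
  if (any(feature_sds < 0) || any(swing_noise_sds < 0)) {
    stop("feature and swing-noise SDs must be >= 0", call. = FALSE)
  }
  if (dispersion <= 0) stop("`dispersion` must be > 0", call. = FALSE)
  if (abs(speed_mass_cor) >= 1) {
    stop("`speed_mass_cor` must lie in (-1, 1)", call. = FALSE)
  }
  if (n_players_train < 0 || n_players_test < 0 || swings_per_player < 1) {
    stop("invalid cohort sizes", call. = FALSE)
  }
  structure(
    as.list(environment()),
    class = "swing_cohort_config"
  )
}

# Saturating unit ramp: 0 below 0, linear to 1, then flat.
ramp01 <- function(z) pmin(pmax(z, 0), 1)

# Expected home runs for latent feature values (data frame with the five
# feature columns at player level).
latent_expected_hr <- function(lat, cfg) {
  eta <- cfg$intercept +
    cfg$speed_effect *
      ramp01((lat$bat_speed - cfg$speed_breakpoint) / cfg$speed_ramp_width) -
    pmin(cfg$mass_curvature * (lat$bat_mass - cfg$mass_optimum)^2,
         cfg$mass_penalty_cap) +
    cfg$rotacc_effect *
      ramp01((lat$rotational_acceleration - cfg$rotacc_breakpoint) /
               cfg$rotacc_ramp_width) +
    cfg$attack_effect * (lat$attack_angle - cfg$feature_means[["attack_angle"]]) +
    cfg$onplane_effect *
      (lat$on_plane_efficiency - cfg$feature_means[["on_plane_efficiency"]])
  pmin(exp(eta), cfg$mu_cap)
}

# Draw one season's players using the current RNG state.
generate_players <- function(n, season, id_start, cfg) {
  if (n == 0) return(NULL)
  mu <- cfg$feature_means
  s <- cfg$feature_sds
  rho <- cfg$speed_mass_cor
  z1 <- rnorm(n)
  z2 <- rnorm(n)
  lat <- tibble::tibble(
    bat_speed = mu[["bat_speed"]] + s[["bat_speed"]] * z1,
    bat_mass = mu[["bat_mass"]] +
      s[["bat_mass"]] * (rho * z1 + sqrt(1 - rho^2) * z2),
    attack_angle = mu[["attack_angle"]] + s[["attack_angle"]] * rnorm(n),
    on_plane_efficiency = pmin(100, pmax(0,
      mu[["on_plane_efficiency"]] + s[["on_plane_efficiency"]] * rnorm(n))),
    rotational_acceleration = mu[["rotational_acceleration"]] +
      s[["rotational_acceleration"]] * rnorm(n)
  )
  mu_hr <- latent_expected_hr(lat, cfg)
  hr <- pmin(rnbinom(n, mu = mu_hr, size = cfg$dispersion), cfg$count_cap)

  k <- cfg$swings_per_player
  idx <- rep(seq_len(n), each = k)
  m <- n * k
  ns <- cfg$swing_noise_sds
  player_id <- sprintf("P%03d", id_start + seq_len(n) - 1L)
  tibble::tibble(
    player_id = player_id[idx],
    season = as.integer(season),
    swing = rep(seq_len(k), times = n),
    swing_id = sprintf("%s-%d-%02d", player_id[idx], as.integer(season),
                       rep(seq_len(k), times = n)),
    bat_speed = lat$bat_speed[idx] + ns[["bat_speed"]] * rnorm(m),
    bat_mass = lat$bat_mass[idx] + ns[["bat_mass"]] * rnorm(m),
    attack_angle = lat$attack_angle[idx] + ns[["attack_angle"]] * rnorm(m),
    on_plane_efficiency = pmin(100, pmax(0,
      lat$on_plane_efficiency[idx] +
        ns[["on_plane_efficiency"]] * rnorm(m))),
    rotational_acceleration = lat$rotational_acceleration[idx] +
      ns[["rotational_acceleration"]] * rnorm(m),
    home_runs = hr[idx]
  )
}

#' Generate a synthetic swing cohort
#'
#' Draws the training cohort (season `train_season`) and the test cohort
#' (season `test_season`, disjoint players) in one reproducible stream.
#'
#' @param cfg A [swing_cohort_config()].
#' @param seed Overrides `cfg$seed` when given.
#'
#' @return A tibble with one row per swing: `player_id`, `season`, `swing`,
#'   `swing_id`, the five [swing_features()], and `home_runs` (the player's
#'   season total, repeated on each of their swings).
#' @export
generate_cohort <- function(cfg = swing_cohort_config(), seed = NULL) {
  stopifnot(inherits(cfg, "swing_cohort_config"))
  set.seed(if (is.null(seed)) cfg$seed else seed)
  dplyr::bind_rows(
    generate_players(cfg$n_players_train, cfg$train_season, 1L, cfg),
    generate_players(cfg$n_players_test, cfg$test_season,
                     101L + cfg$n_players_train, cfg)
  )
}

#' Inject bat-speed outliers into a cohort
#'
#' Perturbs `n_outliers` swings (at most one per player-season) upward by
#' `magnitude` m/s so that, after the perturbation shifts the player's mean,
#' exactly those swings violate the per-player outlier rule
#' (|speed - player mean| > `threshold`) and no clean swing does. Players
#' for whom this cannot be guaranteed are skipped. Swings that already
#' violate the rule by chance are first pulled back toward their player
#' mean, so that the marked set is exactly the set the downstream filter
#' removes.
#'
#' @param cohort A swing cohort tibble, as from [generate_cohort()].
#' @param n_outliers Number of swings to perturb.
#' @param magnitude Speed perturbation, m/s. Should comfortably exceed
#'   `threshold`; default 10.
#' @param seed Seed for choosing players and swings.
#' @param threshold Outlier rule threshold, m/s. Default 2.78.
#'
#' @return A list with `cohort` (the perturbed tibble) and `marked`
#'   (character vector of the perturbed `swing_id`s).
#' @export
inject_speed_outliers <- function(cohort, n_outliers, magnitude = 10,
                                  seed = 1, threshold = 2.78) {
  stopifnot(n_outliers >= 0)
  if (n_outliers == 0) return(list(cohort = cohort, marked = character()))
  if (n_outliers > nrow(cohort)) {
    stop("`n_outliers` exceeds the number of swings", call. = FALSE)
  }
  groups <- cohort |>
    dplyr::distinct(.data$player_id, .data$season)
  if (n_outliers > nrow(groups)) {
    stop("`n_outliers` exceeds the number of player-seasons ",
         "(one injected outlier per player-season)", call. = FALSE)
  }
  set.seed(seed)
  order_idx <- sample(nrow(groups))
  marked <- character()
  out <- temper_natural_outliers(cohort, threshold)
  for (g in order_idx) {
    rows <- which(out$player_id == groups$player_id[g] &
                    out$season == groups$season[g])
    k <- length(rows)
    target <- rows[sample.int(k, 1)]
    speeds <- out$bat_speed[rows]
    new_speeds <- speeds
    new_speeds[rows == target] <- new_speeds[rows == target] + magnitude
    dev <- abs(new_speeds - mean(new_speeds))
    viol <- rows[dev > threshold]
    if (identical(viol, target)) {
      out$bat_speed[target] <- out$bat_speed[target] + magnitude
      marked <- c(marked, out$swing_id[target])
      if (length(marked) == n_outliers) {
        return(list(cohort = out, marked = marked))
      }
    }
  }
  stop("could not place the requested number of unambiguous outliers; ",
       "increase `magnitude` or reduce `n_outliers`", call. = FALSE)
}

# Shrink chance violations of the outlier rule toward the player mean so a
# cohort starts with none. Clamping deviations moves the mean slightly, so
# iterate; a handful of passes always suffices for mild noise.
temper_natural_outliers <- function(cohort, threshold) {
  for (pass in 1:10) {
    flagged <- cohort |>
      dplyr::group_by(.data$player_id, .data$season) |>
      dplyr::mutate(.mean = mean(.data$bat_speed)) |>
      dplyr::ungroup()
    dev <- flagged$bat_speed - flagged$.mean
    bad <- abs(dev) > threshold
    if (!any(bad)) return(cohort)
    cohort$bat_speed[bad] <- flagged$.mean[bad] +
      sign(dev[bad]) * 0.9 * threshold
  }
  stop("could not remove pre-existing outliers from the cohort",
       call. = FALSE)
}
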