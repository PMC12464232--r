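# swinghr

Explainable prediction of annual home-run totals from bat-mounted IMU
swing metrics, with a ballistic cross-check of the learned bat-speed
threshold.

Batting-practice sensors report five per-swing metrics — bat speed, bat
mass, attack angle, on-plane efficiency, and rotational acceleration —
and the interesting question for players and coaches is how these relate
to season home-run totals. `swinghr` is aimed at sports-biomechanics
analysts who want that full analysis chain as tested, seeded, inspectable
R code:

* **Flight simulation.** The batted ball obeys
  `m g + L + D + Y = m ẍ`, with Magnus lift
  `L = ½ ρ C_L A |ẋ|² (ω × ẋ)/|ω × ẋ|`, drag `D = −½ ρ C_D A |ẋ| ẋ`, and a
  side force along `L × D`, integrated by fixed-step RK4 with the
  aerodynamic coefficients evaluated from the spin parameter `r|ω|/|ẋ|`.
  `min_speed_for_distance()` scans a speed grid for the minimum
  batted-ball speed that carries a target distance, and
  `blast_speed_for_home_run()` converts it to sensor units via the
  regression `batted = 0.865·head + 6.425` and the 4.2 m/s sensor offset.
* **Synthetic cohorts.** `generate_cohort()` draws train/test cohorts
  (31 + 10 players × 10 swings by default) with overdispersed
  negative-binomial home-run counts (mean ≈ 3.0, SD ≈ 6.1) and planted
  nonlinear effects: a bat-speed breakpoint at 33.3 m/s, a bat-mass
  optimum at 0.91 kg, a rotational-acceleration breakpoint at 157 m/s².
* **Models.** Random forest (10 trees, depth 5), gradient boosting
  (50 trees, depth 5), standardized linear regression, and a baseline
  mean model, evaluated by repeatedly subsampling 3 swings per test
  player (10 repeats, mean ± SD of R² and RMSE).
* **Explanations from first principles.** Partial dependence and ICE
  curves, exact Shapley attributions by enumeration of all 2⁵ feature
  coalitions (local accuracy, symmetry and dummy axioms hold to 1e-6 and
  are tested), permutation importance, and breakpoint/optimum read-off
  rules for PD curves.

Everything is data-frame-in / tibble-out, with `tidy()`, `glance()` and
`autoplot()` methods for the result objects.

## Worked example

Physics first — the published reference flight (launch angle 33.2°, spin
225 rad/s, spin axis 13.3°/15.4°, height 1.0 m, ball mass 0.14 kg):

```r
simulate_flight(reference_launch(37.5),
                constant_coefficients(0.23, 0.40, -0.05))
#> <swing_flight> speed 37.50 m/s, angle 33.2 deg: carry 91.91 m in 4.62 s

blast_speed_for_home_run(100,
  schedule = constant_coefficients(0.21, 0.40, -0.06))
#> # A tibble: 1 × 4
#>   batted_speed head_speed offset blast_speed
#>          <dbl>      <dbl>  <dbl>       <dbl>
#> 1         40.6       39.5    4.2        35.3
```

So on the 0.28 m/s search grid starting at 37.5 m/s, the first batted-ball
speed carrying ≥ 100 m is 40.6 m/s, which corresponds to a bat-head speed
of 39.5 m/s and a sensor-reported bat speed of about 35.3 m/s — the
physics-based counterpart of a bat-speed threshold learned from data.

The learning side, at a cohort size where the planted structure is
recoverable (500 players; at the default study scale of 31 training
players every metric is very noisy):

```r
library(dplyr)
cfg <- swing_cohort_config(n_players_train = 500, n_players_test = 0,
                           seed = 1)
tab <- build_feature_table(filter_outliers(generate_cohort(cfg))$swings)
m <- train_model(tab, model_spec("random_forest", n_trees = 400,
                                 max_depth = 0, splitrule = "extratrees",
                                 min_node_size = 20, seed = 1))
pd <- partial_dependence(m, tab, "bat_speed", n_grid = 15, trim = 0.02,
                         background_size = 2000, seed = 1001)
pd_breakpoint(pd)
#> [1] 33.41764

set.seed(2001); inst <- tab[sample.int(nrow(tab), 40), ]
mean_abs_shap(shapley_exact(m, tab, inst, background_size = 40,
                            seed = 3001))
#> # A tibble: 5 × 2
#>   feature                 importance
#>   <chr>                        <dbl>
#> 1 bat_speed                    1.58
#> 2 rotational_acceleration      1.25
#> 3 bat_mass                     1.16
#> 4 on_plane_efficiency          0.247
#> 5 attack_angle                 0.210
```

The PD read-off recovers the planted 33.3 m/s breakpoint to within one
grid cell, and bat speed ranks first in mean-|SHAP| importance. The same
call with `"bat_mass"` returns an optimum near 0.91 kg, and with
`"rotational_acceleration"` a breakpoint near 157 m/s².

`run_pipeline(run_config(seed = 1), "out/")` executes the whole chain —
generate, filter, train all four models, evaluate, explain, ballistic
validation — and writes CSV/JSON results plus a manifest of MD5 hashes;
identical configurations give identical hashes.

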