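test_that("partial dependence of simple predictors has the expected shape", {
  tt <- small_tables()
  grid <- seq(25, 40, length.out = 10)
  # a model that only uses bat speed: PD is the line 2g, ICE rows identical
  pd <- partial_dependence(f_linear_speed, tt$train, "bat_speed", grid = grid)
  expect_equal(pd$pd, 2 * grid)
  expect_equal(max(abs(apply(pd$ice, 2, sd))), 0)
  # a constant model: flat PD and flat ICE
  pdc <- partial_dependence(f_constant, tt$train, "bat_speed", grid = grid)
  expect_equal(pdc$pd, rep(7, 10))
  expect_error(pd_breakpoint(pdc), "flat")
  # PD is the column mean of the ICE matrix
  expect_equal(pd$pd, colMeans(pd$ice), tolerance = 1e-12)
  expect_error(partial_dependence(f_constant, tt$train, "no_such_feature"),
               "unknown feature")
})

test_that("partial dependence equals the naive nested-loop oracle on the forest", {
  tt <- small_tables()
  m <- train_model(tt$train, model_spec("random_forest", seed = 5))
  bg <- tt$train[1:40, ]
  grid <- seq(min(bg$bat_speed), max(bg$bat_speed), length.out = 7)
  pd <- partial_dependence(m, bg, "bat_speed", grid = grid)
  # brute force: explicit double loop over (grid x rows)
  oracle <- matrix(NA_real_, nrow(bg), length(grid))
  for (j in seq_along(grid)) {
    for (i in seq_len(nrow(bg))) {
      row <- bg[i, ]
      row$bat_speed <- grid[j]
      oracle[i, j] <- predict(m, row)
    }
  }
  expect_equal(pd$ice, oracle, tolerance = 1e-12)
  expect_equal(pd$pd, colMeans(oracle), tolerance = 1e-12)
})

test_that("PD read-off rules: maximum forward difference and argmax with ties to the left", {
  fake <- structure(list(feature = "x", grid = 1:5, pd = c(0, 0, 0, 5, 5),
                         ice = matrix(c(0, 0, 0, 5, 5), 1)), class = "hr_pd")
  expect_equal(pd_breakpoint(fake), 3)
  expect_equal(pd_argmax(fake), 4)  # ties at 4 and 5 break to the smaller
  # monotone linear PD: constant differences, tie broken to the first cell
  lin <- structure(list(feature = "x", grid = 1:5, pd = as.numeric(1:5),
                        ice = matrix(1:5, 1)), class = "hr_pd")
  expect_equal(pd_breakpoint(lin), 1)
  expect_error(pd_breakpoint(structure(list(grid = 1:2, pd = c(0, 1)),
                                       class = "hr_pd")), "at least 3")
})

test_that("exact Shapley attributions satisfy the axioms", {
  tt <- small_tables()
  bg <- tt$train[1:30, ]
  inst <- tt$train[31:40, ]

  # dummy: a model that ignores a feature gives it zero attribution
  sh <- shapley_exact(f_linear_speed, bg, inst)
  expect_equal(unname(sh$phi[, "bat_mass"]), rep(0, 10))
  expect_equal(unname(sh$phi[, "attack_angle"]), rep(0, 10))

  # additive model: phi_i = f_i(x_i) - mean_background f_i
  sha <- shapley_exact(f_additive, bg, inst)
  expect_equal(unname(sha$phi[, "bat_speed"]),
               2 * inst$bat_speed - mean(2 * bg$bat_speed), tolerance = 1e-9)
  expect_equal(unname(sha$phi[, "bat_mass"]),
               100 * inst$bat_mass - mean(100 * bg$bat_mass),
               tolerance = 1e-9)
  expect_equal(unname(sha$phi[, "attack_angle"]),
               -0.5 * inst$attack_angle - mean(-0.5 * bg$attack_angle),
               tolerance = 1e-9)

  # symmetry: two features used interchangeably get equal attributions
  inst_sym <- inst
  inst_sym$bat_mass <- inst_sym$bat_speed
  bg_sym <- bg
  bg_sym$bat_mass <- bg_sym$bat_speed
  f_sym <- function(d) d$bat_speed + d$bat_mass
  shs <- shapley_exact(f_sym, bg_sym, inst_sym)
  expect_equal(shs$phi[, "bat_speed"], shs$phi[, "bat_mass"],
               tolerance = 1e-9)

  # local accuracy on the forest
  m <- train_model(tt$train, model_spec("random_forest", seed = 5))
  shm <- shapley_exact(m, tt$train, inst, background_size = 50, seed = 2)
  expect_lt(max(abs(shm$base_value + rowSums(shm$phi) - shm$prediction)),
            1e-6)
  expect_equal(shm$prediction, predict(m, inst), tolerance = 1e-9)
  # efficiency over instances
  expect_lt(abs(mean(shm$prediction) - shm$base_value -
                  sum(colMeans(shm$phi))), 1e-6)

  expect_error(shapley_exact(m, bg[0, ], inst), "empty")
})

test_that("mean-|SHAP| importance and beeswarm export are faithful to the attributions", {
  tt <- small_tables()
  bg <- tt$train[1:20, ]
  sh <- shapley_exact(f_additive, bg, tt$train[21:25, ])
  imp <- mean_abs_shap(sh)
  expect_equal(nrow(imp), 5)
  expect_true(all(diff(imp$importance) <= 0))
  # single instance: importance is |phi| itself
  sh1 <- shapley_exact(f_additive, bg, tt$train[26, ])
  imp1 <- mean_abs_shap(sh1)
  expect_equal(imp1$importance,
               unname(abs(sh1$phi[1, ]))[order(-abs(sh1$phi[1, ]))])
  # sign flips leave importances unchanged
  shf <- sh
  shf$phi <- -shf$phi
  expect_equal(mean_abs_shap(shf)$importance, imp$importance)

  bw <- beeswarm_data(sh)
  expect_equal(nrow(bw), 5 * 5)
  expect_equal(bw$shap_value[bw$feature == "bat_speed"],
               unname(sh$phi[, "bat_speed"]))
  # round-trips through CSV losslessly at full precision
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp), add = TRUE)
  write.csv(bw, tmp, row.names = FALSE)
  back <- utils::read.csv(tmp)
  expect_equal(back$shap_value, bw$shap_value, tolerance = 1e-12)
})

test_that("permutation importance isolates the features a model uses", {
  tt <- small_tables()
  dat <- tt$train
  pi_ <- permutation_importance(f_linear_speed, dat,
                                target = "home_runs", n_repeats = 5,
                                seed = 4)
  # f(x) = 2 * bat_speed: bat speed dominates, ignored features do nothing
  expect_equal(pi_$feature[1], "bat_speed")
  ignored <- dplyr::filter(pi_, feature != "bat_speed")
  expect_equal(ignored$mean_drop, rep(0, 4), tolerance = 1e-12)
  # fixed seed: bitwise repeatable
  pi2 <- permutation_importance(f_linear_speed, dat,
                                target = "home_runs", n_repeats = 5,
                                seed = 4)
  expect_identical(as.data.frame(pi_), as.data.frame(pi2))
  # rmse metric also reports degradation as positive
  pir <- permutation_importance(f_linear_speed, dat, metric = "rmse",
                                n_repeats = 3, seed = 4)
  expect_gt(dplyr::filter(pir, feature == "bat_speed")$mean_drop, 0)
})
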