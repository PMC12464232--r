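# The four regression models (random forest, gradient boosting, multiple
# linear regression, baseline mean) and the repeated player-subsampling
# evaluation protocol.

#' Model specification
#'
#' Final hyperparameters: the random forest uses 10 trees of maximum depth
#' 5; gradient boosting uses 50 trees of maximum depth 5; the linear model
#' standardizes its explanatory variables; the baseline predicts the
#' training-target mean for every input. Tree ensembles use all five
#' features as split candidates at each node and a shrinkage of 0.1 for
#' boosting.
#'
#' @param kind One of `"random_forest"`, `"gradient_boosting"`, `"linear"`,
#'   `"baseline_mean"`.
#' @param n_trees Number of trees; defaults depend on `kind`.
#' @param max_depth Maximum tree depth; default 5 for tree ensembles.
#' @param standardize Standardize features (linear model only). Default TRUE.
#' @param seed Seed for tree-ensemble randomness.
#' @param splitrule Split rule for the random forest: `"variance"` (classic
#'   CART splits, the default) or `"extratrees"` (randomized split points,
#'   which remove the end-cut split-point bias and give smoother partial
#'   dependence -- preferred when PD curves are read off quantitatively).
#' @param min_node_size Minimum node size for the random forest. Default 5;
#'   larger values smooth the fitted response.
#'
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(kind = c("random_forest", "gradient_boosting",
                                "linear", "baseline_mean"),
                       n_trees = NULL, max_depth = NULL,
                       standardize = TRUE, seed = 1,
                       splitrule = c("variance", "extratrees"),
                       min_node_size = 5) {
  kind <- match.arg(kind)
  splitrule <- match.arg(splitrule)
  if (is.null(n_trees)) {
    n_trees <- switch(kind, random_forest = 10, gradient_boosting = 50, 0)
  }
  if (is.null(max_depth)) {
    max_depth <- switch(kind, random_forest = 5, gradient_boosting = 5, 0)
  }
  structure(
    list(kind = kind, n_trees = n_trees, max_depth = max_depth,
         standardize = standardize, seed = seed,
         splitrule = splitrule, min_node_size = min_node_size),
    class = "model_spec"
  )
}

#' Train a home-run regression model
#'
#' Regresses the per-swing home-run target on the five swing features.
#'
#' @param table A feature table from [build_feature_table()] (or
#'   [aggregate_per_player()]).
#' @param spec A [model_spec()].
#'
#' @return An object of class `hr_model` with a [predict()][predict.hr_model]
#'   method.
#' @export
train_model <- function(table, spec = model_spec()) {
  stopifnot(inherits(spec, "model_spec"))
  if (is.null(table) || nrow(table) == 0) {
    stop("`table` is empty", call. = FALSE)
  }
  feats <- swing_features()
  x <- as.data.frame(table[, feats, drop = FALSE])
  y <- table$home_runs
  if (spec$kind != "baseline_mean" && length(unique(y)) < 2) {
    # degenerate but allowed: tree models fit a constant
    if (spec$kind == "linear") {
      stop("linear model needs >= 2 distinct target values", call. = FALSE)
    }
  }
  fit <- switch(
    spec$kind,
    baseline_mean = list(mean = mean(y)),
    linear = {
      ctr <- vapply(x, mean, numeric(1))
      scl <- vapply(x, sd, numeric(1))
      scl[scl == 0] <- 1
      xs <- as.data.frame(scale(x, center = ctr, scale = scl))
      lmfit <- lm(y ~ ., data = cbind(xs, y = y))
      list(lm = lmfit, center = ctr, scale = scl)
    },
    random_forest = {
      ranger::ranger(
        x = x, y = y,
        num.trees = spec$n_trees, max.depth = spec$max_depth,
        mtry = length(feats), min.node.size = spec$min_node_size,
        splitrule = spec$splitrule,
        seed = spec$seed, num.threads = 1
      )
    },
    gradient_boosting = {
      dtrain <- xgboost::xgb.DMatrix(data = as.matrix(x), label = y)
      xgboost::xgb.train(
        params = list(objective = "reg:squarederror", max_depth = spec$max_depth,
                      eta = 0.1, nthread = 1, seed = spec$seed),
        data = dtrain, nrounds = spec$n_trees, verbose = 0
      )
    }
  )
  structure(
    list(spec = spec, fit = fit, features = feats,
         train_mean = mean(y), n_obs = nrow(table)),
    class = "hr_model"
  )
}

#' Predict annual home runs for swing feature rows
#'
#' @param object An `hr_model` from [train_model()].
#' @param newdata A data frame containing the five [swing_features()]
#'   columns (extra columns are ignored).
#' @param ... Unused.
#' @return Numeric vector of predicted home-run counts.
#' @export
predict.hr_model <- function(object, newdata, ...) {
  x <- as.data.frame(newdata[, object$features, drop = FALSE])
  switch(
    object$spec$kind,
    baseline_mean = rep(object$fit$mean, nrow(x)),
    linear = {
      xs <- as.data.frame(scale(x, center = object$fit$center,
                                scale = object$fit$scale))
      unname(predict(object$fit$lm, newdata = xs))
    },
    random_forest = predict(object$fit, data = x,
                            num.threads = 1)$predictions,
    gradient_boosting = predict(object$fit, as.matrix(x))
  )
}

#' @export
print.hr_model <- function(x, ...) {
  cat(sprintf("<hr_model> %s trained on %d swings\n",
              x$spec$kind, x$n_obs))
  invisible(x)
}

#' @method glance hr_model
#' @export
glance.hr_model <- function(x, ...) {
  tibble::tibble(kind = x$spec$kind, n_obs = x$n_obs,
                 n_trees = x$spec$n_trees, max_depth = x$spec$max_depth,
                 train_mean = x$train_mean)
}

#' Coefficient of determination
#'
#' `1 - SSE/SST`, with SST about the mean of `y`.
#'
#' @param y Observed values (length >= 2, non-zero variance).
#' @param y_hat Predicted values (same length).
#' @return R-squared (can be negative for models worse than the mean).
#' @export
r_squared <- function(y, y_hat) {
  stopifnot(length(y) == length(y_hat), length(y) >= 2)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("`y` has zero variance; R^2 undefined", call. = FALSE)
  1 - sum((y - y_hat)^2) / sst
}

#' Root mean squared error
#'
#' @inheritParams r_squared
#' @return RMSE (>= 0).
#' @export
rmse <- function(y, y_hat) {
  stopifnot(length(y) == length(y_hat), length(y) >= 1)
  sqrt(mean((y - y_hat)^2))
}

#' Evaluate a model by repeated per-player swing subsampling
#'
#' For each of `n_repeats` repetitions, `n_per_player` swings are drawn
#' without replacement from every test player (players visited in sorted
#' `player_id`/`season` order), and R-squared and RMSE are computed on the
#' pooled per-swing predictions. The mean and SD over repetitions summarize
#' test performance.
#'
#' @param model An `hr_model` (or any function mapping a feature data frame
#'   to predictions).
#' @param test_table Feature table of the test cohort.
#' @param n_per_player Swings sampled per player per repetition. Default 3.
#' @param n_repeats Number of repetitions. Default 10.
#' @param seed Seed for the subsampling.
#'
#' @return An object of class `hr_eval`: list with `repeats` (tibble of
#'   per-repetition `r2` and `rmse`) and the protocol settings. Use
#'   [tidy()][generics::tidy] for per-repeat values and
#'   [glance()][generics::glance] for the mean/SD summary.
#' @export
evaluate_model <- function(model, test_table, n_per_player = 3,
                           n_repeats = 10, seed = 1) {
  pred_fn <- as_predictor(model)
  tab <- dplyr::arrange(test_table, .data$player_id, .data$season)
  groups <- split(seq_len(nrow(tab)),
                  paste(tab$player_id, tab$season, sep = "\r"))
  # preserve sorted player order
  groups <- groups[order(names(groups))]
  too_few <- vapply(groups, length, integer(1)) < n_per_player
  if (any(too_few)) {
    stop("every test player needs at least `n_per_player` swings",
         call. = FALSE)
  }
  set.seed(seed)
  reps <- purrr::map_dfr(seq_len(n_repeats), function(r) {
    idx <- unlist(lapply(groups, function(g) {
      g[sample.int(length(g), n_per_player)]
    }), use.names = FALSE)
    sub <- tab[idx, , drop = FALSE]
    p <- pred_fn(sub)
    tibble::tibble(repeat_id = r,
                   r2 = r_squared(sub$home_runs, p),
                   rmse = rmse(sub$home_runs, p))
  })
  structure(
    list(repeats = reps, n_per_player = n_per_player,
         n_repeats = n_repeats, seed = seed),
    class = "hr_eval"
  )
}

#' @method tidy hr_eval
#' @export
tidy.hr_eval <- function(x, ...) x$repeats

#' @method glance hr_eval
#' @export
glance.hr_eval <- function(x, ...) {
  tibble::tibble(
    r2_mean = mean(x$repeats$r2), r2_sd = sd(x$repeats$r2),
    rmse_mean = mean(x$repeats$rmse), rmse_sd = sd(x$repeats$rmse),
    n_repeats = x$n_repeats
  )
}

#' @export
print.hr_eval <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<hr_eval> %d repeats: R2 %.2f +/- %.2f, RMSE %.2f +/- %.2f\n",
    x$n_repeats, g$r2_mean, g$r2_sd, g$rmse_mean, g$rmse_sd
  ))
  invisible(x)
}

# Turn an hr_model or a plain function into a predictor closure.
as_predictor <- function(model) {
  if (inherits(model, "hr_model")) {
    function(d) predict(model, d)
  } else if (is.function(model)) {
    model
  } else {
    stop("`model` must be an hr_model or a function", call. = FALSE)
  }
}
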