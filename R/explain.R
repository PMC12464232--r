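# Model-agnostic interpretation, implemented from first principles:
# partial dependence / ICE curves, exact Shapley attributions by coalition
# enumeration with interventional background marginalization, permutation
# feature importance, and breakpoint / optimum read-off rules for PD curves.

#' Partial dependence and ICE curves
#'
#' For each grid value g, the chosen feature is replaced by g in every
#' background row and the model is re-predicted. The per-row curves are the
#' ICE curves; their pointwise mean is the partial dependence.
#'
#' @param model An `hr_model` or a function mapping a feature data frame to
#'   predictions.
#' @param data Data frame providing the background rows (feature columns
#'   plus optionally others, which are carried along untouched).
#' @param feature Name of the feature to sweep.
#' @param grid Numeric grid values. If `NULL`, `n_grid` equally spaced
#'   points between the `trim` and `1 - trim` quantiles of the observed
#'   feature (the default `trim = 0` spans min to max).
#' @param n_grid Number of grid points. Default 50.
#' @param trim Quantile trimmed off each end when building the default
#'   grid. Default 0.
#' @param background_size If non-`NULL`, the background is a seeded random
#'   subsample of `data` of this size.
#' @param seed Seed for the background subsample.
#'
#' @return An object of class `hr_pd`: list with `feature`, `grid`, `pd`
#'   (mean prediction per grid value), and `ice` (matrix, background row x
#'   grid value).
#' @export
partial_dependence <- function(model, data, feature, grid = NULL,
                               n_grid = 50, trim = 0,
                               background_size = NULL, seed = 1) {
  pred_fn <- as_predictor(model)
  if (!feature %in% names(data)) {
    stop(sprintf("unknown feature `%s`", feature), call. = FALSE)
  }
  if (!is.null(background_size) && background_size < nrow(data)) {
    set.seed(seed)
    data <- data[sample.int(nrow(data), background_size), , drop = FALSE]
  }
  if (is.null(grid)) {
    if (trim > 0) {
      qq <- quantile(data[[feature]], c(trim, 1 - trim), names = FALSE)
    } else {
      qq <- range(data[[feature]])
    }
    grid <- seq(qq[1], qq[2], length.out = n_grid)
  }
  if (length(grid) == 0) stop("`grid` is empty", call. = FALSE)
  n_bg <- nrow(data)
  big <- data[rep(seq_len(n_bg), times = length(grid)), , drop = FALSE]
  big[[feature]] <- rep(grid, each = n_bg)
  ice <- matrix(pred_fn(big), nrow = n_bg, ncol = length(grid))
  structure(
    list(feature = feature, grid = grid, pd = colMeans(ice), ice = ice),
    class = "hr_pd"
  )
}

#' @method tidy hr_pd
#' @export
tidy.hr_pd <- function(x, ...) {
  n_bg <- nrow(x$ice)
  tibble::tibble(
    feature = x$feature,
    instance = rep(seq_len(n_bg), times = length(x$grid)),
    grid = rep(x$grid, each = n_bg),
    prediction = as.vector(x$ice)
  )
}

#' @export
print.hr_pd <- function(x, ...) {
  cat(sprintf("<hr_pd> %s over %d grid points, %d ICE curves\n",
              x$feature, length(x$grid), nrow(x$ice)))
  invisible(x)
}

#' Breakpoint of a partial dependence curve
#'
#' The read-off rule for "the response rises sharply above ...": the left
#' edge of the grid cell with the largest forward difference of the PD
#' curve. Ties break to the smallest grid value. A flat curve has no
#' breakpoint and raises an error.
#'
#' @param pd An `hr_pd` from [partial_dependence()].
#' @return The breakpoint, in the feature's units.
#' @export
pd_breakpoint <- function(pd) {
  stopifnot(inherits(pd, "hr_pd"))
  if (length(pd$grid) < 3) stop("need at least 3 grid points", call. = FALSE)
  d <- diff(pd$pd)
  if (max(d) - min(d) < 1e-12 && max(abs(d)) < 1e-12) {
    stop("PD curve is flat; breakpoint undefined", call. = FALSE)
  }
  pd$grid[which.max(d)]
}

#' Argmax of a partial dependence curve
#'
#' The read-off rule for "the optimum value is ...": the grid value
#' maximizing the PD curve, ties broken to the smallest value.
#'
#' @inheritParams pd_breakpoint
#' @return The optimum, in the feature's units.
#' @export
pd_argmax <- function(pd) {
  stopifnot(inherits(pd, "hr_pd"))
  pd$grid[which.max(pd$pd)]
}

#' Exact Shapley attributions by coalition enumeration
#'
#' The value of a coalition S for an instance is the interventional
#' expectation: the mean prediction over background rows in which the
#' features in S take the instance's values and the rest keep the
#' background row's values. The Shapley attribution of feature i is the
#' usual weighted sum of `v(S + i) - v(S)` over all coalitions S not
#' containing i, with weight `|S|! (p - |S| - 1)! / p!`. All `2^p`
#' coalitions are enumerated, so attributions satisfy local accuracy,
#' symmetry and the dummy axiom exactly (up to floating point).
#'
#' @param model An `hr_model` or prediction function.
#' @param background Data frame of background rows defining the reference
#'   distribution; subsampled to `background_size` rows (seeded) when
#'   larger.
#' @param instances Data frame of instances to explain.
#' @param features Feature names; defaults to the model's features for an
#'   `hr_model`, else [swing_features()].
#' @param background_size Maximum background rows. Default 100.
#' @param seed Seed for the background subsample.
#'
#' @return An object of class `hr_shap`: list with `phi` (instance x
#'   feature attribution matrix), `base_value` (mean background
#'   prediction), `prediction` (per-instance model prediction) and
#'   `feature_values` (the instances' feature columns).
#' @export
shapley_exact <- function(model, background, instances,
                          features = NULL, background_size = 100, seed = 1) {
  pred_fn <- as_predictor(model)
  if (is.null(features)) {
    features <- if (inherits(model, "hr_model")) model$features
                else swing_features()
  }
  if (nrow(background) == 0) stop("`background` is empty", call. = FALSE)
  if (nrow(background) > background_size) {
    set.seed(seed)
    background <- background[sample.int(nrow(background), background_size), ,
                             drop = FALSE]
  }
  p <- length(features)
  if (p > 12) stop("exact enumeration is limited to <= 12 features",
                   call. = FALSE)
  n_bg <- nrow(background)
  n_inst <- nrow(instances)
  n_sets <- 2^p
  masks <- 0:(n_sets - 1L)
  # v[i, s]: coalition value of subset s for instance i
  v <- matrix(NA_real_, n_inst, n_sets)
  inst_rep <- rep(seq_len(n_inst), each = n_bg)
  base_frame <- background[rep(seq_len(n_bg), times = n_inst), , drop = FALSE]
  for (s in seq_len(n_sets)) {
    in_set <- which(bitwAnd(masks[s], bitwShiftL(1L, 0:(p - 1L))) != 0L)
    d <- base_frame
    for (j in in_set) {
      d[[features[j]]] <- instances[[features[j]]][inst_rep]
    }
    pr <- pred_fn(d)
    v[, s] <- rowsum(pr, inst_rep)[, 1] / n_bg
  }
  phi <- matrix(0, n_inst, p, dimnames = list(NULL, features))
  sizes <- vapply(masks, function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:(p - 1L))) != 0L),
                  integer(1))
  for (i in seq_len(p)) {
    bit <- bitwShiftL(1L, i - 1L)
    without <- which(bitwAnd(masks, bit) == 0L)
    for (s in without) {
      k <- sizes[s]
      w <- factorial(k) * factorial(p - k - 1) / factorial(p)
      s_with <- s + bit  # masks[s] + bit's position in 1-based column index
      phi[, i] <- phi[, i] + w * (v[, s_with] - v[, s])
    }
  }
  structure(
    list(phi = phi, base_value = v[1, 1], prediction = v[, n_sets],
         feature_values = tibble::as_tibble(
           instances[, features, drop = FALSE])),
    class = "hr_shap"
  )
}

#' @export
print.hr_shap <- function(x, ...) {
  cat(sprintf("<hr_shap> %d instances x %d features, base value %.3f\n",
              nrow(x$phi), ncol(x$phi), x$base_value))
  invisible(x)
}

#' Mean absolute Shapley importance
#'
#' The mean of |attribution| per feature over instances, sorted descending —
#' the usual global SHAP importance bar chart.
#'
#' @param shap An `hr_shap` from [shapley_exact()].
#' @return A tibble with `feature` and `importance`, sorted descending.
#' @export
mean_abs_shap <- function(shap) {
  stopifnot(inherits(shap, "hr_shap"), nrow(shap$phi) >= 1)
  tibble::tibble(
    feature = colnames(shap$phi),
    importance = unname(colMeans(abs(shap$phi)))
  ) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' Long-format SHAP data for beeswarm plots
#'
#' @param shap An `hr_shap`.
#' @return A tibble with `feature`, `instance`, `shap_value` and
#'   `feature_value` — one row per instance per feature.
#' @export
beeswarm_data <- function(shap) {
  stopifnot(inherits(shap, "hr_shap"))
  n_inst <- nrow(shap$phi)
  feats <- colnames(shap$phi)
  tibble::tibble(
    feature = rep(feats, each = n_inst),
    instance = rep(seq_len(n_inst), times = length(feats)),
    shap_value = as.vector(shap$phi),
    feature_value = unlist(lapply(feats, function(f) {
      shap$feature_values[[f]]
    }), use.names = FALSE)
  )
}

#' @method tidy hr_shap
#' @export
tidy.hr_shap <- function(x, ...) beeswarm_data(x)

#' Permutation feature importance
#'
#' Shuffles one feature column at a time (seeded) and reports the
#' degradation of the model's metric, repeated `n_repeats` times. With the
#' R-squared metric the degradation is `base - permuted`; with RMSE it is
#' `permuted - base`, so larger is always more important.
#'
#' @param model An `hr_model` or prediction function.
#' @param data Feature table with the target column.
#' @param target Target column name. Default `"home_runs"`.
#' @param metric `"r2"` or `"rmse"`.
#' @param n_repeats Shuffles per feature. Default 10.
#' @param seed Seed for the shuffles.
#' @param features Features to permute; defaults as in [shapley_exact()].
#'
#' @return A tibble of class `hr_perm` with `feature`, `mean_drop`,
#'   `sd_drop`, sorted by decreasing `mean_drop`; the unpermuted baseline
#'   metric, metric name, repeats and seed are attached as attributes.
#' @export
permutation_importance <- function(model, data, target = "home_runs",
                                   metric = c("r2", "rmse"),
                                   n_repeats = 10, seed = 1,
                                   features = NULL) {
  metric <- match.arg(metric)
  pred_fn <- as_predictor(model)
  if (is.null(features)) {
    features <- if (inherits(model, "hr_model")) model$features
                else swing_features()
  }
  stopifnot(n_repeats >= 1)
  y <- data[[target]]
  metric_fn <- if (metric == "r2") r_squared else rmse
  base <- metric_fn(y, pred_fn(data))
  set.seed(seed)
  drops <- matrix(NA_real_, n_repeats, length(features),
                  dimnames = list(NULL, features))
  for (r in seq_len(n_repeats)) {
    for (f in features) {
      d <- data
      d[[f]] <- d[[f]][sample.int(nrow(d))]
      m <- metric_fn(y, pred_fn(d))
      drops[r, f] <- if (metric == "r2") base - m else m - base
    }
  }
  out <- tibble::tibble(
    feature = features,
    mean_drop = unname(colMeans(drops)),
    sd_drop = unname(apply(drops, 2, sd))
  ) |>
    dplyr::arrange(dplyr::desc(.data$mean_drop))
  structure(out, class = c("hr_perm", class(out)),
            baseline = base, metric = metric,
            n_repeats = n_repeats, seed = seed)
}
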