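# ggplot2 displays for the explanation results.

#' @method autoplot hr_pd
#' @export
autoplot.hr_pd <- function(object, max_ice = 50, ...) {
  long <- tidy(object)
  if (length(unique(long$instance)) > max_ice) {
    keep <- sort(sample(unique(long$instance), max_ice))
    long <- dplyr::filter(long, .data$instance %in% keep)
  }
  pd_df <- tibble::tibble(grid = object$grid, pd = object$pd)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$grid, y = .data$prediction,
                                     group = .data$instance)) +
    ggplot2::geom_line(alpha = 0.2, colour = "steelblue") +
    ggplot2::geom_line(data = pd_df,
                       ggplot2::aes(x = .data$grid, y = .data$pd,
                                    group = NULL),
                       linewidth = 1.2, colour = "navy") +
    ggplot2::labs(x = object$feature, y = "predicted home runs / year",
                  title = "Partial dependence (thick) and ICE (thin)") +
    ggplot2::theme_minimal()
}

#' @method autoplot hr_shap
#' @export
autoplot.hr_shap <- function(object, ...) {
  dat <- beeswarm_data(object) |>
    dplyr::group_by(.data$feature) |>
    dplyr::mutate(scaled_value = if (diff(range(.data$feature_value)) > 0) {
      (.data$feature_value - min(.data$feature_value)) /
        diff(range(.data$feature_value))
    } else 0.5) |>
    dplyr::ungroup()
  order_df <- mean_abs_shap(object)
  dat$feature <- factor(dat$feature, levels = rev(order_df$feature))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$shap_value, y = .data$feature,
                                    colour = .data$scaled_value)) +
    ggplot2::geom_jitter(height = 0.2, width = 0, alpha = 0.7, size = 1) +
    ggplot2::scale_colour_gradient(low = "gold", high = "purple",
                                   name = "feature value\n(scaled)") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Shapley attribution (home runs / year)", y = NULL,
                  title = "SHAP beeswarm") +
    ggplot2::theme_minimal()
}

#' @method autoplot hr_perm
#' @export
autoplot.hr_perm <- function(object, ...) {
  dat <- tibble::as_tibble(object)
  dat$feature <- factor(dat$feature, levels = rev(dat$feature))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$mean_drop, y = .data$feature)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(xmin = .data$mean_drop - .data$sd_drop,
                   xmax = .data$mean_drop + .data$sd_drop),
      width = 0.3) +
    ggplot2::labs(
      x = sprintf("%s degradation when permuted", attr(object, "metric")),
      y = NULL, title = "Permutation feature importance") +
    ggplot2::theme_minimal()
}
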