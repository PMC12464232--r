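# Outlier exclusion and assembly of the swing-level feature table.

#' Per-player bat-speed outlier filter
#'
#' For each player-season, the mean bat speed over all of that player's
#' swings is computed once (no iterative re-computation), and swings whose
#' bat speed deviates from the mean by strictly more than `threshold` are
#' removed. A deviation of exactly `threshold` is kept.
#'
#' @param cohort A swing cohort tibble (see [generate_cohort()]); must have
#'   `player_id`, `season`, `swing_id`, `bat_speed`.
#' @param threshold Exclusion threshold, m/s. Default 2.78.
#'
#' @return A list with `swings` (the retained rows) and `removed` (character
#'   vector of excluded `swing_id`s).
#' @export
filter_outliers <- function(cohort, threshold = 2.78) {
  if (is.null(cohort) || nrow(cohort) == 0) {
    stop("`cohort` is empty", call. = FALSE)
  }
  flagged <- cohort |>
    dplyr::group_by(.data$player_id, .data$season) |>
    dplyr::mutate(.dev = abs(.data$bat_speed - mean(.data$bat_speed))) |>
    dplyr::ungroup()
  keep <- flagged$.dev <= threshold
  list(
    swings = cohort[keep, , drop = FALSE],
    removed = cohort$swing_id[!keep]
  )
}

#' Assemble the swing-level feature table
#'
#' One row per swing with the five features and the player's season home-run
#' total as the (unstandardized) target; all swings are treated as
#' independent observations. Errors if any feature value is missing, naming
#' the offending swing and column.
#'
#' @param cohort A (filtered) swing cohort tibble.
#' @return A tibble with `player_id`, `season`, `swing_id`, the five
#'   [swing_features()], and `home_runs`.
#' @export
build_feature_table <- function(cohort) {
  if (is.null(cohort) || nrow(cohort) == 0) {
    stop("`cohort` is empty", call. = FALSE)
  }
  needed <- c("player_id", "season", "swing_id", swing_features(), "home_runs")
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols)) {
    stop("`cohort` lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  tab <- dplyr::select(cohort, dplyr::all_of(needed))
  for (col in c(swing_features(), "home_runs")) {
    bad <- which(is.na(tab[[col]]))
    if (length(bad)) {
      stop(sprintf("missing `%s` for swing %s", col, tab$swing_id[bad[1]]),
           call. = FALSE)
    }
  }
  tab
}

#' Aggregate the feature table to one row per player-season
#'
#' Replaces each player-season's swings by their feature means (the
#' sensitivity mode in which per-player means rather than individual swings
#' are analysed). Aggregating an already aggregated table is a no-op.
#'
#' @param table A feature table from [build_feature_table()].
#' @return A tibble with one row per player-season; `swing_id` is replaced
#'   by a `<player>-<season>-mean` label and `n_swings` records how many
#'   swings were averaged.
#' @export
aggregate_per_player <- function(table) {
  feats <- swing_features()
  table |>
    dplyr::group_by(.data$player_id, .data$season) |>
    dplyr::summarise(
      swing_id = sprintf("%s-%d-mean", dplyr::first(.data$player_id),
                         dplyr::first(.data$season)),
      dplyr::across(dplyr::all_of(feats), mean),
      home_runs = dplyr::first(.data$home_runs),
      n_swings = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::select(dplyr::all_of(c("player_id", "season", "swing_id",
                                  feats, "home_runs", "n_swings")))
}
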