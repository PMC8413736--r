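ant_networks <- function() c("alerting", "orienting", "executive")

#' Donders-subtraction network difference scores
#'
#' Computes the three attentional-network effects per participant, in both
#' speed and accuracy, from condition summaries:
#' \itemize{
#'   \item alerting = no-cue − double-cue,
#'   \item orienting = central-cue − spatial-cue,
#'   \item executive = incongruent − congruent,
#' }
#' applied to the median correct RT (ms) and to the proportion of errors
#' (reported in percentage points). Positive alerting/orienting scores mean
#' the cue helped; a positive executive score is the conflict cost.
#'
#' @param summary A condition-summary tibble from [summarize_conditions()].
#' @return A tibble in long network form: `participant_id`, `group`,
#'   `network`, `rt_diff_ms`, `pe_diff` (percentage points). Scores are `NA`
#'   (with a warning) for participants missing a needed cell.
#' @export
network_differences <- function(summary) {
  stopifnot(all(c("margin", "cell", "median_rt_ms", "pe") %in% names(summary)))
  pairs <- tibble::tibble(
    network = factor(ant_networks(), levels = ant_networks()),
    margin = c("cue", "cue", "flanker"),
    hi = c("none", "central", "incongruent"),
    lo = c("double", "spatial", "congruent")
  )
  cells <- summary |>
    dplyr::filter(.data$margin != "overall") |>
    dplyr::select(
      "participant_id", "group", "margin", "cell", "median_rt_ms", "pe"
    )
  score_one <- function(network, margin_lab, hi, lo) {
    wide <- cells |>
      dplyr::filter(.data$margin == margin_lab, .data$cell %in% c(hi, lo)) |>
      tidyr::pivot_wider(
        id_cols = c("participant_id", "group"),
        names_from = "cell", values_from = c("median_rt_ms", "pe")
      )
    need <- paste0(rep(c("median_rt_ms_", "pe_"), each = 2), c(hi, lo))
    absent <- setdiff(need, names(wide))
    for (column in absent) wide[[column]] <- NA_real_
    tibble::tibble(
      participant_id = wide$participant_id,
      group = wide$group,
      network = network,
      rt_diff_ms = wide[[paste0("median_rt_ms_", hi)]] -
        wide[[paste0("median_rt_ms_", lo)]],
      pe_diff = 100 * (wide[[paste0("pe_", hi)]] - wide[[paste0("pe_", lo)]])
    )
  }
  out <- purrr::pmap(pairs, score_one) |> purrr::list_rbind()
  n_missing <- sum(is.na(out$rt_diff_ms) | is.na(out$pe_diff))
  if (n_missing > 0) {
    rlang::warn(paste0(
      n_missing, " network score(s) are NA because a needed condition cell ",
      "is missing."
    ))
  }
  dplyr::arrange(out, .data$participant_id, .data$network)
}

#' Fit the standardisation context for composite scores
#'
#' The speed–accuracy composite standardises the raw difference scores before
#' averaging them. With `scope = "pooled"` (default) the mean and SD are
#' computed on the *stacked* difference scores, pooled over all participants
#' and all three networks — separately for the RT measure and the PE measure
#' — so a network whose effects run large (executive) keeps positive
#' composites and a network with small effects (alerting, orienting) keeps
#' negative ones. With `scope = "per_network"` each network is standardised
#' over participants on its own, which forces every network's mean composite
#' to zero. Moments are always computed on the combined sample, never per
#' group.
#'
#' @param differences A difference-score tibble from [network_differences()].
#' @param scope `"pooled"` or `"per_network"`.
#' @return An object of class `ant_standardization`: a tibble with columns
#'   `network` (`"pooled"` rows apply to all), `rt_mean`, `rt_sd`, `pe_mean`,
#'   `pe_sd`, plus a `scope` attribute.
#' @export
fit_standardization <- function(differences, scope = c("pooled", "per_network")) {
  scope <- match.arg(scope)
  stopifnot(all(c("network", "rt_diff_ms", "pe_diff") %in% names(differences)))
  if (dplyr::n_distinct(differences$participant_id) < 2) {
    rlang::abort("standardisation needs at least 2 participants.")
  }
  grouped <- if (scope == "pooled") {
    dplyr::group_by(dplyr::mutate(differences, network = "pooled"),
      .data$network
    )
  } else {
    dplyr::group_by(
      dplyr::mutate(differences, network = as.character(.data$network)),
      .data$network
    )
  }
  out <- dplyr::summarise(
    grouped,
    rt_mean = mean(.data$rt_diff_ms, na.rm = TRUE),
    rt_sd = stats::sd(.data$rt_diff_ms, na.rm = TRUE),
    pe_mean = mean(.data$pe_diff, na.rm = TRUE),
    pe_sd = stats::sd(.data$pe_diff, na.rm = TRUE),
    .groups = "drop"
  )
  if (any(!is.finite(c(out$rt_sd, out$pe_sd))) ||
    any(c(out$rt_sd, out$pe_sd) <= 0)) {
    rlang::abort(
      "degenerate sample: a pooled SD of the difference scores is zero."
    )
  }
  structure(out, scope = scope, class = c("ant_standardization", class(out)))
}

#' Composite speed–accuracy network scores
#'
#' Standardises each difference score against the fitted context and averages
#' the two z-scores into one composite per network (a balanced-integration
#' style index). Higher composites mean worse performance in that network
#' (slower and/or more error-prone).
#'
#' @param differences A tibble from [network_differences()].
#' @param context An [fit_standardization()] object; defaults to a pooled fit
#'   on `differences` itself.
#' @return An `ant_scores` tibble: `participant_id`, `group`, `network`,
#'   `rt_diff_ms`, `pe_diff`, `z_rt`, `z_pe`, `composite`.
#' @export
composite_scores <- function(differences, context = NULL) {
  if (is.null(context)) {
    context <- fit_standardization(differences)
  }
  stopifnot(inherits(context, "ant_standardization"))
  ctx <- tibble::as_tibble(context)
  if (attr(context, "scope") == "pooled") {
    joined <- dplyr::cross_join(differences, dplyr::select(ctx, -"network"))
  } else {
    joined <- dplyr::left_join(
      dplyr::mutate(differences, .netkey = as.character(.data$network)),
      dplyr::rename(ctx, .netkey = "network"),
      by = ".netkey"
    ) |> dplyr::select(-".netkey")
  }
  out <- joined |>
    dplyr::mutate(
      z_rt = (.data$rt_diff_ms - .data$rt_mean) / .data$rt_sd,
      z_pe = (.data$pe_diff - .data$pe_mean) / .data$pe_sd,
      composite = (.data$z_rt + .data$z_pe) / 2
    ) |>
    dplyr::select(
      "participant_id", "group", "network", "rt_diff_ms", "pe_diff",
      "z_rt", "z_pe", "composite"
    )
  if (anyNA(out$composite)) {
    rlang::warn("some composites are NA because a component score is missing.")
  }
  structure(out, class = c("ant_scores", class(out)))
}

#' Score a trial table end to end
#'
#' Convenience wrapper: exclusion flagging, condition summaries, network
#' differences, and composite scores in one call.
#'
#' @param trials A trial tibble.
#' @param z_scope Standardisation scope, see [fit_standardization()].
#' @param exclusion_scope See [summarize_conditions()].
#' @param lower_ms,upper_ms Exclusion bounds in ms.
#' @return An `ant_scores` tibble (see [composite_scores()]).
#' @examples
#' trials <- simulate_cohort(cohort_config(n_per_group = 4, seed = 1))
#' score_networks(trials)
#' @export
score_networks <- function(trials, z_scope = c("pooled", "per_network"),
                           exclusion_scope = c("both", "rt_only"),
                           lower_ms = 200, upper_ms = 1700) {
  z_scope <- match.arg(z_scope)
  diffs <- trials |>
    flag_exclusions(lower_ms, upper_ms) |>
    summarize_conditions(exclusion_scope = match.arg(exclusion_scope)) |>
    network_differences()
  composite_scores(diffs, fit_standardization(diffs, z_scope))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot composite network scores by group
#'
#' Box plots of the composite score for each network, split by group —
#' the standard display of ANT group differences.
#'
#' @param object An `ant_scores` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ant_scores <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(
      x = .data$network, y = .data$composite, fill = .data$group
    )
  ) +
    ggplot2::geom_boxplot(outlier.alpha = 0.4) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey40") +
    ggplot2::labs(
      x = NULL, y = "composite score (higher = worse)",
      fill = NULL
    ) +
    ggplot2::theme_minimal()
}
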