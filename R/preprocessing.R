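#' Flag trials excluded from analysis
#'
#' Applies the standard ANT trial-exclusion rules: practice trials are
#' excluded wholesale; response timeouts (missing RT) are excluded; RTs
#' faster than `lower_ms` or slower than `upper_ms` are excluded as extreme
#' values. The inequalities are strict, so RTs exactly on a bound are
#' retained. Flagging is idempotent: any existing `excluded`/`excl_reason`
#' columns are recomputed from scratch.
#'
#' @param trials A trial tibble (see [read_trials()] for the dialect). A
#'   `block` of 0 or an `is_practice` column marks practice trials.
#' @param lower_ms,upper_ms Exclusion bounds in ms (defaults 200 and 1700;
#'   the upper bound equals the response window of [ant_timeline()]).
#' @return `trials` with two added columns: `excluded` (logical) and
#'   `excl_reason` (factor: `none`, `too_fast`, `too_slow`, `timeout`,
#'   `practice`).
#' @examples
#' tr <- tibble::tibble(
#'   participant_id = "P001", group = "gifted", block = 1, trial = 1:4,
#'   cue = "none", flanker = "neutral", accuracy = TRUE,
#'   rt_ms = c(150, 200, 1700, NA)
#' )
#' flag_exclusions(tr)$excl_reason
#' @export
flag_exclusions <- function(trials, lower_ms = 200, upper_ms = 1700) {
  stopifnot(lower_ms > 0, upper_ms > lower_ms)
  required <- c("participant_id", "cue", "flanker", "accuracy", "rt_ms")
  missing_cols <- setdiff(required, names(trials))
  if (length(missing_cols)) {
    rlang::abort(paste0(
      "trial table is missing required columns: ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  bad_rt <- which(!is.na(trials$rt_ms) & trials$rt_ms < 0)
  if (length(bad_rt)) {
    rlang::abort(paste0(
      "negative rt_ms values at rows: ",
      paste(utils::head(bad_rt, 10), collapse = ", ")
    ))
  }
  trials <- dplyr::select(trials, -dplyr::any_of(c("excluded", "excl_reason")))
  practice <- if ("is_practice" %in% names(trials)) {
    trials$is_practice
  } else if ("block" %in% names(trials)) {
    trials$block == 0
  } else {
    rep(FALSE, nrow(trials))
  }
  reason <- dplyr::case_when(
    practice ~ "practice",
    is.na(trials$rt_ms) ~ "timeout",
    trials$rt_ms < lower_ms ~ "too_fast",
    trials$rt_ms > upper_ms ~ "too_slow",
    .default = "none"
  )
  trials$excluded <- reason != "none"
  trials$excl_reason <- factor(
    reason,
    levels = c("none", "too_fast", "too_slow", "timeout", "practice")
  )
  trials
}

#' Summarise trial exclusions
#'
#' Per-participant and overall exclusion rates over test (non-practice)
#' trials. The overall rate counts every excluded test trial (too fast, too
#' slow, or timeout).
#'
#' @param trials A flagged trial tibble (see [flag_exclusions()]).
#' @return A list with `overall` (a one-row tibble: `n_test`, `n_excluded`,
#'   `pct_excluded`, and counts per reason) and `by_participant` (a tibble
#'   with the same columns per participant).
#' @export
exclusion_report <- function(trials) {
  if (!"excl_reason" %in% names(trials)) {
    trials <- flag_exclusions(trials)
  }
  test <- dplyr::filter(trials, .data$excl_reason != "practice")
  tally <- function(d) {
    tibble::tibble(
      n_test = nrow(d),
      n_excluded = sum(d$excluded),
      pct_excluded = 100 * sum(d$excluded) / nrow(d),
      n_too_fast = sum(d$excl_reason == "too_fast"),
      n_too_slow = sum(d$excl_reason == "too_slow"),
      n_timeout = sum(d$excl_reason == "timeout")
    )
  }
  by_part <- test |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_modify(~ tally(.x)) |>
    dplyr::ungroup()
  list(overall = tally(test), by_participant = by_part)
}

#' Per-participant condition summaries
#'
#' Aggregates retained test trials into the per-condition summaries the
#' network scores are built from: for each participant, the median RT over
#' retained *correct* trials and the proportion of errors (PE) over retained
#' trials, computed on each cue margin (collapsing flanker), each flanker
#' margin (collapsing cue), and overall.
#'
#' With `exclusion_scope = "both"` (default) extreme-RT trials are removed
#' from both the RT and the PE computations; with `"rt_only"` they are
#' removed from RT medians only, so PE is computed over all non-practice
#' trials (timeouts always count as errors).
#'
#' @param trials A trial tibble; exclusion flags are added if absent.
#' @param exclusion_scope Either `"both"` or `"rt_only"`.
#' @param lower_ms,upper_ms Exclusion bounds, used only when flags are absent.
#' @return A tibble with columns `participant_id`, `group`, `margin`
#'   (`"cue"`, `"flanker"` or `"overall"`), `cell` (condition label or
#'   `"overall"`), `n_retained`, `n_correct`, `median_rt_ms`, `pe`
#'   (proportion in \[0, 1\]). `median_rt_ms` is `NA` (with a warning) for a
#'   cell with no retained correct trial.
#' @examples
#' trials <- simulate_cohort(cohort_config(n_per_group = 2, seed = 1))
#' summarize_conditions(trials)
#' @export
summarize_conditions <- function(trials, exclusion_scope = c("both", "rt_only"),
                                 lower_ms = 200, upper_ms = 1700) {
  exclusion_scope <- match.arg(exclusion_scope)
  if (!"excl_reason" %in% names(trials)) {
    trials <- flag_exclusions(trials, lower_ms, upper_ms)
  }
  test <- dplyr::filter(trials, .data$excl_reason != "practice")
  if (!"group" %in% names(test)) test$group <- NA_character_
  d <- data.table::data.table(
    participant_id = test$participant_id,
    group = as.character(test$group),
    cue = as.character(test$cue),
    flanker = as.character(test$flanker),
    err = !test$accuracy,
    rt_ms = as.numeric(test$rt_ms),
    in_rt = !test$excluded & test$accuracy,
    in_pe = if (exclusion_scope == "both") !test$excluded else TRUE
  )
  # two gforce-able passes per margin (median over retained correct trials;
  # error counts over retained trials), merged on the cell keys
  summarise_cells <- function(margin_lab, cell_var) {
    dd <- data.table::copy(d)
    dd[, cell := if (is.null(cell_var)) "overall" else dd[[cell_var]]]
    keys <- c("participant_id", "group", "cell")
    a_rt <- dd[in_rt == TRUE,
      list(n_correct = .N, median_rt_ms = median(rt_ms)),
      by = keys
    ]
    a_pe <- dd[in_pe == TRUE, list(n_retained = .N, n_err = sum(err)),
      by = keys
    ]
    all_cells <- unique(dd[, keys, with = FALSE])
    out <- merge(all_cells, a_pe, by = keys, all.x = TRUE)
    out <- merge(out, a_rt, by = keys, all.x = TRUE)
    out[is.na(n_retained), n_retained := 0L]
    out[is.na(n_correct), n_correct := 0L]
    tibble::tibble(
      participant_id = out$participant_id,
      group = out$group,
      margin = margin_lab,
      cell = out$cell,
      n_retained = out$n_retained,
      n_correct = out$n_correct,
      median_rt_ms = out$median_rt_ms,
      pe = ifelse(out$n_retained > 0, out$n_err / out$n_retained, NA_real_)
    )
  }
  out <- dplyr::bind_rows(
    summarise_cells("cue", "cue"),
    summarise_cells("flanker", "flanker"),
    summarise_cells("overall", NULL)
  )
  if (is.factor(test$group)) {
    out$group <- factor(out$group, levels = levels(test$group))
  }
  n_empty <- sum(is.na(out$median_rt_ms))
  if (n_empty > 0) {
    rlang::warn(paste0(
      n_empty, " participant-level cell(s) have no retained correct trial; ",
      "their median RT is NA."
    ))
  }
  out
}

#' Arcsine-square-root transform of an error proportion
#'
#' Returns `asin(sqrt(p))`, the variance-stabilising transform applied to
#' overall error proportions before group comparison. Strictly increasing on
#' \[0, 1\], mapping 0 to 0 and 1 to pi/2.
#'
#' @param p Proportion(s) in \[0, 1\].
#' @return Transformed value(s) in radians.
#' @examples
#' arcsin_transform(c(0, 0.25, 1)) # 0, pi/6, pi/2
#' @export
arcsin_transform <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    rlang::abort("`p` must be proportions in [0, 1].")
  }
  asin(sqrt(p))
}
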