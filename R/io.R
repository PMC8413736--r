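#' Trial-table CSV dialect
#'
#' Declares how a trial-level CSV maps onto the canonical column set. The
#' canonical columns are `participant_id`, `group`, `block`, `trial`, `cue`,
#' `flanker`, `target_location`, `target_direction`, `accuracy` (0/1) and
#' `rt_ms` (numeric or the missing token for a response timeout). A deposit
#' with different column names is absorbed by `rename`, e.g.
#' `trial_dialect(rename = c(participant_id = "subject"))`.
#'
#' @param delim Field delimiter (default `","`).
#' @param na Missing-value tokens for `rt_ms`.
#' @param rename Named character vector mapping canonical names to the
#'   file's column names.
#' @return A list of class `ant_dialect`.
#' @export
trial_dialect <- function(delim = ",", na = c("NA", ""), rename = character()) {
  canonical <- c(
    "participant_id", "group", "block", "trial", "cue", "flanker",
    "target_location", "target_direction", "accuracy", "rt_ms"
  )
  unknown <- setdiff(names(rename), canonical)
  if (length(unknown)) {
    rlang::abort(paste0(
      "`rename` refers to non-canonical columns: ",
      paste(unknown, collapse = ", ")
    ))
  }
  structure(
    list(delim = delim, na = na, rename = rename, canonical = canonical),
    class = "ant_dialect"
  )
}

#' Read and validate a trial-level CSV
#'
#' Parses a trial table under a [trial_dialect()] and validates it:
#' required columns present, cue/flanker labels in the fixed vocabularies,
#' `accuracy` in \{0, 1\}, `rt_ms` numeric or missing, and no duplicated
#' (participant, block, trial) keys. Validation failures are reported with
#' row numbers.
#'
#' @param path Path to the CSV file.
#' @param dialect A [trial_dialect()].
#' @return A validated trial tibble with logical `accuracy`.
#' @export
read_trials <- function(path, dialect = trial_dialect()) {
  stopifnot(inherits(dialect, "ant_dialect"))
  raw <- readr::read_delim(
    path,
    delim = dialect$delim, na = dialect$na,
    show_col_types = FALSE, progress = FALSE
  )
  for (canon in names(dialect$rename)) {
    src <- dialect$rename[[canon]]
    if (!src %in% names(raw)) {
      rlang::abort(paste0("dialect maps `", canon, "` to missing column `", src, "`."))
    }
    names(raw)[names(raw) == src] <- canon
  }
  missing_cols <- setdiff(dialect$canonical, names(raw))
  if (length(missing_cols)) {
    rlang::abort(paste0(
      "trial file is missing columns: ", paste(missing_cols, collapse = ", ")
    ))
  }
  raw <- dplyr::select(raw, dplyr::all_of(dialect$canonical))
  complain <- function(rows, what) {
    if (length(rows)) {
      rlang::abort(paste0(
        what, " at row(s): ",
        paste(utils::head(rows, 10), collapse = ", "),
        if (length(rows) > 10) paste0(" (+", length(rows) - 10, " more)") else ""
      ))
    }
  }
  complain(which(!raw$cue %in% ant_cue_levels()), "unknown cue label")
  complain(which(!raw$flanker %in% ant_flanker_levels()), "unknown flanker label")
  complain(which(!raw$accuracy %in% c(0, 1)), "accuracy not in {0, 1}")
  complain(
    which(!is.na(raw$rt_ms) & !is.finite(suppressWarnings(as.numeric(raw$rt_ms)))),
    "non-numeric rt_ms"
  )
  key <- paste(raw$participant_id, raw$block, raw$trial)
  complain(which(duplicated(key)), "duplicate (participant, block, trial) key")
  raw$rt_ms <- as.numeric(raw$rt_ms)
  raw$accuracy <- as.logical(as.integer(raw$accuracy))
  raw
}

#' @rdname read_trials
#' @param trials A trial tibble.
#' @export
write_trials <- function(trials, path, dialect = trial_dialect()) {
  out <- trials
  out$accuracy <- as.integer(out$accuracy)
  out <- dplyr::select(out, dplyr::all_of(dialect$canonical))
  readr::write_delim(out, path, delim = dialect$delim, na = dialect$na[1])
  invisible(trials)
}

#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end pipeline in one object. Can be
#' round-tripped through YAML with [read_run_config()].
#'
#' @param seed Integer seed driving all randomness (substreams per stage).
#' @param lower_ms,upper_ms RT exclusion bounds (ms).
#' @param exclusion_scope `"both"` or `"rt_only"` (see
#'   [summarize_conditions()]).
#' @param z_scope `"pooled"` or `"per_network"` (see
#'   [fit_standardization()]).
#' @param split `"stratified"` or `"unrestricted"` split-half mode.
#' @param n_permutations Split-half permutations.
#' @param tails `"two"` or `"one"` for the overall Welch tests.
#' @return A list of class `ant_run_config`.
#' @export
ant_run_config <- function(seed = 1L, lower_ms = 200, upper_ms = 1700,
                           exclusion_scope = "both", z_scope = "pooled",
                           split = "stratified", n_permutations = 1000,
                           tails = "two") {
  stopifnot(
    lower_ms > 0, upper_ms > lower_ms, n_permutations >= 1,
    exclusion_scope %in% c("both", "rt_only"),
    z_scope %in% c("pooled", "per_network"),
    split %in% c("stratified", "unrestricted"),
    tails %in% c("two", "one")
  )
  structure(
    list(
      seed = as.integer(seed), lower_ms = lower_ms, upper_ms = upper_ms,
      exclusion_scope = exclusion_scope, z_scope = z_scope, split = split,
      n_permutations = n_permutations, tails = tails
    ),
    class = "ant_run_config"
  )
}

#' @rdname ant_run_config
#' @param path Path to a YAML file whose keys match the arguments of
#'   `ant_run_config()` (missing keys fall back to defaults).
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(ant_run_config)))
  if (length(unknown)) {
    rlang::abort(paste0(
      "unknown config keys: ", paste(unknown, collapse = ", ")
    ))
  }
  do.call(ant_run_config, vals)
}

#' Run the full ANT analysis pipeline
#'
#' Orchestrates every stage on a trial table: exclusion flagging and report,
#' condition summaries, network difference and composite scores, split-half
#' reliability, the mixed-design ANOVA on the composites with post hoc
#' contrasts, the overall speed/accuracy Welch comparisons, and a Cook's
#' distance screen of the composite-on-group regression. If `out_dir` is
#' given, all tables are written as CSV together with a JSON manifest
#' (seed, config, package version) and a plain-text report; a fixed seed
#' makes the outputs byte-identical across runs.
#'
#' @param trials A trial tibble (e.g. from [simulate_cohort()] or
#'   [read_trials()]).
#' @param config An [ant_run_config()].
#' @param out_dir Optional output directory (created if needed).
#' @return A list of class `ant_results`: `exclusions`, `summaries`,
#'   `scores`, `reliability`, `anova`, `group_contrast`, `posthoc`,
#'   `overall_tests`, `cooks`, `config`.
#' @export
run_ant_pipeline <- function(trials, config = ant_run_config(),
                             out_dir = NULL) {
  stopifnot(inherits(config, "ant_run_config"))
  flagged <- flag_exclusions(trials, config$lower_ms, config$upper_ms)
  excl <- exclusion_report(flagged)
  summaries <- summarize_conditions(flagged,
    exclusion_scope = config$exclusion_scope
  )
  diffs <- network_differences(summaries)
  scores <- composite_scores(
    diffs, fit_standardization(diffs, config$z_scope)
  )
  reliability <- split_half_reliability(
    flagged,
    measure = c("rt", "pe"),
    n_permutations = config$n_permutations,
    seed = substream_seed(config$seed, "splits"),
    split = config$split
  )
  incomplete <- unique(scores$participant_id[is.na(scores$composite)])
  if (length(incomplete)) {
    rlang::warn(paste0(
      length(incomplete),
      " participant(s) dropped from the ANOVA for missing composites."
    ))
  }
  fit <- mixed_anova(
    dplyr::filter(scores, !.data$participant_id %in% incomplete)
  )
  contrast <- group_contrast(fit)
  posthoc <- cellwise_posthoc(fit)
  overall <- overall_group_tests(summaries, tails = config$tails)
  sm <- fit$subj_means
  cooks <- cooks_screen(sm$mean, data.frame(group = factor(sm$group)))
  res <- structure(
    list(
      exclusions = excl, summaries = summaries, scores = scores,
      reliability = reliability, anova = fit, group_contrast = contrast,
      posthoc = posthoc, overall_tests = overall, cooks = cooks,
      config = config
    ),
    class = "ant_results"
  )
  if (!is.null(out_dir)) {
    write_results(res, out_dir)
  }
  res
}

#' Overall speed and accuracy group comparisons
#'
#' Welch t tests comparing the groups on the per-participant overall median
#' RT and on the arcsine-square-root transformed overall error proportion,
#' with Holm adjustment over the two outcomes and pooled-SD Cohen's d, plus
#' per-group moment descriptives and the variance ratio.
#'
#' @param summaries A condition-summary tibble from
#'   [summarize_conditions()].
#' @param tails `"two"` or `"one"` (see [welch_t()]).
#' @return A tibble with one row per outcome (`overall_rt`, `overall_ape`):
#'   group means/SDs/skew/kurtosis, `variance_ratio`, `t`, `df`, `p`,
#'   `p_holm`, `d`.
#' @export
overall_group_tests <- function(summaries, tails = "two") {
  overall <- dplyr::filter(summaries, .data$margin == "overall")
  groups <- levels(factor(overall$group))
  if (length(groups) != 2) {
    rlang::abort("`overall_group_tests()` needs exactly 2 groups.")
  }
  one <- function(values, label) {
    x <- values[overall$group == groups[1]]
    y <- values[overall$group == groups[2]]
    tt <- welch_t(x, y, tails = tails)
    dx <- describe(x)
    dy <- describe(y)
    tibble::tibble(
      outcome = label,
      mean_1 = dx$mean, sd_1 = dx$sd, skew_1 = dx$skewness, kurt_1 = dx$kurtosis,
      mean_2 = dy$mean, sd_2 = dy$sd, skew_2 = dy$skewness, kurt_2 = dy$kurtosis,
      variance_ratio = variance_ratio(x, y),
      t = tt$t, df = tt$df, p = tt$p, d = tt$d
    )
  }
  out <- dplyr::bind_rows(
    one(overall$median_rt_ms, "overall_rt"),
    one(arcsin_transform(overall$pe), "overall_ape")
  )
  out$p_holm <- holm_adjust(out$p)
  attr(out, "groups") <- groups
  out
}

#' @export
print.ant_results <- function(x, ...) {
  cat(format_report(x), sep = "\n")
  invisible(x)
}

# Plain-text report in conventional journal style.
format_report <- function(res) {
  fmt_p <- function(p) ifelse(p < .001, "< .001", paste0("= ", sub("^0", "", sprintf("%.3f", p))))
  out <- character()
  excl <- res$exclusions$overall
  out <- c(out, sprintf(
    "Trials excluded (out-of-range or timeout): %d of %d (%.2f%%).",
    excl$n_excluded, excl$n_test, excl$pct_excluded
  ))
  groups <- attr(res$overall_tests, "groups")
  for (i in seq_len(nrow(res$overall_tests))) {
    row <- res$overall_tests[i, ]
    out <- c(out, sprintf(
      "%s: %s %.2f (%.2f) vs %s %.2f (%.2f), t(%.2f) = %.2f, p %s (Holm p %s), d = %.2f.",
      row$outcome, groups[1], row$mean_1, row$sd_1, groups[2], row$mean_2,
      row$sd_2, row$df, row$t, fmt_p(row$p), fmt_p(row$p_holm), row$d
    ))
  }
  rel <- res$reliability |> dplyr::filter(.data$measure == "rt")
  for (i in seq_len(nrow(rel))) {
    out <- c(out, sprintf(
      "Split-half reliability (%s, RT): r = %.3f, 95%% CI [%.3f, %.3f].",
      rel$network[i], rel$mean_corrected_r[i], rel$ci_low[i], rel$ci_high[i]
    ))
  }
  tab <- res$anova$table
  for (i in seq_len(nrow(tab))) {
    out <- c(out, sprintf(
      "ANOVA %s: F(%.2f, %.2f) = %.2f, p %s, ges = %.2f.",
      tab$effect[i], tab$df_num_gg[i], tab$df_den_gg[i], tab$f[i],
      fmt_p(tab$p_gg[i]), tab$ges[i]
    ))
  }
  gc_row <- res$group_contrast
  out <- c(out, sprintf(
    "Group contrast (%s): t(%d) = %.2f, p %s.",
    gc_row$contrast, gc_row$df, gc_row$t, fmt_p(gc_row$p)
  ))
  for (i in seq_len(nrow(res$posthoc))) {
    ph <- res$posthoc[i, ]
    out <- c(out, sprintf(
      "Post hoc (%s): t(%.2f) = %.2f, Holm p %s.",
      ph$within, ph$df, ph$t, fmt_p(ph$p_adj)
    ))
  }
  ck <- glance(res$cooks)
  out <- c(out, sprintf(
    "Cook's D screen: max D = %.3f vs cutoff %.3f; %d flagged.",
    ck$max_d, ck$cutoff, ck$n_flagged
  ))
  out
}

# Write all result tables, a manifest and the text report to out_dir.
write_results <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(
    res$exclusions$by_participant, file.path(out_dir, "exclusions.csv")
  )
  readr::write_csv(res$summaries, file.path(out_dir, "condition_summaries.csv"))
  readr::write_csv(res$scores, file.path(out_dir, "network_scores.csv"))
  readr::write_csv(res$reliability, file.path(out_dir, "reliability.csv"))
  readr::write_csv(res$anova$table, file.path(out_dir, "anova.csv"))
  readr::write_csv(
    dplyr::bind_rows(
      dplyr::mutate(res$group_contrast, within = "all"),
      dplyr::mutate(res$posthoc,
        contrast = res$group_contrast$contrast,
        within = as.character(.data$within), p_adj = .data$p_adj
      )
    ),
    file.path(out_dir, "contrasts.csv")
  )
  readr::write_csv(res$overall_tests, file.path(out_dir, "overall_tests.csv"))
  manifest <- list(
    package = "antnets",
    version = as.character(utils::packageVersion("antnets")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = unclass(res$config),
    sphericity = res$anova$sphericity
  )
  jsonlite::write_json(
    manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  writeLines(format_report(res), file.path(out_dir, "report.txt"))
  invisible(out_dir)
}
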