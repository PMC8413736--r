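.datatable.aware <- TRUE

#' Spearman–Brown correction
#'
#' Projects a half-length split correlation to full test length:
#' `2 * r / (1 + r)`. Monotone increasing on (-1, 1] with fixed points 0
#' and 1.
#'
#' @param r Pearson correlation(s) between half scores.
#' @return Corrected correlation(s).
#' @examples
#' spearman_brown(c(0, 0.48, 1))
#' @export
spearman_brown <- function(r) {
  2 * r / (1 + r)
}

# Precompute everything the permutation loop needs: retained test trials with
# integer participant ids, integer cue / flanker codes, and the stratification
# group structure (participant x cue x flanker cell), sorted by group so the
# per-permutation half assignment is a single order() call.
reliability_prepare <- function(trials, split = "stratified",
                                lower_ms = 200, upper_ms = 1700) {
  if (!"excl_reason" %in% names(trials)) {
    trials <- flag_exclusions(trials, lower_ms, upper_ms)
  }
  keep <- !trials$excluded
  pid <- as.integer(factor(trials$participant_id[keep]))
  cue_i <- match(as.character(trials$cue[keep]), ant_cue_levels())
  fl_i <- match(
    as.character(trials$flanker[keep]),
    c("congruent", "incongruent") # neutral -> NA, outside both margins
  )
  correct <- as.logical(trials$accuracy[keep])
  rt <- as.numeric(trials$rt_ms[keep])
  gid <- if (split == "stratified") (pid - 1L) * 12L + (cue_i - 1L) * 3L +
    match(as.character(trials$flanker[keep]), ant_flanker_levels()) else pid
  ord <- order(gid)
  gid <- gid[ord]
  gid <- match(gid, unique(gid)) # dense 1..G in sorted order
  sizes <- tabulate(gid)
  list(
    pid = pid[ord], cue_i = cue_i[ord], fl_i = fl_i[ord],
    correct = correct[ord], rt = rt[ord],
    gid = gid, sizes = sizes, seq_within = sequence(sizes),
    n = length(gid), n_groups = length(sizes),
    n_pid = max(pid)
  )
}

# Uniformly random balanced halves within each stratification group: ranks of
# iid uniforms alternate between halves, with a random flip per group deciding
# which half receives the odd trial.
assign_halves <- function(prep) {
  u <- stats::runif(prep$n)
  ordv <- order(prep$gid, u, method = "radix")
  flip <- sample.int(2L, prep$n_groups, replace = TRUE) - 1L
  half <- integer(prep$n)
  half[ordv] <- 1L + (prep$seq_within + rep.int(flip, prep$sizes)) %% 2L
  half
}

grouped_median <- function(v, g, n_out) {
  agg <- data.table::data.table(g = g, v = v)[, median(v), by = g]
  out <- rep(NA_real_, n_out)
  out[agg$g] <- agg$V1
  out
}

grouped_mean <- function(v, g, n_out) {
  agg <- data.table::data.table(g = g, v = v)[, mean(v), by = g]
  out <- rep(NA_real_, n_out)
  out[agg$g] <- agg$V1
  out
}

# One permutation: per-half network difference scores for every participant,
# returned as a list of P x 2 matrices, one per network x measure.
half_differences <- function(prep, half, measures) {
  p_n <- prep$n_pid
  need_rt <- any(c("rt", "composite") %in% measures)
  need_pe <- any(c("pe", "composite") %in% measures)
  # grouping ids: participant x margin level x half
  id_cue <- ((prep$pid - 1L) * 4L + (prep$cue_i - 1L)) * 2L + half
  in_fl <- !is.na(prep$fl_i)
  id_fl <- ((prep$pid[in_fl] - 1L) * 2L + (prep$fl_i[in_fl] - 1L)) * 2L +
    half[in_fl]
  margin_mat <- function(vals, n_levels) {
    # rows = participants, cols = (level, half) pairs
    matrix(vals, nrow = p_n, ncol = 2L * n_levels, byrow = TRUE)
  }
  diff_pair <- function(m, hi, lo) {
    cbind(
      m[, 2L * (hi - 1L) + 1L] - m[, 2L * (lo - 1L) + 1L],
      m[, 2L * hi] - m[, 2L * lo]
    )
  }
  out <- list()
  if (need_rt) {
    ok <- prep$correct
    m_cue <- margin_mat(
      grouped_median(prep$rt[ok], id_cue[ok], 8L * p_n), 4L
    )
    m_fl <- margin_mat(
      grouped_median(prep$rt[in_fl & ok], id_fl[ok[in_fl]], 4L * p_n), 2L
    )
    out$alerting_rt <- diff_pair(m_cue, 1L, 3L) # none - double
    out$orienting_rt <- diff_pair(m_cue, 2L, 4L) # central - spatial
    out$executive_rt <- diff_pair(m_fl, 2L, 1L) # incongruent - congruent
  }
  if (need_pe) {
    err <- 100 * !prep$correct
    m_cue <- margin_mat(grouped_mean(err, id_cue, 8L * p_n), 4L)
    m_fl <- margin_mat(grouped_mean(err[in_fl], id_fl, 4L * p_n), 2L)
    out$alerting_pe <- diff_pair(m_cue, 1L, 3L)
    out$orienting_pe <- diff_pair(m_cue, 2L, 4L)
    out$executive_pe <- diff_pair(m_fl, 2L, 1L)
  }
  if ("composite" %in% measures) {
    for (h in 1:2) {
      stack_rt <- c(
        out$alerting_rt[, h], out$orienting_rt[, h], out$executive_rt[, h]
      )
      stack_pe <- c(
        out$alerting_pe[, h], out$orienting_pe[, h], out$executive_pe[, h]
      )
      z_rt <- (stack_rt - mean(stack_rt, na.rm = TRUE)) /
        stats::sd(stack_rt, na.rm = TRUE)
      z_pe <- (stack_pe - mean(stack_pe, na.rm = TRUE)) /
        stats::sd(stack_pe, na.rm = TRUE)
      comp <- matrix((z_rt + z_pe) / 2, nrow = p_n)
      for (j in seq_along(ant_networks())) {
        key <- paste0(ant_networks()[j], "_composite")
        if (is.null(out[[key]])) out[[key]] <- matrix(NA_real_, p_n, 2)
        out[[key]][, h] <- comp[, j]
      }
    }
  }
  out
}

# Corrected split-half correlation for each requested network x measure.
split_half_values <- function(prep, networks, measures) {
  half <- assign_halves(prep)
  mats <- half_differences(prep, half, measures)
  grid <- expand.grid(
    network = networks, measure = measures,
    stringsAsFactors = FALSE
  )
  res <- purrr::pmap(grid, function(network, measure) {
    m <- mats[[paste0(network, "_", measure)]]
    ok <- stats::complete.cases(m)
    r <- if (sum(ok) >= 3) stats::cor(m[ok, 1], m[ok, 2]) else NA_real_
    tibble::tibble(
      network = network, measure = measure, r = r,
      n_used = sum(ok), n_dropped = prep$n_pid - sum(ok)
    )
  }) |> purrr::list_rbind()
  res$corrected_r <- spearman_brown(res$r)
  res
}

#' One random split-half correlation
#'
#' Splits each participant's retained test trials into two random halves,
#' recomputes the requested network score on each half, correlates the half
#' scores across participants (Pearson), and applies the Spearman–Brown
#' correction. Participants with an unestimable score in either half are
#' dropped from the correlation (and counted).
#'
#' @param trials A trial tibble; exclusion flags are added if absent.
#' @param network One or more of `"alerting"`, `"orienting"`, `"executive"`.
#' @param measure One or more of `"rt"`, `"pe"`, `"composite"`. For the
#'   composite, the stacked half differences are standardised within each
#'   half before averaging the two z-scores.
#' @param split `"stratified"` (default; the split is balanced within every
#'   cue x flanker cell so both halves contain every condition) or
#'   `"unrestricted"` (trials split freely within participant).
#' @param seed Optional seed.
#' @return A tibble: `network`, `measure`, `r`, `corrected_r`, `n_used`,
#'   `n_dropped`.
#' @export
split_half_once <- function(trials, network = ant_networks(),
                            measure = c("rt", "pe", "composite"),
                            split = c("stratified", "unrestricted"),
                            seed = NULL) {
  network <- match.arg(network, several.ok = TRUE)
  measure <- match.arg(measure, several.ok = TRUE)
  split <- match.arg(split)
  d <- reliability_prepare(trials, split)
  run <- function() split_half_values(d, network, measure)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Permutation split-half reliability
#'
#' Repeats the random split `n_permutations` times and reports, per network
#' and measure, the mean Spearman–Brown-corrected correlation with a 95%
#' confidence interval. The default interval is the normal standard-error
#' interval `mean ± 1.96 * sd / sqrt(n)`; a percentile interval over the
#' permutation values is available via `ci = "percentile"`.
#'
#' @inheritParams split_half_once
#' @param n_permutations Number of random splits (default 1000).
#' @param ci `"normal"` or `"percentile"`.
#' @param keep_permutations If `TRUE`, attach the per-permutation corrected
#'   correlations as attribute `"permutations"` (a tibble).
#' @return An `ant_reliability` tibble: `network`, `measure`,
#'   `n_permutations`, `mean_corrected_r`, `sd_corrected_r`, `ci_low`,
#'   `ci_high`, `mean_n_dropped`.
#' @examples
#' trials <- simulate_cohort(cohort_config(n_per_group = 8, seed = 1))
#' split_half_reliability(trials, measure = "rt", n_permutations = 20, seed = 2)
#' @export
split_half_reliability <- function(trials, network = ant_networks(),
                                   measure = c("rt", "pe", "composite"),
                                   n_permutations = 1000, seed = NULL,
                                   split = c("stratified", "unrestricted"),
                                   ci = c("normal", "percentile"),
                                   keep_permutations = FALSE) {
  network <- match.arg(network, several.ok = TRUE)
  measure <- match.arg(measure, several.ok = TRUE)
  split <- match.arg(split)
  ci <- match.arg(ci)
  stopifnot(n_permutations >= 1)
  if (n_permutations < 2 && ci == "normal") {
    rlang::warn("CI is undefined with fewer than 2 permutations.")
  }
  d <- reliability_prepare(trials, split)
  run <- function() {
    purrr::map(seq_len(n_permutations), function(i) {
      res <- split_half_values(d, network, measure)
      res$permutation <- i
      res
    }) |> purrr::list_rbind()
  }
  perms <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  out <- perms |>
    dplyr::group_by(.data$network, .data$measure) |>
    dplyr::summarise(
      n_permutations = dplyr::n(),
      mean_corrected_r = mean(.data$corrected_r, na.rm = TRUE),
      sd_corrected_r = stats::sd(.data$corrected_r, na.rm = TRUE),
      ci_low = if (ci == "normal") {
        .data$mean_corrected_r -
          1.96 * .data$sd_corrected_r / sqrt(.data$n_permutations)
      } else {
        stats::quantile(.data$corrected_r, 0.025, na.rm = TRUE, names = FALSE)
      },
      ci_high = if (ci == "normal") {
        .data$mean_corrected_r +
          1.96 * .data$sd_corrected_r / sqrt(.data$n_permutations)
      } else {
        stats::quantile(.data$corrected_r, 0.975, na.rm = TRUE, names = FALSE)
      },
      mean_n_dropped = mean(.data$n_dropped),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      network = factor(.data$network, levels = ant_networks()),
      measure = factor(.data$measure, levels = c("rt", "pe", "composite"))
    ) |>
    dplyr::arrange(.data$network, .data$measure)
  out <- structure(out, class = c("ant_reliability", class(out)))
  if (keep_permutations) {
    attr(out, "permutations") <- tibble::as_tibble(perms)
  }
  out
}

#' Plot split-half reliability estimates
#'
#' Dot-and-interval plot of the mean corrected correlation per network and
#' measure.
#'
#' @param object An `ant_reliability` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ant_reliability <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(
      x = .data$network, y = .data$mean_corrected_r, colour = .data$measure
    )
  ) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      position = ggplot2::position_dodge(width = 0.4)
    ) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey40") +
    ggplot2::labs(
      x = NULL, y = "split-half reliability (Spearman-Brown corrected)",
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}
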