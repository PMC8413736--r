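#' Moment-based descriptive statistics
#'
#' Mean, SD (n−1 denominator), skewness and excess kurtosis of a sample.
#' Defaults are the moment estimators `g1 = m3 / m2^1.5` and
#' `g2 = m4 / m2^2 − 3`; `bias_correct = TRUE` gives the small-sample
#' adjusted forms `G1` and `G2`.
#'
#' @param x Numeric sample (`NA`s dropped); needs `n >= 2` (skewness
#'   `n >= 3`, kurtosis `n >= 4`).
#' @param bias_correct Use the bias-adjusted `G1`/`G2` estimators.
#' @return A one-row tibble: `n`, `mean`, `sd`, `skewness`, `kurtosis`.
#' @examples
#' describe(c(-1, 0, 1)) # skewness 0
#' @export
describe <- function(x, bias_correct = FALSE) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2) {
    rlang::abort("`describe()` needs at least 2 non-missing values.")
  }
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) {
    rlang::warn("constant sample: skewness and kurtosis are undefined.")
    return(tibble::tibble(
      n = n, mean = m, sd = 0, skewness = NA_real_, kurtosis = NA_real_
    ))
  }
  g1 <- mean((x - m)^3) / m2^1.5
  g2 <- mean((x - m)^4) / m2^2 - 3
  if (bias_correct) {
    g1 <- if (n >= 3) g1 * sqrt(n * (n - 1)) / (n - 2) else NA_real_
    g2 <- if (n >= 4) {
      ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
    } else {
      NA_real_
    }
  } else {
    if (n < 3) g1 <- NA_real_
    if (n < 4) g2 <- NA_real_
  }
  tibble::tibble(
    n = n, mean = m, sd = stats::sd(x), skewness = g1, kurtosis = g2
  )
}

#' Variance ratio of two samples
#'
#' `max(var) / min(var)`, the simple screen for heterogeneity of variance;
#' always at least 1 and invariant to argument order.
#'
#' @param x,y Numeric samples.
#' @return The variance ratio (>= 1); `Inf` with a warning if one variance
#'   is zero.
#' @export
variance_ratio <- function(x, y) {
  v <- c(stats::var(x, na.rm = TRUE), stats::var(y, na.rm = TRUE))
  if (any(is.na(v))) {
    rlang::abort("both samples must have a computable variance.")
  }
  if (min(v) == 0) {
    rlang::warn("one sample has zero variance; variance ratio is infinite.")
    return(Inf)
  }
  max(v) / min(v)
}

#' Cohen's d from summary statistics
#'
#' Pooled-SD standardised mean difference:
#' `d = (m1 - m2) / s_pooled` with
#' `s_pooled^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)`.
#'
#' @param m1,m2 Group means.
#' @param sd1,sd2 Group standard deviations.
#' @param n1,n2 Group sizes.
#' @return Cohen's d.
#' @examples
#' cohens_d_from_summary(11.86, 11.84, 1.25, 1.25, 54, 54) # ~0.02
#' @export
cohens_d_from_summary <- function(m1, m2, sd1, sd2, n1, n2) {
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  if (sp2 <= 0) {
    rlang::abort("pooled variance is zero; d is undefined.")
  }
  (m1 - m2) / sqrt(sp2)
}

#' @rdname cohens_d_from_summary
#' @param x,y Numeric samples (`NA`s dropped).
#' @export
cohens_d <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  cohens_d_from_summary(
    mean(x), mean(y), stats::sd(x), stats::sd(y), length(x), length(y)
  )
}

#' Welch's two-sample t test
#'
#' Unequal-variance t test with Welch–Satterthwaite degrees of freedom,
#' implemented directly from the defining formulas, plus a pooled-SD Cohen's
#' d. `tails = "one"` reports the one-sided p-value in the direction of the
#' observed difference.
#'
#' @param x,y Numeric samples (`NA`s dropped; each needs `n >= 2`).
#' @param tails `"two"` (default) or `"one"`.
#' @return An `ant_welch` object (list) with `t`, `df`, `p`, `tails`,
#'   `estimate` (mean difference `x - y`), `d`, `n1`, `n2`.
#' @examples
#' welch_t(c(1, 2, 3), c(2, 3, 4))
#' @export
welch_t <- function(x, y, tails = c("two", "one")) {
  tails <- match.arg(tails)
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 2 || n2 < 2) {
    rlang::abort("each sample needs at least 2 non-missing values.")
  }
  v1 <- stats::var(x)
  v2 <- stats::var(y)
  if (v1 + v2 == 0) {
    rlang::abort("both samples are constant; the t statistic is undefined.")
  }
  se2 <- v1 / n1 + v2 / n2
  t_stat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- if (tails == "two") {
    2 * stats::pt(-abs(t_stat), df)
  } else {
    stats::pt(-abs(t_stat), df)
  }
  structure(
    list(
      t = t_stat, df = df, p = p, tails = tails,
      estimate = mean(x) - mean(y), d = cohens_d(x, y), n1 = n1, n2 = n2
    ),
    class = "ant_welch"
  )
}

#' @export
print.ant_welch <- function(x, ...) {
  cat(sprintf(
    "Welch two-sample t test (%s-tailed)\n  t(%.2f) = %.2f, p = %.3f, d = %.2f\n  mean difference = %.3f (n = %d, %d)\n",
    x$tails, x$df, x$t, x$p, x$d, x$estimate, x$n1, x$n2
  ))
  invisible(x)
}

#' Holm step-down p-value adjustment
#'
#' Step-down correction controlling the family-wise error rate: with the
#' p-values sorted ascending, the i-th is multiplied by `m - i + 1`, running
#' maxima enforce monotonicity, and values are capped at 1. Returned in the
#' original order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @examples
#' holm_adjust(c(0.0012, 0.302))
#' @export
holm_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    rlang::abort("`p` must be probabilities in [0, 1].")
  }
  m <- length(p)
  if (m <= 1) {
    return(p)
  }
  ord <- order(p)
  adj <- pmin(1, cummax((m - seq_len(m) + 1) * p[ord]))
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Pearson chi-square test for a 2x2 table
#'
#' Pearson's chi-square without continuity correction, with the phi
#' coefficient `sqrt(chi2 / N)`.
#'
#' @param table A 2x2 matrix of non-negative counts with positive margins.
#' @return An `ant_chisq` object (list): `chi2`, `df`, `p`, `phi`, `n`.
#' @examples
#' chi_square_2x2(matrix(c(22, 22, 32, 32), nrow = 2))
#' @export
chi_square_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) {
    rlang::abort("`table` must be a 2x2 matrix of counts.")
  }
  if (any(table < 0) || any(table != round(table))) {
    rlang::abort("`table` must contain non-negative integer counts.")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    rlang::abort("all margins of the table must be positive.")
  }
  n <- sum(table)
  expected <- outer(rowSums(table), colSums(table)) / n
  chi2 <- sum((table - expected)^2 / expected)
  structure(
    list(
      chi2 = chi2, df = 1L, p = stats::pchisq(chi2, 1, lower.tail = FALSE),
      phi = sqrt(chi2 / n), n = n
    ),
    class = "ant_chisq"
  )
}

#' @export
print.ant_chisq <- function(x, ...) {
  cat(sprintf(
    "Pearson chi-square (2x2, no continuity correction)\n  chi2(%d) = %.2f, p = %.3f, phi = %.2f (N = %d)\n",
    x$df, x$chi2, x$p, x$phi, x$n
  ))
  invisible(x)
}

# Orthonormal basis of the contrast space (orthogonal complement of the unit
# vector), used for the sphericity machinery.
orthonormal_contrasts <- function(k) {
  q <- qr.Q(qr(cbind(rep(1, k), diag(k))))
  t(q[, 2:k, drop = FALSE])
}

#' Split-plot (mixed-design) repeated-measures ANOVA
#'
#' One between-subjects factor crossed with one within-subjects factor,
#' computed from first principles on complete balanced data: sums of squares
#' by orthogonal projection (between-subject stratum: group and
#' subjects-within-group; within-subject stratum: within effect, interaction,
#' and residual), Mauchly's sphericity test and the Greenhouse–Geisser
#' epsilon on the pooled within-group covariance of orthonormalised
#' contrasts, GG-corrected p-values (F unchanged, degrees of freedom scaled
#' by epsilon), and generalized eta squared
#' `SS_effect / (SS_effect + SS_subjects + SS_residual)`.
#'
#' @param data Long-format data frame.
#' @param dv,subject,between,within Column names (strings) of the response,
#'   subject id, between factor and within factor. Defaults match the
#'   `ant_scores` layout (`composite`, `participant_id`, `group`, `network`).
#' @return An `ant_anova` object: `table` (one row per effect: `effect`,
#'   `ss`, `df_num`, `df_den`, `ms`, `f`, `p`, `df_num_gg`, `df_den_gg`,
#'   `p_gg`, `ges`), `sphericity` (Mauchly `w`, `chi2`, `df`, `p`,
#'   `gg_epsilon`), plus the variance components needed by
#'   [group_contrast()] and [cellwise_posthoc()].
#' @examples
#' scores <- score_networks(simulate_cohort(cohort_config(n_per_group = 6, seed = 1)))
#' fit <- mixed_anova(scores)
#' tidy(fit)
#' @export
mixed_anova <- function(data, dv = "composite", subject = "participant_id",
                        between = "group", within = "within_default") {
  if (identical(within, "within_default")) {
    within <- if ("network" %in% names(data)) "network" else "within"
  }
  need <- c(dv, subject, between, within)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    rlang::abort(paste0(
      "columns not found in `data`: ", paste(missing_cols, collapse = ", ")
    ))
  }
  d <- tibble::tibble(
    y = as.numeric(data[[dv]]),
    s = as.character(data[[subject]]),
    g = as.character(data[[between]]),
    w = as.character(data[[within]])
  )
  if (anyNA(d$y)) {
    rlang::abort("the response contains missing values; the design must be complete.")
  }
  w_levels <- unique(d$w)
  g_levels <- unique(d$g)
  if (is.factor(data[[within]])) w_levels <- levels(droplevels(factor(data[[within]])))
  if (is.factor(data[[between]])) g_levels <- levels(droplevels(factor(data[[between]])))
  k <- length(w_levels)
  g <- length(g_levels)
  if (k < 2 || g < 2) {
    rlang::abort("both factors need at least 2 levels.")
  }
  counts <- table(d$s, d$w)
  if (any(counts != 1)) {
    rlang::abort(
      "unsupported design: every subject must have exactly one observation per within level."
    )
  }
  # wide response matrix, one row per subject
  subjects <- rownames(counts)
  y_mat <- matrix(NA_real_, length(subjects), k,
    dimnames = list(subjects, w_levels)
  )
  y_mat[cbind(match(d$s, subjects), match(d$w, w_levels))] <- d$y
  g_of_s <- d$g[match(subjects, d$s)]
  n_g <- table(factor(g_of_s, levels = g_levels))
  if (any(n_g < 2)) {
    rlang::abort("each group needs at least 2 subjects.")
  }
  n_sub <- length(subjects)

  grand <- mean(y_mat)
  subj_means <- rowMeans(y_mat)
  group_means <- tapply(subj_means, factor(g_of_s, levels = g_levels), mean)

  # between-subject stratum
  ss_between_subj <- k * sum((subj_means - grand)^2)
  ss_group <- k * sum(n_g * (group_means - grand)^2)
  ss_subj <- ss_between_subj - ss_group
  df_group <- g - 1
  df_subj <- n_sub - g

  # within-subject stratum: sequential orthogonal projections of the
  # row-centred responses onto the within-effect and cell-mean subspaces
  z <- y_mat - subj_means
  ss_within_total <- sum(z^2)
  col_means <- colMeans(z)
  ss_within <- n_sub * sum(col_means^2)
  z2 <- sweep(z, 2, col_means)
  rs <- rowsum(z2, g_of_s)
  ng_vec <- as.vector(table(g_of_s)[rownames(rs)])
  cell_means_centred <- rs / ng_vec
  ss_inter <- sum(ng_vec * cell_means_centred^2)
  ss_error <- ss_within_total - ss_within - ss_inter
  df_within <- k - 1
  df_inter <- (g - 1) * (k - 1)
  df_error <- (n_sub - g) * (k - 1)

  ms_group <- ss_group / df_group
  ms_subj <- ss_subj / df_subj
  ms_within <- ss_within / df_within
  ms_inter <- ss_inter / df_inter
  ms_error <- ss_error / df_error

  degenerate <- ms_subj <= 0 || ms_error <= 0
  if (degenerate) {
    rlang::warn("zero error variance: F statistics are undefined (degenerate data).")
  }
  f_group <- if (degenerate) NA_real_ else ms_group / ms_subj
  f_within <- if (degenerate) NA_real_ else ms_within / ms_error
  f_inter <- if (degenerate) NA_real_ else ms_inter / ms_error

  # sphericity: pooled within-group covariance of orthonormalised contrasts
  centred <- y_mat - t(vapply(
    g_of_s, function(gg) colMeans(y_mat[g_of_s == gg, , drop = FALSE]),
    numeric(k)
  ))
  s_pool <- crossprod(centred) / df_subj
  cc <- orthonormal_contrasts(k)
  s_c <- cc %*% s_pool %*% t(cc)
  p_dim <- k - 1
  eps <- sum(diag(s_c))^2 / (p_dim * sum(s_c^2))
  if (p_dim == 1) {
    mauchly <- list(w = 1, chi2 = 0, df = 0L, p = NA_real_)
    eps <- 1
  } else {
    w_stat <- det(s_c) / (sum(diag(s_c)) / p_dim)^p_dim
    # chi-square approximation with the standard second-order correction
    rho <- 1 - (2 * p_dim^2 + p_dim + 2) / (6 * p_dim * df_subj)
    chi2 <- -df_subj * rho * log(max(w_stat, .Machine$double.xmin))
    df_m <- as.integer(p_dim * (p_dim + 1) / 2 - 1)
    w2 <- (p_dim + 2) * (p_dim - 1) * (p_dim - 2) *
      (2 * p_dim^3 + 6 * p_dim^2 + 3 * p_dim + 2) /
      (288 * (df_subj * p_dim * rho)^2)
    pr1 <- stats::pchisq(chi2, df_m, lower.tail = FALSE)
    pr2 <- stats::pchisq(chi2, df_m + 4, lower.tail = FALSE)
    mauchly <- list(
      w = w_stat, chi2 = chi2, df = df_m, p = pr1 + w2 * (pr2 - pr1)
    )
  }

  ges <- function(ss_effect) ss_effect / (ss_effect + ss_subj + ss_error)
  p_of <- function(f, d1, d2) {
    if (is.na(f)) NA_real_ else stats::pf(f, d1, d2, lower.tail = FALSE)
  }
  tab <- tibble::tibble(
    effect = c(between, within, paste0(between, ":", within)),
    ss = c(ss_group, ss_within, ss_inter),
    df_num = c(df_group, df_within, df_inter),
    df_den = c(df_subj, df_error, df_error),
    ms = c(ms_group, ms_within, ms_inter),
    f = c(f_group, f_within, f_inter),
    p = c(
      p_of(f_group, df_group, df_subj),
      p_of(f_within, df_within, df_error),
      p_of(f_inter, df_inter, df_error)
    ),
    df_num_gg = c(df_group, eps * df_within, eps * df_inter),
    df_den_gg = c(df_subj, eps * df_error, eps * df_error),
    p_gg = c(
      p_of(f_group, df_group, df_subj),
      p_of(f_within, eps * df_within, eps * df_error),
      p_of(f_inter, eps * df_inter, eps * df_error)
    ),
    ges = ges(c(ss_group, ss_within, ss_inter))
  )
  structure(
    list(
      table = tab,
      sphericity = c(mauchly, list(gg_epsilon = eps)),
      ss = list(
        subjects = ss_subj, error_within = ss_error, total = ss_between_subj +
          ss_within_total
      ),
      ms = list(subjects = ms_subj, error_within = ms_error),
      df = list(subjects = df_subj, error_within = df_error),
      k = k, g = g, n_g = as.vector(n_g), g_levels = g_levels,
      w_levels = w_levels,
      subj_means = tibble::tibble(
        subject = subjects, group = g_of_s, mean = subj_means
      ),
      cell_means = {
        rs_y <- rowsum(y_mat, g_of_s)
        cm <- rs_y / as.vector(table(g_of_s)[rownames(rs_y)])
        tibble::as_tibble(cm, rownames = "group") |>
          tidyr::pivot_longer(-"group",
            names_to = "within", values_to = "mean"
          )
      },
      vars = list(dv = dv, subject = subject, between = between, within = within)
    ),
    class = "ant_anova"
  )
}

#' @export
print.ant_anova <- function(x, ...) {
  cat(sprintf(
    "Mixed-design ANOVA: %s ~ %s (between) x %s (within)\n",
    x$vars$dv, x$vars$between, x$vars$within
  ))
  tab <- x$table
  for (i in seq_len(nrow(tab))) {
    cat(sprintf(
      "  %-22s F(%.2f, %.2f) = %.2f, p = %.3f (GG p = %.3f), ges = %.3f\n",
      tab$effect[i], tab$df_num_gg[i], tab$df_den_gg[i], tab$f[i],
      tab$p[i], tab$p_gg[i], tab$ges[i]
    ))
  }
  sp <- x$sphericity
  cat(sprintf(
    "  Mauchly W = %.3f, chi2(%d) = %.2f, p = %.3f; GG epsilon = %.3f\n",
    sp$w, sp$df, sp$chi2, if (is.na(sp$p)) 1 else sp$p, sp$gg_epsilon
  ))
  invisible(x)
}

#' Between-group contrast on the subject-average response
#'
#' The overall group comparison that follows a significant between-subjects
#' main effect in [mixed_anova()]: a t statistic on the difference of group
#' means of the per-subject average, with standard error from the
#' subjects-within-group mean square and `df = N - g`. With two groups this
#' is exactly the Tukey HSD comparison of the group means.
#'
#' @param model An `ant_anova` object.
#' @return A one-row tibble: `contrast`, `estimate`, `se`, `t`, `df`, `p`.
#' @export
group_contrast <- function(model) {
  stopifnot(inherits(model, "ant_anova"))
  if (model$g != 2) {
    rlang::abort("`group_contrast()` is defined for 2 groups.")
  }
  sm <- model$subj_means
  m <- tapply(sm$mean, factor(sm$group, levels = model$g_levels), mean)
  n_g <- model$n_g
  # per-subject averages have variance MS_subj / k on the mean-square scale
  se <- sqrt(model$ms$subjects / model$k * (1 / n_g[1] + 1 / n_g[2]))
  t_stat <- unname((m[1] - m[2]) / se)
  df <- model$df$subjects
  tibble::tibble(
    contrast = paste(model$g_levels, collapse = " - "),
    estimate = unname(m[1] - m[2]), se = unname(se), t = unname(t_stat),
    df = df, p = 2 * stats::pt(-abs(t_stat), df)
  )
}

#' Per-level group contrasts with Holm adjustment
#'
#' Group comparisons within each level of the within factor, following a
#' significant interaction. The cell-mean comparison mixes both error strata,
#' so the standard error combines the subjects-within-group and residual mean
#' squares, `(MS_subj + (k-1) MS_error) / k`, and the degrees of freedom are
#' obtained by Satterthwaite interpolation between the two strata. P-values
#' are Holm-adjusted across the within levels by default; `method = "tukey"`
#' instead applies a studentized-range correction over all `g * k` cell
#' means.
#'
#' @param model An `ant_anova` object (2 groups).
#' @param method `"holm"` (default) or `"tukey"`.
#' @return A tibble with one row per within level: `within`, `estimate`,
#'   `se`, `t`, `df`, `p`, `p_adj`.
#' @export
cellwise_posthoc <- function(model, method = c("holm", "tukey")) {
  method <- match.arg(method)
  stopifnot(inherits(model, "ant_anova"))
  if (model$g != 2) {
    rlang::abort("`cellwise_posthoc()` is defined for 2 groups.")
  }
  k <- model$k
  n_g <- model$n_g
  a <- model$ms$subjects
  b <- model$ms$error_within
  df_a <- model$df$subjects
  df_b <- model$df$error_within
  combined_ms <- (a + (k - 1) * b) / k
  df_sat <- (a / k + (k - 1) * b / k)^2 /
    ((a / k)^2 / df_a + ((k - 1) * b / k)^2 / df_b)
  se <- sqrt(combined_ms * (1 / n_g[1] + 1 / n_g[2]))
  cm <- model$cell_means |>
    tidyr::pivot_wider(names_from = "group", values_from = "mean")
  g1 <- model$g_levels[1]
  g2 <- model$g_levels[2]
  est <- cm[[g1]] - cm[[g2]]
  t_stat <- est / se
  p <- 2 * stats::pt(-abs(t_stat), df_sat)
  p_adj <- if (method == "holm") {
    holm_adjust(p)
  } else {
    stats::ptukey(abs(t_stat) * sqrt(2), model$g * k, df_sat,
      lower.tail = FALSE
    )
  }
  tibble::tibble(
    within = factor(cm$within, levels = model$w_levels),
    estimate = est, se = se, t = t_stat, df = df_sat, p = p, p_adj = p_adj
  ) |> dplyr::arrange(.data$within)
}

#' Cook's distance screen for influential observations
#'
#' Least-squares influence diagnostics computed from the hat matrix:
#' `D_i = r_i^2 / ((k+1) s^2) * h_i / (1 - h_i)^2` for a design with `k`
#' predictors plus intercept. Observations are flagged when `D_i` exceeds
#' the median of the `F(k + 1, n - k - 1)` distribution.
#'
#' @param response Numeric response vector.
#' @param design A data frame or matrix of predictors (an intercept is added;
#'   factors are expanded via [stats::model.matrix()]).
#' @return An `ant_cooks` object: `diagnostics` (tibble with `obs`,
#'   `leverage`, `residual`, `cooks_d`, `flagged`), `cutoff`, `k`, `n`.
#' @examples
#' x <- c(1:9, 10)
#' y <- c(1:9, 30) # gross outlier
#' cooks_screen(y, data.frame(x = x))
#' @export
cooks_screen <- function(response, design) {
  y <- as.numeric(response)
  if (is.null(dim(design))) design <- data.frame(x = design)
  mm <- stats::model.matrix(~., data = as.data.frame(design))
  n <- length(y)
  stopifnot(nrow(mm) == n)
  k <- ncol(mm) - 1L
  if (n <= k + 1) {
    rlang::abort("need more observations than parameters.")
  }
  qr_x <- qr(mm)
  if (qr_x$rank < ncol(mm)) {
    rlang::abort("rank-deficient design matrix.")
  }
  q <- qr.Q(qr_x)
  h <- rowSums(q^2)
  resid <- y - q %*% crossprod(q, y)
  s2 <- sum(resid^2) / (n - k - 1)
  d <- as.vector(resid^2 / ((k + 1) * s2) * h / (1 - h)^2)
  cutoff <- stats::qf(0.5, k + 1, n - k - 1)
  structure(
    list(
      diagnostics = tibble::tibble(
        obs = seq_len(n), leverage = h, residual = as.vector(resid),
        cooks_d = d, flagged = d > cutoff
      ),
      cutoff = cutoff, k = k, n = n
    ),
    class = "ant_cooks"
  )
}

#' @export
print.ant_cooks <- function(x, ...) {
  n_flag <- sum(x$diagnostics$flagged)
  cat(sprintf(
    "Cook's distance screen: n = %d, k = %d predictors\n  cutoff = median F(%d, %d) = %.3f; %d observation(s) flagged\n",
    x$n, x$k, x$k + 1, x$n - x$k - 1, x$cutoff, n_flag
  ))
  invisible(x)
}
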