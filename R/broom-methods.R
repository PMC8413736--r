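#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a mixed-design ANOVA
#'
#' @param x An `ant_anova` object.
#' @param ... Unused.
#' @return The effect table as a tibble (one row per effect).
#' @export
tidy.ant_anova <- function(x, ...) {
  x$table
}

#' Glance at a mixed-design ANOVA
#'
#' @param x An `ant_anova` object.
#' @param ... Unused.
#' @return A one-row tibble with design size and sphericity summaries.
#' @export
glance.ant_anova <- function(x, ...) {
  tibble::tibble(
    n_subjects = sum(x$n_g),
    n_groups = x$g,
    n_within = x$k,
    mauchly_w = x$sphericity$w,
    mauchly_p = x$sphericity$p,
    gg_epsilon = x$sphericity$gg_epsilon
  )
}

#' Tidy a Welch t test
#'
#' @param x An `ant_welch` object.
#' @param ... Unused.
#' @return A one-row tibble: `estimate`, `t`, `df`, `p`, `d`, `tails`,
#'   `n1`, `n2`.
#' @export
tidy.ant_welch <- function(x, ...) {
  tibble::tibble(
    estimate = x$estimate, t = x$t, df = x$df, p = x$p, d = x$d,
    tails = x$tails, n1 = x$n1, n2 = x$n2
  )
}

#' Tidy a 2x2 chi-square test
#'
#' @param x An `ant_chisq` object.
#' @param ... Unused.
#' @return A one-row tibble: `chi2`, `df`, `p`, `phi`, `n`.
#' @export
tidy.ant_chisq <- function(x, ...) {
  tibble::tibble(chi2 = x$chi2, df = x$df, p = x$p, phi = x$phi, n = x$n)
}

#' Tidy a Cook's distance screen
#'
#' @param x An `ant_cooks` object.
#' @param ... Unused.
#' @return The per-observation diagnostics tibble.
#' @export
tidy.ant_cooks <- function(x, ...) {
  x$diagnostics
}

#' Glance at a Cook's distance screen
#'
#' @param x An `ant_cooks` object.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `k`, `cutoff`, `n_flagged`, `max_d`.
#' @export
glance.ant_cooks <- function(x, ...) {
  tibble::tibble(
    n = x$n, k = x$k, cutoff = x$cutoff,
    n_flagged = sum(x$diagnostics$flagged),
    max_d = max(x$diagnostics$cooks_d)
  )
}
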