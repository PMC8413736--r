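test_that("descriptives match the moment definitions and an independent oracle", {
  expect_equal(describe(c(-1, 0, 1))$skewness, 0)
  expect_warning(d0 <- describe(rep(5, 10)), "constant")
  expect_true(is.na(d0$skewness) && d0$sd == 0)
  expect_error(describe(1), "at least 2")

  withr::with_seed(1, x <- stats::rnorm(40, 3, 2))
  d <- describe(x)
  expect_equal(d$mean, mean(x))
  expect_equal(d$sd, stats::sd(x))
  expect_equal(d$skewness, e1071::skewness(x, type = 1))
  expect_equal(d$kurtosis, e1071::kurtosis(x, type = 1))
  db <- describe(x, bias_correct = TRUE)
  expect_equal(db$skewness, e1071::skewness(x, type = 2))
  expect_equal(db$kurtosis, e1071::kurtosis(x, type = 2))
})

test_that("large-sample normal kurtosis is near zero", {
  withr::with_seed(2, x <- stats::rnorm(20000))
  se_kurt <- sqrt(24 / length(x))
  expect_lt(abs(describe(x)$kurtosis), 3 * se_kurt)
})

test_that("variance ratio is symmetric and at least one", {
  expect_equal(variance_ratio(c(1, 2, 3), c(4, 5, 6)), 1)
  x <- c(0, 2, 4)
  y <- c(0, 1, 2)
  expect_equal(variance_ratio(x, y), 4)
  expect_equal(variance_ratio(y, x), 4)
  expect_warning(r <- variance_ratio(rep(1, 3), c(1, 2, 3)), "zero variance")
  expect_identical(r, Inf)
})

test_that("Welch t agrees with stats::t.test and the hand-computed example", {
  x <- c(1, 2, 3)
  y <- c(2, 3, 4)
  w <- welch_t(x, y)
  expect_equal(w$t, -sqrt(1.5), tolerance = 1e-10) # = -1.2247
  expect_equal(w$df, 4)
  oracle <- stats::t.test(x, y)
  expect_equal(w$t, unname(oracle$statistic))
  expect_equal(w$df, unname(oracle$parameter))
  expect_equal(w$p, oracle$p.value)

  withr::with_seed(3, {
    a <- stats::rnorm(20, 1, 2)
    b <- stats::rnorm(35, 0, 1)
  })
  w2 <- welch_t(a, b)
  o2 <- stats::t.test(a, b)
  expect_equal(w2$t, unname(o2$statistic))
  expect_equal(w2$df, unname(o2$parameter))
  expect_equal(w2$p, o2$p.value)
  # one-sided p is half the two-sided p for the observed direction
  expect_equal(welch_t(a, b, tails = "one")$p, w2$p / 2)
})

test_that("Welch reduces to Student's t under equal variances and sizes", {
  withr::with_seed(4, {
    x <- stats::rnorm(12)
    y <- stats::rnorm(12)
  })
  w <- welch_t(x, y)
  s <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(w$t, unname(s$statistic))
  expect_error(welch_t(rep(1, 5), rep(1, 5)), "constant")
})

test_that("Cohen's d matches the pooled-SD definition", {
  expect_equal(
    round(cohens_d_from_summary(11.86, 11.84, 1.25, 1.25, 54, 54), 2), 0.02
  )
  x <- c(1, 2, 3, 4)
  y <- c(3, 4, 5, 6)
  sp <- sqrt((3 * stats::var(x) + 3 * stats::var(y)) / 6)
  expect_equal(cohens_d(x, y), (mean(x) - mean(y)) / sp)
})

test_that("Holm adjustment matches p.adjust and its defining properties", {
  expect_equal(holm_adjust(c(0.0012, 0.302)), c(0.0024, 0.302))
  expect_equal(holm_adjust(0.03), 0.03)
  withr::with_seed(5, {
    for (i in 1:5) {
      p <- stats::runif(7)^2
      adj <- holm_adjust(p)
      expect_equal(adj, stats::p.adjust(p, "holm"))
      # dominated by Bonferroni, and monotone in the sorted order
      expect_true(all(adj <= stats::p.adjust(p, "bonferroni") + 1e-15))
      expect_true(all(diff(adj[order(p)]) >= -1e-15))
    }
  })
  expect_error(holm_adjust(c(0.1, 1.4)), "\\[0, 1\\]")
})

test_that("2x2 chi-square matches the closed form and chisq.test", {
  res <- chi_square_2x2(matrix(c(22, 22, 32, 32), nrow = 2))
  expect_equal(res$chi2, 0)
  expect_equal(res$phi, 0)
  expect_equal(res$p, 1)

  res2 <- chi_square_2x2(matrix(c(10, 0, 0, 10), nrow = 2))
  expect_equal(res2$chi2, 20)
  expect_equal(res2$phi, 1)

  tab <- matrix(c(12, 5, 9, 14), nrow = 2)
  mine <- chi_square_2x2(tab)
  oracle <- stats::chisq.test(tab, correct = FALSE)
  expect_equal(mine$chi2, unname(oracle$statistic))
  expect_equal(mine$p, oracle$p.value)
  expect_equal(chi_square_2x2(t(tab))$chi2, mine$chi2)
  expect_error(chi_square_2x2(matrix(c(1, 0, 2, 0), 2)), "margins")
})

test_that("mixed ANOVA reproduces the aov error-strata decomposition on toys", {
  for (seed in c(1, 2, 3)) {
    d <- toy_mixed_data(n_per_group = 4, k = 3, seed = seed, effect = 0.8)
    fit <- mixed_anova(d)
    o <- aov_oracle(d)
    tab <- fit$table
    expect_equal(tab$ss[1], o$ss_group, tolerance = 1e-10)
    expect_equal(tab$ss[2], o$ss_network, tolerance = 1e-10)
    expect_equal(tab$ss[3], o$ss_inter, tolerance = 1e-10)
    expect_equal(fit$ss$subjects, o$ss_subj, tolerance = 1e-10)
    expect_equal(fit$ss$error_within, o$ss_error, tolerance = 1e-10)
    expect_equal(tab$f, c(o$f_group, o$f_network, o$f_inter), tolerance = 1e-10)
    # SS conservation
    total <- sum(
      (d$composite - mean(d$composite))^2
    )
    expect_equal(
      sum(tab$ss) + fit$ss$subjects + fit$ss$error_within, total,
      tolerance = 1e-8
    )
  }
})

test_that("Mauchly test and GG epsilon match the stats::mauchly.test oracle", {
  d <- toy_mixed_data(n_per_group = 5, k = 4, seed = 6)
  fit <- mixed_anova(d)
  wide <- tidyr::pivot_wider(d,
    id_cols = c("participant_id", "group"),
    names_from = "network", values_from = "composite"
  )
  ml <- stats::lm(cbind(a, b, c, d) ~ group, data = wide)
  idata <- data.frame(network = factor(letters[1:4]))
  oracle <- stats::mauchly.test(ml, X = ~1, idata = idata, M = ~network)
  expect_equal(fit$sphericity$w, unname(oracle$statistic), tolerance = 1e-10)
  # the reference implementation's second-order series term uses the full
  # response dimension where the textbook formula uses the contrast
  # dimension, so p-values agree only to ~1e-4
  expect_equal(fit$sphericity$p, oracle$p.value, tolerance = 1e-4)
})

test_that("a two-level within factor forces sphericity", {
  d <- toy_mixed_data(n_per_group = 4, k = 2, seed = 7)
  fit <- mixed_anova(d)
  expect_equal(fit$sphericity$gg_epsilon, 1)
  expect_equal(fit$sphericity$w, 1)
  expect_equal(fit$table$p_gg, fit$table$p)
})

test_that("GG correction only deflates degrees of freedom", {
  d <- toy_mixed_data(n_per_group = 6, k = 3, seed = 8, effect = 0.5)
  fit <- mixed_anova(d)
  eps <- fit$sphericity$gg_epsilon
  expect_gte(eps, 1 / 2)
  expect_lte(eps, 1)
  within_rows <- 2:3
  expect_true(all(
    fit$table$p_gg[within_rows] >= fit$table$p[within_rows] - 1e-12
  ))
  expect_equal(fit$table$df_num_gg[2], eps * fit$table$df_num[2])
})

test_that("generalized eta squared is bounded by partial eta squared", {
  d <- toy_mixed_data(n_per_group = 6, k = 3, seed = 9, effect = 1)
  fit <- mixed_anova(d)
  tab <- fit$table
  expect_true(all(tab$ges >= 0 & tab$ges <= 1))
  partial <- c(
    tab$ss[1] / (tab$ss[1] + fit$ss$subjects),
    tab$ss[2] / (tab$ss[2] + fit$ss$error_within),
    tab$ss[3] / (tab$ss[3] + fit$ss$error_within)
  )
  expect_true(all(tab$ges <= partial + 1e-12))
})

test_that("degenerate and malformed designs are rejected", {
  d <- toy_mixed_data(n_per_group = 3, k = 3, seed = 10)
  d$composite <- 1
  expect_warning(fit <- mixed_anova(d), "degenerate")
  expect_true(all(fit$table$ss == 0))
  expect_true(all(is.na(fit$table$f)))

  d2 <- toy_mixed_data(n_per_group = 3, k = 3, seed = 11)
  expect_error(mixed_anova(d2[-1, ]), "unsupported design")
  expect_error(mixed_anova(d2, dv = "nope"), "not found")
})

test_that("the overall group contrast equals a pooled t on subject means", {
  d <- toy_mixed_data(n_per_group = 5, k = 3, seed = 12, effect = 1)
  fit <- mixed_anova(d)
  gc_row <- group_contrast(fit)
  m <- tapply(d$composite, d$participant_id, mean)
  grp <- tapply(d$group, d$participant_id, \(g) g[1])
  oracle <- stats::t.test(m[grp == "g1"], m[grp == "g2"], var.equal = TRUE)
  expect_equal(gc_row$t, unname(oracle$statistic), tolerance = 1e-10)
  expect_equal(gc_row$df, unname(oracle$parameter))
  expect_equal(gc_row$p, oracle$p.value, tolerance = 1e-10)
  expect_equal(sign(gc_row$t), sign(gc_row$estimate))
})

test_that("cellwise post hocs interpolate dfs between strata and rank planted effects first", {
  d <- toy_mixed_data(n_per_group = 10, k = 3, seed = 13, effect = 1.5)
  fit <- mixed_anova(d)
  ph <- cellwise_posthoc(fit)
  expect_equal(nrow(ph), 3)
  # Satterthwaite df sits strictly between the stratum dfs
  expect_true(all(ph$df > fit$df$subjects))
  expect_true(all(ph$df < fit$df$subjects + fit$df$error_within))
  # the planted effect is on within level "c"
  expect_equal(as.character(ph$within[which.max(abs(ph$t))]), "c")
  expect_true(all(ph$p_adj >= ph$p - 1e-15))
  ph_tukey <- cellwise_posthoc(fit, method = "tukey")
  expect_true(all(ph_tukey$p_adj >= ph_tukey$p - 1e-15))
})

test_that("null data rarely produce significant post hoc contrasts", {
  n_sig <- purrr::map_int(1:30, function(s) {
    d <- toy_mixed_data(n_per_group = 8, k = 3, seed = 100 + s, effect = 0)
    sum(cellwise_posthoc(mixed_anova(d))$p_adj < 0.05)
  })
  # family-wise alpha 0.05: expect about 1-2 of 30 null replicates flagged
  expect_lte(sum(n_sig > 0), 5)
})

test_that("Cook's distances match stats::cooks.distance and flag a gross outlier", {
  withr::with_seed(14, {
    x <- stats::rnorm(20)
    y <- 2 + x + stats::rnorm(20, 0, 0.5)
  })
  y[7] <- y[7] + 8
  res <- cooks_screen(y, data.frame(x = x))
  fit <- stats::lm(y ~ x)
  expect_equal(res$diagnostics$cooks_d, unname(stats::cooks.distance(fit)),
    tolerance = 1e-10
  )
  expect_equal(res$diagnostics$leverage, unname(stats::hatvalues(fit)),
    tolerance = 1e-10
  )
  expect_equal(which.max(res$diagnostics$cooks_d), 7L)
  expect_equal(res$cutoff, stats::qf(0.5, 2, 18))

  # balanced duplicated design: exchangeable, all D equal and small
  xb <- rep(c(0, 1), each = 6)
  yb <- rep(c(1, 2), each = 6) + rep(c(-.1, 0, .1), 4)
  resb <- cooks_screen(yb, data.frame(x = xb))
  expect_false(any(resb$diagnostics$flagged))
  expect_error(cooks_screen(y, data.frame(a = x, b = 2 * x)), "rank-deficient")
})

test_that("tidy and glance methods return the documented shapes", {
  d <- toy_mixed_data(n_per_group = 4, k = 3, seed = 15)
  fit <- mixed_anova(d)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(nrow(tidy(fit)), 3)
  expect_equal(nrow(glance(fit)), 1)
  w <- welch_t(c(1, 2, 3), c(2, 3, 5))
  expect_named(
    tidy(w), c("estimate", "t", "df", "p", "d", "tails", "n1", "n2")
  )
  ck <- cooks_screen(c(1, 2, 3, 4, 6), data.frame(x = 1:5))
  expect_equal(nrow(tidy(ck)), 5)
})
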