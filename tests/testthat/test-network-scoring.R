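# Hand-built condition summary for one or more participants.
summary_fixture <- function(medians, pes = NULL) {
  # medians: named list per participant with cue and flanker cell values
  rows <- purrr::imap(medians, function(cells, pid) {
    tibble::tibble(
      participant_id = pid,
      group = "gifted",
      margin = c(rep("cue", 4), rep("flanker", 3)),
      cell = c("none", "central", "double", "spatial",
        "neutral", "congruent", "incongruent"
      ),
      n_retained = 24, n_correct = 24,
      median_rt_ms = cells,
      pe = if (is.null(pes)) 0.02 else pes[[pid]]
    )
  })
  purrr::list_rbind(rows)
}

test_that("network differences follow the subtraction conventions", {
  sm <- summary_fixture(list(
    P1 = c(600, 610, 570, 564, 630, 620, 704) # none central double spatial | n c i
  ))
  d <- network_differences(sm)
  expect_equal(d$rt_diff_ms[d$network == "alerting"], 30) # no cue - double cue
  expect_equal(d$rt_diff_ms[d$network == "orienting"], 46) # central - spatial
  expect_equal(d$rt_diff_ms[d$network == "executive"], 84) # incongruent - congruent
})

test_that("equal cue medians give zero alerting and orienting scores", {
  sm <- summary_fixture(list(P1 = c(600, 600, 600, 600, 600, 590, 700)))
  d <- network_differences(sm)
  expect_equal(d$rt_diff_ms[d$network == "alerting"], 0)
  expect_equal(d$rt_diff_ms[d$network == "orienting"], 0)
  expect_equal(d$rt_diff_ms[d$network == "executive"], 110)
})

test_that("PE differences are reported in percentage points", {
  sm <- summary_fixture(
    list(P1 = rep(600, 7)),
    pes = list(P1 = c(0.02, 0.02, 0.02, 0.02, 0.02, 0.02, 0.06))
  )
  d <- network_differences(sm)
  expect_equal(d$pe_diff[d$network == "executive"], 4)
  expect_equal(d$pe_diff[d$network == "alerting"], 0)
})

test_that("missing cells propagate as NA scores with a warning", {
  sm <- summary_fixture(list(P1 = c(600, 610, 570, 564, 630, 620, 704)))
  sm <- sm[sm$cell != "double", ]
  expect_warning(d <- network_differences(sm), "missing")
  expect_true(is.na(d$rt_diff_ms[d$network == "alerting"]))
  expect_false(is.na(d$rt_diff_ms[d$network == "executive"]))
})

test_that("pooled standardisation centres the full stack and unit-scales each component", {
  trials <- simulate_cohort(cohort_config(n_per_group = 10, seed = 31))
  sc <- score_networks(trials)
  expect_equal(mean(sc$composite), 0, tolerance = 1e-10)
  expect_equal(stats::sd(sc$z_rt), 1, tolerance = 1e-10)
  expect_equal(stats::sd(sc$z_pe), 1, tolerance = 1e-10)
  # composite is the average of its two z components
  expect_equal(sc$composite, (sc$z_rt + sc$z_pe) / 2)
})

test_that("per-network standardisation forces every network mean to zero", {
  trials <- simulate_cohort(cohort_config(n_per_group = 10, seed = 32))
  sc <- score_networks(trials, z_scope = "per_network")
  means <- tapply(sc$composite, sc$network, mean)
  expect_true(all(abs(means) < 1e-10))
})

test_that("Table-1-scale cohorts give positive executive and negative alerting composites", {
  # under pooled-stack standardisation the large conflict costs sit above the
  # pooled mean and the small alerting benefits below it, in both groups
  sc <- score_networks(simulate_cohort(cohort_config(seed = 33)))
  by_cell <- tapply(sc$composite, list(sc$group, sc$network), mean)
  expect_true(all(by_cell[, "executive"] > 0))
  expect_true(all(by_cell[, "alerting"] < 0))
  expect_true(all(by_cell[, "orienting"] < 0))
})

test_that("composites are invariant to a uniform rescaling of the RT unit", {
  trials <- simulate_cohort(cohort_config(n_per_group = 6, seed = 34))
  sc_ms <- score_networks(trials)
  trials_s <- trials
  trials_s$rt_ms <- trials$rt_ms / 1000
  sc_s <- score_networks(trials_s, lower_ms = 0.2, upper_ms = 1.7)
  expect_equal(sc_s$composite, sc_ms$composite, tolerance = 1e-10)
})

test_that("degenerate cohorts with zero score variance are rejected", {
  sm <- summary_fixture(list(
    P1 = c(600, 610, 570, 564, 630, 620, 704),
    P2 = c(600, 610, 570, 564, 630, 620, 704)
  ))
  d <- network_differences(sm)
  expect_error(fit_standardization(d), "degenerate")
  expect_error(
    fit_standardization(d[d$participant_id == "P1", ]),
    "at least 2 participants"
  )
})

test_that("network mean composites preserve the rank order of the raw RT effects", {
  sc <- score_networks(simulate_cohort(cohort_config(seed = 35)))
  mean_comp <- tapply(sc$composite, sc$network, mean)
  mean_rt <- tapply(sc$rt_diff_ms, sc$network, mean)
  mean_pe <- tapply(sc$pe_diff, sc$network, mean)
  # PE effects are rank-concordant with RT effects here, so composites must be
  expect_equal(order(mean_comp), order(mean_rt))
  expect_equal(order(mean_pe)[3], order(mean_rt)[3])
})

test_that("autoplot returns a ggplot for scores", {
  sc <- score_networks(simulate_cohort(cohort_config(n_per_group = 4, seed = 36)))
  expect_s3_class(ggplot2::autoplot(sc), "ggplot")
})
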