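test_that("Spearman-Brown map fixes 0 and 1 and is monotone", {
  expect_equal(spearman_brown(0), 0)
  expect_equal(spearman_brown(1), 1)
  expect_equal(spearman_brown(0.48), 2 * 0.48 / 1.48) # 0.6486...
  grid <- seq(-0.9, 1, by = 0.01)
  expect_true(all(diff(spearman_brown(grid)) > 0))
})

test_that("split-half estimates are deterministic under a seed", {
  trials <- simulate_cohort(cohort_config(n_per_group = 8, seed = 41))
  a <- split_half_reliability(trials, measure = "rt", n_permutations = 15, seed = 5)
  b <- split_half_reliability(trials, measure = "rt", n_permutations = 15, seed = 5)
  expect_identical(a, b)
  c2 <- split_half_reliability(trials, measure = "rt", n_permutations = 15, seed = 6)
  expect_false(identical(a$mean_corrected_r, c2$mean_corrected_r))
})

test_that("estimates are invariant to participant ordering", {
  trials <- simulate_cohort(cohort_config(n_per_group = 5, seed = 42))
  ids <- unique(trials$participant_id)
  reordered <- purrr::map(
    rev(ids), function(id) trials[trials$participant_id == id, ]
  ) |> purrr::list_rbind()
  a <- split_half_reliability(trials, measure = "rt", n_permutations = 10, seed = 3)
  b <- split_half_reliability(reordered, measure = "rt", n_permutations = 10, seed = 3)
  expect_equal(a, b)
})

test_that("a noiseless cohort with heterogeneous true effects is perfectly reliable", {
  trials <- simulate_cohort(quiet_cohort_config(n_per_group = 6, seed = 43))
  rel <- split_half_reliability(trials, measure = "rt", n_permutations = 10, seed = 1)
  expect_true(all(abs(rel$mean_corrected_r - 1) < 1e-10))
})

test_that("zero between-participant variance drives reliability to zero", {
  cfg <- cohort_config(
    n_per_group = 54, seed = 44,
    sd = list(
      mu_ms = 0, sigma_ms = 0, tau_ms = 0, alert_benefit_ms = 0,
      orient_benefit_ms = 0, flanker_cost_ms = 0, error_logit_base = 0
    )
  )
  rel <- split_half_reliability(
    simulate_cohort(cfg), network = "executive", measure = "rt",
    n_permutations = 60, seed = 2
  )
  expect_lt(abs(rel$mean_corrected_r), 0.35)
})

test_that("stratified splitting balances every design cell across halves", {
  trials <- simulate_cohort(cohort_config(n_per_group = 3, seed = 45))
  prep <- antnets:::reliability_prepare(trials, split = "stratified")
  withr::with_seed(9, {
    half <- antnets:::assign_halves(prep)
  })
  counts <- table(prep$gid, half)
  expect_true(all(abs(counts[, 1] - counts[, 2]) <= 1))
  expect_true(all(counts > 0))
})

test_that("confidence intervals bracket the mean and respond to ci type", {
  trials <- simulate_cohort(cohort_config(n_per_group = 10, seed = 46))
  rel_n <- split_half_reliability(trials, measure = "rt", n_permutations = 40,
    seed = 7
  )
  expect_true(all(rel_n$ci_low <= rel_n$mean_corrected_r))
  expect_true(all(rel_n$ci_high >= rel_n$mean_corrected_r))
  rel_p <- split_half_reliability(trials, measure = "rt", n_permutations = 40,
    seed = 7, ci = "percentile", keep_permutations = TRUE
  )
  expect_equal(rel_p$mean_corrected_r, rel_n$mean_corrected_r)
  expect_true(all(rel_p$ci_high - rel_p$ci_low >= rel_n$ci_high - rel_n$ci_low))
  perms <- attr(rel_p, "permutations")
  expect_equal(nrow(perms), 3 * 40)
})

test_that("single-split values agree with a from-scratch recomputation", {
  trials <- simulate_cohort(cohort_config(n_per_group = 6, seed = 47))
  prep <- antnets:::reliability_prepare(trials, split = "stratified")
  half <- withr::with_seed(11, antnets:::assign_halves(prep))
  flagged <- flag_exclusions(trials)
  kept <- flagged[!flagged$excluded, ]
  kept <- kept[order(
    as.integer(factor(kept$participant_id)),
    (match(kept$cue, ant_cue_levels()) - 1) * 3 +
      match(kept$flanker, ant_flanker_levels())
  ), ]
  kept$half <- half
  # executive RT score per participant per half, the slow way
  slow <- purrr::map(split(kept, kept$participant_id), function(d) {
    score <- function(h) {
      cor_d <- d[d$half == h & d$accuracy, ]
      stats::median(cor_d$rt_ms[cor_d$flanker == "incongruent"]) -
        stats::median(cor_d$rt_ms[cor_d$flanker == "congruent"])
    }
    tibble::tibble(h1 = score(1), h2 = score(2))
  }) |> purrr::list_rbind()
  r <- stats::cor(slow$h1, slow$h2)
  expected <- spearman_brown(r)
  mats <- withr::with_seed(
    11, antnets:::split_half_values(prep, "executive", "rt")
  )
  expect_equal(mats$corrected_r, expected, tolerance = 1e-12)
})
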