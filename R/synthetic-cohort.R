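#' Configure a synthetic ANT cohort
#'
#' Defines the responder model and cohort structure used by
#' [simulate_cohort()]: two groups ("gifted" and "average") of `n_per_group`
#' children, each performing a balanced child-ANT session (default 3 blocks of
#' 96 test trials). Reaction times follow a shifted ex-Gaussian whose location
#' moves with the design cell: any cue removes `alert_benefit_ms`, a spatial
#' cue removes a further `orient_benefit_ms`, and incongruent flankers add
#' `flanker_cost_ms` (neutral trials sit at the congruent baseline). Errors
#' follow a logistic model with an incongruency penalty on the log-odds.
#' Rare contaminants exercise the exclusion rules: anticipations replace the
#' RT by a uniform draw on [80, 199] ms, lapses produce a response timeout
#' (missing RT, scored incorrect).
#'
#' Defaults are calibrated so that a default cohort reproduces the magnitudes
#' typical of child ANT studies this package targets: overall median RT near
#' 635 ms, alerting effect near 30 ms, orienting near 43 ms, executive
#' (conflict) cost near 84 ms in the gifted group and ~10 ms larger in the
#' average group, overall error proportions near 2.5% vs 4.5%, and ~0.7% of
#' trials out of range.
#'
#' @param n_per_group Participants per group (>= 2).
#' @param seed Optional integer seed driving all cohort randomness.
#' @param mu_ms Group-mean ex-Gaussian location of the no-cue congruent cell.
#' @param sigma_ms,tau_ms Group-mean Gaussian SD and exponential tail of the
#'   trial-level RT noise (ms).
#' @param alert_benefit_ms,orient_benefit_ms,flanker_cost_ms Group-mean
#'   condition effects (ms); `flanker_cost_ms` is the gifted-group mean.
#' @param group_effect_flanker_ms Mean flanker-cost difference
#'   (average − gifted), in ms.
#' @param error_logit_base Gifted-group baseline log-odds of an error.
#' @param error_logit_incong Added log-odds of an error on incongruent trials.
#' @param group_effect_error_logit Baseline error log-odds difference
#'   (average − gifted).
#' @param anticipation_rate,lapse_rate Per-trial contamination probabilities.
#' @param sd Named list of between-participant SDs for `mu_ms`, `sigma_ms`,
#'   `tau_ms`, `alert_benefit_ms`, `orient_benefit_ms`, `flanker_cost_ms`,
#'   `error_logit_base`.
#' @param n_blocks,trials_per_block,n_practice Session structure passed to the
#'   schedule generator.
#' @return A list of class `ant_cohort_config`.
#' @seealso [simulate_cohort()], [draw_responders()]
#' @export
cohort_config <- function(n_per_group = 54,
                          seed = NULL,
                          mu_ms = 562,
                          sigma_ms = 90,
                          tau_ms = 90,
                          alert_benefit_ms = 29.8,
                          orient_benefit_ms = 43.1,
                          flanker_cost_ms = 83.7,
                          group_effect_flanker_ms = 10.5,
                          error_logit_base = -4.63,
                          error_logit_incong = 1.35,
                          group_effect_error_logit = 0.62,
                          anticipation_rate = 0.005,
                          lapse_rate = 0.002,
                          sd = list(),
                          n_blocks = 3,
                          trials_per_block = 96,
                          n_practice = 0) {
  if (n_per_group < 2) {
    rlang::abort("`n_per_group` must be at least 2.")
  }
  stopifnot(
    sigma_ms >= 0, tau_ms >= 0,
    anticipation_rate >= 0, anticipation_rate < 1,
    lapse_rate >= 0, lapse_rate < 1
  )
  sd_default <- list(
    mu_ms = 78, sigma_ms = 15, tau_ms = 20,
    alert_benefit_ms = 13, orient_benefit_ms = 5, flanker_cost_ms = 28,
    error_logit_base = 0.8
  )
  unknown <- setdiff(names(sd), names(sd_default))
  if (length(unknown)) {
    rlang::abort(paste0("unknown `sd` fields: ", paste(unknown, collapse = ", ")))
  }
  sd_default[names(sd)] <- sd
  structure(
    list(
      n_per_group = n_per_group, seed = seed,
      mu_ms = mu_ms, sigma_ms = sigma_ms, tau_ms = tau_ms,
      alert_benefit_ms = alert_benefit_ms,
      orient_benefit_ms = orient_benefit_ms,
      flanker_cost_ms = flanker_cost_ms,
      group_effect_flanker_ms = group_effect_flanker_ms,
      error_logit_base = error_logit_base,
      error_logit_incong = error_logit_incong,
      group_effect_error_logit = group_effect_error_logit,
      anticipation_rate = anticipation_rate,
      lapse_rate = lapse_rate,
      sd = sd_default,
      n_blocks = n_blocks, trials_per_block = trials_per_block,
      n_practice = n_practice
    ),
    class = "ant_cohort_config"
  )
}

#' Draw participant-level responder parameters
#'
#' Samples one set of responder parameters per participant from the
#' group-level distributions in `config`: each field is Gaussian around its
#' group mean with the between-participant SD from `config$sd` (dispersion
#' scales truncated at small positive floors). The "average" group's mean
#' flanker cost and baseline error log-odds are shifted by the configured
#' group effects.
#'
#' @param config An [cohort_config()] object.
#' @param seed Optional seed (defaults to a substream of `config$seed`).
#' @return A tibble with one row per participant: `participant_id`, `group`,
#'   `mu_ms`, `sigma_ms`, `tau_ms`, `alert_benefit_ms`, `orient_benefit_ms`,
#'   `flanker_cost_ms`, `error_logit_base`, `error_logit_incong`,
#'   `anticipation_rate`, `lapse_rate`.
#' @export
draw_responders <- function(config, seed = substream_seed(config$seed, "responders")) {
  stopifnot(inherits(config, "ant_cohort_config"))
  n <- 2L * config$n_per_group
  grp <- rep(c("gifted", "average"), each = config$n_per_group)
  run <- function() {
    draw <- function(mean, sd_name, shift = 0) {
      mu <- mean + ifelse(grp == "average", shift, 0)
      stats::rnorm(n, mu, config$sd[[sd_name]])
    }
    tibble::tibble(
      participant_id = sprintf("P%03d", seq_len(n)),
      group = factor(grp, levels = c("gifted", "average")),
      mu_ms = pmax(draw(config$mu_ms, "mu_ms"), 400),
      sigma_ms = pmax(draw(config$sigma_ms, "sigma_ms"), 0),
      tau_ms = pmax(draw(config$tau_ms, "tau_ms"), 0),
      alert_benefit_ms = draw(config$alert_benefit_ms, "alert_benefit_ms"),
      orient_benefit_ms = draw(config$orient_benefit_ms, "orient_benefit_ms"),
      flanker_cost_ms = draw(
        config$flanker_cost_ms, "flanker_cost_ms",
        shift = config$group_effect_flanker_ms
      ),
      error_logit_base = draw(
        config$error_logit_base, "error_logit_base",
        shift = config$group_effect_error_logit
      ),
      error_logit_incong = config$error_logit_incong,
      anticipation_rate = config$anticipation_rate,
      lapse_rate = config$lapse_rate
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# Vectorised responder model: condition-shifted ex-Gaussian RTs, logistic
# errors, anticipation/lapse contamination, 1700 ms response window.
simulate_trials_impl <- function(params_rows, cue, flanker) {
  n <- length(cue)
  timeout <- ant_timeline()$target_timeout_ms
  p <- params_rows # data frame aligned row-wise with trials
  rt <- p$mu_ms -
    p$alert_benefit_ms * (cue != "none") -
    p$orient_benefit_ms * (cue == "spatial") +
    p$flanker_cost_ms * (flanker == "incongruent") +
    stats::rnorm(n, 0, p$sigma_ms) +
    stats::rexp(n, 1 / pmax(p$tau_ms, 1e-9)) * (p$tau_ms > 0)
  rt <- pmax(rt, 80) # physiological floor; anything this fast is excluded anyway
  p_err <- stats::plogis(p$error_logit_base +
    p$error_logit_incong * (flanker == "incongruent"))
  accuracy <- stats::runif(n) >= p_err
  u <- stats::runif(n)
  anticip <- u < p$anticipation_rate
  lapse <- !anticip & u < p$anticipation_rate + p$lapse_rate
  rt[anticip] <- stats::runif(sum(anticip), 80, 199)
  rt[lapse] <- NA_real_
  # no response within the window: timeout, scored incorrect
  slow <- !is.na(rt) & rt > timeout
  rt[slow] <- NA_real_
  accuracy[is.na(rt)] <- FALSE
  list(rt_ms = rt, accuracy = accuracy)
}

#' Simulate a single ANT trial
#'
#' Runs the responder model for one trial specification; mostly useful for
#' inspecting the model (with all noise terms at zero the returned RT equals
#' the deterministic condition-shifted location).
#'
#' @param params A one-row tibble (or named list) of responder parameters, as
#'   produced by [draw_responders()].
#' @param spec A one-row schedule tibble (see [ant_schedule()]).
#' @param seed Optional seed for the trial's random draws.
#' @return A one-row tibble: `cue`, `flanker`, `accuracy`, `rt_ms` (`NA` on a
#'   response timeout).
#' @examples
#' quiet <- tibble::tibble(
#'   mu_ms = 600, sigma_ms = 0, tau_ms = 0, alert_benefit_ms = 30,
#'   orient_benefit_ms = 40, flanker_cost_ms = 90, error_logit_base = -Inf,
#'   error_logit_incong = 0, anticipation_rate = 0, lapse_rate = 0
#' )
#' sched <- ant_schedule(seed = 1)
#' simulate_trial(quiet, sched[30, ], seed = 1)
#' @export
simulate_trial <- function(params, spec, seed = NULL) {
  params <- tibble::as_tibble(params)
  stopifnot(nrow(params) == 1, nrow(spec) == 1)
  run <- function() simulate_trials_impl(params, spec$cue, spec$flanker)
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  tibble::tibble(
    cue = spec$cue, flanker = spec$flanker,
    accuracy = res$accuracy, rt_ms = res$rt_ms
  )
}

#' Simulate a trial-level ANT cohort
#'
#' Generates the full trial table for a two-group cohort under `config`: a
#' balanced schedule is shuffled independently per participant and block, and
#' every trial is run through the responder model. The result conforms to the
#' trial-table dialect consumed by [flag_exclusions()] and [read_trials()].
#'
#' @param config An [cohort_config()] object.
#' @param responders Optional pre-drawn responder tibble (for parameter
#'   recovery studies); defaults to [draw_responders()] under the config seed.
#' @return A tibble with `2 * n_per_group * n_blocks * trials_per_block` test
#'   rows (plus practice rows if requested): `participant_id`, `group`,
#'   `block`, `trial`, `cue`, `flanker`, `target_location`,
#'   `target_direction`, `accuracy`, `rt_ms`.
#' @examples
#' trials <- simulate_cohort(cohort_config(n_per_group = 4, seed = 1))
#' dplyr::count(trials, group)
#' @export
simulate_cohort <- function(config = cohort_config(), responders = NULL) {
  stopifnot(inherits(config, "ant_cohort_config"))
  if (is.null(responders)) {
    responders <- draw_responders(config)
  }
  n_sub <- nrow(responders)
  cells <- ant_design_cells()
  n_cells <- nrow(cells)
  if (config$trials_per_block %% n_cells != 0) {
    rlang::abort(paste0(
      "`trials_per_block` must be a multiple of ", n_cells, "."
    ))
  }
  run <- function() {
    per_block <- config$trials_per_block
    base <- rep(seq_len(n_cells), each = per_block / n_cells)
    n_blocks <- config$n_blocks
    has_practice <- config$n_practice > 0
    practice_base <- rep_len(seq_len(n_cells), config$n_practice)
    one_subject <- function() {
      test <- unlist(lapply(seq_len(n_blocks), function(b) sample(base)),
        use.names = FALSE
      )
      if (has_practice) c(sample(practice_base), test) else test
    }
    idx <- unlist(replicate(n_sub, one_subject(), simplify = FALSE),
      use.names = FALSE
    )
    n_per_sub <- n_blocks * per_block + config$n_practice
    block_seq <- c(
      if (has_practice) rep(0L, config$n_practice),
      rep(seq_len(n_blocks), each = per_block)
    )
    trial_seq <- c(
      if (has_practice) seq_len(config$n_practice),
      rep(seq_len(per_block), times = n_blocks)
    )
    sub_row <- rep(seq_len(n_sub), each = n_per_sub)
    out <- tibble::tibble(
      participant_id = responders$participant_id[sub_row],
      group = responders$group[sub_row],
      block = rep(block_seq, times = n_sub),
      trial = rep(trial_seq, times = n_sub),
      cue = cells$cue[idx],
      flanker = cells$flanker[idx],
      target_location = cells$target_location[idx],
      target_direction = cells$target_direction[idx]
    )
    sim <- simulate_trials_impl(responders[sub_row, ], out$cue, out$flanker)
    out$accuracy <- sim$accuracy
    out$rt_ms <- sim$rt_ms
    out
  }
  seed <- substream_seed(config$seed, "cohort")
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
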