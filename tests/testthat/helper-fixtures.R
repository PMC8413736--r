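# Shared fixtures built in code.

# Responder with every noise source switched off: RTs are exactly the
# condition-shifted location and no errors occur.
quiet_params <- function(mu = 600, alert = 30, orient = 40, flank = 90) {
  tibble::tibble(
    mu_ms = mu, sigma_ms = 0, tau_ms = 0,
    alert_benefit_ms = alert, orient_benefit_ms = orient,
    flanker_cost_ms = flank,
    error_logit_base = -Inf, error_logit_incong = 0,
    anticipation_rate = 0, lapse_rate = 0
  )
}

# Deterministic cohort: heterogeneous true effects, zero trial-level noise.
quiet_cohort_config <- function(n_per_group = 6, seed = 11, ...) {
  cohort_config(
    n_per_group = n_per_group, seed = seed,
    sigma_ms = 0, tau_ms = 0,
    error_logit_base = -30, error_logit_incong = 0,
    anticipation_rate = 0, lapse_rate = 0,
    sd = list(
      sigma_ms = 0, tau_ms = 0, error_logit_base = 0,
      mu_ms = 60, alert_benefit_ms = 10, orient_benefit_ms = 8,
      flanker_cost_ms = 25
    ),
    ...
  )
}

# Minimal hand-built trial table.
toy_trials <- function(rt, accuracy = TRUE, cue = "none", flanker = "neutral",
                       block = 1) {
  n <- max(lengths(list(rt, accuracy, cue, flanker, block)))
  tibble::tibble(
    participant_id = "P001", group = "gifted", block = block,
    trial = seq_len(n), cue = cue, flanker = flanker,
    target_location = "above", target_direction = "left",
    accuracy = accuracy, rt_ms = rt
  )
}

# Long-format toy dataset for the mixed ANOVA, with one subject column.
toy_mixed_data <- function(n_per_group = 4, k = 3, seed = 1, effect = 0) {
  withr::with_seed(seed, {
    d <- expand.grid(
      participant_id = sprintf("s%02d", seq_len(2 * n_per_group)),
      network = letters[seq_len(k)],
      stringsAsFactors = FALSE
    )
    d$group <- ifelse(
      as.integer(factor(d$participant_id)) <= n_per_group, "g1", "g2"
    )
    d$composite <- stats::rnorm(nrow(d)) +
      effect * (d$group == "g2") * (d$network == "c")
    tibble::as_tibble(d)
  })
}

# Independent split-plot oracle via stats::aov error strata.
aov_oracle <- function(d) {
  fit <- stats::aov(
    composite ~ group * network + Error(participant_id / network),
    data = d
  )
  s <- summary(fit)
  between <- s[["Error: participant_id"]][[1]]
  within <- s[["Error: participant_id:network"]][[1]]
  list(
    ss_group = between["group", "Sum Sq"],
    ss_subj = between["Residuals", "Sum Sq"],
    ss_network = within["network", "Sum Sq"],
    ss_inter = within["group:network", "Sum Sq"],
    ss_error = within["Residuals", "Sum Sq"],
    f_group = between["group", "F value"],
    f_network = within["network", "F value"],
    f_inter = within["group:network", "F value"]
  )
}
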