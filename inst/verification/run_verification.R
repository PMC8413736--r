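#!/usr/bin/env Rscript

# Standalone verification run against an external trial-level deposit.
#
# The packaged analyses are validated on synthetic cohorts; this script is the
# clearly separated route for recomputing the complete statistics battery on
# real trial-level data — e.g. the public child-ANT deposit at osf.io/x4bpr —
# once it has been exported to a trial-level CSV and (if needed) mapped onto
# the canonical column names with --map.
#
# Usage:
#   Rscript run_verification.R <trials.csv> <out_dir>
#     [--seed N] [--n-perm N] [--tails one|two]
#     [--map participant_id=subject,rt_ms=rt,...]
#
# Writes every pipeline artifact (exclusion report, condition summaries,
# network scores, split-half reliabilities, ANOVA and contrast tables, plain
# text report) into <out_dir> and prints the report.

suppressMessages(library(antnets))

args <- commandArgs(trailingOnly = TRUE)
positional <- args[!startsWith(args, "--")]
if (length(positional) < 2) {
  stop("usage: Rscript run_verification.R <trials.csv> <out_dir> [options]",
    call. = FALSE
  )
}
opt <- function(name, default) {
  hit <- grep(paste0("^--", name, "="), args, value = TRUE)
  if (length(hit)) sub(paste0("^--", name, "="), "", hit[1]) else default
}

trials_path <- positional[1]
out_dir <- positional[2]
if (!file.exists(trials_path)) {
  stop("trial file not found: ", trials_path, call. = FALSE)
}

map_arg <- opt("map", "")
rename <- character()
if (nzchar(map_arg)) {
  pairs <- strsplit(strsplit(map_arg, ",")[[1]], "=")
  rename <- vapply(pairs, `[`, character(1), 2)
  names(rename) <- vapply(pairs, `[`, character(1), 1)
}

trials <- read_trials(trials_path, trial_dialect(rename = rename))
config <- ant_run_config(
  seed = as.integer(opt("seed", "1")),
  n_permutations = as.integer(opt("n-perm", "1000")),
  tails = opt("tails", "two")
)
results <- run_ant_pipeline(trials, config, out_dir = out_dir)
print(results)
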