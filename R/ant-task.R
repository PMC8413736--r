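#' Condition vocabularies of the Attention Network Test
#'
#' The child ANT crosses four warning-cue conditions with three flanker
#' conditions. Every stage of the pipeline validates condition labels against
#' these vocabularies, so they are exported as the single source of truth.
#'
#' @return A character vector of condition labels, in canonical order.
#' @examples
#' ant_cue_levels()
#' ant_flanker_levels()
#' @export
ant_cue_levels <- function() {
  c("none", "central", "double", "spatial")
}

#' @rdname ant_cue_levels
#' @export
ant_flanker_levels <- function() {
  c("neutral", "congruent", "incongruent")
}

#' Fixed timeline constants of the child ANT trial
#'
#' Durations are in milliseconds unless noted. The response window
#' (`target_timeout_ms`) doubles as the upper reaction-time exclusion bound
#' used by [flag_exclusions()]; the fixation jitter range feeds
#' [ant_schedule()].
#'
#' @return A named list of timeline constants:
#' \describe{
#'   \item{cue_duration_ms}{cue display time (100 ms)}
#'   \item{soa_ms}{cue-to-target stimulus-onset asynchrony (400 ms)}
#'   \item{fixation_range_ms}{uniform jitter range of the fixation cross
#'     (400--1400 ms)}
#'   \item{target_timeout_ms}{maximum response window (1700 ms)}
#'   \item{practice_feedback_ms}{feedback duration on practice trials (500 ms)}
#'   \item{interblock_break_s}{pause between test blocks (5 s)}
#' }
#' @export
ant_timeline <- function() {
  list(
    cue_duration_ms = 100,
    soa_ms = 400,
    fixation_range_ms = c(400, 1400),
    target_timeout_ms = 1700,
    practice_feedback_ms = 500,
    interblock_break_s = 5
  )
}

# One row per design cell: 4 cues x 3 flankers x 2 locations x 2 directions.
ant_design_cells <- function() {
  tidyr::expand_grid(
    cue = ant_cue_levels(),
    flanker = ant_flanker_levels(),
    target_location = c("above", "below"),
    target_direction = c("left", "right")
  )
}

#' Generate a balanced ANT trial schedule
#'
#' Builds a practice block followed by `n_blocks` test blocks. Within each
#' test block every cue x flanker x target-location x target-direction cell
#' occurs equally often and trial order is shuffled independently per block.
#' Fixation durations are drawn uniformly on the jitter range of
#' [ant_timeline()] and rounded to integer milliseconds. Practice trials are
#' flagged (`is_practice`, `block == 0`) and excluded from every analysis
#' stage downstream.
#'
#' @param n_blocks Number of test blocks (default 3).
#' @param trials_per_block Trials per test block; must be a multiple of 48,
#'   the number of design cells (default 96).
#' @param n_practice Number of practice trials (default 24).
#' @param seed Optional integer seed; the same seed reproduces the schedule
#'   exactly.
#' @return A tibble with one row per trial and columns `block` (0 for
#'   practice), `trial` (1-based within block), `cue`, `flanker`,
#'   `target_location`, `target_direction`, `fixation_ms`, `is_practice`.
#' @examples
#' sched <- ant_schedule(seed = 1)
#' nrow(sched)                      # 24 practice + 288 test trials
#' table(sched$cue[!sched$is_practice], sched$flanker[!sched$is_practice])
#' @export
ant_schedule <- function(n_blocks = 3, trials_per_block = 96, n_practice = 24,
                         seed = NULL) {
  cells <- ant_design_cells()
  n_cells <- nrow(cells) # 48
  if (trials_per_block %% n_cells != 0) {
    rlang::abort(paste0(
      "`trials_per_block` must be a multiple of ", n_cells,
      " (4 cues x 3 flankers x 2 target locations x 2 target directions) ",
      "to allow exact per-block cell balance; got ", trials_per_block, "."
    ))
  }
  stopifnot(n_blocks >= 1, n_practice >= 0)
  run <- function() {
    fix_range <- ant_timeline()$fixation_range_ms
    block_cells <- function(n_trials, balanced) {
      if (balanced) {
        idx <- rep(seq_len(n_cells), each = n_trials / n_cells)
      } else {
        idx <- rep_len(seq_len(n_cells), n_trials)
      }
      sample(idx)
    }
    blocks <- c(
      if (n_practice > 0) list(block_cells(n_practice, balanced = FALSE)),
      lapply(seq_len(n_blocks), function(b) block_cells(trials_per_block, TRUE))
    )
    block_id <- if (n_practice > 0) c(0L, seq_len(n_blocks)) else seq_len(n_blocks)
    idx <- unlist(blocks, use.names = FALSE)
    out <- cells[idx, ]
    out$block <- rep.int(block_id, vapply(blocks, length, integer(1)))
    out$trial <- unlist(lapply(blocks, seq_along), use.names = FALSE)
    out$fixation_ms <- round(stats::runif(nrow(out), fix_range[1], fix_range[2]))
    out$is_practice <- out$block == 0L
    dplyr::select(
      out, "block", "trial", "cue", "flanker",
      "target_location", "target_direction", "fixation_ms", "is_practice"
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Read and write ANT schedules as CSV
#'
#' Plain-text round-trip of the schedule produced by [ant_schedule()].
#'
#' @param schedule A schedule tibble.
#' @param path File path.
#' @return `write_schedule()` returns `schedule` invisibly; `read_schedule()`
#'   returns a validated schedule tibble.
#' @export
write_schedule <- function(schedule, path) {
  readr::write_csv(schedule, path)
  invisible(schedule)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    block = readr::col_integer(),
    trial = readr::col_integer(),
    cue = readr::col_character(),
    flanker = readr::col_character(),
    target_location = readr::col_character(),
    target_direction = readr::col_character(),
    fixation_ms = readr::col_double(),
    is_practice = readr::col_logical()
  ))
  bad_cue <- which(!out$cue %in% ant_cue_levels())
  bad_fl <- which(!out$flanker %in% ant_flanker_levels())
  if (length(bad_cue) || length(bad_fl)) {
    rlang::abort(paste0(
      "unknown condition labels in schedule file; rows: ",
      paste(utils::head(sort(c(bad_cue, bad_fl)), 10), collapse = ", ")
    ))
  }
  out
}

# Deterministic sub-seed so that stages driven by one user seed draw from
# independent, individually reproducible streams. Kept below 2^31 - 1.
substream_seed <- function(seed, name) {
  if (is.null(seed)) {
    return(NULL)
  }
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 1009 + h) %% 2147483629)
}
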