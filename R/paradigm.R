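#' Block-design paradigm specification
#'
#' Describes the timing of the block-design experiment: each run presents
#' every expression x condition combination exactly once as a sustained
#' stimulus block, preceded by a fixation cross and followed by a short
#' button task. Defaults reproduce a 4-run design in which each run holds
#' 18 blocks (6 expressions x 3 conditions) of 24 s (12 stimuli of 1.52 s
#' with 0.48 s ISI), 10 s fixation before each block and a 4 s button task
#' after it, at a repetition time of 2 s, for 684 s (11.4 min) per run and
#' 45.6 min in total.
#'
#' @param tr_s Repetition time in seconds.
#' @param fixation_s Fixation duration before every block (including the
#'   first), seconds.
#' @param button_task_s Button-task duration after every block, seconds.
#' @param n_stimuli_per_block Stimuli per block.
#' @param stimulus_dur_s Single-stimulus duration, seconds.
#' @param isi_s Inter-stimulus interval, seconds.
#' @param n_runs Number of runs.
#' @param expressions Ordered expression labels.
#' @param conditions Ordered condition labels.
#' @param discard_initial_volumes Leading volumes dropped from each run
#'   before analysis (T1-equilibration).
#' @return An object of class `paradigm_spec`.
#' @export
#' @examples
#' spec <- paradigm_spec()
#' spec$stimulus_block_s # 24
paradigm_spec <- function(tr_s = 2.0,
                          fixation_s = 10,
                          button_task_s = 4,
                          n_stimuli_per_block = 12,
                          stimulus_dur_s = 1.520,
                          isi_s = 0.480,
                          n_runs = 4,
                          expressions = c("anger", "disgust", "fear",
                                          "joy", "sadness", "surprise"),
                          conditions = c("static", "dynamic", "obscured"),
                          discard_initial_volumes = 5) {
  stopifnot(tr_s > 0, fixation_s > 0, button_task_s > 0,
            stimulus_dur_s > 0, isi_s >= 0,
            n_stimuli_per_block >= 1, n_runs >= 1,
            discard_initial_volumes >= 0)
  if (anyDuplicated(expressions) || anyDuplicated(conditions)) {
    stop("expression and condition labels must be unique")
  }
  spec <- list(
    tr_s = tr_s,
    fixation_s = fixation_s,
    button_task_s = button_task_s,
    n_stimuli_per_block = n_stimuli_per_block,
    stimulus_dur_s = stimulus_dur_s,
    isi_s = isi_s,
    stimulus_block_s = n_stimuli_per_block * (stimulus_dur_s + isi_s),
    n_runs = n_runs,
    expressions = expressions,
    conditions = conditions,
    discard_initial_volumes = discard_initial_volumes
  )
  structure(spec, class = "paradigm_spec")
}

#' @export
print.paradigm_spec <- function(x, ...) {
  cat("<paradigm_spec>\n")
  cat(sprintf("  TR %.3g s | %d expressions x %d conditions | %d runs\n",
              x$tr_s, length(x$expressions), length(x$conditions), x$n_runs))
  cat(sprintf("  block %g s (%d x (%g + %g) s), fixation %g s, button task %g s\n",
              x$stimulus_block_s, x$n_stimuli_per_block, x$stimulus_dur_s,
              x$isi_s, x$fixation_s, x$button_task_s))
  invisible(x)
}

#' Generate a randomized run schedule
#'
#' Draws a pseudo-random order of the expression x condition blocks such
#' that no two consecutive blocks share an expression or a condition, by
#' rejection sampling over permutations (retry-capped). Each block is
#' emitted as a fixation / stimulus-block / button-task event triple.
#'
#' @param spec A [paradigm_spec()].
#' @param run_index Zero-based run index (recorded on the schedule).
#' @param seed Integer seed; schedules are deterministic given it.
#' @param max_tries Rejection-sampling cap before failing.
#' @return A tibble of contiguous events with columns `onset`, `duration`,
#'   `kind` (fixation / stimulus_block / button_task), `expression`,
#'   `condition`, carrying attributes `run_index`, `rng_seed` and `tr_s`.
#' @export
#' @examples
#' sched <- build_run_schedule(paradigm_spec(), run_index = 0, seed = 7)
#' schedule_duration(sched) # 684
build_run_schedule <- function(spec, run_index = 0, seed = 1,
                               max_tries = 10000) {
  stopifnot(inherits(spec, "paradigm_spec"))
  blocks <- expand.grid(condition = spec$conditions,
                        expression = spec$expressions,
                        stringsAsFactors = FALSE)[, c("expression", "condition")]
  n_blocks <- nrow(blocks)
  if (n_blocks == 0) {
    out <- tibble::tibble(onset = numeric(), duration = numeric(),
                          kind = character(), expression = character(),
                          condition = character())
    return(new_run_schedule(out, run_index, seed, spec$tr_s))
  }
  # one try = a random sequential construction: draw each next block
  # uniformly among the remaining blocks that do not repeat the previous
  # expression or condition; a dead end rejects the try
  one_try <- function() {
    remaining <- seq_len(n_blocks)
    out <- integer(n_blocks)
    for (pos in seq_len(n_blocks)) {
      ok <- remaining
      if (pos > 1) {
        prev <- out[pos - 1]
        ok <- remaining[blocks$expression[remaining] != blocks$expression[prev] &
                          blocks$condition[remaining] != blocks$condition[prev]]
      }
      if (length(ok) == 0) return(NULL)
      pick <- if (length(ok) == 1) ok else sample(ok, 1)
      out[pos] <- pick
      remaining <- setdiff(remaining, pick)
    }
    out
  }
  idx <- with_seed(derive_seed(seed, "schedule", run_index), {
    found <- NULL
    for (k in seq_len(max_tries)) {
      cand <- one_try()
      if (!is.null(cand)) {
        found <- cand
        break
      }
    }
    found
  })
  if (is.null(idx)) {
    stop(sprintf(
      "no block order without consecutive repeats found in %d tries; ",
      max_tries),
      "the label sets may make the constraint unsatisfiable")
  }
  per_block <- spec$fixation_s + spec$stimulus_block_s + spec$button_task_s
  onset0 <- (seq_len(n_blocks) - 1) * per_block
  events <- tibble::tibble(
    onset = as.vector(rbind(onset0,
                            onset0 + spec$fixation_s,
                            onset0 + spec$fixation_s + spec$stimulus_block_s)),
    duration = rep(c(spec$fixation_s, spec$stimulus_block_s,
                     spec$button_task_s), n_blocks),
    kind = rep(c("fixation", "stimulus_block", "button_task"), n_blocks),
    expression = as.vector(rbind(NA_character_, blocks$expression[idx],
                                 NA_character_)),
    condition = as.vector(rbind(NA_character_, blocks$condition[idx],
                                NA_character_))
  )
  new_run_schedule(events, run_index, seed, spec$tr_s)
}

#' @keywords internal
#' @noRd
new_run_schedule <- function(events, run_index, seed, tr_s) {
  structure(events,
            run_index = run_index, rng_seed = seed, tr_s = tr_s,
            class = c("run_schedule", class(tibble::tibble())))
}

#' Total duration of a run schedule
#'
#' @param schedule A schedule from [build_run_schedule()].
#' @return Duration in seconds (sum of event durations).
#' @export
schedule_duration <- function(schedule) {
  stopifnot(inherits(schedule, "run_schedule") || is.data.frame(schedule))
  if (nrow(schedule) == 0) return(0)
  sum(schedule$duration)
}

#' Volume-level condition mask for one expression x condition
#'
#' Marks the volumes whose (hemodynamically shifted) acquisition midpoint
#' falls inside a stimulus block of the given expression and condition.
#' Volume `k` (0-based) covers `[k*TR, (k+1)*TR)`; membership is decided by
#' its midpoint shifted back by `hemodynamic_shift_s`, a coarse surrogate
#' for the BOLD delay.
#'
#' @param schedule A run schedule.
#' @param expression,condition Labels; must occur in the schedule.
#' @param tr_s Repetition time, seconds.
#' @param n_volumes Number of volumes covering the schedule.
#' @param hemodynamic_shift_s Forward shift applied to the mask, seconds.
#' @return Integer 0/1 vector of length `n_volumes`.
#' @export
#' @examples
#' sched <- build_run_schedule(paradigm_spec(), 0, seed = 7)
#' sum(condition_boxcar(sched, "anger", "static", 2, 342)) # 12
condition_boxcar <- function(schedule, expression, condition,
                             tr_s = attr(schedule, "tr_s"), n_volumes,
                             hemodynamic_shift_s = 0) {
  blocks <- schedule[schedule$kind == "stimulus_block", , drop = FALSE]
  if (!expression %in% blocks$expression) {
    stop(sprintf("expression '%s' not present in schedule", expression))
  }
  if (!condition %in% blocks$condition) {
    stop(sprintf("condition '%s' not present in schedule", condition))
  }
  hit <- blocks$expression == expression & blocks$condition == condition
  blocks <- blocks[hit, , drop = FALSE]
  mid <- (seq_len(n_volumes) - 0.5) * tr_s - hemodynamic_shift_s
  mask <- integer(n_volumes)
  for (b in seq_len(nrow(blocks))) {
    mask[mid >= blocks$onset[b] & mid < blocks$onset[b] + blocks$duration[b]] <- 1L
  }
  mask
}

#' Write / read a schedule as a BIDS-style events table
#'
#' Tab-separated with columns onset, duration, kind, expression, condition;
#' onsets and durations in seconds with 3 decimals.
#'
#' @param schedule A run schedule.
#' @param path Output file.
#' @return `path`, invisibly (writer); a schedule tibble (reader).
#' @export
write_events <- function(schedule, path) {
  out <- as.data.frame(schedule)
  out$onset <- sprintf("%.3f", out$onset)
  out$duration <- sprintf("%.3f", out$duration)
  out$expression[is.na(out$expression)] <- "n/a"
  out$condition[is.na(out$condition)] <- "n/a"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @param tr_s Repetition time recorded on the returned schedule.
#' @param run_index Run index recorded on the returned schedule.
#' @export
read_events <- function(path, tr_s = 2.0, run_index = 0L) {
  ev <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = "n/a")
  ev$onset <- as.numeric(ev$onset)
  ev$duration <- as.numeric(ev$duration)
  new_run_schedule(tibble::as_tibble(ev), run_index, NA_integer_, tr_s)
}
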