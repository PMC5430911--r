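#' Task configuration for an intention-inference run
#'
#' Describes one run of the two-alternative intention-inference task: an
#' induction phase of fully disclosed action sequences, a testing phase of
#' shortened sequences with a biased intention frequency, and interleaved
#' colour-patch control trials. The four task variants differ only in the
#' labels of the two competing intentions and, for the social task, in the
#' presence of a first actor whose move the second actor tends to mirror
#' (tit-for-tat).
#'
#' @param task_type One of `"basic"`, `"superordinate"`, `"social"`,
#'   `"nonsocial"`. `"basic"` and `"nonsocial"` share the transport/rotate
#'   intention pair; `"superordinate"` uses two cube patterns; `"social"`
#'   uses cooperate/defect.
#' @param n_induction Number of induction-phase trials (fully disclosed
#'   actions at the very-high evidence duration).
#' @param n_testing Number of testing-phase trials; must be divisible by the
#'   number of shortened evidence levels (the first three durations).
#' @param bias Probability of the likely intention in the biased phases,
#'   in (0.5, 1). Realised as an exact integer allocation per evidence level,
#'   not by Bernoulli sampling, so every run has the same likely:unlikely
#'   ratio.
#' @param evidence_levels_ms Strictly increasing action durations (ms) coding
#'   evidence levels 1 (low) to 4 (very high).
#' @param induction_level_ms Action duration used throughout the induction
#'   phase; must equal the highest evidence level.
#' @param tft_prob Social task only: probability that the second actor
#'   mirrors the first actor's move (tit-for-tat bias). Plays the role of
#'   `bias` for the social task.
#' @param n_control Number of colour-patch control trials interleaved at
#'   random positions in the run.
#' @param likely_intention Optional label of the biased intention; by default
#'   it is drawn at random when the run is generated, so that each intention
#'   is equally often the biased one across simulated participants.
#' @param fixation_s,preparation_s,delay_s Length-2 numeric vectors giving
#'   the uniform jitter bounds (seconds) for the fixation, preparation and
#'   pre-response delay periods.
#' @param response_s Response window length in seconds.
#' @param seed Integer seed making the generated run reproducible.
#'
#' @return An object of class `task_config` (a named list).
#' @seealso [generate_run()]
#' @export
#' @examples
#' cfg <- task_config("basic", seed = 1)
#' run <- generate_run(cfg)
#' dplyr::count(run$trials, phase)
task_config <- function(task_type = c("basic", "superordinate", "social", "nonsocial"),
                        n_induction = 36L,
                        n_testing = 108L,
                        bias = 2 / 3,
                        evidence_levels_ms = c(1480, 1560, 1640, 1880),
                        induction_level_ms = 1880,
                        tft_prob = 2 / 3,
                        n_control = 12L,
                        likely_intention = NULL,
                        fixation_s = c(0.5, 2.5),
                        preparation_s = c(1.0, 1.5),
                        delay_s = c(0.5, 1.0),
                        response_s = 1.5,
                        seed = NULL) {
  task_type <- match.arg(task_type)
  stopifnot_scalar_prob(bias, "bias", lo = 0.5, hi = 1, open_lo = TRUE, open_hi = TRUE)
  stopifnot_scalar_prob(tft_prob, "tft_prob")
  if (length(evidence_levels_ms) < 2 || any(diff(evidence_levels_ms) <= 0)) {
    abort("`evidence_levels_ms` must be strictly increasing")
  }
  n_levels_testing <- length(evidence_levels_ms) - 1L
  if (n_testing %% n_levels_testing != 0) {
    abort(sprintf("`n_testing` (%d) must be divisible by the %d shortened evidence levels",
                  n_testing, n_levels_testing))
  }
  if (induction_level_ms != max(evidence_levels_ms)) {
    abort("`induction_level_ms` must equal the highest evidence level")
  }
  for (nm in c("fixation_s", "preparation_s", "delay_s")) {
    b <- get(nm)
    if (length(b) != 2 || any(b <= 0) || b[1] > b[2]) {
      abort(sprintf("`%s` must be positive jitter bounds with lower <= upper", nm))
    }
  }
  if (response_s <= 0) abort("`response_s` must be positive")
  intents <- intention_labels(task_type)
  if (!is.null(likely_intention) && !likely_intention %in% intents) {
    abort(sprintf("`likely_intention` must be one of: %s",
                  paste(intents, collapse = ", ")))
  }
  structure(
    list(
      task_type = task_type,
      intentions = intents,
      n_induction = as.integer(n_induction),
      n_testing = as.integer(n_testing),
      bias = bias,
      evidence_levels_ms = evidence_levels_ms,
      induction_level_ms = induction_level_ms,
      tft_prob = tft_prob,
      n_control = as.integer(n_control),
      likely_intention = likely_intention,
      fixation_s = fixation_s,
      preparation_s = preparation_s,
      delay_s = delay_s,
      response_s = response_s,
      seed = seed
    ),
    class = "task_config"
  )
}

intention_labels <- function(task_type) {
  switch(task_type,
    basic = c("transport", "rotate"),
    nonsocial = c("transport", "rotate"),
    superordinate = c("pattern1", "pattern2"),
    social = c("cooperate", "defect")
  )
}

#' Generate one run of the intention-inference task
#'
#' Lays out an induction phase (all trials at the very-high evidence
#' duration), a testing phase restricted to the three shortened durations
#' with the likely intention allocated exactly `round(bias * n)` times per
#' level, and control trials inserted at random positions. Event onsets are
#' drawn uniformly within the configured jitter windows and trials are
#' scheduled back to back, so trials never overlap.
#'
#' For the social task, each trial's first actor moves at random and the
#' "likely" event is the second actor mirroring that move (tit-for-tat);
#' the recorded intention is the second actor's actual move.
#'
#' @param config A [task_config()].
#' @return An object of class `session_design`: a list with elements
#'   `config`, `trials` (a tibble, one row per trial, with per-event onsets
#'   and durations in seconds), `total_duration_s`, and `seed`.
#' @export
generate_run <- function(config) {
  if (!inherits(config, "task_config")) {
    abort("`config` must be created with task_config()")
  }
  with_seed(config$seed, {
    likely <- config$likely_intention %||% sample(config$intentions, 1L)
    unlikely <- setdiff(config$intentions, likely)

    n_lev <- length(config$evidence_levels_ms)
    testing_levels <- seq_len(n_lev - 1L)
    per_level <- config$n_testing %/% (n_lev - 1L)
    n_likely_per_level <- round(config$bias * per_level)

    make_phase <- function(phase, levels, per_level, n_likely) {
      purrr::map_dfr(levels, function(lv) {
        is_likely <- sample(c(rep(TRUE, n_likely), rep(FALSE, per_level - n_likely)))
        tibble(phase = phase, evidence_level = lv, is_likely = is_likely)
      })
    }

    induction <- make_phase("induction", n_lev, config$n_induction,
                            round(config$bias * config$n_induction))
    testing <- make_phase("testing", testing_levels, per_level, n_likely_per_level)
    # permute trial order within each phase
    induction <- induction[sample(nrow(induction)), ]
    testing <- testing[sample(nrow(testing)), ]
    task_trials <- dplyr::bind_rows(induction, testing)

    if (config$task_type == "social") {
      first <- sample(config$intentions, nrow(task_trials), replace = TRUE)
      # likely = tit-for-tat (second mirrors first); unlikely = anti-mirror
      second <- ifelse(task_trials$is_likely, first,
                       vapply(first, function(m) setdiff(config$intentions, m),
                              character(1)))
      task_trials$first_actor_move <- first
      task_trials$intention <- second
    } else {
      task_trials$first_actor_move <- NA_character_
      task_trials$intention <- ifelse(task_trials$is_likely, likely, unlikely)
    }

    if (config$n_control > 0) {
      control <- tibble(
        phase = "control",
        evidence_level = sample(seq_len(n_lev), config$n_control, replace = TRUE),
        is_likely = NA,
        first_actor_move = NA_character_,
        intention = NA_character_
      )
      pos <- sort(sample(nrow(task_trials) + config$n_control, config$n_control))
      n_total <- nrow(task_trials) + config$n_control
      idx <- integer(n_total)
      idx[pos] <- seq_len(config$n_control) + nrow(task_trials)
      idx[-pos] <- seq_len(nrow(task_trials))
      trials <- dplyr::bind_rows(task_trials, control)[idx, ]
    } else {
      trials <- task_trials
    }

    n <- nrow(trials)
    d_fix <- runif(n, config$fixation_s[1], config$fixation_s[2])
    d_prep <- runif(n, config$preparation_s[1], config$preparation_s[2])
    d_action <- config$evidence_levels_ms[trials$evidence_level] / 1000
    d_delay <- runif(n, config$delay_s[1], config$delay_s[2])
    d_resp <- rep(config$response_s, n)

    trial_len <- d_fix + d_prep + d_action + d_delay + d_resp
    t0 <- cumsum(c(0, trial_len[-n]))

    trials <- trials |>
      dplyr::mutate(
        index = dplyr::row_number(),
        onset_fixation = t0,
        dur_fixation = d_fix,
        onset_preparation = t0 + d_fix,
        dur_preparation = d_prep,
        onset_action = .data$onset_preparation + d_prep,
        dur_action = d_action,
        onset_delay = .data$onset_action + d_action,
        dur_delay = d_delay,
        onset_response = .data$onset_delay + d_delay,
        dur_response = d_resp
      ) |>
      dplyr::select("index", "phase", "intention", "is_likely",
                    "evidence_level", "first_actor_move",
                    dplyr::starts_with("onset_"), dplyr::starts_with("dur_"))

    structure(
      list(
        config = config,
        likely_intention = if (config$task_type == "social") "tit-for-tat" else likely,
        trials = trials,
        total_duration_s = sum(trial_len),
        seed = config$seed
      ),
      class = "session_design"
    )
  })
}

#' @export
print.session_design <- function(x, ...) {
  cat(sprintf("<session_design> task = %s, %d trials (%0.1f s)\n",
              x$config$task_type, nrow(x$trials), x$total_duration_s))
  cat(sprintf("  likely intention: %s\n", x$likely_intention))
  print(dplyr::count(x$trials, .data$phase))
  invisible(x)
}

#' Simulate a tit-for-tat biased response sequence
#'
#' Given the first actor's moves, draws the second actor's moves so that each
#' one independently mirrors the corresponding first move with probability
#' `tft_prob` and takes the opposite move otherwise.
#'
#' @param first_moves Character vector of first-actor moves (two distinct
#'   labels at most).
#' @param tft_prob Mirroring probability in \[0, 1\].
#' @param labels Optional length-2 character vector naming the move alphabet;
#'   defaults to the distinct values of `first_moves`.
#' @param seed Optional integer seed.
#' @return Character vector of second-actor moves, same length as
#'   `first_moves`.
#' @export
#' @examples
#' generate_tft_sequence(c("cooperate", "defect"), tft_prob = 1)
generate_tft_sequence <- function(first_moves, tft_prob, labels = NULL, seed = NULL) {
  stopifnot_scalar_prob(tft_prob, "tft_prob")
  if (length(first_moves) == 0) {
    return(character(0))
  }
  labels <- labels %||% sort(unique(first_moves))
  if (length(labels) > 2) abort("`first_moves` must use at most two labels")
  if (length(labels) == 1) labels <- c(labels, labels)
  if (!all(first_moves %in% labels)) abort("`first_moves` contains labels outside `labels`")
  with_seed(seed, {
    mirror <- runif(length(first_moves)) < tft_prob
    other <- ifelse(first_moves == labels[1], labels[2], labels[1])
    ifelse(mirror, first_moves, other)
  })
}

#' Concatenate per-condition runs into one session
#'
#' Shifts every run's onsets so runs follow each other (separated by
#' `gap_s` seconds) and stacks the trial tables, tagging each row with its
#' run index and task type.
#'
#' @param designs List of `session_design` objects.
#' @param gap_s Gap inserted between consecutive runs (seconds).
#' @return A tibble of trials with additional `run` and `task_type` columns,
#'   onsets expressed in session time.
#' @export
assemble_session <- function(designs, gap_s = 10) {
  if (!length(designs)) abort("`designs` must contain at least one run")
  offset <- 0
  purrr::imap_dfr(designs, function(d, i) {
    if (!inherits(d, "session_design")) abort("all elements must be session_design objects")
    tr <- d$trials |>
      dplyr::mutate(dplyr::across(dplyr::starts_with("onset_"), ~ .x + offset),
                    run = i, task_type = d$config$task_type)
    offset <<- offset + d$total_duration_s + gap_s
    tr
  })
}

`%||%` <- function(x, y) if (is.null(x)) y else x
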