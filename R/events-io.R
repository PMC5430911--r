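#' Write a session design as a BIDS-style events table
#'
#' Unrolls each trial into its five events (fixation, preparation, action,
#' delay, response) and writes a tab-separated events file with `onset` and
#' `duration` in seconds and `n/a` for missing values, the dialect used for
#' `events.tsv` sidecars.
#'
#' @param design A `session_design` from [generate_run()].
#' @param path Output file path.
#' @return The events tibble, invisibly.
#' @seealso [read_events()], [events_table()]
#' @export
export_events <- function(design, path) {
  ev <- events_table(design)
  readr::write_tsv(ev, path, na = "n/a", progress = FALSE)
  invisible(ev)
}

#' Long event table of a session design
#'
#' @param design A `session_design`.
#' @return A tibble with one row per event and columns `onset`, `duration`,
#'   `trial_type` (event name), `trial_index`, `phase`, `intention`,
#'   `is_likely`, `evidence_level`, `first_actor_move`, sorted by onset.
#' @export
events_table <- function(design) {
  tr <- design$trials
  if (nrow(tr) == 0) {
    return(tibble(
      onset = numeric(0), duration = numeric(0), trial_type = character(0),
      trial_index = integer(0), phase = character(0), intention = character(0),
      is_likely = logical(0), evidence_level = integer(0),
      first_actor_move = character(0)
    ))
  }
  tr |>
    tidyr::pivot_longer(
      cols = c(dplyr::starts_with("onset_"), dplyr::starts_with("dur_")),
      names_to = c(".value", "trial_type"),
      names_pattern = "(onset|dur)_(.*)"
    ) |>
    dplyr::transmute(
      onset = .data$onset,
      duration = .data$dur,
      trial_type = .data$trial_type,
      trial_index = .data$index,
      phase = .data$phase,
      intention = .data$intention,
      is_likely = .data$is_likely,
      evidence_level = as.integer(.data$evidence_level),
      first_actor_move = .data$first_actor_move
    ) |>
    dplyr::arrange(.data$onset)
}

#' Read a BIDS-style events table
#'
#' @param path Path to a tab-separated events file written by
#'   [export_events()] (or any events.tsv with the same columns).
#' @return A tibble of events with `n/a` parsed as missing.
#' @export
read_events <- function(path) {
  readr::read_tsv(
    path, na = "n/a", progress = FALSE,
    col_types = readr::cols(
      onset = readr::col_double(),
      duration = readr::col_double(),
      trial_type = readr::col_character(),
      trial_index = readr::col_integer(),
      phase = readr::col_character(),
      intention = readr::col_character(),
      is_likely = readr::col_logical(),
      evidence_level = readr::col_integer(),
      first_actor_move = readr::col_character()
    )
  )
}
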