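#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_col geom_tile
#'   facet_wrap labs theme_minimal autoplot scale_fill_viridis_c
NULL

#' @export
ggplot2::autoplot

#' Plot prior-effect scores across evidence levels
#'
#' Line plot of the prior effect (percentage-point accuracy advantage for
#' the likely intention) as a function of evidence level, one line per
#' condition when present. Under a negative prior-by-evidence interaction
#' the line decreases from low to very high evidence.
#'
#' @param table A `prior_effect_table` from [prior_effect()], or any data
#'   frame with `evidence_level` and `prior_effect` columns (optionally a
#'   condition column).
#' @param condition Optional name of the condition column used for colour.
#' @return A ggplot object.
#' @export
plot_prior_effect <- function(table, condition = NULL) {
  ev <- names(table)[1]
  if (!is.null(condition)) {
    p <- ggplot(table, aes(x = .data$evidence_level, y = .data$prior_effect,
                           colour = .data[[condition]],
                           group = .data[[condition]]))
  } else {
    ev <- setdiff(names(table), c("n_likely", "n_unlikely",
                                  "pct_correct_likely", "pct_correct_unlikely",
                                  "prior_effect", "missing_cell"))[1]
    p <- ggplot(table, aes(x = .data[[ev]], y = .data$prior_effect, group = 1))
  }
  p + geom_line() + geom_point() +
    labs(x = "visuomotor evidence level", y = "prior effect (% points)") +
    theme_minimal()
}

#' @export
autoplot.prior_trace <- function(object, ...) {
  intentions <- attr(object, "intentions")
  long <- tidyr::pivot_longer(object, dplyr::all_of(intentions),
                              names_to = "intention", values_to = "prob")
  ggplot(long, aes(x = .data$trial, y = .data$prob,
                   colour = .data$intention)) +
    geom_line() +
    labs(x = "trial", y = "observer prior probability") +
    theme_minimal()
}

#' @export
autoplot.design_matrix <- function(object, task_only = TRUE, ...) {
  X <- object$X
  if (task_only) X <- X[, object$task_cols, drop = FALSE]
  Xs <- apply(X, 2, function(col) {
    r <- range(col)
    if (diff(r) == 0) col else (col - r[1]) / diff(r)
  })
  d <- as.data.frame(Xs)
  d$volume <- seq_len(nrow(d))
  long <- tidyr::pivot_longer(d, -"volume",
                              names_to = "regressor", values_to = "value")
  long$regressor <- factor(long$regressor, levels = colnames(X))
  ggplot(long, aes(x = .data$regressor, y = .data$volume,
                   fill = .data$value)) +
    geom_tile() +
    scale_fill_viridis_c() +
    ggplot2::scale_y_reverse() +
    labs(x = NULL, y = "volume", fill = "scaled\namplitude") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @export
autoplot.hrf_kernel <- function(object, ...) {
  ggplot(object, aes(x = .data$time, y = .data$value)) +
    geom_line() +
    labs(x = "time (s)", y = "response (peak-normalized)") +
    theme_minimal()
}

#' @export
autoplot.bms_result <- function(object, level = c("model", "family"), ...) {
  level <- match.arg(level)
  tab <- tidy(object, level = level)
  xcol <- names(tab)[1]
  ggplot(tab, aes(x = factor(.data[[xcol]], levels = .data[[xcol]]),
                  y = .data$ep)) +
    geom_col() +
    labs(x = level, y = "exceedance probability") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
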