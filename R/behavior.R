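#' Prior-effect score per evidence level
#'
#' The prior effect at a given evidence level is the percentage of correct
#' responses on likely-intention trials minus the percentage on
#' unlikely-intention trials: positive values mean responses are pulled
#' toward the biased (likely) intention. With a negative prior-by-evidence
#' interaction the score is largest at the lowest evidence level.
#'
#' @param trials Data frame with one row per trial, containing logical
#'   `is_likely`, the evidence level, a 0/1 `correct` column, and optionally
#'   a condition column for grouped output.
#' @param evidence,correct,is_likely,condition Column names (strings);
#'   `condition = NULL` for a single-condition table.
#' @return A tibble of class `prior_effect_table`: one row per (condition x)
#'   evidence level with `pct_correct_likely`, `pct_correct_unlikely`,
#'   `prior_effect` (percentage points), trial counts, and a `missing_cell`
#'   flag where either bias class has no trials.
#' @export
#' @examples
#' d <- tibble::tibble(
#'   evidence_level = rep(1:2, each = 8),
#'   is_likely = rep(c(TRUE, FALSE), 8),
#'   correct = c(rep(1, 8), rep(0:1, 4))
#' )
#' prior_effect(d)
prior_effect <- function(trials, evidence = "evidence_level",
                         correct = "correct", is_likely = "is_likely",
                         condition = NULL) {
  needed <- c(evidence, correct, is_likely, condition)
  for (nm in needed) {
    if (!nm %in% names(trials)) abort(sprintf("column `%s` not found", nm))
  }
  grp <- c(condition, evidence)
  out <- trials |>
    dplyr::filter(!is.na(.data[[is_likely]])) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      n_likely = sum(.data[[is_likely]]),
      n_unlikely = sum(!.data[[is_likely]]),
      pct_correct_likely =
        100 * mean(.data[[correct]][.data[[is_likely]]]),
      pct_correct_unlikely =
        100 * mean(.data[[correct]][!.data[[is_likely]]]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      prior_effect = .data$pct_correct_likely - .data$pct_correct_unlikely,
      missing_cell = .data$n_likely == 0 | .data$n_unlikely == 0
    )
  class(out) <- c("prior_effect_table", class(out))
  out
}

#' Two-factor repeated-measures ANOVA
#'
#' Classical within-subjects two-way ANOVA on a complete balanced design:
#' each effect (A, B, A:B) is tested against its own subject-interaction
#' error stratum, and partial eta squared is
#' `SS_effect / (SS_effect + SS_error)`. Typical uses here: prior (likely vs
#' unlikely) x evidence level on percent correct, or evidence x intention
#' type on the prior-effect score.
#'
#' @param data Long data frame, one row per subject x cell.
#' @param subject,a,b,value Column names (strings) of the subject identifier,
#'   the two within-subject factors, and the response.
#' @return An object of class `rm_anova` whose `table` is a tibble with one
#'   row per effect: `effect`, `df1`, `df2`, `ss_effect`, `ss_error`,
#'   `statistic` (F), `p.value`, `pes` (partial eta squared).
#' @export
rm_anova_2x <- function(data, subject = "subject", a = "A", b = "B",
                        value = "score") {
  for (nm in c(subject, a, b, value)) {
    if (!nm %in% names(data)) abort(sprintf("column `%s` not found", nm))
  }
  d <- tibble(
    subject = factor(data[[subject]]),
    A = factor(data[[a]]),
    B = factor(data[[b]]),
    y = as.numeric(data[[value]])
  )
  ns <- nlevels(d$subject)
  na <- nlevels(d$A)
  nb <- nlevels(d$B)
  if (ns < 2) abort("need at least two subjects")
  counts <- dplyr::count(d, .data$subject, .data$A, .data$B)
  if (nrow(counts) != ns * na * nb || any(counts$n != 1)) {
    abort("design must be complete and balanced: one observation per subject x A x B cell")
  }

  fit <- stats::aov(y ~ A * B + Error(subject / (A * B)), data = d)
  sm <- summary(fit)
  pull_stratum <- function(name, effect) {
    tab <- sm[[paste0("Error: ", name)]][[1]]
    rn <- trimws(rownames(tab))
    i <- match(effect, rn)
    j <- match("Residuals", rn)
    ss_e <- tab[i, "Sum Sq"]
    ss_r <- tab[j, "Sum Sq"]
    fval <- tab[i, "F value"]
    pval <- tab[i, "Pr(>F)"]
    if (ss_e < 1e-24) {
      # no effect variance at all: F degenerates to 0, not 0/0
      fval <- 0
      pval <- 1
    }
    tibble(
      effect = effect,
      df1 = tab[i, "Df"], df2 = tab[j, "Df"],
      ss_effect = ss_e, ss_error = ss_r,
      statistic = fval, p.value = pval,
      pes = if (ss_e + ss_r < 1e-24) 0 else ss_e / (ss_e + ss_r)
    )
  }
  tab <- dplyr::bind_rows(
    pull_stratum("subject:A", "A"),
    pull_stratum("subject:B", "B"),
    pull_stratum("subject:A:B", "A:B")
  )
  structure(list(table = tab, n_subjects = ns, levels_a = na, levels_b = nb),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("<rm_anova> %d subjects, %d x %d within-subject design\n",
              x$n_subjects, x$levels_a, x$levels_b))
  print(x$table)
  invisible(x)
}

#' @method tidy rm_anova
#' @export
tidy.rm_anova <- function(x, ...) x$table

#' @method glance rm_anova
#' @export
glance.rm_anova <- function(x, ...) {
  tibble(n_subjects = x$n_subjects, levels_a = x$levels_a, levels_b = x$levels_b)
}

#' Uncorrected pairwise paired comparisons (Fisher-LSD style)
#'
#' Paired t-tests between levels of one factor within each level of the
#' other, without multiple-comparison correction, as a post-hoc follow-up to
#' [rm_anova_2x()].
#'
#' @inheritParams rm_anova_2x
#' @param within Which factor defines the strata: `"b"` (default) compares
#'   levels of A within each level of B, `"a"` the converse.
#' @return Tibble with one row per stratum and level pair.
#' @export
posthoc_pairwise <- function(data, subject = "subject", a = "A", b = "B",
                             value = "score", within = c("b", "a")) {
  within <- match.arg(within)
  comp <- if (within == "b") a else b
  strat <- if (within == "b") b else a
  d <- tibble(
    subject = factor(data[[subject]]),
    comp = factor(data[[comp]]),
    strat = factor(data[[strat]]),
    y = as.numeric(data[[value]])
  )
  pairs <- utils::combn(levels(d$comp), 2, simplify = FALSE)
  purrr::map_dfr(levels(d$strat), function(s) {
    purrr::map_dfr(pairs, function(pr) {
      d1 <- d[d$strat == s & d$comp == pr[1], ]
      d2 <- d[d$strat == s & d$comp == pr[2], ]
      d1 <- d1[order(d1$subject), ]
      d2 <- d2[order(d2$subject), ]
      tt <- stats::t.test(d1$y, d2$y, paired = TRUE)
      tibble(stratum = s, level1 = pr[1], level2 = pr[2],
             mean_diff = unname(tt$estimate), statistic = unname(tt$statistic),
             df = unname(tt$parameter), p.value = tt$p.value)
    })
  })
}

#' Pearson correlation between per-subject estimates
#'
#' Used to relate behavioural and neural estimates of the same effect across
#' subjects (e.g. the prior-by-evidence interaction coefficient from the
#' choice model vs. the matching parametric GLM beta).
#'
#' @param x,y Numeric vectors of per-subject estimates, length >= 3.
#' @return Tibble with `r`, `statistic` (t), `df`, `p.value`, `n`, and a
#'   `degenerate` flag raised when either input has zero variance (then `r`
#'   is `NA`).
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal lengths")
  if (length(x) < 3) abort("need at least 3 pairs")
  if (any(!is.finite(x)) || any(!is.finite(y))) abort("inputs must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warn("zero variance: correlation undefined")
    return(tibble(r = NA_real_, statistic = NA_real_, df = length(x) - 2L,
                  p.value = NA_real_, n = length(x), degenerate = TRUE))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble(r = unname(ct$estimate), statistic = unname(ct$statistic),
         df = unname(ct$parameter), p.value = ct$p.value,
         n = length(x), degenerate = FALSE)
}
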