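#' Configuration of the memory-decay Bayesian observer
#'
#' The observer tracks, trial by trial, the probability of each candidate
#' intention from the history of enacted intentions. Each past event at lag
#' `p` contributes a weight `alpha^-p` to its intention's count; with
#' `alpha = 1` every past event counts equally (lossless ideal observer),
#' while `alpha > 1` discounts older events, emulating limited memory. A
#' pseudo-count (`smoothing`) is added to every intention so probabilities
#' stay strictly inside (0, 1) and the first trial starts from a flat prior.
#'
#' @param alpha Decay parameter, a scalar `>= 1`, or a vector with one value
#'   per intention for per-intention decay.
#' @param smoothing Pseudo-count added to each intention's weighted count
#'   (default 1, i.e. Laplace smoothing).
#' @return An object of class `observer_config`.
#' @export
observer_config <- function(alpha = 1, smoothing = 1) {
  if (!is.numeric(alpha) || any(!is.finite(alpha)) || any(alpha < 1)) {
    abort("`alpha` must be finite and >= 1 (1 = ideal observer)")
  }
  if (!is.numeric(smoothing) || length(smoothing) != 1 || smoothing <= 0) {
    abort("`smoothing` must be a single positive number")
  }
  structure(list(alpha = alpha, smoothing = smoothing),
            class = "observer_config")
}

#' Trial-by-trial prior probabilities of a memory-decay observer
#'
#' For each trial `t` the observer's estimate of intention `i`, formed
#' *before* observing trial `t`, is
#' \deqn{prob(e_t = i) = \frac{w_i + s}{\sum_j (w_j + s)}, \qquad
#'       w_i = \sum_{p=1}^{t-1} \alpha^{-p}\, [e_{t-p} = i],}
#' where `p` counts lags backwards from `t` (`p = 1` is the most recent
#' event) and `s` is the smoothing pseudo-count. The first row is the flat
#' prior. When a `context` vector is supplied (e.g. the first actor's move in
#' the social task) counts are accumulated separately per context, and each
#' trial's row is the estimate under that trial's context.
#'
#' @param events Character (or factor) vector of enacted intention labels in
#'   chronological order.
#' @param config An [observer_config()].
#' @param intentions Optional character vector fixing the intention alphabet
#'   (and column order); defaults to the sorted distinct values of `events`.
#' @param context Optional vector, same length as `events`, conditioning the
#'   counts (separate event histories per context value).
#' @return A tibble of class `prior_trace` with columns `trial`, one
#'   probability column per intention, and `p_event`, the probability the
#'   observer assigned to the intention actually enacted on that trial.
#' @export
#' @examples
#' prior_trace(c("A", "A", "B"), observer_config(alpha = 2))
prior_trace <- function(events, config = observer_config(),
                        intentions = NULL, context = NULL) {
  if (!inherits(config, "observer_config")) {
    abort("`config` must be created with observer_config()")
  }
  events <- as.character(events)
  intentions <- intentions %||% sort(unique(events))
  k <- length(intentions)
  if (k < 2) abort("need at least two intentions")
  bad <- setdiff(events, intentions)
  if (length(bad)) {
    abort(sprintf("unknown intention label(s): %s", paste(bad, collapse = ", ")))
  }
  alpha <- config$alpha
  if (length(alpha) == 1) alpha <- rep(alpha, k)
  if (length(alpha) != k) abort("`alpha` must be scalar or one value per intention")
  s <- config$smoothing
  n <- length(events)
  if (!is.null(context)) {
    if (length(context) != n) abort("`context` must match `events` in length")
    ctx <- as.character(context)
  } else {
    ctx <- rep("all", n)
  }

  # weighted counts via the recursion w(t+1) = (w(t) + 1[e_t = i]) / alpha_i,
  # evaluated independently within each conditioning context
  ev_idx <- match(events, intentions)
  W <- matrix(0, n, k, dimnames = list(NULL, intentions))
  for (g in unique(ctx)) {
    idx <- which(ctx == g)
    for (i in seq_len(k)) {
      x <- as.numeric(ev_idx[idx] == i)
      w_after <- as.numeric(stats::filter(x / alpha[i], 1 / alpha[i],
                                          method = "recursive"))
      W[idx, i] <- c(0, w_after[-length(w_after)])
    }
  }
  probs <- (W + s) / rowSums(W + s)

  out <- as_tibble(probs)
  out <- dplyr::mutate(out,
                       trial = seq_len(n),
                       p_event = probs[cbind(seq_len(n), ev_idx)],
                       .before = 1)
  class(out) <- c("prior_trace", class(out))
  attr(out, "intentions") <- intentions
  attr(out, "alpha") <- config$alpha
  attr(out, "smoothing") <- s
  out
}

#' Fit the memory-decay parameter jointly with the choice model
#'
#' For each candidate decay value, recomputes the observer's prior trace,
#' refits the logistic prior-by-evidence choice model on standardized
#' predictors, and scores the candidate by the sum of squared residuals
#' between the observed correct responses and the model's fitted
#' probabilities (a Brier-type least-squares criterion). The grid minimum
#' (ties broken toward the smaller decay) is then refined by golden-section
#' search within its bracketing grid interval.
#'
#' @param events Chronological intention labels (the enacted intentions).
#' @param evidence Per-trial ordinal evidence level (e.g. 1--4).
#' @param correct Per-trial binary correct-response indicator.
#' @param grid Candidate decay values, all `>= 1`.
#' @param context Optional conditioning vector passed to [prior_trace()].
#' @param smoothing Pseudo-count for the observer (see [observer_config()]).
#' @param refine Logical: refine the grid minimum by golden-section search
#'   (tolerance `1e-3`)? Skipped for singleton grids.
#' @return An object of class `observer_fit`: a list with `alpha_hat`, the
#'   `objective_curve` tibble (alpha, objective), `betas` (the
#'   [fit_choice_model()] result at `alpha_hat`), and `separation`.
#' @export
fit_alpha <- function(events, evidence, correct,
                      grid = seq(1, 3, by = 0.05),
                      context = NULL, smoothing = 1, refine = TRUE) {
  if (!length(grid)) abort("`grid` must contain at least one alpha value")
  if (any(grid < 1)) abort("all `grid` values must be >= 1")
  n <- length(events)
  if (length(evidence) != n || length(correct) != n) {
    abort("`events`, `evidence` and `correct` must have equal lengths")
  }
  grid <- sort(grid)
  intentions <- sort(unique(as.character(events)))

  objective <- function(a) {
    tr <- prior_trace(events, observer_config(alpha = a, smoothing = smoothing),
                      intentions = intentions, context = context)
    fit <- fit_choice_model(tibble(prior = tr$p_event,
                                   evidence = evidence,
                                   correct = correct))
    sum((correct - fit$fitted)^2)
  }

  obj <- vapply(grid, objective, numeric(1))
  i <- which.min(obj) # which.min already takes the first (smallest alpha) tie
  alpha_hat <- grid[i]
  best <- obj[i]
  if (refine && length(grid) > 1) {
    lo <- grid[max(1, i - 1)]
    hi <- grid[min(length(grid), i + 1)]
    if (hi > lo) {
      opt <- optimize(objective, lower = lo, upper = hi, tol = 1e-3)
      if (opt$objective < best) {
        alpha_hat <- opt$minimum
        best <- opt$objective
      }
    }
  }

  tr <- prior_trace(events, observer_config(alpha = alpha_hat, smoothing = smoothing),
                    intentions = intentions, context = context)
  betas <- fit_choice_model(tibble(prior = tr$p_event,
                                   evidence = evidence,
                                   correct = correct))
  structure(
    list(
      alpha_hat = alpha_hat,
      objective = best,
      objective_curve = tibble(alpha = grid, objective = obj),
      betas = betas,
      prior_trace = tr,
      separation = betas$separation
    ),
    class = "observer_fit"
  )
}

#' @export
print.observer_fit <- function(x, ...) {
  cat(sprintf("<observer_fit> alpha_hat = %.4f (objective = %.4f)\n",
              x$alpha_hat, x$objective))
  if (x$separation) cat("  warning: separation detected; coefficients unreliable\n")
  print(tidy(x$betas))
  invisible(x)
}

#' @method tidy observer_fit
#' @export
tidy.observer_fit <- function(x, ...) {
  dplyr::mutate(tidy(x$betas), alpha_hat = x$alpha_hat)
}

#' @method glance observer_fit
#' @export
glance.observer_fit <- function(x, ...) {
  tibble(alpha_hat = x$alpha_hat, objective = x$objective,
         n_grid = nrow(x$objective_curve), separation = x$separation)
}
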