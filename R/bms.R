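#' Random-effects Bayesian model selection (exceedance probabilities)
#'
#' Treats the model identity as a random effect across subjects: model
#' frequencies `r` get a Dirichlet prior (unit concentration per model), the
#' posterior concentration is estimated by the standard variational scheme
#' (iterating subject-wise posterior model assignments against the Dirichlet
#' parameters), and the exceedance probability of model `k` — the posterior
#' probability that `r_k` exceeds every other frequency — is computed by
#' Monte-Carlo sampling from the fitted Dirichlet.
#'
#' When `grouping` assigns models to families, family-level evidences are
#' formed per subject by log-sum-exp aggregation over the family's models
#' minus the log family size (a uniform within-family prior), and the same
#' machinery is run on the aggregated evidences.
#'
#' @param log_evidence Matrix subjects x models of log model evidences;
#'   `-Inf` marks an excluded (failed) fit. Column names label the models.
#' @param grouping Optional vector (length = models) of family labels.
#' @param n_samples Monte-Carlo sample count for the exceedance computation
#'   (>= 1e4).
#' @param seed Integer seed for the Monte-Carlo step.
#' @param prior_alpha Dirichlet prior concentration per model (default 1).
#' @return Object of class `bms_result` with tibbles `models` and (when
#'   grouped) `families`, each holding the Dirichlet concentration `alpha`,
#'   the expected posterior frequency `expected_prob`, and the exceedance
#'   probability `ep`.
#' @export
bms_exceedance <- function(log_evidence, grouping = NULL, n_samples = 1e4,
                           seed = NULL, prior_alpha = 1) {
  L <- as.matrix(log_evidence)
  if (n_samples < 1e4) abort("`n_samples` must be at least 1e4")
  if (any(is.na(L)) || any(L == Inf)) abort("log evidences must be finite or -Inf")
  models <- colnames(L) %||% paste0("m", seq_len(ncol(L)))
  colnames(L) <- models
  if (ncol(L) == 1) {
    warn("single model: exceedance probability is trivially 1")
    return(structure(
      list(models = tibble(model = models, alpha = prior_alpha + nrow(L),
                           expected_prob = 1, ep = 1),
           families = NULL, n_samples = n_samples, seed = seed),
      class = "bms_result"
    ))
  }

  fit <- bms_dirichlet(L, prior_alpha)
  ep <- dirichlet_exceedance(fit$alpha, n_samples, seed)
  models_tab <- tibble(
    model = models,
    alpha = fit$alpha,
    expected_prob = fit$alpha / sum(fit$alpha),
    ep = ep
  )

  families_tab <- NULL
  if (!is.null(grouping)) {
    if (length(grouping) != ncol(L)) {
      abort("`grouping` must assign a family to every model")
    }
    fams <- unique(grouping)
    Lf <- vapply(fams, function(f) {
      cols <- which(grouping == f)
      apply(L[, cols, drop = FALSE], 1, logsumexp) - log(length(cols))
    }, numeric(nrow(L)))
    Lf <- matrix(Lf, nrow = nrow(L), dimnames = list(NULL, as.character(fams)))
    ffit <- bms_dirichlet(Lf, prior_alpha)
    fep <- dirichlet_exceedance(ffit$alpha, n_samples, seed)
    families_tab <- tibble(
      family = fams,
      alpha = ffit$alpha,
      expected_prob = ffit$alpha / sum(ffit$alpha),
      ep = fep
    )
  }

  structure(
    list(models = models_tab, families = families_tab,
         n_samples = n_samples, seed = seed),
    class = "bms_result"
  )
}

# variational Dirichlet update for random-effects model selection
bms_dirichlet <- function(L, prior_alpha = 1, max_iter = 200, tol = 1e-8) {
  k <- ncol(L)
  alpha <- rep(prior_alpha, k)
  for (it in seq_len(max_iter)) {
    lg <- sweep(L, 2, digamma(alpha) - digamma(sum(alpha)), "+")
    g <- t(apply(lg, 1, function(row) {
      w <- exp(row - logsumexp(row))
      if (!any(is.finite(w)) || sum(w) == 0) rep(1 / k, k) else w / sum(w)
    }))
    alpha_new <- prior_alpha + colSums(g)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }
  list(alpha = alpha, assignments = g)
}

# Monte-Carlo exceedance probabilities of a Dirichlet distribution
dirichlet_exceedance <- function(alpha, n_samples, seed = NULL) {
  k <- length(alpha)
  with_seed(seed, {
    draws <- matrix(rgamma(n_samples * k, shape = rep(alpha, each = n_samples)),
                    nrow = n_samples)
    wins <- max.col(draws, ties.method = "random")
    tabulate(wins, nbins = k) / n_samples
  })
}

#' @export
print.bms_result <- function(x, ...) {
  cat(sprintf("<bms_result> %d models, %d Monte-Carlo samples\n",
              nrow(x$models), x$n_samples))
  print(dplyr::arrange(x$models, dplyr::desc(.data$ep)))
  if (!is.null(x$families)) {
    cat("family level:\n")
    print(dplyr::arrange(x$families, dplyr::desc(.data$ep)))
  }
  invisible(x)
}

#' @method tidy bms_result
#' @export
tidy.bms_result <- function(x, level = c("model", "family"), ...) {
  level <- match.arg(level)
  if (level == "family") {
    if (is.null(x$families)) abort("no family grouping was supplied")
    x$families
  } else {
    x$models
  }
}

#' @method glance bms_result
#' @export
glance.bms_result <- function(x, ...) {
  tibble(n_models = nrow(x$models),
         n_families = if (is.null(x$families)) NA_integer_ else nrow(x$families),
         n_samples = x$n_samples)
}
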