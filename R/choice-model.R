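#' Logistic prior-by-evidence choice model
#'
#' Fits, by maximum likelihood, the logistic model
#' \deqn{\mathrm{logit}\, P(CR_t = 1) = \beta_0 + \beta_{prior} z(prior_t) +
#'       \beta_{evidence} z(evid_t) +
#'       \beta_{prior \times evidence}\, z(prior_t)\, z(evid_t),}
#' where `z()` denotes z-scoring within the supplied data and the
#' interaction is the product of the two standardized predictors, so the
#' coefficients are comparable across subjects and conditions. A negative
#' interaction coefficient means reliance on the prior grows as evidence
#' shrinks.
#'
#' If the likelihood degenerates (perfect separation, e.g. all responses
#' correct), the fit is re-run as ridge-penalized IRLS (penalty `1e-4` on the
#' slopes) and flagged; the flagged coefficients should be treated as
#' unreliable.
#'
#' @param data Data frame with one row per trial.
#' @param prior,evidence,correct Names (strings) of the columns holding the
#'   observer's prior probability of the enacted intention, the ordinal
#'   evidence level, and the 0/1 correct-response indicator.
#' @return An object of class `behavioral_fit` with elements `coefficients`
#'   (named: beta0, beta_prior, beta_evidence, beta_interaction), `se`,
#'   `fitted`, `separation`, `converged`, `n`. Supports [generics::tidy()]
#'   and [generics::glance()].
#' @export
#' @examples
#' d <- tibble::tibble(prior = runif(200), evidence = sample(1:4, 200, TRUE))
#' d$correct <- rbinom(200, 1, plogis(scale(d$prior) + scale(d$evidence)))
#' tidy(fit_choice_model(d))
fit_choice_model <- function(data, prior = "prior", evidence = "evidence",
                             correct = "correct") {
  for (nm in c(prior, evidence, correct)) {
    if (!nm %in% names(data)) abort(sprintf("column `%s` not found in `data`", nm))
  }
  p <- data[[prior]]
  e <- data[[evidence]]
  y <- as.numeric(data[[correct]])
  n <- length(y)
  if (n < 10) abort("need at least 10 trials")
  if (!all(y %in% c(0, 1))) abort("`correct` must be binary 0/1")
  if (length(unique(e)) < 2) abort("`evidence` must take at least 2 distinct levels")
  if (stats::sd(p) == 0) abort("`prior` is constant; cannot standardize")

  zp <- zscore(p)
  ze <- zscore(e)
  X <- cbind(`(Intercept)` = 1, zp = zp, ze = ze, zpe = zp * ze)

  separation <- FALSE
  fit <- withCallingHandlers(
    glm.fit(X, y, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (length(unique(y)) == 1 || any(abs(coef(fit)) > 15)) separation <- TRUE

  if (separation) {
    rf <- irls_ridge(X, y, lambda = 1e-4)
    beta <- rf$beta
    se <- rf$se
    fitted_p <- rf$fitted
    converged <- rf$converged
    warn("perfect separation detected; returning ridge-penalized coefficients")
  } else {
    beta <- coef(fit)
    eta <- drop(X %*% beta)
    fitted_p <- plogis(eta)
    w <- fitted_p * (1 - fitted_p)
    info <- crossprod(X, X * w)
    se <- sqrt(diag(solve(info)))
    converged <- fit$converged
  }

  names(beta) <- names(se) <- c("beta0", "beta_prior", "beta_evidence",
                                "beta_interaction")
  structure(
    list(coefficients = beta, se = se, fitted = fitted_p,
         separation = separation, converged = converged, n = n),
    class = "behavioral_fit"
  )
}

# ridge-penalized logistic IRLS; the intercept is not penalized
irls_ridge <- function(X, y, lambda = 1e-4, max_iter = 100, tol = 1e-10) {
  k <- ncol(X)
  pen <- diag(c(0, rep(lambda, k - 1)))
  beta <- rep(0, k)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    H <- crossprod(X, X * w) + pen
    beta_new <- drop(solve(H, crossprod(X, w * z)))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
  }
  mu <- plogis(drop(X %*% beta))
  H <- crossprod(X, X * pmax(mu * (1 - mu), 1e-10)) + pen
  list(beta = beta, se = sqrt(diag(solve(H))), fitted = mu,
       converged = converged)
}

#' @export
print.behavioral_fit <- function(x, ...) {
  cat(sprintf("<behavioral_fit> n = %d%s\n", x$n,
              if (x$separation) " (separation!)" else ""))
  print(tidy(x))
  invisible(x)
}

#' @method tidy behavioral_fit
#' @export
tidy.behavioral_fit <- function(x, ...) {
  est <- x$coefficients
  se <- x$se
  z <- est / se
  tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(z),
    p.value = 2 * stats::pnorm(-abs(unname(z)))
  )
}

#' @method glance behavioral_fit
#' @export
glance.behavioral_fit <- function(x, ...) {
  tibble(n = x$n, separation = x$separation, converged = x$converged)
}
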