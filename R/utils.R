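#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats plogis qlogis rnorm runif rbinom sd coef glm.fit binomial
#'   pf pt optimize rgamma convolve setNames
#' @importFrom Rcpp evalCpp
#' @useDynLib intentprior, .registration = TRUE
#' @keywords internal
"_PACKAGE"

#' @export
generics::tidy

#' @export
generics::glance

# z-score a numeric vector; a constant vector maps to all zeros rather than NaN
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    return(rep(0, length(x)))
  }
  (x - mean(x)) / s
}

# stable log(sum(exp(x)))
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (!is.finite(m)) {
    return(-Inf)
  }
  m + log(sum(exp(x - m)))
}

stopifnot_scalar_prob <- function(x, name, lo = 0, hi = 1,
                                  open_lo = FALSE, open_hi = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open_lo) x > lo else x >= lo) &&
    (if (open_hi) x < hi else x <= hi)
  if (!ok) {
    abort(sprintf("`%s` must be a single number in %s%g, %g%s",
                  name, if (open_lo) "(" else "[", lo, hi,
                  if (open_hi) ")" else "]"))
  }
  invisible(x)
}
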