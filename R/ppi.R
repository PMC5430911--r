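#' First principal component of a multi-unit time series
#'
#' Column-centers the matrix and returns the first principal-component score
#' series, the usual summary time series of a region of interest. The sign
#' is fixed so that the component correlates positively with the across-unit
#' mean series.
#'
#' @param series Numeric matrix, time points x units (>= 2 time points).
#' @return Numeric vector of PC1 scores (length = time points).
#' @export
extract_first_pc <- function(series) {
  m <- as.matrix(series)
  if (nrow(m) < 2) abort("need at least 2 time points")
  mc <- scale(m, center = TRUE, scale = FALSE)
  if (all(abs(mc) < 1e-14)) abort("constant series: first PC undefined")
  if (ncol(mc) == 1) {
    return(drop(mc))
  }
  sv <- svd(mc, nu = 1, nv = 0)
  pc <- drop(sv$u[, 1] * sv$d[1])
  ref <- rowMeans(mc)
  if (sum(pc * ref) < 0) pc <- -pc
  pc
}

# Toeplitz-like matrix mapping a neural series (grid step dt) to its
# HRF-convolved values at the same grid
convolution_operator <- function(n, kernel) {
  K <- matrix(0, n, n)
  for (j in seq_len(n)) {
    len <- min(length(kernel), n - j + 1)
    K[j:(j + len - 1), j] <- kernel[seq_len(len)]
  }
  K
}

#' Ridge deconvolution of a BOLD series
#'
#' Estimates the underlying neural series by inverting the HRF convolution
#' operator with ridge regularization: the closed-form solution
#' `(K'K + lambda I)^-1 K' y`, where `K` convolves a neural series sampled
#' at `tr / upsample` seconds with the canonical HRF.
#'
#' @param y BOLD series sampled at `tr`.
#' @param tr Sampling interval of `y` (s).
#' @param hrf An [hrf_spec()] (its `dt` is replaced by the deconvolution
#'   grid step).
#' @param ridge_lambda Non-negative ridge penalty (default `1e-2`).
#' @param upsample Integer: neural grid refinement relative to `tr`
#'   (1 = deconvolve at the sampling resolution).
#' @return Numeric neural series of length `length(y) * upsample`, with
#'   attribute `dt`.
#' @export
deconvolve_hrf <- function(y, tr, hrf = hrf_spec(), ridge_lambda = 1e-2,
                           upsample = 1L) {
  if (ridge_lambda < 0) abort("`ridge_lambda` must be non-negative")
  dt <- tr / upsample
  hrf$dt <- dt
  kern <- canonical_hrf(hrf)$value
  n_neural <- length(y) * upsample
  if (n_neural < length(kern)) {
    # a short series is still invertible; just truncate the kernel
    kern <- kern[seq_len(n_neural)]
  }
  Kfull <- convolution_operator(n_neural, kern)
  # rows observed at the BOLD sampling grid
  obs <- seq(1L, n_neural, by = upsample)
  K <- Kfull[obs, , drop = FALSE]
  A <- crossprod(K) + diag(ridge_lambda, n_neural)
  x <- drop(solve(A, crossprod(K, y)))
  attr(x, "dt") <- dt
  x
}

#' Build a psychophysiological-interaction regressor
#'
#' Deconvolves the seed ("physiological") BOLD series with the canonical
#' HRF, multiplies the neural estimate by the signed psychological contrast
#' (e.g. +1 on trials of one condition, -1 on the other), reconvolves with
#' the HRF, and mean-centers. The resulting regressor carries the
#' condition-dependent component of the seed's coupling.
#'
#' @param physio Seed-region BOLD series at `tr`.
#' @param psych Signed psychological series at `tr` (same length), typically
#'   +1/-1 condition coding; must not be all zero.
#' @param tr Sampling interval (s).
#' @param hrf An [hrf_spec()].
#' @param ridge_lambda Ridge penalty for the deconvolution step.
#' @return Numeric PPI regressor at `tr` resolution, mean-centered.
#' @export
build_ppi_regressor <- function(physio, psych, tr, hrf = hrf_spec(),
                                ridge_lambda = 1e-2) {
  if (length(physio) != length(psych)) {
    abort("`physio` and `psych` must have equal lengths")
  }
  if (all(psych == 0)) abort("`psych` must not be all zero")
  neural <- deconvolve_hrf(physio, tr, hrf, ridge_lambda)
  hrf$dt <- tr
  kern <- canonical_hrf(hrf)$value
  ppi <- convolve_hrf(neural * psych, kern)
  ppi - mean(ppi)
}

#' Estimate condition-dependent coupling (PPI regression)
#'
#' Regresses the target region on the seed's physiological series, the
#' psychological contrast (HRF-convolved), the PPI regressor, and optional
#' nuisance covariates. With +1/-1 condition coding the condition-specific
#' coupling slopes are `b_physio + b_ppi` and `b_physio - b_ppi`, and the
#' slope difference (the PPI effect proper) is twice the PPI coefficient.
#'
#' @param target Target-region BOLD series.
#' @param seed_series Seed-region BOLD series.
#' @param psych Signed +1/-1 condition series at `tr`.
#' @param tr Sampling interval (s).
#' @param hrf An [hrf_spec()].
#' @param nuisance Optional matrix of nuisance covariates.
#' @param ridge_lambda Ridge penalty for the deconvolution step.
#' @return Object of class `ppi_result`: `slopes` (named, condition `pos`
#'   for psych = +1 and `neg` for psych = -1), `interaction` (slope
#'   difference), `statistic` and `p.value` of the PPI term, `coefficients`,
#'   `regressor` (the PPI series), `df`.
#' @export
estimate_ppi <- function(target, seed_series, psych, tr, hrf = hrf_spec(),
                         nuisance = NULL, ridge_lambda = 1e-2) {
  n <- length(target)
  if (length(seed_series) != n || length(psych) != n) {
    abort("`target`, `seed_series` and `psych` must have equal lengths")
  }
  ppi <- build_ppi_regressor(seed_series, psych, tr, hrf, ridge_lambda)
  hrf$dt <- tr
  kern <- canonical_hrf(hrf)$value
  psych_conv <- convolve_hrf(psych, kern)
  X <- cbind(physio = seed_series - mean(seed_series),
             psych = psych_conv - mean(psych_conv),
             ppi = ppi)
  if (!is.null(nuisance)) {
    nz <- as.matrix(nuisance)
    colnames(nz) <- colnames(nz) %||% paste0("nuis_", seq_len(ncol(nz)))
    X <- cbind(X, nz)
  }
  X <- cbind(X, intercept = 1)
  fit <- fit_glm(target, X, contrasts = list(ppi = c(ppi = 1)))
  b_phys <- fit$coefficients[["physio"]]
  b_ppi <- fit$coefficients[["ppi"]]
  structure(
    list(
      slopes = c(pos = b_phys + b_ppi, neg = b_phys - b_ppi),
      interaction = 2 * b_ppi,
      statistic = fit$contrasts$statistic[1],
      p.value = fit$contrasts$p.value[1],
      coefficients = fit$coefficients,
      regressor = ppi,
      df = fit$df
    ),
    class = "ppi_result"
  )
}

#' @export
print.ppi_result <- function(x, ...) {
  cat(sprintf("<ppi_result> slope(+1) = %.4f, slope(-1) = %.4f\n",
              x$slopes["pos"], x$slopes["neg"]))
  cat(sprintf("  interaction = %.4f, t(%d) = %.2f, p = %.3g\n",
              x$interaction, x$df, x$statistic, x$p.value))
  invisible(x)
}

#' @method tidy ppi_result
#' @export
tidy.ppi_result <- function(x, ...) {
  tibble(term = c("slope_pos", "slope_neg", "interaction"),
         estimate = c(unname(x$slopes), x$interaction))
}

#' @method glance ppi_result
#' @export
glance.ppi_result <- function(x, ...) {
  tibble(interaction = x$interaction, statistic = x$statistic,
         p.value = x$p.value, df = x$df)
}
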