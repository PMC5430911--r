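#' Canonical double-gamma HRF specification
#'
#' Parameters of the canonical haemodynamic response function used to
#' convolve event regressors: a positive gamma density peaking around 5 s
#' minus a scaled gamma undershoot, sampled on a microtime grid.
#'
#' @param peak_delay Delay of the response peak (s); gamma shape =
#'   `peak_delay / peak_dispersion`.
#' @param undershoot_delay Delay of the undershoot (s).
#' @param peak_dispersion,undershoot_dispersion Gamma scale parameters (s).
#' @param ratio Relative amplitude of the undershoot (default 1/6).
#' @param dt Microtime resolution (s) at which regressors are built before
#'   downsampling to the scan TR.
#' @param length_s Kernel length (s); must cover the undershoot.
#' @return An object of class `hrf_spec`.
#' @export
hrf_spec <- function(peak_delay = 6, undershoot_delay = 16,
                     peak_dispersion = 1, undershoot_dispersion = 1,
                     ratio = 1 / 6, dt = 0.1, length_s = 32) {
  if (dt <= 0) abort("`dt` must be positive")
  if (length_s <= undershoot_delay) {
    abort("`length_s` must extend beyond the undershoot delay")
  }
  if (peak_delay <= 0 || undershoot_delay <= peak_delay) {
    abort("need 0 < peak_delay < undershoot_delay")
  }
  structure(
    list(peak_delay = peak_delay, undershoot_delay = undershoot_delay,
         peak_dispersion = peak_dispersion,
         undershoot_dispersion = undershoot_dispersion,
         ratio = ratio, dt = dt, length_s = length_s),
    class = "hrf_spec"
  )
}

#' Sample the canonical HRF kernel
#'
#' Difference of two gamma densities (response minus `ratio` times
#' undershoot), sampled at the spec's microtime resolution and normalized to
#' a peak of 1.
#'
#' @param spec An [hrf_spec()].
#' @return A tibble of class `hrf_kernel` with columns `time` and `value`;
#'   the `dt` attribute records the sampling step.
#' @export
#' @examples
#' k <- canonical_hrf()
#' k$time[which.max(k$value)] # peak near 5 s
canonical_hrf <- function(spec = hrf_spec()) {
  if (!inherits(spec, "hrf_spec")) abort("`spec` must be an hrf_spec()")
  t <- seq(0, spec$length_s, by = spec$dt)
  g1 <- stats::dgamma(t, shape = spec$peak_delay / spec$peak_dispersion,
                      scale = spec$peak_dispersion)
  g2 <- stats::dgamma(t, shape = spec$undershoot_delay / spec$undershoot_dispersion,
                      scale = spec$undershoot_dispersion)
  h <- g1 - spec$ratio * g2
  h <- h / max(h)
  out <- tibble(time = t, value = h)
  class(out) <- c("hrf_kernel", class(out))
  attr(out, "dt") <- spec$dt
  out
}

hrf_values <- function(hrf) {
  if (inherits(hrf, "hrf_spec")) hrf <- canonical_hrf(hrf)
  if (inherits(hrf, "hrf_kernel") || is.data.frame(hrf)) {
    return(list(values = hrf$value, dt = attr(hrf, "dt") %||% diff(hrf$time[1:2])))
  }
  abort("`hrf` must be an hrf_spec or hrf_kernel")
}

# linear convolution of x with kernel, truncated to length(x)
convolve_hrf <- function(x, kernel) {
  out <- convolve(x, rev(kernel), type = "open")[seq_along(x)]
  out
}
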