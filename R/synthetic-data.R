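#' Generative parameters for a simulated subject
#'
#' @param alpha_true Memory-decay parameter of the generative observer
#'   (`>= 1`).
#' @param beta_true Length-4 numeric: intercept, prior, evidence and
#'   prior-by-evidence coefficients on the standardized-predictor scale.
#' @param lapse Probability of a uniform guess, in \[0, 0.5\].
#' @return Object of class `subject_params`.
#' @export
subject_params <- function(alpha_true = 1,
                           beta_true = c(0, 1, 1, -0.5),
                           lapse = 0) {
  if (!is.numeric(alpha_true) || alpha_true < 1) abort("`alpha_true` must be >= 1")
  if (length(beta_true) != 4) abort("`beta_true` must have 4 elements")
  stopifnot_scalar_prob(lapse, "lapse", hi = 0.5)
  structure(list(alpha_true = alpha_true,
                 beta_true = stats::setNames(as.numeric(beta_true),
                                             c("beta0", "beta_prior",
                                               "beta_evidence", "beta_interaction")),
                 lapse = lapse),
            class = "subject_params")
}

#' Simulate a subject's choices on a generated run
#'
#' Inverts the observer + choice model: computes the generative observer's
#' prior probability of each trial's enacted intention (conditioning on the
#' first actor's move in the social task), z-scores prior and evidence
#' within the session, forms the linear predictor
#' `b0 + bp*z(prior) + be*z(evid) + bpe*z(prior)*z(evid)`, mixes in a lapse
#' rate, and draws the correct/incorrect response from a Bernoulli.
#'
#' @param design A `session_design` from [generate_run()].
#' @param params A [subject_params()].
#' @param seed Integer seed.
#' @return Tibble with one row per non-control trial: `trial_index`,
#'   `intention`, `is_likely`, `evidence_level`, `prior` (generative
#'   observer's probability of the enacted intention), `p_correct`,
#'   `correct`, `response`.
#' @export
simulate_subject <- function(design, params = subject_params(), seed = NULL) {
  if (!inherits(design, "session_design")) abort("`design` must be a session_design")
  if (!inherits(params, "subject_params")) abort("`params` must be subject_params()")
  tr <- design$trials[design$trials$phase != "control", ]
  ctx <- if (design$config$task_type == "social") tr$first_actor_move else NULL
  trace <- prior_trace(tr$intention,
                       observer_config(alpha = params$alpha_true),
                       intentions = design$config$intentions,
                       context = ctx)
  zp <- zscore(trace$p_event)
  ze <- zscore(tr$evidence_level)
  b <- params$beta_true
  eta <- b[1] + b[2] * zp + b[3] * ze + b[4] * zp * ze
  p_correct <- params$lapse / 2 + (1 - params$lapse) * plogis(eta)
  with_seed(seed, {
    correct <- rbinom(nrow(tr), 1, p_correct)
    other <- vapply(tr$intention,
                    function(i) setdiff(design$config$intentions, i),
                    character(1))
    tibble(
      trial_index = tr$index,
      intention = tr$intention,
      is_likely = tr$is_likely,
      evidence_level = tr$evidence_level,
      prior = trace$p_event,
      p_correct = p_correct,
      correct = correct,
      response = ifelse(correct == 1, tr$intention, other)
    )
  })
}

#' BOLD simulation configuration
#'
#' @param tr Repetition time (s), default 2.5.
#' @param n_volumes Usable volumes per run (default 285, i.e. 290 acquired
#'   with the first 5 discarded).
#' @param noise_sd Standard deviation of the AR(1) Gaussian innovation.
#' @param ar1_rho AR(1) coefficient of the noise, |rho| < 1.
#' @param drift_amplitude Amplitude of a slow linear + cosine scanner drift.
#' @param seed Integer seed.
#' @return Object of class `bold_sim_config`.
#' @export
bold_sim_config <- function(tr = 2.5, n_volumes = 285, noise_sd = 1,
                            ar1_rho = 0.3, drift_amplitude = 0, seed = NULL) {
  if (tr <= 0) abort("`tr` must be positive")
  if (abs(ar1_rho) >= 1) abort("`ar1_rho` must satisfy |rho| < 1")
  if (noise_sd < 0) abort("`noise_sd` must be non-negative")
  structure(list(tr = tr, n_volumes = as.integer(n_volumes),
                 noise_sd = noise_sd, ar1_rho = ar1_rho,
                 drift_amplitude = drift_amplitude, seed = seed),
            class = "bold_sim_config")
}

ar1_noise <- function(n, sd, rho) {
  if (sd == 0) return(numeric(n))
  innov <- rnorm(n, sd = sd)
  as.numeric(stats::filter(innov, rho, method = "recursive"))
}

drift_series <- function(n, amplitude) {
  if (amplitude == 0) return(numeric(n))
  t <- seq_len(n) / n
  amplitude * (t - 0.5 + 0.5 * cos(2 * pi * t / 2))
}

#' Simulate an ROI BOLD series from a design matrix
#'
#' `y = X beta + drift + AR(1) noise`, the generative counterpart of
#' [fit_glm()].
#'
#' @param design A `design_matrix` or numeric matrix.
#' @param betas Effect sizes: full-length vector or named by design columns
#'   (unnamed columns get 0).
#' @param cfg A [bold_sim_config()]; its `n_volumes` must equal the design
#'   rows.
#' @return Numeric BOLD series.
#' @export
simulate_bold <- function(design, betas, cfg = bold_sim_config()) {
  X <- if (inherits(design, "design_matrix")) design$X else as.matrix(design)
  if (nrow(X) != cfg$n_volumes) {
    abort(sprintf("design has %d rows but cfg$n_volumes = %d",
                  nrow(X), cfg$n_volumes))
  }
  if (!is.null(names(betas)) && !all(names(betas) == "")) {
    full <- stats::setNames(numeric(ncol(X)), colnames(X))
    bad <- setdiff(names(betas), colnames(X))
    if (length(bad)) abort(sprintf("unknown beta column(s): %s",
                                   paste(bad, collapse = ", ")))
    full[names(betas)] <- betas
    betas <- full
  }
  if (length(betas) != ncol(X)) abort("`betas` length must match design columns")
  with_seed(cfg$seed, {
    drop(X %*% betas) +
      drift_series(nrow(X), cfg$drift_amplitude) +
      ar1_noise(nrow(X), cfg$noise_sd, cfg$ar1_rho)
  })
}

#' Simulate coupled ROI BOLD from a bilinear DCM
#'
#' Integrates the bilinear neural state equation of `model` under the given
#' inputs (see [simulate_dcm()]), convolves each region's neural state with
#' the canonical HRF on the microtime grid, downsamples to the scan TR, and
#' adds AR(1) noise.
#'
#' @param model A `dcm_model` (see [enumerate_models()] or [dcm_model()]).
#' @param inputs Matrix (microtime x n inputs) of driving/modulator inputs.
#' @param cfg A [bold_sim_config()].
#' @param dt Microtime step (s) of `inputs`.
#' @param hrf An [hrf_spec()]; its `dt` is overridden by `dt`.
#' @return Matrix `n_volumes x n_regions` of BOLD series (named columns).
#' @export
simulate_coupled_rois <- function(model, inputs, cfg = bold_sim_config(),
                                  dt = 0.1, hrf = hrf_spec()) {
  states <- simulate_dcm(model, inputs, dt = dt)
  hrf$dt <- dt
  kern <- canonical_hrf(hrf)$value
  n_micro <- nrow(states)
  scan_t <- (seq_len(cfg$n_volumes) - 1) * cfg$tr
  idx <- pmin(n_micro, floor(scan_t / dt) + 1L)
  if (max(scan_t) > n_micro * dt + 1e-9) {
    abort("inputs too short for the requested number of volumes")
  }
  with_seed(cfg$seed, {
    out <- vapply(seq_len(ncol(states)), function(j) {
      bold <- convolve_hrf(states[, j], kern)[idx]
      bold + ar1_noise(cfg$n_volumes, cfg$noise_sd, cfg$ar1_rho)
    }, numeric(cfg$n_volumes))
    colnames(out) <- colnames(states)
    out
  })
}
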