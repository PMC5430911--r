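# Brute-force oracle for the memory-decay observer: direct weighted counting
# over all lags, O(t^2), independent of the package's recursive implementation.
brute_prior_trace <- function(events, alpha, smoothing = 1,
                              intentions = sort(unique(events)),
                              context = NULL) {
  n <- length(events)
  k <- length(intentions)
  ctx <- if (is.null(context)) rep("all", n) else as.character(context)
  probs <- matrix(NA_real_, n, k, dimnames = list(NULL, intentions))
  for (t in seq_len(n)) {
    hist_idx <- which(ctx[seq_len(t - 1)] == ctx[t])
    w <- numeric(k)
    if (length(hist_idx)) {
      # lag p counts backwards within this trial's context
      lags <- rev(seq_along(hist_idx))
      for (h in seq_along(hist_idx)) {
        i <- match(events[hist_idx[h]], intentions)
        w[i] <- w[i] + alpha^(-lags[h])
      }
    }
    probs[t, ] <- (w + smoothing) / sum(w + smoothing)
  }
  probs
}

# i.i.d. biased event stream with evidence levels, mimicking a testing phase
sim_event_stream <- function(n, bias = 2 / 3, n_levels = 4, seed = NULL) {
  intentprior:::with_seed(seed, {
    tibble::tibble(
      event = ifelse(runif(n) < bias, "likely", "unlikely"),
      evidence = sample(seq_len(n_levels), n, replace = TRUE)
    )
  })
}

# choices drawn from the generative observer + logistic model, bypassing the
# full task generator (used for recovery tests)
sim_choices <- function(n, alpha_true, betas, bias = 2 / 3, seed = NULL) {
  st <- sim_event_stream(n, bias, seed = seed)
  tr <- prior_trace(st$event, observer_config(alpha = alpha_true),
                    intentions = c("likely", "unlikely"))
  zp <- (tr$p_event - mean(tr$p_event)) / sd(tr$p_event)
  ze <- (st$evidence - mean(st$evidence)) / sd(st$evidence)
  eta <- betas[1] + betas[2] * zp + betas[3] * ze + betas[4] * zp * ze
  intentprior:::with_seed(if (is.null(seed)) NULL else seed + 1, {
    tibble::tibble(
      event = st$event, evidence = st$evidence,
      prior = tr$p_event, p_correct = plogis(eta),
      correct = rbinom(n, 1, plogis(eta))
    )
  })
}

# independent IRLS logistic oracle (plain Newton iterations, no penalty)
irls_oracle <- function(X, y, max_iter = 50) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    W <- mu * (1 - mu)
    beta <- beta + solve(crossprod(X, X * W), crossprod(X, y - mu))
  }
  drop(beta)
}

# textbook two-way repeated-measures ANOVA from explicit sums of squares;
# y is a 3-d array subject x A x B
rm_anova_oracle <- function(y) {
  ns <- dim(y)[1]; na <- dim(y)[2]; nb <- dim(y)[3]
  gm <- mean(y)
  m_s <- apply(y, 1, mean); m_a <- apply(y, 2, mean); m_b <- apply(y, 3, mean)
  m_sa <- apply(y, c(1, 2), mean); m_sb <- apply(y, c(1, 3), mean)
  m_ab <- apply(y, c(2, 3), mean)
  ss_a <- ns * nb * sum((m_a - gm)^2)
  ss_b <- ns * na * sum((m_b - gm)^2)
  ss_s <- na * nb * sum((m_s - gm)^2)
  ss_sa <- nb * sum((m_sa - outer(m_s, rep(1, na)) -
                       outer(rep(1, ns), m_a) + gm)^2)
  ss_sb <- na * sum((m_sb - outer(m_s, rep(1, nb)) -
                       outer(rep(1, ns), m_b) + gm)^2)
  ss_ab <- ns * sum((m_ab - outer(m_a, rep(1, nb)) -
                       outer(rep(1, na), m_b) + gm)^2)
  ss_tot <- sum((y - gm)^2)
  ss_sab <- ss_tot - ss_a - ss_b - ss_s - ss_sa - ss_sb - ss_ab
  f <- c(A = (ss_a / (na - 1)) / (ss_sa / ((ns - 1) * (na - 1))),
         B = (ss_b / (nb - 1)) / (ss_sb / ((ns - 1) * (nb - 1))),
         `A:B` = (ss_ab / ((na - 1) * (nb - 1))) /
           (ss_sab / ((ns - 1) * (na - 1) * (nb - 1))))
  pes <- c(A = ss_a / (ss_a + ss_sa), B = ss_b / (ss_b + ss_sb),
           `A:B` = ss_ab / (ss_ab + ss_sab))
  list(f = f, pes = pes,
       ss = c(A = ss_a, B = ss_b, `A:B` = ss_ab),
       ss_err = c(A = ss_sa, B = ss_sb, `A:B` = ss_sab))
}

# long-format wrapper around rm_anova_oracle input
array_to_long <- function(y) {
  ns <- dim(y)[1]; na <- dim(y)[2]; nb <- dim(y)[3]
  expand.grid(subject = seq_len(ns), A = seq_len(na), B = seq_len(nb)) |>
    transform(score = as.vector(y))
}

# --- standard PPI simulation conditions (shared by tests and acceptance) ---
# Event-related design: 15 s trials with a 1.5 s preparation and a 3 s
# inference window, 30 s alternating condition blocks, per-trial inference
# input amplitude varying uniformly in (0.2, 1.8), backward mPFC->TPJ
# coupling modulated by condition strength 1 when active, BOLD noise 0.3.
ppi_sim_settings <- function(n_volumes = 200, tr = 2.5, dt = 0.5) {
  n <- ceiling(n_volumes * tr / dt)
  t <- (seq_len(n) - 1) * dt
  list(
    n_volumes = n_volumes, tr = tr, dt = dt, n = n,
    block = rep(c(1, -1), each = 30 / dt, length.out = n),
    trial_id = floor(t / 15) + 1,
    infer_win = t %% 15 >= 3 & t %% 15 < 6,
    prep_win = t %% 15 < 1.5,
    scan_idx = pmin(n, floor((seq_len(n_volumes) - 1) * tr / dt) + 1)
  )
}

ppi_convolve_tr <- function(x, s) {
  hs <- hrf_spec()
  hs$dt <- s$tr
  kern <- canonical_hrf(hs)$value
  v <- convolve(x[s$scan_idx], rev(kern), type = "open")[seq_len(s$n_volumes)]
  v - mean(v)
}

# one PPI simulation + estimation; modulate = FALSE gives the null.
# amp_var adds per-trial variability of the inference input amplitude (the
# trial-to-trial neural variability that gives the PPI term its power);
# the null-calibration setting keeps stereotyped amplitudes, the regime in
# which the classical t test on the PPI coefficient is exact.
run_ppi_once <- function(seed, modulate, s = ppi_sim_settings(),
                         b_mod = 1.2, noise_sd = 0.3, amp_var = modulate) {
  gen <- enumerate_models()[[13]] # family 2, backward INT modulation
  gen$B$INT["TPJ", "mPFC"] <- if (modulate) b_mod else 0
  set.seed(seed)
  amp <- if (amp_var) runif(max(s$trial_id), 0.2, 1.8)[s$trial_id] else 1
  U <- cbind(prep_input = as.numeric(s$prep_win),
             infer_input = as.numeric(s$infer_win) * amp,
             INT = as.numeric(s$infer_win) * s$block,
             PE = 0, PExINT = 0)
  bold <- simulate_coupled_rois(
    gen, U,
    bold_sim_config(tr = s$tr, n_volumes = s$n_volumes,
                    noise_sd = noise_sd, seed = seed + 7919),
    dt = s$dt
  )
  nuis <- cbind(infer_main = ppi_convolve_tr(as.numeric(s$infer_win), s),
                prep_main = ppi_convolve_tr(as.numeric(s$prep_win), s))
  psych <- (as.numeric(s$infer_win) * s$block)[s$scan_idx]
  estimate_ppi(bold[, "TPJ"], bold[, "mPFC"], psych, tr = s$tr,
               nuisance = nuis)
}

# --- standard DCM identification conditions (shared with acceptance) ---
dcm_sim_inputs <- function(seed, n_volumes = 100, tr = 2.5, dt = 0.5) {
  n <- ceiling(n_volumes * tr / dt)
  t <- (seq_len(n) - 1) * dt
  infer <- as.numeric(t %% 25 >= 5 & t %% 25 < 8)
  set.seed(seed)
  cbind(prep_input = as.numeric(t %% 25 < 2),
        infer_input = infer,
        INT = infer * rep(c(1, -1), each = 25 / dt, length.out = n),
        PE = infer * runif(n, -0.3, 0.3),
        PExINT = 0)[, c(1, 2, 3, 4, 4)] |>
    (\(m) {
      m[, 5] <- m[, 4] * m[, 3]
      colnames(m) <- c("prep_input", "infer_input", "INT", "PE", "PExINT")
      m
    })()
}
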