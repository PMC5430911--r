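test_that("canonical HRF has the expected shape", {
  k <- canonical_hrf()
  peak_t <- k$time[which.max(k$value)]
  expect_gte(peak_t, 4.5)
  expect_lte(peak_t, 5.5)
  expect_equal(max(k$value), 1)
  # exactly one sign change: positive lobe then undershoot
  signs <- sign(k$value[abs(k$value) > 1e-10])
  expect_equal(sum(diff(signs) != 0), 1)
  # refinement consistency: halving dt moves the peak by less than dt
  k2 <- canonical_hrf(hrf_spec(dt = 0.05))
  peak_t2 <- k2$time[which.max(k2$value)]
  expect_lte(abs(peak_t2 - peak_t), 0.1)
  expect_error(hrf_spec(dt = 0), "dt")
})

test_that("serial orthogonalization matches a QR oracle", {
  set.seed(55)
  for (rep in 1:20) {
    X <- matrix(rnorm(300), 100, 3)
    got <- serial_orthogonalize(X)
    qrd <- qr(X)
    Q <- qr.Q(qrd)
    R <- qr.R(qrd)
    # QR gives the same nested column spaces; rescale Q by diag(R)
    want <- Q %*% diag(diag(R))
    # both first columns equal X[,1]; later ones equal up to the triangular
    # projection structure: check orthogonality and span instead of values
    expect_equal(got[, 1], X[, 1])
    expect_lt(abs(sum(got[, 1] * got[, 2])), 1e-8)
    expect_lt(abs(sum(got[, 1] * got[, 3])), 1e-8)
    expect_lt(abs(sum(got[, 2] * got[, 3])), 1e-8)
    # column k of the output equals the QR residual of column k on 1..k-1
    expect_equal(abs(got[, 2]), abs(want[, 2]), tolerance = 1e-10)
    expect_equal(abs(got[, 3]), abs(want[, 3]), tolerance = 1e-10)
  }
})

test_that("serial orthogonalization fixed points and degeneracies", {
  X <- diag(4)[, 1:3]
  expect_equal(serial_orthogonalize(X), X)
  dup <- cbind(a = c(1, 2, 3), b = c(1, 2, 3))
  out <- serial_orthogonalize(dup)
  expect_equal(out[, 2], c(0, 0, 0))
  expect_warning(serial_orthogonalize(cbind(rep(0, 3), 1:3, 3:1)), "zero norm")
})

test_that("two-condition design matrix has 16 task regressors in order", {
  r1 <- generate_run(task_config("basic", seed = 1, n_induction = 12,
                                 n_testing = 36, n_control = 4))
  r2 <- generate_run(task_config("superordinate", seed = 2, n_induction = 12,
                                 n_testing = 36, n_control = 4))
  ev1 <- events_table(r1) |> dplyr::mutate(condition = "basic")
  ev2 <- events_table(r2) |>
    dplyr::mutate(onset = onset + r1$total_duration_s + 10,
                  condition = "superordinate")
  ev <- dplyr::bind_rows(ev1, ev2)
  mods <- dplyr::bind_rows(
    simulate_subject(r1, seed = 3) |> dplyr::mutate(condition = "basic"),
    simulate_subject(r2, seed = 4) |> dplyr::mutate(condition = "superordinate")
  ) |> dplyr::transmute(condition, trial_index, evidence = evidence_level, prior)
  nvol <- ceiling((r1$total_duration_s + r2$total_duration_s + 20) / 2.5)
  dm <- build_design_matrix(ev, mods, tr = 2.5, n_volumes = nvol)
  expect_length(dm$task_cols, 16)
  cats <- grep("_x_", dm$task_cols, invert = TRUE, value = TRUE)
  pars <- grep("_x_", dm$task_cols, value = TRUE)
  expect_length(cats, 8)
  expect_length(pars, 8)
  # serial orthogonality within each inference family
  for (cond in c("basic", "superordinate")) {
    e <- dm$X[, paste0("infer_", cond, "_x_evidence")]
    p <- dm$X[, paste0("infer_", cond, "_x_prior")]
    i <- dm$X[, paste0("infer_", cond, "_x_interaction")]
    expect_lt(abs(sum(e * p)), 1e-8)
    expect_lt(abs(sum(e * i)), 1e-8)
    expect_lt(abs(sum(p * i)), 1e-8)
  }
  expect_equal(dm$ortho_record$basic$order,
               c("evidence", "prior", "interaction"))
})

test_that("parametric columns match a Gram-Schmidt oracle on a toy design", {
  run <- generate_run(task_config("basic", seed = 3, n_induction = 8,
                                  n_testing = 12, n_control = 0))
  ev <- events_table(run)
  ch <- simulate_subject(run, seed = 5)
  mods <- dplyr::transmute(ch, trial_index, evidence = evidence_level, prior)
  nvol <- ceiling(run$total_duration_s / 2.5) + 2
  dm <- build_design_matrix(ev, mods, tr = 2.5, n_volumes = nvol,
                            highpass = FALSE)
  # rebuild the raw convolved modulator columns without orthogonalization,
  # then apply classical Gram-Schmidt
  hv <- canonical_hrf(hrf_spec())
  dt <- 0.1
  m <- ceiling(nvol * 2.5 / dt)
  idx <- function(t) pmin(m, pmax(1, floor(t / dt) + 1))
  scan_idx <- idx((seq_len(nvol) - 1) * 2.5)
  act <- ev[ev$trial_type == "action" & ev$phase != "control", ]
  raw_col <- function(vals) {
    x <- numeric(m)
    for (i in seq_len(nrow(act))) {
      x[idx(act$onset[i]):idx(act$onset[i] + act$duration[i] - 1e-9)] <- vals[i]
    }
    convolve(x, rev(hv$value), type = "open")[1:m][scan_idx]
  }
  mi <- match(act$trial_index, mods$trial_index)
  e_raw <- raw_col(mods$evidence[mi] - mean(mods$evidence[mi]))
  p_raw <- raw_col(mods$prior[mi] - mean(mods$prior[mi]))
  i_vals <- mods$evidence[mi] * mods$prior[mi]
  i_raw <- raw_col(i_vals - mean(i_vals))
  gs_p <- p_raw - e_raw * sum(e_raw * p_raw) / sum(e_raw^2)
  gs_i <- i_raw - e_raw * sum(e_raw * i_raw) / sum(e_raw^2)
  gs_i <- gs_i - gs_p * sum(gs_p * gs_i) / sum(gs_p^2)
  expect_equal(dm$X[, "infer_task_x_evidence"], e_raw, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(dm$X[, "infer_task_x_prior"], gs_p, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(dm$X[, "infer_task_x_interaction"], gs_i, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("constant prior modulator is absorbed after centering", {
  run <- generate_run(task_config("basic", seed = 4, n_induction = 8,
                                  n_testing = 12, n_control = 0))
  ev <- events_table(run)
  mods <- tibble::tibble(trial_index = sort(unique(ev$trial_index)),
                         evidence = rep(1:4, 5), prior = 0.5)
  nvol <- ceiling(run$total_duration_s / 2.5) + 2
  suppressWarnings(
    dm <- build_design_matrix(ev, mods, tr = 2.5, n_volumes = nvol)
  )
  expect_lt(max(abs(dm$X[, "infer_task_x_prior"])), 1e-10)
})

test_that("events beyond the scan end are rejected by trial", {
  run <- generate_run(task_config("basic", seed = 5, n_induction = 8,
                                  n_testing = 12, n_control = 0))
  ev <- events_table(run)
  mods <- tibble::tibble(trial_index = sort(unique(ev$trial_index)),
                         evidence = rep(1:4, 5), prior = runif(20))
  expect_error(build_design_matrix(ev, mods, tr = 2.5, n_volumes = 10),
               "beyond scan end")
  expect_error(build_design_matrix(ev, mods[-1, ], tr = 2.5,
                                   n_volumes = ceiling(run$total_duration_s / 2.5) + 2),
               "missing modulator")
})

test_that("GLM t statistics match the closed form on a toy problem", {
  set.seed(66)
  X <- cbind(1, rnorm(30), rnorm(30))
  beta <- c(2, 1, -0.5)
  y <- drop(X %*% beta) + rnorm(30)
  cvec <- c(0, 1, -1)
  fit <- fit_glm(y, X, contrasts = list(d = cvec))
  bhat <- solve(crossprod(X), crossprod(X, y))
  res <- y - X %*% bhat
  s2 <- sum(res^2) / (30 - 3)
  tstat <- drop(t(cvec) %*% bhat) /
    sqrt(s2 * drop(t(cvec) %*% solve(crossprod(X)) %*% cvec))
  expect_equal(fit$contrasts$statistic, tstat, tolerance = 1e-10)
  expect_equal(unname(fit$coefficients), drop(bhat), tolerance = 1e-10)
})

test_that("rank-deficient designs warn and return minimum-norm solutions", {
  X <- cbind(a = rep(1, 20), b = 1:20, c = 2 * (1:20))
  y <- rnorm(20)
  expect_warning(fit <- fit_glm(y, X), "rank deficient")
  expect_true(fit$rank_deficient)
  expect_true(all(is.finite(fit$coefficients)))
})

test_that("Cochrane-Orcutt prewhitening estimates the AR coefficient", {
  set.seed(12)
  X <- cbind(intercept = 1, x = rnorm(500))
  y <- drop(X %*% c(1, 2)) +
    as.numeric(stats::filter(rnorm(500), 0.5, method = "recursive"))
  fit <- fit_glm(y, X, prewhiten = TRUE)
  expect_lt(abs(fit$rho - 0.5), 0.15)
  expect_equal(unname(fit$coefficients["x"]), 2, tolerance = 0.1)
})

test_that("high-pass basis spans the requested cutoff", {
  B <- dct_highpass_basis(285, 2.5, 128)
  expect_equal(ncol(B), floor(2 * 285 * 2.5 / 128))
  expect_equal(colnames(B)[1], "hp_1")
  expect_equal(dct_highpass_basis(10, 1, 128) |> ncol(), 0)
})
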