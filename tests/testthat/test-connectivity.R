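test_that("first principal component matches an SVD oracle", {
  set.seed(70)
  m <- matrix(rnorm(250), 50, 5)
  pc <- extract_first_pc(m)
  mc <- scale(m, center = TRUE, scale = FALSE)
  sv <- svd(mc)
  want <- sv$u[, 1] * sv$d[1]
  expect_equal(abs(pc), abs(want), tolerance = 1e-10, ignore_attr = TRUE)
  expect_gt(cor(pc, rowMeans(mc)), 0)

  # single column: the centered column itself
  one <- matrix(rnorm(20), 20, 1)
  expect_equal(extract_first_pc(one), drop(scale(one, scale = FALSE)),
               ignore_attr = TRUE)
  # two identical columns: proportional to their mean
  two <- cbind(one, one)
  expect_equal(cor(extract_first_pc(two), drop(one) - mean(one)), 1,
               tolerance = 1e-10)
  expect_error(extract_first_pc(matrix(1, 10, 2)), "constant")
})

test_that("ridge deconvolution matches its closed form and round-trips", {
  set.seed(71)
  tr <- 2.5
  n <- 100
  hs <- hrf_spec()
  hs$dt <- tr
  kern <- canonical_hrf(hs)$value
  t_s <- (seq_len(n) - 1) * tr
  neural <- sin(2 * pi * t_s / 60) + 0.6 * cos(2 * pi * t_s / 35) +
    0.3 * sin(2 * pi * t_s / 22 + 1)
  y <- convolve(neural, rev(kern), type = "open")[1:n]

  # closed-form oracle
  K <- matrix(0, n, n)
  for (j in 1:n) {
    len <- min(length(kern), n - j + 1)
    K[j:(j + len - 1), j] <- kern[seq_len(len)]
  }
  lam <- 1e-2
  want <- solve(crossprod(K) + diag(lam, n), crossprod(K, y))
  got <- deconvolve_hrf(y, tr, ridge_lambda = lam)
  expect_equal(as.numeric(got), drop(want), tolerance = 1e-8)

  # near-noiseless round trip; the last kernel-length worth of samples is
  # unidentifiable (its response falls beyond the series end), so compare
  # the interior
  got2 <- deconvolve_hrf(y, tr, ridge_lambda = 1e-6)
  keep <- seq_len(n - ceiling(32 / tr))
  expect_gt(cor(as.numeric(got2)[keep], neural[keep]), 0.99)

  expect_equal(as.numeric(deconvolve_hrf(rep(0, 50), tr)), rep(0, 50))
  expect_error(deconvolve_hrf(y, tr, ridge_lambda = -1), "non-negative")
})

test_that("PPI regressor behaves linearly in the psychological contrast", {
  set.seed(72)
  tr <- 2.5
  physio <- as.numeric(stats::filter(rnorm(80), 0.7, method = "recursive"))
  psych <- rep(c(1, -1), each = 10, length.out = 80)
  ppi <- build_ppi_regressor(physio, psych, tr)
  ppi_flip <- build_ppi_regressor(physio, -psych, tr)
  expect_equal(ppi_flip, -ppi, tolerance = 1e-10)
  expect_equal(mean(ppi), 0, tolerance = 1e-12)

  # constant contrast: regressor proportional to the re-smoothed seed
  ppi1 <- build_ppi_regressor(physio, rep(1, 80), tr)
  resmoothed <- {
    hs <- hrf_spec()
    hs$dt <- tr
    kern <- canonical_hrf(hs)$value
    v <- convolve(as.numeric(deconvolve_hrf(physio, tr)), rev(kern),
                  type = "open")[1:80]
    v - mean(v)
  }
  expect_equal(ppi1, resmoothed, tolerance = 1e-10)
  expect_gt(cor(ppi1, physio - mean(physio)), 0.95)
  expect_error(build_ppi_regressor(physio, rep(0, 80), tr), "all zero")
})

test_that("PPI interaction equals the condition-slope difference and is null without modulation", {
  # noiseless static coupling (target proportional to seed), no modulation:
  # the PPI coefficient is exactly zero
  set.seed(74)
  seed_series <- as.numeric(stats::filter(rnorm(120), 0.7,
                                          method = "recursive"))
  target <- 0.4 * seed_series + 2
  psych <- rep(c(1, -1), each = 12, length.out = 120)
  p0 <- estimate_ppi(target, seed_series, psych, tr = 2.5)
  expect_lt(abs(p0$interaction), 1e-8)
  expect_equal(p0$interaction, unname(p0$slopes["pos"] - p0$slopes["neg"]),
               tolerance = 1e-12)

  p <- run_ppi_once(1, modulate = FALSE, noise_sd = 0)
  expect_equal(p$interaction, unname(p$slopes["pos"] - p$slopes["neg"]),
               tolerance = 1e-12)

  # modulated coupling: positive slope difference in most seeds
  pos <- vapply(1:15, function(s) run_ppi_once(s, TRUE)$interaction > 0,
                logical(1))
  expect_gte(mean(pos), 0.8)
})

test_that("PPI type-I error is near nominal under no modulation", {
  rej <- vapply(1:120, function(s) {
    run_ppi_once(3000 + s, modulate = FALSE)$p.value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.01)
  expect_lte(mean(rej), 0.1)
})

test_that("family enumeration follows the progressive-removal design", {
  fams <- enumerate_families()
  expect_equal(nrow(fams), 5)
  expect_equal(fams$n_connections[5], 1)
  expect_equal(fams$connections[[5]], "prep->mPFC")
  full <- fams$connections[[1]]
  for (i in 2:5) {
    expect_true(all(fams$connections[[i]] %in% full))
  }
  # monotone decreasing connection counts
  expect_true(all(diff(fams$n_connections) <= 0))
})

test_that("model space enumerates 5 x 8 = 40 reproducible models", {
  mods <- enumerate_models()
  expect_length(mods, 40)
  ids <- vapply(mods, function(m) m$id, character(1))
  expect_length(unique(ids), 40)
  fam <- vapply(mods, function(m) m$family, integer(1))
  expect_equal(unname(table(fam)), rep(8L, 5), ignore_attr = TRUE)
  # deterministic across calls
  mods2 <- enumerate_models()
  expect_identical(vapply(mods2, function(m) m$id, character(1)), ids)
  # INT always modulates prep->mPFC where the family has that connection
  for (m in mods) {
    expect_equal(m$B$INT["mPFC", "prep"] > 0, m$A["mPFC", "prep"] != 0)
    # B only where A is nonzero
    for (Bj in m$B) expect_true(all(Bj[m$A == 0] == 0))
    expect_true(all(diag(m$A) < 0))
  }
})

test_that("DCM integration matches closed forms and refinement", {
  # one-region exponential decay from unit state (impulse response)
  m1 <- dcm_model(A = matrix(-1), C = matrix(1), regions = "r1")
  dt <- 0.01
  n <- 500
  z <- simulate_dcm(m1, matrix(0, n, 1), dt = dt, z0 = 1)
  t <- seq_len(n) * dt
  expect_equal(drop(z), exp(-t), tolerance = 1e-6)

  # rest: zero inputs, zero state
  m <- enumerate_models()[[13]]
  U0 <- matrix(0, 100, 5,
               dimnames = list(NULL, c("prep_input", "infer_input", "INT",
                                       "PE", "PExINT")))
  expect_true(all(simulate_dcm(m, U0, dt = 0.1) == 0))

  # refinement: dt vs dt/10 agree
  set.seed(73)
  n <- 100
  U <- matrix(0, n, 5,
              dimnames = list(NULL, c("prep_input", "infer_input", "INT",
                                      "PE", "PExINT")))
  U[, "prep_input"] <- rep(rbinom(10, 1, 0.5), each = 10)
  U[, "infer_input"] <- rep(rbinom(10, 1, 0.5), each = 10)
  z1 <- simulate_dcm(m, U, dt = 0.1)
  U10 <- U[rep(seq_len(n), each = 10), ]
  z10 <- simulate_dcm(m, U10, dt = 0.01)
  expect_equal(z1[n, ], z10[n * 10, ], tolerance = 1e-5)

  # instability is reported
  bad <- dcm_model(A = matrix(c(-1, 2, 2, -1), 2),
                   C = matrix(0, 2, 1), regions = c("a", "b"))
  expect_error(simulate_dcm(bad, matrix(1, 10, 1), dt = 0.1), "unstable")
})

test_that("DCM fit recovers its own parameters without noise", {
  gen <- enumerate_models()[[15]] # f2_m7: backward INT + PE
  U <- dcm_sim_inputs(seed = 80)
  bold <- simulate_coupled_rois(
    gen, U, bold_sim_config(tr = 2.5, n_volumes = 100, noise_sd = 0),
    dt = 0.5
  )
  fit <- fit_dcm_bic(bold, gen, U, tr = 2.5, dt = 0.5)
  expect_true(fit$converged)
  free <- which(gen$A != 0 & row(gen$A) != col(gen$A))
  expect_equal(fit$model$A[free], gen$A[free], tolerance = 0.05)
  expect_equal(fit$model$B$PE["TPJ", "mPFC"], 0.4, tolerance = 0.05)
  expect_equal(fit$model$C["prep", "prep_input"], 1, tolerance = 0.05)
})

test_that("unused free parameters are penalized in the BIC evidence", {
  gen <- enumerate_models()[[13]] # backward INT only
  richer <- enumerate_models()[[15]] # backward INT + PE (superset)
  U <- dcm_sim_inputs(seed = 81)
  bold <- simulate_coupled_rois(
    gen, U, bold_sim_config(tr = 2.5, n_volumes = 100, noise_sd = 0.05,
                            seed = 82),
    dt = 0.5
  )
  f1 <- fit_dcm_bic(bold, gen, U, tr = 2.5, dt = 0.5)
  f2 <- fit_dcm_bic(bold, richer, U, tr = 2.5, dt = 0.5)
  expect_gt(f2$k, f1$k)
  # equal-or-better fit quality cannot compensate the extra-parameter penalty
  expect_gt(f1$log_evidence, f2$log_evidence)
})

test_that("two-model BMS matches the quadrature oracle and symmetry", {
  set.seed(90)
  # identical evidences: EP 0.5 each
  L <- matrix(rnorm(12), 12, 2)
  L[, 2] <- L[, 1]
  colnames(L) <- c("a", "b")
  res <- bms_exceedance(L, n_samples = 5e4, seed = 1)
  expect_equal(res$models$ep[1], 0.5, tolerance = 0.02)
  expect_equal(sum(res$models$ep), 1, tolerance = 1e-12)

  # asymmetric case against P(r1 > r2) = P(Beta(a1, a2) > 1/2)
  L2 <- cbind(a = rnorm(10), b = rnorm(10) - 0.8)
  res2 <- bms_exceedance(L2, n_samples = 2e5, seed = 2)
  a <- res2$models$alpha
  want <- stats::pbeta(0.5, a[2], a[1])
  expect_equal(res2$models$ep[1], want, tolerance = 0.01)
})

test_that("family-level BMS aggregates evidences with log-sum-exp", {
  set.seed(91)
  L <- matrix(rnorm(40), 10, 4)
  colnames(L) <- paste0("m", 1:4)
  grouping <- c("f1", "f1", "f2", "f2")
  res <- bms_exceedance(L, grouping = grouping, n_samples = 2e4, seed = 3)
  expect_equal(nrow(res$families), 2)
  expect_equal(sum(res$families$ep), 1, tolerance = 1e-12)
  # oracle aggregation for subject 1, family 1
  want <- log(mean(exp(L[1, 1:2])))
  Lf11 <- log(sum(exp(L[1, 1:2]))) - log(2)
  expect_equal(Lf11, want, tolerance = 1e-12)
})

test_that("single-model BMS is trivial with a warning", {
  L <- matrix(rnorm(5), 5, 1, dimnames = list(NULL, "only"))
  expect_warning(res <- bms_exceedance(L, n_samples = 1e4), "single model")
  expect_equal(res$models$ep, 1)
})
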