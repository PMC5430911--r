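test_that("prior trace matches hand-worked values", {
  # no history: flat prior
  tr <- prior_trace(c("A", "B"), observer_config(alpha = 3))
  expect_equal(unlist(tr[1, c("A", "B")], use.names = FALSE), c(0.5, 0.5))

  # alpha = 1, history [A, A]: prob(A) = (2+1)/(2+1+0+1) = 0.75
  tr <- prior_trace(c("A", "A", "B"), observer_config(alpha = 1))
  expect_equal(tr$A[3], 0.75)

  # alpha = 2, history [A, B] (B most recent): w_B = 0.5, w_A = 0.25,
  # prob(A) = 1.25 / 2.75
  tr <- prior_trace(c("A", "B", "A"), observer_config(alpha = 2))
  expect_equal(tr$A[3], 1.25 / 2.75, tolerance = 1e-12)
  expect_equal(tr$B[3], 1.5 / 2.75, tolerance = 1e-12)
})

test_that("recursive trace equals brute-force weighted counting", {
  set.seed(101)
  for (rep in 1:60) {
    n <- sample(3:40, 1)
    alpha <- sample(c(1, 1.2, 1.7, 2.5), 1)
    events <- sample(c("A", "B"), n, replace = TRUE)
    got <- prior_trace(events, observer_config(alpha = alpha),
                       intentions = c("A", "B"))
    want <- brute_prior_trace(events, alpha, intentions = c("A", "B"))
    expect_equal(as.matrix(got[, c("A", "B")]), want,
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("context conditioning keeps separate histories per first actor", {
  events <- c("A", "B", "A", "B", "A", "A")
  ctx <- c("x", "y", "x", "y", "x", "y")
  got <- prior_trace(events, observer_config(alpha = 1.5),
                     intentions = c("A", "B"), context = ctx)
  want <- brute_prior_trace(events, 1.5, intentions = c("A", "B"),
                            context = ctx)
  expect_equal(as.matrix(got[, c("A", "B")]), want,
               tolerance = 1e-12, ignore_attr = TRUE)
  # each context starts flat
  expect_equal(unlist(got[1, c("A", "B")], use.names = FALSE), c(0.5, 0.5))
  expect_equal(unlist(got[2, c("A", "B")], use.names = FALSE), c(0.5, 0.5))
})

test_that("trace rows sum to one and stay inside (0, 1)", {
  set.seed(7)
  for (alpha in c(1, 1.3, 2, 3)) {
    events <- sample(c("A", "B"), 300, replace = TRUE)
    tr <- prior_trace(events, observer_config(alpha = alpha))
    p <- as.matrix(tr[, c("A", "B")])
    expect_true(all(abs(rowSums(p) - 1) < 1e-12))
    expect_true(all(p > 0 & p < 1))
  }
})

test_that("alpha = 1 reduces to Laplace-smoothed relative frequency", {
  set.seed(13)
  for (rep in 1:50) {
    n <- sample(5:200, 1)
    events <- sample(c("A", "B"), n, replace = TRUE)
    tr <- prior_trace(events, observer_config(alpha = 1),
                      intentions = c("A", "B"))
    count_a <- c(0, cumsum(events == "A"))[seq_len(n)]
    t_seen <- seq_len(n) - 1
    expect_equal(tr$A, (count_a + 1) / (t_seen + 2), tolerance = 1e-12)
  }
})

test_that("a decaying observer weights recent events above older ones", {
  # swapping the last two (distinct) events must raise the probability of
  # whichever intention now sits at lag 1, strictly for alpha > 1 and with
  # exact indifference for the lossless alpha = 1 observer
  prob_next_a <- function(history, a) {
    tr <- prior_trace(c(history, "A"), observer_config(alpha = a),
                      intentions = c("A", "B"))
    tr$A[length(history) + 1]
  }
  set.seed(23)
  for (rep in 1:40) {
    n <- sample(4:30, 1)
    history <- c(sample(c("A", "B"), n - 2, replace = TRUE), "B", "A")
    swapped <- history
    swapped[c(n - 1, n)] <- history[c(n, n - 1)]
    for (a in c(1.25, 1.5, 2, 3)) {
      expect_gt(prob_next_a(history, a), prob_next_a(swapped, a))
    }
    expect_equal(prob_next_a(history, 1), prob_next_a(swapped, 1),
                 tolerance = 1e-12)
  }
})

test_that("ideal-observer prior converges to the generating bias", {
  set.seed(31)
  events <- ifelse(runif(600) < 2 / 3, "likely", "unlikely")
  tr <- prior_trace(events, observer_config(alpha = 1),
                    intentions = c("likely", "unlikely"))
  expect_lt(abs(tr$likely[500] - 2 / 3), 0.02)
})

test_that("prior trace validates its inputs", {
  expect_error(prior_trace(c("A", "C"), intentions = c("A", "B")), "unknown")
  expect_error(observer_config(alpha = 0.5), "alpha")
  expect_error(observer_config(smoothing = 0), "smoothing")
})

test_that("singleton grid fixes alpha_hat and the objective curve", {
  d <- sim_choices(300, alpha_true = 1, betas = c(0, 1, 1, -0.5), seed = 2)
  fit <- fit_alpha(d$event, d$evidence, d$correct, grid = 1.0)
  expect_equal(fit$alpha_hat, 1.0)
  expect_equal(nrow(fit$objective_curve), 1L)
})

test_that("alpha near 1 is recovered from an ideal-observer subject", {
  d <- sim_choices(2000, alpha_true = 1, betas = c(0, 1.5, 1, -0.5), seed = 5)
  fit <- fit_alpha(d$event, d$evidence, d$correct,
                   grid = seq(1, 2, by = 0.1), refine = FALSE)
  expect_lte(fit$alpha_hat, 1.2)
})

test_that("decaying-memory alpha is recovered within tolerance", {
  hits <- 0
  for (s in 1:10) {
    d <- sim_choices(5000, alpha_true = 1.5, betas = c(0, 2, 1, -0.5),
                     seed = 100 + s)
    fit <- fit_alpha(d$event, d$evidence, d$correct,
                     grid = seq(1, 2.5, by = 0.05), refine = FALSE)
    hits <- hits + (abs(fit$alpha_hat - 1.5) <= 0.15)
  }
  expect_gte(hits, 8)
})

test_that("constant correct responses raise the separation flag", {
  d <- sim_choices(200, alpha_true = 1, betas = c(0, 1, 1, 0), seed = 3)
  d$correct <- 1L
  suppressWarnings(
    fit <- fit_alpha(d$event, d$evidence, d$correct, grid = c(1, 1.5))
  )
  expect_true(fit$separation)
})
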