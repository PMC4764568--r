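make_toy <- function(n = 4000, n_trials = 2, gain = 2, bias = -2.5,
                     h = c(-2, -1), seed = 1) {
  set.seed(seed)
  x <- as.numeric(stats::filter(rnorm(n), 0.9, method = "recursive"))
  x <- x / sd(x)
  tb <- cbind(start = seq(1L, n, by = n %/% n_trials),
              end = c(seq(1L + n %/% n_trials, n, by = n %/% n_trials),
                      n + 1L))
  m <- whisker_glm(list(x = gain), history_filter = h, bias = bias)
  sp <- predict_glm(m, list(x = x), tb, type = "sampled", seed = seed)
  list(x = x, tb = tb, spikes = sp$spikes, model = m)
}

test_that("design matrices have the documented parameter counts and
           never mix trials", {
  toy <- make_toy()
  d1 <- build_design(toy$x, toy$spikes, toy$tb, L_k = 1, L_h = 2)
  expect_identical(ncol(d1$X), 4L)  # 1 stimulus + 2 history + bias
  d5 <- build_design(toy$x, toy$spikes, toy$tb, L_k = 5, L_h = 2)
  expect_identical(ncol(d5$X), 8L)  # 5 stimulus + 2 history + bias
  # brute-force row check on a two-trial design: stimulus lags z-scored,
  # spike history strictly pre-t, no row crosses the trial boundary
  zx <- (toy$x - mean(toy$x)) / sd(toy$x)
  maxL <- 5L
  for (t in c(maxL + 1L, 57L, toy$tb[2, "start"] + maxL)) {
    row <- which(d5$rows == t)
    expect_equal(d5$X[row, 1:5], zx[t:(t - 4)], ignore_attr = TRUE)
    expect_equal(d5$X[row, 6:7], toy$spikes[c(t - 1, t - 2)],
                 ignore_attr = TRUE)
  }
  # the first max(L_k, L_h) bins of each trial are masked
  for (s in toy$tb[, "start"])
    expect_false(any(d5$rows %in% (s:(s + maxL - 1L))))
  expect_error(build_design(toy$x, toy$spikes[-1], toy$tb), "aligned")
  expect_error(build_design(toy$x, toy$spikes, toy$tb, L_k = 0), "L_k")
})

test_that("penalized NLL equals T log 2 at zero and scales linearly in
           alpha", {
  toy <- make_toy(n = 2000)
  d <- build_design(toy$x, toy$spikes, toy$tb, L_k = 3, L_h = 2)
  z <- penalized_nll(d, numeric(ncol(d$X)), alpha = 0.01)
  expect_equal(z$value, length(d$y) * log(2))
  theta <- rnorm(ncol(d$X))
  v1 <- penalized_nll(d, theta, alpha = 0.01)$value
  v2 <- penalized_nll(d, theta, alpha = 0.02)$value
  nll <- penalized_nll(d, theta, alpha = 0)$value
  expect_equal(v2 - nll, 2 * (v1 - nll))
})

test_that("analytic gradient matches central finite differences", {
  set.seed(31)
  for (i in 1:5) {
    toy <- make_toy(n = 800, seed = 30 + i)
    d <- build_design(toy$x, toy$spikes, toy$tb, L_k = 3, L_h = 2)
    theta <- rnorm(ncol(d$X), sd = 0.5)
    got <- penalized_nll(d, theta, alpha = 0.01)$gradient
    want <- fd_gradient(function(th)
      penalized_nll(d, th, alpha = 0.01)$value, theta, eps = 1e-5)
    expect_lt(max(abs(got - want)) / max(abs(want)), 1e-6)
  }
})

test_that("fitting descends, converges from random restarts, and matches
           the training rate", {
  toy <- make_toy(n = 20000, n_trials = 4)
  d <- build_design(toy$x, toy$spikes, toy$tb, L_k = 2, L_h = 2)
  fit <- fit_glm(design = d, alpha = 0.01)
  expect_lte(attr(fit, "final_nll"),
             penalized_nll(d, numeric(ncol(d$X)), 0.01)$value)
  # convexity: random restarts land on the same optimum
  set.seed(77)
  for (i in 1:3) {
    alt <- fit_glm(design = d, alpha = 0.01, init = rnorm(ncol(d$X)))
    expect_equal(attr(alt, "final_nll"), attr(fit, "final_nll"),
                 tolerance = 1e-7)
    expect_equal(alt$bias, fit$bias, tolerance = 1e-4)
  }
  # near-identity for logistic MLE with a bias term
  pr <- predict_glm(fit, list(x = toy$x), toy$tb, type = "sampled",
                    seed = 1)$prob
  expect_lt(abs(mean(pr[d$rows]) / mean(d$y) - 1), 0.02)
  expect_error(fit_glm(toy$x, integer(length(toy$x)), toy$tb),
               "degenerate")
})

test_that("ridge fit agrees with stats::glm at alpha ~ 0", {
  toy <- make_toy(n = 20000, n_trials = 2)
  d <- build_design(toy$x, toy$spikes, toy$tb, L_k = 1, L_h = 2)
  fit <- fit_glm(design = d, alpha = 1e-10)
  ref <- stats::glm(d$y ~ d$X[, 1] + d$X[, 2] + d$X[, 3],
                    family = binomial())
  want <- unname(coef(ref))
  # fit reports raw-unit filters; re-standardize for comparison
  zgain <- fit$stimulus_filters$x * d$scaling$x$scale
  zbias <- fit$bias + fit$stimulus_filters$x * d$scaling$x$center
  expect_equal(c(zbias, zgain, fit$history_filter), want,
               tolerance = 1e-4)
})

test_that("sampled and expected predictions agree when history is zero", {
  toy <- make_toy(n = 3000, h = c(0, 0))
  m <- toy$model
  pe <- predict_glm(m, list(x = toy$x), toy$tb, type = "expected")
  ps <- predict_glm(m, list(x = toy$x), toy$tb, type = "sampled", seed = 4)
  expect_equal(ps$prob, pe$prob)
  ps2 <- predict_glm(m, list(x = toy$x), toy$tb, type = "sampled", seed = 4)
  expect_identical(ps$spikes, ps2$spikes)
})

test_that("negative history filters produce refractoriness", {
  # strong inhibitory history: probability is depressed after a spike
  n <- 20000
  x <- rep(0, n)
  tb <- cbind(start = 1L, end = n + 1L)
  m <- whisker_glm(list(x = 0), history_filter = c(-6, -3), bias = -1)
  ps <- predict_glm(m, list(x = x), tb, type = "sampled", seed = 5)
  spk <- which(ps$spikes == 1L)
  spk <- spk[spk < n - 2]
  base <- 1 / (1 + exp(1))
  expect_lt(mean(ps$prob[spk + 1]), 0.05)          # logistic(-7)
  expect_lt(mean(ps$prob[spk + 2][ps$spikes[spk + 1] == 0]), base)
  # and the same spike rarely repeats in adjacent bins
  expect_lt(mean(ps$spikes[spk + 1]), 0.05)
})

test_that("preferred direction follows the sign of a single-tap filter", {
  mk <- function(k) whisker_glm(list(curvature_change = k),
                                history_filter = c(0, 0), bias = -2)
  expect_identical(preferred_direction(mk(0.3)), "positive")
  expect_identical(preferred_direction(mk(-0.3)), "negative")
  expect_identical(preferred_direction(mk(0)), "undetermined")
  expect_error(preferred_direction(
    whisker_glm(list(a = c(1, 2)), history_filter = 0, bias = 0)),
    "length-1")
  # round trip: a positive-curvature-tuned unit refit from its own spikes
  ses <- generate_session("passive_whitenoise", 10, seed = 52)
  gamma <- 2 / sd(ses$curvature_change_invmm)
  gen <- whisker_glm(list(curvature_change = gamma),
                     history_filter = c(-2, -1), bias = -3)
  sp <- generate_spikes_from_glm(gen, ses, seed = 53)
  fit <- fit_glm(session_features(ses, "curvature_change"), sp,
                 ses$trial_bounds, L_k = 1, L_h = 2)
  expect_identical(preferred_direction(fit), "positive")
})

test_that("quadratic models capture U-shaped tuning that linear ones miss", {
  set.seed(61)
  n <- 60000
  x <- as.numeric(stats::filter(rnorm(n), 0.95, method = "recursive"))
  x <- x / sd(x)
  tb <- cbind(start = 1L, end = n + 1L)
  # magnitude-tuned unit: fires for large |x| of either sign
  prob <- plogis(-4 + 2.5 * x^2)
  spikes <- as.integer(runif(n) < prob)
  dq <- build_design(list(x = x), spikes, tb, L_k = 1, L_h = 2,
                     quadratic = TRUE)
  expect_identical(ncol(dq$X), 5L)  # 1 linear + 1 quadratic + 2 hist + bias
  fq <- fit_glm(design = dq, alpha = 0.01)
  expect_gt(fq$quad_filters$x, 1)          # positive U-shape weight
  fl <- fit_glm(list(x = x), spikes, tb, L_k = 1, L_h = 2)
  pq <- predict_glm(fq, list(x = x), tb, type = "expected")$prob
  pl <- predict_glm(fl, list(x = x), tb, type = "expected")$prob
  rows <- dq$rows
  expect_gt(cor(pq[rows], prob[rows]), 0.95)
  expect_gt(cor(pq[rows], prob[rows]), cor(pl[rows], prob[rows]) + 0.3)
})
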