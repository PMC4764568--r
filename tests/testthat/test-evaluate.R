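test_that("trial splits are disjoint, exhaustive and seed-dependent", {
  sp <- split_trials(10, seed = 1)
  expect_length(sp$train, 5)
  expect_length(sp$test, 5)
  expect_identical(sort(c(sp$train, sp$test)), 1:10)
  expect_length(intersect(sp$train, sp$test), 0)
  draws <- vapply(1:10, function(s)
    paste(split_trials(10, seed = s)$train, collapse = ","), "")
  expect_gt(length(unique(draws)), 5)
  expect_error(split_trials(1), "at least 2")
})

test_that("box-car smoothing preserves mass and respects trials", {
  expect_equal(smooth_boxcar(rep(2, 500), 100), rep(2, 500))
  # single spike spreads into a 1/width plateau of width bins
  x <- numeric(500); x[250] <- 1
  s <- smooth_boxcar(x, 100)
  expect_equal(sum(s > 0), 100)
  expect_equal(max(s), 1 / 100)
  expect_equal(sum(s), 1)
  # matches brute-force convolution away from edges
  set.seed(2)
  y <- rpois(400, 0.1)
  s2 <- smooth_boxcar(y, 21)
  for (t in c(50, 200, 350))
    expect_equal(s2[t], mean(y[(t - 10):(t + 10)]))
  # no bleed across a trial boundary
  tb <- cbind(start = c(1L, 251L), end = c(251L, 501L))
  x2 <- numeric(500); x2[250] <- 1
  s3 <- smooth_boxcar(x2, 100, tb)
  expect_equal(s3[251:500], rep(0, 250))
  expect_error(smooth_boxcar(rnorm(50), 100), "exceeds")
})

test_that("pcc handles the standard and degenerate cases", {
  set.seed(3)
  a <- rnorm(1000)
  expect_equal(pcc(a, a), 1)
  expect_equal(pcc(a, -a), -1)
  expect_lt(abs(pcc(rnorm(1e5), rnorm(1e5))), 0.01)
  expect_warning(r <- pcc(rep(1, 10), rnorm(10)), "zero-variance")
  expect_true(is.na(r))
  expect_error(pcc(1:3, 1:4), "equal length")
})

test_that("cross-validated prediction is high with signal, null without", {
  ses <- generate_session("passive_whitenoise", 12, seed = 41)
  gamma <- 15 / sd(ses$curvature_change_invmm)  # strong gain
  gen <- whisker_glm(list(curvature_change = gamma),
                     history_filter = c(-3, -1), bias = 0)
  gen <- tune_bias_to_rate(gen, ses, 50, seed = 42)
  sp <- generate_spikes_from_glm(gen, ses, seed = 43)
  res <- cross_validated_pcc(ses, sp, glm_config("curvature_change"),
                             seed = 44)
  expect_length(res$pcc_per_repeat, 10)
  expect_true(all(abs(res$pcc_per_repeat) <= 1))
  expect_gt(res$median_pcc, 0.7)
  # spikes with no relation to the stimulus
  set.seed(45)
  null_sp <- as.integer(runif(n_bins(ses)) < 0.05)
  res0 <- cross_validated_pcc(ses, null_sp, glm_config("curvature_change"),
                              seed = 46)
  expect_lt(abs(res0$median_pcc), 0.05)
  # the smoothing sweep runs at every stated width
  for (w in c(1, 5, 10, 20, 50, 70, 100)) {
    r <- cross_validated_pcc(ses, sp, glm_config("curvature_change"),
                             n_repeats = 2, smoothing_ms = w, seed = 47)
    expect_true(is.finite(r$median_pcc))
  }
})

test_that("chance PCCs cluster near zero for a stimulus-locked unit", {
  ses <- generate_session("passive_whitenoise", 12, seed = 51)
  gamma <- 15 / sd(ses$curvature_change_invmm)
  gen <- whisker_glm(list(curvature_change = gamma),
                     history_filter = c(-3, -1), bias = 0)
  gen <- tune_bias_to_rate(gen, ses, 50, seed = 52)
  sp <- generate_spikes_from_glm(gen, ses, seed = 53)
  ch <- chance_pcc(ses, sp, glm_config("curvature_change"), seed = 54)
  expect_true(all(ch$shifts_ms >= 3000 & ch$shifts_ms <= 8000))
  expect_lt(abs(median(ch$chance_pccs)), 0.1)
  expect_error(chance_pcc(ses, sp, shift_range_ms = c(0, 100)),
               "zero not allowed")
  short <- generate_session("passive_whitenoise", 2, seed = 55)
  expect_error(chance_pcc(short, sp$counts[1:n_bins(short)],
                          glm_config("curvature_change")), "shorter")
})

test_that("signed-rank significance behaves at the corrected threshold", {
  set.seed(61)
  ch <- rnorm(10, 0, 0.02)
  expect_false(significance(ch, ch)$significant)
  # a uniform +0.5 offset over 10 pairs is significant at p = 0.0025
  # (one-sided exact signed-rank: min p = 2^-10 < 0.0025)
  s <- significance(ch + 0.5, ch)
  expect_true(s$significant)
  expect_lt(s$p_value, 0.0025)
  expect_error(significance(rnorm(10), rnorm(9)), "equal size")
  # threshold is configurable
  expect_false(significance(ch + 0.5, ch, p = 1e-5)$significant)
})

test_that("episode rates split spikes by touch label", {
  touch <- c(rep(0, 600), rep(1, 400))
  sp <- integer(1000); sp[601:1000] <- rbinom(400, 1, 0.2)
  r <- episode_rates(sp, touch)
  expect_equal(r$nontouch, 0)
  expect_equal(r$touch, 1000 * mean(sp[601:1000]))
  # a homogeneous train has equal rates in both classes
  set.seed(62)
  hom <- as.integer(runif(60000) < 0.01)
  touch2 <- as.integer(runif(60000) < 0.3)
  r2 <- episode_rates(hom, touch2)
  expect_lt(abs(r2$touch - 10), 2.5)
  expect_lt(abs(r2$nontouch - 10), 2.5)
  expect_error(episode_rates(hom, rep(0L, 60000)), "must be present")
  # a curvature-driven unit fires faster during touch
  ses <- generate_session("active_pole", 12, seed = 63)
  gamma <- 4 / sd(ses$curvature_change_invmm)
  gen <- whisker_glm(list(curvature_change = gamma),
                     history_filter = c(-2, -1), bias = -4.5)
  spk <- generate_spikes_from_glm(gen, ses, seed = 64)
  r3 <- episode_rates(spk, ses$touch)
  expect_gt(r3$touch, r3$nontouch)
})

test_that("cross-correlation finds lags and matches the shifted oracle", {
  set.seed(71)
  a <- as.numeric(stats::filter(rnorm(3000), 0.9, method = "recursive"))
  cc <- cross_correlation(a, a, 20)
  expect_equal(cc$cor[cc$lag_ms == 0], 1)
  expect_equal(cc$lag_ms[which.max(cc$cor)], 0)
  b <- c(rep(0, 7), a[1:(3000 - 7)])  # a delayed by 7 ms
  cc2 <- cross_correlation(a, b, 20)
  expect_equal(cc2$lag_ms[which.max(cc2$cor)], 7)
  # brute-force shifted-Pearson oracle at every lag
  d <- rnorm(500)
  e <- as.numeric(stats::filter(rnorm(500), 0.5, method = "recursive"))
  cc3 <- cross_correlation(d, e, 10)
  for (L in c(-10, -3, 0, 4, 10)) {
    n <- 500
    want <- if (L >= 0) cor(d[1:(n - L)], e[(1 + L):n])
            else cor(d[(1 - L):n], e[1:(n + L)])
    expect_equal(cc3$cor[cc3$lag_ms == L], want)
  }
})

test_that("prediction accuracy rises with generating gain", {
  ses <- generate_session("passive_whitenoise", 10, seed = 81)
  meds <- vapply(c(0.5, 2, 8), function(g) {
    m <- vapply(1:3, function(s) {
      gen <- whisker_glm(
        list(curvature_change = g / sd(ses$curvature_change_invmm)),
        history_filter = c(-2, -1), bias = 0)
      gen <- tune_bias_to_rate(gen, ses, 40, seed = 80 + s)
      sp <- generate_spikes_from_glm(gen, ses, seed = 90 + s)
      cross_validated_pcc(ses, sp, glm_config("curvature_change"),
                          n_repeats = 4, seed = 100 + s)$median_pcc
    }, 1)
    mean(m)
  }, 1)
  expect_true(all(diff(meds) > 0))
})

test_that("touch-restricted evaluation is supported", {
  ses <- generate_session("active_pole", 12, seed = 91)
  gamma <- 4 / sd(ses$curvature_change_invmm)
  gen <- whisker_glm(list(curvature_change = gamma),
                     history_filter = c(-2, -1), bias = -4)
  sp <- generate_spikes_from_glm(gen, ses, seed = 92)
  rt <- cross_validated_pcc(ses, sp, glm_config("curvature_change"),
                            n_repeats = 3, seed = 93,
                            bin_filter = "touch")
  rn <- cross_validated_pcc(ses, sp, glm_config("curvature_change"),
                            n_repeats = 3, seed = 93,
                            bin_filter = "nontouch")
  expect_true(is.finite(rt$median_pcc))
  expect_true(is.finite(rn$median_pcc))
  # the restricted scores are genuinely different evaluations
  expect_false(isTRUE(all.equal(rt$median_pcc, rn$median_pcc)))
})
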