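#' GLM configuration for evaluation pipelines
#'
#' Bundles the encoding-model choices used by [cross_validated_pcc()],
#' [chance_pcc()] and [run_pipeline()]. Defaults follow the standard
#' analysis: 5-tap stimulus filter, 2-tap spike-history filter, ridge
#' weight 0.01.
#'
#' @param features character vector of session feature names (see
#'   [session_features()]).
#' @param L_k,L_h stimulus / spike-history filter lengths (bins).
#' @param alpha ridge weight on stimulus filters.
#' @param quadratic use squared z-scored stimulus terms as well.
#' @return A `glm_config` list.
#' @export
glm_config <- function(features = "curvature_change", L_k = 5, L_h = 2,
                       alpha = 0.01, quadratic = FALSE) {
  stopifnot(L_k >= 1, L_h >= 0, alpha >= 0)
  structure(list(features = features, L_k = as.integer(L_k),
                 L_h = as.integer(L_h), alpha = alpha,
                 quadratic = isTRUE(quadratic)),
            class = "glm_config")
}

#' Random train/test split of trials
#'
#' @param session a [whisker_session()] or an integer trial count.
#' @param fraction fraction of trials assigned to training (default 0.5).
#' @param seed RNG seed.
#' @return `list(train, test)` of disjoint, exhaustive trial indices.
#' @export
split_trials <- function(session, fraction = 0.5, seed = NULL) {
  n <- if (inherits(session, "whisker_session"))
    nrow(session$trial_bounds) else as.integer(session)
  if (n < 2L) stop("need at least 2 trials to split")
  n_train <- max(1L, min(n - 1L, round(fraction * n)))
  train <- with_seed(seed, sort(sample.int(n, n_train)))
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Box-car smoothing of spike or probability series
#'
#' Moving average with a `width_ms` box-car, applied within trials only (no
#' mass bleeds across trial boundaries). Windows are truncated at trial
#' edges and normalized by their actual overlap, so a constant series is
#' unchanged and the mean is preserved.
#'
#' @param x numeric series (spike counts or probabilities) at 1 ms bins.
#' @param width_ms box-car width in ms (>= 1).
#' @param trial_bounds optional half-open trial intervals; default one
#'   trial spanning the whole series.
#' @return Smoothed series, same length as `x`.
#' @export
smooth_boxcar <- function(x, width_ms = 100, trial_bounds = NULL) {
  w <- as.integer(width_ms)
  if (w < 1L) stop("width_ms must be >= 1")
  n <- length(x)
  tb <- if (is.null(trial_bounds)) cbind(start = 1L, end = n + 1L)
        else check_trial_bounds(trial_bounds, n)
  if (any(tb[, "end"] - tb[, "start"] < w))
    stop("width_ms exceeds the length of a trial")
  lo <- (w - 1L) %/% 2L
  hi <- w - 1L - lo
  out <- numeric(n)
  for (i in seq_len(nrow(tb))) {
    idx <- tb[i, "start"]:(tb[i, "end"] - 1L)
    s <- cumsum(x[idx])
    m <- length(idx)
    t <- seq_len(m)
    up <- pmin(m, t + hi)
    dn <- pmax(0L, t - lo - 1L)
    upper <- s[up]
    lower <- ifelse(dn >= 1L, s[pmax(1L, dn)], 0)
    out[idx] <- (upper - lower) / (up - dn)
  }
  out
}

#' Pearson correlation between two aligned series
#'
#' @param a,b equal-length numeric vectors; pairs with `NA` are dropped.
#' @return Pearson r, or `NA` with a warning if either input has zero
#'   variance.
#' @export
pcc <- function(a, b) {
  if (length(a) != length(b)) stop("inputs must have equal length")
  ok <- !(is.na(a) | is.na(b))
  a <- a[ok]; b <- b[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero-variance input: PCC undefined")
    return(NA_real_)
  }
  stats::cor(a, b)
}

# Bins used for scoring: test-trial bins minus the first max(L_k, L_h)
# bins of each trial (incomplete histories), optionally filtered by touch.
scoring_bins <- function(session, trials, config,
                         bin_filter = c("all", "touch", "nontouch")) {
  bin_filter <- match.arg(bin_filter)
  tb <- session$trial_bounds
  maxL <- max(config$L_k, config$L_h)
  bins <- unlist(lapply(trials, function(i) {
    s <- tb[i, "start"] + maxL; e <- tb[i, "end"] - 1L
    if (s > e) integer(0) else s:e
  }))
  if (bin_filter == "touch") bins <- bins[session$touch[bins] == 1L]
  if (bin_filter == "nontouch") bins <- bins[session$touch[bins] == 0L]
  bins
}

# One train/predict/score pass for a fixed trial split.
fit_and_score <- function(session, counts, config, split, smoothing_ms,
                          seed, bin_filter = "all") {
  feats <- session_features(session, config$features)
  train_bins <- unlist(lapply(split$train, function(i)
    session$trial_bounds[i, "start"]:(session$trial_bounds[i, "end"] - 1L)))
  design <- build_design(feats, counts, session$trial_bounds,
                         L_k = config$L_k, L_h = config$L_h,
                         quadratic = config$quadratic, bins = train_bins)
  model <- fit_glm(design = design, alpha = config$alpha)
  pred <- predict_glm(model, feats, session$trial_bounds,
                      type = "sampled", seed = seed)
  sm_rec <- smooth_boxcar(counts, smoothing_ms, session$trial_bounds)
  sm_prd <- smooth_boxcar(pred$spikes, smoothing_ms, session$trial_bounds)
  bins <- scoring_bins(session, split$test, config, bin_filter)
  list(pcc = pcc(sm_rec[bins], sm_prd[bins]), model = model)
}

#' Cross-validated single-trial prediction accuracy
#'
#' For each of `n_repeats` random half splits of the trials, fits the GLM
#' on the training trials, generates one sampled predicted spike train,
#' smooths recorded and predicted trains with a `smoothing_ms` box-car
#' (within trials), and computes the Pearson correlation over the
#' concatenated test-trial bins. Reports per-repeat PCCs and their median.
#'
#' @param session a [whisker_session()].
#' @param spikes a [spike_train()] or binary vector.
#' @param config a [glm_config()].
#' @param n_repeats number of random train/test splits (default 10).
#' @param smoothing_ms box-car width (default 100; the sweep
#'   1/5/10/20/50/70/100 ms is supported).
#' @param seed master seed; expanded into per-repeat sub-seeds (logged in
#'   the result for replay).
#' @param bin_filter score all test bins (default), only touch bins, or
#'   only non-touch bins.
#' @return List with `pcc_per_repeat`, `median_pcc`, `models`,
#'   `smoothing_ms`, `seed`, `repeat_seeds`.
#' @export
cross_validated_pcc <- function(session, spikes, config = glm_config(),
                                n_repeats = 10, smoothing_ms = 100,
                                seed = NULL, bin_filter = "all") {
  counts <- if (inherits(spikes, "spike_train")) spikes$counts else spikes
  seeds <- child_seeds(seed, 2L * n_repeats)
  pccs <- numeric(n_repeats)
  models <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    res <- tryCatch({
      split <- split_trials(session, seed = seeds[[2L * r - 1L]])
      fit_and_score(session, counts, config, split, smoothing_ms,
                    seed = seeds[[2L * r]], bin_filter = bin_filter)
    }, error = function(e)
      stop("repeat ", r, " failed: ", conditionMessage(e), call. = FALSE))
    pccs[r] <- res$pcc
    models[[r]] <- res$model
  }
  list(pcc_per_repeat = pccs, median_pcc = stats::median(pccs),
       models = models, smoothing_ms = smoothing_ms, seed = seed,
       repeat_seeds = seeds)
}

#' Chance prediction accuracy by circular spike-train shifts
#'
#' The null hypothesis that a prediction score is explained by random
#' firing at the recorded rate: the spike sequence is circularly shifted by
#' a uniform draw in `shift_range_ms` (rate exactly preserved, stimulus
#' alignment broken) and the full train/test procedure re-applied per
#' shift. By default each shift uses a fresh random split.
#'
#' @inheritParams cross_validated_pcc
#' @param n number of shifts (default 10).
#' @param shift_range_ms inclusive shift bounds in ms (default 3000-8000);
#'   a shift of 0 is not permitted and the recording must be longer than
#'   the maximum shift.
#' @param splits optional list of fixed `list(train, test)` splits to reuse
#'   (length `n`) instead of fresh ones.
#' @return List with `chance_pccs`, `shifts_ms`, `seed`.
#' @export
chance_pcc <- function(session, spikes, config = glm_config(), n = 10,
                       shift_range_ms = c(3000, 8000), smoothing_ms = 100,
                       seed = NULL, splits = NULL, bin_filter = "all") {
  counts <- if (inherits(spikes, "spike_train")) spikes$counts else spikes
  T_ms <- n_bins(session)
  if (any(shift_range_ms < 1) || shift_range_ms[2] < shift_range_ms[1])
    stop("shift_range_ms must be positive and ordered (zero not allowed)")
  if (T_ms <= shift_range_ms[2])
    stop("recording shorter than the maximum shift")
  seeds <- child_seeds(seed, 3L * n)
  pccs <- numeric(n)
  shifts <- integer(n)
  for (j in seq_len(n)) {
    shifts[j] <- with_seed(seeds[[3L * j - 2L]],
      sample(seq.int(shift_range_ms[1], shift_range_ms[2]), 1L))
    shifted <- c(tail(counts, shifts[j]), head(counts, T_ms - shifts[j]))
    split <- if (is.null(splits))
      split_trials(session, seed = seeds[[3L * j - 1L]]) else splits[[j]]
    pccs[j] <- fit_and_score(session, shifted, config, split, smoothing_ms,
                             seed = seeds[[3L * j]], bin_filter)$pcc
  }
  list(chance_pccs = pccs, shifts_ms = shifts, seed = seed)
}

#' Significance of prediction accuracy against chance
#'
#' Paired signed-rank comparison of the actual per-repeat PCCs against the
#' chance PCCs at threshold `p` (default 0.0025, i.e. 0.05
#' Bonferroni-corrected over 20 units).
#'
#' @param actual_pccs,chance_pccs equal-length paired PCC sets (typically
#'   10 each).
#' @param p significance threshold (default 0.0025).
#' @param alternative test direction (default `"greater"`: actual exceeds
#'   chance).
#' @return `list(significant, p_value, threshold)`.
#' @export
significance <- function(actual_pccs, chance_pccs, p = 0.0025,
                         alternative = "greater") {
  if (length(actual_pccs) != length(chance_pccs))
    stop("actual and chance PCC sets must have equal size")
  pv <- suppressWarnings(
    stats::wilcox.test(actual_pccs, chance_pccs, paired = TRUE,
                       alternative = alternative)$p.value)
  list(significant = is.finite(pv) && pv < p, p_value = pv, threshold = p)
}

#' Full single-unit evaluation with chance control
#'
#' Runs [cross_validated_pcc()] and [chance_pcc()] and applies
#' [significance()]; the standard test for whether a unit is sensitive to
#' a sensory feature (e.g. "curvature-sensitive").
#'
#' @inheritParams cross_validated_pcc
#' @param n_repeats repeats for both the actual and the chance sets.
#' @param shift_range_ms circular shift bounds for the chance control.
#' @param p significance threshold passed to [significance()].
#' @return List with the actual results, `chance_pccs`, `significant`,
#'   `p_value`, `smoothing_ms`, `seed`.
#' @export
evaluate_unit <- function(session, spikes, config = glm_config(),
                          n_repeats = 10, smoothing_ms = 100,
                          shift_range_ms = c(3000, 8000), p = 0.0025,
                          seed = NULL, bin_filter = "all") {
  seeds <- child_seeds(seed, 2L)
  act <- cross_validated_pcc(session, spikes, config, n_repeats,
                             smoothing_ms, seed = seeds[[1]], bin_filter)
  ch <- chance_pcc(session, spikes, config, n = n_repeats,
                   shift_range_ms = shift_range_ms,
                   smoothing_ms = smoothing_ms, seed = seeds[[2]],
                   bin_filter = bin_filter)
  sig <- significance(act$pcc_per_repeat, ch$chance_pccs, p = p)
  list(pcc_per_repeat = act$pcc_per_repeat, median_pcc = act$median_pcc,
       chance_pccs = ch$chance_pccs,
       chance_median = stats::median(ch$chance_pccs),
       significant = sig$significant, p_value = sig$p_value,
       smoothing_ms = smoothing_ms, seed = seed)
}

#' Firing rates over touch and non-touch episodes
#'
#' @param spikes a [spike_train()], binary vector, or a probability series
#'   (expected rates).
#' @param touch_labels binary touch labels aligned with `spikes`.
#' @param fs sampling rate in Hz (default 1000).
#' @return `list(touch, nontouch)` rates in spikes/s.
#' @export
episode_rates <- function(spikes, touch_labels, fs = 1000) {
  x <- if (inherits(spikes, "spike_train")) spikes$counts else spikes
  touch_labels <- as.integer(touch_labels)
  if (length(x) != length(touch_labels)) stop("labels must be aligned")
  if (!any(touch_labels == 1L) || !any(touch_labels == 0L))
    stop("both touch and non-touch episodes must be present")
  list(touch = fs * mean(x[touch_labels == 1L]),
       nontouch = fs * mean(x[touch_labels == 0L]))
}

#' Normalized cross-correlation between two series
#'
#' Pearson correlation at each integer-ms lag in `-max_lag_ms..max_lag_ms`
#' (positive lag: `b` delayed relative to `a`). The zero-lag value is the
#' plain correlation between the series.
#'
#' @param a,b equal-length numeric series.
#' @param max_lag_ms maximum lag in ms.
#' @return Data frame with columns `lag_ms` and `cor`.
#' @export
cross_correlation <- function(a, b, max_lag_ms = 50) {
  n <- length(a)
  if (length(b) != n) stop("inputs must have equal length")
  lags <- seq.int(-max_lag_ms, max_lag_ms)
  r <- vapply(lags, function(L) {
    if (L >= 0) pcc(a[seq_len(n - L)], b[seq_len(n - L) + L])
    else pcc(a[seq_len(n + L) - L], b[seq_len(n + L)])
  }, 1)
  data.frame(lag_ms = lags, cor = r)
}
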