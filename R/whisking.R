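#' Whisking amplitude and phase by band-pass filter and Hilbert transform
#'
#' The whisker angle is band-pass filtered in the whisking band (default
#' 6-30 Hz; zero-phase forward-backward Butterworth) and the analytic
#' signal computed per trial. The modulus gives the instantaneous whisking
#' amplitude (degrees), the argument the phase in (-pi, pi], with phase 0
#' at maximum protraction (peak of the band-passed angle).
#'
#' @param angle_series whisker angle (degrees) at 1 ms bins.
#' @param trial_bounds optional half-open trial intervals; filtering and
#'   the analytic signal are computed per trial. Default: one trial.
#' @param band band edges in Hz (default `c(6, 30)`).
#' @param fs sampling rate in Hz (default 1000).
#' @param order Butterworth order (default 2; applied forward and backward
#'   so the effective order is doubled).
#' @return An object of class `whisking_state`: list with `amplitude`
#'   (deg, >= 0), `phase` (radians in (-pi, pi]) and `filtered` (the
#'   band-passed angle).
#' @export
decompose_whisking <- function(angle_series, trial_bounds = NULL,
                               band = c(6, 30), fs = 1000, order = 2) {
  n <- length(angle_series)
  tb <- if (is.null(trial_bounds)) cbind(start = 1L, end = n + 1L)
        else check_trial_bounds(trial_bounds, n)
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  min_len <- 3L * (2L * order + 1L)
  amplitude <- numeric(n); phase <- numeric(n); filtered <- numeric(n)
  for (i in seq_len(nrow(tb))) {
    idx <- tb[i, "start"]:(tb[i, "end"] - 1L)
    if (length(idx) < min_len)
      stop("trial ", i, " shorter than the filter transient")
    xf <- signal::filtfilt(bf, angle_series[idx])
    an <- analytic_signal(xf)
    filtered[idx] <- xf
    amplitude[idx] <- Mod(an)
    phase[idx] <- Arg(an)
  }
  structure(list(amplitude = amplitude, phase = phase, filtered = filtered,
                 band = band, fs = fs),
            class = "whisking_state")
}

#' Equi-populated tuning curve
#'
#' Discretises a continuous variable into `n_bins` bins containing (nearly)
#' equal numbers of samples (quantile-style edges via rank order; per-bin
#' counts differ by at most 1) and computes the mean firing rate and SEM
#' per bin.
#'
#' @param variable_series continuous variable per 1 ms bin (`NA` dropped
#'   together with the matching spikes).
#' @param spikes aligned binary spike counts (or [spike_train()]).
#' @param n_bins number of bins (30 for amplitude, 8 for phase tuning in
#'   the standard battery).
#' @param fs sampling rate (Hz), for spikes/s scaling.
#' @return An object of class `tuning_curve`: data frame with columns
#'   `bin`, `center` (mean of the variable in the bin), `lo`, `hi` (edge
#'   values), `rate` (spikes/s), `sem`, `n`. Massive ties that make the
#'   quantile edges degenerate are flagged with a warning.
#' @export
equi_populated_tuning <- function(variable_series, spikes, n_bins, fs = 1000) {
  x <- variable_series
  s <- if (inherits(spikes, "spike_train")) spikes$counts else spikes
  if (length(x) != length(s)) stop("variable and spikes must be aligned")
  ok <- !is.na(x)
  x <- x[ok]; s <- s[ok]
  m <- length(x)
  if (m < n_bins) stop("need at least n_bins samples")
  ord <- order(x)
  bin <- integer(m)
  bin[ord] <- ceiling(seq_len(m) * n_bins / m)
  edges <- vapply(split(x, bin), range, numeric(2))
  if (length(unique(edges[1, ])) < n_bins / 2)
    warning("heavy ties: equi-populated bin edges are degenerate")
  agg <- function(f) vapply(split(s, bin), f, 1)
  nn <- tabulate(bin, n_bins)
  rate <- fs * agg(mean)
  sem <- fs * agg(stats::sd) / sqrt(nn)
  structure(data.frame(bin = seq_len(n_bins),
                       center = vapply(split(x, bin), mean, 1),
                       lo = edges[1, ], hi = edges[2, ],
                       rate = rate, sem = sem, n = nn),
            class = c("tuning_curve", "data.frame"))
}

#' Amplitude sensitivity: regression slope of the tuning curve
#'
#' Fits a regression line (weighted by per-bin sample counts) to the
#' amplitude tuning curve and tests whether the slope differs from 0 at
#' the configured threshold.
#'
#' @param tuning_curve an [equi_populated_tuning()] result with >= 3 bins.
#' @param p significance threshold (default 0.0025, Bonferroni-corrected).
#' @return `list(slope, p_value, significant, sign)`.
#' @export
amplitude_sensitivity <- function(tuning_curve, p = 0.0025) {
  tc <- tuning_curve
  if (nrow(tc) < 3L) stop("need at least 3 tuning bins")
  fit <- stats::lm(rate ~ center, data = tc, weights = tc$n)
  sm <- summary(fit)$coefficients
  slope <- sm["center", "Estimate"]
  pv <- sm["center", "Pr(>|t|)"]
  list(slope = slope, p_value = pv, significant = is.finite(pv) && pv < p,
       sign = sign(slope))
}

#' Phase tuning with circular-shift shuffle test
#'
#' Phase bins are restricted to bins whose whisking amplitude exceeds
#' `amp_threshold` and discretised into `n_bins` equi-populated bins. The
#' maximum of the phase tuning curve is compared with the 95th percentile
#' of maxima from `n_shuffles` chance curves obtained by circularly
#' shifting the spike sequence by uniform draws in `shift_range_ms`.
#'
#' @param state a [decompose_whisking()] result.
#' @param spikes aligned binary spike counts (or [spike_train()]).
#' @param amp_threshold amplitude threshold in degrees (default 2).
#' @param n_bins number of phase bins (default 8).
#' @param n_shuffles number of chance shifts (default 500).
#' @param shift_range_ms shift bounds in ms (default 3000-8000).
#' @param seed RNG seed.
#' @param fs sampling rate in Hz.
#' @return List with `tuning` (the phase [equi_populated_tuning()] curve),
#'   `maximum`, `null_95`, `null_maxima`, `significant`.
#' @export
phase_tuning_test <- function(state, spikes, amp_threshold = 2, n_bins = 8,
                              n_shuffles = 500,
                              shift_range_ms = c(3000, 8000), seed = NULL,
                              fs = 1000) {
  stopifnot(inherits(state, "whisking_state"))
  s <- if (inherits(spikes, "spike_train")) spikes$counts else spikes
  T_ms <- length(s)
  if (length(state$phase) != T_ms) stop("state and spikes must be aligned")
  if (T_ms <= shift_range_ms[2])
    stop("recording shorter than the maximum shift")
  supra <- which(state$amplitude > amp_threshold)
  if (length(supra) < 10L * n_bins)
    stop("insufficient supra-threshold data for phase tuning")
  tuning <- equi_populated_tuning(state$phase[supra], s[supra], n_bins, fs)
  # bin assignment over all bins (NA below threshold): fixed across
  # shuffles, so each chance curve is a cheap re-tabulation of shifted
  # spike positions
  bin_of <- rep(NA_integer_, T_ms)
  ordsup <- supra[order(state$phase[supra])]
  bin_of[ordsup] <- ceiling(seq_along(supra) * n_bins / length(supra))
  n_per <- tabulate(bin_of[supra], n_bins)
  spk <- which(s == 1L)
  null_max <- with_seed(seed, {
    shifts <- sample(seq.int(shift_range_ms[1], shift_range_ms[2]),
                     n_shuffles, replace = TRUE)
    vapply(shifts, function(sh) {
      pos <- (spk - 1L + sh) %% T_ms + 1L
      cnt <- tabulate(bin_of[pos], n_bins)
      max(fs * cnt / n_per)
    }, 1)
  })
  q95 <- stats::quantile(null_max, 0.95, names = FALSE)
  list(tuning = tuning, maximum = max(tuning$rate), null_95 = q95,
       null_maxima = null_max, significant = max(tuning$rate) > q95)
}

#' Acceleration tuning regression and directional classification
#'
#' Fits `r_i = mu0 + mu1 g(a_i) + mu2 D_i g(a_i)` to an acceleration
#' tuning curve, where `D_i = 1` for negative accelerations and 0
#' otherwise. The default regressor `g(a) = |a|` makes the classification
#' rules self-consistent for rectifier tunings; `form = "printed"` uses
#' `g(a) = a`. Classification at threshold `p`: `mu2` significantly > 0:
#' preference for negative acceleration; `mu2` significantly < 0:
#' preference for positive acceleration; otherwise `mu1` significantly
#' > 0: no preferred direction; otherwise: not acceleration sensitive.
#' In the noise-free limit (zero residual variance) significance reduces
#' to the coefficient being nonzero.
#'
#' @param tuning_curve an [equi_populated_tuning()] curve over angular
#'   acceleration, with both signs of acceleration represented.
#' @param p significance threshold (default 0.05).
#' @param form `"magnitude"` for `g(a) = |a|` (default) or `"printed"`
#'   for `g(a) = a`.
#' @return List with `mu0`, `mu1`, `mu2`, `p_mu1`, `p_mu2`, `class`
#'   (one of `"negative_pref"`, `"positive_pref"`,
#'   `"no_preferred_direction"`, `"not_sensitive"`).
#' @export
acceleration_regression <- function(tuning_curve, p = 0.05,
                                    form = c("magnitude", "printed")) {
  form <- match.arg(form)
  tc <- tuning_curve
  if (all(tc$center >= 0) || all(tc$center <= 0))
    stop("need both signs of acceleration in the tuning curve")
  g <- if (form == "magnitude") abs(tc$center) else tc$center
  D <- as.numeric(tc$center < 0)
  fit <- stats::lm(tc$rate ~ g + I(D * g), weights = tc$n)
  cf <- coef(fit)
  sm <- suppressWarnings(summary(fit))  # noise-free curves fit perfectly
  degenerate <- sm$sigma < 1e-8
  pv <- if (degenerate) ifelse(abs(cf) > 1e-8, 0, 1)
        else sm$coefficients[, "Pr(>|t|)"]
  mu1 <- cf[2]; mu2 <- cf[3]
  cls <- if (is.finite(pv[3]) && pv[3] < p && mu2 > 0) "negative_pref"
    else if (is.finite(pv[3]) && pv[3] < p && mu2 < 0) "positive_pref"
    else if (is.finite(pv[2]) && pv[2] < p && mu1 > 0)
      "no_preferred_direction"
    else "not_sensitive"
  list(mu0 = unname(cf[1]), mu1 = unname(mu1), mu2 = unname(mu2),
       p_mu1 = unname(pv[2]), p_mu2 = unname(pv[3]), class = cls)
}

#' Full whisking battery for one unit
#'
#' Runs the free-whisking analyses on the non-touch bins of a session:
#' amplitude/phase decomposition, 30-bin amplitude tuning with slope test,
#' 8-bin phase tuning with shuffle test, and acceleration tuning (8 bins)
#' with directional classification.
#'
#' @param session a [whisker_session()].
#' @param spikes a [spike_train()] or binary vector.
#' @param amp_bins,phase_bins,accel_bins tuning curve resolutions.
#' @param amp_threshold amplitude threshold (deg) for phase analysis.
#' @param n_shuffles shuffle count for the phase test.
#' @param p_amp,p_phase_quantile,p_accel thresholds.
#' @param seed RNG seed for the shuffle test.
#' @return List with `amplitude_tuning`, `amplitude`, `phase`,
#'   `acceleration_tuning`, `acceleration`.
#' @export
whisking_battery <- function(session, spikes, amp_bins = 30, phase_bins = 8,
                             accel_bins = 8, amp_threshold = 2,
                             n_shuffles = 500, p_amp = 0.0025,
                             p_phase_quantile = 0.95, p_accel = 0.05,
                             seed = NULL) {
  s <- if (inherits(spikes, "spike_train")) spikes$counts else spikes
  state <- decompose_whisking(session$angle_deg, session$trial_bounds)
  nt <- session$touch == 0L
  amp <- state$amplitude; amp[!nt] <- NA
  amp_tc <- equi_populated_tuning(amp, s, amp_bins)
  amp_res <- amplitude_sensitivity(amp_tc, p = p_amp)
  # exclude touch bins from the phase analysis by forcing them below the
  # amplitude threshold
  state_nt <- state
  state_nt$amplitude[!nt] <- -Inf
  phase_res <- phase_tuning_test(state_nt, s, amp_threshold = amp_threshold,
                                 n_bins = phase_bins,
                                 n_shuffles = n_shuffles, seed = seed)
  acc <- angular_acceleration(session$angle_deg)
  acc[!nt] <- NA
  acc_tc <- equi_populated_tuning(acc, s, accel_bins)
  acc_res <- acceleration_regression(acc_tc, p = p_accel)
  list(amplitude_tuning = amp_tc, amplitude = amp_res, phase = phase_res,
       acceleration_tuning = acc_tc, acceleration = acc_res)
}
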