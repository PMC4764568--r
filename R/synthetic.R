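#' Generate a synthetic whisking angle trace
#'
#' Free whisking is emulated as a slow setpoint plus an amplitude-modulated
#' sinusoid in the 6-30 Hz whisking band plus white measurement noise:
#' `angle(t) = setpoint(t) + A(t) sin(2 pi f t) + noise`. The setpoint
#' drifts sinusoidally and the amplitude envelope is modulated around its
#' mean. Deterministic given `seed`.
#'
#' @param duration_ms trace length in ms (1 kHz sampling).
#' @param whisk_freq_hz whisking frequency; must lie in the 6-30 Hz
#'   whisking band.
#' @param amp_envelope list with `mean_deg` (mean amplitude), `depth`
#'   (relative modulation, 0-1) and `freq_hz` (envelope frequency).
#' @param setpoint list with `mean_deg`, `amp_deg` and `freq_hz` for the
#'   slow setpoint drift.
#' @param noise_sd white-noise SD in degrees.
#' @param freq_jitter relative SD of the slow (about 200 ms time-scale)
#'   instantaneous-frequency wander; real whisking is quasi-periodic, and
#'   this drift is what makes circular-shift phase nulls meaningful.
#' @param seed RNG seed.
#' @return Numeric angle trace (degrees) of length `duration_ms`.
#' @export
generate_whisking_angle <- function(duration_ms, whisk_freq_hz = 10,
                                    amp_envelope = list(mean_deg = 15,
                                                        depth = 0.4,
                                                        freq_hz = 0.5),
                                    setpoint = list(mean_deg = 0,
                                                    amp_deg = 3,
                                                    freq_hz = 0.2),
                                    noise_sd = 0.2, freq_jitter = 0.15,
                                    seed = NULL) {
  if (duration_ms <= 0) stop("duration_ms must be > 0")
  if (whisk_freq_hz < 6 || whisk_freq_hz > 30)
    stop("whisk_freq_hz must lie in the 6-30 Hz whisking band")
  duration_ms <- as.integer(duration_ms)
  t_s <- seq_len(duration_ms) / 1000
  with_seed(seed, {
    inst_freq <- rep(whisk_freq_hz, duration_ms)
    if (freq_jitter > 0) {
      # slow multiplicative frequency wander (AR(1), ~200 ms time-scale)
      ar <- as.numeric(stats::filter(stats::rnorm(duration_ms),
                                     exp(-1 / 200), method = "recursive"))
      ar <- ar / max(stats::sd(ar), 1e-12)
      inst_freq <- whisk_freq_hz * pmax(0.5, 1 + freq_jitter * ar)
    }
    phase <- 2 * pi * cumsum(inst_freq) / 1000
    env <- amp_envelope$mean_deg *
      pmax(0, 1 + amp_envelope$depth *
                 sin(2 * pi * amp_envelope$freq_hz * t_s))
    sp <- setpoint$mean_deg +
      setpoint$amp_deg * sin(2 * pi * setpoint$freq_hz * t_s)
    noise <- if (noise_sd > 0) stats::rnorm(duration_ms, 0, noise_sd) else 0
    sp + env * sin(phase) + noise
  })
}

# Default generator parameters per protocol. These are the study
# conditions the analyses assume; see the methods vignette.
session_defaults <- function(protocol) {
  base <- list(trial_ms = 3000L)
  switch(protocol,
    active_pole = modifyList(base, list(
      whisk_freq_hz = 10,
      freq_jitter = 0.15,
      amp_envelope = list(mean_deg = 15, depth = 0.4, freq_hz = 0.5),
      setpoint = list(mean_deg = 0, amp_deg = 3, freq_hz = 0.2),
      angle_noise_sd = 0.2,
      pole_positions_mm = seq(-6, 6, length.out = 11),
      pole_delay_ms = 300L,          # pole raised into reach after this
      contact_theta0_deg = 10,       # contact threshold at pole position 0
      contact_slope_deg_per_mm = 0.9,
      dk_gain0 = 0.004,              # dkappa per deg push at position 0
      dk_gain_slope = 0.5,           # relative gain change over +/-6 mm
      retract_gain = 0.7,            # retraction pushes bend less strongly
      dk_noise_sd = 2e-4,
      ripple_gain = 1.5e-4,          # torsion-like whisking ripple in kappa
      kappa_intrinsic = -0.02,
      kappa_intrinsic_jitter = 0.002,
      kappa_noise_sd = 1e-4)),
    passive_whitenoise = modifyList(base, list(
      tau_ms = 10, angle_sd_deg = 2.1,
      dk_per_deg = 0.005,            # dkappa scale: SD = 0.005 * 2.1
      angle_dk_corr = 0.96,
      stim_delay_ms = 150L)),        # actuator at rest at trial start
    passive_trapezoid = modifyList(base, list(
      freq_hz = 10, amp_deg = 8,
      ramp_ms = 25,                  # rise/fall time within each cycle
      dk_per_deg = 0.005,
      angle_dk_corr = 0.96,
      angle_noise_sd = 0.05,
      stim_delay_ms = 150L)),
    stop("unknown protocol: ", protocol))
}

# Couple curvature change to a standardized angle-like signal at an exact
# target correlation: dk = sd_dk * (rho * z + sqrt(1-rho^2) * noise).
couple_curvature <- function(z_angle, rho, sd_dk) {
  stopifnot(rho >= 0, rho <= 1)
  z <- (z_angle - mean(z_angle)) / max(stats::sd(z_angle), 1e-12)
  eps <- stats::rnorm(length(z))
  sd_dk * (rho * z + sqrt(1 - rho^2) * eps)
}

#' Generate a synthetic session
#'
#' Emulates the statistical structure of the three recording protocols:
#'
#' * `"active_pole"`: trials of 3 s with rhythmic whisking; per trial the
#'   pole occupies one of 11 rostro-caudal positions spanning +/-6 mm
#'   (balanced in blocks of 11). Touch episodes occur when the protracting
#'   whisker angle exceeds a pole-position-dependent contact threshold;
#'   during touch, curvature change follows the push angle times a
#'   pole-position-dependent gain (curvature increases when pushing during
#'   protraction), plus noise; outside touch only a small torsion-like
#'   ripple remains. The pole is absent (no touch possible) for the first
#'   `pole_delay_ms` of each trial, leaving a clean window for intrinsic
#'   curvature estimation.
#' * `"passive_whitenoise"`: angle is Gaussian white noise convolved with a
#'   decaying exponential (time constant 10 ms), rescaled to SD 2.1
#'   degrees; curvature change is a linear rescaling of angle plus
#'   independent noise mixed so the angle-curvature correlation equals
#'   `angle_dk_corr` (default 0.96) in expectation.
#' * `"passive_trapezoid"`: 10 Hz trapezoidal deflection, amplitude 8
#'   degrees, 3 s trials, curvature coupled as in white-noise mode.
#'
#' @param protocol protocol name (see above).
#' @param n_trials number of trials (each 3 s by default).
#' @param params named list overriding the protocol defaults (see
#'   `whiskerglm:::session_defaults`).
#' @param seed RNG seed; generation is bit-reproducible given the seed.
#' @return A [whisker_session()].
#' @export
generate_session <- function(protocol = c("active_pole", "passive_trapezoid",
                                          "passive_whitenoise"),
                             n_trials = 20, params = list(), seed = NULL) {
  protocol <- match.arg(protocol)
  n_trials <- as.integer(n_trials)
  if (n_trials < 1L) stop("n_trials must be positive")
  p <- modifyList(session_defaults(protocol), params)
  trial_ms <- as.integer(p$trial_ms)
  n <- n_trials * trial_ms
  tb <- cbind(start = seq(1L, n, by = trial_ms),
              end = seq(trial_ms + 1L, n + 1L, by = trial_ms))
  with_seed(seed, {
    if (protocol == "active_pole") {
      # balanced pole positions: each block of 11 trials covers all 11
      npos <- length(p$pole_positions_mm)
      pole <- unlist(lapply(seq_len(ceiling(n_trials / npos)),
                            function(i) sample(p$pole_positions_mm)))
      pole <- pole[seq_len(n_trials)]
      angle <- numeric(n); touch <- integer(n); dk_true <- numeric(n)
      kappa <- numeric(n)
      for (i in seq_len(n_trials)) {
        idx <- tb[i, "start"]:(tb[i, "end"] - 1L)
        a <- generate_whisking_angle(
          trial_ms, p$whisk_freq_hz, p$amp_envelope, p$setpoint,
          noise_sd = 0, freq_jitter = p$freq_jitter, seed = NULL)
        a <- a + stats::rnorm(trial_ms, 0, p$angle_noise_sd)
        thresh <- p$contact_theta0_deg +
          p$contact_slope_deg_per_mm * pole[i]
        tch <- as.integer(a > thresh)
        tch[seq_len(min(p$pole_delay_ms, trial_ms))] <- 0L
        # push angle per touch episode, gain varying with pole position;
        # pushing while protracting bends the whisker one way, pushing
        # while retracting bends it the other way
        gain <- p$dk_gain0 * (1 + p$dk_gain_slope * pole[i] / 6)
        push <- push_angle(a, tch)
        vel <- c(0, diff(smooth_boxcar(a, 5L)))
        phase_sign <- ifelse(vel >= 0, 1, -p$retract_gain)
        dk <- ifelse(is.na(push), 0, gain * pmax(push, 0) * phase_sign)
        dk <- dk + tch * stats::rnorm(trial_ms, 0, p$dk_noise_sd)
        # small torsion-like ripple coupled to the whisking oscillation
        dk <- dk + p$ripple_gain * (a - mean(a)) * (1 - tch)
        k_int <- p$kappa_intrinsic +
          stats::rnorm(1, 0, p$kappa_intrinsic_jitter)
        angle[idx] <- a
        touch[idx] <- tch
        dk_true[idx] <- dk
        kappa[idx] <- k_int + dk + stats::rnorm(trial_ms, 0, p$kappa_noise_sd)
      }
    } else if (protocol == "passive_whitenoise") {
      raw <- stats::rnorm(n)
      # convolution with exp(-t/tau) kernel == AR(1) with phi = exp(-1/tau)
      sm <- as.numeric(stats::filter(raw, exp(-1 / p$tau_ms),
                                     method = "recursive"))
      # actuator at rest for the first stim_delay_ms of every trial: gives
      # a clean pre-stimulus window for the intrinsic-curvature estimate
      rest <- sequence(rep.int(trial_ms, n_trials)) <= p$stim_delay_ms
      sm[rest] <- 0
      angle <- sm / stats::sd(sm) * p$angle_sd_deg
      sd_dk <- p$dk_per_deg * p$angle_sd_deg
      dk_true <- couple_curvature(angle, p$angle_dk_corr, sd_dk)
      dk_true[rest] <- 0
      kappa <- -0.02 + dk_true
      touch <- integer(n)
      pole <- rep(NaN, n_trials)
    } else { # passive_trapezoid
      period <- as.integer(round(1000 / p$freq_hz))
      ramp <- as.integer(p$ramp_ms)
      cyc <- numeric(period)
      up <- seq_len(ramp); hold <- (ramp + 1L):(2L * ramp)
      down <- (2L * ramp + 1L):(3L * ramp)
      cyc[up] <- seq(0, 1, length.out = ramp)
      cyc[hold] <- 1
      cyc[down] <- seq(1, 0, length.out = ramp)
      wave <- rep_len(cyc, n) * p$amp_deg
      rest <- sequence(rep.int(trial_ms, n_trials)) <= p$stim_delay_ms
      wave[rest] <- 0
      angle <- wave + stats::rnorm(n, 0, p$angle_noise_sd)
      sd_dk <- p$dk_per_deg * stats::sd(wave)
      dk_true <- couple_curvature(angle, p$angle_dk_corr, sd_dk)
      dk_true[rest] <- 0
      kappa <- -0.02 + dk_true
      touch <- integer(n)
      pole <- rep(NaN, n_trials)
    }
    whisker_session(angle_deg = angle, curvature_invmm = kappa,
                    curvature_change_invmm = curvature_change(kappa, tb),
                    trial_bounds = tb, pole_pos_mm = pole, touch = touch,
                    protocol = protocol, seed = seed, params = p)
  })
}
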