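# Independent oracles used across test files. These deliberately avoid the
# package's own code paths.

# Pure-R reference for the recursive Bernoulli sampler (oracle for the
# compiled version): same recursion, same RNG stream.
r_sample_glm <- function(drive, h, trial_bounds) {
  n <- length(drive)
  Lh <- length(h)
  spikes <- integer(n)
  prob <- numeric(n)
  for (tr in seq_len(nrow(trial_bounds))) {
    t0 <- trial_bounds[tr, 1]
    t1 <- trial_bounds[tr, 2] - 1L
    for (t in t0:t1) {
      z <- drive[t]
      for (j in seq_len(Lh)) {
        s <- t - j
        if (s >= t0) z <- z + h[j] * spikes[s]
      }
      z <- min(max(z, -30), 30)
      prob[t] <- 1 / (1 + exp(-z))
      spikes[t] <- as.integer(runif(1) < prob[t])
    }
  }
  list(spikes = spikes, prob = prob)
}

# Central finite-difference gradient of a scalar function.
fd_gradient <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, 1)
}

# Quadratic Bezier point evaluation from the Bernstein form only.
bernstein_point <- function(P, s) {
  drop((1 - s)^2 * P[1, ] + 2 * s * (1 - s) * P[2, ] + s^2 * P[3, ])
}

# Finite-difference curvature at s = 0, using only point evaluations (the
# polynomial extends smoothly to s < 0, so central differences apply).
fd_curvature_at_base <- function(P, h = 1e-4) {
  p0 <- bernstein_point(P, 0)
  pp <- bernstein_point(P, h)
  pm <- bernstein_point(P, -h)
  d1 <- (pp - pm) / (2 * h)
  d2 <- (pp - 2 * p0 + pm) / h^2
  (d1[1] * d2[2] - d2[1] * d1[2]) / sum(d1^2)^1.5
}

# A random non-degenerate quadratic Bezier control polygon.
random_bezier <- function() {
  repeat {
    P <- matrix(rnorm(6, sd = 3), 3, 2)
    d1 <- P[2, ] - P[1, ]
    if (sqrt(sum(d1^2)) > 0.3) return(P)
  }
}

# Short free-whisking session (pole out of reach, so no touches).
free_session <- function(n_trials = 10, seed = 1) {
  generate_session("active_pole", n_trials = n_trials, seed = seed,
                   params = list(contact_theta0_deg = 100))
}
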