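# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# seed = NULL leaves the RNG stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream of child seeds from one master seed (kept below 2^31).
child_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Logistic link with the linear predictor clipped at |z| = 30 so that
# log(y) and log(1 - y) are always finite.
clipped_logistic <- function(z, clip = 30) {
  z <- pmin(pmax(z, -clip), clip)
  1 / (1 + exp(-z))
}

# Discrete analytic signal via FFT: negative frequencies zeroed, positive
# doubled. Returns a complex vector; Mod() is the envelope, Arg() the phase.
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2L) stop("analytic_signal() needs at least 2 samples")
  X <- stats::fft(x)
  w <- numeric(n)
  if (n %% 2 == 0) {
    w[c(1, n / 2 + 1)] <- 1
    w[2:(n / 2)] <- 2
  } else {
    w[1] <- 1
    w[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * w, inverse = TRUE) / n
}

# Validate a trial-bounds matrix: integer columns start/end, half-open
# [start, end), 1-based, ordered, non-overlapping, covering 1..n_bins.
check_trial_bounds <- function(trial_bounds, n_bins = NULL) {
  tb <- as.matrix(trial_bounds)
  if (ncol(tb) != 2L) stop("trial_bounds must have two columns (start, end)")
  storage.mode(tb) <- "integer"
  colnames(tb) <- c("start", "end")
  if (any(tb[, "end"] <= tb[, "start"])) stop("empty trial in trial_bounds")
  if (nrow(tb) > 1L) {
    if (any(tb[-1L, "start"] != tb[-nrow(tb), "end"]))
      stop("trials must be ordered, non-overlapping and contiguous")
  }
  if (!is.null(n_bins)) {
    if (tb[1L, "start"] != 1L || tb[nrow(tb), "end"] != n_bins + 1L)
      stop("trial_bounds must cover bins 1..n_bins")
  }
  tb
}

# Map each bin to its trial index.
trial_index <- function(trial_bounds, n_bins) {
  tb <- check_trial_bounds(trial_bounds, n_bins)
  rep.int(seq_len(nrow(tb)), tb[, "end"] - tb[, "start"])
}
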