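#' Bernoulli point-process GLM with stimulus and spike-history filters
#'
#' The encoding model: the probability of a spike in 1 ms bin `t` is
#' `y_t = f(sum_i k_i . x_{i,t} + h . n_t + b)` where `x_{i,t}` is the
#' stimulus-history vector of sensory variable `i` (current bin and the
#' `L_k - 1` preceding bins), `n_t` is the spike-history vector (the `L_h`
#' bins strictly before `t`), `k_i` and `h` are filters, `b` a bias, and
#' `f` the logistic link (clipped at |z| = 30). The output is a Bernoulli
#' (spike / no-spike) variable. In quadratic mode the stimulus history is
#' augmented with squared z-scored stimulus values to capture U-shaped
#' tuning. Fitting minimizes the Bernoulli negative log-likelihood plus a
#' ridge penalty `alpha * ||k||^2` on the stimulus filters only; stimulus
#' inputs are z-scored internally during fitting so the penalty treats
#' sensory variables of different physical units symmetrically, and linear
#' filters are reported back in raw units.
#'
#' @param stimulus_filters named list of numeric stimulus filters, one per
#'   sensory variable; element 1 weights the current bin.
#' @param history_filter numeric spike-history filter; element 1 weights the
#'   immediately preceding bin.
#' @param bias scalar bias (sets the spontaneous rate through the link).
#' @param alpha ridge weight on the stimulus filters (default 0.01).
#' @param quadratic logical; if `TRUE`, `quad_filters` weight squared
#'   z-scored stimulus histories.
#' @param quad_filters named list like `stimulus_filters` (quadratic mode).
#' @param scaling named list, per stimulus variable, of `center` and
#'   `scale` constants used for z-scoring quadratic terms.
#' @return An object of class `whisker_glm`.
#' @seealso [fit_glm()], [predict_glm()], [generate_spikes_from_glm()]
#' @export
whisker_glm <- function(stimulus_filters, history_filter = numeric(0),
                        bias = 0, alpha = 0.01, quadratic = FALSE,
                        quad_filters = NULL, scaling = NULL) {
  if (is.numeric(stimulus_filters))
    stimulus_filters <- list(x = stimulus_filters)
  if (is.null(names(stimulus_filters)) || any(names(stimulus_filters) == ""))
    names(stimulus_filters) <- paste0("x", seq_along(stimulus_filters))
  lens <- vapply(stimulus_filters, length, 1L)
  if (any(lens < 1L)) stop("stimulus filter lengths must be > 0")
  if (alpha < 0) stop("alpha must be >= 0")
  pars <- c(unlist(stimulus_filters), unlist(quad_filters),
            history_filter, bias)
  if (!all(is.finite(pars))) stop("all model parameters must be finite")
  if (quadratic) {
    if (is.null(quad_filters)) quad_filters <- lapply(stimulus_filters,
                                                      function(k) 0 * k)
    names(quad_filters) <- names(stimulus_filters)
    if (is.null(scaling))
      scaling <- lapply(stimulus_filters,
                        function(k) list(center = 0, scale = 1))
  }
  structure(list(stimulus_filters = stimulus_filters,
                 history_filter = as.numeric(history_filter),
                 bias = as.numeric(bias), alpha = alpha,
                 quadratic = isTRUE(quadratic),
                 quad_filters = quad_filters, scaling = scaling),
            class = "whisker_glm")
}

#' @export
print.whisker_glm <- function(x, ...) {
  cat(sprintf("<whisker_glm: %s; L_k=%d, L_h=%d, alpha=%g%s>\n",
              paste(names(x$stimulus_filters), collapse = "+"),
              length(x$stimulus_filters[[1]]), length(x$history_filter),
              x$alpha, if (x$quadratic) ", quadratic" else ""))
  for (nm in names(x$stimulus_filters))
    cat(sprintf("  k[%s]: %s\n", nm,
                paste(format(x$stimulus_filters[[nm]], digits = 4),
                      collapse = " ")))
  cat(sprintf("  h: %s   b: %s\n",
              paste(format(x$history_filter, digits = 4), collapse = " "),
              format(x$bias, digits = 4)))
  invisible(x)
}

# Normalize a feature argument into a named list of aligned numeric vectors.
as_feature_list <- function(features) {
  if (inherits(features, "whisker_session"))
    stop("pass session_features(session, names), not the session itself")
  if (is.numeric(features)) features <- list(x = features)
  if (!is.list(features) || !length(features))
    stop("features must be a numeric vector or a named list of them")
  if (is.null(names(features)) || any(names(features) == ""))
    names(features) <- paste0("x", seq_along(features))
  n <- unique(vapply(features, length, 1L))
  if (length(n) != 1L) stop("all feature series must have equal length")
  features
}

#' Extract named feature traces from a session
#'
#' @param session a [whisker_session()].
#' @param names any of `"angle"`, `"curvature"`, `"curvature_change"`,
#'   `"acceleration"` (Savitzky-Golay angular acceleration, edge `NA`s
#'   replaced by 0), `"push_angle"` (0 outside touch).
#' @return Named list of aligned numeric vectors.
#' @export
session_features <- function(session, names) {
  stopifnot(inherits(session, "whisker_session"))
  get1 <- function(nm) switch(
    nm,
    angle = session$angle_deg,
    curvature = session$curvature_invmm,
    curvature_change = session$curvature_change_invmm,
    acceleration = {
      a <- angular_acceleration(session$angle_deg)
      a[is.na(a)] <- 0
      a
    },
    push_angle = {
      p <- push_angle(session$angle_deg, session$touch)
      p[is.na(p)] <- 0
      as.numeric(p)
    },
    stop("unknown session feature: ", nm))
  stats::setNames(lapply(names, get1), names)
}

#' Build the design data for GLM fitting
#'
#' For each valid bin `t`, rows hold the stimulus history
#' `(x_t, ..., x_{t-L_k+1})` for each sensory variable (current bin
#' included), the spike history `(n_{t-1}, ..., n_{t-L_h})` (strictly
#' pre-`t`, so prediction is causal), and an intercept. The first
#' `max(L_k, L_h)` bins of each trial are masked out so no history vector
#' spans a trial boundary. Stimulus values are z-scored (constants
#' estimated from the data passed in, or taken from `scaling` so test data
#' reuse the training constants); quadratic mode appends squared z-scored
#' stimulus histories.
#'
#' @param features numeric vector or named list of aligned 1 ms series.
#' @param spikes binary spike counts aligned with the features (or a
#'   [spike_train()]).
#' @param trial_bounds half-open trial intervals (see [whisker_session()]).
#' @param L_k stimulus filter length in bins (default 5).
#' @param L_h spike-history filter length in bins (default 2).
#' @param quadratic append squared z-scored stimulus histories.
#' @param scaling optional per-variable z-scoring constants to reuse.
#' @param bins optional integer vector restricting the valid bins (e.g. the
#'   bins of the training trials); masked bins are dropped regardless.
#' @return A `glm_design` list: `X` (model matrix), `y` (response bits),
#'   `rows` (bin index of each row), `blocks` (column index groups),
#'   `L_k`, `L_h`, `feature_names`, `quadratic`, `scaling`.
#' @export
build_design <- function(features, spikes, trial_bounds, L_k = 5, L_h = 2,
                         quadratic = FALSE, scaling = NULL, bins = NULL) {
  features <- as_feature_list(features)
  if (inherits(spikes, "spike_train")) spikes <- spikes$counts
  n <- length(features[[1]])
  if (length(spikes) != n) stop("features and spikes must be aligned")
  L_k <- as.integer(L_k); L_h <- as.integer(L_h)
  if (L_k < 1L || L_h < 0L) stop("L_k must be >= 1 and L_h >= 0")
  tb <- check_trial_bounds(trial_bounds, n)
  maxL <- max(L_k, L_h)
  valid <- unlist(lapply(seq_len(nrow(tb)), function(i) {
    s <- tb[i, "start"] + maxL
    e <- tb[i, "end"] - 1L
    if (s > e) integer(0) else s:e
  }))
  if (!is.null(bins)) valid <- intersect(valid, as.integer(bins))
  if (!length(valid)) stop("no valid bins left after masking")

  lagmat <- function(x, L) {
    # rows t = L..n with columns (x_t, x_{t-1}, ..., x_{t-L+1})
    m <- stats::embed(x, L)
    m[valid - L + 1L, , drop = FALSE]
  }
  if (is.null(scaling))
    scaling <- lapply(features, function(x)
      list(center = mean(x), scale = max(stats::sd(x), 1e-12)))
  zfeat <- lapply(names(features), function(nm)
    (features[[nm]] - scaling[[nm]]$center) / scaling[[nm]]$scale)
  names(zfeat) <- names(features)
  blocks <- list(stim = list(), quad = list())
  Xs <- list()
  col <- 0L
  for (nm in names(features)) {
    m <- lagmat(zfeat[[nm]], L_k)
    Xs[[length(Xs) + 1L]] <- m
    blocks$stim[[nm]] <- col + seq_len(L_k); col <- col + L_k
  }
  if (quadratic) {
    for (nm in names(features)) {
      m <- lagmat(zfeat[[nm]]^2, L_k)
      Xs[[length(Xs) + 1L]] <- m
      blocks$quad[[nm]] <- col + seq_len(L_k); col <- col + L_k
    }
  }
  if (L_h > 0L) {
    m <- stats::embed(spikes, L_h + 1L)[valid - L_h, -1L, drop = FALSE]
    Xs[[length(Xs) + 1L]] <- m
    blocks$hist <- col + seq_len(L_h); col <- col + L_h
  } else blocks$hist <- integer(0)
  Xs[[length(Xs) + 1L]] <- matrix(1, length(valid), 1L)
  blocks$bias <- col + 1L
  structure(list(X = do.call(cbind, Xs), y = spikes[valid], rows = valid,
                 blocks = blocks, L_k = L_k, L_h = L_h,
                 feature_names = names(features), quadratic = quadratic,
                 scaling = scaling),
            class = "glm_design")
}

# Indices of penalized (stimulus + quadratic) columns.
penalized_cols <- function(design)
  unlist(c(design$blocks$stim, design$blocks$quad), use.names = FALSE)

# Pack a whisker_glm into the design's parameter vector.
pack_theta <- function(model, design) {
  theta <- numeric(ncol(design$X))
  for (nm in design$feature_names)
    theta[design$blocks$stim[[nm]]] <- model$stimulus_filters[[nm]]
  if (design$quadratic)
    for (nm in design$feature_names)
      theta[design$blocks$quad[[nm]]] <- model$quad_filters[[nm]]
  theta[design$blocks$hist] <- model$history_filter
  theta[design$blocks$bias] <- model$bias
  theta
}

unpack_theta <- function(theta, design, alpha) {
  b <- design$blocks
  whisker_glm(
    stimulus_filters = lapply(b$stim, function(i) theta[i]),
    history_filter = theta[b$hist],
    bias = theta[b$bias],
    alpha = alpha,
    quadratic = design$quadratic,
    quad_filters = if (design$quadratic) lapply(b$quad, function(i) theta[i]),
    scaling = design$scaling)
}

#' Penalized negative log-likelihood and its gradient
#'
#' Bernoulli negative log-likelihood
#' `-sum(n_t log y_t + (1 - n_t) log(1 - y_t))` plus the ridge penalty
#' `alpha * ||k||^2` over the stimulus (and quadratic) filters only; the
#' spike-history filter and the bias are unpenalized. The linear predictor
#' is clipped at |z| = 30 before applying the logistic link, so the
#' likelihood is always finite.
#'
#' @param design a [build_design()] result.
#' @param theta parameter vector ordered as the design columns, or a
#'   [whisker_glm()] (its `alpha` is then used unless overridden).
#' @param alpha ridge weight (default 0.01).
#' @return `list(value, gradient)`.
#' @export
penalized_nll <- function(design, theta, alpha = 0.01) {
  stopifnot(inherits(design, "glm_design"))
  if (inherits(theta, "whisker_glm")) {
    if (missing(alpha)) alpha <- theta$alpha
    theta <- pack_theta(theta, design)
  }
  if (length(theta) != ncol(design$X))
    stop("theta length does not match the design")
  z <- drop(design$X %*% theta)
  y <- clipped_logistic(z)
  nll <- -sum(design$y * log(y) + (1 - design$y) * log(1 - y))
  pen <- penalized_cols(design)
  value <- nll + alpha * sum(theta[pen]^2)
  grad <- drop(crossprod(design$X, y - design$y))
  grad[pen] <- grad[pen] + 2 * alpha * theta[pen]
  list(value = value, gradient = grad)
}

#' Fit the GLM by penalized maximum likelihood
#'
#' Newton's method (iteratively reweighted least squares with the ridge
#' term) on the convex penalized Bernoulli likelihood, with step halving.
#' Deterministic given the initialization (zeros by default). Convergence
#' when the gradient max-norm falls below `tol` (scaled by the number of
#' valid bins).
#'
#' @inheritParams build_design
#' @param design alternatively, a ready [build_design()] object (then
#'   `features`/`spikes`/`trial_bounds` are ignored).
#' @param alpha ridge weight on stimulus filters (default 0.01).
#' @param init optional initial parameter vector (default all zeros).
#' @param max_iter Newton iteration cap (default 100).
#' @param tol gradient tolerance per valid bin (default 1e-9).
#' @return A [whisker_glm()] with attributes `converged`, `n_iter`,
#'   `final_nll` and the design's scaling stored in the model.
#' @export
fit_glm <- function(features = NULL, spikes = NULL, trial_bounds = NULL,
                    L_k = 5, L_h = 2, alpha = 0.01, quadratic = FALSE,
                    design = NULL, init = NULL, max_iter = 100, tol = 1e-9) {
  if (is.null(design))
    design <- build_design(features, spikes, trial_bounds, L_k = L_k,
                           L_h = L_h, quadratic = quadratic)
  y <- design$y
  if (all(y == 0L) || all(y == 1L))
    stop("degenerate fit: response is all-zero or all-one in training bins")
  p <- ncol(design$X)
  theta <- if (is.null(init)) numeric(p) else {
    stopifnot(length(init) == p); as.numeric(init)
  }
  pen <- penalized_cols(design)
  ridge <- numeric(p); ridge[pen] <- 2 * alpha
  obj <- penalized_nll(design, theta, alpha)
  converged <- FALSE
  it <- 0L
  gtol <- tol * length(y)
  while (it < max_iter) {
    it <- it + 1L
    z <- drop(design$X %*% theta)
    mu <- clipped_logistic(z)
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(design$X * w, design$X)
    diag(H) <- diag(H) + ridge + 1e-10
    step <- tryCatch(solve(H, obj$gradient), error = function(e)
      obj$gradient / max(diag(H)))
    # step halving keeps Newton descending even far from the optimum
    lambda <- 1
    repeat {
      cand <- theta - lambda * step
      cobj <- penalized_nll(design, cand, alpha)
      if (cobj$value <= obj$value + 1e-12 || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    theta <- cand
    obj <- cobj
    if (max(abs(obj$gradient)) < gtol) { converged <- TRUE; break }
  }
  model <- unpack_theta(theta, design, alpha)
  if (!design$quadratic) {
    # report linear filters in raw stimulus units: k_raw = k_z / s,
    # b_raw = b_z - sum_j k_z[j] c / s (exactly the same model)
    for (nm in design$feature_names) {
      sc <- design$scaling[[nm]]
      kz <- model$stimulus_filters[[nm]]
      model$bias <- model$bias - sum(kz) * sc$center / sc$scale
      model$stimulus_filters[[nm]] <- kz / sc$scale
    }
    model$scaling <- NULL
  } else {
    model$scaling <- design$scaling
  }
  attr(model, "converged") <- converged
  attr(model, "n_iter") <- it
  attr(model, "final_nll") <- obj$value
  model
}

# Stimulus drive b + sum_i conv(x_i, k_i) with zero-padded histories at
# trial starts (used for generation and prediction over full traces).
# Models carrying scaling constants (quadratic fits) standardize the
# stimulus first; linear fits are unscaled to raw units at fit time.
stimulus_drive <- function(model, features, trial_bounds) {
  features <- as_feature_list(features)
  n <- length(features[[1]])
  tb <- check_trial_bounds(trial_bounds, n)
  drive <- rep(model$bias, n)
  conv1 <- function(x, k) {
    L <- length(k)
    out <- numeric(length(x))
    for (i in seq_len(nrow(tb))) {
      idx <- tb[i, "start"]:(tb[i, "end"] - 1L)
      xp <- c(numeric(L - 1L), x[idx])
      out[idx] <- drop(stats::embed(xp, L) %*% k)
    }
    out
  }
  zscored <- function(nm) {
    if (is.null(model$scaling) || is.null(model$scaling[[nm]]))
      return(features[[nm]])
    sc <- model$scaling[[nm]]
    (features[[nm]] - sc$center) / sc$scale
  }
  for (nm in names(model$stimulus_filters)) {
    if (!nm %in% names(features)) stop("feature missing for filter: ", nm)
    drive <- drive + conv1(zscored(nm), model$stimulus_filters[[nm]])
  }
  if (model$quadratic) {
    for (nm in names(model$quad_filters))
      drive <- drive + conv1(zscored(nm)^2, model$quad_filters[[nm]])
  }
  drive
}

#' Predict spiking from a fitted GLM
#'
#' `"sampled"` mode generates a predicted spike train by recursive
#' Bernoulli sampling, feeding the sampled spikes back through the history
#' filter (the single-trial prediction used for scoring). `"expected"` mode
#' returns the deterministic probability series with the history term
#' disabled (forced through zeros), for diagnostics. Histories never cross
#' trial boundaries; stimulus history is zero-padded at trial starts.
#'
#' @param model a [whisker_glm()].
#' @param features feature list aligned with the model's filters (see
#'   [session_features()]).
#' @param trial_bounds half-open trial intervals.
#' @param type `"sampled"` or `"expected"`.
#' @param seed RNG seed for sampled mode.
#' @return `list(prob, spikes)`; `spikes` is `NULL` in expected mode.
#' @export
predict_glm <- function(model, features, trial_bounds,
                        type = c("sampled", "expected"), seed = NULL) {
  stopifnot(inherits(model, "whisker_glm"))
  type <- match.arg(type)
  features <- as_feature_list(features)
  drive <- stimulus_drive(model, features, trial_bounds)
  tb <- check_trial_bounds(trial_bounds, length(drive))
  if (type == "expected" || length(model$history_filter) == 0L) {
    prob <- clipped_logistic(drive)
    if (type == "expected") return(list(prob = prob, spikes = NULL))
    sp <- with_seed(seed, as.integer(stats::runif(length(prob)) < prob))
    return(list(prob = prob, spikes = sp))
  }
  res <- with_seed(seed,
    sample_bernoulli_glm_cpp(drive, model$history_filter,
                             tb[, "start"], tb[, "end"] - 1L))
  list(prob = res$prob, spikes = res$spikes)
}

#' Generate a spike train from a known GLM
#'
#' Recursive sampling: at each bin the spike probability is computed from
#' the stimulus history and the *sampled* spike history, then a Bernoulli
#' draw is taken. Deterministic given `seed`.
#'
#' @param model a [whisker_glm()] whose filters are named after session
#'   features (see [session_features()]).
#' @param session a [whisker_session()] providing the stimulus traces.
#' @param seed RNG seed.
#' @return A [spike_train()].
#' @export
generate_spikes_from_glm <- function(model, session, seed = NULL) {
  stopifnot(inherits(session, "whisker_session"))
  L <- max(vapply(model$stimulus_filters, length, 1L),
           length(model$history_filter), 1L)
  if (any(session$trial_bounds[, "end"] - session$trial_bounds[, "start"] < L))
    stop("model filter lengths exceed the shortest trial")
  feats <- session_features(session, names(model$stimulus_filters))
  pred <- predict_glm(model, feats, session$trial_bounds,
                      type = "sampled", seed = seed)
  spike_train(pred$spikes, session_id = session$protocol,
              n_bins = n_bins(session))
}

#' Preferred stimulus direction of a single-tap GLM
#'
#' With a length-1 stimulus filter the sign of `k` determines whether
#' positive or negative stimuli drive spikes; used to classify selectivity
#' for curvature-change direction.
#'
#' @param model a [whisker_glm()] with one stimulus variable and `L_k = 1`.
#' @return `"positive"`, `"negative"`, or `"undetermined"` when `k = 0`.
#' @export
preferred_direction <- function(model) {
  stopifnot(inherits(model, "whisker_glm"))
  if (length(model$stimulus_filters) != 1L ||
      length(model$stimulus_filters[[1]]) != 1L)
    stop("preferred_direction() needs a single length-1 stimulus filter")
  k <- model$stimulus_filters[[1]]
  if (k > 0) "positive" else if (k < 0) "negative" else "undetermined"
}
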