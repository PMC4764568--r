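#' Write and read sessions as delimited text
#'
#' Sessions serialize to a tab-separated table with columns `time_ms`,
#' `trial`, `angle_deg`, `curvature_invmm`, `dcurvature_invmm`, `touch`,
#' `pole_pos_mm`, `spike`, plus a YAML sidecar `<path>.meta.yaml` holding
#' protocol, seed and generator parameters. The round trip is lossless up
#' to float formatting precision.
#'
#' @param session a [whisker_session()].
#' @param path output table path (the sidecar gets `.meta.yaml` appended).
#' @param spikes optional aligned [spike_train()] stored in the `spike`
#'   column (otherwise `NA`).
#' @param digits significant digits for numeric columns (default 10).
#' @return `write_session()` returns `path` invisibly; `read_session()`
#'   returns the [whisker_session()]; `read_spike_train()` returns the
#'   [spike_train()] stored in the table (error if absent).
#' @export
write_session <- function(session, path, spikes = NULL, digits = 10) {
  stopifnot(inherits(session, "whisker_session"))
  n <- n_bins(session)
  tr <- trial_index(session$trial_bounds, n)
  df <- data.frame(
    time_ms = seq_len(n) - 1L,
    trial = tr,
    angle_deg = signif(session$angle_deg, digits),
    curvature_invmm = signif(session$curvature_invmm, digits),
    dcurvature_invmm = signif(session$curvature_change_invmm, digits),
    touch = session$touch,
    pole_pos_mm = session$pole_pos_mm[tr],
    spike = if (is.null(spikes)) NA_integer_ else {
      stopifnot(inherits(spikes, "spike_train"),
                length(spikes$counts) == n)
      spikes$counts
    })
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(protocol = session$protocol,
               seed = session$seed,
               params = session$params)
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

read_session_table <- function(path) {
  need <- c("time_ms", "trial", "angle_deg", "curvature_invmm",
            "dcurvature_invmm", "touch", "pole_pos_mm", "spike")
  df <- tryCatch(read.delim(path, sep = "\t"), error = function(e)
    stop("cannot parse session table ", path, ": ", conditionMessage(e)))
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("session table ", path, " is missing columns: ",
         paste(miss, collapse = ", "))
  for (col in setdiff(need, c("pole_pos_mm", "spike"))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v))[1]
    if (!is.na(bad))
      stop("truncated or malformed session table: column '", col,
           "' unreadable at line ", bad + 1L)
    df[[col]] <- v
  }
  df
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  df <- read_session_table(path)
  meta_path <- paste0(path, ".meta.yaml")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path)
          else list(protocol = "active_pole", seed = NULL, params = list())
  if (!meta$protocol %in% c("active_pole", "passive_trapezoid",
                            "passive_whitenoise"))
    stop("unknown protocol tag in metadata: ", meta$protocol)
  r <- rle(df$trial)
  ends <- cumsum(r$lengths)
  tb <- cbind(start = ends - r$lengths + 1L, end = ends + 1L)
  pole <- df$pole_pos_mm[ends - r$lengths + 1L]
  whisker_session(angle_deg = df$angle_deg,
                  curvature_invmm = df$curvature_invmm,
                  curvature_change_invmm = df$dcurvature_invmm,
                  trial_bounds = tb, pole_pos_mm = pole, touch = df$touch,
                  protocol = meta$protocol, seed = meta$seed,
                  params = meta$params)
}

#' @rdname write_session
#' @export
read_spike_train <- function(path) {
  df <- read_session_table(path)
  if (all(is.na(df$spike)))
    stop("session table ", path, " carries no spike column data")
  spike_train(df$spike, session_id = path)
}

#' Serialize a GLM to a structured text file
#'
#' Filters, bias, ridge weight, z-scoring constants and convention flags
#' are written as YAML, so fitted models can be stored and reloaded
#' losslessly.
#'
#' @param model a [whisker_glm()].
#' @param path output file.
#' @export
write_glm <- function(model, path) {
  stopifnot(inherits(model, "whisker_glm"))
  yaml::write_yaml(list(
    stimulus_filters = lapply(model$stimulus_filters, as.numeric),
    history_filter = as.numeric(model$history_filter),
    bias = model$bias, alpha = model$alpha,
    quadratic = model$quadratic,
    quad_filters = if (model$quadratic)
      lapply(model$quad_filters, as.numeric),
    scaling = model$scaling,
    conventions = list(stimulus_includes_current_bin = TRUE,
                       history_strictly_causal = TRUE,
                       link_clip = 30)), path)
  invisible(path)
}

#' @rdname write_glm
#' @export
read_glm <- function(path) {
  x <- yaml::read_yaml(path)
  whisker_glm(stimulus_filters = lapply(x$stimulus_filters, as.numeric),
              history_filter = as.numeric(x$history_filter),
              bias = x$bias, alpha = x$alpha, quadratic = x$quadratic,
              quad_filters = if (isTRUE(x$quadratic))
                lapply(x$quad_filters, as.numeric),
              scaling = x$scaling)
}

#' Run configuration
#'
#' Validated bundle of generator, model and evaluation settings with the
#' standard defaults (L_k = 5, L_h = 2, alpha = 0.01, 10 repeats, 100 ms
#' smoothing, 3000-8000 ms shifts, 500 shuffles, 2 degree amplitude
#' threshold).
#'
#' @param protocol session protocol for simulation.
#' @param n_trials trials to simulate.
#' @param session_params overrides for [generate_session()].
#' @param unit generating-unit settings: `feature`, `drive_sd`,
#'   `history`, `rate_hz`.
#' @param glm list with `L_k`, `L_h`, `alpha`.
#' @param eval list with `n_repeats`, `smoothing_ms`, `shift_range_ms`,
#'   `p`.
#' @param whisking list with `amp_bins`, `phase_bins`, `accel_bins`,
#'   `amp_threshold`, `n_shuffles`.
#' @param feature_sets named list of feature-set definitions to evaluate;
#'   each element is `list(features, quadratic)`.
#' @param seed master seed.
#' @return A validated `run_config` list.
#' @export
run_config <- function(protocol = "active_pole", n_trials = 20,
                       session_params = list(),
                       unit = list(feature = "curvature_change",
                                   drive_sd = 3, history = c(-4, -2),
                                   rate_hz = 25),
                       glm = list(L_k = 5, L_h = 2, alpha = 0.01),
                       eval = list(n_repeats = 10, smoothing_ms = 100,
                                   shift_range_ms = c(3000, 8000),
                                   p = 0.0025),
                       whisking = list(amp_bins = 30, phase_bins = 8,
                                       accel_bins = 8, amp_threshold = 2,
                                       n_shuffles = 500),
                       feature_sets = default_feature_sets(),
                       seed = 1L) {
  defaults <- formals(run_config)
  unit <- modifyList(base::eval(defaults$unit), unit)
  glm <- modifyList(base::eval(defaults$glm), glm)
  eval_ <- modifyList(base::eval(defaults$eval), eval)
  whisking <- modifyList(base::eval(defaults$whisking), whisking)
  stopifnot(glm$L_k >= 1, glm$L_h >= 0, glm$alpha >= 0,
            eval_$n_repeats >= 1, eval_$smoothing_ms >= 1,
            length(eval_$shift_range_ms) == 2,
            eval_$shift_range_ms[1] >= 1,
            diff(eval_$shift_range_ms) >= 0,
            eval_$p > 0, eval_$p < 1,
            whisking$amp_threshold >= 0, whisking$n_shuffles >= 1)
  n_trials <- as.integer(n_trials)
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(protocol = protocol, n_trials = n_trials,
                 session_params = session_params, unit = unit, glm = glm,
                 eval = eval_, whisking = whisking,
                 feature_sets = feature_sets, seed = seed),
            class = "run_config")
}

#' @rdname run_config
#' @export
default_feature_sets <- function() {
  list(curvature = list(features = "curvature_change", quadratic = FALSE),
       angle = list(features = "angle", quadratic = FALSE),
       both = list(features = c("angle", "curvature_change"),
                   quadratic = FALSE),
       push_angle = list(features = "push_angle", quadratic = FALSE),
       acceleration_quadratic = list(features = "acceleration",
                                     quadratic = TRUE))
}

#' @rdname run_config
#' @param path YAML configuration file.
#' @export
load_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(run_config, x[intersect(names(x), names(formals(run_config)))])
}

#' Run the full analysis pipeline
#'
#' Simulates (or takes) a session and a spike train, computes mechanical
#' features, fits and evaluates GLMs per configured feature set (with
#' circular-shift chance controls), runs the whisking battery, and
#' returns a per-feature report table (feature, median PCC, chance
#' median, significant) plus all intermediate results. Every stochastic
#' stage derives its seed from the master seed, so the same configuration
#' and seed reproduce the report exactly.
#'
#' @param config a [run_config()].
#' @param session optional pre-built [whisker_session()] (otherwise
#'   simulated per the config).
#' @param spikes optional [spike_train()] (otherwise generated from the
#'   configured unit).
#' @return List with `report` (data frame), `evaluations`, `whisking`,
#'   `session`, `spikes`, `unit_model`, `seed`.
#' @export
run_pipeline <- function(config = run_config(), session = NULL,
                         spikes = NULL) {
  stopifnot(inherits(config, "run_config"))
  seeds <- child_seeds(config$seed, 4L + length(config$feature_sets))
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed (seed ", config$seed, "): ",
         conditionMessage(e), call. = FALSE))
  if (is.null(session))
    session <- stage("simulate",
      generate_session(config$protocol, config$n_trials,
                       config$session_params, seed = seeds[[1]]))
  unit_model <- NULL
  if (is.null(spikes)) {
    unit_model <- stage("unit", {
      feat <- session_features(session, config$unit$feature)[[1]]
      gamma <- config$unit$drive_sd / max(stats::sd(feat), 1e-12)
      m <- whisker_glm(stats::setNames(list(gamma), config$unit$feature),
                       history_filter = config$unit$history, bias = 0)
      tune_bias_to_rate(m, session, config$unit$rate_hz, seed = seeds[[2]])
    })
    spikes <- stage("spikes",
      generate_spikes_from_glm(unit_model, session, seed = seeds[[3]]))
  }
  evaluations <- list()
  for (i in seq_along(config$feature_sets)) {
    nm <- names(config$feature_sets)[i]
    fs <- config$feature_sets[[i]]
    cfg <- glm_config(features = fs$features, L_k = config$glm$L_k,
                      L_h = config$glm$L_h, alpha = config$glm$alpha,
                      quadratic = isTRUE(fs$quadratic))
    evaluations[[nm]] <- stage(paste0("evaluate:", nm),
      evaluate_unit(session, spikes, cfg,
                    n_repeats = config$eval$n_repeats,
                    smoothing_ms = config$eval$smoothing_ms,
                    shift_range_ms = config$eval$shift_range_ms,
                    p = config$eval$p, seed = seeds[[3L + i]]))
  }
  whisk <- stage("whisking",
    whisking_battery(session, spikes,
                     amp_bins = config$whisking$amp_bins,
                     phase_bins = config$whisking$phase_bins,
                     accel_bins = config$whisking$accel_bins,
                     amp_threshold = config$whisking$amp_threshold,
                     n_shuffles = config$whisking$n_shuffles,
                     seed = seeds[[4L + length(config$feature_sets)]]))
  report <- data.frame(
    feature = names(evaluations),
    median_pcc = vapply(evaluations, `[[`, 1, "median_pcc"),
    chance_median = vapply(evaluations, `[[`, 1, "chance_median"),
    significant = vapply(evaluations, `[[`, TRUE, "significant"),
    row.names = NULL)
  list(report = report, evaluations = evaluations, whisking = whisk,
       session = session, spikes = spikes, unit_model = unit_model,
       seed = config$seed)
}
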