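#' Whisker recording sessions and spike trains
#'
#' A `whisker_session` holds aligned 1 kHz (1 ms bin) traces of whisker angle,
#' whisker curvature and curvature change, together with trial structure,
#' per-trial pole positions, binary touch labels and provenance (protocol,
#' seed, generator parameters). A `spike_train` holds binary spike counts
#' (0/1 per 1 ms bin) aligned to a session.
#'
#' Invariants enforced by the constructor: all traces have equal length;
#' trials are ordered, contiguous, half-open intervals covering every bin;
#' `touch` is 0 wherever the pole is absent; counts are binary.
#'
#' @param angle_deg numeric vector, whisker angle in degrees per 1 ms bin.
#' @param curvature_invmm numeric vector, whisker curvature at the base
#'   (1/mm).
#' @param curvature_change_invmm numeric vector, curvature minus the
#'   per-trial intrinsic curvature (1/mm). If `NULL` it is computed with
#'   [curvature_change()].
#' @param trial_bounds two-column integer matrix of half-open bin intervals
#'   `[start, end)`, 1-based, covering all bins.
#' @param pole_pos_mm numeric vector, one rostro-caudal pole position (mm)
#'   per trial; `NaN` when the pole is absent.
#' @param touch binary vector of touch labels (1 = whisker-pole contact).
#' @param protocol one of `"active_pole"`, `"passive_trapezoid"`,
#'   `"passive_whitenoise"`.
#' @param seed integer seed recorded for provenance (may be `NULL`).
#' @param params list of generator parameters recorded for provenance.
#' @return An object of class `whisker_session`.
#' @seealso [generate_session()], [spike_train()], [write_session()]
#' @export
whisker_session <- function(angle_deg, curvature_invmm,
                            curvature_change_invmm = NULL,
                            trial_bounds, pole_pos_mm, touch,
                            protocol = c("active_pole", "passive_trapezoid",
                                         "passive_whitenoise"),
                            seed = NULL, params = list()) {
  protocol <- match.arg(protocol)
  n <- length(angle_deg)
  tb <- check_trial_bounds(trial_bounds, n)
  if (length(curvature_invmm) != n)
    stop("angle and curvature traces must have equal length")
  if (is.null(curvature_change_invmm))
    curvature_change_invmm <- curvature_change(curvature_invmm, tb)
  if (length(curvature_change_invmm) != n)
    stop("curvature_change trace length mismatch")
  if (length(pole_pos_mm) != nrow(tb))
    stop("need one pole position per trial")
  touch <- as.integer(touch)
  if (length(touch) != n || !all(touch %in% c(0L, 1L)))
    stop("touch must be a binary vector aligned with the traces")
  pole_absent <- is.nan(pole_pos_mm) | is.na(pole_pos_mm)
  if (any(touch[trial_index(tb, n) %in% which(pole_absent)] == 1L))
    stop("touch must be 0 wherever the pole is absent")
  structure(
    list(angle_deg = as.numeric(angle_deg),
         curvature_invmm = as.numeric(curvature_invmm),
         curvature_change_invmm = as.numeric(curvature_change_invmm),
         trial_bounds = tb,
         pole_pos_mm = as.numeric(pole_pos_mm),
         touch = touch,
         protocol = protocol,
         seed = seed,
         params = params),
    class = "whisker_session")
}

#' @rdname whisker_session
#' @param counts binary vector of spike counts per 1 ms bin.
#' @param session_id character label linking the train to a session.
#' @param n_bins expected length (e.g. `n_bins(session)`); checked if given.
#' @export
spike_train <- function(counts, session_id = NA_character_, n_bins = NULL) {
  counts <- as.integer(counts)
  if (!all(counts %in% c(0L, 1L)))
    stop("spike counts must be 0 or 1 per 1 ms bin")
  if (!is.null(n_bins) && length(counts) != n_bins)
    stop("spike train length does not match session length")
  structure(list(counts = counts, session_id = as.character(session_id)),
            class = "spike_train")
}

#' @rdname whisker_session
#' @param x a `whisker_session` or `spike_train`.
#' @export
n_bins <- function(x) {
  if (inherits(x, "whisker_session")) length(x$angle_deg)
  else if (inherits(x, "spike_train")) length(x$counts)
  else stop("n_bins() needs a whisker_session or spike_train")
}

#' @export
print.whisker_session <- function(x, ...) {
  cat(sprintf("<whisker_session: %s, %d trials, %.1f s at 1 kHz>\n",
              x$protocol, nrow(x$trial_bounds), n_bins(x) / 1000))
  cat(sprintf("  touch fraction %.3f; pole positions: %s\n",
              mean(x$touch),
              if (all(is.nan(x$pole_pos_mm))) "none" else
                paste(format(sort(unique(x$pole_pos_mm)), digits = 3),
                      collapse = " ")))
  invisible(x)
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train: %d bins, %d spikes (%.1f spikes/s)>\n",
              length(x$counts), sum(x$counts), 1000 * mean(x$counts)))
  invisible(x)
}
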