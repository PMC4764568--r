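#' Quadratic Bezier whisker curves
#'
#' The proximal whisker segment is described by a quadratic Bezier curve
#' `B(s) = (1-s)^2 P0 + 2 s (1-s) P1 + s^2 P2`, `s` in \[0, 1\], with the
#' whisker base at `s = 0`. Control points are planar (mm).
#'
#' @param control_points 3 x 2 numeric matrix of control points (mm), rows
#'   `P0` (base), `P1`, `P2`.
#' @return An object of class `bezier_curve`.
#' @export
bezier_curve <- function(control_points) {
  P <- as.matrix(control_points)
  if (!all(dim(P) == c(3L, 2L)) || !is.numeric(P) || anyNA(P))
    stop("control_points must be a numeric 3 x 2 matrix")
  dimnames(P) <- list(c("P0", "P1", "P2"), c("x", "y"))
  structure(list(P = P), class = "bezier_curve")
}

# Point and exact derivatives of a quadratic Bezier at parameter s.
bezier_eval <- function(curve, s, deriv = 0L) {
  P <- curve$P
  if (deriv == 0L) {
    cbind((1 - s)^2, 2 * s * (1 - s), s^2) %*% P
  } else if (deriv == 1L) {
    # B'(s) = 2[(P1 - P0) + s (P2 - 2 P1 + P0)]
    outer(rep(2, length(s)), P[2, ] - P[1, ]) +
      2 * s %o% (P[3, ] - 2 * P[2, ] + P[1, ])
  } else if (deriv == 2L) {
    outer(rep(2, length(s)), P[3, ] - 2 * P[2, ] + P[1, ])
  } else stop("deriv must be 0, 1 or 2")
}

#' Signed curvature of a quadratic Bezier at the whisker base
#'
#' Evaluates `kappa = (x' y'' - x'' y') / (x'^2 + y'^2)^(3/2)` at `s = 0`
#' using the exact derivatives of the quadratic Bezier. The sign follows the
#' orientation of the curve (counter-clockwise bending positive).
#'
#' @param curve a [bezier_curve()].
#' @return Signed curvature in 1/mm.
#' @export
curvature_at_base <- function(curve) {
  stopifnot(inherits(curve, "bezier_curve"))
  d1 <- drop(bezier_eval(curve, 0, 1L))
  d2 <- drop(bezier_eval(curve, 0, 2L))
  speed2 <- sum(d1^2)
  if (speed2 < 1e-24)
    stop("degenerate curve: first derivative vanishes at the base")
  unname((d1[1] * d2[2] - d2[1] * d1[2]) / speed2^1.5)
}

#' Whisker angle at the base
#'
#' Angle between the tangent to the whisker at its base (`s = 0`) and the
#' anterior-posterior axis, in degrees. By package convention protraction
#' corresponds to increasing angle.
#'
#' @param curve a [bezier_curve()].
#' @param ap_axis length-2 numeric, direction of the anterior-posterior
#'   axis (default `c(1, 0)`).
#' @return Signed angle in degrees in (-180, 180\].
#' @export
angle_at_base <- function(curve, ap_axis = c(1, 0)) {
  stopifnot(inherits(curve, "bezier_curve"), length(ap_axis) == 2L)
  d1 <- drop(bezier_eval(curve, 0, 1L))
  if (sum(d1^2) < 1e-24) stop("degenerate tangent at the base")
  if (sum(ap_axis^2) == 0) stop("ap_axis must be a nonzero vector")
  cross <- ap_axis[1] * d1[2] - ap_axis[2] * d1[1]
  dot <- sum(ap_axis * d1)
  unname(atan2(cross, dot) * 180 / pi)
}

#' Curvature change relative to per-trial intrinsic curvature
#'
#' The reaction force at the whisker base reflects changes in curvature, not
#' the intrinsic (unforced) curvature. Per trial, the intrinsic curvature is
#' estimated as the mean curvature over the first `intrinsic_window_ms` of
#' the trial (before pole contact) and subtracted from the whole trial.
#'
#' @param kappa_series numeric curvature trace (1/mm) at 1 ms bins.
#' @param trial_bounds half-open trial intervals (see [whisker_session()]).
#' @param intrinsic_window_ms window at trial start used to estimate the
#'   intrinsic curvature (default 100 ms).
#' @return Curvature-change trace, same length as `kappa_series`.
#' @export
curvature_change <- function(kappa_series, trial_bounds,
                             intrinsic_window_ms = 100) {
  n <- length(kappa_series)
  tb <- check_trial_bounds(trial_bounds, n)
  w <- as.integer(intrinsic_window_ms)
  if (w < 1L) stop("intrinsic_window_ms must be >= 1")
  if (any(tb[, "end"] - tb[, "start"] < w))
    stop("every trial must be at least intrinsic_window_ms long")
  out <- numeric(n)
  for (i in seq_len(nrow(tb))) {
    idx <- tb[i, "start"]:(tb[i, "end"] - 1L)
    k_int <- mean(kappa_series[idx[seq_len(w)]])
    out[idx] <- kappa_series[idx] - k_int
  }
  out
}

#' Contact forces from bending moment and contact geometry
#'
#' Given the bending moment `M` at the whisker base and the whisker-pole
#' contact geometry, recovers the contact force magnitude from the
#' definition of moment, `F = M / (r sin(phi))`, and projects it onto the
#' tangent and normal to the whisker at its base:
#' `F_ax = F sin(theta_base - theta_contact)`,
#' `F_lat = F cos(theta_base - theta_contact)`.
#'
#' All angles are in radians here (the internal convention); `M` is in
#' bending-stiffness-scaled units of curvature (see [bending_moment()]).
#'
#' @param M bending moment (proxy scale).
#' @param r lever-arm magnitude, distance base to contact point (mm), > 0.
#' @param phi angle between the lever arm and the force direction (radians);
#'   `sin(phi)` must be nonzero.
#' @param theta_base,theta_contact tangent angle at the base and force
#'   direction angle, both measured from the horizontal (radians).
#' @return An object of class `contact_geometry`: list with fields `M`,
#'   `r`, `phi`, `theta_base`, `theta_contact`, `F`, `F_ax`, `F_lat`.
#'   Entries where `sin(phi)` is (numerically) zero are flagged `NA` with a
#'   warning rather than returned as numbers.
#' @export
contact_forces <- function(M, r, phi, theta_base, theta_contact) {
  if (any(r <= 0)) stop("lever arm r must be > 0")
  args <- cbind(M, r, phi, theta_base, theta_contact) # recycles & checks
  M <- unname(args[, 1]); r <- unname(args[, 2]); phi <- unname(args[, 3])
  theta_base <- unname(args[, 4]); theta_contact <- unname(args[, 5])
  s <- sin(phi)
  bad <- abs(s) < 1e-12
  if (any(bad))
    warning("sin(phi) = 0: force undefined for ", sum(bad),
            " input(s); flagged NA")
  F <- ifelse(bad, NA_real_, M / (r * s))
  dth <- theta_base - theta_contact
  structure(list(M = M, r = r, phi = phi,
                 theta_base = theta_base, theta_contact = theta_contact,
                 F = F, F_ax = F * sin(dth), F_lat = F * cos(dth)),
            class = "contact_geometry")
}

#' Bending moment proxy from curvature change
#'
#' Bending moment is proportional to curvature change, `M = EI * dkappa`.
#' The bending stiffness `EI` is a configurable scale with default 1, i.e.
#' the moment is reported on the curvature-change proxy scale.
#'
#' @param dkappa curvature change (1/mm).
#' @param EI bending stiffness scale (default 1).
#' @return Moment series on the `EI`-scaled proxy scale.
#' @export
bending_moment <- function(dkappa, EI = 1) EI * dkappa

#' Whisker-pole contact point and lever-arm geometry
#'
#' Finds the point on the (distal) whisker curve closest to the pole
#' centre; contact is declared when that distance is within
#' `pole_radius + tol`. Returns the contact location, the lever arm
#' `r` (distance from the whisker base), and `phi`, the angle between the
#' lever-arm vector and the contact-force direction. The force direction is
#' the normal to the whisker tangent at the contact point, signed to point
#' away from the pole centre (the pole pushes the whisker). A contact at the
#' curve endpoint (tip slip-off) is flagged, since the force direction is
#' unreliable there.
#'
#' @param curve a [bezier_curve()] fitted near the pole.
#' @param pole_center length-2 numeric, pole centre (mm).
#' @param pole_radius pole radius (mm).
#' @param tol extra distance tolerance for declaring contact (default
#'   0.1 mm).
#' @return `list(contact = FALSE)` when there is no approach within
#'   `pole_radius + tol`; otherwise a list with `contact = TRUE`, `s`
#'   (curve parameter of the contact), `point`, `distance`, `r`, `phi`
#'   (radians), `theta_contact` (force direction angle from horizontal,
#'   radians), and `tip_slip` flag.
#' @export
contact_point <- function(curve, pole_center, pole_radius, tol = 0.1) {
  stopifnot(inherits(curve, "bezier_curve"), length(pole_center) == 2L,
            pole_radius >= 0)
  dist2 <- function(s) {
    pt <- bezier_eval(curve, s)
    (pt[, 1] - pole_center[1])^2 + (pt[, 2] - pole_center[2])^2
  }
  # distance^2 along a quadratic Bezier is a quartic in s: scan a coarse
  # grid to bracket the global minimum, then refine locally
  grid <- seq(0, 1, length.out = 201)
  d2 <- dist2(grid)
  i <- which.min(d2)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  if (lo == hi) {
    s_min <- grid[i]
  } else {
    opt <- stats::optimize(dist2, c(lo, hi), tol = 1e-10)
    s_min <- if (opt$objective <= d2[i]) opt$minimum else grid[i]
  }
  d_min <- unname(sqrt(dist2(s_min)))
  if (d_min > pole_radius + tol) return(list(contact = FALSE))
  pt <- unname(drop(bezier_eval(curve, s_min)))
  base <- unname(curve$P[1, ])
  lever <- pt - base
  r <- sqrt(sum(lever^2))
  tangent <- drop(bezier_eval(curve, s_min, 1L))
  normal <- c(-tangent[2], tangent[1]) / sqrt(sum(tangent^2))
  away <- pt - pole_center
  if (sum(away^2) > 0 && sum(normal * away) < 0) normal <- -normal
  phi <- acos(pmin(1, pmax(-1, sum(lever * normal) / r)))
  list(contact = TRUE, s = s_min, point = pt, distance = d_min,
       r = r, phi = phi, theta_contact = atan2(normal[2], normal[1]),
       tip_slip = s_min > 1 - 1e-6)
}

#' Angular acceleration by Savitzky-Golay smoothing
#'
#' The moment associated with rigid whisker rotation is proportional to
#' angular acceleration. The angle trace is smoothed with a Savitzky-Golay
#' filter (default polynomial order 5, frame 31 ms at 1 kHz) and then
#' differentiated twice. Two strategies are exposed: `"smooth_diff"`
#' (smooth, then central second differences; the default) and
#' `"sg_derivative"` (the filter's own second-derivative coefficients).
#' Edge bins without a full frame are returned as `NA`; analyses use the
#' interior only.
#'
#' @param angle_series whisker angle (degrees) at 1 ms bins.
#' @param poly_order Savitzky-Golay polynomial order (default 5).
#' @param frame_ms odd frame length in ms (default 31).
#' @param fs sampling rate, Hz (default 1000).
#' @param method differentiation strategy, see above.
#' @return Angular acceleration (deg/s^2), `NA` at the edges.
#' @export
angular_acceleration <- function(angle_series, poly_order = 5, frame_ms = 31,
                                 fs = 1000,
                                 method = c("smooth_diff", "sg_derivative")) {
  method <- match.arg(method)
  frame <- as.integer(frame_ms)
  if (frame %% 2L == 0L || frame <= poly_order)
    stop("frame_ms must be odd and greater than poly_order")
  n <- length(angle_series)
  if (n <= frame) stop("series must be longer than the filter frame")
  half <- (frame - 1L) %/% 2L
  if (method == "smooth_diff") {
    sm <- signal::sgolayfilt(angle_series, p = poly_order, n = frame)
    acc <- c(NA_real_,
             diff(sm, differences = 2) * fs^2,
             NA_real_)
    edge <- half + 1L
  } else {
    acc <- signal::sgolayfilt(angle_series, p = poly_order, n = frame,
                              m = 2) * fs^2
    edge <- half
  }
  if (edge > 0) {
    acc[seq_len(edge)] <- NA_real_
    acc[(n - edge + 1L):n] <- NA_real_
  }
  acc
}

#' Push angle during touch episodes
#'
#' For each touch episode, the whisker angle in the bin immediately before
#' touch onset is taken as reference and subtracted from the angles during
#' the touch. Bins outside touch are `NA`. An episode starting at the first
#' bin of the recording has no reference frame and is flagged (its bins stay
#' `NA`).
#'
#' @param angle_series whisker angle (degrees) at 1 ms bins.
#' @param touch binary touch labels aligned with `angle_series`.
#' @return Numeric series of push angles (degrees), `NA` outside touch, with
#'   attribute `flagged_episodes` listing onset bins lacking a reference.
#' @export
push_angle <- function(angle_series, touch) {
  n <- length(angle_series)
  touch <- as.integer(touch)
  if (length(touch) != n) stop("angle and touch must be aligned")
  out <- rep(NA_real_, n)
  flagged <- integer(0)
  r <- rle(touch)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in which(r$values == 1L)) {
    on <- starts[j]; off <- ends[j]
    if (on == 1L) {
      flagged <- c(flagged, on)
      next
    }
    out[on:off] <- angle_series[on:off] - angle_series[on - 1L]
  }
  structure(out, flagged_episodes = flagged)
}
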