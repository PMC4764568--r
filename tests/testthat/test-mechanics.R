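test_that("Bezier base curvature matches hand values and scaling laws", {
  # collinear control points: a straight whisker has zero curvature
  straight <- bezier_curve(rbind(c(0, 0), c(1, 1), c(2, 2)))
  expect_equal(curvature_at_base(straight), 0)
  # worked case verified against the finite-difference oracle
  P <- rbind(c(0, 0), c(1, 0), c(1, 1))
  expect_equal(curvature_at_base(bezier_curve(P)), 0.5)
  expect_equal(fd_curvature_at_base(P), 0.5, tolerance = 1e-8)
  # dimensional analysis: scaling by c scales curvature by 1/c
  expect_equal(curvature_at_base(bezier_curve(3 * P)), 0.5 / 3)
  expect_error(curvature_at_base(bezier_curve(rbind(c(0, 0), c(0, 0),
                                                    c(1, 1)))),
               "degenerate")
})

test_that("curvature agrees with the finite-difference oracle on random
           curves and is rotation invariant", {
  set.seed(42)
  for (i in 1:100) {
    P <- random_bezier()
    kappa <- curvature_at_base(bezier_curve(P))
    oracle <- fd_curvature_at_base(P)
    denom <- max(abs(oracle), 1e-8)
    expect_lt(abs(kappa - oracle) / denom, 1e-6)
    # rigid rotation leaves curvature unchanged
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    expect_equal(curvature_at_base(bezier_curve(P %*% t(R))), kappa,
                 tolerance = 1e-9)
  }
})

test_that("base angle follows the tangent and rotates exactly", {
  horiz <- bezier_curve(rbind(c(0, 0), c(1, 0), c(2, 1)))
  expect_equal(angle_at_base(horiz), 0)
  vert <- bezier_curve(rbind(c(0, 0), c(0, 1), c(1, 2)))
  expect_equal(angle_at_base(vert), 90)
  set.seed(7)
  P <- random_bezier()
  th0 <- angle_at_base(bezier_curve(P))
  phi <- 17
  R <- matrix(c(cos(phi * pi / 180), sin(phi * pi / 180),
                -sin(phi * pi / 180), cos(phi * pi / 180)), 2, 2)
  base <- P[1, ]
  Prot <- sweep(sweep(P, 2, base) %*% t(R), 2, base, `+`)
  d <- (angle_at_base(bezier_curve(Prot)) - th0 - phi) %% 360
  expect_lt(min(d, 360 - d), 1e-9)
})

test_that("curvature change subtracts the per-trial intrinsic estimate", {
  tb <- cbind(start = c(1L, 301L), end = c(301L, 601L))
  expect_equal(curvature_change(rep(0.3, 600), tb), rep(0, 600))
  # step after the intrinsic window
  k <- c(rep(0.1, 100), rep(0.15, 200), rep(0.1, 100), rep(0.15, 200))
  dk <- curvature_change(k, tb)
  expect_equal(dk[101:300], rep(0.05, 200))
  expect_equal(dk[1:100], rep(0, 100))
  # window mean verified against a direct mean over exactly 100 samples
  set.seed(1)
  k2 <- rnorm(600)
  dk2 <- curvature_change(k2, tb)
  expect_equal(dk2[350], k2[350] - mean(k2[301:400]))
  expect_error(curvature_change(rnorm(120),
                                cbind(start = c(1L, 61L),
                                      end = c(61L, 121L))),
               "intrinsic_window_ms")
})

test_that("contact forces follow the moment definition and projections", {
  z <- contact_forces(0, r = 2, phi = pi / 4, theta_base = 0.3,
                      theta_contact = 0.1)
  expect_equal(c(z$F, z$F_ax, z$F_lat), c(0, 0, 0))
  # equal tangent angles: purely lateral force
  g <- contact_forces(1, r = 2, phi = pi / 2, theta_base = 0.4,
                      theta_contact = 0.4)
  expect_equal(g$F_ax, 0)
  expect_equal(g$F_lat, g$F)
  # direct evaluation: M=2, r=4, phi=30deg -> F = 1; delta 90deg -> axial
  h <- contact_forces(2, r = 4, phi = pi / 6, theta_base = pi / 2,
                      theta_contact = 0)
  expect_equal(h$F, 1)
  expect_equal(h$F_ax, 1)
  expect_equal(h$F_lat, 0, tolerance = 1e-12)
  expect_warning(bad <- contact_forces(1, r = 1, phi = 0, theta_base = 0,
                                       theta_contact = 0), "sin\\(phi\\)")
  expect_true(is.na(bad$F))
  expect_error(contact_forces(1, r = -1, phi = 1, theta_base = 0,
                              theta_contact = 0), "r must be > 0")
})

test_that("force identities hold to machine precision on random inputs", {
  set.seed(8)
  n <- 1e4
  M <- rnorm(n); r <- runif(n, 0.1, 10)
  phi <- runif(n, 0.05, pi - 0.05)
  thb <- runif(n, -pi, pi); thc <- runif(n, -pi, pi)
  g <- contact_forces(M, r, phi, thb, thc)
  expect_equal(g$F_ax^2 + g$F_lat^2, g$F^2, tolerance = 1e-12)
  expect_equal(g$F * g$r * sin(g$phi), g$M, tolerance = 1e-12)
})

test_that("contact point matches a dense grid search and flags no-contact", {
  # straight whisker through the pole centre: foot of the perpendicular
  wc <- bezier_curve(rbind(c(0, 0), c(5, 0), c(10, 0)))
  hit <- contact_point(wc, pole_center = c(4, 0), pole_radius = 0.25)
  expect_true(hit$contact)
  expect_equal(hit$distance, 0, tolerance = 1e-8)
  expect_equal(hit$point, c(4, 0), tolerance = 1e-6)
  expect_equal(hit$r, 4, tolerance = 1e-6)
  expect_false(contact_point(wc, c(4, 30), 0.25)$contact)
  # minimizer vs dense grid on random curved whiskers
  set.seed(21)
  for (i in 1:25) {
    P <- rbind(c(0, 0), c(5, runif(1, -2, 2)), c(10, runif(1, -4, 4)))
    cv <- bezier_curve(P)
    pc <- c(runif(1, 2, 9), runif(1, -3, 3))
    res <- contact_point(cv, pc, pole_radius = 5)
    sgrid <- seq(0, 1, length.out = 200001)
    pts <- cbind((1 - sgrid)^2 * P[1, 1] + 2 * sgrid * (1 - sgrid) *
                   P[2, 1] + sgrid^2 * P[3, 1],
                 (1 - sgrid)^2 * P[1, 2] + 2 * sgrid * (1 - sgrid) *
                   P[2, 2] + sgrid^2 * P[3, 2])
    d2 <- (pts[, 1] - pc[1])^2 + (pts[, 2] - pc[2])^2
    expect_lt(abs(res$s - sgrid[which.min(d2)]), 1e-4)
  }
})

test_that("angular acceleration is exact on polynomials and sinusoids", {
  n <- 2000
  expect_true(all(abs(na.omit(angular_acceleration(rep(3, n)))) < 1e-8))
  # quadratic angle: constant acceleration reproduced in the interior
  a_true <- 5e4  # deg/s^2
  t_s <- (seq_len(n) - 1) / 1000
  acc <- angular_acceleration(0.5 * a_true * t_s^2)
  interior <- 100:(n - 100)
  expect_lt(max(abs(acc[interior] - a_true)) / a_true, 1e-6)
  # 10 Hz sinusoid: second derivative -A w^2 sin(wt), < 2% in interior
  A <- 10; f <- 10
  th <- A * sin(2 * pi * f * t_s)
  acc <- angular_acceleration(th)
  want <- -A * (2 * pi * f)^2 * sin(2 * pi * f * t_s)
  rel <- abs(acc[interior] - want[interior]) / (A * (2 * pi * f)^2)
  expect_lt(max(rel), 0.02)
  expect_error(angular_acceleration(rnorm(100), frame_ms = 30), "odd")
  expect_error(angular_acceleration(rnorm(100), poly_order = 5,
                                    frame_ms = 5), "odd|greater")
  # edges are excluded, not extrapolated
  expect_true(all(is.na(acc[1:15])))
})

test_that("angular acceleration operator is linear", {
  set.seed(3)
  x <- rnorm(500); y <- rnorm(500)
  lhs <- angular_acceleration(2 * x + 3 * y)
  rhs <- 2 * angular_acceleration(x) + 3 * angular_acceleration(y)
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("push angle references the pre-onset frame per episode", {
  a <- rep(10, 50)
  touch <- c(rep(0, 10), rep(1, 10), rep(0, 10), rep(1, 10), rep(0, 10))
  p <- push_angle(a, touch)
  expect_equal(unname(p[11:20]), rep(0, 10))
  # ramping angle: push ends at the total excursion
  a2 <- c(rep(0, 10), seq(0.5, 5, by = 0.5), rep(0, 30))
  p2 <- push_angle(a2, c(rep(0, 10), rep(1, 10), rep(0, 30)))
  expect_equal(unname(p2[20]), 5)
  # each episode uses its own reference (brute-force subtraction)
  set.seed(5)
  a3 <- rnorm(60)
  t3 <- c(rep(0, 5), rep(1, 10), rep(0, 5), rep(1, 20), rep(0, 20))
  p3 <- push_angle(a3, t3)
  expect_equal(unname(p3[6:15]), a3[6:15] - a3[5])
  expect_equal(unname(p3[21:40]), a3[21:40] - a3[20])
  expect_true(all(is.na(p3[t3 == 0])))
  # touch starting at bin 1 has no reference frame: flagged, left NA
  p4 <- push_angle(1:10, c(1, 1, rep(0, 8)))
  expect_identical(attr(p4, "flagged_episodes"), 1L)
  expect_true(all(is.na(p4[1:2])))
})
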