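test_that("lognormal speed has the printed shape: support, mode, area", {
  st <- std_stroke(D = 1, t0 = 0, mu = -1.6, sigma = 0.15)

  # zero at and before the command time
  expect_identical(lognormal_speed(c(-1, 0), st), c(0, 0))
  expect_true(all(lognormal_speed(seq(0.01, 5, by = 0.01), st) >= 0))

  # numeric argmax on a fine grid agrees with t0 + exp(mu - sigma^2)
  g <- seq(0.05, 0.6, by = 1e-5)
  t_hat <- g[which.max(lognormal_speed(g, st))]
  expect_equal(t_hat, exp(-1.6 - 0.15^2), tolerance = 1e-4)
  expect_equal(stroke_peak_time(st), exp(-1.6 - 0.15^2), tolerance = 1e-12)

  # quadrature of the speed recovers the movement extent D
  st2 <- std_stroke(D = 2, t0 = 0, mu = -1.6, sigma = 0.15)
  area <- stats::integrate(function(t) lognormal_speed(t, st2), 0, 10,
                           rel.tol = 1e-10)$value
  expect_equal(area, 2, tolerance = 1e-6)

  # closed-form peak speed matches the profile evaluated at the mode
  expect_equal(stroke_peak_speed(st), lognormal_speed(stroke_peak_time(st), st),
               tolerance = 1e-12)

  expect_error(lognormal_stroke(-1, 0, -1.6, 0.15), "D")
  expect_error(lognormal_stroke(1, 0, -1.6, -0.1), "sigma")
})

test_that("angular progression runs monotonically from theta_s to theta_e", {
  st <- std_stroke(theta_s = 0.5, theta_e = 2.0)
  expect_equal(angular_progress(st$t0, st), 0.5)
  expect_equal(angular_progress(st$t0 - 1, st), 0.5)
  expect_equal(angular_progress(st$t0 + exp(st$mu), st), (0.5 + 2.0) / 2,
               tolerance = 1e-12)
  expect_equal(angular_progress(st$t0 + 1e6, st), 2.0, tolerance = 1e-9)

  set.seed(11)
  for (i in 1:25) {
    s <- random_stroke()
    phi <- angular_progress(seq(s$t0, s$t0 + 2, by = 0.002), s)
    d <- diff(phi) * sign(s$theta_e - s$theta_s + 1e-300)
    expect_true(all(d >= -1e-12))
    expect_true(all(phi >= min(s$theta_s, s$theta_e) - 1e-9 &
                    phi <= max(s$theta_s, s$theta_e) + 1e-9))
  }
})

test_that("velocity superposition adds far-separated strokes pointwise", {
  empty <- synthesize_velocity(action_plan(NULL), duration = 1)
  expect_true(all(empty$samples == 0))

  one <- action_plan(std_stroke(theta_s = 0, theta_e = 0))
  v1 <- synthesize_velocity(one)
  expect_true(all(v1$samples[, "vy"] == 0))

  a <- std_stroke(D = 4, t0 = 0.05, theta_s = 0.3)
  b <- std_stroke(D = 6, t0 = 3.00, theta_s = 1.0)
  vab <- synthesize_velocity(action_plan(rbind(a, b)), t_start = 0,
                             duration = 4)
  va <- synthesize_velocity(action_plan(a), t_start = 0, duration = 4)
  vb <- synthesize_velocity(action_plan(b), t_start = 0, duration = 4)
  expect_equal(signal_speed(vab), signal_speed(va) + signal_speed(vb),
               tolerance = 1e-9)
})

test_that("trajectory endpoints, virtual targets, and the straight limit agree", {
  # quarter-circle arc of length pi/2 ends at (1, 1)
  arc <- action_plan(lognormal_stroke(pi / 2, 0, -1.6, 0.15, 0, pi / 2))
  tr <- synthesize_trajectory(arc, dt = 0.005, duration = 4)
  endp <- tr$samples[nrow(tr$samples), ]
  expect_equal(unname(endp), c(1, 1), tolerance = 1e-6)
  expect_equal(unname(virtual_targets(arc)[2, ]), c(1, 1), tolerance = 1e-12)

  # straight stroke: chord limit
  str <- action_plan(lognormal_stroke(10, 0, -1.6, 0.15, 0, 0))
  tr2 <- synthesize_trajectory(str, dt = 0.005, duration = 4)
  expect_equal(unname(tr2$samples[nrow(tr2$samples), ]), c(10, 0),
               tolerance = 1e-6)
  expect_equal(unname(virtual_targets(str)[2, ]), c(10, 0), tolerance = 1e-12)

  # numeric limit: tiny arc approaches the straight chord
  tiny <- action_plan(lognormal_stroke(10, 0, -1.6, 0.15, 0, 1e-7))
  tr3 <- synthesize_trajectory(tiny, dt = 0.005, duration = 4)
  expect_equal(unname(tr3$samples[nrow(tr3$samples), ]), c(10, 0),
               tolerance = 1e-5)

  # chain of three strokes: VTPs accumulate per-stroke chords
  plan3 <- separated_plan()
  vt <- virtual_targets(plan3)
  acc <- c(0, 0)
  for (j in 1:3) {
    vj <- virtual_targets(action_plan(plan3$strokes[j, ]))
    acc <- acc + (vj[2, ] - vj[1, ])
    expect_equal(unname(vt[j + 1, ]), unname(acc), tolerance = 1e-12)
  }

  # completed trajectory ends at the final virtual target
  trc <- synthesize_trajectory(plan3, dt = 0.002, duration = 4)
  expect_equal(unname(trc$samples[nrow(trc$samples), ]), unname(vt[4, ]),
               tolerance = 1e-6)
})

test_that("trajectory equals the time integral of velocity under overlap", {
  plan <- action_plan(rbind(
    lognormal_stroke(4, 0.05, -1.5, 0.25, 0.3, 1.4),
    lognormal_stroke(5, 0.12, -1.4, 0.30, 1.4, -0.6),
    lognormal_stroke(3, 0.20, -1.6, 0.20, -0.6, 0.1)))
  dt <- 0.002
  v <- synthesize_velocity(plan, dt = dt, t_start = 0, duration = 2)
  tr <- synthesize_trajectory(plan, dt = dt, t_start = 0, duration = 2)
  # trapezoidal cumulative integral of (vx, vy)
  cumtrap <- function(z) c(0, cumsum((z[-1] + z[-length(z)]) / 2 * dt))
  expect_equal(tr$samples[, "x"], cumtrap(v$samples[, "vx"]),
               tolerance = 5 * dt^2, ignore_attr = TRUE)
  expect_equal(tr$samples[, "y"], cumtrap(v$samples[, "vy"]),
               tolerance = 5 * dt^2, ignore_attr = TRUE)
})

test_that("reconstruction SNR matches its closed forms and invariances", {
  plan <- separated_plan()
  v <- synthesize_velocity(plan)

  expect_identical(snr(v, v), Inf)
  expect_equal(snr(v, v, cap = 120), 120)

  zero <- sampled_signal(cbind(vx = 0 * v$samples[, "vx"],
                               vy = 0 * v$samples[, "vy"]),
                         dt = v$dt, t_start = v$t_start)
  expect_equal(snr(v, zero), 0, tolerance = 1e-12)

  half <- sampled_signal(v$samples[, c("vx", "vy")] / 2,
                         dt = v$dt, t_start = v$t_start)
  expect_equal(snr(v, half), 20 * log10(4), tolerance = 1e-12)

  # invariant under common positive rescaling
  s3 <- sampled_signal(v$samples * 3, dt = v$dt, t_start = v$t_start)
  h3 <- sampled_signal(v$samples[, c("vx", "vy")] * 1.5,
                       dt = v$dt, t_start = v$t_start)
  expect_equal(snr(s3, h3), snr(v, half), tolerance = 1e-9)

  other <- sampled_signal(v$samples, dt = v$dt, t_start = v$t_start + 1)
  expect_error(snr(v, other), "time base")
})
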