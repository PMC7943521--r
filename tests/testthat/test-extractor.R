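test_that("candidate peaks are found above the floor, earliest tie first", {
  zero <- sampled_signal(rep(0, 50), dt = 0.01)
  expect_identical(nrow(find_stroke_candidates(zero)), 0L)

  one <- synthesize_velocity(action_plan(std_stroke()))
  cand <- find_stroke_candidates(one)
  expect_identical(nrow(cand), 1L)
  expect_lt(abs(cand$time - stroke_peak_time(std_stroke())), 0.011)

  two <- synthesize_velocity(separated_plan())
  expect_identical(nrow(find_stroke_candidates(two)), 3L)

  # plateau of equal heights: the earlier sample wins
  plat <- sampled_signal(c(0, 1, 2, 2, 2, 1, 0), dt = 0.01)
  cp <- find_stroke_candidates(plat)
  expect_identical(cp$index, 3L)
})

test_that("characteristic-point initializer inverts a clean stroke", {
  truth <- std_stroke(D = 5, t0 = 0.05, mu = -1.6, sigma = 0.15,
                      theta_s = 0.4, theta_e = 0.4)
  obs <- synthesize_velocity(action_plan(truth), t_start = 0, duration = 1)
  cand <- find_stroke_candidates(obs)
  est <- estimate_stroke_from_peak(obs, cand[1, ], trajectory = obs)
  expect_false(is.null(est))
  expect_lt(abs(est$D - truth$D) / truth$D, 0.10)
  expect_lt(abs(est$mu - truth$mu) / abs(truth$mu), 0.10)
  expect_lt(abs(est$sigma - truth$sigma) / truth$sigma, 0.10)
  expect_lt(abs(est$t0 - truth$t0), 0.005)
  expect_lt(abs(est$theta_s - 0.4), 0.1)
  expect_lt(abs(est$theta_e - est$theta_s), 0.2)

  # narrow, nearly Gaussian stroke still yields a small positive sigma
  nar <- std_stroke(sigma = 0.05)
  obs2 <- synthesize_velocity(action_plan(nar), t_start = 0, duration = 1)
  est2 <- estimate_stroke_from_peak(obs2, find_stroke_candidates(obs2)[1, ])
  expect_false(is.null(est2))
  expect_gt(est2$sigma, 0)
  expect_lt(est2$sigma, 0.2)

  # a clipped flank falls back to the clean side; when neither flank
  # reaches its half-maximum crossing the candidate is skipped
  clipped <- sampled_signal(c(0.9, 1.0, 0.95) * 50, dt = obs$dt)
  expect_null(estimate_stroke_from_peak(clipped, list(index = 2L)))
})

test_that("a single noiseless stroke is recovered almost exactly", {
  truth <- std_stroke(D = 5, t0 = 0.05, mu = -1.6, sigma = 0.15,
                      theta_s = 0.3, theta_e = 1.0)
  obs <- synthesize_velocity(action_plan(truth))
  fit <- extract_strokes(obs)
  expect_identical(nrow(fit$strokes), 1L)
  expect_gte(fit$snr, 40)
  expect_true(fit$converged)
  est <- fit$strokes
  expect_lt(abs(est$D - truth$D) / truth$D, 0.02)
  expect_lt(abs(est$mu - truth$mu) / abs(truth$mu), 0.02)
  expect_lt(abs(est$sigma - truth$sigma) / truth$sigma, 0.02)
  expect_lt(abs(est$t0 - truth$t0), 0.002)

  # reported SNR is recomputable from the reconstruction
  expect_equal(fit$snr, snr(obs, fit$reconstruction), tolerance = 1e-9)
})

test_that("a five-stroke overlapping plan is fully resolved", {
  plan <- sample_action_plan(sound_map(), synth_config(n_strokes = 5, seed = 42))
  obs <- synthesize_velocity(plan)
  fit <- extract_strokes(obs, extraction_config(snr_target = 60,
                                                refine_maxiter = 80,
                                                max_strokes = 16,
                                                peak_floor = 0.002))
  expect_identical(nrow(fit$strokes), 5L)
  expect_gte(fit$snr, 25)
  expect_true(all(diff(fit$strokes$t0) >= 0))
})

test_that("extraction of a zero observation converges with no strokes", {
  zero <- sampled_signal(cbind(vx = rep(0, 100), vy = rep(0, 100)), dt = 0.01)
  fit <- extract_strokes(zero)
  expect_identical(nrow(fit$strokes), 0L)
  expect_identical(fit$snr, Inf)
  expect_true(fit$converged)
  expect_error(extract_strokes(sampled_signal(c(1, NA, 2), dt = 0.01)),
               "finite")
})

test_that("joint refinement is a fixed point at the optimum and monotone", {
  plan <- separated_plan()
  obs <- synthesize_velocity(plan)
  cfg <- extraction_config(refine_maxiter = 200)

  # already-optimal strokes stay put
  ref <- refine_strokes(plan$strokes, obs, cfg)
  expect_equal(as.matrix(ref), as.matrix(plan$strokes), tolerance = 1e-6)

  # perturbed truth returns to truth on a noiseless signal
  set.seed(3)
  pert <- plan$strokes
  pert$D <- pert$D * runif(3, 0.9, 1.1)
  pert$mu <- pert$mu * runif(3, 0.9, 1.1)
  pert$sigma <- pert$sigma * runif(3, 0.9, 1.1)
  back <- refine_strokes(pert, obs, cfg)
  expect_equal(back$D, plan$strokes$D, tolerance = 0.01)
  expect_equal(back$mu, plan$strokes$mu, tolerance = 0.01)
  expect_equal(back$sigma, plan$strokes$sigma, tolerance = 0.01)

  # with additive noise the refined fit never scores below its start
  set.seed(4)
  noisy <- obs
  amp <- stats::sd(noisy$samples[, "vx"])
  noisy$samples[, "vx"] <- noisy$samples[, "vx"] + rnorm(nrow(noisy$samples), sd = amp / 10)
  noisy$samples[, "vy"] <- noisy$samples[, "vy"] + rnorm(nrow(noisy$samples), sd = amp / 10)
  ref2 <- refine_strokes(pert, noisy, cfg)
  expect_gte(snr(noisy, sigmalog:::reconstruct_on(ref2, noisy)),
             snr(noisy, sigmalog:::reconstruct_on(pert, noisy)))
})

test_that("analytic Jacobian of the stroke model matches finite differences", {
  st <- lognormal_stroke(3, 0.05, -1.5, 0.2, 0.4, 1.3)
  t <- seq(0, 1, by = 0.01)
  p <- sigmalog:::stroke_model_parts(st, t, planar = TRUE, want_jac = TRUE)
  nm <- c("D", "t0", "mu", "sigma", "theta_s", "theta_e")
  for (k in nm) {
    h <- 1e-7 * max(1, abs(st[[k]]))
    stp <- st
    stp[[k]] <- stp[[k]] + h
    pp <- sigmalog:::stroke_model_parts(stp, t, planar = TRUE, want_jac = FALSE)
    expect_equal(p$jx[, k], (pp$vx - p$vx) / h, tolerance = 1e-4,
                 ignore_attr = TRUE)
    expect_equal(p$jy[, k], (pp$vy - p$vy) / h, tolerance = 1e-4,
                 ignore_attr = TRUE)
  }
})

test_that("extraction is deterministic and idempotent in SNR", {
  plan <- sample_action_plan(sound_map(), synth_config(n_strokes = 4, seed = 9))
  obs <- synthesize_velocity(plan)
  cfg <- extraction_config(snr_target = 40)
  f1 <- extract_strokes(obs, cfg)
  f2 <- extract_strokes(obs, cfg)
  expect_identical(f1$strokes, f2$strokes)
  expect_identical(f1$snr, f2$snr)

  # extracting from the (exactly representable) reconstruction reproduces
  # at least the configured target quality
  f3 <- extract_strokes(f1$reconstruction, cfg)
  expect_gte(f3$snr, min(f1$snr, cfg$snr_target))
  expect_true(f3$converged)
})

test_that("speed-only observations are decomposed with angles held at zero", {
  truth <- std_stroke(D = 5, t0 = 0.05, mu = -1.6, sigma = 0.15)
  obs <- synthesize_velocity(action_plan(truth))
  speed_only <- sampled_signal(signal_speed(obs), dt = obs$dt,
                               t_start = obs$t_start)
  fit <- extract_strokes(speed_only)
  expect_identical(nrow(fit$strokes), 1L)
  expect_true(all(fit$strokes$theta_s == 0))
  expect_true(all(fit$strokes$theta_e == 0))
  expect_gte(fit$snr, 40)
})
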