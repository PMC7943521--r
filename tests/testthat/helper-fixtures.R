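# shared fixtures built in code

std_stroke <- function(D = 5, t0 = 0.05, mu = -1.6, sigma = 0.15,
                       theta_s = 0, theta_e = theta_s) {
  lognormal_stroke(D, t0, mu, sigma, theta_s, theta_e)
}

# three well-separated strokes (supports do not overlap at the 1% level)
separated_plan <- function() {
  action_plan(rbind(
    lognormal_stroke(4, 0.05, -1.7, 0.10, 0.2, 0.2),
    lognormal_stroke(6, 0.80, -1.5, 0.12, 1.2, 1.2),
    lognormal_stroke(3, 1.60, -1.6, 0.09, -0.8, -0.8)))
}

# random valid stroke under a local seed, for property-style loops
random_stroke <- function() {
  lognormal_stroke(D = runif(1, 0.5, 10), t0 = runif(1, 0, 0.3),
                   mu = runif(1, -1.9, -1.2), sigma = runif(1, 0.05, 0.3),
                   theta_s = runif(1, -pi, pi), theta_e = runif(1, -pi, pi))
}

expect_signal_equal <- function(a, b, tol = 1e-9) {
  expect_equal(a$dt, b$dt, tolerance = tol)
  expect_equal(a$t_start, b$t_start, tolerance = tol)
  expect_equal(unname(a$samples), unname(b$samples), tolerance = tol)
}
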