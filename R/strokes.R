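#' Lognormal stroke
#'
#' One simple movement primitive of the Sigma-lognormal model.  A stroke
#' traverses an arc of a circle with a lognormal speed profile.
#'
#' @param D movement extent (arc length), mm; > 0.
#' @param t0 time occurrence of the motor command, s.
#' @param mu log time delay of the neuromuscular response (log-seconds).
#' @param sigma log response time (dimensionless); > 0.
#' @param theta_s,theta_e starting and ending angular directions, rad.
#' @return A one-row data frame with columns
#'   `D, t0, mu, sigma, theta_s, theta_e`.
#' @examples
#' lognormal_stroke(D = 5, t0 = 0.05, mu = -1.6, sigma = 0.15)
#' @export
lognormal_stroke <- function(D, t0, mu, sigma, theta_s = 0, theta_e = theta_s) {
  s <- data.frame(D = D, t0 = t0, mu = mu, sigma = sigma,
                  theta_s = theta_s, theta_e = theta_e)
  validate_strokes(s)
  s
}

# accepts a stroke data frame (one row per stroke) or coercible list
as_strokes <- function(strokes) {
  if (is.null(strokes) || (is.data.frame(strokes) && nrow(strokes) == 0L))
    return(empty_strokes())
  if (!is.data.frame(strokes)) strokes <- as.data.frame(as.list(strokes))
  need <- c("D", "t0", "mu", "sigma", "theta_s", "theta_e")
  if (!all(need %in% names(strokes)))
    stop("strokes must have columns ", paste(need, collapse = ", "))
  strokes[need]
}

empty_strokes <- function() {
  data.frame(D = numeric(0), t0 = numeric(0), mu = numeric(0),
             sigma = numeric(0), theta_s = numeric(0), theta_e = numeric(0))
}

validate_strokes <- function(strokes) {
  strokes <- as_strokes(strokes)
  if (nrow(strokes) == 0L) return(invisible(strokes))
  if (!all(is.finite(as.matrix(strokes))))
    stop("stroke parameters must be finite")
  if (any(strokes$D <= 0)) stop("stroke extent D must be > 0")
  if (any(strokes$sigma <= 0)) stop("stroke sigma must be > 0")
  invisible(strokes)
}

#' Action plan
#'
#' An ordered sequence of lognormal strokes plus the initial virtual target
#' point.  Strokes are sorted by non-decreasing command time `t0`; the chain
#' of virtual target points follows recursively from `vtp0` and each
#' stroke's arc chord.
#'
#' @param strokes data frame of stroke parameters (see [lognormal_stroke()]).
#' @param vtp0 initial virtual target point, length-2 numeric (mm).
#' @return An object of class `action_plan`.
#' @export
action_plan <- function(strokes, vtp0 = c(0, 0)) {
  strokes <- as_strokes(strokes)
  validate_strokes(strokes)
  stopifnot(length(vtp0) == 2L, all(is.finite(vtp0)))
  if (nrow(strokes) > 1L) strokes <- strokes[order(strokes$t0), , drop = FALSE]
  rownames(strokes) <- NULL
  structure(list(strokes = strokes, vtp0 = as.numeric(vtp0)),
            class = "action_plan")
}

#' @export
print.action_plan <- function(x, ...) {
  cat(sprintf("<action_plan> %d stroke(s), vtp0 = (%g, %g) mm\n",
              nrow(x$strokes), x$vtp0[1], x$vtp0[2]))
  if (nrow(x$strokes)) print(x$strokes)
  invisible(x)
}

plan_strokes <- function(x) {
  if (inherits(x, "action_plan")) x$strokes else as_strokes(x)
}

#' Lognormal speed profile of a single stroke
#'
#' `D * Lambda(t; t0, mu, sigma)`, the lognormal velocity magnitude of one
#' simple movement.  The value at and before `t0` is 0 (left limit).
#'
#' @param t times, s (vectorized).
#' @param stroke a single stroke (one-row data frame or named list).
#' @return Speeds in mm/s, non-negative, zero for `t <= t0`.
#' @examples
#' s <- lognormal_stroke(1, 0, -1.6, 0.15)
#' lognormal_speed(exp(-1.6 - 0.15^2), s)  # peak speed
#' @export
lognormal_speed <- function(t, stroke) {
  stroke <- validate_strokes(stroke)
  if (nrow(stroke) != 1L) stop("lognormal_speed expects a single stroke")
  tau <- t - stroke$t0
  v <- numeric(length(t))
  ok <- tau > 0
  v[ok] <- stroke$D * stats::dlnorm(tau[ok], stroke$mu, stroke$sigma)
  v
}

#' Angular position along a stroke's arc
#'
#' Progresses monotonically from `theta_s` to `theta_e` following the
#' lognormal's cumulative time course:
#' `theta_s + (theta_e - theta_s)/2 * (1 + erf((log(t - t0) - mu)/(sigma*sqrt(2))))`.
#'
#' @inheritParams lognormal_speed
#' @return Angles in rad; equals `theta_s` for `t <= t0`.
#' @export
angular_progress <- function(t, stroke) {
  stroke <- validate_strokes(stroke)
  if (nrow(stroke) != 1L) stop("angular_progress expects a single stroke")
  f <- stroke_fraction(t, stroke)
  stroke$theta_s + (stroke$theta_e - stroke$theta_s) * f
}

# completed fraction of a stroke: lognormal CDF of t - t0
stroke_fraction <- function(t, stroke) {
  tau <- t - stroke$t0
  f <- numeric(length(t))
  ok <- tau > 0
  f[ok] <- stats::plnorm(tau[ok], stroke$mu, stroke$sigma)
  f
}

#' Time and value of a stroke's speed peak
#'
#' The lognormal mode lies at `t0 + exp(mu - sigma^2)`; the peak speed is
#' `D * exp(sigma^2/2 - mu) / (sigma * sqrt(2*pi))`.
#'
#' @param strokes stroke data frame (any number of rows).
#' @return `stroke_peak_time`: peak times, s.  `stroke_peak_speed`: peak
#'   speeds, mm/s.
#' @export
stroke_peak_time <- function(strokes) {
  strokes <- as_strokes(strokes)
  strokes$t0 + exp(strokes$mu - strokes$sigma^2)
}

#' @rdname stroke_peak_time
#' @export
stroke_peak_speed <- function(strokes) {
  strokes <- as_strokes(strokes)
  strokes$D * exp(strokes$sigma^2 / 2 - strokes$mu) /
    (strokes$sigma * sqrt(2 * pi))
}

#' Temporal support of a stroke at a fraction of its peak
#'
#' The two times at which the stroke's lognormal speed equals
#' `level * peak`.  In log-time the lognormal speed is Gaussian, so the
#' bounds are exactly `t0 + exp(mu - sigma^2 -/+ sigma*sqrt(-2*log(level)))`.
#' The conventional overlap bound used for phoneme matching is 5% of the
#' peak.
#'
#' @param stroke a single stroke.
#' @param level fraction of the peak speed in (0, 1); default 0.05.
#' @return Numeric `c(t_begin, t_end)`, with `t0 < t_begin < mode < t_end`.
#' @export
lognormal_support <- function(stroke, level = 0.05) {
  stroke <- validate_strokes(stroke)
  if (nrow(stroke) != 1L) stop("lognormal_support expects a single stroke")
  if (!is.numeric(level) || level <= 0 || level >= 1)
    stop("level must be in (0, 1)")
  u0 <- stroke$mu - stroke$sigma^2
  half <- stroke$sigma * sqrt(-2 * log(level))
  stroke$t0 + exp(c(u0 - half, u0 + half))
}

# support bounds for every stroke: matrix with columns t_begin, t_end
strokes_support <- function(strokes, level = 0.05) {
  strokes <- as_strokes(strokes)
  u0 <- strokes$mu - strokes$sigma^2
  half <- strokes$sigma * sqrt(-2 * log(level))
  cbind(t_begin = strokes$t0 + exp(u0 - half),
        t_end = strokes$t0 + exp(u0 + half))
}

# default time span covering a plan's active support
plan_timespan <- function(strokes, level = 0.01, margin = 0.05) {
  strokes <- plan_strokes(strokes)
  if (nrow(strokes) == 0L) return(c(0, 1))
  sup <- strokes_support(strokes, level)
  c(min(0, min(strokes$t0)), max(sup[, "t_end"]) + margin)
}

default_timebase <- function(plan, dt = 0.01, t_start = NULL, duration = NULL) {
  span <- plan_timespan(plan)
  if (is.null(t_start)) t_start <- span[1]
  t_end <- if (is.null(duration)) span[2] else t_start + duration
  n <- max(2L, 1L + ceiling((t_end - t_start) / dt - 1e-9))
  list(t_start = t_start, dt = dt, n = n)
}

# planar velocity matrix (n x 2) of a stroke set on time vector t
velocity_matrix <- function(strokes, t) {
  strokes <- as_strokes(strokes)
  vx <- numeric(length(t))
  vy <- numeric(length(t))
  for (j in seq_len(nrow(strokes))) {
    st <- strokes[j, ]
    v <- lognormal_speed(t, st)
    phi <- angular_progress(t, st)
    vx <- vx + v * cos(phi)
    vy <- vy + v * sin(phi)
  }
  cbind(vx = vx, vy = vy)
}

#' Synthesize the planar velocity of an action plan
#'
#' Vector (time-overlapped) superposition of the strokes' lognormal
#' velocities; the speed channel is the Euclidean norm of the sum.
#'
#' @param plan an [action_plan()] or a stroke data frame.
#' @param dt sampling step, s (default 0.01).
#' @param t_start first sample time; defaults to the plan's support start.
#' @param duration total duration, s; defaults to the plan's active support.
#' @return A [sampled_signal()] with channels `vx`, `vy`, `speed`.
#' @export
synthesize_velocity <- function(plan, dt = 0.01, t_start = NULL,
                                duration = NULL) {
  strokes <- plan_strokes(plan)
  validate_strokes(strokes)
  tb <- default_timebase(strokes, dt, t_start, duration)
  t <- tb$t_start + (seq_len(tb$n) - 1L) * tb$dt
  m <- velocity_matrix(strokes, t)
  sampled_signal(cbind(m, speed = sqrt(m[, "vx"]^2 + m[, "vy"]^2)),
                 dt = tb$dt, t_start = tb$t_start)
}

# tolerance below which |theta_e - theta_s| is treated as a straight stroke
STRAIGHT_TOL <- 1e-8

# per-stroke displacement (n x 2) at times t: the partial arc chord
stroke_displacement <- function(stroke, t) {
  dth <- stroke$theta_e - stroke$theta_s
  if (abs(dth) >= STRAIGHT_TOL) {
    phi <- angular_progress(t, stroke)
    cbind(stroke$D / dth * (sin(phi) - sin(stroke$theta_s)),
          stroke$D / dth * (cos(stroke$theta_s) - cos(phi)))
  } else {
    # straight limit: chord direction weighted by the completed fraction
    f <- stroke_fraction(t, stroke)
    cbind(stroke$D * f * cos(stroke$theta_s),
          stroke$D * f * sin(stroke$theta_s))
  }
}

#' Synthesize the planar trajectory of an action plan
#'
#' Sum of temporally overlapped circle arcs linking consecutive virtual
#' target points, offset by the plan's initial virtual target.  Strokes
#' with `|theta_e - theta_s|` below an internal tolerance use the analytic
#' straight-stroke limit (the arc expressions divide by `theta_e -
#' theta_s`).
#'
#' @inheritParams synthesize_velocity
#' @return A [sampled_signal()] with channels `x`, `y` (mm).
#' @export
synthesize_trajectory <- function(plan, dt = 0.01, t_start = NULL,
                                  duration = NULL) {
  strokes <- plan_strokes(plan)
  validate_strokes(strokes)
  vtp0 <- if (inherits(plan, "action_plan")) plan$vtp0 else c(0, 0)
  tb <- default_timebase(strokes, dt, t_start, duration)
  t <- tb$t_start + (seq_len(tb$n) - 1L) * tb$dt
  x <- rep(vtp0[1], tb$n)
  y <- rep(vtp0[2], tb$n)
  for (j in seq_len(nrow(strokes))) {
    d <- stroke_displacement(strokes[j, ], t)
    x <- x + d[, 1]
    y <- y + d[, 2]
  }
  sampled_signal(cbind(x = x, y = y), dt = tb$dt, t_start = tb$t_start)
}

#' Virtual target points of an action plan
#'
#' The recursive chain of positions each stroke aims at: `VTP_j` is
#' `VTP_{j-1}` plus the stroke's completed arc chord.  Targets are not
#' necessarily reached because successive strokes overlap in time.
#'
#' @param plan an [action_plan()] or stroke data frame.
#' @return Numeric matrix of `(nblog + 1)` rows and columns `x`, `y`; the
#'   first row is the initial virtual target.
#' @export
virtual_targets <- function(plan) {
  strokes <- plan_strokes(plan)
  validate_strokes(strokes)
  vtp0 <- if (inherits(plan, "action_plan")) plan$vtp0 else c(0, 0)
  out <- matrix(0, nrow = nrow(strokes) + 1L, ncol = 2,
                dimnames = list(NULL, c("x", "y")))
  out[1, ] <- vtp0
  for (j in seq_len(nrow(strokes))) {
    st <- strokes[j, ]
    dth <- st$theta_e - st$theta_s
    chord <- if (abs(dth) >= STRAIGHT_TOL) {
      st$D / dth * c(sin(st$theta_e) - sin(st$theta_s),
                     cos(st$theta_s) - cos(st$theta_e))
    } else {
      st$D * c(cos(st$theta_s), sin(st$theta_s))
    }
    out[j + 1L, ] <- out[j, ] + chord
  }
  out
}
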