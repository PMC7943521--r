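#' Formant track
#'
#' A time series of the first two formants with a voiced/unvoiced mask.
#' Unvoiced frames may carry `NA` formants; they are filled by
#' [interpolate_gaps()] before mapping to kinematics.
#'
#' @param t times, s, strictly increasing.
#' @param f1,f2 first and second formant frequencies, Hz.
#' @param voiced logical mask; defaults to frames where both formants are
#'   finite and positive.
#' @return A data frame of class `formant_track` with columns
#'   `t, f1, f2, voiced`.
#' @export
formant_track <- function(t, f1, f2, voiced = NULL) {
  stopifnot(length(t) == length(f1), length(t) == length(f2))
  if (length(t) == 0L) stop("formant track is empty")
  if (is.unsorted(t, strictly = TRUE)) {
    o <- order(t)
    t <- t[o]; f1 <- f1[o]; f2 <- f2[o]
    if (!is.null(voiced)) voiced <- voiced[o]
    if (anyDuplicated(t)) stop("formant track times must be strictly increasing")
  }
  if (is.null(voiced))
    voiced <- is.finite(f1) & is.finite(f2) & f1 > 0 & f2 > 0
  voiced <- as.logical(voiced) & is.finite(f1) & is.finite(f2)
  if (any(voiced & (f1 <= 0 | f2 <= 0)))
    stop("voiced frames must have positive formants")
  structure(data.frame(t = as.numeric(t), f1 = as.numeric(f1),
                       f2 = as.numeric(f2), voiced = voiced),
            class = c("formant_track", "data.frame"))
}

#' Proportion parameter of the acoustic-to-kinematic map
#'
#' The relative contribution of F2 versus F1 to the kinematic space,
#' obtained by fitting the /a/-/i/-/u/ vowel triangle with an equilateral
#' triangle (the /i/-/a/ and /i/-/u/ sides are forced to equal length):
#' `alpha = (F1a - F1i) / ((F1a - F1i) + sqrt(3)/2 * (F2i - F2u))`.
#'
#' @param f1a first formant of /a/, Hz.
#' @param f1i,f2i first and second formants of /i/, Hz.
#' @param f2u second formant of /u/, Hz.
#' @return `alpha` in `[0, 1]` (dimensionless).
#' @examples
#' # adult-male American-English mean vowel formants (Hillenbrand et al.)
#' compute_alpha(768, 342, 2322, 997)  # ~0.27
#' @export
compute_alpha <- function(f1a, f1i, f2i, f2u) {
  d1 <- f1a - f1i
  d2 <- f2i - f2u
  if (d1 < 0 || d2 < 0)
    stop("expected F1a >= F1i and F2i >= F2u (vowel-triangle orientation)")
  if (d1 == 0 && d2 == 0)
    stop("degenerate vowel triangle: both formant spans are zero")
  d1 / (d1 + sqrt(3) / 2 * d2)
}

#' Scale constant of the acoustic-to-kinematic map
#'
#' `k = L2 / (alpha * (F2i - F2u))`, the mm/Hz factor that gives the
#' /i/-/u/ side of the mapped vowel triangle a physical length `L2`.
#'
#' @param L2 target /i/-/u/ distance in kinematic space, mm.
#' @param alpha proportion parameter, > 0.
#' @param f2i,f2u second formants of /i/ and /u/, Hz, with `f2i > f2u`.
#' @return `k` in mm/Hz.
#' @export
compute_k <- function(L2, alpha, f2i, f2u) {
  den <- alpha * (f2i - f2u)
  if (!is.finite(den) || den == 0)
    stop("alpha * (F2i - F2u) must be nonzero")
  L2 / den
}

#' Transfer coefficients of the linear formant-to-kinematics map
#'
#' `c1 = k * (1 - alpha)` weights F1 onto the y axis and `c2 = k * alpha`
#' weights F2 onto the x axis; `c1 + c2 = k`.
#'
#' @param alpha proportion parameter in `[0, 1]`.
#' @param k scale constant, mm/Hz, > 0.
#' @return Named numeric `c(c1, c2)`, mm/Hz.
#' @export
transfer_coefficients <- function(alpha, k) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (k <= 0) stop("k must be > 0")
  c(c1 = k * (1 - alpha), c2 = k * alpha)
}

#' Parameters of the acoustic-to-kinematic map
#'
#' Bundles `alpha`, `k` and the transfer coefficients.  Either pass
#' `alpha`/`k` literals (defaults 0.3 and 0.04 mm/Hz, the values used for
#' continuous-speech analysis) or the four anchor formants (plus `L2`) from
#' which both are derived.
#'
#' @param alpha proportion parameter; ignored when `anchors` is given.
#' @param k scale constant, mm/Hz; derived from `L2` when anchors are given.
#' @param anchors optional named list/vector with `f1a, f1i, f2i, f2u` (Hz).
#' @param L2 target /i/-/u/ kinematic distance, mm (used with `anchors`).
#' @return An object of class `kinematic_map`: list with `alpha`, `k`,
#'   `c1`, `c2`, and `anchors`/`L2` when supplied.
#' @export
kinematic_map_params <- function(alpha = 0.3, k = 0.04, anchors = NULL,
                                 L2 = NULL) {
  if (!is.null(anchors)) {
    anchors <- as.list(anchors)
    alpha <- compute_alpha(anchors$f1a, anchors$f1i, anchors$f2i, anchors$f2u)
    if (!is.null(L2)) k <- compute_k(L2, alpha, anchors$f2i, anchors$f2u)
  }
  cc <- transfer_coefficients(alpha, k)
  structure(list(alpha = alpha, k = k, c1 = unname(cc["c1"]),
                 c2 = unname(cc["c2"]), anchors = anchors, L2 = L2),
            class = "kinematic_map")
}

#' @export
print.kinematic_map <- function(x, ...) {
  cat(sprintf("<kinematic_map> alpha = %.4g, k = %.4g mm/Hz (c1 = %.4g, c2 = %.4g)\n",
              x$alpha, x$k, x$c1, x$c2))
  invisible(x)
}

#' Interpolate unvoiced gaps in a formant track
#'
#' Missing formant information in unvoiced stretches is treated as a
#' movement between the surrounding voiced frames: F1 and F2 are linearly
#' interpolated across interior gaps.  Leading and trailing unvoiced frames
#' are trimmed.
#'
#' @param track a [formant_track()].
#' @return A gap-free `formant_track` (all frames voiced).
#' @export
interpolate_gaps <- function(track) {
  stopifnot(inherits(track, "formant_track"))
  if (!any(track$voiced)) stop("formant track is entirely unvoiced")
  keep <- range(which(track$voiced))
  track <- track[keep[1]:keep[2], , drop = FALSE]
  if (!all(track$voiced)) {
    vi <- which(track$voiced)
    track$f1 <- stats::approx(track$t[vi], track$f1[vi], xout = track$t)$y
    track$f2 <- stats::approx(track$t[vi], track$f2[vi], xout = track$t)$y
    track$voiced <- TRUE
  }
  rownames(track) <- NULL
  structure(track, class = c("formant_track", "data.frame"))
}

#' Resample a formant track to a uniform time step
#'
#' Linear resampling of F1/F2 to a uniform grid (default 0.01 s, the usual
#' formant-tracking time step).  A resampled frame is voiced only when both
#' bracketing original frames are voiced.
#'
#' @param track a [formant_track()].
#' @param dt target sampling step, s.
#' @return A uniformly sampled `formant_track`.
#' @export
resample_track <- function(track, dt = 0.01) {
  stopifnot(inherits(track, "formant_track"))
  if (nrow(track) < 2L) stop("need at least two frames to resample")
  tout <- seq(track$t[1], track$t[nrow(track)], by = dt)
  f1 <- stats::approx(track$t, track$f1, xout = tout)$y
  f2 <- stats::approx(track$t, track$f2, xout = tout)$y
  v <- stats::approx(track$t, as.numeric(track$voiced), xout = tout)$y
  formant_track(tout, f1, f2, voiced = v >= 1 - 1e-9)
}

# uniform step of a track (error if non-uniform)
track_dt <- function(track, tol = 1e-6) {
  d <- diff(track$t)
  if (length(d) == 0L) stop("track too short")
  if (max(d) - min(d) > tol * mean(d))
    stop("track is not uniformly sampled; call resample_track() first")
  mean(d)
}

#' Map a formant track to a kinematic trajectory
#'
#' The linear map `x(t) = c2 * F2(t)`, `y(t) = c1 * F1(t)`, with the track's
#' initial point subtracted so the trajectory starts at the origin (initial
#' conditions are irrelevant to the stroke decomposition).
#'
#' @param track a gap-free, uniformly sampled [formant_track()].
#' @param params a [kinematic_map_params()].
#' @return A planar position [sampled_signal()] (channels `x`, `y`, mm).
#' @export
formants_to_trajectory <- function(track, params = kinematic_map_params()) {
  stopifnot(inherits(track, "formant_track"), inherits(params, "kinematic_map"))
  if (!all(track$voiced))
    stop("track has unvoiced gaps; call interpolate_gaps() first")
  dt <- track_dt(track)
  x <- params$c2 * track$f2
  y <- params$c1 * track$f1
  sampled_signal(cbind(x = x - x[1], y = y - y[1]),
                 dt = dt, t_start = track$t[1])
}

# central differences with one-sided edges; p is a vector, returns dp/dt
central_diff <- function(p, dt) {
  n <- length(p)
  d <- numeric(n)
  if (n >= 3L) d[2:(n - 1)] <- (p[3:n] - p[1:(n - 2)]) / (2 * dt)
  d[1] <- (p[2] - p[1]) / dt
  d[n] <- (p[n] - p[n - 1]) / dt
  d
}

#' Kinematic velocity and speed from formants or a trajectory
#'
#' Differentiates the mapped trajectory by central differences (one-sided
#' at the edges) and returns the planar velocity with its Euclidean-norm
#' speed: `v(t) = sqrt((c2 dF2/dt)^2 + (c1 dF1/dt)^2)`.  Optionally applies
#' a zero-phase 4th-order low-pass (articulatory band) before
#' differentiation; the default is literal differencing.
#'
#' @param x a gap-free uniformly sampled [formant_track()] or a planar
#'   position [sampled_signal()].
#' @param params a [kinematic_map_params()] (used when `x` is a track).
#' @param smooth logical; apply zero-phase low-pass filtering first.
#' @param cutoff_hz low-pass cutoff, Hz (default 15).
#' @return A [sampled_signal()] with channels `vx`, `vy`, `speed`.
#' @export
kinematic_speed <- function(x, params = kinematic_map_params(),
                            smooth = FALSE, cutoff_hz = 15) {
  if (inherits(x, "formant_track")) x <- formants_to_trajectory(x, params)
  stopifnot(inherits(x, "sampled_signal"))
  if (!has_channels(x, c("x", "y")))
    stop("expected a planar position signal with channels 'x' and 'y'")
  n <- n_samples(x)
  if (n < 3L) stop("need at least 3 samples to differentiate")
  px <- x$samples[, "x"]
  py <- x$samples[, "y"]
  if (smooth) {
    ny <- 1 / (2 * x$dt)
    if (cutoff_hz < ny) {
      bf <- signal::butter(4, cutoff_hz / ny)
      px <- signal::filtfilt(bf, px)
      py <- signal::filtfilt(bf, py)
    }
  }
  vx <- central_diff(px, x$dt)
  vy <- central_diff(py, x$dt)
  sampled_signal(cbind(vx = vx, vy = vy, speed = sqrt(vx^2 + vy^2)),
                 dt = x$dt, t_start = x$t_start)
}

#' Estimate anchor formants from a track's extremes
#'
#' Heuristic per-track anchors when no vowel inventory is available: the
#' 95th percentile of F1 for /a/, the 5th of F1 and 95th of F2 for /i/, the
#' 5th of F2 for /u/.  Declared heuristic; prefer measured vowel anchors.
#'
#' @param track a [formant_track()].
#' @return Named list `f1a, f1i, f2i, f2u` (Hz).
#' @export
estimate_anchors <- function(track) {
  stopifnot(inherits(track, "formant_track"))
  v <- track[track$voiced, , drop = FALSE]
  if (nrow(v) < 2L) stop("too few voiced frames to estimate anchors")
  list(f1a = unname(stats::quantile(v$f1, 0.95)),
       f1i = unname(stats::quantile(v$f1, 0.05)),
       f2i = unname(stats::quantile(v$f2, 0.95)),
       f2u = unname(stats::quantile(v$f2, 0.05)))
}
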