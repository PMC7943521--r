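#' Extraction configuration
#'
#' Settings for the reverse engineering of a velocity signal into
#' lognormal strokes.
#'
#' @param snr_target reconstruction SNR (dB) at which extraction stops
#'   adding strokes; default 25.
#' @param snr_accept SNR (dB) above which a reconstruction is flagged as
#'   converged; 15 dB is the conventional acceptability bound.
#' @param max_strokes hard cap on the number of strokes.
#' @param peak_floor candidate peaks below this fraction of the observed
#'   speed maximum are ignored; in (0, 1).
#' @param refine_tolerance relative convergence tolerance of the bounded
#'   least-squares refinement.
#' @param refine_maxiter maximum Levenberg-Marquardt iterations per
#'   refinement call.
#' @param seed integer seed reserved for stochastic restarts (the default
#'   algorithm is deterministic).
#' @return A list of class `extraction_config`.
#' @export
extraction_config <- function(snr_target = 25, snr_accept = 15,
                              max_strokes = 64L, peak_floor = 0.01,
                              refine_tolerance = 1e-9, refine_maxiter = 40L,
                              seed = 1L) {
  if (snr_accept > snr_target) stop("snr_accept must be <= snr_target")
  if (peak_floor <= 0 || peak_floor >= 1) stop("peak_floor must be in (0, 1)")
  structure(list(snr_target = snr_target, snr_accept = snr_accept,
                 max_strokes = as.integer(max_strokes),
                 peak_floor = peak_floor,
                 refine_tolerance = refine_tolerance,
                 refine_maxiter = as.integer(refine_maxiter),
                 seed = as.integer(seed)),
            class = "extraction_config")
}

# physiologically plausible parameter bounds used by the refinement;
# d_max (when finite) caps any stroke extent at a multiple of the observed
# path length, which stops the optimizer exploiting far-tail shapes
stroke_bounds <- function(t_start, t_end, d_max = Inf) {
  list(lower = c(D = 1e-4, t0 = t_start - 0.5, mu = -2.25, sigma = 0.01,
                 theta_s = -6.5, theta_e = -6.5),
       upper = c(D = d_max, t0 = t_end, mu = -0.85, sigma = 1.5,
                 theta_s = 6.5, theta_e = 6.5))
}

clamp_strokes <- function(strokes, bounds) {
  for (p in c("D", "t0", "mu", "sigma", "theta_s", "theta_e")) {
    eps <- if (p %in% c("D", "sigma")) 1e-6 else 1e-9
    strokes[[p]] <- pmin(pmax(strokes[[p]], bounds$lower[[p]] + eps),
                         if (is.finite(bounds$upper[[p]]))
                           bounds$upper[[p]] - eps else strokes[[p]])
  }
  strokes
}

#' Locate candidate stroke peaks in a speed profile
#'
#' Local maxima of the speed signal above `peak_floor` times its global
#' maximum, ordered by time.  Ties between equal-height neighbours resolve
#' to the earlier sample.
#'
#' @param speed a [sampled_signal()] carrying a non-negative speed.
#' @param config an [extraction_config()].
#' @return Data frame with columns `time`, `value`, `index`; zero rows for
#'   an all-zero signal.
#' @export
find_stroke_candidates <- function(speed, config = extraction_config()) {
  stopifnot(inherits(speed, "sampled_signal"))
  s <- signal_speed(speed)
  find_candidates_abs(s, signal_time(speed), config$peak_floor * max(s, 0))
}

find_candidates_abs <- function(s, t, floor_abs) {
  n <- length(s)
  empty <- data.frame(time = numeric(0), value = numeric(0),
                      index = integer(0))
  if (n < 3L || max(s) <= 0) return(empty)
  # strict rise on the left, non-strict on the right: plateaus keep the
  # earliest sample
  idx <- which(s[2:(n - 1)] > s[1:(n - 2)] & s[2:(n - 1)] >= s[3:n]) + 1L
  idx <- idx[s[idx] >= floor_abs & s[idx] > 0]
  if (length(idx) == 0L) return(empty)
  data.frame(time = t[idx], value = s[idx], index = idx)
}

#' Initialize a stroke from a speed peak's characteristic points
#'
#' Closed-form inversion of the lognormal's geometry, which is Gaussian in
#' log-time.  The peak is located to sub-sample precision by parabolic
#' interpolation; with the peak time `tmax` and the half-maximum crossings
#' `t1 < tmax < t2`, the skew ratio `(t2 - tmax)/(tmax - t1) =
#' exp(sigma * sqrt(2 log 2))` yields `sigma`, the absolute half-width
#' yields `mu`, then `t0 = tmax - exp(mu - sigma^2)` and `D` follows from
#' `v_max = D exp(sigma^2/2 - mu)/(sigma sqrt(2 pi))`.  When one flank is
#' contaminated by a neighbouring movement (the profile turns upwards
#' again before crossing), the clean flank's half- and quarter-maximum
#' crossings are inverted instead.  Arc directions are initialized from
#' the velocity direction at the 5% support bounds when a planar signal is
#' available.
#'
#' @param speed a [sampled_signal()] speed profile (typically a residual).
#' @param peak one row of [find_stroke_candidates()] output (or a list with
#'   `index`).
#' @param trajectory optional planar [sampled_signal()] (position `x`/`y`
#'   or velocity `vx`/`vy`) used to estimate `theta_s`/`theta_e`.
#' @return A one-row stroke data frame, or `NULL` when the peak is too
#'   close to the signal edge (or too entangled) to locate usable
#'   crossings (skip-candidate signal).
#' @export
estimate_stroke_from_peak <- function(speed, peak, trajectory = NULL) {
  stopifnot(inherits(speed, "sampled_signal"))
  s <- signal_speed(speed)
  t <- signal_time(speed)
  i <- as.integer(peak$index)
  n <- length(s)
  if (i <= 1L || i >= n) return(NULL)
  # sub-sample peak location by parabolic interpolation through the three
  # samples around the maximum (the grid-quantized peak time makes the
  # closed-form inversion ill-conditioned otherwise)
  # sub-sample peak location: spline maximum over the neighbouring samples
  # (the grid-quantized peak time makes the closed-form inversion
  # ill-conditioned otherwise)
  vmax <- s[i]
  tmax <- t[i]
  ii <- max(1L, i - 3L):min(n, i + 3L)
  if (length(ii) >= 4L && s[i - 1L] - 2 * s[i] + s[i + 1L] < 0) {
    sf <- stats::splinefun(t[ii], s[ii], method = "natural")
    op <- stats::optimize(sf, c(t[i - 1L], t[i + 1L]), maximum = TRUE,
                          tol = 1e-10)
    if (op$objective >= vmax) {
      tmax <- op$maximum
      vmax <- op$objective
    }
  }

  # level crossing on one flank, refined on a shape-preserving spline; NA
  # when the flank turns upwards again (contaminated by a neighbouring
  # stroke) or runs off the signal edge
  rise_tol <- 0.05 * vmax
  cross <- function(level, side) {
    j <- i
    repeat {
      k <- j + side
      if (k < 1L || k > n) return(NA_real_)
      if (s[k] < level) break
      if (s[k] > s[j] + rise_tol) return(NA_real_)
      j <- k
    }
    lo <- min(j, j + side)
    hi <- max(j, j + side)
    ii <- max(1L, lo - 2L):min(n, hi + 2L)
    root <- tryCatch({
      sf <- stats::splinefun(t[ii], s[ii], method = "monoH.FC")
      stats::uniroot(function(x) sf(x) - level, c(t[lo], t[hi]),
                     tol = 1e-10)$root
    }, error = function(e) NA_real_)
    if (is.finite(root)) return(root)
    t[j] + side * speed$dt * (s[j] - level) / (s[j] - s[j + side])
  }
  t50l <- cross(vmax / 2, -1L)
  t50r <- cross(vmax / 2, +1L)

  cc <- sqrt(2 * log(2))       # half-maximum offset in mode-centred units
  bounds <- stroke_bounds(t[1], t[n])
  sigma <- mu <- NA_real_
  if (is.finite(t50l) && is.finite(t50r) && t50l < tmax && t50r > tmax) {
    sigma <- log((t50r - tmax) / (tmax - t50l)) / cc
    sigma <- min(max(sigma, 0.02), 1.2)
    mu <- sigma^2 + log((tmax - t50l) / (1 - exp(-sigma * cc)))
    if (mu < bounds$lower[["mu"]] || mu > bounds$upper[["mu"]]) {
      # clamp mu and re-solve sigma so the full half-width is preserved
      mu <- min(max(mu, bounds$lower[["mu"]] + 0.01),
                bounds$upper[["mu"]] - 0.01)
      w <- t50r - t50l
      froot <- function(sg) 2 * exp(mu - sg^2) * sinh(sg * cc) - w
      sigma <- tryCatch({
        if (froot(0.02) * froot(1.2) < 0)
          stats::uniroot(froot, c(0.02, 1.2), tol = 1e-9)$root
        else sigma
      }, error = function(e) sigma)
    }
  } else {
    # one clean flank: invert from its half- and quarter-maximum crossings
    side <- if (is.finite(t50l) && t50l < tmax) -1L else
      if (is.finite(t50r) && t50r > tmax) +1L else return(NULL)
    t50 <- if (side < 0L) t50l else t50r
    t25 <- cross(vmax / 4, side)
    if (!is.finite(t25)) return(NULL)
    w50 <- abs(tmax - t50)
    w25 <- abs(tmax - t25)
    if (w25 <= w50) return(NULL)
    c25 <- sqrt(2 * log(4))
    # mode offset a = tmax - t0 solves
    # log(a / (a -/+ w50)) / log(a / (a -/+ w25)) = cc / c25 on the left
    # flank (mirrored on the right); scan a log-spaced grid for the root
    a_grid <- exp(seq(log(w25 * 1.02), log(w25 * 60), length.out = 80))
    g <- vapply(a_grid, function(a) {
      b50 <- a - side * w50
      b25 <- a - side * w25
      if (b50 <= 0 || b25 <= 0) return(NA_real_)
      abs(abs(log(a / b50)) / abs(log(a / b25)) - cc / c25)
    }, numeric(1))
    if (all(is.na(g))) return(NULL)
    a <- a_grid[which.min(g)]
    sigma <- abs(log(a / (a - side * w50))) / cc
    sigma <- min(max(sigma, 0.02), 1.2)
    mu <- log(a) + sigma^2
    mu <- min(max(mu, bounds$lower[["mu"]] + 0.01),
              bounds$upper[["mu"]] - 0.01)
  }
  t0 <- tmax - exp(mu - sigma^2)
  D <- vmax * sigma * sqrt(2 * pi) * exp(mu - sigma^2 / 2)

  st <- data.frame(D = D, t0 = t0, mu = mu, sigma = sigma,
                   theta_s = 0, theta_e = 0)
  if (!is.null(trajectory)) {
    vel <- trajectory_to_velocity(trajectory)
    sup <- lognormal_support(st, 0.05)
    tv <- signal_time(vel)
    ib <- which.min(abs(tv - sup[1]))
    ie <- which.min(abs(tv - sup[2]))
    vb <- vel$samples[ib, c("vx", "vy")]
    ve <- vel$samples[ie, c("vx", "vy")]
    if (sum(vb^2) > 0) st$theta_s <- atan2(vb[2], vb[1])
    if (sum(ve^2) > 0) {
      # unwrap so the arc turn is the short way round (a straight stroke
      # along -x must not read as a full-circle arc)
      dth <- atan2(ve[2], ve[1]) - st$theta_s
      st$theta_e <- st$theta_s + atan2(sin(dth), cos(dth))
    } else st$theta_e <- st$theta_s
  }
  st
}

# coerce a planar position or velocity signal to a velocity signal
trajectory_to_velocity <- function(x) {
  stopifnot(inherits(x, "sampled_signal"))
  if (has_channels(x, c("vx", "vy"))) return(x)
  if (has_channels(x, c("x", "y"))) return(kinematic_speed(x))
  stop("expected planar channels 'vx'/'vy' or 'x'/'y'")
}

# ---- least-squares machinery -------------------------------------------

# residual and analytic Jacobian of the planar (or speed-only) model.
# par is the stacked per-stroke parameter vector.
par_names_planar <- c("D", "t0", "mu", "sigma", "theta_s", "theta_e")
par_names_tied <- c("D", "t0", "mu", "sigma", "theta_s")
par_names_speed <- c("D", "t0", "mu", "sigma")

fit_par_names <- function(planar, tie_angles = FALSE) {
  if (!planar) par_names_speed
  else if (tie_angles) par_names_tied
  else par_names_planar
}

strokes_to_par <- function(strokes, planar, tie_angles = FALSE) {
  nm <- fit_par_names(planar, tie_angles)
  as.numeric(t(as.matrix(strokes[nm])))
}

par_to_strokes <- function(par, template, planar, tie_angles = FALSE) {
  nm <- fit_par_names(planar, tie_angles)
  m <- matrix(par, ncol = length(nm), byrow = TRUE,
              dimnames = list(NULL, nm))
  out <- template
  for (p in nm) out[[p]] <- m[, p]
  if (planar && tie_angles) out$theta_e <- out$theta_s
  out
}

# model values and per-parameter partial derivatives for one stroke
stroke_model_parts <- function(st, t, planar, want_jac) {
  tau <- t - st$t0
  ok <- tau > 0
  n <- length(t)
  zero <- numeric(n)
  out <- list(vx = zero, vy = zero)
  if (want_jac) {
    nm <- if (planar) par_names_planar else par_names_speed
    out$jx <- matrix(0, n, length(nm), dimnames = list(NULL, nm))
    out$jy <- if (planar) out$jx else NULL
  }
  if (!any(ok)) return(out)
  tau <- tau[ok]
  z <- (log(tau) - st$mu) / st$sigma
  lam <- exp(-z^2 / 2) / (tau * st$sigma * sqrt(2 * pi))
  dth <- st$theta_e - st$theta_s
  if (planar && abs(dth) > 0) {
    Phi <- stats::pnorm(z)
    phi_ang <- st$theta_s + dth * Phi
  } else {
    Phi <- stats::pnorm(z)
    phi_ang <- rep(st$theta_s, length(tau))
  }
  cf <- cos(phi_ang)
  sf <- sin(phi_ang)
  v <- st$D * lam
  out$vx[ok] <- v * cf
  out$vy[ok] <- v * sf
  if (!want_jac) return(out)

  dn <- stats::dnorm(z)
  dL_dmu <- lam * z / st$sigma
  dL_dsig <- lam * (z^2 - 1) / st$sigma
  dL_dt0 <- lam * (1 + z / st$sigma) / tau
  dPhi_dmu <- -dn / st$sigma
  dPhi_dsig <- -dn * z / st$sigma
  dPhi_dt0 <- -dn / (st$sigma * tau)

  jx <- out$jx
  jy <- out$jy
  jx[ok, "D"] <- lam * cf
  for (p in c("t0", "mu", "sigma")) {
    dL <- switch(p, t0 = dL_dt0, mu = dL_dmu, sigma = dL_dsig)
    dP <- switch(p, t0 = dPhi_dt0, mu = dPhi_dmu, sigma = dPhi_dsig)
    jx[ok, p] <- st$D * (dL * cf - lam * sf * dth * dP)
  }
  if (planar) {
    jy[ok, "D"] <- lam * sf
    for (p in c("t0", "mu", "sigma")) {
      dL <- switch(p, t0 = dL_dt0, mu = dL_dmu, sigma = dL_dsig)
      dP <- switch(p, t0 = dPhi_dt0, mu = dPhi_dmu, sigma = dPhi_dsig)
      jy[ok, p] <- st$D * (dL * sf + lam * cf * dth * dP)
    }
    jx[ok, "theta_s"] <- -st$D * lam * sf * (1 - Phi)
    jx[ok, "theta_e"] <- -st$D * lam * sf * Phi
    jy[ok, "theta_s"] <- st$D * lam * cf * (1 - Phi)
    jy[ok, "theta_e"] <- st$D * lam * cf * Phi
    out$jy <- jy
  }
  out$jx <- jx
  out
}

#' Jointly refine stroke parameters by bounded least squares
#'
#' Levenberg-Marquardt minimization of the planar velocity residual (or
#' the speed residual when the observation has no planar channels) over
#' all stroke parameters at once, with physiological bounds on `sigma`
#' (0.01-1.5), `mu` and `t0`.  The refined set is returned only if it does
#' not decrease the reconstruction SNR; otherwise the input strokes are
#' kept (monotone acceptance).
#'
#' @param strokes stroke data frame (>= 1 row).
#' @param observation a velocity [sampled_signal()] (`vx`/`vy`, or speed
#'   only).
#' @param config an [extraction_config()].
#' @param tie_angles constrain every stroke to a straight trajectory
#'   (`theta_s == theta_e`) during the fit.
#' @return Refined stroke data frame.
#' @export
refine_strokes <- function(strokes, observation, config = extraction_config(),
                           tie_angles = FALSE) {
  strokes <- as_strokes(strokes)
  if (nrow(strokes) == 0L) return(strokes)
  stopifnot(inherits(observation, "sampled_signal"))
  t <- signal_time(observation)
  planar <- has_channels(observation, c("vx", "vy"))
  if (planar) {
    ox <- observation$samples[, "vx"]
    oy <- observation$samples[, "vy"]
  } else {
    ox <- signal_speed(observation)
  }
  d_max <- 3 * sum(signal_speed(observation)) * observation$dt + 1
  bounds <- stroke_bounds(t[1], t[length(t)], d_max)
  orig <- strokes
  strokes <- clamp_strokes(strokes, bounds)
  if (planar && tie_angles)
    strokes$theta_e <- strokes$theta_s
  nm <- fit_par_names(planar, tie_angles)
  k <- nrow(strokes)
  lower <- rep(bounds$lower[nm], k)
  upper <- rep(bounds$upper[nm], k)

  fn <- function(par) {
    ss <- par_to_strokes(par, strokes, planar, tie_angles)
    mx <- numeric(length(t))
    my <- numeric(length(t))
    for (j in seq_len(k)) {
      p <- stroke_model_parts(ss[j, ], t, planar, want_jac = FALSE)
      mx <- mx + p$vx
      if (planar) my <- my + p$vy
    }
    if (planar) c(ox - mx, oy - my) else ox - mx
  }
  jac <- function(par) {
    ss <- par_to_strokes(par, strokes, planar, tie_angles)
    np <- length(nm)
    if (planar) {
      J <- matrix(0, 2L * length(t), np * k)
      for (j in seq_len(k)) {
        p <- stroke_model_parts(ss[j, ], t, planar, want_jac = TRUE)
        jx <- -p$jx
        jy <- -p$jy
        if (tie_angles) {
          # a single direction parameter moves both arc ends
          jx[, "theta_s"] <- jx[, "theta_s"] + jx[, "theta_e"]
          jy[, "theta_s"] <- jy[, "theta_s"] + jy[, "theta_e"]
        }
        cols <- (j - 1L) * np + seq_len(np)
        J[seq_along(t), cols] <- jx[, nm]
        J[length(t) + seq_along(t), cols] <- jy[, nm]
      }
    } else {
      J <- matrix(0, length(t), np * k)
      for (j in seq_len(k)) {
        p <- stroke_model_parts(ss[j, ], t, planar, want_jac = TRUE)
        J[, (j - 1L) * np + seq_len(np)] <- -p$jx[, nm]
      }
    }
    J
  }

  par0 <- strokes_to_par(strokes, planar, tie_angles)
  # hitting maxiter is routine for the inner fits; not worth a warning
  fit <- tryCatch(
    suppressWarnings(
      minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                         fn = fn, jac = jac,
                         control = minpack.lm::nls.lm.control(
                           maxiter = config$refine_maxiter,
                           ftol = config$refine_tolerance,
                           ptol = config$refine_tolerance))),
    error = function(e) NULL)
  if (is.null(fit)) return(orig)
  refined <- par_to_strokes(fit$par, strokes, planar, tie_angles)
  # monotone acceptance: never decrease the reconstruction SNR
  if (fit_snr(refined, observation) + 1e-12 < fit_snr(orig, observation))
    return(orig)
  refined
}

# one coordinate re-estimation sweep: each stroke in turn is re-estimated
# from scratch against the residual of all the others (where its peak is
# clean and the characteristic-point inversion is reliable), refitted
# alone, and swapped in only when the full reconstruction improves.  This
# lets the decomposition escape joint local minima that the
# Levenberg-Marquardt refinement cannot leave.
reestimate_sweep <- function(strokes, observation, residual_signal, t,
                             floor_abs, planar, config) {
  k <- nrow(strokes)
  if (k < 1L) return(strokes)
  cfg1 <- config
  cfg1$refine_maxiter <- min(config$refine_maxiter, 30L)
  best_snr <- fit_snr(strokes, observation)
  for (j in seq_len(k)) {
    recon_o <- velocity_matrix(strokes[-j, , drop = FALSE], t)
    resid <- residual_signal(recon_o)
    cand <- find_candidates_abs(signal_speed(resid), t, floor_abs)
    if (nrow(cand) == 0L) next
    est <- estimate_stroke_from_peak(resid, cand[which.max(cand$value), ],
                                     trajectory = if (planar) resid)
    if (is.null(est)) next
    est <- refine_strokes(est, resid, cfg1)
    trial <- strokes
    trial[j, ] <- est
    trial_snr <- fit_snr(trial, observation)
    if (trial_snr > best_snr + 1e-9) {
      strokes <- trial
      best_snr <- trial_snr
    }
  }
  strokes
}

# single-stroke fit against a residual window around its peak; the window
# (half-way to the neighbouring candidate peaks) stops the lone stroke from
# broadening over movement that belongs to its neighbours
local_fit <- function(est, resid_sig, lo, hi, config) {
  pad <- 3L
  lo <- max(1L, lo - pad)
  hi <- min(n_samples(resid_sig), hi + pad)
  win <- sampled_signal(resid_sig$samples[lo:hi, , drop = FALSE],
                        dt = resid_sig$dt,
                        t_start = resid_sig$t_start + (lo - 1L) * resid_sig$dt)
  cfg <- config
  cfg$refine_maxiter <- min(config$refine_maxiter, 25L)
  refine_strokes(est, win, cfg)
}

# SNR of a stroke set's reconstruction against an observation
fit_snr <- function(strokes, observation, cap = Inf) {
  recon <- reconstruct_on(strokes, observation)
  snr(observation, recon, cap = cap)
}

# synthesize the stroke model on the observation's grid
reconstruct_on <- function(strokes, observation) {
  t <- signal_time(observation)
  m <- velocity_matrix(strokes, t)
  sampled_signal(cbind(m, speed = sqrt(m[, "vx"]^2 + m[, "vy"]^2)),
                 dt = observation$dt, t_start = observation$t_start)
}

#' Decompose a velocity observation into lognormal strokes
#'
#' Reverse engineering of a kinematic observation.  Strokes are first
#' initialized one per observed speed peak, in time order, from their
#' characteristic points ([estimate_stroke_from_peak()]) with a windowed
#' local fit, then refined jointly by bounded least squares
#' ([refine_strokes()]).  Improvement cycles follow: coordinate
#' re-estimation sweeps, greedy strongest-first additions from the
#' residual (stopping at `snr_target`, when no candidate remains above
#' `peak_floor`, when additions stop paying, or at `max_strokes`),
#' parsimony pruning and tentative splits, and an alternative-basin
#' search (tied-angle refit plus seeded perturbation restarts).  Every
#' step is accepted only if the reconstruction SNR does not decrease, and
#' the whole procedure is deterministic given the configuration seed.
#'
#' @param observation a [sampled_signal()]: planar velocity (`vx`/`vy`),
#'   planar position (`x`/`y`, differentiated internally), or a bare speed
#'   profile (angles then fixed at 0 and only the speed residual is
#'   minimized).
#' @param config an [extraction_config()].
#' @return An object of class `slm_extraction`: list with `strokes`
#'   (time-ordered data frame), `snr` (dB), `reconstruction` and `residual`
#'   [sampled_signal()]s, `converged` flag, and `config`.
#' @examples
#' plan <- action_plan(lognormal_stroke(5, 0.05, -1.6, 0.15))
#' obs <- synthesize_velocity(plan)
#' extract_strokes(obs)$strokes
#' @export
extract_strokes <- function(observation, config = extraction_config()) {
  stopifnot(inherits(observation, "sampled_signal"))
  if (has_channels(observation, c("x", "y")))
    observation <- kinematic_speed(observation)
  if (!all(is.finite(observation$samples)))
    stop("observation contains non-finite values")
  planar <- has_channels(observation, c("vx", "vy"))
  t <- signal_time(observation)
  speed_obs <- signal_speed(observation)
  vmax_global <- max(speed_obs)
  floor_abs <- config$peak_floor * vmax_global

  result_signal <- function(strokes) reconstruct_on(strokes, observation)

  if (vmax_global <= 0) {
    recon <- result_signal(empty_strokes())
    res <- observation
    return(structure(list(strokes = empty_strokes(), snr = Inf,
                          reconstruction = recon, residual = res,
                          converged = TRUE, config = config),
                     class = "slm_extraction"))
  }

  residual_signal <- function(recon_m) {
    if (planar) {
      rx <- observation$samples[, "vx"] - recon_m[, "vx"]
      ry <- observation$samples[, "vy"] - recon_m[, "vy"]
      sampled_signal(cbind(vx = rx, vy = ry, speed = sqrt(rx^2 + ry^2)),
                     dt = observation$dt, t_start = observation$t_start)
    } else {
      rs <- pmax(speed_obs - sqrt(recon_m[, "vx"]^2 + recon_m[, "vy"]^2), 0)
      sampled_signal(rs, dt = observation$dt, t_start = observation$t_start)
    }
  }

  # ---- pass 1: time-ordered estimate-and-subtract initialization -------
  # One stroke per local maximum of the observed speed, estimated in time
  # order on the progressively subtracted residual: each peak's left flank
  # is then clean of already-explained movement.  Refinement is deferred
  # to a joint fit so a single early stroke cannot broaden to swallow its
  # neighbours.  The candidate set is fixed up front (residual ripples do
  # not spawn candidates in this pass).
  strokes <- empty_strokes()
  recon_m <- matrix(0, length(t), 2, dimnames = list(NULL, c("vx", "vy")))
  cand0 <- find_candidates_abs(speed_obs, t, floor_abs)
  if (nrow(cand0) > 0L) {
    half_gap <- diff(c(1L, cand0$index, length(t))) %/% 2L
    for (ci in seq_len(min(nrow(cand0), config$max_strokes))) {
      resid_sig <- residual_signal(recon_m)
      rs <- signal_speed(resid_sig)
      # re-localize the peak in the residual near the original candidate
      lo <- max(2L, cand0$index[ci] - half_gap[ci])
      hi <- min(length(t) - 1L, cand0$index[ci] + half_gap[ci + 1L])
      if (hi < lo) next
      i_loc <- lo - 1L + which.max(rs[lo:hi])
      if (rs[i_loc] < floor_abs) next
      est <- estimate_stroke_from_peak(resid_sig, list(index = i_loc),
                                       trajectory = if (planar) resid_sig)
      if (is.null(est)) next
      est <- local_fit(est, resid_sig, lo, hi, config)
      strokes <- rbind(strokes, est)
      recon_m <- velocity_matrix(strokes, t)
    }
  }
  if (nrow(strokes) > 0L)
    strokes <- refine_strokes(strokes, observation, config)
  best_snr <- if (nrow(strokes) > 0L) fit_snr(strokes, observation) else -Inf

  # ---- improvement cycles ----------------------------------------------
  for (cycle in 1:3) {
  snr_cycle_start <- best_snr

  # coordinate re-estimation sweeps until they stop paying off
  for (sweep in 1:4) {
    if (nrow(strokes) < 2L) break
    swept <- reestimate_sweep(strokes, observation, residual_signal, t,
                              floor_abs, planar, config)
    swept <- refine_strokes(swept, observation, config)
    swept_snr <- fit_snr(swept, observation)
    if (swept_snr > best_snr + 0.01) {
      strokes <- swept
      best_snr <- swept_snr
    } else break
  }
  recon_m <- velocity_matrix(strokes, t)

  # ---- pass 2: greedy additions on the residual, strongest first -------
  repeat {
    if (best_snr >= config$snr_target) break
    if (nrow(strokes) >= config$max_strokes) break
    resid_sig <- residual_signal(recon_m)
    cand <- find_candidates_abs(signal_speed(resid_sig), t, floor_abs)
    if (nrow(cand) == 0L) break
    cand <- cand[order(-cand$value, cand$time), , drop = FALSE]
    added <- FALSE
    for (ci in seq_len(min(nrow(cand), 5L))) {
      est <- estimate_stroke_from_peak(resid_sig, cand[ci, ],
                                       trajectory = if (planar) resid_sig)
      if (is.null(est)) next
      trial <- refine_strokes(rbind(strokes, est), observation, config)
      trial_snr <- fit_snr(trial, observation)
      # require a material gain so residual ripples do not accrete strokes
      if (trial_snr > best_snr + 0.01) {
        strokes <- trial
        best_snr <- trial_snr
        recon_m <- velocity_matrix(strokes, t)
        added <- TRUE
        break
      }
    }
    if (!added) break
  }

  # ---- pass 3: parsimony pruning ---------------------------------------
  # The lognormal superposition is flexible enough that spurious extra
  # strokes can fit the data well; a stroke is dropped whenever the
  # remaining set, refined, reconstructs essentially as well without it
  # (within a small margin -- a real stroke's removal costs far more).
  prune_pass <- function() {
    repeat {
      if (nrow(strokes) <= 1L) break
      dropped <- FALSE
      for (j in utils::head(order(strokes$D), 4L)) {  # weakest first
        trial <- refine_strokes(strokes[-j, , drop = FALSE], observation,
                                config)
        trial_snr <- fit_snr(trial, observation)
        if (trial_snr >= best_snr || trial_snr >= 100 ||
            (trial_snr >= config$snr_target && trial_snr >= best_snr - 2)) {
          strokes <<- trial
          best_snr <<- trial_snr
          dropped <- TRUE
          break
        }
      }
      if (!dropped) break
    }
  }
  prune_pass()

  # split move: an unexplained movement hiding under a fitted stroke is
  # searched for by replacing the widest strokes with an offset pair
  if (nrow(strokes) < config$max_strokes && best_snr < 200) {
    for (j in utils::head(order(-strokes$sigma * strokes$D), 2L)) {
      st <- strokes[j, ]
      delta <- max(0.03, 0.25 * exp(st$mu - st$sigma^2))
      pair <- rbind(st, st)
      pair$D <- st$D / 2
      pair$sigma <- max(st$sigma * 0.7, 0.02)
      pk <- st$t0 + exp(st$mu - st$sigma^2)
      pair$t0 <- pk + c(-delta, delta) - exp(pair$mu - pair$sigma^2)
      trial <- refine_strokes(rbind(strokes[-j, , drop = FALSE], pair),
                              observation, config)
      trial_snr <- fit_snr(trial, observation)
      if (trial_snr > best_snr + 0.5) {
        strokes <- trial
        best_snr <- trial_snr
        break
      }
    }
  }

  # ---- pass 4: alternative-basin search --------------------------------
  # The superposition admits near-equivalent decompositions (notably
  # arc-curved pairs standing in for straight strokes); a tied-angle
  # (straight-stroke) hypothesis and a few seeded perturbation restarts
  # are tried, each adopted only when the reconstruction improves.
  if (nrow(strokes) >= 1L && best_snr < 200) {
    if (planar) {
      st0 <- strokes
      st0$theta_s <- (strokes$theta_s + strokes$theta_e) / 2
      st0$theta_e <- st0$theta_s
      tied <- refine_strokes(st0, observation, config, tie_angles = TRUE)
      tied_snr <- fit_snr(tied, observation)
      if (tied_snr > best_snr + 1e-9) {
        strokes <- tied
        best_snr <- tied_snr
      }
    }
    restart <- local({
      old <- get0(".Random.seed", envir = globalenv())
      on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                        envir = globalenv()))
      set.seed(config$seed)
      for (r in 1:4) {
        if (best_snr >= 200) break
        pert <- strokes
        pk <- pert$t0 + exp(pert$mu - pert$sigma^2)
        pert$mu <- pert$mu * stats::runif(nrow(pert), 0.85, 1.15)
        pert$sigma <- pmin(pmax(pert$sigma *
                                  stats::runif(nrow(pert), 0.75, 1.25),
                                0.02), 1.2)
        pert$t0 <- pk - exp(pert$mu - pert$sigma^2)
        tie <- planar && (r %% 2 == 0)
        if (tie) {
          pert$theta_s <- (pert$theta_s + pert$theta_e) / 2
          pert$theta_e <- pert$theta_s
        }
        ref <- refine_strokes(pert, observation, config, tie_angles = tie)
        rsnr <- fit_snr(ref, observation)
        if (rsnr > best_snr + 1e-9) {
          strokes <<- ref
          best_snr <<- rsnr
        }
      }
      invisible(NULL)
    })
  }

  if (best_snr >= 200 || best_snr <= snr_cycle_start + 0.1) break
  }  # end improvement cycles

  # a late basin jump can leave a redundant stroke behind
  prune_pass()

  if (nrow(strokes) > 1L) {
    strokes <- strokes[order(strokes$t0), , drop = FALSE]
    rownames(strokes) <- NULL
  }
  recon <- result_signal(strokes)
  resid_m <- cbind(vx = (if (planar) observation$samples[, "vx"] else
                           speed_obs) - recon$samples[, "vx"],
                   vy = (if (planar) observation$samples[, "vy"] else 0) -
                     recon$samples[, "vy"])
  residual <- sampled_signal(cbind(resid_m,
                                   speed = sqrt(resid_m[, 1]^2 +
                                                resid_m[, 2]^2)),
                             dt = observation$dt,
                             t_start = observation$t_start)
  final_snr <- snr(observation, recon, cap = Inf)
  structure(list(strokes = strokes, snr = final_snr,
                 reconstruction = recon, residual = residual,
                 converged = is.finite(final_snr) &&
                   final_snr >= config$snr_accept,
                 config = config),
            class = "slm_extraction")
}

#' @export
print.slm_extraction <- function(x, ...) {
  cat(sprintf("<slm_extraction> NbLog = %d, SNR = %.2f dB, converged = %s\n",
              nrow(x$strokes), x$snr, x$converged))
  invisible(x)
}
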