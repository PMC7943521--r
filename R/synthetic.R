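#' Hexagonal sound map
#'
#' A lattice of candidate sound targets in kinematic space, bounded by the
#' vowel triangle: /u/ at the origin, /i/ at `(L2, 0)` and /a/ at the apex,
#' an equilateral triangle of side `L2` filled with a triangular
#' (hexagonally packed) grid of sites.
#'
#' @param L2 side of the vowel triangle (the /i/-/u/ distance), mm.
#' @param spacing lattice spacing, mm; default `L2/4` (several sites per
#'   triangle edge).
#' @return A list of class `sound_map` with `sites` (data frame
#'   `label, x, y`), `spacing` and `L2`.
#' @export
sound_map <- function(L2 = 16, spacing = L2 / 4) {
  stopifnot(L2 > 0, spacing > 0, spacing <= L2)
  m <- round(L2 / spacing)
  pts <- list()
  for (a in 0:m) for (b in 0:(m - a)) {
    pts[[length(pts) + 1L]] <- c(a, b)
  }
  pts <- do.call(rbind, pts)
  x <- spacing * (pts[, 1] + pts[, 2] / 2)
  y <- spacing * pts[, 2] * sqrt(3) / 2
  sites <- data.frame(label = sprintf("s%02d", seq_along(x)), x = x, y = y)
  structure(list(sites = sites, spacing = spacing, L2 = L2),
            class = "sound_map")
}

#' @export
print.sound_map <- function(x, ...) {
  cat(sprintf("<sound_map> %d sites, spacing %g mm, triangle side %g mm\n",
              nrow(x$sites), x$spacing, x$L2))
  invisible(x)
}

#' Synthetic-data configuration
#'
#' Study conditions for the synthetic generator: stroke count, command
#' timing gaps, lognormal shape ranges, measurement noise and unvoiced
#' masking.
#'
#' @param n_strokes number of strokes (grid hops).
#' @param dt0_range range (s) of the uniform draw for successive command
#'   gaps; default 0.06-0.12 s (gaps of at least 60 ms).
#' @param mu_range,sigma_range uniform ranges for the lognormal log delay
#'   and log response time; defaults match observed continuous-speech
#'   magnitudes (`mu` in -1.9..-1.2, `sigma` in 0.05..0.3).
#' @param noise_snr additive white Gaussian noise level on the formant
#'   tracks, dB; `Inf` (default) for noiseless.
#' @param gap_fraction fraction of interior samples masked as unvoiced, in
#'   `[0, 0.5)`.
#' @param seed integer seed; the generator is deterministic given the seed.
#' @param first_onset command time of the first stroke, s.
#' @param f1_offset,f2_offset offsets (Hz) placing synthetic tracks in a
#'   plausible formant band.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_strokes = 5L, dt0_range = c(0.06, 0.12),
                         mu_range = c(-1.9, -1.2),
                         sigma_range = c(0.05, 0.3),
                         noise_snr = Inf, gap_fraction = 0, seed = 1L,
                         first_onset = 0.05,
                         f1_offset = 350, f2_offset = 900) {
  stopifnot(n_strokes >= 1L, length(dt0_range) == 2L,
            dt0_range[1] <= dt0_range[2], dt0_range[1] > 0,
            length(mu_range) == 2L, mu_range[1] <= mu_range[2],
            length(sigma_range) == 2L, sigma_range[1] <= sigma_range[2],
            sigma_range[1] > 0)
  if (gap_fraction < 0 || gap_fraction >= 0.5)
    stop("gap_fraction must be in [0, 0.5)")
  structure(list(n_strokes = as.integer(n_strokes), dt0_range = dt0_range,
                 mu_range = mu_range, sigma_range = sigma_range,
                 noise_snr = noise_snr, gap_fraction = gap_fraction,
                 seed = as.integer(seed), first_onset = first_onset,
                 f1_offset = f1_offset, f2_offset = f2_offset),
            class = "synth_config")
}

# adjacency of lattice sites: pairs within 1.01 * spacing
map_neighbors <- function(map) {
  s <- map$sites
  d <- as.matrix(stats::dist(s[, c("x", "y")]))
  lapply(seq_len(nrow(s)), function(i)
    which(d[i, ] > 0 & d[i, ] <= map$spacing * 1.01))
}

#' Sample a random action plan on a sound map
#'
#' Random walk over adjacent lattice sites: each hop becomes one straight
#' stroke whose extent is the hop distance and whose direction follows the
#' hop geometry; command times accumulate gaps drawn uniformly from
#' `dt0_range`, and `mu`, `sigma` are drawn uniformly from their configured
#' ranges.  Deterministic under a fixed seed.
#'
#' @param map a [sound_map()].
#' @param config a [synth_config()].
#' @return An [action_plan()] whose initial virtual target is the walk's
#'   starting site.  The visited site indices are attached as attribute
#'   `sites`.
#' @export
sample_action_plan <- function(map = sound_map(), config = synth_config()) {
  stopifnot(inherits(map, "sound_map"), inherits(config, "synth_config"))
  nb <- map_neighbors(map)
  if (all(lengths(nb) == 0L))
    stop("sound map has no adjacent sites; reduce spacing")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)
  n <- config$n_strokes
  path <- integer(n + 1L)
  path[1] <- sample.int(nrow(map$sites), 1L)
  for (j in seq_len(n)) {
    opts <- nb[[path[j]]]
    if (length(opts) == 0L) stop("random walk reached an isolated site")
    # avoid immediately backtracking when an alternative exists
    if (j > 1L && length(opts) > 1L) opts <- setdiff(opts, path[j - 1L])
    path[j + 1L] <- opts[sample.int(length(opts), 1L)]
  }
  xy <- as.matrix(map$sites[, c("x", "y")])
  hops <- xy[path[-1], , drop = FALSE] - xy[path[-(n + 1L)], , drop = FALSE]
  t0 <- config$first_onset +
    cumsum(c(0, stats::runif(n - 1L, config$dt0_range[1], config$dt0_range[2])))
  ang <- atan2(hops[, 2], hops[, 1])
  strokes <- data.frame(D = sqrt(rowSums(hops^2)), t0 = t0,
                        mu = stats::runif(n, config$mu_range[1], config$mu_range[2]),
                        sigma = stats::runif(n, config$sigma_range[1],
                                             config$sigma_range[2]),
                        theta_s = ang, theta_e = ang)
  plan <- action_plan(strokes, vtp0 = xy[path[1], ])
  attr(plan, "sites") <- path
  plan
}

#' Synthesize a formant track and segmentation from an action plan
#'
#' Inverse of the acoustic-to-kinematic map: the plan's trajectory is
#' converted to formants via `F1 = y/c1 + F1_offset`, `F2 = x/c2 +
#' F2_offset`, optionally corrupted with additive white Gaussian noise at
#' `noise_snr` dB and masked with an unvoiced gap.  A segmentation with one
#' labeled interval per stroke is built with interior boundaries at the
#' stroke velocity peaks (movement peaks accompany sound transitions).
#'
#' @param plan an [action_plan()].
#' @param params a [kinematic_map_params()] with `c1, c2 > 0`.
#' @param config a [synth_config()] (noise, gaps, offsets, seed).
#' @param dt sampling step, s.
#' @return A list with `track` ([formant_track()]), `segmentation`
#'   ([phoneme_segmentation()]) and `plan`.
#' @export
plan_to_formant_track <- function(plan, params = kinematic_map_params(),
                                  config = synth_config(), dt = 0.01) {
  stopifnot(inherits(plan, "action_plan"), inherits(params, "kinematic_map"))
  if (params$c1 <= 0 || params$c2 <= 0) stop("c1 and c2 must be positive")
  traj <- synthesize_trajectory(plan, dt = dt)
  t <- signal_time(traj)
  f1 <- traj$samples[, "y"] / params$c1 + config$f1_offset
  f2 <- traj$samples[, "x"] / params$c2 + config$f2_offset
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed + 1L)
  if (is.finite(config$noise_snr)) {
    for (nm in c("f1", "f2")) {
      v <- get(nm)
      sd_sig <- stats::sd(v)
      assign(nm, v + stats::rnorm(length(v),
                                  sd = sd_sig * 10^(-config$noise_snr / 20)))
    }
  }
  if (any(f1 <= 0) || any(f2 <= 0))
    stop("synthesized formants are nonpositive; increase the offsets")
  voiced <- rep(TRUE, length(t))
  if (config$gap_fraction > 0) {
    glen <- max(1L, round(config$gap_fraction * length(t)))
    lo <- 2L
    hi <- length(t) - glen - 1L
    if (hi >= lo) {
      start <- sample(lo:hi, 1L)
      voiced[start:(start + glen - 1L)] <- FALSE
    }
  }
  f1[!voiced] <- NA_real_
  f2[!voiced] <- NA_real_
  track <- formant_track(t, f1, f2, voiced = voiced)

  strokes <- plan$strokes
  sup <- strokes_support(strokes, 0.05)
  peaks <- stroke_peak_time(strokes)
  n <- nrow(strokes)
  bounds <- c(sup[1, "t_begin"],
              if (n > 1L) peaks[-1] else NULL,
              max(sup[, "t_end"]))
  # command times are ordered but peak times need not be; keep boundaries
  # strictly increasing
  for (i in seq_along(bounds)[-1])
    bounds[i] <- max(bounds[i], bounds[i - 1L] + 1e-6)
  seg <- phoneme_segmentation(sprintf("s%02d", seq_len(n)),
                              bounds[-length(bounds)], bounds[-1])
  list(track = track, segmentation = seg, plan = plan)
}

#' Parameter-recovery benchmark on synthetic action plans
#'
#' Generates seeded random plans (3-8 straight strokes by default, command
#' gaps of at least 60 ms), synthesizes each plan's noiseless planar
#' velocity, runs [extract_strokes()], and scores the recovery: the
#' reconstruction SNR, the recovered stroke count, and per-parameter
#' relative errors on `D`, `mu`, `sigma` for strokes matched to the truth
#' by command time.
#'
#' @param n_plans number of random plans.
#' @param seed master seed; plan `i` uses `seed * 1000 + i`.
#' @param n_strokes_range inclusive range of stroke counts.
#' @param config_args named list of [synth_config()] overrides.
#' @param extraction an [extraction_config()].
#' @param dt sampling step of the synthesized observation, s.
#' @return A list with `plans` (data frame: `seed, nblog_true, nblog_est,
#'   snr`) and `errors` (data frame of pooled matched-stroke relative
#'   errors `rel_D, rel_mu, rel_sigma`), plus summary fields
#'   `snr15_rate`, `nblog_within1_rate`, `median_rel_D`, `median_rel_mu`,
#'   `median_rel_sigma`.
#' @export
recovery_benchmark <- function(n_plans = 100L, seed = 1L,
                               n_strokes_range = c(3L, 8L),
                               config_args = list(),
                               extraction = extraction_config(
                                 snr_target = 60, refine_maxiter = 80,
                                 max_strokes = 16, peak_floor = 0.002),
                               dt = 0.01) {
  rows <- vector("list", n_plans)
  errs <- vector("list", n_plans)
  map <- sound_map()
  for (i in seq_len(n_plans)) {
    si <- (seed %% 1000000L) * 1000L + i
    nstk <- n_strokes_range[1] +
      (si %% (n_strokes_range[2] - n_strokes_range[1] + 1L))
    cfg <- do.call(synth_config,
                   c(list(n_strokes = nstk, seed = si), config_args))
    plan <- sample_action_plan(map, cfg)
    obs <- synthesize_velocity(plan, dt = dt)
    fit <- extract_strokes(obs, extraction)
    truth <- plan$strokes
    est <- fit$strokes
    rows[[i]] <- data.frame(seed = si, nblog_true = nrow(truth),
                            nblog_est = nrow(est), snr = fit$snr)
    errs[[i]] <- match_stroke_errors(truth, est)
  }
  plans <- do.call(rbind, rows)
  errors <- do.call(rbind, errs)
  list(plans = plans, errors = errors,
       snr15_rate = mean(plans$snr >= 15),
       nblog_within1_rate = mean(abs(plans$nblog_est - plans$nblog_true) <= 1),
       median_rel_D = stats::median(errors$rel_D),
       median_rel_mu = stats::median(errors$rel_mu),
       median_rel_sigma = stats::median(errors$rel_sigma))
}

# pair true and estimated strokes greedily by nearest command time and
# return relative parameter errors for the pairs
match_stroke_errors <- function(truth, est) {
  if (nrow(truth) == 0L || nrow(est) == 0L)
    return(data.frame(rel_D = numeric(0), rel_mu = numeric(0),
                      rel_sigma = numeric(0)))
  avail <- rep(TRUE, nrow(est))
  out <- vector("list", nrow(truth))
  for (j in order(truth$t0)) {
    if (!any(avail)) break
    cand <- which(avail)
    k <- cand[which.min(abs(est$t0[cand] - truth$t0[j]))]
    avail[k] <- FALSE
    out[[j]] <- data.frame(rel_D = abs(est$D[k] - truth$D[j]) / abs(truth$D[j]),
                           rel_mu = abs(est$mu[k] - truth$mu[j]) / abs(truth$mu[j]),
                           rel_sigma = abs(est$sigma[k] - truth$sigma[j]) /
                             abs(truth$sigma[j]))
  }
  do.call(rbind, out)
}
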