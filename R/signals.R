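#' Uniformly sampled signal
#'
#' Container for a uniformly sampled one- or two-channel kinematic signal:
#' a speed profile (channel `speed`, mm/s), a planar velocity (channels
#' `vx`, `vy` and derived `speed`, mm/s) or a planar position (channels
#' `x`, `y`, mm).
#'
#' @param samples numeric vector, matrix or data frame of channel samples;
#'   columns must be named.  A bare vector is taken as a `speed` channel.
#' @param dt sampling step in seconds (> 0).
#' @param t_start time of the first sample in seconds.
#' @return An object of class `sampled_signal`: a list with elements
#'   `t_start`, `dt` and the numeric sample matrix `samples`.
#' @examples
#' sampled_signal(cbind(vx = rnorm(10), vy = rnorm(10)), dt = 0.01)
#' @export
sampled_signal <- function(samples, dt, t_start = 0) {
  if (is.null(dim(samples))) {
    samples <- matrix(as.numeric(samples), ncol = 1,
                      dimnames = list(NULL, "speed"))
  } else {
    samples <- as.matrix(samples)
    storage.mode(samples) <- "double"
  }
  if (is.null(colnames(samples)) || anyNA(colnames(samples)))
    stop("signal channels must be named")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("dt must be a single positive number")
  structure(list(t_start = as.numeric(t_start), dt = as.numeric(dt),
                 samples = samples),
            class = "sampled_signal")
}

#' Time axis of a sampled signal
#'
#' @param x a [sampled_signal()].
#' @return Numeric vector of sample times in seconds.
#' @export
signal_time <- function(x) {
  stopifnot(inherits(x, "sampled_signal"))
  x$t_start + (seq_len(nrow(x$samples)) - 1L) * x$dt
}

#' @export
print.sampled_signal <- function(x, ...) {
  n <- nrow(x$samples)
  cat(sprintf("<sampled_signal> %d samples x %d channel(s) [%s], dt = %g s, t in [%g, %g] s\n",
              n, ncol(x$samples), paste(colnames(x$samples), collapse = ", "),
              x$dt, x$t_start, x$t_start + (n - 1L) * x$dt))
  invisible(x)
}

#' @export
as.data.frame.sampled_signal <- function(x, ...) {
  data.frame(t = signal_time(x), x$samples)
}

n_samples <- function(x) nrow(x$samples)

has_channels <- function(x, chans) all(chans %in% colnames(x$samples))

#' Speed channel of a signal
#'
#' Returns the `speed` channel if present, otherwise the Euclidean norm of
#' the planar `vx`/`vy` velocity channels.
#'
#' @param x a [sampled_signal()].
#' @return Numeric vector of speeds, mm/s.
#' @export
signal_speed <- function(x) {
  stopifnot(inherits(x, "sampled_signal"))
  if (has_channels(x, "speed")) return(x$samples[, "speed"])
  if (has_channels(x, c("vx", "vy")))
    return(sqrt(x$samples[, "vx"]^2 + x$samples[, "vy"]^2))
  stop("signal has neither a 'speed' nor planar 'vx'/'vy' channels")
}

# TRUE when the two signals share t_start, dt and length (tol on the grid)
same_timebase <- function(a, b, tol = 1e-9) {
  n_samples(a) == n_samples(b) &&
    abs(a$dt - b$dt) <= tol * max(a$dt, b$dt) &&
    abs(a$t_start - b$t_start) <= tol + tol * abs(a$t_start)
}

#' Reconstruction signal-to-noise ratio
#'
#' Quality of a velocity reconstruction in decibels:
#' `20 * log10(sum(v_o^2) / sum(|v_o - v_r|^2))`, both energies taken as
#' discrete sums on the common sampling grid (the sampling step cancels).
#' When both signals carry planar components the residual is the Euclidean
#' norm of the component-wise difference; otherwise speed channels are
#' compared.  Reconstructions with SNR below about 15 dB are conventionally
#' regarded as inadequate.
#'
#' @param v_o observed velocity, a [sampled_signal()].
#' @param v_r reconstructed velocity on the same time base.
#' @param cap value returned when the residual energy is exactly zero, and
#'   an upper bound on the returned SNR; default `Inf` (uncapped).
#' @return SNR in dB.
#' @examples
#' s <- sampled_signal(sin(seq(0, pi, length.out = 100))^2, dt = 0.01)
#' h <- sampled_signal(0.5 * s$samples[, 1], dt = 0.01)
#' snr(s, h)  # 20*log10(4) ~= 12.04 dB
#' @export
snr <- function(v_o, v_r, cap = Inf) {
  stopifnot(inherits(v_o, "sampled_signal"), inherits(v_r, "sampled_signal"))
  if (!same_timebase(v_o, v_r))
    stop("snr: signals are not on a common time base")
  planar <- has_channels(v_o, c("vx", "vy")) && has_channels(v_r, c("vx", "vy"))
  if (planar) {
    num <- sum(v_o$samples[, "vx"]^2 + v_o$samples[, "vy"]^2)
    den <- sum((v_o$samples[, "vx"] - v_r$samples[, "vx"])^2 +
               (v_o$samples[, "vy"] - v_r$samples[, "vy"])^2)
  } else {
    so <- signal_speed(v_o)
    sr <- signal_speed(v_r)
    num <- sum(so^2)
    den <- sum((so - sr)^2)
  }
  if (den == 0) return(cap)
  min(cap, 20 * log10(num / den))
}
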