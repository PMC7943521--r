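#' Phoneme segmentation
#'
#' Ordered, non-overlapping labeled time intervals.  Intervals are treated
#' as half-open `[t_start, t_end)`.
#'
#' @param label character labels.
#' @param t_start,t_end interval bounds, s, with `t_start < t_end`.
#' @return A data frame of class `phoneme_segmentation` with columns
#'   `label, t_start, t_end`, time-ordered.
#' @export
phoneme_segmentation <- function(label, t_start, t_end) {
  stopifnot(length(label) == length(t_start), length(label) == length(t_end))
  if (length(label) == 0L) stop("segmentation is empty")
  seg <- data.frame(label = as.character(label),
                    t_start = as.numeric(t_start),
                    t_end = as.numeric(t_end))
  if (any(seg$t_start >= seg$t_end))
    stop("segmentation intervals must have t_start < t_end")
  seg <- seg[order(seg$t_start), , drop = FALSE]
  if (nrow(seg) > 1L &&
      any(seg$t_start[-1] < seg$t_end[-nrow(seg)] - 1e-9))
    stop("segmentation intervals overlap")
  rownames(seg) <- NULL
  structure(seg, class = c("phoneme_segmentation", "data.frame"))
}

#' Derived neuromotor parameters of a stroke decomposition
#'
#' Summary parameters describing the timing and shape of the lognormal
#' sequence: the mean inter-command time `mean_dt0`, the mean peak speed
#' `mean_vp`, and the means of `mu`, `sigma` and `D`, plus the stroke count
#' `nblog` and the reconstruction `snr`.
#'
#' By default the printed formula conventions are followed literally: the
#' sums for `mean_dt0` and `mean_vp` start at the second stroke but are
#' divided by `nblog` (not `nblog - 1`).  Setting `conventional_means =
#' TRUE` switches to ordinary means (`nblog - 1` successive differences;
#' peak speeds of all strokes).
#'
#' @param strokes stroke data frame (time-ordered by `t0`).
#' @param snr reconstruction SNR, dB (carried through).
#' @param conventional_means use ordinary-mean denominators instead of the
#'   literal printed ones.
#' @return A list of class `derived_params` with fields `mean_dt0` (s),
#'   `mean_vp` (mm/s), `mean_mu`, `mean_sigma`, `mean_D` (mm), `nblog`,
#'   `snr` (dB), `conventional_means`, and a character vector `flags`.
#' @examples
#' s <- do.call(rbind, lapply(c(0, 0.1, 0.2), function(t0)
#'   lognormal_stroke(1, t0, -1.6, 0.15)))
#' derived_parameters(s)$mean_dt0  # 0.2/3
#' @export
derived_parameters <- function(strokes, snr = NA_real_,
                               conventional_means = FALSE) {
  strokes <- as_strokes(strokes)
  n <- nrow(strokes)
  flags <- character(0)
  if (n == 0L) {
    out <- list(mean_dt0 = NA_real_, mean_vp = NA_real_, mean_mu = NA_real_,
                mean_sigma = NA_real_, mean_D = NA_real_, nblog = 0L,
                snr = snr, conventional_means = conventional_means,
                flags = "empty")
    return(structure(out, class = "derived_params"))
  }
  strokes <- strokes[order(strokes$t0), , drop = FALSE]
  vp <- stroke_peak_speed(strokes)
  if (n == 1L) {
    dt0_sum <- 0
    vp_sum <- 0
    flags <- c(flags, "single-stroke: mean_dt0 and mean_vp are empty sums")
  } else {
    dt0_sum <- sum(diff(strokes$t0))
    vp_sum <- sum(vp[-1])
  }
  if (conventional_means) {
    mean_dt0 <- if (n > 1L) dt0_sum / (n - 1L) else NA_real_
    mean_vp <- mean(vp)
  } else {
    mean_dt0 <- dt0_sum / n
    mean_vp <- vp_sum / n
  }
  out <- list(mean_dt0 = mean_dt0, mean_vp = mean_vp,
              mean_mu = mean(strokes$mu), mean_sigma = mean(strokes$sigma),
              mean_D = mean(abs(strokes$D)), nblog = n, snr = snr,
              conventional_means = conventional_means, flags = flags)
  structure(out, class = "derived_params")
}

#' @export
print.derived_params <- function(x, ...) {
  cat(sprintf(paste0("<derived_params> NbLog = %d, SNR = %.4g dB\n",
                     "  mean_dt0 = %.4g s, mean_vp = %.4g mm/s, mean_mu = %.4g,",
                     " mean_sigma = %.4g, mean_D = %.4g mm\n"),
              x$nblog, x$snr, x$mean_dt0, x$mean_vp, x$mean_mu,
              x$mean_sigma, x$mean_D))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Match lognormal strokes to phoneme intervals
#'
#' For each phoneme interval, a stroke "overlaps" it when the stroke's
#' temporal support at `level` (default 5%) of its peak intersects the
#' interval.  Per phoneme `i`: `TP_i = 1` when at least one stroke overlaps
#' (the assigned stroke being the overlapping one whose peak time is
#' nearest the phoneme midpoint); `FP_i` is the number of overlapping
#' strokes minus one; `FN_i = 1` only when no stroke overlaps; `TN_i` is
#' the number of non-overlapping strokes.  Thus `TP_i + FP_i + TN_i`
#' always equals the stroke count.  Rates: `TPR = sum(TP)/N_p` and
#' `TNR = sum(TN)/(NbLog - 1)` (literal denominator, which can exceed 1;
#' flagged rather than clipped; `NaN` when `NbLog == 1`).
#'
#' The report also carries the root-mean-square timing error between
#' phoneme transitions (interior interval boundaries) and the nearest
#' stroke peak times ([timing_error()]).
#'
#' @param strokes stroke data frame (`NbLog >= 1`).
#' @param seg a [phoneme_segmentation()].
#' @param level support level as a fraction of each stroke's peak.
#' @return A list of class `match_report`: per-phoneme data frame `table`
#'   (`label, tp, fp, fn, tn, assigned`), `tpr`, `tnr`, `eps_t` (s),
#'   `nblog`, `np`, and `flags`.
#' @export
match_phonemes <- function(strokes, seg, level = 0.05) {
  strokes <- as_strokes(strokes)
  stopifnot(inherits(seg, "phoneme_segmentation"))
  n <- nrow(strokes)
  np <- nrow(seg)
  if (n < 1L) stop("need at least one stroke")
  sup <- strokes_support(strokes, level)
  peaks <- stroke_peak_time(strokes)
  tp <- fp <- fn <- tn <- integer(np)
  assigned <- integer(np)
  for (i in seq_len(np)) {
    # half-open phoneme interval vs open stroke support
    ov <- sup[, "t_begin"] < seg$t_end[i] & sup[, "t_end"] > seg$t_start[i]
    k <- sum(ov)
    if (k > 0L) {
      tp[i] <- 1L
      fp[i] <- k - 1L
      mid <- (seg$t_start[i] + seg$t_end[i]) / 2
      cand <- which(ov)
      assigned[i] <- cand[which.min(abs(peaks[cand] - mid))]
    } else {
      fn[i] <- 1L
      assigned[i] <- NA_integer_
    }
    tn[i] <- n - k
  }
  tpr <- sum(tp) / np
  flags <- character(0)
  if (n == 1L) {
    tnr <- NaN
    flags <- c(flags, "NbLog = 1: TNR undefined")
  } else {
    # literal printed formula: sum over phonemes, denominator NbLog - 1
    tnr <- sum(tn) / (n - 1L)
  }
  if (is.finite(tnr) && tnr > 1) flags <- c(flags, "TNR > 1 (literal denominator)")
  eps_t <- if (np >= 2L) {
    timing_error(peaks, seg$t_end[-np])
  } else NA_real_
  structure(list(table = data.frame(label = seg$label, tp = tp, fp = fp,
                                    fn = fn, tn = tn, assigned = assigned),
                 tpr = tpr, tnr = tnr, eps_t = eps_t,
                 nblog = n, np = np, level = level, flags = flags),
            class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("<match_report> N_p = %d, NbLog = %d, TPR = %.3f, TNR = %.3f, eps_t = %.4g s\n",
              x$np, x$nblog, x$tpr, x$tnr, x$eps_t))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' RMS timing error between velocity peaks and phoneme transitions
#'
#' Each phoneme transition time is paired with the nearest stroke velocity
#' peak; the error is the root mean square of the paired differences:
#' `sqrt(mean((t_v - t_p)^2))` over the transitions.
#'
#' @param peak_times stroke velocity-peak times, s (non-empty).
#' @param transitions phoneme transition times, s (non-empty).
#' @return RMS timing error, s.
#' @examples
#' timing_error(c(0.13, 0.24), c(0.1, 0.2))  # sqrt((0.03^2 + 0.04^2)/2)
#' @export
timing_error <- function(peak_times, transitions) {
  if (length(transitions) == 0L) stop("no phoneme transitions")
  if (length(peak_times) == 0L) stop("no velocity peaks")
  d <- vapply(transitions,
              function(tp) peak_times[which.min(abs(peak_times - tp))] - tp,
              numeric(1))
  sqrt(mean(d^2))
}

#' Compare a derived parameter across labeled groups
#'
#' One-way analysis of variance across the groups, followed (for more than
#' two groups) by pairwise comparisons with Bonferroni correction.  Groups
#' are judged statistically different at the 0.05 threshold.
#'
#' @param values numeric parameter samples.
#' @param groups group labels (same length as `values`), or `values` may be
#'   a two-column data frame `(group, value)`.
#' @param alpha significance threshold reported alongside (default 0.05).
#' @return A list of class `group_comparison` with `f`, `p_value` (overall
#'   ANOVA), `pairwise` (data frame `group1, group2, p_adj, significant`),
#'   `alpha`, and group sizes `n`.
#' @export
group_compare <- function(values, groups = NULL, alpha = 0.05) {
  if (is.data.frame(values)) {
    stopifnot(ncol(values) >= 2L)
    groups <- values[[1]]
    values <- values[[2]]
  }
  stopifnot(length(values) == length(groups))
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need at least two groups")
  sizes <- table(g)
  if (any(sizes < 2L)) stop("each group needs at least two samples")
  if (stats::sd(values) == 0) stop("degenerate input: zero overall variance")
  fit <- stats::aov(values ~ g)
  an <- summary(fit)[[1]]
  fval <- an[["F value"]][1]
  pval <- an[["Pr(>F)"]][1]
  pw <- NULL
  lv <- levels(g)
  if (nlevels(g) >= 2L) {
    pt <- stats::pairwise.t.test(values, g, p.adjust.method = "bonferroni")
    m <- pt$p.value
    rows <- list()
    for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
      if (!is.na(m[i, j]))
        rows[[length(rows) + 1L]] <- data.frame(group1 = colnames(m)[j],
                                                group2 = rownames(m)[i],
                                                p_adj = m[i, j])
    }
    pw <- do.call(rbind, rows)
    pw$significant <- pw$p_adj < alpha
  }
  structure(list(f = fval, p_value = pval, pairwise = pw, alpha = alpha,
                 n = as.integer(sizes)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> F = %.4g, p = %.4g (threshold %.3g)\n",
              x$f, x$p_value, x$alpha))
  if (!is.null(x$pairwise)) print(x$pairwise)
  invisible(x)
}
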