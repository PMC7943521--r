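test_that("derived parameters follow the printed formulas literally", {
  s <- do.call(rbind, lapply(c(0, 0.1, 0.2), function(t0)
    lognormal_stroke(1, t0, -1.6, 0.15)))
  d <- derived_parameters(s, snr = 20)
  expect_equal(d$mean_dt0, 0.2 / 3, tolerance = 1e-12)
  expect_equal(d$mean_mu, -1.6)
  expect_equal(d$mean_sigma, 0.15)
  expect_equal(d$mean_D, 1)
  expect_identical(d$nblog, 3L)
  expect_identical(d$snr, 20)

  # literal peak-speed mean: sum from the second stroke over NbLog
  vps <- c(10, 20, 30)
  s2 <- s
  # choose D so that each stroke's peak speed is exactly vps[j]
  s2$D <- vps / (exp(s$sigma^2 / 2 - s$mu) / (s$sigma * sqrt(2 * pi)))
  d2 <- derived_parameters(s2)
  expect_equal(d2$mean_vp, (20 + 30) / 3, tolerance = 1e-9)

  # conventional means use the ordinary denominators
  dc <- derived_parameters(s2, conventional_means = TRUE)
  expect_equal(dc$mean_dt0, 0.1, tolerance = 1e-12)
  expect_equal(dc$mean_vp, 20, tolerance = 1e-9)
  # algebraic identity between the two conventions
  expect_equal(dc$mean_dt0, d2$mean_dt0 * 3 / (3 - 1), tolerance = 1e-12)

  # degenerate sizes
  d0 <- derived_parameters(NULL)
  expect_identical(d0$nblog, 0L)
  d1 <- derived_parameters(s[1, ])
  expect_identical(d1$nblog, 1L)
  expect_equal(d1$mean_dt0, 0)
  expect_equal(d1$mean_vp, 0)
  expect_match(paste(d1$flags, collapse = " "), "single")
})

test_that("the 5%-of-peak support brackets the mode and shifts with t0", {
  st <- std_stroke()
  sup <- lognormal_support(st, 0.05)
  pk <- stroke_peak_time(st)
  expect_lt(st$t0, sup[1]); expect_lt(sup[1], pk); expect_lt(pk, sup[2])
  # defining property: the speed at both bounds is exactly 5% of the peak
  expect_equal(lognormal_speed(sup, st) / stroke_peak_speed(st), c(0.05, 0.05),
               tolerance = 1e-9)
  # time-shift equivariance and amplitude independence
  st2 <- std_stroke(t0 = st$t0 + 0.37)
  expect_equal(lognormal_support(st2, 0.05), sup + 0.37, tolerance = 1e-12)
  st3 <- std_stroke(D = 40)
  expect_equal(lognormal_support(st3, 0.05), sup, tolerance = 1e-12)
  expect_error(lognormal_support(st, 1.5), "level")
})

test_that("lognormal-phoneme matching counts TP/FP/FN/TN as defined", {
  # one phoneme covering one stroke's support
  st <- lognormal_stroke(1, 0.0, -2.2, 0.1)   # support within [0, 0.2]
  seg1 <- phoneme_segmentation("a", 0, 0.2)
  m1 <- match_phonemes(st, seg1)
  expect_identical(m1$table$tp, 1L)
  expect_identical(m1$table$fp, 0L)
  expect_identical(m1$table$fn, 0L)
  expect_identical(m1$table$tn, 0L)
  expect_equal(m1$tpr, 1)

  # three overlapping strokes on one phoneme: TP = 1, FP = 2
  s3 <- do.call(rbind, lapply(c(0, 0.01, 0.02), function(t0)
    lognormal_stroke(1, t0, -2.2, 0.1)))
  m3 <- match_phonemes(s3, seg1)
  expect_identical(m3$table$tp, 1L)
  expect_identical(m3$table$fp, 2L)
  expect_identical(m3$table$tn, 0L)

  # two strokes entirely outside the phoneme: FN, literal TNR above 1
  far <- do.call(rbind, lapply(c(2, 2.5), function(t0)
    lognormal_stroke(1, t0, -2.2, 0.1)))
  mf <- match_phonemes(far, seg1)
  expect_identical(mf$table$fn, 1L)
  expect_identical(mf$table$tn, 2L)
  expect_equal(mf$tpr, 0)
  expect_equal(mf$tnr, 2 / (2 - 1))
  expect_match(paste(mf$flags, collapse = " "), "TNR > 1")

  # single stroke: TNR undefined but TPR still reported
  m1s <- match_phonemes(st, phoneme_segmentation(c("a", "b"), c(0, 0.2),
                                                 c(0.2, 0.4)))
  expect_true(is.nan(m1s$tnr))
  expect_false(is.nan(m1s$tpr))
})

test_that("TP + FP + TN equals NbLog for every phoneme on random fixtures", {
  set.seed(17)
  for (rep in 1:15) {
    k <- sample(2:7, 1)
    strokes <- do.call(rbind, lapply(seq_len(k), function(j)
      lognormal_stroke(runif(1, 1, 5), 0.1 * j + runif(1, 0, 0.05),
                       runif(1, -1.9, -1.2), runif(1, 0.05, 0.3))))
    bounds <- sort(runif(5, 0, 1.2))
    seg <- phoneme_segmentation(letters[1:4], bounds[-5], bounds[-1])
    m <- match_phonemes(strokes, seg)
    expect_true(all(m$table$tp + m$table$fp + m$table$tn == k))
    expect_true(all(m$table$tp + m$table$fn == 1L))
    expect_gte(m$tpr, 0); expect_lte(m$tpr, 1)
  }
})

test_that("the RMS timing error pairs transitions with nearest peaks", {
  expect_equal(timing_error(c(0.1, 0.2), c(0.1, 0.2)), 0)
  expect_equal(timing_error(0.11, 0.1), 0.01, tolerance = 1e-12)
  expect_equal(timing_error(c(0.13, 0.24), c(0.1, 0.2)),
               sqrt((0.03^2 + 0.04^2) / 2), tolerance = 1e-12)
  expect_equal(round(timing_error(c(0.13, 0.24), c(0.1, 0.2)), 5), 0.03536)
  expect_error(timing_error(c(0.1), numeric(0)), "transitions")
})

test_that("group comparison runs ANOVA with Bonferroni-corrected pairs", {
  # identical groups: F ~ 0, p ~ 1
  set.seed(8)
  x <- rnorm(40)
  g1 <- group_compare(c(x, x), rep(c("a", "b"), each = 40))
  expect_gt(g1$p_value, 0.9)

  # separated groups: p below the F-distribution tail oracle
  y1 <- rnorm(50); y2 <- rnorm(50, mean = 5)
  g2 <- group_compare(c(y1, y2), rep(c("a", "b"), each = 50))
  expect_lt(g2$p_value, 1e-3)
  # oracle: recompute the one-way F statistic and its tail by hand
  v <- c(y1, y2); lab <- rep(1:2, each = 50)
  gm <- mean(v)
  ssb <- sum(tapply(v, lab, function(z) length(z) * (mean(z) - gm)^2))
  ssw <- sum(tapply(v, lab, function(z) sum((z - mean(z))^2)))
  f_oracle <- (ssb / 1) / (ssw / 98)
  expect_equal(g2$f, f_oracle, tolerance = 1e-9)
  expect_equal(g2$p_value, stats::pf(f_oracle, 1, 98, lower.tail = FALSE),
               tolerance = 1e-9)

  # three groups: Bonferroni multiplies raw pairwise p by 3, capped at 1
  z <- list(a = rnorm(20), b = rnorm(20, 0.1), c = rnorm(20, 3))
  g3 <- group_compare(unlist(z), rep(names(z), each = 20))
  expect_identical(nrow(g3$pairwise), 3L)
  praw <- stats::pairwise.t.test(unlist(z), rep(names(z), each = 20),
                                 p.adjust.method = "none")$p.value
  pab <- g3$pairwise$p_adj[g3$pairwise$group1 == "a" &
                           g3$pairwise$group2 == "b"]
  expect_equal(pab, min(1, praw["b", "a"] * 3), tolerance = 1e-9)
  expect_identical(g3$alpha, 0.05)

  expect_error(group_compare(c(1, 2), c("a", "b")), "at least two samples")
  expect_error(group_compare(rep(1, 10), rep(c("a", "b"), 5)), "degenerate")
})
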