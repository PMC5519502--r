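test_that("difference spectra isolate the changed metabolite", {
  p <- tparams()
  ds <- glu_only_subject()            # +1.92 % Glu, equal widths, no noise
  comb <- combine_condition(reduce_block_data(ds$fids, ds$design))
  stim <- fid_to_spectrum(comb$stimulation, p)
  base <- fid_to_spectrum(comb$baseline, p)
  diff <- difference_spectrum(stim, base)
  # identical inputs give the zero spectrum
  zero <- difference_spectrum(base, base)
  expect_true(all(Mod(zero$y) == 0))
  # mismatched grids are refused
  expect_error(difference_spectrum(fid_to_spectrum(comb$stimulation, p,
                                                   zf = 2), base), "grids")
  # absorption-mode energy concentrates in the glutamate regions
  # (2.0-2.5 and 3.7-3.8 ppm); dispersive tails are excluded by taking the
  # real part of the phased difference
  glu_idx <- which((diff$ppm >= 2.0 & diff$ppm <= 2.5) |
                     (diff$ppm >= 3.7 & diff$ppm <= 3.8))
  other_idx <- setdiff(which(diff$ppm >= 0.5 & diff$ppm <= 4.2), glu_idx)
  e_glu <- sum(Re(diff$y[glu_idx])^2)
  e_other <- sum(Re(diff$y[other_idx])^2)
  expect_gt(e_glu, 5 * e_other)
})

test_that("percent change is relative to the baseline-bin mean", {
  tc <- time_course(c(10, 10, 10.2, 10.2), c(8, 24, 40, 56),
                    rep(c("baseline", "stimulation"), each = 2))
  d <- delta_glu_timecourse(tc)
  expect_equal(d$values, c(0, 0, 2, 2), tolerance = 1e-12)
  expect_equal(d$baseline_mean, 10)
  # baseline-bin mean of the percent series is exactly zero
  expect_equal(mean(d$values[d$condition == "baseline"]), 0)
  # constant series maps to all zeros
  const <- time_course(rep(5, 4), 1:4, rep(c("baseline", "stimulation"), 2))
  expect_true(all(delta_glu_timecourse(const)$values == 0))
  # non-positive baselines are refused
  bad <- time_course(c(0, 0, 1, 1), 1:4,
                     rep(c("baseline", "stimulation"), each = 2))
  expect_error(delta_glu_timecourse(bad), "positive")
  # familiarization variant: the leading baseline run is excluded
  tc2 <- time_course(c(20, 10, 10.2, 10), c(8, 24, 40, 56),
                     c("baseline", "baseline", "stimulation", "baseline"))
  d2 <- delta_glu_timecourse(tc2, exclude_first_block = TRUE)
  expect_equal(d2$baseline_mean, 10)
})

test_that("moving-average smoothing is centred with shrinking edges", {
  imp <- time_course(c(0, 0, 3, 0, 0), 1:5, rep("baseline", 5))
  expect_equal(smooth_moving_average(imp, 3)$values, c(0, 1, 1, 1, 0))
  const <- time_course(rep(2.5, 6), 1:6, rep("baseline", 6))
  expect_equal(smooth_moving_average(const)$values, rep(2.5, 6))
  expect_equal(smooth_moving_average(imp, 1)$values, imp$values)
  set.seed(71)
  r <- time_course(stats::rnorm(32, 10), 1:32, rep("baseline", 32))
  sm <- smooth_moving_average(r, 3)
  expect_lt(abs(mean(sm$values) - mean(r$values)) / mean(r$values), 0.01)
  expect_error(smooth_moving_average(imp, 2), "odd")
  expect_error(smooth_moving_average(imp, 7), "smaller")
})

test_that("glutamate-BOLD correlation behaves at the extremes and under the null", {
  tc <- function(v) time_course(v, seq_along(v),
                                rep(c("baseline", "stimulation"),
                                    length.out = length(v)))
  x <- stats::rnorm(32)
  self <- correlate_with_bold(tc(x), tc(x))
  expect_equal(self$r, 1, tolerance = 1e-12)
  expect_equal(self$df, 30)
  expect_error(correlate_with_bold(tc(rep(1, 32)), tc(x)), "variance")
  # type-I error calibration under independence
  set.seed(72)
  sig <- replicate(1000, {
    ct <- correlate_with_bold(tc(stats::rnorm(32)), tc(stats::rnorm(32)))
    c(ct$r, ct$p < 0.05)
  })
  expect_lt(abs(mean(sig[1, ])), 0.05)
  expect_lt(abs(mean(sig[2, ]) - 0.05), 0.02)
  # familiarization variant drops the four leading baseline bins
  labs <- rep(rep(c("baseline", "stimulation"), 4), each = 4)
  g <- time_course(stats::rnorm(32), 1:32, labs)
  b <- time_course(stats::rnorm(32), 1:32, labs)
  expect_equal(correlate_with_bold(g, b, drop_first_baseline = TRUE)$n, 28)
})

test_that("z-normalization is exact", {
  set.seed(73)
  z <- z_normalize(stats::rnorm(32, 50, 4))
  expect_lt(abs(mean(z)), 1e-12)
  expect_lt(abs(stats::sd(z) - 1), 1e-12)
  expect_error(z_normalize(rep(3, 10)), "zero-variance")
})

test_that("condition contrasts aggregate per-subject differences", {
  est <- data.frame(subject = rep(c("a", "b", "c"), each = 2),
                    metabolite = "Glu",
                    variant = rep("corrected", 6),
                    baseline_iu = c(10, 10, 9, 9, 11, 11),
                    stim_iu = c(10, 10, 9, 9, 11, 11))
  est <- est[!duplicated(est[c("subject", "metabolite", "variant")]), ]
  ct <- condition_contrast(est)
  expect_equal(ct$delta_iu, 0)
  expect_equal(ct$t_stat, 0)
  expect_equal(ct$df, 2)
  expect_error(condition_contrast(est[, -1]), "columns")
  expect_error(condition_contrast(est[est$subject == "a", ]), "two subjects")
  # exchanging the condition columns flips the sign of the contrast
  est2 <- est
  est2$stim_iu <- est$baseline_iu + c(1, 2, 3)
  ct2 <- condition_contrast(est2)
  est3 <- est2
  names(est3)[names(est3) == "baseline_iu"] <- "tmp"
  names(est3)[names(est3) == "stim_iu"] <- "baseline_iu"
  names(est3)[names(est3) == "tmp"] <- "stim_iu"
  ct3 <- condition_contrast(est3)
  expect_equal(ct3$delta_iu, -ct2$delta_iu)
  expect_equal(abs(ct3$t_stat), abs(ct2$t_stat))
})

test_that("a coupled subject yields a positive glutamate-BOLD correlation", {
  # low-noise subject so a single scan carries the effect
  ds <- simulate_subject(tparams(), tdesign(),
                         ground_truth(noise_sd = 700), seed = 74)
  tc <- fit_timecourse(ds)
  expect_length(tc$glu$values, 32)
  d <- smooth_moving_average(delta_glu_timecourse(tc$glu))
  ct <- correlate_with_bold(d, tc$bold)
  expect_gt(ct$r, 0)
  expect_lt(ct$p, 0.05)
  # per-bin CRLBs improve as noise drops: well under the default-noise level
  expect_lt(mean(tc$crlb_pct), 5)
})
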