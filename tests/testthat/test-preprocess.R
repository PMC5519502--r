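test_that("eddy-current correction inverts a shared phase distortion exactly", {
  ds <- clean_subject()
  p <- ds$fids$params
  t <- time_axis(p)
  phi <- 0.8 * exp(-t / 0.04) * sin(2 * pi * 15 * t)
  distorted <- ds$fids
  distorted$fids <- distorted$fids * exp(1i * phi)
  water <- ds$water_reference * exp(1i * phi)
  fixed <- eddy_current_correct(distorted, water)
  rel <- max(Mod(fixed$fids - ds$fids$fids)) / max(Mod(ds$fids$fids))
  expect_lt(rel, 1e-10)
  # unit-modulus operation: per-sample magnitudes unchanged
  expect_lt(max(abs(Mod(fixed$fids) - Mod(distorted$fids))), 1e-9)
  # water with identically zero phase leaves the series untouched
  ident <- eddy_current_correct(ds$fids, Mod(ds$water_reference) + 0i)
  expect_equal(ident$fids, ds$fids$fids, tolerance = 1e-12)
  # guards
  expect_error(eddy_current_correct(fixed, water), "already been applied")
  expect_error(eddy_current_correct(ds$fids, rep(0 + 0i, p$n_points)),
               "sample 1")
})

test_that("frequency alignment recovers injected shifts and drifts", {
  ds <- clean_subject()
  p <- ds$fids$params
  t <- time_axis(p)
  # inject +3 Hz into a single TR: its recovered shift relative to the
  # untouched TRs must match
  shifted <- ds$fids
  shifted$fids[, 5] <- shifted$fids[, 5] * exp(1i * 2 * pi * 3 * t)
  al <- align_frequency(shifted)
  rel <- al$result$shift_hz[5] - mean(al$result$shift_hz[-5])
  expect_lt(abs(rel - 3), 0.3)
  # drift-free series: every shift within half a raw resolution bin of zero
  al0 <- align_frequency(clean_subject()$fids)
  res <- p$spectral_width / p$n_points
  expect_true(all(abs(al0$result$shift_hz) <= res / 2))
  expect_false(any(al0$result$flagged))
  # linear drift at realistic noise: slope recovered within 0.01 Hz/TR
  dr <- ground_truth(drift_rate = 0.05, phase_jitter_sd = 0, eddy_amp = 0)
  dsd <- simulate_subject(tparams(), tdesign(), dr, seed = 41)
  ald <- align_frequency(eddy_current_correct(dsd$fids, dsd$water_reference))
  slope <- stats::coef(stats::lm(ald$result$shift_hz ~
                                   seq_len(nrow(ald$result))))[2]
  expect_lt(abs(slope - 0.05), 0.01)
})

test_that("phase correction recovers injected zero-order phases", {
  ds <- clean_subject()
  # self-reference: recovered phases are zero
  ph0 <- phase_correct(ds$fids)
  expect_lt(max(abs(ph0$result$phase_deg)), 0.5)
  # a 30 degree rotation is undone
  rot <- ds$fids
  rot$fids <- rot$fids * exp(1i * 30 * pi / 180)
  n <- nrow(rot$fids); h <- n %/% 2
  ref <- rowMeans(stats::mvfft(ds$fids$fids))[c((h + 1L):n, 1L:h)]
  ph30 <- phase_correct(rot, reference = ref)
  expect_lt(max(abs(ph30$result$phase_deg + 30)), 1)
  expect_error(phase_correct(ph30$series), "already been applied")
})

test_that("random per-TR phases are corrected to a tight spread", {
  ds <- simulate_subject(tparams(), tdesign(),
                         ground_truth(drift_rate = 0, eddy_amp = 0,
                                      phase_jitter_sd = 0), seed = 42)
  set.seed(43)
  injected <- stats::runif(n_trs(ds$fids), -45, 45)
  jit <- ds$fids
  for (k in seq_len(n_trs(jit)))
    jit$fids[, k] <- jit$fids[, k] * exp(1i * injected[k] * pi / 180)
  ph <- phase_correct(jit)
  # applied phase ~ -injected + common offset; the residual spread is small
  residual <- injected + ph$result$phase_deg
  expect_lt(stats::sd(residual), 2)
})

test_that("block reduction drops exactly the leading TRs of every block", {
  ds <- clean_subject()
  d <- tdesign()
  red <- reduce_block_data(ds$fids, d)
  expect_equal(n_trs(red), 112)                 # 12.5 % of 128 excluded
  expect_equal(1 - n_trs(red) / n_trs(ds$fids), 0.125)
  expect_equal(sum(red$condition_labels == "baseline"), 56)     # 14 x 4
  expect_equal(sum(red$condition_labels == "stimulation"), 56)
  # retained FIDs are the original ones, labels preserved
  expect_identical(red$fids[, 1], ds$fids$fids[, 3])
  # discard 0 is the identity
  red0 <- reduce_block_data(ds$fids, tdesign(discard_per_block = 0))
  expect_identical(red0$fids, ds$fids$fids)
  # guards
  short <- ds$fids; short$fids <- short$fids[, 1:100]
  short$condition_labels <- short$condition_labels[1:100]
  expect_error(reduce_block_data(short, d), "design implies")
  expect_error(reduce_block_data(red, d), "already been applied")
})

test_that("binning sums consecutive TRs into labelled 16-s points", {
  ds <- clean_subject()
  bn <- bin_averages(ds$fids, 4)
  expect_equal(n_trs(bn$series), 32)
  expect_equal(bn$bin_times, (seq_len(32) - 0.5) * 16)
  expect_equal(sum(bn$series$condition_labels == "baseline"), 16)
  expect_identical(bn$series$fids[, 1], rowSums(ds$fids$fids[, 1:4]))
  # bin size 1 is the identity
  b1 <- bin_averages(ds$fids, 1)
  expect_identical(b1$series$fids, ds$fids$fids)
  # indivisible length is refused with advice
  odd <- ds$fids; odd$fids <- odd$fids[, 1:126]
  odd$condition_labels <- odd$condition_labels[1:126]
  expect_error(bin_averages(odd, 4), "divisible")
})

test_that("the chain is near-identity on an undistorted singlet series", {
  # an isolated NAA singlet: no interference displaces the alignment
  # template, so the chain reduces to sub-resolution re-registration
  p <- tparams()
  fid <- singlet_fid(9.72, amp = 100, ppm = 2.01, params = p)
  series <- fid_series(matrix(rep(fid, 8), ncol = 8),
                       rep(c("baseline", "stimulation"), each = 4), p)
  out <- phase_correct(align_frequency(
    eddy_current_correct(series, Mod(fid) + 0i))$series)
  expect_lt(max(abs(out$result$phase_deg)), 0.5)
  rel <- max(Mod(out$series$fids - series$fids)) / max(Mod(series$fids))
  expect_lt(rel, 0.05)
})
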