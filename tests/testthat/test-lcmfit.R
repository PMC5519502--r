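test_that("noiseless spectra generated from the basis are recovered exactly", {
  p <- tparams(); b <- build_default_basis()
  # single metabolite
  sp <- fid_to_spectrum(synthesize_fid(b, c(Glu = 10), 7.72, p), p)
  fit <- fit_spectrum(sp, b)
  expect_lt(abs(fit$amplitudes[["Glu"]] - 10) / 10, 0.001)
  others <- fit$amplitudes[setdiff(names(fit$amplitudes), "Glu")]
  expect_lt(max(others), 0.001 * 10)
  # two-metabolite mixture
  sp2 <- fid_to_spectrum(synthesize_fid(b, c(Glu = 10, Cr = 8), 7.72, p), p)
  fit2 <- fit_spectrum(sp2, b)
  expect_lt(abs(fit2$amplitudes[["Glu"]] - 10) / 10, 0.005)
  expect_lt(abs(fit2$amplitudes[["Cr"]] - 8) / 8, 0.005)
})

test_that("the global broadening parameter recovers an injected width", {
  p <- tparams(); b <- build_default_basis()
  conc <- default_concentrations()
  sp <- fid_to_spectrum(synthesize_fid(b, conc, 2.0, p), p)
  fit <- fit_spectrum(sp, b)
  expect_lt(abs(fit$global_extra_fwhm - 2.0), 0.2)
})

test_that("CRLBs vanish on noiseless data and grow monotonically with noise", {
  p <- tparams(); b <- build_default_basis()
  tru <- ground_truth()
  conc <- tru$baseline_concentrations *
    tru$water_amplitude * (1 - tru$csf_fraction)
  pure <- synthesize_fid(b, conc, 7.72, p)
  f0 <- compute_crlb(fit_spectrum(fid_to_spectrum(pure, p), b))
  expect_lt(f0$crlb_pct[["Glu"]], 0.01)
  set.seed(51)
  noise <- complex(real = stats::rnorm(p$n_points),
                   imaginary = stats::rnorm(p$n_points))
  crlbs <- vapply(condition_noise_sd() * c(1, 2, 4), function(s) {
    fit <- compute_crlb(fit_spectrum(fid_to_spectrum(pure + s * noise, p), b))
    fit$crlb_pct[["Glu"]]
  }, numeric(1))
  expect_true(all(diff(crlbs) > 0))
})

test_that("doubling the averages shrinks the CRLB by about sqrt(2)", {
  p <- tparams(); b <- build_default_basis()
  tru <- ground_truth()
  pure <- synthesize_fid(b, tru$baseline_concentrations *
                           tru$water_amplitude * (1 - tru$csf_fraction),
                         7.72, p)
  set.seed(52)
  s <- condition_noise_sd() * 2
  n1 <- add_complex_noise(pure, s)
  n2 <- add_complex_noise(pure, s)
  f1 <- compute_crlb(fit_spectrum(fid_to_spectrum(n1, p), b))
  f2 <- compute_crlb(fit_spectrum(fid_to_spectrum((n1 + n2) / 2, p), b))
  ratio <- f2$crlb_pct[["Glu"]] / f1$crlb_pct[["Glu"]]
  expect_lt(abs(ratio - 1 / sqrt(2)), 0.1)
})

test_that("institutional units are water-referenced, CSF-corrected and scale-invariant", {
  p <- tparams(); b <- build_default_basis()
  tru <- ground_truth()
  iu <- tru$water_amplitude * (1 - tru$csf_fraction)
  fid <- synthesize_fid(b, tru$baseline_concentrations * iu, 7.72, p)
  water <- tru$water_amplitude * exp(-pi * 9.72 * time_axis(p))
  fit <- fit_spectrum(fid_to_spectrum(fid, p), b)
  scaled <- water_reference_scale(fit, water, tru$csf_fraction)
  expect_equal(scaled$concentrations_iu[["Glu"]], 7.8125, tolerance = 1e-3)
  # csf = 0 is the pure water ratio
  plain <- water_reference_scale(fit, water, 0)
  expect_equal(plain$concentrations_iu[["Glu"]],
               scaled$concentrations_iu[["Glu"]] * (1 - 0.0816),
               tolerance = 1e-9)
  # the printed CSF fraction multiplies concentrations by 1/(1 - 0.0816)
  expect_equal(scaled$concentrations_iu[["Glu"]] /
                 plain$concentrations_iu[["Glu"]], 1 / (1 - 0.0816),
               tolerance = 1e-9)
  # doubling the water amplitude halves every value
  half <- water_reference_scale(fit, 2 * water, tru$csf_fraction)
  expect_equal(unname(half$concentrations_iu),
               unname(scaled$concentrations_iu) / 2, tolerance = 1e-9)
  expect_error(water_reference_scale(fit, water, 1), "csf_fraction")
  # scaling equivariance: alpha on spectrum and water leaves I.U. unchanged
  alpha <- 3.7
  fit_a <- fit_spectrum(fid_to_spectrum(alpha * fid, p), b)
  scaled_a <- water_reference_scale(fit_a, alpha * water, tru$csf_fraction)
  expect_equal(unname(scaled_a$concentrations_iu),
               unname(scaled$concentrations_iu), tolerance = 1e-4)
})

test_that("tCho/tCr pairing sums constituents with the covariance CRLB rule", {
  p <- tparams(); b <- build_default_basis()
  tru <- ground_truth()
  iu <- tru$water_amplitude * (1 - tru$csf_fraction)
  pure <- synthesize_fid(b, tru$baseline_concentrations * iu, 7.72, p)
  set.seed(53)
  fit <- fit_spectrum(fid_to_spectrum(
    add_complex_noise(pure, condition_noise_sd()), p), b)
  fit <- combine_pairs(compute_crlb(fit))
  expect_equal(fit$amplitudes[["tCr"]],
               fit$amplitudes[["Cr"]] + fit$amplitudes[["PCr"]])
  expect_equal(fit$amplitudes[["tCho"]],
               fit$amplitudes[["GPC"]] + fit$amplitudes[["PCho"]])
  # overlapping constituents are anticorrelated: the pair bound is tighter
  expect_lt(fit$crlb_pct[["tCr"]],
            max(fit$crlb_pct[["Cr"]], fit$crlb_pct[["PCr"]]))
  expect_lt(fit$crlb_pct[["tCho"]],
            max(fit$crlb_pct[["GPC"]], fit$crlb_pct[["PCho"]]))
  # a missing constituent drops the pair with a warning
  b_sub <- build_default_basis(c("Glu", "sNAA", "Cr", "PCr"))
  sp <- fid_to_spectrum(synthesize_fid(b_sub, c(Glu = 8, sNAA = 9,
                                                Cr = 4, PCr = 4), 7.72, p), p)
  fit_sub <- compute_crlb(fit_spectrum(sp, b_sub))
  expect_warning(fit_sub <- combine_pairs(fit_sub), "tCho")
  expect_false("tCho" %in% names(fit_sub$amplitudes))
  expect_true("tCr" %in% names(fit_sub$amplitudes))
})

test_that("reliability filtering uses a strict 20 percent CRLB rule", {
  fake <- function(crlb) {
    structure(list(crlb_pct = crlb), class = "fit_result")
  }
  rep1 <- filter_reliable(list(fake(c(Glu = 19.9, Lac = 20.0, GABA = 25))))
  expect_true(rep1$reliable[rep1$metabolite == "Glu"])      # 19.9 < 20
  expect_false(rep1$reliable[rep1$metabolite == "Lac"])     # 20.0 is out
  expect_false(rep1$reliable[rep1$metabolite == "GABA"])
  empty <- filter_reliable(list())
  expect_equal(nrow(empty), 0)
})
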