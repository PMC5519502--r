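# Shared fixtures. Expensive simulations are memoized for the duration of
# one test run; every seed is a fixed constant so the suite is reproducible.

.cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

tparams <- function(...) acquisition_params(...)
tdesign <- function(...) block_design(...)

# truth with every stochastic and instrumental nuisance switched off
clean_truth <- function(...) {
  ground_truth(noise_sd = 0, drift_rate = 0, phase_jitter_sd = 0,
               eddy_amp = 0, bold_noise_sd = 0, ...)
}

# truth for resting-state ('sham') runs: no condition-dependent signal
resting_truth <- function(...) {
  ground_truth(stim_glu_increase = 0, stim_tcr_fwhm = 9.72,
               bold_amplitude = 0, ...)
}

clean_subject <- function() {
  cached("clean_subject",
         simulate_subject(tparams(), tdesign(), clean_truth(), seed = 101))
}

default_subject <- function() {
  cached("default_subject",
         simulate_subject(tparams(), tdesign(), ground_truth(), seed = 102))
}

# a clean subject whose only condition effect is the glutamate increase
# (equal line widths, so the difference spectrum isolates glutamate)
glu_only_subject <- function() {
  cached("glu_only_subject",
         simulate_subject(tparams(), tdesign(),
                          clean_truth(stim_tcr_fwhm = 9.72), seed = 103))
}

# single-resonance helpers
singlet_basis <- function(ppm = 3.03, base_fwhm = 0) {
  structure(data.frame(metabolite = "X", ppm = ppm, weight = 1,
                       base_fwhm = base_fwhm),
            class = c("basis_set", "data.frame"))
}

singlet_fid <- function(fwhm, amp = 1, ppm = 3.03, params = tparams()) {
  synthesize_fid(singlet_basis(ppm), c(X = amp), fwhm, params)
}

add_complex_noise <- function(fid, sd) {
  fid + complex(real = stats::rnorm(length(fid), 0, sd),
                imaginary = stats::rnorm(length(fid), 0, sd))
}

# noise level of a 56-average condition spectrum at the default truth
condition_noise_sd <- function() ground_truth()$noise_sd / sqrt(56)
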