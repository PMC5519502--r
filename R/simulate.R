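# Synthetic combined fMRI-MRS data: per-TR metabolite FIDs with condition-
# dependent glutamate and line width, nuisance processes (drift, phase
# jitter, eddy-current phase, thermal noise), an unsuppressed water
# reference, and an HRF-convolved BOLD series.

#' Canonical double-gamma hemodynamic response function
#'
#' `h(t) = dgamma(t, 6, 1) - dgamma(t, 16, 1) / 6` (peak near 6 s, undershoot
#' near 16 s), evaluated on the supplied time grid.
#'
#' @param t Time grid in seconds.
#' @return Numeric vector of HRF values.
#' @export
hrf_double_gamma <- function(t) {
  stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
}

#' Simulate an ROI-mean BOLD time series
#'
#' A boxcar over the stimulation blocks is convolved with the canonical
#' double-gamma HRF (kernel support 0-32 s, normalized to unit sum so the
#' within-block plateau equals the requested amplitude), expressed as percent
#' signal change over a baseline of 100, sampled at the centre of each TR,
#' and perturbed with white noise.
#'
#' @param design A [block_design()].
#' @param amplitude_pct Plateau percent signal change (>= 0).
#' @param tr Repetition time in seconds.
#' @param noise_sd White-noise SD in percent of baseline.
#' @param seed Integer seed (required whenever `noise_sd > 0`).
#' @return Numeric vector, one sample per TR, baseline level 100.
#' @export
simulate_bold <- function(design, amplitude_pct, tr, noise_sd = 0,
                          seed = NULL) {
  if (amplitude_pct < 0) stop("amplitude_pct must be >= 0")
  if (noise_sd > 0 && is.null(seed))
    stop("seed is required when noise_sd > 0")
  dt <- 0.1
  total <- design$block_length * 2 * design$n_cycles
  tt <- seq(0, total - dt, by = dt)
  block_of <- floor(tt / design$block_length)
  stim_first <- design$first_condition == "stimulation"
  box <- as.numeric((block_of %% 2 == 0) == stim_first)
  h <- hrf_double_gamma(seq(0, 32, by = dt))
  h <- h / sum(h)
  resp <- stats::convolve(box, rev(h), type = "open")[seq_along(box)]
  signal <- 100 * (1 + amplitude_pct / 100 * resp)
  n_tr <- as.integer(round(total / tr))
  centers <- (seq_len(n_tr) - 0.5) * tr
  out <- signal[pmin(length(signal), round(centers / dt) + 1)]
  if (noise_sd > 0) {
    set.seed(seed)
    out <- out + stats::rnorm(n_tr, 0, noise_sd)
  }
  out
}

#' Estimate the BOLD percent signal change of a block experiment
#'
#' Plateau level = mean over the final half of every stimulation block
#' (where the HRF has fully evolved); baseline level = mean over the final
#' half of every baseline block (where the post-stimulus undershoot has
#' resolved). Returns `100 * (plateau - baseline) / baseline`.
#'
#' @param bold Per-TR signal as returned by [simulate_bold()].
#' @param design A [block_design()].
#' @param tr Repetition time in seconds.
#' @return Percent signal change.
#' @export
estimate_bold_amplitude <- function(bold, design, tr) {
  tpb <- as.integer(round(design$block_length / tr))
  n <- length(bold)
  if (n != tpb * 2 * design$n_cycles)
    stop("bold length does not match the design")
  block_of <- rep(seq_len(2 * design$n_cycles), each = tpb)
  within <- rep(seq_len(tpb), times = 2 * design$n_cycles)
  stim_first <- design$first_condition == "stimulation"
  is_stim <- (block_of %% 2 == 1) == stim_first
  late <- within > tpb / 2
  plateau <- mean(bold[is_stim & late])
  base <- mean(bold[!is_stim & late])
  100 * (plateau - base) / base
}

#' Simulate one subject's combined fMRI-MRS dataset
#'
#' Generates `n_averages` per-TR FIDs in which (i) glutamate is at its
#' baseline level during baseline TRs and elevated by `stim_glu_increase`
#' percent during stimulation TRs; (ii) every resonance carries the
#' condition's global line width (`baseline_tcr_fwhm` / `stim_tcr_fwhm`),
#' modelling the BOLD T2* effect, together with the accompanying
#' echo-amplitude modulation `exp(pi * (fwhm_base - fwhm_cond) * TE)`;
#' (iii) cumulative frequency drift, per-TR phase jitter, an eddy-current
#' phase shared with the water reference, and complex Gaussian noise are
#' applied. Metabolite FID amplitudes are
#' `conc_IU * (1 - csf_fraction) * water_amplitude`, so water referencing
#' with unit scaling constant recovers institutional units.
#'
#' @param params An [acquisition_params()].
#' @param design A [block_design()] consistent with `params`.
#' @param truth A [ground_truth()].
#' @param seed Integer seed; mandatory, reproducibility is part of the
#'   contract.
#' @param basis A `basis_set` (default [build_default_basis()]).
#' @param subject_id Identifier.
#' @return An object of class `subject_dataset`: `fids` (a [fid_series()]),
#'   `water_reference`, `bold`, `design`, `csf_fraction`, `truth`, `seed`.
#' @export
simulate_subject <- function(params, design, truth, seed,
                             basis = build_default_basis(),
                             subject_id = "s01") {
  if (missing(seed) || is.null(seed))
    stop("seed must be supplied: simulations are reproducible by contract")
  labels <- design_labels(design, params)
  set.seed(seed)
  bold_seed <- sample.int(.Machine$integer.max - 1, 1)
  t <- time_axis(params)
  n <- params$n_points
  # intrinsic width of the tCr singlet component in this basis: the global
  # broadening is chosen so the observed singlet width equals the truth value
  singlet_base <- basis$base_fwhm[basis$metabolite == "Cr"][1]
  if (is.na(singlet_base)) singlet_base <- min(basis$base_fwhm)
  iu_scale <- truth$water_amplitude * (1 - truth$csf_fraction)
  conc_base <- truth$baseline_concentrations * iu_scale
  conc_stim <- conc_base
  if ("Glu" %in% names(conc_stim))
    conc_stim[["Glu"]] <- conc_stim[["Glu"]] * (1 + truth$stim_glu_increase / 100)
  widths <- c(baseline = truth$baseline_tcr_fwhm,
              stimulation = truth$stim_tcr_fwhm)
  pure <- list(
    baseline = synthesize_fid(basis, conc_base,
                              max(widths["baseline"] - singlet_base, 0), params),
    stimulation = synthesize_fid(basis, conc_stim,
                                 max(widths["stimulation"] - singlet_base, 0),
                                 params))
  eddy_phase <- truth$eddy_amp * exp(-t / truth$eddy_tau) *
    sin(2 * pi * truth$eddy_freq * t)
  fids <- matrix(0 + 0i, n, params$n_averages)
  for (k in seq_len(params$n_averages)) {
    cond <- labels[k]
    bold_enh <- exp(pi * (truth$baseline_tcr_fwhm - widths[[cond]]) * params$te)
    shift <- truth$drift_rate * (k - 1)
    phase <- stats::rnorm(1, 0, truth$phase_jitter_sd) * pi / 180
    fid <- pure[[cond]] * bold_enh *
      exp(1i * (2 * pi * shift * t + phase + eddy_phase))
    if (truth$noise_sd > 0)
      fid <- fid + complex(real = stats::rnorm(n, 0, truth$noise_sd),
                           imaginary = stats::rnorm(n, 0, truth$noise_sd))
    fids[, k] <- fid
  }
  water <- truth$water_amplitude *
    exp(-pi * truth$baseline_tcr_fwhm * t) * exp(1i * eddy_phase)
  bold <- simulate_bold(design, truth$bold_amplitude, params$tr,
                        truth$bold_noise_sd,
                        seed = if (truth$bold_noise_sd > 0) bold_seed else NULL)
  structure(list(fids = fid_series(fids, labels, params, subject_id),
                 water_reference = water,
                 bold = bold,
                 design = design,
                 csf_fraction = truth$csf_fraction,
                 truth = truth,
                 seed = seed),
            class = "subject_dataset")
}

#' @export
print.subject_dataset <- function(x, ...) {
  cat(sprintf("<subject_dataset> %s: %d TRs, seed %d, CSF %.3f\n",
              x$fids$subject_id, n_trs(x$fids), x$seed, x$csf_fraction))
  invisible(x)
}

#' Simulate a group of subjects
#'
#' Derives one reproducible seed per subject from the master seed and draws
#' each subject's truth around the group truth with the perturbation SDs in
#' `truth_distribution` (default: no perturbation, so the group values are
#' exact per-subject truth and all variability is measurement noise).
#'
#' @param n_subjects Number of subjects (default 13).
#' @param params,design,truth Group-level settings (see
#'   [simulate_subject()]).
#' @param truth_distribution Named numeric vector of between-subject SDs for
#'   any of `stim_glu_increase`, `baseline_tcr_fwhm`, `stim_tcr_fwhm`,
#'   `bold_amplitude`, `csf_fraction` (width perturbations are applied to
#'   both conditions jointly unless given separately).
#' @param seed Master integer seed.
#' @param basis A `basis_set`.
#' @return List of `subject_dataset` objects.
#' @export
simulate_group <- function(n_subjects = 13,
                           params = acquisition_params(),
                           design = block_design(),
                           truth = ground_truth(),
                           truth_distribution = numeric(),
                           seed,
                           basis = build_default_basis()) {
  if (missing(seed) || is.null(seed)) stop("seed must be supplied")
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  set.seed(seed)
  subject_seeds <- sample.int(.Machine$integer.max - 1, n_subjects)
  perturb_seeds <- sample.int(.Machine$integer.max - 1, n_subjects)
  perturbable <-c("stim_glu_increase", "baseline_tcr_fwhm", "stim_tcr_fwhm",
                   "bold_amplitude", "csf_fraction")
  bad <- setdiff(names(truth_distribution), perturbable)
  if (length(bad)) stop("cannot perturb field(s): ", paste(bad, collapse = ", "))
  lapply(seq_len(n_subjects), function(i) {
    ti <- truth
    if (length(truth_distribution)) {
      set.seed(perturb_seeds[i])
      for (f in names(truth_distribution))
        ti[[f]] <- stats::rnorm(1, truth[[f]], truth_distribution[[f]])
      # keep the generator's physical constraints intact
      ti$stim_tcr_fwhm <- min(ti$stim_tcr_fwhm, ti$baseline_tcr_fwhm)
      ti$csf_fraction <- min(max(ti$csf_fraction, 0), 0.99)
      ti$bold_amplitude <- max(ti$bold_amplitude, 0)
    }
    simulate_subject(params, design, ti, seed = subject_seeds[i],
                     basis = basis,
                     subject_id = sprintf("s%02d", i))
  })
}
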