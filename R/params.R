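#' Acquisition parameters for a combined fMRI-MRS run
#'
#' Bundles the spectroscopy acquisition metadata needed to interpret a free
#' induction decay (FID): carrier frequency, digitization, repetition and echo
#' times, and the chemical-shift reference of the carrier.
#'
#' Defaults describe a 7 T semi-LASER-like short-TE acquisition: 297.2 MHz
#' proton frequency, 6000 Hz spectral width over 2048 complex points,
#' TR = 4 s, TE = 36 ms, 128 averages, carrier on water at 4.70 ppm.
#'
#' @param spectrometer_freq Proton frequency in MHz.
#' @param spectral_width Sampling bandwidth in Hz (inverse dwell time).
#' @param n_points Number of complex points per FID (>= 512).
#' @param tr Repetition time in seconds.
#' @param te Echo time in seconds (metadata; used by the BOLD amplitude model).
#' @param n_averages Number of acquired transients.
#' @param reference_ppm Chemical shift of the carrier (0 Hz offset), in ppm.
#' @return An object of class `acquisition_params`.
#' @export
acquisition_params <- function(spectrometer_freq = 297.2,
                               spectral_width = 6000,
                               n_points = 2048,
                               tr = 4,
                               te = 0.036,
                               n_averages = 128,
                               reference_ppm = 4.70) {
  if (spectral_width <= 0) stop("spectral_width must be > 0")
  if (n_points < 512) stop("n_points must be >= 512")
  if (tr <= 0) stop("tr must be > 0")
  if (n_averages < 1) stop("n_averages must be >= 1")
  structure(list(spectrometer_freq = spectrometer_freq,
                 spectral_width = spectral_width,
                 n_points = as.integer(n_points),
                 tr = tr, te = te,
                 n_averages = as.integer(n_averages),
                 reference_ppm = reference_ppm),
            class = "acquisition_params")
}

#' Block design of a baseline/stimulation experiment
#'
#' @param block_length Duration of one block in seconds.
#' @param n_cycles Number of baseline+stimulation cycles.
#' @param first_condition Condition of the first block, `"baseline"` or
#'   `"stimulation"`.
#' @param discard_per_block Number of TRs discarded at the start of every
#'   block by [reduce_block_data()] (transition period of the BOLD response).
#' @return An object of class `block_design`.
#' @export
block_design <- function(block_length = 64,
                         n_cycles = 4,
                         first_condition = c("baseline", "stimulation"),
                         discard_per_block = 2) {
  first_condition <- match.arg(first_condition)
  if (block_length <= 0) stop("block_length must be > 0")
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  if (discard_per_block < 0) stop("discard_per_block must be >= 0")
  structure(list(block_length = block_length,
                 n_cycles = as.integer(n_cycles),
                 first_condition = first_condition,
                 discard_per_block = as.integer(discard_per_block)),
            class = "block_design")
}

#' Per-TR condition labels implied by a block design
#'
#' @param design A [block_design()].
#' @param params An [acquisition_params()]; `block_length` must be an integer
#'   multiple of `tr` and the design must span exactly `n_averages` TRs.
#' @return Character vector of length `n_averages`, values `"baseline"` /
#'   `"stimulation"`.
#' @export
design_labels <- function(design, params) {
  tpb <- design$block_length / params$tr
  if (abs(tpb - round(tpb)) > 1e-9)
    stop("block_length must be divisible by tr")
  tpb <- as.integer(round(tpb))
  if (design$discard_per_block >= tpb)
    stop("discard_per_block must be smaller than the TRs per block")
  other <- setdiff(c("baseline", "stimulation"), design$first_condition)
  labels <- rep(rep(c(design$first_condition, other), times = design$n_cycles),
                each = tpb)
  if (length(labels) != params$n_averages)
    stop(sprintf("design spans %d TRs but n_averages is %d",
                 length(labels), params$n_averages))
  labels
}

#' Ground truth for the synthetic-data generator
#'
#' Collects every quantity the generator treats as true: metabolite
#' concentrations in institutional units (I.U.), the stimulation glutamate
#' increase, condition-specific spectral line widths, the BOLD amplitude, and
#' the nuisance processes (frequency drift, phase jitter, eddy-current phase,
#' thermal noise).
#'
#' Defaults encode the study conditions this package emulates: a +1.92 %
#' glutamate increase during stimulation, total-creatine singlet FWHM of
#' 9.72 Hz at baseline narrowing to 9.51 Hz during activation, a 1.43 %
#' BOLD plateau, and a CSF fraction of 8.16 %. The noise level is calibrated
#' so a single-TR spectrum has an NAA-singlet SNR near 10.
#'
#' @param baseline_concentrations Named numeric vector, metabolite -> I.U.
#' @param stim_glu_increase Percent increase of glutamate during stimulation.
#' @param baseline_tcr_fwhm,stim_tcr_fwhm Observed FWHM (Hz) of the tCr
#'   singlet during baseline / stimulation; stimulation must not be broader
#'   (BOLD narrows, never broadens).
#' @param bold_amplitude BOLD plateau percent signal change.
#' @param bold_noise_sd White-noise SD of the per-TR ROI-mean BOLD signal, in
#'   percent of baseline.
#' @param drift_rate Cumulative frequency drift in Hz per TR.
#' @param phase_jitter_sd SD of per-TR zero-order phase jitter, degrees.
#' @param eddy_amp,eddy_tau,eddy_freq Eddy-current phase model
#'   `phi(t) = eddy_amp * exp(-t/eddy_tau) * sin(2*pi*eddy_freq*t)`
#'   (rad, s, Hz).
#' @param noise_sd SD of complex Gaussian noise per FID point (arbitrary
#'   units, same scale as `water_amplitude`).
#' @param csf_fraction CSF fraction of the voxel, in `[0, 1)`.
#' @param water_amplitude First-point magnitude of the unsuppressed water
#'   reference FID (arbitrary units; sets the I.U. scale).
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(baseline_concentrations = default_concentrations(),
                         stim_glu_increase = 1.92,
                         baseline_tcr_fwhm = 9.72,
                         stim_tcr_fwhm = 9.51,
                         bold_amplitude = 1.43,
                         bold_noise_sd = 0.5,
                         drift_rate = 0.03,
                         phase_jitter_sd = 5,
                         eddy_amp = 0.5,
                         eddy_tau = 0.05,
                         eddy_freq = 20,
                         noise_sd = 3500,
                         csf_fraction = 0.0816,
                         water_amplitude = 1000) {
  if (any(baseline_concentrations < 0)) stop("concentrations must be >= 0")
  if (is.null(names(baseline_concentrations)))
    stop("baseline_concentrations must be a named vector")
  if (stim_tcr_fwhm > baseline_tcr_fwhm)
    stop("stim_tcr_fwhm must be <= baseline_tcr_fwhm (BOLD narrows lines)")
  if (baseline_tcr_fwhm <= 0) stop("line widths must be > 0")
  if (csf_fraction < 0 || csf_fraction >= 1)
    stop("csf_fraction must be in [0, 1)")
  if (noise_sd < 0 || bold_noise_sd < 0) stop("noise SDs must be >= 0")
  if (bold_amplitude < 0) stop("bold_amplitude must be >= 0")
  structure(list(baseline_concentrations = baseline_concentrations,
                 stim_glu_increase = stim_glu_increase,
                 baseline_tcr_fwhm = baseline_tcr_fwhm,
                 stim_tcr_fwhm = stim_tcr_fwhm,
                 bold_amplitude = bold_amplitude,
                 bold_noise_sd = bold_noise_sd,
                 drift_rate = drift_rate,
                 phase_jitter_sd = phase_jitter_sd,
                 eddy_amp = eddy_amp, eddy_tau = eddy_tau,
                 eddy_freq = eddy_freq,
                 noise_sd = noise_sd,
                 csf_fraction = csf_fraction,
                 water_amplitude = water_amplitude),
            class = "ground_truth")
}

#' Default baseline metabolite concentrations (institutional units)
#'
#' Occipital-cortex levels typical of short-TE 7 T work. The glutamate level
#' is 7.8125 I.U. so that a 1.92 % stimulation increase corresponds to an
#' absolute change of 0.15 I.U.
#'
#' @return Named numeric vector of I.U. values.
#' @export
default_concentrations <- function() {
  c(Glu = 7.8125, Gln = 2.5, GABA = 1.3,
    sNAA = 9.0, mNAA = 3.3,
    Cr = 4.4, PCr = 3.7,
    GPC = 0.7, PCho = 0.4,
    Ins = 6.5, GSH = 1.4, Lac = 0.9,
    MM09 = 3.0, MM12 = 2.5, MM17 = 2.0)
}
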