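# End-to-end orchestration: preprocessing, condition analysis with and
# without BOLD correction, group statistics, and the time-course path.

#' Preprocess a subject's FID series
#'
#' Applies the standard chain: eddy-current correction against the water
#' reference, frequency alignment to the NAA singlet, and zero-order phase
#' correction.
#'
#' @param ds A `subject_dataset`.
#' @return List: `series` (corrected [fid_series()]), `qc` (per-TR
#'   data.frame of shifts, phases, flags).
#' @export
preprocess_subject <- function(ds) {
  s <- eddy_current_correct(ds$fids, ds$water_reference)
  al <- align_frequency(s)
  ph <- phase_correct(al$series)
  qc <- data.frame(tr = al$result$tr,
                   shift_hz = al$result$shift_hz,
                   flagged = al$result$flagged,
                   phase_deg = ph$result$phase_deg)
  list(series = ph$series, qc = qc)
}

#' Condition-path analysis of one subject
#'
#' Preprocesses, drops the first `discard_per_block` TRs of every block,
#' averages the retained TRs per condition, estimates the tCr singlet line
#' width of each condition, broadens the stimulation average to the
#' baseline width (the BOLD correction, echo-time extrapolated), and fits
#' the baseline, uncorrected-stimulation and corrected-stimulation spectra
#' with the linear-combination model, scaled to water-referenced
#' institutional units with CSF correction and with the tCho/tCr pairs
#' appended.
#'
#' @param ds A `subject_dataset`.
#' @param basis,config Fitting dictionary and configuration.
#' @param linewidths_only Skip the linear-combination fits and return only
#'   the line-width table (fast path for width-focused analyses).
#' @return List: `linewidths` (data.frame: condition FWHMs, narrowing
#'   percent, applied broadening), `fits` (named list of `fit_result`s:
#'   `baseline`, `stim_uncorrected`, `stim_corrected`), `n_baseline`,
#'   `n_stimulation`, `qc`.
#' @export
analyze_subject_conditions <- function(ds, basis = build_default_basis(),
                                       config = fit_config(),
                                       linewidths_only = FALSE) {
  pp <- preprocess_subject(ds)
  red <- reduce_block_data(pp$series, ds$design)
  comb <- combine_condition(red)
  params <- red$params

  lw <- lapply(c(baseline = "baseline", stimulation = "stimulation"),
               function(cond)
                 fit_tcr_linewidth(fid_to_spectrum(comb[[cond]], params,
                                                   zf = 4),
                                   condition = cond))
  broadening <- max(lw$baseline$fwhm - lw$stimulation$fwhm, 0)
  lw_table <- data.frame(
    subject = ds$fids$subject_id,
    baseline_fwhm = lw$baseline$fwhm,
    stim_fwhm = lw$stimulation$fwhm,
    narrowing_pct = narrowing_percent(lw$baseline, lw$stimulation),
    applied_broadening_hz = broadening)
  if (linewidths_only)
    return(list(linewidths = lw_table, fits = NULL,
                n_baseline = comb$n_baseline,
                n_stimulation = comb$n_stimulation, qc = pp$qc))
  stim_corr <- match_linewidth(comb$stimulation, lw$stimulation$fwhm,
                               lw$stimulation$fwhm + broadening, params,
                               te = params$te)

  fit_one <- function(fid) {
    fit <- fit_spectrum(fid_to_spectrum(fid, params), basis, config)
    fit <- compute_crlb(fit)
    fit <- water_reference_scale(fit, ds$water_reference, ds$csf_fraction)
    combine_pairs(fit)
  }
  fits <- list(baseline = fit_one(comb$baseline),
               stim_uncorrected = fit_one(comb$stimulation),
               stim_corrected = fit_one(stim_corr))
  list(linewidths = lw_table,
       fits = fits,
       n_baseline = comb$n_baseline,
       n_stimulation = comb$n_stimulation,
       qc = pp$qc)
}

#' Group analysis over a list of subjects (condition path)
#'
#' Runs [analyze_subject_conditions()] per subject and assembles the
#' group-level tables: per-subject line widths, per-subject condition
#' concentrations (corrected and uncorrected variants), the group
#' condition contrast, and the CRLB reliability report (from the baseline
#' fits).
#'
#' @param group List of `subject_dataset`s.
#' @param basis,config Fitting dictionary and configuration.
#' @param metabolites Metabolites to carry into the contrast table
#'   (default: all fitted, including the tCho/tCr pairs).
#' @param linewidths_only Skip the linear-combination fits (see
#'   [analyze_subject_conditions()]).
#' @return List: `linewidths`, `estimates` (per subject/metabolite/variant),
#'   `contrasts` (a `group_stats` data.frame), `reliability`, `subjects`
#'   (the per-subject analysis objects).
#' @export
run_group_analysis <- function(group, basis = build_default_basis(),
                               config = fit_config(), metabolites = NULL,
                               linewidths_only = FALSE) {
  subjects <- lapply(group, analyze_subject_conditions,
                     basis = basis, config = config,
                     linewidths_only = linewidths_only)
  linewidths <- do.call(rbind, lapply(subjects, `[[`, "linewidths"))
  if (linewidths_only)
    return(list(linewidths = linewidths, estimates = NULL, contrasts = NULL,
                reliability = NULL, subjects = subjects))
  estimates <- do.call(rbind, lapply(subjects, function(s) {
    id <- s$linewidths$subject
    mets <- names(s$fits$baseline$concentrations_iu)
    if (!is.null(metabolites)) mets <- intersect(mets, metabolites)
    rbind(
      data.frame(subject = id, metabolite = mets, variant = "uncorrected",
                 baseline_iu = unname(s$fits$baseline$concentrations_iu[mets]),
                 stim_iu = unname(s$fits$stim_uncorrected$concentrations_iu[mets])),
      data.frame(subject = id, metabolite = mets, variant = "corrected",
                 baseline_iu = unname(s$fits$baseline$concentrations_iu[mets]),
                 stim_iu = unname(s$fits$stim_corrected$concentrations_iu[mets])))
  }))
  contrasts <- condition_contrast(estimates)
  reliability <- filter_reliable(lapply(subjects,
                                        function(s) s$fits$baseline),
                                 threshold = config$crlb_threshold)
  list(linewidths = linewidths, estimates = estimates,
       contrasts = contrasts, reliability = reliability,
       subjects = subjects)
}

#' Time-course path: per-bin metabolite concentrations
#'
#' Preprocesses the full series (no block reduction, so the default design
#' yields 32 bins at 16-s resolution), sums every `bin_size` consecutive
#' TRs, fits each bin with the linear-combination model and returns the
#' concentration time course of one metabolite in institutional units,
#' together with the identically binned BOLD series.
#'
#' @param ds A `subject_dataset`.
#' @param metabolite Metabolite reported (default `"Glu"`).
#' @param basis,config Fitting dictionary and configuration.
#' @param bin_size TRs per bin (default 4).
#' @return List: `glu` ([time_course()], I.U.), `bold` ([time_course()],
#'   a.u.), `fits` (per-bin `fit_result`s), `crlb_pct` (per-bin CRLB of the
#'   reported metabolite).
#' @export
fit_timecourse <- function(ds, metabolite = "Glu",
                           basis = build_default_basis(),
                           config = fit_config(), bin_size = 4) {
  pp <- preprocess_subject(ds)
  bn <- bin_averages(pp$series, bin_size)
  params <- bn$series$params
  nb <- n_trs(bn$series)
  fits <- vector("list", nb)
  vals <- numeric(nb)
  crlb <- numeric(nb)
  for (b in seq_len(nb)) {
    fit <- fit_spectrum(fid_to_spectrum(bn$series$fids[, b] / bin_size,
                                        params),
                        basis, config)
    fit <- compute_crlb(fit)
    fit <- water_reference_scale(fit, ds$water_reference, ds$csf_fraction)
    fit <- combine_pairs(fit)
    fits[[b]] <- fit
    vals[b] <- fit$concentrations_iu[[metabolite]]
    crlb[b] <- fit$crlb_pct[[metabolite]]
  }
  labels <- bn$series$condition_labels
  bold_bins <- vapply(seq_len(nb), function(b)
    mean(ds$bold[((b - 1) * bin_size + 1):(b * bin_size)]), numeric(1))
  list(glu = time_course(vals, bn$bin_times, labels, units = "I.U."),
       bold = time_course(bold_bins, bn$bin_times, labels, units = "a.u."),
       fits = fits, crlb_pct = crlb)
}
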