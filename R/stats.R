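# Condition contrasts, difference spectra, glutamate time courses and
# glutamate-BOLD coupling statistics.

#' Construct a time course
#'
#' @param values Per-bin quantity (glutamate I.U., BOLD signal, ...).
#' @param bin_times Bin-centre times in seconds.
#' @param condition Per-bin condition labels.
#' @param units One of `"I.U."`, `"percent"`, `"z"`, `"a.u."`.
#' @param baseline_mean Optional mean over baseline bins (filled by
#'   [delta_glu_timecourse()]).
#' @return An object of class `time_course`.
#' @export
time_course <- function(values, bin_times, condition,
                        units = c("I.U.", "percent", "z", "a.u."),
                        baseline_mean = NULL) {
  units <- match.arg(units)
  if (length(values) != length(bin_times) ||
      length(values) != length(condition))
    stop("values, bin_times and condition must have equal length")
  structure(list(values = values, bin_times = bin_times,
                 condition = condition, units = units,
                 baseline_mean = baseline_mean),
            class = "time_course")
}

#' @export
print.time_course <- function(x, ...) {
  cat(sprintf("<time_course> %d bins (%s), %d baseline / %d stimulation\n",
              length(x$values), x$units,
              sum(x$condition == "baseline"),
              sum(x$condition == "stimulation")))
  invisible(x)
}

#' Difference spectrum (stimulation minus baseline)
#'
#' Pointwise subtraction of the condition-averaged baseline spectrum from
#' the (line-matched) stimulation spectrum on a shared ppm grid. Fitting
#' the difference isolates metabolites that changed between conditions.
#'
#' @param stim_spec,base_spec `mrs_spectrum`s on identical grids; the
#'   stimulation spectrum should already be line-matched to baseline.
#' @return An `mrs_spectrum` holding the difference.
#' @export
difference_spectrum <- function(stim_spec, base_spec) {
  if (length(stim_spec$y) != length(base_spec$y) ||
      max(abs(stim_spec$ppm - base_spec$ppm)) > 1e-9)
    stop("spectra are on different ppm grids")
  out <- stim_spec
  out$y <- stim_spec$y - base_spec$y
  out
}

#' Percent glutamate change relative to the baseline mean
#'
#' `delta_i = 100 * (G_i - G_baseline) / G_baseline` per bin, with
#' `G_baseline` the mean over baseline-labelled bins; positive values are
#' increases. Optionally the first baseline block's bins are excluded from
#' the baseline mean (familiarization period).
#'
#' @param tc A [time_course()] of concentrations (I.U. or a.u.).
#' @param exclude_first_block Drop the leading run of baseline bins from
#'   the baseline mean (default FALSE).
#' @return A `time_course` in percent units, `baseline_mean` recorded.
#' @export
delta_glu_timecourse <- function(tc, exclude_first_block = FALSE) {
  base_idx <- which(tc$condition == "baseline")
  if (exclude_first_block && length(base_idx)) {
    first_run <- base_idx[cumsum(c(1, diff(base_idx)) != 1) == 0]
    base_idx <- setdiff(base_idx, first_run)
  }
  if (!length(base_idx)) stop("no baseline bins to define the reference")
  g0 <- mean(tc$values[base_idx])
  if (!is.finite(g0) || g0 <= 0)
    stop("baseline mean must be positive to express percent change")
  time_course(100 * (tc$values - g0) / g0, tc$bin_times, tc$condition,
              units = "percent", baseline_mean = g0)
}

#' Centered moving-average smoothing
#'
#' k-point centred mean with shrinking windows at the edges (the first and
#' last bins average over the available neighbours only).
#'
#' @param tc A [time_course()].
#' @param k Odd window length (default 3), smaller than the series.
#' @return The smoothed `time_course`.
#' @export
smooth_moving_average <- function(tc, k = 3) {
  n <- length(tc$values)
  if (k %% 2 != 1) stop("k must be odd")
  if (k >= n) stop("k must be smaller than the series length")
  half <- (k - 1) / 2
  sm <- vapply(seq_len(n), function(i) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    mean(tc$values[lo:hi])
  }, numeric(1))
  out <- tc
  out$values <- sm
  out
}

#' z-normalize a vector (mean 0, SD 1)
#' @param x Numeric vector with positive variance.
#' @return The normalized vector.
#' @export
z_normalize <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("cannot z-normalize a zero-variance series")
  (x - mean(x)) / s
}

#' Correlate a glutamate time course with the BOLD time course
#'
#' Pearson correlation over bins, two-sided p-value, with the BOLD series
#' z-normalized. The `drop_first_baseline` variant excludes the first
#' baseline block's bins (familiarization period).
#'
#' @param glu_tc,bold_tc [time_course()]s binned identically.
#' @param drop_first_baseline Exclude the leading run of baseline bins
#'   (default FALSE).
#' @return List: `r`, `p`, `df` (`n - 2`), `n`.
#' @export
correlate_with_bold <- function(glu_tc, bold_tc, drop_first_baseline = FALSE) {
  if (length(glu_tc$values) != length(bold_tc$values))
    stop("time courses must be binned identically")
  keep <- seq_along(glu_tc$values)
  if (drop_first_baseline) {
    base_idx <- which(glu_tc$condition == "baseline")
    first_run <- base_idx[cumsum(c(1, diff(base_idx)) != 1) == 0]
    keep <- setdiff(keep, first_run)
  }
  g <- glu_tc$values[keep]
  b <- z_normalize(bold_tc$values[keep])
  if (stats::sd(g) == 0) stop("zero-variance glutamate series")
  ct <- stats::cor.test(g, b, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value,
       df = length(g) - 2L, n = length(g))
}

#' Group condition contrast (stimulation minus baseline) per metabolite
#'
#' Takes per-subject condition concentration estimates and returns, for
#' each metabolite and correction variant, the mean difference, its
#' s.e.m., a one-sample t-test against zero (`df = n_subjects - 1`), the
#' percent change relative to the group-mean baseline level, and a
#' Holm-adjusted p-value column (the primary inference is uncorrected for
#' multiplicity; Holm is reported for transparency).
#'
#' @param estimates data.frame with columns `subject`, `metabolite`,
#'   `variant` (`"corrected"`/`"uncorrected"`), `baseline_iu`, `stim_iu`.
#' @return data.frame of class `group_stats` with one row per metabolite
#'   and variant.
#' @export
condition_contrast <- function(estimates) {
  req <- c("subject", "metabolite", "variant", "baseline_iu", "stim_iu")
  if (!all(req %in% names(estimates)))
    stop("estimates must have columns: ", paste(req, collapse = ", "))
  if (length(unique(estimates$subject)) < 2)
    stop("at least two subjects are required for a group contrast")
  out <- do.call(rbind, lapply(split(estimates,
                                     estimates[c("metabolite", "variant")],
                                     drop = TRUE), function(d) {
    delta <- d$stim_iu - d$baseline_iu
    n <- length(delta)
    m <- mean(delta); se <- stats::sd(delta) / sqrt(n)
    tt <- if (stats::sd(delta) > 0) stats::t.test(delta) else
      list(statistic = c(t = 0), p.value = 1)
    data.frame(metabolite = d$metabolite[1], variant = d$variant[1],
               n_subjects = n,
               delta_iu = m, sem_iu = se,
               delta_pct = 100 * m / mean(d$baseline_iu),
               sem_pct = 100 * se / mean(d$baseline_iu),
               t_stat = unname(tt$statistic), df = n - 1L,
               p = tt$p.value, row.names = NULL)
  }))
  out$p_holm <- NA_real_
  for (v in unique(out$variant)) {
    i <- out$variant == v
    out$p_holm[i] <- stats::p.adjust(out$p[i], method = "holm")
  }
  rownames(out) <- NULL
  class(out) <- c("group_stats", "data.frame")
  out
}

#' Sham analysis of resting-state data
#'
#' Runs the identical condition pipeline on resting-state datasets with the
#' task's block labels applied as if stimulation had been delivered; with a
#' condition-free truth the expected contrast is null. This is the
#' specificity control of the analysis.
#'
#' @param resting List of `subject_dataset`s simulated without any
#'   condition-dependent truth (see [ground_truth()] with
#'   `stim_glu_increase = 0` and equal line widths).
#' @param basis,config Passed to the fitting stage.
#' @return A `group_stats` data.frame (see [condition_contrast()]).
#' @export
sham_analysis <- function(resting, basis = build_default_basis(),
                          config = fit_config()) {
  res <- run_group_analysis(resting, basis = basis, config = config)
  res$contrasts
}
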