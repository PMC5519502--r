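# Spectrum construction and axis conventions.
#
# A resonance at chemical shift d (ppm) sits at frequency offset
# (d - reference_ppm) * spectrometer_freq Hz from the carrier. The displayed
# ppm axis increases with frequency; conventional plots draw it decreasing
# left to right.

#' Time axis of an FID
#'
#' @param params An [acquisition_params()].
#' @param n Number of points (default `params$n_points`).
#' @return Numeric vector of sample times in seconds starting at 0.
#' @export
time_axis <- function(params, n = params$n_points) {
  (seq_len(n) - 1) / params$spectral_width
}

# reorder an FFT so the zero-frequency bin sits at position n/2 + 1
fftshift_vec <- function(x) {
  n <- length(x)
  h <- n %/% 2
  x[c((h + 1L):n, 1L:h)]
}

#' Fourier transform an FID into a spectrum
#'
#' Applies an optional zero-fill, a discrete Fourier transform, and a
#' frequency shift so the carrier sits at the centre of the axis. The first
#' FID point is halved before transformation (standard trapezoid correction
#' for the one-sided sampling of the decay) so that flat baselines stay flat.
#'
#' @param fid Complex vector (time domain).
#' @param params An [acquisition_params()] describing `fid`.
#' @param zf Zero-filling factor (integer >= 1); the output grid has
#'   `zf * length(fid)` points.
#' @return An object of class `mrs_spectrum`: list with complex `y`, axes
#'   `hz` and `ppm`, and the originating `params`.
#' @export
fid_to_spectrum <- function(fid, params, zf = 1) {
  n0 <- length(fid)
  fid[1] <- fid[1] / 2
  n <- as.integer(n0 * zf)
  if (n > n0) fid <- c(fid, rep(0 + 0i, n - n0))
  y <- fftshift_vec(stats::fft(fid))
  df <- params$spectral_width / n
  hz <- (seq_len(n) - 1 - n %/% 2) * df
  structure(list(y = y,
                 hz = hz,
                 ppm = params$reference_ppm + hz / params$spectrometer_freq,
                 params = params, n_fid = n0, zf = zf),
            class = "mrs_spectrum")
}

#' @export
print.mrs_spectrum <- function(x, ...) {
  cat(sprintf("<mrs_spectrum> %d points, %.1f Hz width, %.2f-%.2f ppm\n",
              length(x$y), x$params$spectral_width,
              min(x$ppm), max(x$ppm)))
  invisible(x)
}

# indices of a ppm interval (inclusive)
ppm_indices <- function(spectrum, lo, hi) {
  which(spectrum$ppm >= lo & spectrum$ppm <= hi)
}

#' Measure the FWHM of the tallest peak in a ppm window
#'
#' Locates the maximum of the real part (or magnitude) inside the window and
#' finds the half-maximum crossings by linear interpolation. Used by tests
#' and the line-width diagnostics; the quantitative line-width estimate is
#' [fit_tcr_linewidth()].
#'
#' @param spectrum An `mrs_spectrum`.
#' @param lo,hi ppm window.
#' @param part `"real"` or `"mod"`.
#' @return FWHM in Hz.
#' @export
measure_fwhm <- function(spectrum, lo, hi, part = c("real", "mod")) {
  part <- match.arg(part)
  idx <- ppm_indices(spectrum, lo, hi)
  if (length(idx) < 5) stop("window too narrow for FWHM measurement")
  v <- if (part == "real") Re(spectrum$y[idx]) else Mod(spectrum$y[idx])
  hz <- spectrum$hz[idx]
  imax <- which.max(v)
  half <- v[imax] / 2
  left <- NA_real_; right <- NA_real_
  for (i in seq(imax, 2)) {
    if (v[i - 1] <= half) {
      left <- hz[i - 1] + (half - v[i - 1]) / (v[i] - v[i - 1]) * (hz[i] - hz[i - 1])
      break
    }
  }
  for (i in seq(imax, length(v) - 1)) {
    if (v[i + 1] <= half) {
      right <- hz[i] + (v[i] - half) / (v[i] - v[i + 1]) * (hz[i + 1] - hz[i])
      break
    }
  }
  if (is.na(left) || is.na(right))
    stop("half-maximum crossing outside the window")
  right - left
}
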