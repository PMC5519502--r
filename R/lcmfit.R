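# Linear-combination model (LCM) fitting of a preprocessed spectrum.
#
# The model for the real part of the phased spectrum over the fit range is
#   Re{ e^{i phi} ( S(v) - sum_m c_m B_m(v; delta, df) ) } - baseline(v)
# minimized over non-negative amplitudes c_m, one global extra Lorentzian
# broadening delta, one global frequency shift df, a zero-order phase phi,
# and polynomial baseline coefficients. The nonlinear triple (delta, df,
# phi) is searched by bounded quasi-Newton iterations from three
# deterministic starts; at every iterate the amplitudes are solved by
# non-negative linear least squares with the baseline projected out
# (variable projection), so the search space stays three-dimensional.

#' Fitting configuration
#'
#' @param fit_range ppm interval fitted (default `c(0.5, 4.2)`).
#' @param baseline_order Polynomial order of the baseline (default 4).
#' @param max_broadening Upper bound of the global extra Lorentzian
#'   broadening in Hz (default 15).
#' @param shift_bound Bound on the global frequency shift, Hz (default 4).
#' @param crlb_threshold Reliability threshold in percent (default 20; a
#'   metabolite is reliable iff its CRLB is strictly below the threshold).
#' @param nonneg Constrain amplitudes to be non-negative (default TRUE).
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(fit_range = c(0.5, 4.2), baseline_order = 4,
                       max_broadening = 15, shift_bound = 4,
                       crlb_threshold = 20, nonneg = TRUE) {
  if (crlb_threshold <= 0) stop("crlb_threshold must be > 0")
  if (max_broadening <= 0) stop("max_broadening must be > 0")
  if (diff(fit_range) <= 0) stop("fit_range must be an increasing interval")
  structure(list(fit_range = fit_range, baseline_order = baseline_order,
                 max_broadening = max_broadening, shift_bound = shift_bound,
                 crlb_threshold = crlb_threshold, nonneg = nonneg),
            class = "fit_config")
}

# prepare the fixed pieces of a fit: windowed data, basis FID matrix,
# unshifted fft row indices for the window, baseline QR
lcm_workspace <- function(spectrum, basis, config) {
  params <- spectrum$params
  if (spectrum$zf != 1)
    stop("fit_spectrum expects an unzero-filled spectrum (zf = 1)")
  idx <- ppm_indices(spectrum, config$fit_range[1], config$fit_range[2])
  if (length(idx) < 50) stop("fit range too narrow for the acquired grid")
  n <- length(spectrum$y)
  h <- n %/% 2
  ord <- c((h + 1L):n, 1L:h)        # unshifted index -> shifted position
  raw_idx <- ord[idx]               # rows of mvfft output for the window
  B <- basis_fid_matrix(basis, params)
  B[1, ] <- B[1, ] / 2              # same first-point convention as the data
  x <- seq(-1, 1, length.out = length(idx))
  P <- stats::poly(x, degree = config$baseline_order, raw = FALSE)
  P <- cbind(1, P)
  noise_idx <- ppm_indices(spectrum, 0.0, 0.4)
  list(params = params, idx = idx, raw_idx = raw_idx,
       t = time_axis(params), basis_fids = B, qrB = qr(P), P = P,
       S = spectrum$y[idx], noise = spectrum$y[noise_idx],
       mets = colnames(B))
}

# metabolite design matrix at a nonlinear iterate (real part, windowed)
lcm_design <- function(ws, delta, df, phi) {
  mod <- exp((-pi * delta + 1i * 2 * pi * df) * ws$t)
  spec <- stats::mvfft(ws$basis_fids * mod)[ws$raw_idx, , drop = FALSE]
  Re(exp(1i * phi) * spec)
}

lcm_solve <- function(ws, theta, config) {
  X <- lcm_design(ws, theta[1], theta[2], theta[3])
  y <- Re(exp(1i * theta[3]) * ws$S)
  yt <- qr.resid(ws$qrB, y)
  Xt <- qr.resid(ws$qrB, X)
  if (config$nonneg) {
    sol <- tryCatch(pracma::lsqnonneg(Xt, yt),
                    error = function(e) NULL)
    if (is.null(sol)) {
      co <- qr.coef(qr(Xt), yt); co[is.na(co) | co < 0] <- 0
      sol <- list(x = co)
    }
    coef <- sol$x
  } else {
    coef <- qr.coef(qr(Xt), yt)
    coef[is.na(coef)] <- 0
  }
  res <- yt - Xt %*% coef
  list(coef = as.numeric(coef), rss = sum(res^2), X = X, y = y)
}

#' Fit a spectrum with the linear-combination model
#'
#' @param spectrum An `mrs_spectrum` on the native grid (no zero-filling),
#'   normally from [fid_to_spectrum()] of a preprocessed, condition- or
#'   bin-combined FID.
#' @param basis A `basis_set`.
#' @param config A [fit_config()].
#' @return An object of class `fit_result`: `amplitudes` (named),
#'   `global_extra_fwhm` (Hz), `global_shift` (Hz), `zero_order_phase`
#'   (degrees), `baseline_coeffs`, `residual_rms`, `sigma` (noise SD of the
#'   real spectrum from the signal-free region), plus internal state used by
#'   [compute_crlb()]. `concentrations_iu`, `crlb_pct` and `reliable` are
#'   filled by [water_reference_scale()], [compute_crlb()] and
#'   [filter_reliable()].
#' @export
fit_spectrum <- function(spectrum, basis, config = fit_config()) {
  ws <- lcm_workspace(spectrum, basis, config)
  obj <- function(theta) lcm_solve(ws, theta, config)$rss
  lower <- c(0, -config$shift_bound, -pi)
  upper <- c(config$max_broadening, config$shift_bound, pi)
  starts <- list(c(1, 0, 0),
                 c(min(6, config$max_broadening - 0.5), 0, 0),
                 c(min(11, config$max_broadening - 0.5), 0, 0))
  best <- NULL
  diagnostics <- character()
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 200,
                                  parscale = c(1, 0.5, 0.1))),
      error = function(e) NULL)
    if (is.null(fit)) { diagnostics <- c(diagnostics, "optim error"); next }
    if (is.null(best) || fit$value < best$value - 1e-12 ||
        (abs(fit$value - best$value) <= 1e-12 && fit$par[1] < best$par[1]))
      best <- fit
  }
  if (is.null(best)) {
    e <- simpleError("linear-combination fit failed to converge")
    e$diagnostics <- diagnostics
    stop(e)
  }
  sol <- lcm_solve(ws, best$par, config)
  bl <- qr.coef(ws$qrB, sol$y - sol$X %*% sol$coef)
  amplitudes <- stats::setNames(sol$coef, ws$mets)
  fitted <- as.numeric(sol$X %*% sol$coef + ws$P %*% bl)
  # noise SD from the signal-free region, quadratically detrended so slow
  # Lorentzian tails do not inflate the estimate
  nr <- Re(exp(1i * best$par[3]) * ws$noise)
  xs <- seq_along(nr)
  sigma <- stats::sd(stats::lm.fit(cbind(1, xs, xs^2), nr)$residuals)
  structure(list(amplitudes = amplitudes,
                 concentrations_iu = NULL,
                 crlb_pct = NULL,
                 reliable = NULL,
                 global_extra_fwhm = best$par[1],
                 global_shift = best$par[2],
                 zero_order_phase = best$par[3] * 180 / pi,
                 baseline_coeffs = as.numeric(bl),
                 residual_rms = sqrt(sol$rss / length(sol$y)),
                 sigma = sigma,
                 fitted = fitted,
                 theta = best$par,
                 workspace = ws,
                 config = config),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>\n")
  cat(sprintf("  broadening %.2f Hz, shift %.2f Hz, phase %.1f deg, residual RMS %.3g\n",
              x$global_extra_fwhm, x$global_shift, x$zero_order_phase,
              x$residual_rms))
  tab <- data.frame(amplitude = round(x$amplitudes, 4))
  if (!is.null(x$concentrations_iu)) tab$iu <- round(x$concentrations_iu, 4)
  if (!is.null(x$crlb_pct)) tab$crlb_pct <- round(x$crlb_pct, 2)
  print(tab)
  invisible(x)
}

#' Cramer-Rao lower bounds of the fitted amplitudes
#'
#' Builds the Jacobian of the model with respect to every free parameter
#' (amplitudes, global broadening, shift, phase, baseline coefficients),
#' forms the Fisher matrix `F = J' J / sigma^2` with `sigma^2` estimated
#' from the residual variance in the signal-free 0.0-0.4 ppm region, and
#' reports `100 * sqrt(diag(F^-1))_m / c_m` per metabolite. A singular
#' Fisher matrix falls back to the pseudo-inverse with a warning and the
#' affected metabolites are flagged.
#'
#' @param fit A [fit_spectrum()] result.
#' @return The `fit_result` with `crlb_pct` (named percent vector, `Inf`
#'   for zero amplitudes) and `amp_covariance` (amplitude block of the
#'   inverse Fisher matrix) filled in.
#' @export
compute_crlb <- function(fit) {
  ws <- fit$workspace
  theta <- fit$theta
  X <- lcm_design(ws, theta[1], theta[2], theta[3])
  coef <- fit$amplitudes
  # numeric derivatives of the model vector wrt the nonlinear parameters
  dcol <- function(i, h) {
    tp <- theta; tm <- theta
    tp[i] <- tp[i] + h; tm[i] <- max(tm[i] - h, if (i == 1) 0 else -Inf)
    (lcm_design(ws, tp[1], tp[2], tp[3]) %*% coef -
       lcm_design(ws, tm[1], tm[2], tm[3]) %*% coef) / (tp[i] - tm[i])
  }
  J <- cbind(X,
             dcol(1, 1e-3), dcol(2, 1e-3), dcol(3, 1e-5),
             ws$P)
  sigma2 <- max(fit$sigma^2, .Machine$double.eps)
  Fm <- crossprod(J) / sigma2
  inv <- tryCatch(solve(Fm), error = function(e) NULL)
  singular <- is.null(inv)
  if (singular) {
    warning("singular Fisher matrix: using pseudo-inverse; affected metabolites flagged")
    inv <- pracma::pinv(Fm)
  }
  m <- length(coef)
  var_amp <- pmax(diag(inv)[seq_len(m)], 0)
  crlb <- 100 * sqrt(var_amp) / coef
  crlb[coef <= 0] <- Inf
  names(crlb) <- names(coef)
  fit$crlb_pct <- crlb
  fit$amp_covariance <- inv[seq_len(m), seq_len(m), drop = FALSE]
  dimnames(fit$amp_covariance) <- list(names(coef), names(coef))
  fit$fisher_singular <- singular
  fit
}

#' Scale fitted amplitudes to water-referenced institutional units
#'
#' `conc_IU[m] = k * (c_m / A_water) / (1 - csf_fraction)` where `A_water`
#' is the first-point magnitude of the unsuppressed water FID. Only the CSF
#' partial-volume correction is applied; no relaxation corrections, so the
#' units are institutional (consistent within an experiment, not absolute
#' molar values).
#'
#' @param fit A `fit_result`.
#' @param water Complex water-reference FID.
#' @param csf_fraction CSF fraction in `[0, 1)`.
#' @param k Scaling constant (default 1).
#' @return The `fit_result` with `concentrations_iu` filled in (CRLB
#'   percentages, being relative, carry over unchanged).
#' @export
water_reference_scale <- function(fit, water, csf_fraction, k = 1) {
  if (csf_fraction >= 1 || csf_fraction < 0)
    stop("csf_fraction must be in [0, 1)")
  a_water <- Mod(water[1])
  if (a_water <= 0) stop("water reference has zero first-point magnitude")
  fit$concentrations_iu <- k * (fit$amplitudes / a_water) / (1 - csf_fraction)
  fit
}

#' Add the summed metabolite pairs tCho and tCr
#'
#' Appends `tCho = GPC + PCho` and `tCr = PCr + Cr` to the amplitudes (and
#' institutional units when present). When the amplitude covariance from
#' [compute_crlb()] is available, the pair CRLB uses the summed-covariance
#' rule `var(a+b) = var(a) + var(b) + 2 cov(a, b)`, so anticorrelated
#' constituents (the usual case for overlapping pairs) yield a tighter
#' bound than either constituent alone.
#'
#' @param fit A `fit_result`.
#' @return The `fit_result` with pair entries appended.
#' @export
combine_pairs <- function(fit) {
  pairs <- list(tCho = c("GPC", "PCho"), tCr = c("PCr", "Cr"))
  for (p in names(pairs)) {
    parts <- pairs[[p]]
    if (!all(parts %in% names(fit$amplitudes))) {
      warning(sprintf("pair %s omitted: missing constituent", p))
      next
    }
    amp <- sum(fit$amplitudes[parts])
    fit$amplitudes[p] <- amp
    if (!is.null(fit$concentrations_iu))
      fit$concentrations_iu[p] <- sum(fit$concentrations_iu[parts])
    if (!is.null(fit$amp_covariance)) {
      v <- sum(fit$amp_covariance[parts, parts])
      fit$crlb_pct[p] <- if (amp > 0) 100 * sqrt(max(v, 0)) / amp else Inf
    }
  }
  fit
}

#' Group-level reliability report from CRLB values
#'
#' A metabolite is reliable iff its group-mean CRLB is strictly below the
#' threshold (a mean of exactly the threshold is unreliable). Unreliable
#' metabolites should be excluded from downstream statistics.
#'
#' @param results List of `fit_result`s with `crlb_pct` filled.
#' @param threshold Percent threshold (default 20).
#' @return data.frame with `metabolite`, `mean_crlb`, `reliable`.
#' @export
filter_reliable <- function(results, threshold = 20) {
  if (length(results) == 0)
    return(data.frame(metabolite = character(), mean_crlb = numeric(),
                      reliable = logical()))
  mets <- names(results[[1]]$crlb_pct)
  mean_crlb <- vapply(mets, function(m)
    mean(vapply(results, function(r) r$crlb_pct[[m]], numeric(1))),
    numeric(1))
  data.frame(metabolite = mets, mean_crlb = unname(mean_crlb),
             reliable = unname(mean_crlb) < threshold,
             row.names = NULL)
}
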