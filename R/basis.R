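# Metabolite basis: each metabolite is a small set of Lorentzian resonances
# (simplified multiplets with literature chemical shifts), plus broad
# macromolecule components. The same resonance table drives both the
# synthetic-data generator and the linear-combination fitting dictionary.

#' Build the default metabolite basis
#'
#' Returns the resonance table of the default panel. Each metabolite is
#' modelled as one or more Lorentzian lines; `weight` values within a
#' metabolite sum to 1, so the metabolite amplitude equals the summed line
#' area. Intrinsic (`base_fwhm`) widths are 2 Hz for metabolites and 40 Hz
#' for the three broad macromolecule components (MM09/MM12/MM17); in-vivo
#' widths arise from the additional global broadening applied at synthesis
#' or estimated at fitting time.
#'
#' Panel and positions (ppm):
#' \itemize{
#'  \item Glu 2.04/2.12/2.35/3.75; Gln 2.14/2.45/3.76; GABA 1.89/2.28/3.01
#'  \item sNAA singlet 2.01; mNAA 2.49/2.67
#'  \item Cr 3.030/3.913; PCr 3.029/3.930 (tCr singlet region 3.03)
#'  \item GPC 3.212/3.65; PCho 3.208/3.59; Ins 3.52/3.61/4.05
#'  \item GSH 2.55/2.95/3.77; Lac 1.31/4.10
#'  \item MM09 0.93; MM12 1.24; MM17 1.70 (FWHM 40 Hz)
#' }
#'
#' @param metabolites Optional character vector selecting a sub-panel; an
#'   empty selection is an error.
#' @return A `basis_set`: data.frame with columns `metabolite`, `ppm`,
#'   `weight`, `base_fwhm`.
#' @export
build_default_basis <- function(metabolites = NULL) {
  tab <- rbind(
    data.frame(metabolite = "Glu",
               ppm = c(2.04, 2.12, 2.35, 3.75),
               weight = c(0.25, 0.25, 0.30, 0.20), base_fwhm = 2),
    data.frame(metabolite = "Gln",
               ppm = c(2.14, 2.45, 3.76),
               weight = c(0.30, 0.35, 0.35), base_fwhm = 2),
    data.frame(metabolite = "GABA",
               ppm = c(1.89, 2.28, 3.01),
               weight = c(1, 1, 1) / 3, base_fwhm = 2),
    data.frame(metabolite = "sNAA", ppm = 2.01, weight = 1, base_fwhm = 2),
    data.frame(metabolite = "mNAA",
               ppm = c(2.49, 2.67), weight = c(0.5, 0.5), base_fwhm = 2),
    data.frame(metabolite = "Cr",
               ppm = c(3.030, 3.913), weight = c(0.6, 0.4), base_fwhm = 2),
    data.frame(metabolite = "PCr",
               ppm = c(3.029, 3.930), weight = c(0.6, 0.4), base_fwhm = 2),
    data.frame(metabolite = "GPC",
               ppm = c(3.212, 3.65), weight = c(0.7, 0.3), base_fwhm = 2),
    data.frame(metabolite = "PCho",
               ppm = c(3.208, 3.59), weight = c(0.7, 0.3), base_fwhm = 2),
    data.frame(metabolite = "Ins",
               ppm = c(3.52, 3.61, 4.05),
               weight = c(0.4, 0.3, 0.3), base_fwhm = 2),
    data.frame(metabolite = "GSH",
               ppm = c(2.55, 2.95, 3.77),
               weight = c(0.3, 0.4, 0.3), base_fwhm = 2),
    data.frame(metabolite = "Lac",
               ppm = c(1.31, 4.10), weight = c(0.7, 0.3), base_fwhm = 2),
    data.frame(metabolite = "MM09", ppm = 0.93, weight = 1, base_fwhm = 40),
    data.frame(metabolite = "MM12", ppm = 1.24, weight = 1, base_fwhm = 40),
    data.frame(metabolite = "MM17", ppm = 1.70, weight = 1, base_fwhm = 40)
  )
  if (!is.null(metabolites)) {
    if (length(metabolites) == 0)
      stop("empty metabolite selection: the basis may not be empty")
    missing <- setdiff(metabolites, unique(tab$metabolite))
    if (length(missing))
      stop("unknown metabolite(s): ", paste(missing, collapse = ", "))
    tab <- tab[tab$metabolite %in% metabolites, , drop = FALSE]
  }
  rownames(tab) <- NULL
  structure(tab, class = c("basis_set", "data.frame"))
}

#' Metabolite names in a basis
#' @param basis A `basis_set`.
#' @return Character vector in order of first appearance.
#' @export
basis_metabolites <- function(basis) unique(basis$metabolite)

#' Synthesize a free induction decay from Lorentzian resonances
#'
#' Forward model shared by the generator and the fitting dictionary:
#' `FID(t) = sum_r c_r * w_r * exp(i*2*pi*f_r*t - pi*(base_fwhm_r + fwhm)*t)`
#' where `f_r` is the resonance offset from the carrier and `fwhm` is a
#' global additional Lorentzian broadening. A resonance with zero intrinsic
#' width synthesized with broadening `fwhm` shows a spectral FWHM of `fwhm`.
#'
#' @param resonances A `basis_set` (or any data.frame with columns
#'   `metabolite`, `ppm`, `weight`, `base_fwhm`).
#' @param concentrations Named numeric vector, metabolite -> amplitude;
#'   metabolites absent from the vector contribute nothing.
#' @param fwhm Additional global Lorentzian broadening in Hz (>= 0).
#' @param params An [acquisition_params()].
#' @return Complex vector of length `params$n_points`.
#' @export
synthesize_fid <- function(resonances, concentrations, fwhm, params) {
  if (fwhm < 0) stop("fwhm must be >= 0")
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  t <- time_axis(params)
  fid <- rep(0 + 0i, params$n_points)
  conc <- concentrations[match(resonances$metabolite, names(concentrations))]
  conc[is.na(conc)] <- 0
  for (r in seq_len(nrow(resonances))) {
    c_r <- conc[r] * resonances$weight[r]
    if (c_r == 0) next
    f_r <- (resonances$ppm[r] - params$reference_ppm) * params$spectrometer_freq
    fid <- fid + c_r * exp((1i * 2 * pi * f_r -
                              pi * (resonances$base_fwhm[r] + fwhm)) * t)
  }
  fid
}

# time-domain basis matrix (n_points x n_metabolites), unit amplitude,
# intrinsic widths only
basis_fid_matrix <- function(basis, params) {
  mets <- basis_metabolites(basis)
  out <- matrix(0 + 0i, params$n_points, length(mets),
                dimnames = list(NULL, mets))
  for (m in mets) {
    cc <- stats::setNames(1, m)
    out[, m] <- synthesize_fid(basis[basis$metabolite == m, , drop = FALSE],
                               cc, 0, params)
  }
  out
}
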