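---
title: "Methods: simulating and analysing combined fMRI-MRS glutamate experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing combined fMRI-MRS glutamate experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Functional MRS (fMRS) tracks task-driven changes in brain metabolites —
above all glutamate — by acquiring proton spectra continuously while a
stimulus alternates with rest. When the spectroscopy voxel is
simultaneously imaged with BOLD-fMRI, two confounded effects appear in the
spectra during activation: a genuine metabolic change (of order 2 % for
glutamate during visual stimulation at 7 T) and a purely physical
BOLD effect — the T2* lengthening that accompanies activation narrows
every spectral line by about 2 %. Left uncorrected, line narrowing
masquerades as a concentration increase. `fmrsglu` implements the full
analysis chain for such experiments, and a synthetic-data generator whose
defaults encode the study conditions the package emulates, so that every
stage is testable without access to scanner data.

## The data model

Each subject contributes `n_averages = 128` complex free induction decays
(FIDs), one per TR of 4 s, over four 64-s baseline / 64-s stimulation
cycles; an unsuppressed water reference FID from the same voxel; an
ROI-mean BOLD series sampled once per TR; and a CSF fraction. The
spectrometer frequency is fixed at 297.2 MHz (a 7 T proton system) with a
6000 Hz spectral width over 2048 complex points — enough to resolve
0.1-ppm-spaced peaks. The carrier sits on water at 4.70 ppm and the ppm
axis increases with frequency offset.

Every metabolite is modelled as a small set of Lorentzian resonances with
literature chemical shifts (simplified multiplets, documented in
`build_default_basis()`), with 2 Hz intrinsic width, plus three broad
(40 Hz) macromolecule components. This deliberately preserves the
structure of the fitting problem — the Glu/Gln/NAA multiplet overlap
around 2.0-2.5 ppm, the Cr/PCr and GPC/PCho near-degeneracies — at desk
scale; it does not reproduce J-evolution or density-matrix lineshapes,
which is why absolute fit quality on real semi-LASER data cannot be
inferred from these simulations.

### What the generator injects

`simulate_subject()` builds per-TR FIDs in which

* glutamate is elevated by `stim_glu_increase` (default **1.92 %**) during
  stimulation TRs;
* *all* resonances carry the condition's global line width — the tCr
  singlet reads `baseline_tcr_fwhm = 9.72` Hz at rest and
  `stim_tcr_fwhm = 9.51` Hz during stimulation (a global T2* effect);
* the BOLD T2* change also modulates the echo amplitude by
  `exp(pi * (fwhm_base - fwhm_cond) * TE)` (about +2.4 % at TE = 36 ms
  for a 0.21 Hz narrowing). This is the package's model of why line
  narrowing produces an *apparent* concentration increase: with a purely
  width-changing model, a linear-combination fit with a free broadening
  parameter estimates line integrals and would be unbiased, and the
  line-broadening correction would have nothing to correct. The
  echo-amplitude term makes the confound real, and the matching
  correction (below) removes it;
* nuisance processes: cumulative frequency drift (0.03 Hz/TR), per-TR
  zero-order phase jitter (SD 5 deg), an eddy-current phase
  `0.5 * exp(-t/50 ms) * sin(2 pi 20 t)` shared with the water reference,
  and complex white noise.

The noise SD (3500 a.u.) is calibrated so a single-TR spectrum has an
NAA-singlet SNR near 10, which puts the Cramer-Rao lower bound (CRLB) of
glutamate on a 4-average spectrum near 8-9 % — the regime of short-TE
7 T fMRS. Metabolite amplitudes are `conc_IU * (1 - csf) * water_amplitude`
so water referencing returns institutional units (I.U.) directly; the
glutamate baseline of 7.8125 I.U. makes a 1.92 % increase equal 0.15 I.U.

Between-subject truth perturbations default to zero: at this SNR the
measurement noise alone reproduces across-subject spreads of the size
seen in group fMRS studies (width SDs of a few tenths of a Hz, percent-change
s.e.m. near 0.7 %), so the group values are used as exact per-subject truth
and all variability is attributed to noise. `simulate_group()` accepts
perturbation SDs where biological heterogeneity is wanted.

The BOLD series is a stimulation boxcar convolved with the canonical
double-gamma HRF (kernel support 0-32 s, unit sum, so the within-block
plateau equals the requested percent signal change, default **1.43 %**),
over a baseline of 100, with 0.5 % white noise per TR. The nominal run is
128 TR x 4 s = 512 s; descriptions of such protocols sometimes quote
slightly shorter wall-clock durations, and the simulator always uses the
TR arithmetic.

## Preprocessing

1. **Eddy-current correction** (Klose): multiply each FID by
   `exp(-i arg(water(t)))`. Unit-modulus, so magnitude spectra are
   untouched; exact when metabolite and water FIDs share the distortion.
2. **Frequency alignment** to the NAA singlet at 2.01 ppm: per-TR shifts
   by cross-correlating the windowed (±0.15 ppm) magnitude spectrum
   against the series mean, with parabolic peak interpolation, applied as
   time-domain phase ramps. Two estimation passes are used — after the
   first pass the template is recomputed from the partially aligned
   series, which matters when drift has smeared the raw mean. TRs whose
   windowed peak is below 3x the noise are flagged and imputed from
   neighbours. Absolute registration has a caveat: on a multi-resonance
   spectrum, complex interference displaces the magnitude peak by a few
   tenths of a Hz, so a common sub-resolution shift remains; the fit's
   global shift parameter absorbs it. Alignment precision is therefore
   quoted *relative* (injected shifts are recovered to 0.3 Hz).
3. **Phase correction**: per-TR zero-order phase minimizing
   `||exp(i phi) s - ref||^2` over 1.8-3.5 ppm, solved in closed form as
   `phi = -arg(<s, ref>)`. A real-part-only criterion was considered and
   rejected: its per-TR phase noise (~3.3 deg at this SNR) exceeds the
   2 deg spread the pipeline budgets for; the complex criterion is the
   matched-filter (maximum-likelihood) estimator and achieves ~1.7 deg.

Two data-reduction paths follow, matching how such experiments are
analysed:

* **condition path** — `reduce_block_data()` drops the first 2 TRs of
  every block (the hemodynamic transition; 12.5 % of the data, leaving
  14 averages per block and 56 per condition), then the retained TRs are
  averaged per condition;
* **time-course path** — all 128 TRs are summed in non-overlapping groups
  of 4 (`bin_averages()`), giving 32 points at 16-s resolution. The
  2-TR exclusion is *not* applied here, because 32 points require all
  128 averages; both behaviours are available.

Every correction sets a provenance flag and refuses to run twice.

## Linear-combination fitting

`fit_spectrum()` minimizes, over the real part of the phased spectrum in
0.5-4.2 ppm,

```
|| Re{ e^{i phi} (S(v) - sum_m c_m B_m(v; delta, df)) } - baseline(v) ||^2
```

with non-negative amplitudes `c_m`, one global extra Lorentzian broadening
`delta` in [0, 15] Hz, one global shift `df` in ±4 Hz, a zero-order phase
`phi`, and a polynomial baseline (order 4 — a deliberate, swappable
simplification of spline regularization). The nonlinear triple is searched
by bounded quasi-Newton iterations from three deterministic starts
(`delta` = 1, 6, 11 Hz; ties broken by residual, then smaller `delta`);
at each iterate the amplitudes are solved by non-negative least squares
with the baseline projected out (variable projection), keeping the search
three-dimensional. On noiseless data generated from the basis itself the
fit recovers amplitudes to better than 0.1 %.

**CRLBs** come from the Fisher matrix `J'J / sigma^2` over all free
parameters, with `sigma` estimated in the signal-free 0.0-0.4 ppm region
after quadratic detrending (so slow Lorentzian tails do not inflate it),
reported as percent of each amplitude. Monte-Carlo spreads of the
glutamate amplitude agree with the mean reported CRLB within the
0.7-1.5x band. Metabolites are *reliable* iff CRLB < 20 % (strict); at the
default conditions the GPC/PCho constituents are individually unreliable
(as their overlap dictates) while their sum tCho, and tCr, are tight —
the summed-covariance rule credits the anticorrelation of overlapping
pairs.

**Institutional units**: `conc = k (c_m / A_water) / (1 - csf)` with
`k = 1` and `A_water` the water FID's first-point magnitude. No
T1/T2-relaxation or tissue-composition corrections are applied, so the
units are internally consistent but not molar; only differences and
ratios are interpreted.

## BOLD line-narrowing estimation and correction

Under the assumption that total creatine is metabolically stable during
activation, the width change of its 3.03-ppm singlet measures the BOLD
T2* effect. `fit_tcr_linewidth()` fits one absorptive Lorentzian plus a
linear local baseline in a ±0.1 ppm window. The GABA resonance 0.02 ppm
away contributes a small shoulder that biases the absolute width by about
+0.1 Hz in *both* conditions; the bias cancels almost exactly in the
narrowing percentage. At the default SNR the per-subject width precision
is ~0.25 Hz — close to the information bound for a 9.7-Hz line at this
peak SNR and grid — which makes the narrowing percentage the noisiest
primitive of the pipeline (per-subject SD near 3.5 points).

`match_linewidth()` broadens each subject's stimulation-period FID to its
baseline width by exponential apodization `exp(-pi dFWHM (t + TE))`. The
`TE` term extrapolates the apodization back to the echo and thereby
reverses the echo-amplitude modulation the generator attributes to the
T2* change; with `te = 0` the function is the classical width-matching
apodization. Broadening is one-directional: requests to *narrow* a
measured spectrum are refused. Whether broadening precedes water
referencing is immaterial here (the water scaling is width-independent);
the pipeline broadens before fitting and records the order.

## Statistics

* **Condition contrast**: per-subject stimulation minus baseline I.U. per
  metabolite, one-sample t against zero (`df = n - 1`), reported for both
  the corrected and uncorrected variants; percent changes are relative to
  the group-mean baseline. No multiplicity correction is applied to the
  primary p-values (one focused hypothesis per metabolite); a
  Holm-adjusted column is emitted alongside.
* **Difference spectrum**: line-matched stimulation minus baseline on a
  shared grid; with a pure glutamate change the absorption-mode energy
  concentrates in 2.0-2.5 and 3.7-3.8 ppm (dispersion tails decay only as
  1/df, so this statement is about the real part).
* **Time course**: per-bin glutamate from the 32-bin path,
  `delta_i = 100 (G_i - G_base) / G_base` against the mean of
  baseline-labelled bins (optionally excluding the first, familiarization,
  block), 3-point centred moving average with shrinking edges, then
  Pearson correlation against the identically binned, z-normalized BOLD
  series. Correlation degrees of freedom are reported as `n - 2`.
* **Sham analysis**: the identical pipeline applied to resting-state
  simulations with the task's labels; the expected null contrast is the
  specificity control.

## Numerical choices and problem sizes

Spectra are transformed with a half-first-point convention (flat
baselines stay flat); width measurements use 4x zero-filling; the LCM fit
runs on the native grid. Seeds are mandatory everywhere randomness
enters, and subject seeds derive deterministically from a master seed, so
every experiment is bit-reproducible.

The test-suite problem sizes were chosen so the whole suite exercises
13-subject groups where a group-level claim is asserted and smaller
simulations elsewhere. Because the group-mean recoveries are stochastic
with an s.e.m. comparable to the asserted bands at n = 13 (that is the
regime the conditions imply), the acceptance checks average several
independent replicate experiments (6 in the tests, 8 in
`scripts/acceptance.R`) rather than enlarging any single experiment;
per-experiment size stays at 13 subjects.

A consequence of the one-directional correction deserves note: the
applied broadening is `max(fwhm_base_hat - fwhm_stim_hat, 0)`, and with a
per-subject width-difference noise of ~0.36 Hz on a true difference of
0.21 Hz the clip engages in roughly a third of subjects. This raises the
*mean* applied broadening above the true narrowing and biases the
group-mean corrected glutamate change downward by roughly half a
percentage point at the default conditions (recovered ≈1.4-1.5 % for a
true 1.92 %), while the narrowing percentage itself reads ≈1.8 % for a
true 2.16 %. Both recoveries remain comfortably inside the uncertainty a
13-subject experiment carries; a two-directional correction would remove
the clip bias but is refused deliberately, since "narrowing" a measured
spectrum amplifies noise and has no physical counterpart.

## Known limitations

* Lorentzian-only lineshapes (no Gaussian/Voigt component, no
  density-matrix multiplets); macromolecules are three broad Lorentzians,
  not measured inversion-recovery spectra.
* The echo-amplitude BOLD model is the package's own minimal mechanism
  linking narrowing to apparent concentration changes; real sequences
  refocus part of the static dephasing, so the in-vivo effect size need
  not equal `exp(pi dFWHM TE)`.
* Absolute I.U. values are not comparable across implementations with
  different water-scaling constants; only within-experiment contrasts
  are meaningful.
* No physiological noise (cardiac/respiratory), no motion, no voxelwise
  fMRI modelling — the BOLD series stands in for an ROI mean extracted
  elsewhere.
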