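# fmrsglu

Simulation and analysis of **combined fMRI-MRS** experiments: block-design
studies in which proton MR spectra and a BOLD-fMRI signal are acquired
concurrently from the same voxel, and the question is whether — and by how
much — **glutamate** rises during stimulation once the BOLD line-narrowing
confound is removed.

The package is aimed at spectroscopists and methods researchers who want a
fully testable, scanner-free implementation of the analysis chain used in
short-TE 7 T functional MRS:

1. **Synthetic data** (`simulate_subject()`, `simulate_group()`,
   `simulate_bold()`): per-TR complex FIDs over four 64-s baseline /
   stimulation cycles (TR 4 s, 128 averages) with a simplified Lorentzian
   metabolite basis, macromolecule background, frequency drift, phase
   jitter, eddy-current phase, thermal noise, a water reference, and an
   HRF-convolved BOLD series.
2. **Preprocessing** (`eddy_current_correct()`, `align_frequency()`,
   `phase_correct()`, `reduce_block_data()`, `bin_averages()`).
3. **Linear-combination fitting** (`fit_spectrum()`, `compute_crlb()`,
   `water_reference_scale()`, `combine_pairs()`, `filter_reliable()`):
   non-negative metabolite amplitudes with a common Lorentzian broadening,
   shift, phase and polynomial baseline; Cramér-Rao lower bounds from the
   Fisher matrix; water-referenced institutional units (I.U.) with CSF
   correction; tCho/tCr pairing; CRLB < 20 % reliability rule.
4. **BOLD correction** (`fit_tcr_linewidth()`, `narrowing_percent()`,
   `match_linewidth()`): the tCr singlet at 3.03 ppm measures the
   BOLD-induced line narrowing (9.72 → 9.51 Hz, ≈2 %), and
   stimulation-period FIDs are broadened back to the baseline width.
5. **Statistics** (`condition_contrast()`, `difference_spectrum()`,
   `delta_glu_timecourse()`, `smooth_moving_average()`,
   `correlate_with_bold()`, `sham_analysis()`).

The core scientific quantity is the condition contrast

```
ΔGlu = Glu_stim − Glu_base   (I.U.),    ΔGlu% = 100 · (G_i − G_base) / G_base
```

estimated per subject from condition-averaged spectra (or per 16-s bin for
the time course), with and without the line-narrowing correction, and
tested against zero across subjects.

## Worked example

```r
library(fmrsglu)

params <- acquisition_params()       # 297.2 MHz, 6000 Hz / 2048 pts, TR 4 s, TE 36 ms
design <- block_design()             # 64-s blocks, 4 cycles, discard 2 TRs/block
truth  <- ground_truth()             # +1.92 % Glu, 9.72/9.51 Hz, 1.43 % BOLD, CSF 8.16 %

group <- simulate_group(13, params, design, truth, seed = 1)
res   <- run_group_analysis(group)

subset(res$contrasts, metabolite == "Glu")
colMeans(res$linewidths[, 2:4])
```

which prints (seed 1):

```
   metabolite     variant n_subjects  delta_iu     sem_iu delta_pct   sem_pct
4         Glu   corrected         13 0.1108720 0.06786748  1.408845 0.8623888
21        Glu uncorrected         13 0.2603209 0.07169792  3.307886 0.9110621
     t_stat df           p     p_holm
4  1.633654 12 0.128275435 1.00000000
21 3.630802 12 0.003445653 0.05513045
baseline_fwhm     stim_fwhm narrowing_pct
     9.892132      9.783845      1.078303
```

Reading this: the **uncorrected** contrast (+3.3 %) overstates the true
+1.92 % glutamate increase because the BOLD effect inflates
stimulation-period amplitudes; after subject-specific line broadening the
**corrected** estimate (+1.41 ± 0.86 %) is consistent with the simulated
truth. The tCr line-width fits carry a ~+0.15 Hz upward bias in both
conditions (the GABA shoulder next to the 3.03-ppm singlet) that cancels
in the narrowing percentage, and a single 13-subject experiment measures
the ≈2 % narrowing with an s.e.m. of about one percentage point — which
is why the acceptance script averages replicate experiments.

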