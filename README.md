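# metapanel

An R implementation of the complete analysis path of a multiplexed
colorimetric metabolite panel read out by a CMOS photodiode array — the kind
of lab-on-chip platform that measures a small panel of plasma metabolites
(total L-amino acids, glutamate, choline, sarcosine) with oxidase/peroxidase
Trinder-type assays and uses the panel as a prostate-cancer (PCa) biomarker
signature.

The physical instrument and the clinical plasma samples are replaced by a
seeded simulator; everything downstream of the photodiodes is implemented as
reusable, tested functions:

1. **Synthetic data** — frame stacks from a 16 x 16 photodiode array
   (~36.5 fps, 12-bit ADC over 3.3 V): Michaelis–Menten product formation per
   microfluidic channel, Beer–Lambert absorbance in the channel, baseline
   drift, read noise, dead sensors, a shared nonspecific sample background,
   plus calibration series and clinical-style cohorts.
2. **Signal processing** — per-sensor zero-phase Butterworth low-pass
   (normalized cutoff 0.1, order 8), bad-sensor exclusion, spatial averaging
   (48 sensors/channel), 1-s temporal binning, a double-exponential fit
   `y(t) = y0 + a1(1 − e^(−k1 t)) + a2(1 − e^(−k2 t))`, and the initial
   reaction rate as the analytic derivative at t = 0.
3. **Calibration** — nonlinear least squares for
   `y = V_max x / (K_m + x) + c`, linear fits `Y = S·x + C`, the R² > 0.9
   prefix rule for the linear range, and IUPAC detection limits
   `LOD = µ_c + 3.3 δ_c`, `LOQ = µ_c + 10 δ_c` converted to µM through the
   Michaelis–Menten curve.
4. **Quantification** — standard addition with two spikes [A] < [B] on top of
   the sample: background correction `r_t* = r_t − r_n`, the sensitivity
   secants `S′ = (r_b − r_a)/([B] − [A])`, `S″ = (r_b − r_t)/[B]`,
   `S‴ = (r_a − r_t)/[A]`, and `[T] = r_t*/mean(S′, S″, S‴)`.
5. **Classification** — cohort univariate statistics (group ratios, Welch
   t-tests, cross-correlations) and a random-forest panel classifier
   (500 trees, ≤3 features per split) validated by stratified tenfold
   cross-validation repeated 100 times, with pooled ROC, percentile and
   bootstrap AUC confidence intervals, and a Youden operating point compared
   against the PSA literature reference (sens 0.32, spec 0.87, AUC 0.68).

A command-line interface (`panel_cli()`, installed script in `exec/`) chains
the stages through documented CSV/JSON formats with per-artifact manifests.

## Worked example

```r
library(metapanel)

# detection limits for the choline assay, from the negative-control
# statistics (5.0 ± 2.7 µV/s) and the published calibration
detection_limits(negative_control_defaults(), panel_mm_params("choline"))
#> LOD: 0.014 mV/s = 1.7 uM; LOQ: 0.032 mV/s = 3.9 uM

# one full simulated sample: a 4-channel cartridge (negative control, test,
# and two spiked positive controls), processed frame stack -> rates -> [T]
run <- simulate_sample_run("choline", true_conc = 12, seed = 7,
                           duration = 120, model = "linear")
quantify_sample_run(run)
#> standard addition: r_t* = 0.1269 mV/s, S = 0.009891 mV/s/uM, [T] = 12.83 uM

# a synthetic 26-sample cohort with the published group statistics,
# univariate screen and cross-validated random-forest classifier
co <- simulate_cohort(seed = 1)
rep <- crossval_rf(co, classifier_config(n_trees = 100, repeats = 10, seed = 1))
rep
#> repeated 10-fold CV x 10: mean AUC 0.875 (95% CI 0.84-0.90), pooled AUC 0.876
operating_point(rep)[c("sensitivity", "specificity")]
#> $sensitivity [1] 0.92;  $specificity [1] 0.70
```

The detection limits reproduce the platform characterization (LOD 1.7 µM,
LOQ 3.9 µM for choline); the quantification recovers the true 12 µM within
the platform's replicate variability; the classifier AUC on a synthetic
cohort falls in the regime reported for the real 26-sample study (AUC 0.78,
95% CI 0.55–0.99 — a synthetic cohort is easier than the real one because
concentrations are drawn exactly from the group distributions).

## Notes

- The double-exponential is accepted over a straight-line fit only when a
  nested-model F-test supports it; on flat (control/drift) channels the
  reported rate is the fitted linear slope, which keeps control rates
  unbiased.
- With rates that follow the saturating Michaelis–Menten calibration exactly,
  the standard-addition estimator has an intrinsic positive linearization
  bias that grows with [T]/K_m and spike size; see the methods vignette for
  the quantitative analysis and what the tests do and do not establish.
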