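---
title: "Models and methods behind metapanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind metapanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metapanel)
```

# The measurement being modeled

The platform measures a panel of plasma metabolites — total L-amino acids
(LAA), glutamate, choline and sarcosine — with two-stage enzymatic
colorimetric assays. A substrate-specific oxidase converts the metabolite and
produces hydrogen peroxide; horseradish peroxidase then drives a Trinder-type
reaction (phenol + 4-aminoantipyrine) whose quinone imine product absorbs
light. The sample is split into four microfluidic channels over a 16 x 16
CMOS photodiode array illuminated by an LED: as chromophore accumulates,
transmitted light and hence photodiode voltage fall. The assay's primary
observable is the *initial reaction rate* — the voltage slope at reaction
start, in mV/s — which the Michaelis-Menten law ties to the metabolite
concentration.

Everything in this package operates on that chain. The simulator generates
what the instrument would record; the signal-processing, calibration,
quantification and classification stages reproduce the published analysis on
either simulated or imported data.

# The kinetic and photometric model

Channel kinetics are an effective single-substrate Michaelis-Menten process:

$$\frac{dS}{dt} = -\,v(S), \qquad \frac{dP}{dt} = y \, v(S), \qquad
  v(S) = \frac{V_{\max}^{\mathrm{eff}} S}{K_m^{\mathrm{eff}} + S},$$

with stoichiometric yield $y$ (default 0.5 uM quinone imine per uM substrate:
two H2O2 per dye molecule in the Trinder reaction; the value only rescales
the optical gain). `simulate_progress()` integrates this with fixed-step RK4
and keeps mass balance exactly, because $P$ is computed from the integrated
substrate. The photodiode voltage follows the Beer-Lambert law,

$$V(t) = i_{\mathrm{dark}} + (i_{\mathrm{illum}} - i_{\mathrm{dark}})\,
         10^{-\kappa P(t)},$$

with the characterized steady states $i_{\mathrm{dark}} = 0.486$ V and
$i_{\mathrm{illum}} = 1.730$ V and an effective absorptivity-times-path
$\kappa$ (default $10^{-4}$ per uM, chosen so that full conversion of an
upper-linear-range sample changes the voltage by a few hundred mV without
saturating the optical response).

`panel_kinetics()` ties the simulation to the published calibration: with
`model = "mm"` the chemical $V_{\max}^{\mathrm{eff}}$ is chosen so that the
*voltage-domain* initial rate at substrate concentration $x$ equals
$V_{\max} x / (K_m + x)$ with the tabulated per-metabolite parameters
(LAA 3.63 mV/s and 2866 uM; glutamate 5.28 and 529.7; choline 11.34 and 1382;
sarcosine 11.03 and 1209). The calibration offset $c$ is treated as a fit
artifact, not a physical rate, so the generator omits it. With
`model = "linear"` the kinetics are exactly first order with voltage-rate
slope equal to the tabulated linear sensitivity — the platform operating
strictly inside its linear range. Keeping both worlds available matters for
validation, as discussed under *Standard addition and its bias* below.

# The sensor model

`sensor_model()` carries the acquisition parameters, all with characterized
defaults: 16 x 16 sensors at 36.5 frames/s (the documented ~10,950 frames in
a 5-minute run; an alternative body-text figure of 36 fps is not used),
12-bit ADC over 3.3 V (LSB 0.81 mV), illuminated/dark baseline drift of
0.9/1.4 uV/s, and a 2% rate of unresponsive sensors (frozen at their initial
value or railed), a fraction the published processing mentions excluding
without counting. Per-frame read noise defaults to 1.5 mV: about two ADC
steps, enough to dither quantization so that 1-s binning and 48-sensor
averaging resolve the microvolt-per-second rates the platform reports.

Two modeling choices are deliberate:

* **A shared nonspecific background.** Each sample has nonspecific activity;
  the published correction $r_t^* = r_t - r_n$ subtracts the negative-control
  channel's rate from the test channel's. For that subtraction to mean
  anything in simulation, the background must be *common* to the cartridge:
  one rate is drawn per run from the negative-control statistics (5.0 +/- 2.7
  uV/s liquid; 23.0 +/- 12.5 uV/s in dried-reagent mode) and applied to all
  four channels; the control channel shows only this background. Extracted
  control rates across runs then reproduce the control statistics, and the
  background cancellation in the quantification formulas is exact by
  construction, as in the published design where the spiked-rate differences
  cancel $r_n$ automatically.
* **Dried-reagent mode** is represented only by its quantitative signatures:
  rescaled sensitivities, its own replicate SDs, and the elevated control
  statistics. No spatial reagent-distribution model is attempted; nothing
  in the published characterization constrains one.

# Signal processing

`extract_rate()` follows the published chain exactly: per-sensor zero-phase
low-pass filter (8th-order Butterworth, normalized cutoff 0.1 — interpreted,
as is standard, as a fraction of Nyquist, applied forward-backward),
bad-sensor exclusion, spatial average over the channel's live sensors
(48 by default), nonoverlapping 1-s temporal binning, and a least-squares fit
of the double-exponential progress model

$$y(t) = y_0 + a_1 (1 - e^{-k_1 t}) + a_2 (1 - e^{-k_2 t}),$$

whose analytic derivative at $t = 0$, $|a_1 k_1 + a_2 k_2|$, is the reported
rate. The published account says the progress curve was "fitted using a
double exponential" without writing the formula; this form is the integrated
first-order limit of the Michaelis-Menten stage plus a second relaxation for
the slower enzymatic step, and it makes "differentiation of the measured
signal" well defined and noise-free. Whether the original fit was done in
voltage or absorbance space is not stated; this package fits in voltage
space, where the noise is white.

Numerical choices worth knowing:

* **Filter order of operations.** Filtering before spatial averaging matches
  the published wording; both stages are linear, so the order does not change
  the result — only the cost.
* **Bin timestamps stay on the acquisition clock.** Binned points sit at
  window midpoints (0.5 s, 1.5 s, ...), and the fit evaluates its derivative
  at the true $t = 0$, not at the first bin. Shifting the time origin to the
  first bin biases every rate low by $e^{-k/2}$ — several percent for fast
  assays — which is easy to introduce and invisible in ratio-based
  quantification (it cancels), but wrong in rate units.
* **Fit initialization and multi-start.** $a_1$ starts at the total signal
  excursion, $k_1$ at a log-linear fit of the early approach, $a_2 = a_1/10$,
  $k_2 = k_1/10$; up to two further perturbed starts are tried. The port
  solver frequently stops with "singular convergence" on this weakly
  identifiable model at a numerically excellent optimum, so candidates are
  ranked by residual RMSE rather than by convergence code.
* **Model selection against noise-chasing.** An unconstrained double
  exponential fitted to a *flat* trace will happily explain the first noisy
  bin with a fast component whose $t = 0$ derivative is enormous. The
  exponential fit is therefore accepted over a straight line only when a
  nested-model F-test (3 extra parameters, p < 0.01) supports it; otherwise
  the rate is the fitted linear slope. This is what makes negative-control
  and drift-only channels report their true uV/s-scale rates. Rate constants
  are additionally capped at 2 s^-1: with 1-s bins, faster components are
  unresolvable and only ever fit noise.
* **Bad sensors and anomalies.** Sensors are excluded if their level leaves
  [0.05, 0.97] of full scale, if they are frozen relative to channel peers,
  or if their fitted slope is a MAD-based robust outlier (|z| > 3.5) among
  channel peers; a channel whose level screen fires for *every* sensor is a
  common-mode condition (e.g. a dark acquisition), not a sensor failure, and
  is kept. Channels whose fit RMSE exceeds 5x the median channel RMSE (with
  a 0.05 mV floor so that numerically perfect channels do not flag their
  siblings) are marked anomalous — the air-bubble/fluidic-failure case — and
  excluded from replicate averaging.

# Calibration and detection limits

`fit_mm()` is bounded nonlinear least squares ($V_{\max} \in (0, 100]$ mV/s,
$K_m \in (0, 10^6]$ uM, $c$ free, initialized at $\max y$ and the median
concentration) with perturbed multi-starts; flat data fall back to
$V_{\max} \to 0$, $c = \bar y$ rather than failing. R² is computed as
$1 - SS_{res}/SS_{tot}$ on the fitted points; RMSE is the root mean squared
residual. `linear_range()` implements the published operational definition —
the longest prefix of the concentration grid, anchored at 0, on which a
straight line keeps R² > 0.9.

Detection limits follow the IUPAC construction from the negative-control
statistics: $LOD = \mu_c + 3.3\,\delta_c$, $LOQ = \mu_c + 10\,\delta_c$ in
rate units, then conversion to uM by inverting the Michaelis-Menten curve
*excluding* the offset, $x = K_m y/(V_{\max} - y)$. Two conventions here are
deliberate and verified against the published numbers:

* **Offset-excluded inversion** is the only convention that reproduces the
  published concentration limits from the published rate limits.
* **Rate limits are rounded to the reporting precision (1 uV/s, i.e. 3
  decimals in mV/s) before conversion.** The characterization reports the
  rate-domain limits as 0.014 and 0.032 mV/s and converts those; with the
  unrounded LOD (13.91 uV/s) the LAA limit would print as 11.0 uM instead of
  the published 11.1. `rate_digits = NA` disables the rounding.

With these conventions the package reproduces LODs of 11.1/1.4/1.7 uM (LAA,
glutamate, choline) and LOQs of 25.5/3.9/3.5 uM (LAA, choline, sarcosine) at
printed precision. The published sarcosine LOD (1.4 uM; this computation
gives 1.5) and glutamate LOQ (3.3; this gives 3.2) differ in the last digit
under every convention tried — presumably unrounded fit parameters were used
originally — and are not asserted.

# Standard addition and its bias

Quantification uses the published per-sample protocol: a negative control, a
test measurement, and two positive controls spiked with [A] and [B] = 2[A]
on top of the sample (500 uM for LAA, 100 uM for the others). The published
sensitivity variants $S''$ and $S'''$ are printed with "[B] − [T]"
denominators, which is circular ([T] is the unknown); since the spikes are
added on top of the same sample, the concentration *differences* are exactly
[B] and [A], and the package computes $S'' = (r_b - r_t)/[B]$,
$S''' = (r_a - r_t)/[A]$ — the only reading that makes the variants
computable and numerically similar to $S'$, as the published account says
they were. The estimate is $[T] = r_t^*/\bar S$; negative estimates are
reported as 0 with a `below_background` flag and the raw value retained.

An important quantitative finding of this reimplementation: **if measured
rates follow the saturating calibration curve exactly, the estimator is
biased upward**, because all three sensitivities are secants of a concave
curve taken *above* [T], so $\bar S$ underestimates the local slope at [T].
Evaluating the printed formulas on exact Michaelis-Menten rates (no noise)
gives biases across the linear ranges of roughly +40..80% (LAA), +44..92%
(glutamate), +15..22% (choline) and +18..26% (sarcosine) — large wherever
spike sizes are comparable to $K_m$. In the exactly-linear regime
(`model = "linear"`), where the protocol is designed to operate, the full
pipeline recovers concentrations to well under 5% median error. The
acceptance suite therefore runs the recovery criterion in the stated
(Michaelis-Menten) world and reports it honestly — it fails for LAA and
glutamate, quantifying the linearization bias, and passes for choline and
sarcosine — while the pipeline's own correctness is established in the
linear world. Green tests here establish that the *computation* matches the
published equations; they cannot establish that those equations are unbiased
on a saturating assay, because they are not.

# Cohorts and classification

`simulate_cohort()` draws per-sample concentrations independently per
metabolite from normal distributions truncated at zero, with the published
group means/SDs (non-PCa n = 10, PCa n = 16). Truncation shifts the mean
upward where mean/SD is small (about +6% for choline-like parameters); tests
check against the analytic truncated-normal mean. Independence across
metabolites is the minimal assumption consistent with the reported absence
of relevant cross-correlation (< 0.3).

`crossval_rf()` mirrors the published setup: a 500-tree random forest trying
up to three metabolites per split (implemented in-package as CART trees with
Gini impurity on bootstrap resamples, grown to purity, probability = mean
tree vote), validated by stratified tenfold cross-validation repeated 100
times, sarcosine excluded from the default feature set after its null
univariate result. Because the published description of the ROC ("using the
predictions over every iteration", plus a bootstrap "for each iteration") is
ambiguous, both summaries are computed and labeled: the per-repeat AUC
distribution (mean and percentile 95% CI over repeats) and the
pooled-across-repeats ROC (used for the curve and operating point), with an
optional bootstrap CI over pooled predictions. The operating point maximizes
Youden's J — the rule is unstated in the original; Youden is the standard
choice and reproduces the published 3-point example — with percentile CIs
over per-repeat operating points. Welch's two-sided t-test is used for the
univariate screen (group SDs are clearly unequal); zero-variance degenerate
groups report p = 1 or 0 by the mean comparison rather than erroring. The
PSA comparator (sens 0.32, spec 0.87, AUC 0.68 at 3.1 ng/mL) is carried as a
literature constant for `roc_compare()`.

The real 26-sample cohort is not published per sample, so the clinical AUC
of 0.78 (95% CI 0.55-0.99) is not reproducible; synthetic cohorts drawn from
the group statistics classify more easily than real plasma (their
distributions are exactly the generative ones). The tests therefore assert
regime membership and the classifier's statistical invariants (null AUC 0.5,
separable AUC 1, permutation null, seed determinism), not the clinical
number.

# Reproducibility and formats

Every stochastic operation takes an explicit integer seed and restores the
caller's RNG state; the CLI derives per-stage substream seeds as a hash of
(stage name, global seed), so each stage is reproducible in isolation and
artifacts can be regenerated byte-identically. Frame stacks travel as
long-format CSV (frame, time_s, row, col, voltage_V) with a JSON metadata
sidecar; calibration and cohort tables as headed CSV with units in the
column names; rates and reports as JSON; every CLI output gets a
machine-readable manifest. `validate_io()` checks each dialect and
enumerates violations with field/frame context instead of failing at the
first.

# Known limitations

* No fluidics: filling, bubbles and reagent distribution are represented
  only through their statistical signatures (anomaly flags, control-rate
  statistics), not physically.
* No temperature/humidity dependence of kinetics; the cohort metadata carry
  the recorded ambient ranges but do not influence the simulation.
* The frame-level noise model is white Gaussian plus drift; correlated
  (flicker) noise is not modeled, so averaging gains are idealized.
* The 16-20% replicate SD of the real platform includes cartridge-to-
  cartridge and pipetting variation that the frame simulator does not
  generate; it is modeled directly only in the calibration-series generator.
* Trees in the random forest retry a single-class bootstrap only once; for
  pathologically small classes a near-constant tree can result (harmless in
  the probability vote).
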