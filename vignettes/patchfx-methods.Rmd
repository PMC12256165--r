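---
title: "Methods: feature extraction, synthetic validation and the statistical ladder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: feature extraction, synthetic validation and the statistical ladder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchfx)
```

`patchfx` turns whole-cell patch-clamp sweep sets from olfactory-bulb
dopaminergic neurons (and similar small interneurons) into a per-cell
feature table, and compares experimental groups with the normality-gated
statistical ladder used in that literature.  This vignette documents the
measurement definitions, the synthetic-data model the package validates
itself against, the numerical choices, and the limitations a user should
know about.

## Measurement definitions

All computations use mV, pA, ms, MOhm and pF internally; sweeps carry time
in seconds at the acquisition boundary.

**Passive properties** come from a voltage-clamp membrane test: a 10 ms,
-10 mV step from a -60 mV holding potential, sampled at 50 kHz.

* Series resistance `R_s = dV / (I_peak - I_baseline)` from the peak of
  the capacitive transient.
* Input resistance `R_i = dV / (I_ss - I_baseline)` from the steady-state
  current, with `I_ss` averaged over the final 20% of the step.  For a
  pipette in series with the membrane this measures `R_s + R_i`; with
  `R_s` below ~10 MOhm and `R_i` near 900 MOhm the bias is ~1%.
* Membrane capacitance `C_m` as the trapezoid-integrated charge between
  the transient and the steady state, from the peak sample (inclusive) to
  the step end, divided by `dV`.  Starting at the peak (rather than
  extrapolating to the step edge) under-counts charge by the factor
  `(R_i/(R_i+R_s))^2`; the synthetic oracle quantifies this at ~2% under
  typical conditions.
* Resting potential is the mean of the first 5 s of an I = 0 recording;
  spontaneously spiking cells are excluded from this measure because
  their baseline reflects pacemaking, not rest.

**Single-spike features** come from 10 ms depolarising steps (10 pA
increments from 0) sampled at 200 kHz.  The voltage is smoothed with a
20-point (100 us) sliding boxcar *before* differentiation; threshold is
the voltage at the first sample whose smoothed dV/dt exceeds 10 V/s,
found by scanning backwards from the peak to the last non-exceeding
sample (robust to early noise blips).  Width at half height is measured
at the midpoint between threshold and peak with sub-sample linear
interpolation; at 200 kHz the interpolation changes whh by well under
5 us.  The 10 V/s criterion is applied to the smoothed derivative — the
smoothing is specified as happening before differentiation, so the
criterion naturally sees the smoothed signal.

**Train features** come from 500 ms steps (10 pA increments from 0,
ladders stopped at depolarisation block), sampled at 50 kHz.  Spikes are
contiguous excursions above 0 mV, timed at their maxima.  Per sweep:
`IF = 1/ISI_1`, `CV = SD(ISI)/mean(ISI)` with the sample (n-1) SD,
`SFA = (f_first - f_last)/f_first * 100` on ISI-reciprocal frequencies,
and `SAA`/`SWA` as the first-to-last percentage drop in peak voltage and
width.  Each spike's width uses its own local 10 V/s threshold, because
later spikes in a train ride on accumulated depolarisation.  IF and SAA
are summarised as ordinary least-squares slopes against current over the
sweeps spanning the first suprathreshold step up to the first step
reaching 80% of the maximum spike count; CV, SFA and SWA are read off the
sweep nearest 1.5x rheobase (exact ties resolved toward the higher
current, since step ladders rarely contain the exact multiple).

**mAHP**: ten 2 ms / 500 pA pulses at 50 Hz, ten sweeps.  Sweeps that do
not fire exactly ten spikes are excluded; the remaining sweeps are
averaged point-wise and the amplitude is the drop from holding to the
minimum within 250 ms after the train.

**Sag**: 500 ms hyperpolarising steps (-10 pA increments) until the
steady-state voltage reaches -100 mV.  Per step,
`sag index = (V_hold - V_ss)/(V_hold - V_sag)` with `V_ss` the mean over
the last 10% of the step and `V_sag` the step minimum; the index at
-100 mV is linearly interpolated in `V_ss` between the two bracketing
steps (a single step within 2 mV of -100 mV is accepted when no bracket
exists, and flagged).

**QC**: cells are excluded from statistics when any series-resistance
measurement exceeds 30 MOhm or when the pooled measurements drift more
than 20% relative to the first one.  The drift reference is the first
measurement; all measurements of a recording are pooled rather than
averaged per protocol.  Excluded cells keep their feature rows, flagged
`qc_pass = FALSE`, so exclusion never alters other cells' values.

Missing protocols yield `NA` for the affected features only — per-feature
cell counts therefore differ across features, as they do in real
datasets.

## The synthetic cell model

The generator exists to give every extractor an exact oracle, so its
design trades biophysical sophistication for analytic transparency.

* **Subthreshold dynamics** are an adaptive leaky integrate-and-fire
  membrane (Euler-integrated on the sampling grid): a leak defined by
  `R_i` and `C_m`, a spike-triggered adaptation current (increment ~30 pA
  decaying with tau ~200 ms by default) that produces spike-frequency
  adaptation in the 40–70% range, and a hard threshold.  We use a hard
  threshold rather than an exponential spike-onset term because the spike
  shape is pasted anyway — the onset nonlinearity would add a free
  parameter without changing anything the extractor measures.
* **Spike waveforms are pasted, stylised, piecewise-linear shapes** — a
  flat pre-segment at threshold, a linear rise to the peak, a linear fall
  to the fast-AHP trough, and a linear recovery — with every kink time
  snapped to the sampling grid.  Real spikes are smooth; the piecewise
  shape is chosen because (i) the recorded cells' spikes are monophasic,
  so a single-rise shape is structurally adequate, and (ii) linear
  interpolation between samples of a piecewise-linear function is exact,
  so threshold, peak, width and maximum rate of rise all have closed-form
  values the extractor must reproduce to floating-point precision.  The
  flat pre-segment (0.1 ms) is what makes the 10 V/s threshold crossing
  land exactly on the nominal threshold voltage at both 50 and 200 kHz.
* **Within-train adaptation** scales each successive spike's peak down
  (amplitude adaptation) and its rise/fall durations down (width
  adaptation, snapped to the grid so the ledger width stays exact).
* **Depolarisation block** is emulated as a spikeless plateau for steps
  at or above a per-cell current ceiling; it is a stand-in for sodium
  channel inactivation, not a quantitative model of it.
* **mAHP and sag are injected analytic kernels.**  The mAHP is a
  difference of exponentials of known trough depth
  (`ahp_conductance` x 1 mV/nS) anchored after the last pulse-train
  spike; the last spike's trough is clipped at the holding voltage so the
  post-train minimum is the kernel trough rather than the fast AHP.  Sag
  steps are double-exponential relaxations whose sampled minimum is tuned
  (by root-finding) to the nominal sag voltage, and the cell's sag index
  is a linear function of `V_ss` with value `1 - 0.08 * sag_conductance`
  at -100 mV — linear so that the extractor's linear interpolation is
  unbiased.
* **Noise** is additive Gaussian voltage noise, low-pass filtered over
  100 us to mimic a ~10 kHz acquisition filter (recordings were made with
  synaptic blockers, so no synaptic noise is modelled).  Noise is applied
  to subthreshold samples only; pasted spike samples stay clean so that
  spike-level ledgers (times, peaks, widths) remain exact oracles.  This
  is the one deliberately unrealistic feature of the noise model: real
  noise rides on spikes too, at amplitudes (~0.1 mV) three orders of
  magnitude below the spike signal.

Default parameters are drawn per cell around the population values
reported for these neurons: input resistance ~870 MOhm, capacitance
~20.5 pF, threshold ~-34.5 mV, peak ~36 mV, width ~0.36 ms, fast AHP
~25 mV, sag index ~0.92, mAHP means declining with maturation (2.35,
1.92, 1.29 mV), spontaneous-firing fractions (0.13, 0.47, 0.40) across
the 5 wpi / 9 wpi / resident groups, and a +4 mV spike-peak shift under
naris occlusion.  The default noise SD of 0.1 mV reflects the post-filter
baseline RMS noise of a good whole-cell recording.

What passing the recovery suite shows — and does not show.  Exact
recovery of pasted-waveform features demonstrates that the extraction
arithmetic (smoothing, differentiation, interpolation, the formula set)
is correct, and the noisy-cohort medians demonstrate robustness at
realistic noise.  It does not demonstrate robustness to the failure modes
the generator omits: electrode drift, partial depolarisation block,
biphasic (axon-bearing) waveforms, bursting, or seal degradation
mid-protocol.  The QC rule and the biphasic phase-plane flag address the
common cases, but real data should still be inspected.

## The statistical ladder

Group comparisons mirror the screening cascade standard in this
literature:

1. **Normality battery**: D'Agostino–Pearson omnibus test for n >= 8
   ("sufficiently large" is not quantified in the source convention; 8 is
   the smallest n at which the kurtosis transformation is defined),
   Shapiro–Wilk below that; alpha = 0.05.
2. Data failing the battery get a **normal-fit variance check**: a
   normal distribution is fitted by mean and SD and the ordered data are
   regressed on the fitted quantiles; if more than 10% of the variance is
   unexplained (1 - R² > 0.10) the data are sent to the transform ladder,
   otherwise they are analysed untransformed.  The Q–Q R² definition is a
   documented surrogate for an unspecified original computation, chosen
   because it is scale-free and reduces to 0 for exactly normal samples.
3. **Transform ladder**: log10, sqrt(x+1), 1/x, x+1 in that order; the
   first transform whose result passes the battery is used.  When none
   passes, the analysis falls back to **mid-ranks** of the pooled data
   (the rank-transform approach to factorial designs).
4. **Two-way ANOVA** (maturation x occlusion) uses classical Type II sums
   of squares, computed by nested model comparisons — Type II because the
   cell counts are unbalanced and no interaction is assumed when testing
   main effects; the choice is recorded in every report so deviations
   from other conventions are auditable.  Post hoc sham-vs-occluded
   contrasts within each maturation level use the cell-means model with
   the pooled residual MSE and a closed-form Sidak adjustment for three
   comparisons, `p_adj = 1 - (1 - p)^3`.
5. **One-way comparisons** use ANOVA with Tukey HSD when the battery
   passes and Kruskal–Wallis with Dunn's tie-corrected z post hocs
   (Bonferroni-adjusted over all pairs) otherwise.
6. **Proportions** (spontaneous firing) use Fisher's exact test: the
   minimum-likelihood two-sided rule for 2x2 tables, the exact
   network-algorithm extension for 2x3, with the pairwise alpha
   Bonferroni-corrected (0.05/3 displayed as 0.017).

Calibration: on normal null data the full ladder (screen, fallback
checks, transform, Type II ANOVA) holds a type-I error within [3%, 7%] at
nominal 5% over 2000 simulations of a 3x2 design with 8 cells per cell
(the problem size used by the acceptance checks; chosen to match the
study's per-group cell counts).

Mixed-model designs are out of scope: a repeated-measures analysis can
be approximated by the two-way machinery, but the package does not fit
random-effect models.

## qPCR

Amplification efficiency comes from the standard-curve slope,
`E = 10^(-1/slope) - 1`.  Relative expression uses the classic
`2^(-ddCt)` method: technical replicates are averaged on the Ct scale,
`dCt = Ct_target - Ct_reference` per sample, `ddCt` subtracts the mean
control-group dCt, and the fold change is `2^(-ddCt)`.  The method
assumes E = 1 even though measured efficiencies (e.g. 1.07, 1.01) differ
slightly — this is deliberate fidelity to the standard method; an
efficiency-corrected variant is available via the `efficiency` argument
but is off by default.  Normalising to the mean control *dCt* (default)
versus the mean control *fold* differ by a common factor when control
dCts vary; both are implemented and the choice is recorded in the output.

## Numerical choices and degenerate inputs

* Steady-state windows: final 20% of the membrane-test step, final 10% of
  sag steps.
* The boxcar window is centred (one extra trailing point for even
  windows); edges shrink the window symmetrically.  Smoothing and
  central-difference differentiation commute to numerical precision, as
  linear operators must.
* Ties at 1.5x rheobase resolve to the higher current; a missing
  rheobase propagates `NA`.
* Zero steady-state current (infinite resistance), flat traces at
  threshold search, all-subthreshold ladders, empty spike trains and
  degenerate (zero-margin) contingency tables all return errors, `NA`s or
  the p = 1 convention with a warning, rather than numbers.
* Spearman correlations use an exact permutation p for n <= 9 and the
  t approximation above.
* Feature tables serialise numerics at 17 significant digits, so write →
  read round-trips are bit-exact.

## Known limitations

* SFA monotonicity in the adaptation strength holds for trains long
  enough to express adaptation; very short trains near rheobase truncate
  the last ISI and can locally mask it.
* The depolarisation-block emulation and the injected mAHP/sag kernels
  are phenomenological; parameter *recovery* results transfer to real
  data only insofar as real waveforms resemble the stylised geometry.
* The I = 0 protocol is generated at 10 kHz (spike presence and a 5 s
  mean need no more bandwidth); all other current-clamp protocols use
  50 kHz and the single-AP protocol 200 kHz.
* ABF/NWB readers are interface hooks only; sweeps enter as CSV with a
  JSON sidecar.
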