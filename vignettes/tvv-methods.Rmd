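---
title: "Trajectory quantiles of the T-vector velocity: model, pipeline and design notes"
author: "tvvloop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trajectory quantiles of the T-vector velocity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The biomarker family

During ventricular repolarization the heart's net electrical dipole traces a
three-dimensional loop, the T loop. Reconstructed from the eight independent
surface leads (V1–V6, I, II) by the inverse Dower transform, the dipole has a
position $(x(t), y(t), z(t))$ and an instantaneous speed

$$\mathrm{TVV}(t) = \sqrt{\dot x(t)^2 + \dot y(t)^2 + \dot z(t)^2},$$

the *T-vector velocity*. Its time integral is the distance travelled along the
loop. Normalizing the total trajectory length of the repolarization window
$[J+20\,\mathrm{ms},\,T_{end}]$ to one turns the loop into a distribution over
time, and the quantiles of that distribution,

$$Tr_X = \min\{\,t : L(t)/L_{total} \ge X/100\,\},\qquad X = 10, 20, \dots, 100,$$

localize *when* electrical activity happens within repolarization. A drug that
blocks the outward hERG/iKr potassium current slows the action-potential
downslope throughout repolarization, so every $Tr_X$ grows with concentration;
a drug that blocks inward late-sodium or calcium currents steepens early
phase-2 repolarization, so the early quantiles shrink while the late ones are
largely spared. The vector of placebo-corrected, heart-rate-corrected changes
$\Delta\Delta Tr_{10c} \dots \Delta\Delta Tr_{100c}$ at a representative
concentration — the *effect profile* — is therefore a fingerprint of which
ionic currents a drug engages, and mid-range quantiles separate pure
potassium-channel block from multichannel block better than either QTc
(≈ $Tr_{100}$) or T-peak-based intervals.

## Pipeline and parameters

Each annotated 10-second 12-lead ECG passes through:

1. **Isoelectric correction.** One knot per beat: the median amplitude over
   the PQ segment, placed at the PQ midpoint; a natural cubic spline through
   the knots (constant extrapolation beyond the first/last knot) is
   subtracted per lead. With fewer than two beats the correction degenerates
   to a constant. Derived limb leads are recomputed from the corrected I and
   II so the Einthoven/Goldberger identities stay exact.
2. **Low-pass filtering.** An order-2 analog-prototype Bessel filter
   (−3 dB at 36 Hz), discretized by the bilinear transform and applied
   forward and backward (effective order 4, exactly zero phase). Edges are
   handled by odd-reflection padding. The Bessel family is chosen for its
   maximally flat group delay, which preserves T-wave morphology.
3. **VCG reconstruction.** The published Edenbrandt–Pahlm inverse Dower
   coefficients (the Moore–Penrose pseudo-inverse of the Dower lead field;
   verified to invert it to 0.05% per entry). Leads zeroed as noisy simply
   contribute nothing. The matrix is a function argument for sensitivity
   analyses.
4. **Derivatives.** Savitzky–Golay differentiation, polynomial order 3,
   window 31 samples at 500 Hz (60 ms); at other sampling rates the odd
   sample count closest to 60 ms. Derivatives are computed on the
   full-length VCG and only then windowed to the loop, so no filter edge
   transients fall inside it. The filter is exact for cubic trends.
5. **Quantile readout.** Trapezoidal cumulative arc length, matching the
   linear interpolation used to find the earliest crossing of each $X/100$
   threshold; flat stretches resolve to the earliest crossing; $Tr_{100}$ is
   the loop duration by definition. Beats must be normal sinus with a
   usable window (at least 20 ms plus one half-window past J); at least
   three per ECG, averaged arithmetically.
6. **Heart-rate correction.** `TrX ~ 1 + RR + (1 + RR | subject)` fitted by
   REML to drug-free data (placebo arm plus all pre-dose baselines); the
   fixed slope $\beta$ gives $Tr_{Xc} = Tr_X - \beta(RR - 1000)$. A singular
   fit falls back to independent random effects and is flagged. RR is
   centered and scaled internally; coefficients are reported in ms/ms.
7. **Exposure response.** Replicate averaging, then
   $\Delta P = P(t) - P(t_0)$ within subject and period, then
   $\Delta\Delta P = \Delta P_{drug} - \Delta P_{placebo}$ matched on
   subject and nominal time. Concentration models are origin-anchored:
   `dd ~ 0 + C + (0 + C | subject)` for one drug,
   `dd ~ 0 + C1 + C2 + C1:C2 + (0 + (C1 + C2) | subject)` for two (the
   interaction term is optional, e.g. when one compound is never given
   alone). Effect profiles evaluate the fixed effects at representative
   concentrations; 95% intervals come from a subject-level (cluster)
   bootstrap with refitting, 2000 replicates by default, seeded.
8. **Discrimination.** Maximum-likelihood logistic regression of the block
   label on one or all ten $\Delta\Delta Tr_{Xc}$ features; in-sample AUC by
   the midrank (Mann–Whitney) formula; 95% CI by class-stratified bootstrap
   (percentile, 2000 replicates).

## The synthetic study generator

Real pharmaco-ECG studies cannot ship with a package, so every stage is
validated against a generator whose ground truth is available in closed form.
Its central device is a time warp in the arc-length domain: the T loop's
spatial path is fixed (a smooth open loop, parameterized by arc length via a
high-resolution table) and a timing map $\tau(q)$ prescribes when arc
fraction $q$ is reached, so the true quantiles are $\tau(X/100)$ exactly.
Per record,

$$\tau(q) = s_{RR}\,\tau_0(q) + \textstyle\sum_d C_d\,\delta_d(q)\,(1 + b_d),$$

with

* $\tau_0$: baseline timing with arc coverage
  $c_0(s) = s - \sin(2\pi s)/2\pi$ — speed rises smoothly from zero at the
  loop boundaries, peaks mid-loop and tapers off, the gentle T onset/offset
  of real ECGs; default duration 280 ms (QT ≈ 410 ms at 60 bpm, mid-normal),
  per-subject SD 5%;
* $s_{RR} = 1 + \beta_{dur}(RR - 1000)/T_0$: heart-rate dilation,
  $\beta_{dur} = 0.1$ ms/ms with 10% subject SD, giving per-quantile true
  slopes $\beta_{dur}\tau_0(q)/T_0$ in the physiologic 0.015–0.10 range;
* $\delta_d$: the drug's effect shape in ms per concentration unit —
  `"herg"` is linear in $q$ (increasing delay), `"sodium"` is a smooth
  negative shoulder up to $q = 0.4$ then flat; shapes superpose;
* $b_d \sim N(0, \sigma_b^2)$: per-subject relative effect-size deviation.

Records are assembled beat by beat (P bump, Gaussian-pulse QRS loop, warped
T loop), with each beat's fiducial layout jittered by ±2 ms — real sinus
beats are not identical, and this beat-to-beat variability is what gives
replicate ECGs their few-ms parameter spread and dithers the integer-sample
quantization of the annotations. Dipoles are projected with the forward
Dower matrix; white noise (10 µV SD), a 0.33 Hz sinusoidal wander
(150 µV) and a slow random walk are added to the eight independent leads,
so derived leads stay consistent. Concentrations follow one-compartment
oral kinetics $C(t) \propto e^{-k_e t} - e^{-k_a t}$ with 15% log-normal
subject variability. RR has a circadian swing (60 ms), subject offsets
(80 ms SD) and record-level jitter (20 ms SD). The default design mirrors a
thorough crossover study (22 subjects, 5 periods, 16 timepoints,
triplicate 10-s ECGs); the test suite runs reduced designs — 12 subjects ×
8 timepoints × triplicates with 6-s records for recovery checks, chosen so
that the between-subject sampling error of the mean effect (SD
$\sigma_b/\sqrt{n}$) stays small against the bootstrap interval widths.

What the generator does **not** emulate: realistic P/QRS morphology beyond
fiducial plausibility, T-wave notching and flattening, torso
volume-conductor effects, ectopy and artifacts (beat class is an input),
annotation errors, or cellular electrophysiology — drug effects are injected
as timing warps, not through ionic models. Passing the recovery tests
therefore demonstrates that the pipeline measures what was injected under
controlled conditions, not that any particular clinical effect size will be
reproduced in real recordings.

## Measurement properties worth knowing

* **Smoothing gain.** The 60 ms derivative window slightly redistributes
  arc length in time. On noiseless injected warps the placebo-corrected
  change is read back with a gain of ≈ 1.10 at $Tr_{10}$, ≈ 1.07 at
  $Tr_{20}$, shrinking to exact at $Tr_{50}$ and $Tr_{100}$. Constant
  biases cancel in $\Delta\Delta$; this residual gain does not, and it
  grows quickly for loops whose content exceeds the window's passband — a
  warp with a velocity singularity (e.g. $\tau \propto q^2$, which puts 10%
  of the arc inside the first sample) cannot be read back at sub-sample
  accuracy by any 60 ms-window method.
* **Interval coverage.** Bootstrap intervals resample subjects only. A
  10-study accounting experiment puts the within-study subject-level SE at
  ~0.85–0.9 of the estimate's true across-study variability, i.e. the
  intervals are honest but slightly narrow at 6–12 clusters, as expected
  for percentile cluster bootstraps. Joint statements over all ten
  (strongly correlated) quantile intervals — "every CI covers zero" — are
  themselves ~90% probability events per study, not certainties.
* **Quantization.** Fiducials are integer sample indices; at 500 Hz,
  $Tr_{100}$ (the loop duration) inherits 2 ms quantization unless
  beat-to-beat variability dithers it, which the generator provides and
  real data have naturally.

## Design decisions that were genuinely open

* Bessel order is unstated in common practice descriptions; order 2 per
  pass (effective 4 bidirectionally) preserves T morphology while meeting
  pass/stop-band behaviour (gain 0.99 at 5 Hz, 0.02 at 100 Hz,
  bidirectional, at 500 Hz).
* Spline knot abscissa: the PQ midpoint, centering the isoelectric
  estimate in its defining window.
* Derivatives before windowing, so the loop interior is transient-free.
* Drug-free data for rate correction: the placebo arm plus every arm's
  pre-dose baseline.
* Bootstrap resampling unit: subject, respecting the random-slope grouping;
  residual or parametric schemes would understate between-subject effect
  heterogeneity.
* Percentile intervals (not BCa): simplest defensible default.
* In-sample AUC, matching the comparison convention for biomarker ranking;
  cross-validation is possible but not the default.
* Recovery checks compare the estimated profile to the effect actually
  injected for the simulated sample, $C\,\delta(q)\,(1+\bar b)$, read from
  the generator's truth metadata; the sampling error of $\bar b$ around
  zero is a property of the subject draw, covered separately by the
  slope-recovery simulations.

## Known limitations

Only linear (origin-anchored) exposure-response models are provided — no
Emax or hysteresis. Confidence intervals are unadjusted across the ten
quantiles. T-peak detection is out of scope; externally measured J-Tpeak
values can be carried as additional columns but are never computed. WFDB
support is read-only (formats 16 and 212) with annotations from the JSON
sidecar dialect; the full HL7 aECG format is not parsed.
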