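---
title: "Quantification methods: excitability, calcium transients, splicing and behavior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantification methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nphys)
```

nphys re-implements, as a tested pipeline, the quantification procedures
used in slice-electrophysiology and in vivo imaging studies of cortical
GABAergic interneurons: intrinsic-excitability feature extraction from
current-clamp step protocols, somatic calcium transient statistics from
two-photon ROI fluorescence, exon percent-spliced-in (PSI) from junction
read counts, closed-form behavior metrics, and the nonparametric group
statistics that tie them together. Because raw recordings are rarely
shareable, every stage is paired with a synthetic-data generator whose
ground truth is exact, so the pipeline's correctness is verifiable end to
end on a laptop.

## Electrophysiology feature extraction

The substrate is a current-clamp sweep: a voltage trace with a square
current step of known amplitude, onset and duration. Two protocols cover
the standard characterization: a subthreshold series (six 10-pA increments
from −30 pA, 500 ms) for passive properties and an excitability series
(0–400 pA in 20-pA increments, 500 ms) for firing properties.

**Passive properties.** The resting membrane potential (RMP) is the mean
voltage over the pre-stimulus baseline; at least 50 ms of baseline is
required. Input resistance $R_\mathrm{in}$ is the ordinary-least-squares
slope of the steady-state voltage deflection against injected current,
using the mean over the last 100 ms of the step (the slowest cells in this
preparation have $\tau \le 35$ ms, so more than three time constants have
elapsed) and excluding any sweep containing an action potential. A slope
in mV/pA is a conductance inverse in GΩ and is reported in MΩ. The
membrane time constant $\tau$ comes from a single-exponential fit
$V(t) = V_{ss} + (V_0 - V_{ss})e^{-t/\tau}$ over at most 200 ms from step
onset, on hyperpolarizing sweeps only (depolarizing steps can engage
voltage-gated conductances); fits outside $(0.1, 200)$ ms are dropped and
the surviving sweeps averaged. Capacitance is $C_m = \tau / R_\mathrm{in}$
(ms/MΩ = nF, reported in pF). The fit uses `nls` with a `scaleOffset` so
that noiseless synthetic traces, whose residual is exactly zero, still
satisfy the relative-offset convergence test.

**Action potentials.** An AP is a local voltage maximum that either
exceeds −10 mV or rises at least 70 mV above the pre-stimulus baseline;
candidate peaks closer than 1 ms are deduplicated keeping the taller one
(fast-spiking cells top out near 160 Hz, leaving ≥ 6 ms between genuine
spikes). Per AP: the threshold is the last point before the peak, within
a 5-ms back-window, where $dV/dt$ first exceeds 5% of that AP's maximal
rise; the fast-afterhyperpolarization (fAHP) nadir is the voltage minimum
between the peak and the next AP's threshold (or peak + 10 ms); amplitude
is peak minus nadir; maximum rise and decay slopes are the extreme
$dV/dt$ on the corresponding flanks, computed by central differences on
the raw grid (a 3-point moving average is applied first below 10 kHz).
The half-width reference level is the midpoint of peak and threshold
voltage: the source convention defines amplitude from the fAHP nadir but
leaves the half-height base unstated, and the threshold-referenced
midpoint is the more reproducible choice because the nadir depends on the
following spike.

**Excitability.** The input–output curve counts APs per step; rheobase is
the smallest step amplitude with at least one AP, reported on the 20-pA
grid without interpolation. Latency to first AP, first inter-spike
interval and the fAHP depth (threshold minus nadir) are measured on the
sweep at rheobase + 100 pA, the fAHP averaged over the first five APs
(fewer available APs are averaged and flagged). Fast-spiking (FS)
classification requires $\tau < 15$ ms and strictly more than 35 APs at
the 400-pA step — 70 Hz over 500 ms. Inclusion criteria: RMP more
negative than −55 mV, access resistance below 25 MΩ (or varying less than
30% across the recording), input resistance below 1000 MΩ, and more than
one AP evoked over the whole series; violations are itemized per cell.
Voltages are reported uncorrected for the liquid junction potential.

## The LIF ground-truth generator

Subthreshold dynamics follow $\tau \dot V = -(V - E_L) + R I(t)$,
integrated with the exact exponential update per sample, so the
closed-form relaxation $V(t) = E_L + RI(1 - e^{-t/\tau})$ holds to
machine precision and the analytic acceptance checks are meaningful.
Reaching threshold emits a stereotyped 2-ms spike (1-ms linear rise to
+30 mV, 1-ms fall to 5 mV below the reset), unambiguously satisfying both
AP criteria, then clamps the membrane at the reset for the refractory
period and logs the crossing time. Two deliberate choices:

* **Noise is additive measurement noise** on the recorded trace, not
  process noise in the dynamics. The spike log therefore remains exact
  ground truth at any noise level, which is what parameter-recovery and
  detection tests need; channel-noise realism is out of scope.
* **Threshold equality tolerance.** The exponential trajectory approaches
  its steady state asymptotically, so a step whose steady-state voltage
  equals threshold exactly would never fire in floating point. Crossings
  are therefore detected at $V \ge V_{th} - 10^{-6}$ mV; with a 500-ms
  step this admits the marginal amplitude whenever
  $\tau \lesssim 25$ ms, and the closed-form rheobase
  (`lif_rheobase()`) applies the same convention, keeping simulator and
  formula consistent by construction.

## Calcium transient quantification

ROI traces are mean pixel intensity inside the ROI minus mean background,
per frame. $F_0$ is the minimum, over all contiguous 3.5-s windows, of
the window mean — the quietest stretch of the recording — and
$\Delta F/F_0 = (F - F_0)/F_0$. Events are maximal runs of frames with
$\Delta F/F_0 > 3\sigma$ spanning at least two frames (a single-frame
crossing at the 1.7-Hz default frame rate is far shorter than a GCaMP6s
transient and is treated as noise). Four statistics summarize a cell: AUC
(trapezoidal integral of $\Delta F/F_0$ per complete 35-s window,
averaged; partial tails dropped; traces shorter than one window are
integrated whole and flagged), mean event peak, mean event full width at
the threshold level, and events per minute. Motion-artifact segments are
excised by a frame mask before any computation. All statistics are
invariant to rescaling the raw fluorescence, since $F_0$ scales with $F$;
adding an offset is *not* invariant and is tested as a sensitivity.

**Noise level $\sigma$.** The event threshold needs the baseline noise
s.d. on the $\Delta F/F_0$ scale. The 3.5-s minimal window contains only
six frames at 1.7 Hz, and a six-sample s.d. is unstable by a factor of
about three — enough to turn the 3σ rule into an effective 1σ rule on
unlucky traces and flood the event list with noise runs (we measured a
recovered event rate of 2.7/min against a true 1.0/min that way). nphys
instead estimates σ robustly from the whole trace as
$\mathrm{mad}(\Delta(\Delta F/F_0))/\sqrt 2$: first differencing removes
the slow transient component and the MAD ignores the sparse event-related
jumps. The estimate is floored at $10^{-4}$ so noiseless synthetic traces
do not yield a zero threshold. With this estimator the recovered event
rate on the generator's reference conditions (λ = 1.0 min⁻¹, 8σ
amplitude, 200 cells × 105 s) is within 3% of truth.

**Interpretation choices.** "Full width" is the supra-threshold segment
width (not half-maximum); AUC integrates the signed $\Delta F/F_0$; σ is
computed on $\Delta F/F_0$ rather than raw F (scale invariance).

The calcium generator draws homogeneous Poisson event times, renders each
as a one-frame rise and a 1.5-s exponential decay (GCaMP6s-like), adds
the kernels linearly on a multiplicative baseline — so the injected
$\Delta F/F_0$ amplitude is exact ground truth — and adds Gaussian sensor
noise. Amplitudes are parameterized in multiples of the noise σ; for
noise-free traces an explicit `amplitude_dff` is given instead. The
generator does not emulate correlated network activity, motion artifacts,
neuropil contamination or bleaching, so passing tests demonstrate correct
quantification of well-formed transients, not robustness to those
real-data pathologies.

## Splicing

Percent spliced-in uses the standard junction ratio
$\Psi = \bar I / (\bar I + S)$ with $\bar I$ the mean of the available
(one or two) inclusion junction counts; estimates below 10 effective
reads are undefined, since below that coverage the ratio is dominated by
sampling noise. Differential inclusion pools counts per group into a 2×2
table and applies the two-sided Fisher exact test under the
probability-mass rule (sum of all tables no more probable than the
observed one — exact on asymmetric tables, unlike doubling), with
Benjamini–Hochberg adjustment across exons. RT-PCR band intensities give
$\Psi$ as the inclusion fraction, optionally dividing each band by its
amplicon length first so molarity rather than stained mass is compared.
These are deliberately simple surrogates for full junction-model
pipelines; read alignment and junction extraction are out of scope.

At 200 reads per group, the binomial sampling error of
$\widehat{\Delta\Psi}$ is about 0.042, so individual replicates land
within ±0.05 of the true contrast only ~77–80% of the time; the *mean*
recovered contrast across 200 replicates is unbiased to ~0.003. The
recovery checks therefore test the mean contrast (and the per-replicate
detection rate at FDR < 0.05, which is essentially 100% at this effect
size), and the acceptance script also reports the per-replicate in-band
fraction for transparency.

## Behavior

Y-maze spontaneous alternation counts sliding-window triads of three
distinct arms over (entries − 2) windows; the chance level for a
three-arm maze under memoryless uniform entries is
$100 \times \frac{2}{3}\times\frac{1}{3} \approx 22\%$. Elevated-plus-maze
times are percentages of the 300-s trial. Gait metrics are literal
combinations of lettered footfall distances (A = left fore, B = left
hind, C = right fore, D = right hind, fixed so AB/CD are same-side
fore–hind pairs): FP–HP = mean(AB, CD), step length = mean of the four
same-paw stride distances, stance width = mean(AC, BD), and the
alternation coefficient AB/BD, implemented literally as a distance ratio.

## Statistics

The Mann-Whitney U statistic uses midranks; the two-sided p-value is
exact (null permutation distribution via `pwilcox`) when the combined n
is at most 16 with no ties — enumeration is cheap there and that range
covers typical per-group cell counts — and otherwise a normal
approximation with tie and continuity corrections. The input–output
curves are compared with a repeated-measures two-way ANOVA (between
factor: genotype; within: current step), reporting the between-subject F
on $(1, n_a + n_b - 2)$ degrees of freedom with sphericity assumed (no
Greenhouse–Geisser correction), matching the uncorrected df convention of
slice-physiology reports. BH adjustment and descriptive mean ± SEM
round out the module.

## Problem sizes and verification

The test suite checks every operation against independent oracles: a
brute-force minimal-window mean for $F_0$, a loop-transcribed trapezoid
rule for AUC, full labeling enumeration for Mann-Whitney, hypergeometric
enumeration for Fisher, the direct step-up formula for BH, a
hand-partitioned sum of squares for the mixed ANOVA, and the generators'
logs for spikes and calcium events. The heavier recovery experiments run
at 100 seeded LIF sweep sets, 200 synthetic calcium cells (105 s at
1.7 Hz), 100 designed-contrast pipeline runs at 100 cells per group and
class, $10^4$ null simulations for test calibration, and 200 binomial
PSI replicates — sizes chosen so the full suite completes in a few
minutes on one core while keeping Monte-Carlo standard errors well inside
the asserted tolerances.

## Known limitations

* The LIF generator has no adaptation, channel noise or biophysical spike
  shape; it validates feature *extraction*, not biophysical realism.
* Event detection assumes a sensible frame rate (~1–10 Hz); at very high
  rates the two-frame minimum span would need rescaling.
* The Fisher/BH differential-splicing test is a pooled surrogate, not a
  reproduction of full junction-count model pipelines.
* ABF/NWB ingestion is not provided; sweeps arrive as CSV + JSON
  manifests (`read_sweep_set()`), image stacks as in-memory arrays or
  TIFF via the optional `tiff` package.
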