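---
title: "Current-clamp spike-train and evoked-PSP analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Current-clamp spike-train and evoked-PSP analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msnephys)
```

This vignette documents the models, conventions and numerical choices
behind `msnephys`: how sweeps are represented, how spikes and
depolarization block are detected, how evoked postsynaptic potentials
(PSPs) are classified, what the synthetic cohorts emulate (and what they
do not), and where the design was genuinely open.

## Data model and units

A `msn_sweep` is one episodic current-clamp trial: a membrane-potential
trace (mV) with its command current step (pA), step window (s), light
condition and stimulation protocol, and pharmacology tags. A `msn_cell`
holds a cell's ordered sweeps plus subtype (D1/D2 by dopamine-receptor
expression), access resistance and provenance metadata. Units are fixed
package-wide: mV, pA, ms for reported features, seconds for sample
timestamps. Traces are stored at their native sampling rate (nominally
50 kHz) and never resampled on ingest.

The interchange format is a plain-text bundle: a JSON manifest (cell and
sweep tables) plus one two-column tab-delimited trace file per sweep.
Reading validates sample counts and rates against the manifest and fails
with a named integrity error on mismatch. Vendor episodic binaries (e.g.
ABF) are supported through an adapter contract — a user-supplied reader
function mapping a file to a `msn_cell` — so the core carries no
binary-format logic.

Quality control follows the recording conventions: cells with access
resistance strictly above 30 MΩ are discarded (a value of exactly 30 is
kept), cells with missing access resistance are discarded with their own
reason, and optionally cells whose no-light step series contains a
zero-spike sweep between the first spiking sweep and the block sweep
("discontinuous spike trains" — the term is not formally defined in the
source conventions, so this operationalization is a documented choice).

## Spike detection and train features

Spike onsets are found where the smoothed derivative dV/dt crosses
20 mV/ms. The derivative estimator is a five-point Savitzky–Golay
(quadratic) filter; any estimator reproducing the crossing behavior on
template spikes is conforming. A candidate event must then satisfy two
amplitude criteria:

* **prominence** — the voltage peak within 5 ms of the crossing must rise
  at least 10 mV above the crossing point;
* **repolarization** — the trace must fall by at least half the
  prominence criterion within 3 ms of the peak. A spike repolarizes; the
  passive RC response to a current step does not, so this rejects
  slope-criterion crossings that ride the step onset under noise.

Events closer than 1 ms are merged to the larger peak, and detection is
restricted to the current-step window when one is defined. The threshold
sample is the last upward crossing of the smoothed derivative before the
peak; on noiseless templates this is exact to one sample (0.02 ms at
50 kHz). The detector is invariant under DC shifts of the trace.

Per-AP geometry: height is threshold-to-peak (the alternative,
baseline-to-peak, is never used; the block detector is insensitive to the
choice as long as it is uniform); half-width is the full width at half
height with linearly interpolated crossings (no spline fitting); rise
time is the 10–90% interval on the rising limb. Features whose crossings
cannot be found are flagged `NA`, never fabricated.

Per-train conventions: frequency is AP count over the step duration;
latency is measured from step onset to the **threshold crossing** of the
first AP (onset semantics; peak-referenced latency differs by the fixed
rise time on templates); mean ISI is always the mean of successive peak
differences over all APs, which equals (t_last − t_first)/(n − 1);
"first spike" refers to the first AP and "train mean" to the average
excluding the first. Attenuated APs still count toward frequency and ISI.

## Depolarization block

All AP heights of a cell in one light condition are pooled into a
histogram with 2 mV bins. Pooling across the cell's sweeps (rather than
per sweep) is a deliberate reading of an ambiguous convention: a single
train rarely yields a usable bimodal histogram; a per-sweep mode is
available behind a flag. Bin edges are anchored at multiples of the bin
width rather than at the observed minimum, so bin placement does not
drift with the sample.

Counts are smoothed with a 3-bin moving average before the local-maximum
search; each candidate mode is refined to the raw-count maximum within
one bin (moving-average smoothing can otherwise displace a sharp mode
into an empty neighbor bin), ties resolve toward the lower bin center,
and the two best candidates at least 10 mV apart are the full-AP and
attenuated-AP modes. With fewer than two such maxima the distribution is
declared unimodal and the cell reports an explicit "no block" outcome,
excluding it from high-depolarization comparisons.

The full/attenuated boundary is the **upper edge of the lower-mode bin**
(reported as `attenuation_cutoff_mV` alongside the bin-center peaks):
heights inside the modal bin are part of the attenuated population, so
the strict "below the lower peak" rule is applied at the top of that bin.
Applying it at the bin center would misclassify half of the modal bin by
construction whenever measurement noise is symmetric. A height exactly at
the cutoff is full.

The **block sweep** is the first sweep whose attenuated fraction reaches
at least 0.5 ("at least half", so a train with exactly half its APs
attenuated qualifies). This sweep — detected in the no-light condition —
anchors all high-depolarization measurements in *both* conditions, so
every light/no-light comparison is paired within the same sweep.

## Input–output curves and designated sweeps

"Normalization" of group f–I curves is alignment (re-indexing), not
amplitude scaling — the y axis remains a frequency. Two anchors are
provided: the first step with recorded spikes in both conditions, and the
highest completed paired step. Because recordings stop once the cell
reaches depolarization block, the highest completed step is in practice
the no-light block region, where the light condition still fires at full
rate; which anchor a given figure uses is a documented per-analysis
choice. Relative indices supported by fewer than `min_cells` (default 3,
an artifact decision) are flagged rather than silently dropped.

Designated sweeps for paired comparisons: latency uses the first step
with APs in both conditions; low-depolarization ISI uses one step above
that (so that intervals between multiple APs exist); high-depolarization
measurements of every feature use the no-light block sweep. Cells without
a qualifying sweep are excluded with a machine-readable reason.

The two-way OLS ANOVA on I/O tables (frequency ~ light × step, treatment
coding, Type II tests) treats rows as independent even though cells
contribute several steps — reproducing the convention being emulated. A
warning notes the repeated-measures caveat and a cell-cluster-robust
covariance is available behind a flag. Type II sums of squares were
chosen because the designs are near-balanced and no interaction is the
primary target; on balanced designs Type II equals Type I.

## Evoked-PSP classification

Sweeps sharing a protocol are averaged (about five sweeps is the
convention), smoothed with a 5 ms boxcar, and measured relative to the
mean of the 100 ms pre-onset baseline. The response window runs from
pulse onset to the last pulse offset plus 300 ms — long enough to capture
slow GABA_B-receptor-mediated hyperpolarization, which spans hundreds
rather than tens of milliseconds. A deflection counts when it exceeds
θ = max(3 × baseline SD of the smoothed average, 0.3 mV); depolarization
only → excitatory, hyperpolarization only → inhibitory, both → mixed,
neither → none. The source conventions report classes without a numeric
criterion, so this threshold rule is an explicit design decision, stored
in every call for provenance. Classification uses the averaged trace (not
a per-sweep majority vote), and both the peak and the window-mean
hyperpolarization metrics are computed since it is ambiguous which one
defined "inhibition". The boxcar smoothing exists because the peak of raw
noise over a multi-second window would otherwise exceed any fixed
threshold; 5 ms is short against even the fast EPSP kernel.

The slow component is quantified as the mean change from baseline 200–300
ms after pulse onset; the same metric, computed per phase, drives the
paired wash-on comparison (pre vs post GABA_B-receptor blockade), which
is baseline-relative and therefore immune to DC drift between phases.

Breakdowns report per-class counts and percentages rounded to the nearest
integer, half away from zero, against an explicit total (which may exceed
the sum of classified cells). Cross-protocol transition tables include
only cells characterized under all three protocols; their marginals
reproduce the per-protocol breakdowns restricted to those cells.

## Statistics

Paired comparisons use the two-sided Wilcoxon signed-rank test with zero
differences dropped before ranking (the classical rule; recorded in the
result because the convention is unstated), exact null distribution up to
n = 25 without ties, and a continuity-corrected normal approximation
otherwise. Unpaired (subtype) comparisons use the two-sided Mann–Whitney
U test, exact when the smaller group has at most 8 observations and there
are no ties. Bonferroni adjustment is min(1, m·p) for a declared family
of m comparisons; which comparisons form a family is a pipeline-config
declaration, since no enumeration is given in the source conventions.
Response-class distributions are compared with Pearson's chi-squared test
without continuity correction (a flag enables it). Exact-vs-approximate
switchover thresholds are arguments, not constants.

The test suite pins the exact tests to brute-force enumeration over all
sign assignments / rank subsets for n ≤ 10, and checks the ANOVA's type-I
error rate at α = 0.05 over 1000 null replicates.

## The synthetic cohorts

The generator produces the study conditions by construction:

* **Current-step cells.** 500 ms steps in 50 pA increments, paired
  no-light/light sweeps per step, 50 kHz sampling, resting −80 mV. Spike
  count follows the closed-form rule round(gain × (I − rheobase) ×
  0.5 s) with gain 0.08 Hz/pA; latency scales as 120 ms × rheobase/I;
  ISIs are evenly spaced with zero-mean jitter (SD 1 ms, centered within
  the sweep so the mean ISI is exact). Spikes are triangular templates
  (80 mV height, 1.5 ms half-width, 0.5 ms rise) inserted on a passive RC
  step response (τ = 10 ms) — stereotyped templates rather than an ODE
  neuron model, because they give exact ground truth for
  detector/feature tests that a biophysical model would blur. Gaussian
  noise (default SD 0.3 mV) is added to every sample.
* **Depolarization block.** From the configured block step onward the
  spike count drops by a factor 0.6 and all APs attenuate to
  `full_height × attenuated_height_fraction`. The fraction defaults to
  0.46: with 2 mV bins anchored at whole millivolts, a fraction of
  exactly 0.45 of an 80 mV spike places the attenuated mode precisely on
  a bin boundary — a degenerate configuration for any histogram-mode
  method — while 0.46 (36.8 mV) sits in the bin interior. Light delays
  block onset by `light_extra_full_steps` (default 1) and shifts
  latency/ISI by configurable signed deltas (defaults −10 ms and +5 ms),
  reproducing the resilient-spiking direction by construction.
* **PSP cells.** Noise-free traces are resting potential plus, per light
  pulse, a fast EPSP kernel (difference of exponentials, rise 2 ms, decay
  20 ms) minus a slow IPSP kernel (rise 60 ms, decay 250 ms) delayed by
  30 ms — time constants chosen inside the slow 100–500 ms
  GABA_B envelope, with the onset lag and both τ values exposed as
  configuration, not constants. Kernel amplitudes (2 mV EPSP, 1.5 mV
  IPSP) are placeholders: no population amplitude statistics exist for
  these synapses. Superposition is linear by construction. Class mixtures
  in cohorts are allocated deterministically in cell order — not sampled
  — so realized counts equal the configuration exactly and printed-count
  checks are sharp.
* **Wash-on cells.** Paired `cgp_pre`/`cgp_post` long-pulse sweeps where
  blockade removes the IPSP component (1.5 mV → 0), with n = 9 cells in
  the default acceptance cohort.

Every generator output is a pure function of (configuration, seed); seeds
are recorded in the ground truth, and the global RNG state is restored
after each call.

**What passing tests do and do not show.** Recovery on these cohorts
demonstrates that the pipeline implements its stated rules exactly and is
robust at realistic noise (0.3 mV SD on a 50 kHz trace). It does not
demonstrate robustness to spike-shape drift, electrode artifacts,
seal-quality changes, adaptation, or PSP nonlinearity — none of which the
generator emulates. Real recordings should still be spot-checked against
the per-sweep feature tables.

## Problem sizes and determinism

The shipped checks use desk-scale cohorts chosen as the package's own
validation sizes: 50 seeded noisy cells for block-sweep recovery (exact
recovery required in all of them), 207 cells at 0.3 mV noise for
response-class recovery (45 noiseless), 1000 null replicates for the
ANOVA type-I rate, and exhaustive enumeration for the exact tests up to
n = 10. All randomness flows from explicit seeds; reruns are
bit-identical.

## Known limitations

* The block detector assumes the attenuated and full height populations
  are at least 10 mV apart (the default mode-separation criterion);
  gradual, unimodal height rundown is reported as "no block".
* The OLS ANOVA ignores within-cell correlation unless the
  cluster-robust flag is used.
* Access resistance is taken as supplied metadata; it is not re-estimated
  from test pulses.
* Voltage-clamp currents are stored but not analyzed.
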