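---
title: "Quantifying mTOR-dependent epileptogenesis: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mTOR-dependent epileptogenesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiphys)
```

## The scientific setting

Loss of TSC1/TSC2 function disinhibits mTOR signaling and, in conditional
mouse models, converts a healthy hippocampal network into a
seizure-generating one within roughly two weeks of gene deletion.
Tracking that conversion quantitatively requires two kinds of measurement:
whole-cell patch-clamp features of single pyramidal neurons (how many
action potentials a cell fires, how strongly it adapts, how its synaptic
excitation and inhibition balance, how large its NMDA component is
relative to AMPA), and bulk transcriptome snapshots across the days of
epileptogenesis, with a rapamycin-treated arm to test whether mTOR
inhibition reverses the changes.

`epiphys` implements both analysis arms as testable, deterministic
operations, together with ground-truth simulators for every input class.
The simulators are first-class package code: every extractor in the
pipeline is validated against data whose true parameters are known, which
is the only way to attach error bounds to the pipeline when the original
recordings cannot be redistributed.

## Current-clamp excitability

### Generative model

The current-clamp simulator is an adaptive exponential integrate-and-fire
(AdEx) neuron,

$$C\,\dot V = -g_L (V - E_L) + g_L \Delta_T e^{(V - V_T)/\Delta_T} + I - w,
\qquad \tau_w \dot w = a (V - E_L) - w,$$

with a spike reset $V \to V_\mathrm{reset}$, $w \to w + b$ when $V$
crosses 0 mV. AdEx was chosen because its two adaptation parameters map
directly onto the phenotype of interest: the spike-triggered increment
`b_pA` (pA) and the subthreshold coupling `a_nS` (nS) control
spike-frequency adaptation, so lowering them reproduces the
hyperexcitable, weakly adapting phenotype (more spikes per step, T1/T2
nearer 1). Integration is forward Euler at `dt_ms = 0.025` ms, vectorized
across sweeps, with the exponential argument clipped at 20 and a
divergence guard that aborts with an error if the voltage leaves the
physiological range (non-finite or below −500 mV).

Model spikes are truncated; at each spike time a stereotyped waveform
(quadratic foot carrying 10% of the amplitude, linear rise and fall,
configurable amplitude and half-width) is superimposed on the trace. This
is a documented stylization, not a biophysical claim: it gives the
waveform extractors a realistic shape to work on while the ground truth
(exact spike times) stays known. Default cell parameters are generic
pyramidal-cell magnitudes (150 pF, 10 nS leak, −70 mV rest, −50 mV
threshold parameter, 2 mV slope factor); no quantitative waveform values
are available to fit against, and fitting the simulator to any particular
dataset is deliberately out of scope.

### Feature extraction

* **Spike detection** — local maxima above 0 mV with at least 20 mV
  prominence and a 2 ms refractory separation (all configurable in
  `feature_config()`). The analysis source these values emulate counts
  spikes without stating a rule; these are conservative values for clean
  somatic recordings.
* **F-I curve and rheobase** — spikes are counted inside the step window
  only; the rheobase is the smallest injected current with at least one
  spike, and is `NA` when nothing fires.
* **AP threshold** — the first derivative (central differences, no
  smoothing by default, since smoothing biases half-widths) is scanned
  backward in time from the peak; the first sample with
  $\mathrm{d}V/\mathrm{d}t$ *below* 10 mV/ms is the threshold. The
  convention of a criterion on a *sub*-threshold derivative scanned
  backward is one of two plausible readings of the usual phrasing (the
  other takes the first sample *exceeding* the criterion going forward);
  on steep upstrokes the two coincide to within a sample, and the package
  exposes the criterion in `feature_config()` so either convention can be
  reproduced. Amplitude is peak minus threshold; half-width is the
  linearly interpolated width at the midpoint voltage; maximum rise and
  decay are the extrema of the derivative inside the AP window.
* **Adaptation ratio** — on the sweep firing 16–18 spikes (ties broken
  toward the lowest current, which is deterministic for increasing-step
  protocols), T1 is the first inter-spike interval and T2 the last; the
  ratio T1/T2 is 1 for a non-adapting cell and approaches 0 under strong
  adaptation. Cells with no qualifying sweep are *excluded* (a result
  state with a machine-readable reason, not an error), matching the
  analysis convention the package follows.
* **Passive properties** — resting potential from the pre-step baseline;
  input resistance from the least-squares slope of steady-state
  deflection against hyperpolarizing current; the membrane time constant
  from a single-exponential fit to the onset of the smallest
  hyperpolarizing step; capacitance as $1000\,\tau/R_\mathrm{in}$ (pF).
  Capacitance via $\tau/R$ was preferred over integrating the capacitive
  transient because the latter depends on series-resistance compensation
  settings that are not part of the data model (series resistance enters
  only as a metadata quality flag).

## Voltage-clamp synaptic analysis

### Miniature events

The mini simulator draws Poisson onsets (exponential inter-onset
intervals), difference-of-exponentials kernels with configurable rise and
decay time constants, log-normal amplitudes at a stated mean and CV, and
additive white Gaussian noise. White noise is an analytic convenience —
real recordings carry 1/f components — so detector false-positive rates
measured here are a best case; the acceptance checks therefore also fix
the signal-to-noise ratio (default: 30 pA events over 3 pA noise).

Detection replaces manual event curation with scaled template matching in
the Clements–Bekkers style: at every offset the unit-peak kernel is
fitted with free scale and baseline in closed form, and the detection
statistic is the fitted scale over the residual standard error, at a
criterion of 3.5. Two numerical choices matter:

* The sliding sums are computed with an FFT cross-correlation padded to a
  2–3–5–smooth length; R's mixed-radix FFT degrades to quadratic cost on
  pathological lengths otherwise.
* The template is kept *compact* — peak delay plus one decay time
  constant — and super-threshold offsets closer than 2 ms are merged to
  the best-scoring one. With a long template, two events closer than one
  template length produce a single criterion excursion and the second
  event is silently swallowed; the compact filter keeps frequency
  recovery within 10% up to 15 Hz while holding the false-positive rate
  on pure noise at zero (at the default criterion and SNR). Attempting to
  split merged excursions at local criterion maxima instead either
  over-counts single events or recovers nothing, so that route was
  rejected.
* A detected event must deflect beyond the global trace median in its
  own direction by at least half the minimum amplitude; this rejects
  template matches on the recovery flank of opposite-polarity events.

Per-event kinetics: amplitude is the (lightly smoothed, 0.5 ms boxcar)
peak minus the median of a 3 ms pre-onset baseline — the smoothing damps
the upward bias of a raw extremum under noise; the 10–90% rise time is
interpolated; the decay constant is a least-squares single-exponential
fit from two rise time constants past the peak (where the rising
exponential no longer biases the estimate) to 90% recovery. Per-cell
summaries apply the inclusion rule exactly: at least 50 events or the
recording is flagged excluded. E/I ratios divide mEPSC by mIPSC frequency
(and mean absolute amplitude) within one cell and are undefined — with a
reason — when either recording fails inclusion or the mIPSC frequency is
zero.

### Evoked NMDA/AMPA ratio

At −70 mV the evoked response is AMPA-only (inward); at +40 mV it is the
outward AMPA component plus the slow NMDA component. The analysis
averages the (default 10) sweeps per holding, blanks the 1 ms stimulus
artifact, takes the AMPA peak from the −70 mV average, finds `t10` — the
first post-peak time at which the AMPA current has decayed below 10% of
its peak — and reads the NMDA amplitude as the mean of the +40 mV average
over a 5 ms window centered on `t10` (a point sample would be needlessly
noisy). The quantity "decayed to more than 10%" is interpreted as
*residual below 10%* (decayed by more than 90%); the literal complement
would not isolate the NMDA component at all, which settles the ambiguity.

The simulator scales the AMPA component at +40 mV by 0.4 rather than the
ohmic driving-force ratio 4/7, reflecting AMPA-receptor inward
rectification (polyamine block) at depolarized potentials. The closed-form
value of the composite +40 mV curve at the analytic `t10`, divided by the
AMPA peak, is carried in the ground truth as the oracle the estimator is
tested against.

## Group statistics

* `rm_anova_two_way()` implements the classical univariate mixed-design
  partition (one between-subject factor, complete within-subject factor):
  the between-subject stratum splits into the group effect and
  subjects-within-groups, the within stratum into the within effect,
  interaction, and within-error. It is computed directly from weighted
  cell means, handles unequal group sizes, satisfies the
  $SS$ partition identity to numerical precision, and is tested against
  the independent `stats::aov` error-strata route at $10^{-8}$. No
  sphericity correction is applied by default (matching the reporting
  convention it reproduces); Greenhouse–Geisser is available via `gg =
  TRUE`.
* `one_way_anova_control()` runs the omnibus fixed-effects ANOVA and
  many-to-one post hoc comparisons. Dunnett's test (default) adjusts by
  the distribution of the maximum absolute statistic, evaluated by seeded
  Monte Carlo on the correlated multivariate t (20 000 draws by default;
  the draw count trades precision against runtime and is a parameter).
  Dunn's rank-based many-to-one test with Bonferroni adjustment is the
  alternative, since both names appear in the reporting conventions this
  package mirrors; the comparisons-to-control structure matches Dunnett,
  hence the default.
* `two_sample_t()` wraps `stats::t.test` (Student by default, Welch by
  flag — the source convention does not state which; Student is the
  default). The degenerate both-samples-constant case returns p = 1 by
  convention rather than erroring.

## The count matrix and the expression funnel

### Generator

`simulate_counts()` draws a genes × samples matrix from a negative
binomial with log-normal baseline means, gamma-distributed gene-wise
dispersions (mean 0.1, typical of bulk tissue), and log-normal
library-size factors (CV 0.2 — large enough that size-factor estimation
is non-trivial). The design is six conditions × 4 replicates: control
genotype, days 4/6/8/13 after deletion, and a rapamycin-treated arm.
Planted genes reach their full |log2FC| (default 1.5) at day 13 following
a non-decreasing schedule (0.2, 0.35, 0.7, 1.0 of the full effect),
emulating the escalation of transcriptome changes over epileptogenesis;
a configurable fraction (default 0.95) of planted genes is *rescued* —
treated-arm means equal to the control baseline — while the rest keep
their day-13 effect under treatment. A curated gene subset (default 10%
of genes) stands in for an ion-channel/action-potential gene list; it is
always an input file, never a live database query, so results cannot
drift with annotation versions.

What the generator does not emulate: GC/length biases, batch effects,
count outliers, correlated genes. Passing tests therefore demonstrate
correctness of the estimators under the stated noise model, not
robustness to every artifact of real libraries.

### Normalization and DE testing

Size factors are median-of-ratios against the geometric-mean
pseudo-reference over all-nonzero genes, rescaled so the median factor is
1 — this anchors "a sample with doubled counts" at factor 2 with the rest
at 1. One consequence of any purely relative normalization: globally
rescaling all counts shifts `log2(normalized + 1)` non-affinely through
the pseudocount, so z-score heatmaps are invariant to global scaling only
up to terms of order 1/count (exact invariance is impossible without
dropping the pseudocount).

The DE test is a simplified negative-binomial Wald test, documented as an
approximation to full GLM machinery: gene-wise method-of-moments
dispersions are estimated from *all* conditions in the matrix (per-group
sample variances combined by least squares through the NB mean–variance
relation, so large fold changes do not inflate the estimate), then shrunk
in log space (weight 0.5) toward a fitted `a0 + a1/mu` trend. The log2
fold change contrasts size-factor-weighted group means with a small prior
count; its standard error follows from the NB variance; and the Wald
statistic is referred to a t distribution with twice the dispersion
residual degrees of freedom — the shrinkage contributes roughly as much
information as the gene-wise estimate, in the spirit of moderated
statistics. These choices were fixed by a design requirement of raw-p
calibration under the null simulation (fraction of p < 0.05 within
[0.03, 0.07]), which the acceptance suite re-verifies on every run.
BH adjustment runs across tested genes, and the DE flag is
`padj < 0.05 & |log2FC| > 0.5`; a flag exists to threshold raw p instead,
since both conventions circulate.

### The candidate funnel and rescue

`run_funnel()` executes the stages in order: all genes → "truly
expressed" (normalized count strictly above 10 in at least 50% of
samples; the boundary reading is ≥ half of samples, floor strictly
exceeded) → DE at the reference day versus control → intersection with
the curated list → per-gene one-way ANOVA of log2 normalized counts
across the untreated conditions at α = 0.05. The ANOVA stage applies no
multiplicity correction by default, mirroring a direct per-gene
comparison across conditions; a BH option exists. Stage counts are
recorded and are non-increasing by construction; the up/down split at the
reference day always sums to the DE total.

`rescue_classify()` labels a candidate rescued when the treated arm is
statistically *and* practically indistinguishable from control: the
Dunnett-adjusted p of the treated-vs-control contrast is at least 0.05,
and the empirical-Bayes shrunken |log2FC| is at most 0.5. Both prongs are
needed because non-significance alone cannot assert equivalence. The
shrinkage uses a zero-centered normal prior whose scale is matched to the
upper 5% quantile of the genome-wide raw fold changes (floored at 0.1);
without it, a truly rescued gene at n = 4 crosses the 0.5 bound by
sampling noise alone roughly one time in eight, which would cap
classification accuracy well below what the data support.

### Clustering and PCA

`hclust_complete()` is a direct agglomerative implementation (complete
linkage, Euclidean distance) with a fully specified tie-break: among
equal-distance pairs, the pair whose clusters contain the smallest
original item index wins. Merge heights are non-decreasing (the
ultrametric property of complete linkage), the tree exports to Newick
with branch lengths equal to merge-height differences, and the suite
checks tree identity against an $O(n^3)$ oracle that recomputes every
inter-cluster distance from scratch. `pca_samples()` runs `prcomp` on
per-gene-centered `log2(normalized + 1)` values with samples as
observations.

## Cohort assembly and the end-to-end run

`assemble_report()` aggregates per-cell measures into per-condition
mean ± SEM, applies the per-animal cap (at most 8 randomly picked cells
per animal, seeded and reproducible), and records every exclusion with a
machine-readable reason (`insufficient events`, `no 16-18-spike sweep`,
`undefined ratio`, `per-animal cap`). `run_study()` chains the whole
pipeline on synthetic data — two-genotype current-clamp cohort (the
mutant lowers `b` to 10 pA; cells carry 5% CV jitter on conductance and
capacitance and 1 mV threshold jitter so cohort statistics see realistic
variability), paired minis, one evoked pair, the six-condition count
matrix and funnel — and writes all artifacts plus a manifest under one
directory. Identical configuration and seed give identical outputs.

The command-line surface of this package is R itself: the exported
functions, `run_study()`, and `scripts/acceptance.R` cover the simulate /
analyze / report cycle without a separate shell tool.

## Problem sizes and tolerances

The test suite and the acceptance script run everything at sizes chosen
to exercise the estimators well inside a single-CPU desk budget: AdEx
protocols of 30–40 sweeps at 0.025 ms resolution, 60–120 s mini traces at
0.1 ms, count matrices of 1200–2000 genes × 24 samples, 5000-replicate
Monte-Carlo calibrations for the ANOVA and t-test type-I rates, and
6–10 seeds per stochastic acceptance quantity. Tolerances mirror what
each estimator can deliver under the stated noise model: exact index
agreement for the threshold rule, 2% for noiseless kinetics fits, 10% for
detection-level recovery, 15% for end-to-end ratio recovery, and
[0.03, 0.07] / [0.04, 0.06] calibration bands for the DE test and the
classical tests respectively.

## Known limitations

* The AdEx waveform insertion makes threshold/half-width values internally
  consistent but not biophysically predictive; only spike *times* and
  counts are proper ground truth.
* Template-matching detection undercounts at high rates (≈8% at 15 Hz)
  because near-coincident events merge; deconvolution-based detection is
  explicitly out of scope.
* The NB Wald test approximates, but does not replicate, full GLM
  pipelines (no Cook's filtering, no per-coefficient shrinkage of
  reported fold changes outside the rescue classifier).
* Series-resistance quality control is a metadata flag only; raw Rs
  traces are not modeled.
* The rank-based many-to-one test uses a normal approximation with
  Bonferroni adjustment, which is conservative at small n.
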