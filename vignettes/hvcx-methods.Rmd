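---
title: "Modelling HVC_X intrinsic properties: methods and design notes"
author: "hvcx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling HVC_X intrinsic properties: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hvcx)
```

## The scientific problem

Basal-ganglia projecting neurons of the songbird premotor nucleus HVC
(HVC_X neurons) have strikingly uniform intrinsic properties *within* an
individual zebra finch — similar spike waveforms, similar spike-train timing
— while those properties vary widely *between* birds, in lawful relation to
how similar the birds' songs are. The phenomenon can be summarized
quantitatively by fitting a single-compartment conductance-based model to
each neuron's current-clamp responses and studying the population geometry
of the five fitted maximal conductances (`gNa`, `gK`, `gSK`, `gh`, `gCaT`)
in 5-D conductance space: each bird occupies a tight cluster; clusters
scatter across the species range; the clusters dissolve in juveniles still
learning their song and in adults singing under delayed auditory feedback
(cDAF).

This package implements that entire computational pipeline — simulator,
feature extraction, error function and exhaustive grid-search fitting, and
the population statistics — and, because the original recordings are not
publicly deposited, a synthetic-cohort generator that reproduces the
*statistical structure* of the data so every stage runs and is validated
end to end.

## The model

Membrane potential obeys the single-compartment current balance

$$C_m \frac{dV}{dt} = -(I_L + I_K + I_{Na} + I_{CaL} + I_{CaT} + I_A +
I_{SK} + I_h) + I_{app},$$

in units of mV, ms, pA, pF and nS (so the equation is dimensionally
consistent as written). The five fitted currents are:

* $I_{Na} = g_{Na}\, m_\infty(V)^3\, h\,(V - E_{Na})$ — instantaneous
  activation, dynamic inactivation;
* $I_K = g_K\, n^4 (V - E_K)$;
* $I_{SK} = g_{SK} \frac{[Ca]^2}{[Ca]^2 + k_s^2}(V - E_K)$, driven by a
  first-order calcium pool fed by the two calcium currents — this current
  produces the spike-rate accommodation;
* $I_h = g_h\, r\,(V - E_h)$ with a slow ($\sim$100–400 ms) activation
  variable — produces the sag under hyperpolarization;
* $I_{CaT} = g_{CaT}\, a_\infty(V)^2\, b\,(V - E_{Ca})$ with slow
  deinactivation at hyperpolarized potentials — produces rebound firing.

$I_{CaL}$, $I_A$ and the leak are held fixed: the L-type current is not
separable from `gSK` in fits of this kind, and the A-current is very small
in HVC_X. Capacitance is 50 pF in adults, 75 pF in juveniles (50% larger
cells).

### The reference parameterization is a stand-in

The gating kinetics of the published HVC_X model are defined in earlier
primary literature and are not reproduced here. The constants in
`inst/extdata/reference_parameters.yaml` are therefore an *explicit,
versioned stand-in*: Boltzmann midpoints, slopes and time constants chosen
once so that the reference conductance set displays the canonical HVC_X
phenotype —

* an adapting spike train riding a depolarized plateau at +100 pA
  (monotonically lengthening inter-spike intervals);
* sag and post-offset rebound firing at −140 pA, both abolished when
  `gh = gCaT = 0` (the juvenile-like phenotype);
* natural rest near −70 mV, holding current at −70 mV within the
  experimentally reported ±30 pA, input resistance inside the reported
  181 ± 35 MΩ band;
* spike count non-decreasing over the +40…+200 pA step family, and
  decreasing in `gSK`.

The test suite asserts this phenotype, so any edit to the YAML that breaks
the model class is caught. No claim is made that these constants equal the
original ones; all population-level conclusions here depend only on the
model class, not the exact kinetics.

## Stimulation and numerics

The canonical protocol family is ±40…±200 pA in 40 pA steps plus the
canonical +100 pA (fitting) and −140 pA (sag/rebound) pulses, each 200 ms
flanked by 200 ms of quiescence, delivered from a −70 mV holding
equilibrium. The holding state is computed exactly (all gates at steady
state, calcium at its fixed point, bias = total ionic current at the
target), so a no-stimulus simulation is stationary to integrator precision.
Chaotic stimuli are the x-component of a Lorenz system, seeded,
mean-subtracted and rescaled; they are used for qualitative prediction
checks only, never for fitting.

Integration is fixed-step 4th-order Runge–Kutta with the injected current
treated as piecewise-constant per step (a step edge aligned to the grid is
then represented exactly; interpolating the current across the edge smears
charge by $I\,\Delta t/2$ and degrades convergence to first order — we
measured this and fixed it). Voltage-dependent gating terms are evaluated
through a per-call lookup table (0.05 mV knots, linear interpolation),
which is what makes exhaustive grid searches affordable on one CPU.

**Accuracy statement.** Working step sizes are 0.02 ms for single-trace
work and 0.05 ms inside grid searches (recovery tests generate their
targets at the search step, so the self-consistency oracle is exact).
Sample-wise convergence under step halving is asserted at dt = 0.005 ms
(< 0.1 mV everywhere); at the working steps the *sample-wise* difference
under halving can reach ~1 mV because the late, long inter-spike intervals
of an adapting train are intrinsically phase-sensitive — a microsecond-scale
timing shift on an 80 mV spike is a large pointwise difference. What the
analysis consumes is features, and those are converged at the working
steps: spike counts are identical and spike times agree within 0.5 ms
(a tenth of the 5 ms timing normalizer) between dt = 0.02 and 0.01.

## Feature extraction

Spikes are detected as upward crossings of dV/dt ≥ 10 mV/ms on a ~0.2 ms
smoothed derivative, merged within 2 ms, and validated by a ≥ 15 mV rise
within 5 ms (robust to the 0.3 mV additive noise of synthetic traces; the
same compiled routine serves feature extraction and the grid search's
disregard rule, so the two can never disagree). Threshold is the voltage at
the crossing, amplitude is peak − threshold, duration is full width at half
amplitude. The published feature definitions were in supplementary material
that is not reproduced here, so these operational definitions are explicit
substitutes, stated once and used consistently:

* **plateau amplitude** — mean of inter-spike voltage minima during the
  pulse minus rest (fallback with < 2 spikes: spike-free pulse mean minus
  rest);
* **sag ratio** — $(V_{ss} - V_{min})/(V_{base} - V_{min})$ with $V_{ss}$
  the final-20 ms mean, $V_{base}$ the 50 ms pre-pulse mean;
* **rebound firing** — spike count in the 200 ms after pulse offset;
* **input resistance** — $\Delta V_{ss}/\Delta I$ from 5–25 pA
  hyperpolarizing steps.

## The error function and grid search

The fitting error between a model and a biological response sums squared,
normalized differences over eight features: plateau amplitude, spike
amplitude, spike duration, spike count, the timing of each individual
spike, resting potential, sag ratio, and rebound firing. The published
description sums features with heterogeneous units and does not state
weights; we make the sum unit-free by dividing each difference by a fixed,
versioned species-scale constant (10 mV for amplitudes, 5 ms for
timing/duration, 1 for counts, 0.1 for sag ratio) before squaring. Because
those constants are conventions, *absolute* error values are not comparable
with the published ones — only orderings and ratios are used anywhere in
the package, which is also how such errors are used in the original analyses.

During a grid search, any candidate whose depolarizing-pulse spike count
(or hyperpolarizing-pulse rebound count) differs from the target is
disregarded before the error is computed; checking the depolarizing count
first lets the search skip the second simulation for most candidates. In
prediction and cross-validation nothing can be disregarded, so unequal
counts instead charge a fixed penalty of (pulse duration / 5 ms)² per
unmatched spike; a feature computable on one side only is charged the same
penalty, never silently skipped. Ties resolve to the lexicographically
smallest (gNa, gK, gSK, gh, gCaT) tuple; the candidate enumeration is
lexicographic, so "first minimum" implements this deterministically.

The published full-resolution grid (`speciesGrid()`: gNa 200–2500 by 20,
gK 50–750 by 10, gSK and gh 0–15 by 0.2, gCaT 0–10 by 0.2) has
2,426,127,936 candidates and is cluster-scale; `deskGrid()` spans
workstation-sized sub-grids (5 points per axis ≈ 12 s per neuron here).

## Population statistics

* **Trace volume** $V(B) = \sqrt{\tfrac{1}{N-1}\sum_i \|g^i - \bar g\|^2}$:
  the square root of the summed eigenvalues (trace) of the sample
  covariance. The source alternates between $1/b$ and $1/(N-1)$
  normalizations in adjacent definitions; we use $1/(N-1)$ everywhere so
  the identity $V(B)^2 = \mathrm{trace}(\Sigma)$ holds exactly (asserted to
  1e-10).
* **Geometric volume** $\sqrt{\det \Sigma}$, a length⁵ hyperellipsoid
  measure; zero (flagged degenerate) when neurons ≤ dimensions. Normalized
  volumes divide by the same quantity computed on a pooled reference
  ("species") set supplied by the caller — never hard-coded — so the
  normalization convention cancels. A cloud occupying 0.1 of each axis of
  an isotropic reference yields exactly $10^{-5}$.
* **Mahalanobis distance** $D = \sqrt{x P^{-1} x'}$ with $P$ the pooled
  covariance; scale-invariant (asserted numerically); singular $P$ uses a
  flagged Moore–Penrose inverse on request.
* **MANOVA** on spiking frequency + first three ISIs (cells with < 4
  spikes removed): Wilks' $\Lambda = |W|/|W+B|$ from $T = B + W$, p-value
  by Rao's F approximation (cross-checked against `stats::manova`), seeded
  permutation p available for small cohorts. Pairwise mode Bonferroni-corrects
  over the *testable* pairs (a bird with fewer neurons than covariates makes
  the pair untestable), reporting both that count and nominal C(n, 2).

### Bespoke comparison tests and their calibration

The clustering-distance test draws, for each neuron, one same-bird and one
across-bird partner and compares the two distance samples. The source text
calls the comparison unpaired, but reports df = 240 for 241 neurons — the
degrees of freedom of a *paired* test (unpaired would give ≈ 480). We
implement the paired form, which is also the statistically calibrated one:
under a single shared cloud its type-I error is ≈ 0.05, while the unpaired
form is conservative (≈ 0.02) because the two samples share focal neurons.

The spike-timing and waveform variability comparisons accumulate pairwise
ratios (first spikes against each other, second against second, …, within
spike-count groups; groups of one cell discarded) or pairwise first-spike
mean-squared differences, and compare distributions with two-sample F
tests. When a cell participates in many pairs these values are positively
dependent and the F test is anticonservative — an inherent property of the
published procedure, which we reproduce rather than repair. The calibration
suites therefore use null generators that produce *independent* values
(two-cell spike-count groups with per-index independent times; disjoint
waveform pairs), verifying the test statistic itself is calibrated at
nominal level; results on shared-cell data should be read as orderings with
very small p-values, which is how they are used.

The rundown check (amplitude ratios later-cell/first-cell tested against
1.0) is similarly calibrated with two cells per bird so the pooled ratios
are independent.

## The synthetic-cohort generator

The generator's defaults encode the study conditions:

* **adult** — per-bird centroids drawn across the full published grid
  ranges, log-uniformly for `gNa` and `gK` (their spans are large —
  combined with within-bird jitter the species span of `gNa` reaches the
  reported ~19×) and uniformly for the small conductances; within-bird
  jitter is independent per-axis multiplicative log-normal with
  $\sigma = \log(\mathrm{fold})/2$, folds set to the reported per-axis
  values (1.23, 1.24, 1.14, 1.17, 1.19). The recovery convention is
  $\mathrm{fold} = \exp(2\,\mathrm{sd}(\log g))$, which the generator
  inverts exactly.
* **juvenile** — centroids confined to the low-`gNa`/low-`gSK` sub-box of
  the adult space, 75 pF capacitance, a 30% fraction of neurons with
  `gh` ≈ 0 (the little-sag/no-rebound juvenile phenotype). The per-axis
  fold inflations are not quantified in the source; they are free,
  documented parameters set once (1.8, 2.8, 1.8, 3.5, 1.3 — `gh` and `gK`
  the most inflated, as reported qualitatively) so that juvenile trace
  volumes sit clearly above adult ones, consistent with the reported
  juvenile normalized trace volume of 0.355 ± 0.12 and its t = 7.9
  separation from adults.
* **cdaf** — adult-like centroids with the `gSK` centroid range halved
  (the reported downward `gSK` shift), and per-bird dispersion multiplied
  by $1 + b\log(m/5.9)$ where $m$ is the bird's motif count ($b$ = 1 by
  default; 5.9 motifs is where the published fit crosses the top of the
  adult range). The multiplier scales the *linear* deviation from the
  centroid, so per-axis spread — hence trace volume — follows the
  logarithmic law exactly in expectation; applying it to the log-normal
  $\sigma$ instead makes volume superlinear in the multiplier and breaks
  the law (we measured this and chose the linear form). The default motif
  ladder follows the 4 h…6 days exposure ladder at ~35 motifs per 4 h of
  singing.

Song similarity is generated by perturbing the pairwise centroid distances
with Gaussian noise scaled by $(1 - \mathrm{coupling}) \times 5$ distance
standard deviations and mapping them through a decreasing affine transform
onto (0, 100]. At coupling 1 similarity is exactly affine in distance
(pooled $R = -1$); at the default coupling 0.8 the pooled correlation
concentrates around $-1/\sqrt2 \approx -0.71$, bracketing the reported
$R = -0.70$ regime; at coupling 0 the correlation is null.

Trace noise is additive white Gaussian voltage noise (default σ = 0.3 mV);
no channel noise is simulated.

**What passing tests do and do not show.** The synthetic cohorts share the
real data's *group geometry* (tight within-bird clusters, wide species
ranges, preset-ordered dispersion, similarity coupling) but none of its
biological nuisance structure: no electrode drift, no correlated
conductance co-regulation within birds, no non-Gaussian outliers, perfectly
known protocols. Passing the acceptance suite demonstrates that the
pipeline's machinery is correct and calibrated under those conditions — not
that the biological conclusions would replicate on new recordings.

## Problem sizes used by the validation suites

Desk-scale searches use a 5⁵ grid (3125 candidates, ~12 s per neuron);
recovery is checked on one noise-free and ten noisy (σ = 0.3 mV) targets.
Calibration suites run 1000 replicates per test. Structure checks use
cohorts of 6–8 birds × 3–8 neurons (trace-bearing cohorts drawn from a
mid-range centroid box where every neuron spikes); the coupling check uses
18 birds × 20 seeds, matching the 18-bird song-recorded subset of the
original design.

## Known limitations

* The kinetics are a documented stand-in; absolute fitted conductance
  values are meaningful only relative to this parameterization.
* Error-function weights are conventions; absolute error values are not
  comparable across implementations.
* The F-test-based variability comparisons are anticonservative under
  shared-cell dependence (see above).
* Single compartment, fixed reversal potentials (no GHK), no temperature
  dependence, no synaptic conductances, no voltage-clamp simulation.
* The grid search is exhaustive by construction; no gradient-based or
  Bayesian assimilation is provided.
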