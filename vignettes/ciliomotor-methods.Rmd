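---
title: "Methods: ciliomotor circuit and ciliary activity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ciliomotor circuit and ciliary activity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciliomotor)
```

## The biological problem

Planktonic larvae of many marine invertebrates swim with bands of
multiciliated cells. In nectochaete-stage annelid larvae the whole ciliary
system alternates between two phases: cilia across all bands beat together,
then arrest together ("closures"), in a rhythm with cycle lengths typically
around a minute. The rhythm is autonomous — generated by a small ciliomotor
circuit in which cholinergic neurons (notably a single large head neuron,
here called MC, and a pair of body-spanning Loop neurons) are active during
arrests, while serotonergic neurons are active in anti-phase, during
beating. Ciliary arrest coincides with rising intracellular calcium in the
ciliated cells; beating resumes as calcium falls.

This package implements the computational side of studying such a system:
building and partitioning the synapse-weighted connectome, quantifying
calcium-imaging recordings, quantifying ciliary dynamics from kymographs,
and the associated cohort statistics. A synthetic-data generator emulates
the stop-and-go pacemaker structure so that every analysis stage can be
validated against known ground truth.

## Connectome analysis

**Network model.** Neurons and multiciliated cells are nodes of a directed
graph; an edge `(pre, post)` carries the number of synapses as an integer
weight. Duplicate rows in an edge table are summed at load, because
connector exports naturally arrive one synapse per row.

**Ciliomotor inclusion rule.** A neuron counts as ciliomotor when it forms
at least five synapses *combined* — summed over all multiciliated targets —
onto ciliated cells. The comparison is inclusive (a neuron with exactly
five synapses is retained), and the rule is monotone in the threshold.

**Module detection.** Communities are found by maximising resolution-scaled
Newman modularity on the symmetrised graph (reciprocal weights summed):

$$Q(\gamma) = \sum_c \left[ \frac{w_c}{2m} - \gamma \left(\frac{K_c}{2m}\right)^2 \right]$$

with $w_c$ twice the internal weight of community $c$, $K_c$ its degree
sum, $m$ the total weight, and resolution $\gamma = 1.4$ as the default
(the value at which the ciliomotor network splits into its three
characteristic communities: a prototroch/head module and left and right
trunk modules). The optimiser is a multi-level greedy (Louvain) scheme,
written in the package rather than delegated, with one deliberate
extension: the first restart uses the classic all-singletons start, and
every further restart begins from a *random* partition. The greedy
singleton start can only merge and provably misses some optima on small
graphs; since the global optimum is always a fixed point of single-node
moves, random restarts can reach it. With the default 20 restarts the
optimiser matched an exhaustive search over all set partitions on 50/50
random graphs of up to 8 nodes. Results are deterministic given
`(seed, n_restarts)`.

A consequence of the objective worth knowing: for a uniform clique,
all-singletons scores $-\gamma/n$ against $1-\gamma$ for the single
module, so at $\gamma = 1.4$ any uniform clique of four or more nodes is
*optimally* split into singletons. Cohesive modules at this resolution
need heterogeneous structure (hubs, blocks), which real connectomes and
the planted-block generator both have.

**Cable length.** Manually traced skeletons are jittery; length is
measured after Gaussian smoothing with $\sigma = 6\,\mu m$ along arc
length. The tree is decomposed into unbranched segments between root,
branch points and leaves; each segment is resampled at 0.5 µm, its
interior convolved with an end-renormalised Gaussian kernel, and its
endpoints pinned. Pinning keeps branch points fixed so smoothing cannot
shrink the tree topologically; a straight segment keeps its exact length,
and $\sigma = 0$ returns the raw polyline length.

## Calcium-imaging analysis

**Baseline and ΔF/F₀.** The baseline F₀ is taken from the quietest epoch:
among all contiguous 10-frame windows, the one with minimal sample
standard deviation is selected (earliest wins ties) and F₀ is its *mean*.
The minimal standard deviation itself is not a fluorescence level, so the
mean of the selected window is the only dimensionally sensible reading of
a minimum-variance-window baseline. ΔF/F₀ = (F − F₀)/F₀ and the transform
is exactly invertible given F₀.

**Correlation maps.** Every pixel's time series is Pearson-correlated with
a reference ROI trace, giving one image of coefficients in [−1, 1]. Pixels
with zero temporal variance are marked `NA` — never silently 0 — so static
background is distinguishable from genuinely uncorrelated signal. Pearson
r is invariant to per-series affine transforms, so the map is identical
whether computed on raw or ΔF/F₀ series.

**Cycle length.** The series is mean-subtracted and the discrete Fourier
transform taken; the dominant positive-frequency bin gives the frequency
and its reciprocal the cycle length. No detrending, windowing or
zero-padding is applied by default (padding is exposed as an option):
the fewest hidden knobs, at a bin resolution of `rate/T`. The estimate is
invariant to affine transforms of the trace, so prior 0–1 normalisation
does not change it. Cohort summaries report the median period and the
fraction of recordings in an inclusive band (default 50–100 s).

**Motion correction** is rigid integer translation registered to the
first frame by exhaustive search up to `max_shift`, scored by Pearson
correlation of the overlap; vacated pixels are filled with the frame
median. This deliberately handles only the rigid-drift case.

**Derivatives** are central differences scaled by the frame rate,
one-sided at the ends.

## Ciliary activity analysis

**Kymographs** are sampled from movies by bilinear interpolation at unit
arc-length steps along a polyline, optionally averaged across a
perpendicular width.

**Arrest detection.** Arrested cilia leave a static stripe, so the
temporal variance of the position-averaged signal collapses. The detector
slides a standard-deviation window (default choices in tests: 9 frames)
over that signal, references the upper quartile of sliding std as the
beating level, and marks frames below a threshold fraction (default 0.25)
of it. A frame only scores low when its whole window lies inside the
arrest, which shortens raw runs by the window half-widths; the detector
corrects this known bias by dilating runs and merging any overlaps. Runs
shorter than `min_duration` (default 0.2 s worth of frames — below a
typical inter-beat interval, above frame noise) are discarded. The
statistic is invariant to affine intensity rescaling. Interval bounds are
half-open `[start, end)` in 1-based frames (R convention; the time of
frame k is `(k-1)/rate`).

**Beat frequency** is the median across positions of per-position
spectral peaks over the longest beating segment (arrest frames excluded);
estimates at the Nyquist bin are flagged unreliable.

**Resumption delay.** Bands resume beating in a fixed order with a small
delay. The default measure matches each resumption event (interval end)
in band *a* to the nearest one in band *b* within `max_lag` and averages
the signed differences — chosen because resumption, not arrest onset, is
the sharply defined event. A cross-correlation variant (lag maximising
the overlap of the binary arrest indicators) is exposed for comparison;
both agree to within a frame on planted offsets. Event timing is
quantised to frames, so sub-frame delays (tens of milliseconds at video
rates) need correspondingly high frame rates.

**The derivative law.** The qualitative law — cilia arrested while
calcium rises, beating while it falls — is quantified as two fractions:
arrest frames with positive d[Ca²⁺]/dt and beating frames with
non-positive d[Ca²⁺]/dt. Frames with |derivative| below a dead-band of 5%
of the derivative's interquartile range are excluded from both
denominators, so numerical-noise sign flips near zero slope do not count.
On noiseless generated scenes both fractions are exactly 1; under
arrest labels assigned independently of calcium both sit near 0.5.

## The synthetic-data generator

The generator is first-class, tested code, and its defaults are the study
conditions the analyses assume:

- **Pacemaker traces.** A square-wave drive with period 71 s (a typical
  pacemaker cycle) and duty 0.5 is 1 during the arrest half of each
  cycle; "sync" cells follow it, "anti" cells its complement. A
  first-order indicator kernel `dc/dt = s − c/τ` with τ = 1.5 s (a slow
  genetically encoded indicator regime; an exposed parameter, not a
  measured value) is integrated by forward Euler at the frame rate, and
  F = 100(1 + c) plus Gaussian noise. An optional sigmoidal-edge drive
  tests robustness of the spectral analysis to waveform shape.
- **Movies** render each cell as a disk following its trace over flat
  background, with per-pixel noise and optional accumulating integer
  drift; ground-truth masks are returned pre-drift, and overlapping cells
  are rejected rather than blended.
- **Kymographs** carry a metachronal travelling wave
  `A sin(2π f t + g p) + B` during beating and a flat `B` during planted
  arrests.
- **Planted connectomes** are directed block models: dense heavy edges
  within blocks, sparse light ones between; a degeneracy flag is raised
  when `p_out >= p_in`.
- **The connectome fixture** (`make_paper_fixture()`) encodes the
  published census — 80 multiciliated cells (23 prototroch, 8 akrotroch,
  6 nuchal, 1 crescent, 8 metatroch, 8+14+12 paratroch) — and the
  published MC synapse budget: one edge to each of the 23 prototroch
  cells with weights in [3, 25] summing to 335, and 341 outgoing synapses
  in total. The per-cell weight sequence is a fixed documented choice
  (any sequence meeting the printed constraints is equally valid), the 6
  non-prototroch synapses are placed on two metatroch cells, and all
  non-MC weights are synthetic, chosen to plant the three-community
  left/right organisation of the circuit. The fixture is a labelled
  synthetic stand-in, not reconstructed data.
- **The cohort generator** (`gen_mc_cohort()`) plants a fixed set of 96
  periods with median 71 s and 41/96 (43%) in the inclusive 50–100 s
  band, with faster and slower tails on either side — the published
  cohort summary statistics. Each recording spans a whole number of
  cycles (at least 3 cycles and at least 600 s, at 1 Hz), so planted
  periods sit on spectral bins and the median is recovered exactly in
  the noiseless limit.

What the generator does *not* emulate: non-rigid motion, photobleaching,
indicator saturation, irregular (non-stationary) rhythms, spatially
correlated noise, and per-cilium kinematics. Passing tests on generated
data therefore validate the *computations* — baselines, spectra,
correlation maps, detection logic — not the biological variability of
real recordings.

## Numerical choices and problem sizes

- Frames are 1-based throughout; times are `(k-1)/rate` seconds;
  intervals are half-open `[start, end)`.
- Ties: the earliest window wins in baseline selection; the lowest
  frequency wins among equal spectral peaks.
- The Wilcoxon signed-rank test drops zero differences, mid-ranks ties,
  and enumerates the exact null via the rank generating function up to
  n = 25 (two-sided p = `2 min(P(W ≤ w), P(W ≥ w))`, capped at 1); above
  that a normal approximation with tie and continuity corrections is
  used. Both modes are exposed. The D'Agostino–Pearson omnibus K² is
  implemented from the standard skewness and kurtosis z-approximations
  and requires n ≥ 20. Unpaired t-tests default to Welch; the pooled
  form is an option.
- Test-suite problem sizes were chosen to exercise each method at
  desk scale: 600-frame kymographs, 32×32-pixel movies, 96-trace
  cohorts at ≥ 600 s, exhaustive modularity checks up to 8 nodes, 2000
  replicates for test calibration. The whole suite runs in well under a
  minute.

## Known limitations

- Module detection guarantees optimality only where exhaustive search is
  feasible; on larger graphs the restarts give a strong heuristic, not a
  certificate.
- Arrest-edge localisation is limited to about half the sliding-std
  window even after bias correction.
- Delays are quantised to frames; cross-correlation on indicators does
  not interpolate sub-frame lags.
- The rigid registration handles translation only — no rotation, scaling
  or non-rigid deformation.
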