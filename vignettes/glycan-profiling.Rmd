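---
title: "Quantifying serum N-glycan HILIC-UHPLC profiles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying serum N-glycan HILIC-UHPLC profiles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoprof)
```

## The problem

A whole-serum N-glycan profile is a fluorescence chromatogram: released
glycans labelled with 2-aminobenzamide, separated on a HILIC (amide)
column, and read out as intensity against retention time. Dozens of
partially overlapping peaks carry the biological signal as *relative*
areas. Comparing profiles across samples requires (i) a reproducible
quantification of every peak in every sample over a *common* peak set
and (ii) statistics that separate within-person (technical, tube,
processing) variation from between-person (biological) variation.
`glycoprof` implements both halves, plus a generator of synthetic
chromatograms with exact ground truth that stands in for instrument
data in all tests.

## Quantification model

**Normalization and alignment.** Percent peak areas are invariant to
any positive rescaling of a trace, so the normalization contract is
simply unit total trapezoidal area (`normalize_intensity()`). Alignment
is shift-only: each trace is translated so its global-maximum apex
(the dominant biantennary-glycan peak in serum profiles) lands on the
median apex time of the collection. No time warping is attempted —
modern UHPLC gradients are stable enough that residual per-peak jitter
is handled downstream by the matching tolerance, and a warping step
would couple samples' intensities before integration.

**Peak calling.** The smoothed signal and its first two derivatives are
estimated by local-polynomial Gaussian-kernel regression
(`KernSmooth::locpoly`). Local cubics are used for all three estimates:
for the first derivative specifically, a cubic fit preserves the
zero-crossing of closely spaced shoulder peaks (e.g. the GU 7.65/7.72
pair, 0.23 min apart at peak widths of ~0.05 min) at bandwidths where a
local quadratic already merges them. An apex is a down-going zero
crossing of f̂′ (linearly interpolated between grid points) with
f̂″ < 0; troughs are the up-going crossings; trace ends close the
outermost intervals.

Bandwidth is the pipeline's main knob. `"auto"` uses the direct plug-in
rule (`KernSmooth::dpill`) with up to 21 pilot blocks — the default
five-block pilot treats a 42-peak trace's structure as noise and
oversmooths roughly sixfold. The plug-in value is clamped to
[3 grid steps, span/10], and falls back to 5 grid steps when the rule
fails (as on noiseless signals). The second derivative reuses the
bandwidth inflated by 1.5, reflecting the larger optimal bandwidth of
curvature estimation; it only gates apex acceptance, so its exact value
is uncritical.

**Prominence filter.** Real traces contain sub-noise wiggles that are
not glycan peaks. An apex is kept when its smoothed height exceeds the
higher of its two flanking troughs by at least `min_prominence` times
the maximum smoothed intensity. The trough reference is floored at
zero because local-polynomial fits ring below the (physically
non-negative) baseline at sharp peak bases, and prominence measured
from such undershoot would promote flat baseline bumps. The default is
0.05% of the trace maximum: the smallest peak worth retaining in a
whole-serum panel runs near 0.06% of total area against a largest peak
of ~36% — a height ratio of ~0.17% before smoothing attenuation — so
the threshold must sit well below 0.1% while remaining, under the
default noise model, about nine smoothed-noise standard deviations
above the floor. Raising it prunes aggressively; it is exposed in
`pipeline_config()`.

**Integration.** Peak area is the trapezoidal integral of the *raw*
normalized trace between perpendicular cuts at the troughs
("perpendicular drop"). Integrating the raw rather than the smoothed
trace keeps areas independent of the bandwidth. Boundary intensities
are linearly interpolated, which makes integration exactly additive:
a contiguous run of peaks partitions the signal with no double
counting, to machine precision. Negative intervals (noisy baselines)
clip to zero and are logged, never silent.

**GU calibration.** The retention-time → glucose-unit map is a
monotone (Hyman-filtered) piecewise cubic through the ladder apexes,
which passes through every ladder point exactly and cannot oscillate
between points — the classic high-order polynomial fit can. Outside
the ladder span the map extrapolates linearly along the end segments
with a warning. The neutral/charged split is positional (first 16 of
42 groups) when the canonical 42-group layout is recovered, and
otherwise uses the threshold GU < 8.3, the midpoint gap between the
canonical last-neutral (8.15) and first-charged (8.49) peaks.

**Cross-sample matching.** All samples' apex times are pooled and
clustered by average-linkage agglomerative clustering on |Δt|, cutting
the tree at `position_tolerance` (default 0.1 min). Average linkage is
a deliberate choice: the cut height then compares against the *mean*
within-group spacing (≈ 1.13 × jitter SD for Gaussian jitter), whereas
a complete-linkage cut compares the group *diameter* — for 20–30
samples the range of N(0, 0.02 min) jitter regularly exceeds 0.1 min,
so a complete-linkage cut splinters true peak groups while any
tolerance large enough to avoid that would begin merging neighbouring
peaks (closest template spacing 0.27 min). Simulation confirms
average linkage reproduces the nearest-template-position assignment in
20/20 seeded cohorts where complete linkage manages 2/20. Clusters
holding two peaks from one sample are split by reassigning the peak
farther from the cluster median. Groups present in at least
`min_fraction` (default 0.5, inclusive) of all samples are retained.

**Imputation.** A sample missing a retained group — typically in
overlapping-peak regions — gets an imputed apex at the group consensus
time plus the sample's own time offset, linearly interpolated between
its nearest matched groups on either side (constant beyond the edges).
Boundaries are the group's median trough offsets applied at the imputed
apex; conflicts with neighbouring boundaries resolve by midpoint split;
all cells are flagged and re-integrated from the raw trace, so the
matrix is complete by construction.

## Statistical battery

Let `x` be a percent area (rows sum to 100; the neutral subset is
renormalized to 100 within itself before subset analyses).

* **Geometric mean** `exp(mean(ln x))` and the **log-normal CV**
  `100·√(exp(s²) − 1)`, `s` the n−1 standard deviation of `ln x`. Two
  variants are emitted: pooled across all samples (dominated by
  inter-individual spread) and the mean across patients of the
  within-patient CV (`intra_individual_cv()`), which isolates
  tube/processing variation; reproducibility claims refer to the
  latter. Zeros are replaced by half the column's smallest positive
  value before logs, with a message per substitution batch.
* **Pearson correlation** between sample profiles, and the distance
  `d = 1 − |r|`. `d` is symmetric with zero diagonal but *not* a
  metric; it is used only for complete-linkage clustering and
  classical MDS, neither of which needs the triangle inequality. The
  absolute value means a perfectly anti-correlated pair is "close" —
  irrelevant in practice since glycan profiles correlate positively.
* **Complete-linkage clustering** on `d`, exported as Newick with
  branch lengths from merge heights; leaf order is deterministic given
  the sample order.
* **PCoA / classical MDS** via double-centering of −d²/2
  (`stats::cmdscale`); negative eigenvalues (possible for
  non-Euclidean d) are reported and never used for coordinates.
* **Blocked ANOVA** per peak: log percent area ~ patient + tube,
  restricted to patients with all three tubes, so the design is a
  balanced complete block (asserted at run time; the tube sum of
  squares is then unambiguous). Bonferroni correction multiplies by
  the retained-group count, capped at 1.

## The synthetic generator

`simulate_dataset()` draws, per patient, a profile
`template × exp(N(0, σ_inter²))` renormalized to 100, then per tube a
perturbation `exp(N(0, σ_intra²))` and optional multiplicative tube
effects, renormalized again. Traces are sums of Gaussians (area = true
percent, σ = 0.05 min) at `rt_model(GU) + jitter + shift`, plus a slow
sinusoidal baseline and white noise on a 0.005-min grid; a glucose
homopolymer ladder (integer GU 4–14, no jitter) accompanies every
dataset. Truth tables carry each sample's true percent areas, apex
times and shift.

Default parameters and what they encode:

| parameter | default | rationale |
|---|---|---|
| template | 42 peaks, GU 5.89–12.50 | canonical whole-serum 2-AB panel; mean areas span 0.06–36.29% |
| σ_inter (log) | 0.3 | individuals differ markedly (pooled CV ~30%) |
| σ_intra (log) | 0.02 | repeat tubes nearly identical (within-patient CV ~2%) |
| rt model | linear, GU 5.89 → 16 min, 12.50 → 38 min | the panel's elution window on a BEH-amide gradient |
| peak σ | 0.05 min | narrow UHPLC peaks; closest template pair 0.27 min stays resolved |
| RT jitter | 0.02 min SD/peak | run-to-run retention drift after alignment |
| sample shift | 0.05 min SD | global drift removed by alignment |
| baseline | amplitude 0.3, period 15 min | slow gradient drift, ~0.1% of the largest peak height |
| noise SD | 0.05 | detector noise ~10% of the smallest peak height |
| grid | 0.005 min | ten points per σ |

With these defaults the simulated regime reproduces the qualitative
behaviour expected of real serum panels: intra-individual Pearson r
above 0.99, clean patient-wise clustering, within-patient CVs of ~1–5%
for major peaks and much larger for noise-limited minor peaks.

What the generator does **not** emulate: exponentially modified
(tailing) peak shapes, inter-batch instrument drift, carry-over, and
sialic-acid degradation chemistry. Passing tests therefore demonstrate
correctness of the algorithms under the stated statistical structure,
not robustness to every instrument pathology; the bandwidth,
prominence and tolerance knobs exist precisely because real data will
need them re-examined.

Seeding is hierarchical — dataset, patient, sample and noise draws use
seeds derived from the single config seed — so an individual sample's
draw is stable when the cohort size changes.

## Numerical choices and edge cases

* Zero crossings are localized by linear interpolation of f̂′ between
  grid points; apex localization error is far below the grid step.
* A renormalization-to-100 subtlety: a peak holding a fraction `w` of
  total area has its effective log-scale variation shrunk by roughly
  `(1 − w)` after closure, so the largest peak's within-patient CV
  estimates run below the raw σ_intra — a property of closed
  (compositional) data, not an estimator bug; tests assert the
  closed-form expectation.
* With `n = 3` tubes per patient the per-patient SD carries the usual
  small-sample factor (c₄ ≈ 0.886), which the mean within-patient CV
  inherits.
* Degenerate inputs fail loudly and early: non-monotone time axes,
  zero-integral traces, non-monotone ladders, unmatched samples,
  incomplete block designs, matrices with unfilled cells.
* Ties in the alignment reference (even sample counts) resolve to the
  median; ties in cluster reassignment resolve to the lower sample
  index, making every output byte-reproducible under a fixed seed.

## Problem sizes used in the shipped tests

The test suite and the acceptance script run entirely on synthetic
data: cohorts of 10 patients × 3 tubes (30 traces of ~5200 points),
20 repeated cohorts for clustering and ANOVA calibration summaries, a
12-replicate technical-reproducibility run, and hand-sized fixtures
for the closed-form oracles. These sizes make every stage's behaviour
measurable while keeping the default check fast; nothing in the
implementation depends on them.

## Known limitations

* Shift-only alignment cannot correct non-linear retention drift; with
  severe drift the matching tolerance must grow, eventually merging
  close peaks.
* Perpendicular drop under-estimates the smaller of two heavily
  overlapped peaks (no deconvolution, by design).
* The prominence filter is global; a locally adaptive threshold would
  behave better under strongly sloping baselines.
* `1 − |r|` clustering is scale-free but insensitive to profile
  differences that preserve correlation, e.g. uniform multiplicative
  changes across all peaks.
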