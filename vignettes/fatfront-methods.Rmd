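---
title: "Whole-muscle fat-fraction profiling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-muscle fat-fraction profiling: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fatfront)
```

## The measurement model

Two-point Dixon MRI yields co-registered fat (`F`) and water (`W`)
magnitude images; the voxelwise fat fraction is

$$\mathrm{FF} = 100 \cdot \frac{F}{F + W} \quad [\%].$$

Where the total signal `F + W` falls at or below a noise threshold
`epsilon` (default 0), the ratio is the noise floor divided by itself and
carries no information: those voxels are marked missing and excluded from
every downstream mean, rather than contributing spurious 0/0 values. The
map is invariant to any positive rescaling of both channels, which is why
inter-protocol intensity differences do not propagate.

**Scanner-upgrade harmonization.** When a reconstruction-software change
shifts the FF scale mid-study, baseline maps are mapped through a linear
cross-calibration `FF' = a·FF + b` (defaults `a = 1.1864`,
`b = −2.7878` percentage points, fitted on patients scanned under both
versions). The raw line sends FF below ~2.35% negative and above ~86.6%
past 100, so outputs are clipped to `[0, 100]` — clipping preserves the
range invariant at the cost of flattening the extreme percent or so of
the scale, which whole-muscle means are insensitive to. The correction is
voxelwise and applied to baseline maps only.

**Stack stitching.** Hip-to-ankle coverage is acquired as axial stacks
with a fixed overlap (9 slices = 45 mm at the default 5 mm thickness).
In overlap regions each output slice is taken from the stack in which it
lies farther from that stack's edge, because coil sensitivity — and with
it fat–water separation quality — degrades toward stack edges. The
distance-to-edge rule is deterministic and switches stacks at the overlap
midpoint; voxelwise averaging is available as an alternative policy. Gaps
between stacks are a hard validation error, never interpolated.

**Orientation and alignment.** All volumes are normalized slice-1-distal.
Longitudinal pairs are cropped to their shared feet–head extent; no
voxelwise registration is attempted, because every per-muscle analysis
runs on that muscle's own relative-length axis and needs only consistent
coverage.

## Profiles, segments, and localized sampling

A muscle's profile is its per-slice mean FF over labeled, non-missing
voxels, ordered distal to proximal. Slice `i` (0-based) of `N` sits at
relative length `100·i/(N−1)`, pinning the endpoints to exactly 0% and
100% and making muscles of different lengths comparable. Interior slices
with zero labeled voxels (segmentation holes) are dropped with a warning
and positions are computed over the retained slices.

Five equal segments partition relative length into `[0,20), [20,40),
[40,60), [60,80), [80,100]` (half-open, last closed). For any `N ≥ 5`
every bin receives at least one slice under the position formula, so
segment means are always defined. Segment (and whole-muscle) means are
voxel-weighted, hence identical to the plain mean over the underlying
voxel set; volume-weighted composites over muscles likewise equal the
pooled voxel mean on a shared grid.

Two reduced sampling schemes mimic clinical shortcuts: `central5` takes
five contiguous slices starting at `floor((N−5)/2)` (the extra slice of
an uneven split falls proximal — any fixed convention works, this one is
documented and tested), and `spread5` takes the slices nearest 10, 30,
50, 70 and 90% of muscle length, rounding half away from zero. The
rounding is done in integer arithmetic, `(k·(N−1)+5) div 10`, because
floating-point products like `0.7·45` land a hair below an exact `.5` tie
and would flip the convention. Subsampled values are *unweighted* means
over the selected slices — a five-slice acquisition has no volume context
to weight by — whereas anything called "whole-muscle" is voxel-weighted;
for the `whole` scheme in the bias audit the two coincide by definition,
so its error is identically zero.

The profile-shape heuristic (`decreasing` / `reversed` / `u_shape` /
`homogeneous` / `other`, threshold 5 pp, fixed evaluation order) is a
deterministic convenience label, not a validated classifier: published
work classified shapes visually, and we make no claim of equivalence.

## The fat-front model

Profiles of partially infiltrated muscles follow a high distal plateau, a
transition, and a spared proximal plateau. We model this as a reversed
logistic

$$\mathrm{FF}(x) = \pi_{base} + \frac{\pi_{top} - \pi_{base}}
{1 + \exp\!\big((x - x_0)/w\big)}, \qquad x \in [0, 1],$$

with `x` the relative position (0 distal), front position `x0` at the
half-maximum point, and width `w > 0`. The logistic family is a choice —
nothing in the data dictates this sigmoid over another — made for its
closed-form mean
(`coverage C(x0, w) = w·[log1p(e^{x0/w}) − log1p(e^{(x0−1)/w})]`,
numerically stable for small `w`) and interpretable parameters. `x0` may
sit in `[−0.5, 1.5]`: fronts beyond the muscle ends render fully spared
or fully infiltrated muscles.

**Fitting.** Bounded nonlinear least squares (Levenberg–Marquardt via
`minpack.lm`) on `(π_base, amplitude, x0, w)` — the amplitude
parameterization enforces `π_base ≤ π_top` by construction — with a
data-driven start (plateaus from profile extremes, `x0` at the
half-maximum crossing) plus seeded random restarts (default 10 total).
The lowest-RMSE fit wins; a profile with (near-)zero variance carries no
front information and returns a flagged plateau-only fit rather than a
spurious position. At least 8 slices are required; fewer cannot constrain
four parameters.

**Progression law.** For synthesis and simulation, the front advances
proximally with a velocity that depends on current whole-muscle FF
through a Gaussian bell `v(FF) = v_max · exp(−((FF − μ_v)/s_v)²)`,
defaults `μ_v = 35%`, `s_v = 20%` — encoding progression that is fastest
at intermediate (30–40%) severity and slow in both nearly spared and
nearly end-stage muscles. `v_max = 0.04` relative lengths/year was chosen
so a typical 80-pp-amplitude muscle at peak velocity gains roughly 3 pp
of whole-muscle FF per year, the order of magnitude reported for
intermediately affected lower-extremity muscles. The width grows by
`dw = 0.02`/year, flattening the slope as infiltration advances.

Width growth is *mean-conserving*: after widening, `x0` is re-solved so
the whole-muscle mean equals the value attained by the advance alone, and
widening is capped once the front saturates the proximal end. A naive
`w ← w + dw·t` alone would *reduce* the mean of any muscle past 50%
coverage — i.e. fatty replacement would regress, which it does not. With
`dw = 0` the position advance is exactly `v·years`; with `dw > 0` the
mean is still monotone non-decreasing, which is the property the analysis
relies on.

## Synthetic phantoms

`generate_leg()` builds a label map of disjoint elliptical cylinders
(radii 6–10 mm, lengths 55–85% of the leg) on the acquisition grid
(1.36 × 1.36 × 5 mm), paints each muscle with its front profile, adds
voxelwise Gaussian noise in FF space (default SD 2 pp, clipped to
[0, 100]), converts to a Dixon pair `F = FF·I`, `W = (100 − FF)·I`, and
splits the leg into overlapping stacks. Noise is applied in FF space
rather than as complex-valued Dixon noise — adequate for testing the
analysis chain, not a physics simulation. A subcutaneous fat shell
(FF 90%) frames the field of view. Per-muscle whole-FF targets are drawn
uniformly over 3–87% and the front position solved to hit them, so every
baseline-severity bin is populated the way a mixed cohort populates them;
plateaus draw from `π_top ∈ [60, 95]`, `π_base ∈ [0, 6]`,
`w ∈ [0.04, 0.12]`.

`generate_cohort()` (defaults: 9 patients × 12 muscles, follow-up
3.67 years — 3 years 8 months) regenerates each leg at follow-up from
fronts advanced by the progression law, with a per-patient severity
multiplier on `v_max` drawn from `[0.6, 1.4]` to model between-patient
heterogeneity. All draws flow from one master seed with fixed per-leg
offsets; identical seeds give bit-identical volumes.
`simulate_profile_cohort()` produces profiles directly from the front
model (slice-mean noise, constant voxel count) for studies needing
hundreds of muscles, where voxel rasterization adds runtime but no
information; the voxel path is exercised by the leg generator.

What the phantoms do **not** contain: partial-volume mixing beyond
voxelization, bias fields, motion, fat–water swaps, anatomically shaped
muscles, or within-muscle heterogeneity beyond the 1-D front. Passing
tests therefore demonstrate that the *analysis chain* is correct and that
the claimed signatures follow from front-like infiltration — not that
real scanners or real anatomy behave this simply.

## Statistics

The proximo-distal gradient is estimated by a random-intercept model
`FF = β₀ + β₁·segment + u_patient + ε` (segment numeric 1–5), REML, with
variance-components structure — muscles are level 1, patients level 2.
Baseline-bin contrasts of annualized change use the bin as a fixed factor
with reference `0–10%` and Bonferroni correction at `m = 8`. Both
delegate to `nlme::lme`; fixed-effect p-values use `nlme`'s containment
(residual-df) approximation, and since the df convention behind published
p-values is rarely stated, estimates and standard errors are the
quantities to compare across software, p-values only approximately. If
REML fails to converge the gradient falls back to the pooled OLS slope,
flagged `converged = FALSE`.

The Wilcoxon signed-rank test drops zero differences and midranks ties;
for `n ≤ 25` the two-sided p-value is exact, from the full null
distribution of the positive-rank sum computed by dynamic programming
over doubled midranks (doubling makes tied midranks integral, so the
distribution is exact even with ties — which off-the-shelf exact
implementations refuse). Above `n = 25` it defers to the standard normal
approximation with continuity correction. At `n = 7` the achievable size
nearest 0.05 is `6/128 ≈ 0.047`, which the suite verifies empirically.

Bland–Altman summaries report mean error, sample SD (`n−1`), and limits
of agreement `mean ± 1.96·SD`; the multiplier is configurable since
conventions differ. The absolute-error significance test is an
intercept-only random-intercept model on `|error|` grouped by patient; a
single-patient input degrades to a one-sample t-test with a warning.

Binning conventions: severity classes (`<10`, `10–30`, `30–60`, `>60`)
and 10-point baseline bins are half-open `[lo, hi)` — boundary values
belong to the upper bin — and fat fractions ≥ 90% fold into `80–90` with
a warning. Empty bins are reported as empty, never as zero change.

## Problem sizes and tolerances

The test suite and the acceptance script run entirely on seeded synthetic
data at sizes chosen to keep the full run in minutes on one core while
leaving the statistical checks well-powered: 1,000 random profiles for
the enumeration-oracle equivalences (tolerance 1e-9 relative), 200
replicates for noisy front recovery (`x0` within ±0.05, ≥95% of fits)
and for mixed-model CI coverage (target ≈95%, accepted 90–99%), 10,000
replicates for the signed-rank size check, the default 9 × 12-muscle
voxel cohort for the wave signature, and 200 front-shaped muscles at
10–60% FF for the sampling-bias direction. Noiseless round-trips through
the full map–stitch–profile chain agree with the analytic front to
< 0.5 pp (the slack covers mask-edge effects only; with slice-constant
generation the agreement is exact to machine precision).

## Known limitations

- The front model is 1-D along the muscle axis; medial fat bulks,
  counter-gradients and U-shaped profiles found in a minority of real
  muscles are represented only as the heuristic's `other`/`u_shape`
  labels, and the generator does not produce them.
- The progression law is phenomenological; it reproduces the wave-like
  signature but is not a biophysical model of disease spread.
- Harmonization assumes one global linear map; spatially varying
  reconstruction differences are out of scope.
- Left/right and composite weighting pools both legs' muscles into a
  single volume-weighted set; alternatives (weight-then-average) differ
  at second order.
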