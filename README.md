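# fatfront

Whole-muscle proximo-distal fat-fraction profiling for quantitative muscle
MRI.

## The problem

In facioscapulohumeral muscular dystrophy (FSHD) and other fatty muscle
diseases, muscle tissue is progressively replaced by fat. Quantitative
Dixon MRI measures this as a voxelwise **fat fraction**
`FF = 100 · F / (F + W)` (percent), where `F` and `W` are the fat and
water images. Clinical protocols often quantify a muscle from a few slices
at its belly — but fat does not infiltrate uniformly: it enters distally
and advances proximally as a **fat front**, so a central sample can badly
misestimate both severity and progression. This package implements the
whole-muscle alternative for analysts working with co-registered fat/water
volumes and muscle label maps:

- fat-fraction mapping with a noise-floor mask, a linear scanner-upgrade
  harmonization (`FF' = clip(1.1864·FF − 2.7878, 0, 100)`), and stitching
  of overlapping acquisition stacks (distance-to-edge overlap policy);
- per-muscle, per-slice profiles on a relative-length axis (most distal
  slice 0%, most proximal 100%), five equal proximo-distal segments, and
  volume-weighted whole-muscle and composite fat fractions;
- a parametric front model
  `FF(x) = π_base + (π_top − π_base) / (1 + exp((x − x0)/w))`
  — a reversed logistic with distal plateau `π_top`, proximal plateau
  `π_base`, front position `x0` and width `w` — with bounded multi-start
  least-squares fitting and a bell-shaped progression law
  `v(FF) = v_max · exp(−((FF − 35)/20)²)` peaking at intermediate
  severity;
- longitudinal change per year, 10-point baseline-severity bins, and the
  segment-wise change matrix whose per-bin peak moves proximally with
  severity (the "wave");
- a localized-sampling audit: error of central-5 / spread-5 slice schemes
  against whole-muscle values, Bland–Altman limits of agreement, and a
  random-intercept model of the absolute error;
- the inferential layer: random-intercept (patient-level) REML mixed
  models for the segment gradient and baseline-bin contrasts, exact
  small-sample Wilcoxon signed-rank tests, Bonferroni correction;
- a seeded synthetic phantom generator (tubular muscles, front-shaped
  infiltration, overlapping Dixon stacks, longitudinal propagation) so the
  entire pipeline runs and is tested without patient data.

## Worked example

```r
library(fatfront)

# a phantom leg: 4 muscles, 60 slices, two overlapping Dixon stacks
leg <- generate_leg(synthetic_leg_config(n_muscles = 4, n_slices = 60,
                                         seed = 7))
ffv <- stitch_stacks(lapply(leg$stacks, compute_ff_map))
prof <- extract_profile(ffv, leg$labels, 1)

whole_muscle_ff(prof)
#> [1] 67.49445
segment_means(prof)$ff
#> [1] 94.616685 94.565869 91.744714 52.140295  5.706591
fit <- fit_front(prof, seed = 1)
unlist(fit$params)
#>     pi_top    pi_base         x0          w
#> 94.6143539  1.4757873  0.7139887  0.0532054
leg$truth[1, c("pi_top", "pi_base", "x0", "w")]
#>     pi_top  pi_base        x0          w
#> 1 94.61183 1.462496 0.7136564 0.05326844
```

The profile reads distal → proximal: the distal 60% of this muscle sits on
an infiltrated plateau near 95% fat, then the fat front (at 71% of muscle
length, `x0 = 0.714`) drops to a spared proximal end near 1.5% — and the
fit recovers the generating parameters from 2-pp-noise voxel data. The
whole-muscle value, 67.5%, is what a trial endpoint should see; a
central-slice protocol samples the distal plateau instead:

```r
subsampled_ff(prof, "central5") - whole_muscle_ff(prof)  # central 5 slices
#> [1] 25.16479
subsampled_ff(prof, "spread5") - whole_muscle_ff(prof)   # 10..90% spread
#> [1] 1.493182
```

A command-line wrapper covers the same workflow
(`exec/fatfront simulate|ffmap|profile|fit-front|bias|cohort|report`).

## Scope

The package consumes finished label maps (segmentation itself, e.g. by
slice propagation, is upstream) and NIfTI fat/water volumes; Dixon
reconstruction, bias-field correction, inter-timepoint registration and
inflammation (TIRM) scoring are out of scope. Fat-water-swapped muscles
are excluded via an explicit exclusion list, not detected automatically.
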