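---
title: "Quantifying symmetry breaking in 3D stem-cell aggregates"
author: "gastrupol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying symmetry breaking in 3D stem-cell aggregates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gastrupol)
```

## The measurement problem

When two cell populations are co-cultured in a spherical 3D aggregate — for
example wild-type human pluripotent stem cells mixed with an engineered,
signal-activated line — the mixture can remain dispersed, sort into two
hemispheres, form a core–shell arrangement, or break into local same-type
patches. Fluorescence microscopy gives per-nucleus positions and marker
intensities; the question is how to turn those into defensible, per-aggregate
statements such as "this aggregate is polarized", "the two populations are
90% segregated along the best axis", or "this knockdown converts
hemispherical into radial sorting".

gastrupol implements that quantification layer: nucleus detection and marker
calling from multichannel stacks or maximum-intensity projections (MIPs),
estimation of the maximal-separation axis, normalized line-trace profiles,
polarization scoring against a well-mixed null, pattern classification, and
the ΔΔCt computation for accompanying qPCR panels. Because suitable raw
imaging data are rarely shareable at package scale, a ground-truthed
synthetic-aggregate generator is a first-class component: every downstream
stage is exercised against simulated aggregates whose true organization is
known by construction.

## The model and its statistics

An aggregate is a table of nuclei $i = 1..n$ with positions $x_i \in
\mathbb{R}^d$ ($d = 3$ for stacks, $d = 2$ for MIPs) and a two-group label
$g_i$ (a genotype reporter or a marker call). The core quantities are:

* **Maximal-separation axis.** The unit vector $w$ along which the two
  groups are best resolved. The default estimator is the two-class linear
  discriminant direction $w \propto (S_W + \lambda\,\mathrm{tr}(S_W)/d\,
  I)^{-1}(\bar{x}_2 - \bar{x}_1)$, with $S_W$ the pooled within-group
  covariance and ridge $\lambda = 10^{-3}$ guarding near-singular pooled
  covariances. An alternative `search` method maximizes the projected AUC
  directly over ≥10,000 near-uniform directions (Fibonacci lattice) plus a
  5° cone refinement. The axis is oriented so the reference group projects
  low; exact ties are broken lexicographically so results are reproducible.
* **Axial AUC.** The Mann–Whitney AUC of the dichotomy along $w$, folded to
  $[0.5, 1]$ because the axis sign is a convention (experimentally, the
  orientation of the two hemispheres is random). The projected AUC equals
  $U/(n_1 n_2)$; the test suite verifies this against all-pairs enumeration.
* **Segregation percentage.** $100\times$ the best balanced accuracy over
  all single split points along the axis, each group scored on its majority
  side. Balanced accuracy (not raw accuracy) keeps the score honest when the
  two populations are strongly unequal, the known failure mode of
  under-mixed aggregates.
* **Permutation test.** Polarization is declared by comparing the observed
  folded axial AUC with its distribution when labels are shuffled over the
  fixed positions. Crucially, the axis is refit for every permutation: the
  observed statistic is a maximum over directions, so a null that skips the
  maximization would be strongly anti-conservative. $p = (1 + \#\{\text{null}
  \ge \text{obs}\})/(n_\mathrm{perm} + 1)$; with `exact = TRUE` all distinct
  label assignments are enumerated instead (small $n$). The test suite checks
  type-I calibration on well-mixed aggregates and super-uniformity of $p$.
* **Radial AUC.** The same folded AUC computed on distances to the aggregate
  centroid, detecting core–shell organization. Because the centroid is
  estimated from the same $n$ nuclei it sits $O(R/\sqrt{n})$ off the true
  center, so even a perfectly sharp core–shell aggregate scores slightly
  below 1 (≈0.993 at $n = 200$).
* **k-NN mixing score.** $M$ is the mean fraction of each nucleus's $k$
  nearest neighbours sharing its type and $M_0 = \sum_t p_t^2$ its
  random-labelling expectation; the score is $(M - M_0)/(1 - M_0)$. It flags
  local patchiness with no global symmetry. Note a geometric ceiling: at
  $n = 200$, $k = 10$ the neighbourhood radius is ≈0.37 aggregate radii, so
  even perfectly sorted hemispheres score ≈0.8, not 1 — the plane region
  always sees mixed neighbourhoods at this resolution.
* **Pattern class.** Rules evaluated in order with config-exposed
  thresholds (defaults $\tau_{ax} = \tau_{rad} = 0.8$, $\tau_{mix} = 0.3$,
  $\alpha = 0.05$): *hemispherical* iff polarized ∧ axial AUC ≥ $\tau_{ax}$
  ∧ radial AUC < $\tau_{rad}$; *radial* iff radial AUC ≥ $\tau_{rad}$ ∧
  axial AUC < $\tau_{ax}$; *fragmented* iff neither ∧ mixing ≥ $\tau_{mix}$;
  else *mixed*. All thresholds used are recorded in the output.

`polarize()` bundles all of the above into one classed fit with print,
summary, plot and `as.data.frame` methods.

### Line traces

Each nucleus's scalar coordinate along the axis is min–max normalized to
$[0,1]$ over the aggregate's own projected extent (its "normalized
diameter"), binned into `n_bins = 20` equal-width bins, and summarized as
the per-bin fraction of marker-positive nuclei. Empty bins are reported as
missing, never interpolated — interpolation would fabricate profile values
at sparse poles. Pooling across aggregates treats the aggregate as the unit
of replication: per-bin mean, sample SD and SEM over the per-aggregate
fractions, with pairwise exclusion of empty bins.

Normalizing per aggregate (rather than by a fitted sphere diameter) makes
traces comparable across aggregates of different size and robust to
non-spherical shapes; its cost is that the extreme bins are anchored by the
two outermost nuclei.

## Marker calling

The per-nucleus intensity distribution of a real marker is right-skewed and,
when a genuine positive population exists, bimodal on the log scale. Three
calling rules are provided, applied per aggregate by default (each aggregate
is quantified independently; a cohort rule via `cohort_threshold()` exists
for low-count aggregates):

* `otsu` (default): histogram Otsu threshold on log intensities;
* `gmm2`: two-component Gaussian mixture on log intensities (mclust),
  calling posterior membership of the high-mean component;
* `fixed`: a user-supplied raw-scale threshold.

Degenerate inputs (constant intensities, no resolvable split) yield
all-negative calls plus a warning rather than an error, because unstimulated
control aggregates are legitimately all-negative for differentiation
markers. Both automatic rules operate on shifted logs with a data-derived
offset, which makes calls exactly invariant to a global rescaling of a
channel (gain changes). The choice of rule is a recorded configuration
field: the appropriate rule for a given experiment is an analysis decision,
not something the package infers.

## The synthetic generator: what it emulates and what it does not

`generate_aggregate()` places `n_cells` nuclei uniformly in a ball of radius
`radius` and assigns types by pattern:

* **mixed** — independent Bernoulli(`frac_type_a`) labels (the dark-control
  regime);
* **hemispherical** — type probability is a logistic function of signed
  distance to a plane with uniformly random normal, scale
  `interface_width` × diameter; the plane offset is set so the expected
  type-A volume fraction equals `frac_type_a` (the plane passes through the
  centroid at 0.5). `interface_width = 0` is the deterministic sharp limit;
* **radial** — logistic in $r - \texttt{core\_fraction}\times R$ (type A
  core);
* **fragmented** — nearest-of-`n_patches` Voronoi patches, each patch typed
  Bernoulli(`frac_type_a`) with a re-flip guard so both types occur.

Channel intensities are log-normal per type and channel. The default
`marker_model()` uses a 3-SD log-scale separation between positive and
negative modes, chosen to sit at the lower edge of what a usable
immunostain delivers — calling accuracy at this separation has an intrinsic
ceiling of ≈93% (overlap of the two modes), which is what the round-trip
tests are measuring against.

Key defaults and their rationale:

| parameter | default | why |
|---|---|---|
| `n_cells` | 200 | seeding density of the aggregates being emulated |
| `radius` | 40 µm | ≈200 nuclei of ~10 µm at ~0.6 packing; diameter is not asserted anywhere, only used for geometry |
| `frac_type_a` | 0.5 | 1:1 co-culture mixing ratio |
| `interface_width` | 0.05 | strongly but not perfectly sorted hemispheres |
| `core_fraction` | 0.5 | core–shell with both groups above the size floor |
| `n_patches` | 8 | "random pockets" at a scale of ~25 cells per pocket |

Positions are uniform in the ball with no packing or repulsion: the
downstream metrics depend on relative arrangement, not contact mechanics. A
greedy minimum-spacing thinning (`min_spacing`) is available (and used by
the imaging round-trip tests, where resolvable nuclei are part of the test
conditions) but off by default. The generator does **not** simulate the
sorting process itself (no differential-adhesion mechanics), nuclear shape,
optical aberrations, or depth-dependent attenuation — so passing tests
demonstrate the correctness and calibration of the *quantification*, not
that real aggregates behave like the simulation.

`rasterize_aggregate()` renders nuclei as isotropic Gaussian blobs
(`blob_sigma` 3 µm ≈ an 8 µm nucleus) on an anisotropic grid (2 × 1 × 1 µm
z–y–x by default, emulating a 20X confocal), adds constant background and
Poisson–Gaussian noise, and can emit MIPs; TIFF output carries a YAML
sidecar with channel names, voxel size and intensity scale.

## Numerical choices and degenerate inputs

* Bin membership is `floor(t × n_bins)` with the $t = 1$ point folded into
  the last bin; projected coordinates are continuous so interior bin-edge
  ties have measure zero.
* AUCs use midranks, so ties contribute ½ — this is what makes the AUC equal
  the brute-force pair count with half-credit for ties.
* The direction search's AUC objective is piecewise constant, hence
  set-valued at the optimum; within the tied plateau the search picks the
  direction maximizing the projected two-sample t statistic. This makes the
  search deterministic and brings it within a few degrees of the Fisher
  direction on sharp hemispheres; with soft interfaces the plateau is
  smaller but noisier and the two estimators can differ by several degrees
  while reporting nearly identical AUCs.
* The permutation p-value uses the add-one estimator, so $p \ge
  1/(n_\mathrm{perm}+1)$ and the test is exact-level at
  $\alpha = m/(n_\mathrm{perm}+1)$.
* `detect_nuclei()` refuses smoothing kernels below half a voxel (extreme
  anisotropy) instead of silently degrading; all-zero images return an
  empty table, not an error.
* Aggregates below the `min_nuclei` floor (default 20) are skipped with a
  logged warning in the pipeline, never silently dropped; dichotomy groups
  below 5 nuclei are refused.

## Known limitations

* Centroid-plus-aperture intensity measurement is not instance
  segmentation; in very crowded fields neighbouring nuclei bleed into the
  aperture. The metrics used here (fraction positive per bin) are robust to
  modest bleed, which the round-trip tests quantify.
* The fragmented class is intrinsically hard to separate from hemispherical
  under the rule order above: a random assignment of ~8 patches is often
  itself near-linearly separable (mean axial AUC ≈0.86 at 8 patches), so a
  large share of genuinely patchy aggregates satisfies the hemispherical
  rule first. At the default thresholds the fragmented-class recovery is
  therefore far below that of the other three classes, whose recovery
  exceeds 90%. Treat "fragmented" as a conservative residual category, or
  raise $\tau_{ax}$ for cohorts where patchiness is the phenotype of
  interest.
* Permutation p-values are per aggregate; cohort-level claims should
  aggregate them explicitly (e.g. fraction polarized), and a dark-cohort
  calibration (`calibration_threshold()`) is provided as the literal
  deviation-from-dark alternative.

## Cohort sizes used by the automated checks

The test suite and `scripts/acceptance.R` run: 50 strongly hemispherical
aggregates (200 nuclei, width 0.05, 199 permutations) for the polarized
fraction and mean segregation; 500 mixed aggregates for type-I calibration;
100 seeds per pattern at width 0 for pattern recovery; four 50-nucleus
well-separated aggregates for the imaging round trip; and exhaustive
enumeration oracles on ≤12-nucleus toys. These sizes give stable rates
(binomial SEs of a few percent) while keeping a full run in the minutes
range on one core.
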