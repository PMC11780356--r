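---
title: "Quantifying projection-specific rabies tracing with trioquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying projection-specific rabies tracing with trioquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trioquant)
```

## The measurement problem

Projection-specific monosynaptic rabies tracing labels the presynaptic
inputs to thalamic neurons that project to one chosen higher visual area
(HVA). Interpreting such an experiment requires a chain of quantitative
steps, each with its own conventions: postmortem tangential sections must
be aligned to the in-vivo map of visual-area borders, every labelled cell
must be assigned to an area and a cortical layer, counts must be turned
into comparable fractions, and the central scientific claims — that layer
6 corticothalamic (L6CT) "modulator" inputs are enriched near the injected
area while layer 5 (L5CT) "driver" inputs avoid it — must be tested
against a null model that respects the structure of the data. This
vignette documents how `trioquant` implements each step, which knobs
matter, and what the synthetic-data tests do and do not establish.

## Registration and virtual flattening

Cortex is curved, so a cell in a deep section sits laterally displaced
from the surface position of its column. The standard correction aligns
each deeper section onto the one above it using radial blood vessels (and
matched apical dendrites) as landmarks, then composes those pairwise
alignments so every section maps into the surface frame where the area
borders live.

`fit_affine()` estimates a full 6-parameter 2D affine per adjacent pair by
least squares. A full affine (rather than a rigid or similarity
transform) is used because shear and anisotropic scale absorb cutting and
mounting distortion. All landmark kinds are weighted equally — there is no
principled reason to trust one vessel more than another. Degeneracy is
detected by QR rank (collinear sources) and a determinant floor of 1e-12
on the linear part; both raise errors naming the offending configuration
rather than returning a silent garbage fit. `flatten_stack()` composes
fits deep-to-superficial (section 0, the 250 µm surface section, receives
the identity; deeper sections follow at 50 µm pitch), and `warp_map()`
carries the in-vivo border map into tissue coordinates from
surface-vessel pairs, re-validating polygon simplicity after the warp and
warning with the area name if a polygon self-intersects.

With noiseless landmarks the composed transforms equal the composed
ground truth to floating-point precision; with 2 µm landmark noise the
surface-frame error after five compositions stays below 10 µm in the test
suite (20 synthetic stacks of 6 sections, 8 landmarks per pair). Since
composition multiplies errors, long stacks with few, noisy landmarks are
the failure mode to watch; the residual RMS reported by `fit_affine()` is
the diagnostic.

## Area and layer assignment

`assign_area()` is point-in-polygon on the warped map. Two conventions
make it deterministic: polygons are tested in the parcellation's fixed
order and a point on a shared border goes to the first area that contains
it; points outside every polygon are `"unassigned"` (a counted outcome,
not an error). Every cell therefore lands in exactly one bucket and
per-area counts plus unassigned always sum to the total.

Layers use a per-experiment depth interval for the L5 marker (Ctip2)
band. Intervals are half-open `[top, bottom)`: a depth exactly at the top
of the band is L5. The band is a depth model, not an image segmentation —
the package deliberately contains no pixel data, so a column-wise or
global band must be supplied (defaults 550–700 µm). Changing the band by
δ only moves cells within δ of a boundary.

`tabulate_starters()` reports counts and percentages of total starters
per thalamic nucleus, rounding percentages to one decimal as printed in
primary tables; `qc_experiment()` flags experiments whose pulvinar
starter fraction falls below a configurable threshold (default 0.5 — an
artifact convention: published exclusions were expert judgements, and any
numeric threshold here is a package choice, not a reported value).

## Descriptive quantities

* `input_fractions()` – counts over the brain-wide region vocabulary
  divided by total inputs; sums to 1 within 1e-12 or errors on an empty
  experiment.
* `visual_normalized_fractions()` – HVA comparisons are normalised to
  total **visual** cortical input, because animals with large
  subcortical fractions would otherwise depress every areal fraction.
  A layer with zero visual input yields flagged `NA`s that are excluded
  from group medians rather than treated as zeros.
* `hexbin_density()` – pointy-top hexagons with flat-to-flat width
  180.6 µm anchored at the map origin. Any fixed convention works; this
  one is documented and stable, counts are conserved, and shifting points
  and origin together is a pure relabelling.
* `distance_density()` / `theta_pdf()` – Gaussian kernel estimates with
  Silverman's rule-of-thumb bandwidth and boundary correction by
  reflection (at 0 for distances; at 0° and 90° for the polar angle).
  Reflection is the simplest estimator that satisfies the stated boundary
  correction; the evaluation grid is grown automatically until its
  spacing is well under the bandwidth, so the densities integrate to
  1 ± 0.01 even for boundary-hugging samples. Both accept an explicit
  `bw`; at fixed bandwidth, duplicating a sample leaves the estimate
  exactly unchanged, which is why pooling across animals commutes with
  estimation.
* `pooled_mean_sem()` (SEM = sample SD/√n) and `median_mad()` (MAD
  unscaled, `median(|x − median|)`) are the pooled summaries;
  `relative_strength_matrix()` divides each target column by its maximum
  for relative-strength visualisation, leaving all-zero columns at zero
  with a flag.

## The shuffled-target permutation framework

The reciprocity question is "are there more L6CT cells near the injected
area than one would expect if the target identity were arbitrary?". The
null model (`shuffle_null()`) reassigns each experiment's target
uniformly at random among the five candidate HVAs — original target
included, independently across experiments — moves the reference point to
the shuffled target's centroid *in that animal's own map*, keeps all cell
positions fixed, and recomputes the statistic. Keeping the original
target in the support keeps the observed configuration inside the null;
using each animal's own map respects per-animal border variability.

Implementation note: because the statistic depends on the shuffle only
through which candidate each experiment received, the per-(experiment,
candidate) values are precomputed once and shuffles reduce to index
sampling, so 10,000 shuffles cost no more than 5 × n statistic
evaluations. An exhaustive mode enumerates all candidate combinations for
small families and is the oracle for the sampled mode in tests.

Sampled-null p-values use the add-one estimator `(1 + k)/(N + 1)`, whose
floor at N = 10,000 is 1/10,001 ≈ 1.0e-4; `format_pvalue()` prints values
at the floor as `p < 1.0e-04` rather than a hard zero. Exhaustive nulls
use the plain proportion, since the enumeration already contains the
observed configuration. Families of tests (one per target HVA, or the
L6/L5 pair) are adjusted with Benjamini–Hochberg (`bh_adjust()`,
delegating to `stats::p.adjust`).

Two reference-point rules are available for the observed statistic in
`reciprocity_test()`. The default, `observed_ref = "site"`, anchors the
disc at the recorded injection site — this matches how the radius is
defined experimentally and maximises power against effects planted at the
site. It is, however, not perfectly exchangeable with the centroid-based
null: a site near an area border loses part of its disc to neighbours,
while a centroid does not. `observed_ref = "centroid"` applies the exact
null rule to the observed statistic as well; with targets assigned
independently of the cells, observed and null draws are then identically
distributed and the p-value is exactly uniform. The package's calibration
test uses the centroid rule (type-I error of 200 null replicates checked
against the exact binomial 99% interval around α = 0.05), and the power
tests use the site rule; both choices are visible in the result objects
and the pipeline's results JSON records the convention used.

The area-count variant (`reciprocal_fraction_test()`) applies the same
shuffle to the fraction of visual cortical cells assigned to the target
area itself. For contingency-table questions, `fisher_mc()` samples
tables with fixed margins (Patefield's algorithm via `stats::r2dtable`)
and measures extremeness by conditional table probability with a 1e-7
tie tolerance — `mc_shuffles_needed(h, c)` gives the worst-case binomial
sizing `ceiling(z² / 4h²)` for a desired p-value precision (9.604e7
draws for ±1e-4 at 95% confidence) — and `chi2_independence()` is the
large-sample alternative. `kruskal_wallis()` wraps the standard
rank test; `dunn_sidak()` implements Dunn's pooled-rank z-tests with tie
correction and Šidák adjustment `1 − (1 − p)^m`, gated behind a
significant omnibus test (default α = 0.05) as post hoc tests
conventionally are.

## The superior-colliculus polar analysis

SC inputs are summarised in four 500 µm anterior–posterior bins with
centres at −3.05, −3.55, −4.05 and −4.55 mm from bregma (half-open on the
anterior side, posterior edge included, out-of-range cells flagged). The
mediolateral position of each cell is the angle θ between the ray from
the bin origin to the cell and the ventral SC boundary ray, with the
midline at 90°. Only the two axis endpoints are anatomically defined; the
origin is a package choice, fixed at the intersection of the midline with
the ventral SC boundary, which makes both stated anchors exact. An
alternative origin (e.g. the SC centroid) would change θ values but not
the endpoints; it is noted, not implemented as a default. θ is invariant
to uniform scaling of the coronal coordinates about the origin, and cells
at the origin itself get a flagged undefined angle. Laminar fractions
distribute each experiment's SC share of total inputs across the seven
laminae; pooling across animals is plain concatenation, so animals with
weak SC labelling do not reweight the distribution. The
superficial/deep split used for summary densities is {zo, sg, op} versus
{ig, iw, dg, dw} — a package convention consistent with the usual
superficial-versus-multisensory division.

## What the synthetic generator emulates — and what it does not

`synth_config()` defaults encode the study conditions the analyses
assume:

| parameter | default | why |
|---|---|---|
| `targets`, `n_animals_per_target` | 5 HVAs × 5 | the experimental design's 4–5 animals per target |
| `n_L6_cells` : `n_L5_cells` | 999 : 111 | the reported 9:1 L6CT:L5CT input ratio |
| `reciprocity_radius_um` | 400 | the radius used for the proximity statistic |
| `areal_weights_L5` | V1 0.62, HVAs 0.03 each, RSP 0.15 | V1-dominant driver input with a substantial retrosplenial term |
| `areal_weights_L6` | V1 0.40, HVAs 0.08 each | distributed modulator input |
| `brainwide_base` | cortex 0.414, TRN 0.151, pretectum 0.108, remainder split | pooled region rates; non-SC rates are rescaled per target so pooled means match exactly |
| `sc_fraction_by_target` | LM 0.239, AL 0.117, PM 0.103, RL 0.069, AM 0.064 | the reported per-target SC input medians |
| `starter_weights` | pulvinar 0.82, LD 0.10, rest 0.08 | ~82% pulvinar starters |
| `sc_theta_params` | LM/PM high-θ (75°/70°, scale 12), AM/RL/AL broad (45–50°, scale 20–22) | medial concentration for LM- and PM-projecting populations |
| `border_jitter_um` | 50 | per-animal border variability around the template map |

Reciprocal structure is planted by multiplying cell intensity inside the
disc around the injection site — thinning for multipliers below 1, and
superposed duplicates (placed uniformly within the disc inside the parent
cell's area) for multipliers above 1. Multiplying intensity rather than
moving cells keeps the areal weights interpretable; with multiplier m = 3
every in-disc cell gains exactly two duplicates, which the generator
tests exploit as an exact oracle. The spatial scale of reciprocal
clustering beyond the analysis radius is not asserted anywhere; it is
exposed as the free `reciprocity_radius_um` parameter.

The flatmap is a hand-drawn schematic: a conforming mesh of 11 areas (V1,
five HVAs, five surrounding non-visual areas) in which shared border
vertices appear in both polygons, so per-animal jitter — applied jointly
per unique vertex, displacement at most `border_jitter_um` — preserves
disjointness by construction (validated anyway, with halved jitter on
retry). The SC cross-section is a quarter annulus, making θ and laminar
radius analytically exact. Every experiment draws from an RNG stream
keyed by (seed, animal, target), so outputs are byte-identical given a
config and independent of generation order.

The generator does **not** emulate: fluorescence or image formation (no
pixel data anywhere), real areal geometry or retinotopy, within-area
density gradients, section-to-section cell splitting, starter/input
ambiguity near the injection site, or atlas registration error. Passing
tests therefore establish that the *quantification chain* is correct and
calibrated under the generative assumptions — uniform within-area
placement, multinomial counts, disc-shaped planted effects — not that it
is robust to every failure mode of real histology.

## Numerical choices and problem sizes

Tolerances: probability vectors must sum to 1 within 1e-9; fraction
vectors within 1e-12; densities integrate to 1 within 0.01; affine
invertibility requires |det| > 1e-12; Fisher tie tolerance 1e-7 on log
probability. Degenerate inputs error early and descriptively (empty
experiments, all-tied Kruskal–Wallis groups, zero margins, sub-minimal
landmark sets) rather than propagating NaN.

The test suite and acceptance script run the stochastic checks at sizes
chosen to make their pass/fail criteria sharp while keeping the whole
suite in minutes on one core: type-I calibration uses 200 null replicates
of 4 experiments × 150 L6 cells with 199 shuffles (199 makes the
achievable p-values an exact 1/200 grid, so the α = 0.05 rejection
probability is exactly 0.05); power uses 50 replicates of 4 experiments
with ~1,000 cells in the tested layer and 1,000 shuffles against
multipliers 3 (L6, upper tail) and 0.2 (L5, lower tail); Fisher MC is
checked against full enumeration on 2×2/2×3 tables with totals ≤ 30.

## Limitations

Registration is strictly affine — no thin-plate or diffeomorphic option —
and the package never resamples images. Area assignment inherits any
border-placement error from the map; near-border cells are the dominant
uncertainty for small populations (a handful of reciprocal L5CT cells can
flip a fraction). The site-anchored observed statistic is mildly
non-exchangeable with the centroid-anchored null, as discussed above. L6
sublaminae are not distinguished, and the starter/input split is taken as
given (the generator produces them separately rather than modelling the
injection-site exclusion zone).
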