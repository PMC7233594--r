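---
title: "Vascular trunk geometry and the hemisphere of visual field onset: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vascular trunk geometry and the hemisphere of visual field onset: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcshift)
```

## The scientific model

In myopic eyes the outer, load-bearing wall of the globe expands during
axial elongation while the inner retinal structures — including the
Bruch's membrane opening (BMO) — are comparatively preserved. The lamina
cribrosa (LC), anchored in the outer wall, shifts with it. Because the
central retinal vascular trunk is embedded in the LC's connective tissue
and sits centrally in the neonatal disc, its displacement from the BMO
centre is usable as a per-eye surrogate of LC shift. The package
operationalizes one hypothesis about the consequence of that shift: LC
pores on the side *opposite* the shift carry additional tensile stress, so
under the uniform radial stress of high intraocular pressure those pores —
and the retinal nerve fibre bundles passing through them — fail first.
Observationally this predicts that the hemifield of the first glaucomatous
visual field defect is aligned with the trunk's vertical displacement, that
both hemifields become involved as the disease progresses, and that eyes
presenting late (worse baseline mean deviation) are already bi-hemispheric.

## Geometry

All landmark work happens in the BMO plane, in micrometres, with +y
superior. Coordinates are normalized to right-eye orientation first: left
eyes are mirrored about the vertical axis through the BMO centroid, which
exchanges nasal and temporal raw coordinates while preserving
superior/inferior.

The **BMO centre** is the area centroid of the closed polygon through the
delineated margin points (typically 24, one per radial scan). A vertex
mean is available (`center_method = "vertex_mean"`) because devices do not
document which definition they use; the centroid is the default as it is
robust to uneven vertex spacing. The **fovea–BMO axis** is the unit vector
from the centre to the fovea; its negation is the nasal 0° reference ray.

The **angular deviation** α is the signed angle from the nasal ray to the
centre→trunk ray, positive when the trunk lies on the superior side of the
reference line. Because the sign convention is anchored to the image's +y
axis, α is invariant under translations and under rotations that keep the
fovea–BMO axis within ±90° of horizontal — amply satisfied by real scans,
where the axis tilts by single-digit degrees. A trunk coinciding with the
centre yields α = 0 with a warning rather than an error, so that pipelines
survive degenerate synthetic draws.

The **shift index** is a/b: the centre-to-trunk distance over the
centre-to-margin distance along the same ray. b is computed by exact
ray/segment intersection against the piecewise-linear closed polygon,
taking the first intersection outward from the centre. The delineated
margin is a point set; the original measurements were made with on-image
calipers and no interpolation scheme is documented, so piecewise-linear is
the least-assumption choice and has the advantage of being testable: on
circles the index reduces to a/r, and on convex polygons it is checked
against an independent point-in-polygon bisection oracle to 10⁻⁶ relative
error. When the trunk lies outside the BMO the index is 1 by convention
and α is undefined; such eyes form shift group C (severe). Groups A
(index < 0.5) and B (0.5 ≤ index < 1) are mild and moderate shift. The
group-C threshold is `index ≥ 1 − 1e-9`: a measured index can only reach 1
through the absent-trunk convention, so the tolerance guards against
floating-point noise, not against measured values.

**Obliqueness** folds α into its quadrant, 90 − ||α| − 90| after wrapping
to (−180°, 180°], so 0 is horizontal and 90 vertical; it enters the model
of defects that remain confined to a single hemisphere (a vertical shift
produces maximal superior/inferior asymmetry). **Lamina cribrosa depth**
is the axial distance of the trunk emergence below the BMO reference
plane, floored at zero with a warning. Device magnification correction is
assumed already applied to the input landmarks.

## Visual field classification

The Humphrey 24-2 grid is modelled as its standard 54-point lattice
(6° spacing, two extra nasal points at 27°, the two blind-spot points at
(15°, ±3°) never scored). Pattern-deviation categories are ordinal:
normal, p < 5%, p < 2%, p < 1%, p < 0.5%.

A **qualifying cluster** is a maximal connected component of abnormal
points (category ≥ p < 5%) of size ≥ 3 containing at least one point at
p < 1%. Two conventions are deliberate and configurable:

* **Connectivity** is 8-neighbourhood (diagonals included) by default,
  switchable to 4; the source analysis says only "connected", and
  8-connectivity matches common perimetric cluster usage.
* **Hemifield confinement**: components are computed separately within
  each hemifield, because assigning a cluster to a hemisphere is only
  well-defined if clusters cannot straddle the horizontal meridian. The
  hemifield-agnostic variant exists solely inside the diagnostic
  glaucomatous-defect criterion.

An alternative rule (all points at p < 0.5%, shipped as
`cluster_rule("abstract")`) reflects a stricter published phrasing of the
same criterion; the 5%/1% rule is the default.

Exams are **reliable** when fixation losses ≤ 20% and false-positive and
false-negative rates ≤ 25% (inclusive); unreliable exams are skipped, not
imputed. The **initial hemisphere** scans reliable exams chronologically
and establishes a hemifield once its qualifying cluster appears on
`confirm_n` consecutive reliable exams (default 2, mirroring the
"confirmed on two consecutive reliable tests" convention used for
diagnosis). The first hemifield to establish wins; a tie — including both
hemifields present from the initial examination — is bi-hemispheric; no
establishment is "undetermined". The **final hemisphere** applies the same
presence test to the last `confirm_n` reliable exams. The "pattern
standard deviation of less than 5%" diagnostic criterion is read as the
PSD *probability* < 0.05 (the dB reading would need a normative database
the inputs do not carry).

## The synthetic cohort generator

The generator exists so that every downstream stage is testable with known
ground truth. Its defaults emulate the modelled cohort: 81 eyes; age
54.7 ± 14.2 years; axial length 25.5 ± 1.3 mm truncated at ≥ 24 mm; peak
IOP 25.2 ± 4.1 mmHg truncated at > 21 mmHg; baseline MD −8.11 ± 5.85 dB;
follow-up 5.0 ± 2.7 years truncated at ≥ 2. Truncation shifts moments, so
each lower-bounded covariate is drawn from a pre-truncation normal whose
*truncated* mean and sd match the targets (solved once at configuration
time; sampling is by inverse CDF, stable even when the matched solution
sits deep in the parent tail, as it does for IOP). With 10⁵ draws each
covariate's sample mean and sd land within 1% of the configured values.

The trunk angle is drawn from a superior-biased two-component normal
mixture (55% at +40° ± 35°, 45% at −35° ± 30°), reflecting the reported
preponderance of superior shift; the shift index from a Beta(1.5, 1.6)
with a 6/81 point mass at 1 (trunk outside the BMO), reproducing the
published group A/B/C split and group means. The BMO margin is a
24-vertex ellipse (semi-axes 950 × 870 µm, ≈ 2.6 mm² area, within the
published group range) with radial jitter; the trunk is placed at the
drawn α and shift index *relative to the measured centroid*, so the
geometry stage recovers the drawn values exactly and the closed loop tests
wiring rather than luck.

Ground truth: P(inferior onset) = logistic(log(0.83)·α) — the per-degree
odds ratio reported for the real cohort — and P(bi-hemispheric onset) =
logistic(−5.1 − 0.35·MD₀), with severe-shift eyes bi-hemispheric with
probability 2/3. Intercepts and the conversion hazard of the second
hemifield (0.07/year) were calibrated once, analytically, to the published
onset distribution (44%/33%/22% superior/inferior/bi initially, 42% bi at
the final visit) and not revisited. Visual field series seed a qualifying
cluster in each truly affected hemifield from the first visit, add the
second hemifield at its drawn conversion time, decline MD by 0.5 dB/year,
sprinkle isolated false-positive points (1%/point/visit) and mark 5% of
exams unreliable. Because an isolated false positive is capped at the
p < 5% category it can never mint a qualifying cluster on its own, which
is why classification degrades gracefully rather than catastrophically
with noise.

What the generator does **not** emulate: biomechanics (no actual LC
mesh), spatially correlated test-point noise, long-term perimetric
learning or cataract effects, and treatment-dependent progression. Passing
tests therefore demonstrate that the pipeline recovers the *assumed*
structure faithfully, not that the structure is true of any real cohort.

Randomness is organized as per-eye substreams keyed by (seed, eye index,
stage), so adding eyes to a cohort never changes earlier eyes, and a fixed
seed makes every file the pipeline writes byte-identical across runs.

## Statistics

`anova_from_summary`, `scheffe_posthoc` and `two_sample_t` work directly
from (n, mean, sd) triples and are algebraically identical to their
raw-data counterparts (tested to 10⁻¹⁰ against `aov()`/`t.test()` on
reconstructed data). This is what makes the published group table
recomputable: its printed counts and summaries are sufficient statistics
for these tests. The chi-square test uses the Pearson statistic without
continuity correction — the convention under which the published
categorical p-values (0.442, 0.394, 0.411) reproduce exactly.

Logistic regression is fitted by iteratively reweighted least squares with
step-halving, which makes the log-likelihood provably non-decreasing
across iterations; convergence is declared on the coefficient change
(10⁻¹⁰ relative), Wald intervals are exp(b ± z·se), and separation is
flagged rather than silently reported. The univariate → multivariate
screen keeps candidates with univariate Wald *P* < 0.20. At the real
cohort's α dispersion (±40°) a per-degree log-odds of ln 0.83 makes the
onset nearly deterministic, so small-cohort fits sit at quasi-separation —
the estimate's sign is then the informative output, and the
parameter-recovery experiment instead draws α from N(0, 8°), chosen a
priori so |log-OR| × sd(α) ≈ 1.5: informative but estimable. At that
design, 200 replicates of n = 2000 give Wald CI coverage at the nominal
95% level.

The conditional inference tree is a deliberately simplified recursive
partitioner: at each node every covariate's association with the
categorical response is tested by a Monte-Carlo permutation test on the
one-way ANOVA F statistic, p-values are Bonferroni-corrected across
covariates, and the node splits only if the smallest adjusted p is below
α = 0.05 (and the node has ≥ 10 observations, children ≥ 5). The split
threshold maximizes the Pearson chi-square of the child-by-class table
over candidate midpoints, ties toward the smaller threshold. It makes no
attempt at bit-compatibility with any published tree package; the real
cohort's split values (−1.169°, −7.95 dB) are artifacts of unavailable
patient data, and the tree is validated instead by recovery (trunk angle
at the root, baseline MD below, in ≥ 80% of strong-effect replicates) and
by its null behaviour (≤ 10% spurious splits at α = 0.05). The default
permutation count is 9999; the experiments use 499, which bounds the
Monte-Carlo error of a 0.05-level test at ±0.01 while keeping 100-replicate
experiments in seconds.

## Pipeline

`run_pipeline()` chains loading (or simulation) → eligibility filtering
(axial length ≥ 24 mm, peak IOP > 21 mmHg, follow-up ≥ 2 years, optional
quality flag; one eye per subject by a seeded draw keyed by subject id;
every exclusion logged with its rule) → geometry → hemisphere
classification → cohort assembly → statistics. Eyes with fewer than two
reliable exams are excluded and logged. The report comprises the cohort
table, a shift-group-stratified summary, three logistic screens (initial
inferior onset among single-hemisphere eyes; initial bi-hemispheric onset;
final single-hemisphere persistence, with obliqueness among the
candidates), the tree (fitted to eyes with a measurable α — severe-shift
eyes carry no angle), and a polar plot of α by onset hemisphere. The SVG
is rendered by hand rather than through a graphics device so report bytes
are reproducible.

## Numerical choices and edge cases

* Polygon validity is checked by exhaustive non-adjacent segment
  intersection; self-intersecting margins are rejected at construction.
* Ray/boundary intersection tolerates vertex-grazing hits (edge parameter
  within 10⁻⁹ of its ends) and rejects rays that miss the boundary with a
  diagnostic naming the centre and direction.
* Angles live in (−180°, 180°]; the −180° boundary maps to +180°.
* The shift index is clipped to [0, 1] against floating-point overshoot
  when the trunk sits exactly on the margin.
* Cluster ordering (superior hemifield first, then smallest point index)
  is fixed so that reports and tests are deterministic.
* Problem sizes in the validation experiments — 200 × n = 2000 logistic
  replicates, 100 × n = 200 tree replicates, 1000 random maps against the
  exhaustive cluster oracle — were chosen to bound Monte-Carlo error well
  below the acceptance margins while keeping the full suite in minutes.

## Known limitations

* The fovea–BMO axis uses the two-landmark definition; a device's
  proprietary axis may differ slightly.
* Whether the device's "BMO centre" is an area centroid or a vertex mean
  is undocumented; both are offered, and they differ for unevenly spaced
  margins.
* The cluster rule's connectivity and the confirmation count are
  conventions, surfaced as configuration, not recovered facts.
* Real-cohort regression and tree coefficients are reproduced in
  direction and recoverability only; their numerical values require the
  original patient-level data.
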