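# lcshift

Geometry of the central retinal vascular trunk within the Bruch's membrane
opening (BMO), and its relationship to the hemisphere in which glaucomatous
visual field damage first appears, in myopic high-tension glaucoma.

During axial elongation of the myopic eye the outer load-bearing sclera —
and the lamina cribrosa (LC) embedded in it — shifts relative to the inner
retinal structures. The central retinal vascular trunk travels with the LC,
so its displacement from the BMO centre is a per-eye surrogate of LC shift.
The working hypothesis is that the LC pores *opposite* the shift direction
carry extra tensile stress, so under high intraocular pressure the
corresponding hemifield is damaged first: a superiorly displaced trunk
predicts an initially superior visual field defect, an inferiorly displaced
trunk an inferior one, and eyes diagnosed late (worse baseline mean
deviation) tend to present with both hemifields already involved.

`lcshift` is for researchers who have per-eye ONH landmark annotations and
longitudinal Humphrey 24-2 visual fields and want to reproduce this whole
analysis chain, or stress-test it on synthetic cohorts with known ground
truth.

## What it computes

**Landmark geometry** (per eye, right-eye orientation, µm):

- angular deviation *α* of the trunk from the nasal horizontal midline
  (positive superior), measured against the fovea–BMO axis;
- shift index *a/b* — centre-to-trunk distance over centre-to-margin
  distance along the same ray, with *a/b* ≡ 1 when the trunk lies outside
  the BMO; shift groups A (<0.5), B (0.5–1), C (=1);
- β-zone parapapillary atrophy angle *β* from the temporal midline;
- obliqueness 90 − ||α| − 90| (0 horizontal … 90 vertical);
- lamina cribrosa depth (trunk depth below the BMO plane) and BMO area.

**Visual field classification**: the defect-cluster rule (≥3 connected
abnormal points at p < 5% on the pattern-deviation plot, ≥1 at p < 1%,
confined to one hemifield; 8- or 4-connectivity), reliability filtering
(fixation losses ≤ 20%, false positives/negatives ≤ 25%), the glaucomatous
defect criteria (GHT / cluster / PSD probability), and longitudinal
determination of the initial and final defect hemisphere (a hemifield is
established after its cluster appears on `confirm_n` consecutive reliable
exams; both at once ⇒ bi-hemispheric).

**Statistics**: Pearson chi-square (no continuity correction), one-way
ANOVA and Scheffé post hoc tests computed directly from (n, mean, sd)
summaries, pooled t, logistic regression fitted by IRLS with Wald CIs and
the univariate *P* < 0.20 → multivariate screen, and a simplified
conditional inference tree (permutation tests on an ANOVA-type statistic,
Bonferroni correction, exhaustive threshold search).

**Synthetic cohorts**: `sim_config()` / `simulate_cohort()` generate
landmark records, covariates and longitudinal pattern-deviation series with
a configurable true per-degree effect of *α* on onset hemisphere (default
log-odds `log(0.83)`) and a bi-hemispheric propensity increasing with worse
baseline MD, calibrated to the cohort moments of the modelled study
(n = 81, age 54.7 ± 14.2 y, axial length 25.5 ± 1.3 mm, peak IOP
25.2 ± 4.1 mmHg, baseline MD −8.11 ± 5.85 dB).

## Worked example

```r
library(lcshift)

# one annotated right eye: 24-point BMO margin, fovea, trunk
theta  <- seq(0, 2*pi, length.out = 25)[-25]
margin <- cbind(850 * cos(theta), 780 * sin(theta))
rec <- landmark_record(
  eye_id = "OD-001", laterality = "right", bmo_margin = margin,
  fovea = c(-4700, -550), trunk = c(260, 410),
  trunk_depth_um = 540, bmo_plane_depth_um = 0)
measure_onh(rec)
#>   eye_id alpha_deg shift_index shift_group beta_deg obliqueness_deg lcd_um bmo_area_mm2
#> 1 OD-001      50.9       0.608           B       NA            50.9    540         2.06
```

The trunk sits 50.9° superior of the nasal midline, 61% of the way to the
margin (moderate shift, group B), 540 µm below the BMO plane, in a 2.06 mm²
BMO. Under the shift hypothesis this eye should develop its first defect in
the *superior* hemifield.

The full pipeline on a simulated 81-eye cohort:

```r
rep <- run_pipeline(pipeline_config(
  simulate = sim_config(n_eyes = 81, seed = 7), n_perm = 499, seed = 7))
print(rep)
#> lcshift pipeline report
#>   cohort: 81 eyes; 0 exclusion(s)
#>   shift groups: A=33 B=39 C=9
#>   initial hemisphere: bi=19 inferior=24 superior=38
#>   final hemisphere: bi=40 inferior=14 superior=27
#> ...
#>     alpha_deg  0.871 0.00368 59
#> ...
#> alpha_deg (adj p = 0.01), n=72 (bi:13 inferior:22 superior:37)
#> <= 2.59:
#>   * n=32 (bi:11 inferior:20 superior:1)
#> >  2.59:
#>   * n=40 (bi:2 inferior:2 superior:36)
```

Reading the output: initially 38 eyes show superior, 24 inferior and 19
bi-hemispheric defects; by the final visit 40 eyes are bi-hemispheric —
both hemifields are eventually involved, but the first one is set by the
trunk position. The univariate screen finds the trunk angle as the risk
factor for inferior onset (odds ratio 0.871 per degree: more superior trunk,
lower odds of inferior onset), and the conditional inference tree splits
first on the trunk angle near 0°, separating superior from inferior onset,
with bi-hemispheric eyes concentrating on the worse-MD side. Passing
`out_dir =` writes the cohort table, Table-style summaries, the tree and a
polar plot (CSV/JSON/SVG/text) deterministically for a given seed.

A thin command-line wrapper with subcommands `simulate`, `measure`,
`classify`, `analyze` and `run-all` ships in `inst/cli/lcshift.R`.

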