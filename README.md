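# lobetrial

Simulation and analysis of **within-patient lobe-randomized radionuclide
uptake trials** in bilobar liver disease.

In this design every patient carries both trial arms: a radiolabelled
somatostatin analogue is infused intra-arterially into *one* (randomized)
hepatic artery, the contralateral liver lobe is exposed only through
recirculation ("second-pass" effect) and serves as the within-patient
control. The question is whether intra-arterial delivery multiplies tumour
uptake. Because imaging data from such trials are rarely shareable, the
package couples the full analysis chain to a synthetic phantom and cohort
generator, so every stage is testable end to end without clinical data.

It is aimed at nuclear-medicine physicists and trial statisticians who want
to prototype, power, or audit this class of design.

## What it computes

**Voxel-level quantification.** On the baseline receptor image, each target
lesion VOI is segmented by shrinking a rough VOI to the voxels at or above
42% of its maximum (26-connected component of the hottest voxel). VOIs are
transferred onto each post-cycle emission volume through a known rigid
transform (nearest-voxel mapping) and two uptake statistics are extracted per
lesion: the mean counts/voxel, and the *peak* — the mean counts/voxel in a
1-cm-diameter sphere centred on the hottest voxel. The tumour-to-non-tumour
ratio per lobe is the volume-weighted lesion uptake over the mean uptake of a
&ge;15 mL lesion-free VOI in the control lobe:

    T/N = ( Σ_i v_i u_i / Σ_i v_i ) / u_normal

**Inference.** With T/N_IA and T/N_control per patient-cycle, the package
runs the paired battery: a paired t-test on the differences (primary, cycle
1); a paired t-test on log T/N whose estimate and CI are exponentiated into a
geometric ratio; a two-level random-intercept mixed model over all cycles
(`tn ~ arm + (1|patient) + (1|patient:cycle)`, REML); effect-modification
tests for patient-level covariates; and exact Fisher tests (complete
enumeration of r×c tables with fixed margins) on the per-lobe RECIST 1.1
response tables. Toxicity uses table-driven grading with a baseline-delta
rule: an event is treatment-emergent only if the worst follow-up grade
exceeds the baseline grade.

**Design.** Permuted-block in-patient randomization (block sizes 1 and 2)
and exact noncentral-t power/sample-size for the paired t-test (Cohen's
d_z: power = P(|t| > t_crit) with noncentrality d_z·√n, df = n−1).

## Worked example

```r
library(lobetrial)

cfg <- cohort_config(n_patients = 8, n_cycles = 2,
                     grid_shape = c(48, 48, 48), seed = 7)
report <- run_pipeline(cfg)
report
```

```
<analysis_report> 8 patients, seed 7, config c12dc1a8

Primary endpoint (cycle 1, mean basis):
  paired t-test on T/N differences (n = 8)
  mean difference 11.732 (95% CI [-14.748, 38.211]), t(7) = 1.048, p = 0.3296
Relative difference:
  paired t-test on log T/N, back-transformed (n = 8)
  geometric ratio 1.062 (95% CI [0.746, 1.513]), t(7) = 0.405, p = 0.6973
Any T/N increase: 5/8 (62%)
All cycles:
  Two-level random-intercept model (natural scale, REML, 32 rows)
  arm effect 17.1519 (SE 6.9354, 95% CI [2.3695, 31.9343]), p = 0.02584
  variance components: patient 1951, cycle-in-patient 1141, residual 384.8
```

The mean difference is the absolute T/N gap between the treated and control
lobe after cycle 1; the geometric ratio is the multiplicative version (1.062
= a 6% average relative increase in this small run, against a generator truth
of 17%); the mixed model pools all cycles. The per-cycle T/N table behind
these numbers is a tibble:

```r
head(report$tn, 4)
#> # A tibble: 4 × 5
#>   patient_id cycle basis tn_ia tn_control
#>   <chr>      <int> <chr> <dbl>      <dbl>
#> 1 P01            1 mean   33.9       44.8
#> 2 P01            1 peak   33.5       44.3
#> 3 P01            2 mean   42.5       38.8
#> 4 P01            2 peak   39.3       36.1
```

Response and toxicity stages produce contingency-style tables with exact
Fisher p-values per timepoint:

```r
report$response_p
#> # A tibble: 2 × 2
#>   timepoint p_value
#>   <chr>       <dbl>
#> 1 3mo         1
#> 2 6mo         0.608
```

Power calculations for designing such a trial:

```r
power_paired_t(26, dz = 0.65)        # 0.8896
power_paired_t(27, dz = 0.65)        # 0.9015
min_n_paired_t(dz = 0.65, power = 0.9)  # 27
```

`autoplot(report)` draws the paired boxplot of T/N by arm;
`plot_response_waterfall()` shows per-lobe diameter changes.

## Package layout

- `R/volume.R`, `R/quantify.R` — image containers, NIfTI I/O, segmentation,
  VOI transfer, mean/peak uptake, T/N.
- `R/phantom.R` — phantom and cohort generator (image and tabular layers).
- `R/design.R` — randomization and power.
- `R/stats.R` — paired/ratio tests, mixed models, exact Fisher.
- `R/response.R` — RECIST 1.1 classifier, grading rules, toxicity.
- `R/pipeline.R`, `R/plots.R` — orchestration, report tables, figures.

See the methods vignette (`vignettes/lobetrial-methods.Rmd`) for the model,
calibration derivations and design choices.
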