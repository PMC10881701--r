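---
title: "Methods: simulating and analysing within-patient lobe-randomized uptake trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing within-patient lobe-randomized uptake trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(lobetrial)
```

## The design and the estimand

In a within-patient lobe-randomized trial of intra-arterial radionuclide
therapy, each patient has bilobar liver disease with at least one metastasis
of at least 3 cm per lobe. One hepatic artery (left or right, randomized by
permuted blocks of sizes 1 and 2) receives the radiopharmaceutical directly
for every treatment cycle; the contralateral lobe is exposed only via
recirculation and acts as the control arm. The estimand is the multiplicative
effect ρ of intra-arterial delivery on the tumour-to-non-tumour uptake ratio

$$ T/N \;=\; \frac{\sum_i v_i\, u_i / \sum_i v_i}{u_{\text{normal}}}, $$

where $u_i$ is the mean (or peak) counts/voxel in target-lesion VOI $i$,
$v_i$ its volume in mL, and $u_{\text{normal}}$ the mean counts/voxel of a
lesion-free VOI of at least 15 mL in the control lobe. The weight is the VOI
volume: the numerator is then the aggregate concentration over all target
tissue of the lobe. T/N is formed per lobe and per cycle; the within-patient
pair (T/N over the treated lobe, T/N over the control lobe) is the analysis
unit. Because both lobes are divided by the *same* normal-tissue uptake, the
within-patient ratio $T/N_{IA} / T/N_{control}$ is independent of the
denominator and of any global count scaling — the design is self-normalizing.

## The quantification chain

1. **Segmentation** (baseline receptor image). A rough VOI around each target
   lesion is shrunk to the voxels with value at or above 42% of the maximum
   voxel value inside the rough VOI. Choices the rule leaves open and how
   this package closes them: the comparison is `>=`, so the maximum voxel is
   always retained; the result is restricted to the 26-connected component
   containing the maximum voxel (26-connectivity is the natural choice for
   blob-like lesions; it prevents a second hot island inside a generous
   rough VOI from contaminating the lesion); ties at the maximum are broken
   by the lowest lexicographic (z, y, x) index, which makes results
   deterministic on noise-free data.
2. **Transfer.** Baseline-to-cycle alignment is a *known* rigid transform
   (registration estimation is out of scope; the generator records the truth).
   Each source voxel centre is mapped through the transform and assigned to
   the nearest target voxel; duplicates collapse, out-of-grid points are
   dropped with a logged count, and an entirely lost VOI is an error. The
   rule is the simplest reproducible one; its volume error is bounded by a
   one-voxel shell, which the tests assert.
3. **Uptake.** Mean uptake is the arithmetic mean of counts/voxel. Peak
   uptake is the mean of all grid voxels whose centres lie within 5 mm
   (Euclidean, world coordinates) of the hottest VOI voxel's centre — the
   sphere may leave the VOI but is clipped at the grid boundary. At 4 mm
   isotropic spacing the sphere holds the hot voxel and its six face
   neighbours, so a single hot voxel of value 100 gives a peak of 100/7.
   Uptake stays in raw counts/voxel; no SUV calibration is applied, since
   every reported quantity is a ratio.

A practical subtlety: on noise-free uniform lesions every lesion voxel ties
for the maximum, the tie rule picks an edge voxel, and the peak sphere then
includes background — so the *peak*-based ratio recovers ρ only
approximately, while the *mean*-based ratio recovers it exactly. With Poisson
noise the hottest voxel is an interior voxel essentially always and both
bases behave as intended.

## The synthetic generator

The generator replaces unavailable clinical data with phantoms whose
statistical structure matches the trial's assumptions.

* **Geometry.** The liver is an ellipsoid (semi-axes up to 110 × 75 × 60 mm,
  shrunk on small grids) split by a sagittal plane into a left lobe of one
  third and a right lobe of two thirds of the volume. Grids default to 64³
  voxels at 4 mm isotropic spacing. Lesions are spheres, 1–3 per lobe,
  diameters 30–50 mm (the eligibility floor of 3 cm is enforced), placed by
  uniform sampling over the feasible voxel centres (fully inside the eroded
  liver ellipsoid and fully on the lobe's side of the split plane, with a
  one-voxel buffer at the plane so lesions of opposite lobes can never touch —
  otherwise threshold segmentation could 26-connect a control-lobe lesion
  into a treated-lobe VOI); an
  infeasible configuration raises a placement error after a bounded number
  of attempts. Overlapping same-lobe spheres model confluent composite
  lesions.
* **Counts.** Healthy liver has expectation `background_counts` (default 30
  counts/voxel, a desk-scale choice that keeps relative Poisson noise in the
  normal VOI around 1%); lesion voxels have expectation
  `background × multiplier` on the baseline and control side and additionally
  `× ρ` in the treated lobe on post-cycle volumes. Observed volumes are
  voxelwise-independent Poisson draws (a deterministic noise-free mode
  exists for exactness tests). No acquisition physics — collimator response,
  attenuation, scatter, reconstruction — is modelled, so passing tests
  establish correctness of the *analysis chain*, not robustness to SPECT
  image degradation.
* **Calibration.** Defaults are back-derived from the design's published
  operating point: control-lobe T/N is lognormal with log-mean `ln 16.2`;
  the enhancement is lognormal with log-mean `ln 1.17`; and the within-pair
  SD of log ratios is 0.39, obtained by inverting a one-sample t relation
  (a two-sided p of 0.045 at n = 27 on a mean log-ratio of ln 1.17 implies
  sd = ln(1.17)·√27 / t, with t the 0.9775 quantile of t(26), giving 0.387 ≈
  0.39). The total between-patient spread of log T/N (≈ 0.97, recovered from
  a reported control-arm CI half-width of 8 on a mean of 16.2 at n = 27) is
  split once into a between-patient component of 0.90 and a
  within-patient/between-cycle drift of 0.35; the drift multiplies both
  lobes equally, so it widens the T/N distribution without touching the
  within-patient ratio. Per-lesion multipliers default to the patient-level
  value with zero jitter: that makes the noise-free lobe ratio equal ρ
  *exactly*, which pins down the chain's algebra in tests; a
  `lesion_multiplier_sd > 0` re-introduces lesion heterogeneity when wanted.
* **Enhancement draws.** ρ is drawn independently per patient-cycle,
  `log ρ ~ N(log 1.17, 0.39)`. This makes the cycle-1 paired log-ratio
  analysis see exactly the calibrated within-pair SD and gives the mixed
  model genuine within-patient variation across cycles.
* **Follow-up.** Each lobe independently draws a response *type* from a
  mixture profile (the same profile in both lobes — the generator's null of
  no differential response). The default mixture (25% responders at 3
  months; 35% responders, 61% stable, 4% progression at 6 months, with small
  Gaussian jitter on the fractional changes) is tuned so the expected cohort
  response table matches the design's published shape.
* **Laboratories.** Per analyte, a baseline value (abnormal with
  configurable probability), a multiplicative random walk across visits, and
  rare treatment-emergent excursions. The grading table shipped by
  `default_grading_rules()` covers the tracked hepatic, haematological and
  renal analytes with closed-bound thresholds (`>=` for elevations, `<=` for
  depressions, value exactly at a threshold takes that grade); it is
  **approximate and synthetic** — grade cut-points follow the usual
  multiples-of-limit pattern but are not a validated clinical table, and the
  engine is fully table-driven so a validated JSON table can be supplied.
* **Dropout.** Optional (off by default): two patients stop after cycle 1
  and one after cycle 2, the completion pattern of a 27-patient cohort.
* **Two layers.** `build_phantom()`/`generate_cohort()` produce image-level
  data; `simulate_tn_cohort()` draws the same distributional model directly
  at the T/N-table level. Replicated operating-characteristic studies
  (type-I error over 1000 cohorts, parameter recovery over 200) run on the
  tabular layer — identical structure by construction, at a fraction of the
  cost — while the image chain is exercised by its own exactness and
  Monte-Carlo tests (200 phantom replicates on 36³ grids). Test problem
  sizes (8³ oracle volumes, 36³–48³ phantom grids, 100–1000 replicates)
  were chosen as desk-scale defaults that keep the full suite in the
  low minutes.

## Inference

* **Primary:** paired t-test on `tn_ia − tn_control` at cycle 1 (mean
  basis), two-sided, 95% CI. Incomplete pairs are dropped with a message;
  fewer than two pairs is an error. If the differences have (numerically)
  zero variance the test is reported degenerately: p = 1 for a zero mean
  difference, p = 0 otherwise, with a point CI.
* **Ratio:** the same test on natural-log T/N; estimate and CI are
  exponentiated (geometric mean ratio). Non-positive T/N values are an error
  naming the offending records; an exactly constant ratio is reported as a
  degenerate-case error rather than a fabricated p-value.
* **All cycles:** `tn ~ arm + (1|patient) + (1|patient:cycle)` by REML with
  Satterthwaite p-values (`lmerTest`). With a single cycle the per-cycle
  intercept is perfectly confounded with the per-patient intercept and is
  dropped — in that balanced case the fixed arm effect equals the paired-t
  mean difference, an algebraic identity the tests assert to 1e-6. Singular
  fits (variance components at the 0 boundary) are reported, not hidden;
  genuine non-convergence is an error. REML rather than ML because variance
  components at n ≈ 27 are the point of the model.
* **Covariates:** effect modification is the `arm × covariate` interaction
  added to the same model; the reported p-value is the Satterthwaite F test
  of that interaction. Constant covariates are an error.
* **Fisher:** exact conditional p by complete enumeration of all tables with
  the observed margins (multivariate hypergeometric; tables no more probable
  than the observed one are summed, with a 1e-7 relative tie tolerance, and
  the sum is normalized by the total mass over all margin-consistent tables
  to cancel accumulated floating error). Enumeration is exact and fast for
  trial-sized tables; the suite cross-checks it against `stats::fisher.test`.
* **No multiplicity adjustment** and two-sided p-values throughout, matching
  the analysis plan this class of trial reports.
* **Increase proportion:** strict inequality; ties count as no increase
  (the conservative reading).

## Power and sample size

`power_paired_t()` is the exact noncentral-t computation: power =
$1 - F_{n-1,\delta}(t_{crit}) + F_{n-1,\delta}(-t_{crit})$ with
$\delta = d_z\sqrt{n}$. At $d_z = 0.65$ and two-sided α = 0.05 this gives
0.8896 at n = 26 and 0.9015 at n = 27, so `min_n_paired_t()` returns 27.
Trial documentation in this design space often prints 26 for the same inputs;
neither a one-sided test (n = 22) nor a normal approximation reproduces 26
exactly, and the closest reading is that 26 sits just below 0.90 and was
rounded by the original software. The package returns the exact answer and
documents the discrepancy rather than forcing agreement.

## RECIST and toxicity rules

`recist_classify()` takes the per-lobe diameter sums: CR at a sum of 0, PD at
a ≥ 20% *and* ≥ 5 mm increase from the nadir (the minimum of all prior sums,
baseline included), PR at a ≥ 30% decrease from baseline, SD otherwise, with
PD taking precedence over PR. All comparisons are closed at the boundary and
the test suite pins each clause exactly at its threshold. Per-lobe sums are
treated as independent lesion sets because the lobes are the paired arms.
CR cannot arise from the default generator (baseline diameters ≥ 30 mm never
shrink to zero) but is implemented for completeness. For composite confluent
lesions the generator models unions of spheres; the diameter bookkeeping uses
per-lesion diameters, and how a clinical reader would measure a confluent
union (longest diameter of the union vs a sum) remains a flagged judgement
call rather than a hidden default.

Toxicity attribution takes the worst follow-up grade per patient-analyte and
emits an event only when it exceeds the baseline grade — a pre-existing
grade-3 elevation that stays grade 3 is not treatment-emergent, while the
same patient moving to grade 4 is exactly one grade-4 event.

## Numerical and degenerate-input choices

* Voxel indices are 1-based inside R; world = origin + (index − 1) · spacing;
  NIfTI I/O translates to the on-disk 0-based convention. Only axis-aligned
  grids without shear are supported.
* Rough VOIs with no signal (max 0), empty VOIs, mixed grids, nadir above
  baseline, unknown analytes, non-positive normal-tissue uptake: all are
  errors, not silent NA propagation.
* Differences at floating-point noise level (relative 1e-12) are treated as
  exact ties in the paired test, so noise-free null phantoms yield p = 1
  rather than a t-test on rounding error.
* All generator randomness flows through explicit integer seeds
  (`withr::with_seed`), and `generate_cohort()` writes byte-identical CSV
  manifests for identical (config, seed).

## Known limitations

* No SPECT physics: Poisson counts on a piecewise-constant expectation are a
  deliberate abstraction. Partial-volume effects, scatter, attenuation and
  reconstruction artefacts — all present in real data — are absent, so
  real-data T/N ratios will be noisier and biased in ways the phantom does
  not show.
* Spherical lesions and an ellipsoidal liver are topological stand-ins;
  anatomical realism is a non-goal.
* Registration is assumed known; mis-registration error beyond the recorded
  transform is not modelled (a bounded random transform can be switched on
  to probe sensitivity to VOI transfer itself).
* The peak basis has the uniform-lesion edge effect described above.
* Threshold segmentation at 42% of the maximum can only isolate a lesion
  whose uptake exceeds background by a factor of at least 1/0.42 ≈ 2.4. The
  default calibration (lognormal contrast around 16.2) puts roughly 1.6% of
  simulated patients below that limit; for those, background voxels join the
  lesion VOI and dilute the measured T/N — exactly as the rule would behave
  on a real low-contrast lesion. Exactness checks therefore run at fixed
  contrast (`tn_true_log_sd = 0`).
* The shipped grading table is approximate; real analyses must load a
  validated one.
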