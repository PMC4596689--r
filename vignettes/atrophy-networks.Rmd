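---
title: "Atrophy networks from deformation-based morphometry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atrophy networks from deformation-based morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atrophynet)
```

This vignette documents the statistical models behind `atrophynet`, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the design decisions taken where several defensible choices
existed.

## 1. The deformation model

Non-linear registration of a subject's brain to a template yields a
displacement field $U(x) = (u_1, u_2, u_3)$ in mm. Local volume change is
carried by the derivative of the displacement, not the displacement itself:
a uniform translation changes no volume. `jacobian_determinant_map()`
therefore estimates $J_{ij} = \partial u_i / \partial x_j$ by central
differences with per-axis step $\delta_j$ (the voxel dimension; anisotropic
spacing is supported) and returns

$$\det(I + J) - 1,$$

where the identity accounts for the displacement being relative to
position: $U \equiv 0$ (or any constant) gives exactly 0, values below 0
mean local tissue smaller than the template — the atrophy direction. The
pure $\det(J)$ reading is rejected because it returns $-1$ for a zero field
and violates the no-change-under-translation requirement.

**Boundary policy.** Central differences are undefined on the outermost
slices. The default (`one_sided`) uses first-order one-sided differences
there; `replicate` pads by edge replication (halving the apparent gradient
at the border). The policy is recorded in the map's provenance. Interior
voxels are identical under both.

**Numerical behaviour.** The estimator is second-order accurate: on
analytic fields the interior error shrinks by a factor of four when the
voxel size halves. A single shear field has an exactly triangular discrete
Jacobian, so its determinant is exact (unit) at any resolution; crossed
shears expose the $O(\delta^2)$ truncation error and are used in the tests
to verify the convergence order.

## 2. Spatial ICA and mixture-model z-scoring

Stacked DBM maps (subjects × voxels, voxel-wise demeaned) are whitened by
PCA to $K$ dimensions and unmixed by fixed-point iteration with the
logcosh contrast and symmetric decorrelation, treating voxels as samples —
spatial ICA. The number of components is a parameter (default $K = 30$, the
order estimated in the reference analysis); automatic order selection is a
tool internal of the original software and out of scope here.

ICA leaves sign and scale indeterminate per component. Conventions adopted
(and asserted in tests): each spatial map has positive skewness; loading
columns have unit variance, with their scale absorbed into the maps;
components are ordered by explained variance. With these conventions the
direction of a group difference on the loadings is meaningful — patients
load *lower* on the disease component (less volume).

Component maps are converted to z-statistic images by fitting a three-class
mixture to the in-mask values: a Gaussian null plus positive- and
negative-tail activation classes modelled as gamma densities on the
distance above/below the null mean, fit by EM with moment-matched gamma
updates. Voxels are expressed as $z = (v - \mu_0)/\sigma_0$ relative to the
fitted null and thresholded at $z \ge 3$ (default). Initialisation is
robust (median/MAD for the null, activation classes seeded at ±3.5 null SD
with 3% total weight), which keeps the null class dominant and calibrated
on activation-free maps: on pure Gaussian input the fitted null mean and SD
are within a few percent and the supra-threshold mass stays near the
Gaussian tail value $\bar\Phi(3) \approx 0.00135$. Degenerate fits (null
weight < 0.5) and small inputs (< 1000 voxels) fall back to median/MAD
standardisation with a warning recorded in the result — never silently.

The ICA contrast assumes sparse, super-Gaussian sources;
`check_super_gaussianity()` reports the plain fourth-standardised-moment
kurtosis per map (Gaussian = 3) and flags maps exceeding the conventional
cutoff of 4.

## 3. Component-level inference

Group differences use the unpaired pooled-variance t-test (Welch available
by flag), Bonferroni-corrected over the $K$ fitted components — two-sided
throughout. Age effects are Pearson correlations per component, same
correction, computed without partialling out group (a flag for the
partialled variant was considered and left out; the unpartialled form is the
direct reading of correlating component expression with age). Clinical
models are ordinary least squares with intercept: in patients
`loading ~ age + UPDRS-III + SBR`, in controls `loading ~ age + SBR`. The
site model adds the acquisition site as a categorical term to
`loading ~ group + age + sex` and tests it by a nested-model F-test per
component, Bonferroni over components.

## 4. Network overlap

Spatial similarity between maps is Pearson correlation over the common
in-mask voxels of *unthresholded* maps, with |r| > 0.25 as the similarity
rule; Dice overlap is computed on *thresholded* supports — the dual
reporting mirrors the reference analysis. The permutation null reassigns
one map's in-mask values to random in-mask coordinates (1000 permutations
by default), which destroys spatial structure while preserving the value
histogram; p-values use the add-one rule $(1 + \#\{|r_\mathrm{null}| \ge
|r|\})/(n_\mathrm{perm} + 1)$, so they are valid (conservative-exact) and
never zero. The permutation is restricted to the mask (whether the original
analysis shuffled within the mask or the full box is unstated; the mask is
the defensible choice and the maps carry it explicitly).
Spatial-autocorrelation-preserving nulls are a documented non-goal: the
coordinate-reassignment null is the literal generative model being tested.

## 5. Connectomes

Subject ROI correlation matrices are averaged in Fisher-z space:
$Z = \tanh^{-1}(R)$ element-wise, averaged over subjects, back-transformed.
The diagonal is excluded ($\tanh^{-1}(1)$ is undefined) and set to 1 by
convention; off-diagonal |r| = 1 raises an error unless clamping to
$1 - 10^{-7}$ is requested. Cells on which all subjects agree are returned
exactly (the transform pair is a mathematical identity there, and bit-exact
fixed points make reruns reproducible).

Anatomical connection probabilities (ACP, in [0, 1], symmetric, zero
diagonal) become effective distances by transforming each edge and taking
all-pairs shortest paths. The default edge length is $-\log(\mathrm{ACP})$:
under independence of connection failures, the shortest path is then the
most probable path, and the path length is $-\log$ of its reliability (an
identity asserted against a max-product brute-force oracle in the tests).
`one_minus` and `reciprocal` transforms are selectable and recorded in the
output. ACP = 0 means no edge; disconnected pairs get infinite distance and
are excluded pairwise downstream (not imputed). Hop-count geodesics are
provided separately (`graph_geodesic()`), since "geodesic distance" is used
in both senses in this literature; both are reported rather than guessing.

The simplified seed-connectivity map correlates each voxel with the mean
seed time series per subject, Fisher-transforms, and computes a one-sample
t across subjects, with a parametric threshold option. Mixed-effects
random-field thresholding is out of scope: the contribution being tested is
the comparison with the atrophy map, not the GLM machinery.

## 6. Epicenter analysis

Regional atrophy is the per-region t-statistic of the group term in
`regional DBM ~ group + age` (ANCOVA-style age correction, the direct
reading of "corrected for age"), oriented so negative t = greater atrophy
in patients.

Epicenter correlations relate each region's connectivity to the candidate
seed (functional mode) or effective distance to it (structural mode) to the
regional *atrophy severity*, defined as $-t$. This orientation choice is
deliberate: it makes a true functional epicenter produce a **positive** r
(more connected → more atrophied) and a true distance-based epicenter a
**negative** r (farther → less atrophied), matching the sign conventions of
the published propagator tables, and it makes "sort descending by r" the
correct functional ranking rule. The seed region is always excluded from
its own correlation vector — including its self-connectivity of 1 together
with its own atrophy value would inflate r. Euclidean-proximity control is
a partial correlation via OLS residualisation of both variables on the
centroid distance to the seed. Spearman rank correlation is available as
`method = "spearman"` (the non-linear option used for the anatomical
connectome); Pearson is the default.

`rank_propagators()` repeats the analysis with every region as the seed and
sorts by propagation strength (descending r functional, ascending r
structural), ties broken by region id for determinism. Ranking — not the
per-seed p-value — carries the inference: under the null, the maximum |r|
over 112 candidate seeds crosses the per-seed α = 0.05 cutoff far more
often than 5% (a max-statistic effect demonstrated by a property test), so
per-seed significance would overstate the evidence.

## 7. The synthetic-data generator

The generator is the package's replacement for non-redistributable clinical
imaging data. It produces data *under the model the analysis inverts* — a
deliberate choice: recovery then tests the pipeline's correctness, not the
model's realism.

* **Source maps** are smooth Gaussian random fields restricted to disjoint
  compact patches of the spherical mask (k-means patches), windowed and
  soft-thresholded until each map's *excess* kurtosis exceeds 4 — strictly
  sparser than the plain-kurtosis > 4 property checked downstream, so the
  generated data satisfy the ICA contrast's assumption with margin.
  Disjoint supports make cross-source spatial correlations ≈ 0, so the
  |r| > 0.25 matching rule separates planted from non-planted pairs by
  construction.
* **Loadings** are independent standard normal per component. Exactly one
  component carries the group effect: patient loadings shifted down by `d`
  within-group standard deviations (default d = 1 — chosen for
  testability; the reference study reports significance, not an effect
  size). The disease loading carries an age slope (r = −0.38) and the
  clinical covariates are generated at the reported correlation scales
  (UPDRS-III −0.22, SBR +0.23 in patients, +0.33 in controls), with
  demographics from the reference cohort table (232/117 subjects, ages
  61.2 ± 9.1 / 59.7 ± 11.3, UPDRS-III 21.9 ± 9.1, SBR 1.4 ± 0.4 / 2.6 ±
  0.6, disease duration 6.9 ± 7.1 months). Null components receive *random*
  loadings, so their sample group differences are nonzero by chance; with
  K = 30 this means a null component crosses the Bonferroni line in about
  4.7% of cohorts — the family-wise rate the correction is designed to
  bound, visible in the generator because the generator is honest about it.
* **Maps** are `map_scale × (loadings · sources + noise)` with per-voxel
  noise SD 0.25 on the unit mixing scale and `map_scale = 0.15`, keeping
  |J|−1 values in a physical range (a 15% local volume change is a large
  but plausible deformation; values ≤ −1 are impossible volumes and are
  rejected when converting to fields).
* **Displacement fields** reproducing a target map are built by a
  single-axis construction: $u_1$ = trapezoidal cumulative integral of the
  target along $x_1$, $u_2 = u_3 = 0$. Rows 2 and 3 of $I + J$ are then
  unit rows, so $\det(I+J) - 1$ equals the central difference of $u_1$ — a
  (1, 2, 1)/4-smoothed copy of the target, exact for constants. The
  contract is the round-trip tolerance (interior MAE < 0.02 on smooth
  targets), not the construction, which the reference analysis never needed
  (it goes field → map only).
* **ROI time series** are stationary multivariate normal draws with the
  target correlation (eigen square root), so the Fisher-averaged group
  connectome converges to the truth.
* **Spread data**: regional severity is linear in connectivity to the
  planted epicenter (functional) or in effective distance (structural),
  plus Gaussian noise. `target_r` calibrates the noise SD to
  $\sigma_\mathrm{signal}\sqrt{1/r^2 - 1}$ so the attained correlation
  magnitude matches a requested scale (0.4 functional / 0.28 structural,
  the observed scales being emulated). The attained sample correlation is
  recorded in the ground truth.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: registration artifacts, spatially correlated
noise, partial-volume effects, site- or scanner-specific noise beyond a
mean offset, non-linear covariate relationships, overlapping atrophy
networks, and any temporal disease dynamics. Recovery results here validate
the *pipeline*, not the biological claim.

## 8. Orchestration and problem sizes

`run_pipeline()` chains the stages on synthetic data with a single master
seed fanned out to per-stage seeds (`seed + 101 × stage index`), so
toggling one stage does not shift another's random stream; reruns are
byte-identical. The default run uses the study conditions (232/117
subjects, K = 30, 112 regions) on a 24³ grid — the grid at which the mask
holds ~5600 voxels, enough for 30 disjoint sources and a stable mixture
fit, while a full run completes in well under a minute. Test and
acceptance simulations use 16³–24³ grids, 50–200 subjects, 500-replicate
calibration loops and 60–100-seed recovery studies; these sizes were chosen
so the full suite exercises every stage against ground truth in a few
minutes on one CPU.

## 9. Known limitations

* Fixed-point ICA with user-set K replaces variational probabilistic ICA
  with automatic order selection; results at badly misspecified K are not
  characterised.
* The mixture-model z calibration is validated on unimodal null maps with
  modest activation fractions; heavily bimodal maps trigger the (loud)
  robust fallback instead.
* The permutation null ignores spatial autocorrelation, by design (see §4);
  p-values against spatially smooth reference maps are anti-conservative in
  the autocorrelation-preserving sense.
* Structural-mode rankings treat infinite distances by pairwise exclusion;
  graphs with many disconnected pairs lose power.
* The pipeline driver wires synthetic data only; applying the modules to
  real NIfTI inputs uses the module functions (and the I/O helpers)
  directly.
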