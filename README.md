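# atrophynet

Detecting disease-specific atrophy networks from deformation-based
morphometry (DBM), and testing whether their spatial pattern is explained by
trans-neuronal spread from a candidate epicenter.

## The scientific problem

In neurodegenerative disease, gray-matter atrophy is not diffuse: it follows
spatially coherent networks, consistent with pathology propagating along
anatomical and functional connections. This package implements, as a tested
and reusable pipeline, the analysis chain used to demonstrate such a network
in early Parkinson's disease:

1. **DBM** — each subject's non-linear warp to a template is summarised per
   voxel by the determinant of the local Jacobian of the displacement field
   `U(x) = (u1, u2, u3)`:

   `J_ij = ∂u_i/∂x_j ≈ (u_i(x + δ_j e_j) − u_i(x − δ_j e_j)) / (2 δ_j)`

   and the relative local volume change `det(I + J) − 1` (0 = no change,
   negative = local tissue smaller than template, the atrophy direction).
2. **Spatial ICA** — the subjects × voxels matrix of DBM maps is decomposed
   into K spatially independent source maps with per-subject loadings
   (fixed-point ICA on PCA-whitened data, voxels as samples). Component maps
   are converted to z-statistic images via a Gaussian-null + two-gamma
   mixture model and thresholded at z ≥ 3; super-Gaussianity of the data
   (kurtosis > 4) is checked explicitly.
3. **Component statistics** — per-component unpaired t-tests between
   patients and controls (Bonferroni over K), age correlations, clinical
   regressions (loading ~ age + UPDRS-III + SBR in patients), and a
   categorical site model.
4. **Network overlap** — spatial Pearson correlation of the atrophy
   component against reference network maps (similarity rule |r| > 0.25),
   with a voxel-coordinate permutation null and Dice overlap of thresholded
   supports.
5. **Connectomes** — a healthy-reference functional connectome by Fisher-z
   averaging of subject ROI-correlation matrices
   (`Z = atanh(R)`, averaged, `R_group = tanh(Z̄)`), a voxel-wise
   seed-connectivity t-map, and effective anatomical distances as shortest
   paths through −log(ACP) edge lengths (ACP = anatomical connection
   probability).
6. **Epicenter analysis** — per-region age-corrected atrophy t-scores
   (negative = more atrophy in patients) correlated with each region's
   connectivity (or effective distance) to a candidate epicenter, with
   Euclidean-proximity control via partial correlation, and every region
   ranked as a potential disease propagator.

The raw clinical MRI data behind the original analysis are not
redistributable, so the package ships a **synthetic-data module** that
generates every input with the statistical structure the analysis assumes —
super-Gaussian source maps with a planted disease component, covariates
correlated with component expression at the reported scales, ROI time series
with known correlation structure, and connectome/atrophy pairs with a
planted epicenter — so that every stage is exercised against ground truth at
desk scale.

## Worked example

```r
library(atrophynet)
report <- run_pipeline(run_config(seed = 11))
print(report)
```

```
atrophynet run report (version 0.1.0)
  config hash:          9b83c65c8d880c171c3074a68919e8c9
  subjects:             232 patients / 117 controls
  components flagged:   1 (component 12, p_bonf = 1.66e-15)
  truth recovered:      TRUE
  best-match r:         0.974
  planted epicenter rank: 1 (attained r = 1)
```

Reading the output: the simulated cohort (232 patients, 117 controls, the
default study conditions) was decomposed into 30 spatial components; exactly
one showed a Bonferroni-corrected group difference (the planted disease
component — `truth recovered: TRUE` means the flagged component is the one
that carries the planted effect). Its spatial map correlates r = 0.974 with
its planted reference network, and the planted epicenter is ranked first
among all 112 candidate propagator regions at zero spread noise.

The same run from a shell:

```sh
Rscript inst/cli/atrophynet.R run --simulate --seed 11 --out-dir results/run11
```

writes the covariate table, component tests, match table, regional atrophy
profile, functional connectome and propagator ranking as TSV, plus the
serialised configuration (`config.yaml`). Re-running with the same seed
reproduces every artifact byte for byte.

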