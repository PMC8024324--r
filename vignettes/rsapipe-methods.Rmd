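---
title: "Comparing brain and model representational geometries with rsapipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing brain and model representational geometries with rsapipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Representational similarity analysis (RSA) compares two measurement systems
— here, human visual cortex and candidate model layers — without mapping
units to units. Each system is summarized by its representational
dissimilarity matrix (RDM): the K x K matrix of pairwise distances between
its condition response patterns. Two systems "represent alike" to the
extent that their RDMs correlate. `rsapipe` implements the full group-level
workflow: voxel selection, RDM construction, noise ceilings, a
hierarchy-correspondence test, a variance-captured test, and 2-D
visualization, together with a synthetic generator that plants every
quantity the pipeline is supposed to recover.

## The model and its statistics

**RDMs.** For a brain region, run-averaged beta patterns are z-normalized
per condition (mean 0, unit *sample* standard deviation, denominator V-1)
and all pairwise Euclidean distances taken; for a model layer the same is
done to category-averaged activations. A correlation-distance variant
(1 - Pearson r between raw rows) is provided. Under sample-sd
z-normalization the two are monotonically linked,
d^2 = 2 (V - 1)(1 - r), so rank-based comparisons are identical across the
two metrics on tie-free data while Pearson comparisons need not be — which
is exactly why the suite tests that invariant.

**Comparison.** RDMs are compared via Spearman correlation of their
K(K-1)/2 off-diagonal vectors (upper triangle, row-major; mid-rank tie
handling), with Pearson available as a variant. Correlations are Fisher
z-transformed (arctanh) before group statistics.

**Noise ceiling.** How well could the *true* model do, given inter-subject
variability? The upper bound averages each subject's correlation with the
group-mean dissimilarity vector including all subjects; the lower bound
uses the leave-one-out group mean. Averaging is over raw correlations (an
`average = "fisher_z"` variant exists for sensitivity analysis); the group
RDM is the arithmetic mean of subject vectors.

**Hierarchy correspondence.** Per subject, the layer best correlated with
each of the six regions (V1, V2, V3, V4, LOT, VOT) is found (argmax;
ties to the lowest index, logged). The Spearman correlation between region
order and best-layer index, Fisher-transformed, is tested above zero with
a one-tailed one-sample t across subjects — only positive correspondence
is meaningful. p values are Benjamini–Hochberg adjusted across whatever
family the analysis declares (the image conditions of an experiment);
families are explicit configuration, never inferred.

**Variance captured.** A subject's brain–layer correlation r, divided by
the region's lower ceiling bound and squared, estimates the proportion of
explainable RDM variance the layer captures. Per region the layer with the
highest group-mean proportion is selected and the subject proportions are
tested *below* 1 (one-tailed; values above 1 carry no evidence of
shortfall), BH-adjusted across the six regions. A `per_subject_max`
variant tests each subject's own best layer instead; it biases the mean
proportion upward and is off by default.

**MDS.** Classical (Torgerson) scaling: double-center -1/2 J D^2 J, embed
with the top-2 nonnegative eigenpairs, report dropped negative eigenvalues
and a root-mean-square stress. Published panels of this kind are usually
rotated/flipped by hand; `rsapipe` replaces that irreproducible step with
Procrustes alignment (rotation/reflection + translation, never scale, so
within-panel distances are untouched) to a configurable reference panel.

## Key parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 75 | most-reliable voxels kept per ROI (split-half, odd vs even runs) |
| `selectivity_alpha` | 0.05 | per-comparison level of the paired, one-tailed selectivity t tests |
| `q` | 0.05 | FDR level of the BH adjustment |
| `metric` | `euclidean_z` | RDM metric (`correlation_distance` variant) |
| `method` | `spearman` | RDM comparison (`pearson` variant) |

Voxel selectivity follows the conjunction rule: a voxel is face-selective
iff its response is higher for faces than for *every* non-face category at
p < alpha (paired t across runs, one-tailed since the criterion is
directional); likewise body (bodies/cats/elephants averaged) and scene
(houses). Condition format variants (original/controlled, spatial-frequency
bands) are averaged before testing; reliability selection uses the
uncollapsed conditions.

## The synthetic world

The generator (`simulation_config()`, defaults mirroring the study design:
6 subjects, 6 ROIs, 8 categories x 10 exemplars, 16 runs, 200 voxels per
ROI of which 75 carry signal, 11 sampled layers) plants:

- a chain of latent category geometries, one level per layer, mixed
  AR(1)-style (`level_mixing` = 0.75) so level similarity decays with
  level distance; each level's innovation carries animate/inanimate (and
  artificial shape family) cluster structure plus category and exemplar
  components, and exemplars are averaged into category geometries the same
  way the real pipeline averages exemplar responses;
- a region-to-layer mapping (default 1,3,5,7,9,11) realized by giving
  region r a random linear readout of its mapped level; subjects perturb
  the readout weights (`subject_loading_sd` = 0.4);
- i.i.d. Gaussian run noise (`run_noise_sd`). The default 3.8 was
  calibrated once, against the prescribed target band only, so the group
  lower noise ceiling lands at ~0.7–0.9 in every region (measured grand
  mean ~0.79); it was frozen before any recovery test was run;
- pure-noise voxels (the other 125), so top-75 selection has a planted
  answer;
- category-selective voxels in the LOT/VOT analogs: a fraction of signal
  voxels responds to its category group (offset x indicator + 10% jitter)
  instead of the shared geometry, with no subject readout deviation — they
  are selective *by construction*, the way a face-selective voxel's tuning
  is category-driven rather than geometry-driven.

Random streams are split hierarchically (truth / region / subject), so
adding subjects never perturbs existing subjects' data.

What the generator does **not** emulate: temporal autocorrelation, spatial
voxel correlations, hemodynamics (the pipeline consumes GLM betas, not
time series), non-Gaussian noise, attentional or session effects. A green
recovery test therefore establishes the pipeline's correctness on its own
stated world, not the validity of any particular empirical claim about
cortex.

## Numerical choices

- z-normalization uses the sample sd (V-1); rank-based results are
  invariant to the choice, and the 2(V-1)(1-r) identity holds exactly.
- `fisher_z` clamps |r| >= 1 to 1 - 1e-12 with a warning, so degenerate
  noise-free runs do not halt.
- The correspondence statistic over n regions is discrete; at |rho| = 1 it
  is clamped to the midpoint between 1 and the next achievable untied rho,
  1 - 12/(n(n^2-1)) (z = 2.11 at n = 6), not to 1 - 1e-12. The generic
  clamp maps one perfect subject to z ~ 14.6, which dominates the group
  variance and destroys the power of the group t for a reason unrelated to
  the hypothesis; a resolution-commensurate boundary keeps a perfect
  subject large but comparable to near-perfect ones.
- Zero-variance group tests resolve by the sign of the mean (p = 0 or 1)
  with a warning; they arise only in noise-free simulations.
- Argmax ties break to the lowest layer index; top-k reliability ties to
  the lowest voxel index (deterministic across platforms). Constant voxel
  profiles get a -Inf reliability sentinel and are never selected.
- BH adjustment is the step-up `min_{j>=i} m p_(j)/j`, capped at 1;
  rejection iff adjusted p <= q.

## Design choices where the design was open

- **Layer number** in the correspondence statistic means the index within
  the sampled layer list, not raw network depth.
- **The vs-1 capture test** uses the group-mean-selected layer by default
  (a per-subject-max variant exists); selecting per subject would bias the
  tested proportion upward.
- **Type-I calibration world.** A one-sample t across subjects controls
  its nominal level only when subject statistics are independent draws.
  With a *fixed* null model and subjects who share a reliable geometry,
  the best-layer assignments covary across subjects and the rejection rate
  genuinely exceeds alpha — the classic stimulus-as-fixed-effect problem,
  a property of the method rather than a bug. The package's type-I
  acceptance world is therefore the noise-dominated regime (lower ceiling
  ~ 0), where subject statistics are exchangeable and the measured
  rejection rate sits at the nominal 5%.
- **Selectivity specificity** is assessed on voxels with no true response
  preference (the pure-noise voxels). Signal voxels whose random geometry
  happens to prefer a category group are genuinely selective under the
  conjunction definition, so flagging them is a hit, not a false alarm.
- Ceiling plotting conventions (re-anchoring at a common value) and manual
  MDS rotation are presentation-layer concerns and intentionally absent;
  Procrustes alignment and display scale factors live in the plot layer.

## Known limitations

- Crossvalidated (e.g. Mahalanobis/crossnobis) distances, searchlight
  mapping, and mixed RSA (voxel-to-unit remapping) are out of scope.
- Noise ceilings carry no bootstrap confidence intervals.
- The group t treats subjects as the only random effect; see the type-I
  discussion above for when that matters.
- With fewer than ~5 subjects the one-tailed t on Fisher z values is
  fragile; the generator's defaults (6 or 10) follow the study design.

## A minimal run

```{r, eval = FALSE}
library(rsapipe)
cfg <- analysis_config(simulation = simulation_config(seed = 1))
res <- run_pipeline(cfg, out_dir = "report")
res$correspondence$p_fdr        # group hierarchy-correspondence test
res$capture                     # per-region variance-captured table
```

All quantitative claims above (calibration band, rejection rates, recovery
rates) are recomputed by `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`; the vignette states nothing they do not measure.
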