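---
title: "Locating states of ongoing thought in a gradient-based neural state space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating states of ongoing thought in a gradient-based neural state space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

Ongoing thought — sustained attention to an external task, off-task
mind-wandering, deliberate future planning — is accompanied by distributed
changes in cortical activity. A compact way to describe such whole-brain
states is to locate them in a low-dimensional *neural state space* whose
axes are macroscale connectivity gradients: smooth spatial maps obtained by
nonlinear dimension reduction of a functional connectivity matrix, of which
the first five are conventionally retained. A brain map's coordinate on
axis $j$ is its spatial Spearman rank correlation with gradient $j$ across
parcels,

$$\rho_j(m) \;=\; \mathrm{corr}\bigl(\mathrm{rank}(m),\, \mathrm{rank}(g_j)\bigr),$$

computed over the parcels the map and the gradient share (average ranks for
ties). Two maps close in this 5-d space engage similar macroscale cortical
hierarchies even if they differ voxel by voxel.

The experiential side of the state is measured by multidimensional
experience sampling (mDES): during a sustained-attention task, probes
interrupt participants and collect 13 ratings of ongoing thought on a
continuous 1–10 scale. A principal component analysis of the probe × item
correlation matrix with varimax rotation summarises the ratings as a small
number of interpretable *thought patterns*; probe-level scores are the dot
product of standardized items with the rotated loadings. The analysis then
asks where task states (vigilance periods, infrequent targets) and
thought patterns (off-task, deliberate, verbal self-relevant) sit in the
state space, and whether their locations differ.

## What the package implements

`gradientspace` implements this pipeline end to end on synthetic data:

1. **Gradient construction** (`makeGradients`): smooth circular random
   fields over parcels, decorrelated in rank space by iterative
   Gram–Schmidt sweeps on centred ranks until every pairwise Spearman
   correlation is below 0.005 (at most 200 sweeps). Network labels for the
   seven canonical cortical networks come from k-means on the gradient
   profiles.
2. **Cohort synthesis** (`simulateMdes`, `simulateTaskRun`,
   `simulateBrainMaps`): probe ratings generated from a planted 13 × 3
   loading matrix; task runs with 3-s trials, 1.5–2.5-s jittered intervals,
   20% targets and eight probes per run placed in vigilance periods; brain
   maps as planted gradient mixtures plus parcel noise, or via the full
   task-GLM route.
3. **First-level GLM** (`buildDesign`, `fitParcelGLM`,
   `fixedEffectsAverage`): boxcars by volume-overlap fraction, convolved
   with a gamma HRF of mean 6 s and sd 3 s (shape 4, scale 1.5); a 6-s
   pre-probe reporting window snapped to whole volumes; mean-centred
   probe-score parametric regressors; per-parcel OLS; z from t by exact
   two-sided tail matching; runs combined by inverse-variance fixed
   effects. A Gaussian-weighted running-line highpass (sigma 50 s) is
   available for drifting series.
4. **State-space coordinates** (`computeCoordinates`, `mapCoordinates`,
   `networkSummary`): Spearman coordinates aligned by parcel id; per-network
   parcel means.
5. **Inference** (`fitLMM`, `bootstrapParams`, `stateByNetworkLMM`,
   `prevalenceByContext`, `rtRegression`): linear mixed models with
   participant random intercepts, REML, sum-to-zero contrasts, type-3 F
   tests with Satterthwaite degrees of freedom, estimated marginal means;
   cluster bootstrap (participants resampled whole, 1000 iterations,
   percentile intervals, two-sided p floored at 2/n); Bonferroni alpha
   0.05 divided by the number of models in a family (and by 7 for
   network-wise pairwise contrasts); response-time regressions after
   zeroing |z| > 2.5 outliers.
6. **Orchestration** (`runPipeline`): the stages in order on a seeded
   cohort, writing a tidy coordinates CSV, a model-results JSON, a report
   and a YAML provenance sidecar; identical seeds give byte-identical
   output bundles.

## The synthetic cohort and its parameters

The generator defaults describe the emulated study design: 62 scanned
participants, three runs of 267 volumes at TR 3 s, eight probes per run,
four participants missing one run (62 × 24 − 4 × 8 = 1456 scanning probes);
a separate behavioral cohort of 91 participants with one session of eight
probes (728 probes); 400 parcels; 13 items; three planted thought
components. These sizes are the package's own simulation choices and the
scale at which its properties are verified.

The planted truth (`plantedTruth`) fixes, once, the quantities recovery is
judged against: a simple-structure 13 × 3 loading matrix with mild
cross-loadings (so rotation is non-degenerate), per-condition 5-vectors of
gradient mixing weights, and a −0.3 coupling between deliberate-thought
scores and response time.

## Numerical choices worth knowing

- **Window snapping.** The 6-s pre-probe window becomes exactly two volumes
  at TR 3 s. Snapping makes the mean-centred parametric regressors exactly
  orthogonal to the window regressor, which the tests use as an oracle.
- **All-zero regressors** (e.g. the probe window in a probe-free run) are
  dropped before fitting; rank deficiency among the remaining columns is a
  named error, not a silent pseudo-inverse.
- **Sign conventions.** Rotated components are ordered by descending
  rotated variance and sign-anchored so the largest-magnitude item loads
  positively; recovery is judged by Tucker congruence on absolute values
  with greedy matching.
- **Scoring scale.** External data are standardized by the *training* item
  means and standard deviations; `projectExternal` is contractually
  identical to `scoreProbes`.
- **z from t** uses log-scale tail probabilities, so extreme statistics do
  not underflow to infinite z.
- **ICC(3,1)** is computed from ANOVA mean squares,
  $(\mathrm{MS}_R - \mathrm{MS}_E)/(\mathrm{MS}_R + (k-1)\mathrm{MS}_E)$,
  on participants with complete run sets.
- **Determinism.** Every stochastic routine takes an explicit seed;
  `runPipeline` reruns are byte-identical and every output bundle carries
  the seed and a config hash.

## A short worked example

```{r, eval = FALSE}
library(gradientspace)

sim <- simulationConfig(nParticipants = 20, nParcels = 200, seed = 1)
res <- runPipeline(pipelineConfig(tempfile("demo_"), simulation = sim))

head(res$coordinates)
varianceExplained(res$pca)
readLines(res$files$report)
```

## What the tests do and do not establish

The test suite verifies *computational* properties: exactness against
closed-form oracles (Spearman via rank-then-Pearson, GLM via the normal
equations, mixed-model F via the paired t-test), calibration under planted
nulls (z normality, type-I error, bootstrap coverage), and recovery of
planted structure at study scale (loading congruence ≥ 0.95, coordinate
recovery r ≥ 0.95, end-to-end detection of a planted dimension-3 offset).

They do **not** compute or confirm any empirical finding about real brains:
no claim about where actual task states sit in the state space, which
thought patterns real cohorts show, or how response time relates to
ongoing thought follows from these tests. The published statistics derive
from subject-level fMRI maps that are not bundled here; the package
establishes that, were such data supplied in the documented formats, the
arithmetic applied to them would be the intended one.

## Limitations

- Synthetic gradients are smooth decorrelated fields, not diffusion-map
  embeddings of real connectivity; network labels are k-means clusters,
  not an anatomical atlas.
- The simulator plants linear, additive structure; real rating and BOLD
  data are neither.
- The highpass filter is available but not applied inside
  `simulateTaskRun`'s generative model, whose drift is optional and linear.
- Mixed models use a random intercept per participant only; random slopes
  are out of scope.
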