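# manifoldRemap

Tools for asking how two simultaneously recorded neural populations treat a
temporal task structure that is shared between two behavioral contexts: does
a population reuse its low-dimensional activity manifold across contexts, or
does it re-express the same within-context geometry in a reoriented form —
rotated within a shared plane, or elongated into orthogonal dimensions? The
motivating system is the cortico-cerebellar pathway: layer-5 pyramidal-tract
(L5PT) cortical neurons that generalize across contexts, and cerebellar
granule cells (GrCs) that remap them. The package also contains a
granule-layer network simulation comparing three circuit hypotheses (relay,
high-rank expansion recoding, low-rank rotation) in an alternating two-task
continual-learning curriculum.

Because no imaging data ship with the package, a synthetic-session generator
with *planted* transformations defines the study conditions; every analysis
stage is validated by recovering what was planted.

## What it computes

For trial-aligned tensors (neuron × time × trial, time relative to reward):

* **Reliability filtering** — odd/even split-half correlation *r*,
  Spearman–Brown correction `R_raw = 2r/(1+r)`, prophecy standardization to
  100 trials `R_adj = K R_raw / (1 + (K−1) R_raw)` with `K = 100/n`, and the
  joint filter `R_adj > 0.4` in both sessions; attenuation-corrected
  cross-session correlations `r_true = r_raw / sqrt(r_xx r_yy)`.
* **Dimensionality** — per-task and joint-task PCA (concatenation along
  time of independently z-scored trial averages), participation ratio
  `PR = (Σλ)² / Σλ²`, PR saturation curves, PC coherence against a random
  projection, cross-task PC correlations.
* **Manifold geometry** — planar Procrustes rotation (translation + scale +
  rotation, no reflection) between shared-space trajectory blocks;
  isoperimetric circularity `4πA/P²`; elongation
  `1 − Circ_shared / Circ_task` (pair maximum); temporal-covariance RSA
  (time × time Gram matrices compared by Spearman's ρ within and across
  task blocks); pairwise-correlation preservation.
* **Population coupling** — ridge-regularized CCA communicating subspaces on
  whole-session matrices; cross-session linear regression transfer (top-20
  predictor PCs → top-2 target PCs, R² on held-out sessions); LDA decoding
  of delay vs reward epochs with cross-task generalization.
* **Behavior** — smoothed lick rates (1 kHz bins, 33-ms Gaussian), the
  predictive licking score `pre/(pre+post)` from median rates in
  [−0.5, 0) s and [1.0, 1.5) s, and the dual-task minimum score.
* **Circuit simulation** — sheared circular manifolds (intrinsic dimension
  2) embedded in 100-D, separated across tasks by an out-of-plane
  translation; granule layers with exactly 4 mossy-fiber inputs per cell;
  Adam training of a linear readout through a task-1/2/1/2 curriculum;
  learning-speed exponential fits, previous-task interference, active-set
  Jaccard overlap, activation PC spectra, and a sinusoidal input-shattering
  control.

## Worked example

Generate a session pair in which population 1 reuses its latents across
contexts while population 2's latents are rotated 50° in the top-2 latent
plane, with trial noise calibrated to a split-half reliability of 0.7 at
100 trials — then run the full analysis chain:

```r
library(manifoldRemap)
cfg <- synthConfig(crossContextRotation = 50, reliabilityTarget = 0.7,
                   nTrialsPerTask = 100, seed = 1)
ps  <- generateSessionPair(cfg)
res <- analyzeSessionPair(ps, threshold = 0.4)
```

Output (printed from this exact configuration):

```
pop1: angle 0.9 deg | cross-task PC cor 0.99 | elongation 0.07 | PR 5.5/5.5 | cell cor 0.83 (corrected 1.00)
pop2: angle 49.8 deg | cross-task PC cor 0.64 | elongation 0.08 | PR 5.6/5.5 | cell cor 0.66 (corrected 0.79)
RSA rho within 0.95 cross 0.66 | pairwise-corr preservation 0.85 / 0.86
```

Reading: the generalizing population's shared-space trajectories align
across contexts (0.9°, PC correlation 0.99), while the remapping
population's trajectories sit 49.8° apart — the planted 50° recovered
through reliability filtering, z-scoring, joint PCA and Procrustes, despite
noise calibrated to realistic reliability. Both populations keep similar
effective dimensionality (participation ratio ≈ 5), and the RSA comparison
shows within-task geometry preserved (ρ = 0.95) while cross-task geometry
degrades (ρ = 0.66).

The circuit side:

```r
geom <- taskGeometry(seed = 1)
res  <- compareArchitectures(geom, nSeeds = 5, nGranule = 2000)
aggregate(cbind(speed, interference, jaccard) ~ kind, res, median)
#>        kind  speed interference jaccard
#> 1 expansion 0.0060         2.84   0.061
#> 2     relay 0.0817         3.12   0.418
#> 3  rotation 0.0815         2.54   0.336
```

Relay and rotation learn an order of magnitude faster than the sparse
expansion code; relay pays for its shared representation with the worst
previous-task interference, which rotation mitigates to expansion-like
levels while keeping relay-like speed and dense (Jaccard ≈ 0.34) population
overlap — geometric alignment, not population partitioning.

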