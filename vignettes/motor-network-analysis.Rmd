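---
title: "Graph-theoretic analysis of the motor execution network: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-theoretic analysis of the motor execution network: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motornet)
library(dplyr)
```

motornet implements a complete resting-state fMRI connectomics workflow for
the 21-node motor execution network: a synthetic cohort generator, signal
conditioning, sphere-ROI network construction, small-world and efficiency
metrics with matched random-network normalization, network-based-statistic
(NBS) permutation inference, and covariate-adjusted group statistics. This
vignette explains the models behind each stage, the parameters that matter,
the numerical choices we made where the methodology left the design open,
and what the package's tests do and do not establish about real data.

## The network and its nodes

The motor execution network is defined by 21 spherical regions of interest
(ROIs): bilateral anterior inferior cerebellum, dentate nucleus, superior
cerebellum, basal ganglia, thalamus, supplementary motor area, superior
parietal lobule, primary motor cortex, dorsal and ventral premotor cortex,
plus the right postcentral gyrus. Centers are MNI-mm coordinates; each node
is a 10-mm-diameter sphere, and the closest pair (left/right SMA) sits at
exactly 10 mm, so no two spheres overlap.

```{r atlas}
atlas <- motor_atlas()
atlas
atlas_min_distance(atlas)
```

Sphere membership on volumetric input uses a half-open ball: a voxel belongs
to an ROI when its center lies strictly within 5 mm of the ROI center, in
world coordinates through the image affine (voxel indices 0-based). This
rule is grid-independent and unambiguous at any voxel size; the package's
miniature NIfTI renderer (`roi_volume()`, `write_roi_nifti()`) exercises the
extraction path on a 3-mm grid without real scanner data.

## The synthetic cohort generator

Subject-level recordings are rarely shareable in this setting, so every quantitative
claim the package makes is established on synthetic cohorts whose design
constants mirror the target study population: 23 patients and 15 controls; 185
acquired volumes at TR = 2 s with the first 10 discarded (175 retained);
patient age 22.30 ± 5.49 years and control age 24.67 ± 5.21, truncated to
the recruited 15–36 range; sex 11/12 female/male in patients and 7/8 in
controls; patient onset age 13.48 ± 4.57 and illness duration 8.83 ± 5.10
years.

**Signal model.** Each subject's ROI series is stationary Gaussian with
lag-1 autocorrelation `ar_coefficient` (default 0.3, a typical value for
BOLD sampled at TR = 2 s): AR(1) innovations of unit marginal variance are
colored by the Cholesky factor of a target correlation matrix, so the
population Pearson correlation of every ROI pair equals the target exactly.
The default target is block-structured on the three anatomical subsystems
(cerebellar, subcortical, cortical): r = 0.5 within a subsystem, 0.1
between. These two values are package choices representing a realistic
contrast between within-system and between-system coupling; they put the
within-block correlations far above, and the between-block correlations far
below, the Bonferroni critical r at T = 175 (0.274), which is what gives
the thresholded graphs their modular, small-world character.

**Planted effects.** Group differences are planted as additive deltas on
the patient-group correlation target before the Cholesky factorization, so
effect sizes are controlled directly in r units. The default pattern
mirrors the reported cerebello-thalamo-striato-cortical circuit: +0.25 on
left dentate nucleus to left thalamus and −0.20 on nine decreased
cortico-cortical, cortico-subcortical and cortico-cerebellar edges. The
magnitudes are package choices: published group differences arrive as t
statistics, which do not identify an effect size in r units. After perturbation the target is checked for positive definiteness
and, if needed, repaired by clipping eigenvalues at 1e-6 and rescaling to
unit diagonal (`repair_covariance = FALSE` turns the repair into an error
naming the offending eigenvalue).

**Motion model.** Head motion is a per-axis Gaussian random walk with
reflecting bounds at ±2 mm and ±2°, the usual subject-inclusion thresholds.
Rotation steps are scaled by 1/50 mm so that, through the 50-mm-sphere FD
convention, translations and rotations contribute equally. The default step
scale of 0.02 mm yields mean framewise displacement around 0.09–0.10 mm,
matching the reported group means (0.093 and 0.104) without further tuning.
Two AR(1) noise channels stand in for white-matter and CSF signals; no
segmentation is simulated.

**Reproducibility.** A single master seed is split into per-subject
substreams, so cohorts are reproducible subject-by-subject and robust to
parallel evaluation order.

What the generator does *not* emulate: hemodynamics, scanner drift and
artifacts, spatially varying noise, registration error, or the 1/f spectral
profile of real BOLD. Consequently, passing tests demonstrate correctness
of the pipeline's statistics under its own assumptions (stationary Gaussian
signals with exact target correlations), not robustness to the full
physics of fMRI acquisition.

## Signal conditioning

`condition_timeseries()` implements the post-normalization preprocessing
stages: detrending, nuisance regression, motion-spike regression, and
band-pass filtering.

* **Framewise displacement** follows the sum-of-absolute-differences
  convention: FD(t) = Σ|Δ translations| + 50 mm · Σ|Δ rotations|, FD(1) = 0.
  The methodology names no FD formula or head radius; this convention and
  the 50-mm radius are the de-facto standard of resting-state toolchains. Volumes with FD > 0.5 mm (configurable) receive one indicator
  regressor each.
* **Friston-24 expansion**: the six realignment parameters, their squares,
  their one-volume lags, and the squared lags; lag rows are zero-padded.
* **Regression** removes, in a single OLS design: intercept, polynomial
  trend (order 1 by default), the Friston-24 set, optional tissue signals,
  and the spike indicators. Constant regressors (e.g. an axis with zero
  motion) are dropped as they duplicate the intercept; any remaining rank
  deficiency is an error naming the deficiency, as is a design with more
  regressors than time points.
* **Band-pass**: zero-phase (forward-backward) order-2 Butterworth,
  0.01–0.08 Hz at TR = 2 s. A 0.04 Hz probe retains > 99% amplitude; a
  0.2 Hz probe is attenuated by more than 50 dB on interior samples. Edge
  samples see filter transients, which is why filter-related assertions in
  the test suite exclude the first and last ~60 s.

**Ordering.** The reference description lists detrend → filter →
regression. Regressing nuisance terms *after* filtering can reintroduce
out-of-band nuisance energy, so the package default regresses everything
(including spikes) in one design and filters the residuals
(`order = "regress_then_filter"`); the published order is available as
`order = "filter_then_regress"`. Whether spikes were originally regressed
before or after filtering is unstated; both orders are supported and
neither is asserted as the original. With regression last, an OLS identity
guarantees spike-flagged samples are exactly annihilated.

## Network construction

Per subject, the 21×21 Pearson matrix is thresholded at the significance
level α = 0.05 with Bonferroni correction over the 210 node pairs. The
per-edge p-value uses the exact Student-t null of the Pearson coefficient,
t = r·√(df/(1−r²)) with df = T − 2: at T = 175 the critical |r| is 0.274.
We chose the t-transform over the Fisher-z normal approximation because it
is exact at this series length and bit-reproducible; which of the two the
original toolbox used is unknowable from the text. The nominal df ignores
the autocorrelation the band-pass induces — the conventional toolbox
behavior — which makes the threshold anticonservative in effective-df
terms; this is a documented caveat, not a correctness bug, and permutation
inference downstream is unaffected by it.

Two views are built from the surviving edges: a binary adjacency and a
weighted matrix holding the surviving correlations. One textual conflict
had to be resolved: the construction section restricts analysis to positive
correlations while the network-analysis section binarizes on absolute
values. We follow the explicit restriction — only positive correlations are
eligible by default — and expose `edge_sign = "abs"` as the alternative.

## Graph metrics and null normalization

Binary definitions are the standard ones: clustering coefficient
c_i = 2t_i/(k_i(k_i−1)) (0 when k_i < 2), characteristic path length as the
mean shortest-path distance, global efficiency as the mean inverse
distance, local efficiency as the mean global efficiency of each node's
neighbor-induced subgraph, and nodal degree as the number of incident
edges. Weighted generalizations: Onnela's geometric-mean clustering on
weights normalized by the graph maximum, edge length 1/weight for
distances, and nodal strength as the sum of incident weights. With all
weights equal to 1 the weighted metrics reduce exactly to the binary ones,
which the test suite asserts.

Sparse subject graphs can be disconnected. Unreachable pairs are *excluded*
from the path-length average (finite-pairs mean) rather than imputed with a
pseudo-distance, and their count is reported alongside (`n_unreachable`),
making the choice auditable per subject; whether the original toolbox used
finite-pairs averaging or largest-component restriction is unstated. This
choice affects cross-subject comparability when connectedness differs
between subjects, which is why the diagnostic is part of the output.

Gamma, Lambda and Sigma = Gamma/Lambda normalize clustering and path
length by their means over 100 matched random networks (the conventional
ensemble size) generated by Maslov–Sneppen double-edge swaps — 10 attempted
swaps per edge, self-loops and multi-edges rejected — which preserve the
degree sequence exactly (asserted per null). For weighted graphs the
topology is rewired and the multiset of observed weights is randomly
reassigned to the new edges. Graphs admitting no valid swap (e.g. complete
graphs) yield an ensemble of copies with a warning flag. All metrics are
verified against brute-force implementations (exhaustive triangle counts,
Floyd–Warshall distances, explicit subgraph construction) to 1e-12 on
randomized small graphs.

## NBS inference

`nbs()` tests for a connected component of altered edges. For each of the
210 edges, values are residualized across subjects against an intercept
plus covariates (age, sex, mean FD by default), and a pooled-variance
two-sample t is computed on the residuals with the sign convention control
minus patient — an edge *increased* in patients carries a *negative* t. The
edge p-value uses df = n − 2 per the plain two-sample-on-residuals
contract; the handful of degrees of freedom absorbed by the nuisance fit is
knowingly ignored, which permutation inference renders harmless because the
threshold is applied identically to observed and permuted statistics.

Edges with p < 0.01 (strict inequality) form the suprathreshold graph; its
connected components are scored by extent (edge count — the default,
matching the way such components are reported) or intensity (sum of |t|).
The null distribution of the maximal component statistic comes from
permuting group labels over the covariate-residualized data (a
Freedman–Lane-style scheme; the original only states that covariates were
"regressed out"). Monte-Carlo p-values use the add-one formula
(1 + #{null ≥ observed})/(1 + B), bounded below by 1/(B+1); when the number
of distinct label arrangements is within the permutation budget the
procedure switches to exhaustive enumeration and reports the exact
proportion. NBS operates on the full unthresholded r-matrix (the
conventional choice; the subject-level Bonferroni threshold exists for the
graph metrics, not for NBS), with a Fisher-z flag for variance-stabilized
contrasts.

The permutation loop is vectorized: all B permutation t-matrices are
computed with a handful of crossproducts, and component extraction uses a
union-find on the (typically few) suprathreshold edges, so 1,000
permutations on a 38-subject cohort take well under a second.

## Group statistics

Global metrics and nodal degree are compared by residualizing against
age, sex and mean FD and applying a pooled-variance two-sample t on the
residuals (Welch available as a flag); with no covariates this reduces
exactly to the plain pooled t-test. Nodal-degree p-values are
Benjamini–Hochberg corrected across the 21 nodes, with binary and weighted
families corrected separately because the two graph modes are reported
separately. Both raw and adjusted p-values are emitted, since reported
nodal results are ambiguous about which is printed. Demographics use the
rank-sum z with tie correction (the z statistic itself is part of the
output contract, hence implemented directly and cross-checked against
`wilcox.test`), Fisher's exact test for sex tables, and Spearman
correlations (patients only) between network indicators and onset age /
illness duration.

## Simulation scale and verification design

The test suite establishes, at desk scale:

* exact agreement of every graph metric with brute-force oracles on 200
  random graphs of ≤ 8 nodes (tolerance 1e-12), and of the NBS Monte-Carlo
  p with exhaustive enumeration on a 3-vs-3 toy cohort;
* the small-world signature — group-mean Gamma > 1 with Lambda in
  [0.8, 1.3] for binary and weighted graphs — on a default synthetic
  cohort (38 subjects, 100 nulls per subject);
* empirical NBS family-wise error within two binomial standard errors of
  the nominal 0.05, over 200 null cohorts with 1,000 permutations each
  (1,000 rather than 5,000 keeps the estimate cheap without changing its
  expectation);
* recovery of a planted circuit (+0.25 on L-DN–L-Th, −0.20 on five edges
  of the decreased pattern chosen so the circuit is one connected
  component) as a single FWER-significant component containing all six
  planted edges, in at least 80% of 50 cohorts.

The recovery check runs NBS on connectivity computed from the generator's
output series; it is a test of the inference machinery recovering known
population structure. When the band-pass conditioning stage is inserted
before correlation, the 0.01–0.08 Hz band retains roughly 30 effective
samples of the 175, edge estimates become correspondingly noisier and
co-fluctuate across edges (the block structure acts as a common factor),
and measured recovery power at these effect sizes drops to roughly
0.5–0.7. This is a real property of band-limited correlation estimates at
this series length, not an implementation artifact; FWER control is
unaffected (it rests only on exchangeability), but users planning studies
at these sample sizes should expect component-level power well below
edge-level power whenever the permutation null develops heavy max-component
tails.

## Known limitations

* Effective degrees of freedom: both the edge threshold (df = T − 2) and
  the autocorrelation left by filtering are handled the way conventional
  toolboxes handle them, i.e. ignored; subject-level edge significance is
  therefore nominal, not exact.
* The generator's Gaussian AR(1) signals lack the 1/f structure of real
  BOLD; absolute levels of Gamma/Lambda on real data will differ from the
  synthetic values even though the qualitative signature is robust.
* Weighted-graph path lengths depend on the 1/weight distance mapping;
  alternatives (e.g. −log w) would change Lp and Eg scales.
* The pipeline starts from motion parameters and (nominally normalized)
  ROI or voxel signals; slice timing, realignment and spatial
  normalization are out of scope.
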