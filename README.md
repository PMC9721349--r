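# motornet

Graph-theoretic analysis of the resting-state motor execution network.

Movement disorders — as in Wilson's disease, where copper accumulation
damages the basal ganglia and cerebellum — motivate asking whether the
*topology* of the brain's motor execution circuitry differs between
patients and controls. motornet implements the complete analysis for a
21-node motor network (cerebellar, basal-ganglia, thalamic and
motor-cortical spherical ROIs at fixed MNI coordinates) from
resting-state fMRI ROI time series:

* **Synthetic cohorts** — a generator producing two-group cohorts
  (23 patients + 15 controls, 175 volumes at TR = 2 s by default) of
  Gaussian AR(1) ROI signals with a block-structured correlation target,
  planted group effects on chosen edges, bounded random-walk head-motion
  traces, and demographics matched to the study population. Every
  quantitative claim in the package is verified against this generator.
* **Signal conditioning** — framewise displacement (FD), Friston-24 motion
  expansion, nuisance + FD-spike regression, and zero-phase 0.01–0.08 Hz
  band-pass filtering.
* **Network construction** — per-subject 21×21 Pearson matrices,
  thresholded by edge-level significance (P < 0.05, Bonferroni over 210
  pairs, exact t-transform null at df = T−2), restricted to positive
  correlations; binary and weighted graph views.
* **Graph metrics** — clustering coefficient Cp, characteristic path
  length Lp, global/local efficiency Eg/Eloc, nodal degree/strength, and
  the small-world coefficients Gamma = Cp/⟨Cp_rand⟩,
  Lambda = Lp/⟨Lp_rand⟩, Sigma = Gamma/Lambda against 100
  degree-preserving Maslov–Sneppen rewired null networks per subject.
* **NBS inference** — covariate-adjusted edge-wise two-sample contrasts,
  primary thresholding (P < 0.01), connected-component extraction, and
  max-component permutation FWER p-values (vectorized; exact enumeration
  on small designs).
* **Group statistics** — covariate-adjusted t-tests with BH-FDR across
  nodes, Wilcoxon rank-sum z, Fisher's exact test, Spearman clinical
  correlations.

Everything is tidyverse-shaped: cohorts are tibbles with list-columns,
results are tidy tibbles, fitted NBS objects support `tidy()`, `glance()`
and `autoplot()`.

## Worked example

Simulate the default cohort (which plants a +0.25 correlation increase on
left dentate nucleus ↔ left thalamus and −0.20 on nine cortical/cerebellar
edges in patients), condition it, build thresholded graphs, and compute
small-world metrics:

```r
library(motornet)
library(dplyr)

cohort <- cohort_spec() |>            # 23 patients + 15 controls, T = 175
  simulate_cohort() |>
  condition_cohort() |>               # FD, Friston-24 + spike regression, band-pass
  cohort_connectivity()               # Bonferroni-thresholded positive edges

metrics <- cohort_graph_metrics(cohort, mode = "binary", n_nulls = 100,
                                seed = 1)
metrics |>
  group_by(group) |>
  summarise(across(c(cp, lp, gamma, lambda, sigma, eg, eloc), mean))
#> # A tibble: 2 × 8
#>   group      cp    lp gamma lambda sigma    eg  eloc
#>   <fct>   <dbl> <dbl> <dbl>  <dbl> <dbl> <dbl> <dbl>
#> 1 patient 0.773  1.82  1.70   1.11  1.57 0.630 0.854
#> 2 control 0.792  1.72  1.64   1.09  1.52 0.674 0.877
```

Both groups show the small-world signature: clustering well above the
degree-matched random ensembles (Gamma ≈ 1.7) at essentially random path
length (Lambda ≈ 1.1), hence Sigma > 1. Patients and controls barely
differ globally — the planted effects are edge-level, which is what the
network-based statistic detects. On connectivity computed directly from
the generator's output series (before band-pass conditioning, which at
T = 175 roughly halves the effective sample and with it edge-level power —
see the vignette):

```r
raw <- cohort_spec() |> simulate_cohort() |> cohort_connectivity()
raw$mean_fd <- purrr::map_dbl(raw$motion, ~compute_fd(.x)$mean_fd)
fit <- nbs(raw, covariates = c("age", "sex", "mean_fd"),
           primary_alpha = 0.01, n_perm = 5000, seed = 1)
fit
#> <nbs_result> primary p < 0.01, 5000 permutations, statistic = extent
#>   2 component(s), 1 significant at FWER 0.05
#>   largest: 9 edges / 9 nodes, corrected p = 0.0186
tidy(fit)$edges[[1]]
#> # A tibble: 9 × 3
#>   roi_i roi_j     t
#>   <chr> <chr> <dbl>
#> 1 L-SMA L-M1   7.59
#> 2 L-SMA R-M1   7.55
#> 3 L-SMA L-PMd  7.49
#> 4 R-SMA L-PMd  7.14
#> 5 R-SMA L-SCb  7.29
#> 6 R-M1  L-SCb  9.08
#> 7 R-M1  R-SCb  6.81
#> 8 L-DN  L-Th  -8.67
#> 9 L-M1  L-Th   6.44
```

The significant 9-edge component is the planted
cerebello-thalamo-cortical circuit: the dentate–thalamus edge carries a
negative t (connectivity *increased* in patients; the sign convention is
control minus patient) and the cortical/cerebellar edges positive t
(decreased in patients). On the fully conditioned pipeline the same
component is recovered but, at these effect sizes and series length, its
corrected p hovers near the 0.05 boundary (0.069 for the default seed).
Nodal and global group comparisons, FDR correction, and clinical Spearman
correlations are available through `compare_global_metrics()`,
`compare_nodal_degree()` and `correlate_clinical()`, or in one call:

```r
res <- run_full_analysis(cohort_spec(), out_dir = "run1", nbs_n_perm = 5000)
```

which writes a manifest, per-stage TSV/JSON outputs and a human-readable
`report.md` into `run1/`.

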