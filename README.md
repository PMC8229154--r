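# icanets

Group ICA network expression analysis for resting-state fMRI cohorts.

## The problem

In case–control resting-state fMRI studies — the motivating setting is
Parkinson's disease (PD) versus healthy controls — one often wants to go
beyond voxel-wise group maps and ask: *how strongly does each subject
express each intrinsic brain network, and which combinations of networks
track each cognitive domain?* `icanets` implements that full chain as a
reusable, tested R package:

1. **Group spatial ICA.** Per-subject BOLD series (voxels × time, under a
   common mask) are reduced by subject-level PCA, temporally concatenated,
   reduced again to `K` dimensions, and unmixed with the InfoMax algorithm
   (natural gradient, logistic nonlinearity). The model order `K` is
   selected by the minimum description length (MDL) criterion in the
   Wax–Kailath form
   `MDL(k) = −(p−k)·N·log(GM(λ_{k+1..p})/AM(λ_{k+1..p})) + ½k(2p−k+1)log N`.
2. **ICASSO stabilization.** InfoMax is rerun under bootstrap resampling,
   the pooled estimates are clustered by average linkage on `1 − |r|`, and
   each cluster is summarized by its centrotype and the stability index
   `Iq = mean intra-cluster similarity − mean extra-cluster similarity`.
3. **Component QC.** Maps are z-scored; components are dropped if their
   `Iq` falls below 0.8, if a user label marks them as artifact, or if
   fewer than 50 voxels reach `|z| ≥ 1.0`; low-frequency dominance of the
   component time courses (fraction of periodogram power below 0.1 Hz) is
   reported.
4. **Dual regression.** Subject-specific time courses (stage 1) and
   spatial maps (stage 2) are back-reconstructed from the group maps by
   two least-squares stages.
5. **SSM expression scores.** Each subject's expression of each network is
   a doubly-centered projection of their map onto the group topography
   (scaled-subprofile-model style), z-scored against the control group, so
   patient scores read as deviations from normal expression.
6. **Domain-related networks.** Each cognitive domain score (MoCA domains
   in the motivating design) is regressed on the network scores by
   bidirectional stepwise selection (enter p ≤ 0.05, remove p ≥ 0.10);
   each fitted model composes a *domain-related network map* as the
   coefficient-weighted sum of the component z-maps, and components
   recurring across ≥ 2 domain models are flagged as hubs.

A synthetic cohort generator (`simulate_cohort()`) plants known spatial
sources, band-limited time courses, subject loadings, and sparse linear
domain-score models, so every stage above has a ground-truth recovery
test. The default configuration emulates the motivating study design:
40 PD + 15 controls, TR 2 s, 150 volumes, MoCA administered to patients
only, levodopa-equivalent dose computed as
`levodopa/carbidopa×1 + entacapone×0.35 + pramipexole×100 + ropinirole×20 +
rotigotine×10 + selegiline×10 + amantadine×1`.

## Worked example

```r
library(icanets)

co  <- simulate_cohort(cohort_config(n_pd = 16, n_ctr = 6,
                                     grid = c(16, 16, 8), n_components = 4,
                                     n_timepoints = 80), seed = 7)
res <- run_network_pipeline(co$bold, co$metadata, K = 4, n_runs = 8, seed = 7)

round(res$icasso$iq, 3)
#>   IC1   IC2   IC3   IC4
#> 0.987 0.985 0.983 0.981

res$models$attention
#> <domain_model> attention: R^2 = 0.72 (p = 0.000249), n = 16
#>  ic_id      B  ci_lo  ci_hi        p
#>    IC4  0.685  0.392  0.978 0.000220
#>    IC1 -0.702 -1.050 -0.354 0.000779

m <- match_components(res$components$z_maps, co$truth$sources$maps)
round(m$correlations, 3)
#> [1] 0.999 1.000 0.999 1.000
```

All four ICASSO clusters are highly stable (`Iq ≈ 0.98`), the recovered
component maps correlate ≥ 0.999 with the planted sources, and the
stepwise model for the attention-like domain selects exactly the two
components that carry planted signal in this cohort (the planted support,
components 1 and 3, maps to IC4 and IC1 after matching), with R² = 0.72
against a generating R² of 0.6 at n = 16.

The `analysis/` directory holds numbered drivers that run the same
workflow as a narrative — `01_simulate_cohort.R` through
`05_published_models.R` — writing tables under `results/` and bulky NIfTI
intermediates under `scratch/`. `05_published_models.R` analyses the
packaged reference table (`inst/extdata/domain_models_pd.tsv`) of fitted
domain models from a published 40-patient PD study: six of seven domains
have generated networks (delayed recall has none), and four components —
IC49 (three domains), IC14, IC48, IC54 — act as hubs across domains.

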