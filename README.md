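# morphoshift

Comparative analysis of 3D skull (or any landmark-based) shape evolution on
a time-calibrated phylogeny, centered on the question: is morphological
diversity better explained by an early burst of evolution, or by discrete
shifts between Simpsonian adaptive zones?

The package takes specimen-level 3D landmark/semilandmark configurations, a
phylogeny, and optional discrete ecological characters, and runs the full
chain a morphologist needs:

1. **Landmark completion** — reflected relabeling across the midsagittal
   plane for missing bilateral landmarks, then iterative low-rank PCA
   imputation (`estimate_missing()`), with a simulation check that
   including imputed specimens beats excluding them
   (`validate_missing_inclusion()`).
2. **Superimposition** — generalized Procrustes analysis with optional
   Procrustes-distance sliding of semilandmarks (`gpa_align()`), species
   consensus shapes with bilateral symmetrization (`species_consensus()`).
3. **Morphospace** — standard and phylogenetically corrected PCA
   (`pca()`, `ppca()`; the latter eigendecomposes the evolutionary
   covariance R = (X−1a′)′C⁻¹(X−1a′)/(n−1) about the GLS root estimate a),
   parallel-analysis axis retention (`parallel_analysis()`), and absolute
   shape variation per axis by Procrustes regression (`axis_variance_r2()`).
4. **Disparity through time** — relative subclade disparity from mean
   pairwise Procrustes distances, the MDI statistic (signed area between
   the observed curve and the median of Brownian-motion simulations), and
   its one-sided simulation p-value (`dtt_curve()`, `mdi_test()`).
5. **Tanglegram** — UPGMA morphology dendrogram vs. phylogeny, co-rotated
   to minimize tip mismatch; mean tip displacement with a BM null
   (`upgma()`, `untangle()`, `displacement_null_test()`).
6. **Adaptive-zone shifts** — multi-peak Ornstein–Uhlenbeck model
   dY_j = α_j(θ_j(t) − Y_j)dt + σ_j dB_t per retained axis with a shared
   set of shift branches, searched by a group lasso over branch optima,
   selected by phylogenetic BIC, with parametric-bootstrap support
   (`detect_shifts()`, `bootstrap_support()`).
7. **Model comparison** — fully multivariate BM, single-optimum OU, early
   burst, and multi-peak OU on regime paintings (from shift configurations
   or stochastic character maps of diet/echolocation-type characters),
   ranked by AICc with n = tips × traits (`fit_bm()`, `fit_ou1()`,
   `fit_eb()`, `fit_oum()`, `simmap()`, `compare_models()`).

A synthetic-data generator (`simulate_tree()`, `simulate_bm_traits()`,
`simulate_shifted_ou_traits()`, `simulate_landmark_dataset()`,
`simulate_dataset()`) produces trees, landmark datasets and shifted-OU
trait matrices with known ground truth, so the entire pipeline is testable
without specimen data. `run_pipeline()` orchestrates everything from one
config and writes a report bundle (CSV/JSON + manifest).

See `vignettes/morphoshift-methods.Rmd` for the models, parameter
conventions, numerical choices, and limitations.

## Worked example

Simulate a 48-species study with two planted adaptive-zone shifts (4%
landmark missingness) and run the full pipeline:

```r
library(morphoshift)
sim <- simulate_dataset(n_tips = 48, n_landmarks = 16, p = 3,
                        n_shifts = 2, shift_size = 8,
                        missing_fraction = 0.04, seed = 7)
res <- run_pipeline(pipeline_config(sim$landmarks, sim$tree,
                                    out_dir = tempfile(), n_sim = 200,
                                    seed = 7))
res
#> morphoshift pipeline result
#>   48 species, 16 landmarks
#>   MDI = -0.01937 (p = 0.245); TD = 4.75 (p = 0.665)
#>   ppca shifts: 7
#>   model ranking:  shift_model < OU1 < BM < EB
res$models[, c("model", "regimes", "k", "logL", "AICc", "dAICc")]
#>         model regimes  k      logL      AICc    dAICc
#> 1 shift_model       8 33 -238.7250  563.8499   0.0000
#> 2         OU1       1 15 -503.9547 1041.6594 477.8094
#> 3          BM       1  9 -524.7043 1068.7518 504.9019
#> 4          EB       1 10 -524.7043 1071.0627 507.2127
sapply(sim$true_shifts, `[[`, "edge")
#> [1] 22 65
res$shifts$ppca$edges
#> [1] 22 24 28 32 63 65 68
```

What the numbers mean: MDI near 0 with p = 0.245 says subclade disparity
tracks the Brownian expectation here (the planted shifts are mean
displacements, which barely move the disparity profile at this size); tip
displacement 4.75 against a null range 0.7–10.4 (p = 0.665) says
morphology-phylogeny concordance is unexceptional; both planted shift
branches (22 and 65) are recovered by the shift search — along with
descendant branches absorbing the abrupt displacement, a known behavior
when the generating jump is instantaneous rather than an OU optimum shift —
and the multi-peak OU model beats BM by ~505 AICc units, the signature of
adaptive-zone structure that BM/OU1/EB cannot express.

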