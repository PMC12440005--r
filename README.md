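# spatfuse

Sparse spatially varying coefficient regression for spatial transcriptomics.

## What problem this solves

Spatial assays (Visium spots, Xenium cells) measure a response feature and
many candidate predictors at every tissue location, and the scientifically
interesting question is often not *where* a gene is high but *how the
relationship* between features changes across the tissue: which
transcription factors explain a target gene in which cortical layer, how
much of a spot's expression each deconvolved cell type contributes, whether
gene–gene coupling holds only inside particular niches. Classical
regression assumes one global coefficient vector; `spatfuse` instead
estimates a **coefficient field** — one coefficient per predictor per
location:

```
y(s_i) = Σ_k x_k(s_i) β_k(s_i) + ε(s_i)
```

With one observation per location this is under-determined, so the field is
estimated by minimizing a convex composite objective

```
(1/n) Σ_i (y(s_i) − Σ_k x_k(s_i) β_k(s_i))²
  + λ1 Σ_k ‖H β_k‖₁        graph fused lasso — spatial coherence
  + λ2 Σ_k ‖β_k‖₁          element lasso — per-spot sparsity
  + λ3 Σ_k √n ‖β_k‖₂       group lasso — global predictor removal
```

where `H` is the incidence operator of a k-nearest-neighbor graph or
Euclidean minimum spanning tree over the locations. The result is sparse,
piecewise-smooth coefficient maps that respect sharp histological
boundaries, with the set of active predictors allowed to change across the
tissue.

Around the estimator the package provides the full working pipeline:
spatially blocked cross-validation for the three penalties
(`tune_hyperparameters`), cluster-wise post-hoc refitting with joint FDR
control (`refit_and_test`), cell-type-attributed expression under
non-negativity and presence constraints (`attribute_celltypes`), Moran's I
permutation tests for spatially variable gene/cell-type pairs
(`detect_svgs`), cross-cell-type gene covariation tensors
(`covariation_test`, `aggregate_tensors`), local-composition/niche context
features (`build_context_features`), and a synthetic-data benchmark scored
by Adjusted Rand Index (`simulate_dataset`, `recovery_pipeline`).

## Worked example

Simulate 300 spots with 20 predictors of which 3 are active, their
coefficients constant within each of 2 spatial clusters; fit, threshold,
test, and score recovery:

```r
library(spatfuse)

sim   <- simulate_dataset(n = 300, p = 20, n_active = 3, n_clusters = 2,
                          seed = 1)
ds    <- sim$dataset
graph <- build_spatial_graph(ds$coords)
graph
#> spatial_graph (knn): 300 nodes, 1227 edges

fit <- fit_svc(ds, graph, penalty_config(1e-3, 1e-4, 1e-5),
               optimizer_config(max_iter = 3000))
fit
#> svc_fit: 300 spots x 20 predictors; objective 0.350655 after 3000
#> iterations (hit max_iter)

field  <- hard_threshold(fit$field)
labels <- cluster_spots(ds$coords, default_posthoc_clusters(300), seed = 1)
sel    <- refit_and_test(ds, field, labels)
sel
#> svc_selection: 776 selected entries across 10 clusters (alpha = 0.05)

recovery_benchmark(sim$truth, field, sel, seed = 1)
#> recovery_report: ARI 0.934, precision 1.000, recall 1.000, active-RMSE 0.084
```

The objective 0.351 sits near the noise floor (noise SD 0.5 gives an
irreducible data term of 0.25). ARI 0.934 says the spatial clustering of
the fitted coefficient rows almost exactly matches the true two-cluster
partition; precision and recall 1.0 say post-hoc selection kept exactly the
three truly active predictors (columns 3, 5 and 12); RMSE 0.084 is the
error on truly active coefficients whose magnitudes are 1–2. In practice
the penalties come from `tune_hyperparameters()` rather than being set by
hand — see `recovery_pipeline()` for the complete
simulate → tune → fit → test loop.

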