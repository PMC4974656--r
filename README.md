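# saltpepper

Quantifying the spatial organization of visual tuning from two-photon
calcium imaging.

## The problem

Is the arrangement of stimulus preferences in rodent visual cortex truly
*salt-and-pepper* — statistically independent of cortical position — or is
there residual local order?  Answering this requires an analysis chain
that runs from raw fluorescence traces to a population-level spatial
statistic:

1. **Signal extraction.**  Per-ROI neuropil correction by a robust
   (least-absolute-deviations) linear fit; noise estimation by
   `mad(diff(y)) / sqrt(2)`; spike inference by constrained non-negative
   deconvolution under an AR(1) calcium model `c_t = γ c_{t-1} + s_t`
   (γ = 2^(−Δt/τ½), τ½ = 135 ms): minimize Σs subject to `s ≥ 0` and
   `‖y − c − drift‖₂ ≤ σ√T`, with a 10-knot cubic-spline drift.
2. **Tuning estimation.**  Each cell's joint orientation–spatial-frequency
   profile `w(ωx, ωy)` is estimated from responses to a pseudo-random
   Hartley stimulus (4 Hz updates, spatial frequency ≤ 0.15 cpd) via the
   separable linear model
   `y(t) = Σ w(ωx,ωy) v(τ) s(ωx,ωy,t−τ) + b + a·r(t)`,
   fit by alternating least squares with a unit-norm temporal kernel and a
   cross-validated Laplacian smoothness penalty on `w`.  Model quality is
   `r_L = √(1 − SSE_L/SSE_B)` against a stimulus-free baseline; cells with
   `r_L ≥ 0.15` in fields with > 20 such cells are analysed.
3. **Clustering statistics.**  Tuning similarity of a cell pair is the
   Pearson correlation of their kernels.  Similarity is binned against
   cortical distance (rank-sum tests against the ~200 µm bin), fitted with
   `c + A·exp(−d/λ)` (bootstrap CI on the length constant λ), compared
   near (< 50 µm) versus far (> 150 µm) in preferred orientation and
   spatial frequency, split by cortical depth (columnar analysis), and
   re-run under three robustness filters (trace kurtosis ≥ 15, peak SF
   > 0.025 cpd, largest 80% of ROIs).

Because raw recordings of this kind are rarely public, the package also
contains a full generative model of the experiment
(`simulate_dataset()`) — clustered or salt-and-pepper preference maps,
thresholded Poisson spiking, AR(1) calcium, neuropil contamination,
drift, and interneuron-like contaminant traces — so every stage has a
parameter-recovery test.

## Worked example

Simulate a clustered cortical sheet at the default study conditions
(50 cells in a 250 µm field, 20-minute Hartley session, 15.5 Hz imaging),
run the full pipeline, and look at the clustering:

```r
library(saltpepper)

cfg <- default_config()
cfg$seed <- 1
run <- run_pipeline(cfg)
run
#> <run_report> 50 cells, 43 significant; field accepted
#>   lambda = 25.3 um (95% CI 17.6-37.2), first-bin p = 0.0021

glance(run$clustering$decay)
#> # A tibble: 1 × 8
#>   length_constant_um ci_low ci_high amplitude asymptote identifiable n_boot     rss
#>                <dbl>  <dbl>   <dbl>     <dbl>     <dbl> <lgl>         <dbl>   <dbl>
#> 1               25.3   17.6    37.2     0.601     0.121 TRUE            200 0.00948
```

43 of 50 cells pass the `r_L ≥ 0.15` selection, so the field is accepted.
Mean tuning similarity in the nearest distance bin (< 30 µm) exceeds the
~200 µm reference bin (rank-sum p ≈ 0.002), and the similarity decay has
a fitted length constant of about 25 µm with a bootstrap CI of 18-37 µm.
The default sheet is generated with a 40 µm similarity length scale;
single-field estimates scatter widely around that truth because one
250 µm field realizes only a handful of independent map patches (the
methods vignette quantifies this), which is why the acceptance script
also reports the length constant of pairs pooled across replicate
sheets.  `autoplot(run$clustering$decay)`
draws the binned curve with the exponential overlaid;
`plot_kernel(run$fits$W[, 1], run$dataset$design)` shows one cell's
estimated kernel on the full Fourier plane.

A salt-and-pepper control (`cfg$sheet$map_length_um <- 0`) shows no
significant bins and an unidentifiable decay.

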