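---
title: "Methods: quantifying spatial clustering of visual tuning from calcium imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying spatial clustering of visual tuning from calcium imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(saltpepper)
```

## The scientific question

In carnivores and primates, neighbouring neurons in primary visual cortex
prefer similar stimuli, forming smooth feature maps.  In rodents the
arrangement has long been described as *salt-and-pepper*: preferences
statistically independent of cortical position.  This package implements a
complete analysis pipeline for testing that hypothesis with two-photon
calcium imaging data: it estimates each cell's joint orientation and
spatial-frequency tuning from responses to a rapid Hartley-subspace
stimulus, and then asks whether the similarity of tuning between two cells
decays with the cortical distance between them — in the imaging plane and
across depth.

Because raw recordings of this kind are rarely shared, the package pairs
the analysis chain with a generative model of the same experiment
(`simulate_dataset()`), so that every stage has a parameter-recovery test
against known ground truth.

## The stimulus and the response model

The stimulus is a pseudo-random sequence of flashed Hartley basis images
`cas(2*pi*(kx*x + ky*y)/n)` (`cas(z) = cos z + sin z`), updated 4 times per
second, with integer Fourier indices `(kx, ky)` capped at 0.15 cycles per
degree on a 60 x 34 cm screen viewed at 20 cm (112 x 80 degrees of visual
angle).  Each index pair corresponds to one orientation, spatial frequency
and spatial phase; `(kx, ky)` and `(-kx, -ky)` differ only in phase, and the
analysis pools them into one cell of the Fourier grid (`fold_symmetry` in
`build_design()`).  Phase pooling means the estimated profile describes
simple and complex cells alike.

The response of a cell is modelled as separable in the Fourier plane and
in time:

    y(t) = sum_{w, tau} w(kx, ky) * v(tau) * s(kx, ky, t - tau) + b + a r(t) + noise

where `y` is the inferred spike signal, `s` the one-hot stimulus indicator
realized on the imaging clock, `w` the spatial (Fourier-plane) kernel, `v`
a temporal kernel constrained to unit norm, `b` a rest offset and `a` an
additive offset active while the animal runs (`r(t)` is the 0/1 locomotion
indicator).

### Conventions chosen where the experiment leaves them open

* **Orientation convention.**  Orientation of the grating is perpendicular
  to the wave vector: `(atan2(ky/height_deg, kx/width_deg) + 90) mod 180`,
  so 0 degrees is a horizontal grating.  Any fixed convention works; this
  one is used everywhere (generator, fits, tests).
* **Fourier grid.**  Integer `(kx, ky)` with spatial frequency at most
  0.15 cpd, DC excluded (a constant screen carries no tuning information).
  The folded grid has 320 cells for the default screen.
* **Stimulus-to-frame alignment.**  Each imaging frame (15.5 Hz) is
  assigned the condition on screen at the frame's mid-time.  With exact
  synthetic timestamps this is lossless; for real data it reproduces
  TTL-based alignment to within half a frame.

## Signal extraction

Starting from per-ROI raw and neuropil fluorescence:

1. **Neuropil correction** (`neuropil_correct()`).  The raw trace is
   `raw - (alpha + beta * neuropil)` with `(alpha, beta)` minimizing the
   sum of absolute residuals; least absolute deviations ignore the sparse
   positive transients, so `beta` reflects the contamination rather than
   the signal.  `beta` is clipped to `[0, 2]`.  The estimator is exact:
   for fixed `beta` the optimal `alpha` is the residual median, and the
   profiled objective is convex in `beta`, minimized by a 1-D search.
2. **Noise estimate** (`estimate_noise()`).  `mad(diff(trace))/sqrt(2)`:
   differencing suppresses the slow calcium component, the MAD (with its
   Gaussian-consistency constant 1.4826, already inside R's `mad()`)
   ignores transient onsets, and `sqrt(2)` undoes the variance doubling of
   differencing.  The scale matters: the deconvolution constraint below
   compares the residual norm to `sigma * sqrt(T)`, which is only
   meaningful if `sigma` estimates a standard deviation.
3. **Constrained non-negative deconvolution** (`deconvolve()`).  Calcium
   follows an AR(1) model `c(t) = gamma c(t-1) + s(t)` with
   `gamma = 2^(-dt/tau_half)`; the default `tau_half = 135` ms gives
   `gamma = 0.718` at 15.5 Hz (the trace halves every ~2.09 frames).  The
   spike signal solves

       minimize sum(s)   subject to   s >= 0,
       || trace - c - drift ||_2 <= sigma * sqrt(T)

   with the drift an unconstrained natural cubic spline with 10 interior
   knots.  The program is solved through its Lagrangian: for a fixed
   penalty, the l1-penalized AR(1) subproblem has an exact
   pool-adjacent-violators solution (computed in compiled code in O(T)),
   alternated with the spline regression until joint convergence; an outer
   bisection on the penalty drives the residual onto the noise budget.
   The tests verify the solver against an independent dense quadratic
   programming oracle to 1e-4 relative in the objective.  If even the
   unpenalized fit cannot reach the budget (noise underestimated), the
   minimal-residual solution is returned flagged `feasible = FALSE`.
4. **Cell-type classification** (`trace_kurtosis()`,
   `classify_putative_excitatory()`).  Non-excess kurtosis `m4/m2^2` of
   the corrected fluorescence separates sparse, transient-dominated
   pyramidal traces (kurtosis far above 15) from the dense, tonic traces
   of interneurons (kurtosis near the Gaussian value of 3).  The
   non-excess convention is used because reported interneuron values
   (around 4) sit just above the Gaussian landmark of 3 under it.  The
   kurtosis is computed on the corrected fluorescence, not on inferred
   spikes, since it is the raw trace dynamics that differ between classes.

## Kernel estimation

`fit_kernels()` fits the separable model per cell by alternating least
squares:

* given `v`, the spatial kernel `w` (with `b`, `a`) solves a penalized
  least-squares problem; the penalty is the squared discrete Laplacian of
  `w` on the folded grid with reflecting boundaries — a generic smoothness
  prior on tuning surfaces;
* given `w`, the temporal kernel `v` (with `b`, `a`) solves an ordinary
  least-squares problem.

The unit-norm constraint on `v` is enforced at convergence, with the
scale exchanged into `w` and the sign fixed so the largest-magnitude lag
is positive.  Normalizing inside the loop would rescale the penalty term
between half-steps and void the monotone-descent guarantee of block
coordinate descent; deferring it leaves every half-step an exact
minimization of one common objective.

Initialization is a delta at lag 2 frames for `v` plus one unpenalized
regression for `w`.  Because the stimulus indicators are one-hot, all
normal equations collapse onto precomputed cross-products of lagged
condition indices, so each iteration costs one small linear solve no
matter how long the recording is.  A vanishing ridge (1e-8 of the mean
diagonal) guards the near-collinearity between the kernel mean and the
intercept; it perturbs solutions at the eighth decimal, below every
tolerance used.

The penalty strength is chosen by fivefold cross-validation over
**contiguous time blocks** — random frame folds would leak information
through the temporal autocorrelation of calcium.  Selection follows the
one-standard-error convention (as in penalized-regression practice): the
largest penalty whose summed held-out SSE lies within one between-fold
standard error of the minimum.  For stimulus-independent cells the CV
curve is flat and noisy, and plain argmin would pick essentially at
random among the heavier penalties; the one-SE rule resolves that
towards smoothness, while clean tuned cells (tiny SE) still get the
argmin.  Exact ties likewise go to the larger penalty.  The lag window
(default 8 frames, about half a second) covers the indicator impulse
response at 15.5 Hz.

**Selection.**  Model quality is summarized by
`r_L = sqrt(max(0, 1 - SSE_L / SSE_B))` where `SSE_L` is the pooled
held-out SSE at the selected penalty and `SSE_B` the SSE of the baseline
`y = b + a r(t)`.  The square-root form makes `r_L` comparable to a
Pearson correlation.  Cells with `r_L >= 0.15` count as significantly
tuned; a field enters the clustering analysis only when more than 20
cells pass.

## Clustering statistics

For every within-field cell pair: tuning similarity is the Pearson
correlation of the two kernels; cortical distance is the Euclidean
distance of the cell-body centres projected on the cortical surface;
depth difference is the difference of plane depths.

* `bin_similarity()` bins pairs into seven 30-um bins up to 210 um
  (configurable) and tests each bin against the rightmost one with a
  one-sided rank-sum test.  The rank-sum implementation is exact (via the
  null distribution of the statistic) for pooled samples up to 12 without
  ties, and a tie- and continuity-corrected normal approximation
  otherwise; tests verify the approximation against exhaustive
  enumeration.
* `fit_exponential_decay()` fits `c + A exp(-d/lambda)` to the bin means
  (the quantity usually plotted), multi-started over initial length
  constants {10, 20, 40, 80, 160} um.  The 95% CI of `lambda` comes from
  a percentile bootstrap that resamples *pairs* and rebins, propagating
  pair-level noise through the binning.  A flat curve makes `lambda`
  unidentifiable: the fit is flagged and its CI spans the start grid
  rather than pretending precision.  The default 200 bootstrap replicates
  put the Monte-Carlo error of the CI endpoints well below the bin width.
* `near_far_preference_test()` compares preference differences (in
  orientation, or log spatial frequency) for pairs closer than 50 um
  against pairs farther than 150 um, one-sided in the direction "near
  pairs are more alike".  Test directions are always explicit arguments,
  never inferred from the data.
* `per_field_correlation()` is the per-experiment Pearson correlation of
  similarity against distance with a one-sided (negative) p-value.  Pairs
  sharing a cell are dependent, which makes the naive t p-value
  anti-conservative (measured false-positive rate ~11% at a nominal 5% on
  salt-and-pepper sheets); the p-value therefore comes from a
  Mantel-style permutation null that relabels cells, exactly calibrated
  under independence of tuning and position.  The parametric t p-value
  remains available (`method = "t"`) and is used automatically for bare
  pair lists without cell indices.
* `depth_similarity_analysis()` repeats the binned analysis separately
  for pairs at each depth separation (0/40/80/120 um with the default
  40-um plane spacing), probing columnar organization.
* `robustness_filter()` re-runs the analysis after each control filter:
  kurtosis >= 15 (exclude putative interneurons), peak spatial frequency
  > 0.025 cpd (exclude broadly tuned, low-pass kernels), and removal of
  the smallest 20% of ROIs (exclude likely dendritic fragments).

Pairs never span imaging fields; pooled statistics weight by pair, not by
field (the alternative — equal field weights — changes little at matched
field sizes and is less natural for rank-based tests).

## The synthetic experiment

`simulate_dataset()` generates the full experiment from seed to raw
fluorescence:

* **Preference maps.**  Complex white noise smoothed with an isotropic
  Gaussian of s.d. `map_length_um`; orientation is half the argument of
  the smoothed field, log2 preferred spatial frequency an independent
  smoothed field scaled to mean `log2(0.04)` and s.d. 0.5 octaves —
  typical mouse V1 values.  The default `map_length_um = 30` was
  calibrated once, on ground-truth kernels pooled over replicate sheets,
  so that the similarity-versus-distance curve has an exponential-fit
  length constant of 40 um — the similarity length scale the pipeline is
  designed to resolve.  (The map autocorrelation is Gaussian in shape;
  an exponential fitted over 0-210 um to the resulting similarity decay
  lands well below the map's own 1/e distance, so the calibration is
  empirical rather than analytic.)  `map_length_um = 0` produces a
  salt-and-pepper sheet.  Columnar structure is depth-invariance of the
  shared map; `column_decorrelation` replaces a fraction of each plane's
  preferences with draws from an independent per-plane *clustered* map,
  so depth structure can be removed without touching in-plane clustering.
* **Cells.**  About 50 cells per plane in a 250-um field (realistic
  density for GCaMP-labelled layer 2/3 populations), uniform positions
  with an 8-um soma exclusion, log-normal ROI areas, log-normal stimulus
  gains.
* **Kernels.**  A Gaussian bump in (orientation, log-SF) with s.d. 20
  degrees and 0.7 octaves, plus a shared low-spatial-frequency template
  weighted by `low_sf_bias_weight`; the shared component is what makes
  tuning similarity asymptote above zero at large distances.
* **Spiking.**  Linear-nonlinear-Poisson: the rectified separable drive
  sets the rate; counts are Poisson per frame.  The rectified-linear (not
  exponential) nonlinearity keeps the linear-regression estimand
  proportional to the true kernel.  Each cell's rest offset is its tonic
  rate minus a threshold set at the 92nd percentile of its own linear
  drive (`suprathreshold_frac = 0.08`), so cells fire sparse,
  stimulus-locked transients at 0.05-0.4 Hz — the regime in which the
  kurtosis separation between cell classes exists at all.  A filtered
  Poisson process at a constant rate above ~0.4 Hz cannot reach kurtosis
  15, whatever the noise level; sparse thresholded firing is therefore a
  structural requirement of the generator, not a tuning nicety.
* **Interneurons.**  A configurable fraction of cells instead fire as
  temporally smoothed averages of their 10 nearest pyramidal neighbours
  plus a 3-Hz tonic rate — pooled, dense, low-kurtosis traces.
* **Fluorescence.**  AR(1) calcium with the 135-ms half-decay, a shared
  neuropil trace (slow random process plus mean population calcium) mixed
  into each ROI with weight 0.7, a slow sinusoidal drift, and i.i.d.
  Gaussian noise (s.d. 0.08 per unit spike amplitude).  The measured
  neuropil channel carries small independent noise.

With these defaults, at the 20-minute default session: over 90% of
pyramidal traces have kurtosis above 15 and interneuron traces below 7;
the median correlation between estimated and ground-truth kernels is
about 0.85; and `r_L` straddles the 0.15 selection threshold, so cell
selection is actually exercised.  These defaults were calibrated once
against those stated contracts and are not adjusted per analysis.

### What the generator does *not* emulate

Pixel-level movies, optics, motion artefacts, eye movements, true synaptic
connectivity, non-Poisson firing statistics (bursting beyond rate
thresholding), indicator nonlinearity and saturation, and any real
between-animal variability.  Passing recovery tests on these simulations
shows the *analysis chain* is correct and calibrated under the stated
generative assumptions — not that real cortex satisfies them.  In
particular the length-constant recovery band is wide ([20, 80] um for a
40-um truth) because binning, rectified tuning similarity and bounded
fields all bias an exponential fit; the same caveats apply, unquantified,
to any experimental estimate.

## Statistical caveats the tests respect

Two properties of pair-based statistics shape how the recovery checks are
phrased:

* **Map-realization variance.**  A 250-um sheet realizes only a handful
  of independent map patches, so the fitted length constant of a single
  sheet scatters widely around the ensemble value even with thousands of
  pairs; the pair bootstrap, which conditions on the realized map,
  cannot (and should not) absorb that variance.  Sheet-level recovery is
  therefore stated about the median across replicate sheets, while the
  bootstrap CI itself is validated on pairs drawn independently around a
  known decay curve, where its assumptions hold and coverage is nominal.
* **Pair dependence.**  Pairs sharing a cell or a map patch are
  correlated, which inflates the dispersion of single-sheet rank-sum
  p-values (a form of pseudo-replication equally present in experimental
  data).  Qualitative contrasts (columnar versus depth-decorrelated
  sheets) are therefore judged on the median p across replicate sheets,
  not on a single draw.

## Numerical choices and degenerate inputs

* Deconvolution declares infeasibility (rather than failing) when the
  noise estimate is too small to explain the residual, and returns the
  minimal-residual solution flagged.
* As the noise budget tends to zero, the deconvolution optimum provably
  shifts mass from spikes into the unconstrained drift spline (the
  spline lowers `sum(s)` by absorbing part of the smooth decay), so
  support-recovery statements are made at a small but realistic noise
  floor rather than at machine precision.
* Constant kernels have undefined similarity; such pairs are dropped with
  a message and counted in an attribute.
* A constant running indicator folds the locomotion offset into the
  intercept.
* Empty distance bins carry `NA` statistics; the rightmost bin's
  self-comparison is defined as p = 1.
* Kernel-peak ties (exactly equal maxima) resolve to the first grid index,
  which is deterministic for a fixed grid ordering.
* All simulation functions take explicit integer seeds and are bitwise
  reproducible; the pipeline derives stage seeds from one master seed.

## Problem sizes used by the test-suite and the acceptance script

End-to-end checks run the generator at its default scale (50 cells per
plane, 20-minute session, 18,600 frames).  Statistical calibrations use
1,000 synthetic salt-and-pepper fields (type-I error of the per-field
test), 10-20 replicate sheets (length-constant recovery and its bootstrap
coverage), 30-40 untuned cells (selection calibration), and five
replicate four-plane sheets per condition for the columnar contrast.
These sizes put the Monte-Carlo error of each checked rate well inside
the asserted bands while keeping a full run in the tens of minutes on one
core.
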