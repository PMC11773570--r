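---
title: "Methods: evaluating compressive sensing for Raman hyperspectral imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evaluating compressive sensing for Raman hyperspectral imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ramancs)
```

## The question the package answers

Spontaneous Raman microscopy is slow: a confocal map of a cell at a few
seconds per pixel takes hours. Compressive acquisition proposes measuring
each spectrum at only a random subset of wavenumber channels and recovering
the rest computationally. Whether that is safe depends not on raw
reconstruction error but on whether the *downstream* chemistry survives:
concentration calibration, segmentation of a cell map, detection of a trace
component, clustering of tissue layers.

`ramancs` implements that evaluation loop end to end on synthetic scenes
with known ground truth: generate a low-rank hyperspectral scene, discard a
controlled fraction of spectral samples, recover the matrix by nuclear-norm
minimization, run the standard Raman preprocessing chain, and score the
final scientific task against the generating truth across sparsity levels
and seeds.

## Model and assumptions

A hyperspectral cube is flattened to an `n_pixels x L` matrix `M` (pixels
row-major; columns are wavenumber channels). The central assumption is
*chemical sparsity*: each spectrum is a mixture of a handful of endmember
spectra, so `M` is approximately low-rank. Random spectral under-sampling
keeps, per pixel, an exact count `round((1 - s) L)` of channels drawn
uniformly (scheme `per_spectrum_exact`; an entrywise Bernoulli scheme is
also provided). Recovery solves

$$\min_X \; \tfrac12 \lVert P_\Omega(X - M) \rVert_F^2 + \lambda \lVert X \rVert_*$$

by FISTA: proximal gradient steps whose proximal operator is singular value
soft-thresholding (`svt()`), Nesterov momentum
`t_{k+1} = (1 + \sqrt{1 + 4 t_k^2})/2`, and a monotone restart — any
momentum step that would increase the objective is replaced by a plain
proximal step, so the reported objective trace never increases. The
unconstrained Lagrangian form (rather than an equality-constrained variant)
is used because it degrades gracefully on noisy observations.

## Tunable parameters

| parameter | default | units / range | why |
|---|---|---|---|
| `sparsity` | study grids | fraction in [0, 1) | fraction of spectral samples discarded |
| `lam` | `"auto"` = `0.01 * sigma_max(P_Omega(M))` | intensity units | scale-equivariant; strong enough to suppress sampling noise, weak enough to keep dominant chemistry |
| `step` | 1 | (0, 1] | the sampling operator is a projection (Lipschitz constant 1) |
| `tol` | 1e-6 | relative objective change | balances accuracy and runtime in sweeps |
| `max_iter` | 500 | iterations | non-convergence returns `converged = FALSE`, never throws |
| `poly_order` / `baseline_iters` | 5 / 20 | degree / iterations | clipped-refit polynomial tracks fluorescence but not peaks |
| `median_window`, `despike_k` | 5, 8 | channels, MAD multiples | removes single-channel spikes; the robust gate spares genuine peaks |
| `sg_window`, `sg_order` | 9, 3 | channels, degree | conventional Savitzky-Golay smoothing |
| `n_components` (PLS) | 2 | latent variables | chemical rank of a two-component mixture |
| `pca_components` | 10 | components | conventional depth for tissue clustering |
| `cv_threshold` | 2 | percent | CV level defining the limit of quantification |

`choose_lambda()` also offers `cross_validate_holdout`: hide 10% of the
observed entries, scan a log grid of fractions of `sigma_max`, and pick the
weight minimizing held-out RMSE. The exact-recovery checks use it; the
sweeps use the fixed fraction for speed and determinism.

## What the generator emulates — and what it does not

Three seeded scene families mirror the package's three studies:

* **Mixture series** (`make_mixture_series()`): water/protein mixtures at
  60–80% water in 2% steps, 10 replicates per level — the physiological
  range of a skin-hydration phantom. Spectra are exact convex mixtures of
  two endmembers plus an optional smooth baseline of fixed shape with a
  random per-spectrum amplitude (adding exactly one to the chemical rank)
  and i.i.d. Gaussian noise (`noise_sd = 0.01` on unit-amplitude peaks —
  a bulk droplet measured for seconds is a high-SNR target).
* **Cell scene** (`make_cell_scene()`): a 32 x 36 grid, elliptical cell on
  background, drug confined to contiguous blobs grown from random seeds
  (compact accumulations, not scattered single pixels) covering 3% of
  pixels; only the drug endmember carries the 1168 cm^-1 marker. Defaults
  `noise_sd = 0.04` and `baseline_amplitude = 1` reflect the modest SNR and
  visible autofluorescence of a ~10 s fixed-cell acquisition; a cleaner
  scene would let completion pin down individual drug pixels from their
  directly observed marker channels, which no realistic cell measurement
  supports.
* **Tissue scene** (`make_tissue_scene()`): three wavy horizontal layers
  (background / gray-matter-like / white-matter-like). Each pixel adds a
  random degree-3 polynomial baseline scaled by `baseline_amplitude`
  (default 10, i.e. ten times the peak scale — raw autofluorescence
  dominates, as fresh tissue under 532 nm excitation does) plus additive
  and shot-like noise (standard deviation proportional to the square root
  of the total noiseless intensity, so baseline-laden spectra are noisier).
  The default grid is 16 x 36; the full-scale 65 x 145 study geometry is a
  constructor argument away.

Endmember peak positions sit at familiar Raman bands (1003 cm^-1 ring
breathing, 1440–1450 cm^-1 CH2, 1657 cm^-1 amide I, 1640 cm^-1 water
bending) with Lorentzian lineshape by default, but they are generic
stand-ins: no attempt is made to match measured spectra of any particular
protein, drug, or tissue, and no instrument optics, confocal point spread,
or wavenumber-dependent response is simulated. Passing tests therefore show
that the *pipeline logic* behaves as the theory predicts on data satisfying
its assumptions — not that any particular instrument will achieve the same
numbers.

## Numerical choices

* Initialization is `X0 = P_Omega(M)` (zeros at missing entries):
  deterministic and standard.
* The stopping rule is `|F_k - F_{k-1}| / max(1, F_{k-1}) < tol`. On
  small-scale problems where `F` itself is tiny this rule can stop early;
  the exact-recovery tests therefore tighten `tol` rather than rely on the
  sweep default.
* `svt()` uses a full (LAPACK) decomposition; all study matrices have at
  most a few hundred columns, where a truncated solver buys nothing.
* A running median reproduces monotone stretches exactly, so the MAD of
  the despiking deviations can degenerate to zero; the gate then falls back
  to the MAD of the nonzero deviations before treating the spectrum as
  spike-free.
* k-means is plain Lloyd from `n_init = 10` seeded random starts (lowest
  inertia wins); an emptied cluster is re-seeded to the point farthest from
  its assigned centroid; assignment ties break to the lowest cluster index.
* Label alignment searches all permutations (k <= 8 everywhere in the
  package), breaking ties by the lexicographically lowest permutation.
* PCA loading signs are fixed by making each loading's largest-magnitude
  element positive; loading similarity uses absolute cosine, so the
  convention never affects comparisons.
* The LoQ is the smallest tested concentration from which *every* higher
  tested concentration keeps CV below threshold — a single failing lowest
  level moves the LoQ up one step, while a failure at the top makes the
  grid unquantifiable (`NA`; sweep records encode this as `Inf` so medians
  stay ordered).

## Design choices in the study pipelines

* **Completion output convention.** `complete_cube()` defaults to
  `clamp_observed = TRUE` — measured values are trusted and restored
  exactly, which is what a user recovering a dataset wants. The *study*
  pipelines instead run with `clamp_observed = FALSE`: downstream analysis
  consumes the low-rank estimate at every channel, so reconstruction also
  acts as a shrinkage denoiser. This convention is what makes the tissue
  ordering experiment meaningful: with a large fluorescence background the
  top singular value — and hence the automatic `lambda` — is inflated by
  the background, and the small Raman peaks that distinguish tissue classes
  fall below the shrinkage threshold. Masking *processed* spectra first
  avoids exactly that failure mode.
* **Drug detection threshold.** Within a sweep, the intensity threshold at
  1168 cm^-1 is learned once by Otsu's method on the full-sampling
  preprocessed reference and then applied as a fixed threshold to every
  reconstruction. Learning it per reconstruction would let the threshold
  chase the shrinking peak (Otsu always splits *something*), destroying the
  quantity the study measures — whether the reconstructed marker still
  clears the full-data bar.
* **Accuracy metrics.** "Cell accuracy" is pixel agreement of the aligned
  binary cell-vs-background map from k = 2 clustering; "drug accuracy" is
  recall over true drug pixels, so an empty detection of a present class
  scores exactly 0. Cluster labels are aligned to truth by the
  best-agreement permutation before scoring.
* **Level 0 bypass.** Sparsity 0 skips completion entirely, giving an exact
  full-data baseline (and making the two tissue orderings coincide there).
* **PLS depth.** Two latent variables for two-component mixtures; the
  baseline term is nearly orthogonal to the concentration direction and
  the leave-one-concentration-out scheme guards against optimistic depth.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` run the studies at the package's
default scales: 40 x 60 matrices of rank at most 3 for exact recovery,
11 concentration levels x 10 replicates x 300 channels for the mixture
study, the 32 x 36 cell grid, and the 16 x 36 tissue grid, with 10 seeds
per sparsity level in the test suite (the acceptance script uses 5 seeds
for the two imaging studies). These sizes keep a full run at a few minutes
per study on one core while leaving every qualitative contrast the package
asserts clearly resolved; the full 65 x 145 tissue geometry runs through
the identical code path.

## Known limitations

* Nuclear-norm completion with FISTA is the only reconstruction engine; no
  tensor completion, dictionary learning, or learned priors.
* Sampling is random in the spectral domain only — no structured patterns
  (Hadamard, blue-noise) and no spatial under-sampling.
* The generator produces statistically idealized scenes: Gaussian and
  shot-like noise, polynomial fluorescence, exact endmember mixing. Real
  data add wavenumber calibration drift, detector etaloning, and spatially
  correlated backgrounds that none of the tests exercise.
* Recall-style drug accuracy ignores false positives by design (it mirrors
  how trace-detection performance is reported in the evaluated workflow);
  precision can be recovered from `detect_drug_pixels()` output directly.
* `align_labels()` is exhaustive and capped at 8 classes; the package's
  studies use at most 3.
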