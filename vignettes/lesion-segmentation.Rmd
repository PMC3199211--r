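---
title: "Probabilistic pixel labeling for skin lesion segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic pixel labeling for skin lesion segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`lesioncrf` labels every pixel of a dermoscopic image as *lesion* or
*skin*. It implements two supervised models over a shared feature
pipeline: an independent per-pixel (PP) maximum a-posteriori classifier,
and a grid-structured conditional random field (CRF) that couples
neighboring pixels and is trained by maximum likelihood with
saddle-point-approximated gradients. This vignette is the package's own
account of the science: the models and their assumptions, the parameters
that matter, what the synthetic data generator does and does not
emulate, and the numerical choices behind the implementation.

```{r setup, eval = FALSE}
library(lesioncrf)
```

## The feature pipeline

Images are converted from sRGB to CIE L\*a\*b\* (D65 white point,
standard sRGB transfer curve — the de facto interpretation for
uncalibrated consumer imagery, which dermoscopy atlas photographs are).
Before filtering, the mean of the L\* channel is subtracted
(`normalize_lstar()`): a global camera-exposure difference shifts L\* by
a constant, so mean-subtraction aligns images acquired with different
equipment. The a\* and b\* channels are untouched.

Each channel is then filtered with a Gaussian and a
Laplacian-of-Gaussian at scales $\sigma = (1.25, 2.5, 5, 10, 20)$
pixels, giving $2 \times 5 \times 3 = 30$ feature channels per pixel:
smoothed color at five scales plus blob/edge responses at five scales.
Kernels are truncated at $4\sigma$ (residual mass below $10^{-4}$) and
applied with reflective boundary padding, which avoids the dark-border
artifacts that zero padding would inject into lesion likelihoods near
the frame. The discrete second-derivative taps are mean-corrected so a
constant image yields an exactly zero LoG response. Scale-normalized LoG
($\sigma^2 \nabla^2 G$) is available via `log_scale_normalized = TRUE`
but off by default. Filtering is implemented as dense separable
convolution matrices; at the image sizes this package targets that
route is exact, fast, and handles kernels wider than the image
transparently.

Pixels are indexed row-major and 1-based throughout; feature-stack rows,
label fields and grid nodes all share this convention.

## The per-pixel model

With binary labels the 30-dimensional features are first projected to
one dimension by linear discriminant analysis: `fit_lda()` solves the
generalized eigenproblem of the between-class scatter $S_b$ against the
within-class scatter $S_w$ (the sum of per-class maximum-likelihood
covariances), keeping the $N_L - 1$ leading eigenvectors of
$S_w^{-1} S_b$. The eigenproblem is solved symmetrically through the
Cholesky factor of $S_w$ rather than by explicit inversion; if $S_w$ is
ill-conditioned (highly correlated channels are common once large-scale
filters act on small images) a shrinkage ridge
$10^{-6}\,\mathrm{tr}(S_w)/N_C$ is added, with a warning.

In the projected space each class gets a Gaussian
$P(xQ \mid y = l_j) = N(\mu_j^Q, \Sigma_j^Q)$ fitted by pooled
maximum likelihood (an `unbiased` flag switches the denominator), and
the label prior is the pooled pixel fraction per class across all
training images, without per-image reweighting. Prediction is the
per-pixel argmax of density times prior; the *normalized likelihood*

$$\mathcal{L}_{i,j} =
  \frac{P(x_i^Q \mid y_i = l_j)}{\sum_k P(x_i^Q \mid y_i = l_k)}$$

is exposed as `likelihood_map()`, both for threshold sweeps
(`threshold_labeling()`, ROC analysis) and as the CRF's node feature.
All densities are evaluated in log space and normalized by log-sum-exp,
so simultaneous underflow cannot produce `NaN` rows. Argmax ties break
toward the lowest label index, deterministically.

## The conditional random field

The CRF places the pixels on a 4-connected grid $\mathcal{G} =
(\mathcal{V}, \mathcal{E})$ and defines
$P(y \mid x; w) = \exp(-E(y, x; w)) / Z(x, w)$ with the energy a
weighted sum of feature functions, $E = \sum_k w_k \Phi_k(y, x)$. Two
features are used:

* **node** — $\Phi^V(y, x) = \sum_i (1 - \mathcal{L}_{i, y_i})$, the
  complement of the per-pixel likelihood of the assigned label. The
  complement (cost) form makes minimizing the energy favor likely
  labels, and makes the weight vector $w = [1, 0]$ reproduce the
  per-pixel model *exactly* — a fixed point the test suite checks
  pixel-by-pixel. (Summing the likelihood itself into a minimized
  energy would invert that relationship.)
* **edge** — $\Phi^E(y, x) = \sum_{(i,j) \in \mathcal{E}}
  |L^*(x_i) - L^*(x_j)|\,\mathbf{1}[y_i \neq y_j]$: label changes are
  charged where lightness is locally flat and cheap across real
  contrast edges. Differences of L\* are invariant to the global mean,
  so the normalized and raw channels give identical edge costs; the
  implementation uses the normalized one.

Edge costs are nonnegative, incurred only across differing labels, and
carry nonnegative weights, so the binary energy is submodular and the
MAP labeling is found *exactly* as an s-t minimum cut
(`map_inference()`, via `igraph::max_flow()`). Each pixel is a node
between a source (label 1) and sink (label 2); per-node costs are
shifted by their minimum so all capacities are nonnegative, which
changes the energy by a constant and never the argmin. Inference for
more than two labels is deliberately not implemented rather than
approximated. When several labelings tie at the minimum energy any one
may be returned; tests compare energies in that situation. The
exhaustive oracle `brute_force_inference()` (lexicographic
tie-breaking) and the exact `partition_function()` /
`label_probability()` are provided for grids up to 20 pixels and anchor
the correctness tests.

## Maximum-likelihood weight learning

With $P \propto \exp(-E)$, the regularized log-likelihood of training
instances $\{x^m, y^m\}$ is

$$\ell(w) = \sum_m \left[ -E(y^m, x^m; w) - \ln Z(x^m, w) \right]
  - \frac{\lVert w \rVert^2}{2\sigma^2},$$

whose gradient per weight is the model expectation of the feature minus
its ground-truth value, shrunk by $w_k/\sigma^2$:
$\partial\ell/\partial w_k = \sum_m
\left[ \mathbb{E}_{P(y \mid x^m; w)}\Phi_k(y) - \Phi_k(y^m) \right]
- w_k/\sigma^2$. All signs are derived from this one convention and
validated against central finite differences (worst relative error
around $10^{-10}$ on random tiny instances, asserted at $10^{-6}$).

The expectation is a sum over all $2^{N_P}$ labelings — exact only on
tiny grids. At image scale the partition function is replaced by the
saddle-point approximation: the sum collapses onto the single MAP
labeling $y^*$, turning the expectation into $\Phi_k(y^*)$, one min-cut
per instance. The approximation is exact in the low-temperature limit;
the tests verify sub-1% agreement with the exact gradient on scaled
instances whose MAP labeling holds over 99.9% of the probability mass,
and convergence of the error toward zero as the scaling grows.

`train_weights()` runs projected gradient ascent:

* **step size** `gamma` (default $10^{-3}$), scaled per weight by the
  average magnitude of its feature over the ground truths so node and
  edge features — whose raw sums differ by orders of magnitude — train
  at comparable rates;
* **positivity projection**: after each step edge weights are clipped
  to the floor $10^{-8}$, keeping the energy submodular;
* **termination** when the *projected* gradient norm falls below
  `epsilon` (default $10^{-4}$) — a clipped edge weight with an
  inward-pointing gradient is stationary under the constraint and must
  not keep the loop alive — or after `n_itr` iterations (default 200);
* **best-iterate tracking**: saddle-point gradients oscillate rather
  than settle, so the returned weights are those of the best-scoring
  evaluated iterate, not the last. The score is the exact
  regularized log-likelihood when every instance is tiny and exact
  gradients are in use, otherwise the saddle-point surrogate
  $\sum_m [E(y^*) - E(y^m)] - \lVert w\rVert^2/2\sigma^2$, which reuses
  the same MAP labelings as the gradient (one min-cut per instance per
  iteration in total).

The regularization variance defaults to $\sigma^2 = 10$;
$\sigma^2 = \infty$ disables the penalty. Performance is insensitive to
this value over many orders of magnitude, consistent with the penalty's
role being numerical (bounding the scale invariance of $w$) rather than
statistical.

## Evaluation

`confusion()` / `sens_spec()` give pixel-wise sensitivity and
specificity; `roc_sweep()` sweeps 256 evenly spaced thresholds
(including exact endpoints) on the pooled likelihood maps;
`nearest_point_comparison()` finds the curve point closest in
$(1-\text{spec}, \text{sens})$ space to a single-operating-point
method, and `sens_at_spec()` interpolates a curve at a matched
specificity. `cross_validate()` computes features once per image and
refits *everything downstream* — projection, class-conditionals, prior
and (optionally) CRF weights — inside each fold, predicting only
held-out images; a test asserts that corrupting a held-out image's
ground truth cannot change its prediction. Metrics are micro-averaged
(pooled pixel counts); per-image counts are returned for
macro-averaging. The CRF contributes a single operating point, not a
curve: its MAP output is not thresholded.

## The synthetic data generator

`generate_scene()` builds dermoscopy-like scenes: a darker elliptical
lesion on lighter skin, composed in sRGB, with (in order) an optional
Gaussian blur of the color transition (default 1 px, emulating
low-contrast boundaries; set 0 for a hard two-color image), dark
anti-aliased hair-like streaks, per-channel Gaussian sensor noise, and
finally a global L\* exposure offset applied in CIELab — exposure acts
on the fully composed scene, as a camera would. The ground-truth mask
is exact analytic ellipse membership and is provably independent of
blur, hair, noise and exposure. Given the same specification and seed
the generator is bitwise reproducible. `generate_dataset()` samples
per-scene parameters from stated ranges with a seed-derived stream;
each image draws its own exposure offset, emulating a set of
uncalibrated acquisitions.

Default conditions — 32–48 px images, skin sRGB (0.80, 0.62, 0.52),
lesion (0.38, 0.24, 0.20), noise sd 0.02, offsets ±10 L\*, no hair —
describe a moderately easy task a scientist would consider realistic at
desk scale. What the generator does *not* emulate: pigment-network
texture, vignetting, specular highlights, color charts, or any
photometric statistics of a specific atlas. Passing tests on these
scenes show the pipeline's internal consistency and its behavior under
the modeled nuisances (exposure, noise, occluding hair); they are not a
clinical performance claim.

Two experiments deserve their design rationale:

* **Exposure-normalization experiment.** Two conditions are needed
  before mean-centering L\* can show an effect. First, with the default
  colors skin and lesion separate in a\*/b\* alone, so exposure never
  hurts; the experiment uses a lesion that differs from skin in L\*
  *only* (equal a\*, b\*, built by shifting the skin color −12 L\* in
  Lab), with noise sd 0.06, lesion radii 12–38% of the frame and
  per-image offsets ±20. Second, the images (128 × 128) must be much
  larger than the biggest filter scale: when the frame is comparable to
  σ = 20, that channel approximates the per-image mean and the
  discriminant synthesizes its own exposure correction (small-scale
  minus large-scale L\* responses), masking the effect regardless of
  colors. Under these conditions cross-validated sensitivity at the
  un-normalized model's specificity is strictly higher with
  normalization on, consistently across probe seeds.
* **Weight-recovery experiment.** Training is checked by generating 50
  nine-pixel instances from known weights $w_{\text{true}} = [1, 0.6]$
  (exact Gibbs sampling by enumeration) and re-estimating the weight
  direction with exact gradients. Instance costs are drawn
  $U(0, 6)$ — the magnitude the real pipeline's node and edge features
  take — because at unit scale the *maximum-likelihood estimate
  itself*, computed independently by L-BFGS-B on the exact likelihood,
  misses the true direction by up to ~25% across seeds: the experiment
  must be powered so that a 10% recovery band tests the trainer, not
  estimator sampling noise. At these magnitudes the exact MLE lies
  within ~5% of the true direction across probe seeds, and
  `train_weights()` reproduces the L-BFGS-B optimum to six digits.

## Study sizes and runtime

The shipped tests and the acceptance script use sizes chosen so the
full suite re-runs comfortably on one CPU: 32 × 32 images, 10-fold
cross-validation on 40 images, CRF training with 12 SPA iterations per
fold, min-cut oracle comparisons on 1000 grids of at most 16 pixels,
and gradient checks on 100 tiny instances. One min-cut on a 32 × 32
grid costs ~35 ms through `igraph`, which puts the end-to-end
cross-validation around three minutes.

## Known limitations

* Binary label sets only for CRF inference; the data structures admit
  $N_L > 2$ (the per-pixel model fully supports it) but exact min-cut
  does not, and move-making approximations are out of scope.
* No color calibration beyond L\* mean-subtraction.
* No hair removal or inpainting: robustness to hair comes only from
  the models themselves.
* The saddle-point surrogate score can prefer degenerate weights when
  ground truths are very far from any MAP labeling; best-iterate
  tracking mitigates but does not eliminate this.
* `convertColor`'s sRGB matrix differs from other published sRGB
  matrices in the fourth decimal; Lab values may differ from other
  software by a few tenths of a unit for saturated colors.
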