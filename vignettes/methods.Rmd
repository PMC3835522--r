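---
title: "Local Gaussian MAP level-set segmentation with bias-field estimation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lsbias)
```

## The model

Medical images — MR slices in particular — are corrupted by a *bias field*: a
smooth multiplicative modulation of the true tissue intensities caused by the
acquisition hardware. `lsbias` models the observed image as

\[ J = I \cdot b \quad (\text{plus noise}), \]

with \(I\) piecewise constant over \(N\) tissue regions (\(I = c_i\) on region
\(\Omega_i\)) and \(b\) strictly positive and slowly varying. After a log
transform the bias becomes additive,

\[ \tilde J(x) = \tilde I(x) + \tilde b(x) + n(x), \]

and the noise \(n\) is taken to be zero-mean Gaussian with a region-specific
variance \(\sigma_i^2\).

Around every pixel \(y\) we take a circular neighbourhood
\(O_y = \{x : |x-y| \le r\}\) weighted by a truncated Gaussian window
\(\omega\) (standard deviation \(\sigma\), radius \(r\), normalised to sum
to 1). Because \(\tilde b\) is slowly varying it is approximately constant over
\(O_y\), so within the window the log-intensities of region \(i\) are Gaussian
with mean \(c_i + \tilde b(y)\) and variance \(\sigma_i^2\). Combining this
likelihood with a spatially varying prior \(p_i(y)\) for region \(i\) through
Bayes' rule, and integrating the resulting negative log-posterior over all
window centres, gives the data energy

\[
E = \int_\Omega \sum_{i=1}^N \int_{\Omega_i} \omega(x-y)
\left( -\log p_i(y) + \log\!\big(\sqrt{2\pi}\,\sigma_i\big)
+ \frac{(\tilde J(x) - \tilde b(y) - c_i)^2}{2\sigma_i^2} \right) dx\, dy .
\]

The regions are represented implicitly: for \(N = 2\) one level-set function
\(\phi\) with \(\Omega_1 = \{\phi > 0\}\); for \(N = 3, 4\) two functions whose
smoothed-Heaviside products form the membership functions. Two geometric terms
complete the objective: a contour length penalty (weight \(\nu\)) and a
penalty on the deviation of each \(\phi\) from a signed distance function
(weight \(\mu\)), which keeps the evolution well-conditioned without any
reinitialisation.

## Minimisation

The energy is minimised by interleaving:

1. closed-form updates of \(c_i\) and \(\sigma_i\) (window-weighted means of
   the residuals and squared residuals over each region);
2. one explicit Euler step of the gradient flow for the level sets, driven by
   per-pixel *evidence fields* \(e_i(x)\) — the window-integrated MAP cost of
   assigning \(x\) to region \(i\);
3. a pointwise closed-form update of \(\tilde b\) (a precision-weighted local
   average of the residuals \(\tilde J - c_i\));
4. a closed-form update of the priors \(p_i\) under the pointwise simplex
   constraint (window-smoothed membership fractions).

Every window integral is a discrete convolution with the kernel mask; the
package evaluates them with zero-padded FFTs and forms all ratio-type
quantities as quotients of two convolutions, so the effective window
renormalises itself near image boundaries instead of inventing padding
intensities. The equivalence of the convolution forms with the literal double
integrals is asserted against brute-force loop oracles in the test suite, not
assumed.

Each closed-form update is the exact minimiser of \(E\) in its variable, so
with the level sets held fixed the energy is non-increasing to numerical
precision (a tested property). The finite-step PDE update is *not* an exact
descent step: the total objective fluctuates by a fraction of a percent per
iteration and descends in trend, which is what the corresponding test asserts.

## Parameters

| parameter | meaning | default | units |
|---|---|---|---|
| `kernel_sigma` | window standard deviation | 4 | px |
| `kernel_radius` | window truncation radius | 15 | px |
| `dt` | Euler time step | 0.1 | — |
| `mu` | signed-distance penalty weight | 1.0 | — |
| `nu` | contour length weight | 0.001·255² | — |
| `eps` | Heaviside/delta smoothing width | 1 | px of \(\phi\) |
| `c0` | binary-step initialisation height | 2 | — |
| `intensity_floor` | minimum raw intensity kept by the log transform | 1 | 8-bit intensity |
| `sigma_floor` | lower bound on each \(\sigma_i\) | 1e-3 | log intensity |
| `prior_floor` | lower bound on each prior before its log | 1e-6 | — |

The defaults are the values the model was designed and demonstrated with.
`nu` is expressed on an 8-bit intensity scale; the evolution here runs on
log-transformed intensities, where the printed default turns out to be of the
same order as the data forces, so it is kept and exposed in the
configuration. The floors exist because the evidence fields take
\(\log p_i\) and divide by \(\sigma_i^2\): noise-free phantom regions would
otherwise produce zero variances.

Convergence is declared when the hard label map is unchanged for
`stable_iters` (10) consecutive iterations, bounded by `max_iter` (500). The
original formulation states no concrete criterion; label stability is this
package's substitute and both knobs are exposed.

## Initialisation, and why it matters

Each \(\phi_j\) starts as a binary step: \(-c_0\) inside a seed region,
\(+c_0\) outside. Seeds are rectangles, discs, or unions of them (one seed per
level-set function; for four phases the two seeds should jointly separate the
four sign combinations).

The smoothed Heaviside used throughout is
\(H_\varepsilon(x) = \tfrac12[1 + \tfrac2\pi \arctan(x/\varepsilon)]\). Its
tails decay only as \(1/x\): at the binary-step plateau \(|\phi| = c_0 = 2\)
every pixel still carries membership \(H_\varepsilon(-2) \approx 0.15\) in the
*wrong* region. Two consequences follow, both visible in experiments with the
package and both accounted for in its design:

* **Reported statistics are refit from hard labels.** The in-loop estimates
  of \(c_i\), \(\sigma_i\) and \(\tilde b\) mix ~15% of every other region
  through the membership tails. After convergence, `segment()` re-derives the
  reported constants, standard deviations and bias by iterating the same
  closed-form updates with the exact indicator memberships of the final
  labels (`refit_iters` sweeps). The segmentation itself is never touched by
  the refit. On two-phase phantoms this reduces the constant error from
  several percent to about 0.1%.

* **The energy can prefer degenerate partitions at the plateau.** Because the
  bias update is an unconstrained local average, the membership tails let it
  absorb the contrast of any structure wider than the kernel window; with the
  contrast absorbed, regions with similar variances become indistinguishable
  and the length term erases them. Whether a segmentation run escapes this
  depends on the structure scale relative to the window, on the variance
  contrast between regions, and on the initial contours — which is why the
  method is conventionally initialised with contours drawn near the objects.
  Multiphase runs are far more sensitive than two-phase runs, because
  adjacent classes are separated by smaller log-contrasts.

## The phantom generator

`generate_phantom()` builds a piecewise-constant image from labelled discs
and rectangles over a background, multiplies it by a smooth mean-one bias
field, and adds noise under one of three formation models:

* `"scanner"`: \(J = I\,b + n\) — additive noise, independent of the bias;
* `"biological"`: \(J = (I + n)\,b\) — noise scaled by the bias;
* `"log_additive"`: \(\log J = \log I + \log b + n\) — the model the
  segmentation core itself assumes, which makes parameter recovery a
  well-posed question.

`noise_sd` is in intensity units (8-bit scale) for the first two models and
in log-intensity units for the third; the first-order intensity equivalent of
a log-noise \(s\) at brightness \(c\) is \(s\,c\), so an intensity-equivalent
noise of sd 10 in a region of constant \(c_i\) corresponds to log-noise
\(10/c_i\). Bias fields are radial quadratics whose minimum is
\((1-\text{amplitude})\) times their maximum (`amplitude = 0.4` is a 40%
total variation) or Gaussian-blurred random fields; all bias fields are
normalised to mean one, which fixes the gauge for recovery comparisons (the
energy is invariant under \(\tilde b \to \tilde b + \kappa\),
\(c_i \to c_i - \kappa\); estimates are reported with the bias normalised to
zero mean over the valid mask).

All randomness sits behind the single integer `seed` in the spec; generation
restores the caller's RNG state.

What phantom tests do and do not show: the phantoms are piecewise-constant
blobs with stationary Gaussian noise and a smooth analytic bias. Real tissue
has texture, partial-volume boundaries, and fine-scale anatomy; notably,
fine-scale anatomy *helps* this method (windows then mix all classes
everywhere, so the bias update cannot absorb per-class contrast), so blob
phantoms are in this respect a harder test of the bias/segmentation coupling
than brain images, while being an easier test of boundary geometry.

## Built-in recovery studies

Three fixed studies (`recovery_study()` / `run_recovery_study()`) define the
package's quantitative self-checks; the test suite and
`scripts/acceptance.R` run exactly these:

* **`two_phase`** — one disc (radius 32) on a 128×128 background, constants
  (60, 180), 40% corner-apex quadratic bias, log-additive noise at
  intensity-equivalent sd 10 per region, initial contour a circle of radius
  38. Scored: per-region Jaccard, relative error of the gauge-normalised
  constants against the log-domain truth, and Pearson correlation between
  estimated and true log-bias over the interior. The bias-correlation ceiling
  implied by the window size and noise level (effective window sample size
  ≈ 200, background log-noise 0.167, interior log-bias spread 0.074) is
  itself about 0.99, so that metric sits near its theoretical limit by
  construction.

* **`multiphase`** — the default phantom (three discs of radius 20–22 on a
  128×128 background, constants (40, 100, 160, 220), 40% quadratic bias,
  scanner noise sd 10), segmented with \(N = 4\). At this severity the
  four-phase flow is *not* stable: even initialised at the true partition it
  drifts away, because the darkest class has log-noise ≈ 0.25 and the bias
  update absorbs the contrast of window-sized structures. The corresponding
  acceptance test asserts per-region Jaccard ≥ 0.95 and is expected to fail;
  the study exists to measure and report the behaviour honestly rather than
  to pass.

* **`multiphase_mild`** — the same four-region layout with larger discs
  (radius 24–26) and uniform mild log-noise 0.045 (the intensity equivalent
  of sd 10 at the brightest tissue). In this regime four-region recovery from
  over-covering initial contours succeeds; the test asserts all regions
  ≥ 0.90 and mean ≥ 0.95 Jaccard.

## Numerical choices

* Spatial derivatives: central differences with replicated edges; 5-point
  Laplacian; curvature guarded by \(\eta = 10^{-10}\) added to
  \(|\nabla\phi|\) (the flow is singular where the gradient vanishes).
* Time stepping: explicit Euler at fixed `dt`; no CFL adaptation and no
  reinitialisation, ever — the \(\mu\)-term is the only conditioning
  mechanism.
* Convolutions: zero-padded FFT products with the kernel spectrum cached per
  image size; agreement with direct summation is tested to 1e-10.
* Hard labels: argmax over exact (non-smoothed) memberships, ties broken
  toward the lowest region index; masked-out pixels carry label 0.
* Label matching for evaluation: predicted labels are matched to truth by the
  permutation maximising mean Jaccard (exhaustive, \(N \le 4\)),
  deterministically.
* Degenerate inputs: regions whose weighted mass vanishes keep their previous
  constants/variances with a warning; bias pixels with empty windows keep
  their previous value; priors are floored and renormalised, so the simplex
  constraint holds exactly.

## Known limitations

* The bias field is only constrained by the window average; it can absorb
  genuine tissue contrast at scales larger than the window. This is intrinsic
  to the formulation, and is the dominant failure mode on high-noise blob
  phantoms (see the `multiphase` study above).
* The per-region variances are global; spatially varying within-class
  variance is outside the model.
* Segmentation quality depends on the initial contours, especially for
  \(N > 2\); the package deliberately does not guess seeds from the data.
* Runs are 2-D only.
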