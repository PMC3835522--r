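# lsbias

Variational level-set segmentation of 2-D grayscale images with simultaneous
estimation of the intensity inhomogeneity (bias) field.

## The problem

Intensity-based segmentation of medical images — brain MR slices, X-ray
vessel images, ultrasound — is confounded by a *bias field*: a smooth,
slowly varying multiplicative modulation of tissue intensities introduced by
the scanner. The same tissue then takes different intensities in different
parts of the image, and global intensity models misclassify it.

`lsbias` models the observed image as `J = I · b` (plus noise), with `I`
piecewise constant over `N` tissue classes and `b` smooth and positive. After
a log transform the bias is additive:

```
J̃(x) = Ĩ(x) + b̃(x) + n(x),      n ~ N(0, σᵢ²) on class i.
```

Within a truncated-Gaussian window around each pixel `y` the bias is locally
constant, so class-`i` log-intensities there are Gaussian with mean
`cᵢ + b̃(y)` and variance `σᵢ²`. Combining these local likelihoods with
spatially varying class priors `pᵢ(y)` via Bayes' rule (MAP classification of
each window) and integrating over all window centres yields a global energy

```
E = ∫ Σᵢ ∫_Ωᵢ ω(x−y) [ −log pᵢ(y) + log(√(2π) σᵢ)
                       + (J̃(x) − b̃(y) − cᵢ)² / (2σᵢ²) ] dx dy,
```

minimised over a level-set representation of the partition `{Ωᵢ}`, the class
constants `cᵢ`, variances `σᵢ²`, the bias `b̃`, and the priors `pᵢ` — plus a
contour length penalty (weight `ν`) and a signed-distance regulariser
(weight `μ`). Minimisation interleaves explicit gradient-flow steps of the
level sets with closed-form coordinate-descent updates of all statistical
variables, so segmentation, bias correction, and tissue statistics come out
of one pass. Two-phase (`N = 2`, one level-set function) and multiphase
(`N = 3, 4`, two functions) formulations are included.

## Worked example

Segment a synthetic phantom with a 40% bias field and recover its parameters:

```r
library(lsbias)

# one bright disc (intensity 180) on a darker background (60), corrupted by
# a 40% quadratic bias field and intensity noise of sd 10 (8-bit scale)
study <- recovery_study("two_phase", seed = 7)
ph  <- generate_phantom(study$spec)
res <- segment(ph$image, study$config)
print(res)
#> Segmentation: 2 regions, 894 iterations (converged)
#>   constants (gauge-normalised log): 4.0905, 5.1909
#>   stddevs: 0.1697, 0.0561

log(c(60, 180))   # ground truth: 4.0943, 5.1930

ev <- segmentation_jaccard(res$labels, ph$labels)
ev$js
#> 0.9997 0.9988
```

The estimated log-constants match the truth to about 0.1%, both regions
overlap the ground truth with Jaccard ≥ 0.9988, and `res$bias_field` /
`res$corrected` hold the estimated intensity-domain bias and the
bias-corrected image. `run_recovery_study("two_phase")` wraps this run and
its scoring (it also reports the Pearson correlation between the estimated
and true log-bias, 0.991 for this study).

From a shell, the same machinery is available as:

```sh
Rscript inst/cli/lsbias phantom --out ph --seed 7
Rscript inst/cli/lsbias segment --in ph/image.tif --out seg --phases 4
Rscript inst/cli/lsbias evaluate --labels seg/labels.png --truth ph/labels.png --regions 4
```

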