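---
title: "Quantifying egg pattern mimicry with threshold-sweep Minkowski functionals"
author: "minkpat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying egg pattern mimicry with threshold-sweep Minkowski functionals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minkpat)
```

## The problem and the method

Hosts of avian brood parasites reject foreign eggs, and parasites evolve
egg mimicry in response. In the cuckoo finch / tawny-flanked prinia
system the mimicry is visibly imperfect: prinia eggs carry fine, long,
thin curvilinear pigment lines ("scribbles") that parasitic eggs lack.
Conventional pattern statistics — dominant marking size from a bandpass
("granularity") decomposition, marking counts, coverage — cannot isolate
scribbliness, because a scribble is simultaneously large (long) and
small (thin).

This package quantifies such markings with the three 2-D Minkowski
functionals. An image is first converted to a *marking-intensity field*:
intensity is inverted if necessary so that markings are bright,
smoothed with a Gaussian filter, and min–max normalized to $[0,1]$
inside a region of interest (ROI). The field is then thresholded at
$n = 80$ levels placed evenly *strictly inside* the in-ROI intensity
range; at each level $t$ the binary pattern $B_t$ (pixels with intensity
strictly greater than $t$) is measured by:

* **area** $A(t)$ — foreground pixel count;
* **perimeter** $P(t)$ — total boundary length of the foreground;
* **Euler characteristic** $\chi(t)$ — connected components minus
  holes, a topological connectivity measure.

Each per-level sequence is integrated by a plain (unweighted) sum over
the sweep, giving $\Sigma P$, $\Sigma A$, $\Sigma \chi$ and, most
importantly, the dimensionless

$$\Sigma(P^2/A) \;=\; \sum_{t} \frac{P(t)^2}{A(t)},$$

which is scale-invariant per level and large precisely for long, thin
markings: at the thresholds where scribbles are isolated, perimeter is
high while area stays low. Compact blotches of the same total area score
much lower. $\Sigma\chi$ is complementary: scribbles connect markings
into fewer components and create enclosed background, driving
$\Sigma\chi$ down.

## Assumptions and conventions

The method assumes a single-channel intensity image in which markings
are darker (or lighter) than the background monotonically enough that
level sets capture them; it does not model colour, gloss, or visual
acuity of the receiver. Specific conventions, all exposed as arguments:

* **Retention is strict** (`> t`), so a two-level image yields the
  marking mask at every level.
* **Level grid interior to (min, max)**: endpoints would give trivially
  full or empty masks that only add constants to the sums.
* **Degenerate images** (constant inside the ROI) are accepted, flagged,
  and yield an all-zero curve, so batch runs never abort on a blank
  frame.
* **Connectivity**: 8-connected foreground with 4-connected background,
  the standard consistent pairing of digital topology; `connectivity = 4`
  selects the complementary pairing. The configuration-count
  implementation is verified against a flood-fill component/hole oracle
  in the tests.
* **Perimeter**: the default `crofton4` estimator applies the
  Cauchy–Crofton formula to intercept counts along four directions,
  $P = (\pi/4)\,(R_h + R_v + (R_{d1} + R_{d2})/\sqrt 2)$; it recovers a
  radius-25 digital disc's circumference to about 1%. The alternative
  `boundary_edges` counts foreground–background 4-neighbour edges — the
  exact digital boundary length (exactly $4n$ for an $n \times n$
  square) and the oracle used in testing, but biased upward ($4/\pi$)
  on smooth contours.
* **ROI handling**: out-of-ROI pixels are background. Foreground
  touching the ROI edge contributes perimeter there; this is a
  measurement artifact, but it is identical across specimens measured
  with the same ROI geometry and therefore cancels in comparisons.
* **Empty levels** contribute $P^2/A = 0$ rather than being dropped, so
  every curve shares the same 80-point support.
* **Integration is an unweighted sum.** A trapezoidal option
  (`integrateFunctional(..., "trapezoid")`) exists but is off by
  default; with an evenly spaced grid the two differ only by a constant
  factor and endpoint terms.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `nLevels` | 80 | thresholds | the standard sweep resolution; finer grids change the sums only by near-proportional rescaling |
| `sigma` | 2 | px | Gaussian noise-suppression scale; large enough to remove pixel noise, small relative to stroke widths (≥3 px). The filter scale is a free choice and is recorded in the image metadata |
| `invert` | TRUE | — | egg photographs have dark markings on a pale shell; the sweep needs markings bright |
| `method` | `crofton4` | — | near-unbiased on smooth shapes; `boundary_edges` kept as the exact-digital oracle |
| `connectivity` | 8 | — | foreground 8 / background 4 |

Smoothing uses reflective boundary padding: zero padding would create a
dark frame whose edge registers as spurious perimeter at every level.
Whether to crop to an egg ellipse before analysis is left to the ROI
argument rather than hard-coded.

## The synthetic generators

The package is verifiable without any photographs because it ships
seeded generators for the two marking morphologies:

* **Scribbles** (`generateScribble`): a stroke is the trace of a unit-
  speed walk whose heading receives wrapped-normal increments with sd
  `curvatureScale` (default 0.2 rad/step — bounded curvature, so the
  stroke wanders smoothly instead of jittering), dilated to
  `strokeWidth` (default 3 px) by disc stamping. Stroke length is set
  from `targetTotalArea / (count × strokeWidth)`.
* **Blotches** (`generateBlotch`): elliptical discs of bounded
  eccentricity (axis ratio ≥ 0.75), placed disjointly with at least two
  background pixels between discs, so $\chi$ equals the blotch count by
  construction.
* **Area matching** (`matchArea`): solves $r = \sqrt{T/(m\pi)}$ and
  applies a multiplicative digital correction until the blotch total is
  within 5% of the scribble total — the synthetic analogue of the
  equal-area control treatment.
* **Egg composition** (`composeEgg`): smooth low-frequency background
  (base 0.25, cosine ripple amplitude 0.05), markings composited at
  intensity 0.85, Gaussian pixel noise (sd 0.02), elliptical ROI.
* **Painting** (`paintMarkings`): composites 5 scribbles or 10 blotches
  (the treatment counts of the rejection experiment) at a paint
  intensity defaulting to the marking intensity, since the experimental
  paint was colour-matched to natural pigment; `"water"` is the
  handling-only identity control.

Defaults mirror the experimental design (5 scribbles vs 10 area-matched
blotches vs water). What the generator does *not* emulate: 3-D egg
geometry and foreshortening, illumination gradients and specularity,
pigment translucency, camera noise structure, and the within-clutch
correlation of real patterns. Tests passing on synthetic eggs therefore
demonstrate the *measurement chain* (geometry in, statistics out), not
field-data effect sizes; the published field statistics (assignment
rates, painting t-statistic) require the archived photographs and are
out of scope here.

## Simplified granularity-style traits

The classical trait set (principal marking size, marking size
variation, contrast, coverage, pole dispersion) has published recipes
living in external MATLAB/ImageJ toolchains. This package defines
deliberately simplified, self-contained analogues so the discriminant
stage can run on a full multi-trait table: band energies from the 2-D
FFT power spectrum in octave-spaced isotropic bands (centres 2, 4, …,
128 px); principal size = centre wavelength of the dominant band;
variation = entropy of band energies; contrast = in-ROI intensity sd;
coverage = foreground fraction at the median sweep level; pole
dispersion = $|c_1 - c_2|/(c_1 + c_2)$ over the two long-axis halves.
They are *not* claimed equivalent to the originals, and
`computeTraits(..., simplifiedPrefix = TRUE)` renames them
`simplified_*` in output headers to keep that distinction visible. The
long-axis orientation cannot be inferred from pixels, so it is a
required argument.

## Classification by optimal scoring

Flexible discriminant analysis is implemented as optimal scoring:
regress the class-indicator matrix on the standardized (optionally
degree-2 polynomial-expanded) traits, eigen-decompose
$\Pi^{-1/2}\,(Y^\top\hat Y/n)\,\Pi^{-1/2}$ (with $\Pi$ the class
proportions), and take the nontrivial eigenvectors as optimal scores;
the regression coefficients mapped through the scores give the
discriminant directions. Assignment minimizes the within-class
Mahalanobis distance to the class centroid in discriminant space, with
per-coordinate weights $1/(\lambda_j(1-\lambda_j))$, the metric scaled
by $(n-K)/n$ — the bias-corrected pooled covariance — minus
$2\log \pi_k$. With the linear basis this rule coincides *exactly* with
classical LDA under proportional priors; the test suite asserts
identical assignments against an independent LDA implementation on 100
random data sets, and this equivalence is what makes the optimal-scoring
machinery trustworthy before the polynomial basis is used.

Conventions declared here because the field reports them loosely:

* **Coefficient importance** is the absolute standardized
  first-discriminant coefficient, normalized to sum to 100% across
  basis columns.
* **Assignment rates** depend on the scheme; both resubstitution and
  leave-one-out are implemented, resubstitution is the default, and the
  scheme is always printed with the rates.
* `pcaReduce` selects the smallest component count reaching a target
  explained-variance fraction on standardized traits, for reducing
  correlated trait blocks before the discriminant fit.
* Singular scoring regressions (collinear traits) fail with a message
  pointing to the `ridge` argument rather than returning an unstable
  fit.

## Receiver-response statistics

The response module reconstructs trial-level data from reported
rejection percentages: counts are `round-half-up(freq × n)` per
treatment, expanded to Bernoulli records, and `rejection ~ treatment`
is fitted as a binomial logit (IRLS with a tightened convergence
tolerance of $10^{-14}$, so that Wald statistics agree with the
saturated-design closed form — log-odds differences, SEs
$\sqrt{\sum 1/\text{cell}}$ — to better than $10^{-6}$). The reference
level defaults to `blotches`: alphabetically first, hence the default
reference of the factor coding, and the only reference under which the
six reported Wald statistics are jointly reproduced from the
reconstructed counts. Complete separation is detected and flagged
instead of silently diverging. The matched-pairs t-test takes
`after - before` differences with $df = n - 1$; all-zero differences
return $t = 0, p = 1$ by convention (flagged), while constant nonzero
differences error, since no valid t statistic exists.

## Problem sizes used in the checks

The shipped checks run on sizes chosen to exercise every code path at
desk scale: synthetic eggs of 96 × 72 px with ~20% marking coverage and
the full 80-level sweep for the separation and painting properties (50
seeded pairs each); 16 × 16 random binaries (1000 of them) for the
Euler oracle; cohorts of 6–10 eggs per class for the end-to-end
demonstration. These are the package's default study conditions for
synthetic work; all scale up by argument.

## Known limitations

* Perimeter estimates are resolution-dependent below stroke widths of
  ~2 px; generate or photograph at sufficient resolution.
* $\Sigma$ summaries depend on the number of levels; compare specimens
  only at a fixed `nLevels`.
* The granularity-style traits are simplified stand-ins (see above).
* The FDA implements linear and degree-2 polynomial bases only; no
  spline/MARS bases, and no probability calibration.
* Painting simulations share the generator's idealizations; they test
  direction and detectability of the $\Sigma(P^2/A)$ response, not its
  field magnitude.

## A minimal end-to-end run

```{r example, eval = FALSE}
sc  <- generateScribble(markingSpec("scribble", count = 5,
                                    targetTotalArea = 1400, seed = 3),
                        canvas = c(96, 72))
bl  <- matchArea(sc, markingSpec("blotch", count = 10, seed = 3),
                 canvas = c(96, 72))
eggS <- smoothImage(composeEgg(c(96, 72),
                               list(list(mask = sc, intensity = 0.85)),
                               seed = 11), sigma = 1)
eggB <- smoothImage(composeEgg(c(96, 72),
                               list(list(mask = bl, intensity = 0.85)),
                               seed = 11), sigma = 1)
curveSummaries(minkowskiCurve(eggS))[["sumP2A"]]   # scribbled egg
curveSummaries(minkowskiCurve(eggB))[["sumP2A"]]   # equal-area blotched

demo <- demoExperiment(seed = 1)                   # full pipeline
sort(demo$fda$importance, decreasing = TRUE)
```
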