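# minkpat

Threshold-sweep Minkowski functionals for quantifying biological
surface patterns — in particular the long, thin, curvilinear egg
markings ("scribbles") whose absence makes a brood parasite's egg
mimicry imperfect.

## The problem

Tawny-flanked prinia eggs carry fine scribbled pigment lines; the eggs
of their brood parasite, the cuckoo finch, do not. Standard pattern
statistics (dominant marking size, marking counts, coverage) cannot
isolate scribbliness, because a scribble is both large (long) and small
(thin). minkpat is for researchers in animal coloration, mimicry and
camouflage who need a pattern statistic that separates line-like
markings from blobs, plus the surrounding machinery to ask whether a
receiver actually uses that trait.

## The method

An image is converted to a marking-intensity field (inverted so
markings are bright, Gaussian-smoothed, min–max normalized inside an
ROI) and thresholded at 80 levels placed evenly strictly inside the
intensity range. At each level *t* the binary pattern is measured by the
three 2-D Minkowski functionals — area *A(t)* (pixel count), perimeter
*P(t)* (Cauchy–Crofton 4-direction estimate by default), and the Euler
characteristic χ(t) (components minus holes, by 2×2 configuration
counting). Each is integrated as a plain sum across the sweep:

    Σ(P²/A) = Σ_t P(t)²/A(t)      ΣEuler = Σ_t χ(t)

Σ(P²/A) is dimensionless per level and large precisely for long thin
markings; ΣEuler is low when scribbles connect markings into few
components. The package adds:

- seeded generators for synthetic scribble/blotch egg images, an
  area-matching control, and the "painting" manipulation (5 scribbles /
  10 equal-area blotches / water), so every stage is testable without
  photographs;
- simplified granularity-style traits (principal marking size, size
  variation, contrast, coverage, pole dispersion) to fill a multi-trait
  table;
- flexible discriminant analysis by optimal scoring (linear basis ≡
  classical LDA, verified against an independent implementation;
  optional degree-2 basis), PCA reduction, and coefficient importances;
- receiver-response statistics: reconstruction of trial counts from
  reported rejection frequencies, the rejection ~ treatment binomial
  logit with Wald reporting, and matched-pairs t-tests.

## Worked example

```r
library(minkpat)

## five scribbles vs ten blotches of the same total area
sc  <- generateScribble(markingSpec("scribble", count = 5,
                                    targetTotalArea = 1400, seed = 3),
                        canvas = c(96, 72))
bl  <- matchArea(sc, markingSpec("blotch", count = 10, seed = 3),
                 canvas = c(96, 72))
binaryArea(sc); binaryArea(bl)
#> 1400
#> 1393

eggS <- smoothImage(composeEgg(c(96, 72),
                    list(list(mask = sc, intensity = 0.85)), seed = 11), 1)
eggB <- smoothImage(composeEgg(c(96, 72),
                    list(list(mask = bl, intensity = 0.85)), seed = 11), 1)
minkowskiCurve(eggS)
#> MinkowskiCurve over 80 levels (crofton4 perimeter, 8-connectivity)
#>   SigmaP = 34398.5  SigmaA = 115688  SigmaEuler = -56  Sigma(P2/A) = 14555.38
minkowskiCurve(eggB)
#> MinkowskiCurve over 80 levels (crofton4 perimeter, 8-connectivity)
#>   SigmaP = 32211.0  SigmaA = 125683  SigmaEuler = 687  Sigma(P2/A) = 9861.66
```

Same marking area, but the scribbled egg scores ~50% higher on Σ(P²/A)
and far lower on ΣEuler (scribbles connect, blotches fragment). Painting
scribbles onto the blotch-only egg raises its Σ(P²/A):

```r
painted <- paintMarkings(eggB, "scribbles", seed = 21,
                         targetTotalArea = 1400)
#> Sigma(P2/A): 9861.7 -> 15907.5
```

And the receiver-response side — rejection counts reconstructed from
per-treatment rejection frequencies (65% of 17 scribble-painted, 57% of
14 blotch-painted, 62% of 13 water controls) and fitted as a logit:

```r
ns     <- c(blotches = 14, scribbles = 17, water = 13)
counts <- reconstructCounts(c(blotches = 0.57, scribbles = 0.65,
                              water = 0.62), ns)
counts
#>  blotches scribbles     water
#>         8        11         8
fitLogistic(buildTrialRecords(counts, ns), reference = "blotches")
#> Binomial logit fit, n = 44 trials, reference level 'blotches'
#>   (Intercept)              0.29 +/- 0.54  Z_41 = 0.53, p = 0.59
#>   treatment-scribbles      0.32 +/- 0.74  Z_41 = 0.43, p = 0.67
#>   treatment-water          0.18 +/- 0.79  Z_41 = 0.23, p = 0.82
```

No treatment effect: hosts do not discriminate on scribbles, despite
the measurable trait difference — the trait-based and response-based
measures of mimicry disagree, which is the scientific point. `blotches`
is the reference level because it is alphabetically first (the default
factor coding) and it is the only reference under which all six Wald
statistics above are jointly reproduced from the reconstructed counts.

`demoExperiment(seed = 1)` runs the whole pipeline (cohorts → traits →
FDA → painting t-test → trial GLM) and writes a markdown report; a thin
CLI over the same functions lives in `inst/cli/minkpat.R`
(`measure`, `batch`, `synth`, `respond`, `demo`).

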