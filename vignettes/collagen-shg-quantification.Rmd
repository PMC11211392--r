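---
title: "Quantifying collagen architecture in SHG images"
author: "collagenSHG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying collagen architecture in SHG images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(collagenSHG)
```

## The problem and the measurement model

Fibrillar collagen produces a coherent second harmonic generation (SHG)
signal, so an SHG tile is effectively a map of collagen architecture.
Around a true tumor invasion front the stroma is desmoplastic: collagen
accumulates in long, relatively aligned fascicles. Around benignly
misplaced glands (pseudoinvasion) the reaction is fibro-muscular:
sparse, short fibers without consistent alignment. This package reduces
each grayscale tile to twelve parameters chosen to be sensitive to
exactly those contrasts — how much collagen there is, how its intensity
is distributed, how it is textured locally, how anisotropic it is
globally, and how space-filling the thresholded pattern is — and then
compares two groups of tiles parameter by parameter.

The unit of analysis is a single tile (`SHGImage`), a non-negative
integer intensity matrix at 8- or 16-bit depth, at least 8×8 pixels.
No pixel-size metadata is used: every parameter is dimensionless or in
intensity units.

## Per-tile parameters and their conventions

**First-order statistics.** Population (not sample-corrected) moments
of all pixels: with central moments $m_k$, skewness $g_1 = m_3 /
m_2^{3/2}$ and kurtosis in excess form $g_2 = m_4/m_2^2 - 3$ (Gaussian
→ 0). Tiles contain $\ge 2.6\times 10^5$ pixels, so the bias
correction would be negligible; fixing the population form makes runs
reproducible across tools. A constant tile has undefined skewness and
kurtosis; these propagate as `NA` sentinels and the comparison stage
drops them per parameter.

**Triangle threshold and TC-ratio.** The threshold histogram always has
256 bins: native values for 8-bit tiles, min–max rescaled values for
16-bit tiles (the selected bin is mapped back to native intensity
before binarization). Zack's construction finds the peak, picks the
side whose farthest non-empty bin is farther from the peak (ties to the
bright side — collagen is the bright tail), and maximizes the
perpendicular distance between the histogram and the peak-to-tail-end
chord. Two tie-break rules are fixed so the construction is exactly
mirror-symmetric: distance ties resolve toward the peak. Foreground is
*strictly above* the level. The TC-ratio is the foreground fraction;
the same mask feeds the fractal stage. The threshold is computed per
tile, so exposure differences between tiles do not leak into the
density estimate.

**GLCM features.** Distance-1 co-occurrences in the four directions,
symmetrized (each pair counted in both orders) and normalized; the five
features are averaged over directions, which makes them exactly
invariant under 90° rotations and flips. Gray levels: $L = 256$, with
16-bit tiles min–max rescaled into the 256 levels. Energy is the
angular second moment $\sum p^2$ and homogeneity the inverse difference
moment $\sum p/(1+(i-j)^2)$ — the definitions vary across toolboxes, so
both formulas are fixed here. Entropy uses base 2, which gives the
two-level checkerboard the value 1 exactly. A constant tile has
undefined correlation (zero marginal variance).

**Orientation index.** The mean-subtracted tile is Fourier transformed,
the squared magnitude centered, and $\log(1+P)$ thresholded
automatically; an ellipse is fitted to the foreground coordinates by
second central moments (axes $2\sqrt{\lambda}$ of the coordinate
covariance), and $N = 1 - S/L$ reported. The central row and column of
the spectrum — the leakage cross of the finite, unwindowed tile — are
masked before thresholding and fitting; no window is applied because
tiles are large and the leakage is confined to that cross.

Two numerical choices matter here and were decided by experiment
during development:

* *Threshold method.* Otsu's criterion on the log-power histogram is
  bistable: the histogram is a noise-floor bulge plus a bright signal
  tail, and when the tail carries little mass the Otsu threshold dives
  into the bulge, turning the foreground into isotropic salt and
  collapsing $N$ by an order of magnitude between nearly identical
  fields. The default is therefore a Triangle construction on the
  log-power histogram with the tail pinned to the bright side (the
  spectral foreground is, by construction, the bright tail above the
  noise-floor mode), which behaves continuously across
  signal-to-noise regimes; `shgConfig(spectrumMethod = "otsu")`
  restores Otsu for comparison.
* *Log transform.* Raw power spans many orders of magnitude and a
  histogram threshold on it keeps only a handful of central pixels,
  making the ellipse fit unstable; the log transform is applied first.

$N$ ranges from 0 (isotropic) to 1 (aligned); the spectral major axis
is perpendicular to the fiber axis. Note one caveat inherited from the
measurement definition: $N$ saturates well below 1 for realistic
fields, because fiber curvature and the point-spread function both
broaden the spectral streak. The aligned limit ($N > 0.5$) is reached
only by nearly straight fibers under a sharp PSF.

**Fractal dimension.** Box counting on the Triangle mask with an
origin-anchored grid and a power-of-two size ladder from 2 to a quarter
of the smaller tile dimension (exact tilings, reproducible fits);
$D$ is the least-squares slope of $\log N(s)$ against $\log(1/s)$.
Offset averaging is deliberately not performed, matching basic
box-count plugins; the ladder is configurable.

## Group comparison

Each parameter is compared between groups with the classic
pooled-variance unpaired Student's t-test, two-sided, $df = n_1+n_2-2$
(Welch's form behind a flag). "Two-sided" is an interpretation choice:
the star-tier convention (`*` p < 0.05 through `****` p < 0.0001)
presumes two-sided p-values. Normality is assessed per group by the
D'Agostino–Pearson omnibus test ($K^2 = Z(g_1)^2 + Z(g_2)^2$ against
$\chi^2_2$, using the standard D'Agostino 1970 skewness and
Anscombe–Glynn 1983 kurtosis z-transforms; it requires $n \ge 20$).
Normality failures are reported as flags but do not alter the test —
the t-test is run regardless, and the flags let the reader judge.
No multiple-testing correction is applied by default across the twelve
parameters; Bonferroni and Holm adjustments are available via
`shgConfig(adjust =)`. Tiles are treated as independent replicates;
when several tiles come from one specimen this overstates the
effective sample size, a limitation of the design rather than of the
implementation.

## The synthetic fiber generator

`generateFiberImage()` renders fibers as random-walk polylines: each
fiber draws a heading from a von Mises distribution (mean
`orientationMu`, concentration `orientationKappa`; $\kappa = 0$ is
uniform), wanders by Gaussian per-step jitter (`curvatureJitter`,
degrees per half-pixel step), has log-normal length and fixed stamp
width and intensity. The stamped field is blurred by a Gaussian PSF,
offset by a detector background, degraded by additive Gaussian noise
and clipped to bit depth. Additive Gaussian noise (rather than Poisson)
reflects PMT detection at these signal levels and is simpler to seed
reproducibly; a background offset of 20 with noise SD 6 keeps the noise
floor clear of the zero-clipping rail, so the intensity histogram of an
empty field stays a clean Gaussian bump rather than acquiring a
spurious zero-bin spike.

The two class presets encode the qualitative stromal contrast, scaled
to the 512×512 default tile:

| preset | fibers | mean length | width | κ | intensity |
|---|---|---|---|---|---|
| invasion | 120 | 200 px | 3 px | 6 | 170 |
| pseudoinvasion | 45 | 60 px | 2 px | 0.5 | 140 |

All preset numbers are package conventions, chosen once to look like
plausible SHG fields of desmoplastic vs fibro-muscular stroma; the
invasion preset has more, longer and more aligned fibers by
construction. `generateCohort()` derives per-tile seeds from a master
seed and jitters fiber count and mean length by ±15%, concentration by
±20% and intensity by ±10%, and draws each tile's mean direction
uniformly over 180° (each field has its own tumor axis), creating
within-class variance. Generation is deterministic: identical
(config, seed) pairs give pixel-identical tiles, and the generator
restores the caller's RNG state.

What the generator does *not* emulate: spatially correlated fiber
bundling (fascicle clustering), SHG speckle and coherence effects,
intensity falloff across the field, glandular dark regions, and
within-tile density gradients. Passing tests on these surrogates
therefore demonstrate that the measurement chain recovers planted
statistical structure and that the statistical stage is calibrated —
not that any particular effect size will be observed on real tissue.

## Validation design and problem sizes

The test suite validates each stage against independent brute-force
oracles (exhaustive Triangle search, nested-loop GLCM and box counts,
literal moment loops, Monte-Carlo permutation p-values) and known
closed forms (checkerboard GLCM, filled square $D=2$, line $D=1$,
depth-5 Sierpinski carpet $D = \log 8/\log 3$). End-to-end checks use
cohorts of 88 invasion-like and 65 pseudoinvasion-like 512×512 tiles —
the study-scale configuration — and require at least 11 of the 12
parameters to separate at p < 0.05. Planted-parameter recovery uses
256×256 tiles (20 per concentration level); null calibration uses 200
replicate pairs of n = 12 cohorts of 64×64 tiles, sizes chosen to
exercise the full chain at statistically meaningful scale while a
complete run stays comfortably on a laptop. At very small cohort sizes
(n ≲ 8) the t-test becomes mildly anticonservative for skewness and
kurtosis, whose per-tile sampling distributions are themselves skewed;
calibration is restored by n ≈ 12 and is a non-issue at study scale.

## Known limitations

* The orientation index measures spectral anisotropy of the whole
  tile; it cannot distinguish one aligned population from two crossed
  ones, and it saturates below 1 for curved fibers (above).
* The Triangle threshold presumes a dominant background mode with a
  bright tail; histograms without a bright tail (empty or saturated
  tiles) are rejected and propagate `NA` sentinels.
* Box-count dimension on a thresholded natural image is
  scale-range-dependent; the reported $D$ is tied to the documented
  power-of-two ladder and grid anchoring.
* Group comparison treats tiles as independent; hierarchical designs
  (tiles within specimens) need mixed models outside this package's
  scope.
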