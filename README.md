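# collagenSHG

Quantitative analysis of fibrillar collagen architecture in second
harmonic generation (SHG) microscopy images.

In colorectal pathology, distinguishing true submucosal invasion in a
malignant polyp from *pseudoinvasion* (benign epithelial misplacement)
is a recurring diagnostic challenge. The stroma differs between the two:
invasive fronts mount a desmoplastic reaction — dense, long, partially
aligned collagen fascicles — while pseudoinvasion shows a sparser
fibro-muscular reaction of short, randomly oriented fibers. SHG
microscopy images fibrillar collagen directly, and texture analysis of
SHG tiles turns that architectural difference into numbers.

This package is for microscopists and image analysts who have grayscale
SHG tiles (8- or 16-bit TIFF/PNG) and want a reproducible per-tile
parameter set plus a two-group statistical comparison, with every
methodological convention explicit and swappable.

## The twelve parameters

Per tile (all pixels, no background exclusion):

* **First-order histogram statistics** — mean, population standard
  deviation, skewness g₁ = m₃/m₂^{3/2}, excess kurtosis
  g₂ = m₄/m₂² − 3.
* **TC-ratio** — fraction of pixels whose intensity strictly surpasses
  the Triangle automatic threshold (Zack's geometric construction on
  the 256-bin histogram); a collagen-density proxy.
* **GLCM texture features** — gray-level co-occurrence matrix at pixel
  distance 1, symmetrized and normalized, averaged over the four
  directions (0°, 45°, 90°, 135°): contrast Σp(i,j)(i−j)², homogeneity
  Σp(i,j)/(1+(i−j)²), energy Σp(i,j)², entropy −Σp log₂ p, and
  correlation Σ(i−μᵢ)(j−μⱼ)p(i,j)/(σᵢσⱼ).
* **Orientation index** — the centered log-power FFT spectrum is
  binarized by an automatic threshold (DC leakage cross masked), an
  ellipse is fitted to the foreground by second central moments, and
  N = 1 − S/L from the minor/major semi-axes: 0 for randomly oriented
  fibers, 1 for perfectly aligned ones.
* **Fractal dimension** — box-counting dimension of the
  Triangle-thresholded mask over a power-of-two size ladder.

Two groups of tiles are compared per parameter with the unpaired
Student's t-test (two-sided, pooled variance; Welch optional), with
D'Agostino–Pearson normality flags, t-based 95% confidence intervals
and star significance tiers (p < 0.05 `*` … p < 0.0001 `****`).

A built-in synthetic collagen-fiber generator (von Mises fiber
orientations, log-normal lengths, random-walk curvature, Gaussian PSF
and detector noise) plants known structure so the entire chain is
testable without any image download.

## Worked example

```r
library(collagenSHG)

img <- generateFiberImage(classPreset("invasion", imageSize = 256), seed = 7)
img
#> SHGImage 'synthetic_7': 256 x 256, 8-bit
#>   intensity range [0, 201], mean 39.84
round(measureImage(img), 4)
#>              mean                sd          skewness          kurtosis
#>           39.8423           43.2662            2.0599            2.9500
#>          tc_ratio          contrast       homogeneity            energy
#>            0.2061          323.8946            0.1106            0.0012
#>           entropy       correlation orientation_index fractal_dimension
#>           11.0145            0.9138            0.2701            1.5600
```

The tile covers about a fifth of its area with collagen above the
Triangle threshold (`tc_ratio` 0.21), is right-skewed (bright sparse
fibers over a dark background), and shows partial fiber alignment
(`orientation_index` 0.27).

Comparing two small synthetic cohorts:

```r
inv <- generateCohort(classPreset("invasion", 256), 10, masterSeed = 1)
psi <- generateCohort(classPreset("pseudoinvasion", 256), 10, masterSeed = 2)
cmp <- compareGroups(measureImages(inv), measureImages(psi))
attr(cmp, "n_significant")
#> [1] 11
```

Eleven of the twelve parameters already separate the two stromal
phenotypes at n = 10 per group; the invasion-like cohort has the higher
mean intensity, SD and TC-ratio, the pseudoinvasion-like cohort the
higher skewness and kurtosis.

For shell use, `inst/cli/shgquant.R` wraps the same functions:

```sh
Rscript inst/cli/shgquant.R simulate --preset invasion --n 88 --seed 1 --outdir inv/
Rscript inst/cli/shgquant.R measure inv/*.tif --out inv.csv
Rscript inst/cli/shgquant.R compare inv.csv psi.csv --out comparison.csv
```

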