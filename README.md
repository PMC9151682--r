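# msmeal

Classification of plant species from visible–near-infrared (vis-NIR)
reflectance spectra when labeled samples are scarce. `msmeal` is built
for the close-range grassland-survey setting: a line-scanning imaging
spectrometer yields one mean reflectance spectrum per grass patch
(here 125 bands over 400–1000 nm), species labels require a botanist at
the plot, and the question is how much accuracy a budget of ~100 labels
out of 750 samples can buy.

The package couples two stages:

**MSM — multivariate smooth mapping.** Multiplicative scatter
correction (MSC) fits each spectrum as an affine image of the training
mean reference, `x ≈ a + b·ref`, and inverts it, `(x − a)/b`; a
weighted moving window (width `2n + 1`, default 5) then suppresses
band-wise noise. The corrected spectra are embedded by Isomap: a k-NN
graph, all-pairs geodesic distances `D_G`, and classical MDS
coordinates `Y = V_Z F_Z^{1/2}` from the eigendecomposition of
`−½ H D_G² H`, with `Z` chosen by the reconstruction RMSE over
`Z = 1…20`. Test spectra enter through a Nyström out-of-sample
extension — nothing is refitted on test data.

**EAL — extreme active learning.** Pool-based active learning around a
from-scratch second-order gradient-boosted tree classifier (softmax
multiclass; leaf weights `w* = −G/(H + λ)`, exact greedy splits with
gain `½[G_L²/(H_L+λ) + G_R²/(H_R+λ) − G²/(H+λ)] − γ`). From 52 initial
labels, each of 5 iterations queries the 12 least-confident pool
samples (`1 − max_c p_c`), refits, and evaluates on a held-out 30%
test split. Entropy and random querying, a logistic-regression AL
baseline, and passive random-forest/decision-tree comparators are
included, plus confusion-matrix metrics (OA, Cohen's kappa, macro
precision/recall/F1).

Field campaigns of this kind rarely allow their data to be
redistributed, so the package ships a synthetic generator that
reproduces the shape and phenomenology of such a dataset (15 species ×
50 samples, shared spectral landmark positions, class-specific
amplitudes, affine scatter + noise); every result below is reproducible
from a seed. See
`vignettes/msmeal-methods.Rmd` for the model details, parameter
defaults and known limitations.

## Worked example

```r
library(msmeal)

spectra <- simulateGrassBenchmark(seed = 42)   # 750 x 125 labeled spectra
spectra
#> SpectraSet: 750 samples x 125 bands (400.0-1000.0 nm)
#>   labels: 15 classes

config <- pipelineConfig(seed = 42)
run <- runPipeline(spectra, config)    # MSC + smoothing + Isomap + EAL
finalReport(run)
#> MetricsReport (15 classes, 225 samples)
#>   OA 0.9422 | kappa 0.9381 | macro P 0.9662 R 0.9422 F1 0.9321

length(run@labeledIdx)
#> [1] 112
sapply(run@history, function(h) h$report@oa)
#> [1] 0.569 0.809 0.924 0.933 0.942
```

Reading: starting from 52 labeled spectra (one of each species
guaranteed) the model reaches 94% overall accuracy on the 225 held-out
samples after spending its 60-query budget — 112 labels in total, 15%
of the dataset. The per-iteration trace shows most of the gain arriving
with the first two query batches. `runBenchmark(config)` reproduces the
full method grid (MSC / smoothing / MS, each with and without Isomap,
and EAL vs logistic AL vs RF vs DT at matched label counts), and
`inst/cli/msmeal` exposes the stages as shell subcommands
(`simulate | preprocess | embed | train | evaluate | benchmark`).

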