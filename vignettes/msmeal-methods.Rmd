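---
title: "Methods: spectral reconstruction and extreme active learning for grass spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral reconstruction and extreme active learning for grass spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msmeal)
```

## The problem

Close-range visible–near-infrared (vis-NIR) hyperspectral imaging can
separate grass species that look identical to broadband sensors, but
labeled spectra are expensive: every label requires a botanist at the
plot. `msmeal` implements a classification pipeline built for that
regime — 15 species, 125 bands over 400–1000 nm, and a labeling budget
of ~100 samples out of 750:

1. **MS preprocessing** — multiplicative scatter correction (MSC)
   followed by weighted moving-window smoothing;
2. **Isomap spectral reconstruction** — a geodesic (manifold) embedding
   of the preprocessed spectra into a few components chosen by
   reconstruction RMSE;
3. **EAL** — pool-based active learning with least-confidence querying
   around a second-order gradient-boosted-tree classifier.

## The MS stage

Field reflectance spectra carry additive baseline shifts and
multiplicative gain distortions (uneven canopy height, illumination,
shadow) on top of band-wise noise. MSC models each spectrum as an affine
image of a reference spectrum, `x ≈ a + b·ref`, estimates `(a, b)` by
ordinary least squares across bands, and inverts the fit:
`x_corrected = (x − a) / b`. The reference is the per-band mean of the
*training* set; held-out spectra are always corrected against the stored
training reference (`applyMSTransform()`), never their own mean, so no
test information leaks into preprocessing.

Smoothing replaces band `k` by a normalized weighted mean over the
window `k−n … k+n`. Defaults: half width `n = 2` (window 5) and uniform
weights `1/(2n+1)`; triangular weights are selectable. At the spectrum
ends the window *shrinks and renormalizes* rather than padding — no
reflectance is invented beyond the measured 400/1000 nm limits, and
constants are preserved everywhere. Uniform smoothing of i.i.d. noise
divides its variance by `2n + 1`, the package's test for the smoothing
operator.

Degenerate inputs: a zero-variance reference and per-sample slopes below
`1e-12` raise errors naming the offending sample — silently dividing by
a near-zero slope would produce arbitrarily large corrected values.

## Isomap reconstruction

The preprocessed spectra are assumed to lie near a low-dimensional
manifold. The embedding is classical Isomap:

* a k-nearest-neighbor graph (default `k = 10`, symmetrized by union,
  distance ties broken toward the smaller index, zero distances floored
  at `1e-12` so edge weights stay positive);
* all-pairs shortest-path ("geodesic") distances `D_G` along the graph
  (Dijkstra per source, via igraph);
* classical MDS: eigendecomposition of `B = −½ H D_G² H`, coordinates
  `Y = V_Z F_Z^{1/2}`, eigenvector signs fixed so each column's
  largest-magnitude entry is positive.

Negative eigenvalues of `B` (geodesic matrices need not be Euclidean)
are clipped to zero for the coordinates and their count is reported.
Disconnected graphs raise an error by default; `onDisconnect =
"bridge"` instead joins components through their single shortest
inter-component Euclidean link, because silently imputing infinite
distances would corrupt the MDS step.

**Dimension choice.** `reconstructionRMSE(model, Z)` is the
root-mean-square discrepancy over all pairs between `D_G[i, j]` and the
embedded Euclidean distance at `Z` components; `selectComponents()`
scans `Z = 1…20` and returns the smallest `Z` within `1e-8` of the
curve's minimum. The tolerance matters: on exactly embeddable data the
curve's tail differs only by `~1e-16` floating-point noise, and a bare
argmin would report an arbitrary large `Z`. Note the RMSE definition
(geodesic vs embedded distances) is this package's choice; the quantity
is scale-dependent, so its absolute values are not comparable across
preprocessing variants.

**Out-of-sample points** (test spectra) are embedded by a Nyström
extension: geodesics from a new point are routed through its `k`
nearest training neighbors, then projected onto the stored eigenbasis.
A new point that coincides with a training point reproduces that
point's training coordinates exactly, which anchors the method's
self-consistency tests. The embedding is fitted once on the training
partition before the active-learning loop begins, not refitted per
iteration: refitting would change the feature space under the
classifier between iterations and couples two sources of variance the
experiments want separated.

## The boosted-tree classifier

The learner is a from-scratch second-order gradient-boosted tree
ensemble with softmax multiclass output (one tree per class per round).
Per boosting round the multiclass cross-entropy is expanded to second
order; with `g_i, h_i` the first/second derivatives and an L2 leaf
penalty `λ` plus a per-leaf penalty `γ`, the optimal leaf weight is
`w* = −G/(H + λ)` and the split gain is

```
gain = 1/2 [ G_L²/(H_L+λ) + G_R²/(H_R+λ) − (G_L+G_R)²/(H_L+H_R+λ) ] − γ
```

Split finding is exact greedy over the sorted unique values of each
candidate feature (no histogram approximation — datasets here are
hundreds of rows, and exactness lets tests compare against exhaustive
enumeration). Ties prefer the lower feature index, then the lower
threshold. A split must have positive gain and both children must meet
the minimum Hessian sum (`minChildWeight`, the standard reading).

Defaults (160 rounds, depth 5, `η = 0.1`, `λ = 1`, `minChildWeight =
1`, row/column subsampling 0.6) are the shipped reference
configuration, grid-search-tuned for this class of task. The raw base
score is 0 for all classes (uniform
prior). Subsampling draws from a private RNG stream seeded by the
ensemble seed only, so equal seeds give bit-identical ensembles. The
recorded `objectiveTrace` is the per-round regularized objective
(training loss plus the penalties of that round's trees); in
full-sample mode it is non-increasing, which the suite asserts. A
`squarederror` objective is included for single-output regression
checks of the tree mechanics.

One practical caveat the experiments surface: with softmax Hessians
`h = p(1−p) ≤ 1/4`, `minChildWeight = 1` requires roughly ≥ 5 samples
per child early in training, so on very small labeled pools (tens of
samples) trees may refuse to split and probabilities stay near uniform
until the pool grows.

## The active-learning protocol

`initPools()` draws a stratified 30% test split, then 52 initial labels
(at least one per class) from the remainder; the other 473 samples form
the unlabeled pool (750 = 52 + 473 + 225 under the defaults). Each of
5 iterations scores the pool with the current model, moves the 12 most
uncertain samples — `batch = budget 60 / 5` iterations, equal batches —
with their hidden true labels into the labeled set (a simulated,
error-free annotator), refits, and evaluates on the held-out test set.
Uncertainty is least confidence `1 − max_c p_c` by default; entropy and
random querying are available. Score ties break toward the lowest pool
index, deterministically. Evaluation always uses the fixed test split,
never pool samples, and a queried sample never returns to the pool.

`runComparison()` reproduces the comparison shape of the underlying
experiment: active EAL and logistic-regression AL (via `nnet::multinom`)
run the full protocol; passive random forest and decision tree are
fitted once on a random labeled set of the same final size, sharing the
pools and test split within each replicate run. Replicate runs use
explicit derived seeds so "average of 5 runs" is reproducible. The
rpart baseline uses `minsplit = 4` (the rpart default, 20, would refuse
any split on small seed pools).

## The synthetic benchmark

Field campaigns of this kind usually cannot redistribute their data, so
the package ships a generator that emulates the phenomenology of such a
dataset (15 grass species × 50 samples, 125 bands). Each class is a smooth vegetation-like
base curve sharing fixed landmark *positions* — green-reflectance bump
at 550 nm, chlorophyll absorption trough at 680 nm, red-edge rise
centered at 715 nm, NIR plateau, water-absorption dip at 970 nm — with
class-specific *amplitudes* (visible floor 0.03–0.08, green bump
0.04–0.10, trough depth 0.025–0.06, NIR level 0.32–0.60, red-edge width
15–22 nm, dip depth 0.02–0.10). The width floor of 15 nm keeps the
red-edge rise below a 0.05 per-band smoothness bound on the 4.8 nm
grid, and the amplitude ranges guarantee the 680 nm trough is not
swamped by the red-edge tail, so every generated class shows the full
landmark set.

Each sample is `a + b·base + ε` with `a ~ N(0, 0.01)`,
`b ~ U(0.85, 1.15)` and per-band `ε ~ N(0, 0.005)` — exactly the affine
distortion family MSC inverts, which makes the MSC tests analytic
(recovery to `1e-10`). With these defaults a passively trained
classifier given *all* training labels reaches OA 1.0 on the MSM
features, i.e. end-to-end accuracy checks exercise the machinery, not a
hard generator.

What the generator does **not** emulate: residual within-class shape
variability that survives scatter correction (real species overlap even
at full labels), radiative-transfer leaf optics, spatially correlated
noise, or label noise. Passing end-to-end tests therefore demonstrate
the pipeline's mechanics and bookkeeping, not field-level accuracy.

## What the benchmark shows about querying strategies

On this benchmark, least-confidence querying does **not** dominate
random querying: across seeds both reach mean final OA ≈ 0.96–0.97 and
their difference is within run-to-run noise (random is often slightly
ahead). Two effects drive this, both visible in the query logs. First,
after MS + Isomap the classes are nearly separable, so random sampling
reaches the accuracy ceiling with ~100 labels and leaves uncertainty
sampling no headroom. Second, with batch size 12 and no diversity term
(out of scope here), least confidence spends entire batches on a single
confused class — near-tied scores collapse onto the deterministic
lowest-index tie-break — while random querying covers all 15 classes
quickly. This is the familiar batch-mode pathology of pure uncertainty
sampling and should be kept in mind when reading the comparison tables;
the preprocessing comparison (MS + Isomap vs raw spectra, ~0.96 vs
~0.59 OA at 112 labels) is the robust effect on this benchmark.

## Numerical and design choices

* Spectra CSV: `sample_id,label,<wavelength columns>`; reflectance at
  17 and wavelengths at 17 significant digits, so `read(write(x))` is
  bit-exact.
* ENVI support is a deliberate minimal subset — BIL interleave, data
  types 4 (float32) and 12 (uint16), header offset, optional wavelength
  block; region means are plain per-band arithmetic means over mask
  pixels.
* A single global seed derives every stage seed (generator = seed,
  sampling = seed + 1000, pools/AL = seed + 2000, refits = AL seed +
  iteration); changing the output directory changes no numeric result.
* Problem sizes in the test suite: module tests run on small fixtures
  (tens of samples, ≤ 40 bands); end-to-end checks run the full
  750 × 125 benchmark over 5 seeds, the size at which the protocol's
  pool arithmetic (52/473/225) is exact.

## Limitations

* The geodesic RMSE criterion tends to select the largest candidate
  dimension on data whose eigenspectrum decays slowly; the `1e-8` tie
  tolerance only guards the exactly-embeddable case.
* The Nyström extension assumes new points lie on the training
  manifold; far-off-manifold points are projected anyway.
* The boosted learner's probabilities are uncalibrated; uncertainty
  rankings inherit leaf-induced ties on small training sets.
* No batch-diversity querying, BALD, or committee strategies; the
  simulated annotator is error-free by default (`labelNoise` in
  `runEAL()` flips queried labels to a random wrong class at the given
  rate).
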