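---
title: "Hyperspectral calibration of total free amino acids in tea processing"
author: "tenchaHSI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hyperspectral calibration of total free amino acids in tea processing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tenchaHSI)
```

## The problem

Total free amino acid content (TFAA, expressed as percent of dry mass) is a
key quality marker for Tencha, the shaded, steamed and dried tea leaf that is
milled into matcha. TFAA is conventionally measured by the ninhydrin
colorimetric assay, which is destructive and slow; visible/near-infrared
hyperspectral imaging (VNIR-HSI, 400--1000 nm) offers a non-destructive
alternative that can follow the leaf through the processing line —
fresh-leaf spreading (FLS), steaming fixation (SF) and hot-air drying (HD) —
and can render a pixel-wise concentration map of each leaf.

`tenchaHSI` implements the complete calibration workflow: reflectance
calibration of raw cubes against whiteboard and dark-current references,
spectral pretreatment, SPXY sample-set partitioning, CARS and VISSA
wavelength selection, PLSR and LS-SVR regression with cross-validated
tuning, RPD-based evaluation tables, and pixel-wise mapping. Because the
kind of leaf-level dataset such a study rests on is rarely public, the
package also ships a seedable synthetic-data generator that emulates the
study design end to end, so every stage is testable against known ground
truth.

## The data model

The central container is the `CalibrationSet`, a `SummarizedExperiment`
whose assay holds reflectance with rows = spectral channels (with
`wavelength_nm` in `rowData`) and columns = samples (with step, batch,
replicate and reference TFAA in `colData`). Subsetting rows trims bands and
subsetting columns selects samples, with all metadata kept aligned.

```{r}
design <- studyDesign()      # 3 steps x 30 batches x 3 replicates, 951 channels
ds <- simulateTeaSpectra(design, seed = 1)
calibration(ds)
```

## The synthetic-data generator

The generator draws per-sample TFAA from per-step normal distributions and
maps composition to reflectance through Beer--Lambert-style exponential
attenuation of a smooth envelope,

$$ r(\lambda) = \mathrm{clip}_{(0,1]}\Big\{\big[a\,
   e^{-\sum_k c_k\,\mathrm{profile}_k(\lambda)} +
   \mathrm{baseline}(\lambda)\big](1+\mathrm{slope}) + \mathrm{offset} +
   \varepsilon\Big\}, $$

with component absorption profiles built from Gaussian bands: an analyte
profile with the O--H first-overtone band at 947 nm and an N--H band at
1000 nm, a chlorophyll-like pigment absorbing in the blue and red
(620--780 nm) but only weakly in the green (490--560 nm), and a water
band near 970 nm. This produces the dual reflectance peaks at 500--600 nm
and 750--950 nm familiar from leaf spectra. Exponential (rather than purely
linear) mixing was chosen deliberately: it gives the pretreatments real
scatter and curvature to remove while keeping reflectance locally linear in
TFAA, so that a linear calibration can succeed — which is the regime the
workflow addresses.

Defaults encode the study conditions: 270 samples (3 × 30 × 3), TFAA
concentrated around 4 % dry mass with a slight dip (3.8 %) at the middle
step and within-step sd 0.5 % (the magnitudes of the between-step
difference and the within-step spread are not published; these values encode
"approximately 4, with only a slight difference at the second step" and are
config-exposed rather than claims about real data), multiplicative scatter
(slope sd 0.03, offset sd 0.01), quadratic baseline drift (coefficient sd
0.005), additive reflectance noise (sd 0.002), and 5 % relative jitter on
the pigment and water coefficients to emulate composition variability.
Pigment absorption rises along the processing line (factors 1 / 1.05 /
1.15), reflecting the deepening leaf colour.

Ground truth for selector validation is *planted*: the channels where the
analyte profile reaches at least half its maximum. With every stochastic
term off, absorbance $-\log r$ at a planted channel is exactly linear in
TFAA ($R^2 = 1$ to machine precision); on the reflectance scale the
relationship is locally linear ($R^2 > 0.999$).

What the generator does **not** emulate: spatial texture within a leaf,
moisture kinetics across processing, wavelength-dependent instrument
response drift, and real between-batch covariance structure. Passing tests
therefore demonstrate that the algorithms are implemented correctly and
behave sensibly under study-shaped conditions — not that any particular
accuracy would be attained on real leaf spectra.

### The selector-validation fixture

`simulateSelectorFixture()` is a compact 100-channel fixture for validating
wavelength selectors against known truth. Two design points matter:

* **TFAA is a total.** It is modelled as the sum of five amino-acid-like
  sub-components, each recorded by exactly one channel with its own
  semi-independently drawn concentration. A single-component analyte would
  make all its channels perfectly collinear — one channel then suffices for
  a perfect fit and *no* selector could be expected to recover all five, so
  recovery would be meaningless. With a total over sub-components, every
  planted channel is individually necessary.
* **A sensor-noise floor (sd 0.001) stays on.** The nuisance structure
  (scatter, baseline, pigment/water blocks) is low-rank; with strictly zero
  noise the spectral matrix is rank-deficient, regression coefficients are
  non-identifiable, and near-zero-variance flank channels become noise-free
  collinear proxies that attract arbitrarily large cancelling coefficients.
  "Noise-free" in the validation sense means no scatter or baseline and no
  measurement noise *worth speaking of*; composition variability between
  samples is retained, since without it irrelevant channels are constant
  and all selection paths tie trivially.

## Pretreatments

The four pretreatments — multiplicative scatter correction (MSC), mean
centring (CT), Savitzky--Golay first derivative (D1) and Savitzky--Golay
smoothing (SG) — are implemented as fit-on-calibration / apply-anywhere
transforms (`pretreatment()`, `fitPretreatment()`, `applyPretreatment()`).
MSC's reference spectrum and CT's channel means are learned from
calibration rows only and then applied unchanged to prediction rows and to
map pixels, which rules out leakage and guarantees pixel/tabular
consistency. Windows and polynomial orders are not published for this kind
of workflow; the defaults (SG: window 11, order 2; D1: window 7, order 2,
scaled per nm) are common chemometrics practice and are config-exposed. D1
is a Savitzky--Golay derivative rather than simple differencing for noise
robustness, and is applied standalone (not on pre-smoothed spectra).

## Sample-set partitioning

`spxySplit()` implements SPXY: Kennard--Stone greedy max--min selection
under the joint distance
$d_{ij} = \lVert x_i-x_j\rVert_2/\max d_X + |y_i-y_j|/\max d_y$ (the
additive form of the SPXY literature). The train size is
$\lceil 0.75\,n\rceil$, giving 203/67 on 270 samples at the 3:1 ratio. Ties
break on the lowest original row index, so the split is fully
deterministic; distances are computed on raw trimmed spectra, before any
pretreatment comparison, so all models for one process type share one
split. The comprehensive-process (CP) model splits within each processing
step and unions the index sets, so every step contributes proportionally.

## Wavelength selection

**CARS** (`carsSelect()`): per Monte-Carlo iteration an 80 % row subset is
drawn, a PLSR is fitted on the currently retained channels, and its
absolute regression coefficients become selection weights. An exponentially
decreasing schedule ($r_1 = 1$, $r_N = 2/p$) forces retention of the top
$\lceil r_i p\rceil$ channels; adaptive reweighted sampling — $p$ weighted
draws with replacement, a channel surviving if drawn at least once —
further thins negligible-weight channels. Each iteration records the
k-fold RMSECV (5 folds by default, N = 65 iterations) of a PLSR on the
retained set. Two numerical choices deserve note:

* The PLS component count inside CARS is chosen **once** by CV (capped at
  10) rather than always using the cap: surplus components fit CV noise and
  place large cancelling coefficients on collinear nuisance channels,
  corrupting the weights.
* The returned iteration follows a **one-standard-error parsimony rule** by
  default: the sparsest (latest) iteration whose RMSECV lies within one
  fold-to-fold standard error of the minimum. On data where the trace is
  flat within CV noise over a wide band-count range, the strict argmin
  lands arbitrarily among statistically tied iterations and tends to return
  junk-inflated early sets. `rule = "min"` restores the strict first
  argmin.

**VISSA** (`vissaSelect()`): per-channel inclusion weights start at 0.5;
each iteration draws sub-models by weighted binary matrix sampling (column
$j$ holds exactly $\mathrm{round}(w_j \cdot n_\mathrm{sub})$ ones,
independently shuffled), scores each sub-model by k-fold PLSR RMSECV, and
updates each weight to its channel's inclusion frequency among the best
5 % of sub-models — gradually shrinking the variable space. The
best-sub-model RMSECV typically falls to a minimum and then rises again as
relevant channels begin to be discarded, so iteration stops once the
running minimum has not improved for `patience` (5) iterations, and the
channel combination of the minimum-RMSECV iteration is returned (the
channels whose weights converged to 1 there). Sub-model counts of a few
hundred are sufficient at desk scale; 1000 is the default for
study-scale runs.

## Regression models

**PLSR** is a hand-implemented SIMPLS (successive deflation of the X--y
cross-covariance), deterministic, centred on the training rows; it agrees
with an independent PLS implementation to machine precision and collapses
to OLS at full rank. The number of latent variables is chosen by 10-fold
CV (contiguous folds after a seeded shuffle; smallest nLV on ties). One
fold assignment is shared across all pretreatment/selector/regressor
comparisons within a process so that differences reflect methods, not
folds.

**LS-SVR** solves the single linear KKT system
$[[0, \mathbf 1^\top],[\mathbf 1, K + I/C]]\,[b;\alpha] = [0;y]$ with an
RBF kernel; hyperparameters come from an exhaustive grid search
($\gamma \in 2^{-15..3}$, $C \in 2^{-5..15}$, step $2^2$ — the customary
powers-of-two ranges) under the same shared folds, ties resolved toward
smaller $C$ then smaller $\gamma$. X is centred only (matching the PLSR
treatment). A linear-kernel mode exists purely as a test oracle (large $C$
reproduces OLS).

## Evaluation

`rSquared()`, `rmse()` and `rpd()` implement the standard definitions;
RPD = SD(prediction-set reference)/RMSEP with the $n-1$ denominator. The
printed-form variant of RPD found in parts of the applied literature
(a ratio of predicted-deviation sums) is available as
`rpd(..., method = "printed")` for comparison but is not the default, as
its operational definition is ambiguous. Credibility classes: RPD < 1.4
unreliable, 1.4--2.0 (inclusive) credible, > 2.0 highly credible. For
mean-unbiased predictions the identity
$RPD^2\,(1-R^2)\,(n-1)/n = 1$ links the three metrics and is asserted in
the tests. `buildReport()` assembles one row per process ×
pretreatment × selector × regressor, normalises the occasional "ST" label
to SF, and flags the best row per process (max $R_p^2$, ties by RPD).

## Mapping

`predictMap()` applies trim → fitted pretreatment → selected channels →
model to every foreground pixel (`maskBackground()`: mean reflectance over
750--950 nm above 0.15, which separates leaf from the 0.02 background
filler). MSC at pixel level uses the calibration reference spectrum, so a
uniform cube reproduces the tabular prediction exactly. The colour scale
defaults to the 2nd--98th percentile of foreground values for robustness
to outlier pixels; `renderPseudocolor()` writes deterministic PNG bytes.

## Numerical and scale choices

* Band trim: which eight edge channels were dropped from 951 to 943 is not
  published; a symmetric 4 + 4 trim is the default (edge channels carry the
  sensor-noise concentration) and is config-exposed.
* Reflectance outside [0, 1] after calibration is retained with a warning
  rather than clipped, to avoid biasing pretreatments.
* The ninhydrin formula takes the dry-matter percentage as a fraction
  (m/100); at protocol values (0.25 g specimen, 1 mL volumes) this lands at
  the plausible ~4 % TFAA scale, whereas a literal percent reading is off
  by a factor of 100.
* Desk-scale problem sizes: the test suite runs the full 270 × 943 fixture
  for the pipeline checks, 100-channel/80-sample fixtures with 200
  sub-models for selector validation, and a 6-batch matrix for the
  determinism check. These sizes were chosen so the whole suite completes
  in a couple of minutes while exercising every code path at study shape.

## Known limitations

Wet-chemistry and imaging are linked only through the generator (no real
paired dataset ships with the package); LS-SVR stores the full training
kernel, so very large calibration sets would need low-rank approximation;
the ENVI dialect is pinned (BSQ float32 little-endian, BIL accepted on
read) and compressed variants are out of scope; and selector validation on
synthetic data bounds implementation correctness, not field performance.
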