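---
title: "Rank-based shading correction: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based shading correction: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shadecor)
```

## The model and its assumptions

Brightfield whole-slide imaging acquires tiles $Y_1,\dots,Y_n$ at different
stage positions of one slide. The acquisition is modeled as

$$Y_i(k) = X_i(k)\,F(k) + D(k),$$

where $X_i$ is the tile's true content, $F$ the multiplicative flat-field
distortion at pixel $k$ (uneven illumination times static per-pixel sensor
gain), and $D$ the dark field. Because the dark field of a brightfield
camera varies by only a few intensity counts, we set $D = 0$; an optional
dark frame can still be subtracted before estimation for cameras where that
matters. Correction is plain division, $\hat X_i = Y_i / \hat F$, applied
per channel.

The estimator rests on two assumptions:

1. **Background majority.** Tissue attenuates light, so background pixels
   are brighter than object pixels, and any fixed pixel is background in a
   substantial fraction of the tiles. The per-pixel descending sort then
   places (noisy copies of) $F$ in the low ranks.
2. **Sparse artifacts.** Dust, scratches and bubbles are bright or
   localized and appear in a minority of tiles, so they contaminate only the
   few brightest ranks at any pixel, and they raise the local coefficient of
   variation (LCoV) of the rank images they touch.

Selection minimizes $S_r = \sum_k \sigma_r(k)/\mu_r(k)$, the image-wide sum
of the LCoV over a sliding window, independently per channel. Nothing ever
smooths the selected field: a rank image is an actual per-pixel order
statistic of the data, so the static gain pattern (fixed-pattern noise) is
retained in $\hat F$ and removed from the tiles by the division. This is the
deliberate difference from smoothness-regularized estimators, which cannot
represent the fixed pattern; the package's acceptance checks demonstrate it
by showing that mean-filtering the estimate strictly lowers its correlation
with the true field.

## Parameters that matter

* `window` (pixels, odd; default 5). Side length of the LCoV window. It
  must be larger than the fixed-pattern grain (1 px) and smaller than real
  artifacts; 5×5 satisfies both for typical 40x tiles and is the default
  throughout.
* `epsilon` (intensity units; default `1e-6 * bit_depth_max`). Guard added
  to the local mean in the LCoV denominator. The model never needs it on
  sane data (background means are far from zero), but candidate pixels can
  be 0 in pathological inputs. At `epsilon = 0` the score is exactly
  scale-invariant, which the invariance tests use.
* `search_ranks` (default all). Restricting the searched ranks trades
  completeness of the $S_r$ profile for speed on very large $n$; the
  selected model is identical whenever the restriction contains the global
  minimizer.
* `scale_mode` (default `preserve_mean`). The literal division produces
  transmittance-scale values near 1. `preserve_mean` multiplies each
  channel by the spatial mean of $\hat F$, restoring the original intensity
  scale; `raw` keeps the literal quotient. Corrected values are clipped to
  the bit depth only when written as integer files, never in memory.

## Numerical choices

Three details of $S_r$ are not forced by its definition; the package fixes
them as follows and uses the same conventions in its brute-force test
oracles:

* **Population standard deviation** (divide by the window area), the usual
  local-statistics convention.
* **Symmetric reflection at borders** (edge pixel repeated), so the sum
  runs over all $H \times W$ pixels rather than excluding a border band.
* **Global minimum of $S_r$**, with ties broken toward the smaller
  (brighter) rank, which is closer to the background-maximum ideal. A
  first-local-minimum rule was considered and rejected: with acquisition
  noise the $S_r$ curve is not guaranteed unimodal, and the global rule is
  the one that matches "fewest artifacts".

Candidate sorting is exact (a vectorized per-pixel sort), and windowed
moments are accumulated by shift-and-add of the reflected image rather than
cumulative-sum tables, avoiding catastrophic cancellation; the test suite
holds the implementation to the naive double-loop oracle at 1e-9 relative
tolerance.

## Evaluation conventions

The correction score $\Gamma$ is the single collection-wide ratio
$\sum_i |\hat X_i - X_i^{true}| \,/\, \sum_i |Y_i - X_i^{true}|$ — not a
per-tile average (per-tile ratios are available as a diagnostic attribute).
Its endpoints are identities: $\Gamma = 0$ when the corrected stack equals
ground truth and $\Gamma = 1$ when it equals the uncorrected input, and the
tests assert them exactly.

$\Gamma$ presumes commensurate intensity scales. The package's convention
is the `preserve_mean` scale on both sides: real ground truth is built by
dividing the observed tiles by the empty-zero reference field (the
per-pixel mean of empty-slide images) and rescaling by that field's channel
means (`ground_truth_from_empty()`); synthetic ground truth is the known
content rescaled by the channel means of the true field. PSNR uses
`bit_depth_max` as the peak, the standard convention for integer imagery,
and reports `Inf` for identical stacks.

An amusing exact property falls out of the construction: re-estimating the
flat field on a corrected stack selects the same rank and returns an
exactly constant field, because dividing by the rank-$r^*$ order statistic
makes the rank-$r^*$ candidate of the corrected stack equal to the channel
mean at every pixel. "Idempotence" for this estimator is therefore not
approximate; the acceptance suite bounds the deviation at 2% but observes
machine-level constancy.

## What the synthetic generator emulates — and what it does not

`make_collection()` realizes the forward model with every piece the
estimator must survive, each controlled and seeded:

* a radial cosine-squared vignette (`vignette_strength`, default 0.3; the
  noise-free corner/center ratio is `1 - strength`, giving a closed form
  the tests check);
* static per-pixel lognormal gain with mean 1 (`fixed_pattern_sd`, default
  0.02) drawn once per field — the fixed-pattern noise;
* darker elliptical objects (semi-axes 6–20 px, attenuation 0.5) at a
  Poisson density calibrated to cover ≈20% of the default 256×256 tile, so
  the background-majority assumption holds with a wide margin;
* bright bubble rings and dark dust specks stamped into the content of
  `ceiling(artifact_rate · n)` tiles (default 10%), before multiplication
  by the field, so bright artifacts surface in the brightest candidates
  exactly as slide contamination does;
* per-acquisition multiplicative noise (`photon_noise_sd`, default 0.01),
  drawn per tile — the temporal noise the method does not model — and
  sensor saturation by clamping at the bit depth.

Defaults (100 tiles of 256×256 RGB, background 200 of 255) are the
collection scale the convergence experiment uses; smaller tests rescale
`object_density` with the pixel count to keep coverage constant. What the
generator does **not** emulate: real histology texture (objects are flat
ellipses, not stained tissue), tile overlap and stage-positioning structure
(tiles are independent fields of view), chromatic or focus variation across
the slide, and additive dark current. Passing tests therefore demonstrate
the estimator's behavior under the model's own assumptions — order
statistics over background-majority stacks with sparse artifacts — not
robustness to every property of real slides.

## Degenerate inputs and error behavior

Stacks need $n \ge 2$ (sorting one tile is vacuous); a channel that is zero
in every searched candidate, a zero-mean empty-slide pixel, or a
nonpositive field pixel at correction time raise degenerate-field errors
rather than dividing by zero; an uncorrected stack that already equals
ground truth makes $\Gamma$ undefined and errors. All conditions carry
classes (`shadecor_dimension_error`, `shadecor_insufficient_stack_error`,
`shadecor_degenerate_field_error`, `shadecor_undefined_score_error`,
`shadecor_parameter_error`) that the command-line interface maps to exit
codes 1 (data) and 2 (usage).

## Reproducibility and problem sizes

Every stochastic routine takes an explicit seed. Subset draws in
`score_convergence()` derive one substream per `(m, repeat)` cell
(`seed + 1000·m + repeat`), so a cell's subset does not depend on
evaluation order, and rerunning with the same seed is bit-identical. The
test suite exercises the estimator at three scales: exhaustive oracle
comparisons on stacks up to 8×8×5, behavioral tests on 64×64 collections of
30 tiles, and the full default 100-tile 256×256 collection for the
convergence, recovery and idempotence checks — the last chosen to match the
collection size the method targets while keeping a full test run in a few
minutes on one core.

## Known limitations

The estimator needs bright background: darkfield and fluorescence stacks
(background darker than signal) violate the sorting assumption outright.
Pixels that are object-covered in nearly all tiles (dense tissue across the
whole collection) leave no background sample for any low rank, and the
selected value underestimates $F$ there. Temporal noise is not removed —
the selected rank image carries one realization of the acquisition noise —
and very small $n$ leaves visibly noisy fields; the convergence experiment
quantifies how quickly that stabilizes with $n$. Finally, the method
corrects shading within tiles; it does not blend, stitch, or normalize
color between slides.
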