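---
title: "Robust Difference Normalization: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust Difference Normalization: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rdnorm)
```

## The problem

Short-oligonucleotide expression arrays measure each transcript through a
probe set of roughly eleven 25-nt probes. The measured intensity of a probe
is not just its target's abundance: it carries an additive optical floor
from the scanner, background from non-specifically binding RNA (strongly
sequence-dependent), a multiplicative, sequence-dependent distortion of the
hybridization itself, a 3'-biased gradient from incomplete in-vitro
transcription during amplification, and spatially smooth multiplicative
distortions over the array surface (blemishes, batch-scale gradients). When
arrays are run in different batches, or few replicates are available, these
technical effects dominate the comparisons downstream analyses depend on.

`rdnorm` implements Robust Difference Normalization (RDN). Its organizing
idea is to correct *differences* in technical effects between arrays rather
than each array's absolute bias: per-array bias estimates from simplified
models are large and noisy, and subtracting them costs precision; per-array
*difference* estimates against a common reference are small and cancel
shared model error. Background is therefore not subtracted up front; it is
carried through normalization and used *inside* summarization, where it
down-weights background-dominated probes and, through backscaling, keeps
their fold changes from being blown up.

## The component model

Each probe j on array i measures, on linear scale,

    s_ij  =  O + B_j + X_j    (reference decomposition: s_j = o + b_j + x_j)

with `O` the scalar optical background, `B` non-specific binding and `X`
true signal. The pipeline (see `run_rdn()`):

1a. **Reference.** The median pseudo-array `s_ref = median_i(s_ij)`
    (`build_reference()`); every array is compared to it, avoiding a
    quadratic number of pairwise comparisons.

1b. **Reference components.** `fit_background()` robustly fits
    `log2(o + 2^tau_j(phi_bg))` to `log2 min_i(s_ij)` — the per-probe
    minimum is the closest available estimate of an only-background
    signal — and `decompose_reference()` splits `s_ref` under the
    constraint `s >= o + b`: `b_j = min(2^tau_j, max(s_j - o, 0))`, the
    remainder being `x_j >= 0`. An asymmetric weight multiplies the loss by
    `eta = 10` wherever the model *over*-predicts its target, so the
    background is deliberately under- rather than over-estimated
    (over-estimation would eat true signal). `eta = 1` gives a symmetric
    fit for bias-sensitive ("accuracy") use.

2a. **Per-array differences** (`fit_array_difference()`). For each array
    separately, the reference is distorted by the technical-difference
    model

        s_hat_ij = (o + d_i) + b_j 2^{tau_j(phi_b_i)}
                             + x_j 2^{tau_j(phi_f_i) + kappa_j(a_i)}

    — an additive optical difference `d_i`, separate background and
    foreground hybridization differences (non-specific binding hybridizes
    differently from the targeted sequence), and an amplification
    difference acting only on the true signal — and the parameters
    minimize the Huber loss of `log2 s_ij - log2 s_hat_ij`. The fitted
    technical difference `t_ij = log2 s_hat_ij - log2 s_ref_j` is then
    subtracted from the measured log2 signal
    (`apply_difference_correction()`). Log scale is used throughout
    because the corrected effects are multiplicative.

2b. **Distribution and location.** Quantile normalization onto the median
    array's distribution (`quantile_to_reference()`), then array-location
    correction (`estimate_location_field()` /
    `apply_location_correction()`), then quantile normalization again —
    quantile normalization is idempotent, so the bracketing costs nothing.
    Location residuals `eps_ij = log2(s_ij - o) - log2(median_i(s_ij) - o)`
    are computed after optical subtraction (location effects act on the
    hybridization signal, not the scanner floor), mapped to the physical
    probe grid, and smoothed by a 9 x 9 median box filter that uses only
    valid cells — empty grid positions (mismatch rows), border clipping
    and probes masked at or below the optical floor simply shrink the
    window. The corrected signal is `(s - o) 2^{-lambda} + o`.

3.  **Summarization** (`fit_probeset()` via `summarize_probesets()`). Per
    probe set, a Huber fit of

        log2 y_ij  ~  log2( o + b_j + 2^{omega + alpha_i + rho_j} )

    with mean level `omega`, per-array fold changes `alpha_i`
    (`sum_i alpha_i = 0`) and probe affinities `rho_j` (`sum_j rho_j = 0`,
    per probe set — a global zero-sum over all probes would not be
    identifiable). Because `b_j` stays inside the model, a probe whose
    true-signal share is small moves the residual little when `alpha`
    changes, so background-dominated probes automatically lose influence.
    Probes with Huber weight below 0.9 on more than one third of the
    arrays are removed worst-first, never below five retained probes, and
    the set is refitted once. Optionally (and by default) fold changes are
    backscaled:

        alpha~_ik = log2( (F_k + 2^{omega_k + alpha_ik}) / (F_k + 2^{omega_k}) )

    with `F_k = o + median_j b_j` over the retained probes — the fold
    change an observer of the *full* (background-included) signal would
    see. Backscaling strictly shrinks toward zero, monotonically in `F_k`.

## Sequence models

The hybridization effect `tau` (log2 scale, linear in its parameters) has
two parts. Part one assigns each of the 24 dinucleotides in a 25-mer a
position-dependent weight, smoothed over position by a clamped cubic
B-spline with five knot weights per dinucleotide (a full 16 x 24 weight
matrix would invite overfitting; binding affinities vary smoothly along
the probe). Part two adds smooth functions of the *count* of nucleotides
from ten sets ({A}, {C}, {G}, {T} and the six unordered pairs) within
three sequence ranges — whole probe, 5' half, 3' half — because
contributions are not additive in practice (probes with many adjoining
C/G report more signal than a linear model predicts) and non-specific
binding often involves only part of the probe. With five knots this gives
16·5 + 10·3·5 = 230 free parameters, few against the >10^5 probes of a
real array. The spline bases are partitions of unity, evaluated through
`splines::splineDesign()` with clamped uniform knots; count-spline domains
are `[0, range length]`, the position-spline domain `[1, 24]` (dinucleotide
start positions).

The amplification effect `kappa_j(a_i) = p_j . a_i` is an inner product of
a per-probe vector `p_j` — the number of occurrences of each dinucleotide
between the probe centre and the probe-set 3' end — with 16 per-array
coefficients. It captures the 3' bias left by incomplete amplification
copies, which starts at the poly-A tail; the probe-set 3' end stands in
for the (hard to locate) poly-A tail. A probe at the 3' end has an empty
window and zero effect. The sequence dependence matters: 3' regions are
A-rich, so position along the transcript and probe composition are
confounded, which is why amplification and hybridization differences are
estimated jointly in one model.

Several display equations in the source this package reconstructs were
truncated; the exact forms of the difference model, the clamping order of
the decomposition, the backscaling formula and the overlap-score
normalization are reconstructions consistent with the surrounding
derivations, and are documented as such here.

## Numerical choices

* **Robust core.** All fits are Huber M-estimates via iteratively
  reweighted least squares, weights `min(1, c sigma / |r|)` with
  `sigma = 1.4826 * median|r|` re-estimated each iteration and `c = 1.345`
  (95 percent Gaussian efficiency; the tuning constant is this package's
  choice). Nonlinear models are linearized by damped Gauss-Newton steps
  with a halving line search that never accepts a loss increase.
* **Collinearity.** Partition-of-unity bases make the hybridization design
  exactly rank-deficient (each smooth contains the constant direction), so
  every solve carries a small ridge (1e-8 of the mean diagonal; 1e-6 for
  the cold-start solve). The fitted per-probe effects are unaffected; the
  raw knot weights are only identified up to these constant directions and
  are interpreted through the per-probe `tau`.
* **Block order.** The per-array fit sweeps `d -> phi_b -> phi_f -> a`
  three times (two Gauss-Newton steps per block); iterating the whole
  normalization adds nothing noticeable, so each stage runs once.
* **Background-fit convergence**: relative parameter change below 1e-6 or
  50 iterations, warning and best iterate on non-convergence (the
  asymmetric weight switches discretely, which can keep the iterate
  jittering below the loss plateau).
* **Summarization bounds.** A probe set column whose signal sits at or
  below `o + b_j` has an unidentifiable foreground: its raw fold change
  would drift to minus infinity along a flat loss direction. Parameters are
  boxed (`omega` in [-20, 40], `alpha` in ±25, `rho` in ±15, per-step
  trust region of 4 log2) so such columns saturate instead. The backscaled
  output — the default, and the algorithm's final output — is immune: it
  reports what the full signal shows, which for a background-dominated
  column is a fold change near zero.
* **Quantile reference.** The target distribution is the per-rank median
  of the column-sorted values (the median array's distribution in the
  distributional sense). Mapping onto the sorted per-probe-median
  pseudo-array instead is *not* idempotent (rotating columns of three
  values gives constant row medians), and idempotence is what lets the
  pipeline bracket the location step with two quantile passes.
* **Ties** in quantile mapping are assigned stably in input order;
  location-residual entries at or below the optical floor are masked and
  pass through the correction unchanged; a filter window with no valid
  probe yields a zero location effect.

## The synthetic generator

`synth_generate()` mirrors the generative component model exactly: random
transcript 3' regions tiled by 11 probes (30-nt centre spacing), giving
true sequences, 3' distances and exact dinucleotide-count vectors; a
random smooth sequence background (mean 2^5, sd 1 log2) over an optical
floor of 60 units; per-array optical shifts uniform in ±15; per-array
background and foreground hybridization differences as random smooth
models of sd 0.3 and 0.5 log2; per-array dinucleotide amplification
coefficients of sd 0.004 (≈0.3 log2 per probe over typical 3' distances);
two 40 x 40 blemish blocks at +0.8 and −0.6 log2 on two arrays; and
multiplicative log-normal noise of sd 0.15 log2. The effect magnitudes
were fixed once to match the batch-scale differences real arrays display —
GC-stratified median curves separated by up to 1–2 log2 at composition
extremes, visible blemish blocks, 3'-bias profiles differing across
batches — so that a distribution-only normalization is measurably
insufficient, which is the regime the method exists for. Spike-in probe
sets follow a rotated 2-fold concentration series (each set entering the
series at a different offset), emulating a Latin-square spike-in design
with exact ground-truth fold changes of 1 log2 between consecutive groups.

What the generator does **not** emulate: probe-level cross-hybridization
networks, scanner saturation, transcript-specific amplification beyond
the dinucleotide model, non-stationary spatial noise, or annotation errors.
Passing tests on this generator therefore show the estimators invert the
effects they model, under the model's own noise assumptions — not that
real arrays contain no further structure.

Default study sizes (200 probe sets x 11 probes x 12 arrays, 10 spike
sets) keep a full pipeline run near ten seconds, so the test suite and the
acceptance script can afford paired multi-seed comparisons.

## Evaluation utilities

`roc50()` is the area under the ROC curve truncated at 50 false positives,
normalized to [0, 1]; when fewer than 50 negatives exist the truncation
point is the number of negatives, making the score coincide with the full
AUC. `spikein_roc50()` applies the spike-in protocol: for each pair of
subsequent concentration groups, probe sets are ranked by absolute fold
change (or SAM statistic) between the groups' arrays; positives are the
spike sets stepping exactly 2-fold (a step from concentration zero to the
lowest level counts), spike sets with any other step — the rotated set
restarting its series — leave the ranking; pair scores are averaged.
`sam_statistic()` is the moderated mean-difference statistic
`(mean_a - mean_b) / (s + s0)` with pooled standard error `s` and fudge
constant `s0` (median of `s` when `"auto"`). `overlap_score()` measures
agreement of per-batch top-gene lists: a gene in the top-m lists of `c` of
`|B|` batches scores `(c - 1)/(|B| - 1)` at depth m (identical lists score
1, disjoint 0 — a plain membership average would carry no information),
summed over genes and averaged over depths 1..M with normalization
`sum(1..M)`.

## Limitations

* The method assumes most genes keep similar expression across arrays (as
  does quantile normalization); global shifts of all genes are absorbed as
  technical effects.
* Raw (non-backscaled) fold changes of background-dominated probe-set
  columns are reported saturated, not as honest point estimates; use the
  backscaled default, or the `"accuracy"` output mode when absolute levels
  matter more than detection.
* Amplification distances are measured to the probe-set 3' end, not the
  poly-A tail; probe sets far from the tail keep a shared, uncorrected
  amplification component.
* The per-array difference fit needs the reference components; on data
  where nearly every probe is strongly expressed, the min-signal
  background target is contaminated and the background/foreground split
  degrades gracefully toward a foreground-only correction.
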