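# rdnorm — Robust Difference Normalization for short-oligonucleotide arrays

`rdnorm` is probe-level preprocessing for short-oligonucleotide expression
arrays (Affymetrix-style 25-mer platforms), aimed at studies with few
replicates or visible batch effects — the situations where technical
variation, not biology, dominates array comparisons.

The measured intensity of probe *j* on array *i* is modelled as three
components, `s_ij = O + B_j + X_j`: a scalar optical background *O*,
sequence-dependent non-specific binding *B*, and true signal *X*. Instead of
subtracting a per-array bias estimate up front, RDN estimates per-array
**differences** in technical effects against a median reference pseudo-array
and removes those:

```
s_hat_ij = (o + d_i) + b_j * 2^tau_j(phi_b_i) + x_j * 2^(tau_j(phi_f_i) + kappa_j(a_i))
```

with `d_i` an optical difference, `tau` a 230-parameter B-spline
hybridization model over dinucleotide positions and nucleotide counts
(fitted separately for the background and foreground components), and
`kappa_j(a_i) = p_j · a_i` a dinucleotide amplification model of the 3'
bias left by incomplete in-vitro transcription. All fits are Huber
M-estimates (IRLS). Quantile normalization and a 9×9 median-box-filter
array-location correction handle distribution and spatial effects
(`Q ∘ L ∘ Q`). Background is removed only *inside* summarization,

```
log2 y_ij  ~  log2( o + b_j + 2^(omega_k + alpha_ik + rho_j) )
```

so background-dominated probes lose influence automatically; outlier probes
(Huber weight < 0.9 on more than a third of arrays) are removed down to a
floor of five, and reported fold changes are *backscaled* —
`log2((F_k + 2^(omega+alpha)) / (F_k + 2^omega))` with `F_k` the probe-set
background level — so that probe sets measuring mostly background do not
report inflated fold changes.

The package also ships a synthetic array generator with exact ground truth
for every technical effect, and the evaluation utilities used to benchmark
normalizations: truncated ROC (`roc50()`, `spikein_roc50()`), a SAM-type
statistic, and a batch top-gene overlap score. The methods vignette
(`vignettes/rdn-methods.Rmd`) documents the model, its assumptions, and
every numerical choice.

## Worked example

Simulate a small study (60 probe sets × 11 probes × 6 arrays, 10 spike-in
sets on a rotated 2-fold concentration series, all technical effects
injected), run the full pipeline, and inspect the result:

```r
library(rdnorm)

sim <- synth_generate(synth_config(n_probesets = 60, n_arrays = 6, seed = 42))
sim$arrays
#> <rdn_arrayset> 660 probes, 60 probe sets, 6 arrays

res <- run_rdn(sim$arrays)          # rdn_config() defaults: full RDN
res
#> <rdn_expression> 60 probe sets x 6 arrays (backscaled output), 49 probes removed

glance(res)
#> # A tibble: 1 × 6
#>   n_probesets n_arrays n_probes_removed output     optical_background
#>         <int>    <int>            <int> <chr>                   <dbl>
#> 1          60        6               49 backscaled               91.5

tidy(res) |> head(4)
#> # A tibble: 4 × 6
#>   probeset_id array    omega  alpha alpha_backscaled expression
#>   <chr>       <chr>    <dbl>  <dbl>            <dbl>      <dbl>
#> 1 ps0001      array_01  7.48 -1.47            -0.778       6.70
#> 2 ps0002      array_01  7.72 -0.759           -0.476       7.24
#> 3 ps0003      array_01  7.32 -0.184           -0.110       7.21
#> 4 ps0004      array_01  7.25  0.489            0.305       7.56
```

Per probe set and array, `omega` is the log2 mean level, `alpha` the raw
log2 fold change against it, `alpha_backscaled` the background-aware fold
change, and `expression = omega + alpha_backscaled` the reported log2
expression. Against the generator's ground truth, the output fold changes
correlate at 0.941, and ranking probe sets by fold change between
consecutive spike-in concentration groups gives a truncated-ROC score of
0.988:

```r
cor(as.vector(res$alpha_backscaled), as.vector(sim$truth$alpha))
#> [1] 0.941
spikein_roc50(res$expression, sim$truth$spike_design)$score
#> [1] 0.988
```

`autoplot(res)` draws the fold-change-versus-level view;
`write_expression_table(res, "expr.tsv")` / `read_probe_table()` handle the
TSV interchange formats. A thin command-line front end is available as
`exec/rdn` (`rdn normalize`, `rdn simulate`, `rdn eval`). Ablated variants
(e.g. quantile-only) come from the stage toggles:
`run_rdn(arrays, rdn_config(optical = FALSE, hyb = FALSE, amp = FALSE,
location = FALSE))`.

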