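# pdcnet

Directed (effective) connectivity analysis for resting-state multichannel
EEG, built around multivariate autoregressive (MVAR) modelling and partial
directed coherence (PDC), with a fully seeded synthetic-cohort generator
whose ground truth every pipeline stage can be validated against.

The package is aimed at researchers studying frequency-resolved directed
interactions between brain regions — here an eight-channel default-mode
network montage (FZ, F3, F4 over medial prefrontal cortex; PZ over
posterior cingulate/precuneus; P3, P4 over lateral parietal cortex; CP5,
CP6 over supramarginal cortex) in a four-group social-anxiety severity
design — and at methodologists who want a testbed where the true directed
coupling is known.

## The model

Each epoch of the 8-channel series is modelled as an MVAR(p),

    x_t = A_1 x_{t-1} + ... + A_p x_{t-p} + e_t,   e_t ~ N(0, Σ),

and directed influence from channel *j* to channel *i* at frequency *f* is
measured by partial directed coherence,

    π_ij(f) = |Ā_ij(f)| / sqrt( Σ_k |Ā_kj(f)|² ),
    Ā(f)    = I − Σ_r A_r exp(−i 2π f r / fs),

which is normalised over each source's outflows: Σ_i π_ij(f)² = 1 at every
frequency. Spectra are averaged into the five canonical bands (delta,
theta, alpha, low beta, high beta), per-subject tensors are 8 × 8 × 5 with
zero diagonal, and the group layer provides one-way ANOVA with η², Tukey
HSD, Bonferroni correction, Lilliefors normality screening, and Pearson
correlation of connectivity with Social Interaction Anxiety Scale (SIAS)
scores.

The pipeline is: simulate (or load) recordings → artifact screening and
4-s epoching at 256 Hz → per-subject MVAR fit (AIC model order, pooled
across epochs) → PDC spectra → band-averaged tensors → group statistics.
The vignette (`vignettes/pdc-methods.Rmd`) documents the estimator choices,
including why common-average referencing and deep band-pass filtering are
kept out of the fitting path by default.

## Worked example

```r
library(pdcnet)

pl <- run_pipeline(n_per_group = 5, duration_s = 120, seed = 42)

group_summary(pl$connectivity, band = "delta")
#> # A tibble: 4 × 4
#>   group      mean      sd     n
#>   <fct>     <dbl>   <dbl> <int>
#> 1 control  0.0733 0.00554     5
#> 2 mild     0.125  0.00210     5
#> 3 moderate 0.118  0.00121     5
#> 4 severe   0.0661 0.00635     5

connectivity_anova(pl$connectivity, "delta", layout = "subject")
#> # A tibble: 1 × 8
#>   statistic df_between df_within  p_value eta_squared     n band  layout
#>       <dbl>      <dbl>     <dbl>    <dbl>       <dbl> <int> <chr> <chr>
#> 1      233.          3        16 2.07e-13       0.978    20 delta subject

sias_correlation(pl$connectivity, pl$cohort$subjects, band = "alpha")
#> # A tibble: 5 × 6
#>   group    band       r     n statistic p_value
#>   <chr>    <chr>  <dbl> <int>     <dbl>   <dbl>
#> 1 control  alpha -0.896     5    -3.49  0.0397
#> 2 mild     alpha  0.478     5     0.942 0.416
#> 3 moderate alpha -0.304     5    -0.554 0.618
#> 4 severe   alpha  0.976     5     7.74  0.00449
#> 5 pooled   alpha -0.214    20    -0.930 0.365
```

Reading the output: the delta-band group means show the designed ordering
(mild ≈ moderate above control ≈ severe) with a very large subject-level
F; the alpha-band connectivity–SIAS correlation is positive and significant
in the severe group and negative in controls, and absent in the middle
groups — the sign pattern the generator encodes. `plot_connectivity()`
draws the per-group 8 × 8 band heat-maps and `plot_sias_correlation()` the
per-group scatter plots; `export_results()` writes the manifest,
connectivity table, statistics and per-group band matrices as CSV/JSON.

A tensor for a single subject:

```r
spec <- make_group_spec("severe", seed = 1)         # calibrated ground truth
rec  <- simulate_recording(spec, 120, seed = 2)     # 8 x 30720 recording
ep   <- preprocess_recording(rec, bandpass = FALSE) # 30 clean 4-s epochs
ct   <- subject_connectivity(ep, subject_id = "S1") # 8 x 8 x 5, AIC order
ggplot2::autoplot(ct)
```

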