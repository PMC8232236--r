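---
title: "Directed connectivity from MVAR models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed connectivity from MVAR models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

pdcnet estimates directed (effective) connectivity between eight
default-mode-network (DMN) regions of interest from resting-state EEG-like
multichannel time series, and provides a synthetic-cohort generator with known
ground truth so that every stage of the pipeline can be validated against an
analytic oracle. This vignette explains the model, the generator, the
estimator, and the design decisions that were genuinely open.

## The model: MVAR and partial directed coherence

Each 8-channel epoch is modelled as a multivariate autoregression of order
$p$:

$$x_t = \sum_{r=1}^{p} A_r\, x_{t-r} + \varepsilon_t,
\qquad \varepsilon_t \sim \mathcal N(0, \Sigma),$$

where $A_r[i,j]$ is the influence of channel $j$ at lag $r$ on channel $i$.
The Fourier transform of the coefficient polynomial,
$\bar A(f) = I - \sum_r A_r e^{-i 2\pi f r / f_s}$, yields partial directed
coherence (PDC) from source $j$ to sink $i$:

$$\pi_{ij}(f) = \frac{|\bar A_{ij}(f)|}
  {\sqrt{\sum_k |\bar A_{kj}(f)|^2}}.$$

PDC is normalised over the *outflows* of each source column, so
$\sum_i \pi_{ij}^2(f) = 1$ at every frequency — an identity the test suite
checks to $10^{-10}$ on random stable models. We use the original
(unsquared) PDC; the squared variant is available via `squared = TRUE` and
preserves all orderings. Spectra are evaluated on a 0.5 Hz grid from 0 to
Nyquist and averaged into five bands — delta [1,4), theta [4,8), alpha
[8,13), low beta [13,22), high beta [22,30] Hz. The half-open convention
closes the gaps left by the conventional printed band edges (e.g. theta
"4–8" vs alpha "8–12"); only the last band includes its upper edge.

Stability (stationarity) holds iff the companion matrix of the stacked
MVAR(1) form has spectral radius below 1; `check_stability()` enforces a
$1-10^{-6}$ margin before any spectrum is computed.

## The synthetic cohort generator

No recorded data are distributed with the package; the generator defines the
study conditions. It emulates a 4-group design (control, mild, moderate,
severe social anxiety; 22 subjects per group by default) with
group-specific directed coupling:

* **Channel dynamics.** Each channel's diagonal polynomial is the product of
  two damped-oscillator AR(2) factors: a low-frequency pole near 2.5 Hz and
  an alpha pole at 10 Hz (modulus 0.93). PDC from a source peaks where the
  source's own spectrum peaks (the $|\bar A_{jj}(f)|$ in the denominator dips
  at resonance), so the sharpness of the delta pole carries the delta-band
  group contrast.
* **Coupling graphs.** Minimal directed edge sets (7–8 edges) encode the
  qualitative group structure: the precuneus (PZ) is the dominant outflow hub
  in the severe and moderate groups; controls have elevated medial-prefrontal
  (FZ/F3/F4) outflow; the mild group emphasises right-hemisphere flow. Edges
  act at lags 2–6 samples (8–23 ms at 256 Hz), mimicking conduction delays
  and making the true model order 6.
* **Calibration.** Per group, the global coupling scale is bisected until the
  analytic alpha-band mean off-diagonal PDC matches the group anchor values
  (control 0.0797, mild 0.0501, moderate 0.0776, severe 0.0587), and the
  delta pole radius is bisected toward the delta anchors (control 0.0563,
  mild 0.1064, moderate 0.1466, severe 0.0514). Two anchors are not exactly
  attainable, and deliberately so: the moderate delta anchor exceeds the
  ceiling that PDC column normalisation imposes on a sparse graph, and the
  pole-radius search is bounded at 0.97 because a sharper pole decays more
  slowly than a 4-s epoch — a quasi-deterministic oscillation that violates
  the within-epoch stationarity the segmentation is designed to guarantee.
  The moderate group therefore lands below its delta anchor while preserving
  the designed ordering (moderate ≈ mild > control ≈ severe).
* **Between-subject variability.** Each subject perturbs the calibrated
  coupling scale by a log-normal factor (sd 0.15, truncated at 1.5 sd) plus
  small per-edge jitter, keeping every subject's analytic alpha mean within
  30% of the group anchor.
* **SIAS scores.** Scores are drawn inside the group's bin (control < 20,
  mild < 35, moderate < 50, severe ≥ 50) as a linear function of the
  subject's *true* analytic alpha-band mean PDC plus Gaussian noise:
  increasing in the severe group, decreasing in controls, flat for
  mild/moderate. The slope is expressed per standard deviation of the
  generator's own realised between-subject PDC spread (computed analytically
  at calibration time) — PDC responds sub-linearly to the coupling scale, so
  standardising by the nominal jitter sd would silently halve the designed
  correlation.
* **Innovations and seeds.** Innovation covariance is diagonal with
  per-channel scales 0.9–1.1; an optional 50 Hz line-noise sinusoid is off by
  default. All randomness is drawn from R's RNG; per-subject seeds fan out
  from the master seed by a counter scheme, so adding subjects never perturbs
  existing ones and every cohort is bit-reproducible.

What the generator does *not* emulate: scalp-level volume conduction and
re-referencing, 1/f broadband background, ocular/muscle artifacts beyond
amplitude spikes, or non-Gaussian innovations. Passing tests therefore
demonstrate estimator correctness under the model's own assumptions, not
robustness to every property of recorded EEG.

## Preprocessing: what runs where, and why

The preprocessing module implements the conventional chain — common average
reference, zero-phase FIR band-pass (0.4–50 Hz), amplitude/robust-z artifact
marking on 1-s spans, anti-aliased downsampling to 256 Hz, segmentation into
non-overlapping 4-s epochs. Two steps are deliberately *not* applied before
MVAR fitting in the default pipeline:

* **Common average reference.** Averaging across exactly the eight channels
  that are subsequently modelled forces the channel sum to zero at every
  sample — an exact collinearity under which the MVAR coefficients are not
  identifiable (rank-deficient least squares, singular innovation
  covariance). CAR belongs to the scalp stage of a recording workflow, where
  the reference is computed over a larger electrode set than the analysis
  montage; it is available (`car = TRUE`) for that situation and is validated
  by its own tests.
* **Band-pass before fitting.** A zero-phase FIR with a ~100 dB stop band
  over more than half the Nyquist range forces the autoregression to
  approximate the filter's notch rather than the signal's dynamics. On
  generator data this inflates off-diagonal PDC roughly two-fold and drags
  AIC order selection to the top of its search range — consistent with the
  published advice against filtering before VAR-based directed-connectivity
  estimation (Florin et al. 2010, *NeuroImage*; Barnett & Seth 2011,
  *J. Neurosci. Methods*). The filter remains the default in
  `preprocess_recording()` where its job is artifact and line-noise control
  (its attenuation contract — ≥ 40 dB at half the low edge and beyond
  high + 10 Hz — is tested on sinusoids), and is a switch in the
  connectivity pipeline, off for clean synthetic data.

Filtering is implemented as FFT convolution with $|H(\omega)|^2$ (the exact
forward–backward magnitude response of the Hamming-window FIR design) with
reflection padding, which keeps the tap counts demanded by a 0.4 Hz edge
affordable.

Artifact marking uses per-channel robust z-scores (median/MAD over the whole
recording, threshold 5) and an optional absolute-amplitude threshold on 1-s
spans; marked spans split the recording, and each clean span is greedily
tiled with complete epochs from its start. 116 s of clean data yields exactly
29 four-second epochs.

## Estimation: pooled fits, grand-mean centring, order selection

`fit_mvar()` solves the stacked lag regression by QR least squares; the
innovation covariance uses the residual degrees of freedom
$N_{\mathrm{eff}} - n\,p$. Two estimator modes exist:

* **Pooled (default).** One multi-trial fit per subject, stacking the lag
  regressions of all epochs without crossing epoch boundaries. Pooling is
  essential for accuracy here: PDC of a truly-null connection estimates the
  *magnitude* of complex coefficient noise, so a per-epoch fit on 1024
  samples carries an upward bias of roughly 0.09 that epoch-averaging cannot
  remove. The pooled estimate reaches a mean absolute off-diagonal error of
  about 0.016 against the analytic PDC of the generating model at 29 epochs.
* **Per-epoch** (`fit = "per_epoch"`). The literal per-segment reading:
  an MVAR and PDC spectrum per 4-s epoch, band averages then averaged across
  epochs, unstable epoch fits skipped. Provided for comparison; its bias is
  documented above.

Channels are centred with one grand mean per channel per fit. Removing a
separate mean from every short epoch subtracts an estimate whose variance
scales with the process's near-DC power; with strong low-frequency poles this
injects per-epoch constant errors that masquerade as long-lag structure and
push AIC toward its cap.

The order is selected once per subject by AIC,
$N \ln \det \hat\Sigma + 2 p n^2$, over 1–12 on the first eight epochs
(about half a minute of data) and held fixed; all candidate orders are scored
on the common sample obtained by trimming $p_{\max}$ leading samples per
epoch, solved from a single cross-product matrix. With $n = 8$ channels the
per-order penalty of $2 n^2 = 128$ makes AIC over-selection negligible, and
on default cohorts the selected orders concentrate at 4 (the true order is 6,
but the lag-5/6 edges are weak enough that the parsimonious choice is
correct by AIC's account). The search range 1–12 strictly contains the 4–10
range reported for comparable resting-state data, so that range is an
outcome, not a constraint.

## Statistics

The group layer mirrors a conventional reporting stack: Lilliefors-corrected
KS normality screening (advisory only), one-way ANOVA with
$\eta^2 = SS_b/SS_t$, Tukey HSD post hoc tests, Bonferroni correction across
the five band-wise ANOVAs, and Pearson correlations of per-subject mean
off-diagonal alpha-band PDC with SIAS scores, per group and pooled.

Two ANOVA layouts are exposed because the unit of analysis is genuinely
ambiguous in this literature. The *connection* layout treats the per-group
mean PDC of each of the 64 directed pairs as an observation
(df = (3, 252) for four groups — the degrees of freedom printed in
comparable reports); it is the reproduction-mode default. The *subject*
layout takes one observation per subject (that subject's mean off-diagonal
PDC; df = (3, 84) at 22 per group) and is the statistically defensible
inference mode — with an edge-sparse generator, the connection layout's
error term is dominated by between-connection spread and has essentially no
power, which is itself informative about what such F-statistics measure.

The acceptance suite validates the stage on closed forms (a hand-computed
toy ANOVA, the two-group F = t² identity, Tukey's reduction to the pooled
t-test) and its operating characteristics: with all four groups drawn from
the same generator spec distribution, the subject-level ANOVA rejects at
5% ± 2% over 1000 replicates. That null check runs at the design level
(true analytic per-subject means through the generator's jitter
distribution) rather than through 88,000 simulated recordings; the
estimation stage adds exchangeable noise and cannot change the test's size.

## Numerical choices and degenerate inputs

* Frequency grid 0.5 Hz; PDC denominators are guarded against exact zero.
* Stability margin $10^{-6}$ on the companion spectral radius; unstable
  pooled fits are an error, unstable per-epoch fits are skipped and counted.
* AIC regularises a numerically singular residual covariance by
  $10^{-12}\,\mathrm{tr}(\Sigma)/n \cdot I$ and warns.
* Rank-deficient regressors (constant or collinear channels) are an error,
  not a silent pseudo-inverse.
* Order-selection ties break toward the smaller order.
* The SIAS generator clips scores to the group bin after adding noise;
  clipping slightly attenuates the designed correlations and is accounted
  for in the design margins.
* Zero-variance samples are rejected by the normality screen and the
  correlation; single-subject groups yield `sd = NA` with a warning.

## Problem sizes used by the tests

The packaged test-suite and acceptance checks run the full design at
22 subjects per group with 120-s recordings (29–30 epochs per subject — the
canonical 29-epoch/116-s usage arises whenever a span is trimmed), 50
replicate cohorts for the design-effect recovery check, 100 replicates for
order recovery, and 1000 replicates for the normalisation identity and the
ANOVA size check. These sizes were chosen so the whole suite completes on a
single CPU in well under half an hour while leaving every Monte-Carlo
margin wide.

## Known limitations

* The generator's band structure lives near the saturation regime of PDC's
  column normalisation; calibrated coupling coefficients are small
  (0.001–0.01) and group contrasts are carried by pole sharpness as much as
  by coupling strength. This is a property of PDC itself, worth keeping in
  mind when interpreting absolute PDC magnitudes anywhere.
* Estimated PDC carries a small positive bias on null connections even in
  pooled mode (~0.01–0.02 at the default problem size); group *contrasts*
  are unaffected.
* No statistical thresholding of individual edges (asymptotic PDC null
  distributions are out of scope), no time-varying MVAR, no regularised
  estimation, and no generalized/renormalised PDC variants.
* eLORETA-style source reconstruction is out of scope; the pipeline operates
  directly on region-of-interest time series.
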