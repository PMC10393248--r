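---
title: "Nonlinear EEG dynamics and supervised tensor biomarkers: methods"
author: "eegdyn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nonlinear EEG dynamics and supervised tensor biomarkers: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegdyn)
```

## The analysis in one paragraph

`eegdyn` implements a biomarker-discovery pipeline for developmental EEG:
multichannel resting-state recordings are reduced to the 19 classical 10–20
electrodes, each channel is split into six frequency bands by a Daubechies-4
discrete wavelet transform, and twelve nonlinear dynamical measures are
computed on every band sub-signal. The resulting participant × measure ×
channel × band array (optionally with a fifth recording-age mode) is
factorized with a *supervised* canonical polyadic model (SupCP) whose latent
participant scores are regressed on class labels and covariates. Because the
model is a proper Gaussian likelihood, held-out participants can be scored by
the marginal likelihood of their tensor slice under each candidate class and
classified through Bayes rule; the same latent factors feed standard
regressors for age prediction. The cohort data this design targets are
restricted, so the package ships synthetic-data generators that emulate the
relevant structure with known ground truth.

## Band decomposition

Each channel is decomposed with an orthogonal, periodized (circular) DB4
(8-tap Daubechies) DWT, and each named band is the time-domain reconstruction
of one detail level. At 500 Hz the dyadic detail intervals force the
assignment D7 → delta (≈2–3.9 Hz), D6 → theta, D5 → alpha, D4 → beta,
D3 → gamma, D2 → gamma⁺ (62.5–125 Hz); D1 and the level-7 approximation form
the residual. At other sampling rates each band receives the detail level
whose dyadic interval maximizes Jaccard overlap with the band's canonical
range, and the mapping is recorded in the output.

We chose the *periodized* boundary mode rather than symmetric extension: the
periodized transform is exactly orthogonal, so two useful identities hold to
machine precision — the reconstructed details plus residual reproduce the
input sample-for-sample, and the band energies add to the signal energy when
the length is a multiple of $2^L$. Signals with other lengths are padded
cyclically and trimmed after reconstruction; reconstruction stays exact, and
the energy identity becomes approximate near the boundary (tests use
multiple-of-$2^L$ lengths for the energy check). Wraparound can blur a few
edge samples of each band series; for the segment lengths used here this is
negligible relative to the measure variance.

## The twelve nonlinear measures

Per (channel, band) sub-signal the pipeline computes sample entropy (m = 2,
r = 0.2 SD, Chebyshev distance, self-matches excluded), the
Grassberger–Procaccia correlation dimension (embedding dimension 10, delay
1), the DFA scaling exponent (order-1 detrending, boxes 4…N/4), and nine
recurrence measures: recurrence rate, determinism, laminarity, trapping
time, diagonal line-length entropy, maximum and mean diagonal length,
vertical line-length entropy, and the average white (non-recurrent) vertical
line length. Recurrence plots use time-delay embedding with dimension 10 and
delay 1, Euclidean distances, and a *fixed recurrence rate* of 0.05: the
threshold is the 5% quantile of all off-diagonal embedded distances, which
also makes every recurrence measure invariant under affine rescaling of the
input. The Theiler window is 1 (the line of identity alone is excluded from
diagonal structures) and minimum line lengths are lmin = vmin = 2. Empty
line-length distributions yield 0 by convention, and degenerate (constant)
sub-signals are recorded as missing with a reason rather than imputed.

Where the underlying conventions are genuinely open — the embedding delay,
the distance norm, the Theiler window, the precise membership of the
"seven" recurrence-quantification values — we fixed the defaults above,
counted the recurrence rate itself among the recurrence measures, and kept
the measure registry data-driven so a different set can be configured
without code changes.

Sample entropy, the recurrence kernels and the correlation sum are
implemented in C++; for delay 1 the embedded distance along each diagonal
offset is updated incrementally, making the full twelve-measure vector
roughly O(N²) in the segment length. Recurrence analysis is quadratic, so
population-scale runs use analysis windows of a few seconds (the examples
below use 1–1.5 s at 500 Hz, i.e. 500–750 samples — within the range
commonly used for recurrence analysis); `recurrence_matrix()` materializes
plots only up to 6000 embedded states.

## The SupCP model and its EM fit

For participant $i$ with vectorized slice $x_i \in \mathbb{R}^D$:

$$x_i = W u_i + e_i, \qquad u_i = B^\top y_i + f_i,$$

with $W = V_K \odot \cdots \odot V_1$ the column-wise Khatri–Rao product of
unit-norm per-mode loading matrices, $f_i \sim N(0, \Sigma_f)$ diagonal, and
$e_i \sim N(0, \sigma^2 I)$. Marginally $x_i \sim N(W B^\top y_i,\,
W \Sigma_f W^\top + \sigma^2 I)$; this marginal (evaluated via the Woodbury
identity) is both the fitting objective and the classification score.

Fitting is expectation–conditional–maximization: the E-step computes the
conditional mean and covariance of $u_i$; the M-step updates each $V_k$ (a
matricized least-squares problem solved through the MTTKRP normal
equations), then $B$, the diagonal $\Sigma_f$, and $\sigma^2$, all in closed
form, so the observed-data log-likelihood is non-decreasing (asserted in the
tests at 1e-8 relative). Loading columns are renormalized each iteration
with the scale absorbed into $B$ and $\Sigma_f$, which leaves the likelihood
invariant and resolves the CP scale indeterminacy; factor order and sign
remain arbitrary, so recovery is scored after permutation/sign matching
(`factor_congruence()`).

Two numerical choices matter in practice. *Initialization*: random
orthonormal loadings can collapse a factor into a local optimum even on
noiseless low-rank data, so the default start is spectral — each $V_k$ is
initialized from the top singular vectors of the mode-$k$ unfolding, padded
with seeded random orthonormal columns when $R$ exceeds the mode dimension
(`init = "random"` remains available). *Noise floor*: $\sigma^2$ is floored
at $10^{-8}$ × the initial data variance and reaching the floor terminates
the fit; below it the model is effectively noiseless and the Woodbury
evaluation of the log-likelihood loses precision to cancellation.

The rank defaults to 30, the value at which adding factors stopped improving
results in the cohort analysis this design derives from; it is an ordinary
argument, and fits are cheap enough at the package's problem sizes that a
scan is a loop. The supervision matrix is taken as given; the pipeline
prepends an intercept column so that class coefficients are offsets from a
baseline (with a lone intercept the fitted $B$ reduces to the per-factor
score means, which the tests assert).

## Classification, cross-validation, and age regression

For a two-group contrast, each held-out participant is scored by the
marginal log-likelihood of their (training-standardized) slice under
$y^\ast$ = (candidate class, own covariates), and Bayes rule with
training-fold class proportions (configurable to uniform) yields posteriors;
the higher posterior is the predicted label, with exact ties resolved to the
first class in canonical (control, case) order. Cross-validation is
stratified k-fold with k = 5, reduced to the minority-class size when that
is smaller (n-fold rule). Two leakage guards are structural: per-cell
z-scoring uses training-fold statistics only, and the factorization sees
only training participants — deleting a held-out participant provably leaves
the fold model unchanged (tested). AUROC is computed on the pooled held-out
positive-class posteriors (per-fold averaging available by flag; pooling was
chosen because small minority classes make per-fold AUROCs unstable), ties
counted one half; the Brier score is the mean squared probability error.

Age regression is deliberately thin glue: the latent factors whose
individual correlation with age exceeds |r| > 0.2 (the retention rule of the
factor report) are fed to a linear model, k-nearest neighbours, a random
forest and a radial-kernel SVM under seeded k-fold CV, reporting r, r², and
mean absolute error per regressor.

## Synthetic data: what it emulates, and what it does not

Two generators stand in for the restricted cohort. The *tensor generator*
inverts the SupCP model exactly — balanced class indicator plus Gaussian
covariates, $U = YB + F$, orthonormal loadings, Gaussian noise — giving
ground truth for recovery, congruence, and noise-variance tests
(orthonormal loadings require $R \le$ every mode dimension, hence the
generator's rank error).

The *cohort generator* produces multichannel recordings in which, within
each canonical band, independent band-limited Gaussian noise (FFT-masked,
unit variance) is mixed with a participant-level sinusoidal tone (per-band
frequencies near 3, 6, 11, 22, 45, 90 Hz, jittered per participant, phases
shared across channels), plus a small logistic-map (r = 3.99) chaotic
component. A single deterministic weight $w$ controls the mixture:
$w = 0.85 - 0.70\,a\,(\mathrm{age}-1)/6 + 0.25\,g\,[\mathrm{anxiety}] -
0.15\,g\,[\mathrm{externalizing}]$, clipped to [0.05, 0.95], where $a$ and
$g$ are the age- and group-effect strengths. The 0.85→0.15 span was chosen
because the measured response of band sample entropy and determinism to the
tone fraction is steep and monotone across it, so the generator's stated
contracts hold by construction: sample entropy rises with age (complexity
increasing through development), determinism separates groups
monotonically in the group effect, and zero effects give a null. Covariates
are drawn to match the cohort's published summary statistics (sex ≈ 1:1,
birthweight ≈ N(3541 g, 701 g), first-recording age ≈ N(7.9, 2.75) months).
The effect strengths are free parameters of the generator, not estimates of
any real cohort.

What passing tests on these data do *not* show: the generator has no scalp
topography (channels are exchangeable), no 1/f broadband background beyond
the band mixture, no artifacts (blinks, muscle, line noise), no
non-stationarity, and its group effect is a global regularity shift rather
than a spatially specific signature. Results on it validate the machinery —
measure correctness, factorization recovery, absence of leakage, sane null
behaviour — not clinical effect sizes. The headline numbers of the original
cohort analysis (e.g. age correlation ≈ 0.76, the best AUROC/Brier cells)
require the restricted recordings and are expressly out of scope; the
synthetic benchmarks are qualitative analogues (cross-validated r ≥ 0.6 on
an n = 80 age-gradient cohort; AUROC ≥ 0.9 on a strongly separated n = 40
cohort; label-permutation null at chance).

## Problem sizes and runtime

The default test and acceptance runs use: 19-channel cohorts of 40
(classification, 20 per group) and 80 (age gradient) participants at 500 Hz,
4-s generated recordings with 1.25-s (classification) and 1.0-s (age)
analysis windows; rank-30 fits with ≤200 EM iterations and tolerance 1e-6;
20 label permutations for the null. These sizes keep a full pipeline run in
the tens of minutes on one CPU while leaving every qualitative contract
testable. Recording length, window, rank and folds are ordinary arguments,
so study-scale runs (30-s segments, deeper ranks) differ only in cost.

## Known limitations

- EDF I/O is 16-bit: samples are recovered to within one digital quantum of
  the per-channel physical range, not exactly.
- Recurrence analysis is O(N²) in time and memory; full 30-s, 500-Hz
  segments (N = 15000) are outside the intended desk scale and are rejected
  by `recurrence_matrix()` rather than silently subsampled.
- The marginal-likelihood classifier assumes the SupCP Gaussian model; with
  rank ≫ training participants the per-fold fits are regularized only by
  EM's implicit shrinkage and early stopping.
- The correlation-dimension scaling region is selected automatically (radii
  where the correlation sum is between ~10 pair counts and 0.2); series with
  exotic geometry may need a hand-chosen region.
- Longitudinal (5-way) tensors use complete cases per age configuration; no
  imputation is attempted, matching the shrinking-N design of the cohort
  analyses this mirrors.
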