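---
title: "Information dynamics of audio-visual speech tracking: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information dynamics of audio-visual speech tracking: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avspeechinfo)
```

## The scientific problem

When listeners watch a speaker's face, comprehension of noisy speech
improves. One mechanistic account holds that slow cortical rhythms
track ("entrain to") the temporal envelope of speech and the motion of
the speaker's lips, and that this tracking — together with directed
interactions between network nodes — carries the behavioral benefit.
This package implements the full statistical machinery needed to test
that account on band-limited neural time series recorded under a
factorial design crossing acoustic signal-to-noise ratio (SNR: 2, 4,
6, 8 dB) with visual context (informative face, VI, coded +1, versus
non-informative face, VN, coded -1; 8 conditions in total), plus a
synthetic-data generator that produces such data with known ground
truth so every stage can be validated by parameter recovery.

## Local encoding: Gaussian-copula mutual information

Entrainment is quantified as the mutual information (MI) between a
band-limited neural signal and a stimulus feature (acoustic envelope
or lip trajectory) at an optimal stimulus-to-brain lag. MI is
estimated bin-lessly under a Gaussian copula: each variable is mapped
to the standard-normal quantiles of its ranks
(`qnorm((rank - 0.5) / n)`, average ranks for ties) and the Gaussian
MI is evaluated from the joint sample covariance, in bits. The
estimator is invariant to monotone marginal transforms and
non-negative by construction. No analytic small-sample bias term is
applied inside the estimator; bias is removed by permutation
downstream (below).

The audio-visual decomposition combines three MI terms for each
neural signal: the speech MI, the lip MI, the joint MI
`I(neural; envelope, lip)`, the conditional MI
`CMI = MI_joint - MI_lip` (speech information not explained by lip
dynamics), and the normalized redundancy

```
Red = (MI_speech + MI_lip - MI_joint) / (MI_speech + MI_lip) * 100 ,
```

which is 0 for independent feature representations and reaches 50%
when the two features carry identical information (under this
normalization 50% is the ceiling whenever the joint MI is at least as
large as each marginal).

## Band bank and signal preparation

All stages share an eight-band filter bank (0.25–1, 1–4, 4–8, 8–12,
12–18, 18–24, 24–36, 30–48 Hz) applied as a forward–reverse
fourth-order Butterworth band-pass (zero phase; −6 dB total at the
band edges; reflect padding of roughly one second suppresses edge
transients). The wide-band speech envelope is the average of the
Hilbert envelopes of six audio sub-bands spaced to equal widths on
the ERB-rate cochlear scale between 100 and 4000 Hz, resampled to
150 Hz. Two implementation notes:

* Resampling is performed as staged integer decimation with zero-phase
  low-pass filtering at 0.4× the intermediate Nyquist before each
  stage, followed by interpolation at the target sample times. Staging
  keeps the normalized Butterworth cutoffs away from the numerically
  fragile near-zero region that a single 16000 → 150 Hz step would
  require. Proper anti-aliasing matters scientifically as well: it
  removes the fast Rayleigh fluctuations of the wide upper cochlear
  bands, which is why the envelope of stationary noise has a
  coefficient of variation near 0.09 rather than the unsmoothed
  6-band value 0.523/sqrt(6) = 0.21.
* The analytic signal is computed by the FFT construction; inputs
  whose length retains a prime factor above 127 are reflect-padded to
  a 2-3-5-smooth length first (R's mixed-radix FFT is quadratic in
  the largest prime factor) and trimmed after.

Envelope–lip coherence is a Welch estimate (Hann taper, 10 s
segments, 50% overlap — configurable; the analytic chance level for
independent signals with L averaged segments is `1 - 0.05^(1/(L-1))`).

## Optimal lags and permutation bias correction

MI is evaluated at a per-node, per-band optimal lag. The lag search
computes the group-average MI-by-lag curve over a 0–250 ms window
(1-sample steps at 150 Hz), obtains permutation p-values per lag from
matched null curves, masks lags by Benjamini–Hochberg FDR at q = 0.01,
and takes the vertex of the least-squares parabola over the
significant lags, clipped to the window and rounded to the nearest
sample. Fewer than three significant lags yield no estimate, and the
band-wise median lag is substituted. With six segments the minimal
permutation p-value is 1/120 at the default 120-permutation subset,
small enough for the q = 0.01 mask; identity permutations are excluded
from the significance nulls (they tie with the observed value by
construction) but retained in the bias median below, as one of the
possible assignments.

The null/bias scheme permutes the assignment of stimulus segments to
neural segments: one permutation of the segment indices applied
identically within every condition and across bands for a given draw.
With six segments per condition the exhaustive set has 6! = 720
permutations; at reduced scale a seeded random subset (default 120,
always containing the identity) stands in. The bias-corrected MI is
the raw MI minus the median MI over the permutation set. Because
permuting stimulus segments only reorders whole blocks of the
rank-transformed feature, the entire permutation family is assembled
from precomputed block cross-products, which makes the exhaustive
720-permutation correction cheap.

One statistical subtlety is worth recording: under independence the
expectation of the median-corrected MI is the mean–median gap of the
permutation family, which is slightly positive because the MI null is
right-skewed — not exactly zero. The package's null tests therefore
check the corrected values against that exchangeability-derived
reference (and for smallness on the bits scale). The group-level
framework is unaffected, because participant null distributions
receive the identical median correction.

## Directed connectivity

Directed information (transfer entropy) from a seed to a target node
is

```
DI*(tau_brain) = I(target_t ; seed_{t - tau} | target_{t - tau}) ,
```

with both node signals entering through a bivariate embedding (sample
and first difference) and estimates never spanning segment
boundaries. The speech-conditioned variant subtracts the same
quantity additionally conditioned on the envelope value at a speech
lag:

```
DI(tau_brain, tau_speech) = DI*(tau_brain) - DI*(tau_brain) | speech(tau_speech) ,
```

evaluated over a grid of brain lags 1–37 samples (0 is excluded: the
conditioning requires a strictly past sample) by speech lags 0–75
samples at 150 Hz, on signals band-limited to 0.25–8 Hz. The
conditioning speech variable is the scalar envelope value; the
bivariate embedding is reserved for neural responses. Grids are
Z-scored per point against segment-shuffled estimates (seed and
envelope segments permuted jointly relative to the target; identity
assignments excluded; at least 20 shuffles). For dense grids the
copula transform is computed once per concatenated embedded series
and lagged copies are read off by indexing; the standalone
`di_star()` / `di_feature()` estimates re-rank each lagged subset and
define the reference semantics — the two agree closely and the grid
path is used only where the dense evaluation would otherwise dominate
the runtime.

Two properties of this estimator deserve emphasis, because they
constrain what synthetic validation can claim:

* **Common input.** The subtraction cancels pathways that a shared
  input creates when that input is *not* the conditioning feature: a
  common broadband drive produces a strongly significant DI* while DI
  stays at null level. A common drive *by the feature itself* at
  matched lags is mathematically indistinguishable from
  feature-carried transfer — no conditioning on a single envelope
  sample (scalar or with its derivative) can separate the two — and
  the package makes no claim to separate them.
* **Direction.** For a planted unidirectional edge the raw DI maxima
  order the direction correctly in every construction we tested,
  whereas the Z-scored maxima need not: the shuffle null of the
  reverse direction is systematically tighter (the receiving node is
  more self-predictable), which can inflate reverse Z values. The
  directionality validation therefore compares raw DI; the Z-scored
  grids remain the quantity entering condition-level statistics,
  where the same normalization is applied to every condition of one
  connection and the asymmetry cancels.

## Group statistics

All group inference is permutation-based random effects over
participants:

* **One-sample tests** on bias-corrected quantities compare the
  observed group T per index with a permutation distribution of the
  maximum cluster-enhanced statistic built by drawing one null value
  per participant per sample from the participant-specific null
  distributions (the same draw across indices, preserving their
  correlation). Cluster-mass enhancement sums |T| over
  adjacency-connected supra-threshold indices (forming threshold
  T = 2.1; positive and negative excursions separately); significance
  is the 95th percentile of the maximum-mass distribution (FWE 0.05).
  Adjacency is a user-supplied graph — consecutive bands chain
  together; ROI-level data default to no spatial adjacency.
* **Condition effects** use a per-participant GLM on the 8 condition
  cells: response and regressors (SNR, VIVN, and their product) are
  z-scored within participant, giving standardized betas; the group T
  on betas is tested with the Freedman–Lane procedure — residuals of
  the reduced model excluding the tested regressor are permuted
  across conditions within participant, the full model is refitted,
  and the maximum cluster-enhanced |T| over indices forms the
  two-sided FWE null.
* **Lateralization** contrasts participant betas between an ROI and
  its contralateral counterpart with a sign-permutation of the paired
  difference, exhaustively enumerated when 2^P fits the permutation
  budget (exact p-values), with max-|T| correction across ROIs.
* **Neuro-behavioral correlations** compute per-participant Pearson
  correlations across conditions between accuracy and the neural
  quantity, Fisher-Z transform them (for lag-resolved connectivity,
  per lag and then averaged across lags), and test the
  participant-average Z against a within-participant condition-label
  permutation null, percentile p-values, max-statistic FWE across
  regions.
* **Behavioral ANOVA** is the standard two-way within-subject
  decomposition (SNR × visual context), F unadjusted, p-values on
  Huynh–Feldt-corrected degrees of freedom; epsilon comes from the
  covariance of orthonormal within-participant contrasts (the
  interaction uses the Kronecker product of the factor contrasts),
  capped at 1. Partial eta squared is reported per effect.
* **Amplitude and PAC analyses** reuse the same machinery: mean
  Hilbert amplitudes per node/band/condition go through the
  Freedman–Lane GLM with FWE across node × band indices;
  phase-amplitude coupling is the modulus of the amplitude-weighted
  mean phase vector with amplitudes normalized by their mean —
  Eq.-style complex averaging yields a complex number, and the
  mean-normalization makes the modulus dimensionless in [0, 1]
  (amplitude `1 + cos(theta)` against uniform phase gives exactly
  0.5), comparable across conditions.

## The synthetic generator: what it emulates, and what not

`gen_envelope()` produces low-pass-filtered rectified 1/f-shaped
noise: Gaussian noise is spectrally shaped toward low frequencies,
half-wave rectified, low-pass filtered at 6 Hz and clipped
non-negative — a non-negative signal whose spectral power is
concentrated below 8 Hz, like the syllabic/prosodic dominance of
natural speech envelopes (≥ 80% of power below 8 Hz is asserted in
the tests). `gen_lip()` mixes a delayed standardized copy of the
envelope with an independent, spectrally matched signal so that the
1–8 Hz magnitude-squared coherence approximates the requested level
(default 0.7, the delta/theta coherence regime of natural
audio-visual speech). Node signals are
`gain(node, condition) × envelope(t - lag)` plus an optional
lip-driven term, plus directed edge contributions transferring a
delayed component of a seed node (its envelope-driven part when the
edge is speech-mediated, its full signal otherwise), plus Gaussian
noise band-limited to 0.25–48 Hz, matching the analysis band bank.
Participants receive log-normal gain multipliers (sd 0.15) to create
between-participant variance for the random-effects stages. All draws
derive from one master seed through a splitting scheme, so identical
configurations are bit-identical.

Behavioral accuracies follow a logistic base curve in SNR plus an
accuracy-scale visual bonus per SNR level (defaults: intercept 1.0,
slope 0.15 per dB, bonuses 0.02/0.06/0.03/0.06 concentrated at
intermediate SNRs, noise sd 0.06, clipped to [0, 1]) — chosen once to
mimic word-recognition performance rising from roughly 65% to 80%
with a visual benefit at intermediate SNRs, with an overall mean near
73%.

The generator reproduces the *statistical* structure the analyses
assume — condition-dependent coupling gains, fixed integer lags,
coherent lip dynamics, behavioral monotonicity — not speech itself.
There is no phonetic or articulatory content, no auditory-periphery
model beyond the envelope statistics, no video. Passing recovery
tests therefore demonstrates that the estimators and the permutation
framework recover planted effects of realistic size under realistic
noise; they do not certify performance on real MEG source signals,
whose noise spectra, artifacts and inter-regional leakage the
generator does not emulate.

## Problem sizes, defaults and numerical choices

Full-scale defaults mirror the study design (19 participants, 6
segments of 60 s per condition, 150 Hz, 720 bias permutations, 10,000
statistical permutations). The packaged analyses, tests and the
acceptance script run a desk-scale version chosen to keep every stage
in seconds-to-minutes: typically 4–6 participants, 6 segments of
12 s, 120 bias permutations, 200–1000 statistical permutations, and
lag searches over 0–20/25 samples. Six segments are retained even at
desk scale because lag-significance needs a permutation space larger
than 1/q: with q = 0.01 the minimal p of a 3-segment design (1/6)
can never pass the FDR mask, in which case every node falls back to
the band-median lag.

Other numerical choices: ties in ranks take average ranks
(deterministic, monotone-invariant); degenerate inputs (constant
dimensions, singular covariances, zero null variance, incomplete
designs) raise errors rather than propagating NaN; a seed identical
to its target returns DI* = 0 directly (the conditioning makes the
joint covariance singular while the true value is 0); conditioning on
a constant envelope returns the unconditioned value, so the DI
difference is 0; quadratic lag fits that are not concave return the
boundary favoured by the fitted trend; permutation p-values use the
(1 + k)/(1 + n) correction.

## Known limitations

* The Gaussian copula captures monotone dependence; information
  carried purely by non-monotone relationships is invisible to it.
* Speech-carried common drive versus relayed transfer is not
  identifiable from two nodes and a scalar feature (above).
* Heavily oversampled smooth signals blur lag localization: the DI
  grid maximum drifts along the `tau_speech - tau_brain` ridge when
  the relaying node carries strong independent noise; DI* localizes
  the brain lag more sharply than DI localizes the pair.
* The node graph replaces the study's volumetric voxel grid; spatial
  cluster enhancement across a 3-D brain and the 10-mm map smoothing
  have no equivalent here and are deliberately out of scope.
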