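---
title: "Space-frequency-time MEG markers: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Space-frequency-time MEG markers: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`megwave` implements a bimodal MEG classification pipeline for three-way
discrimination of Alzheimer's disease (AD), mild cognitive impairment (MCI)
and healthy controls (HC), together with the synthetic data machinery needed
to exercise every stage without access to clinical recordings. This vignette
is the package's methodological account: the signal model, the marker
construction, the classifiers and fusion rule, the evaluation schemes, and
the design decisions taken where the design was genuinely open.

## The pipeline at a glance

1. **Input**: 306-channel Elekta-style resting-state MEG (102 magnetometers,
   204 planar gradiometers; two orthogonal gradiometers per site), sampled at
   1000 Hz or synthesised directly at 200 Hz.
2. **Preprocessing**: zero-phase 4th-order Butterworth band-limiting and
   resampling to 200 Hz, band-pass 0.5–80 Hz, central 180-s crop, 10-s
   epochs (2000 samples).
3. **MEG images**: per epoch, the sensors of one region of interest (ROI)
   and one modality are stacked into an M × N matrix (M = 2000 time samples,
   N = ROI sensors).
4. **Markers**: a full 2D wavelet-packet decomposition (db4, 3 levels); the
   21 nodes whose final step is the horizontal-detail filter are summarised
   to one scalar each — the mean of the raw coefficients for magnetometer
   images, the population SD of the time-axis coefficient gradient for
   gradiometer images.
5. **Classification**: 3-nearest-neighbour vote fractions for magnetometer
   markers, a shrinkage-regularised quadratic Bayes normal classifier (QBNC)
   for gradiometer markers; per-epoch score rows sum to 1.
6. **Fusion**: per participant, each modality's test-epoch scores are
   averaged into a class-mean vector and the two vectors are multiplied
   element-wise (product rule); the argmax is the bimodal decision.
7. **Evaluation**: leave-one-participant-out CV, epoch-level Monte Carlo
   random subsampling (MCRS), and the hybrid LOO–MCRS scheme (hold out one
   participant per class, test a random 50% of their epochs, repeat).

## The 2D wavelet-packet transform

Each MEG image is decomposed with a separable 2D transform: a low/high-pass
quadrature-mirror pair applied along the time axis (rows) and the sensor
axis (columns) splits every subband into approximation (A),
horizontal-detail (H), vertical-detail (V) and diagonal-detail (D) children;
recursing on *all* children gives the full quad-tree (4^l nodes at level l,
84 nodes at 3 levels).

Numerical choices:

* **Axis convention.** The image stores time down the rows and sensors
  across the columns. "Horizontal detail" is defined as high-pass across
  sensors and low-pass along time — spatial contrast. Both readings of the
  naming convention are defensible; this one is fixed, documented, and the
  transpose is available via `feature_config(transpose = TRUE)` rather than
  guessed per call.
* **Wavelet.** The marker design does not hinge on a specific mother
  wavelet; `db4` is the default (smooth, compact, orthonormal), `haar` and
  `db2` are available, and `haar` makes analytic test cases exact.
* **Extension mode: periodization.** Subband sizes are exactly halved each
  level, the transform matrix is orthogonal for any even length (so level-1
  energy conservation holds to ~1e-16 relative), and reconstruction is exact.
  Odd-sized subbands are first extended by repeating the final row/column;
  the appended sample is a copy, so truncation at synthesis makes the
  round-trip exact for every size (tested below 1e-8, observed ~1e-15).
  Images only need every filtering input to be at least 2 wide, so 7-sensor
  ROIs decompose to level 3 (their deepest sensor subbands have width 1).
* **Basis products.** The separable basis uses the standard products
  (scaling×scaling for A, the mixed products for H/V, wavelet×wavelet
  for D); published presentations of separable wavelet systems sometimes
  typeset all three detail products identically, which cannot be literal —
  the standard definitions are used.
* **Band labels.** For display, a node's time-axis filter sequence is
  sequency-ordered (the Gray-code permutation that accounts for spectral
  mirroring after high-pass downsampling) and the 0–80 Hz analysis band is
  tiled into 2^level equal nominal bands — 10 Hz wide at level 3. Labels are
  nominal: packet filters overlap heavily. Feature order always follows path
  order, not band order.

The 21-node terminal-H rule keeps, at every level 1–3, the nodes whose final
step is H: 1 + 4 + 16 nodes, ordered by level and then by the natural child
order A, H, V, D. The `grid_experiment()` driver sweeps all four terminal
letters × both statistics per modality, mirroring the marker-design table
that motivated the defaults.

Coefficient gradients use central differences in the interior and one-sided
differences at the borders (unit spacing); the magnitude mode is
\(\sqrt{d_t^2 + d_s^2}\) and requires at least 2 rows and columns. The node
statistic `sd` is the population SD (divisor n), chosen so that a constant
subband maps exactly to 0.

## Classifiers and fusion

Features are z-scored with training-fold statistics only (zero-variance
columns map to 0). The 3-NN classifier scores a query by the vote fractions
of its k = 3 Euclidean-nearest training points — the simplest mapping of
neighbour counts to confidence scores that sums to 1 — with distance ties
broken by training-sample order so results are deterministic.

The QBNC fits one Gaussian per class. With 21-dimensional markers and as few
as ~36 training epochs per class in reduced designs, the sample covariance
can be ill-conditioned, so each class covariance is shrunk toward its
diagonal, \((1-\lambda)S + \lambda\,\mathrm{diag}(S) + \epsilon I\) with
\(\lambda = 10^{-3}\) by default, and posteriors are computed from
log-densities with log-sum-exp stabilisation. Priors are uniform — the study
design is balanced by construction.

Fusion is performed at the participant level: each modality's scores over
the participant's test epochs are averaged (class-mean vector), the two
vectors are multiplied element-wise, and the argmax decides. Per-epoch
product fusion is available (`fusion_level = "epoch"`, majority vote over
epochs) but the participant-level rule is the default — averaging first
suppresses epoch-level score noise before the product amplifies agreement.
The raw product is kept alongside a renormalised copy; renormalisation
cannot change the argmax, so the choice only affects reporting. Exact ties
are broken by the fixed class order AD < MCI < HC.

## Evaluation schemes

* **LOOCV** holds out the i-th participant of *every* class in fold i
  (participants are paired across classes by sorted id index — the pairing
  is arbitrary and any fixed pairing gives the same test partition).
* **MCRS** splits at the epoch level, ignoring participant identity on
  purpose: it is the baseline whose optimism the hybrid scheme corrects.
  Epochs of one participant can appear on both sides of a split, and the
  participant-level confounds built into the generator make that leakage
  visible as inflated accuracy.
* **Hybrid LOO–MCRS**: per repetition and class, one participant is held
  out uniformly at random, the remaining participants train, and
  floor(0.5 × epochs) of the held-out participant's epochs (sampled without
  replacement) are evaluated. 100 repetitions by default. With
  `participant_selection = "exhaustive"` and `test_frac = 1` the scheme
  reproduces LOOCV exactly — a degeneracy used as a consistency test.

One master seed drives all repetition-level randomness; each repetition's
derived seed and fold composition are logged in the result's `folds` table.
Standardisation and classifier fitting always happen inside the training
fold. Confusion matrices are reported actual × predicted and averaged
entry-wise over repetitions, which is why averaged counts can be fractional.

Significance testing wraps the Kruskal–Wallis H test (tie-corrected,
chi-square approximation) with Holm step-down adjustment across comparisons;
a comparison whose pooled values are all identical is assigned H = 0, p = 1
by convention (the rank statistic is undefined there).

## The synthetic generator

The generator emulates *post-tSSS* resting-state recordings — interference
suppression is assumed done upstream and is out of scope. Each recording is
a sum of latent components, one unit-SD time course times one smooth spatial
profile each:

* `n_background = 6` pink-noise components (1/f^α, α = 1) with random
  Gaussian spatial foci on the upper hemisphere, amplitude 1;
* one band-limited oscillation per row of `default_oscillations()` — alpha
  8–12 Hz (occipital focus), theta 4–8 Hz, beta 13–30 Hz and gamma 30–80 Hz
  (left-frontal foci) — with amplitude = base amplitude × class power scale
  × participant gain;
* independent white sensor noise (SD 0.5) on every channel.

Magnetometers sample the latent field at the site position; planar
gradiometer channels are symmetric finite differences of the field along
the two tangential directions at each site (offset 0.02 sphere units) —
a deliberately simple surrogate for the physical pick-up geometry, not a
forward model.

The class structure mirrors the qualitative pattern reported for
resting-state dementia MEG: slow (theta) power elevated in AD frontally,
beta/gamma power highest in controls and ordered HC > MCI > AD, with the HC
gamma scale three times AD's. The `effect` parameter scales all class
deviations multiplicatively (`effect = 0` is the null configuration with no
class differences), and per-participant log-normal gain (SD 0.2) plus
band-edge jitter (SD 0.5 Hz) provide the participant-level confounds that
make epoch-level train/test leakage detectable. The base amplitudes were
fixed once so that the hybrid-CV gradiometer accuracy of the default
21-participant study lands in the 0.8–0.9 band at the default effect
preset; they were not revisited afterwards.

Study-design defaults follow the packaged protocol: 7 participants per
class, 5-minute AD and 3-minute MCI/HC sessions (AD recordings are cropped
to their central 3 minutes so all classes contribute equal data), synthesis
directly at 200 Hz for desk-scale runs with a 1000 Hz mode to exercise the
resampling path.

What the generator does **not** emulate: cortical sources and head
geometry, artefacts (blinks, cardiac), non-stationarity within a session,
realistic cross-channel noise covariance, and the absolute physical units
of MEG data. Passing tests therefore demonstrate the pipeline's mechanics
and its statistical guarantees (leakage-freedom, chance-level behaviour,
effect monotonicity, MCRS optimism) — they do not certify clinical
performance on real recordings.

## Sensor geometry and ROI membership

The packaged layout places 102 sites deterministically on the unit sphere
(6 on the head centerline, 48 per hemisphere in four colatitude rings), each
with one magnetometer and a latitude/longitude gradiometer pair. The 10 ROIs
(left/right × frontal, temporal, central, parietal, occipital) partition the
non-centerline channels of each modality; centerline channels are excluded
to keep the left/right analysis symmetric.

ROI membership in sensor space follows labelling conventions whose exact
channel lists are not recoverable from published summaries, so membership
lives in a packaged, user-overridable YAML (`inst/extdata/roi_map.yaml`).
The left-frontal region is fixed at 22 channels *in each modality* — 22
magnetometer sites, and 11 gradiometer sites contributing adjacent
latitude/longitude column pairs. Whether a published "22 sensors" counts
one modality or both is ambiguous; applying 22 to each listing is this
package's documented resolution. Column order within an ROI is ascending
site index.

## Zero-phase filtering

Band-limiting and band-passing use 4th-order Butterworth responses applied
zero-phase. Rather than running a forward-backward IIR pass per channel, the
squared magnitude response \(|H(f)|^2\) — exactly the LTI response of
forward-backward filtering — is applied in the frequency domain after odd
reflection padding (up to 2000 samples per end). This is vectorised across
all channels, agrees with per-channel forward-backward filtering away from
the edges to ~1e-10, and is linear to machine precision. Phase handling is
zero-phase by default throughout; epochs are cropped after filtering, so
filter edge effects fall outside the analysed window.

## Problem sizes used by the test-suite

The suite exercises full-size structures where the numbers matter (306
channels, 2000 × 22 images, 21 participants end-to-end with 100 hybrid
repetitions) and reduced designs elsewhere, chosen as the smallest sizes
that leave the statistical checks informative: chance-level behaviour is
checked on eight independent null datasets (7 participants/class, 60-s
sessions) pooled into ~168 participant-level decisions against a 99%
binomial reference band around 1/3; effect-size monotonicity uses three
effect levels × ten seeds on 4-participant, 20-s designs; the MCRS-optimism
ordering uses one confounded 7-participant dataset. The chance-level check
disables the participant-level confounds: subject-held-out accuracy under a
confounded null is biased slightly *below* chance (removing a participant
shifts their own class's training statistics away from them), which is real
behaviour of leave-subject-out validation, not a pipeline defect — but it
invalidates a binomial reference centred at 1/3, so the null oracle uses the
epoch-exchangeable configuration.

## Known limitations

* The synthetic class structure is qualitative; no claim is made that
  default accuracies transfer to clinical data.
* The ROI map and sensor geometry are nominal stand-ins for the vendor
  layout, adequate for pipeline logic but not for source-level
  interpretation.
* 3-NN confidence scores are vote fractions — coarse (multiples of 1/3),
  which the participant-level averaging partly smooths.
* The QBNC assumes Gaussian class conditionals; with 21 dimensions and few
  participants the shrinkage parameter, not the data, keeps it well-posed
  in small designs.
* Only three wavelets ship with the package; arbitrary filter banks are a
  one-line extension of `wpd_filters()`.

## Worked example

```{r, eval = FALSE}
library(megwave)

layout <- build_layout()
map <- default_roi_map(layout)

# a reduced synthetic study: 3 participants/class, 60-80 s sessions
cfg <- sim_config(participants_per_class = 3,
                  session_seconds = c(AD = 80, MCI = 60, HC = 60),
                  seed = 7)
feats <- simulate_features(cfg, roi = "LF", layout = layout, map = map,
                           duration_s = 60)

cv <- hybrid_loo_mcrs_run(feats, repetitions = 20, seed = 2)
glance(cv)
autoplot(cv)

# marker heat map, grid and ROI sweeps
plot_feature_heatmap(feats)
```
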