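---
title: "Desk-scale resilience experiments for fully convolutional sleep staging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Desk-scale resilience experiments for fully convolutional sleep staging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psgres)
```

## The problem

Automatic sleep staging assigns one of five stages (W, N1, N2, N3, REM) to
every 30-second epoch of an overnight polysomnography (PSG) recording.
State-of-the-art stagers are fully convolutional sequence-to-sequence
networks that map a two-channel (one EEG, one EOG derivation) signal block
of `L` epochs to `L` stage probability vectors. Three practical questions
about such stagers keep recurring:

(i) does the choice of electrode derivation matter, i.e. can a model
trained on *atypical* (non-recommended) derivations stage as well as one
trained on the AASM-recommended montage;
(ii) does training on one acquisition center generalize to another, and
how do direct transfer (DT), training from scratch (S) and fine-tuning
(FT) compare under a center shift; and
(iii) does conditioning the network on the subject's age group — via
categorical-conditional (CCBN) or sandwich (SaBN) batch normalization —
improve staging over a pooled model.

`psgres` implements the full computational stack needed to study these
questions — generator, preprocessing, montage, hierarchical sampler,
network, training, evaluation, experiment orchestration — at *desk scale*:
synthetic cohorts small enough that every experiment runs in minutes on one
CPU core. The point is not to reproduce clinical benchmark numbers (real
multi-center registries are far outside this scope) but to exercise and
test every mechanism of the pipeline on data whose ground truth is known
by construction.

## The synthetic cohort generator

`generate_cohort()` realizes a `cohort_spec()`. Its assumptions, and what
they emulate:

* **Hypnograms** are first-order Markov chains over the five stages.
  `stage_transition_matrix()` parameterizes the chain by its stationary
  distribution plus a `persistence` term (default 0.85), so stages come in
  multi-epoch bouts as in real hypnograms. Age shifts the stationary law
  (`age_stage_prior()`): subjects under 13 get REM 0.30 and N3 0.20,
  adults REM 0.20, subjects over 60 more wake and less N3. This gives the
  age-conditioning experiment a real signal: children genuinely carry more
  REM sleep.
* **Signals** are synthesized per referential electrode (F3, F4, C3, C4,
  O1, O2, M1, M2, E1, E2), not per derivation, so the montage module can
  form arbitrary derivations downstream. Every electrode carries a 1/f
  (pink) noise floor; each scored epoch adds stage-specific band-limited
  components with independent realizations per electrode (so a difference
  of two electrodes keeps, rather than cancels, the stage signature):
  alpha (8–12 Hz) in W, theta (4–7 Hz) in N1 and REM, delta (0.5–4 Hz)
  moderate in N2 and strong in N3, and 1-s Gaussian-windowed 13 Hz spindle
  packets at Poisson times (rate 3/epoch) in N2. EOG electrodes carry
  large slow (0.3–2 Hz) deflections in W (blinks) and REM (rapid eye
  movements). Mastoids carry a 0.2-attenuated copy of the same-side scalp
  average plus independent noise, which keeps mastoid-referenced
  derivations informative. Amplitude ratios were fixed once so that a
  nearest-centroid classifier on log bandpower separates the stages well
  above 0.8 accuracy — the generator's separability contract — and were
  not revisited afterwards.
* **Center effects**: per-dataset hardware gain (a multiplicative factor),
  an optional low-pass filter (second-order Butterworth, applied
  forward-backward), and a scorer confusion matrix that corrupts the
  *stored* labels while the latent truth is retained for diagnostics.
  These emulate hardware variability and inter-scorer disagreement, the
  two components of center shift the resilience experiments manipulate.
* **Masked epochs** (MOVEMENT/UNKNOWN analogues, code −1) carry only the
  noise floor and are excluded from losses and metrics.

What the generator deliberately does *not* model: EMG/respiration/ECG
channels, arousals and apnea events, within-night stage-structure
nonstationarity, realistic EEG microstructure, or electrode artifacts.
Passing tests on these cohorts therefore demonstrate that the *machinery*
is correct and that the qualitative experiment logic behaves as designed —
not that any quantitative result transfers to clinical PSG.

## Preprocessing

`preprocess_recording()` applies, in order: polyphase resampling to the
target rate (default 128 Hz; the desk-scale experiments use 32 Hz),
trimming of signal outside the scored hypnogram, and per-channel,
per-recording robust scaling to median 0 and inter-quartile range 1 with
clipping of absolute values above 20. No band-pass filtering is applied.
Numerical choices that the scaling contract leaves open are fixed for
reproducibility: quartiles use linear interpolation (type 7), and clipping
is applied after rescaling, bounding outputs to [−20, 20] (equivalent to
clipping deviations above 20·IQR up to scaling). A constant channel (IQR
0) is centered but not scaled, with a warning.

## Montage

`recommended_derivations()` intersects the AASM table (F4-M1, C4-M1,
O2-M1, F3-M2, C3-M2, O1-M2; EOG E1-M2, E2-M2) with the electrodes present;
`atypical_derivations()` draws uniformly random ordered pairs of distinct
electrodes (EEG pairs over scalp+mastoid electrodes, EOG pairs anchored at
E1/E2), emulating training with non-conventional derivations. Pre-derived
channels can be represented with the reserved reference `ZERO`.
`enumerate_combinations()` forms the EEG×EOG Cartesian product used by the
majority-vote ensemble (2 EEG × 2 EOG → 4 combinations).

## Sampling and augmentation

A training batch element is drawn hierarchically: dataset by
`P(D) = αP₁ + (1−α)P₂` with `α = 0.5` (P₁ uniform over datasets, P₂
size-proportional); recording uniformly within the dataset; one EEG and
one EOG derivation (uniform over the recommended table, or freshly random
in atypical mode); then a class-balanced segment — a stage uniform over
the stages *present in the recording*, an epoch of that stage uniform, and
the anchor shifted to a uniform position inside the `L`-epoch window, with
the window clamped in-bounds. Sampling classes only among present stages
avoids rejection loops on short recordings; clamping is the simplest
in-bounds rule that keeps anchor placement near-uniform.

Augmentation follows the original recipe: with probability 0.1 a
contiguous fraction of the segment — log-uniform in [0.001, 0.33] — is
replaced by Gaussian noise with the segment's mean and variance 0.01, and
with probability 0.1 at most one channel is entirely replaced. Untouched
samples are bit-identical.

## Network

`build_model()` assembles the encoder/decoder/segment-classifier:

* encoder block: conv(k = 9, stride 1, zero-padded) → ELU → BN → max-pool
  (stride 2); the BN output feeds the skip connection. Default depth 12
  gives a cumulative downsampling of 2¹² = 4096; desk-scale experiments
  use depth 3.
* a bottleneck block, then decoder blocks: nearest-neighbor upsample (×2)
  → conv → ELU → BN → concatenation with the skip → conv → ELU → BN.
* segment classifier: 1-tap conv + tanh (dense segmentation), average
  pooling with kernel = stride = 30 s·fs (one feature vector per epoch),
  then 1-tap conv + ELU + BN and a zero-initialized 1-tap conv + softmax.
  Zero initialization makes the untrained model exactly uniform, a useful
  diagnostic.

Filter counts follow `ceiling(base·√2^block)` (base 5 by default; the
original figure-level schedule is not published, so the schedule is
configurable). Inputs of any whole number of epochs are accepted: the
block is right-padded with zeros to a multiple of 2^depth and outputs are
cropped, preserving the length-agnostic contract.

The normalization family is the package's conditional-learning mechanism
(`conditional_normalize()`, and `norm_mode` in the model config):

* vanilla BN: `h = γ·(f−μ)/σ + β`;
* CCBN: per-group affines `γ_g, β_g`, selected by each sample's condition
  index `g`;
* SaBN: a shared "sandwich" affine cascaded by the per-group affines,
  `h = γ_g·(γ_sa·x̂ + β_sa) + β_g`.

With `γ_sa = 1, β_sa = 0` SaBN reduces exactly to CCBN; with `G = 1` and
`γ_1 = γ` CCBN reduces exactly to vanilla BN — both reductions are tested
at bit level. SaBN replaces every BN layer (encoder, decoder, classifier).
Statistics are computed over the batch and time axes (the 1-D adaptation
of image-style BN). Running estimates for inference use bias-corrected
exponential averaging (rate 0.1): exact after the first batch and tracking
parameter drift with a ~10-batch memory, which keeps inference-mode
normalization faithful during the short desk-scale runs.

## Training

`fit()` minimizes the masked cross-entropy (masked epochs contribute
nothing; probabilities clamped at 1e-12) with Adam (β₁ = 0.9, β₂ = 0.999).
One *iteration* is `batches_per_iteration` optimizer steps followed by one
validation pass — the iteration unit is otherwise arbitrary, and fixing it
makes `patience` and `max_iterations` well-defined. Validation staging
uses a single fixed recommended derivation per recording with epochs
pooled across the validation set, a deliberately cheap but monotone proxy
for the full majority-vote metric. Early stopping requires a *strict*
improvement of validation macro F1; the state at the best-validation
checkpoint is returned, with exact ties resolved toward the most recent
model. The tie rule matters at desk scale: on a small validation pool
the pooled F1 can plateau for several iterations while the fit still
improves, and returning the first plateau checkpoint would discard that
progress. The full-scale defaults mirror the original
training recipe (lr 1e-5, patience 100, max 1000 iterations);
the desk-scale experiments use lr in the 1e-3 range, a few dozen
iterations, and 4–16-element batches of short (L = 1–4) segments, which
on these separable cohorts reach high validation F1 in two to three
minutes of CPU. Short segments also strengthen the effective class
balance (the anchor is 1/L of the loss epochs), which is what lets the
rare N1 stage be learned within the small step budget.

`fine_tune()` continues training with all parameters free at a smaller
learning rate (default 1e-6 full-scale; one tenth of the scratch rate in
the desk-scale experiments). Converting a pretrained vanilla model to
CCBN/SaBN duplicates the learned affines into every group and initializes
the sandwich affine to identity, so pre-fine-tuning predictions are
unchanged for every condition index.

## Evaluation

`predict_recording()` scores the whole recording in one forward pass per
EEG×EOG combination and ensembles the per-combination argmax votes by
majority; ties go to the class with the higher mean predicted probability,
then the lower stage index (a deterministic, probability-aware rule).
Masked epochs are excluded from metrics. `stage_f1()` computes per-class
F1 `2TP/(2TP+FP+FN)` and aggregates either unweighted (macro) or weighted
by true support; by default the average runs over classes present in truth
or prediction, so a short recording missing a stage is not zero-penalized
(`classes = "all"` switches to fixed five-class averaging).
`cohens_kappa()` is the chance-corrected agreement. `evaluate_cohort()`
aggregates per-recording metrics as mean ± population standard deviation,
and `paired_test()` provides the paired t-test (two-sided or one-sided)
across recordings, returning a flagged degenerate result on zero-variance
differences rather than a spurious p-value.

## The three experiments

`run_experiment()` orchestrates desk-scale analogues (defaults: 32 Hz,
depth-3 model, cohorts of tens of recordings with 50–80 epochs each;
every report embeds the resolved configuration and all derived seeds):

* **kind "i" (derivation resilience)**: twin models trained on the same
  cohorts with recommended vs atypical derivations, compared by per-
  recording test F1 and a two-sided paired t-test. Because the generator
  places stage information in all electrodes, the expected outcome is *no
  significant difference*.
* **kind "ii" (center generalization)**: the target center is clean; the
  source centers carry a strong shift (gain ×4, 8 Hz low-pass, scorer
  confusion with 35% error). Direct transfer of the source-pretrained
  model is compared with scratch training and fine-tuning on the target.
  The expected qualitative outcome is DT < S on the shifted target.
  The hardware gain itself is neutralized by robust scaling — by design —
  so the operative shift is the filter and the scorer noise, mirroring
  the observation that label variability dominates center shift.
* **kind "iii" (age conditioning)**: a pooled pretrained model fine-tuned
  pooled (FT), per age group (FT-I), and group-conditioned through SaBN
  (FT-SaBN) for the two-group scheme (babies/children vs the rest) or the
  seven-group scheme, evaluated per group with one-sided paired tests
  against FT. The SaBN model's parameter count exceeds FT's by exactly
  the G extra per-group affine sets (the sandwich affine inherits the
  vanilla affine's size).

Statistical reporting deliberately mirrors paired-per-recording testing
without multiplicity correction and should be read as qualitative at desk
scale.

## Numerical and design notes

* All randomness flows through explicit integer seeds; child seeds are
  derived with a fixed linear-congruential map, so cohorts, batches and
  training histories are bit-reproducible.
* Quartile type, clipping order, anchor clamping, vote tie-breaking and
  the class set of the macro average are all fixed, documented choices
  where the underlying contracts are silent.
* EDF export quantizes to 16-bit integers over each channel's physical
  range; the native RDS container round-trips recordings losslessly.
* Degenerate paths are explicit: constant channels warn and skip scaling;
  all-masked losses warn and return 0; equal-constant raters yield kappa 1
  with a message; zero-variance paired differences return a flagged
  sentinel.

## Limitations

The cohorts are stationary, five-band caricatures of sleep EEG; their
stages are far more separable than clinical data, inter-scorer noise is
symmetric and age effects are step functions. Consequently the absolute
F1/kappa values produced here say nothing about clinical performance —
they validate mechanism, ordering and reproducibility, which is what the
desk-scale experiment suite is for.
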