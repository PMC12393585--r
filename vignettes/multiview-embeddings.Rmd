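---
title: "Multi-view study embeddings: model, training and audit methodology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-view study embeddings: model, training and audit methodology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

An echocardiographic study is a *set* of video clips — a median of about 41
per examination, up to 118 — each already summarised upstream by a vision
foundation model as a fixed-length vector ("view embedding").  Downstream
models want one vector per study.  The conventional recipe classifies each
video into one of 15 view groups and averages within groups, giving a fixed
15 x 512 block.  `mvecho` implements the alternative this package is built
around: a small permutation-invariant transformer (the multi-view encoder,
MVE) that attends over the whole set and compresses it into a single
512-dimensional study embedding, pretrained self-supervised and audited for
demographic shortcut content.

This vignette documents the model, every tunable that matters, the
synthetic cohort the tests run on, the numerical choices, and the known
limitations.  It states no result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The encoder

`encoder_config()` fixes the architecture: 2 pre-norm transformer layers
with 8 attention heads (defaults; both configurable), GELU feed-forward of
width `2 * embed_dim`, and capacity for 128 views with attention masking for
shorter studies.  Views are an unordered set, so there are no positional
encodings; permutation invariance and padding invariance are property-tested
(`test-mve-encoder.R`) at 1e-5 / 1e-6 tolerances.

Where the upstream description leaves the design open we chose:

* **Pooling.**  A learnable aggregation token is prepended; its final-layer
  state is the study embedding.  This keeps pooling inside the attention
  mechanism and differentiable.  `pooling = "masked_mean"` is provided as an
  ablation.
* **Pre-norm blocks** rather than post-norm: they train stably at the small
  scales this package targets, without warmup.
* **Overflow.**  Studies longer than `max_views` are truncated with a
  warning by default (`overflow_policy = "truncate"`); the synthetic data
  cap (118) sits below the capacity (128), so truncation is exceptional.
* **Initialisation.**  Truncated normal, sd 0.02, seeded — every training
  run is bit-reproducible.

The forward and backward passes are written directly in R against BLAS
matrix primitives; gradients of every parameter group are checked against
central finite differences in `test-pretraining.R` (relative tolerance
1e-4 on a small configuration).

## Pretraining objective

`train_mve()` minimises, per batch,

    total = recon + lambda_clin * clinical + sex_CE + race_CE

* **recon** — 50% of each study's views (`mask_ratio`, clamped so at least
  one view is hidden and one visible; a study with a single view is
  skipped) are replaced at the input by a learnable mask token; a linear
  head maps each masked token's output back to the original view embedding
  and is scored by mean squared error over masked positions only.  MSE is
  the natural choice for continuous embedding targets.
* **clinical** — one linear logit per task on the study embedding, mean
  binary cross-entropy over the observed (non-missing) task-study pairs.
  `lambda_clin = 0` removes the term; the default 1 reflects the reading
  that clinical heads are trained together with pretraining.
* **sex_CE / race_CE** — two-layer GELU discriminators (hidden width
  `d / 2`) over 3 sex classes (female/male/unknown) and 4 race classes
  (white/black/other/unknown).  "Unknown" is a real class for the heads.
  The heads receive these losses directly; the encoder receives them
  through a gradient reversal layer (`gradient_reversal()`): identity
  forward, gradient multiplied by `-omega` backward.  Omega never changes
  the forward loss value, only the reversed gradient — asserted by a
  linearity-in-omega test.

Optimisation is AdamW (decoupled weight decay 0.01 on weight matrices
only), learning rate 1e-4 and 50 epochs by default, early stopping on total
validation loss (patience 5) with best-checkpoint restore.  The two
scaled-down experiments below use learning rate 1e-3 and 10 epochs so they
fit in minutes on one CPU; these are the only deviations from the default
optimiser settings and they are fixed inside
`experiment_signal_recovery()` / `experiment_shortcut_suppression()`.

### Making the minimax real

Three defaults exist purely to keep the adversarial game honest, and are
worth understanding before changing:

* `disc_steps = 5`: after each encoder update the discriminator heads take
  five extra AdamW steps on the batch's already-computed embeddings (their
  own optimizer state).  Without this the heads lag the encoder and the
  reversed gradient merely relocates the demographic direction instead of
  shrinking it.
* `head_lr_multiplier = 10`: the heads live on a faster timescale than the
  encoder, the standard two-timescale arrangement for minimax training.
* `head_weight_decay = 0.1`: a confident discriminator saturates its
  softmax and its cross-entropy gradients vanish — exactly when the signal
  is strongest.  Bounding the head norm keeps gradients alive.

Even so, adversarial suppression of a *strong* demographic signal is
limited — see "What the audit shows" below.

## The synthetic cohort

`generate_cohort()` produces data with the statistical structure the
method assumes, so the full pipeline runs with no access-controlled data:

* **View counts** follow a discretised log-normal solved against the three
  published quantiles (median 41, quartiles 34 and 48), truncated to
  [4, 118].  Two free parameters, three matched quantiles.
* **Demographics** are assigned at subject level: 51.5/48.5 female/male
  among knowns with 5.8% unknown; 71.6/18.5/9.9 white/black/other among
  knowns with 6.9% unknown.  The finer race categories are collapsed to
  the 4-way grouping every downstream analysis uses.
* **Latent pathophysiology** is a K-vector (default 8) per subject, shared
  by all of that subject's studies — within-subject correlation is what
  makes subject-based splitting meaningful.  Each of the 15 view types
  exposes only a cyclic window of K/2 latent factors through its own
  loading matrix, so no single view type carries the full state and
  study-level recovery requires integrating several view types.
* **Labels** for the 21-task panel come from a logistic link on the
  latents whose intercept is calibrated by bisection Monte-Carlo
  (`calibrate_intercept()`, tolerance 1e-3) to the published prevalences
  (1.8%–50.1%); per-task missingness mirrors the published missingness
  profile (2%–72%), applied independently per task and study.
* **Demographic shortcut**: every view row receives `s * (g_sex + g_race)`
  where the unit directions `g` are orthogonalised against the span of all
  clinical loadings whenever the ambient dimension allows.  `s = 0`
  disables the shortcut; the generator invariant tests check that a sex
  probe on mean-pooled raw embeddings is at chance for `s = 0` and ≥ 0.8
  for `s = 2 * noise_sd`.
* **Studies per subject**: 80% one study, 15% two, 5% three.  No empirical
  distribution is published for this; the choice only needs to create some
  multi-study subjects so fold-inheritance is exercised.

What the generator does *not* emulate: realistic correlation structure
between demographics and pathophysiology (shortcut and clinical signal are
orthogonal by construction, the cleanest test case but the easiest one),
view-quality variation, temporal drift between repeat studies, or any
realism at the level of the raw videos.  A result on this cohort shows the
machinery works under the stated statistical assumptions, not that the
clinical conclusions transfer.

## Evaluation protocol

Subjects are split 42.5% / 7.5% / 50% (pretrain-train / pretrain-val /
test) by seeded shuffle and largest-remainder rounding; the test half is
evaluated with subject-disjoint 4-fold cross-validation.  Probes are
ridge-penalised logistic regressions (glmnet, `alpha = 0`) on features
standardised with training-fold statistics; `l2_strength` follows the
inverse-strength convention (`lambda = 1 / (C * n)`), default `C = 1`.
Decision thresholds maximise F1 on the training scores over midpoints of
adjacent unique scores (ties toward the lowest threshold); AUC uses the
Mann-Whitney rank form with half credit for ties.  Folds with a
single-class training set are skipped with a warning, and undefined AUCs
are dropped from means rather than imputed — at 1.8% prevalence and desk
scale, empty folds happen.

Demographic predictability uses the same probe family and the same
subject-disjoint folds: sex as female-vs-male among knowns, race as the
macro one-vs-rest AUC over white/black/other.  Subgroup reports rescore the
*same* held-out predictions inside strata (sex, race, and the <20 / 20–39 /
40–59 / ≥60 video-count bins) without refitting.  Model comparisons use a
mixed-effects model `auc ~ model + (1 | task)` (lmerTest) with a paired
fallback below three tasks, and Holm–Bonferroni for multiplicity.

## The two desk-scale experiments

`experiment_signal_recovery(seed)` — ~2,000 studies (1,600 subjects) at
`embed_dim = 64`, 21 calibrated tasks, encoder trained at `omega = 0` for
10 epochs, compared against the 15-slot weighted-averaging baseline on the
same folds.  Because each view type exposes only half the latent factors,
set-level integration is required, and the trained 64-dimensional embedding
outperforms the 960-dimensional slot average by a wide margin (the
acceptance suite requires ≥ 2 AUC points).

`experiment_shortcut_suppression(seed)` — same scale, but the generator
injects a pure additive demographic direction at `s = 2 * noise_sd`,
orthogonal to all clinical loadings, and encoders are trained at
`omega ∈ {0, 0.1, 1}`.

### What the audit shows

Two asymmetric findings, both computed by the acceptance suite:

1. **Clinical cost is real.**  Mean clinical AUC declines monotonically in
   omega; at `omega = 1` it is clearly below `omega = 0.1`.
2. **Probe-level suppression is weak.**  The sex probe on extracted
   embeddings stays near-perfect at every omega.  The per-view offset is
   amplified to roughly `sqrt(41) * s / sigma ≈ 13` standard deviations at
   study level, so the post-hoc probe has an enormous margin; the reversed
   cross-entropy gradient vanishes whenever the discriminator becomes
   confident; and because the value/output projections are shared between
   the aggregation token and the masked-token reconstruction lanes — whose
   targets *contain* the demographic offset — stripping the study embedding
   carries a real reconstruction cost.  The encoder's cheapest response to
   adversarial pressure is to rotate the direction, which a linear probe
   does not care about.  We regard this as a property of gradient-reversal
   debiasing against strong additive signals, not an implementation defect:
   the gradient checks, the omega-linearity test and the discriminator-only
   learning curves all pass, and the same limitation is what the adversarial
   sweep is designed to expose.

## Numerical choices and degenerate inputs

* All computation is double precision; on-disk formats are plain text
  (CSV/YAML/JSON) and checkpoints are RDS.
* Attention masking adds `-Inf` to masked key logits inside a max-shifted
  softmax; a study always has at least one valid key (the aggregation
  token).
* Layer norm uses eps 1e-5.  GELU is the exact Gaussian-CDF form.
* `mask_ratio = 0` or a single-view study yields an empty mask and a zero
  reconstruction term, not an error; `mask_ratio = 1` is rejected.
* Probes on all-constant features return an intercept-only model (chance
  scores) instead of failing; training folds with fewer than two
  observations of a class are skipped with a warning.
* Every stage draws its randomness from `derive_seed(global_seed, stage)`,
  a 31-bit deterministic substream, so rerunning one stage never perturbs
  another and repeat experiments are individually reproducible.

## Problem sizes used by the shipped checks

Unit tests run on cohorts of 5–60 subjects at `embed_dim` 4–16 with 1–3
tasks, plus a handful of medium cohorts (up to 4,000 subjects at
`embed_dim = 2`) for distributional checks.  The two experiments above use
1,600 subjects at `embed_dim = 64` and 10 training epochs.  These sizes
were chosen so the full suite completes on a single CPU in well under half
an hour while keeping every qualitative property measurable.

## Known limitations

* The encoder is trained and evaluated only on synthetic embeddings; no
  claim is made about real echocardiographic data.
* Adversarial debiasing, as shipped, does not remove strong linear
  demographic signal (see above); alternative debiasing families
  (disentanglement, reweighting) are out of scope.
* The mixed-effects comparison implements a random intercept per task
  only; random slopes and richer interaction structure are not modelled.
* Training is single-threaded R; it is fast enough for desk-scale studies
  (minutes), not for 512-dimensional production pretraining.
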