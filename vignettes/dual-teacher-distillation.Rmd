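---
title: "Entropy-gated dual-teacher distillation for motor-imagery EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy-gated dual-teacher distillation for motor-imagery EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Motor-imagery (MI) brain–computer interfaces classify short multi-channel
EEG segments into a handful of imagined-movement classes. Two practical
obstacles dominate: single-trial EEG has a very low signal-to-noise ratio,
and the number of labeled trials per subject is small. Ensembling several
copies of a decoder reliably helps, but an online BCI cannot afford K
forward passes per trial. Knowledge distillation squares this circle —
"train heavy, infer light" — by transferring the ensemble's predictive
distribution into one deployable student.

On top of the accuracy question sits a *stability* question. With scarce,
noisy data, student optimisation is itself noisy: predictions stay flatter
than they should (elevated predictive entropy) and keep fluctuating across
late epochs, which makes final-checkpoint selection unreliable when no
validation split is available. `eegdistill` implements a training recipe
that attacks both: a dual-teacher distillation objective and a two-stage
cosine-annealed schedule, with predictive entropy used both as a per-sample
gating signal during training and as the post-hoc diagnostic of stability.

## The model

Let $z_S(x) \in \mathbb{R}^C$ be the student's logits for trial $x$ with
label $y$, $\sigma_\tau(z) = \mathrm{softmax}(z/\tau)$, and
$\mathrm{KD}(q, z) = \tau^2\,\mathrm{KL}(q \,\|\, \sigma_\tau(z))$ the
temperature-scaled distillation loss. Two teachers provide targets:

* **Ensemble teacher** (offline, fixed): $K$ copies of the backbone are
  trained with plain cross-entropy, member $k$ on the training set minus
  fold $k$ of a balanced $K$-fold split (bagging for diversity). Its target
  is $q_{\mathrm{ens}}(x) = \sigma_\tau\!\big(\tfrac1K \sum_k z^{(k)}(x)\big)$
  — averaged in *logit* space, then softened.
* **EMA teacher** (online): a shadow parameter copy updated after every
  optimiser step as $\theta_{\mathrm{ema}} \leftarrow \alpha\,
  \theta_{\mathrm{ema}} + (1-\alpha)\,\theta$ — a first-order low-pass
  filter on the optimisation trajectory whose logits are temporally
  smoothed versions of the student's own.

The per-sample objective is

$$
L = L_{\mathrm{ce}}
  + \lambda_{\mathrm{ens}}\,\mathrm{KD}(q_{\mathrm{ens}}, z_S)
  + \lambda_{\mathrm{ema}}(e)\, w(x)\,\mathrm{KD}(q_{\mathrm{ema}}, z_S),
$$

where $w(x) = \mathrm{clip}\!\big(\tfrac{h(x) - h_{\mathrm{low}}}
{h_{\mathrm{high}} - h_{\mathrm{low}}}, 0, 1\big)$ is the **entropy gate**,
$h(x)$ the entropy of $q_{\mathrm{ema}}(x)$ normalised by $\log C$. The
gate concentrates EMA smoothing on uncertain samples and switches it off
for confident ones. Batch loss is the arithmetic mean of per-sample totals;
teacher distributions and the gate are constants with respect to gradients
— only the student's parameters are updated.

The run lasts $3N$ epochs under cosine annealing with one warm restart:
Phase I (epochs $1..N$, stage length $N$) trains with cross-entropy and
ensemble KD only ($\lambda_{\mathrm{ema}}(e)=0$); at epoch $N{+}1$ the EMA
teacher is initialised from the student, the learning rate restarts at
$\eta_{\max}$, and Phase II (length $2N$) adds the gated EMA term. Delaying
EMA activation matters because an EMA of an untrained student is a poor
teacher. The deployed model is always the last epoch's student — no early
stopping and no validation split, which is exactly why the stability of the
late-training trajectory is worth engineering for.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `tau` | 4 | distillation temperature (both teachers) |
| `lambda_ens` | 0.5 | ensemble KD weight, all epochs |
| `lambda_ema` | 0.4 | EMA KD weight, Phase II only |
| `h_low`, `h_high` | 0.6, 0.9 | gate knots on normalised entropy |
| `alpha` | 0.995 | EMA smoothing (time constant ≈ 200 steps) |
| `K` | 5 | ensemble members / folds |
| `E_T`, `eta_T` | 750, 1e-3 | teacher epochs and fixed teacher lr |
| `N` | 500 | Phase-I length; total student epochs `3N` |
| `eta_max`, `eta_min` | 1e-3, 1e-5 | student cosine bounds |
| `batch_size`, `weight_decay` | 64, 0.009 | AdamW settings, all fits |

The loss-side constants are the reference settings used across datasets and
backbones; they are deliberately *not* retuned per experiment. The student
learning-rate bounds are not pinned down by the reference protocol, which
prints only the teacher's fixed 1e-3; we reuse 1e-3 as `eta_max` and set
`eta_min = 1e-5`, both exposed in the config and logged per epoch.

One composition subtlety is worth stating: the gate entropy is computed on
the *temperature-softened* EMA distribution $q_{\mathrm{ema}}$ (that is how
the defining equations compose), and at $\tau = 4$ softening pushes
normalised entropy toward 1, so with the reference knots the gate sits near
its open end for most samples. We follow the printed composition rather
than substituting the temperature-1 distribution. The post-hoc entropy
*diagnostics*, by contrast, are defined on the student's temperature-1
probabilities.

Ablation flags reproduce the component analysis: `A1` removes ensemble KD
(EMA still activates at epoch $N{+}1$), `A2` removes the EMA branch
entirely, `A3` replaces the schedule with a fixed 1e-3 learning rate while
leaving all phase bookkeeping untouched, `A4` forces $w(x) \equiv 1$.
`A1+A2` is plain cross-entropy training; the test suite asserts both
equivalences bitwise against reference loops with the ablated module
absent from the code.

## Numerical choices

* Natural logarithms throughout (cross-entropy, KL, entropy); the
  normalisation $h = H/\log C$ is base-independent.
* A floor of $10^{-12}$ inside every logarithm enforces
  $0 \log 0 = 0$ and prevents NaNs without measurably altering values in
  double precision.
* Softmaxes are max-subtracted before exponentiation.
* The sliding-window entropy variance uses the *population* variance
  (divide by the window count): the defining statistic is written as a bare
  variance with no Bessel correction, and the choice is fixed and tested.
  Early epochs use the truncated window `max(1, e - W + 1) .. e`; a
  single-epoch window has variance 0 by convention.
* Argmax ties in evaluation resolve to the lowest class index.
* An empty correct/misclassified subset in the entropy split yields an
  undefined marker (`NA`), never 0.
* Fold sizes differ by at most one trial; per-member teacher seeds, the
  student initialisation seed and each epoch's shuffle seed are derived
  deterministically from the config seed, making every run bitwise
  replayable from its manifest.
* Ensemble logits for the training set are precomputed once before the
  student loop; the teachers are frozen, so caching changes nothing
  numerically.

## Backbones

The package ships three compact convolutional decoders mapping
`(channels × time)` trials to $C$ logits: `tinycnn` (two conv blocks and a
pooled linear head, the default for tests and the desk benchmark),
`eegnet_like` (shared temporal filters, 1×1 spatial mixing across channels,
two pooled stages) and `shallowconvnet_like` (temporal + spatial filtering
followed by square → mean-pool → log band-power features). They are
deliberately normalisation- and dropout-free so every forward is
deterministic and the EMA parameter list is the complete model state;
regularisation comes from AdamW weight decay. The registry
(`register_backbone()`) accepts external architectures — e.g. an
attention-TCN whose parallel branches are aggregated by averaging branch
logits — without touching the trainer. All backbones are implemented on a
small pure-R im2col convolution engine whose analytic gradients are checked
against finite differences in the test suite.

## The synthetic benchmark: what it emulates, and what it does not

All build and test paths run on a synthetic generator rather than the
public MI recordings. Each trial of class $c$ is a Hann-enveloped sinusoid
whose frequency is drawn per trial around a class centre (default centres
3 Hz apart from 10 Hz; Gaussian jitter, sd 1.5 Hz), with lognormal
amplitude variability (unit mean power, sigma 0.5) and random phase, placed
on the class's active channels (by default all classes share the same two
channels, so class identity is carried by spectral content alone) and
scaled to an electrode-level linear SNR — expected signal power per
active-channel sample over the unit noise power — before adding white
Gaussian noise everywhere.

The desk conditions are 3 classes, 4 channels, 256 samples at 128 Hz, 300
training and 150 test trials at SNR 1, a tiny CNN student, `K = 3` teachers
trained 40 epochs, and `N = 20` (60 student epochs), repeated over seeds
1–5 with one independent data draw, teacher bank and student per seed (one
seed plays the role of one subject). These sizes were chosen so the whole
pipeline runs on a single CPU core in minutes; the trial-count-to-geometry
ratio and the resulting single-model accuracy (≈ 0.7–0.85) were calibrated
once to sit in the regime typical of subject-dependent MI benchmarks, so
that the distillation and stability effects are exercised away from both
chance and saturation. Full-scale defaults (`N = 500`, `E_T = 750`,
`K = 5`) remain the config defaults for real runs.

What passing the benchmark shows: the implemented losses, schedule, EMA
dynamics and diagnostics interact as designed on band-limited oscillatory
signals at realistic difficulty. What it does not show: performance on real
EEG. The generator has no volume conduction, no 1/f background, no
artifacts, no event-related desynchronisation dynamics, and its class
structure is far more stationary than real inter-session variability; the
real-data adapter (`load_bnci_trials()`) exists for that purpose and
expects the public per-subject recordings converted to a plain-text
signal/events layout, cropped to the 0.5 s pre-cue / 4 s post-cue window at
250 Hz (`T = 1125`) with no further preprocessing.

## Entropy diagnostics

Three post-hoc analyses connect training dynamics to the predictive
distribution, all on temperature-1 student probabilities of the test set:

1. **Correct/wrong entropy trajectories** — per epoch, mean entropy over
   correctly and incorrectly classified samples separately.
2. **Fluctuation score** — per sample, the population variance of its
   entropy over the last `W = 20` epochs; averaged over samples.
3. **Delta correlations** — across subjects, the Pearson correlation
   between the accuracy gain of the full method over a baseline arm and
   that arm's entropy (or fluctuation) excess.

The benchmark checks assert, at seed-majority level, the two qualitative
signatures this recipe is designed to produce: lower late-stage test
entropy for the dual-teacher student than for the ensemble-only ablation,
and higher late-stage entropy fluctuation for the fixed-learning-rate
ablation than for both cosine arms. A caveat applies to both at desk
scale. The EMA smoothing coefficient `alpha = 0.995` corresponds to a time
constant of about 200 optimiser steps — which is the *whole* of Phase II
at the desk sizes (40 epochs × 5 batches), whereas at full scale Phase II
is over an order of magnitude longer than the time constant. A lagging EMA
teacher serves systematically flatter targets, which works against the
entropy-decrease signature; and the 20-epoch fluctuation windows of a
60-epoch run reach back into the cosine arms' own warm-restart transient,
which works against the fluctuation contrast. The acceptance checks state
the signatures as designed and report honestly whether the desk horizon
reproduces them; the accuracy contract (the distilled student does not
fall behind plain cross-entropy training) is asserted the same way.

## Known limitations

* The convolution engine is plain R: fine at desk scale (minutes per
  benchmark), not intended for full-scale runs (1500 epochs × 9 subjects ×
  3 backbones) that the reference protocol performs on GPUs.
* No dropout or normalisation layers; the EMA-over-parameters question for
  normalisation running statistics therefore does not arise here. If a
  registered external backbone carries such state, it must fold it into the
  parameter list to be EMA-averaged.
* Pooling is non-overlapping, and the EEGNet/ShallowConvNet variants are
  compact reinterpretations, not layer-for-layer ports.
* The `2a`/`2b` adapter reads a documented plain-text export of the public
  matrix layout rather than the original binary files; conversion is a
  one-off external step.
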