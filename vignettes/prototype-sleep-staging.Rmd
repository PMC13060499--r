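---
title: "Prototype-quantized sleep staging: model, explanations and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prototype-quantized sleep staging: model, explanations and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepproto)
```

## The problem and the model

Overnight polysomnography (PSG) is scored in 30-second epochs into five
stages (Wake, N1, N2, N3, REM). Sequence-to-sequence stagers reach
human-level agreement but act as black boxes, and they describe only sleep
*macro*-structure — the stage sequence — while much of the clinically
interesting signal lives in *micro*-structure: spindles, slow waves, eye
movements, muscle tone, and their combinations within epochs.

`sleepproto` implements a sequence-to-sequence stager whose decisions are
forced through a discrete bottleneck: every epoch embedding is vector-
quantized onto one of `P` learnable prototype vectors before the sequence
encoder sees it. Because inference is constant within each prototype's
assignment region, a prototype is a faithful summary of how the model treats
all epochs assigned to it, and the per-night sequence of assignments (the
*prototype-gram*) is a compact micro-structure descriptor that downstream
clinical analyses can consume.

The forward pipeline for a batch of `L = 21` consecutive epochs, each a
`C = 3` channel (EEG, EOG, EMG) time-frequency image of `T = 29` frames by
`F = 129` bins, is:

1. **Frame projection.** Each frame's frequency profile is mapped
   independently to a `D`-vector by a learnable linear filterbank over `F`
   plus `tanh`. The map is strictly frame-local: perturbing frame *t* can
   change only output frame *t*. This locality is a tested contract — it is
   what makes the later mask interpretable as a window over the input frames.
2. **Time-wise hard-attention masking.** All contiguous windows with lengths
   in a configured set are pre-enumerated (`build_candidate_masks()`).
   Per-frame logits over the candidates are softmaxed and summed into a vote
   distribution; a Gumbel-softmax draw (straight-through in hard mode) picks
   exactly one window, and the epoch embedding is the mean of the retained
   frames. Soft attention can scatter weight over non-adjacent frames; the
   hard contiguous mask cannot, which keeps the pooled evidence temporally
   coherent. The learned mask is an aggregation mechanism, not an
   explanation artifact: the explanation framework below never reads it.
3. **Channel mixing with adaptive channel dropout.** The three channel
   embeddings are fused by a gated residual attention over the channel axis;
   with the gate at its zero initialization the fusion is exactly the channel
   mean. During training a channel is occluded (zeroed) with probability
   proportional to its recent single-channel accuracy, so individually strong
   channels — usually EEG — are hidden most often and the model cannot
   collapse onto one modality.
4. **Prototype quantization.** The mixed embedding is snapped to its most
   cosine-similar codebook row (ties to the lowest index). The forward value
   is the codebook row exactly; the backward pass copies the gradient to the
   embedding unchanged (straight-through), and a commitment loss
   `2 - sim(CM, P)` pulls embeddings and prototypes together.
5. **Sequence encoding and heads.** A gated bidirectional temporal
   convolution over the `L` axis adds sequence context, and a shared linear
   head produces stage logits at three residual depths (post-mixing,
   post-quantization, post-sequence-encoding). The per-depth cross-entropies
   are summed, which both regularizes and attributes improvement to blocks.

### Identity at initialization and the quantizer warm-up

All residual blocks carry a scalar gate initialized at zero, so the network
is an exact identity across depths at initialization. A pure straight-through
replacement at the prototype layer cannot be the identity (the codebook is
random at the start), so the quantization block runs as a pass-through for
the first `vq_warmup_frac` (default 0.3) of planned updates and as exact
replacement afterwards. This keeps both desired properties exact rather than
approximate: per-depth logits agree to machine precision at initialization,
and for a trained model the final predictions depend on the mixed embedding
*only* through the selected codebook rows — replacing the embedding by its
prototype before the sequence encoder leaves evaluation outputs bit-identical
(both are tested).

### Parameters that matter

| parameter | default | role |
|---|---|---|
| `L` | 21 epochs | sequence context length |
| `D` | 32 | embedding width |
| `P` | 15 | prototype count; more prototypes trade interpretability for resolution |
| `mask_lengths` | 5, 9, 15, 21, 29 frames | candidate window lengths (10–58 s of the 2-s-frame epoch); a stride-1 enumeration of these lengths gives 71 candidates, against 435 for all lengths 1–29 |
| `dropout_rate` | 0.25 | channel-dropout event probability per epoch |
| `commit_weight` | 0.25 | commitment term weight in the total loss |
| `tau_start`, `tau_end` | 1.0 → 0.3 | linear Gumbel temperature annealing over training |
| `vq_warmup_frac` | 0.3 | fraction of updates with the quantizer pass-through |
| `lr`, `clip` | 1e-3, 5 | Adam step size and gradient-norm clip |

The codebook is parameterized as a frozen random basis times a trainable
linear map (`codebook_method = "simvq"`), so every prototype moves under
every gradient step; a directly trainable codebook is available via
`"plain"`. Dead prototypes (unused for a full training epoch) are
re-initialized near the most-used prototype at epoch boundaries. The
commitment loss is applied symmetrically to both the embedding and the
selected prototype, following its printed form; the classic one-sided
stop-gradient variant was not adopted because task gradients never reach the
codebook here, so the symmetric term is the codebook's only learning signal.

## Preprocessing

EDF recordings are resampled to 100 Hz (polyphase rational resampling),
EEG/EOG band-passed to [0.3, 40] Hz and EMG high-passed at 10 Hz with
4th-order Butterworth filters applied forward-backward — zero-phase filtering
avoids smearing stage boundaries. Each channel is standardized to zero mean
and unit variance per recording, divided into 30-s epochs, and transformed
with 2-s Hamming windows at 50% overlap and a 256-point FFT; the amplitude
spectrum in dB (`20*log10(|A| + 1e-12)`) is clipped below at −25 dB. A 30-s
epoch at 100 Hz therefore yields exactly `T = floor((3000−200)/100)+1 = 29`
frames and `F = 256/2+1 = 129` bins. Leading and trailing Wake runs are
trimmed to a configurable margin (default 60 epochs = 30 min) around the
first and last sleep epoch; the margin is this package's choice of a common
convention, as is epoch/label alignment (epoch *n* covers samples
`[n·3000, (n+1)·3000)`, 0-based, half-open).

## The synthetic generator

`generate_recording()` produces stage-labeled PSG that carries exactly the
features the pipeline consumes: per-stage EEG band powers realized as
band-limited Gaussian noise mixed by template weights; EOG blink events
(300-ms biphasic kernel, 0.5–2 Hz content) and rapid eye movements (150-ms
alternating-polarity kernel, 2–5 Hz content) at Poisson rates; EMG tone as
amplitude-modulated broadband noise; and a Markov stage chain with strong
self-transitions. Default templates encode textbook stage physiology
(beta/alpha-rich Wake with blinks and high tone, sigma/delta N2, delta N3,
wake-like EEG with dense REMs and atonia in REM). `generate_cohort()` derives
per-subject seeds as master + index and applies per-condition multiplicative
shifts to transition rows (renormalized) and band powers, planting the group
differences the clinical pipeline is meant to detect.

What the generator deliberately does **not** emulate: volume-conducted
artifacts, apneas/arousals and other microevents, scorer disagreement,
non-stationary electrode drift, and realistic 1/f background structure.
Passing tests on this data show the machinery is correct and sensitive to
planted spectral/occupancy effects; they do not certify staging accuracy on
real recordings.

## The explanation framework

*Local.* The relevance of each input cell to a prototype assignment is the
integrated gradient of the cosine similarity between the epoch encoding and
the prototype, along the straight path from a baseline (the per-cell mean of
a reference epoch set — the package uses the training epochs, configurable)
to the instance. The integral uses the midpoint rule (default 64 points). The
hard mask is frozen at the instance's selected window along the path; this
makes the attributed function smooth, so the completeness identity
`sum(relevance) = sim(instance) − sim(baseline)` holds up to the Riemann
error, which `local_relevance()` reports as `completeness_gap`.

*Global.* Prototypes live in embedding space, so they are visualized through
input-space reconstructions: nearest training epochs (`data_driven`),
projected gradient ascent on the similarity from noise (`model_driven`), or
ascent seeded with the nearest epochs (`hybrid`). Ascent uses backtracking
step-halving with an accept-only-on-improvement rule, so fidelity is
non-decreasing by construction; iterates are kept above the −25 dB input
floor. Three metrics score the strategies: **fidelity** (cosine similarity of
the reconstruction's embedding to the prototype), **plausibility** (squared
MMD between the optimized batch and the empirical neighbors; the biased
V-statistic estimator is used here so that the data-driven strategy scores
exactly 0 against itself and the score is nonnegative), and **stability**
(mean pairwise MMD of reconstruction batches across independent datasets).
The MMD kernel is a Gaussian RBF with bandwidth set by the median pairwise
distance of the pooled sample. The general `mmd()` defaults to the unbiased
estimator, which can be slightly negative by design.

*Feature level.* Element-wise maps are too granular for clinical reading, so
relevance is aggregated over physiological feature groups — EEG bands (delta
0.5–4, theta 4–8, alpha 8–12, sigma 12–16, beta 16–30, gamma 30–40 Hz), EOG
components (SEMs 0.3–1 Hz, blinks 0.5–2 Hz, REMs 2–5 Hz, residual > 5 Hz; the
SEM and blink bands overlap by construction) and overall EMG tone — by an
occlusion strategy: replace the group's cells with the baseline values and
record the similarity drop, averaged over the reconstruction batch. Theta,
alpha and gamma edges follow AASM convention within the 40 Hz passband; the
SEM band is this package's assignment since slow eye movements have no
standard spectral definition. Occlusion relevances are not additive across
groups unless the encoder is linear. Features passing a relevance threshold
(default 0.05) are rendered as natural-language clauses with the feature's
mean power and a ↑/↓ indicator versus baseline, ordered by absolute
relevance.

## Clinical prototype-gram analysis

Per subject, `time_in_prototype()` turns a protogram into occupancy features
(hours or fractions). `monte_carlo_cv()` draws a stratified test set of 8
subjects per condition, fits an L2-penalized multinomial logistic classifier
(weight decay 1.0, features standardized on the training fold) and reports
one-vs-rest AUC per condition, accuracy and macro-F1 over 20 repeats; AUC is
computed per repeat and then averaged, and a leakage guard asserts train/test
disjointness in every repeat. Group differences in occupancy use two-sided
Mann–Whitney U tests — exact when the combined group size is ≤ 20 and
tie-free, normal approximation with tie correction otherwise — under
Benjamini–Hochberg correction across the `P` features (the correction method
is this package's choice; only that *a* correction is applied is inherited).

## Numerical choices and degenerate inputs

- Pooling stabilizer `eps = 1e-6`; an all-zero mask yields a zero embedding.
- Cosine similarities are guarded at norm `1e-12`; a zero vector warns and
  scores 0.
- Argmax ties (quantization and mask selection) break to the lowest index,
  making evaluation fully deterministic.
- All-Wake recordings pass `trim_wake()` unchanged with a warning flag;
  empty batches and out-of-range labels raise validation errors; non-finite
  training loss aborts with the last loss components in the message.
- All stochastic components (generator, Gumbel draws, dropout, CV splits)
  take explicit seeds and restore the caller's RNG state.

## Scaled-down study sizes

The test suite and the acceptance script exercise the full pipeline at desk
scale, a deliberate configuration of this package: models with `D = 16`,
`P ∈ {4, 8}`, `L = 5` trained for ~300 Adam updates on 200–360-epoch
synthetic recordings; reconstruction batches of 8–16 (the API default is
256); 2,000-epoch chains for occupancy checks; cohorts of 10 subjects per
condition with 100-epoch nights. With two to four well-separated planted
spectral classes these sizes are sufficient for the stager to reach its
asymptote and for the planted effects to be detected, while a full run of
suite plus acceptance script stays within minutes on one CPU core.

## Known limitations

- The gradient engine is purpose-built for this architecture; swapping in an
  arbitrary epoch encoder requires providing its forward/backward pair.
- The reference sequence encoder is convolutional over `L`; recurrent or
  transformer alternatives fit the same interface but are not included.
- Training is single-threaded, full-precision, CPU-only; the implementation
  targets method fidelity and testability at desk scale, not throughput on
  10,000-night corpora.
- Only the continuous-recording EDF subset is read; EDF+ annotations are not
  parsed (hypnograms are read from sidecar text files).
- Synthetic validation bounds what can be claimed about real PSG; see the
  generator section above.
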