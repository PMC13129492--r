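---
title: "Methods: federated CNN-LSTM stress monitoring on synthetic herds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: federated CNN-LSTM stress monitoring on synthetic herds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fedherd)
```

This vignette is the package's own account of what it models, the choices
that were genuinely open, and what its tests do and do not demonstrate.

## The problem and the modelling setup

Wearable sensors on dairy cattle produce multimodal time series — heart
rate (bpm), core body temperature (°C), an accelerometer-derived activity
index, plus ambient temperature, humidity and GPS. Clinical stress ground
truth is rarely available, so supervision comes from *proxy labels*:
veterinary threshold rules flag a sample as physiologically stressed when
heart rate exceeds 100 bpm or body temperature exceeds 39.5 °C. These are
indicators of possible stress, not diagnoses, and everything downstream
inherits that caveat.

Raw streams stay on the farm: each simulated edge client (a farm gateway
holding a disjoint set of animals) trains a local copy of the model, and a
server aggregates parameter vectors only. Aggregation is sample-size
weighted federated averaging,

$$k^{t+1} = \sum_y \frac{|X_y|}{\sum_j |X_j|}\, k_y^{t},$$

iterated over communication rounds of $E$ local epochs each. Because each
client owns different animals with different baselines, the client
distributions differ — the non-IID regime that makes federated averaging
non-trivial.

## The synthetic herd generator

No public labelled ground truth exists at desk scale, so the generator is
a first-class, tested component, not a fixture. It emulates the
statistical structure a multimodal cattle dataset exhibits:

* **Per-animal baselines** drawn once per animal: heart rate
  $\mathcal N(70, 5^2)$ bpm, temperature $\mathcal N(38.5, 0.2^2)$ °C,
  activity $\mathcal N(0.3, 0.1^2)$ (non-negative, unitless). Within-animal
  measurement noise: 3 bpm, 0.1 °C, 0.05 respectively. Baselines sit more
  than four combined standard deviations below the label thresholds, so an
  unstressed animal essentially never crosses them; labels are driven by
  episodes.
* **Stress episodes** arrive per animal as a Poisson process (default 2
  per animal-day) and last 60 minutes; during an episode heart rate is
  raised by 40 bpm, temperature by 1.5 °C, and the activity index shifted
  by +0.2, all plus noise. Episodes are animal-level intervals rather than
  per-row coin flips so that 30-minute rolling features have temporal
  structure to exploit.
* **Environment**: a shared sinusoidal diurnal ambient cycle (mean 22 °C,
  amplitude 6 °C, warmest mid-afternoon) and Gaussian humidity clipped to
  [0, 100] %.
* **GPS** is a small-step random walk around a paddock origin — enough to
  exercise the schema, with no behavioural content. The activity index and
  GPS dynamics have no published numeric ranges; the defaults above are
  declared choices, not inferences.
* **Sampling**: one row per animal per 15 minutes. At that interval a
  30-minute trailing window spans 2–3 samples, which is the regime the
  rolling-feature arithmetic is designed around.
* **Faults** are injected separately: physiological cells go missing in
  geometric-length runs (default mean run length 1, i.e. independent
  cells) and spike outliers are displaced by at least 6 feature standard
  deviations — far enough past the z = 3 screen that the preprocessing
  pipeline can provably remove them.

Every stage draws its seed from a master seed via a tagged hash
(`sub_seed(master, "stage", ...)`), so toggling fault injection never
perturbs the base signals, and identical configurations are bit-identical
on disk.

What the generator does **not** emulate: sensor drift and calibration
error, circadian physiology beyond the ambient cycle, behavioural
coupling between animals, heat-stress correlation between ambient
conditions and episodes, or the marginal distributions of any real herd.
Passing tests on this herd demonstrate that the machinery is correct, not
that the classifier would reach the same numbers on real cattle.

## Preprocessing

The pipeline runs per client table in a fixed order:

1. **Fill**: per animal and feature, forward fill then backward fill —
   values are carried verbatim, never interpolated. An animal with zero
   observations for a feature is an error rather than a silent zero.
2. **Outlier removal**: means and standard deviations are computed over
   the whole client table (not per animal), and any row with |z| > 3 on
   heart rate, temperature or activity is dropped whole. A zero-variance
   feature flags nothing.
3. **Rolling features**: trailing, current-sample-inclusive time windows
   of 30 minutes; rolling means of heart rate and temperature, rolling
   *population* variance (divide by n) of activity, so the two-sample
   window {0.2, 0.4} has variance exactly 0.01. Causality is deliberate:
   an edge device cannot see the future.
4. **Labels** are computed from *raw-unit* heart rate and temperature
   with strict inequalities (100.0 bpm is normal, 100.1 is not). Because
   100 bpm and 39.5 °C are only meaningful before scaling, the label step
   is ordered before normalization and guarded: a table whose heart rates
   are all ≤ 1 is rejected as evidence the pipeline was run out of order.
5. **Min–max scaling** to [0, 1]. Bounds are learned on training clients
   only, frozen, shipped with the model, and applied verbatim at
   inference with clipping; degenerate features map to 0.

Windowing cuts per-animal sliding windows of 8 samples (2 h of context),
stride 1 for training and stride 8 (non-overlapping tiling) for
reporting; a window's label is its final row's label, i.e. detection at
window end. Eight-sample windows with the default model features — the
five numeric sensor channels plus the three rolling features, GPS
excluded — are the model's input unit. None of these windowing constants
are externally prescribed; they are package defaults chosen so a window
covers a meaningful fraction of a one-hour episode.

## The model and its training

The classifier is a hybrid: a 1-D temporal convolution front-end (valid
cross-correlation + ReLU) extracts local patterns from the sensor window,
and a single-layer LSTM integrates them over time. The printed equation
set for the cell omits the forget gate; the implementation completes it
in the only way consistent with the cell-state update,
$f_t = \sigma(W_f [h_{t-1}, x_t] + b_f)$, and reads the candidate term as
$\tilde c_t = \tanh(W_c [h_{t-1}, x_t] + b_c)$. The head is a single
sigmoid logit; this is exactly the two-class softmax (softmax class-1
probability of logits $(0, u)$ equals $\sigma(u)$), which reconciles a
softmax output layer with a binary cross-entropy loss. The visual branch
a camera deployment would add is out of scope: on sensor-only input the
convolution is temporal.

Training is mini-batch Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e-8) on the mean
binary cross-entropy, probabilities clipped to [1e-7, 1−1e-7]. Gradients
are hand-derived backpropagation through time, verified against central
finite differences in the test suite. Parameters are stored as R doubles;
the *deployment* payload is accounted at 32 bits per parameter plus a
64-byte header, and that is the size the communication ledger uses. The
serialization container itself stores float64 so that round-trips are
bit-exact.

Numerical conventions worth stating: weights initialize uniform on
(−0.3, 0.3) with zero biases. The relatively large half-width is
deliberate — with very small initializations the LSTM starts in a regime
where the output is almost input-independent, and short federated
schedules (5 local epochs per round from a fresh optimizer state) can sit
at the constant-prior predictor indefinitely, while long uninterrupted
centralized schedules eventually escape. A stronger symmetry break removes
that asymmetry between the two arms.

Two configurations play distinct roles. The **shipped default**
(`model_config()`: 16 conv channels, kernel 3, LSTM hidden 256, dense 64;
296,465 parameters ≈ 1.13 MiB at 32-bit) represents the deployment-scale
model inside the 1–2 MB payload band that the communication-cost
arithmetic assumes. The **benchmark configuration** (8 channels, hidden
16, dense 8; 1,945 parameters) is the package's choice for the end-to-end
study so that the full two-arm experiment remains a minutes-scale,
single-CPU computation; the learning problem it must solve is identical.

## Federated orchestration

Each round: sample ⌈participation · n⌉ clients without replacement
(seeded per round), broadcast the global parameters, run E = 5 local
epochs of Adam per client *with fresh optimizer state* (stateless
clients match the broadcast-then-train reading of the procedure; whether
moments persist across rounds is unspecified, and statelessness is the
deployment-realistic choice), aggregate with FedAvg, evaluate on the
held-out animals, append ledger entries. Aggregation folds updates in
client-id-sorted order so the result is bit-identical under any
permutation of the update list. With one client, the whole procedure
reduces exactly — bit for bit — to centralized training, which the suite
asserts.

The held-out set is 20 % of animals, never assigned to any client; the
train/test protocol is the package's own, as is the window-level (rather
than animal-level) metric granularity. The centralized baseline uses the
same architecture and optimizer on pooled windows for rounds × epochs
epochs, so optimization budgets match. The ledger counts
participants × payload bytes per round in each direction, with
1 MB = 2^20 bytes documented everywhere. Encryption, stragglers,
differential privacy and real transport are interface-level concerns only
and are not simulated; advanced aggregation schemes (FedProx, SCAFFOLD)
are out of scope.

## What the benchmark shows — and what it cannot

The headline end-to-end check trains on the default synthetic herd (20
animals, 7 days, 15-minute sampling, 10 clients, 20 rounds × 5 epochs,
master seed 42) and asserts held-out window-level F1 ≥ 0.85, accuracy
≥ 0.90, and federated accuracy within 3 percentage points of the matched
centralized run. On this herd both arms in fact reach F1 = 1.0: the proxy
label is a deterministic threshold function of two features the model
observes, so with correct preprocessing the task is realizable exactly,
and the benchmark is best read as a stringent integration test of
generator → pipeline → optimizer → aggregator. Real sensor data, where
labels are noisy and the signal is not a function of the inputs, would
sit well below that ceiling; reproducing any particular published number
on an external dataset is explicitly not claimed.

Degenerate inputs are handled conservatively: empty herds produce empty
tables with full headers; animals shorter than one window yield zero
windows; empty clients are skipped with a warning and weight zero;
undefined precision/recall are reported as 0 with a warning; a
probability exactly at the 0.5 decision threshold is classified negative
(strict inequality).

## Reproducibility

One master seed determines every stream through tagged sub-seeds; the
experiment manifest (config hash, stage seeds, problem sizes) plus the
config document reproduce any run exactly. `scripts/acceptance.R`
re-derives the communication totals, the default model size and the full
benchmark from scratch under a caller-supplied seed.
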