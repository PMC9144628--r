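---
title: "Methods: attention convolution networks and meta-learning for sEMG gesture decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: attention convolution networks and meta-learning for sEMG gesture decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Surface electromyography recorded by a dense electrode grid (HD-sEMG)
carries enough information to decode hand gestures, but the signal is
strongly subject-specific: skin impedance, muscle geometry and — above all —
electrode placement differ between users and between donning sessions. A
classifier trained conventionally on a cohort of subjects can exceed 90%
accuracy on held-out trials of those same subjects yet collapse toward
chance on a new subject. `semgmeta` implements a pipeline whose goal is
*fast adaptation*: a model whose parameters are explicitly optimized so
that a handful of labelled examples from a new subject (an N-way K-shot
support set) suffice to recover high accuracy after one or a few gradient
steps.

## Pipeline and model

**Preprocessing.** Each raw recording (C channels × T samples at 1 kHz) is
band-stop filtered at 45–55 Hz with a second-order Butterworth design to
remove 50 Hz powerline interference. Filtering is applied
forward-backward (zero-phase), a choice we make explicit because the
downstream window is analyzed time-locked; zero-phase filtering squares
the magnitude response, which only deepens the stop band. The middle
one-second window (start index `floor((T − L)/2)`, ties toward the earlier
sample) is then cut out, giving the canonical 1000-sample multichannel
analysis unit, and each channel is z-scored (SD floored at 1e−12; constant
channels map to zero). Normalization is applied to the time signal, before
any spectral transform.

**Features.** The principal representation is the per-channel short-time
Fourier magnitude spectrogram with a Hanning window of 64 samples. The
frame hop is 29 samples with full-support frames (no centering, no
padding): `floor((1000 − 64)/29) + 1 = 33` frames by `64/2 + 1 = 33`
one-sided bins, i.e. a 33 × 33 time–frequency image per electrode. The
hop is the one free parameter of this geometry and 29 is the unique value
reproducing the 33 × 33 shape under full-support framing. Magnitude (not
power, not dB) is the default; a `log1p` compression is exposed as an
option and is switched on in the packaged synthetic studies because it
stabilizes the variance of magnitude bins, whose signal-to-noise ratio per
pixel is otherwise of order one. Alternative representations — one-sided
FFT magnitude spectrum, the raw 1000 × C signal image, and sliding-window
mean absolute value (MAV, 200 ms windows advanced by 25 ms → 33 windows) —
are provided for baseline comparisons. MAV is computed on `|x|`; the name
denotes the mean *absolute* value even where the defining sum is sometimes
printed without the modulus.

**Network.** CSAC-Net consists of three attention–convolution cells and a
softmax classifier. Each cell applies:

1. a 3×3 convolution (padding 1) from C1 to C2 feature maps;
2. a channel–spatial attention module (CSAM): channel attention
   `Y = X · σ(W₂ δ(W₁ (GAP + GMP)))` — global average plus max pooling per
   channel, a bottleneck of ratio r = 4, ReLU δ and sigmoid σ — followed
   by spatial attention `Y = X · σ(W₃ δ(w₁ GAP + w₂ GMP))`, where the
   poolings here run across channels per pixel, w₁ and w₂ are scalar 1×1
   maps and W₃ is a single 7×7 convolution producing one attention map;
3. batch normalization, ReLU, and 2×2 max pooling with stride 2.

Sigmoid gating realizes the soft-threshold behavior — attention values lie
strictly in (0, 1), so gated features are attenuated, never amplified.
For a 33 × 33 input the spatial sizes run 33 → 16 → 8 → 4 and the
classifier sees the flattened 4 × 4 × C3 tensor. The full-scale channel
plan is 128 → 64 → 64 → 32 (a 512-dimensional flattened feature); the
small synthetic studies use compact plans (16 → 8 → 8 → 8 for the
adaptation study, 16 → 16 → 16 → 8 for the transfer study). Kernel sizes, widths,
padding and the classifier width are design choices of this package: the
architecture's defining elements are the cell structure and the attention
algebra above. Inputs whose final maps exceed 4 × 4 (raw-signal or
spectrum images) are reduced by adaptive average pooling so the classifier
width is input-independent. Max pooling no-ops on spatial dimensions
smaller than its kernel, so degenerate (tiny) inputs still flow through
all three cells — convenient for gradient checking.

Ablation variants replace attention stages by a *depthwise* 3×3
convolution (one filter per channel): `sac` drops channel attention,
`cac` drops spatial attention, `cnn` drops both. A dense channel-mixing
replacement would add ~9C² parameters per cell and change model capacity
by >50%; the depthwise form keeps the parameter counts of all four
variants within a few percent of each other, which is the point of the
ablation ("keep the overall complexity unchanged").

All forward and backward passes are implemented in the package (C++
kernels via RcppArmadillo; im2col+GEMM convolutions). Analytic gradients
of every stage and of the composed network agree with central finite
differences to relative error below 1e−4 in the test suite (typically
~1e−9).

**Episodes.** An N-way K-shot task draws N classes uniformly without
replacement, then 2K distinct samples per class — K into the support set,
K into the query set. Support and query therefore share exactly the same
N classes but never share a sample; labels are remapped per task. This
follows the standard protocol (and the verbal description "half for
training, half for verification"); a formulation in which support and
query *class* sets are disjoint would leave query classification undefined
under a support-adapted N-way head and is not implemented. Top-k accuracy
uses the conventional definition (true label among the k best-scored
classes), which is non-decreasing in k; reported "top-5 below top-1"
values in some tables of the source literature are not reproducible under
any standard definition and are not emulated.

**Meta-learning.** MAML with the usual two loops. Inner loop:
`θ′ = θ − α ∇θ L_support(θ)`, with fast rate α = 0.1 and one step during
meta-training (more steps at test time, where one iterates "until best").
Outer loop: Adam at meta-rate β on the query loss of the adapted
parameters, averaged over a meta-batch of 8 tasks. With
`second_order = TRUE` (the default) the meta-gradient is
`(I − α H_support(θ)) ∇ L_query(θ′)` per inner step, applied recursively
along the inner trajectory; the Hessian-vector product is computed by
finite differences of the support gradient (step scaled to parameter
norm) — central differences by default, or forward differences that
reuse the inner loop's gradient at one extra evaluation per step
(`hvp = "forward"`). This is exact algebra with a numerical HVP rather
than a second differentiation pass. `second_order = FALSE` gives first-order
MAML (the query gradient at θ′). Batch normalization uses batch
statistics during adaptation and query evaluation, the transductive
convention of episodic evaluation; running statistics are maintained only
by the conventional supervised trainer.

For meta-learned models the classifier weights start at zero
(`init_params(..., zero_head = TRUE)`): one inner step from a zero head
scores query samples by the inner product with class-mean support
features, so adaptation is meaningful from the first meta-update and
meta-training concentrates on shaping the feature extractor. This is an
initialization convention, not an algorithm change.

## The synthetic data generator

Every stage is testable without external data through a generator that
emulates the structure of grid-electrode gesture recordings:

* **Gesture identity is spatial.** Each gesture g has a fixed Gaussian
  activation envelope E_g over the electrode grid (amplitude 1, width 2
  electrodes, centers spread deterministically over the grid), mimicking
  which muscle regions a gesture recruits.
* **The carrier is stochastic.** Channel c of a recording is
  `gain_s · E_g(shift_s(c)) · carrier(t) + noise + powerline`: a fresh
  band-limited Gaussian carrier (20–150 Hz, 4th-order Butterworth,
  unit RMS) per channel and repetition — sEMG is noise-like, so two
  repetitions of the same gesture share statistics, never waveforms.
* **Subjects perturb the map.** Per subject: a log-normal gain
  (SD 0.2 easy / 0.5 strong), a circular electrode-column shift (≤1
  easy / ≤2 strong) emulating whole-column electrode-band offset, and —
  in the strong-shift profile — a continuous 2-D displacement of every
  activation center (SD 0.75 electrodes), the fractional placement
  offset that makes a new subject's activation maps genuinely novel
  (an integer shift on a small grid can recur across subjects; a
  continuous offset cannot). Column distances wrap circularly, as the
  electrode band wraps around the limb. Plus white sensor noise
  (SD 0.3) and 50 Hz powerline interference (relative amplitude 0.2,
  common phase across channels per recording).

Because preprocessing z-scores every channel, absolute amplitude is
deliberately destroyed; what survives is each channel's *band-power
contrast* (carrier-band versus broadband noise floor), which encodes
E_g(c) through the per-channel signal-to-noise ratio. A nearest-centroid
classifier on time-averaged log spectral profiles separates the easy
profile's classes perfectly within a subject, which the test suite uses
as the separability oracle. What the generator does *not* emulate:
motor-unit action potentials and their firing statistics, force-dependent
spectral compression, inter-channel propagation correlation, electrode
artifacts. Passing tests on this generator therefore demonstrate correct
mechanics and the qualitative phenomena (adaptability, subject-transfer
failure), not clinical-grade performance.

## Study conditions and problem sizes

The packaged studies (`adaptation_study()`, `transfer_study()`, also run
by `scripts/acceptance.R`) are sized for a single workstation CPU:

* **Easy profile**: 8 subjects × 8 gestures × 25 repetitions, 4×4 grid,
  1 s at 1000 Hz. Subjects 1–6 meta-train, 7 meta-validates, 8 is the
  held-out meta-test subject. The 25 repetitions correspond to a longer
  acquisition session per subject and are what make the small-sample
  regime learnable for a convolutional model trained on spectrogram
  pixels (with 10 repetitions the network memorizes per-sample carrier
  noise long before it generalizes).
* **Adaptation study**: 5-way 5-shot, 300 meta-batches × 8 tasks (2400
  tasks), second-order meta-gradients with the forward-difference
  Hessian-vector product, fast rate α = 0.1, outer Adam at β = 0.02 with
  gradient clipping at norm 10, a 16→8→8→8 channel plan, 10 inner steps at
  test, 40 test tasks. Second-order gradients matter here: with a zero
  classifier head the first inner step changes only the head, so the
  feature extractor receives its training signal through the mixed
  head-body Hessian term — first-order MAML discards it and, on this
  short schedule, escapes the initial plateau only for lucky
  initializations. The outer rate is raised relative to the full-scale
  value (β = 0.001 over 20000 tasks) because the desk schedule is roughly
  an order of magnitude shorter; shortened schedules re-tune the step
  size, not the algorithm. The full-scale settings remain the package
  defaults in `meta_config()` (β = 0.001, central-difference second order,
  20000 tasks).
* **Transfer study**: strong-shift profile, conventional training of the
  8-class network on subjects 1–6 (70/30 train/validation, 30 epochs,
  batch 32, learning-rate drop halfway, weight decay 1e−4), frozen
  evaluation on subjects 7–8.

Under these conditions the meta-trained model reaches roughly 60–70%
5-way 5-shot accuracy on the held-out subject after adaptation (chance
20%, unadapted ≈ 20% because task labels are permuted per episode),
while the conventionally pretrained model shows a ≥ 20-point gap between
within-subjects validation and new-subject test accuracy. The exact
numbers for a given seed are computed, not quoted: run
`Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json`.

## Numerical choices and degenerate inputs

* Cross-entropy clamps predicted probabilities at 1e−12.
* Z-scoring floors the channel SD at 1e−12; constant channels map to 0.
* Batch-norm ε = 1e−5; batches of one sample are disallowed in training.
* Max-pool ties resolve to the first element in column-major order.
* The softmax subtracts the column maximum before exponentiation.
* The finite-difference HVP uses ε = 1e−4 · max(1, ‖θ‖)/‖v‖; the outer
  meta-gradient is clipped at global norm 10.
* Seeds: every stochastic stage (generation, task sampling, init,
  training shuffles) is reseeded explicitly; identical configurations
  reproduce bit-identical results on the same BLAS.

## Known limitations

* Second-order meta-training costs one (forward-difference) or two
  (central-difference) extra support-gradient evaluations per inner step;
  first-order MAML remains available via `second_order = FALSE`.
* The MAT reader supports real numeric arrays (including compressed
  elements), which covers grid-sEMG releases, but not cell arrays,
  structs or sparse matrices.
* Batch normalization under episodic evaluation uses query-batch
  statistics; single-query inference would require calibrated running
  statistics (supported in the supervised path only).
* The synthetic subject effect is a gain/shift/noise triple; real
  inter-subject variability is richer, so absolute synthetic accuracies
  do not forecast real-data accuracies.
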