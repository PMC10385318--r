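---
title: "fedseizr: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fedseizr: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fedseizr)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the tunables that matter, what the
synthetic world does and does not emulate, and where the design was
genuinely open. It states no empirical claim that the test suite does not
itself compute.

## The prediction problem

Scalp EEG before a seizure (the *preictal* state) differs from the
seizure-free baseline (*interictal*), but the signature is
patient-specific and the labeled data per patient is scarce. The pipeline
therefore (i) learns a generalized preictal/interictal discriminator
across simulated hospitals without moving raw signals (weight-only
federated averaging), (ii) personalizes each hospital's model against the
global one (coarse-grained personalization), and (iii) stages each
patient's risk with heart-rate-variability (HRV) and clinical features
(fine-grained personalization).

## Preprocessing

Each channel is bandpass filtered with a second-order Butterworth design
(default band 0.5–40 Hz, covering the clinical delta-to-gamma range; the
band edges are configurable in `run_config()$filter`). The filter is
applied forward and backward (zero phase) so transient shapes — which the
spiking encoder depends on — are not skewed; the magnitude response is
squared in the process. No dedicated DSP package exists in the target
stack, so the design (analog prototype → bandpass transform → bilinear
transform with pre-warping) and the `filtfilt` application (odd-extension
padding plus steady-state initial conditions) are implemented here and
pinned against reference coefficients in the test suite.

Signals are then z-scored per channel in non-overlapping 1-s blocks.
Per-second normalization keeps slow amplitude drift and inter-channel
gain differences from dominating training; its cost is that *absolute*
amplitude is no longer a feature — all downstream discrimination rests on
within-window temporal structure. Degenerate (constant) blocks become
zeros rather than NaNs.

Channel selection is a wrapper around any user-supplied evaluator
(channel subset → validation accuracy): a two-level screening design
(12-run Plackett–Burman for ≤ 11 channels, a seeded balanced fold-over
design above that) ranks channels by the main effect of their presence,
then backward elimination removes channels in ascending-effect order
while accuracy does not drop by more than a tolerance (default 0 — the
strict reading of "ignore a channel that does not improve accuracy").
Ties remove the higher index first, so a fully uninformative montage
collapses deterministically to channel 1. The selected set is never
empty.

## Segmentation and the bi-timescale choice

Windows of 1/2/4/8 s are cut with a sliding window (half-open intervals,
0-based seconds; a window is labeled by the annotation covering at least
half of it). Balanced training sets segment the majority class without
overlap and the minority class with the largest stride whose window count
reaches the majority count (found by bisection on the sample grid), then
truncate to exact balance.

Each timescale is scored by the validation AUC of a cheap, deterministic
probe (logistic model on per-window spike-statistic summaries), and the
two best scales are kept; ties prefer the shorter scale (cheaper and
better localized). The full graph network is deliberately not used for
selection — fitting it four times per hospital would dominate the runtime
budget while the probe recovers the same ordering on planted data.
Because federated weight averaging is only meaningful when every client's
branches ingest the same window lengths, `run_pipeline()` averages the
per-hospital AUCs per scale and fixes one consensus pair for the whole
federation.

## The spiking encoder

Per channel, `up = mu + kappa*sigma` and `down = mu - kappa*sigma` over
the window. Two encodings are provided:

* `"mean"` — spike iff the sample is at or above the midpoint of up and
  down (the channel mean). This is the literal threshold rule, kept as
  the documented default of `encode_spikes()`. Note its structural
  degeneracy: the threshold sits at the window mean, so the spike count
  is pinned near half the window for any input and carries no class
  information, and `kappa` is inert.
* `"crossing"` — spike iff the sample leaves the `[down, up]` band. Spike
  counts and run lengths now respond to genuine amplitude excursions,
  which is what high-rate brief epileptiform transients produce. The
  pipeline configuration (`run_config()$spiking$mode`) defaults to this
  mode for exactly that reason; during development the separability gap
  between the two modes on the default synthetic world was substantial,
  and the end-to-end recovery the acceptance suite computes is achieved
  in this mode.

Spike statistics per channel are the count, the number of spike runs and
the mean run length ("spike duration", in samples). The seizure indicator
flags a channel High when it spikes *more often* than the cross-channel
mean and *more briefly* than the cross-channel mean duration (both
strict); the fraction of High channels is the window's seizure
probability. Fine tuning ANDs the spike matrix with the indicator. The
encoder's comparison point carries a trainable offset (in units of
`sigma`); the spike step function is differentiated with the fast-sigmoid
surrogate `beta/(1+beta|x|)^2` (default `beta = 10`), and the offset is
clamped to ±0.5 σ so training cannot push the encoding into an all-ones
or all-zeros regime.

## The spiking graph network

Channels are nodes; edges carry `|Pearson correlation|` when it reaches
`corr_threshold` (default 0.3). Propagation uses the symmetric
renormalization `D̃^(-1/2)(A+I)D̃^(-1/2)`, whose spectrum lies in [-1, 1]
(verified exhaustively over all small 0/1 graphs). Per node the input
features are the spike fraction, mean spike duration (s), spike-run rate
(runs/s, scaled) and the window standard deviation; the per-node gate
`RS` is the spike fraction, entering every layer as a diagonal matrix
(the only dimensionally consistent reading of a layer-independent
spike-score gate). Two conv layers of width 16 (GELU, then Tanh) feed a
mean-pool per branch; the two timescale branches are concatenated into a
Sigmoid dense head followed by softmax.

Three choices deviate from the most literal architecture reading, each
forced by measurement during implementation:

* Node features use the **raw** spike statistics, not the
  indicator-gated ones. The binary indicator is noisy at the
  single-window level; hard-gating multiplies informative channels by
  zero essentially at random and measurably lowers held-out AUC. The
  indicator itself remains fully implemented and tested, and still
  supplies the High/Low counts used by the federation's probability
  normalization.
* Features are standardized with per-feature mean/sd estimated on the
  client's training windows. The raw features live on scales of
  10⁻²–10⁰; squeezed through the bounded Sigmoid head, the resulting
  gradients are so small that Adam at the prescribed learning rate and
  epoch budget barely moves. The statistics travel inside the parameter
  container and are averaged by FedAvg like any weight.
* Training is plain minibatch Adam (lr 0.01, batch 128, dropout 0.2
  after each conv layer, ≤ 10 epochs per round) with hand-written
  backpropagation (no autodiff engine in the target stack); the analytic
  gradients are verified against central finite differences in the test
  suite.

## Federated learning and coarse personalization

Per round every client trains from the current global parameters on
`L_P = w1·L_pred + w2·L_div`, where `L_pred` is the cross-entropy and
`L_div` the Bregman divergence generated by the logistic loss — the KL
divergence between Bernoulli distributions — between the (normalized)
global preictal probability and the client's own. The global probability
is used as-is on clients whose spiking indicator flags more High than Low
windows and is otherwise damped to `clamp(-log P_G, eps, 1)`: the printed
"log P_G" branch cannot be a probability literally (it is ≤ 0), and the
clamped negative log preserves the evident intent — a confident global
preictal probability is shrunk on clients whose own data shows little
seizure activity. Defaults `w1 = 1`, `w2 = 0.1` keep the divergence a
regularizer rather than the objective.

The server aggregates with FedAvg (sample-count weighted elementwise
mean). Only parameter containers and scalar counts cross the client
boundary — the payload is architecture-sized, orders of magnitude below
any signal window, and this is asserted in the tests.

Early stopping monitors the pooled validation loss of the **personalized
client models**, each on its own stratified 20% split, with patience 3
(up to 30 rounds). The aggregated global model is the wrong object to
monitor here: with 10 local epochs per round the clients drift to
individually good but mutually misaligned weights, and the raw average's
loss can rise monotonically even while warm-started personalized models
improve every round — which is exactly what the deployed artifact is.
The best round's global and client parameters are retained.

A single client with `w2 = 0` reproduces centralized training *exactly*
(same RNG stream, identical parameters), which the acceptance suite
asserts; it pins the whole federation loop to the tested local trainer.

## ANFIS-PSO risk staging

Nine raw inputs (coarse EEG probability; Lmax, SDNN, LF/HF, mean HR,
pNN50; genetic, metabolic, seizure-event count) are folded into three
composite inputs on [0, 1]: the EEG probability passes through, and the
HRV/clinical composites are means of per-feature class scores
(Low/Medium/High → 0/0.5/1) obtained by triangular-membership
fuzzification against the reference class ranges. A full 9-input, 3-MF
Sugeno system would have 3⁹ = 19 683 rules; the 3-input fold gives 27
first-order rules, which 30–60 training pairs can actually identify.
Class ranges overlap for several HRV features; the triangles peak at
each class's midpoint with feet at the class bounds, overlapping supports
are kept (fuzzy by design), argmax ties resolve toward the higher-risk
class (clinically conservative), and a nearest-peak fallback keeps the
membership sum positive inside range gaps.

Training is the classic hybrid: rule consequents by ridge-regularized
least squares given the firing strengths (the 108-coefficient system is
typically underdetermined; ridge `lambda = 1e-6`), premise parameters by
finite-difference gradient steps on the mean absolute error, accepted
only when the MAE does not increase. A global-best PSO (inertia 0.7,
cognitive/social 1.5/1.5, swarm 30, 50 iterations by default) searches
premise initializations with fitness = −training MAE; particle 1 is
always the default premise vector, so a swarm of one with zero iterations
reduces exactly to plain hybrid training. ANFIS output tiers (thirds of
the min-max-calibrated training output range) give the fallback risk
class.

HRV transition patterns dominate the staging: with relative changes
discretized by `delta_small` (5%, "approximately equal") and
`delta_large` (25%, "much greater") — both configurable, since the
source criteria never quantify them — the patterns are α = moderate rise
then jump (sustained thereafter), β = flat, rise, jump, γ = flat, flat,
rise, jump. Each of the five HRV features votes; majority wins, ties
toward higher risk. The earliest match wins and, at the same start
index, α ≻ β ≻ γ. Preictal-onset localization finds the earliest pair of
two successive much-greater jumps; the preceding sample marks the
preictal start and alarm onset, and the seizure prediction horizon (SPH)
is the time from alarm to seizure onset — explicitly NA (not zero) when
no jump pair exists.

## The synthetic world

The generator states one simulated world and the tests live in it: three
hospitals, two subjects each, 8 channels at 128 Hz, 5 min interictal and
2.5 min preictal per subject. The background is AR(1)-colored noise
(unit sd). Epileptiform transients are damped-sinusoid bursts whose
decay constant equals their nominal duration (so "duration" means what
it says for run-length statistics), at 3× the background sd, confined to
a fixed per-subject focal channel subset — a stable seizure onset zone,
which is both the clinical reality and the structure the cross-channel
seizure indicator needs to be exercisable. Preictal bursts are frequent,
brief and fast (2/s, 40–80 ms, 25 Hz); interictal bursts sparse, long
and slow (0.2/s, 150–300 ms, 6 Hz). These values were chosen once, as
plausible for interictal discharges vs. preictal fast activity on scalp
EEG, before any end-to-end measurement.

HRV series sit at each feature's class-range midpoint and plant exactly
one α/β/γ pattern at a random position, with fluctuations well below
`delta_small` elsewhere; when the pattern does not start at the first
observation, the step immediately before it is a small guard drop (1.5×
`delta_small`). Without that guard the planted class is formally
unidentifiable — flat noise steps extend any α into a β/γ prefix — so
the guard is the minimal marker that makes 100% recovery a meaningful
target. Clinical records follow the class table (Low: no etiology flags,
1–2 events; Medium: flags, 3–5; High: flags, > 5).

What a green test does establish: the pipeline recovers planted
rate/duration/amplitude structure through filtering, normalization,
encoding, graph propagation and federation, at the stated sizes and
seeds. What it does not: performance on real scalp EEG — real background
is nonstationary and rhythmic (alpha, spindles, artifacts), real
preictal signatures are far subtler and patient-specific, and real HRV
does not present textbook transition patterns. The published benchmark
figures of the underlying method are therefore out of scope here.

## Numerical choices and degenerate inputs

Half-open `[start, end)` second intervals everywhere; a sample at a
boundary belongs to the right interval. Constant channels: sd 0 blocks
normalize to zero, correlations are defined as 0, `up = down = mu`, and
values exactly at the comparison point spike (the "otherwise" branch
covers equality). Probabilities entering logs are clamped at 1e-12
(prediction) or validated (Eq.-style operations error outside their
domain). The minority-class stride bisection runs 60 halvings (below
sample resolution); balanced counts are then truncated to exact
equality. All randomized operations take an integer seed (default 42)
and are exactly reproducible; seeded sub-streams are derived additively
and stay below 2³¹.

## Known limitations

* The graph is built from whole-recording correlations of the
  preprocessed signal; on the synthetic world the normalized background
  is nearly independent across channels, so the default threshold often
  yields an edgeless graph and propagation reduces to per-node feature
  maps with self-loops. Real EEG montages are strongly correlated and
  would populate the graph.
* The Sigmoid-before-softmax head bounds class probabilities to roughly
  [0.27, 0.73]; rankings and argmax decisions are unaffected, but the
  probabilities are not calibrated confidences.
* `loocv()` implements leave-one-*subject*-out generically (train/eval
  callbacks) and is tested with stub models; the default pipeline
  evaluation is window-stratified per hospital, because retraining the
  federation once per held-out subject would multiply the runtime by the
  subject count for no additional coverage of the federation logic.
* The offset surrogate gradient flows only through the spike-count
  feature (run-duration and run-rate changes under a threshold shift are
  not differentiable in any useful sense); the offset is accordingly a
  slow, coarse tuner.
* ECG waveform processing is out of scope by design: HRV enters as
  feature series, mirroring how the underlying method synthesized them.
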