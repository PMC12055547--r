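---
title: "cardiofed: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cardiofed: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiofed)
```

`cardiofed` simulates and trains a privacy-preserving, federated,
multimodal classifier for cardiac disease, plus a reinforcement-learning
diet recommender. This vignette explains the model, the synthetic data the
package is validated on, the numerical choices, and where the design was
genuinely open.

## 1. What the synthetic cohorts emulate — and what they do not

Real multimodal cardiac datasets (ECG archives, cine-MRI collections,
tabular risk-factor registries, diet logs) cannot be redistributed with a
package, and no public resource links all four modalities per patient. The
generator therefore produces *jointly labeled* multimodal tuples whose
statistical structure exercises every stage of the pipeline:

* **ECG** (`ecgLength` samples at `ecgFs = 125` Hz): a shared 1 Hz
  baseline-wander sinusoid plus a class-specific tone at a distinct
  frequency per class (3, 8, 14, 20, 26, 32 Hz for up to six classes) with
  a first harmonic, plus white noise of sd `noiseSd`. Classes are
  *frequency-coded* so that frequency-domain features are provably
  informative — arrhythmia-like pathologies express themselves as shifted
  dominant rhythms. The tone amplitude scales with `classSeparation` so
  that at separation 0 all classes are exchangeable.
* **Images** (`16 x 16` default, values in [0, 1]): smooth illumination
  gradient plus a centred blob whose intensity shifts with class, plus
  pixel noise. This gives the grid descriptor a class signal without
  pretending to be cardiac MRI.
* **Records** (13 features): unit-sd Gaussians whose per-class means are
  exactly `classSeparation` apart on every feature. This yields a
  closed-form single-feature Bayes error of `pnorm(-classSeparation / 2)` —
  about 2.3% at the default separation 4 — which anchors the end-to-end
  accuracy checks: a converged model should approach, and a threshold on a
  single feature should not beat, that bound by much.
* **Nutrition** (7 days of calories, total fat, saturated fat, protein,
  carbohydrate): per-day draws around class-shifted means. Saturated fat is
  generated as a bounded *fraction* of total fat, so `sat <= total` holds by
  construction rather than by clamping.

Defaults (`classSeparation = 4`, `noiseSd = 1`, 125 Hz, balanced labels)
are the conditions under which the package's end-to-end guarantees are
stated. What the generator deliberately does **not** model: P-QRS-T
morphology, imaging physics, record correlation structure, missingness, or
inter-modality correlation beyond the shared label. Passing the test suite
therefore demonstrates that the *machinery* (features, fusion, optimization,
federation, privacy accounting, recommendation) is correct, not that the
pipeline reaches any particular accuracy on clinical data.

## 2. Preprocessing operators

* **Median filter**: window-wise median with reflect padding, default 3×3
  (no window size is canonical; 3×3 is the smallest that denoises while
  preserving edges). `window = 1` is the identity.
* **Band-pass**: an *ideal* (brick-wall) filter — the DFT is multiplied by
  the indicator of `f1 <= |f| <= f2` and inverted. The indicator form is
  taken literally rather than approximated by an IIR design (e.g.
  Butterworth): it is exactly linear-phase, exactly annihilates bin-aligned
  out-of-band tones (tested to 1e-10 relative power), and never amplifies.
  The cost is ringing at band edges for non-aligned components, acceptable
  for feature extraction (the features are spectral anyway). Default ECG
  band 0.5–40 Hz covers baseline wander removal through clinical QRS
  content at fs = 125 Hz.
* **ICA**: FastICA with the tanh contrast, deflation scheme, on whitened
  data; deterministic given a seed; non-convergence after `maxIter` is an
  error, not a warning. Validated by recovering known sources from a known
  mixing to |corr| ≥ 0.95 after permutation matching.
* **Min–max scaling**: statistics are fitted on the training split and
  frozen; held-out values outside the training range are clipped to [0, 1]
  (the network's input domain must be bounded; extrapolated z-scores are
  not meaningful for indicator-like record features). Constant features map
  to 0 and are flagged.
* **Diet k-means**: Lloyd iterations from a k-means++ seeding, with the
  within-cluster sum of squares recorded at every iteration and asserted
  non-increasing. An emptied cluster is re-seeded at the point farthest
  from its nearest centroid. Cluster membership enters the model as a
  one-hot nutrition feature — the clusters' role is to expose consumption
  patterns to the classifier and recommender, so a hard membership code is
  the most transparent interface.

## 3. Feature extraction

ECG features: magnitude spectrum on positive frequencies; the top five
local maxima (frequencies in Hz, magnitudes normalized to the strongest
peak) plus band-power fractions over [0,5), [5,15), [15,40), [40, fs/2] Hz.
Five peaks and these edges cover the clinically interpretable range at
125 Hz sampling; fractions sum to one by construction and an all-zero
signal returns a flagged zero vector rather than NaN.

Image features: per-cell mean intensity and mean forward-difference
gradient magnitude over a 4×4 tiling (32 features). A pretrained-CNN
embedding can be substituted through the `embedding` adapter; the fusion
layer is agnostic to the image feature's provenance.

Record features: the scaled record vector itself *and* its per-patient
mean, population variance (`1/n`, so a single value has variance 0) and sd.
Whether raw values, summary statistics, or both should feed the fusion
layer was an open choice; both are emitted, and `includeRecordStats`
switches the statistics off.

Nutrition features: aggregate-then-divide. Ratios are formed after summing
over the table (fat ratio = total saturated / total fat) rather than
averaging per-day ratios, which is numerically stable when single days have
near-zero denominators. Zero denominators yield flagged fallbacks (ratio 0
for fat; a configurable cap for protein/carb).

## 4. Attention fusion

Modality dimensions differ, so a weighted sum of raw `F_i` is not
well-typed. Each modality gets a trainable linear projection `P_i` into a
common `dCommon`-dimensional space (default 128), and a *single shared*
scorer `(Wa, ba)` produces `s_i = Wa' P_i(F_i) + ba`; `alpha = softmax(s)`
(max-subtracted), `z_fused = sum_i alpha_i P_i(F_i)`. Sharing one scorer is
the minimal reading of "trainable parameters Wa and ba"; a per-modality
scorer is available behind `perModalityScorer = TRUE`. The raw
concatenation `z` is kept as a diagnostic output only.

The backward pass is exact, including the softmax Jacobian that couples
modalities; a shared score bias provably has zero gradient (softmax shift
invariance), and with a single modality nothing flows into the scorer —
both are asserted in tests, alongside finite-difference agreement at 1e-6.

## 5. Network and optimizer

Architecture: 512/256/128/64/32 ReLU hidden layers; batch normalization on
hidden layer 3 only; dropout 0.3 (inverted scaling) on hidden layer 4 only;
softmax output. He-normal initialization for ReLU layers and Xavier-normal
for linear/softmax layers; biases zero.

Loss: mean cross-entropy plus `(lambda/2) ||W||^2` with the norm over
weight matrices only — biases and batch-norm scale/shift are not penalized
(standard practice; penalizing them fights their calibrating role).

Optimizer: heavy-ball momentum. The update is implemented as
`v <- gamma v + eta g; theta <- theta - v`, with the learning rate inside
the velocity, so `gamma = 0` reduces exactly to plain SGD and the
regularized gradient `g = ∇L_B + lambda theta` enters once. The literal
variant without `eta` in the velocity is available via
`etaInVelocity = FALSE`. Mini-batch gradients are averaged over the batch.

Batch-norm running statistics are updated with momentum 0.9 in train mode
and used in eval mode. In the federated setting the running statistics
travel inside the node's parameter state and are averaged by FedAvg like
every other tensor — they are excluded from gradients, momentum and the L2
norm, but a global model must carry usable inference statistics, and this
choice also makes single-node federation reproduce centralized training
bitwise.

## 6. Federated engine and differential privacy

Each round: broadcast, local `T_N`-epoch updates per node (momentum buffers
reset at round boundaries), per-node privacy protection, FedAvg
aggregation `W = sum(n_k W_k) / sum(n_k)`, validation on a held-out split.
Nodes execute sequentially in-process under a parallel-safe contract: node
updates are independent, and aggregation is bitwise order-invariant (the
accumulation order is canonicalized, since floating-point addition is
commutative but not associative). The transport layer accepts only
`paramDelta` containers — attempting to send a cohort, a matrix or a data
frame is an error, which is the package's enforcement of "raw data never
leaves the node".

Nodes return absolute parameter states weighted by shard size; the
Gaussian mechanism is applied to the *update* `ΔW = W_local − W_global`
(clip to L2 norm `C`, add `N(0, σ²)` per coordinate,
`σ = C √(2 ln(1.25/δ)) / ε`, computed once per configuration), after which
the protected state `W_global + ΔW'` is shared. Clipping is what gives the
noise a defined sensitivity; the calibration is the analytic Gaussian
mechanism. Privacy spend is reported per round as naive composition
`rounds × ε`; formal accountants (moments/RDP) are out of scope and the
log field is labeled accordingly.

Noise is added per coordinate, so its norm grows with `sqrt(d)` of the
parameter count: under a tight budget a compact architecture retains far
more utility than the full 512-wide stack. The DP tests therefore run a
32/16 network with the clip bound set near the typical raw update norm;
with the budget effectively off (ε = 1000) accuracy matches the DP-off run
within two points, and at ε = 0.1 the model collapses — the expected
monotone privacy–utility trade-off.

## 7. Evaluation

Metrics are computed from explicit one-vs-rest confusion counts and
macro-averaged (the multiclass tables the metrics mirror do not state an
averaging; macro is the convention that weights classes equally), with
pooled accuracy and `hamming_loss = 1 − accuracy` for single-label
prediction. Degenerate 0/0 cells contribute 0 and are flagged rather than
propagating NaN. The paired t-test uses the sample-sd form with Student
p-values; the Wilcoxon signed-rank test excludes zero differences, uses
mid-ranks with tie-corrected variance and a continuity correction, and
both are cross-checked against `stats::t.test` / `stats::wilcox.test` in
the test suite (the hand implementations exist because the z statistic and
degeneracy flags are part of the interface).

## 8. Diet recommender

The Q-network is the same from-scratch network with a linear output head.
Training uses uniform experience replay (FIFO ring buffer), a target
network synced every 100 gradient steps, and ε-greedy exploration annealed
linearly from 1.0 to 0.05 — the standard stabilization set for value-based
learning; the reward is `0.7 × normalized health improvement + 0.3 ×
adherence`, weights chosen once as a clinically plausible trade-off between
outcome and compliance.

Because no transition model exists for real patients, correctness is
defined against a small synthetic diet MDP: six discretized health levels,
three actions (intensive change / moderate adjustment / maintain) with
deterministic health drift (+2/+1/0, capped) and decreasing adherence
(0.4/0.7/1.0), discount 0.9. Exact value iteration (tolerance 1e-10) is the
oracle; the learned greedy policy must match it on ≥ 95% of states across
seeds, and its policy value must be within 5% of the optimum. The optimal
policy is structured — intensive intervention for sick states, maintenance
when healthy — so recommendations ordered by Q-value are clinically
sensible by construction. Patient-facing states are normalized by fixed
physiologic bounds (BP 90–200 mmHg, cholesterol 120–320 mg/dL, BMI
15–45 kg/m²) and discretized onto the agent's levels; recommendations are
gated on a positive classifier prediction.

## 9. Numerical choices and degenerate inputs

* Softmax is computed with row-max subtraction; probabilities at the true
  class are clamped at 1e-12 in the loss (flagged).
* Gradient checks use central differences with step 1e-5 and reject draws
  whose ReLU pre-activations sit within the step of the kink, where a
  two-sided difference cannot represent the one-sided derivative.
* `fedavg` of a single update returns it unchanged (the weighted mean of
  one vector *is* that vector), which keeps K = 1 aggregation exact.
* K-means ties in assignment go to the lowest cluster index; ε-greedy ties
  go to the lowest action id; both are deterministic.
* All randomness (generation, shuffling, dropout, DP noise, exploration)
  derives from user-supplied seeds through a mixing function; identical
  seeds give bitwise-identical runs whenever DP is off.

## 10. Problem sizes used in validation

The shipped tests and the acceptance script run at sizes a laptop handles
in minutes: the end-to-end federated experiment uses a 2,000-patient
training cohort (4 nodes, 30 rounds, full default architecture) with 500
held-out patients; gradient audits use ~160-parameter fused networks over
20 random instances; the DP calibration uses 1e6 noise coordinates; the
DQN runs 2,000 episodes per seed on the 6-state MDP. These sizes were
chosen as the smallest at which each property is sharply testable.

## 11. Known limitations

* Synthetic cohorts only; adapters for real data are format hooks, and no
  claim transfers to clinical distributions.
* Naive privacy composition across rounds; no subsampling amplification.
* Sequential in-process "nodes"; no real transport, stragglers, or
  asynchrony.
* FedAvg only (no FedProx/FedSGD variants); no secure aggregation or
  homomorphic encryption.
* The image branch is a deterministic descriptor, not a learned
  representation; the recommender's sequential (LSTM/transformer) extension
  is out of scope — the health state carries adherence directly instead.
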