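---
title: "Dual-output decoding of wristband force myography: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-output decoding of wristband force myography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fmgdual)
```

## The problem and the model

A force-myography (FMG) wristband carries ten barometric pressure cells
around the wrist. When a finger flexes at the metacarpophalangeal (MCP)
joint, the tendons and muscles that drive it deform the wrist surface and
press on a finger-specific subset of the cells. From the 10-channel
pressure series sampled at 40 Hz, `fmgdual` decodes two things at once:

* **which finger is moving** — a 5-class gesture label (thumb, index,
  middle, ring, pinky), and
* **how far it is flexed** — the continuous MCP joint angle in degrees.

Both come from a single *dual-output* network: a shared trunk ending in two
parallel dense heads, a K-way softmax classifier and a one-unit linear
regressor. Training minimises the weighted joint loss

$$\mathrm{loss}_{total} = w_c\,\mathrm{loss}_c + w_r\,\mathrm{loss}_r,$$

where $\mathrm{loss}_c$ is categorical cross-entropy over the class
probabilities (Eq. implemented in `crossEntropyLoss()`), $\mathrm{loss}_r$
the mean-squared error of the angle head (`mseLoss()`), and the default
weight ratio is $w_r : w_c = 4 : 1$, which balances the two losses'
scales. Multi-task sharing of the trunk acts as a regulariser: the
classification features and the angle features are driven by the same
underlying tendon activity.

## Movement-image augmentation

A plain $L \times N$ multichannel series only exposes each channel to its
two printed neighbours, so a 2-D convolution can never see the interaction
of, say, channels 1 and 6. The augmentation step therefore *expands* the
channel axis along an **arrangement** — an ordered, repeating sequence of
channel indices — before windowing:

1. arrange the N-channel signals as an $L \times N$ array;
2. permute/repeat columns into $L \times M$ so channel pairs occur side by
   side (`buildArrangement()`, `expandSignals()`);
3. cut the expanded array into square $M \times M$ windows
   (`sliceWindows()`), sliding one sample at a time;
4. label every window with its modal finger class and the angle at its
   last time step (`assignTargets()`).

For $N = 10$ the package ships the published 42-element arrangement
verbatim (`buildArrangement(10, "paper_fixture")`), giving the
$42 \times 42$ movement images and the window counts $L_s - 42$ (958 per
1000-sample trial; 8958 for nine concatenated training trials). Two
properties of this fixture deserve note:

* **It is not pair-complete.** The pairs (2,7), (3,8), (4,9) and (5,10)
  never occur adjacently, although the surrounding description suggests
  every pair should. The fixture is reproduced as printed — it is a
  fixture, not a construction — and `buildArrangement(mode =
  "pair_complete")` offers a genuinely complete alternative built as an
  Eulerian path over the complete channel-pair graph with minimal edge
  duplication: length $\binom{N}{2}+1$ for odd $N$,
  $\binom{N}{2}+(N-2)/2+1$ for even $N$ (8 for $N=4$, the provable
  minimum; 50 for $N=10$). The sensor-count ablation uses pair-complete
  arrangements for $k < 10$ channels because no printed fixture exists
  there.
* **Window count.** A series of length $L_s$ admits $L_s - w + 1$ windows
  mathematically, but all printed dimensions use $L_s - w$. We emit
  exactly $L_s - w$ windows, dropping the *first* possible window so that
  the final window ends at the last sample — the angle target of the last
  image is the series' last angle, consistent with the last-time-step
  convention.

Tie-breaks in the modal label (possible only in windows straddling a
segment boundary) go to the class whose last occurrence is latest, again
consistent with the last-time-step convention, and deterministic.

Standardization (per-channel mean 0, sd 1; the angle target likewise) is
fitted on the training split of each cross-validation fold only and
applied unchanged to the test split — fitting it on all data would leak
test statistics into training. The standard-deviation convention is
population ($\div n$) by default and configurable; it matters only at
small $n$. $R^2$ is invariant to the affine angle rescaling, so reported
$R^2$ is identical on the degree and standardized scales.

## Architectures and training

`cnn_aug` (the primary model) filters the $42 \times 42$ image with 32
$3\times3$ kernels, max-pools $2\times2$, repeats both, flattens, passes a
32-unit rectified dense layer and ends in the two heads. With same-padding
convolutions the spatial sides go $42 \to 21 \to 10$, so the flatten size
is $10 \times 10 \times 32 = 3200$. (The corresponding 10×10 no-augmentation
model flattens to exactly $2 \times 2 \times 32 = 128$; a printed
128-dimension flatten for the 42×42 model is not reachable under any
standard padding scheme, so `layerShapes()` always reports the true
value.) `cnn_noaug` is the identical network on raw $10 \times 10$
windows. `gru` runs one 32-unit gated recurrent layer over length-10 raw
windows (input dropout 0.2, recurrent dropout 0.2, masks drawn per batch
and shared across time steps) and feeds the final hidden state through the
same dense-plus-two-heads tail — the wiring mirrors the CNN trunk tail
since only the principle, not the wiring, is prescribed.

Training uses RMSprop (learning rate 0.001 — the optimizer's conventional
default, exposed in `dualModelConfig()` — decay 0.9, epsilon 1e-7), batch
size 32, 10 epochs, no validation split or early stopping. Weights are
Glorot-uniform (orthogonal recurrent matrices); probabilities are clipped
at $\varepsilon = 10^{-7}$ inside the log. Every stochastic element —
initialisation, shuffling, dropout — flows from the single `seed` in the
config, so runs are exactly reproducible. The convolution and pooling
kernels are compiled (Rcpp/RcppArmadillo, im2col + BLAS), with analytic
gradients; the test suite checks every parameter's gradient against
central finite differences at $10^{-6}$ relative tolerance.

## Shallow benchmarks and sensor selection

The single-output baselines operate on raw per-time-step standardized
10-channel vectors: an RBF-kernel SVC ($C=5$, $\gamma=0.1$) and SVR
($C=10$, $\gamma=0.1$) via `e1071`, and random forests via
`randomForest` — a 100-tree classifier with $\lfloor\sqrt{d}\rfloor$
candidate features per split and a 60-tree regressor with
$\lfloor\log_2 d\rfloor$. (The classifier's printed mtry reads as a plain
"$n_{features}$", which in context — contrasted with the regressor's
$\log_2$ — we read as the square-root convention with a typeset-lost
radical; it is configurable.) No windowing is applied: the description of
these baselines involves none, and per-sensor feature importance only
makes sense on the raw channels.

Sensor selection fits, per subject, the forest classifier on the labels
and the forest regressor on the angles, takes normalised impurity
importances $\alpha_c$ and $\alpha_r$, averages them into the subject's
total importance $\alpha$, then averages across subjects and sorts
descending (`computeImportance()`; permutation importance is available as
an alternative mode). The ablation (`sensorAblation()`) retains the top-k
channels, rebuilds a pair-complete arrangement for $k$ channels (the
printed fixture only at $k=10$; at $k=1$ the identity arrangement, where
the "image" degenerates to a single pressure value and the CNN reduces to
a small dense network), and reruns the full cross-validation. By default
importances are computed once globally, matching the method's global
description; a strictly fold-local mode is the leakage-safe alternative
and is what the audit tests exercise.

## Evaluation protocol

Leave-one-trial-out cross-validation per subject: each of the 10 trials is
the test set once, the other 9 train. In the default `concatMode =
"paper"` the 9 training trials are concatenated along time before
windowing — reproducing the printed $(9000-42, 42, 42)$ training dimension
at the cost of a handful of windows straddling trial boundaries —
while the test trial is always windowed alone ($(1000-42, 42, 42)$);
`per_trial` windowing is available when no cross-trial windows are wanted.
Accuracy is pooled over all test images of a fold, the subject score is
the unweighted mean over folds, and the cohort summary is the unweighted
mean and across-subject sd. `auditLeakage()` verifies fold by fold that
the held-out trial contributed to neither the standardizer nor the
training windows.

Model comparison uses the exact Wilcoxon signed-rank test on the paired
per-subject scores (`pairedSignedRankTest()`): zero differences dropped
with their count recorded, average ranks for ties, and the two-sided
p-value computed from the full $2^m$ sign-assignment distribution (via a
rank-sum convolution identical to brute-force enumeration — the suite
checks this at $10^{-12}$), rather than a normal approximation, which
would be inaccurate at $m = 10$ subjects.

## The synthetic wristband simulator

The study's recordings are not publicly deposited, so the package ships a
generative stand-in (`simulateDataset()`) that reproduces the protocol's
*structure* — it makes no claim about wrist physiology:

* five contiguous single-finger segments per trial in thumb-to-pinky
  order; 40 Hz; 5 s per segment, hence $5\times5\times40 = 1000$ samples
  per trial and 100,000 samples in the 10-subject × 10-trial design
  (the protocol's printed per-trial totals fix T = 1000, which implies
  5 s of recording per finger segment);
* a raised-cosine MCP trajectory $\theta(t) = \tfrac{A}{2}(1 - \cos(2\pi
  f t))$ per segment, $A = 55°$ for the thumb and $90°$ otherwise. The
  self-selected pace is modelled as a subject trait — one preferred
  frequency per subject drawn from 0.4–0.6 Hz, as "their self-selected
  frequency" suggests — with small per-segment variation, rounded to a
  whole number of cycles per segment so each finger starts from and
  returns to rest and the signal is continuous at segment boundaries
  (subjects begin each finger relaxed; a segment cut mid-cycle would put
  a nonphysical jump in both angle and pressure);
* per-subject sensitivity: each finger strongly drives two
  finger-specific channels plus a weaker neighbour, with log-normal
  inter-subject gain jitter (sd 0.15), uniform baselines, and an optional
  per-subject amplitude attenuation in [0.85, 1] for subjects who cannot
  reach the nominal maximum angle (on by default);
* pressures = baseline + coupling × $g(\theta/A)$ + slow random-walk
  drift + white Gaussian noise, where $g(u) = \tanh(1.5u)/\tanh(1.5)$ is
  a fixed monotone saturating map. The modest steepness keeps $g$ well
  conditioned at full flexion, so the angle remains recoverable from the
  pressures over the whole range — with a harder saturation the angle
  near the peak becomes numerically unobservable, a property of the
  stand-in rather than of the method under test;
* defaults chosen once as realistic for high-SNR barometric FMG in
  normalised full-scale units: sensor noise sd 0.05 (5% of full scale),
  drift step sd 0.002 per sample, crosstalk fraction 0.15. The recording
  hardware's true noise magnitudes are unpublished, so these are
  documented knobs, not reference values.

All randomness derives from one root seed through a fixed per-(subject,
trial) arithmetic, so any single trial is reproducible in isolation.

What passing tests on this simulator do and do not show: they verify that
the pipeline is correct end to end (dimensions, leakage-freedom,
determinism) and that the models can recover a known generative mapping —
on noiseless data the dual-output CNN reaches near-perfect fold accuracy
and $R^2$. They do not certify performance on real wristband data, whose
noise structure, inter-trial nonstationarity, electrode-shift analogues
and multi-finger coupling the simulator deliberately omits.

## Problem sizes used by the test suite

The automated checks run on deliberately small cohorts chosen as the
smallest sizes that still exercise every code path: the noiseless recovery
check uses 2 subjects × 3 trials at the full 1000-sample trial length; the
noisy augmented-vs-raw comparison uses 2 subjects × 3 trials at 400
samples per trial over 3 simulator seeds; the ablation oracle uses
6-channel trials with two informative channels. The full 10 × 10 design is
simulated only where a check concerns the design's arithmetic itself.

## Known limitations

* The simulator is a structural stand-in; absolute accuracies on it do
  not transfer to hardware recordings.
* Single-finger gestures only — multi-finger coupling is out of scope.
* The published 42-element arrangement is reproduced with its missing
  pairs; results with `pair_complete` arrangements at $N=10$ (M = 50)
  are not numerically comparable to the 42-column configuration.
* Kernel SVMs scale quadratically in the training rows; the optional
  seeded `subsample` switch in `shallowConfig()` trades fidelity for time
  on large concatenated sets (off by default, logged when used).
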