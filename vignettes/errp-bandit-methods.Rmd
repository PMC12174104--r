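---
title: "Adaptive motor-imagery BCIs from ErrP-derived rewards: models and methods"
author: "errpBandit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive motor-imagery BCIs from ErrP-derived rewards: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Non-invasive motor-imagery (MI) brain-computer interfaces decode imagined
left- versus right-hand movement from sensorimotor EEG. Static classifiers
degrade as the EEG drifts (electrode impedance, mental state), which
motivates interfaces that keep learning during use. When an interface
misinterprets the user, the EEG itself contains a stereotyped signature of
that error — the interaction error-related potential (ErrP) — so the
error signal needed for adaptation comes for free, without extra workload.

`errpBandit` implements this loop as a *contextual bandit*: on every trial
the agent observes a feature vector derived from the MI epoch (the
context), picks an action (left/right), and receives a binary reward
derived from ErrP detection — reward 1 when no ErrP is (simulated to be)
detected, 0 otherwise. The context on the next trial does not depend on
the action taken, which is what distinguishes the bandit setting from full
reinforcement learning.

The package provides the full desk-scale pipeline:

1. a trial data model with FIR preprocessing (`EEGRecording`, `TrialSet`,
   `filterContinuous`, `epochTrials`, `rejectArtifacts`);
2. a synthetic-EEG simulator of a fast-paced snake-game protocol
   (`simulateSnakeProtocol`, `generateCohort`);
3. Morlet-wavelet band-power features (`extractFeatures`);
4. LinUCB and NeuralUCB agents (`LinUCB`, `NeuralUCB`, `ucbScores`,
   `updateAgent`);
5. the reward/evaluation loop with its statistics (`streamRun`,
   `errpReward`, `wilcoxonSignedRank`, `gridSearch`);
6. neurophysiological verification analyses (`erpAverage`,
   `differenceWave`, `ersp`, `erspPermutationTest`, `pointwiseFDR`,
   `findPeaks`).

# Data model and preprocessing

A `TrialSet` holds an `n_trials x n_channels x n_samples` array in
microvolts with per-trial labels (left/right), outcomes (error/correct)
and session/run indices. Epochs use the half-open convention
`[t_start, t_end)`, so a (-1, 2) s window at 500 Hz holds exactly 1500
samples and there is no off-by-one ambiguity; time 0 is the alignment
event (the snake's movement onset). Events coded `auto_forward`
(automatic straight steps of the snake) never produce trials.

Filtering applies Hamming windowed-sinc FIR stages *separately*
(high-pass, low-pass, notch). The default kernel is one second long; the
high-pass is built by spectral inversion of a DC-normalised low-pass so
direct current is cancelled essentially exactly. Each stage is applied
with exact group-delay compensation (centred convolution with reflection
padding), i.e. zero phase: ERP component latencies — the quantities of
interest downstream — are not shifted by filtering. The notch defaults to
50 Hz (mains frequency is site-dependent and configurable).

Artifact rejection is an automated amplitude rule: any trial whose peak
absolute amplitude on any channel exceeds a threshold (default 100 µV) is
removed, and a removal log is kept in the object metadata. Manual
screening is irreproducible; a fixed threshold is not, and it is the
standard desk substitute.

The native archive format is a versioned RDS container with named fields
(`saveTrialSet`/`loadTrialSet`); loading validates the container and names
any missing field. Readers for external binary EEG formats (e.g. the GDF
files of public MI benchmarks) are out of scope: no suitable reader
exists in the supported dependency set and all package functionality is
testable from the simulator.

# The synthetic-EEG simulator

The simulator is first-class, tested code: it defines the study
conditions under which every downstream module is validated.

**Protocol.** The snake takes a step every 2 s and turns only on a
directional command; each run contains 120 command trials whose
ground-truth label comes from a pre-programmed dot path with balanced
left/right turns (the path guarantees labels without online decoding).
With probability 0.05 — independently per trial — the executed turn
opposes the command; the trial is flagged `error` and an ErrP is added.
Independent Bernoulli draws are used because the protocol does not
rate-limit consecutive errors; nothing downstream is sensitive to that
choice.

**MI signal.** Mu (10 Hz) and beta (20 Hz) oscillations ride on 1/f
background noise (default SD 5 µV, slope -1) over an 8-channel
fronto-centro-parietal montage. From movement onset to the end of the
epoch, the channel contralateral to the imagined hand (right hand - C3,
left hand - C4) has its oscillation amplitude multiplied by
`1 - erdDepth`: event-related desynchronization modelled as multiplicative
attenuation, which reproduces the dB-scale ERSP phenomenology with a
single separability knob. `erdDepth = 0` gives chance-level data,
`erdDepth = 0.8` a strongly separable subject.

**ErrP.** Error trials receive a template of Gaussian-windowed deflections
at fronto-central channels: +5 µV at 200 ms, -5 µV at 252 ms, +5 µV at
348 ms, all with 60 ms FWHM. Latencies and polarities follow the
interaction-ErrP literature; widths and amplitudes are free choices (the
sources report peak latencies, not shapes), picked so the summed template
keeps distinct peaks within a few ms of the nominal latencies.

**What the simulator does not emulate.** Volume conduction from a head
model, ocular/muscle artifacts, inter-subject latency variability,
non-stationary drift within a session, and any dependence between MI
quality and outcome. Passing tests therefore demonstrate that the
pipeline recovers the structure it assumes, at realistic SNR — not
performance on real recordings.

# MI feature extraction

Per channel (C3, Cz, C4) and band (mu 6–13 Hz, beta 17–30 Hz), power is
the squared magnitude of complex Morlet coefficients on the 2 s
post-onset window (0.5 s for short cue-based datasets), sampled every
1 Hz. The two band matrices have different heights (8 and 14 rows), so
both are resized to 15 x 32 with separable cubic-spline interpolation —
equal representation of the bands in the final vector. Blocks are
flattened row-major and concatenated channel-major, band-minor: 3
channels x 2 bands x 15 x 32 = 2880 dimensions.

Choices the underlying protocol leaves open, and what this package does:

* **Pre-resize frequency step** 1 Hz: both bands get at least two rows
  and genuinely different sizes, which makes the equal-representation
  resize meaningful.
* **Wavelet cycles** `max(3, f/2)`: a standard compromise between
  temporal and spectral resolution that remains (marginally) feasible at
  6 Hz in a 0.5 s window; wavelet support is truncated with zero padding
  at the epoch edges, so edge power is attenuated rather than wrapped.
* **Cubic ringing**: resized power can slightly undershoot zero; negative
  values are clipped to 0 (power semantics). The raw `resizeBicubic`
  output is not clipped, so it can be validated against reference
  interpolators exactly.
* **Standardization**: raw band power spans orders of magnitude, which
  cripples UCB exploration terms. The default is an *online* per-dimension
  z-score using running (Welford) mean/variance over the stream — the
  agent never sees future trials, matching online use. A static whole-set
  z-score and no standardization are available.

# Bandit agents

**LinUCB** (disjoint arms) keeps, per action, a ridge design matrix
$A_a = I + \sum x x^\top$ and response accumulator $b_a = \sum r x$ over
the trials where $a$ was chosen, and scores
$\mathrm{UCB}_a(x) = \theta_a^\top x + \alpha \sqrt{x^\top A_a^{-1} x}$
with $\theta_a = A_a^{-1} b_a$. The inverse is maintained by
Sherman–Morrison rank-1 updates (with $\theta$ updated through an exact
$O(d)$ identity) and a full re-solve every 256 updates per arm for
numerical hygiene; the contract — tested against a brute-force ridge
solve — is exact equivalence to the direct solution at 1e-10. The
exploration grid for $\alpha$ is (0.01, 0.1, 1, 2, 4, 10).

**NeuralUCB** replaces the linear model with a one-hidden-layer ReLU
network shared across actions; action $a$ is encoded by placing the
context in the $a$-th input block (zeros elsewhere). Exploration uses the
diagonal approximation of the confidence matrix: $Z$ accumulates
elementwise squared gradients (initialised at $\lambda$) and the bonus is
$\nu \sqrt{g_a^\top \mathrm{diag}(Z)^{-1} g_a / m}$. The full confidence
matrix is quadratic in the parameter count and is out of scope. After
each reward the network is trained by full-batch gradient descent on the
squared error over the replay of all observed triples, up to 100 steps
with early stop at loss 1e-3 — a budget that bounds desk-scale runtime
while letting the network fit deterministic reward mappings. Grids follow
the standard search: hidden size (16…512), $\nu$ (0.1, 1, 10), $\lambda$
($10^{-1}..10^{-4}$), learning rate ($2\cdot10^{-i}, 5\cdot10^{-i}$).

Both agents expose the same generic surface (`ucbScores`, `selectAction`,
`updateAgent`) and are interchangeable in `streamRun`. Ties in the argmax
are broken toward the lowest action index by default (deterministic
tests); a seeded uniform rule is available. Rewards are binary in this
framework, but the contract accepts any value in [0, 1] for future soft
ErrP probabilities.

**Exploration weight matters at high dimension.** With d = 2880 and only
~120 trials, the UCB bonus $\alpha\sqrt{x^\top A^{-1}x} \approx
\alpha\sqrt{d}$ dominates the estimated reward for a long time: at
$\alpha = 1$ the agent keeps exploring for the whole run and its error
curve stays flat. This is correct bandit behaviour, and it is why the
evaluation protocol optimizes hyperparameters before streaming: the
package's evaluation of synthetic cohorts selects $\alpha$ by exhaustive
grid search (`gridSearch`, objective: mean training accuracy over seeds)
on a separate calibration subject, then holds it fixed — mirroring, at
desk scale, the per-subject hyperparameter optimization of the underlying
protocol.

# Reward loop, splits and statistics

`errpReward` realizes the reward rule through a detector confusion model:
a true error elicits a detection with probability `sensitivity`; a correct
trial is falsely flagged with probability `1 - specificity`; reward is 1
iff nothing is detected. The perfect detector (1, 1) reduces to
reward = [action == label], the offline assumption; the knobs expose
reward-corruption studies (accuracy degrades monotonically as symmetric
detector error grows — an acceptance property).

`streamRun` simulates online use trial by trial and records the per-trial
rewards, the accumulated-error curve (the cumulative regret under binary
rewards) and the final accuracy $1 - \mathrm{errors}/T$. Agents keep
learning during evaluation streams by default — accumulated-error curves
of online agents are the headline figure of this framework — and
`learn = FALSE` freezes the policy for a conventional train/test reading.
Chance level for balanced two-action streams is 0.5.

Splits: a seeded random shuffle with the first 80% for training, or the
session split (sessions 1–3 train, 4–5 evaluation) for five-session
datasets.

**Wilcoxon signed-rank tests** (two-sided for agent comparisons,
one-sided for first- versus second-half learning progress) are computed
from the exact conditional distribution of the positive-rank sum for up
to 25 non-zero pairs, via dynamic programming over the observed midranks,
so ties are handled exactly; zero differences are dropped (Wilcoxon's
original rule) and a tie-corrected normal approximation takes over for
larger n. `stats::wilcox.test` falls back to a normal approximation in
the presence of ties or zeros, which is why the exact path is
implemented in-package; the test suite checks it against brute-force
enumeration of all $2^n$ sign patterns up to n = 12 and against
`stats::wilcox.test` where the latter is exact. With nine subjects all
improving, the one-sided exact p-value is $2^{-9} \approx 0.00195$.

FDR control uses `stats::p.adjust(method = "BH")` throughout.

# Neurophysiological verification

**ERP/ErrP.** `erpAverage` subtracts the per-trial baseline mean
([-0.2, 0] s) and averages within outcome; the ErrP estimate is the
error-minus-correct `differenceWave`. `pointwiseFDR` runs Welch's t per
time point with BH correction. `findPeaks` reports local extrema ordered
by latency with signed polarity, filtered by *topographic prominence*
(height above the highest enclosing saddle): averaged background noise
superimposes micro-extrema on broad components, and amplitude thresholds
alone misreport them as peaks. The default threshold is
`max(2 * pre-onset SD, half the largest in-window amplitude)` — the first
term is the noise floor (and keeps noiseless recovery exact), the second
treats sub-half-amplitude bumps as non-components.

**ERSP.** Morlet power per trial, averaged, expressed per frequency as
`10 log10(power / mean baseline power)` with the divisive pre-stimulus
baseline [-750, -500] ms — so ERSP is exactly invariant to global
amplitude scaling, stationary data sit at 0 dB, and an amplitude scaled
by s after the stimulus reads `20 log10(s)` dB. The frequency axis is
3–30 Hz. The cycle parameterisation `c(2, 0.1)` is interpreted as: 2
cycles at the lowest frequency, growing linearly to
`2 * (fmax/fmin) * (1 - 0.1)` cycles at the highest — i.e. the growth
reaches 90% of the fully linear (constant time-window) increase.
Equivalence with any particular toolbox implementation is not claimed.

**Permutation testing.** Condition labels are permuted across trials
(default 800 permutations, seeded); the pointwise statistic is Welch's t
on single-trial log power (log stabilises the variance of power), the
p-value is the add-one fraction of permuted |t| at least as large as
observed, and BH masks the p-matrix at alpha = 0.05. The permuted
statistic is a package choice — the underlying toolbox statistic is
unspecified — and the test suite validates null calibration (rejections
at most alpha on average) and power on separable synthetic data.

# Problem sizes and numerical choices in the test suite

The suite validates the pipeline at sizes a desk machine handles in
minutes: cohorts of 9 subjects x 1 run (120 trials) for the
learning-progress property (10 replicate cohorts), 10 subjects x 200
trials for the chance-level property, 10 000 event-only trials for the
error-rate property, 200 error + 800 correct trials at 5 µV noise for
ErrP recovery, and a d = 10, margin-1 Gaussian benchmark (noise SD 0.25)
for regret sublinearity, evaluation accuracy and reward-corruption
monotonicity. Protocol-level statistics use the event-only fast path of
the simulator (`signals = FALSE`), since synthesising 10 000 full EEG
epochs contributes nothing to a rate estimate.

Other numerical choices: features are extracted with a per-config wavelet
bank computed once per trial length; cubic resize is implemented as a
precomputed linear operator per grid pair (cubic-spline interpolation is
linear in the data), bit-equivalent to per-row splines; the LinUCB
rank-1 update avoids dense temporaries and its periodic re-solve bounds
float drift; NeuralUCB raises an error advising a smaller learning rate
if training diverges to a non-finite loss.

# Known limitations

* Synthetic validation only, by design: no claim transfers to real EEG
  without the optional external-dataset path, which requires downloads
  and a GDF reader.
* The ErrP detector is a confusion model, not a trained classifier; the
  reward-corruption sweep brackets, but does not reproduce, a real
  detector's trial-to-trial structure.
* NeuralUCB uses the diagonal confidence approximation and a bounded
  training budget; with very small budgets it behaves close to a linear
  model on ReLU features.
* The ERSP cycle rule and permutation statistic are documented package
  choices; figures from other toolboxes will differ in detail.
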