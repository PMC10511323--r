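---
title: "Modelling striatal dopamine and acetylcholine dynamics in a two-armed bandit task"
author: "BanditPhotometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling striatal dopamine and acetylcholine dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BanditPhotometry)
```

## The problem

During flexible reward-guided behaviour, striatal dopamine (DA) and
acetylcholine (Ach) are released on sub-second timescales and are thought to
interact: phasic DA can suppress cholinergic interneuron firing through D2
receptors, with a short delay. Quantifying this interaction from fibre
photometry recorded while a mouse works a probabilistic two-armed bandit task
(2ABT) requires a chain of analyses — behavioural modelling, signal
conditioning, event-aligned statistics, encoding models, and trial-resolved
covariance analysis — each of which can silently distort the answer if its
conventions (alignment, binning, lag signs, cross-validation grouping) are
wrong.

This package implements that chain end to end, together with a synthetic-data
generator whose ground truth (event kernels, history-dependent gains, a lagged
negative DA-to-Ach coupling) is known exactly, so every stage can be validated
against what was actually put in.

## Task and behavioural model

`simulateSession()` runs the 2ABT: a centre poke initiates the trial, a side
poke is rewarded with probability $P_{high} = 0.95$ on the current high port
and $1 - P_{high}$ on the other, and the high port reverses after 30 rewards
have been collected in the block. Side-port withdrawal starts a 1-s
inter-trial interval. These task constants are the package defaults. Block
advancement counts *rewards*, not trials, so an agent that earns few rewards
sees long blocks.

Inter-event latencies are drawn from log-normal distributions (fast centre
dwell, slower centre-to-side approach, outcome-dependent side occupancy) with
an exponential jitter added to the minimum ITI; rewarded trials carry a
Poisson lick train during side occupancy while unrewarded trials rarely lick.
These shapes were chosen once as typical of freely moving rodents on a ported
task; only their broad structure (positive, right-skewed, outcome-dependent
occupancy) matters to the analyses downstream.

Choices come from a recursively formulated logistic regression (RFLR) agent:

$$\psi_t = \alpha\, c_{t-1} + \beta\, \phi_t, \qquad
  \phi_{t+1} = c_t r_t + e^{-1/\tau} \phi_t,$$

with choices $c_t \in \{-1, +1\}$, rewards $r_t \in \{0, 1\}$, perseveration
weight $\alpha$, evidence weight $\beta$, and decay constant $\tau$ (trials).
The default generative agent uses $\alpha = 1$, $\beta = 2$, $\tau = 1.5$,
values in the range where simulated behaviour reproduces the hallmark task
dynamics: a transient rise in $P(\mathrm{switch})$ and a monotone recovery of
$P(\mathrm{high\ port})$ over the first trials after a block reversal.

`fitRFLR()` estimates the parameters by profile likelihood: for each $\tau$
on a log-spaced grid (25 points in $[0.25, 10]$) the evidence series is
rebuilt and $(\alpha, \beta)$ are fitted by logistic regression without an
intercept (the model carries no side bias); the grid optimum is refined by
one-dimensional search. First trials, having no predecessor, are excluded
from the likelihood. One caveat is deliberate: when testing whether
$\beta = 0$ (e.g., on choice-shuffled controls), fit at a *fixed* $\tau$ —
under that null $\tau$ is unidentified, and profile-maximizing it inflates
the Wald statistic.

## The synthetic photometry generator

`synthesizeTraces()` builds both channels as linear sums of per-event kernels
plus coupling, drift and noise:

$$\mathrm{DA}(t) = \sum_e a_e\, k^{DA}_{f(e)}(t - t_e) + d(t) + \varepsilon(t),
\qquad
\mathrm{Ach}(t) = \sum_e a_e\, k^{Ach}_{f(e)}(t - t_e)
 - g(t)\,\mathrm{DA}_{clean}(t - \delta) + d(t) + \varepsilon(t).$$

Design choices that matter, and why:

* **Kernels** are differences of Gaussians on a lag axis snapped to 54-ms
  bins, *causal* (identically zero at negative lags) and with support inside
  about one second. Causality is what makes "outcome effects appear only
  after side entry" literally true in the ground truth; the 1-s support keeps
  every kernel inside the $\pm T \cdot 54\,\mathrm{ms} = \pm 1.08$ s lag
  range the encoding model can estimate, so recovery is well-posed.
  Kernel evaluation is exactly zero outside a kernel's support — linear
  interpolation is never allowed to smear a causal step across lag 0 (a
  subtle leak that otherwise puts outcome-scaled signal one sample before
  the event).
* **Channel selectivity.** DA carries centre-entry, side-entry and reward
  kernels; Ach carries side-entry, side-exit, lick and (negative) reward
  kernels, and no centre-port response. With the side-entry-locked events
  shared but alignment-locked, the explicit coupling is the *only*
  cross-channel covariance source in the defaults, which is what makes it
  identifiable. The DA centre-exit kernel is identically zero, providing a
  known-null feature for leave-out analyses.
* **Amplitude rules.** The side-entry-locked transient complex (side-entry
  plus reward kernels) is scaled by an outcome gain, by history gains over
  the eight stay/switch × previous × current outcome labels (largest for an
  unexpected win after a loss, absent on switch trials), and by independent
  per-trial log-normal jitter with cv 0.25 per channel. The jitter emulates
  the 20–30% trial-to-trial variability of real transients and gives the
  noise-correlation analyses genuine within-condition signal variance to
  work with.
* **Coupling** acts on the noiseless DA signal with gain $g = 0.5$ and lag
  $\delta = 108$ ms (100 ms snapped to the bin grid) by default; an optional
  gate $g(t) = 0$ inside a window relative to side entry emulates a
  within-trial epoch where the interaction shuts off. Coupling the clean
  signal (not the noisy observation) keeps recovery well-posed: observation
  noise is never shared between channels.
* **Sampling.** Traces are generated at four samples per 54-ms analysis bin
  (~74 Hz). At exactly one sample per bin, every trial shares a sub-bin
  alignment phase and the two channels' kernel *slopes* become spuriously
  correlated; bin-mean aggregation over four samples averages that phase
  out.
* **Drift and noise**: slow sinusoids (< 0.01 Hz, amplitude 0.05) exercise
  baseline logic; additive white noise with sd 0.1 (trace units) is the
  default observation noise.

`modulateCarriers()` optionally places two envelopes on 167/223-Hz carriers
at 2 kHz, emulating frequency-multiplexed acquisition.

What the generator does *not* emulate: photobleaching, sensor binding
kinetics, motion and haemodynamic artefacts, inter-mouse variability beyond
independent seeds, and aversive outcomes. Passing tests therefore demonstrate
the *analysis chain* is correct on data with the assumed linear structure —
not that real recordings satisfy that structure.

## Preprocessing

* `demodulate()` performs quadrature lock-in demodulation: multiply by sine
  and cosine references, low-pass each arm (4th-order Butterworth at 15 Hz,
  forward-backward for zero phase), return $2\sqrt{I^2 + Q^2}$ so a constant
  envelope is returned at unit gain. At the default carrier pair the
  round-trip envelope correlation exceeds 0.99 with crosstalk far below 1%.
* `dff()` computes $\Delta F/F_0$; the task-data default is a 10th-percentile
  running baseline over a 30-s window (much longer than a trial, robust to
  transients), computed on a 1-s anchor grid and interpolated.
* `zscoreSession()` z-scores over the whole session. Per-session (rather
  than per-segment) normalization was chosen for simplicity and is flagged
  for sensitivity analysis.
* `alignTrials()` cuts windows around a named event into a trials × bins
  tensor by *bin means* — not interpolation — preserving the noise
  statistics the covariance analyses rely on. The alignment timestamp falls
  in the bin whose left edge is $t = 0$; edge trials are dropped, never
  zero-padded.

## Trial metrics and classification

`meanSignal()` (window mean, the "mean DA" metric) and `deltaSignal()`
(max − min, the "delta-Ach" metric for multiphasic transients) reduce each
trial to a scalar. `groupCompare()` aggregates to per-mouse condition means
*first* and then applies a paired two-sided t-test, so mice with different
trial counts weigh equally. `ldaClassify()` decodes trial type from the
window's bins with shrinkage LDA (pooled covariance shrunk toward a scaled
identity, intensity 0.2 whenever bins exceed trials/5 — waveform features
are strongly collinear), under stratified 5-fold cross-validation;
`ldaPermutationNull()` provides the label-shuffle reference distribution.
Default analysis windows are pre = $[-1, 0]$ s and post = $[0, 1]$ s around
side entry, configurable.

When many windows/conditions are tested, Benjamini–Hochberg adjustment can
be applied to the returned p-values with `p.adjust`; the package reports raw
p-values.

## The encoding GLM

`buildDesign()` bins the session at 54 ms, marks each behavioural event with
a 0/1 indicator in its bin (the reward indicator sits at the side-entry bin
of rewarded trials, since reward is triggered by side entry), and expands
every feature into $2T + 1$ time-shifted copies ($T = 20$). Only bins from
1 s before centre entry to 1 s after side exit are modelled; the long ITI
carries no task events. Where adjacent trials' extended spans overlap, the
overlapping bins appear once per trial, flagged, and both copies carry the
earlier trial's group key: every split (train/test and the grouped
cross-validation folds) acts on group keys, so duplicated rows are never
separated across a split — boundary events stay fully represented with no
literal row leakage (the leakage audit in the fit output should always be
zero).

`fitGLM()` minimizes the standard cost functions — OLS
$\lVert y - X\beta\rVert_2^2$; ridge adds $\alpha\lVert\beta\rVert_2^2$;
elastic net $\frac{1}{2N}\lVert y - X\beta\rVert_2^2 +
\alpha(\lambda\lVert\beta\rVert_1 + \frac{1-\lambda}{2}
\lVert\beta\rVert_2^2)$ with $\lambda = 1$ giving the lasso — with an
unpenalized intercept. The two ridge parameterizations differ by the row
count; `ridgeAlphaFromEnet()` converts. OLS and ridge are solved in closed
form through per-group Gram matrices (which also makes the leave-out
analysis cheap); the lasso/elastic net go through glmnet, with the penalty
remapped so the objective above is the one actually minimized (glmnet's
internal response standardization rescales its quadratic penalty by the
standard deviation of $y$; the package corrects for this, and a test checks
the corrected solution against the closed-form ridge through the documented
scale conversion).

`runProtocol()` implements the evaluation protocol: per run, a 50/50
trial-level train/test split; a 10-fold group shuffle split on the training
half with an 80–20 fit/validation division inside each fold; the validation
MSE is the mean of the concatenated squared residuals across folds; the
model is then refit on the entire training half and evaluated on the
held-out test half. `leaveOutAnalysis()` reruns the protocol with identical
splits after dropping each feature's columns and reports the change in
validation/test MSE, together with the full model's cross-validation noise
band (2 sd of its per-fold validation MSEs) against which a null feature's
change should be judged. `extractKernels()` reshapes coefficients into
per-feature lag vectors (mean ± sd across runs); `reconstructSignal()`
returns predictions, $R^2$ and a trial-averaged overlay with a
bootstrap-over-trials 95% interval.

Design-matrix variants: `"history"` replaces the single side-entry column
with eight columns segregated by history label (the first trial, having no
label, is dropped; note that the reward column then equals the sum of the
four current-win label columns, a structural collinearity that the solvers
handle and that leaves predictions unchanged); `"photometry"` appends a
continuous, shift-expanded predictor from another channel.

## Covariance analyses

`crosscovLagged()` estimates the lagged covariance between channels with the
convention *positive lag = channel A leads channel B*, asserted in tests by
construction (a delayed copy peaks at a positive lag) because this is the
classic place for silent sign flips. `"raw"` mode centres by session means;
`"noise"` mode first subtracts condition-specific trial-averaged waveforms
(`conditionMeanResiduals()`). For coupling recovery on generator data the
conditioning label is the full trial type (the eight history labels):
history gains are deterministic per trial type and belong in the condition
mean, not in the noise. Overlapping-segment estimates are used at nonzero
lags; nothing is zero-padded.

`covMatrix2D()` computes $K(t_1, t_2)$, the across-trial covariance between
channel A at $t_1$ and channel B at $t_2$; `offDiagonal()` averages a band
at a fixed offset (default +108 ms, DA leading, one-bin half-width) as a
function of within-trial time, which is how a time-localized weakening of
the interaction (e.g., at side entry) becomes visible.

`nullControls()` provides permutation references: `"circular_shift"`
(independent random circular time shift per trial of one channel) and
`"session_swap"` (pairing with another session's trials). Besides pointwise
2.5/97.5 percentile bands it returns a *simultaneous* band built from each
permutation's across-lag extrema. The simultaneous band is the correct
reference when asking whether *any* lag shows coupling: with ~41 lags, a
pointwise 95% band is expected to be crossed somewhere by pure chance, so
"every lag inside the band" is only a meaningful null statement against the
extremum distribution.

## Numerical choices and degenerate inputs

* Bin width 54 ms everywhere by default; $T = 20$ shifts; trial margin 1 s.
* Event indicators use floor binning (the bin containing the event), which
  is unbiased when responses are bin means; coupling lags are snapped to
  the sample grid with a warning.
* Rank-deficient OLS systems (all-zero columns, structural collinearities)
  are solved with a minimal-jitter pseudo-solution and flagged; coordinate
  descent uses tolerance 1e-9 with a short decreasing lambda path.
* Degenerate behavioural data (all choices identical) yield a fit flagged
  `converged = FALSE` rather than an error; zero-variance traces, empty
  windows, singleton conditions and Nyquist violations raise errors naming
  the offending quantity.
* All randomness flows from per-call seeds through internal substreams; no
  function disturbs the caller's RNG state.

## Problem sizes

The shipped tests and the acceptance script exercise: kernel recovery and
leave-out analyses on 300-trial sessions; coupling-lag recovery on 500
trials for $\delta \in \{54, 108, 216\}$ ms; the gated-coupling epoch on 800
trials; RFLR recovery on 10,000 trials; the outcome dissociation on 8
simulated mice × 250 trials; demodulation on 30-s two-tone records at
2 kHz. These sizes give comfortable statistical margins for every property
tested while keeping a full run in a few minutes on one CPU.

## A short demonstration

```{r demo, eval = FALSE}
cfg <- readPipelineConfig(system.file("extdata", "demo_config.yaml",
                                      package = "BanditPhotometry"))
report <- runPipeline(cfg)
makeReport(report)
```

## Known limitations

* The generator is linear by construction; saturation, sensor kinetics and
  bleaching are out of scope, so the encoding model's excellent $R^2$ on
  synthetic data says nothing about the variance explainable in vivo.
* The DA-to-Ach interaction is modelled as subtractive (matching the linear
  covariance analyses); a divisive interaction would require a different
  recovery analysis.
* Per-session z-scoring and the running-percentile baseline are sensible
  defaults, not optimal estimators, and both are configurable precisely
  because real recordings may need different settings.
* The RFLR is fitted per session (optionally concatenated); hierarchical
  across-mouse fitting is not implemented.
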