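---
title: "Methods: the staircase, the observer model, and the analysis rules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the staircase, the observer model, and the analysis rules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tplearn)
```

This vignette is the package's own account of its science: the measurement
model, the bookkeeping conventions the staircase uses, the exclusion rules,
the generative observer, and the design choices made where more than one
reasonable reading existed.

## The task and the tracked point

A 2IFC duration-discrimination trial presents a standard interval $T$ and a
comparison $T + \Delta t$ in random order; the observer reports the longer
one. The one-up-three-down rule decreases $\Delta t$ after three
consecutive correct responses and increases it after every error. At
equilibrium the probability of a downward move equals that of an upward
move, $p^3 = 1/2$, so the staircase tracks

$$p^{*} = 0.5^{1/3} \approx 0.794,$$

returned by `convergence_probability(3)`. The protocol constants
(`staircase_config()`) are: initial $\Delta t = 0.20\,T$, step $0.10\,T$
until the third reversal and $0.05\,T$ afterwards, 60 trials per block.
Fixation (500 ms), inter-stimulus interval (800 ms) and feedback (1000 ms)
durations are carried as metadata only — the simulation has no real-time
path.

## Staircase bookkeeping conventions

The adaptive rule itself is standard; the bookkeeping around it is not
fully determined by the protocol description, so the package fixes these
conventions:

* **Reversal definition.** A reversal occurs at the trial whose update
  flips the *realized* direction of $\Delta t$ movement (down→up or
  up→down). Trials without a $\Delta t$ change carry the last realized
  direction. The reversal value is the $\Delta t$ at the turning point —
  the level in force on the flipping trial.
* **First change.** The first realized change establishes a direction
  without counting as a reversal: a flip requires a prior direction.
* **Step-switch timing.** "After the third reversal" is read as post hoc:
  the reversal-causing change itself still uses the coarse step; the fine
  step applies from the next change onward.
* **Floor.** $\Delta t$ is clamped at one fine step ($0.05\,T$, i.e. 10 ms
  at $T = 200$ ms) and never reaches zero — a zero difference would make
  "correct" undefined, and a floor of one fine step keeps the step grid
  regular. A down-move absorbed entirely by the clamp is not a realized
  movement and therefore cannot create a reversal. An optional
  `quantize_ms` flag snaps $\Delta t$ to a display-frame grid (e.g. 10 ms
  for a 100 Hz display); it is off by default.
* **Ties.** The staircase never presents $\Delta t = 0$, but
  `respond_2ifc()` guards the degenerate input anyway: with equal physical
  intervals, correctness is a fair coin.

These conventions are enforced by property tests that recount reversals
from the emitted $\Delta t$ sequence with an independent brute-force
oracle. Whether a recorded data set counted a block-final pending direction
change differently is unknowable from a protocol description alone; the
package's definition is self-consistent and recomputable from the logs.

## Threshold estimation and exclusion rules

* **Block threshold** (`block_threshold()`): the mean of the reversal
  values excluding the first three; fewer than five reversals excludes the
  block (exclusion is a value with a reason, never an error). Weber
  fraction: $\mathrm{WF} = \Delta t / T$.
* **Session screening** (`session_threshold()`): within each participant ×
  training session, blocks farther than 3 scaled MADs (normal-consistency
  constant 1.4826) from the center are dropped and the survivors averaged.
  The center is the **participant-session median** by default: the unit
  being screened is a block within one participant's session, and a MAD
  criterion is only coherent around a median. A group-session mean center
  is available (`center = "group_mean"`) for the alternative reading.
  The screen is the strict $|x - c| \le 3\,\mathrm{MAD}$ rule; with an
  all-equal session the MAD is zero and nothing is excluded, while a
  zero-MAD session with discrepant blocks drops exactly the off-center
  blocks.
* **Participant exclusion** (`exclude_participants()`): a
  participant-session is flagged when its WF exceeds the per-group session
  mean by more than 3 group SDs; a participant is excluded when more than
  one session is flagged. The rule is applied once, before any learning
  analysis, on training-session WFs only — the pre/post tests are the
  measured outcome, not a screening variable. Zero-SD sessions flag
  nobody. Exclusion rules only ever change membership; they never alter
  surviving values.

## Learning and transfer analysis

The learning index is $\mathrm{LI} = (\mathrm{WF}_{pre} -
\mathrm{WF}_{post}) / \mathrm{WF}_{pre}$, computed per condition from the
single pre- and post-test blocks (no pooling across conditions); it is
scale-invariant by construction. A **learner** is a participant whose
trained-condition threshold strictly decreased — ties classify as
non-learners because "decreased" is strict. The trained condition defines
learner status by default (configurable in `learning_summaries()`).
`group_summary()` reports cell means with between-subject SEM
($s/\sqrt{n}$); statistical modelling (ANOVA, post hoc tests, Bayes
factors) is deliberately out of scope — the tables are tidy exports for
any external statistics package.

## The generative observer

No generative model of participants comes with the protocol; the one here
is an artifact choice, used for simulation and testing:

* **Scalar timing.** Percepts are Gaussian with mean equal to the physical
  duration and SD $= w \times$ duration (truncated at zero by resampling —
  at realistic $w \le 0.5$ the truncation is never hit in practice). The
  Weber coefficient $w$ is the observer's internal analogue of the
  measured WF. Gaussian scalar noise is the simplest model consistent with
  the scalar property and the WF measure; it yields the closed-form
  psychometric function
  $P(\text{correct}) = \Phi\!\left(\Delta t \big/ w\sqrt{(T+\Delta t)^2 + T^2}\right)$
  (`psychometric_2ifc()`), used as the independent check on every
  simulation.
* **Lapses.** With probability $\lambda$ the response is uniform at
  random, capping accuracy at $1 - \lambda/2$.
* **Learning dynamics.** Per condition,
  $w(s) = w_\infty + (w_0 - w_\infty)\,e^{-s/\tau}$ over sessions
  $s = 0$ (pre-test), $1\ldots4$ (training days), $5$ (post-test);
  `wf_trajectory()` is non-increasing by construction.
* **Defaults** (`default_observer()`, `make_cohort()`): $w_0 = 0.20$,
  $w_\infty = 0.13$, $\tau = 1.5$ sessions, $\lambda = 0.02$. Improvement
  applies to the empty-200 ms and filled-200 ms conditions for
  empty-interval-trained observers (learning plus same-duration format
  transfer) and to no condition for filled-interval-trained observers.
  Cohorts jitter $w_0$ log-normally (SD 0.12 on the log scale, roughly
  ±12% between individuals — a typical spread of timing sensitivity)
  while preserving each condition's asymptote-to-start ratio. These values
  are fixtures that reproduce the qualitative group structure
  (empty-trained observers improve and transfer; filled-trained observers
  do not); they are not estimates of any human cohort.

What the synthetic data do **not** emulate: the filled-duration illusion
and any format-specific bias, reaction times, trial-to-trial
non-stationarity within a session, criterion drift, and floor effects tied
to individual pre-test thresholds. Passing tests therefore certify the
measurement chain — staircase, estimator, exclusion rules, indices — not
any claim about human observers.

## Numerical and reproducibility choices

* **RNG.** Every participant receives a seed derived from the master seed
  by a deterministic integer hash, split again per block, so any block can
  be re-simulated in isolation from its logged seed (`run_block(seed = )`).
  All derived seeds stay below $2^{31}$.
* **Determinism.** `simulate_experiment()` is a pure function of (cohort,
  seed, options); `run_pipeline()` is a pure function of the trial log.
  Logs round-trip bit-exactly through CSV.
* **Problem sizes.** The test suite checks staircase convergence with 100
  runs of 1,000 trials; oracle equivalence over 1,000 random 60-trial
  response sequences; parameter recovery with 250 blocks per noise level
  over $w \in \{0.10, \ldots, 0.30\}$ (mean block threshold within ±15% of
  the true 79.4% point — a tolerance sized for the sampling noise and
  small start-point bias of single 60-trial blocks, tracked rather than
  tuned); and an end-to-end run of the default 11 + 12 cohorts. These
  sizes keep the whole suite around a minute on one core while holding
  Monte-Carlo error well inside each tolerance.
* **Single-block noise.** A 60-trial block estimates the threshold with a
  coefficient of variation near 25%, and the staircase's fixed start at
  $0.20\,T$ biases single-block estimates slightly toward the start point
  (about +13% at $w = 0.10$, −4% at $w = 0.30$ in the recovery tests).
  Consequently per-cell learning indices of a single simulated cohort
  scatter visibly around their expectations — exactly as single-block
  pre/post designs do in practice.

## Known limitations

Only the one-up-three-down rule is implemented (no QUEST/PEST, no
interleaving); thresholds are reversal averages, not maximum-likelihood
psychometric fits; no bootstrap confidence intervals; the import path
expects the package's own CSV schema, so externally deposited data must be
mapped to it first.
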