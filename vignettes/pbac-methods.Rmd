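---
title: "Closed-loop gaze-contingent interception: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop gaze-contingent interception: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbac)
```

This vignette is the package's own account of the science it implements:
the closed-loop task, the generative agents that stand in for participants,
the signal pipelines, the learning models and their fitting, and the design
choices made where the design was genuinely open.

## The task and its geometry

A viewer stands at the court midline and intercepts balls released from one
of two wall holes at lateral offset ±3.67 m, an angular separation of ~85°
apart. The viewer-to-wall distance is not an independent quantity: it is
pinned by the offset/angle pair through `2·atan(x/d) = θ`, which
`derive_viewer_distance()` inverts (3.67 m and 85° give d ≈ 4.005 m). The
same relation makes the two printed anchors slightly inconsistent at the
second decimal: a 0.4 m offset subtends 5.703° at 4.005 m, while the
printed 5.71° corresponds to d ≈ 4.001 m. Both are consistent with a true
distance of about 4 m once the "~85°" rounding is taken into account, and
the acceptance tests propagate exactly that half-degree rounding bound.

Ball flight is a no-bounce parabola from the release hole to the
interception point (±0.75 m lateral, 1.5 m high, at the viewer plane).
Horizontal velocity is constant and vertical motion is under gravity
(9.81 m/s² by default); the flight time T is solved by bracketed
root-finding so that the arc length divided by T equals the 10 m/s mean
speed to within 1e-6 m/s, taking the faster of the two admissible arcs. The
hole height is not fixed by the task layout; it defaults to the
interception height (1.5 m) and is configurable. With gravity switched off
the solver reduces exactly to straight-line distance over speed, which the
tests use as an oracle. Endpoints that no arc can reach at the requested
mean speed raise an error rather than returning a degenerate path.

## Trial scheduling and the three allocation rules

The 80/20 contingency is realised as a *fixed 40/10 count* per 50-trial
block in a seeded pseudo-random permutation, not as iid Bernoulli draws:
the design fixes per-block counts and prespecified order sequences. The
permutation is unconstrained (no maximum-run rule). A 10-trial practice
block with an 8/2 split precedes the three study blocks, which always run
in the order probability-controlled → PbAC → matched.

- *Probability-controlled*: expected trials release from the
  counterbalanced likely side, unexpected from the other.
- *PbAC (gaze-contingent)*: the gate is the horizontal in-world gaze
  coordinate at 50 ms before onset; gaze right of the midline predicts
  right. A gaze sample exactly on the midline classifies **left** (the
  design only defines strict > 0 / < 0; a deterministic tie-break keeps
  the rule total, and it is logged). A missing gate sample falls back to
  the last valid sample, also logged.
- *Matched-order*: replays the PbAC block's release sides trial by trial
  and inherits its expectedness labels unchanged.

Onset delays are drawn from a continuous uniform distribution on [0, 5] s
under the session seed.

## Synthetic agents

Agents close the loop that real participants would: a generative learning
model (3-level HGF by default) tracks the ball-side tendency; the one-step
prediction `μ̂₁` passes through the unit-square sigmoid
`p(y=1) = μ̂₁^ζ / (μ̂₁^ζ + (1-μ̂₁)^ζ)` to choose a gaze side; the agent
fixates that hole with Gaussian noise (`gaze_noise_sd`, default 0.1 m);
after release gaze pursues the ball with a first-order lag (`pursuit_lag`,
default 0.12 s). Interception is a Bernoulli outcome with probability 0.8
when gaze and release side agree and 0.3 otherwise — the hypotheses concern
hit proportions, so racquet-contact physics would add nothing testable.

Pupil traces are `baseline + gain · surprise · k(t) + noise`, where
surprise is the Shannon surprisal `-log p(observed side)` under the agent's
own pre-trial prediction and `k(t) = (t/L)^a · exp(a(1 - t/L))` is a
gamma-shaped impulse response with unit maximum at latency `L` (default
1 s, width 0.7 s, so shape a ≈ 2). The surprisal definition and the kernel
are artifact choices — the task literature links pupil peaks to
computationally salient events without committing to a quantitative model —
and they are validated purely by recovery: on noiseless traces the
regression of measured peak-minus-baseline on injected surprise must
recover the gain within 2%, and measured peaks must be strictly monotone in
surprise. Blinks are contiguous missing runs of 100–300 ms at a
configurable rate (default 10/min), knocking out both eyes' pupil samples.

What the generator deliberately does **not** emulate: saccade dynamics
(pre-release gaze is a noisy fixation, not a scan path), tonic pupil
drift and luminance effects (luminance is constant in the task), biased
eye-specific noise, and any arm/racquet biomechanics. Passing tests
therefore certify the *pipelines and models*, not realism of human data.

## Signal processing

Gaze: a three-frame moving median followed by a second-order 15 Hz low-pass
Butterworth. Pupil: blink runs padded by 150 ms on each side (the padding
side is unstated in the source description; symmetric padding is the
conservative reading), gaps replaced by a least-squares line over up to
100 ms of valid samples flanking each gap, a second-order 10 Hz low-pass,
then binocular averaging. Two open choices were resolved as follows: both
Butterworth passes are run **zero-phase** (forward–backward, with
odd-reflection padding to suppress edge transients), because a causal pass
would lag pupil peak latencies by tens of milliseconds; and the pupil
filter order, never stated, is set to 2 to match the gaze filter. Streams
arrive at 90 Hz and are never resampled; missing samples are bridged only
for the filter's benefit and restored as missing afterwards.

The predictive-gaze window is half-open, `[release − 50 ms, release)`,
holding 4–5 samples at 90 Hz; the mean over valid samples is classified by
sign (0 → left, consistent with the gate rule). The baseline window is
`[release − 200 ms, release)`, mean-aggregated. The surprisal peak is the
maximum over `[release, arrival + 3 s]` minus the baseline mean; a trial
whose windows contain no valid sample yields a missing metric rather than
a fabricated zero. Gaze–ball tracking error is the per-frame angle between
the gaze and ball direction unit vectors (from the viewer's eye position,
1.6 m by default), minimised between release and arrival; it is invariant
to common rotations of both vector sets by construction.

## Learning models

The binary HGF levels evolve as Gaussian random walks: level 2 is the
logit-scale tendency of the outcome, level 3 its log-volatility, level 4
(when present) the drift of that volatility. The trial update is the
standard variational scheme: predictions are the previous posteriors,
`σ̂₂ = σ₂ + exp(κμ₃ + ω₂)` (top level uses `exp(ω)` alone),
`π₂ = 1/σ̂₂ + μ̂₁(1-μ̂₁)`, `μ₂ = μ̂₂ + δ₁/π₂`, and the volatility
prediction error `δ₂ = (σ₂ + ε₂²)/σ̂₂ − 1` drives the next level up. The
coupling κ is fixed at 1 with zero variance — at 150 trials a free κ is not
identifiable alongside the ω's. The precision-weighted prediction errors
are defined as the belief increments `ε_k = μ_k − μ̂_k`, and the trial-wise
learning rate as `α₂ = 1/π₂`. Under this convention α₂ is positive by
construction, so the interpretive rule "negative learning rates are
transformed into positive values" is a no-op; summaries report magnitudes
(`|ε₂|`, `|ε₃|`, `α₂`) so the convention is explicit. Any update that
would produce a non-positive precision rejects the parameter point (the
fit assigns it −∞ joint density) instead of returning invalid
trajectories; this is also why very volatile settings (e.g. ω₃ near 0 with
wide level-3 starting variance) are rejected rather than silently
clipped.

Rescorla–Wagner is the fixed-rate delta rule; Sutton K1 adds a
state-dependent log-rate driven by the correlation of current and recent
errors, with the rate clipped at 1 (and flagged) if it diverges. K1 with
meta-rate 0 reduces *exactly* to RW, and a 3-level HGF with ω₃ → −∞ and a
collapsed level-3 starting belief reproduces the 2-level filter to 1e-6 —
both limits are enforced in the tests, alongside a hand-coded closed-form
oracle for the HGF single step at 1e-10 over a 100-point parameter grid.

The filters are implemented in C++ (they sit inside the fitting
objective); the test oracles are independent plain-R recurrences.

## Fitting, evidence, and model selection

Fitting is observing-the-observer: the stimulus sequence `u` (1 = the
block-1 likely side) and response sequence `y` (gaze side, same coding)
jointly determine the likelihood through the perceptual model's
predictions and the ζ-sigmoid response model (the response model is not
specified in the source description; the unit-square sigmoid is the
standard choice in this line of work). Free parameters — the ω's and
log ζ, plus logit α for RW and the K1 rates — get wide Gaussian priors in
their estimation spaces (ω ~ N(−3 or −6, 4²), log ζ ~ N(0, 2²),
logit α ~ N(0, 2²), i.e. neutral α = 0.5). MAP estimation uses
derivative-free Nelder–Mead with 10 seeded multistarts (the first at the
prior means, the rest drawn from the priors) and objective tolerance 1e-6.
The log-model evidence is the Laplace approximation
`LME = log joint + (d/2)·log 2π − ½·log det(−H)` with a central
finite-difference Hessian (step 1e-4); non-positive-definite Hessians are
regularised by flooring eigenvalues at 1e-8 and flagged, and a MAP sitting
at the edge of the admissible region (where a probe point is rejected)
falls back to the prior precisions for the curvature, also flagged.
`ideal_observer_priors()` regenerates starting-belief means by minimising
the summed surprisal of the input sequences themselves and returning the
resulting posterior means, with a neutral fallback if the optimiser fails.

Random-effects model selection places a uniform Dirichlet prior on model
frequencies and runs the standard variational update on the participants ×
models LME table. Exceedance probabilities use 1e6 seeded Monte-Carlo
Dirichlet draws (the K = 2 case is analytic through the Beta tail); the
Bayes omnibus risk comes from the free-energy comparison against the
equal-frequency null, and `PXP = EP·(1 − BOR) + BOR/K`. Bayes factors in
the statistics layer are BIC approximations,
`exp((BIC₀ − BIC₁)/2)`, and are labelled as such — they substitute for
fully Bayesian factors computed under different priors, so the numbers are
not comparable across implementations.

## Validation design: why reversal sequences

On a single stationary 40/10 block, a fixed-rate learner with a well-chosen
α tracks the HGF's predictions almost exactly; per-participant LME
differences are a fraction of a nat and no selection procedure can separate
the models at 20 participants. This is not an implementation artifact —
hierarchical volatility tracking only earns evidence when volatility
actually varies. The model-recovery suite therefore generates from HGF3
agents on contingency-**reversal** sequences (`make_reversal_sequence()`,
10 segments × 15 trials, majority side flipping each segment), the
canonical identifiable design, and compares at the model-*family* level
(summed PXP of the 2/3/4-level HGFs against RW and against SK1).
RW-generated data must reverse the preference decisively, and does.
Parameter recovery runs on the stationary study-like schedule: ω₂ drawn
across [−5, −1.5] for 20 agents at 150 trials must be recovered with
correlation ≥ 0.8.

## Cleaning rules

Trials with more than 25% missing pupil data (after blink padding) are
discarded — strictly more, so a trial at exactly 25% survives. Participants
with more than a third of trials removed are excluded, same strictness.
Outliers beyond 3 sample SDs (denominator n − 1, computed once, single
pass) are Winsorized to 1% beyond the next most extreme retained score; the
tail rule is sign-aware (×1.01 when the neighbour is positive on the upper
tail, ×0.99 when negative, mirrored below) so the substitute is always
slightly *more* extreme than the retained extreme regardless of sign — the
source rule does not address negative-valued metrics. Two facts worth
knowing: with the sample SD, an n-point sample cannot contain a value
beyond `(n−1)/√n` SDs, so the 3-SD screen is inert below n = 12 and must
be applied to distributions pooled across participants (here: per metric
within condition × expectedness cells); and on the package's default
synthetic data the *gaze-error* battery genuinely changes with
Winsorization on/off, because incongruent-trial tracking errors are
heavy-tailed by construction — the stability-under-Winsorization property
is therefore asserted on the interception, pupil and manipulation-check
battery, where conclusions are identical with and without it.

## Problem sizes and seeds

The shipped validation suite uses 3-agent cohorts for the end-to-end
pipeline checks, an 8-agent cohort for the Winsorization sensitivity
property, 20 agents × 150 trials for model and parameter recovery, 500
trials for the fitting self-consistency check, 1e6 Dirichlet draws for the
exceedance symmetry check, and 120 noiseless trials for the pupil gain
recovery. Every stochastic step takes an explicit integer seed and derives
any internal seeds deterministically from it; the same seed reproduces
sessions byte-for-byte in the serialised CSV artifacts.

## Known limitations

- The agents' response model and the fitted response model coincide (both
  ζ-sigmoid); misspecification robustness is untested.
- The pupil generator is linear in surprisal with a fixed kernel shape;
  real phasic responses saturate and their latency varies.
- Group-level fitting is per-participant MAP + random-effects selection;
  there is no hierarchical (empirical-Bayes) pooling of parameters, no
  MCMC posterior, and no continuous-input HGF variant.
- The matched-order block inherits the PbAC block's labels, so at
  simulation time its "expectedness" is decoupled from the agent's beliefs
  exactly as in the task design — summaries for that block measure
  sequence effects, not belief congruence.
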