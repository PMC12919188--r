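---
title: "Delayed CoM feedback models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delayed CoM feedback models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(comfeedback)
```

This vignette explains the model the package implements, the identification
procedure, the synthetic study it is validated against, and the design
choices made where several reasonable options existed.

## The model and its assumptions

Standing balance is corrected by joint torques that track the deviation of
the body centre of mass (CoM) relative to the feet. The package models one
joint's reactive torque as a *quasi-linear sum of delayed CoM feedback
loops*:

- **One instantaneous acceleration loop.** Torque proportional to the
  full-wave CoM acceleration at a near-zero delay. Physiologically this
  captures the intrinsic mechanical response of loaded limbs — it appears
  at the moment the body accelerates, before any neural feedback can act.
- **Four sign-gated residual loops.** Each loop sees only the positive or
  only the negative half-wave of the CoM channels (displacement, velocity,
  acceleration), carries one shared delay across its three gains, and is
  dedicated to reconstructing either the positive or the negative component
  of the torque response. The four loops cover the four
  (CoM half-wave) × (torque sign) combinations.

The structure is linear in its gains but nonlinear through the half-wave
rectification and the sign assignment — hence *quasi-linear*. With every
gain in use it exposes 18 free parameters (2 for the acceleration loop,
4 loops × 3 gains + 1 delay); in practice fitted models use far fewer
because unneeded gains are driven to zero. The same single structure can
therefore describe responses in every perturbation direction: a joint that
only produces (say) plantarflexion torque for forward sway simply has zero
gains in the loops that would reconstruct the opposite component.

Key modelling assumptions:

- torque depends on the CoM state only through delayed, rectified, linearly
  scaled copies — no history effects beyond the delays, no saturation;
- each loop's displacement/velocity/acceleration terms share one delay
  (`lambda_i`), reflecting a common neural pathway per loop;
- the torque-sign dedication of a loop is enforced through *sign bounds on
  its gains* (a loop that reconstructs positive torque from the positive
  CoM half-wave has nonnegative gains, crossed combinations nonpositive),
  not by clipping the loop output. Clipping would destroy linearity in the
  gains and with it the exactness of the inner least-squares fit.
- sagittal-plane CoM deviation drives the ankle plantarflexion, knee
  flexion and hip flexion models; frontal-plane deviation drives hip
  adduction. Models carry their axis and refuse mismatched inputs.

## Signal conventions

All signals are uniformly sampled; the analysis rate is 1 kHz (external
recordings at other rates are linearly upsampled, mirroring common motion
capture practice). Delays are quantized to the nearest sample — at 1 kHz
the quantization error (≤ 0.5 ms) is far below physiological delay scales.
Delayed signals are back-filled with their first value, consistent with a
quiescent pre-perturbation background after background-torque subtraction.

Low-pass filtering is zero-phase: a Butterworth design applied forward and
backward (with odd-reflection end padding to suppress transients). The
nominal order names the combined order, so the conventional
"fourth-order, 10 Hz" filter is a second-order design applied twice. The
zero-phase choice matters here: a causal filter's group delay would bias
every fitted feedback delay. Filtering is *off* by default in the synthetic
pipeline — the rectification inside the model does not commute with
filtering, so filtered-channel fits of unfiltered ground truth would not be
exact; for real recordings the primitives are exported.

Analysis windows are closed intervals with inclusive endpoints: the ramp
window [−0.25 s, +1 s] around perturbation onset holds 1251 samples at
1 kHz, the sinusoid window [−0.25 s, +15 s] holds 15251. The mean torque
over the 0.25 s before onset is subtracted before fitting ("background
torque"), so models are fit to the perturbation-evoked deviation.

## The staged fitting procedure

1. **Stage 1 — acceleration loop only.** Grid search over the acceleration
   delay (default bounds 0–20 ms, 5 ms step, 1 ms local refinement); at each
   delay the gain is the closed-form least-squares solution, capped in
   magnitude. If this loop explains **strictly more than 95%** of the
   torque variance over the fit window, fitting stops: the response is
   dominated by the intrinsic mechanical pathway.
2. **Stage 2 — residual loops.** Otherwise all four residual loops are fit.
   Their delays (default bounds 40–250 ms, spanning physiological reactive
   latencies) are searched by coordinate descent over the delay grid from
   several seeded starting points; at every candidate the gains of *all*
   loops are re-solved by bounded least squares, which is a small convex
   box-constrained QP solved exactly by an active-set method. The
   acceleration gain and delay are re-estimated jointly in this stage
   (`refit_accel = TRUE`); fitting the acceleration loop alone first and
   freezing it is available (`refit_accel = FALSE`) but biased, because the
   lone acceleration regressor absorbs whatever correlated displacement and
   velocity structure it can — under joint refit, noiseless synthetic data
   are recovered exactly, under freezing they are not.
3. **Parsimony.** Greedy backward elimination over gain columns: a gain is
   kept only if removing it (and refitting the rest) worsens the residual
   SSE by more than `prune_tol` (default 5%). The rationale: a genuine
   loop's unique contribution is large relative to the residual, while a
   term fitting measurement noise moves the residual by a fraction of
   itself. This replaces the hand-tuning of bounds that an analyst would
   otherwise use to stop parallel loops from reconstructing the same
   response features, and it is exact in the noiseless limit (zero-cost
   terms are always removed). After any removal the retained structure is
   refit once with doubled gain caps, in case a removed term was
   compensating for a bound-limited one. Gain magnitude caps default to
   10 × `range(torque) / range(channel)` — generous, data-scaled, and
   configurable.

Goodness of fit uses the coefficient of determination against the mean
(R²), and RMSE divided by body mass (Nm/kg) so errors are comparable across
participants. A fit or transfer cell whose averaged torque range is below
10 Nm is excluded as too noisy to score; the threshold is configurable and
the boundary is a strict less-than (a 10.0 Nm range is retained). A
transfer is a "good fit" when mean R² > 0.7 and mean RMSE < 0.2 Nm/kg.

Determinism: the multistart is the only stochastic ingredient of fitting
and draws from a private seeded RNG stream, so identical inputs and
configuration reproduce bit-identical results without disturbing the
caller's RNG.

## The four generalization protocols

Models are always trained on averaged cardinal-direction (0/90/180/270°)
ramp-and-hold responses, one model per direction × magnitude × joint —
training per *signed* direction is what lets the transfer rules respect
left/right and forward/backward asymmetries.

- **Direction.** Diagonal responses (45/135/225/315°) are predicted by
  summing the two quadrant-matched cardinal models applied to their own CoM
  axes (135° uses the 180° model on the frontal axis plus the 90° model on
  the sagittal axis), same magnitude only. Joints modelled on a single axis
  contribute only that axis's term.
- **Magnitude.** Each magnitude's model predicts every other magnitude's
  response, cardinal directions only, direction-matched. The train = test
  diagonal reproduces the training metrics (asserted in tests).
- **Sinusoid.** Ramp-trained models predict the averaged response to
  continuous 0.75 Hz, 7.7 cm platform sinusoids over [−0.25, +15] s, with
  gains matched to the plane's cardinal direction by starting direction.
- **Superimposed perturbations.** Responses to discrete ramps injected at
  sinusoid zero crossings are isolated by subtracting the averaged
  perturbation-free sinusoid response (phase-verified), segmenting at each
  injection onset, and averaging per perturbation direction — pooling over
  the background sinusoid's starting direction and over accelerating versus
  braking injections, because the transfer rule matches gains to the
  perturbation direction regardless of the background motion. Ramp-trained
  models then predict each averaged segment.

Results aggregate as mean ± sample SD (n − 1) per protocol × joint over
unexcluded cells; excluded cells are reported as excluded, never as zeros.

The phase verification deserves a note: the residual-extraction contract
rejects a trial whose platform sinusoid is more than one sample out of
phase with the average it is subtracted from. The discrete
cross-correlation peak of a 0.75 Hz sinusoid sampled at 1 kHz wanders a few
samples under measurement noise, so when the sinusoid frequency is known
from trial metadata the lag is estimated coherently (least-squares phase
projection at that frequency); the correlation peak is the fallback for
unlabelled data.

## The synthetic study

No public dataset accompanies this kind of protocol, so the package
generates its own from known ground truth — the generator is first-class,
tested code, and its defaults are the study conditions.

**Protocol.** Ramp-and-hold translations in 8 directions × 4 magnitudes
(4.9 cm/16 cm s⁻¹/1.06 g "small slow"; 4.9/24/1.6 "small fast";
7.7/16/1.06 "medium"; 12.6/24/1.6 "large") × 5 repetitions = 160 trials,
with symmetric trapezoidal velocity profiles evaluated analytically on the
grid. A sinusoid block of 2 planes × {none, slow, fast superimposed} × 6
repetitions (3 starts per direction) = 36 trials; sinusoids run 10 cycles
at 0.75 Hz, 7.7 cm, with half-cycle cosine on/off tapers (a physical
platform cannot step its acceleration; the taper leaves the zero crossings
in place and is removable). Superimposed ramps are injected at displacement
zero crossings 5, 9 and 13, alternating accelerating/braking across
repetitions.

**Plant.** Per horizontal axis a linearized inverted pendulum in the
platform frame,

    d'' = (g/h) d − (b v + tau_total) / (m h) − p''(t),

driven by platform acceleration `p''`, with gravity destabilizing, a
passive viscous term `b` (damping ratio 0.5 of `2 m h sqrt(g/h)`), and
stabilized in closed loop by the summed torque of that axis's ground-truth
joint models evaluated on the delayed, rectified simulated CoM history.
Integration is fixed-step at 1 kHz; because every ground-truth delay is at
least one sample, the loop is explicit, and with zero measurement noise the
recorded torque channels equal `predict_torque(ground truth, recorded CoM)`
sample for sample — the self-consistency that makes exact parameter
recovery a meaningful test. Divergence (|d| > 0.5 m) is an error naming the
unstable parameter set. Measurement noise is seeded Gaussian, SD 2% of each
channel's noiseless range, added to the recordings only (not fed back).

**Ground truth.** Gains scale with body mass (default 70 kg, CoM height
1 m). Sagittal stabilizing torque (≈ 18 Nm per m CoM displacement per kg;
5.5 Nm·s/m/kg velocity) is split ankle 55% / knee 15% / hip flexion 30%;
hip adduction alone stabilizes the frontal plane. Each joint uses the
(+CoM → +torque) and (−CoM → −torque) loops with the negative side scaled
by 0.8–0.85 for directional asymmetry, delays 85–110 ms. The ankle has *no*
acceleration loop (its response is purely delayed feedback), knee and hip
have one at 10 ms — mirroring the reported dominance of intrinsic mechanics
at proximal joints. By default the plant is context-dependent at exactly
the joints where transfer across movement contexts fails in humans: the
sinusoid-context ankle shifts weight from displacement to velocity
feedback, and the sinusoid-context hip adduction becomes
displacement-dominant with a 220 ms delay. These modifications were chosen
to keep the closed loop stable while genuinely changing the controller's
transfer function at 0.75 Hz, so ramp-trained models transfer well at knee
and hip flexion and poorly at ankle and hip adduction. Knee/hip gains are
context-invariant.

**What the generator does and does not emulate.** It produces
physiologically scaled, closed-loop-consistent multichannel trials with the
study's timing, magnitudes and noise — sufficient to exercise every
pipeline stage and to make parameter recovery falsifiable. It is *not* a
biomechanical model of a person: one pendulum per axis, additive per-joint
torques, no multi-segment coupling, no stepping, no trial-to-trial gain
variability, no inertial platform artifacts. Passing tests therefore
demonstrate that the pipeline is correct and well-conditioned under the
study conditions, not that the model describes any particular human
dataset.

## Numerical choices and degenerate inputs

- Bounded least squares is solved by an in-package active-set method
  (validated in tests against `optim(method = "L-BFGS-B")` and dense grid
  search); near-zero regressor columns (e.g. a rectified half-wave of a
  one-sided signal) are fixed at zero with a warning in the exported
  fitting entry point.
- The delay search is a deterministic grid (5 ms step) plus 1 ms local
  refinement; multistart (default 3 seeded starts) protects the coordinate
  descent against local minima in the delay dimensions.
- A zero-variance torque target is an error (unusable trial); a
  zero-variance prediction defines stage-1 R² as 0.
- Trial averaging requires identical condition keys and a shared time base;
  trial onsets come from metadata (simulation ground truth), with a
  threshold-crossing detector (`detect_onset`) available for external data.
- Problem sizes in the test-suite and acceptance runs are chosen to keep a
  full run to a few minutes on one CPU: recovery tests use 1–5 repetitions
  and 2 directions, cohort checks 2–20 synthetic participants, and the
  acceptance script simulates the full 196-trial protocol for 2
  participants. All sizes are arguments, so larger studies are one call
  away.

## Known limitations

- The plant's minimal realism means absolute transfer metrics on synthetic
  data should not be read as predictions of human values; only the
  qualitative patterns (direction/magnitude transfer, context dissociation)
  are designed into the ground truth.
- The parsimony tolerance (5% of residual SSE) is a fixed heuristic, not a
  formal model-selection criterion; for borderline loops a bootstrap or
  information criterion would be the next step.
- Diagonal prediction for single-axis joints sums only the modelled axis;
  whether a second-axis contribution should be added is unresolved in the
  protocol definition and the missing-axis term is simply zero (logged).
- Sinusoid-context transfer uses the model trained at the cardinal matched
  to the trial's starting direction; with strongly asymmetric responses the
  choice of cardinal within the plane matters and is configurable only by
  refitting.
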