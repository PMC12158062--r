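---
title: "Per-second energy expenditure from heart rate: model, environment, and training"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Per-second energy expenditure from heart rate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The estimation problem

Energy expenditure (EE) is the energy a body consumes per unit time.  The
reference measurement is indirect calorimetry — EE inferred from oxygen
consumption:

$$\mathrm{EE}\ (\mathrm{kcal/min}) = \mathrm{VO_2} \cdot W \cdot 5 / 1000,$$

with $\mathrm{VO_2}$ in mL/kg/min and weight $W$ in kg.  It is accurate but
requires a respiratory mask, so it serves here only as ground truth
(`ee_from_vo2()`, per second via `gt_ee_per_second()`).

Two closed-form field estimators are practical with wearable data:

* **MET-based**: $\mathrm{EE} = \mathrm{MET} \cdot W \cdot 3.5/200$
  kcal/min (`ee_met()`).  It needs the activity's MET index known in
  advance and reacts to nothing the person actually does.
* **Keytel regression**: a linear model of EE (kJ/min) on heart rate,
  weight and age with separate male/female coefficients (`ee_keytel()`).
  It tracks heart rate but assumes one fixed HR–VO$_2$ proportionality.

This package implements a third estimator that keeps the MET structure but
*learns* the intensity in real time.  With the Mifflin–St Jeor resting
metabolic rate (RMR, kcal/day; males $10W + 6.25H - 5A + 5$, females
$10W + 6.25H - 5A - 161$) divided by 86,400 into kcal/s, the prediction at
each second is

$$\widehat{\mathrm{EE}}_{sec} = \mathrm{RMR}_{sec} \cdot (1 + a),$$

where $a \in \{0, 0.1, \ldots, 20\}$ is an *activity-intensity
coefficient* — effectively MET $-$ 1 on a discrete grid of 201 values —
chosen every second by a deep Q-network (DQN) from the state
$[W, H, A, G, \mathrm{HR}_t]$.  Because $a$ is capped at 20, predictions
are bounded in $[\mathrm{RMR}_{sec}, 21\,\mathrm{RMR}_{sec}]$ by
construction, which structurally limits overestimation at high intensity.

## Units

The canonical internal unit is **kcal/s**: ground truth is per-second, and
every estimator is converted before comparison (`convert_energy()`).  The
kJ→kcal factor is fixed at the thermochemical 4.184; the per-day→per-second
divisor is exactly 86,400.  The Keytel formula itself is returned
*unclamped* (it is negative below roughly 56 bpm for a typical male
profile); clamping negatives to zero is an evaluation-stage decision
(`keytel_series(clamp = TRUE)`, the default there), so the formula module
stays faithful and the choice is visible and reported.

## The episodic environment

A training episode is one **window** of $L$ consecutive seconds of one
session (default $L = 300$; the 60-s alternative supports the
scenario-length ablation).  Windows slide forward by a configurable stride;
with stride 1 a session of $T$ seconds yields $T - L + 1$ windows.  Time is
0-based and windows are half-open $[t, t+L)$.

At each second the environment emits the raw state
$[W, H, A, G, \mathrm{HR}_t]$, receives an action index, converts it to
$a = \mathrm{index}/10$, forms the prediction and pays the reward

$$r = -\,\frac{|\mathrm{GT} - \widehat{\mathrm{EE}}|}{1 + \mathrm{GT}},$$

a normalized absolute error: non-positive, zero only at exactness, and —
for a fixed absolute error — smaller in magnitude at higher intensity, so
the learning signal is comparable across rest and running.  The
denominator adds a dimensionless 1 to a kcal/s quantity; it is implemented
literally on the kcal/s scale, as defined.  `done` is true exactly at the
window's last second; there is no discounting across windows.

Ties in every argmax (greedy action, brute-force best action) break toward
the lowest index — deterministic and testable.  `optimal_action()` is the
brute-force oracle over all 201 actions; the test suite checks it against
the independent closed form
$\mathrm{clamp}(\mathrm{round}(10(\mathrm{GT}/\mathrm{RMR}_{sec} - 1)), 0, 200)$.

## The agent

The Q-network is a fully connected 5–64–64–201 net, ReLU hidden layers,
linear output.  Training follows standard DQN practice: FIFO replay
buffer, uniform minibatch sampling without replacement, epsilon-greedy
exploration, a target network for the bootstrap term, mean-squared
temporal-difference loss, Adam.

Defaults, with provenance:

| parameter | default | why |
|---|---|---|
| learning rate | 1e-4 | reference hyperparameter |
| discount $\gamma$ | 0.95 | reference hyperparameter |
| replay capacity | 50,000 | reference hyperparameter |
| epochs | 35 | reference stopping point |
| window length | 300 s | reference scenario length |
| batch size | 64 | our choice; reference silent |
| warm-up | 1,000 transitions | our choice |
| update every | 4 env steps | our choice (see below) |
| target sync | every 1,000 gradient steps | our choice; standard DQN |
| $\varepsilon$ schedule | 1.0 → 0.05, linear over first 50% of steps | our choice |
| training stride | 30 s | desk-scale default; stride 1 s available |

Two of these deserve comment.  *Update frequency*: a gradient step every 4
environment steps is the canonical DQN training frequency; per-step
updates (`update_every = 1`) are available but quadruple compute while
consecutive per-second states within a window are nearly identical, so the
extra updates are largely redundant.  *Stride*: with stride 1 every
session second starts a window and an epoch costs ~30× more; stride 30
keeps full coverage of the data (windows still overlap 10×) at desk scale.

**Standardization.** Raw state components span 0/1 (gender) to ~180 (HR,
height); the agent z-scores states with statistics fitted on its training
sessions.  The environment always exposes raw states; the scaler belongs
to the agent and travels with its checkpoint, so a loaded checkpoint
reproduces predictions exactly.

**Determinism.** All R-side draws flow through explicit seeds without
touching the caller's RNG stream; the C++ training loop uses one
`std::mt19937` seeded from the config.  Two runs with the same seed are
byte-identical end to end (generator CSVs, checkpoints, reports) on a
fixed platform.

**Implementation note.** The training loop is compiled (RcppArmadillo).
The TD gradient at the output layer has exactly one nonzero per batch row,
so the 201-wide matrix products of a dense backward pass collapse to
scatters; this makes a 10-epoch desk-scale run a matter of minutes on one
CPU.  The exported `td_update()` calls the same kernel the trainer uses —
what the tests exercise is what training runs.

## The synthetic generator

Real sessions of the kind this method targets pair a participant's
demographics with per-second heart rate and VO$_2$ over a fixed 30-minute
protocol: Sitting, Standing, Cycling (low/high), Running (low/high), five
minutes each.  The generator (`generate_session()`) emulates exactly that
stated world:

* demographics uniform in the observed cohort brackets (age 23–41 y,
  height 160–186 cm, weight 53–99 kg, gender fair coin);
* per-segment target MET fixed at 1 (sitting) and 1.2 (standing), and
  sampled uniformly within the observed per-segment ranges otherwise
  (e.g. Cycle2 in [12, 16], Run2 in [10, 20]);
* target VO$_2$ = 3.5 × MET mL/kg/min — the MET definition, matching the
  3.5 constant of the MET formula;
* effective VO$_2$ follows the target through a first-order lag with time
  constant $\tau = 30$ s, a minimal model of the cardiorespiratory
  transition delay that real protocols show at segment boundaries;
* heart rate is linear in effective MET
  ($\mathrm{HR} = 65 + 9(\mathrm{MET}_{eff} - 1)$ bpm) plus AR(1) noise
  (innovation sd 2 bpm, coefficient 0.9) — the simplest structure under
  which HR carries recoverable intensity information, which is the
  premise of the method;
* ground truth is indirect calorimetry on the effective VO$_2$.

The resting heart rate (65 bpm), slope (9 bpm/MET) and noise level are
fixed once at values typical for healthy adults; they are inputs to the
stated world, not tuning knobs.

What the generator does **not** emulate: heart-rate variability and PPG
sensor artifacts, HR drift under sustained load, inter-individual
differences in HR–VO$_2$ coupling (every synthetic participant shares one
HR curve), missing-data patterns of field devices, and accelerometry.
Consequently a green synthetic test establishes that the machinery learns
and evaluates correctly **when heart rate is informative of intensity by
construction** — it does not certify accuracy on real wearable data, whose
headline error tables require the real cohort.

## Evaluation

`compare_methods()` produces the three-estimator report — `ours`,
`keytel`, `met` — as overall (`Total`) plus per-segment MAE in kcal/s,
pooling per-second absolute errors across sessions, so `Total` is exactly
the duration-weighted mean of the segment values.  Missing HR seconds are
forward-filled (leading gaps back-filled) with counts reported; excluding
them instead is available via `fill = "none"`.  The deliberate +2 MET
mis-specification (`met_offset = 2`) reproduces the qualitative failure
mode of the MET baseline — accurate at rest, overestimating during
activity — against which the learned estimator is compared.

The train/test split holds out one male and one female (the first of each
in session order, a deterministic rule), mirroring the reference
protocol's 15/2 participant split.  `scenario_length_ablation()` trains
otherwise-identical agents at 300-s and 60-s windows and reports both
MAEs; the direction of the difference is reported, not asserted, since it
is a property of the data.

## Known limitations

* **Grid-exact recovery is hard for a DQN.**  Adjacent actions differ in
  reward by about $0.1\,\mathrm{RMR}_{sec}/(1+\mathrm{GT}) \approx 2
  \times 10^{-3}$, while $\gamma = 0.95$ inflates Q-values to roughly
  $20\times$ the per-step reward.  Resolving the argmax to the exact 0.1
  grid cell therefore requires relative Q accuracy near $10^{-4}$, which
  mean-squared TD learning at the fixed reference learning rate does not
  reach in a desk-scale run: minibatch gradient noise sets an error floor
  well above the adjacent-action gap.  The policy converges to the right
  neighbourhood (reward climbs, MAE falls far below the mis-specified MET
  baseline) but exact-index agreement with the brute-force oracle remains
  low.  The acceptance suite states the exact-agreement criterion
  faithfully and reports the measured value rather than relaxing it.
* The per-second action reading (the agent acts at every second of the
  window) is one of two readings the reference description admits; the
  alternative (one action per window) would change the environment
  contract, not the formulas.
* The loss scale reported in training history is mean per-batch squared
  TD error; no attempt is made to match unnormalized, summed loss
  magnitudes reported elsewhere.
* Keytel's kJ/min output is compared on kcal/s via 4.184 and 60; any
  other calorie convention shifts that baseline by ~0.1%.
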