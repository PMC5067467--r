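---
title: "A system-level neural model of instrumental devaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A system-level neural model of instrumental devaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(devalsim)
```

## The behavior being modeled

In an instrumental devaluation experiment a rat first learns, in separate
sessions, to press two levers for two different foods. One food is then
devalued by satiation, and the rat is finally offered both levers *in
extinction* (no food is ever delivered). Intact rats press the lever whose
food is still valued far more than the other; this instrumental devaluation
effect is the standard behavioral signature of goal-directed control,
because the choice can only reflect an internal valuation of the anticipated
outcome, not new feedback. Lesion studies localize the effect: basolateral
amygdala (BLA), gustatory insular cortex (IC), nucleus accumbens core (NAc)
and posterior dorsomedial striatum (DMS) are needed both to acquire and to
express it, while prelimbic cortex (PL) is needed to acquire but not to
express it.

`devalsim` implements a firing-rate network that reproduces this pattern,
together with the full simulated experiment battery (training, satiation,
extinction tests, pre- and post-training lesions, 40 replicates per
condition) and the associated statistics.

## Units

Every node abstracts a neural population with a leaky integrator,

$$\tau \dot u = -u + I, \qquad v = [\tanh(\sigma (u - \theta))]^+,$$

where $I$ is the weighted input sum and $[x]^+$ is zero for $x \le 0$.
Activations therefore always lie in $[0, 1)$. Striatal units are the same
integrator with a dopamine-modulated input gain,

$$\tau \dot u = -u + (\iota + \delta \, da)\, I,$$

so dopamine multiplies the *efficacy* of whatever cortical input a striatal
channel receives; it cannot excite a channel that receives none. Onset
units couple an excitatory and an inhibitory population,

$$\tau_o \dot u_o = -u_o + [I - u_i]^+, \qquad \tau_i \dot u_i = -u_i + I,
\qquad o = [\tanh(u_o)]^+,$$

and respond to a sustained input with a transient that decays on the
$\tau_i$ time scale. They model the phasic reward responses of the
pedunculopontine nucleus (PPN) and lateral hypothalamus (LH), and the four
cue/outcome cells of the BLA/IC bank. Exploration is driven by a decaying
moving average of uniform noise injected into every thalamic unit,
$\tau \dot n = -n + \nu z$, $z \sim U[-0.5, 0.5]$, drawn once per
environment cycle.

## Architecture

Three basal ganglia-thalamo-cortical loops with two topographic channels
each perform selection by disinhibition: striatum inhibits an internal
pallidum (GPi/SNpr) that is tonically active at rest and holds the thalamus
down; cortex and thalamus excite each other reciprocally; the subthalamic
nucleus provides diffuse pallidal excitation (off-center/on-surround), and
thalamic units exchange reciprocal inhibition. The *goal* loop (NAc-PL)
selects outcome representations, the *associative* loop (DMS-parietal/dorsal
prefrontal cortex) selects associative content, and the *motor* loop
(DLS-MC) selects one of the two actions: an action is emitted whenever its
motor-cortex unit exceeds $\theta_{mc}$ for 10 consecutive 0.05 s cycles.

The BLA/IC bank holds two cue (CS) and two outcome (US) onset units. Food
ingestion drives a US unit directly; satiation inhibits it one-to-one with
a weight large enough to suppress recall completely. All-to-all lateral
connections within the bank learn with a differential Hebbian rule applied
to slow activity traces ($\tau_t \dot t = -t + \alpha o$):

$$\Delta w_{post,pre} = \eta_b \,[da - \theta_{da}]^+ \,[\dot t_{post}]^+
\,[\dot t_{pre}]^- \,(w_{max} - w),$$

which potentiates a connection only when the presynaptic trace is falling
while the postsynaptic trace is rising — a cue followed by a food, never the
reverse. Out-of-loop inputs to the three striatal stages (levers to DMS and
DLS, BLA/IC outputs to NAc) learn with the three-factor rule

$$\Delta w = \eta \,[da - \theta_{da}]^+ \,[v_{str} - \theta_{str}]^+
\,[v_{inp} - \theta_{inp}]^+ ,$$

gated by phasic dopamine and by the cortically reinforced activity of the
winning channel. All plastic weights start at exactly zero, increments are
non-negative (no extinction is modeled), and each projection carries a
configurable ceiling.

Dopamine comes from a VTA unit driven phasically by the LH, and from two
SNpc modules (one per dorsal striatal stage) driven phasically by the PPN.
Each SNpc channel couples a fast excitatory dopamine unit with a slow
inhibitory unit; the striato-nigro-striatal spirals let NAc inhibit the
inhibitory unit of the DMS module and DMS inhibit that of the DLS module,
so sustained striatal activity upstream raises tonic dopamine one stage
downstream, channel by channel. This is the sub-cortical route by which a
selected goal biases action selection.

Two fixed, weak, channel-preserving cortico-cortical pathways link the
loops. The descending arm (PL to associative cortex to MC) carries a
sub-threshold goal bias: it only matters when the associative loop's own
basal ganglia have already disinhibited it, which is why lesioning DMS or
cutting the spirals abolishes expression even though the cortical wires are
intact. The ascending arm (MC to associative cortex to PL) carries the
identity of the action currently in execution. We found the ascending arm
to be structurally necessary: the NAc learning rule credits whichever goal
channel is active when the reward arrives, and without an action-locked
bias on PL that channel is seeded by noise, so the learned outcome-goal
mapping ends up uncorrelated with the action that actually earns the food
in a substantial fraction of simulated rats. With the ascending arm, the
executing action holds its own goal channel active through the delivery
window and the mapping aligns in essentially every replicate. Value still
flows downward only through the spirals; the ascending arm carries action
identity, not value.

## The simulated experiment

Each interaction cycle is 0.05 s. A press is the completion of a 0.5 s hold;
a rewarded press turns the food input on for 1 s (the hold requirement is
released) and ends the trial; otherwise the trial times out at 15 s and the
units, traces and noise are reset (weights persist). An action without an
environmental consequence — the absent manipulandum in the two-lever
sessions, the unrewarded direction of the single manipulandum in the
one-lever sessions — switches its motor channel (striatum, STN, pallidum,
thalamus, cortex) off for 2 s. Extinction-test actions are effective but
unrewarded, so they are never switched off and trials run to timeout with
repeated pressing. A replicate is two 20-min training sessions
(manipulandum 1 with food 1, then manipulandum 2 with food 2), a weight
snapshot, any post-training lesion, and two 2-min extinction tests: first
with no satiation, then with the second food satiated. Lesions clamp a
structure's activations to zero permanently; the spiral disconnection
zeroes the two spiral projections. Batteries run 40 replicates per
condition with seeds `base_seed + 0..39`, matched across conditions.

Learning curves are press counts in ten 2-min bins, one series per
replicate and manipulandum (80 series), compared with a one-factor
repeated-measures ANOVA over bins — for the 80 x 10 design the degrees of
freedom are (9, 711). Test preferences use two-sided paired t-tests across
the 40 replicates (df 39). The devaluation effect is scored present when
the preference is non-significant in the first test and significant in the
second ($\alpha = 0.05$; no sphericity correction is applied anywhere).

## Why the lesion battery comes out the way it does

During training, motor and associative channels learn the lever inputs by
trial and error under phasic dopamine; the winning channel's cortical
feedback keeps the competitor below the learning threshold, so the
lever-to-action mapping follows the environment. In parallel the BLA/IC
associates each cue with its food, and the NAc associates the food's
representation with the goal channel of the action that earns it (aligned
by the ascending pathway). At test, a lever recalls its outcome; satiation
suppresses one outcome's unit, so only the valued outcome can activate its
goal channel. The held goal raises tonic dopamine along the spirals, which
multiplies the lever input of the matching associative and motor channels,
and that channel wins the selection race essentially every trial.

Removing BLA/IC or NAc removes the valuation signal (acquisition and
expression). Removing PL before training removes the cortical feedback the
NAc learning rule needs, so the valuation-to-goal mapping is never learned
— but removing PL after training leaves expression intact, because the
recall-driven NAc transient still opens the spiral route without cortical
support. Removing DMS, or cutting the spirals, interrupts the only channel
that carries value downstream, in acquisition and in expression alike.

## Parameters and numerical choices

All parameters live in one YAML file
(`system.file("extdata", "default-params.yaml", package = "devalsim")`) and
in `default_config()`. The architecture, the signs and the
learning rules fix the structure of the model but not its magnitudes, so
the shipped defaults are this package's own calibration; the choices that
matter most are:

* **Integration.** Forward Euler at the environment-cycle step (0.05 s),
  with a `substeps` knob for refinement. Halving the step moves the fastest
  phasic transients (onset units with $\tau_o = 0.05$ s are integrated at
  $h = \tau_o$) by up to ~0.25 in activation units at their peak; tonic
  variables, traces and weights move far less, and the behavioral
  statistics are unchanged. Noise draws and learning updates are applied
  once per cycle so both are invariant to `substeps`.
* **Selection operating point.** Pallidal rest tone, thalamic threshold and
  noise amplitude ($\nu = 2.7$, amplitude s.d. about 0.17) are set so that
  a naive channel ignites from noise on the order of once per half minute,
  a lever-trained channel several times faster, and a dopamine-boosted
  channel essentially immediately. The devaluation choice is decided by
  this ignition race, and the winner then suppresses the loser through the
  subthalamic and thalamic lateral projections.
* **Weight ceilings.** The three-factor striatal rule has no intrinsic bound;
  we cap lever weights at 0.2 so that the *difference* between boosted and
  unboosted channels stays in the graded range of the striatal
  nonlinearity (with both levers present the common drive would otherwise
  saturate selection), and cap the BLA-to-NAc weights at 3.
* **Goal persistence.** The goal loop has stronger cortico-striatal
  feedback and a slower cortex ($\tau = 0.2$ s on PL) than the other
  loops, so a goal selected from recall
  holds for the remainder of a 15 s trial. This is what keeps the devalued
  channel silent for whole trials in the test.
* **Learning thresholds.** The NAc input threshold (0.6) sits between the
  food-driven outcome activation (~0.8) and the residual cue activation at
  reward time, so only outcome units acquire goal associations — cue
  shortcuts straight to the goal loop would bypass satiation and destroy
  outcome-specific devaluation.
* **Channel switch-off.** The duration of the switch-off after an
  inconsequential action is a free protocol choice; it is a config
  parameter (`experiment$silence_s`, default 2 s; `-1` clamps for
  the rest of the trial). The 2 s default lets a channel that is being
  driven by a (wrong) goal keep re-asserting itself and thereby delay the
  competing action — the behavioral cost that teaches the goal loop which
  goal pays.

## What the synthetic environment does and does not capture

The environment is the standard operant-chamber abstraction: binary cue,
food and satiation variables, a fixed hold requirement, immediate reward
delivery and trial resets. It reproduces the closed-loop structure of the
real experiments (actions change stimuli, stimuli drive learning) but has
no spatial structure, no lever kinematics, no variable reward schedules and
no inter-trial interval (the next trial starts immediately; this is a
configurable choice). Passing the battery therefore shows that the
*circuit-level hypotheses* are sufficient for the devaluation pattern under
idealized sensing and acting; it does not show robustness to noisy
perception, timing variability or degraded contingencies, none of which are
modeled.

## Known limitations

* In the one-manipulandum variant the no-devaluation test shows a residual
  preference for the action trained in the first session: its recalled
  outcome enjoys an incumbency advantage that two full sessions do not
  erase at this calibration. The devalued-test contrast itself is intact
  and very large.
* In the training curves, the BLA/IC-lesioned group patterns with the
  NAc-lesioned groups rather than with controls, because at this
  calibration the goal loop's contribution to training speed runs almost
  entirely through the recalled outcome. The empirical pattern (BLA/IC
  lesions spare instrumental learning) would require a goal contribution
  that does not depend on the amygdala.
* Extinction learning, contingency degradation, Pavlovian-instrumental
  transfer, the pallidal indirect pathway and differentiated BLA vs IC
  roles are out of scope by design.

## Problem sizes

The shipped experiment sizes are the study conditions themselves: 40
replicates per condition, 20-min training sessions, 2-min tests, 0.05 s
cycles. The full eleven-condition battery is about 2 x 10^7 network cycles
and runs in well under a minute through the compiled core; the complete
test suite, including the acceptance battery, runs in a few minutes.
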