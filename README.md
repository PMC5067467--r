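# devalsim

`devalsim` simulates the rat **instrumental devaluation** paradigm with a
system-level firing-rate model of the brain circuits for goal-directed
behavior, and reproduces the classic lesion battery around it. It is aimed
at computational and behavioral neuroscientists who want an executable,
parameter-transparent account of *how the current value of an outcome can
control which action is performed* — and what breaks when specific
structures are removed.

## The model in brief

Every node is a population rate unit, `τ u̇ = −u + I`,
`v = [tanh(σ(u − θ))]⁺`; striatal units scale their input by a dopamine
gain `(ι + δ·da)`, and "onset" units (a coupled excitatory/inhibitory pair)
turn sustained inputs into phasic transients. The architecture comprises:

* a **BLA/IC valuation bank** — two cue (CS) and two outcome (US) onset
  units with plastic lateral connections trained by a dopamine-gated
  *differential Hebbian* rule on slow activity traces
  (`Δw ∝ [da−θ]⁺ [ṫ_post]⁺ [ṫ_pre]⁻ (w_max − w)`), so a cue that precedes a
  food comes to recall it; satiation inhibits an outcome unit directly;
* three **basal ganglia–thalamo–cortical loops** (goal: NAc–PL;
  associative: DMS–PPC/PFCd; motor: DLS–MC), two channels each, selecting
  by striatal disinhibition of a tonically active pallidum, with thalamic
  noise driving exploration;
* a **dopamine system** — phasic bursts from LH→VTA and PPN→SNpc gate all
  learning (three-factor striatal rule
  `Δw ∝ [da−θ_da]⁺ [v_str−θ_str]⁺ [v_inp−θ_inp]⁺`), while
  **striato-nigro-striatal spirals** (NAc→SNpc→DMS→SNpc→DLS,
  channel-preserving) convert sustained goal selection into tonic dopamine
  that biases downstream selection;
* fixed, weak cortico-cortical pathways between the loops (descending goal
  bias, ascending action identity).

A simulated rat runs the full protocol: two 20-min training sessions (one
manipulandum + food each), then two 2-min extinction tests — first with no
satiation, then with the second food satiated. Lesions (BLA/IC, NAc, DMS,
PL; pre- or post-training) clamp a structure to zero; the spiral
disconnection zeroes the spiral projections. The analysis layer reproduces
the standard statistics: binned learning curves with repeated-measures
ANOVA (df (9, 711) for 80 series × 10 bins), mixed lesion × bin ANOVA,
Bonferroni post-hocs, paired t-tests (df 39 for 40 replicates) and the
devaluation-effect verdict (no preference before devaluation, preference
for the valued lever after).

## Worked example

```r
library(devalsim)
cfg <- experiment_config(default_config(), n_reps = 10)
battery <- run_battery(c("CONTROL", "BLA/IC-pre", "PL-post"), cfg)
print(battery)
#> <ide_battery> 3 condition(s), 10 replicates each
#>   CONTROL     final bin 15.35 | ND 82.80 vs 124.20 | D 160.20 vs 31.00
#>   BLA/IC-pre  final bin  4.95 | ND 86.30 vs 82.30 | D 83.50 vs 67.00
#>   PL-post     final bin 15.35 | ND 85.20 vs 120.80 | D 143.60 vs 41.00

s <- summary(battery)
s$test[c("condition","nd_a1","nd_a2","nd_p","d_a1","d_a2","d_t","d_p","ide")]
#>    condition nd_a1 nd_a2  nd_p  d_a1 d_a2   d_t     d_p   ide
#> 1    CONTROL  82.8 124.2 0.285 160.2   31 6.512 0.00011  TRUE
#> 2 BLA/IC-pre  86.3  82.3 0.913  83.5   67 0.526 0.61185 FALSE
#> 3    PL-post  85.2 120.8 0.360 143.6   41 3.570 0.00602  TRUE
```

Reading the output: in the first (non-devalued, `nd`) extinction test,
intact rats press the two levers statistically equally (`nd_p = 0.29`). In
the second test, with food 2 satiated, they press the valued lever about
five times more (`160 vs 31`, paired `t(9) = 6.5`, `p = 1e-4`): the
devaluation effect (`ide = TRUE`). A pre-training BLA/IC lesion abolishes
the effect (both tests flat), while a *post*-training PL lesion spares it —
the signature dissociation showing PL is needed to acquire, but not to
express, goal-directed control. `plot(battery)` draws the per-condition
ND/D bar charts, `write_results(battery, "out/")` the CSV tables, and
lower-level entry points (`build_model()`, `step_model()`, `run_trial()`,
`run_session()`, `model_weights()`) expose the circuit cycle by cycle.

A command-line front end is installed at
`system.file("cli", "devalsim", package = "devalsim")` with `run`,
`battery` and `report` subcommands.

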