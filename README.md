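# reachdnf

Neurodynamical simulation of how reaching movements are selected, stopped,
and switched. The package is for computational motor-control researchers who
want to regenerate and probe the behavioral predictions of a dynamic neural
field (DNF) architecture coupled to stochastic optimal reach controllers —
and for experimentalists who want to run the same kinematic analysis on
recorded joystick trajectories.

## The model in brief

Six neural fields (spatial sensory input, expected outcome, reach cost, stop
signal, pause, and reach planning) evolve under Amari-type dynamics

τ u̇ = −u + h + S(t) + W ∗ g(u) + ξ,

with a logistic rate function g and local-excitation/global-inhibition
lateral interactions in the planning field. Directional fields have 181
neurons covering 0–180° at 1° spacing. Planning neurons crossing the action
initiation threshold trigger finite-horizon LQR controllers steering a
damped point-mass cursor toward the goal 20.37 cm along their preferred
direction, and the executed force is the desirability-weighted mixture

π_mix(x_t) = Σ_j d_j(x_t) π_j(x_t),

where d_j is the neuron's supra-threshold activation normalized over all
active neurons. A pause field, excited one-to-all by the stop field and
inhibiting the planning field one-to-all, implements motor inhibition.
Three architectures differ in when the pause field engages during action
switching: always (`ARCH1`), never (`ARCH2`), or only after the signal in
one-target trials (`ARCH3`); they make opposite predictions about one- vs
two-target switch reaction times.

On top of the model sit the three task protocols (decision-making,
stop-signal, switch — reward-based and internally guided) with adaptive
±50 ms delay staircases, and a trajectory-analysis layer (cubic smoothing
splines, 10%-of-peak-speed reaction times, the 100 ms / 3 SD exclusion
rules, stop-probability curves, heading-cone switch reaction times) applied
identically to simulated and recorded data.

## Worked example

Simulate a 40-trial decision-making session (instructed and choice trials
interleaved) and summarize reaction times:

```r
library(reachdnf)
spec <- model_spec("ARCH2")
ex <- experiment_spec(task = "decision", n_trials = 40, trial_type = "mixed",
                      seed = 7)
res <- run_experiment(ex, spec)
rt_summary(res, by = c("task", "trial_type"))
#> # A tibble: 2 × 5
#>   task     trial_type  mean    se     n
#>   <chr>    <chr>      <dbl> <dbl> <int>
#> 1 decision instructed  250.  3.33    20
#> 2 decision choice      385. 15.1     19
```

Instructed reaches start ~250 ms after target onset; choice reaches are
~135 ms slower because the two target representations must fight through
mutual inhibition before one crosses the initiation threshold (one choice
trial was excluded by the outlier rules, hence n = 19).

Stop-signal blocks show why stopping gets harder the later the stop cue
arrives, and easier with two targets:

```r
sw <- simulate_stop_sweep("ARCH2", n_per_ssd = 20, n_unregulated = 0, seed = 7)
sw$curve_one          # one-target (instructed) stop trials
#>     ssd p_stop     n
#> 1   200   1       20
#> 2   350   1       20
#> 3   500   0.15    20
#> 4   650   0       20
#> 5   800   0       20
sw$curve_two          # two-target (choice) stop trials
#>     ssd p_stop     n
#> 1   200    1      20
#> 2   350    1      20
#> 3   500    1      20
#> 4   650    0.3    20
#> 5   800    0      20
```

The stop probability is non-increasing in the stop-signal delay (SSD), and
at every SSD the two-target curve is at least as high as the one-target
curve: choice trials carry weaker planning activity (competition), so the
pause mechanism suppresses them faster.

Command-line wrappers expose the same pipeline:

```sh
Rscript inst/cli/simulate.R --task stop --arch 2 --trial-type instructed \
    --n-trials 60 --seed 3 --out sim_out
Rscript inst/cli/analyze.R --in sim_out     # rt_summary.csv, stop_curve.csv, ...
Rscript inst/cli/fixtures.R --n 10 --out fixtures_out
```

## Layout

- `R/` — field engine (`lattice.R`, `field.R`), controllers (`control.R`),
  model wiring and architectures (`architecture.R`), task protocols and
  staircases (`tasks.R`), kinematic analysis and fixtures (`behavior.R`),
  experiment helpers (`experiments.R`), CSV/JSONL export (`io.R`).
- `vignettes/action-regulation-model.Rmd` — the model, its assumptions,
  parameter defaults and design choices.
- `tests/testthat/` — unit, property and end-to-end behavioral tests.
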