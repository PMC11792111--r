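# defvar

Partitioning the effect of plant defense variability on herbivore
performance into its mechanisms, by counterfactual simulation.

## The problem

Variation in a plant's chemical defense — between leaves of one plant or
between neighboring plants — can either suppress or boost the herbivores
feeding on it, and for opposite reasons at once:

- **Nonlinear averaging (Jensen's effect, `Jr`).** When performance
  `f(x)` is a nonlinear function of toxin dose `x`, the average response
  to a varying dose, `E[f(X)]`, differs from the response to the average
  dose, `f(E[X])`, in the direction of the local curvature `f''`.
- **Selective feeding (`S`).** A choosy herbivore concentrates on
  less-defended tissue, lowering the mean dose it actually ingests.
- **Their interaction (`JS`).** Selectivity relocates the dietary dose
  distribution to a differently curved region of `f`.
- **A residual (`ε`).** Whatever the three explicit mechanisms cannot
  explain — notably limits on physiological tracking of fluctuating toxin
  levels.

With `f` a dose-response curve, `Xo` the observed (preference-weighted)
dietary dose distribution and `Xr` the counterfactual no-selectivity diet:

    Jr = E[f(Xr)] − f(E[Xr])
    S  = f(E[Xo]) − f(E[Xr])
    JS = {E[f(Xo)] − f(E[Xo])} − Jr
    T̂  = Jr + S + JS = E[f(Xo)] − f(E[Xr])
    ε  = To − T̂

where `To` is the observed total effect of the variability treatment
(variable minus constant arm, standardized by the SD of the
link-transformed response). The package estimates every ingredient from
the three tables such an experiment produces — a dose-response ladder,
leaf-level herbivory, and cage-level responses — and propagates
uncertainty by crossing dose-response curve draws with preference
bootstrap draws (500 × 500 = 250,000 simulations by default), summarized
with equal-tailed 89% intervals. It is aimed at ecologists analyzing
mean × variance manipulation experiments, and ships a full synthetic
study generator with analytic ground truth so every stage is testable
without data downloads.

## Worked example

Simulate the emulated study design (412 cages: low/high cage-mean dose of
0.66/1.89 nmol/mg crossed with constant vs. within-plant ±0.61 variation;
a 10-level dose ladder, 0.031–16.1 nmol/mg) and partition the variability
effect on caterpillar relative growth rate at the high mean:

```r
library(defvar)

cfg    <- sim_config(seed = 42)
expt   <- generate_variation_experiment(cfg)
ladder <- generate_dose_ladder_experiment(cfg)

fit <- partition_variability(ladder, expt$leaves, expt$cages,
                             response = "rgr", mean_treatment = "high",
                             seed = 1)
fit
#> Counterfactual decomposition of the defense-variability effect
#>   response: rgr |  mean treatment: high 
#>   doses 1.89 +/- 0.61 nmol/mg;  500 curve x 500 preference draws;  standardized (link-SD units)
#>  quantity     mean     lower    upper
#>        jr  0.01582 -0.028830 0.058400
#>         s  0.05135 -0.022130 0.119400
#>        js -0.00230 -0.006703 0.002214
#>     t_hat  0.06487 -0.045370 0.168000
#>     t_obs -0.09754 -0.324900 0.123900
#>       eps -0.16240 -0.413300 0.081160
```

Reading the output: all quantities are in SD units of the link-scale
response. For this seed, nonlinear averaging (`jr`, +0.016 SD) and
selective feeding (`s`, +0.051 SD) are both estimated to mildly *benefit*
the caterpillar under within-plant variation at the high mean dose, with
a negligible interaction; the observed total effect (`t_obs`) is more
negative than the predicted total (`t_hat`), leaving a negative residual
(`eps`, −0.16 SD [−0.41, 0.08]) attributable to mechanisms outside the
partition. The generating truth for this configuration (available in
`expt$truth`) is `jr = 0.021`, `s = 0.057`, `js = −0.003` SD — inside
each interval.

The selectivity stage alone:

```r
estimate_preference(expt$leaves, "high", n_draws = 500, seed = 2)
#> Herbivore preference estimate (high mean treatment, 103 plants)
#>   mean herbivory: low-dose leaves 0.2038, high-dose leaves 0.1009
#>   relative preference for low dose: 102.0% [86.4%, 118.6%]
```

`plot(fit)` draws the dot-and-interval panel (asterisks mark intervals
excluding zero), `mechanism_shares(fit)` gives each mechanism's share of
`T̂`, and `report_decomposition(fit)` renders a plain-text report. File
workflows (`write_dataset()`, `run_decomposition()`,
`read_sim_config()`) and a thin command-line wrapper
(`inst/cli/defvar.R` with `simulate` / `decompose` / `report`
subcommands) cover scripted use; every output directory gets a JSON
manifest that reproduces it bit for bit.

## Learn more

The methods vignette (`vignettes/variability-decomposition.Rmd`) documents
the model, the estimation stages, the synthetic generator's calibration,
numerical choices, and known limitations.
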