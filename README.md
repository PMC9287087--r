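# portalcomp

Energetic compensation analysis for long-term rodent removal experiments.

## What it does, and for whom

For community ecologists working with paired control/exclosure
live-trapping designs, `portalcomp` turns monthly capture records (census,
date, plot, species, body mass) into treatment-level energy and biomass
series and asks how much of the energy freed by removing the dominant
granivore guild — kangaroo rats, *Dipodomys* spp. — the remaining community
absorbs, and how that changes across decadal time periods.

Each individual's metabolic rate is estimated from body mass *m* (grams) by
the allometric scaling

&nbsp;&nbsp;&nbsp;&nbsp;*b* = 5.69 · *m*^0.75,

per-plot guild totals are averaged within treatments per monthly census,
and three statistics are compared across time periods:

| statistic | definition | meaning |
|---|---|---|
| compensation | (SG_E − SG_C) / KR_C | fraction of freed kangaroo-rat energy taken up by small granivores on exclosures |
| total energy ratio | Etot_E / Etot_C | community function on exclosures relative to controls (1 = fully maintained) |
| proportional use | e.g. KR_C / Etot_C, CB_E / Etot_E | baseline composition and the focal colonizer's share |

Ratio metrics are modelled by generalized least squares with a
continuous-time AR(1) correlation (corr = φ^|Δt| within each multi-year
period, independent across periods; optional per-period variances),
proportions by quasi-binomial logit GLMs, and period-level estimated
marginal means, 95% intervals and Tukey-adjusted pairwise contrasts are
computed for every model. A synthetic community generator with closed-form
ground truth makes the entire pipeline verifiable offline. See the methods
vignette (`vignettes/compensation-methods.Rmd`) for the model details and
design choices.

## Worked example

Simulate the default synthetic world — 4 control + 4 exclosure plots,
monthly censuses Feb 1988–Jan 2020, true per-period compensation
(0.18, 0.58, 0.28), kangaroo-rat control shares (0.92, 0.70, 0.70), a
colonizer arriving mid-1996 and declining after period 2 — then run the full
analysis:

```r
library(portalcomp)
scen <- scenario_config(seed = 2020)
cfg  <- run_config(scenario = scen)     # add out_dir = "results" for files
rep  <- run_pipeline(cfg)
rep$summaries$energy$compensation
```

```
Estimated marginal means for 'period_label' (95% intervals, link = identity)
 level estimate     se       df  lower  upper
    P1   0.1849 0.0029 38.63221 0.1790 0.1908
    P2   0.5859 0.0075 51.86741 0.5710 0.6009
    P3   0.2924 0.0052 40.91955 0.2819 0.3029
Pairwise contrasts (link scale, tukey adjustment):
 contrast estimate     se       df       t  p_value
  P1 - P2  -0.4011 0.0080 66.86153 -50.034 0.00e+00
  P1 - P3  -0.1075 0.0060 64.00701 -18.011 9.48e-12
  P2 - P3   0.2935 0.0091 88.16677  32.250 3.64e-10
```

The period means recover the stated truths (0.18, 0.58, 0.28); the
contrasts say compensation rose sharply with the colonizer's establishment
(P1 → P2) and fell back after its decline (P2 → P3). The other fitted
models behave the same way — e.g. the total energy ratio estimates were
0.248 / 0.711 / 0.506 against ground truth 1 − q(1 − c) =
0.2456 / 0.706 / 0.496, and the estimated correlation parameter was
φ̂ = 0.483 against a simulated 0.5. `ground_truth(scen)` prints the exact
targets for any scenario.

With real data, supply delimited tables instead of a scenario:

```r
cfg <- run_config(captures = "captures.csv", plots = "plots.csv",
                  registry = "species.csv", out_dir = "results")
run_pipeline(cfg)
```

and `reproduce_paper("data-dir/")` prints the fitted period estimates side
by side with the published values for the archived field dataset (a local
copy of the Zenodo deposit re-exported to the package's table dialect).

A command-line front end with `simulate`, `run` and `reproduce`
subcommands is installed at `inst/scripts/portalcomp-cli.R`.

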