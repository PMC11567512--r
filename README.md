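# prioritysim

An individual-based simulator for evaluating **health benefits package
(HBP) prioritisation policies** in a health system whose delivery
capacity is capped by healthcare-worker time.

## The problem

In many health systems, the time available from clinical officers,
nurses and pharmacists cannot meet the demand for care. Which patients
are served then depends on how services are (implicitly) prioritised.
`prioritysim` models this directly: disease episodes among simulated
individuals generate daily demand for facility-level services, each with
a fixed per-cadre minute footprint; a *rigid* queue delivers services in
policy-defined priority order until each cadre's daily minutes run out
(overtime only to finish the last appointment, no task shifting, no
shortened visits); unserved patients re-seek care for up to seven
consecutive days and then default permanently. Policies — assignments of
high/low priority to treatments, fast-track rules for vulnerable
patients (under-fives, pregnant women, HIV- and TB-diagnosed), and
outright exclusions — are compared by **disability-adjusted life years**:

    DALY = YLL + YLD,   YLL = max(0, L - a) with L = 70 years,
    YLD  = disability weight x years lived with the condition,

undiscounted, accumulated per cause and calendar year, and aggregated
over Monte-Carlo replicates run with common random numbers (the policy
never enters seed derivation, so contrasts are paired).

The package ships a synthetic scenario generator reproducing the
*structure* such analyses rely on — an initially dominant infectious
cause whose incidence escalates when its treatment is excluded, a
demographically rising child respiratory cause, vaccine-preventable
mortality, perinatal emergencies, stochastic consumable stock-outs — at
desk scale. It deliberately reproduces no real country's magnitudes.

## Worked example

```r
library(prioritysim)

b <- make_default_scenario(1, initial_size = 2000)   # desk-scale world
res <- run_experiment(b, policies = c("NP", "CV", "LCOA"),
                      replicates = 4, horizon_years = 5)
res$report$totals
```

Output (seed 1, 2000 persons, 5 years, 4 replicates):

```
  policy    mean      lo      hi n pct_change
1     CV 1735216 1591006 1879426 4  -5.994808
2   LCOA 2703633 2561288 2845978 4  46.469122
3     NP 1845872 1681365 2010380 4   0.000000
```

`NP` (no prioritisation) is the benchmark. The `mean` column is total
DALYs over the horizon scaled to the national population, with
normal-approximation 95% confidence bounds over replicates. `CV`
(fast-tracking all clinically vulnerable patients) lowers the 5-year
DALY total by ~6% here, while `LCOA` — which excludes HIV treatment
outright — incurs a ~46% early excess as untreated HIV escalates. At a
3-year horizon (`horizon_view(res$report, 3)$totals`) CV's gain is
−6.4% and LCOA's excess +45.9%; over 20 years LCOA's relative position
improves markedly: the characteristic event-horizon effect of excluding
infectious-disease care.

Other entry points:

* `make_default_scenario()`, `write_scenario()`, `read_scenario()` —
  the six-cause / twelve-treatment synthetic world, serialised as a
  diffable JSON document.
* `run_scenario(bundle, policy, replicate)` — one replicate; returns the
  DALY ledger plus event, delivery and death logs (flat data frames).
* `policy_presets()` — the seven shipped policies (NP, LCOA, HSSP3, VP,
  RMNCH, CMD, CV).
* `assign_priority()`, `order_queue()`, `run_day()`, `close_day()` —
  the queue mechanism, usable standalone.
* `compute_yll()`, `compute_yld()`, `aggregate_replicates()`,
  `horizon_view()`, `rank_causes()` — DALY accounting and comparison.
* `population_divergence()` — the constant-capability vs growing-
  population diagnostic.
* `inst/cli/prioritysim` — minimal CLI (`make`, `validate`, `run`,
  `presets`).

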