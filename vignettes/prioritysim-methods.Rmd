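---
title: "prioritysim: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{prioritysim: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prioritysim)
```

## The question the package addresses

When a health system cannot deliver everything that is demanded of it,
*which* services get delivered is decided — implicitly or explicitly — by
some prioritisation rule. A health benefits package (HBP) can be read as
such a rule: a statement of the relative priority of each treatment,
possibly refined by patient characteristics, possibly excluding some
treatments outright. `prioritysim` is an individual-based, daily-timestep
simulator for comparing such prioritisation policies by the
disability-adjusted life years (DALYs) incurred under each, when service
delivery is constrained by healthcare-worker (HCW) time.

The package is a self-contained synthetic test bed: it does not attempt to
reproduce any country's calibrated disease burden. Its scenario generator
produces worlds with the *structural* features that make prioritisation
interesting — competition between services for the same cadre minutes, a
dominant infectious cause whose incidence escalates when its treatment is
withheld, a demographically rising child cause, preventable mortality
concentrated in vulnerable groups — at a scale that runs on a desktop.

## The model

### Demand side (epidemiology)

Each simulated person has an age, sex, vital status, a set of active
conditions, and flags (`pregnant`, `hiv_diagnosed`, `tb_diagnosed`,
`unvaccinated`, `contracepting`; `under5` and `fertile` are derived from
age and sex on access). Each day:

1. **Demography.** Births occur at the crude birth rate among alive,
   non-contracepting individuals (daily probability `1 - exp(-r/365)`);
   newborns start unvaccinated. Background deaths occur at age-band
   hazards and are attributed to the residual "other" cause.
2. **Incidence.** Person `i` acquires cause `c` with daily probability
   `1 - exp(-h/365)` where
   `h = base(year) * under5_mult * (1 + beta * P_untreated) * immunity`,
   `base(year)` is piecewise-linear in calendar year, `beta` is the
   transmission coefficient (0 for non-infectious causes),
   `P_untreated` is the prevalence of untreated active cases computed
   once at the start of the day (synchronous update, so within-day order
   cannot matter), and `immunity` is a reinfection multiplier applied
   after a prior recovery. Perinatal causes apply only to fertile
   individuals and toggle the `pregnant` flag for the episode's duration.
3. **Care seeking.** A new episode requests the treatment mapped to its
   cause (emergency-severity episodes always seek care the same day;
   routine ones with the cause's care-seeking probability), creating a
   care episode with a first-seek date and a tiebreak number drawn once.
   Preventive services (vaccination, contraception) generate demand at a
   per-person rate among eligible individuals.
4. **Queue delivery** (below).
5. **Progression.** Ongoing episodes die at the treated or untreated
   per-year hazard (times risk-modifier products, e.g. unvaccinated
   measles cases or under-five respiratory cases) converted to a daily
   probability, or recover deterministically once their (treated or
   untreated) duration has elapsed.

### Supply side (the rigid health system)

Each treatment is an HSI type with a fixed per-cadre minute footprint at
one facility level (the catalogue includes the canonical example: a
standard adult outpatient appointment at level 1a taking 27 clinical
officer, 18 nurse and 9.5 pharmacist minutes). Daily capability minutes
per (facility, cadre) are capped and constant over the horizon. Delivery
is *rigid*:

* HSIs always take their full stated footprint; durations are never
  shortened under load.
* No task shifting between cadres.
* An HSI is deliverable only if **every** required cadre has strictly
  positive remaining minutes; the full footprint is then committed, and
  balances may go negative — this single local rule realises "no overtime
  except to complete the last HSI of the day", and guarantees per
  cadre-day overtime never exceeds one delivered footprint.
* The queue scan *continues* past infeasible entries (skip-and-continue),
  so lower-priority services still run while some capability remains.
* Consumables are drawn per attempt: if any required item is stocked out,
  the patient receives a substituted treatment (reduced effectiveness),
  requests a repeat visit (re-queues), or defaults from care, with
  configurable branch probabilities (default 0.5/0.3/0.2 — the branch
  structure is modelled, its probabilities are not empirically anchored).

### Prioritisation

Care episodes are ordered each day within each facility by a strict total
order: engine tier, then first-seek date (longest-waiting first), then
the fixed tiebreak, then person id. Four engine tiers exist: 0
(emergency, under five), 1 (emergency), 2 (high), 3 (low). Tiers 0-1 are
engine-reserved: policies only decide high/low for non-emergency
treatments, fast-track rules (vulnerable categories promoted to high for
given treatments), and exclusions (never delivered, zero minutes).
Unserved patients re-seek daily at the same facility up to `max_attempts`
(default 7) consecutive days, then default permanently.

Seven policy presets ship with the package: `NP` (equal priority,
benchmark), `LCOA` (selective high tier, HIV treatment excluded),
`HSSP3`, `VP`, `RMNCH`, `CMD`, and `CV` (all treatments fast-tracked for
all four vulnerable categories: under-fives, pregnant women, HIV- and
TB-diagnosed patients).

### Outcomes

DALYs = YLL + YLD, undiscounted. YLL for a death at age `a` is
`max(0, L - a)` with reference life expectancy `L = 70` years (a single
fixed reference, not an age-conditional life table). YLD is disability
weight times time lived with the condition, attributed pro rata to
365-day calendar years; ongoing disability is censored at the horizon
end, and deaths after the horizon are not imputed. Deaths are attributed
wholly to the episode's cause; background deaths to the residual cause.
Totals are scaled by `national_population / initial_size`. Replicates are
aggregated as `mean ± 1.96 sd/sqrt(n)` (a normal-approximation interval —
the interval construction is a documented choice), and percent changes
are computed on means against the benchmark arm.

## Randomness and common random numbers

All randomness derives from one master seed. Stage-level draws use
streams `stream_seed(master, replicate, "<stage>:<day>")`; the policy id
never enters seed derivation, so replicate `r` experiences identical
epidemiology under every policy until their delivery histories diverge —
policy contrasts are paired (common random numbers). Event-level draws
whose *order* would otherwise depend on the queue (consumable
availability, treatment effectiveness) are counter-based uniforms keyed
on (care episode, attempt) via a murmur3-style integer hash, making
delivery outcomes independent of scan order. This is what makes the
unconstrained-capacity limit exact: with capability above total demand
and no exclusions, all policies produce byte-identical event logs.

## The default synthetic world

Six causes, twelve treatments, three facility levels, three cadres, 4,000
individuals standing in for a national population of 580,000 (scale
factor 145), 20-year horizon, 10 replicates. The calibration targets
*structure*, not magnitudes:

* `hiv`: chronic infectious cause, 20% initial prevalence among adults,
  declining incidence trend, transmission feedback coupling incidence to
  untreated prevalence. Prevalent cases seek care staggered over the
  first year. Untreated mortality is front-loaded (0.2/yr over a 4-year
  untreated phase) so that excluding its treatment causes an early surge
  of deaths, while effective treatment (hazard 0.006/yr) almost removes
  them — this reproduces the qualitative signature of excluding the
  treatment of a dominant infectious disease: escalating incidence and
  losses concentrated in the first years.
* `lri`: acute child respiratory infections, rising trend plus population
  growth, under-five incidence multiplier 5 and an under-five mortality
  risk modifier of 4. This is the cause that overtakes `hiv` as the
  leading DALY contributor within the horizon, and the reason
  patient-centred fast-tracking (CV) averts deaths: the vulnerable flag
  genuinely marks higher lethality.
* `neonatal`: perinatal episodes among fertile women, one quarter
  emergencies.
* `measles`: epidemic-prone (transmission coefficient 3, near-complete
  immunity after recovery), with vaccination as a preventive service
  clearing the `unvaccinated` flag that triples case fatality.
* `cmd`: slow chronic cardiometabolic disease, low initial burden, rising.
* `other`: residual burden, not subject to resource constraints — it
  contributes DALYs identically under every policy.

Capability minutes are set so that demand exceeds supply at level 1a from
the start and increasingly over time as the population grows (capacity is
constant), and so that level 1b is stressed during the first-year HIV
backlog. When `make_default_scenario(initial_size = n)` rescales the
population, capability minutes rescale proportionally, preserving the
demand-to-capacity ratio. One caveat bounds how far down this scales:
because the overtime rule always completes the first HSI of the day
whenever a cadre has any positive balance, every facility-cadre can
deliver at least roughly one HSI per day regardless of its minute
budget. Once a scaled-down population's daily demand falls near that
floor (below roughly 2,000 persons for the default world), the system
stops being capacity-bound and policies stop mattering; structural
tests therefore run at 1,500-2,000 persons, not smaller.

What the generator does **not** emulate: age-conditional life tables,
seasonality, disease-specific natural history (HIV staging, TB latency),
referral between facilities, provider switching, bed/equipment
constraints, and any calibrated magnitudes. A green structural test
therefore establishes that the *mechanism* behaves as described, not that
any real-world burden estimate is reproduced.

## Numerical and design choices

* **Daily step, hazards via `1 - exp(-h/365)`.** The queue operates
  daily, so the epidemiology does too.
* **Binomial-count sampling.** Person-level Bernoulli sweeps are drawn as
  stratified binomial counts plus uniform subsampling — equivalent in
  distribution, much faster at small daily probabilities.
* **Episode coalescing.** A person holds at most one open care episode
  per cause (and per preventive service); a new episode of a cause whose
  care request is still queued does not create a second request.
* **Delivered-but-ineffective HSIs are terminal** for the care episode:
  the interaction happened, the patient does not re-seek for that
  episode. Only capacity postponement and the repeat-visit consumable
  branch re-queue.
* **Diagnosis at care contact.** The `hiv_diagnosed` fast-track flag is
  set when an HIV care episode is created, so patient-centred policies
  can only fast-track patients the system has seen.
* **Excluded episodes** are logged with zero minutes and do not re-seek
  alternative services (the engine stays agnostic about substitution
  behaviour the source analysis does not describe).
* **Ties.** Tiebreak collisions resolve by person id, making the queue
  key a strict total order; cause ranking ties resolve by cause id.
* **Contraception** sets a permanent `contracepting` flag; births are
  drawn from all alive non-contracepting individuals at the crude rate
  (a crude-birth-rate model, not a fertility model) — coverage of the
  fertile population therefore lowers the birth stream, which is the
  demographic-divergence channel exposed by `population_divergence()`.
* **Degenerate inputs.** Zero-capability days postpone everything; zero
  rates are exact fixed points; single-replicate experiments flag their
  confidence intervals as degenerate rather than erroring.

## Event horizons

Because the default world's burden composition shifts over time (the
HIV-to-LRI crossover), policy rankings depend on the evaluation horizon.
`horizon_view(report, h)` recomputes every comparison on cumulative DALYs
over the first `h` years only; the package's acceptance suite checks the
characteristic pattern that an excluding policy looks worst at a 3-year
horizon and recovers by 20 years.

## Known limitations

* R-level daily loop: a full 20-year default run takes on the order of a
  minute; experiments at the default 10 replicates x 7 policies are
  batch jobs, not interactive calls.
* The normal-approximation CI is anti-conservative at very small
  replicate counts.
* A care episode's seek decision is made once at onset; chronic untreated
  cases do not spontaneously re-enter care later (except the initial
  prevalent stock, which seeks over the first year).
* Vulnerable categories are flags, not risk strata with their own natural
  history; `tb_diagnosed` exists only as an initial-prevalence flag in
  the default world.
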