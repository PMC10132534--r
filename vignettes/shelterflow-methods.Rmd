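---
title: "Modeling a homelessness response system as a blocking queue network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling a homelessness response system as a blocking queue network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The system and the model

A homelessness response system has two scarce resources. *Housing* —
units or permanent subsidies — is the terminal resource: occupancy times
run to years and many occupants never leave. *Emergency shelter* is a
buffer in front of housing: people are meant to stay weeks, but because
housing is scarce they stay until a housing unit frees. People who can get
neither resource wait unsheltered. shelterflow models this as a tandem
queueing network with **blocking**: the shelter stage cannot release a
person while the downstream housing stage is full, so shelter throughput is
governed by housing vacancies, not by shelter capacity.

Two configurations ship with the package:

* an **aggregate model** — one population, one housing pool, horizon
  2022–2027, housing occupancy `Tri(0, 6, 8)` years (about 52% of occupants
  leave within five years, `triangular_cdf(5, 0, 6, 8) = 25/48`);
* a **detailed model** — eight pathways with distinct arrival shares,
  shelter use and occupancy laws, horizon 2023–2028. Youth transitional,
  long- and short-term rapid resolution go straight from the queue to their
  housing resource; rapid rehousing, dedicated affordable and the two
  permanent-supportive pathways wait in shelter (blocked) for their housing;
  self-resolvers use shelter for a fixed five months and then leave the
  system.

Arrivals follow a non-homogeneous Poisson process whose rate is constant
within a calendar year: a base 10 persons/day with year-over-year factors
(+20% in 2022, +10% in 2023, flat 2024, −10% in 2025 and again in 2026).
Factors compound because each published change is phrased relative to the
prior year; a base-relative variant is available
(`arrival_spec(compounding = FALSE)`). Years beyond the last factor hold the
last rate. Of people exiting housing, 17% return to the system after a
`Uniform(0, 2)`-year delay, re-entering as fresh arrivals with a redrawn
pathway (switchable to keep-pathway).

Capacity is time-varying. An *investment policy* is one capacity schedule
per resource, anchored at calendar dates (beginning-of-year anchors for the
aggregate plan, end-of-year anchors for the detailed plans). Between
anchors, capacity is interpolated linearly in continuous time and realized
as unit-by-unit additions at the instants the interpolant crosses each
integer; a step mode is available per schedule. Capacity *decreases* never
evict: excess units are marked retiring and disappear as occupants leave.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| base arrival rate | 10 | persons/day | published HMIS estimate (~3,500/yr) |
| year factors | 1.2, 1.1, 1.0, 0.9, 0.9 (2022–2026) | — | published planning assumptions |
| return probability | 0.17 | — | published two-year return share |
| return delay | Uniform(0, 730) | days | "within two years", no shape given |
| housing laws | Table-driven (`Tri(2,6,8)` yr, `Unif(1,2)` yr, 91 d fixed) | days | published pathway table |
| SR shelter stay | 152 | days | published "5 months"; 1 month ≈ 30.4 d |
| shelter priority | PSH = PSH-Seniors (1) < DA (2) < RRH (3) < SR (4) | rank | only the PSH classes are named top priority; the rest ordered by housing-need severity; configurable |
| sample interval | 7 | days | fine enough for the trajectory shapes at negligible cost |
| replications | 100 | — | matches the published experiments |

Time conventions: 1 year = 365.25 days; "5 months" = 152 days; "3 months" =
91 days; all durations are converted to days at load time; calendar dates
are real dates (2024 and 2028 are leap years).

## Initial state and the Q0 calibration

The published study does not print its initial conditions, so the shipped
default (`default_initial_state()`) is an explicit rule. Detailed model:
start-of-2023 per-pathway housing capacities are the plan's end-of-2023
anchors rescaled to total 6,000 units (factor 6,000/7,362), shelter
capacity 2,500 — the aggregate plan's beginning-of-2023 totals — with every
unit occupied; shelter occupants are split over the shelter-using pathways
by renormalized arrival shares; and the initial unsheltered queue is a
single total `Q0` split by arrival share (largest-remainder apportionment
so totals are exact).

`Q0` is the one number not derivable from printed tables. It is fixed by
`calibrate_q0()`: monotone bisection (under common random numbers, so the
response is smooth) of the mean end-of-2023 total unmet need over 100
replications against the published 7,125. The shipped value is
`default_q0()` = 3,456 (achieved mean 7,120, SE 6.9). The aggregate model
reuses the same `Q0` with its 2022 capacities (1,500 shelter / 4,000
housing) fully occupied.

Initially occupied units draw **stationary residual** service times by
default: the residual law of an occupant observed at a random instant in
equilibrium, sampled as `U · X̃` with `X̃` length-biased. The alternative
`fresh_draw` (full service times starting at t = 0) is implemented and
switchable, but it implies *zero* turnover of every `Tri(2, 6, 8)`-year
resource for the first two simulated years — a system whose entire housing
stock turned over at t = 0, which is not how an operating system behaves
and visibly suppresses early-year throughput. We consider the equilibrium
residual the defensible default for a simulation that starts mid-operation
and document the choice here because the two rules produce materially
different 2023–2025 trajectories.

## Queue disciplines

Three admission rules are implemented (`options$admission_rule`):

* `fifo_overall` (default): when a housing unit frees, the earliest-arrived
  waiter of that pathway is admitted whether currently sheltered or
  unsheltered. This avoids artificial starvation when shelter is full.
* `shelter_first`: sheltered waiters are preferred over unsheltered ones.
* `shelter_transit`: housing never bypasses shelter — shelter-using
  pathways are housed only out of shelter, so the shelter stage is a strict
  serial bottleneck.

The choice matters most when capacity is scarce. Under `fifo_overall` a
starved shelter cannot throttle housing absorption, so uniformly scaled-down
policies still drain their backlog; under `shelter_transit` scarce shelter
propagates into idle housing units and scaled-down policies can be
qualitatively unstable. The published policy contrasts show features of the
transit discipline (a deeply unstable 80% policy) *and* of the bypass
discipline (differential scalings that favour the blocked pathways do not
overtake the baseline); no single rule reproduces both, and we ship the
bypass rule as the default. Shelter admission itself is priority-based
(smaller rank first, FIFO within rank, no preemption) in every rule.

Simultaneous events are ordered `capacity_change < housing_stay_end <
shelter_stay_end < arrival < sample_tick`, then by insertion sequence, so
capacity present at an instant is usable by departures and arrivals at that
instant. Admissions run to a fixed point at every event time: a housing
admission can free a shelter unit whose refill can unblock another housing
unit within the same instant.

## Randomness and reproducibility

All streams derive deterministically from `(master_seed, replication)`
via hashed splitmix64 streams: one for arrival times (exact
piecewise-exponential gaps across rate changes), one for pathway
assignment, and a per-person stream keyed by a stable person identity (for
returners, by the parent's key). Identical inputs give byte-identical
traces, and — because person identities are shared across policies that
differ only in capacity — compared policies run under tight common random
numbers: person *k* has the same arrival instant, pathway and service
demands everywhere. This makes capacity comparisons nearly monotone
replication-by-replication, which the test suite checks.

## Validation strategy

The full system (blocking, priorities, time-varying integer capacity) has
no tractable closed form, so validation is layered:

* **Exact invariants** on every trace: person conservation (cumulative
  arrivals = queued + sheltered + housed + exits at every sample),
  occupancy never exceeding active units (hard-checked inside the engine at
  every event), and a blocking audit on exported event logs.
* **Hand-traced micro-scenario** (`micro_worked_example()`): one blocking
  pathway, unit capacities, deterministic arrivals at t = 0, 1, 2; the
  complete event log is known on paper and asserted exactly.
* **Analytic oracles in engineered regimes**: the engine configured as a
  stationary M/M/c (exponential service, constant capacity, no shelter, no
  returns) reproduces Erlang-C mean queue lengths within Monte-Carlo error;
  Erlang-C itself is cross-checked against a brute-force truncated
  birth-death solve; the triangular sampler is checked against its
  closed-form CDF inside Dvoretzky–Kiefer–Wolfowitz bands; yearly arrival
  counts match the Poisson mean and dispersion; Little's law holds on
  stationary windows.

Passing these shows the *engine* is right, not that the *calibration*
matches any real county: the synthetic scenarios emulate printed planning
tables and stylized service laws, not person-level administrative data,
seasonality, capacity noise, or behavioural responses (no balking,
reneging, or voluntary shelter exits — in an overloaded system a vacated
spot refills immediately anyway).

## Numerical choices

* Unit counts are integers everywhere; `scale_policy()` rounds half-up
  (2,776.5 → 2,777), with `floor` as an option.
* Largest-remainder apportionment for splitting integer totals by shares.
* Year-end summary snapshots are taken at Dec 31 sample points (forced into
  the sampling grid regardless of the sampling interval).
* Exact event-time integrals of queue length and unmet need (person-days)
  are accumulated in the engine, so long-run averages do not depend on the
  sampling grid.
* Quartiles in `replication_stats()` use `stats::quantile()` type 7.

## Known limitations

* Returns are triggered by housing exits only; self-resolver exits are
  permanent. The published two-year return share arguably covers all
  system leavers, so steady-state load is slightly understated.
* The initial state is a documented reconstruction, not printed data; the
  end-of-2023 calibration pins one degree of freedom (`Q0`) and the
  trajectory mid-transition (2025–2026) is sensitive to the rest.
* Households are single adults; family households (~10% of the population)
  are out of scope, as in the source study.
* Dollar figures require a user-supplied per-unit cost table
  (`policy_cost()`); no cost defaults are shipped because per-unit costs
  are not printed.

## Problem sizes used in the shipped checks

The test suite runs the detailed policies at 100 replications each
(~25 ms/replication), the oracle suite at 12–24 replications of ten-year
M/M/c runs, and 10^5-draw distribution checks; the full suite completes in
well under a minute on one core.
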