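---
title: "Model and methods: smoke-alarm promotion cost-effectiveness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: smoke-alarm promotion cost-effectiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alarmcea)
```

## The decision problem

Seven strategies for increasing the possession of functioning smoke
alarms in households with a child under five are compared on lifetime
discounted costs and QALYs: usual care (UC) and six active programmes
built from education (E), free/low-cost equipment (FE), equipment fitting
(F) and home safety inspection (HI). The effect of the alarm on health
runs entirely through the pre-school years: a functioning alarm lowers
the probability that a house fire injures the child, and shifts the
severity distribution of injuries that do occur. Severe injury (an
ICU-level burn or inhalation injury) leaves a lifelong disability with a
utility decrement and ongoing care costs; minor and moderate injuries
have one-off acute costs and no lasting decrement; a fatal injury ends
the child's accrual.

## Model structure and assumptions

**Stage 1 — intervention tree.** With alarm prevalence $p$, acceptance
probability $a$ and per-strategy enablement probability $\pi_k$, the four
household branches (owner; non-owner accepting and enabled; non-owner
accepting, not enabled; non-owner declining) have probabilities
$p,\; (1-p)a\pi_k,\; (1-p)a(1-\pi_k),\; (1-p)(1-a)$, summing to one. The
first two branches enter stage 2 in the functioning-alarm state, so

$$P(\text{functioning at age } 0) = p + (1-p)\,a\,\pi_k .$$

One acceptance probability is shared across strategies. Delivery costs
are charged to the non-owning accepters — including accepters that do not
end up enabled, since delivery still happened — giving an expected cost
$(1-p)\,a \sum_{c \in k} \text{cost}_c$. Charging every offered household
instead is available as `psa_settings(cost_basis = "offered")`. Usual
care has $\pi_{UC} = 0$ and no delivery cost; the tree can only add
alarms, never remove them, so the starting coverage is never below $p$.

**Stage 2 — pre-school Markov model (ages 0–4).** Five states: alarm
(functioning / non-functioning) × child history (never-severe /
post-severe), plus absorbing death. Within each yearly cycle events apply
in a fixed order:

1. house fire with probability $p_{fire}$ (at most one per cycle);
2. if a fire, child injury with probability $p_{inj|F}$ or $p_{inj|NF}$
   by alarm state;
3. if an injury, severity from the alarm-state-specific split over
   {minor, moderate, severe, fatal}; fatal moves to death, a first severe
   injury sets the post-severe flag;
4. background mortality from the life table at the child's age;
5. alarm decay (functioning→non-functioning, probability $d$) or repair
   (the reverse, also $d$), affecting the *next* cycle's alarm state.

The decay/repair factor is a single value applied in both directions
(0.1/year in the base case); the zero-decay scenario zeroes both. Injury
hazards are history-independent — a previous fire changes nothing — and a
repeat severe injury in a post-severe child adds acute costs only.

**Stage 3 — lifetime model (ages 5–99).** Healthy / post-severe / dead.
Both alive states face the same life-table mortality (the package exposes
an optional hazard ratio on post-severe mortality, default 1, because the
base case attributes only utility and cost consequences to disability).
Healthy accrues the age-band utility norm $u(t)$; post-severe accrues
$u(t) - \Delta u_{sev}$ and the annual care cost. The model stops after
age 99; remaining survivors contribute nothing further.

**Rewards and discounting.** State rewards are evaluated at cycle start
with no half-cycle correction (the convention is stated so results are
bit-reproducible; with yearly cycles and rare events the correction is
second-order here). The discount factor is $(1+r)^{-t}$ with $t$ the age
(years since birth) in both stages, $r = 3.5\%$ for costs and effects.
Acute event costs are booked, and the severe decrement and annual care
cost begin, in the event cycle itself; a child fatally injured in cycle
$t$ still received that cycle's start-of-cycle utility.

**Households and perspectives.** The unit of analysis is the household
with $h$ children under five (base case $h = 1$; the SA4 scenario uses
1.8, assuming all children suffer the same consequences of a fire).
Child-level quantities — QALYs, injury and fatality costs, ongoing care
costs, event counts — scale by $h$; household-level quantities — delivery
cost, fire & rescue attendance, property damage — do not. Costs carry
category tags; `cost_total` sums the categories active under the chosen
perspective: NHS/PSS, public sector (adds other public-sector costs such
as fire & rescue; the default), or extended household (adds property
damage and fatality-related household costs). The programme's own
delivery cost is part of every perspective — a perspective restricts
which *downstream* costs count, not whether the evaluated programme is
paid for — and productivity losses are never included. Health outcomes
are perspective-invariant.

## Uncertainty

Every input is declared in a parameter table as a distribution
(`fixed`, `beta`, `gamma`, `lognormal`, `normal` or `dirichlet` for the
severity splits, which then sum to one by construction). The PSA draws
`n_draws` joint realisations (5,000 in the base case) and pairs draw $i$
with row $i$ of the effectiveness posterior — mirroring how a
simulation-based effectiveness synthesis is consumed — rather than
resampling. Effectiveness uncertainty is emulated by a multivariate
normal on the log-odds-ratio scale (the standard output scale of a
network meta-analysis), with mean effects ordered by intervention
complexity, an exchangeable correlation of 0.6, and an inverse-logit map
against a baseline enablement log-odds, which keeps every $\pi_k$ in
$[0,1]$; the usual-care column is identically zero. Decision analytics
follow the standard definitions: per-strategy means over draws, the
dominance / extended-dominance frontier with strictly increasing ICERs,
$\text{NMB} = \lambda\,\text{QALY} - \text{cost}$, CEACs as the per-draw
NMB-argmax frequencies, and
$\text{EVPI} = E[\max_s \text{NMB}] - \max_s E[\text{NMB}]$, scaled to a
population value over a 10-year horizon of 31,000 decision-relevant
households per year, discounted at the model's rate (an undiscounted
variant is a flag).

Numerical conventions: NMB ties within a draw (measure-zero for
continuous draws, but reachable with degenerate tables) go to the
lower-cost strategy, then the lower id — conservative toward cheaper
care and deterministic. In the frontier, effectiveness ties are broken by
ascending cost, exact duplicates collapse to the earlier id, and a zero
QALY increment makes the ICER undefined (`NA`), handled by the dominance
logic rather than division. All sampling is driven by one integer seed;
identical seed and configuration give byte-identical PSA output.

## The synthetic fixture

The supplementary input tables behind the original analysis are not
publicly available, so the package ships a synthetic fixture
(`parameter_fixture()`, `life_table_fixture()`,
`utility_norms_fixture()`, `posterior_defaults()`). Quantities printed in
the base case are fixed exactly: prevalence 0.80, acceptance 0.90,
decay/repair 0.1, injury probability without a functioning alarm 0.91,
discount rate 0.035, one child per household, reporting cohort 100,000.
Everything else is a documented, epidemiologically plausible choice made
once: annual fire risk with mean 0.002 (rare — of the order of national
domestic-fire counts over households); injury risk with a functioning
alarm centred on 0.45 (roughly half the non-functioning risk); severity
splits concentrated on minor/moderate outcomes, and worse without an
alarm (fatal share 3% vs 1%); delivery costs of £10–£40 per component;
acute costs from £100 (minor) to £30,000 (severe, ICU-level); £2,000/year
ongoing care and a 0.15 lifelong utility decrement after severe injury;
per-fire fire & rescue (£2,000) and property damage (£8,000) costs; a
UK-norm-like utility step function (0.94 falling to 0.73 by age 75+); and
a Gompertz-type synthetic life table. Utility norms are a fixed step
function rather than a sampled parameter — population norms are
comparatively precise — with utility uncertainty carried by the severe
decrement.

Consequences: the *absolute* base-case outputs (ICERs in £/QALY, CEAC
levels, EVPI) are properties of the fixture, not reproductions of any
published estimate, and the package deliberately does not calibrate the
fixture toward published totals. What the test suite does establish is
structural: probability bookkeeping and occupancy conservation,
closed-form discounting identities, monotonicities (more effectiveness
never harms health when the alarm protects; costlier component sets cost
more), the equal-risk invariance (when injury risk and severity are
alarm-independent, health outcomes are independent of alarm coverage),
frontier equivalence with an independent convex-envelope construction,
and agreement of all three composed stages with a 200,000-household
individual-level microsimulation within Monte-Carlo error. Real data
would add features the generator does not emulate — between-parameter
correlations beyond the declared distributions, age-dependent fire risk,
household moves, multiple fires per year — so passing tests validate the
machinery, not UK-specific point estimates.

Expected QALYs are reported per household (`mean_outcomes()` adds the
cohort scale alongside), since decision analytics are invariant to that
affine rescaling; with the fixture's norms a child's discounted lifetime
expectation is ≈ 25 QALYs, so the 100,000-cohort scale is ≈ 2.5 million.

## Problem sizes used in the checks

The shipped checks run the full pipeline at 5,000 draws (the base-case
simulation count), property suites at tens of random replicates each, the
frontier/envelope comparison at 1,000 random instances of up to 8
strategies, and the microsimulation validation at 200,000 households for
three seeds and two strategies — sizes chosen so Monte-Carlo error is
well below the tolerances being asserted.

## Worked run

```{r example}
res <- run_scenario("base", n_draws = 500, seed = 1)
frontier_report(res$frontier, res$psa)
evpi(res$psa, 30000)
```

```{r plots, fig.width = 6, fig.height = 4}
autoplot(res$ceac)
```

## Known limitations

No spill-over benefit to siblings or adults (conservative); no
seasonal/age-varying fire hazard; no repeat-injury risk dependence; no
equity weighting or subgroup analysis; EVPPI/EVSI are out of scope. The
fixture's absolute cost and utility levels are placeholders; analyses of
real settings should supply their own parameter table, life table and
utility norms through the documented CSV interfaces.
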