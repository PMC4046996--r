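# alarmcea

Decision-analytic cost-effectiveness modelling of interventions that
promote **functioning smoke alarms** in households with pre-school
children.

House fires are a leading cause of injury death in young children, and
functioning smoke alarms reduce the risk of fire-related injury — but
programmes that hand out, fit or inspect alarms cost money, and the most
effective programme is not automatically the best use of a fixed public
budget. `alarmcea` implements a probabilistic decision model for comparing
seven promotion strategies, from usual care (UC) upward through
combinations of education (E), free/low-cost equipment (FE), fitting (F)
and home safety inspection (HI), for a birth cohort followed over a
lifetime. It is aimed at health economists and public-health analysts who
want a transparent, fully scriptable and testable pipeline for this class
of problem.

## The model

Three stages, composed per strategy *k* and per parameter draw:

1. **Intervention decision tree.** A household may already own a
   functioning alarm (prevalence *p*); otherwise it accepts the offered
   intervention with probability *a* and, if it accepts, becomes an
   *enabled* functioning-alarm household with probability *π<sub>k</sub>*
   (drawn from a correlated effectiveness posterior across strategies).
   The probability of entering stage 2 with a functioning alarm is

   > P(functioning at start) = *p* + (1 − *p*) · *a* · *π<sub>k</sub>*

   and delivery costs are incurred by the non-owning accepters,
   (1 − *p*) · *a* · Σ component costs.

2. **Pre-school Markov model (ages 0–4, yearly cycles).** Joint state of
   the alarm (functioning / non-functioning) and the child's severe-injury
   history, plus death. Each cycle: a house fire with probability
   *p<sub>fire</sub>*; given a fire, a child injury with an
   alarm-state-specific probability; given injury, a severity in {minor,
   moderate, severe, fatal} from an alarm-state-specific split; then
   life-table background mortality; then alarm decay/repair (0.1/year each
   way in the base case). At most one fire per household per cycle. Severe
   survivors carry a lifelong utility decrement and an ongoing annual care
   cost from the event cycle onward.

3. **Lifetime Markov model (ages 5–99).** Healthy / post-severe / dead,
   with life-table mortality and age-specific utility norms.

QALYs and costs are discounted to birth at 3.5 %/year. Costs are itemised
by category (intervention delivery, NHS & personal social services, other
public sector such as fire & rescue attendance, household costs such as
property damage and fatality-related costs) so the analysis can be run
from an NHS/PSS, public-sector (default) or extended household
perspective. Uncertainty is propagated by Monte-Carlo simulation (5,000
draws in the base case, one parameter draw paired with one effectiveness
posterior row), and the PSA feeds the standard decision analytics:
dominance / extended-dominance **frontier** with ICERs, **net monetary
benefit**, **CEACs** and per-decision / population **EVPI**. Five named
one-way sensitivity scenarios (SA1–SA5: lower alarm prevalence, lower
acceptance, no decay, 1.8 children per household, equal injury risk by
alarm state) are built in.

All inputs flow through a declarative parameter table (CSV-serialisable;
beta/gamma/lognormal/normal/dirichlet/fixed families). The package ships a
**synthetic fixture**: printed base-case quantities (80 % prevalence, 90 %
acceptance, 0.1 decay/repair, 0.91 injury risk without a functioning
alarm, 3.5 % discounting, 1 child/household, cohort 100,000) are fixed at
those values, while unpublished inputs (fire risk, injury risk with an
alarm, severity splits, unit costs, utilities, the life table) are
plausible synthetic values — so absolute outputs are illustrative, while
the model mechanics, orderings and invariances are fully testable.

## Worked example

```r
library(alarmcea)

res <- run_scenario("base", n_draws = 1000, seed = 1)
frontier_report(res$frontier, res$psa)
```

```
  label           qalys  cost strategy_id status        inc_qalys inc_cost   icer p_ce_30000 p_ce_50000
1 UC               25.0  50.4           1 frontier     NA           NA        NA       0.069      0.02
2 E                25.0  51.1           2 frontier      0.000186     0.655  3520.      0.687      0.505
3 E + HI           25.0  56.2           6 dominated    NA           NA        NA       0.021      0.042
4 E + FE           25.0  55.1           3 frontier      0.0000786    4.02  51093.      0.132      0.178
5 E + FE + HI      25.0  60.2           4 extendedly_… NA           NA        NA       0.045      0.103
6 E + FE + F       25.0  61.9           5 extendedly_… NA           NA        NA       0.024      0.068
7 E + FE + F + HI  25.0  67.0           7 frontier      0.000136    11.8   86868.      0.022      0.084
```

Reading this: each row is one strategy with its expected discounted QALYs
and costs *per household* under the synthetic fixture (≈ 25.0 QALYs per
child; `mean_outcomes()` also reports the cohort scale). Strategies that
cost more without more health are `dominated`; strategies whose ICER
exceeds that of a more effective option are `extendedly_dominated`; the
remaining chain is the frontier, with ICERs (£/QALY) increasing along it
(£3,520 → £51,093 → £86,868 here). The last two columns are the CEAC
values: the probability each strategy is the cost-effective choice at a
£30,000 or £50,000 willingness-to-pay threshold.

```r
evpi(res$psa, threshold = 30000)
#> threshold  evpi
#>     30000 0.932          # GBP per household decision
population_evpi(0.932)     # 10-year horizon, 31,000 households/yr, 3.5%
#> [1] 248643
autoplot(res$ceac)         # acceptability curves
autoplot(res$frontier)     # cost-effectiveness plane with frontier
```

Scenario analyses use the same interface, e.g.
`run_scenario("SA4", n_draws = 5000, seed = 1)` for 1.8 children per
household, or `psa_settings(perspective = "NHS_PSS")` to drop non-health
public-sector costs.

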