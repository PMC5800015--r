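---
title: "The filter-cascade cost-effectiveness model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The filter-cascade cost-effectiveness model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carecascade)
```

## The model and its assumptions

`carecascade` models a care pathway as a sequence of independent
filters applied to a target group. A scenario fixes a population size
$N$, a prevalence $p$ of the target condition, and $K$ ordered filters
with pass rates $r_i$ and per-entrant unit costs $c_i$. The target
group $N p$ enters the first filter; each stage's expected passers
$E_i r_i$ become the next stage's entrants, so successes are
$S = N p \prod_i r_i$ and total cost is $C = \sum_i c_i E_i$. In the
depression-in-cancer configuration the four filters are detection,
provider response, patient acceptance and treatment; by convention the
final filter is always the treatment stage, its entrants are "patients
receiving care" and its passers are successful outcomes.

Three structural assumptions matter:

* **Independence.** Each filter acts independently on its entrants.
  In reality a change in how providers respond, or in what treatment is
  offered, may change patients' willingness to accept; the model does
  not represent such interactions, and multi-way changes should be
  expressed as distinct scenarios rather than composed from one-way
  ones.
* **Expected-value flows.** Flows are deterministic expected values
  and are kept fractional internally. A per-person micro-simulation
  with independent Bernoulli draws at each stage converges to exactly
  these values (the test suite verifies agreement within three standard
  errors at 100,000 simulated persons), so the deterministic cascade is
  the infinite-population limit of the stochastic one.
* **Direct per-entrant costs only.** Every cost is charged per stage
  entrant. Costs of false positives, of undetected depression, and
  downstream savings (avoided hospitalisations) are out of scope, so
  model costs are direct system costs of the pathway, not net
  healthcare costs. Costs that are really per provider or per centre
  have to be approximated as per-patient averages.

A consequence worth knowing: because costs are charged per entrant, the
final filter's pass rate affects successes but never total cost, and a
unit cost never affects any flow. Both facts are enforced as invariants
in the tests.

### Cost accounting choices

Two accounting conventions were genuinely open and are fixed as
follows. First, the detection filter's cost is charged over the
*target group* (the $Np$ depressed patients), not the whole screened
population: the packaged worked example is only consistent under that
convention ($5 \times 1{,}500 = \$7{,}500$ for filter 1). The
alternative — charging screening across all $N$ patients — is arguably
more realistic for population screening, and can be expressed in this
framework by scaling the detection unit cost by $1/p$. Second,
"patients receiving care", the denominator of cost per patient, means
entrants to the final filter (those who accepted treatment), which is
what makes the example's $15{,}300 / 63 = \$242.86$ reproduce.

## Parameters and their meaning

| Parameter | Units | Domain | Worked-example default |
|---|---|---|---|
| `population_size` | persons | $> 0$ | 10,000 |
| `prevalence` | proportion | $[0,1]$ | 0.15 |
| `pass_rate` (per filter) | proportion of entrants | $[0,1]$ | 0.20 / 0.70 / 0.30 / 0.30 |
| `unit_cost` (per filter) | currency per entrant | $\ge 0$ | \$5 / \$5 / \$0 / \$100 |

Currency is an opaque unit with a configurable display symbol; there is
no discounting or inflation adjustment (the model is a single-period
snapshot). The worked example's four intervention scenarios each raise
one pass rate by 15 percentage points (0.35 / 0.85 / 0.45 / 0.45) at a
raised unit cost (\$10 / \$10 / \$7.50 / \$300).

The published table this example reproduces prints a target group of
"n = 55,500", which is arithmetically inconsistent with 15% of 10,000;
every downstream figure in that table (300 detected at 20%, \$7,500 for
filter 1, and so on) confirms 1,500, which is what `table1_fixture()`
encodes. Likewise that table prints a scenario-2 total of \$18,110
while its own filter components, incremental cost (\$2,850) and cost
per success (\$791) all imply \$18,150; `carecascade` computes totals
from components and reports \$18,150.

## Rounding and display

All computation uses unrounded flows; rounding happens once, at
display, through `display_round()`. Halves round **away from zero**
(76.5 → 77, 94.5 → 95), not to even as base `round()` does — the
worked example's printed counts discriminate between the two
conventions. Counts and whole-currency cells round to integers;
cost per patient can be rendered at 2 decimals (`cents = TRUE` in
`render_report()`), mirroring the mixed precision of published cascade
tables. Because the ICER is computed on unrounded increments, the
displayed ICER can differ from the ratio of the displayed increments
(scenario 1: $13{,}350 / 14.175 = \$942$, whereas $13{,}350 / 14 =
\$954$); this is deliberate and the machine-readable exports always
carry the unrounded values alongside the display strings.

Undefined ratios stay undefined: a zero denominator yields `NA` (and
`"n/a"` in reports), never zero or infinity. In particular the ICER of
a zero-effect comparison is `NA` — a cost difference divided by no
effect difference has no decision meaning — and the cost-effectiveness
quadrant carries the signal instead. On the quadrant boundaries
(exactly one increment zero) classification follows the non-zero sign:
equally effective at higher cost is weakly dominated, equally costly
with more successes is weakly dominant.

## Sensitivity analysis

`one_way_sweep()` re-evaluates a scenario over an evenly spaced grid
for exactly one parameter, validating the whole grid against the
parameter's domain before evaluating anything. `tornado()` ranks
parameters by the span of a metric between their low and high
plausible values, ties broken alphabetically by parameter label so the
ordering is stable. No default "plausible extreme" is imposed — ranges
are part of the analyst's input; ±50% around the current value,
clipped to the domain, is a reasonable starting point when nothing
better is known.

`threshold_solve()` inverts the model by bisection: it finds the
parameter value at which the ICER versus a fixed baseline equals a
target willingness-to-pay. Tolerance is $10^{-6}$ on the parameter
with a 200-iteration cap, far more than bisection needs on any
realistic bracket; the cascade is cheap and smooth, so there is no
reason to use a faster but less robust root finder. Monotonicity of
the ICER over the bracket is *checked* (endpoints plus midpoint), not
assumed: with mixed cost structures the ICER is a ratio of two affine
functions of the parameter and can have a pole (zero incremental
successes) inside a careless bracket, where it is violently
non-monotone. Targets outside the ICER range achieved on the bracket
are rejected with the achieved range in the error message.

## The random-scenario generator

`generate_random_scenario()` draws structurally valid scenarios —
uniform pass rates, unit costs, population size and prevalence within
caller-supplied bounds, 1–6 filters by default — for property testing.
Its defaults emulate the *shape* of realistic cascade configurations
(a few stages, costs from \$0 to \$500 per entrant, prevalences up to
50%), not any particular disease area. Property tests over these
scenarios establish algebraic invariants: flow conservation, the
closed-form success count, linearity of cost in unit costs, scale
equivariance in population size, and the ICER identity
$\Delta C = \mathrm{ICER} \times \Delta S$. Passing them shows the
*arithmetic* is right for any valid configuration; it says nothing
about whether a given configuration's rates and costs are empirically
credible, which is the analyst's burden, nor about filter
interactions, which the model excludes by construction.

The test suite runs the invariants over 1,000 generated scenarios and
the micro-simulation oracle at 100,000 persons; both sizes keep the
full suite under a minute on one CPU while leaving Monte Carlo noise
(standard error ≈ 0.03% on the per-person cost mean) far below any
defect the oracle is meant to catch.

## Configuration files

Configurations are YAML (primary) or JSON with identical schemas; see
`inst/extdata/depression_cancer_table1.yaml` for the worked example and
`inst/extdata/config-schema.json` for the shape. Unknown keys are
**errors**, not warnings: in a decision tool, a typo like
`pass_rate_typo:` silently ignored would change the answer. All
validation failures are classed conditions
(`cascade_validation_error` / `cascade_config_error`) naming the
offending field, which the command-line interface maps to exit
status 2 (64 for usage errors).

## Known limitations

* One pathway at a time; no efficiency frontiers or extended dominance
  across multiple interventions, and no willingness-to-pay decision
  rule (threshold analysis solves for a parameter, it does not rank
  options).
* Deterministic only: parameter uncertainty is explored by one-way
  sweeps, not by probabilistic sensitivity analysis or CEACs.
* Costs are homogeneous across patients within a filter; real
  treatment intensity varies with need.
* The model is a decision *aid*: with arbitrary or expert-elicited
  inputs its outputs rank options under stated assumptions, they do
  not establish what the best policy is.
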