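# carecascade

Deterministic filter-cascade cost-effectiveness modelling for care
pathways, built around depression care in cancer settings.

## The problem

Depression is common among cancer patients but under-detected and
under-treated. Whether a depressed patient ends up successfully treated
depends on a chain of events: the depression must be **detected**, the
provider must **respond** (offer treatment or a referral), the patient
must **accept** the offer, and the **treatment** must work. Each step
filters out a fraction of patients, so even good treatments reach few
people when upstream steps leak. Policy makers deciding where to invest
— better screening, provider prompts, patient engagement, or more
effective treatment — need a transparent way to compare those options
on both effectiveness and cost.

`carecascade` is for health-economics analysts, treatment centres and
research groups who want that comparison as a small, auditable model
rather than a spreadsheet.

## The model

A scenario is a population of size `N` with target-condition prevalence
`p`, and an ordered sequence of filters `i = 1..K`, each with a pass
rate `r_i ∈ [0,1]` and a unit cost `c_i ≥ 0` charged per stage
*entrant*. Expected flows are propagated fractionally:

```
E_1 = N·p            (the target group enters filter 1)
E_{i+1} = E_i · r_i
total cost  C = Σ_i c_i · E_i
successes   S = N·p · Π_i r_i       (passers of the final filter)
```

Per scenario the model reports `C`, cost per patient receiving care
(`C / E_K`, the entrants to the final, treatment filter) and cost per
successful outcome (`C / S`). Against a designated baseline it reports
the incremental cost `ΔC`, incremental successes `ΔS`, the incremental
cost-effectiveness ratio `ICER = ΔC / ΔS` (computed on unrounded
increments), and a policy-advice classification on the
cost-effectiveness plane (more/less expensive × more/less effective,
with dominance labelled). One-way deterministic sensitivity analysis,
tornado ordering and threshold solving (which parameter value attains a
target ICER) complete the toolkit.

## Worked example

The packaged fixture models 10,000 cancer patients with 15% depression
prevalence (target group 1,500) under usual care and four interventions,
each raising one filter's pass rate by 15 percentage points at a higher
unit cost:

```r
library(carecascade)
render_report(table1_fixture(), cents = TRUE)
```

```
                                   baseline  scenario1  scenario2  scenario3  scenario4
                        Total cost  $15,300    $28,650    $18,150    $20,025    $27,900
   Cost per patient receiving care  $242.86    $259.86    $237.25    $211.90    $442.86
       Cost per successful outcome     $810       $866       $791       $706       $984
Incremental total cost vs baseline      n/a    $13,350     $2,850     $4,725    $12,600
 Incremental successes vs baseline      n/a         14          4          9          9
                              ICER      n/a       $942       $704       $500     $1,333
```

Reading the table: improving detection (scenario 1) buys the most extra
successes (14) but at $942 per extra success; improving patient
acceptance (scenario 3) buys 9 extra successes at only $500 each — the
most cost-effective option — while buying the *same* 9 successes
through a more effective treatment (scenario 4) costs $1,333 each. All
four scenarios are more expensive and more effective than usual care.

The same model is scriptable:

```r
fx <- table1_fixture()
res <- run_cascade(fx$scenarios[["baseline"]])
res$n_success                     # 18.9 expected successes (flows stay fractional)
compare_scenarios(fx$scenarios[["baseline"]], fx$scenarios[["scenario3"]])$icer  # 500

# what acceptance rate would push scenario 3's ICER to $500?
threshold_solve(fx$scenarios[["scenario3"]], fx$scenarios[["baseline"]],
                parameter_path("pass_rate", "acceptance"),
                target_icer = 500, bracket = c(0.31, 0.9))   # 0.45
```

A command-line entry point covers the same workflow
(`Rscript inst/cli/carecascade.R demo`, plus `run`, `sweep`,
`threshold` and `validate` subcommands over YAML/JSON configs; see
`?cascade_cli` and `inst/extdata/depression_cancer_table1.yaml`).

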