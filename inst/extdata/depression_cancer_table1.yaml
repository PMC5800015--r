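# Depression-in-cancer filter cascade: usual care baseline plus four
# intervention scenarios, each improving one filter's pass rate by 15
# percentage points at a higher unit cost. Unit costs are charged per
# stage entrant; the target group (population x prevalence = 1,500)
# enters the first filter.
currency_symbol: "$"
baseline_id: baseline
scenarios:
- scenario_id: baseline
  label: "Usual care (target group 1,500 = 15% of 10,000)"
  population_size: 10000
  prevalence: 0.15
  filters:
  - name: detection
    description: Clinician judgement
    pass_rate: 0.20
    unit_cost: 5
  - name: provider_response
    description: Clinician judgement
    pass_rate: 0.70
    unit_cost: 5
  - name: acceptance
    description: Patient judgement
    pass_rate: 0.30
    unit_cost: 0
  - name: treatment
    description: Referral to primary care
    pass_rate: 0.30
    unit_cost: 100
- scenario_id: scenario1
  label: Increase detection
  population_size: 10000
  prevalence: 0.15
  filters:
  - name: detection
    description: Computerised short screening tool
    pass_rate: 0.35
    unit_cost: 10
  - name: provider_response
    description: Clinician judgement
    pass_rate: 0.70
    unit_cost: 5
  - name: acceptance
    description: Patient judgement
    pass_rate: 0.30
    unit_cost: 0
  - name: treatment
    description: Referral to primary care
    pass_rate: 0.30
    unit_cost: 100
- scenario_id: scenario2
  label: Increase provider response
  population_size: 10000
  prevalence: 0.15
  filters:
  - name: detection
    description: Clinician judgement
    pass_rate: 0.20
    unit_cost: 5
  - name: provider_response
    description: Provision of patient distress screening scores and recommendation
      to clinician
    pass_rate: 0.85
    unit_cost: 10
  - name: acceptance
    description: Patient judgement
    pass_rate: 0.30
    unit_cost: 0
  - name: treatment
    description: Referral to primary care
    pass_rate: 0.30
    unit_cost: 100
- scenario_id: scenario3
  label: Increase patient acceptance
  population_size: 10000
  prevalence: 0.15
  filters:
  - name: detection
    description: Clinician judgement
    pass_rate: 0.20
    unit_cost: 5
  - name: provider_response
    description: Clinician judgement
    pass_rate: 0.70
    unit_cost: 5
  - name: acceptance
    description: Distress scores & recommendation provided to patient
    pass_rate: 0.45
    unit_cost: 7.50
  - name: treatment
    description: Referral to primary care
    pass_rate: 0.30
    unit_cost: 100
- scenario_id: scenario4
  label: Increase treatment effectiveness
  population_size: 10000
  prevalence: 0.15
  filters:
  - name: detection
    description: Clinician judgement
    pass_rate: 0.20
    unit_cost: 5
  - name: provider_response
    description: Clinician judgement
    pass_rate: 0.70
    unit_cost: 5
  - name: acceptance
    description: Patient judgement
    pass_rate: 0.30
    unit_cost: 0
  - name: treatment
    description: Collaborative care model
    pass_rate: 0.45
    unit_cost: 300
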