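accrual:
  start_rate: 63.0
  end_rate: 105.0
  ramp_months: 24.0
  total_n: 2632
control_hazard:
  breakpoints: [3.0]
  rates: [0.089, 0.039]
interims:
- trigger_events: 148
  futility_bound: 0.05
  efficacy_bound: 0.00025
- trigger_time: 2.5
  futility_bound: 0.25
  efficacy_bound: 0.0005
- trigger_time: 3.0
  futility_bound: 0.5
  efficacy_bound: 0.001
- trigger_time: 3.5
  futility_bound: 0.5
  efficacy_bound: 0.001
- trigger_time: 4.0
  futility_bound: 0.5
  efficacy_bound: 0.001
- trigger_time: 4.5
  futility_bound: 0.5
  efficacy_bound: 0.001
final:
  trigger_events: 592
  significance: 0.0246
allocation: [1.0, 1.0]
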