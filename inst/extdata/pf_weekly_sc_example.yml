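# Example run config: IgG-format BCMA TCE, 1 mg/kg weekly subcutaneous
# dosing in the human physiology, 70-day simulation.
task: simulate
molecule: PF-06863135
physiology: human
regimen:
  route: sc
  dose_mg_kg: 1
  n_doses: 10
  interval_days: 7
solver:
  t_end_days: 70
  dt_days: 0.25
output: pf_weekly_sc
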