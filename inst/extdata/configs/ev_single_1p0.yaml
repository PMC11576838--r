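# Enfortumab vedotin 1.0 mg/kg single dose (single-dose verification run).
schema: study_config/1
label: ev-single-1.0
compounds: {adc: enfortumab_vedotin, mmae: mmae}
population: {source: cancer, master_seed: 20230101}
regimens:
  adc: {route: iv_infusion, dose_mg_kg: 1.0, dose_cap_mg: 100, infusion_h: 0.5}
scenario: {type: exposure, end_h: 672}
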