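# Enfortumab vedotin 1.25 mg/kg (max 125 mg), single 30-min IV infusion,
# modified cancer population. Exposure run for conjugated antibody and MMAE.
schema: study_config/1
label: ev-single-1.25
compounds: {adc: enfortumab_vedotin, mmae: mmae}
population: {source: cancer, master_seed: 20230101}
regimens:
  adc: {route: iv_infusion, dose_mg_kg: 1.25, dose_cap_mg: 125, infusion_h: 0.5}
scenario: {type: exposure, end_h: 672}
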