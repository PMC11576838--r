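# Brentuximab vedotin 2.7 mg/kg single dose (baseline-model verification).
schema: study_config/1
label: bv-single-2.7
compounds: {adc: brentuximab_vedotin, mmae: mmae}
population: {source: cancer, master_seed: 20230101}
regimens:
  adc: {route: iv_infusion, dose_mg_kg: 2.7, infusion_h: 0.5}
scenario: {type: exposure, end_h: 672}
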