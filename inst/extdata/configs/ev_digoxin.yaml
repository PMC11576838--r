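# Digoxin 0.5 mg single oral dose with vs without enfortumab vedotin
# 1.25 mg/kg, healthy-volunteer population.
schema: study_config/1
label: ev-digoxin
compounds: {adc: enfortumab_vedotin, mmae: mmae, victim: digoxin}
population: {source: healthy, master_seed: 20230101}
regimens:
  adc: {route: iv_infusion, dose_mg_kg: 1.25, dose_cap_mg: 125,
        infusion_h: 0.5}
  victim: {route: oral, dose_mg: 0.5, offset_h: 72}
scenario: {type: ddi, victim_analyte: victim, end_h: 312, nca_start_h: 72}
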