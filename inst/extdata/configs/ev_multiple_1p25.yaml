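# Enfortumab vedotin 1.25 mg/kg on days 1, 8 and 15 of a 28-day cycle
# (multiple-dose verification run; day-1 and day-15 windows analysed).
schema: study_config/1
label: ev-multiple-1.25
compounds: {adc: enfortumab_vedotin, mmae: mmae}
population: {source: cancer, master_seed: 20230101}
regimens:
  adc: {route: iv_infusion, dose_mg_kg: 1.25, dose_cap_mg: 125,
        infusion_h: 0.5, dosing_days: [1, 8, 15], cycle_days: 28,
        n_cycles: 1}
scenario: {type: exposure, end_h: 672}
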