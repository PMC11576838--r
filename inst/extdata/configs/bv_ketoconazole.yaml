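# Brentuximab vedotin 1.2 mg/kg with ketoconazole 400 mg oral QD
# (calibration/verification scenario mirroring the clinical DDI study).
schema: study_config/1
label: bv-ketoconazole
compounds: {adc: brentuximab_vedotin, mmae: mmae, perpetrator: ketoconazole}
population: {source: cancer, master_seed: 20230101}
regimens:
  adc: {route: iv_infusion, dose_mg_kg: 1.2, infusion_h: 0.5, offset_h: 72}
  perpetrator: {qd: {start_h: 0, n_days: 31, dose_mg: 400}}
scenario: {type: ddi, victim_analyte: mmae, end_h: 744, nca_start_h: 72}
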